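#' Frame stack container
#'
#' A `fish_stack` holds a T-frame acquisition of one fluorescence channel as
#' an `H x W x T` array of non-negative camera intensities (ADU), together
#' with the physical pixel pitch and acquisition metadata. Frames are stored
#' along the third dimension; pixel `(i, j)` (0-based) spans
#' `[j*p, (j+1)*p) x [i*p, (i+1)*p)` nanometres with `p = pixel_size_nm`,
#' x to the right and y downward.
#'
#' @param data numeric matrix (single frame) or `H x W x T` array, all
#'   values `>= 0`.
#' @param pixel_size_nm physical camera pixel pitch in nanometres.
#' @param channel one of `"HER2"`, `"CEP17"`, `"DAPI"`.
#' @param exposure_ms exposure time per frame in milliseconds (default 30).
#' @param metadata free-form named list.
#' @return An object of class `fish_stack`.
#' @export
fish_stack <- function(data, pixel_size_nm = 100,
                       channel = c("HER2", "CEP17", "DAPI"),
                       exposure_ms = 30, metadata = list()) {
  channel <- match.arg(channel)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_fq("fq_format", "'data' must be a matrix or an H x W x T array")
  if (dim(data)[3] < 1L) stop_fq("fq_format", "stack needs at least 1 frame")
  if (anyNA(data) || min(data) < 0)
    stop_fq("fq_format", "stack intensities must be non-negative")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop_fq("fq_param", "'pixel_size_nm' must be > 0")
  storage.mode(data) <- "double"
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 channel = channel, exposure_ms = exposure_ms,
                 metadata = metadata),
            class = "fish_stack")
}

#' @export
print.fish_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fish_stack> %s: %d frame(s) of %d x %d px (%g nm/px, %g ms)\n",
              x$channel, d[3], d[1], d[2], x$pixel_size_nm, x$exposure_ms))
  invisible(x)
}

#' @rdname fish_stack
#' @param x a `fish_stack`.
#' @export
n_frames <- function(x) dim(x$data)[3]

#' Extract one frame as a matrix
#' @param stack a `fish_stack`.
#' @param t frame index (1-based).
#' @export
get_frame <- function(stack, t) stack$data[, , t]

sidecar_path <- function(path) paste0(path, ".json")

#' Read / write frame stacks as multi-page TIFF
#'
#' Stacks are written as 16-bit unsigned multi-page TIFF; pixel size,
#' channel and exposure round-trip through a JSON sidecar (`<path>.json`).
#' Writing is lossless for integer data in `[0, 65535]`; negative values
#' are a format error.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm,channel,exposure_ms metadata used when no sidecar
#'   is found next to the file.
#' @return `read_stack` returns a [fish_stack()]; `write_stack` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path, pixel_size_nm = 100, channel = "HER2",
                       exposure_ms = 30) {
  if (!file.exists(path)) stop_fq("fq_io", "no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop_fq("fq_format", "not a readable TIFF: ", path,
                              " (", conditionMessage(e), ")"))
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop_fq("fq_format", "TIFF has no pages: ", path)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  data <- array(unlist(pages, use.names = FALSE), dim = c(h, w, length(pages)))
  meta <- list()
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  fish_stack(data,
             pixel_size_nm = meta$pixel_size_nm %||% pixel_size_nm,
             channel = meta$channel %||% channel,
             exposure_ms = meta$exposure_ms %||% exposure_ms,
             metadata = meta$metadata %||% list())
}

#' @rdname read_stack
#' @param stack a [fish_stack()] with integer-valued data in `[0, 65535]`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fish_stack"))
  d <- stack$data
  if (min(d) < 0)
    stop_fq("fq_format", "negative intensities cannot be written as uint16")
  if (max(d) > 65535)
    stop_fq("fq_format", "intensities exceed the 16-bit range")
  if (max(abs(d - round(d))) > 0) {
    warning("non-integer intensities rounded on write")
    d <- round(d)
  }
  pages <- lapply(seq_len(dim(d)[3]), function(t) d[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_nm = stack$pixel_size_nm,
                            channel = stack$channel,
                            exposure_ms = stack$exposure_ms,
                            metadata = stack$metadata),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Split a stack into single frames / merge frames into a stack
#'
#' The two operations are exact inverses: `merge_frames(split_frames(s))`
#' reproduces `s`.
#'
#' @param stack a [fish_stack()].
#' @return `split_frames` returns a list of `H x W` matrices in frame
#'   order; `merge_frames` returns a [fish_stack()].
#' @export
split_frames <- function(stack) {
  stopifnot(inherits(stack, "fish_stack"))
  lapply(seq_len(n_frames(stack)), function(t) stack$data[, , t])
}

#' @rdname split_frames
#' @param frames list of equally sized matrices.
#' @inheritParams fish_stack
#' @export
merge_frames <- function(frames, pixel_size_nm = 100,
                         channel = c("HER2", "CEP17", "DAPI"),
                         exposure_ms = 30, metadata = list()) {
  if (length(frames) == 0L) stop_fq("fq_format", "no frames to merge")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_fq("fq_dim", "frames differ in shape")
  data <- array(unlist(frames, use.names = FALSE),
                dim = c(dims[1, 1], dims[2, 1], length(frames)))
  fish_stack(data, pixel_size_nm, match.arg(channel), exposure_ms, metadata)
}

LOC_COLUMNS <- c("frame", "x_nm", "y_nm", "sigma_nm", "photons",
                 "background", "uncertainty_nm")

#' Localization tables
#'
#' Sub-pixel emitter localizations are kept in a plain `data.frame` with
#' columns `frame` (0-based acquisition frame), `x_nm`, `y_nm` (nanometre
#' coordinates), `sigma_nm` (fitted PSF width), `photons`, `background`
#' (per-pixel offset, ADU) and `uncertainty_nm` (Thompson-style localization
#' precision). Serialization is CSV with exactly this header, the de-facto
#' SMLM table convention.
#'
#' @param table localization `data.frame`.
#' @param path CSV path.
#' @export
write_localizations <- function(table, path) {
  table <- as_localizations(table)
  write.csv(format(table, digits = 15, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) stop_fq("fq_io", "no such file: ", path)
  df <- read.csv(path)
  if (!identical(names(df), LOC_COLUMNS))
    stop_fq("fq_schema", "localization CSV must have columns: ",
            paste(LOC_COLUMNS, collapse = ","))
  as_localizations(df)
}

#' @rdname write_localizations
#' @export
as_localizations <- function(table) {
  if (is.null(table) || nrow(table) == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(LOC_COLUMNS)),
                                  LOC_COLUMNS))
    out$frame <- integer(0)
    return(out)
  }
  missing <- setdiff(LOC_COLUMNS, names(table))
  if (length(missing))
    stop_fq("fq_schema", "localization table lacks columns: ",
            paste(missing, collapse = ", "))
  out <- table[LOC_COLUMNS]
  out$frame <- as.integer(out$frame)
  for (cc in LOC_COLUMNS[-1]) out[[cc]] <- as.numeric(out[[cc]])
  rownames(out) <- NULL
  out
}
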