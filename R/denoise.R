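#' Blind-spot (self-supervised) frame denoising
#'
#' Implements the blind-spot principle behind self-supervised denoisers:
#' each pixel is predicted from its square neighborhood *excluding the
#' pixel itself*, so pixel-wise independent noise cannot be reproduced and
#' is averaged away, while structure shared with the neighbors survives.
#' Two desk-scale predictors are provided: a masked-neighborhood median
#' (training-free) and a linear regression on the neighborhood values
#' fitted by least squares on randomly masked pixels. A deep network
#' backend could be slotted behind the same interface.
#'
#' @param frames training data: a [fish_stack()], an `H x W x T` array, a
#'   matrix or a list of matrices.
#' @param kind `"linear"` (least-squares neighborhood regression) or
#'   `"median"` (no training).
#' @param radius neighborhood radius in px (`>= 1`); the neighborhood is
#'   the `(2*radius+1)^2` square minus its center.
#' @param mask_fraction fraction of pixels per frame used as masked
#'   training targets, in (0, 0.5].
#' @param seed optional RNG seed for the pixel masking.
#' @return An object of class `blindspot_model` with the predictor kind,
#'   radius, learned coefficients (linear kind) and training metadata
#'   (`n_frames`, `mask_fraction`, `seed`, `loss` = mean squared training
#'   error).
#' @export
train_blindspot <- function(frames, kind = c("linear", "median"), radius = 2,
                            mask_fraction = 0.02, seed = NULL) {
  kind <- match.arg(kind)
  if (radius < 1) stop_fq("fq_param", "'radius' must be >= 1")
  if (mask_fraction <= 0 || mask_fraction > 0.5)
    stop_fq("fq_param", "'mask_fraction' must be in (0, 0.5]")
  arr <- as_stack_array(frames)
  h <- dim(arr)[1]; w <- dim(arr)[2]; t <- dim(arr)[3]
  if (min(h, w) < 2 * radius + 1)
    stop_fq("fq_size", "frames smaller than the 2*radius+1 neighborhood")
  offsets <- neighborhood_offsets(radius)
  model <- structure(list(kind = kind, radius = radius, offsets = offsets,
                          weights = NULL, bias = NULL,
                          meta = list(n_frames = t,
                                      mask_fraction = mask_fraction,
                                      seed = seed, loss = NA_real_)),
                     class = "blindspot_model")
  if (kind == "median") return(model)
  if (!is.null(seed)) set.seed(seed)
  n_samp <- max(1L, ceiling(mask_fraction * h * w))
  X <- vector("list", t); Y <- vector("list", t)
  for (tt in seq_len(t)) {
    padded <- pad_mirror(arr[, , tt], radius)
    idx <- sample.int(h * w, n_samp)
    ri <- (idx - 1L) %% h + 1L
    ci <- (idx - 1L) %/% h + 1L
    neigh <- vapply(seq_len(nrow(offsets)), function(o)
      padded[cbind(ri + radius + offsets[o, 1], ci + radius + offsets[o, 2])],
      numeric(n_samp))
    X[[tt]] <- matrix(neigh, nrow = n_samp)
    Y[[tt]] <- arr[, , tt][idx]
  }
  X <- do.call(rbind, X); y <- unlist(Y)
  fit <- stats::lm.fit(cbind(1, X), y)
  model$bias <- unname(fit$coefficients[1])
  wts <- unname(fit$coefficients[-1])
  wts[is.na(wts)] <- 0        # collinear neighbors (e.g. constant input)
  model$weights <- wts
  model$meta$loss <- mean(fit$residuals^2)
  model
}

#' @export
print.blindspot_model <- function(x, ...) {
  cat(sprintf("<blindspot_model> kind=%s radius=%d", x$kind, x$radius))
  if (!is.na(x$meta$loss))
    cat(sprintf(" (trained on %d frame(s), MSE %.4g)", x$meta$n_frames,
                x$meta$loss))
  cat("\n")
  invisible(x)
}

#' Apply a blind-spot model to a stack
#'
#' Replaces every pixel of every frame by the model's blind-spot
#' prediction; frame count and shape are preserved, borders use mirror
#' padding, and the output is clipped at zero.
#'
#' @param model a [train_blindspot()] model.
#' @param stack a [fish_stack()] (or array/matrix).
#' @return Same type as the input (`fish_stack` in, `fish_stack` out).
#' @export
denoise_stack <- function(model, stack) {
  stopifnot(inherits(model, "blindspot_model"))
  arr <- as_stack_array(stack)
  r <- model$radius
  if (min(dim(arr)[1:2]) < 2 * r + 1)
    stop_fq("fq_size", "frames smaller than the model neighborhood")
  out <- if (model$kind == "median") {
    cpp_blindspot_median(arr, as.integer(r))
  } else {
    h <- dim(arr)[1]; w <- dim(arr)[2]
    mi <- function(q, nn) ifelse(q < 1, 2 - q, ifelse(q > nn, 2 * nn - q, q))
    padded <- arr[mi(seq(1 - r, h + r), h), mi(seq(1 - r, w + r), w), ,
                  drop = FALSE]
    acc <- array(model$bias, dim = dim(arr))
    for (o in seq_len(nrow(model$offsets))) {
      dy <- model$offsets[o, 1]; dx <- model$offsets[o, 2]
      acc <- acc + model$weights[o] *
        padded[seq_len(h) + r + dy, seq_len(w) + r + dx, , drop = FALSE]
    }
    acc
  }
  out <- pmax(out, 0)
  if (inherits(stack, "fish_stack")) {
    res <- stack
    res$data <- out
    res
  } else out
}

neighborhood_offsets <- function(radius) {
  g <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  as.matrix(g[!(g$dy == 0 & g$dx == 0), ])
}

pad_mirror <- function(mat, r) {
  n <- nrow(mat); m <- ncol(mat)
  mi <- function(q, nn) ifelse(q < 1, 2 - q, ifelse(q > nn, 2 * nn - q, q))
  mat[mi(seq(1 - r, n + r), n), mi(seq(1 - r, m + r), m), drop = FALSE]
}

as_stack_array <- function(x) {
  if (inherits(x, "fish_stack")) return(x$data)
  if (is.list(x)) return(array(unlist(x, use.names = FALSE),
                               dim = c(dim(x[[1]]), length(x))))
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop_fq("fq_format", "expected a fish_stack, array, matrix or frame list")
}
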