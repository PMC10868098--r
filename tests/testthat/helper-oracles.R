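# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (direct definitions, exhaustive
# enumeration) and never call the package's own implementation paths.

# grayscale disk opening straight from the definition: min over the disk,
# then max over the disk, out-of-bounds neighbours ignored
brute_disk_opening <- function(img, radius) {
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  h <- nrow(img); w <- ncol(img)
  pass <- function(m, f, init) {
    out <- matrix(init, h, w)
    for (k in seq_len(nrow(offs))) {
      di <- offs$di[k]; dj <- offs$dj[k]
      ri <- max(1, 1 - di):min(h, h - di)
      ci <- max(1, 1 - dj):min(w, w - dj)
      out[ri, ci] <- f(out[ri, ci], m[ri + di, ci + dj])
    }
    out
  }
  pass(pass(img, pmin, Inf), pmax, -Inf)
}

# exact two-sided signed-rank p-value by literal enumeration of all 2^m
# sign patterns on the observed (midrank) absolute ranks
enum_wilcoxon_p <- function(x, y) {
  d <- (x - y)[x != y]
  m <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  ws <- signs %*% r
  p_le <- mean(ws <= W + 1e-12)
  p_ge <- mean(ws >= W - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided Mann-Whitney p by enumeration of all group labelings
enum_mann_whitney <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(r), n1)
  us <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  list(U = U, p = min(1, 2 * min(mean(us <= U + 1e-12),
                                 mean(us >= U - 1e-12))))
}

# closed-form ordinary least squares for tau ~ mean + sd via the normal
# equations
normal_equations_fit <- function(cal) {
  X <- cbind(1, cal$mean, cal$sd)
  solve(t(X) %*% X, t(X) %*% cal$tau_opt)[, 1]
}
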