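# internal numeric helpers

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# aggregate a matrix into eps x eps block sums, blocks anchored top-left;
# partial blocks at the right/bottom edges are kept
block_sum <- function(mat, eps) {
  h <- nrow(mat); w <- ncol(mat)
  ri <- (seq_len(h) - 1L) %/% eps
  ci <- (seq_len(w) - 1L) %/% eps
  t(rowsum(t(rowsum(mat, ri)), ci))
}

# summed-area table; S[i+1, j+1] = sum(mat[1:i, 1:j]) with zero-padded border
sat <- function(mat) {
  s <- apply(mat, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

# 31-ary polynomial hash mod 2^31-1, as 8 hex digits (config tagging only,
# not cryptographic)
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# logical matrix: pixel centers inside the closed disk of diameter d_mm
disk_mask <- function(res, d_mm) {
  px <- d_mm / res
  cc <- (seq_len(res) - 0.5) * px - d_mm / 2
  outer(cc, cc, function(y, x) sqrt(x^2 + y^2) <= d_mm / 2 + 1e-12)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# unweighted OLS slope and R^2 (closed form; exact fits give R^2 = 1
# without the summary.lm perfect-fit warning)
ols_slope <- function(x, y) {
  vx <- stats::var(x)
  if (vx == 0) stopf("degenerate regression: single scale")
  vy <- stats::var(y)
  slope <- stats::cov(x, y) / vx
  r2 <- if (vy == 0) 1 else stats::cov(x, y)^2 / (vx * vy)
  c(slope = slope, r2 = min(r2, 1))
}
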