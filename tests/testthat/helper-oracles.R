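# Independent brute-force oracles.  Everything here is coded from the model
# definition directly (own Gaussian sampling, own mirror indexing, own
# double loops) and never calls into the package's transform code, so the
# comparisons in the tests are genuinely two-route.

# 0-based index folded into 1..n by symmetric reflection with edge repeat
oracle_mirror <- function(i, n) {
  p <- 2L * n
  i <- i %% p
  i[i < 0] <- i[i < 0] + p
  ifelse(i < n, i, p - 1L - i) + 1L
}

oracle_gauss2d <- function(sigma, truncate = 3) {
  r <- ceiling(truncate * sigma)
  xs <- -r:r
  K <- outer(xs, xs, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  K / sum(K)
}

# plain double-loop 2-D convolution with mirror padding
oracle_conv2 <- function(img, K) {
  nr <- nrow(img); nc <- ncol(img)
  r <- (nrow(K) - 1L) / 2L
  out <- matrix(0, nr, nc)
  off <- -r:r
  for (i in seq_len(nr)) {
    ri <- oracle_mirror(i - 1L + off, nr)
    for (j in seq_len(nc)) {
      cj <- oracle_mirror(j - 1L + off, nc)
      out[i, j] <- sum(K * img[ri, cj])
    }
  }
  out
}

# per-pixel evaluation of the full transform:
# O(x) = (m*I)(x) - lambda * sum_i w_i atan(I(y_i) - (g*I)(x))
oracle_inrf <- function(img, sigma_m = 1.74, sigma_w = 25, sigma_g = 1,
                        lambda = 3, truncate = 3) {
  Km <- oracle_gauss2d(sigma_m, truncate)
  Kg <- oracle_gauss2d(sigma_g, truncate)
  Kw <- oracle_gauss2d(sigma_w, truncate)
  mI <- oracle_conv2(img, Km)
  cI <- oracle_conv2(img, Kg)
  nr <- nrow(img); nc <- ncol(img)
  r <- (nrow(Kw) - 1L) / 2L
  off <- -r:r
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    ri <- oracle_mirror(i - 1L + off, nr)
    for (j in seq_len(nc)) {
      cj <- oracle_mirror(j - 1L + off, nc)
      out[i, j] <- mI[i, j] -
        lambda * sum(Kw * atan(img[ri, cj] - cI[i, j]))
    }
  }
  out
}

# classical rank formula with average ranks for ties
oracle_srcc <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

rand_image <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}
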