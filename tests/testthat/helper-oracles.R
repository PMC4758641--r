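# Independent brute-force oracles: naive loop implementations of the
# convolution, normalization and pooling operations, used to validate the
# FFT/matrix fast paths on small inputs.

# direct double-loop 2-D convolution, zero padding, "same" output
brute_conv2 <- function(x, k) {
  n1 <- nrow(x); n2 <- ncol(x)
  r1 <- (nrow(k) - 1) / 2; r2 <- (ncol(k) - 1) / 2
  out <- matrix(0, n1, n2)
  for (i in 1:n1) for (j in 1:n2) {
    acc <- 0
    for (a in -r1:r1) for (b in -r2:r2) {
      ii <- i - a; jj <- j - b
      if (ii >= 1 && ii <= n1 && jj >= 1 && jj <= n2)
        acc <- acc + k[a + r1 + 1, b + r2 + 1] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# naive divisive normalization: per-cell Gaussian-blurred orientation sum
brute_divisive_normalize <- function(e, sigma_inh, c) {
  d <- dim(e)
  k1 <- attnet:::gaussian_kernel_1d(sigma_inh)
  k2 <- outer(k1, k1)
  pooled <- matrix(0, d[1], d[2])
  for (ch in 1:d[3]) pooled <- pooled + e[, , ch]
  inh <- brute_conv2(pooled, k2)
  out <- e
  for (ch in 1:d[3]) out[, , ch] <- e[, , ch] / (inh + c)
  out
}

# naive top-layer pooling: explicit double sum over space (separable
# Gaussian, zero padding) then circular orientation convolution
brute_pool <- function(resp, sigma_top, sigma_ori) {
  d <- dim(resp)
  k1 <- attnet:::gaussian_kernel_1d(sigma_top)
  k2 <- outer(k1, k1)
  sp <- resp
  for (ch in 1:d[3]) sp[, , ch] <- brute_conv2(resp[, , ch], k2)
  n <- d[3]
  sig_ch <- sigma_ori * n / pi
  r <- ceiling(3 * sig_ch)
  w <- exp(-(-r:r)^2 / (2 * sig_ch^2)); w <- w / sum(w)
  out <- array(0, d)
  for (ch in 1:n) for (o in -r:r) {
    src <- ((ch - 1 + o) %% n) + 1
    out[, , ch] <- out[, , ch] + w[o + r + 1] * sp[, , src]
  }
  out
}

# small random oriented map for oracle comparisons
random_map <- function(h, w, n_ori = 8, seed = 1) {
  set.seed(seed)
  array(stats::runif(h * w * n_ori), c(h, w, n_ori))
}

small_params <- function(...) {
  attnet_params(canvas = c(9, 9), sigma_top = 1.5, sigma_inh = 0.8,
                c_bottom = 0.5, c_top = 0.01, ...)
}
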