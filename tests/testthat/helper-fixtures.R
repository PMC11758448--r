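# Shared fixtures and independent reference implementations used as oracles.

# Small phantom for fast tests (lesions sized for the 32^2 brain).
tiny_phantom <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(32L, 32L), radius_range = c(3, 5),
         lesion_count_range = c(1L, 2L)),
    list(...))
  do.call(phantom_config, args)
}

# Independent PSNR (different formulation path: via RMSE and log laws).
psnr_reference <- function(pred, ref, R = 256) {
  rmse <- sqrt(sum((as.vector(pred) - as.vector(ref))^2) / length(pred))
  if (rmse == 0) return(Inf)
  20 * log10(R) - 20 * log10(rmse)
}

# Independent SSIM: direct per-position weighted window statistics using an
# explicit neighbour-index matrix (replicate-clamped), no shared filtering
# code with the package implementation.
ssim_reference <- function(x, y, R = 256, window_size = 11L, sigma = 1.5,
                           K1 = 0.01, K2 = 0.03) {
  stopifnot(length(dim(x)) == 2L)
  h <- nrow(x); w <- ncol(x)
  rad <- (window_size - 1L) %/% 2L
  off <- expand.grid(di = -rad:rad, dj = -rad:rad)
  k1 <- dnorm(-rad:rad, sd = sigma); k1 <- k1 / sum(k1)
  wts <- k1[off$di + rad + 1L] * k1[off$dj + rad + 1L]
  pos <- expand.grid(i = seq_len(h), j = seq_len(w))
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (t in seq_len(nrow(off))) {
    ii <- pmin(pmax(pos$i + off$di[t], 1L), h)
    jj <- pmin(pmax(pos$j + off$dj[t], 1L), w)
    idx[, t] <- (jj - 1L) * h + ii
  }
  X <- matrix(x[idx], nrow(pos)); Y <- matrix(y[idx], nrow(pos))
  mx <- X %*% wts; my <- Y %*% wts
  sxx <- (X * X) %*% wts - mx^2
  syy <- (Y * Y) %*% wts - my^2
  sxy <- (X * Y) %*% wts - mx * my
  C1 <- (K1 * R)^2; C2 <- (K2 * R)^2
  mean(((2 * mx * my + C1) * (2 * sxy + C2)) /
         ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
}

# Permutation oracle for the paired DeLong test on binary calls: for binary
# ratings the AUC difference is a sum of fixed per-case contributions, so
# the label-swap permutation distribution is a random-sign sum. The
# permutation null is discrete with a large atom at the observed value, so
# the mid-p (half weight on ties) is the quantity comparable to a
# continuous asymptotic p-value.
delong_permutation_p <- function(calls_a, calls_b, gold, n_perm = 1e5, seed = 1) {
  gold <- as.logical(gold)
  a <- as.numeric(calls_a); b <- as.numeric(calls_b)
  m <- sum(gold); n <- sum(!gold)
  contrib <- ifelse(gold, (a - b) / (2 * m), -(a - b) / (2 * n))
  obs <- sum(contrib)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * length(contrib), replace = TRUE),
                  nrow = n_perm)
  perm <- as.numeric(signs %*% contrib)
  mean(abs(perm) > abs(obs) + 1e-12) +
    0.5 * mean(abs(abs(perm) - abs(obs)) <= 1e-12)
}

# OLS recovery of the mixing coefficient k from a rendered case.
recover_k <- function(case) {
  sel <- case$lesion_mask > 0 & case$iom > 1e-6
  stats::coef(stats::lm(I(case$sect[sel] - case$vnc[sel]) ~ 0 + case$iom[sel]))[[1]]
}
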