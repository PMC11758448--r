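# Image-quality metrics: PSNR and windowed SSIM, with per-case and
# aggregate (mean +/- sd) reporting for the sVNC and sIOM targets.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(R^2 / MSE)` in decibels. The data range `R` is fixed to the
#' normalization width (256) rather than a per-image range so values are
#' comparable across cases. Identical inputs give `Inf`.
#'
#' @param pred,ref numeric arrays of identical shape.
#' @param R data range (intensity span).
#' @return PSNR in dB.
#' @export
psnr <- function(pred, ref, R = 256) {
  if (!identical(dim(pred), dim(ref))) stop("shape mismatch in psnr")
  stopifnot(R > 0)
  mse <- mean((pred - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(R^2 / mse)
}

gaussian_kernel_1d <- function(size, sigma) {
  rad <- (size - 1L) %/% 2L
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k / sum(k)
}

# Local weighted filtering with a separable kernel, replicate edges.
separable_filter <- function(img, k1d) {
  shape <- dim(img)
  rad <- (length(k1d) - 1L) %/% 2L
  for (d in seq_along(shape)) {
    n <- shape[d]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      js <- pmin(pmax(i + (-rad:rad), 1L), n)
      for (t in seq_along(js)) K[i, js[t]] <- K[i, js[t]] + k1d[t]
    }
    perm <- c(d, seq_along(shape)[-d])
    v <- aperm(img, perm)
    dv <- dim(v)
    v <- K %*% matrix(v, nrow = n)
    dim(v) <- dv
    img <- aperm(v, order(perm))
  }
  img
}

ssim_2d <- function(x, y, R, window_size, sigma, K1, K2) {
  k <- gaussian_kernel_1d(window_size, sigma)
  C1 <- (K1 * R)^2
  C2 <- (K2 * R)^2
  mx <- separable_filter(x, k)
  my <- separable_filter(y, k)
  sxx <- separable_filter(x * x, k) - mx * mx
  syy <- separable_filter(y * y, k) - my * my
  sxy <- separable_filter(x * y, k) - mx * my
  num <- (2 * mx * my + C1) * (2 * sxy + C2)
  den <- (mx^2 + my^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Structural similarity index
#'
#' Standard windowed SSIM with a Gaussian window (default 11x11, sigma 1.5)
#' and constants C1 = (K1*R)^2, C2 = (K2*R)^2, averaged over positions.
#' Rank-3 volumes are evaluated slice-wise in the axial plane and averaged.
#'
#' @param pred,ref numeric arrays of identical shape (2D or 3D).
#' @param R data range.
#' @param window_size odd window edge length.
#' @param sigma Gaussian window width.
#' @param K1,K2 stabilisation constants.
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(pred, ref, R = 256, window_size = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  if (!identical(dim(pred), dim(ref))) stop("shape mismatch in ssim")
  if (any(dim(pred)[1:2] < window_size)) stop("window does not fit")
  if (length(dim(pred)) == 2L)
    return(ssim_2d(pred, ref, R, window_size, sigma, K1, K2))
  mean(vapply(seq_len(dim(pred)[3L]), function(z)
    ssim_2d(pred[, , z], ref[, , z], R, window_size, sigma, K1, K2), 1))
}

#' Image-quality report over paired predictions
#'
#' Computes PSNR and SSIM of each generated sVNC/sIOM against its ground
#' truth and aggregates as mean +/- sd per target.
#'
#' @param predictions list of `list(svnc =, siom =)` (from [tg_generate()]),
#'   parallel to `cases`.
#' @param cases list of `paired_case` objects.
#' @param R data range.
#' @return a `quality_report`: `per_case` data frame and `aggregate` data
#'   frame (target, metric, mean, sd).
#' @export
evaluate_pairs <- function(predictions, cases, R = 256) {
  if (length(predictions) != length(cases)) stop("unmatched prediction/case lists")
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]; pr <- predictions[[i]]
    data.frame(case_id = cs$case_id,
               psnr_svnc = psnr(pr$svnc, cs$vnc, R),
               ssim_svnc = ssim(pr$svnc, cs$vnc, R),
               psnr_siom = psnr(pr$siom, cs$iom, R),
               ssim_siom = ssim(pr$siom, cs$iom, R))
  })
  per_case <- do.call(rbind, rows)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  agg <- do.call(rbind, lapply(c("svnc", "siom"), function(tg) {
    do.call(rbind, lapply(c("psnr", "ssim"), function(m) {
      v <- per_case[[paste0(m, "_", tg)]]
      data.frame(target = tg, metric = m, mean = mean(v), sd = sd0(v))
    }))
  }))
  structure(list(per_case = per_case, aggregate = agg, R = R),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Image quality over ", nrow(x$per_case), " cases (R = ", x$R, ")\n",
      sep = "")
  a <- x$aggregate
  fmt <- function(m, s, pct) if (pct) sprintf("%.2f%% ± %.2f%%", 100 * m, 100 * s)
  else sprintf("%.2f ± %.2f", m, s)
  for (tg in c("svnc", "siom")) {
    p <- a[a$target == tg & a$metric == "psnr", ]
    s <- a[a$target == tg & a$metric == "ssim", ]
    cat(sprintf("  %s:  PSNR %s dB   SSIM %s\n", toupper(tg),
                fmt(p$mean, p$sd, FALSE), fmt(s$mean, s$sd, TRUE)))
  }
  invisible(x)
}
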