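# Diagnostic-accuracy statistics for the reader evaluation: 2x2 summaries
# with exact binomial confidence intervals, single-operating-point AUC,
# paired DeLong comparison, unweighted Cohen's kappa, and reconstruction of
# confusion tables from rounded printed metrics.

#' 2x2 confusion table
#'
#' @param tp,fp,fn,tn nonnegative integer counts (positive = ICH).
#' @return a `confusion2x2`.
#' @export
confusion2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be nonnegative integers")
  if (sum(counts) == 0) stop("empty table")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion2x2")
}

#' @export
print.confusion2x2 <- function(x, ...) {
  cat(sprintf("          gold+  gold-\n call+  %6d %6d\n call-  %6d %6d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Confusion table from binary calls
#'
#' @param calls,gold equal-length binary (logical or 0/1) vectors; TRUE/1 =
#'   positive (ICH).
#' @return a [confusion2x2()].
#' @export
confusion_from_calls <- function(calls, gold) {
  calls <- as.logical(calls); gold <- as.logical(gold)
  if (length(calls) != length(gold)) stop("length mismatch")
  confusion2x2(sum(calls & gold), sum(calls & !gold),
               sum(!calls & gold), sum(!calls & !gold))
}

round_half_up <- function(x, digits = 2L) floor(x * 10^digits + 0.5) / 10^digits

# Exact (Clopper-Pearson) binomial interval.
clopper_pearson <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int)
}

#' Single-operating-point AUC of a confusion table
#'
#' The trapezoidal area under the two-segment ROC through the single
#' operating point: (sensitivity + specificity) / 2.
#'
#' @param table a [confusion2x2()].
#' @return AUC in \[0, 1\].
#' @export
binary_auc <- function(table) {
  if (table$tp + table$fn == 0 || table$fp + table$tn == 0)
    stop("both classes must be present")
  sens <- table$tp / (table$tp + table$fn)
  spec <- table$tn / (table$fp + table$tn)
  (sens + spec) / 2
}

# DeLong variance of a single binary-rating AUC (placement values).
binary_auc_ci <- function(table, conf = 0.95) {
  m <- table$tp + table$fn
  n <- table$fp + table$tn
  # placements of positives: calls are 1 (tp of them) or 0 (fn)
  v10 <- c(rep((table$tn + 0.5 * table$fp) / n, table$tp),
           rep(0.5 * table$tn / n, table$fn))
  v01 <- c(rep((table$tp + 0.5 * table$fn) / m, table$tn),
           rep(0.5 * table$tp / m, table$fp))
  auc <- binary_auc(table)
  va <- if (m > 1) stats::var(v10) / m else 0
  vb <- if (n > 1) stats::var(v01) / n else 0
  se <- sqrt(va + vb)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

#' Diagnostic summary of a confusion table
#'
#' Sensitivity, specificity, positive/negative predictive value, accuracy
#' (exact Clopper-Pearson 95% CIs) and the single-operating-point AUC (CI
#' from the DeLong variance of the binary-rating placements). A metric with
#' a zero denominator is reported as `NA` (undefined), not 0.
#'
#' @param table a [confusion2x2()].
#' @param conf confidence level.
#' @return a `diag_summary` data frame (metric, estimate, lo, hi).
#' @export
summarize_confusion <- function(table, conf = 0.95) {
  prop <- function(x, n) {
    if (n == 0) return(data.frame(estimate = NA_real_, lo = NA_real_, hi = NA_real_))
    ci <- clopper_pearson(x, n, conf)
    data.frame(estimate = x / n, lo = ci[1L], hi = ci[2L])
  }
  n <- table$tp + table$fp + table$fn + table$tn
  rows <- rbind(
    cbind(metric = "accuracy", prop(table$tp + table$tn, n)),
    cbind(metric = "sensitivity", prop(table$tp, table$tp + table$fn)),
    cbind(metric = "specificity", prop(table$tn, table$fp + table$tn)),
    cbind(metric = "ppv", prop(table$tp, table$tp + table$fp)),
    cbind(metric = "npv", prop(table$tn, table$tn + table$fn)))
  auc_row <- if (table$tp + table$fn > 0 && table$fp + table$tn > 0) {
    ci <- binary_auc_ci(table, conf)
    data.frame(metric = "auc", estimate = binary_auc(table), lo = ci[1L], hi = ci[2L])
  } else data.frame(metric = "auc", estimate = NA_real_, lo = NA_real_, hi = NA_real_)
  out <- rbind(rows, auc_row)
  rownames(out) <- NULL
  class(out) <- c("diag_summary", "data.frame")
  out
}

#' @export
print.diag_summary <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %s\n", x$metric[i],
                if (is.na(x$estimate[i])) "undefined"
                else sprintf("%.2f (%.2f-%.2f)", x$estimate[i], x$lo[i], x$hi[i])))
  invisible(x)
}

#' Paired DeLong test for two reading conditions
#'
#' Compares the AUCs of two paired rating sets (same cases, same gold) with
#' the DeLong covariance of placement values; valid for binary ratings,
#' where the AUC equals (sensitivity + specificity)/2. Degenerate variance
#' (e.g. identical ratings) returns p = 1 by convention.
#'
#' @param calls_a,calls_b binary calls of the two conditions, paired by case.
#' @param gold binary truth.
#' @return `list(auc_a, auc_b, diff, se, z, p_value)`.
#' @export
delong_paired <- function(calls_a, calls_b, gold) {
  gold <- as.logical(gold)
  a <- as.numeric(calls_a); b <- as.numeric(calls_b)
  if (length(a) != length(gold) || length(b) != length(gold))
    stop("length mismatch")
  if (!any(gold) || all(gold)) stop("both classes must be present in gold")
  placements <- function(x) {
    xs <- x[gold]; ys <- x[!gold]
    v10 <- vapply(xs, function(v) (sum(ys < v) + 0.5 * sum(ys == v)) / length(ys), 1)
    v01 <- vapply(ys, function(v) (sum(xs > v) + 0.5 * sum(xs == v)) / length(xs), 1)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(a); pb <- placements(b)
  m <- sum(gold); n <- sum(!gold)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (!is.finite(var_diff) || var_diff <= 0) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = 0, z = 0,
                p_value = 1))
  }
  se <- sqrt(var_diff)
  z <- d / se
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Unweighted Cohen's kappa for two raters
#'
#' Chance-corrected agreement from the 2x2 agreement table, with the
#' large-sample (Fleiss-Cohen-Everitt) standard error and a Wald 95% CI
#' truncated to \[-1, 1\]. If both raters are constant and equal (expected
#' agreement 1) kappa is undefined and reported as `NA`.
#'
#' @param calls1,calls2 equal-length binary vectors.
#' @param conf confidence level.
#' @return a `kappa_result`: `kappa`, `p_o`, `p_e`, `se`, `lo`, `hi`.
#' @export
cohen_kappa <- function(calls1, calls2, conf = 0.95) {
  x <- as.integer(as.logical(calls1)); y <- as.integer(as.logical(calls2))
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  p <- matrix(0, 2, 2)
  for (i in 0:1) for (j in 0:1) p[i + 1, j + 1] <- sum(x == i & y == j) / n
  prow <- rowSums(p); pcol <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(prow * pcol)
  if (pe >= 1) {
    return(structure(list(kappa = NA_real_, p_o = po, p_e = pe, se = NA_real_,
                          lo = NA_real_, hi = NA_real_), class = "kappa_result"))
  }
  k <- (po - pe) / (1 - pe)
  A <- sum(diag(p) * (1 - (prow + pcol) * (1 - k))^2)
  B <- (1 - k)^2 * (p[1, 2] * (pcol[1] + prow[2])^2 + p[2, 1] * (pcol[2] + prow[1])^2)
  C <- (k - pe * (1 - k))^2
  v <- (A + B - C) / (n * (1 - pe)^2)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(kappa = k, p_o = po, p_e = pe, se = se,
                 lo = max(-1, k - z * se), hi = min(1, k + z * se)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (is.na(x$kappa)) cat("kappa undefined (expected agreement = 1)\n")
  else cat(sprintf("kappa %.2f (%.2f-%.2f), p_o %.2f, p_e %.2f\n",
                   x$kappa, x$lo, x$hi, x$p_o, x$p_e))
  invisible(x)
}

#' Reconstruct confusion tables from rounded printed metrics
#'
#' Exhaustively enumerates all 2x2 tables with `tp+fp+fn+tn = n` whose
#' sensitivity, specificity, PPV and NPV round (half-up, `decimals` places)
#' to the supplied printed values; metrics given as `NA` are unconstrained.
#' The empty set is a valid result for inconsistent constraints.
#'
#' @param n total case count.
#' @param sensitivity,specificity,ppv,npv printed (rounded) values or `NA`.
#' @param accuracy optional printed accuracy, also matched when given.
#' @param decimals printed decimal places.
#' @return list of [confusion2x2()] solutions.
#' @export
reconstruct_table <- function(n, sensitivity = NA, specificity = NA,
                              ppv = NA, npv = NA, accuracy = NA,
                              decimals = 2L) {
  stopifnot(n > 0)
  g <- expand.grid(tp = 0:n, fp = 0:n, fn = 0:n)
  g <- g[g$tp + g$fp + g$fn <= n, ]
  g$tn <- n - g$tp - g$fp - g$fn
  match_metric <- function(num, den, printed) {
    if (is.na(printed)) return(rep(TRUE, length(num)))
    ok <- den > 0
    ok[ok] <- round_half_up(num[ok] / den[ok], decimals) == round_half_up(printed, decimals)
    ok
  }
  keep <- match_metric(g$tp, g$tp + g$fn, sensitivity) &
    match_metric(g$tn, g$fp + g$tn, specificity) &
    match_metric(g$tp, g$tp + g$fp, ppv) &
    match_metric(g$tn, g$tn + g$fn, npv) &
    match_metric(g$tp + g$tn, rep(n, nrow(g)), accuracy)
  g <- g[keep, , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i)
    confusion2x2(g$tp[i], g$fp[i], g$fn[i], g$tn[i]))
}

#' Reader-evaluation report over reading conditions
#'
#' For each condition, builds the confusion table of the (consensus) calls
#' against gold and its diagnostic summary; when two readers are supplied
#' per condition, adds their inter-reader kappa; consecutive condition pairs
#' are compared with the paired DeLong test.
#'
#' @param ratings data frame with columns `case_id`, `gold`, `condition`,
#'   `reader`, `call` (binary gold/call; one row per case x condition x
#'   reader), or a named list of per-condition binary call vectors.
#' @param gold binary truth vector (required for the list form; for the
#'   data-frame form it is taken from the `gold` column).
#' @return a `reader_report`: per-condition `tables` and `summaries`,
#'   `kappa` per condition (or NULL), and `delong` comparisons.
#' @export
evaluate_readings <- function(ratings, gold = NULL) {
  if (is.data.frame(ratings)) {
    conds <- unique(ratings$condition)
    per_cond <- lapply(conds, function(cd) {
      sub <- ratings[ratings$condition == cd, ]
      readers <- unique(sub$reader)
      case_ids <- sort(unique(sub$case_id))
      calls_by_reader <- lapply(readers, function(r) {
        s <- sub[sub$reader == r, ]
        as.logical(s$call[match(case_ids, s$case_id)])
      })
      gold_v <- as.logical(sub$gold[match(case_ids, sub$case_id)])
      consensus <- if (length(readers) == 1L) calls_by_reader[[1L]] else {
        m <- Reduce(`+`, lapply(calls_by_reader, as.integer))
        m >= length(readers) / 2  # ties read as positive (safety bias)
      }
      list(condition = cd, calls = consensus, gold = gold_v,
           kappa = if (length(readers) >= 2L)
             cohen_kappa(calls_by_reader[[1L]], calls_by_reader[[2L]]) else NULL)
    })
  } else {
    if (is.null(gold)) stop("gold required for list input")
    per_cond <- lapply(names(ratings), function(cd)
      list(condition = cd, calls = as.logical(ratings[[cd]]),
           gold = as.logical(gold), kappa = NULL))
  }
  tables <- lapply(per_cond, function(pc) confusion_from_calls(pc$calls, pc$gold))
  names(tables) <- vapply(per_cond, `[[`, "", "condition")
  summaries <- lapply(tables, summarize_confusion)
  kappas <- lapply(per_cond, `[[`, "kappa")
  names(kappas) <- names(tables)
  delong <- list()
  if (length(per_cond) >= 2L) {
    for (i in seq_len(length(per_cond) - 1L)) {
      a <- per_cond[[i]]; b <- per_cond[[i + 1L]]
      if (identical(a$gold, b$gold) && any(a$gold) && !all(a$gold))
        delong[[paste(a$condition, "vs", b$condition)]] <-
          delong_paired(a$calls, b$calls, a$gold)
    }
  }
  structure(list(tables = tables, summaries = summaries, kappa = kappas,
                 delong = delong), class = "reader_report")
}

#' @export
print.reader_report <- function(x, ...) {
  for (nm in names(x$tables)) {
    cat("Condition:", nm, "\n")
    print(x$summaries[[nm]])
    if (!is.null(x$kappa[[nm]])) { cat("  inter-reader "); print(x$kappa[[nm]]) }
  }
  for (nm in names(x$delong)) {
    d <- x$delong[[nm]]
    cat(sprintf("DeLong %s: AUC %.3f vs %.3f, p = %.3f\n", nm, d$auc_a, d$auc_b,
                d$p_value))
  }
  invisible(x)
}
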