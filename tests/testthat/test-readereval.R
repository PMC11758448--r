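# Diagnostic statistics: exact intervals, single-operating-point AUC,
# DeLong pairing, kappa and table reconstruction.

test_that("confusion summaries match integer arithmetic and exact CIs", {
  tb <- confusion2x2(16, 7, 0, 24)
  sm <- summarize_confusion(tb)
  g <- function(m, f) sm[[f]][sm$metric == m]
  expect_equal(g("sensitivity", "estimate"), 1)
  # Clopper-Pearson lower bound for 16/16: 0.025^(1/16)
  expect_equal(g("sensitivity", "lo"), 0.025^(1 / 16), tolerance = 1e-9)
  expect_equal(round(g("sensitivity", "lo"), 2), 0.79)
  expect_equal(g("accuracy", "estimate"), 40 / 47)
  expect_equal(g("ppv", "estimate"), 16 / 23)

  tb2 <- confusion2x2(18, 4, 1, 3)
  sm2 <- summarize_confusion(tb2)
  expect_equal(sm2$estimate[sm2$metric == "accuracy"], 21 / 26)
  expect_equal(round(21 / 26, 2), 0.81)

  perfect <- summarize_confusion(confusion2x2(5, 0, 0, 5))
  expect_true(all(perfect$estimate[perfect$metric %in%
    c("accuracy", "sensitivity", "specificity")] == 1))
  undef <- summarize_confusion(confusion2x2(0, 0, 3, 7))
  expect_true(is.na(undef$estimate[undef$metric == "ppv"]))
})

test_that("single-operating-point AUC follows (sens + spec) / 2", {
  expect_equal(binary_auc(confusion2x2(10, 0, 0, 10)), 1)
  # sens 1.00, spec 24/31 = 0.77: the printed-operating-point AUC 0.885
  # displays as 0.88 under exact-decimal half-even rounding
  expect_equal(binary_auc(confusion2x2(16, 7, 0, 24)), (1 + 24 / 31) / 2)
  expect_equal(auc_from_printed(1.00, 0.77), 0.88)
  expect_equal(auc_from_printed(0.95, 0.43), 0.69)
  # chance line: spec = 1 - sens
  expect_equal(binary_auc(confusion2x2(8, 8, 2, 2)), 0.5)
  # label-swap invariance: swapping classes swaps sens and spec only
  expect_equal(binary_auc(confusion2x2(24, 0, 7, 16)),
               binary_auc(confusion2x2(16, 7, 0, 24)))
  expect_error(binary_auc(confusion2x2(3, 0, 2, 0)), "classes")
})

test_that("paired DeLong test matches oracles and conventions", {
  set.seed(2)
  gold <- c(rep(TRUE, 16), rep(FALSE, 24))
  a <- ifelse(gold, runif(40) < 0.9, runif(40) < 0.35)
  b <- ifelse(gold, runif(40) < 0.7, runif(40) < 0.4)
  dl <- delong_paired(a, b, gold)
  expect_equal(dl$auc_a, binary_auc(confusion_from_calls(a, gold)))
  expect_equal(dl$auc_b, binary_auc(confusion_from_calls(b, gold)))
  expect_equal(dl$diff, dl$auc_a - dl$auc_b)

  # identical ratings: degenerate variance convention
  same <- delong_paired(a, a, gold)
  expect_equal(same$p_value, 1)
  expect_equal(same$diff, 0)

  # permutation oracle on the paired binary design
  p_perm <- delong_permutation_p(a, b, gold, n_perm = 1e5, seed = 2)
  expect_lt(abs(dl$p_value - p_perm), 0.02)

  skip_if_not_installed("pROC")
  ra <- pROC::roc(gold, as.numeric(a), quiet = TRUE, direction = "<")
  rb <- pROC::roc(gold, as.numeric(b), quiet = TRUE, direction = "<")
  pr <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(dl$p_value, as.numeric(pr$p.value), tolerance = 1e-9)
})

test_that("Cohen's kappa matches closed forms and behaves at the edges", {
  x <- c(rep(TRUE, 10), rep(FALSE, 10))
  k1 <- cohen_kappa(x, x)
  expect_equal(k1$kappa, 1)

  # agreement table [[20,5],[5,20]]: p_o = 0.8, p_e = 0.5, kappa = 0.6
  r1 <- c(rep(TRUE, 25), rep(FALSE, 25))
  r2 <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 20))
  k2 <- cohen_kappa(r1, r2)
  expect_equal(k2$p_o, 0.8)
  expect_equal(k2$p_e, 0.5)
  expect_equal(k2$kappa, 0.6)
  expect_true(k2$lo >= -1 && k2$hi <= 1 && k2$lo < 0.6 && k2$hi > 0.6)

  # independent raters: kappa near zero
  set.seed(13)
  a <- runif(1e4) < 0.4; b <- runif(1e4) < 0.6
  expect_lt(abs(cohen_kappa(a, b)$kappa), 0.05)

  const <- rep(TRUE, 8)
  expect_true(is.na(cohen_kappa(const, const)$kappa))
})

test_that("table reconstruction inverts rounded summaries", {
  # internal validation, generated-image reading: unique solution
  sols <- reconstruct_table(47, 1.00, 0.77, 0.70, 1.00)
  expect_length(sols, 1L)
  expect_identical(unlist(sols[[1]][c("tp", "fp", "fn", "tn")]),
                   c(tp = 16L, fp = 7L, fn = 0L, tn = 24L))

  # external validation, generated-image reading: unique solution
  sols2 <- reconstruct_table(26, 0.95, 0.43, 0.82, 0.75)
  expect_length(sols2, 1L)
  expect_identical(unlist(sols2[[1]][c("tp", "fp", "fn", "tn")]),
                   c(tp = 18L, fp = 4L, fn = 1L, tn = 3L))

  # inconsistent constraints give the empty set
  expect_length(reconstruct_table(10, 1.00, NA, NA, 0.00), 0L)

  # inverse consistency: every solution re-rounds to the printed metrics
  sols3 <- reconstruct_table(20, 0.80, 0.60, NA, NA)
  expect_gt(length(sols3), 1L)
  for (tb in sols3) {
    expect_equal(sectmdi:::round_half_up(tb$tp / (tb$tp + tb$fn), 2), 0.80)
    expect_equal(sectmdi:::round_half_up(tb$tn / (tb$fp + tb$tn), 2), 0.60)
  }
})

test_that("reader reports recompute from stored tables and rate simulated readers", {
  set.seed(17)
  n <- 60
  gold <- runif(n) < 0.4
  good <- ifelse(gold, runif(n) < 0.95, runif(n) < 0.1)
  poor <- ifelse(gold, runif(n) < 0.7, runif(n) < 0.35)
  rep <- evaluate_readings(list(output = good, input = poor), gold)
  expect_identical(names(rep$tables), c("output", "input"))
  sm <- rep$summaries$output
  tb <- rep$tables$output
  expect_equal(sm$estimate[sm$metric == "accuracy"],
               (tb$tp + tb$tn) / n)
  expect_true("output vs input" %in% names(rep$delong))

  # data-frame form with two readers per condition gives a kappa
  df <- rbind(
    data.frame(case_id = 1:n, gold = gold, condition = "output",
               reader = "R1", call = good),
    data.frame(case_id = 1:n, gold = gold, condition = "output",
               reader = "R2", call = ifelse(runif(n) < 0.9, good, !good)))
  rep2 <- evaluate_readings(df)
  expect_false(is.null(rep2$kappa$output))
  expect_gt(rep2$kappa$output$kappa, 0.3)
})

test_that("sensitivity/specificity estimates cover truth at the exact-CI rate", {
  set.seed(19)
  sens_t <- 0.85; spec_t <- 0.7
  hits <- replicate(400, {
    gold <- runif(500) < 0.35
    calls <- ifelse(gold, runif(500) < sens_t, runif(500) >= spec_t)
    sm <- summarize_confusion(confusion_from_calls(calls, gold))
    s <- sm[sm$metric == "sensitivity", ]
    p <- sm[sm$metric == "specificity", ]
    c(s$lo <= sens_t && sens_t <= s$hi, p$lo <= spec_t && spec_t <= p$hi)
  })
  # exact intervals: per-metric coverage at least nominal (MC slack to 93%)
  expect_gte(mean(hits[1, ]), 0.93)
  expect_gte(mean(hits[2, ]), 0.93)
})
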