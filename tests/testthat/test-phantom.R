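# Phantom simulator: forward-model conservation, label semantics,
# determinism, placement invariants and the stratified split contract.

test_that("lesion sampling respects config, invariants and determinism", {
  pc <- tiny_phantom(lesion_count_range = c(1L, 1L), class_prevalence = 0.999)
  ls <- sample_lesions(pc, seed = 5)
  expect_length(ls, 1L)
  expect_true(ls[[1]]$kind %in% c("ICH", "MIXED"))
  expect_identical(sample_lesions(pc, seed = 5), ls)

  pc2 <- tiny_phantom()
  for (s in 1:20) {
    for (l in sample_lesions(pc2, seed = s)) {
      expect_true(sectmdi:::ellipsoid_inside_brain(l$center, l$radii,
                                                   pc2$grid_shape))
      if (l$kind == "ICH") expect_true(l$blood_intensity > 0 && l$iodine_intensity == 0)
      if (l$kind == "CS") expect_true(l$blood_intensity == 0 && l$iodine_intensity > 0)
      if (l$kind == "MIXED") expect_true(l$blood_intensity > 0 && l$iodine_intensity > 0)
    }
  }
})

test_that("ICH prevalence over many draws sits in the binomial 99% band", {
  pc <- tiny_phantom(class_prevalence = 0.32)
  n <- 1000L
  pos <- vapply(seq_len(n), function(i) {
    ls <- sample_lesions(pc, seed = 10000L + i)
    any(vapply(ls, function(l) l$kind %in% c("ICH", "MIXED"), TRUE))
  }, TRUE)
  band <- qbinom(c(0.005, 0.995), n, 0.32) / n
  expect_gte(mean(pos), band[1L])
  expect_lte(mean(pos), band[2L])
})

test_that("noiseless rendering satisfies SECT = VNC + k * IOM exactly", {
  pc <- tiny_phantom(noise_sd = 0, blur_sigma = 0, mixing_k = 1.7)
  for (s in 1:5) {
    cs <- render_case(sample_lesions(pc, seed = s), pc, seed = s)
    expect_equal(max(abs(cs$sect - (cs$vnc + 1.7 * cs$iom))), 0)
  }
})

test_that("a pure-CS case leaves the VNC at background within lesions", {
  pc <- tiny_phantom(class_prevalence = 1e-6, noise_sd = 0, blur_sigma = 0)
  cs <- render_case(sample_lesions(pc, seed = 3), pc, seed = 3)
  expect_identical(cs$case_label, "CS")
  inles <- cs$lesion_mask > 0
  # VNC inside lesions is just background texture: bounded by background band
  expect_lt(max(abs(cs$vnc[inles] - pc$background_mean)),
            6 * pc$background_sd)
  expect_gt(mean(cs$iom[inles]), 0)
})

test_that("least squares on lesion voxels recovers k within 1% (noiseless)", {
  pc <- tiny_phantom(noise_sd = 0, blur_sigma = 0, mixing_k = 0.8,
                     class_prevalence = 1e-6)
  cs <- render_case(sample_lesions(pc, seed = 7), pc, seed = 7)
  expect_lt(abs(recover_k(cs) - 0.8) / 0.8, 0.01)
})

test_that("rendering is fully determined by config and seed", {
  pc <- tiny_phantom()
  a <- simulate_cases(pc, 3, seed = 42)
  b <- simulate_cases(pc, 3, seed = 42)
  expect_identical(a, b)
  expect_false(identical(simulate_cases(pc, 1, seed = 43)[[1]]$sect, a[[1]]$sect))
})

test_that("decomposition rule agrees with the construction label", {
  pc <- tiny_phantom(noise_sd = 0, blur_sigma = 0)
  for (s in 21:50) {
    cs <- render_case(sample_lesions(pc, seed = s), pc, seed = s)
    expect_identical(
      classify_by_decomposition(cs$vnc, cs$iom, cs$lesion_mask, brain = cs$brain),
      cs$case_label)
  }
  # all-zero VNC elevation reads as contrast staining
  flat <- cs
  flat$vnc <- ifelse(cs$brain, pc$background_mean, 0)
  expect_identical(
    classify_by_decomposition(flat$vnc, cs$iom, cs$lesion_mask, brain = cs$brain),
    "CS")
  expect_error(classify_by_decomposition(cs$vnc, cs$iom, array(0L, dim(cs$vnc)),
                                         brain = cs$brain), "empty")
})

test_that("rank AUC matches the closed-form on a separable toy", {
  expect_equal(threshold_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(threshold_auc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(threshold_auc(c(1, 1, 1, 1), c(TRUE, FALSE, TRUE, FALSE)), 0.5)
  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- rnorm(60); lb <- runif(60) < 0.4
  expect_equal(threshold_auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("stratified split follows the per-class rounding contract", {
  mk <- function(lab, i) structure(list(case_label = lab, case_id = i),
                                   class = "paired_case")
  cases <- c(lapply(1:2, function(i) mk("ICH", i)),
             lapply(3:10, function(i) mk("CS", i)))
  sp <- stratified_split(cases, c(4L, 1L), seed = 1)
  expect_length(sp$train, 8L)
  expect_length(sp$validation, 2L)
  nv_ich <- sum(vapply(sp$validation, `[[`, "", "case_label") == "ICH")
  expect_true(nv_ich %in% c(0L, 1L))  # round(2 * 0.2) = 0

  # the published cohort arithmetic: 237 cases at the training prevalence
  # 61/190 -> 76 ICH; a 4:1 stratified split gives 190 train / 47 validation
  cases2 <- c(lapply(1:76, function(i) mk("ICH", i)),
              lapply(77:237, function(i) mk("CS", i)))
  sp2 <- stratified_split(cases2, c(4L, 1L), seed = 2)
  expect_length(sp2$train, 190L)
  expect_length(sp2$validation, 47L)

  sp3 <- stratified_split(cases2, c(4L, 1L), seed = 2)
  expect_identical(vapply(sp3$validation, `[[`, 1L, "case_id"),
                   vapply(sp2$validation, `[[`, 1L, "case_id"))
  expect_error(stratified_split(cases2[1:76], c(4L, 1L)), "classes")
})

test_that("cases round-trip through NIfTI with spacing and labels intact", {
  pc <- tiny_phantom(voxel_spacing = c(0.5, 0.5))
  cases <- simulate_cases(pc, 2, seed = 8)
  dir <- tempfile("cases")
  write_cases(cases, dir, split = c("train", "validation"))
  back <- read_cases(dir)
  expect_equal(back[[1]]$sect, cases[[1]]$sect, tolerance = 1e-6)
  expect_equal(as.numeric(back[[2]]$spacing)[1:2], c(0.5, 0.5), tolerance = 1e-6)
  expect_identical(back[[1]]$case_label, cases[[1]]$case_label)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(man$split, c("train", "validation"))
})
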