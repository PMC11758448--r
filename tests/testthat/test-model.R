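# Generator/discriminator computation graph: shape algebra, independence of
# the two decoder branches, window locality, determinism.

test_that("patch embedding and merge/expand follow the shape algebra", {
  v <- array(runif(64 * 64), c(64, 64))
  g <- patch_embed(v, p = 2L, C = 16L, seed = 1)
  expect_identical(g$spatial, c(32L, 32L))
  expect_identical(g$channels, 16L)

  m1 <- patch_merge(g, seed = 2)
  expect_identical(m1$spatial, c(16L, 16L))
  expect_identical(m1$channels, 32L)
  m3 <- patch_merge(patch_merge(m1, seed = 3), seed = 4)
  expect_identical(m3$spatial, c(4L, 4L))
  expect_identical(m3$channels, 128L)

  e <- patch_expand(m3, seed = 5)
  expect_identical(e$spatial, c(8L, 8L))
  expect_identical(e$channels, 64L)
  # merge then expand round-trips the shape
  rt <- patch_expand(patch_merge(m1, seed = 6), seed = 7)
  expect_identical(rt$spatial, m1$spatial)
  expect_identical(rt$channels, m1$channels)

  # rank-3 block arithmetic
  v3 <- array(runif(16^3), c(16L, 16L, 16L))
  g3 <- patch_embed(v3, p = 4L, C = 12L, seed = 8)
  expect_identical(g3$spatial, c(4L, 4L, 4L))
  m3d <- patch_merge(g3, seed = 9)
  expect_identical(m3d$spatial, c(2L, 2L, 2L))
  expect_identical(m3d$channels, 24L)

  expect_error(patch_embed(array(0, c(5, 5)), 2L, 8L), "divisible")
  expect_error(patch_merge(feature_grid(matrix(0, 9, 2), c(3L, 3L))), "even")
})

test_that("zero input with zero bias embeds to zero (linearity)", {
  v <- array(0, c(8, 8))
  g <- patch_embed(v, p = 2L, C = 4L, seed = 1)
  expect_equal(max(abs(g$values)), 0)  # init_linear sets biases to zero
})

test_that("attention pair preserves shape and window locality", {
  g <- feature_grid(matrix(rnorm(64 * 8), 64, 8), c(8L, 8L))
  out <- attention_pair(g, heads = 2L, window_size = 4L, seed = 3)
  expect_identical(out$spatial, g$spatial)
  expect_identical(out$channels, g$channels)

  # without the shifted second block, permuting whole windows permutes the
  # outputs identically (strict locality of windowed attention)
  widx <- sectmdi:::window_index(c(8L, 8L), 4L, 0L)
  nwin <- 4L; wt <- 16L
  perm_windows <- c(2L, 1L, 4L, 3L)
  perm_rows <- integer(64)
  for (w in seq_len(nwin)) {
    src <- widx[((w - 1L) * wt + 1L):(w * wt)]
    dst <- widx[((perm_windows[w] - 1L) * wt + 1L):(perm_windows[w] * wt)]
    perm_rows[dst] <- src
  }
  gp <- feature_grid(g$values[perm_rows, ], c(8L, 8L))
  o1 <- attention_pair(g, 2L, 4L, shift_second = FALSE, seed = 3)
  o2 <- attention_pair(gp, 2L, 4L, shift_second = FALSE, seed = 3)
  expect_equal(o2$values, o1$values[perm_rows, ], tolerance = 1e-10)

  # weights are shared across space: parameter shapes do not depend on grid
  big <- feature_grid(matrix(rnorm(256 * 8), 256, 8), c(16L, 16L))
  expect_identical(dim(attention_pair(big, 2L, 4L, seed = 3)$values),
                   c(256L, 8L))
})

test_that("encoder pyramid, bottleneck and generator shapes compose", {
  m <- transgan(model_config(), c(64L, 64L), seed = 1)
  v <- array(runif(64 * 64, 0, 256), c(64, 64))
  enc <- tg_encode(m, v)
  expect_identical(lapply(enc, `[[`, "spatial"),
                   list(c(32L, 32L), c(16L, 16L), c(8L, 8L), c(4L, 4L)))
  expect_identical(vapply(enc, `[[`, 1L, "channels"), c(16L, 32L, 64L, 128L))

  out <- tg_generate(m, v)
  expect_identical(dim(out$svnc), dim(v))
  expect_identical(dim(out$siom), dim(v))
  expect_true(all(is.finite(out$svnc)) && all(is.finite(out$siom)))
  expect_identical(tg_generate(m, v), out)  # deterministic at inference
})

test_that("bottleneck and decode operations compose back to input shape", {
  m <- transgan(model_config(), c(64L, 64L), seed = 5)
  v <- array(runif(64 * 64, 0, 256), c(64, 64))
  enc <- tg_encode(m, v)
  bt <- tg_bottleneck(m, enc[[4L]])
  expect_identical(bt$spatial, c(8L, 8L))
  expect_identical(bt$channels, 64L)
  dec <- tg_decode_branch(m, bt, enc, "vnc")
  expect_identical(dim(dec), c(64L, 64L))
  # composition equals the full generator pass
  full <- tg_generate(m, v)
  expect_equal(dec, full$svnc, tolerance = 1e-10)
  expect_equal(tg_decode_branch(m, bt, enc, "iom"), full$siom,
               tolerance = 1e-10)
})

test_that("the two decoder branches share no parameters", {
  m <- transgan(model_config(), c(32L, 32L), seed = 2)
  v <- array(runif(32 * 32, 0, 256), c(32, 32))
  base <- tg_generate(m, v)
  for (nm in grep("^diom", names(m$params), value = TRUE))
    m$params[[nm]] <- m$params[[nm]] + 0.05
  pert <- tg_generate(m, v)
  expect_equal(pert$svnc, base$svnc)
  expect_gt(max(abs(pert$siom - base$siom)), 0)
})

test_that("discriminators score scalars per image and are independent", {
  m <- transgan(model_config(), c(32L, 32L), seed = 3)
  v1 <- array(runif(32 * 32, 0, 256), c(32, 32))
  v2 <- array(runif(32 * 32, 0, 256), c(32, 32))
  s <- tg_discriminate(m, list(v1, v2), "vnc")
  expect_length(s, 2L)
  base_vnc <- tg_discriminate(m, v1, "vnc")
  for (nm in names(m$disc_params$iom))
    m$disc_params$iom[[nm]] <- m$disc_params$iom[[nm]] - 0.1
  expect_equal(tg_discriminate(m, v1, "vnc"), base_vnc)
  expect_error(tg_discriminate(m, array(0, c(16, 16)), "vnc"), "shape")
})

test_that("every generator parameter receives gradient from the task losses", {
  m <- transgan(model_config(), c(32L, 32L), seed = 4)
  plan <- sectmdi:::get_plan(m, c(32L, 32L), 1L)
  tape <- sectmdi:::ad_tape()
  lv <- sectmdi:::leaves_for(tape, m$params)
  set.seed(1)
  x <- sectmdi:::ad_const(tape, matrix(runif(1024), ncol = 1))
  out <- sectmdi:::gen_forward_tape(tape, lv, x, m$config, plan)
  tgt <- matrix(runif(1024, 0, 256), ncol = 1)
  loss <- sectmdi:::ad_add(sectmdi:::ad_l1_loss(out$svnc, tgt),
                           sectmdi:::ad_l1_loss(out$siom, tgt))
  g <- sectmdi:::ad_backward(loss)
  missing <- setdiff(names(m$params), names(g))
  expect_identical(missing, character(0))
  norms <- vapply(names(m$params), function(nm) max(abs(g[[nm]])), 1)
  expect_true(all(norms > 0))
})

test_that("the rank-3 generator and discriminator run shape-preserving", {
  cfg <- model_config(spatial_rank = 3L, patch_size = 2L, embed_dim = 8L)
  m <- suppressWarnings(transgan(cfg, c(16L, 16L, 16L), seed = 1))
  v <- array(runif(16^3, 0, 256), c(16L, 16L, 16L))
  out <- suppressWarnings(tg_generate(m, v))
  expect_identical(dim(out$svnc), dim(v))
  expect_identical(dim(out$siom), dim(v))
  expect_true(all(is.finite(out$svnc)))
  expect_length(suppressWarnings(tg_discriminate(m, v, "iom")), 1L)
})

test_that("input shapes not divisible by patch * 8 are rejected", {
  expect_error(transgan(model_config(), c(60L, 60L)), "divisible")
  expect_error(tg_generate(transgan(model_config(), c(32L, 32L)),
                           array(0, c(24, 24))), "divisible")
})
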