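# Losses, GradNorm, plateau scheduling and the training loop contracts.

test_that("L1 loss matches hand arithmetic", {
  a <- array(c(0, 2), c(2, 1)); b <- array(c(1, 1), c(2, 1))
  expect_equal(l1_loss(a, b), 1)
  expect_equal(l1_loss(b, b), 0)
  expect_equal(l1_loss(b + 3, b), 3)
  expect_error(l1_loss(array(0, c(2, 2)), array(0, c(4, 1))), "shape")
})

test_that("adversarial losses take the non-saturating closed forms", {
  m <- transgan(model_config(), c(32L, 32L), seed = 1)
  # zero the final fully connected layer: D outputs logit 0 everywhere
  for (br in c("vnc", "iom")) {
    m$disc_params[[br]]$fc.W[] <- 0
    m$disc_params[[br]]$fc.b[] <- 0
  }
  v <- array(runif(32 * 32, 0, 256), c(32, 32))
  al <- adversarial_losses(m, v, v, "vnc")
  expect_equal(al$gen_term, log(2), tolerance = 1e-12)
  expect_equal(al$disc_term, 2 * log(2), tolerance = 1e-12)

  # a confidently correct discriminator drives its loss toward zero
  m$disc_params$vnc$fc.b[] <- 30    # logit +30 for everything
  al2 <- adversarial_losses(m, v, v, "vnc")
  expect_lt(abs(al2$disc_term - (0 + 30)), 1e-4)  # -log sig(30) ~ 0; fake term ~ 30
  expect_lt(al2$gen_term, 1e-10)
})

test_that("task losses assemble the two-branch breakdown", {
  pc <- tiny_phantom()
  cs <- render_case(sample_lesions(pc, seed = 1), pc, seed = 1)
  m <- transgan(model_config(), c(32L, 32L), seed = 2)
  pred <- tg_generate(m, cs$sect)
  lb <- task_losses(m, pred, cs, use_adv = FALSE)
  expect_equal(lb$total_vnc, lb$l1_vnc)
  expect_equal(lb$adv_vnc, 0)
  lb2 <- task_losses(m, pred, cs, use_adv = TRUE)
  expect_equal(lb2$total_vnc, lb2$l1_vnc + lb2$adv_vnc)
  expect_equal(lb2$total_iom, lb2$l1_iom + lb2$adv_iom)

  # perfect predictions with D at logit 0: task loss is exactly ln 2
  for (br in c("vnc", "iom")) {
    m$disc_params[[br]]$fc.W[] <- 0
    m$disc_params[[br]]$fc.b[] <- 0
  }
  lb3 <- task_losses(m, list(svnc = cs$vnc, siom = cs$iom), cs)
  expect_equal(lb3$total_vnc, log(2), tolerance = 1e-12)
})

test_that("GradNorm is symmetric, renormalized and matches a hand-derived step", {
  st <- gradnorm_state(alpha = 1.5, weight_lr = 0.025)
  # identical tasks: weights stay (1, 1)
  st1 <- gradnorm_step(st, losses = c(2, 2), grad_norms = c(0.7, 0.7))
  expect_equal(unname(st1$w), c(1, 1))
  st1 <- gradnorm_step(st1, c(1.2, 1.2), c(0.5, 0.5))
  expect_equal(unname(st1$w), c(1, 1))

  # hand-derived asymmetric step (scalar oracle, alpha = 1)
  st2 <- gradnorm_state(alpha = 1, weight_lr = 0.1)
  st2 <- gradnorm_step(st2, losses = c(4, 1), grad_norms = c(2, 1))
  # L0 = (4, 1); r = (1, 1); target = mean(G) = 1.5 for both
  # G = (2, 1): gw = (sign(0.5)*2, sign(-0.5)*1) = (2, -1)
  # first Adam step is lr * sign(gw) (moment ratios cancel):
  # w_raw = (1 - 0.1, 1 + 0.1) = (0.9, 1.1), already summing to 2
  expect_equal(unname(st2$w), c(0.9, 1.1), tolerance = 1e-6)
  expect_equal(sum(st2$w), 2)

  st3 <- gradnorm_step(st2, losses = c(2, 0.9), grad_norms = c(1, 1))
  expect_equal(sum(st3$w), 2)
  expect_true(all(st3$w > 0))
})

test_that("plateau scheduler halves after patience is exceeded", {
  s <- plateau_scheduler(lr = 1e-3, factor = 0.5, patience = 5L)
  for (m in c(10, 9, 8, 7)) s <- scheduler_step(s, m)
  expect_equal(s$lr, 1e-3)                 # strictly improving: unchanged
  for (i in 1:6) s <- scheduler_step(s, 7) # six non-improving evaluations
  expect_equal(s$lr, 5e-4)
  for (i in 1:6) s <- scheduler_step(s, 7)
  expect_equal(s$lr, 2.5e-4)               # second plateau: lr0 / 4
})

test_that("training runs, logs every iteration, and is seed-reproducible", {
  pc <- tiny_phantom()
  cases <- simulate_cases(pc, 3, seed = 5)
  cfg <- train_config(iterations = 6L, batch_size = 2L, seed = 9L)
  m1 <- transgan(model_config(), c(32L, 32L), seed = 1)
  f1 <- train_transgan(m1, cases, cfg)
  expect_identical(nrow(f1$history), 6L)
  expect_true(all(is.finite(f1$history$objective)))
  m2 <- transgan(model_config(), c(32L, 32L), seed = 1)
  f2 <- train_transgan(m2, cases, cfg)
  expect_equal(f1$history, f2$history)
  expect_equal(m1$params$dvnc.head.W, m2$params$dvnc.head.W)
})

test_that("GradNorm off with fixed (1,1) weights equals the plain loss", {
  pc <- tiny_phantom()
  cases <- simulate_cases(pc, 2, seed = 6)
  cfg_off <- train_config(iterations = 4L, batch_size = 2L, seed = 3L,
                          use_gradnorm = FALSE, use_adv = FALSE)
  m <- transgan(model_config(), c(32L, 32L), seed = 4)
  f <- train_transgan(m, cases, cfg_off)
  expect_true(all(f$history$w_vnc == 1))
  expect_true(all(f$history$w_iom == 1))
  expect_equal(f$history$objective, f$history$l1_vnc + f$history$l1_iom)
})

test_that("GradNorm weight trajectory swaps under task relabeling", {
  pc <- tiny_phantom()
  cases <- simulate_cases(pc, 2, seed = 7)
  mk_symmetric <- function() {
    m <- transgan(model_config(), c(32L, 32L), seed = 11)
    # make the two branches and discriminators identical so the only
    # asymmetry is the data
    for (nm in grep("^dvnc", names(m$params), value = TRUE))
      m$params[[sub("^dvnc", "diom", nm)]] <- m$params[[nm]]
    m$disc_params$iom <- m$disc_params$vnc
    m
  }
  swap <- function(cs) { tmp <- cs$vnc; cs$vnc <- cs$iom; cs$iom <- tmp; cs }
  cfg <- train_config(iterations = 4L, batch_size = 2L, seed = 5L,
                      gradnorm_warmup = 0L)
  f1 <- train_transgan(mk_symmetric(), cases, cfg)
  f2 <- train_transgan(mk_symmetric(), lapply(cases, swap), cfg)
  expect_equal(f2$history$w_vnc, f1$history$w_iom, tolerance = 1e-6)
  expect_equal(f2$history$w_iom, f1$history$w_vnc, tolerance = 1e-6)
  expect_equal(f2$history$l1_vnc, f1$history$l1_iom, tolerance = 1e-6)
})

test_that("L1-only ablation decreases the objective on toy data", {
  pc <- tiny_phantom()
  cases <- simulate_cases(pc, 2, seed = 8)
  m <- transgan(model_config(), c(32L, 32L), seed = 6)
  f <- train_transgan(m, cases, train_config(iterations = 40L, batch_size = 2L,
                                             use_adv = FALSE, seed = 2L))
  first <- mean(f$history$objective[1:10])
  last <- mean(f$history$objective[31:40])
  expect_lt(last, first)
})
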