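# Training: L1 + adversarial losses for the two decoding tasks, GradNorm
# dynamic task weighting, Adam, and a plateau learning-rate schedule driven
# by the rolling mean training loss.

#' Training configuration
#'
#' Defaults follow the training protocol of the method: Adam with beta1 =
#' 0.9, beta2 = 0.999, initial learning rate 1e-3 decayed by a plateau
#' scheduler (factor 0.5, patience 5) on the mean training loss of the last
#' 50 iterations, batch size 4, 200 iterations.
#'
#' @param lr initial learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param scheduler_factor multiplicative learning-rate decay on plateau.
#' @param scheduler_patience evaluations without improvement tolerated
#'   before decaying.
#' @param loss_window iterations averaged for the scheduler signal.
#' @param batch_size cases per iteration.
#' @param iterations number of training iterations.
#' @param gradnorm_alpha GradNorm asymmetry exponent.
#' @param gradnorm_lr step size for the task-weight update.
#' @param gradnorm_warmup iterations before GradNorm engages (weights fixed
#'   at (1, 1) and reference losses recorded afterwards). The default, one
#'   scheduler window, lets the quickly-learned background offset decay so
#'   the inverse-training-rate ratios compare lesion learning, not the
#'   initial transient.
#' @param use_gradnorm adapt task weights dynamically; if `FALSE` the plain
#'   multi-task loss with fixed weights (1, 1) is used.
#' @param use_adv include the adversarial terms (and train discriminators);
#'   `FALSE` gives the L1-only ablation.
#' @param gan_loss `"bce"` (non-saturating binary cross-entropy) or `"ls"`
#'   (least-squares).
#' @param crop_size optional crop (per axis) drawn identically from each
#'   case's volumes each iteration; `NULL` uses full volumes.
#' @param augment apply random flip / right-angle rotation augmentation.
#' @param seed integer; all training randomness derives from it.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         scheduler_factor = 0.5, scheduler_patience = 5L,
                         loss_window = 50L, batch_size = 4L, iterations = 200L,
                         gradnorm_alpha = 0.5, gradnorm_lr = 0.025,
                         gradnorm_warmup = 50L,
                         use_gradnorm = TRUE, use_adv = TRUE,
                         gan_loss = c("bce", "ls"),
                         crop_size = NULL, augment = FALSE, seed = 1L) {
  gan_loss <- match.arg(gan_loss)
  stopifnot(lr > 0, beta1 > 0, beta2 > 0, scheduler_factor > 0,
            scheduler_factor < 1, scheduler_patience > 0, loss_window > 0,
            batch_size > 0, iterations > 0, gradnorm_alpha > 0, gradnorm_lr > 0)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 loss_window = as.integer(loss_window),
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 gradnorm_alpha = gradnorm_alpha, gradnorm_lr = gradnorm_lr,
                 gradnorm_warmup = as.integer(gradnorm_warmup),
                 use_gradnorm = isTRUE(use_gradnorm), use_adv = isTRUE(use_adv),
                 gan_loss = gan_loss, crop_size = crop_size,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

#' Mean absolute (L1) loss
#'
#' @param pred,target numeric arrays of identical shape.
#' @return mean voxelwise absolute difference.
#' @export
l1_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("shape mismatch in l1_loss")
  mean(abs(pred - target))
}

#' Adversarial loss terms for one discriminator
#'
#' Non-saturating GAN formulation: the discriminator term is
#' -log(sigma(D(real))) - log(1 - sigma(D(fake))) and the generator term is
#' -log(sigma(D(fake))). The fake image enters the discriminator term as a
#' fixed (detached) input. With `gan_loss = "ls"` the least-squares variant
#' (D(real)-1)^2 + D(fake)^2 and (D(fake)-1)^2 is used.
#'
#' @param model a [transgan()] model.
#' @param fake,real volumes of the model's input shape (or lists thereof).
#' @param which `"vnc"` or `"iom"` discriminator.
#' @param gan_loss `"bce"` or `"ls"`.
#' @return `list(gen_term =, disc_term =)`.
#' @export
adversarial_losses <- function(model, fake, real, which = c("vnc", "iom"),
                               gan_loss = c("bce", "ls")) {
  which <- match.arg(which); gan_loss <- match.arg(gan_loss)
  zf <- tg_discriminate(model, fake, which)
  zr <- tg_discriminate(model, real, which)
  if (gan_loss == "bce") {
    bce <- function(z, y) mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
    list(gen_term = bce(zf, 1), disc_term = bce(zr, 1) + bce(zf, 0))
  } else {
    list(gen_term = mean((zf - 1)^2), disc_term = mean((zr - 1)^2) + mean(zf^2))
  }
}

#' Per-task loss breakdown for one paired prediction
#'
#' Assembles the two task losses: L_VNC = L1(sVNC, VNC) + adversarial term
#' from the VNC discriminator, and likewise L_IOM from the IOM branch.
#'
#' @param model a [transgan()] model (used for the discriminators).
#' @param pred `list(svnc =, siom =)` prediction (as from [tg_generate()]).
#' @param case a `paired_case` holding the `vnc` and `iom` ground truths.
#' @param use_adv include adversarial terms; if `FALSE` they are zero.
#' @return a `loss_breakdown` list with fields `l1_vnc`, `adv_vnc`,
#'   `l1_iom`, `adv_iom`, `disc_vnc`, `disc_iom`, `total_vnc`, `total_iom`.
#' @export
task_losses <- function(model, pred, case, use_adv = TRUE) {
  lv <- l1_loss(pred$svnc, case$vnc)
  li <- l1_loss(pred$siom, case$iom)
  if (use_adv) {
    av <- adversarial_losses(model, pred$svnc, case$vnc, "vnc")
    ai <- adversarial_losses(model, pred$siom, case$iom, "iom")
  } else {
    av <- ai <- list(gen_term = 0, disc_term = 0)
  }
  structure(list(l1_vnc = lv, adv_vnc = av$gen_term,
                 l1_iom = li, adv_iom = ai$gen_term,
                 disc_vnc = av$disc_term, disc_iom = ai$disc_term,
                 total_vnc = lv + av$gen_term, total_iom = li + ai$gen_term),
            class = "loss_breakdown")
}

## ---- GradNorm ----

#' GradNorm task-weight state
#'
#' Task weights start at (1, 1) and are renormalised to sum to 2 after every
#' update; initial task losses are recorded on the first step.
#'
#' @param alpha asymmetry exponent (higher pushes harder on lagging tasks).
#' @param weight_lr step size of the weight update.
#' @return a `gradnorm_state` list.
#' @export
gradnorm_state <- function(alpha = 0.5, weight_lr = 0.025) {
  structure(list(w = c(vnc = 1, iom = 1), L0 = NULL, ema = NULL, ema_g = NULL,
                 alpha = alpha, weight_lr = weight_lr,
                 m = c(0, 0), v = c(0, 0), t = 0L),
            class = "gradnorm_state")
}

#' One GradNorm update
#'
#' Given the current task losses and the norms of each task-loss gradient on
#' the shared layer, computes weighted gradient norms G_i = w_i * g_i,
#' inverse training rates r_i = (L_i / L_i(0)) normalised to mean one, and
#' the gradient of sum_i |G_i - mean(G) * r_i^alpha| (the target treated as
#' constant) with respect to the weights. The weights take one Adam step of
#' size `weight_lr` on that gradient (Adam keeps the step scale independent
#' of the raw gradient-norm magnitude), then are clamped away from zero and
#' renormalised to sum 2.
#'
#' @param state a [gradnorm_state()].
#' @param losses numeric(2), current task losses (VNC, IOM).
#' @param grad_norms numeric(2), unweighted gradient norms g_i of each task
#'   loss over the shared layer.
#' @return the updated state.
#' @export
gradnorm_step <- function(state, losses, grad_norms) {
  losses <- as.numeric(losses); grad_norms <- as.numeric(grad_norms)
  if (is.null(state$L0)) state$L0 <- pmax(losses, 1e-12)
  # smooth both signals: small batches make per-batch losses and per-layer
  # gradient norms far too noisy to steer the weights directly
  state$ema <- if (is.null(state$ema)) losses else 0.9 * state$ema + 0.1 * losses
  state$ema_g <- if (is.null(state$ema_g)) grad_norms
                 else 0.9 * state$ema_g + 0.1 * grad_norms
  grad_norms <- state$ema_g
  G <- state$w * grad_norms
  r <- state$ema / state$L0
  r <- r / mean(r)
  target <- mean(G) * r^state$alpha
  gw <- sign(G - target) * grad_norms
  # Adam step on the weights
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  state$m <- b1 * state$m + (1 - b1) * gw
  state$v <- b2 * state$v + (1 - b2) * gw * gw
  mh <- state$m / (1 - b1^state$t)
  vh <- state$v / (1 - b2^state$t)
  w <- state$w - state$weight_lr * mh / (sqrt(vh) + eps)
  # bounded trust region: with two closely related tasks the useful
  # adaptation range is modest, and wider bounds let noise-driven drift
  # starve one branch
  w <- pmin(pmax(w, 0.5), 1.5)
  state$w <- 2 * w / sum(w)
  state
}

## ---- plateau scheduler ----

#' Plateau learning-rate scheduler
#'
#' Tracks the best rolling-mean loss seen so far; after more than `patience`
#' consecutive evaluations without improvement the learning rate is
#' multiplied by `factor` and the counter resets.
#'
#' @param lr initial learning rate.
#' @param factor decay factor in (0, 1).
#' @param patience tolerated consecutive non-improving evaluations.
#' @return a `plateau_scheduler` list.
#' @export
plateau_scheduler <- function(lr = 1e-3, factor = 0.5, patience = 5L) {
  structure(list(lr = lr, factor = factor, patience = as.integer(patience),
                 best = Inf, bad = 0L), class = "plateau_scheduler")
}

#' Advance the scheduler with a new rolling-mean loss
#'
#' @param sched a [plateau_scheduler()].
#' @param mean_loss mean training loss of the last window.
#' @return the updated scheduler (field `lr` holds the current rate).
#' @export
scheduler_step <- function(sched, mean_loss) {
  if (mean_loss < sched$best) {
    sched$best <- mean_loss
    sched$bad <- 0L
  } else {
    sched$bad <- sched$bad + 1L
    if (sched$bad > sched$patience) {
      sched$lr <- sched$lr * sched$factor
      sched$bad <- 0L
    }
  }
  sched
}

## ---- Adam ----

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(params[[nm]])) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

## ---- training loop ----

tape_bce <- function(logits, y) ad_bce_logits(logits, y)

tape_ls <- function(logits, y) {
  d <- ad_node(logits$tape, (ad_value(logits) - y)^2, logits$id,
               function(g) list(2 * g * (ad_value(logits) - y)))
  ad_mean(d)
}

grad_l2_norm <- function(g) if (is.null(g)) 0 else sqrt(sum(g * g))

#' Train a trans-GAN
#'
#' Alternates discriminator and generator updates per batch. The generator
#' objective is w_VNC * (L1 + adversarial) + w_IOM * (L1 + adversarial) with
#' GradNorm-adapted weights; the shared layer for GradNorm gradient norms is
#' the last encoder block's patch-merge projection. Adam optimises the
#' generator and each discriminator separately; a plateau scheduler decays
#' the learning rate based on the rolling mean of the generator objective.
#' Fully replayable from `config$seed` (single-threaded).
#'
#' @param model a [transgan()] model (updated by reference, being an
#'   environment; also returned).
#' @param cases list of `paired_case` objects (see [render_case()]); volumes
#'   must match the model input shape after optional cropping.
#' @param config a [train_config()].
#' @param verbose print progress every 25 iterations.
#' @return `list(model =, history =)` where `history` is a data frame with
#'   one row per iteration (loss terms, task weights, learning rate).
#' @export
train_transgan <- function(model, cases, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "transgan"), length(cases) >= 1L)
  cfg <- model$config
  set.seed(config$seed)
  shape <- model$input_shape
  batch <- config$batch_size
  plan <- get_plan(model, shape, batch)
  shared <- "enc4.mg.W"

  opt_g <- adam_state(model$params)
  opt_d <- list(vnc = adam_state(model$disc_params$vnc),
                iom = adam_state(model$disc_params$iom))
  gn <- gradnorm_state(config$gradnorm_alpha, config$gradnorm_lr)
  sched <- plateau_scheduler(config$lr, config$scheduler_factor,
                             config$scheduler_patience)
  gan_term <- if (config$gan_loss == "bce") tape_bce else tape_ls

  hist <- vector("list", config$iterations)
  recent <- numeric(0)

  draw_batch <- function() {
    ids <- sample.int(length(cases), batch, replace = length(cases) < batch)
    lapply(cases[ids], function(cs) {
      if (config$augment) cs <- augment_case(cs)
      if (!is.null(config$crop_size)) cs <- random_crop(cs, config$crop_size)
      cs
    })
  }

  for (it in seq_len(config$iterations)) {
    bt <- draw_batch()
    sect <- vols_to_matrix(lapply(bt, `[[`, "sect")) / 256
    yv <- vols_to_matrix(lapply(bt, `[[`, "vnc"))
    yi <- vols_to_matrix(lapply(bt, `[[`, "iom"))

    # generator forward
    tape <- ad_tape()
    lvg <- leaves_for(tape, model$params)
    out <- gen_forward_tape(tape, lvg, ad_const(tape, sect), cfg, plan)

    disc_losses <- c(vnc = 0, iom = 0)
    if (config$use_adv) {
      # discriminator updates on detached fakes
      for (br in c("vnc", "iom")) {
        fake <- ad_value(out[[if (br == "vnc") "svnc" else "siom"]]) / 256
        real <- (if (br == "vnc") yv else yi) / 256
        td <- ad_tape()
        lvd <- leaves_for(td, model$disc_params[[br]])
        zr <- disc_forward_tape(td, lvd, ad_const(td, real), cfg, plan)
        zf <- disc_forward_tape(td, lvd, ad_const(td, fake), cfg, plan)
        ld <- ad_add(gan_term(zr, 1), gan_term(zf, 0))
        disc_losses[br] <- ad_value(ld)
        gd <- ad_backward(ld)
        upd <- adam_step(model$disc_params[[br]], gd, opt_d[[br]], sched$lr,
                         config$beta1, config$beta2)
        model$disc_params[[br]] <- upd$params
        opt_d[[br]] <- upd$state
      }
    }

    # task losses (adversarial term through the updated discriminators)
    l1v <- ad_l1_loss(out$svnc, yv)
    l1i <- ad_l1_loss(out$siom, yi)
    if (config$use_adv) {
      lvd1 <- leaves_for(tape, model$disc_params$vnc, prefix = "D1:")
      lvd2 <- leaves_for(tape, model$disc_params$iom, prefix = "D2:")
      zf1 <- disc_forward_tape(tape, lvd1, ad_scale(out$svnc, 1 / 256), cfg, plan,
                               prefix = "D1:")
      zf2 <- disc_forward_tape(tape, lvd2, ad_scale(out$siom, 1 / 256), cfg, plan,
                               prefix = "D2:")
      advv <- gan_term(zf1, 1)
      advi <- gan_term(zf2, 1)
      Lv <- ad_add(l1v, advv)
      Li <- ad_add(l1i, advi)
    } else {
      advv <- advi <- NULL
      Lv <- l1v
      Li <- l1i
    }

    gv <- ad_backward(Lv)
    gi <- ad_backward(Li)
    if (!is.finite(ad_value(Lv)) || !is.finite(ad_value(Li)))
      stop("non-finite generator loss at iteration ", it,
           " (L_VNC = ", ad_value(Lv), ", L_IOM = ", ad_value(Li), ")")

    if (config$use_gradnorm && it > config$gradnorm_warmup) {
      gn <- gradnorm_step(gn, c(ad_value(Lv), ad_value(Li)),
                          c(grad_l2_norm(gv[[shared]]), grad_l2_norm(gi[[shared]])))
    }
    w <- gn$w

    gcomb <- gv
    for (nm in names(gi)) {
      gcomb[[nm]] <- if (is.null(gcomb[[nm]])) w[2L] * gi[[nm]]
                     else w[1L] * gcomb[[nm]] + w[2L] * gi[[nm]]
    }
    for (nm in names(gv)) if (is.null(gi[[nm]])) gcomb[[nm]] <- w[1L] * gv[[nm]]
    gcomb <- gcomb[!grepl("^D[12]:", names(gcomb))]
    upd <- adam_step(model$params, gcomb, opt_g, sched$lr,
                     config$beta1, config$beta2)
    model$params <- upd$params
    opt_g <- upd$state

    gen_obj <- w[1L] * ad_value(Lv) + w[2L] * ad_value(Li)
    recent <- c(recent, gen_obj)
    # one scheduler evaluation per completed window of `loss_window` iterations
    if (length(recent) == config$loss_window) {
      sched <- scheduler_step(sched, mean(recent))
      recent <- numeric(0)
    }

    hist[[it]] <- data.frame(
      iteration = it,
      l1_vnc = ad_value(l1v), adv_vnc = if (is.null(advv)) 0 else ad_value(advv),
      l1_iom = ad_value(l1i), adv_iom = if (is.null(advi)) 0 else ad_value(advi),
      disc_vnc = disc_losses["vnc"], disc_iom = disc_losses["iom"],
      w_vnc = w[1L], w_iom = w[2L], lr = sched$lr, objective = gen_obj)
    if (verbose && it %% 25L == 0L)
      message(sprintf("iter %d  L1(VNC)=%.3f  L1(IOM)=%.3f  w=(%.2f, %.2f)  lr=%.2e",
                      it, ad_value(l1v), ad_value(l1i), w[1L], w[2L], sched$lr))
  }
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  list(model = model, history = history)
}
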