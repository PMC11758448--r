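# trans-GAN computation graph: pyramidal windowed-transformer encoder, a
# bottleneck attention pair, two task-specific transformer decoders (sVNC and
# sIOM) and two strided-convolution discriminators.

#' Model configuration for the trans-GAN
#'
#' The generator is a four-block pyramidal transformer encoder (patch
#' embedding, then attention pairs followed by patch merging, halving the
#' resolution and doubling the channels at each block), a bottleneck
#' attention pair with one patch expansion, and two structurally identical
#' decoders of three cascaded blocks (attention pairs plus patch expansion,
#' the last block expanding by the patch size back to input resolution with a
#' linear one-channel head). Two independent discriminators score generated
#' VNC and IOM images with four strided convolutions and a fully connected
#' layer.
#'
#' @param spatial_rank 2 or 3; rank-2 runs the whole pipeline on 2D slices at
#'   desk scale, rank-3 operates on volumes.
#' @param patch_size edge length of the non-overlapping patches embedded by
#'   the first encoder block. Input shape must be divisible by
#'   `patch_size * 8` per axis.
#' @param embed_dim channel width after patch embedding; doubled at each of
#'   the three patch-merge steps.
#' @param encoder_depths integer(4), attention pairs per encoder block (the
#'   first block is the patch embedding and by default carries none).
#' @param head_counts integer(4), attention heads at each channel level
#'   (`embed_dim`, 2x, 4x, 8x). Each level's width must be divisible by its
#'   head count.
#' @param window_size edge length of the attention windows; clamped (with a
#'   warning) to the grid when a pyramid level is smaller.
#' @param decoder_depths integer(3), attention pairs per decoder block.
#' @param use_skips fuse each decoder block's input with the matching encoder
#'   feature grid (concatenation + linear reduction).
#' @param disc_channels integer(4), channel widths of the discriminator's
#'   convolution layers.
#' @param mlp_ratio feed-forward expansion factor inside attention blocks.
#' @return a `tg_config` list.
#' @export
model_config <- function(spatial_rank = 2L, patch_size = 2L, embed_dim = 16L,
                         encoder_depths = c(0L, 1L, 1L, 1L),
                         head_counts = c(1L, 2L, 4L, 8L),
                         window_size = 4L,
                         decoder_depths = c(1L, 1L, 1L),
                         use_skips = TRUE,
                         disc_channels = c(8L, 16L, 32L, 64L),
                         mlp_ratio = 4L) {
  stopifnot(spatial_rank %in% c(2L, 3L), patch_size >= 1L, embed_dim >= 1L,
            length(encoder_depths) == 4L, length(head_counts) == 4L,
            length(decoder_depths) == 3L, length(disc_channels) == 4L,
            window_size >= 1L)
  widths <- embed_dim * 2L^(0:3)
  if (any(widths %% head_counts != 0L))
    stop("embed_dim * 2^level must be divisible by the matching head count")
  structure(list(spatial_rank = as.integer(spatial_rank),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 encoder_depths = as.integer(encoder_depths),
                 head_counts = as.integer(head_counts),
                 window_size = as.integer(window_size),
                 decoder_depths = as.integer(decoder_depths),
                 use_skips = isTRUE(use_skips),
                 disc_channels = as.integer(disc_channels),
                 mlp_ratio = as.integer(mlp_ratio)),
            class = "tg_config")
}

check_input_shape <- function(cfg, shape) {
  if (length(shape) != cfg$spatial_rank)
    stop("input rank ", length(shape), " != spatial_rank ", cfg$spatial_rank)
  div <- cfg$patch_size * 8L
  if (any(shape %% div != 0L))
    stop("input shape must be divisible by patch_size * 8 (= ", div, ") per axis")
  invisible(shape)
}

## ---- shape plan (cached index sets per input shape x batch) ----

attn_site <- function(res, w_req, shifted, batch, heads) {
  w <- min(w_req, min(res))
  while (any(res %% w != 0L)) w <- w - 1L
  if (w < w_req && min(res) < w_req)
    warning("window clamped from ", w_req, " to ", w, " for grid ",
            paste(res, collapse = "x"), call. = FALSE)
  shift <- if (shifted && w < max(res)) w %/% 2L else 0L
  ntok <- prod(res)
  idx <- rep_batch_index(window_index(res, w, shift), ntok, batch)
  list(idx = idx, inv = inverse_perm(idx), w_tokens = as.integer(w^length(res)),
       nwb = as.integer(ntok / w^length(res) * batch), heads = as.integer(heads))
}

build_plan <- function(cfg, shape, batch) {
  r <- cfg$spatial_rank
  p <- cfg$patch_size
  check_input_shape(cfg, shape)
  res <- lapply(0:3, function(i) shape %/% (p * 2L^i))
  plan <- list(shape = shape, batch = batch, npix = prod(shape),
               res = res, n_tok = vapply(res, prod, 1) * batch)
  plan$embed_idx <- rep_batch_index(group_index(shape, p), prod(shape), batch)
  plan$sites <- lapply(1:4, function(lvl) list(
    reg = attn_site(res[[lvl]], cfg$window_size, FALSE, batch, cfg$head_counts[lvl]),
    sh  = attn_site(res[[lvl]], cfg$window_size, TRUE, batch, cfg$head_counts[lvl])))
  plan$merge_idx <- lapply(1:3, function(lvl)
    rep_batch_index(group_index(res[[lvl]], 2L), prod(res[[lvl]]), batch))
  plan$expand_idx <- lapply(1:3, function(lvl)   # level lvl+1 -> lvl
    rep_batch_index(ungroup_index(res[[lvl]], 2L), prod(res[[lvl]]), batch))
  plan$head_idx <- rep_batch_index(ungroup_index(shape, p), prod(shape), batch)
  dshapes <- vector("list", 5L); dshapes[[1L]] <- shape
  plan$disc <- vector("list", 4L)
  for (l in 1:4) {
    ci <- conv_index(dshapes[[l]], 3L, 2L, 1L)
    plan$disc[[l]] <- list(
      idx = rep_batch_index(ci$idx, prod(dshapes[[l]]), batch),
      n_out = prod(ci$out_shape) * batch)
    dshapes[[l + 1L]] <- ci$out_shape
  }
  plan$disc_flat <- prod(dshapes[[5L]])
  plan
}

get_plan <- function(model, shape, batch) {
  key <- paste(c(shape, "b", batch), collapse = "_")
  pl <- model$plans[[key]]
  if (is.null(pl)) {
    pl <- build_plan(model$config, shape, batch)
    model$plans[[key]] <- pl
  }
  pl
}

## ---- parameter construction ----

init_generator_params <- function(cfg) {
  r <- cfg$spatial_rank; C <- cfg$embed_dim; no <- 2L^r
  P <- list()
  P <- init_linear(P, "embed", cfg$patch_size^r, C)
  width <- function(lvl) C * 2L^(lvl - 1L)
  for (d in seq_len(cfg$encoder_depths[1L]))
    P <- init_attention_block(init_attention_block(P, sprintf("enc1.p%d.a", d), C, cfg$mlp_ratio),
                              sprintf("enc1.p%d.b", d), C, cfg$mlp_ratio)
  for (blk in 2:4) {
    lvl <- blk - 1L
    for (d in seq_len(cfg$encoder_depths[blk])) {
      P <- init_attention_block(P, sprintf("enc%d.p%d.a", blk, d), width(lvl), cfg$mlp_ratio)
      P <- init_attention_block(P, sprintf("enc%d.p%d.b", blk, d), width(lvl), cfg$mlp_ratio)
    }
    P <- init_linear(P, sprintf("enc%d.mg", blk), width(lvl) * no, width(lvl + 1L))
  }
  P <- init_attention_block(P, "bot.p.a", width(4L), cfg$mlp_ratio)
  P <- init_attention_block(P, "bot.p.b", width(4L), cfg$mlp_ratio)
  P <- init_linear(P, "bot.ex", width(4L), no * width(3L))
  for (br in c("dvnc", "diom")) {
    for (blk in 1:3) {
      cb <- width(4L - blk)                      # 4C, 2C, C
      if (cfg$use_skips)
        P <- init_linear(P, sprintf("%s.b%d.fuse", br, blk), 2L * cb, cb)
      for (d in seq_len(cfg$decoder_depths[blk])) {
        P <- init_attention_block(P, sprintf("%s.b%d.p%d.a", br, blk, d), cb, cfg$mlp_ratio)
        P <- init_attention_block(P, sprintf("%s.b%d.p%d.b", br, blk, d), cb, cfg$mlp_ratio)
      }
      if (blk < 3L)
        P <- init_linear(P, sprintf("%s.b%d.ex", br, blk), cb, no * (cb %/% 2L))
    }
    P <- init_linear(P, paste0(br, ".head"), C, cfg$patch_size^r)
  }
  P
}

init_disc_params <- function(cfg) {
  r <- cfg$spatial_rank; k3 <- 3L^r
  P <- list()
  cin <- 1L
  for (l in 1:4) {
    P <- init_linear(P, sprintf("c%d", l), cin * k3, cfg$disc_channels[l])
    cin <- cfg$disc_channels[l]
  }
  P
}

#' Build a trans-GAN model
#'
#' Creates generator and discriminator parameters for a fixed input shape.
#' The fully connected discriminator head is sized for `input_shape`, which
#' therefore also fixes the training crop size.
#'
#' @param config a [model_config()].
#' @param input_shape integer vector (length = `spatial_rank`) of the
#'   (preprocessed, cropped) input grid.
#' @param seed integer seed for weight initialisation.
#' @return a `transgan` model object.
#' @export
transgan <- function(config = model_config(), input_shape = c(64L, 64L), seed = 1L) {
  input_shape <- as.integer(input_shape)
  check_input_shape(config, input_shape)
  set.seed(seed)
  params <- init_generator_params(config)
  mk_disc <- function() {
    P <- init_disc_params(config)
    flat <- prod(input_shape %/% 16L) * config$disc_channels[4L]
    init_linear(P, "fc", flat, 1L)
  }
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$input_shape <- input_shape
  model$params <- params
  model$disc_params <- list(vnc = mk_disc(), iom = mk_disc())
  model$plans <- list()
  class(model) <- "transgan"
  model
}

#' @export
print.transgan <- function(x, ...) {
  cfg <- x$config
  np <- function(p) sum(vapply(p, length, 1))
  cat("trans-GAN generator (rank ", cfg$spatial_rank, ", patch ", cfg$patch_size,
      ", embed ", cfg$embed_dim, ", window ", cfg$window_size, ")\n",
      "  input shape: ", paste(x$input_shape, collapse = "x"), "\n",
      "  generator params: ", np(x$params), "\n",
      "  discriminator params: 2 x ", np(x$disc_params$vnc), "\n", sep = "")
  invisible(x)
}

## ---- tape-level forward passes ----

# prefix namespaces leaf (gradient) names when two parameter sets share a tape
leaves_for <- function(tape, params, prefix = "") {
  lv <- lapply(names(params), function(nm)
    ad_leaf(tape, params[[nm]], paste0(prefix, nm)))
  names(lv) <- paste0(prefix, names(params))
  lv
}

run_pairs <- function(x, leaves, prefix, ndepth, site, C, cfg) {
  for (d in seq_len(ndepth))
    x <- ad_attn_pair(x, leaves, sprintf("%s.p%d", prefix, d),
                      site$reg, site$sh, C)
  x
}

# Encoder: returns the four per-block feature nodes (after merge for 2-4).
gen_encode_tape <- function(tape, leaves, x, cfg, plan) {
  r <- cfg$spatial_rank; C <- cfg$embed_dim
  width <- function(lvl) C * 2L^(lvl - 1L)
  x <- ad_patch_merge(x, leaves, "embed", plan$embed_idx, plan$n_tok[1L],
                      1L, cfg$patch_size, r)
  x <- run_pairs(x, leaves, "enc1", cfg$encoder_depths[1L], plan$sites[[1L]], C, cfg)
  feats <- list(x)
  for (blk in 2:4) {
    lvl <- blk - 1L
    x <- run_pairs(x, leaves, sprintf("enc%d", blk), cfg$encoder_depths[blk],
                   plan$sites[[lvl]], width(lvl), cfg)
    x <- ad_patch_merge(x, leaves, sprintf("enc%d.mg", blk), plan$merge_idx[[lvl]],
                        plan$n_tok[lvl + 1L], width(lvl), 2L, r)
    feats[[blk]] <- x
  }
  feats
}

gen_bottleneck_tape <- function(tape, leaves, deepest, cfg, plan) {
  r <- cfg$spatial_rank
  w4 <- cfg$embed_dim * 8L
  x <- ad_attn_pair(deepest, leaves, "bot.p", plan$sites[[4L]]$reg,
                    plan$sites[[4L]]$sh, w4)
  ad_patch_expand(x, leaves, "bot.ex", plan$expand_idx[[3L]], plan$n_tok[4L],
                  w4 %/% 2L, 2L, r)
}

gen_decode_tape <- function(tape, leaves, z, feats, branch, cfg, plan) {
  r <- cfg$spatial_rank; C <- cfg$embed_dim
  width <- function(lvl) C * 2L^(lvl - 1L)
  for (blk in 1:3) {
    lvl <- 4L - blk                              # resolution level of this block
    cb <- width(lvl)
    if (cfg$use_skips) {
      z <- ad_cbind(z, feats[[lvl]])
      z <- ad_linear(z, leaves, sprintf("%s.b%d.fuse", branch, blk))
    }
    z <- run_pairs(z, leaves, sprintf("%s.b%d", branch, blk),
                   cfg$decoder_depths[blk], plan$sites[[lvl]], cb, cfg)
    if (blk < 3L)
      z <- ad_patch_expand(z, leaves, sprintf("%s.b%d.ex", branch, blk),
                           plan$expand_idx[[lvl - 1L]], plan$n_tok[lvl],
                           cb %/% 2L, 2L, r)
  }
  out <- ad_patch_expand(z, leaves, paste0(branch, ".head"), plan$head_idx,
                         plan$n_tok[1L], 1L, cfg$patch_size, r)
  ad_scale(out, 256)                             # head works in normalised units
}

gen_forward_tape <- function(tape, leaves, x, cfg, plan) {
  feats <- gen_encode_tape(tape, leaves, x, cfg, plan)
  z <- gen_bottleneck_tape(tape, leaves, feats[[4L]], cfg, plan)
  list(svnc = gen_decode_tape(tape, leaves, z, feats, "dvnc", cfg, plan),
       siom = gen_decode_tape(tape, leaves, z, feats, "diom", cfg, plan),
       feats = feats)
}

disc_forward_tape <- function(tape, leaves, x, cfg, plan, prefix = "") {
  r <- cfg$spatial_rank
  cin <- 1L
  for (l in 1:4) {
    x <- ad_conv(x, leaves, sprintf("%sc%d", prefix, l), plan$disc[[l]]$idx,
                 plan$disc[[l]]$n_out, cin, 3L, r)
    x <- ad_lrelu(x, 0.2)
    cin <- cfg$disc_channels[l]
  }
  n4 <- plan$disc_flat
  batch <- plan$batch
  x <- ad_reshape(x, c(n4, batch, cin))
  x <- ad_aperm(x, c(2L, 1L, 3L))
  x <- ad_reshape(x, c(batch, n4 * cin))
  ad_linear(x, leaves, paste0(prefix, "fc"))
}

## ---- user-facing inference ----

# Volumes (or lists of volumes) to a stacked (batch*npix, 1) matrix.
vols_to_matrix <- function(vols) {
  if (!is.list(vols)) vols <- list(vols)
  matrix(unlist(lapply(vols, as.vector), use.names = FALSE), ncol = 1L)
}

matrix_to_vols <- function(m, shape, batch) {
  npix <- prod(shape)
  lapply(seq_len(batch), function(s)
    array(m[((s - 1L) * npix + 1L):(s * npix), 1L], dim = shape))
}

#' Generate synthetic material decomposition images
#'
#' Runs the full generator (encoder, bottleneck, both decoders) on one or
#' more SECT inputs and returns the paired (sVNC, sIOM) predictions, each of
#' the same shape as its input.
#'
#' @param model a [transgan()] model.
#' @param sect a volume (array of the model's input shape, normalised
#'   intensities in \[0, 256\]) or a list of such volumes.
#' @return for a single input, `list(svnc =, siom =)` of arrays; for a list
#'   input, a list of such pairs.
#' @export
tg_generate <- function(model, sect) {
  single <- !is.list(sect)
  vols <- if (single) list(sect) else sect
  shape <- dim(vols[[1L]])
  plan <- get_plan(model, shape, length(vols))
  tape <- ad_tape()
  lv <- leaves_for(tape, model$params)
  x <- ad_const(tape, vols_to_matrix(vols) / 256)
  out <- gen_forward_tape(tape, lv, x, model$config, plan)
  sv <- matrix_to_vols(ad_value(out$svnc), shape, length(vols))
  si <- matrix_to_vols(ad_value(out$siom), shape, length(vols))
  res <- lapply(seq_along(vols), function(i) list(svnc = sv[[i]], siom = si[[i]]))
  if (single) res[[1L]] else res
}

#' Discriminator realness scores
#'
#' Scores one or more images with one of the two discriminators (four strided
#' convolutions and a fully connected head; one scalar logit per image).
#'
#' @param model a [transgan()] model.
#' @param image a volume of the model's input shape, or a list of volumes.
#' @param which `"vnc"` or `"iom"`.
#' @return numeric vector of logits (length = number of images).
#' @export
tg_discriminate <- function(model, image, which = c("vnc", "iom")) {
  which <- match.arg(which)
  single <- !is.list(image)
  vols <- if (single) list(image) else image
  shape <- dim(vols[[1L]])
  if (!identical(as.integer(shape), model$input_shape))
    stop("discriminator expects shape ", paste(model$input_shape, collapse = "x"))
  plan <- get_plan(model, shape, length(vols))
  tape <- ad_tape()
  lv <- leaves_for(tape, model$disc_params[[which]])
  x <- ad_const(tape, vols_to_matrix(vols) / 256)
  as.numeric(ad_value(disc_forward_tape(tape, lv, x, model$config, plan)))
}

#' Encoder feature pyramid
#'
#' Runs the four-block encoder alone and returns the hierarchical feature
#' grids (strictly decreasing resolution, doubling channels).
#'
#' @inheritParams tg_generate
#' @return list of 4 [feature_grid()] objects.
#' @export
tg_encode <- function(model, sect) {
  shape <- dim(sect)
  plan <- get_plan(model, shape, 1L)
  tape <- ad_tape()
  lv <- leaves_for(tape, model$params)
  x <- ad_const(tape, vols_to_matrix(sect) / 256)
  feats <- gen_encode_tape(tape, lv, x, model$config, plan)
  lapply(seq_along(feats), function(i)
    feature_grid(ad_value(feats[[i]]), plan$res[[i]]))
}

#' Sliding-window (tiled) generation
#'
#' Runs the generator over overlapping tiles of the training crop size and
#' averages the overlapping predictions — the standard way to apply a
#' crop-trained volumetric network to a full-size volume, keeping every
#' attention window at the grid sizes seen during training.
#'
#' @param model a [transgan()] model.
#' @param sect a volume at least as large as `tile` per axis.
#' @param tile tile shape (defaults to the model's training input shape).
#' @param stride step between tile origins (defaults to half the tile).
#' @return `list(svnc =, siom =)` volumes of the input shape.
#' @export
tg_generate_tiled <- function(model, sect, tile = model$input_shape,
                              stride = tile %/% 2L) {
  shape <- dim(sect)
  r <- length(shape)
  tile <- as.integer(rep(tile, length.out = r))
  stride <- as.integer(rep(stride, length.out = r))
  if (any(tile > shape)) stop("tile larger than volume")
  offs <- lapply(seq_len(r), function(d) {
    o <- seq(0L, shape[d] - tile[d], by = stride[d])
    unique(c(o, shape[d] - tile[d]))      # always cover the far edge
  })
  grid <- as.matrix(expand.grid(offs))
  tiles <- lapply(seq_len(nrow(grid)), function(i) {
    idx <- lapply(seq_len(r), function(d) grid[i, d] + seq_len(tile[d]))
    array(do.call(`[`, c(list(sect), idx, list(drop = FALSE))), dim = tile)
  })
  preds <- tg_generate(model, tiles)
  acc_v <- acc_i <- array(0, dim = shape)
  cnt <- array(0, dim = shape)
  one <- array(1, dim = tile)
  for (i in seq_len(nrow(grid))) {
    idx <- lapply(seq_len(r), function(d) grid[i, d] + seq_len(tile[d]))
    add <- function(a, v) do.call(`[<-`, c(list(a), idx, list(
      value = do.call(`[`, c(list(a), idx, list(drop = FALSE))) + v)))
    acc_v <- add(acc_v, preds[[i]]$svnc)
    acc_i <- add(acc_i, preds[[i]]$siom)
    cnt <- add(cnt, one)
  }
  list(svnc = acc_v / cnt, siom = acc_i / cnt)
}

#' Bottleneck transform of the deepest encoder grid
#'
#' One attention pair at the deepest resolution followed by a patch
#' expansion (doubled resolution, halved channels), using the model's
#' bottleneck parameters.
#'
#' @param model a [transgan()] model.
#' @param deepest the fourth grid from [tg_encode()].
#' @return a [feature_grid()].
#' @export
tg_bottleneck <- function(model, deepest) {
  shape <- deepest$spatial * model$config$patch_size * 8L
  plan <- get_plan(model, shape, 1L)
  tape <- ad_tape()
  lv <- leaves_for(tape, model$params)
  x <- ad_const(tape, deepest$values)
  out <- gen_bottleneck_tape(tape, lv, x, model$config, plan)
  feature_grid(ad_value(out), deepest$spatial * 2L)
}

#' Decode one branch from the bottleneck output
#'
#' Runs the three cascaded decoder blocks of the requested branch (skip
#' fusion with the encoder pyramid, attention pairs, patch expansion) and
#' the final patch-size expansion with the one-channel linear head.
#'
#' @param model a [transgan()] model.
#' @param bottleneck_out the [tg_bottleneck()] output grid.
#' @param pyramid the encoder pyramid from [tg_encode()].
#' @param branch `"vnc"` or `"iom"`.
#' @return a volume of the generator input shape.
#' @export
tg_decode_branch <- function(model, bottleneck_out, pyramid,
                             branch = c("vnc", "iom")) {
  branch <- match.arg(branch)
  shape <- bottleneck_out$spatial * model$config$patch_size * 4L
  plan <- get_plan(model, shape, 1L)
  tape <- ad_tape()
  lv <- leaves_for(tape, model$params)
  feats <- lapply(pyramid, function(g) ad_const(tape, g$values))
  z <- ad_const(tape, bottleneck_out$values)
  out <- gen_decode_tape(tape, lv, z, feats,
                         if (branch == "vnc") "dvnc" else "diom",
                         model$config, plan)
  matrix_to_vols(ad_value(out), shape, 1L)[[1L]]
}

## ---- standalone feature-grid operations (unit-testable primitives) ----

#' Feature grid container
#'
#' A spatial grid of feature vectors: `values` is a (tokens x channels)
#' matrix with tokens in column-major grid order; `spatial` the grid shape.
#'
#' @param values numeric matrix (prod(spatial) rows).
#' @param spatial integer vector of grid dimensions.
#' @return a `feature_grid`.
#' @export
feature_grid <- function(values, spatial) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == prod(spatial))
  structure(list(values = values, spatial = as.integer(spatial),
                 channels = ncol(values)), class = "feature_grid")
}

#' @export
print.feature_grid <- function(x, ...) {
  cat("feature_grid ", paste(x$spatial, collapse = "x"), " x ", x$channels,
      " channels\n", sep = "")
  invisible(x)
}

with_seeded_params <- function(seed, build, run) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  P <- build()
  tape <- ad_tape()
  run(tape, leaves_for(tape, P))
}

#' Patch embedding of a volume into a feature grid
#'
#' Partitions the volume into non-overlapping `p`-patches and applies a
#' learned linear embedding to `C` channels (weights drawn from `seed`).
#'
#' @param volume numeric array, each dimension divisible by `p`.
#' @param p patch edge length.
#' @param C embedding width.
#' @param seed seed for the embedding weights.
#' @return a [feature_grid()] with spatial shape `dim(volume)/p`.
#' @export
patch_embed <- function(volume, p, C, seed = 1L) {
  shape <- dim(volume)
  if (any(shape %% p != 0L)) stop("volume dimensions must be divisible by p")
  r <- length(shape)
  gi <- group_index(shape, p)
  out <- with_seeded_params(seed,
    function() init_linear(list(), "w", p^r, C),
    function(tape, lv) {
      x <- ad_const(tape, vols_to_matrix(volume))
      ad_value(ad_patch_merge(x, lv, "w", gi, prod(shape %/% p), 1L, p, r))
    })
  feature_grid(out, shape %/% p)
}

#' Patch merging (downsample a feature grid)
#'
#' Concatenates each 2^rank neighbourhood along channels and linearly reduces
#' to twice the input width, halving every spatial dimension.
#'
#' @param grid a [feature_grid()] with even spatial dimensions.
#' @param seed seed for the reduction weights.
#' @return a [feature_grid()].
#' @export
patch_merge <- function(grid, seed = 1L) {
  if (any(grid$spatial %% 2L != 0L)) stop("spatial dimensions must be even")
  r <- length(grid$spatial); C <- grid$channels
  gi <- group_index(grid$spatial, 2L)
  out <- with_seeded_params(seed,
    function() init_linear(list(), "w", C * 2L^r, 2L * C),
    function(tape, lv) {
      x <- ad_const(tape, grid$values)
      ad_value(ad_patch_merge(x, lv, "w", gi, prod(grid$spatial %/% 2L), C, 2L, r))
    })
  feature_grid(out, grid$spatial %/% 2L)
}

#' Patch expansion (upsample a feature grid)
#'
#' Linear up-projection then rearrangement to a grid of doubled resolution
#' and halved channel width.
#'
#' @param grid a [feature_grid()] with even channel count.
#' @param seed seed for the projection weights.
#' @return a [feature_grid()].
#' @export
patch_expand <- function(grid, seed = 1L) {
  if (grid$channels %% 2L != 0L) stop("channel count must be even")
  r <- length(grid$spatial); C <- grid$channels
  fine <- grid$spatial * 2L
  ui <- ungroup_index(fine, 2L)
  out <- with_seeded_params(seed,
    function() init_linear(list(), "w", C, 2L^r * (C %/% 2L)),
    function(tape, lv) {
      x <- ad_const(tape, grid$values)
      ad_value(ad_patch_expand(x, lv, "w", ui, prod(grid$spatial), C %/% 2L, 2L, r))
    })
  feature_grid(out, fine)
}

#' Windowed self-attention pair on a feature grid
#'
#' Two successive pre-norm windowed multi-head self-attention blocks with
#' residual connections and feed-forward expansions; the second block uses
#' cyclically shifted windows (disable with `shift_second = FALSE` to keep
#' strict window locality).
#'
#' @param grid a [feature_grid()].
#' @param heads attention heads (must divide the channel count).
#' @param window_size window edge length (clamped to the grid if larger).
#' @param shift_second shift the second block's windows by half a window.
#' @param seed seed for the block weights.
#' @return a [feature_grid()] of identical shape.
#' @export
attention_pair <- function(grid, heads, window_size, shift_second = TRUE, seed = 1L) {
  C <- grid$channels
  if (C %% heads != 0L) stop("channels must be divisible by heads")
  s_reg <- attn_site(grid$spatial, as.integer(window_size), FALSE, 1L, heads)
  s_sh <- if (shift_second)
    attn_site(grid$spatial, as.integer(window_size), TRUE, 1L, heads)
  else s_reg
  out <- with_seeded_params(seed,
    function() init_attention_block(init_attention_block(list(), ".a", C), ".b", C),
    function(tape, lv) {
      x <- ad_const(tape, grid$values)
      ad_value(ad_attn_pair(x, lv, "", s_reg, s_sh, C))
    })
  feature_grid(out, grid$spatial)
}
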