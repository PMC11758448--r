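# Index plans and neural building blocks for the windowed-transformer
# generator and the convolutional discriminators.
#
# All token/pixel tensors are stored as (rows = voxels or tokens, cols =
# channels) matrices with rows in column-major grid order, samples of a batch
# stacked. Spatial reorganisations (window partitioning, patch merge/expand,
# im2col) are precomputed integer gathers so the tape only ever sees row
# gathers, reshapes and dimension permutations.

## ---- integer index builders (0-based coords, 1-based linear indices) ----

grid_coords <- function(shape) {
  as.matrix(expand.grid(lapply(shape, function(n) 0:(n - 1L))))
}

lin_index <- function(coords, shape) {
  strides <- cumprod(c(1L, shape[-length(shape)]))
  as.integer(coords %*% strides) + 1L
}

# Rows ordered (coarse token outer, child offset inner); gathering with this
# index groups each f^rank block of the fine grid into consecutive rows.
group_index <- function(shape, f) {
  r <- length(shape)
  coarse <- grid_coords(shape %/% f)
  off <- grid_coords(rep(f, r))
  nc <- nrow(coarse); no <- nrow(off)
  fine <- coarse[rep(seq_len(nc), each = no), , drop = FALSE] * f +
    off[rep(seq_len(no), times = nc), , drop = FALSE]
  lin_index(fine, shape)
}

# For each fine-grid token (column-major), the row it occupies in the
# (coarse, child) ordering produced by patch expansion.
ungroup_index <- function(shape, f) {
  r <- length(shape)
  fine <- grid_coords(shape)
  tl <- lin_index(fine %/% f, shape %/% f)
  jl <- lin_index(fine %% f, rep(f, r))
  no <- f^r
  (tl - 1L) * no + jl
}

# Window-major gather for (optionally cyclically shifted) window attention.
window_index <- function(shape, w, shift = 0L) {
  r <- length(shape)
  wg <- shape %/% w
  wins <- grid_coords(wg)
  pos <- grid_coords(rep(w, r))
  nw <- nrow(wins); np <- nrow(pos)
  cc <- wins[rep(seq_len(nw), each = np), , drop = FALSE] * w +
    pos[rep(seq_len(np), times = nw), , drop = FALSE]
  src <- sweep(cc, 2L, rep(shift, length.out = r), "-") %% rep(shape, each = nrow(cc))
  lin_index(src, shape)
}

inverse_perm <- function(idx) {
  inv <- integer(length(idx))
  inv[idx] <- seq_along(idx)
  inv
}

# im2col gather: rows ordered (output position outer, kernel offset inner);
# index 0 marks zero padding.
conv_index <- function(shape, k, stride, pad) {
  r <- length(shape)
  out_shape <- (shape + 2L * pad - k) %/% stride + 1L
  outs <- grid_coords(out_shape)
  off <- grid_coords(rep(k, r))
  no <- nrow(outs); nf <- nrow(off)
  cc <- outs[rep(seq_len(no), each = nf), , drop = FALSE] * stride - pad +
    off[rep(seq_len(nf), times = no), , drop = FALSE]
  inside <- rowSums(cc >= 0 & cc < rep(shape, each = nrow(cc))) == r
  idx <- integer(nrow(cc))
  idx[inside] <- lin_index(cc[inside, , drop = FALSE], shape)
  list(idx = idx, out_shape = out_shape)
}

rep_batch_index <- function(idx, ntok, batch) {
  if (batch == 1L) return(idx)
  out <- integer(length(idx) * batch)
  for (s in seq_len(batch)) {
    piece <- idx
    piece[piece > 0L] <- piece[piece > 0L] + (s - 1L) * ntok
    out[((s - 1L) * length(idx) + 1L):(s * length(idx))] <- piece
  }
  out
}

## ---- parameter initialisation ----

init_linear <- function(params, name, fin, fout, sd = 0.02) {
  params[[paste0(name, ".W")]] <- matrix(stats::rnorm(fin * fout, 0, sd), fin, fout)
  params[[paste0(name, ".b")]] <- numeric(fout)
  params
}

init_layernorm <- function(params, name, C) {
  params[[paste0(name, ".g")]] <- rep(1, C)
  params[[paste0(name, ".B")]] <- numeric(C)
  params
}

init_attention_block <- function(params, name, C, mlp_ratio = 4L) {
  params <- init_layernorm(params, paste0(name, ".ln1"), C)
  for (w in c("q", "k", "v", "o")) params <- init_linear(params, paste0(name, ".", w), C, C)
  params <- init_layernorm(params, paste0(name, ".ln2"), C)
  params <- init_linear(params, paste0(name, ".m1"), C, C * mlp_ratio)
  init_linear(params, paste0(name, ".m2"), C * mlp_ratio, C)
}

## ---- tape-level building blocks ----

ad_linear <- function(x, leaves, name) {
  ad_add_bias(ad_matmul(x, leaves[[paste0(name, ".W")]]), leaves[[paste0(name, ".b")]])
}

ad_ln <- function(x, leaves, name) {
  ad_layernorm(x, leaves[[paste0(name, ".g")]], leaves[[paste0(name, ".B")]])
}

# One windowed multi-head self-attention + MLP block (pre-norm, residual).
# site: list(idx, inv, w_tokens, slices, heads) from the shape plan.
ad_attn_block <- function(x, leaves, name, site, C) {
  h <- ad_ln(x, leaves, paste0(name, ".ln1"))
  hg <- ad_gather_rows(h, site$idx, perm = TRUE)
  heads <- site$heads
  d <- C %/% heads
  wt <- site$w_tokens
  nb <- site$nwb   # windows x batch
  Q <- ad_to_cube(ad_linear(hg, leaves, paste0(name, ".q")), wt, nb, d, heads)
  K <- ad_to_cube(ad_linear(hg, leaves, paste0(name, ".k")), wt, nb, d, heads)
  V <- ad_to_cube(ad_linear(hg, leaves, paste0(name, ".v")), wt, nb, d, heads)
  O <- ad_attention(Q, K, V, 1 / sqrt(d))
  O <- ad_from_cube(O, wt, nb, d, heads)
  O <- ad_linear(O, leaves, paste0(name, ".o"))
  O <- ad_gather_rows(O, site$inv, perm = TRUE)
  x <- ad_add(x, O)
  h <- ad_ln(x, leaves, paste0(name, ".ln2"))
  h <- ad_gelu(ad_linear(h, leaves, paste0(name, ".m1")))
  h <- ad_linear(h, leaves, paste0(name, ".m2"))
  ad_add(x, h)
}

# Two successive attention blocks, the second over shifted windows.
ad_attn_pair <- function(x, leaves, name, site_reg, site_shift, C) {
  x <- ad_attn_block(x, leaves, paste0(name, ".a"), site_reg, C)
  ad_attn_block(x, leaves, paste0(name, ".b"), site_shift, C)
}

# Patch merge / embed: concat f^rank neighbours along channels, then linear.
ad_patch_merge <- function(x, leaves, name, midx, n_coarse, cin, f, rank) {
  no <- f^rank
  y <- ad_gather_rows(x, midx, perm = TRUE)
  y <- ad_reshape(y, c(no, n_coarse, cin))
  y <- ad_aperm(y, c(2L, 3L, 1L))
  y <- ad_reshape(y, c(n_coarse, cin * no))
  ad_linear(y, leaves, name)
}

# Patch expand: linear up-projection then redistribute channels to a
# factor-f finer grid. Output channels = cout per fine token.
ad_patch_expand <- function(x, leaves, name, uidx, n_coarse, cout, f, rank) {
  no <- f^rank
  y <- ad_linear(x, leaves, name)            # (n_coarse, no*cout)
  y <- ad_reshape(y, c(n_coarse, cout, no))
  y <- ad_aperm(y, c(3L, 1L, 2L))
  y <- ad_reshape(y, c(no * n_coarse, cout))
  ad_gather_rows(y, uidx, perm = TRUE)
}

# Strided convolution layer via im2col gather; weights laid out
# (channels fastest, kernel offset next) x cout.
ad_conv <- function(x, leaves, name, cidx, n_out, cin, k, rank) {
  nf <- k^rank
  y <- ad_gather_rows(x, cidx)
  y <- ad_reshape(y, c(nf, n_out, cin))
  y <- ad_aperm(y, c(2L, 3L, 1L))
  y <- ad_reshape(y, c(n_out, cin * nf))
  ad_linear(y, leaves, name)
}
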