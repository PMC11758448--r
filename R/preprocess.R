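# Preprocessing: resampling to isotropic spacing, min-max normalization to
# [0, 256], center crop/pad to a fixed grid, synchronized random cropping
# and flip/right-angle rotation augmentation.

#' Preprocessing specification
#'
#' @param target_spacing mm per voxel after resampling (default isotropic 1).
#' @param target_grid grid size after center crop/pad (default 256x256x128
#'   at full scale; set to the phantom grid at desk scale).
#' @param crop_size training crop per axis (default 96^3 at full scale).
#' @param norm_range ascending intensity pair, default \[0, 256\].
#' @param augment_flags named logical vector with `flip` and `rotate`.
#' @param seed integer seed for the random crop/augmentation stream.
#' @return a `preproc_spec` list.
#' @export
preproc_spec <- function(target_spacing = c(1, 1, 1),
                         target_grid = c(256L, 256L, 128L),
                         crop_size = c(96L, 96L, 96L),
                         norm_range = c(0, 256),
                         augment_flags = c(flip = TRUE, rotate = TRUE),
                         seed = 1L) {
  stopifnot(all(crop_size <= target_grid), norm_range[2L] > norm_range[1L])
  structure(list(target_spacing = target_spacing,
                 target_grid = as.integer(target_grid),
                 crop_size = as.integer(crop_size),
                 norm_range = norm_range, augment_flags = augment_flags,
                 seed = as.integer(seed)), class = "preproc_spec")
}

# n-linear interpolation of `vol` at fractional 0-based voxel coordinates.
interp_linear <- function(vol, coords) {
  shape <- dim(vol)
  r <- length(shape)
  f <- floor(coords)
  w <- coords - f
  out <- numeric(nrow(coords))
  corners <- grid_coords(rep(2L, r))
  for (ci in seq_len(nrow(corners))) {
    off <- corners[ci, ]
    idx <- sweep(f, 2L, off, "+")
    idx <- pmin(pmax(idx, 0), rep(shape - 1L, each = nrow(idx)))
    wt <- rep(1, nrow(coords))
    for (d in seq_len(r)) wt <- wt * if (off[d] == 1L) w[, d] else 1 - w[, d]
    out <- out + wt * vol[lin_index(idx, shape)]
  }
  out
}

#' Resample a volume to a target voxel spacing
#'
#' Trilinear (n-linear) interpolation; the physical extent is preserved to
#' within one voxel. Use `method = "nearest"` for label volumes.
#'
#' @param volume numeric array.
#' @param spacing current mm per voxel.
#' @param target_spacing desired mm per voxel.
#' @param method `"linear"` or `"nearest"`.
#' @return resampled array with attribute `spacing`.
#' @export
resample_volume <- function(volume, spacing, target_spacing,
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (any(spacing <= 0) || any(target_spacing <= 0))
    stop("voxel spacings must be positive")
  shape <- dim(volume)
  out_shape <- as.integer(round(shape * spacing / target_spacing))
  out_shape <- pmax(out_shape, 1L)
  cc <- grid_coords(out_shape)
  src <- sweep(cc, 2L, target_spacing / spacing, "*")
  vals <- if (method == "linear") interp_linear(volume, src)
  else {
    idx <- pmin(pmax(round(src), 0), rep(shape - 1L, each = nrow(src)))
    volume[lin_index(idx, shape)]
  }
  out <- array(vals, dim = out_shape)
  attr(out, "spacing") <- target_spacing
  out
}

#' Min-max normalize a volume
#'
#' Affine map of the volume minimum to `norm_range[1]` and maximum to
#' `norm_range[2]` (defaults \[0, 256\]). Idempotent on already-normalized
#' volumes; a constant volume is an error (degenerate range).
#'
#' @param volume numeric array.
#' @param norm_range ascending pair.
#' @return normalized array.
#' @export
normalize_minmax <- function(volume, norm_range = c(0, 256)) {
  lo <- min(volume); hi <- max(volume)
  if (hi <= lo) stop("constant volume: min-max normalization is degenerate")
  norm_range[1L] + (volume - lo) / (hi - lo) * (norm_range[2L] - norm_range[1L])
}

#' Center crop and/or zero-pad a volume to a target grid
#'
#' @param volume numeric array.
#' @param target_grid integer target shape.
#' @return array of shape `target_grid` with attributes `crop_offset` and
#'   `pad_offset` (0-based, per axis) for inverse mapping.
#' @export
fit_to_grid <- function(volume, target_grid) {
  shape <- dim(volume)
  r <- length(shape)
  crop_off <- pmax((shape - target_grid) %/% 2L, 0L)
  pad_off <- pmax((target_grid - shape) %/% 2L, 0L)
  keep <- pmin(shape, target_grid)
  idx <- lapply(seq_len(r), function(d) crop_off[d] + seq_len(keep[d]))
  cropped <- do.call(`[`, c(list(volume), idx, list(drop = FALSE)))
  out <- array(0, dim = target_grid)
  place <- lapply(seq_len(r), function(d) pad_off[d] + seq_len(keep[d]))
  ins <- function(a, idx, value) do.call(`[<-`, c(list(a), idx, list(value = value)))
  out <- ins(out, place, cropped)
  attr(out, "crop_offset") <- as.integer(crop_off)
  attr(out, "pad_offset") <- as.integer(pad_off)
  out
}

case_volumes <- c("sect", "vnc", "iom")

apply_to_case <- function(case, f_vol, f_int) {
  for (nm in case_volumes) case[[nm]] <- f_vol(case[[nm]])
  case$lesion_mask <- f_int(case$lesion_mask)
  if (!is.null(case$brain)) case$brain <- f_int(case$brain)
  case
}

#' Synchronized random crop of a paired case
#'
#' One offset is drawn uniformly and applied identically to SECT, VNC, IOM,
#' the lesion mask and the brain mask, so the forward-model identity is
#' preserved on the crop.
#'
#' @param case a `paired_case`.
#' @param crop_size integer crop per axis (must not exceed the case shape).
#' @param offset optional explicit 0-based offset (for replay); drawn
#'   uniformly when `NULL`.
#' @return the cropped `paired_case` (attribute `crop_offset` records the
#'   offset used).
#' @export
random_crop <- function(case, crop_size, offset = NULL) {
  shape <- dim(case$sect)
  crop_size <- as.integer(rep(crop_size, length.out = length(shape)))
  if (any(crop_size > shape)) stop("crop larger than volume")
  if (is.null(offset))
    offset <- vapply(shape - crop_size, function(m) sample.int(m + 1L, 1L) - 1L, 1L)
  idx <- lapply(seq_along(shape), function(d) offset[d] + seq_len(crop_size[d]))
  sub <- function(v) {
    out <- do.call(`[`, c(list(v), idx, list(drop = FALSE)))
    array(out, dim = crop_size)
  }
  case <- apply_to_case(case, sub, sub)
  attr(case, "crop_offset") <- as.integer(offset)
  case
}

flip_lr <- function(v) {
  idx <- c(list(rev(seq_len(dim(v)[1L]))),
           lapply(dim(v)[-1L], seq_len), list(drop = FALSE))
  array(do.call(`[`, c(list(v), idx)), dim = dim(v))
}

# k * 90-degree rotation in the first two (axial in-plane) dimensions
rot90_axial <- function(v, k) {
  k <- k %% 4L
  if (k == 0L) return(v)
  for (i in seq_len(k)) {
    perm <- seq_along(dim(v)); perm[1:2] <- c(2L, 1L)
    v <- aperm(v, perm)
    v <- flip_lr(v)
  }
  v
}

#' Flip / rotation augmentation of a paired case
#'
#' Applies a left-right flip and/or an axial in-plane rotation by a multiple
#' of 90 degrees identically to all volumes and masks. The case label is
#' invariant. With `flip`/`quarter_turns` `NULL` the choices are random.
#'
#' @param case a `paired_case`.
#' @param flags named logical vector enabling `flip` and `rotate`.
#' @param flip logical; force/suppress the flip (random if `NULL`).
#' @param quarter_turns integer 0-3; rotation amount (random if `NULL`).
#' @return the augmented `paired_case`.
#' @export
augment_case <- function(case, flags = c(flip = TRUE, rotate = TRUE),
                         flip = NULL, quarter_turns = NULL) {
  do_flip <- if (!isTRUE(flags[["flip"]])) FALSE
  else if (is.null(flip)) stats::runif(1) < 0.5 else flip
  turns <- if (!isTRUE(flags[["rotate"]])) 0L
  else if (is.null(quarter_turns)) sample(0:3, 1L) else as.integer(quarter_turns)
  # right-angle rotations require square axial dimensions
  if (turns %% 2L == 1L && dim(case$sect)[1L] != dim(case$sect)[2L])
    turns <- (turns + 1L) %% 4L
  f <- function(v) rot90_axial(if (do_flip) flip_lr(v) else v, turns)
  apply_to_case(case, f, f)
}

#' Preprocess a paired case for training/inference
#'
#' Resamples all volumes to the target spacing (nearest-neighbour for the
#' masks), fits to the target grid, and optionally min-max normalizes the
#' SECT (the VNC/IOM targets are left on the common intensity scale so the
#' material forward model stays linear).
#'
#' @param case a `paired_case`.
#' @param spec a [preproc_spec()].
#' @param normalize min-max normalize the SECT input.
#' @return the preprocessed `paired_case`.
#' @export
preprocess_case <- function(case, spec, normalize = FALSE) {
  sp <- case$spacing
  if (!isTRUE(all.equal(as.numeric(sp), as.numeric(spec$target_spacing)))) {
    rs_lin <- function(v) resample_volume(v, sp, spec$target_spacing, "linear")
    rs_nn <- function(v) {
      out <- resample_volume(v * 1.0, sp, spec$target_spacing, "nearest")
      array(as.integer(out), dim = dim(out))
    }
    case <- apply_to_case(case, rs_lin, rs_nn)
    case$spacing <- spec$target_spacing
  }
  if (!identical(dim(case$sect), as.integer(spec$target_grid))) {
    ft <- function(v) fit_to_grid(v, spec$target_grid)
    fti <- function(v) array(as.integer(ft(v * 1.0)), dim = spec$target_grid)
    case <- apply_to_case(case, ft, fti)
  }
  if (normalize) case$sect <- normalize_minmax(case$sect, spec$norm_range)
  case
}
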