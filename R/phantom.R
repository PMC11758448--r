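# Digital DECT phantom: paired (SECT, VNC, IOM) cases from a linearized
# three-material forward model, SECT = blur(VNC + k * IOM) + noise.
#
# The phantom encodes the clinical premise of post-thrombectomy imaging:
# focal hyperdensities caused by blood (hemorrhage, ICH) and by retained
# iodinated contrast (contrast staining, CS) are drawn from overlapping
# added-intensity ranges, so they cannot be separated by SECT attenuation
# alone, but they are separable on the material decomposition images because
# blood lives on the VNC and iodine on the IOM. Hemorrhages additionally
# carry internal texture while contrast staining is homogeneous with
# feathered margins, mirroring the heterogeneous appearance of acute
# hematomas versus the smooth distribution of extravasated contrast; this is
# the (realistic) cue a decomposition network can exploit.

#' Phantom configuration
#'
#' Intensities are kept in the normalized \[0, 256\] range used throughout
#' the pipeline.
#'
#' @param grid_shape integer vector (length 2 or 3) of voxels per axis.
#' @param voxel_spacing mm per voxel, same length as `grid_shape`.
#' @param background_mean,background_sd mean and textural standard deviation
#'   of the brain background on the VNC (normalized units).
#' @param lesion_count_range integer pair, lesions per case (inclusive).
#' @param class_prevalence probability a case is ICH-positive (default 0.32,
#'   the hemorrhage proportion typical of post-thrombectomy hyperdensity
#'   cohorts).
#' @param blood_range added VNC intensity of a hemorrhage (normalized units).
#' @param iodine_range IOM intensity of contrast staining; the default sits
#'   slightly above the blood range to offset the margin feathering of
#'   staining, so the SECT-elevation distributions of the two classes
#'   overlap and an intensity threshold cannot separate them.
#' @param mixing_k dimensionless iodine-to-SECT attenuation scale k in
#'   SECT = VNC + k * IOM.
#' @param noise_sd Gaussian noise added to the SECT (normalized units).
#' @param blur_sigma point-spread blur of the SECT (voxels).
#' @param radius_range lesion semi-axis range (voxels).
#' @param blood_texture_sd internal speckle amplitude of hemorrhages
#'   (normalized units).
#' @param texture_scale correlation length of the textures (voxels); the
#'   default keeps hematoma speckle fine-grained so heterogeneity is visible
#'   locally.
#' @param iodine_edge_sigma margin feathering of contrast staining (voxels).
#' @param brain_edge_sigma feathering of the parenchyma boundary (voxels).
#' @param mixed_prob probability that the index lesion of an ICH-positive
#'   case also stains (kind MIXED: blood plus iodine).
#' @param seed default seed for case generation.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L),
                           voxel_spacing = rep(1, length(grid_shape)),
                           background_mean = 100, background_sd = 3,
                           lesion_count_range = c(1L, 2L),
                           class_prevalence = 0.32,
                           blood_range = c(40, 90),
                           iodine_range = c(45, 100),
                           mixing_k = 1.0,
                           noise_sd = 5, blur_sigma = 0.6,
                           radius_range = c(5, 10),
                           blood_texture_sd = 45, texture_scale = 1.2,
                           iodine_edge_sigma = 2,
                           brain_edge_sigma = 1.2,
                           mixed_prob = 0.15,
                           seed = 1L) {
  stopifnot(length(grid_shape) %in% c(2L, 3L),
            length(voxel_spacing) == length(grid_shape),
            diff(range(blood_range)) > 0, diff(range(iodine_range)) > 0,
            lesion_count_range[1L] >= 1L,
            lesion_count_range[2L] >= lesion_count_range[1L],
            class_prevalence > 0, class_prevalence < 1,
            mixing_k > 0, noise_sd >= 0, blur_sigma >= 0,
            radius_range[1L] > 0, diff(range(radius_range)) > 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 background_mean = background_mean, background_sd = background_sd,
                 lesion_count_range = as.integer(lesion_count_range),
                 class_prevalence = class_prevalence,
                 blood_range = blood_range, iodine_range = iodine_range,
                 mixing_k = mixing_k, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, radius_range = radius_range,
                 blood_texture_sd = blood_texture_sd,
                 texture_scale = texture_scale,
                 iodine_edge_sigma = iodine_edge_sigma,
                 brain_edge_sigma = brain_edge_sigma,
                 mixed_prob = mixed_prob, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Lesion specification
#'
#' @param center voxel coordinates of the ellipsoid center.
#' @param radii semi-axes in voxels.
#' @param kind `"ICH"`, `"CS"` or `"MIXED"`.
#' @param blood_intensity VNC intensity added by blood (> 0 unless CS).
#' @param iodine_intensity IOM intensity (> 0 unless ICH).
#' @return a `lesion_spec`.
#' @export
lesion_spec <- function(center, radii, kind, blood_intensity, iodine_intensity) {
  kind <- match.arg(kind, c("ICH", "CS", "MIXED"))
  ok <- switch(kind,
               ICH = iodine_intensity == 0 && blood_intensity > 0,
               CS = blood_intensity == 0 && iodine_intensity > 0,
               MIXED = blood_intensity > 0 && iodine_intensity > 0)
  if (!ok) stop("intensities inconsistent with lesion kind ", kind)
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 kind = kind, blood_intensity = blood_intensity,
                 iodine_intensity = iodine_intensity), class = "lesion_spec")
}

# Brain = centered ellipsoid with semi-axes 0.42 * grid.
brain_geometry <- function(shape) {
  list(center = (shape - 1) / 2, semi = 0.42 * shape)
}

brain_mask <- function(shape) {
  geo <- brain_geometry(shape)
  cc <- grid_coords(shape)
  d <- sweep(cc, 2L, geo$center, "-")
  d <- sweep(d, 2L, geo$semi, "/")
  array(rowSums(d * d) <= 1, dim = shape)
}

# Separable Gaussian blur with replicate edges (exact identity at sigma 0).
gaussian_blur <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  shape <- dim(vol)
  rad <- max(1L, ceiling(3 * sigma))
  ker <- stats::dnorm(-rad:rad, sd = sigma)
  ker <- ker / sum(ker)
  for (d in seq_along(shape)) {
    n <- shape[d]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      js <- pmin(pmax(i + (-rad:rad), 1L), n)
      for (t in seq_along(js)) K[i, js[t]] <- K[i, js[t]] + ker[t]
    }
    perm <- c(d, seq_along(shape)[-d])
    v <- aperm(vol, perm)
    dv <- dim(v)
    v <- K %*% matrix(v, nrow = n)
    dim(v) <- dv
    vol <- aperm(v, order(perm))
  }
  vol
}

# Smooth Gaussian random field with unit variance.
smooth_noise <- function(shape, scale) {
  z <- array(stats::rnorm(prod(shape)), dim = shape)
  if (scale > 0) z <- gaussian_blur(z, scale)
  z / stats::sd(z)
}

ellipsoid_inside_brain <- function(center, radii, shape) {
  geo <- brain_geometry(shape)
  # sufficient criterion: the lesion's bounding sphere-scaled extremes lie in
  # the brain ellipsoid (conservative axis-aligned check)
  d <- abs(center - geo$center) + radii
  sum((d / geo$semi)^2) <= 1
}

#' Sample lesion specifications for one case
#'
#' Draws the case class (ICH-positive with probability `class_prevalence`),
#' a lesion count within `lesion_count_range`, and per-lesion geometry and
#' material intensities. An ICH-positive case carries at least one lesion of
#' kind ICH (or MIXED with probability `mixed_prob`); remaining lesions and
#' all lesions of negative cases are contrast staining.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return list of [lesion_spec()]s.
#' @export
sample_lesions <- function(config, seed = config$seed) {
  set.seed(seed)
  shape <- config$grid_shape
  positive <- stats::runif(1) < config$class_prevalence
  n <- sample(seq(config$lesion_count_range[1L], config$lesion_count_range[2L]), 1L)
  draw_geom <- function() {
    for (try in 1:200) {
      radii <- stats::runif(length(shape), config$radius_range[1L],
                            config$radius_range[2L])
      geo <- brain_geometry(shape)
      center <- geo$center + (stats::runif(length(shape), -1, 1) *
                                (geo$semi - radii))
      if (ellipsoid_inside_brain(center, radii, shape))
        return(list(center = center, radii = radii))
    }
    stop("could not place lesion inside the brain mask after bounded retries")
  }
  lesions <- vector("list", n)
  for (i in seq_len(n)) {
    g <- draw_geom()
    if (positive && i == 1L) {
      kind <- if (stats::runif(1) < config$mixed_prob) "MIXED" else "ICH"
    } else {
      kind <- "CS"
    }
    blood <- if (kind %in% c("ICH", "MIXED"))
      stats::runif(1, config$blood_range[1L], config$blood_range[2L]) else 0
    iodine <- if (kind %in% c("CS", "MIXED"))
      stats::runif(1, config$iodine_range[1L], config$iodine_range[2L]) else 0
    lesions[[i]] <- lesion_spec(g$center, g$radii, kind, blood, iodine)
  }
  lesions
}

ellipsoid_indicator <- function(center, radii, shape) {
  cc <- grid_coords(shape)
  d <- sweep(cc, 2L, center, "-")
  d <- sweep(d, 2L, radii, "/")
  array(rowSums(d * d) <= 1, dim = shape)
}

#' Render a paired (SECT, VNC, IOM) case
#'
#' VNC = textured brain background plus blood contributions; IOM = iodine
#' contributions on a zero background; SECT = blur(VNC + k * IOM) plus
#' Gaussian noise, clipped to nonnegative intensities. With `noise_sd = 0`
#' and `blur_sigma = 0` the forward-model identity SECT = VNC + k * IOM
#' holds voxel-exactly.
#'
#' @param lesions list of [lesion_spec()]s (see [sample_lesions()]).
#' @param config a [phantom_config()].
#' @param seed integer seed (rendering noise and textures).
#' @param case_id identifier string.
#' @return a `paired_case`: volumes `sect`, `vnc`, `iom`, integer
#'   `lesion_mask` (0 = background, i = lesion i), logical `brain`,
#'   `case_label` (`"ICH"`/`"CS"`), `case_id`, `seed`, `k`, `spacing`,
#'   `lesions`.
#' @export
render_case <- function(lesions, config, seed = config$seed, case_id = "case") {
  set.seed(seed + 1000003L)
  shape <- config$grid_shape
  brain <- brain_mask(shape)
  bg <- config$background_mean +
    config$background_sd * smooth_noise(shape, config$texture_scale)
  vnc <- ifelse(brain, bg, 0)
  if (config$brain_edge_sigma > 0)   # feathered parenchyma boundary
    vnc <- gaussian_blur(vnc, config$brain_edge_sigma)
  iom <- array(0, dim = shape)
  mask <- array(0L, dim = shape)
  for (i in seq_along(lesions)) {
    ls <- lesions[[i]]
    ind <- ellipsoid_indicator(ls$center, ls$radii, shape)
    mask[ind] <- i
    if (ls$blood_intensity > 0) {
      tex <- config$blood_texture_sd * smooth_noise(shape, config$texture_scale)
      add <- pmax(ls$blood_intensity + tex, 0)
      vnc <- vnc + ifelse(ind, add, 0)
    }
    if (ls$iodine_intensity > 0) {
      contrib <- ifelse(ind, ls$iodine_intensity, 0)
      if (config$iodine_edge_sigma > 0)
        contrib <- gaussian_blur(contrib, config$iodine_edge_sigma)
      iom <- iom + contrib
    }
  }
  sect <- gaussian_blur(vnc + config$mixing_k * iom, config$blur_sigma)
  if (config$noise_sd > 0)
    sect <- sect + array(stats::rnorm(prod(shape), 0, config$noise_sd), dim = shape)
  sect <- pmax(sect, 0)
  label <- if (any(vapply(lesions, function(l) l$kind %in% c("ICH", "MIXED"), TRUE)))
    "ICH" else "CS"
  structure(list(sect = sect, vnc = vnc, iom = iom, lesion_mask = mask,
                 brain = brain, case_label = label, case_id = case_id,
                 seed = as.integer(seed), k = config$mixing_k,
                 spacing = config$voxel_spacing, lesions = lesions),
            class = "paired_case")
}

#' @export
print.paired_case <- function(x, ...) {
  cat("paired_case ", x$case_id, ": ", paste(dim(x$sect), collapse = "x"),
      ", label ", x$case_label, ", ", max(x$lesion_mask), " lesion(s)\n", sep = "")
  invisible(x)
}

#' Simulate a collection of paired cases
#'
#' @param config a [phantom_config()].
#' @param n number of cases.
#' @param seed base seed; case i uses a seed derived deterministically.
#' @return list of `paired_case` objects.
#' @export
simulate_cases <- function(config, n, seed = config$seed) {
  lapply(seq_len(n), function(i) {
    si <- (seed + i * 7919L) %% 2147483647L
    render_case(sample_lesions(config, seed = si), config, seed = si,
                case_id = sprintf("case_%04d", i))
  })
}

## ---- decomposition-rule reading ----

lesion_elevations <- function(img, lesion_mask, background) {
  ids <- setdiff(sort(unique(as.integer(lesion_mask))), 0L)
  if (length(ids) == 0L) stop("empty lesion mask")
  vapply(ids, function(i) mean(img[lesion_mask == i]) - background, 1)
}

estimate_background <- function(img, lesion_mask, brain = NULL) {
  sel <- lesion_mask == 0L
  if (!is.null(brain)) sel <- sel & brain else sel <- sel & img > 0
  stats::median(img[sel])
}

#' Continuous decomposition score of a case reading
#'
#' The maximum over lesions of the mean VNC-like elevation above the
#' estimated background: high values indicate blood on the (true or
#' generated) VNC, i.e. hemorrhage. When the iodine map is supplied the
#' score is the VNC elevation minus the mean IOM signal per lesion — the
#' two-image form of the DECT reading (blood visible on the VNC, iodine
#' confined to the IOM), which stays discriminative when a generated pair
#' splits lesion intensity between the branches.
#'
#' @param vnc_like VNC or generated sVNC volume.
#' @param lesion_mask integer lesion label volume.
#' @param brain optional logical brain mask used for the background estimate
#'   (otherwise positive non-lesion voxels are used).
#' @param iom_like optional IOM or generated sIOM volume.
#' @return scalar score (normalized intensity units).
#' @export
decomposition_score <- function(vnc_like, lesion_mask, brain = NULL,
                                iom_like = NULL) {
  bg <- estimate_background(vnc_like, lesion_mask, brain)
  ev <- lesion_elevations(vnc_like, lesion_mask, bg)
  if (!is.null(iom_like)) {
    ids <- setdiff(sort(unique(as.integer(lesion_mask))), 0L)
    ei <- vapply(ids, function(i) mean(iom_like[lesion_mask == i]), 1)
    ev <- ev - ei
  }
  max(ev)
}

#' Classify a case by the DECT decomposition rule
#'
#' A hyperdensity is read as hemorrhage (ICH) when blood is visible on the
#' VNC-like image: the case is labelled ICH iff the mean VNC elevation over
#' background within any lesion exceeds `threshold`; otherwise the
#' hyperdensity is attributed to iodine (CS).
#'
#' @param vnc_like,iom_like volumes sharing the mask's shape (the iodine map
#'   is accepted for interface completeness; the rule thresholds the VNC).
#' @param lesion_mask integer lesion label volume (error if empty).
#' @param threshold elevation threshold (normalized units; default half the
#'   minimum default blood intensity).
#' @param brain optional logical brain mask for the background estimate.
#' @return `"ICH"` or `"CS"`.
#' @export
classify_by_decomposition <- function(vnc_like, iom_like, lesion_mask,
                                      threshold = 20, brain = NULL) {
  if (!identical(dim(vnc_like), dim(lesion_mask)))
    stop("volume and mask shapes differ")
  if (decomposition_score(vnc_like, lesion_mask, brain) > threshold) "ICH" else "CS"
}

#' SECT intensity score of a case (baseline reading)
#'
#' The same lesion-elevation score computed on the SECT input; because blood
#' and iodine attenuations overlap by construction, this score cannot
#' separate the classes well.
#'
#' @param case a `paired_case`.
#' @return scalar score.
#' @export
sect_intensity_score <- function(case) {
  bg <- estimate_background(case$sect, case$lesion_mask, case$brain)
  max(lesion_elevations(case$sect, case$lesion_mask, bg))
}

#' Rank (Mann-Whitney) AUC of a score against binary labels
#'
#' Area under the ROC over all thresholds of a continuous score; equivalent
#' to the probability a random positive scores above a random negative (ties
#' count half).
#'
#' @param scores numeric vector.
#' @param labels logical or 0/1 vector (TRUE/1 = positive).
#' @return AUC in \[0, 1\].
#' @export
threshold_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

## ---- stratified split ----

#' Stratified train/validation split
#'
#' Per class, the validation count is `round(class_n * v / (t + v))` for a
#' `t:v` ratio; the remaining cases train. Deterministic given `seed`.
#'
#' @param cases list of `paired_case` objects (or any list with a
#'   `case_label` field).
#' @param ratio integer pair `(train, validation)`, default 4:1.
#' @param seed integer seed.
#' @return `list(train =, validation =)` partitioning `cases`.
#' @export
stratified_split <- function(cases, ratio = c(4L, 1L), seed = 1L) {
  labels <- vapply(cases, function(cs) cs$case_label, "")
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present")
  if (any(tab < 2L)) stop("each class needs at least 2 members")
  set.seed(seed)
  frac <- ratio[2L] / sum(ratio)
  val_idx <- integer(0)
  for (cl in names(tab)) {
    ids <- which(labels == cl)
    nv <- round(length(ids) * frac)
    val_idx <- c(val_idx, sample(ids, nv))
  }
  val_idx <- sort(val_idx)
  list(train = cases[setdiff(seq_along(cases), val_idx)],
       validation = cases[val_idx])
}

## ---- NIfTI + manifest IO ----

#' Write paired cases as NIfTI volumes with a CSV manifest
#'
#' Writes `<id>_sect.nii.gz`, `<id>_vnc.nii.gz`, `<id>_iom.nii.gz` and
#' `<id>_mask.nii.gz` per case (voxel spacing in the header) plus
#' `manifest.csv` (case_id, paths, case_label, split, seed).
#'
#' @param cases list of `paired_case` objects.
#' @param dir output directory (created).
#' @param split optional character vector of split names per case.
#' @return the manifest data frame, invisibly.
#' @export
write_cases <- function(cases, dir, split = rep(NA_character_, length(cases))) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    paths <- vapply(c("sect", "vnc", "iom", "mask"), function(w)
      file.path(dir, paste0(cs$case_id, "_", w, ".nii.gz")), "")
    wr <- function(vol, path) {
      img <- RNifti::asNifti(vol * 1.0)
      RNifti::pixdim(img) <- cs$spacing
      RNifti::writeNifti(img, path)
    }
    wr(cs$sect, paths[1L]); wr(cs$vnc, paths[2L]); wr(cs$iom, paths[3L])
    wr(cs$lesion_mask, paths[4L])
    data.frame(case_id = cs$case_id, sect = paths[1L], vnc = paths[2L],
               iom = paths[3L], mask = paths[4L], case_label = cs$case_label,
               split = split[i], seed = cs$seed)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read paired cases back from a manifest directory
#'
#' @param dir directory written by [write_cases()].
#' @return list of `paired_case` objects (geometry fields reconstructed from
#'   the volumes; lesion specs are not round-tripped).
#' @export
read_cases <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    rd <- function(p) {
      img <- RNifti::readNifti(p)
      array(as.numeric(img), dim = dim(img))
    }
    sect <- rd(row$sect); vnc <- rd(row$vnc); iom <- rd(row$iom)
    mask <- array(as.integer(rd(row$mask)), dim = dim(sect))
    spacing <- RNifti::pixdim(RNifti::readNifti(row$sect))
    structure(list(sect = sect, vnc = vnc, iom = iom, lesion_mask = mask,
                   brain = vnc > 0, case_label = row$case_label,
                   case_id = row$case_id, seed = row$seed, k = NA_real_,
                   spacing = spacing, lesions = NULL), class = "paired_case")
  })
}
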