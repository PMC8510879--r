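# Synthetic PET/CT phantom: high-SUV ellipsoidal lesions on a low-SUV
# background, with CT context and optional physiological hotspots, mirroring
# the statistical structure of a whole-body FDG-PET/CT oncology cohort
# (sparse positive slices, right-skewed lesion sizes, 2x2x3 mm voxels).

#' Phantom cohort configuration
#'
#' Defines the statistical structure of a synthetic PET/CT cohort: geometry,
#' positive-slice fraction, lesion-size law, intensity distributions, and the
#' rate of physiological hotspots (high-uptake structures that are *not*
#' tumor, e.g. brain or bladder analogues, which create false-positive
#' pressure for weakly supervised methods).
#'
#' Defaults emulate a whole-body FDG-PET/CT oncology registry at desk scale:
#' about 13.5% of slices contain tumor, lesion voxel counts follow a
#' right-skewed log-normal law, and voxels measure 2 x 2 x 3 mm. The grid is
#' 64 x 64 x 32 by default so that a full cohort fits a single-CPU budget;
#' full 256 x 256 geometry is available through `slice_shape`.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param slices_per_subject axial slices per subject volume.
#' @param slice_shape in-plane (rows, cols) in voxels.
#' @param voxel_spacing (x, y, z) spacing in mm, aligned to (row, col, slice).
#' @param positive_slice_fraction target fraction of slices containing tumor,
#'   in `[0, 1)`; 0 produces tumor-free volumes.
#' @param lesion_size_meanlog,lesion_size_sdlog log-normal parameters of the
#'   lesion size distribution (voxel count).
#' @param lesions_per_slice_probs probabilities of 1, 2 or 3 co-planar lesion
#'   foci sharing one axial run.
#' @param background_suv,lesion_suv length-2 vectors `(mean, sd)` of the SUV
#'   (g/ml) of background tissue and lesions.
#' @param physiological_hotspot_rate expected number of non-tumor high-uptake
#'   hotspots per volume (Poisson).
#' @param noise_sd additive Gaussian noise on the PET channel (g/ml).
#' @param seed integer root seed for cohort generation.
#' @return A `phantom_config` list, validated.
#' @export
phantom_config <- function(n_subjects = 100L,
                           slices_per_subject = 32L,
                           slice_shape = c(64L, 64L),
                           voxel_spacing = c(2, 2, 3),
                           positive_slice_fraction = 0.135,
                           lesion_size_meanlog = 5.0,
                           lesion_size_sdlog = 0.8,
                           lesions_per_slice_probs = c(0.7, 0.2, 0.1),
                           background_suv = c(mean = 1.0, sd = 0.2),
                           lesion_suv = c(mean = 6.0, sd = 1.5),
                           physiological_hotspot_rate = 0.1,
                           noise_sd = 0.2,
                           seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    slices_per_subject = as.integer(slices_per_subject),
    slice_shape = as.integer(slice_shape),
    voxel_spacing = as.numeric(voxel_spacing),
    positive_slice_fraction = positive_slice_fraction,
    lesion_size_meanlog = lesion_size_meanlog,
    lesion_size_sdlog = lesion_size_sdlog,
    lesions_per_slice_probs = lesions_per_slice_probs / sum(lesions_per_slice_probs),
    background_suv = unname(background_suv),
    lesion_suv = unname(lesion_suv),
    physiological_hotspot_rate = physiological_hotspot_rate,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (cfg$n_subjects < 1L || cfg$slices_per_subject < 1L || any(cfg$slice_shape < 1L))
    stop("phantom_config: all counts must be >= 1", call. = FALSE)
  if (any(cfg$voxel_spacing <= 0))
    stop("phantom_config: voxel spacing components must be > 0", call. = FALSE)
  if (cfg$positive_slice_fraction < 0 || cfg$positive_slice_fraction >= 1)
    stop("phantom_config: positive_slice_fraction must lie in [0, 1)", call. = FALSE)
  if (cfg$lesion_suv[1] <= cfg$background_suv[1])
    stop("phantom_config: lesion SUV mean must exceed background SUV mean", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$physiological_hotspot_rate < 0)
    stop("phantom_config: rates and noise must be nonnegative", call. = FALSE)
  structure(cfg, class = "phantom_config")
}

#' Sample lesion sizes (voxel counts)
#'
#' Draws from the configured log-normal lesion-size law; used both by the
#' generator and to inspect the right-skewed size distribution directly.
#'
#' @param n number of draws.
#' @param config a [phantom_config()].
#' @return integer voxel counts (>= 1).
#' @export
sample_lesion_sizes <- function(n, config) {
  pmax(1L, as.integer(round(stats::rlnorm(n, config$lesion_size_meanlog,
                                          config$lesion_size_sdlog))))
}

# voxels of one blob: per-slice disks whose radius tapers towards the run ends;
# guarantees >= 1 voxel in every slice of [z0, z1] (min radius 0.8 covers the
# rounded center voxel). Returns integer matrix (row, col, slice).
blob_voxels <- function(r0, c0, z0, z1, volume_vox, shape, aspect = 1) {
  len <- z1 - z0 + 1L
  rmax <- sqrt(3 * volume_vox / (2 * pi * len))
  zc <- (z0 + z1) / 2
  out <- vector("list", len)
  for (i in seq_len(len)) {
    z <- z0 + i - 1L
    rel <- (z - zc) / (len / 2 + 0.5)
    rz <- max(rmax * sqrt(max(1 - rel^2, 0)), 0.8)
    a <- max(rz * aspect, 0.8)
    b <- max(rz / aspect, 0.8)
    rr <- max(1L, ceiling(r0 - a)):min(shape[1], floor(r0 + a))
    cc <- max(1L, ceiling(c0 - b)):min(shape[2], floor(c0 + b))
    g <- expand.grid(r = rr, c = cc)
    keep <- ((g$r - r0) / a)^2 + ((g$c - c0) / b)^2 <= 1
    g <- g[keep, , drop = FALSE]
    if (nrow(g) == 0L) {
      g <- data.frame(r = min(max(round(r0), 1L), shape[1]),
                      c = min(max(round(c0), 1L), shape[2]))
    }
    out[[i]] <- cbind(g$r, g$c, rep.int(z, nrow(g)))
  }
  do.call(rbind, out)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate one synthetic PET/CT volume
#'
#' Builds one subject: a PET-SUV volume, a coarse CT-HU volume (soft tissue
#' around 40 HU, lung blocks at -700 HU, lesions +20 HU), a ground-truth
#' lesion mask, and per-slice binary labels derived from the mask. Lesions
#' are tapered ellipsoidal blobs with log-normal voxel counts placed away
#' from the image border; physiological hotspots are small high-SUV blobs in
#' the border band with `gt_mask = 0`. Deterministic given
#' `(config, subject_seed)`.
#'
#' @param config a [phantom_config()].
#' @param subject_seed integer seed for this subject.
#' @param subject_id subject identifier string.
#' @return A `volume_sample`: list with `pet_suv`, `ct_hu`, `gt_mask`
#'   (arrays `(row, col, slice)`), `voxel_spacing`, `slice_labels`,
#'   `subject_id`.
#' @export
generate_volume <- function(config, subject_seed, subject_id = sprintf("S%05d", subject_seed)) {
  if (!inherits(config, "phantom_config")) stop("config must be a phantom_config", call. = FALSE)
  with_seed(subject_seed, {
    shp <- config$slice_shape
    d <- config$slices_per_subject
    dim3 <- c(shp, d)
    mask <- array(0L, dim3)
    # elliptical body cross-section surrounded by air (as in whole-body PET,
    # where air dominates each slice and anchors the SUV percentiles)
    ctr <- (shp + 1) / 2
    ax <- 0.46 * shp
    rr <- matrix(seq_len(shp[1]), shp[1], shp[2])
    cc <- matrix(seq_len(shp[2]), shp[1], shp[2], byrow = TRUE)
    body2d <- ((rr - ctr[1]) / ax[1])^2 + ((cc - ctr[2]) / ax[2])^2 <= 1
    body <- array(body2d, dim3)
    pet <- array(0, dim3)
    pet[body] <- stats::rnorm(sum(body), config$background_suv[1],
                              config$background_suv[2])
    ct <- array(-1000, dim3)
    ct[body] <- stats::rnorm(sum(body), 40, 10)
    # lung analogues: two low-HU blocks in the upper body half
    lr <- seq(max(1L, round(shp[1] * 0.20)), round(shp[1] * 0.45))
    lc1 <- seq(max(1L, round(shp[2] * 0.20)), round(shp[2] * 0.42))
    lc2 <- seq(round(shp[2] * 0.58), min(shp[2], round(shp[2] * 0.80)))
    ct[lr, lc1, ] <- ct[lr, lc1, ] - 740
    ct[lr, lc2, ] <- ct[lr, lc2, ] - 740

    n_pos <- stats::rbinom(1L, d, config$positive_slice_fraction)
    margin <- max(6L, round(min(shp) * 0.22))
    min_sep <- min(8, (min(shp) - 2 * margin) / 2) # feasible on small grids
    # choose non-overlapping axial runs totalling n_pos positive slices
    runs <- list()
    remaining <- n_pos
    while (remaining > 0L) {
      v <- sample_lesion_sizes(1L, config)
      z_aspect <- config$voxel_spacing[3] / config$voxel_spacing[1]
      len <- max(1L, round(2 * 0.62 * v^(1 / 3) / z_aspect))
      len <- min(len, remaining)
      runs[[length(runs) + 1L]] <- list(len = len, v = v)
      remaining <- remaining - len
    }
    occupied <- rep(FALSE, d)
    for (rn in runs) {
      starts <- seq_len(d - rn$len + 1L)
      ok <- vapply(starts, function(s) {
        lo <- max(1L, s - 1L); hi <- min(d, s + rn$len)
        !any(occupied[lo:hi])
      }, logical(1))
      if (!any(ok)) ok <- vapply(starts, function(s) !any(occupied[s:(s + rn$len - 1L)]), logical(1))
      if (!any(ok)) next
      s <- sample(rep(starts[ok], 2L), 1L) # rep() guards length-1 sample()
      z0 <- s; z1 <- s + rn$len - 1L
      occupied[z0:z1] <- TRUE
      k <- sample(1:3, 1L, prob = config$lesions_per_slice_probs)
      prop <- stats::runif(k, 0.5, 1); prop <- prop / sum(prop)
      centers <- matrix(stats::runif(2L, margin + 1, shp - margin), 1L)
      tries <- 0L
      while (nrow(centers) < k && tries < 50L) {
        cand <- stats::runif(2L, margin + 1, shp - margin)
        tries <- tries + 1L
        if (all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > min_sep))
          centers <- rbind(centers, cand)
      }
      k <- nrow(centers) # degrade gracefully if separation is infeasible
      for (j in seq_len(k)) {
        vox <- blob_voxels(centers[j, 1], centers[j, 2], z0, z1,
                           max(1, rn$v * prop[j]), shp,
                           aspect = stats::runif(1, 0.75, 1.3))
        vox <- vox[body2d[vox[, 1:2, drop = FALSE]], , drop = FALSE]
        if (nrow(vox) == 0L) next
        suv <- max(stats::rnorm(1, config$lesion_suv[1], config$lesion_suv[2]),
                   config$background_suv[1] + 1.5)
        mask[vox] <- 1L
        pet[vox] <- suv
        ct[vox] <- ct[vox] + 20
      }
    }
    # physiological hotspots: high SUV, empty mask, confined to the border band
    n_hot <- stats::rpois(1L, config$physiological_hotspot_rate)
    for (h in seq_len(n_hot)) {
      v <- max(4L, round(stats::rlnorm(1, 2.3, 0.5)))
      len <- min(d, max(1L, round(v^(1 / 3))))
      z0 <- sample.int(d - len + 1L, 1L)
      # at the body periphery (brain/bladder analogues sit off-center)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0.78, 0.90)
      rc <- c(ctr[1] + rad * ax[1] * sin(ang), ctr[2] + rad * ax[2] * cos(ang))
      vox <- blob_voxels(rc[1], rc[2], z0, z0 + len - 1L, v, shp)
      vox <- vox[body2d[vox[, 1:2, drop = FALSE]], , drop = FALSE]
      if (nrow(vox) == 0L) next
      suv <- max(stats::rnorm(1, config$lesion_suv[1], config$lesion_suv[2]),
                 config$background_suv[1] + 1.5)
      pet[vox] <- suv
    }
    noise <- stats::rnorm(prod(dim3), 0, config$noise_sd)
    noise[!body] <- noise[!body] * 0.1 # air carries little PET noise
    pet <- pmax(pet + noise, 0)
    structure(list(subject_id = subject_id,
                   pet_suv = pet, ct_hu = ct, gt_mask = mask,
                   voxel_spacing = config$voxel_spacing,
                   slice_labels = derive_slice_labels(mask)),
              class = "volume_sample")
  })
}

#' Generate a phantom cohort with a subject-level split
#'
#' Generates `n_subjects` volumes and assigns each subject to the train,
#' validation or test split (60/20/20 at subject level; no subject appears in
#' two splits). Deterministic given the config seed.
#'
#' @param config a [phantom_config()].
#' @return A tibble with one row per subject: `subject_id`, `split`
#'   (train/val/test) and a `volume` list-column of `volume_sample` objects.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "phantom_config")) stop("config must be a phantom_config", call. = FALSE)
  n <- config$n_subjects
  if (n < 5L) stop("generate_cohort: need n_subjects >= 5 to fill a 60/20/20 split", call. = FALSE)
  n_train <- floor(0.6 * n); n_val <- floor(0.2 * n)
  split <- with_seed(config$seed, {
    sample(rep(c("train", "val", "test"),
               c(n_train, n_val, n - n_train - n_val)))
  })
  ids <- sprintf("S%03d", seq_len(n))
  vols <- lapply(seq_len(n), function(i) {
    generate_volume(config, subject_seed = config$seed * 1000L + i, subject_id = ids[i])
  })
  tibble::tibble(subject_id = ids, split = split, volume = vols)
}

#' @export
print.volume_sample <- function(x, ...) {
  cat(sprintf("<volume_sample %s>  %s voxels, %d/%d positive slices, spacing %s mm\n",
              x$subject_id, paste(dim(x$pet_suv), collapse = "x"),
              sum(x$slice_labels), length(x$slice_labels),
              paste(x$voxel_spacing, collapse = "x")))
  invisible(x)
}
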