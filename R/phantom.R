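# Synthetic lung phantom generator.
#
# Each study is the tuple (volume, lobe masks, clinical vector, metadata
# vector) with a class label (lesioned lobe), an ordinal severity grade, a
# multi-label vector, a cohort tag (two cohorts with an intensity shift), and
# an optional second "view" of the same anatomy under a perturbed protocol.
#
# Generative model, published here so tests can reason about it:
#   volume  = 0.4 * lung + lesion_intensity * lesion + shift * [cohort == B]
#             + N(0, noise_sd) i.i.d. per voxel
#   lesion  = the n(s) region voxels nearest the lobe centroid, where
#             n(s) = ceiling(m * (0.15 + 0.6 * s / (S - 1))) and m is the
#             smallest lobe size, so lesion voxel count is strictly
#             increasing in severity s and identical across lobes
#   clinical c = w * s/(S-1) + N(0, 0.1), w = (0.9, -0.6, 0.4, 0.2) recycled
#   metadata m = e_A or e_B (cohort indicator) + N(0, 0.05)
#   view    = a * volume + b + N(0, view_noise_sd), a ~ U(0.9, 1.1),
#             b ~ U(-0.05, 0.05), optional integer voxel jitter

#' Configuration for the synthetic lung phantom generator
#'
#' @param grid_size voxels per axis (cubic grid), at least 8.
#' @param n_regions number of lobes K to carve (default 5: RUL, RML, RLL,
#'   LUL, LLL).
#' @param n_samples number of studies to generate.
#' @param lesion_intensity additive intensity of the lesion (> 0, arbitrary
#'   units; 0 gives lesion-free volumes).
#' @param noise_sd standard deviation of i.i.d. voxel noise (>= 0).
#' @param severity_levels number of ordinal severity grades (>= 2).
#' @param n_labels width of the multi-label vector (>= 1).
#' @param cohort_shift additive intensity offset applied to cohort B (>= 0).
#' @param view_noise_sd voxel noise of the paired view (>= 0).
#' @param view_jitter maximum integer voxel jitter applied to views.
#' @param label_mode `"region"`: class label is the 0-based lesioned lobe
#'   index; `"presence"`: binary lesion presence (severity 0 carries no
#'   lesion).
#' @param n_clinical,n_metadata lengths p and q of the tabular vectors.
#' @param make_views generate a paired view for every study.
#' @param seed integer root seed; all randomness flows from it through named
#'   substreams (`cohort`, `lesion`, `noise`, `view`).
#' @return A `phantom_config` list, validated.
#' @export
phantom_config <- function(grid_size = 16L, n_regions = 5L, n_samples = 100L,
                           lesion_intensity = 1, noise_sd = 0.05,
                           severity_levels = 4L, n_labels = 3L,
                           cohort_shift = 0.3, view_noise_sd = 0.05,
                           view_jitter = 0L,
                           label_mode = c("region", "presence"),
                           n_clinical = 4L, n_metadata = 3L,
                           make_views = TRUE, seed = 1L) {
  label_mode <- match.arg(label_mode)
  cfg <- list(grid_size = as.integer(grid_size), n_regions = as.integer(n_regions),
              n_samples = as.integer(n_samples),
              lesion_intensity = lesion_intensity, noise_sd = noise_sd,
              severity_levels = as.integer(severity_levels),
              n_labels = as.integer(n_labels), cohort_shift = cohort_shift,
              view_noise_sd = view_noise_sd, view_jitter = as.integer(view_jitter),
              label_mode = label_mode, n_clinical = as.integer(n_clinical),
              n_metadata = as.integer(n_metadata), make_views = isTRUE(make_views),
              seed = as.integer(seed))
  if (cfg$grid_size < 8L)
    stop("phantom_config: grid_size must be at least 8 voxels per axis")
  if (cfg$n_regions < 1L) stop("phantom_config: n_regions must be >= 1")
  if (cfg$n_samples < 1L) stop("phantom_config: n_samples must be >= 1")
  if (cfg$lesion_intensity < 0) stop("phantom_config: lesion_intensity must be >= 0")
  if (cfg$noise_sd < 0 || cfg$view_noise_sd < 0)
    stop("phantom_config: noise standard deviations must be >= 0")
  if (cfg$severity_levels < 2L) stop("phantom_config: severity_levels must be >= 2")
  if (cfg$n_labels < 1L) stop("phantom_config: n_labels must be >= 1")
  if (cfg$cohort_shift < 0) stop("phantom_config: cohort_shift must be >= 0")
  class(cfg) <- "phantom_config"
  cfg
}

#' Carve disjoint ellipsoidal lobe masks on a cubic grid
#'
#' Two axis-aligned ellipsoidal "lungs" are split into axial sectors: for
#' K = 5 the right lung holds three sectors (RUL, RML, RLL, superior to
#' inferior) and the left lung two (LUL, LLL). For other K the split is
#' `n_left = round(2K/5)` sectors on the left and the rest on the right.
#'
#' @param grid_size voxels per axis.
#' @param n_regions number of lobes K.
#' @return List with `masks` (named list of K binary arrays, pairwise
#'   disjoint), `names`, `side` ("R"/"L" per region), `centroids` (K x 3),
#'   and `lung` (binary union mask).
#' @export
carve_lobe_masks <- function(grid_size, n_regions) {
  G <- as.integer(grid_size)
  K <- as.integer(n_regions)
  ax <- seq_len(G)
  gx <- array(rep(ax, times = G * G), dim = c(G, G, G))
  gy <- array(rep(rep(ax, each = G), times = G), dim = c(G, G, G))
  gz <- array(rep(ax, each = G * G), dim = c(G, G, G))
  ellipsoid <- function(cen, semi) {
    ((gx - cen[1]) / semi[1])^2 + ((gy - cen[2]) / semi[2])^2 +
      ((gz - cen[3]) / semi[3])^2 <= 1
  }
  right <- ellipsoid(c(0.70, 0.50, 0.50) * G, c(0.18, 0.30, 0.40) * G)
  left <- ellipsoid(c(0.30, 0.50, 0.50) * G, c(0.16, 0.28, 0.38) * G)
  n_left <- max(0L, min(K - 1L, as.integer(round(2 * K / 5))))
  n_right <- K - n_left
  split_lung <- function(inside, n) {
    if (n == 0L) return(list())
    z <- gz[inside]
    if (length(z) < n)
      stop(sprintf(
        "carve_lobe_masks: grid of %d^3 voxels is too small to carve %d disjoint lobes",
        G, K))
    # superior-to-inferior sectors with (near-)equal voxel counts
    qs <- quantile(z, probs = seq(0, 1, length.out = n + 1), type = 1)
    sector <- cut(z, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
    if (length(unique(qs)) < n + 1 || length(unique(sector)) < n)
      stop(sprintf(
        "carve_lobe_masks: grid of %d^3 voxels is too small to carve %d disjoint lobes",
        G, K))
    idx <- which(inside)
    lapply(rev(seq_len(n)), function(s) { # rev: high z = superior first
      m <- array(0, dim = c(G, G, G))
      m[idx[sector == s]] <- 1
      m
    })
  }
  masks <- c(split_lung(right, n_right), split_lung(left, n_left))
  if (any(vapply(masks, sum, numeric(1)) == 0))
    stop(sprintf(
      "carve_lobe_masks: grid of %d^3 voxels is too small to carve %d disjoint lobes",
      G, K))
  nm <- if (K == 5L && n_right == 3L) c("RUL", "RML", "RLL", "LUL", "LLL")
  else c(if (n_right) paste0("R", seq_len(n_right)),
         if (n_left) paste0("L", seq_len(n_left)))
  names(masks) <- nm
  centroids <- t(vapply(masks, function(m) {
    i <- which(m == 1)
    c(mean(gx[i]), mean(gy[i]), mean(gz[i]))
  }, numeric(3)))
  list(masks = masks, names = nm,
       side = substr(nm, 1, 1),
       centroids = centroids,
       lung = pmin(Reduce(`+`, masks), 1))
}

# per-region voxel indices sorted by distance to the lobe centroid,
# giving deterministic nested lesion footprints
lesion_order <- function(lobes, grid_size) {
  G <- grid_size
  ax <- seq_len(G)
  gx <- array(rep(ax, times = G * G), dim = c(G, G, G))
  gy <- array(rep(rep(ax, each = G), times = G), dim = c(G, G, G))
  gz <- array(rep(ax, each = G * G), dim = c(G, G, G))
  lapply(seq_along(lobes$masks), function(k) {
    i <- which(lobes$masks[[k]] == 1)
    cen <- lobes$centroids[k, ]
    d2 <- (gx[i] - cen[1])^2 + (gy[i] - cen[2])^2 + (gz[i] - cen[3])^2
    i[order(d2, i)] # ties broken by voxel index: fully deterministic
  })
}

lesion_size <- function(severity, severity_levels, min_region, label_mode) {
  s <- severity
  S <- severity_levels
  if (label_mode == "presence") {
    as.integer(ceiling(min_region * 0.6 * s / (S - 1)))
  } else {
    as.integer(ceiling(min_region * (0.15 + 0.6 * s / (S - 1))))
  }
}

clinical_weights <- function(p) rep_len(c(0.9, -0.6, 0.4, 0.2), p)

#' Generate a seeded cohort of synthetic lung studies
#'
#' Deterministic for a fixed `config$seed`: the same configuration always
#' yields bitwise-identical studies. Lesioned lobes and severity grades are
#' assigned in balanced, shuffled rotation; cohorts A and B alternate.
#'
#' @param config a [phantom_config()].
#' @return List of `phantom_study` objects. Each holds `volume` (3D array),
#'   `masks` (K disjoint binary arrays), `clinical`, `metadata`,
#'   `class_label` (0-based), `severity` (0-based ordinal), `multilabel`,
#'   `cohort` ("A"/"B"), `region` (1-based lesioned lobe index),
#'   `lesion_voxels`, and optionally `view_pair`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  G <- config$grid_size; K <- config$n_regions; n <- config$n_samples
  S <- config$severity_levels
  lobes <- carve_lobe_masks(G, K)
  ord <- lesion_order(lobes, G)
  min_region <- min(vapply(lobes$masks, sum, numeric(1)))
  base <- 0.4 * lobes$lung

  regions <- with_seed(substream_seed(config$seed, "lesion"), {
    r <- sample(rep_len(seq_len(K), n))
    s <- sample(rep_len(seq_len(S) - 1L, n))
    list(r = r, s = s)
  })
  cohorts <- with_seed(substream_seed(config$seed, "cohort"),
                       sample(rep_len(c("A", "B"), n)))
  w <- clinical_weights(config$n_clinical)
  upper <- vapply(seq_len(K), function(k) {
    grp <- lobes$side[k]
    k == min(which(lobes$side == grp))
  }, logical(1))

  noise_seed <- substream_seed(config$seed, "noise")
  studies <- with_seed(noise_seed, lapply(seq_len(n), function(i) {
    k <- regions$r[i]; s <- regions$s[i]
    nles <- lesion_size(s, S, min_region, config$label_mode)
    vol <- base
    if (nles > 0 && config$lesion_intensity > 0)
      vol[ord[[k]][seq_len(nles)]] <- vol[ord[[k]][seq_len(nles)]] +
        config$lesion_intensity
    if (cohorts[i] == "B") vol <- vol + config$cohort_shift
    if (config$noise_sd > 0)
      vol <- vol + array(rnorm(G^3, sd = config$noise_sd), dim = dim(vol))
    cl <- w * (s / (S - 1)) + rnorm(config$n_clinical, sd = 0.1)
    meta <- numeric(config$n_metadata)
    meta[if (cohorts[i] == "A") 1L else min(2L, config$n_metadata)] <- 1
    meta <- meta + rnorm(config$n_metadata, sd = 0.05)
    ml <- vapply(seq_len(config$n_labels), function(j) {
      switch(((j - 1L) %% 3L) + 1L,
             as.numeric(upper[k]),
             as.numeric(s >= ceiling((S - 1) / 2)),
             as.numeric(lobes$side[k] == "R"))
    }, numeric(1))
    label <- if (config$label_mode == "presence") as.integer(nles > 0) else k - 1L
    study <- list(
      id = i, volume = vol, masks = lobes$masks,
      clinical = cl, metadata = meta,
      class_label = label, severity = s, multilabel = ml,
      cohort = cohorts[i], region = k, lesion_voxels = nles,
      view_pair = NULL)
    class(study) <- "phantom_study"
    study
  }))

  if (config$make_views) {
    view_root <- substream_seed(config$seed, "view")
    studies <- lapply(studies, function(st)
      generate_view_pair(st, config, seed = substream_seed(view_root, as.character(st$id))))
  }
  studies
}

#' Attach a paired view of the same anatomy to a study
#'
#' The second view is an intensity-affine transform of the first plus
#' additive noise and an optional small integer voxel jitter; masks and all
#' labels are shared with the primary volume.
#'
#' @param study a `phantom_study`.
#' @param config the [phantom_config()] governing view perturbations.
#' @param seed integer seed for the view substream (defaults to a seed
#'   derived from the config seed and the study id).
#' @param protocol `"affine"` (default) applies the perturbation model;
#'   `"identity"` copies intensities unchanged (noise still added if
#'   `view_noise_sd > 0`).
#' @return The study with `view_pair` set to the second volume.
#' @export
generate_view_pair <- function(study, config, seed = NULL,
                               protocol = c("affine", "identity")) {
  protocol <- match.arg(protocol)
  if (is.null(seed))
    seed <- substream_seed(substream_seed(config$seed, "view"),
                           as.character(study$id))
  with_seed(seed, {
    v <- study$volume
    if (protocol == "affine") {
      a <- runif(1, 0.9, 1.1)
      b <- runif(1, -0.05, 0.05)
      v <- a * v + b
      if (config$view_jitter > 0) {
        sh <- sample(seq(-config$view_jitter, config$view_jitter), 3, replace = TRUE)
        v <- shift_volume(v, sh[1], sh[2], sh[3])
      }
    }
    if (config$view_noise_sd > 0)
      v <- v + array(rnorm(length(v), sd = config$view_noise_sd), dim = dim(v))
    study$view_pair <- v
  })
  study
}
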