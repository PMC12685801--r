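# Disk layout for a simulated cohort:
#   <dir>/volumes/study_<id>.nii.gz      primary volume
#   <dir>/volumes/view_<id>.nii.gz       paired view (if present)
#   <dir>/masks/labelmap.nii.gz          shared lobe label map (1..K)
#   <dir>/clinical.csv                   id + clinical + metadata columns
#   <dir>/labels.csv                     id, class, severity, cohort, labels
#   <dir>/manifest.json                  config, region names, view_of map

#' Write a phantom cohort to disk
#'
#' Volumes and masks as NIfTI, tables as CSV (one row per study id), plus a
#' JSON manifest. Phantoms are index-space objects: the NIfTI affine is the
#' identity.
#'
#' @param studies list of `phantom_study` objects from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param config the generating [phantom_config()], stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(studies, dir, config) {
  dir.create(file.path(dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  K <- length(studies[[1]]$masks)
  labelmap <- Reduce(`+`, lapply(seq_len(K), function(k) k * studies[[1]]$masks[[k]]))
  RNifti::writeNifti(labelmap, file.path(dir, "masks", "labelmap.nii.gz"))
  view_of <- character(0)
  for (st in studies) {
    RNifti::writeNifti(st$volume,
                       file.path(dir, "volumes", sprintf("study_%04d.nii.gz", st$id)))
    if (!is.null(st$view_pair)) {
      RNifti::writeNifti(st$view_pair,
                         file.path(dir, "volumes", sprintf("view_%04d.nii.gz", st$id)))
      view_of <- c(view_of, sprintf("study_%04d", st$id))
    } else view_of <- c(view_of, NA_character_)
  }
  tab <- data.frame(id = vapply(studies, `[[`, numeric(1), "id"))
  cl <- t(vapply(studies, `[[`, numeric(length(studies[[1]]$clinical)), "clinical"))
  colnames(cl) <- paste0("clin_", seq_len(ncol(cl)))
  mt <- t(vapply(studies, `[[`, numeric(length(studies[[1]]$metadata)), "metadata"))
  colnames(mt) <- paste0("meta_", seq_len(ncol(mt)))
  utils::write.csv(cbind(tab, cl, mt), file.path(dir, "clinical.csv"), row.names = FALSE)
  ml <- t(vapply(studies, `[[`, numeric(length(studies[[1]]$multilabel)), "multilabel"))
  colnames(ml) <- paste0("label_", seq_len(ncol(ml)))
  lab <- cbind(tab,
               class = vapply(studies, `[[`, numeric(1), "class_label"),
               severity = vapply(studies, `[[`, numeric(1), "severity"),
               cohort = vapply(studies, `[[`, character(1), "cohort"),
               region = vapply(studies, `[[`, numeric(1), "region"),
               ml)
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- list(config = unclass(config),
                   regions = names(studies[[1]]$masks),
                   n_studies = length(studies),
                   view_of = view_of)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a phantom cohort from disk
#'
#' Inverse of [write_cohort()].
#' @param dir cohort directory.
#' @return List of `phantom_study` objects.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  cfg <- manifest$config
  labelmap <- array(as.numeric(RNifti::readNifti(file.path(dir, "masks", "labelmap.nii.gz"))),
                    dim = rep(cfg$grid_size, 3))
  K <- length(manifest$regions)
  masks <- lapply(seq_len(K), function(k) (labelmap == k) * 1)
  names(masks) <- manifest$regions
  clin <- utils::read.csv(file.path(dir, "clinical.csv"))
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  lapply(seq_len(nrow(lab)), function(i) {
    id <- lab$id[i]
    vol <- array(as.numeric(RNifti::readNifti(
      file.path(dir, "volumes", sprintf("study_%04d.nii.gz", id)))),
      dim = rep(cfg$grid_size, 3))
    vf <- file.path(dir, "volumes", sprintf("view_%04d.nii.gz", id))
    st <- list(
      id = id, volume = vol, masks = masks,
      clinical = as.numeric(clin[i, grep("^clin_", names(clin))]),
      metadata = as.numeric(clin[i, grep("^meta_", names(clin))]),
      class_label = lab$class[i], severity = lab$severity[i],
      multilabel = as.numeric(lab[i, grep("^label_", names(lab))]),
      cohort = lab$cohort[i], region = lab$region[i],
      lesion_voxels = NA_integer_,
      view_pair = if (file.exists(vf))
        array(as.numeric(RNifti::readNifti(vf)), dim = rep(cfg$grid_size, 3)))
    class(st) <- "phantom_study"
    st
  })
}

#' Fit z-score standardization parameters on training tabular data
#'
#' @param x numeric matrix (rows = samples).
#' @return List with `mean` and `sd` per column (`sd` floored at 1e-8).
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  list(mean = colMeans(x), sd = pmax(apply(x, 2, sd), 1e-8))
}

#' Apply fitted z-score standardization
#' @param x numeric matrix or vector.
#' @param zs parameters from [zscore_fit()].
#' @return Standardized matrix/vector.
#' @export
zscore_apply <- function(x, zs) {
  if (is.null(dim(x))) return((x - zs$mean) / zs$sd)
  sweep(sweep(as.matrix(x), 2, zs$mean), 2, zs$sd, "/")
}

#' Persist z-score parameters to JSON (and read them back)
#' @param zs parameters from [zscore_fit()].
#' @param path JSON file path.
#' @return `path` invisibly; `zscore_read()` returns the parameter list.
#' @export
zscore_write <- function(zs, path) {
  jsonlite::write_json(lapply(zs, as.numeric), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname zscore_write
#' @export
zscore_read <- function(path) {
  zs <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(mean = as.numeric(zs$mean), sd = as.numeric(zs$sd))
}
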