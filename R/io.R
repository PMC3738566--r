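# On-disk interchange: NIfTI-1 volumes, ROI/VOI JSON, spec YAML, transform
# JSON, measurement CSV.

#' Write a phantom study to a directory
#'
#' Writes the 4D dynamic series, both structural images, the truth label /
#' CBV / leakage maps as NIfTI-1, the generating spec as YAML, the true
#' mass outline polygons as ROI JSON, and a manifest with MD5 hashes.
#'
#' @param study a `phantom_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_phantom_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) {
    stop_validation("dir", sprintf("output directory '%s' is not writable", dir))
  }
  vs <- study$spec$voxel_size_mm
  wn <- function(img, name) {
    path <- file.path(dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = vs), path)
    path
  }
  files <- c(
    wn(study$dynamic$signal, "dynamic"),
    wn(study$ce_t1wi, "ce_t1wi"),
    wn(study$t2wi, "t2wi"),
    wn(study$truth_labels$labels, "truth_labels"),
    wn(study$truth_cbv, "truth_cbv"),
    wn(study$truth_k2, "truth_k2")
  )
  spec_path <- file.path(dir, "spec.yaml")
  yaml::write_yaml(spec_to_list(study$spec), spec_path)
  ref <- simulate_observer_rois(
    study, observer_spec(boundary_jitter_mm = 0, inclusion_error_rate = 0,
                         nawm_roi_placement_jitter_mm = 0, rng_seed = 1L),
    "ce_t1wi")
  roi_path <- file.path(dir, "true_outline.json")
  write_roi_json(ref$roi, ref$voi, roi_path)
  files <- c(files, spec_path, roi_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$tissue_table <- as.list(out$tissue_table)
  out
}

spec_from_list <- function(lst) {
  lst$tissue_table <- data.frame(lst$tissue_table, stringsAsFactors = FALSE)
  lst$noise_model <- lst$noise_model %||% "gaussian"
  do.call(phantom_spec, lst)
}

#' Read a phantom study from a directory
#'
#' Inverse of [write_phantom_study()]; errors name any missing file.
#'
#' @param dir study directory.
#' @return a `phantom_study`.
#' @export
read_phantom_study <- function(dir) {
  need <- c("dynamic.nii.gz", "ce_t1wi.nii.gz", "t2wi.nii.gz",
            "truth_labels.nii.gz", "truth_cbv.nii.gz", "truth_k2.nii.gz",
            "spec.yaml")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop_validation("dir", sprintf("missing study file '%s' in %s", f, dir))
    }
  }
  spec <- spec_from_list(yaml::read_yaml(file.path(dir, "spec.yaml")))
  rd <- function(name) {
    v <- RNifti::readNifti(file.path(dir, paste0(name, ".nii.gz")))
    array(as.numeric(v), dim = dim(v))
  }
  labels <- rd("truth_labels")
  structure(list(
    dynamic = dynamic_series(rd("dynamic"), spec$tr_s, spec$te_s,
                             spec$voxel_size_mm, spec$baseline_points),
    ce_t1wi = rd("ce_t1wi"),
    t2wi = rd("t2wi"),
    truth_labels = structure(list(labels = array(as.integer(round(labels)),
                                                 dim = dim(labels)),
                                  voxel_size_mm = spec$voxel_size_mm),
                             class = "tissue_label_map"),
    truth_cbv = rd("truth_cbv"),
    truth_k2 = rd("truth_k2"),
    spec = spec
  ), class = "phantom_study")
}

#' Write ROI polygons and VOI to JSON
#'
#' Slice-indexed polygon vertex lists in mm plus the ellipsoid center and
#' semi-axes.
#'
#' @param roi a `planar_roi_set`.
#' @param voi an `ellipsoid_voi` (optional).
#' @param path output path.
#' @export
write_roi_json <- function(roi, voi = NULL, path) {
  obj <- list(
    structural_tag = roi$structural_tag,
    slices = lapply(roi$slices, function(sl) list(
      z_index = sl$z_index - 1L,            # serialized 0-based
      vertices_mm = unname(apply(sl$vertices, 1, as.numeric, simplify = FALSE))
    ))
  )
  if (!is.null(voi)) {
    obj$voi <- list(center_mm = voi$center_mm, semi_axes_mm = voi$semi_axes_mm)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read ROI polygons and VOI from JSON
#'
#' @param path JSON path written by [write_roi_json()].
#' @return list with `roi` (a `planar_roi_set`) and `voi` (or NULL).
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  slices <- lapply(obj$slices, function(sl) list(
    z_index = as.integer(sl$z_index) + 1L,
    vertices = do.call(rbind, lapply(sl$vertices_mm, unlist))
  ))
  roi <- structure(list(slices = slices, structural_tag = obj$structural_tag),
                   class = "planar_roi_set")
  voi <- if (!is.null(obj$voi)) {
    ellipsoid_voi(unlist(obj$voi$center_mm), unlist(obj$voi$semi_axes_mm))
  }
  list(roi = roi, voi = voi)
}

#' Serialize a rigid transform to JSON
#'
#' @param transform a `rigid_transform`.
#' @param path output path.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(list(
    translation_mm = transform$translation_mm,
    rotation_deg = transform$rotation_deg,
    convention = transform$convention
  ), path, auto_unbox = TRUE, digits = NA)
}

#' Read a rigid transform from JSON
#'
#' @param path JSON path.
#' @return a `rigid_transform`.
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(obj$translation_mm, obj$rotation_deg)
}
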