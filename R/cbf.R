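# Per-compartment CBF extraction: absolute means, whole-cortex ratios and
# ictal - inter-ictal subtraction maps.

#' Construct a CBF volume
#'
#' Wraps a quantified CBF image (ml/100 g/min) with its affine and
#' examination metadata. Values must be finite; negative voxels are
#' permitted (they occur as ASL noise) but counted in
#' `meta$n_negative_voxels`.
#'
#' @param data Real-valued 3D array, ml/100 g/min.
#' @param affine 4x4 voxel-to-world affine (RAS+).
#' @param meta Named list of examination metadata; recognised fields are
#'   `subject_id`, `exam_id`, `age_months`, `scanner`, `sedation`,
#'   `state` (`"ictal"`, `"interictal"` or `"control"`), `group`, and
#'   `artifact` (upstream visual QC flag; artifacted images should be
#'   discarded before analysis).
#' @return An object of class `cbf_volume`.
#' @export
cbf_volume <- function(data, affine, meta = list()) {
  if (length(dim(data)) != 3L) {
    abort_cst("cst_format_error", "CBF image must be a 3D array")
  }
  if (!all(is.finite(data))) {
    abort_cst("cst_format_error", "CBF image contains non-finite values")
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    abort_cst("cst_format_error", "affine must be a 4x4 matrix")
  }
  meta$n_negative_voxels <- sum(data < 0)
  structure(list(data = data, affine = affine, meta = meta),
            class = "cbf_volume")
}

#' @export
print.cbf_volume <- function(x, ...) {
  cat(sprintf("<cbf_volume> %s grid, subject %s, exam %s, state %s (%d negative voxels)\n",
              paste(dim(x$data), collapse = "x"),
              x$meta$subject_id %||% "?", x$meta$exam_id %||% "?",
              x$meta$state %||% "?", x$meta$n_negative_voxels))
  invisible(x)
}

#' Read a CBF volume from NIfTI
#'
#' @param path Path to a `.nii`/`.nii.gz` CBF image in ml/100 g/min.
#' @param meta Examination metadata list (see [cbf_volume()]).
#' @return A [cbf_volume()].
#' @export
load_cbf_volume <- function(path, meta = list()) {
  img <- RNifti::readNifti(path)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  cbf_volume(as.array(img), affine, meta)
}

#' Write a CBF volume to NIfTI
#'
#' @param vol A [cbf_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_cbf_volume <- function(vol, path) {
  ni <- RNifti::asNifti(vol$data)
  RNifti::sform(ni) <- structure(vol$affine, code = 2L)
  RNifti::qform(ni) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(ni, path)
  invisible(path)
}

# ids of atlas labels matching a compartment key (merged atlas).
compartment_label_ids <- function(atlas, structure, subdivision, hemisphere) {
  lb <- atlas$labels
  if (!"subdivision" %in% names(lb)) {
    abort_cst("cst_config_error",
              "atlas labels lack a subdivision column; apply merge rules first")
  }
  lb$label_id[lb$structure == structure & lb$subdivision == subdivision &
                lb$hemisphere == hemisphere]
}

#' Mean CBF over one compartment
#'
#' Arithmetic mean of the CBF image over all voxels carrying the
#' compartment's label. Grids must align (shape and affine within 1e-4).
#'
#' @param cbf A [cbf_volume()].
#' @param atlas A merged [atlas_volume()] (see [apply_merge_rules()]).
#' @param structure,subdivision,hemisphere Compartment key.
#' @return List with `mean` (ml/100 g/min) and `n_voxels`.
#' @export
roi_mean <- function(cbf, atlas, structure, subdivision, hemisphere) {
  check_same_grid(cbf$data, cbf$affine, atlas$img, atlas$affine,
                  "CBF and atlas volumes")
  ids <- compartment_label_ids(atlas, structure, subdivision, hemisphere)
  sel <- atlas$img %in% ids
  n <- sum(sel)
  if (n == 0L) {
    abort_cst("cst_empty_roi_error",
              sprintf("empty compartment: %s",
                      key_label(structure, subdivision, hemisphere)))
  }
  list(mean = mean(cbf$data[sel]), n_voxels = n)
}

#' Whole-brain-cortex mean CBF
#'
#' Voxel-weighted mean over the union of all cortical compartments of both
#' hemispheres (not a mean of compartment means). This is the denominator
#' of every ratio (R-CBF) value.
#'
#' @inheritParams roi_mean
#' @return Mean CBF (ml/100 g/min).
#' @export
whole_cortex_mean <- function(cbf, atlas) {
  check_same_grid(cbf$data, cbf$affine, atlas$img, atlas$affine,
                  "CBF and atlas volumes")
  ids <- atlas$labels$label_id[atlas$labels$structure == "cortex"]
  sel <- atlas$img %in% ids
  if (!any(sel)) {
    abort_cst("cst_empty_roi_error", "no cortical voxels in atlas")
  }
  mean(cbf$data[sel])
}

#' Build the per-examination CBF table
#'
#' Computes, for all 36 compartments, the absolute mean CBF (A-CBF) and the
#' ratio to the whole-brain-cortex mean (R-CBF), plus voxel counts. By
#' default all voxels inside a compartment contribute, including negative
#' ones (ASL noise); setting `exclude_nonpositive = TRUE` drops voxels with
#' CBF <= 0 from every mean (off by default, mirroring an analysis without
#' voxel-level QC).
#'
#' @inheritParams roi_mean
#' @param exclude_nonpositive Drop voxels with CBF <= 0 from all means.
#' @return A data frame of class `cbf_table` with columns `exam_id`,
#'   `structure`, `subdivision`, `hemisphere`, `voxel_count`, `a_cbf`,
#'   `r_cbf`, `whole_cortex_mean` (36 rows, canonical order). The
#'   whole-cortex mean and examination metadata are also attached as
#'   attributes.
#' @export
build_cbf_table <- function(cbf, atlas, exclude_nonpositive = FALSE) {
  check_same_grid(cbf$data, cbf$affine, atlas$img, atlas$affine,
                  "CBF and atlas volumes")
  keys <- compartment_keys()
  key_str <- paste(keys$structure, keys$subdivision, keys$hemisphere)
  lb <- atlas$labels
  if (!"subdivision" %in% names(lb)) {
    abort_cst("cst_config_error",
              "atlas labels lack a subdivision column; apply merge rules first")
  }
  lab_to_key <- match(paste(lb$structure, lb$subdivision, lb$hemisphere), key_str)

  vec <- as.vector(atlas$img)
  vals <- as.vector(cbf$data)
  fg <- vec != 0L
  vec <- vec[fg]
  vals <- vals[fg]
  kidx <- lab_to_key[match(vec, lb$label_id)]
  if (exclude_nonpositive) {
    keep <- vals > 0
    vals <- vals[keep]
    kidx <- kidx[keep]
  }
  sums <- rowsum(vals, kidx)
  cnts <- rowsum(rep(1L, length(kidx)), kidx)
  a_cbf <- rep(NA_real_, 36L)
  n_vox <- rep(0L, 36L)
  got <- as.integer(rownames(sums))
  a_cbf[got] <- sums[, 1] / cnts[, 1]
  n_vox[got] <- as.integer(cnts[, 1])

  empty <- which(n_vox == 0L)
  if (length(empty)) {
    abort_cst("cst_empty_roi_error",
              sprintf("empty compartment(s): %s",
                      paste(key_label(keys$structure[empty],
                                      keys$subdivision[empty],
                                      keys$hemisphere[empty]),
                            collapse = "; ")))
  }
  ctx <- keys$structure == "cortex"
  wcm <- sum(a_cbf[ctx] * n_vox[ctx]) / sum(n_vox[ctx])
  if (!is.finite(wcm) || wcm <= 0) {
    abort_cst("cst_empty_roi_error",
              "whole-cortex mean is not positive; check input volume")
  }
  out <- cbind(
    data.frame(exam_id = cbf$meta$exam_id %||% NA_character_,
               stringsAsFactors = FALSE),
    keys,
    data.frame(voxel_count = n_vox, a_cbf = a_cbf, r_cbf = a_cbf / wcm,
               whole_cortex_mean = wcm))
  attr(out, "whole_cortex_mean") <- wcm
  attr(out, "meta") <- cbf$meta
  class(out) <- c("cbf_table", "data.frame")
  out
}

#' Write / read a CBF table as TSV
#'
#' Plain TSV with the `cbf_table` columns; values round-trip to better than
#' 1e-6 relative.
#'
#' @param tab A `cbf_table`.
#' @param path File path.
#' @return `path` (write) or a `cbf_table` (read).
#' @export
write_cbf_table <- function(tab, path) {
  df <- as.data.frame(tab)
  df$a_cbf <- formatC(df$a_cbf, digits = 15, format = "g")
  df$r_cbf <- formatC(df$r_cbf, digits = 15, format = "g")
  df$whole_cortex_mean <- formatC(df$whole_cortex_mean, digits = 15, format = "g")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cbf_table
#' @export
read_cbf_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("exam_id", "structure", "subdivision", "hemisphere",
              "voxel_count", "a_cbf", "r_cbf", "whole_cortex_mean")
  miss <- setdiff(needed, names(out))
  if (length(miss)) {
    abort_cst("cst_format_error",
              sprintf("CBF table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  attr(out, "whole_cortex_mean") <- out$whole_cortex_mean[1]
  class(out) <- c("cbf_table", "data.frame")
  out
}

#' Ictal minus inter-ictal subtraction map
#'
#' Voxelwise difference of two examinations of the same subject on the same
#' grid; highlights state-dependent perfusion changes.
#'
#' @param ictal,interictal [cbf_volume()] objects from the same subject,
#'   sharing grid and affine.
#' @return A `cbf_volume` (state `"subtraction"`) whose metadata records
#'   both source examinations.
#' @export
subtraction_map <- function(ictal, interictal) {
  sid_i <- ictal$meta$subject_id
  sid_j <- interictal$meta$subject_id
  if (is.null(sid_i) || is.null(sid_j) || !identical(sid_i, sid_j)) {
    abort_cst("cst_pairing_error",
              "subtraction requires two examinations of the same subject")
  }
  ok <- tryCatch({
    check_same_grid(ictal$data, ictal$affine, interictal$data,
                    interictal$affine, "examinations")
    TRUE
  }, cst_geometry_error = function(e) FALSE)
  if (!ok) {
    abort_cst("cst_pairing_error",
              "subtraction requires matching grids and affines")
  }
  cbf_volume(ictal$data - interictal$data, ictal$affine,
             meta = list(subject_id = sid_i,
                         exam_id = paste0(ictal$meta$exam_id %||% "ictal", "-minus-",
                                          interictal$meta$exam_id %||% "interictal"),
                         state = "subtraction",
                         source_ictal = ictal$meta$exam_id,
                         source_interictal = interictal$meta$exam_id))
}
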