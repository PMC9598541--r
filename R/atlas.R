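# Compartment taxonomy, atlas label volumes and subregion merge rules.
#
# The unit of every statistic in this package is the compartment: one
# (structure, functional subdivision, hemisphere) triple. Cortex, striatum
# and thalamus are each divided into the same six functional subdivisions so
# that circuit-level coincidences can be read off aligned compartments.

#' Canonical functional subdivisions
#'
#' The six functional subdivisions shared by cortex, striatum and thalamus:
#' prefrontal, rostral motor (precentral/SMA-connected), caudal motor
#' (primary-motor-connected), parietal, occipital and temporal. The order is
#' fixed; it drives the clockwise sector layout of donut charts.
#'
#' @return Character vector of length 6.
#' @export
subdivisions <- function() {
  c("prefrontal", "rostral_motor", "caudal_motor",
    "parietal", "occipital", "temporal")
}

#' Canonical anatomical structures
#'
#' Cortex, striatum and thalamus, ordered outside to inside as in the donut
#' chart rings.
#'
#' @return Character vector of length 3.
#' @export
structures <- function() c("cortex", "striatum", "thalamus")

#' Hemisphere labels
#' @return Character vector `c("left", "right")`.
#' @export
hemispheres <- function() c("left", "right")

#' All 36 compartment keys for one examination
#'
#' @return A data frame with columns `structure`, `subdivision`,
#'   `hemisphere` in canonical order (structure slowest, hemisphere fastest),
#'   3 x 6 x 2 = 36 rows.
#' @export
compartment_keys <- function() {
  k <- expand.grid(hemisphere = hemispheres(),
                   subdivision = subdivisions(),
                   structure = structures(),
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  k <- k[, c("structure", "subdivision", "hemisphere")]
  rownames(k) <- NULL
  k
}

#' Enumerate compartments over a set of examinations
#'
#' Every examination contributes 36 compartments; group denominators in
#' reports are multiples of 36 (e.g. 4 examinations give 144 compartments,
#' 14 give 504, 8 give 288).
#'
#' @param n_examinations Positive integer number of examinations.
#' @return Data frame with columns `examination`, `structure`,
#'   `subdivision`, `hemisphere`; `n_examinations * 36` rows in deterministic
#'   order (examination slowest, then canonical key order).
#' @export
enumerate_compartments <- function(n_examinations) {
  if (length(n_examinations) != 1L || is.na(n_examinations) ||
      n_examinations < 1 || n_examinations != round(n_examinations)) {
    abort_cst("cst_argument_error", "n_examinations must be a positive integer")
  }
  n <- as.integer(n_examinations)
  keys <- compartment_keys()
  out <- cbind(examination = rep(seq_len(n), each = nrow(keys)),
               keys[rep(seq_len(nrow(keys)), times = n), ])
  rownames(out) <- NULL
  out
}

#' Construct an atlas label volume
#'
#' @param img Integer 3D array; 0 is background, every nonzero value must
#'   appear in `labels$label_id`.
#' @param labels Data frame with columns `label_id`, `structure`,
#'   `subregion` (source subregion name) and optionally `hemisphere`
#'   (`"left"`/`"right"`; `NA` to derive from world x-coordinates, see
#'   [load_atlas()]). Merged atlases use a `subdivision` column instead of
#'   `subregion`.
#' @param affine 4x4 voxel-to-world affine (RAS+).
#' @param space Free-text space tag (e.g. `"MNI-adult"`, `"fixture"`).
#' @return An object of class `atlas_volume`.
#' @export
atlas_volume <- function(img, labels, affine, space = "fixture") {
  if (length(dim(img)) != 3L) {
    abort_cst("cst_format_error", "atlas image must be a 3D array")
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    abort_cst("cst_format_error", "affine must be a 4x4 matrix")
  }
  if (!all(c("label_id", "structure") %in% names(labels))) {
    abort_cst("cst_format_error",
              "label table needs at least columns label_id and structure")
  }
  if (anyDuplicated(labels$label_id)) {
    abort_cst("cst_format_error", "duplicate label_id in label table")
  }
  present <- unique(as.vector(img))
  present <- present[present != 0]
  unknown <- setdiff(present, labels$label_id)
  if (length(unknown)) {
    abort_cst("cst_label_error",
              sprintf("labels present in volume but absent from label table: %s",
                      paste(sort(unknown), collapse = ", ")))
  }
  bad_struct <- setdiff(unique(labels$structure), structures())
  if (length(bad_struct)) {
    abort_cst("cst_label_error",
              sprintf("unknown structure(s) in label table: %s",
                      paste(bad_struct, collapse = ", ")))
  }
  structure(
    list(img = img, labels = as.data.frame(labels, stringsAsFactors = FALSE),
         affine = affine, space = space),
    class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  merged <- "subdivision" %in% names(x$labels)
  cat(sprintf("<atlas_volume> %s grid, %d labels (%s), space '%s'\n",
              paste(dim(x$img), collapse = "x"), nrow(x$labels),
              if (merged) "merged subdivisions" else "source subregions",
              x$space))
  invisible(x)
}

#' Load an atlas label volume from NIfTI
#'
#' Reads a NIfTI-1 volume and its label table. A 3D integer volume is taken
#' as a label image directly. A 4D volume is treated as a probabilistic
#' atlas (one 3D map per label) and reduced to a max-probability label
#' image: each voxel takes the label of its highest-probability map if that
#' probability reaches `prob_threshold`, and background otherwise. Ties go
#' to the lowest label id so the reduction is deterministic.
#'
#' Hemisphere assignment: labels whose `hemisphere` entry is present are
#' used as-is. Labels with missing hemisphere are split by the sign of the
#' world x-coordinate (RAS+: negative x is left); voxels exactly on the
#' x = 0 plane are assigned to background.
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param label_table Path to a TSV with columns `label_id`, `structure`,
#'   `subregion` and optionally `hemisphere`. For 4D input, `label_id` j
#'   refers to the j-th 3D map.
#' @param prob_threshold Probability floor for max-probability reduction
#'   (default 0.25).
#' @param space Space tag stored on the result.
#' @return An [atlas_volume()].
#' @export
load_atlas <- function(path, label_table, prob_threshold = 0.25,
                       space = "unknown") {
  img <- RNifti::readNifti(path)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  labels <- utils::read.delim(label_table, stringsAsFactors = FALSE)
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 4L) {
    arr <- maxprob_reduce(arr, prob_threshold)
  } else if (nd == 3L) {
    if (any(arr != round(arr))) {
      abort_cst("cst_format_error",
                "3D atlas volume has non-integer values; pass a 4D stack for probabilistic atlases")
    }
    arr <- array(as.integer(round(arr)), dim = dim(arr))
  } else {
    abort_cst("cst_format_error", "atlas volume must be 3D (labels) or 4D (probabilistic)")
  }
  atl <- atlas_volume(arr, labels, affine, space = space)
  resolve_hemispheres(atl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Max-probability reduction of a 4D probabilistic stack; ties -> lowest id.
maxprob_reduce <- function(arr, prob_threshold) {
  d <- dim(arr)
  n_lab <- d[4]
  best_p <- array(-Inf, d[1:3])
  best_l <- array(0L, d[1:3])
  for (l in seq_len(n_lab)) {
    p <- arr[, , , l]
    better <- p > best_p   # strict: earlier (lower) label wins ties
    best_l[better] <- l
    best_p[better] <- p[better]
  }
  best_l[best_p < prob_threshold] <- 0L
  best_l
}

# Split any label with missing hemisphere by world x sign.
resolve_hemispheres <- function(atlas) {
  labels <- atlas$labels
  if (!"hemisphere" %in% names(labels)) labels$hemisphere <- NA_character_
  pending <- labels$label_id[is.na(labels$hemisphere)]
  if (!length(pending)) {
    bad <- setdiff(unique(labels$hemisphere), hemispheres())
    if (length(bad)) {
      abort_cst("cst_label_error",
                sprintf("unknown hemisphere value(s): %s", paste(bad, collapse = ", ")))
    }
    atlas$labels <- labels
    return(atlas)
  }
  img <- atlas$img
  xw <- voxel_world_x(dim(img), atlas$affine)
  next_id <- max(labels$label_id) + 1L
  vec <- as.vector(img)
  for (id in pending) {
    row <- labels[labels$label_id == id, ]
    sel <- which(vec == id)
    left <- sel[xw[sel] < 0]
    right <- sel[xw[sel] > 0]
    mid <- sel[xw[sel] == 0]
    vec[mid] <- 0L                     # x = 0 plane -> background
    vec[left] <- id                    # reuse id for left
    vec[right] <- next_id
    labels$hemisphere[labels$label_id == id] <- "left"
    new_row <- row
    new_row$label_id <- next_id
    new_row$hemisphere <- "right"
    labels <- rbind(labels, new_row)
    next_id <- next_id + 1L
  }
  atlas$img <- array(vec, dim = dim(img))
  atlas$labels <- labels[order(labels$label_id), , drop = FALSE]
  rownames(atlas$labels) <- NULL
  atlas
}

#' Default subregion merge rules
#'
#' Encodes how each structure's source subregions map onto the six shared
#' functional subdivisions: for the striatum, the limbic and executive
#' subregions merge into prefrontal; for the thalamus, premotor maps to
#' rostral motor, primary motor to caudal motor, and the sensory and
#' posterior parietal subregions merge into parietal; cortical subregions
#' named after the six subdivisions map to themselves.
#'
#' @return A data frame with columns `structure`, `subregion`,
#'   `subdivision` (a merge rule set).
#' @seealso [apply_merge_rules()], [identity_merge_rules()]
#' @export
default_merge_rules <- function() {
  rbind(
    data.frame(structure = "striatum",
               subregion = c("limbic", "executive", "rostral_motor",
                             "caudal_motor", "parietal", "occipital", "temporal"),
               subdivision = c("prefrontal", "prefrontal", "rostral_motor",
                               "caudal_motor", "parietal", "occipital", "temporal"),
               stringsAsFactors = FALSE),
    data.frame(structure = "thalamus",
               subregion = c("prefrontal", "premotor", "primary_motor",
                             "sensory", "posterior_parietal", "occipital", "temporal"),
               subdivision = c("prefrontal", "rostral_motor", "caudal_motor",
                               "parietal", "parietal", "occipital", "temporal"),
               stringsAsFactors = FALSE),
    data.frame(structure = "cortex",
               subregion = subdivisions(),
               subdivision = subdivisions(),
               stringsAsFactors = FALSE)
  )
}

#' Identity merge rules
#'
#' Maps each of the six subdivision names to itself for the given
#' structures. Useful for atlases already expressed in the shared
#' subdivision scheme (e.g. re-applying rules to a merged atlas).
#'
#' @param for_structures Character vector of structures to cover.
#' @return A merge rule set data frame.
#' @export
identity_merge_rules <- function(for_structures = structures()) {
  do.call(rbind, lapply(for_structures, function(s) {
    data.frame(structure = s, subregion = subdivisions(),
               subdivision = subdivisions(), stringsAsFactors = FALSE)
  }))
}

#' Default cortical grouping table
#'
#' A documented default for regrouping a lobar cortical parcellation into
#' the six functional subdivisions. Fixture atlases generated by
#' [make_fixture_atlas()] are already expressed in the six subdivisions and
#' bypass this table; it is provided for users bringing their own cortical
#' parcellations, and is a configurable choice, not a canonical standard.
#'
#' @return A merge rule set data frame for `structure = "cortex"`.
#' @export
default_cortical_grouping <- function() {
  data.frame(
    structure = "cortex",
    subregion = c("superior_frontal", "middle_frontal", "inferior_frontal",
                  "orbitofrontal", "anterior_cingulate",
                  "precentral", "supplementary_motor",
                  "postcentral", "paracentral", "rolandic_operculum",
                  "superior_parietal", "inferior_parietal", "precuneus",
                  "occipital", "calcarine", "cuneus", "lingual",
                  "superior_temporal", "middle_temporal", "inferior_temporal",
                  "fusiform"),
    subdivision = c(rep("prefrontal", 5), rep("rostral_motor", 2),
                    rep("caudal_motor", 3), rep("parietal", 3),
                    rep("occipital", 4), rep("temporal", 4)),
    stringsAsFactors = FALSE)
}

#' Apply subregion merge rules to an atlas
#'
#' Relabels an atlas of source subregions into the six shared functional
#' subdivisions. Voxel membership is conserved: no voxel gains or loses
#' foreground status, and merged counts equal the sums of their source
#' counts. Every structure present in the atlas must end with exactly six
#' subdivisions.
#'
#' @param atlas An [atlas_volume()] with a `subregion` label column.
#' @param rules A merge rule set (see [default_merge_rules()]).
#' @return An [atlas_volume()] whose labels are (structure, subdivision,
#'   hemisphere) triples, with new label ids in canonical order.
#' @export
apply_merge_rules <- function(atlas, rules = default_merge_rules()) {
  labels <- atlas$labels
  src_col <- if ("subregion" %in% names(labels)) "subregion" else "subdivision"
  if (anyNA(labels$hemisphere)) {
    abort_cst("cst_label_error", "resolve hemispheres before merging")
  }
  rule_key <- paste(rules$structure, rules$subregion)
  lab_key <- paste(labels$structure, labels[[src_col]])
  hit <- match(lab_key, rule_key)
  if (anyNA(hit)) {
    missing <- unique(lab_key[is.na(hit)])
    abort_cst("cst_config_error",
              sprintf("no merge rule for source subregion(s): %s",
                      paste(missing, collapse = ", ")))
  }
  new_sub <- rules$subdivision[hit]
  bad <- setdiff(unique(new_sub), subdivisions())
  if (length(bad)) {
    abort_cst("cst_config_error",
              sprintf("merge rules target unknown subdivision(s): %s",
                      paste(bad, collapse = ", ")))
  }
  # New label table: one id per (structure, subdivision, hemisphere).
  tgt <- data.frame(structure = labels$structure, subdivision = new_sub,
                    hemisphere = labels$hemisphere, stringsAsFactors = FALSE)
  keys <- compartment_keys()
  key_str <- paste(keys$structure, keys$subdivision, keys$hemisphere)
  tgt_str <- paste(tgt$structure, tgt$subdivision, tgt$hemisphere)
  new_id <- match(tgt_str, key_str)   # canonical ids 1..36
  present <- sort(unique(new_id))
  new_labels <- cbind(label_id = present, keys[present, , drop = FALSE])
  rownames(new_labels) <- NULL
  # Per-structure completeness.
  for (s in unique(new_labels$structure)) {
    n_sub <- length(unique(new_labels$subdivision[new_labels$structure == s]))
    if (n_sub != 6L) {
      abort_cst("cst_config_error",
                sprintf("structure '%s' has %d subdivisions after merging; expected 6",
                        s, n_sub))
    }
  }
  lut <- integer(max(labels$label_id))
  lut[labels$label_id] <- new_id
  vec <- as.vector(atlas$img)
  fg <- vec != 0L
  vec[fg] <- lut[vec[fg]]
  atlas_volume(array(vec, dim = dim(atlas$img)), new_labels, atlas$affine,
               space = atlas$space)
}

#' Combine per-structure atlases into one compartment atlas
#'
#' Stacks merged atlases (e.g. cortex + striatum + thalamus) into a single
#' label volume whose 36 label ids follow the canonical compartment order.
#' All inputs must share grid shape and affine (tolerance 1e-4) and must
#' not overlap.
#'
#' @param atlases List of merged [atlas_volume()] objects.
#' @return A single [atlas_volume()] with up to 36 labels.
#' @export
combine_atlases <- function(atlases) {
  if (!length(atlases)) abort_cst("cst_argument_error", "no atlases given")
  ref <- atlases[[1]]
  keys <- compartment_keys()
  key_str <- paste(keys$structure, keys$subdivision, keys$hemisphere)
  out <- array(0L, dim = dim(ref$img))
  rows <- list()
  for (atl in atlases) {
    check_same_grid(ref$img, ref$affine, atl$img, atl$affine, "atlas volumes")
    if (!"subdivision" %in% names(atl$labels)) {
      abort_cst("cst_config_error", "combine_atlases expects merged atlases")
    }
    ids <- match(paste(atl$labels$structure, atl$labels$subdivision,
                       atl$labels$hemisphere), key_str)
    lut <- integer(max(atl$labels$label_id))
    lut[atl$labels$label_id] <- ids
    vec <- as.vector(atl$img)
    fg <- which(vec != 0L)
    if (any(out[fg] != 0L)) {
      abort_cst("cst_label_error", "atlases overlap; compartments must be disjoint")
    }
    out[fg] <- lut[vec[fg]]
    rows[[length(rows) + 1L]] <- ids
  }
  present <- sort(unique(unlist(rows)))
  labels <- cbind(label_id = present, keys[present, , drop = FALSE])
  rownames(labels) <- NULL
  atlas_volume(out, labels, ref$affine, space = ref$space)
}
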