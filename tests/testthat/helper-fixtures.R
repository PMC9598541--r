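# Shared fixtures, built in code. The 16-voxel compartment atlas is small
# enough that every simulation below runs in milliseconds but still has all
# 36 compartments nonempty.

small_atlas <- fixture_compartment_atlas(grid = 16L, seed = 1L)

# A CBF volume with a constant value everywhere on the atlas grid.
uniform_cbf <- function(atlas, value, meta = list(exam_id = "uniform")) {
  cbf_volume(array(value, dim = dim(atlas$img)), atlas$affine, meta)
}

# A CBF volume with iid noise around a mean.
random_cbf <- function(atlas, seed, mean = 50, sd = 10,
                       meta = list(exam_id = "random")) {
  set.seed(seed)
  cbf_volume(array(stats::rnorm(length(atlas$img), mean, sd),
                   dim = dim(atlas$img)),
             atlas$affine, meta)
}

# A hand-built single-structure merged atlas for arithmetic examples.
tiny_atlas <- function(voxels_per_label, structure = "cortex",
                       subdivision = c("prefrontal", "prefrontal"),
                       hemisphere = c("left", "right")) {
  n_lab <- length(voxels_per_label)
  total <- sum(voxels_per_label)
  dims <- c(total, 1L, 1L)
  img <- array(rep.int(seq_len(n_lab), voxels_per_label), dim = dims)
  labels <- data.frame(label_id = seq_len(n_lab), structure = structure,
                       subdivision = subdivision, hemisphere = hemisphere,
                       stringsAsFactors = FALSE)
  atlas_volume(img, labels, diag(4), space = "fixture")
}

# Patient effect spec helper (empty effects = null patient).
null_effects <- function() {
  data.frame(structure = character(), subdivision = character(),
             hemisphere = character(), factor = numeric(),
             stringsAsFactors = FALSE)
}

cst_effects <- function(subdivision, hemisphere, factor,
                        structures_involved = c("cortex", "striatum", "thalamus")) {
  data.frame(structure = structures_involved, subdivision = subdivision,
             hemisphere = hemisphere, factor = factor,
             stringsAsFactors = FALSE)
}

# Exhaustive two-sided Fisher p-value by enumerating all tables with the
# observed margins, probabilities from binomial coefficients.
fisher_enumeration_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Brute-force circuit enumeration over all strata and structure subsets.
circuit_oracle <- function(status) {
  out <- list()
  for (m in unique(status$measure)) {
    for (sub in subdivisions()) {
      for (h in hemispheres()) {
        for (dir in c("increase", "decrease")) {
          rows <- status[status$measure == m & status$subdivision == sub &
                           status$hemisphere == h &
                           !is.na(status$direction) & status$direction == dir, ]
          structs <- structures()[structures() %in% rows$structure]
          if (length(structs) >= 2) {
            out[[length(out) + 1L]] <- data.frame(
              measure = m, subdivision = sub, hemisphere = h, direction = dir,
              pattern = paste(c(cortex = "C", striatum = "S",
                                thalamus = "T")[structs], collapse = "-"),
              n_structures = length(structs), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Random complete status table over all 36 keys x both measures.
random_status <- function(seed, p_change = 0.3) {
  set.seed(seed)
  keys <- compartment_keys()
  out <- do.call(rbind, lapply(c("A-CBF", "R-CBF"), function(m) {
    cbind(exam_id = "sim", keys, measure = m,
          data.frame(patient_value = stats::runif(36, 30, 90),
                     control_mean = 50, control_sd = 5, n_controls = 20,
                     t = 0, p = 1,
                     direction = sample(c("increase", "decrease", "normal"), 36,
                                        replace = TRUE,
                                        prob = c(p_change / 2, p_change / 2,
                                                 1 - p_change)),
                     note = "", stringsAsFactors = FALSE))
  }))
  class(out) <- c("compartment_status", "data.frame")
  out
}
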