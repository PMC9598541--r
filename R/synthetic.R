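# Synthetic-data generators: fixture atlases, age-structured control
# cohorts, patient examinations with injected circuit effects, and
# polygraphic EEG/EMG recordings with periodic discharges. Every generator
# keeps full ground-truth bookkeeping so downstream recovery can be tested.

#' Cortical CBF age curve
#'
#' Mean cortical CBF as a function of age: rises from its neonatal value
#' toward an asymptote with cortical maturation,
#' `c_adult - (c_adult - c_birth) * exp(-age / tau)`.
#'
#' @param age_months Age(s) in months.
#' @param curve List with `c_birth`, `c_adult` (ml/100 g/min) and `tau`
#'   (months).
#' @return Mean cortical CBF, ml/100 g/min.
#' @export
cortical_cbf <- function(age_months,
                         curve = list(c_birth = 30, c_adult = 60, tau = 24)) {
  curve$c_adult - (curve$c_adult - curve$c_birth) * exp(-age_months / curve$tau)
}

#' Subcortical/cortical CBF ratio age curve
#'
#' Ratio of striatal/thalamic to cortical CBF:
#' `r_inf + (r0 - r_inf) * exp(-(age / sigma)^2)`. With the defaults the
#' ratio stays near 1.5 throughout the first year of life and decays to
#' about 1 by mid-childhood, reflecting the later maturation of cortical
#' perfusion.
#'
#' @param age_months Age(s) in months.
#' @param curve List with `r0` (value at birth), `r_inf` (asymptote) and
#'   `sigma` (months).
#' @return Dimensionless ratio.
#' @export
subcortical_ratio <- function(age_months,
                              curve = list(r0 = 1.5, r_inf = 1, sigma = 72)) {
  curve$r_inf + (curve$r0 - curve$r_inf) * exp(-(age_months / curve$sigma)^2)
}

#' Specification of a synthetic control cohort
#'
#' Collects every parameter of the control-cohort generator: cohort size
#' and demographics, the cortical CBF age curve, the subcortical/cortical
#' ratio curve, between-subject dispersion and within-image voxel noise.
#'
#' @param n_controls Number of control subjects (default 232).
#' @param age_range_months Uniform age range in months (default 3-190,
#'   infancy through adolescence); ignored when `ages` is given.
#' @param ages Optional explicit vector of ages (months), recycled to
#'   `n_controls`.
#' @param scanners Scanner id pool (sampled uniformly).
#' @param sedation_age_cutoff_months Subjects younger than this are flagged
#'   as sedated (default 36; infants are routinely sedated for MRI).
#' @param cortical_curve See [cortical_cbf()].
#' @param ratio_curve See [subcortical_ratio()].
#' @param subject_cv Between-subject coefficient of variation of the
#'   log-normal global perfusion factor (default 0.12).
#' @param voxel_sd Gaussian voxel noise sd, ml/100 g/min (default 5).
#' @param seed Integer seed; the same spec and seed give an identical
#'   cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 232, age_range_months = c(3, 190),
                        ages = NULL, scanners = c("GE_1.5T", "GE_3T"),
                        sedation_age_cutoff_months = 36,
                        cortical_curve = list(c_birth = 30, c_adult = 60, tau = 24),
                        ratio_curve = list(r0 = 1.5, r_inf = 1, sigma = 72),
                        subject_cv = 0.12, voxel_sd = 5, seed = 1) {
  if (n_controls < 1) abort_cst("cst_argument_error", "n_controls must be >= 1")
  if (subject_cv < 0 || voxel_sd < 0) {
    abort_cst("cst_argument_error", "dispersions must be nonnegative")
  }
  if (!is.null(ages) && any(ages < 0)) {
    abort_cst("cst_argument_error", "ages must be nonnegative")
  }
  structure(list(n_controls = as.integer(n_controls),
                 age_range_months = age_range_months, ages = ages,
                 scanners = scanners,
                 sedation_age_cutoff_months = sedation_age_cutoff_months,
                 cortical_curve = cortical_curve, ratio_curve = ratio_curve,
                 subject_cv = subject_cv, voxel_sd = voxel_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# log-normal multiplier with mean 1 and coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a fixture atlas set
#'
#' Builds deterministic, contiguous-block label volumes on a cubic grid:
#' a striatal and a thalamic atlas with seven source subregions per
#' hemisphere each (matching the connectivity-based subregion schemes the
#' merge rules expect) and a cortical atlas already expressed in the six
#' subdivisions. Hemispheres split at the world x = 0 plane; structures
#' occupy disjoint slabs so the three volumes can be combined after
#' merging.
#'
#' @param grid Cubic grid side length in voxels (>= 16).
#' @param seed Recorded on the output; the construction itself is fully
#'   deterministic.
#' @return List of class `fixture_atlas_set` with elements `cortex`,
#'   `striatum`, `thalamus` (each an [atlas_volume()]).
#' @export
make_fixture_atlas <- function(grid = 32L, seed = 1L) {
  grid <- as.integer(grid)
  if (grid < 16L) {
    abort_cst("cst_size_error",
              "grid must be at least 16 voxels per side to host all 40 regions")
  }
  g <- grid
  affine <- rbind(c(1, 0, 0, -(g - 1) / 2),
                  c(0, 1, 0, -(g - 1) / 2),
                  c(0, 0, 1, -(g - 1) / 2),
                  c(0, 0, 0, 1))
  third <- g %/% 3L
  bands <- list(cortex = 1:third,
                striatum = (third + 1L):(2L * third),
                thalamus = (2L * third + 1L):g)
  striatal_subregions <- c("limbic", "executive", "rostral_motor",
                           "caudal_motor", "parietal", "occipital", "temporal")
  thalamic_subregions <- c("prefrontal", "premotor", "primary_motor",
                           "sensory", "posterior_parietal", "occipital",
                           "temporal")
  hemi_idx <- list(left = 1:(g %/% 2L), right = (g %/% 2L + 1L):g)

  build_one <- function(structure_name, subregions) {
    n_sub <- length(subregions)
    breaks <- round(seq(0, g, length.out = n_sub + 1L))
    img <- array(0L, dim = c(g, g, g))
    labels <- data.frame(label_id = integer(), structure = character(),
                         subregion = character(), hemisphere = character(),
                         stringsAsFactors = FALSE)
    id <- 0L
    for (h in names(hemi_idx)) {
      for (s in seq_len(n_sub)) {
        id <- id + 1L
        kk <- (breaks[s] + 1L):breaks[s + 1L]
        img[hemi_idx[[h]], bands[[structure_name]], kk] <- id
        labels <- rbind(labels,
                        data.frame(label_id = id, structure = structure_name,
                                   subregion = subregions[s], hemisphere = h,
                                   stringsAsFactors = FALSE))
      }
    }
    atlas_volume(img, labels, affine, space = "fixture")
  }
  structure(list(cortex = build_one("cortex", subdivisions()),
                 striatum = build_one("striatum", striatal_subregions),
                 thalamus = build_one("thalamus", thalamic_subregions),
                 seed = as.integer(seed), grid = g),
            class = "fixture_atlas_set")
}

#' Fixture compartment atlas
#'
#' Convenience wrapper: builds the fixture atlas set, applies the default
#' merge rules to each structure and combines the three into a single
#' 36-label compartment atlas.
#'
#' @inheritParams make_fixture_atlas
#' @return A merged, combined [atlas_volume()] with 36 labels.
#' @export
fixture_compartment_atlas <- function(grid = 32L, seed = 1L) {
  set <- make_fixture_atlas(grid, seed)
  rules <- default_merge_rules()
  combine_atlases(list(apply_merge_rules(set$cortex, rules),
                       apply_merge_rules(set$striatum, rules),
                       apply_merge_rules(set$thalamus, rules)))
}

# Fill a volume from per-compartment means + voxel noise.
fill_volume <- function(atlas, mu_cortex, ratio, voxel_sd) {
  lb <- atlas$labels
  means <- ifelse(lb$structure == "cortex", mu_cortex, mu_cortex * ratio)
  vec <- numeric(length(atlas$img))
  lab <- as.vector(atlas$img)
  fg <- which(lab != 0L)
  vec[fg] <- means[match(lab[fg], lb$label_id)]
  if (voxel_sd > 0) vec[fg] <- vec[fg] + stats::rnorm(length(fg), 0, voxel_sd)
  array(vec, dim = dim(atlas$img))
}

#' Generate a synthetic control cohort
#'
#' Draws control subjects from the age-structured perfusion model: each
#' subject's cortical mean is the age curve times a log-normal subject
#' factor; subcortical compartments are the cortical mean times the
#' age-dependent subcortical/cortical ratio; Gaussian voxel noise is added
#' on top. Ground truth (ages, factors, means) is retained.
#'
#' @param spec A [cohort_spec()].
#' @param atlas A combined compartment [atlas_volume()] (see
#'   [fixture_compartment_atlas()]).
#' @return List of class `synthetic_cohort` with `volumes` (list of
#'   [cbf_volume()]), `metadata` (data frame: `subject_id`, `exam_id`,
#'   `age_months`, `scanner`, `sedation`, `state`, `group`) and
#'   `ground_truth` (per-subject `mu_cortex`, `ratio`, `subject_factor`).
#' @export
generate_control_cohort <- function(spec, atlas) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_controls
  ages <- if (!is.null(spec$ages)) {
    rep_len(spec$ages, n)
  } else {
    stats::runif(n, spec$age_range_months[1], spec$age_range_months[2])
  }
  scanner <- sample(spec$scanners, n, replace = TRUE)
  sedation <- ages < spec$sedation_age_cutoff_months
  sf <- rlnorm_cv(n, spec$subject_cv)
  mu_c <- cortical_cbf(ages, spec$cortical_curve) * sf
  ratio <- subcortical_ratio(ages, spec$ratio_curve)
  ids <- sprintf("ctrl_%03d", seq_len(n))
  volumes <- vector("list", n)
  for (i in seq_len(n)) {
    volumes[[i]] <- cbf_volume(
      fill_volume(atlas, mu_c[i], ratio[i], spec$voxel_sd),
      atlas$affine,
      meta = list(subject_id = ids[i], exam_id = ids[i],
                  age_months = ages[i], scanner = scanner[i],
                  sedation = sedation[i], state = "control",
                  group = "control"))
  }
  names(volumes) <- ids
  structure(list(
    volumes = volumes,
    metadata = data.frame(subject_id = ids, exam_id = ids, age_months = ages,
                          scanner = scanner, sedation = sedation,
                          state = "control", group = "control",
                          stringsAsFactors = FALSE),
    ground_truth = data.frame(subject_id = ids, age_months = ages,
                              subject_factor = sf, mu_cortex = mu_c,
                              ratio = ratio, stringsAsFactors = FALSE),
    spec = spec), class = "synthetic_cohort")
}

#' CBF tables for a synthetic cohort
#'
#' @param cohort A [generate_control_cohort()] result.
#' @param atlas The compartment atlas the cohort was generated on.
#' @return Named list of `cbf_table` objects.
#' @export
cohort_cbf_tables <- function(cohort, atlas) {
  lapply(cohort$volumes, build_cbf_table, atlas = atlas)
}

#' Specification of a synthetic patient examination
#'
#' Describes the compartment-restricted multiplicative effects to inject
#' into a patient volume drawn from the control model, plus the patient's
#' matching metadata.
#'
#' @param effects Data frame with columns `structure`, `subdivision`,
#'   `hemisphere`, `factor` (multiplicative effect on mean CBF, > 0). A
#'   whole circuit is injected by listing its structures with the same
#'   subdivision/hemisphere.
#' @param age_months,scanner,sedation Patient metadata used for control
#'   matching.
#' @param state `"ictal"` or `"interictal"`.
#' @param subject_id,exam_id Identifiers.
#' @param seed Integer seed.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(effects, age_months, scanner = "GE_1.5T",
                        sedation = TRUE, state = c("ictal", "interictal"),
                        subject_id = "patient", exam_id = "patient_exam",
                        seed = 1) {
  state <- match.arg(state)
  needed <- c("structure", "subdivision", "hemisphere", "factor")
  if (!all(needed %in% names(effects))) {
    abort_cst("cst_argument_error",
              sprintf("effects needs columns %s", paste(needed, collapse = ", ")))
  }
  if (any(effects$factor <= 0)) {
    abort_cst("cst_argument_error", "effect factors must be > 0")
  }
  bad <- !(effects$structure %in% structures() &
             effects$subdivision %in% subdivisions() &
             effects$hemisphere %in% hemispheres())
  if (any(bad)) {
    abort_cst("cst_key_error",
              sprintf("unknown compartment key(s): %s",
                      paste(key_label(effects$structure[bad],
                                      effects$subdivision[bad],
                                      effects$hemisphere[bad]), collapse = "; ")))
  }
  structure(list(effects = as.data.frame(effects), age_months = age_months,
                 scanner = scanner, sedation = sedation, state = state,
                 subject_id = subject_id, exam_id = exam_id,
                 seed = as.integer(seed)),
            class = "effect_spec")
}

#' Generate a synthetic patient examination
#'
#' Draws a volume from the control perfusion model at the patient's age
#' (same curves and noise as the cohort spec), then multiplies the voxels
#' of each targeted compartment by its effect factor. The ground-truth
#' record lists every affected compartment with its factor.
#'
#' @param espec An [effect_spec()].
#' @param cspec The [cohort_spec()] whose model the patient is drawn from.
#' @param atlas A combined compartment [atlas_volume()].
#' @return List of class `synthetic_patient` with `volume` (a
#'   [cbf_volume()]) and `ground_truth`.
#' @export
generate_patient <- function(espec, cspec, atlas) {
  stopifnot(inherits(espec, "effect_spec"), inherits(cspec, "cohort_spec"))
  set.seed(espec$seed)
  sf <- rlnorm_cv(1, cspec$subject_cv)
  mu_c <- cortical_cbf(espec$age_months, cspec$cortical_curve) * sf
  ratio <- subcortical_ratio(espec$age_months, cspec$ratio_curve)
  arr <- fill_volume(atlas, mu_c, ratio, cspec$voxel_sd)
  for (i in seq_len(nrow(espec$effects))) {
    ef <- espec$effects[i, ]
    ids <- compartment_label_ids(atlas, ef$structure, ef$subdivision,
                                 ef$hemisphere)
    sel <- atlas$img %in% ids
    if (!any(sel)) {
      abort_cst("cst_key_error",
                sprintf("compartment %s has no voxels in this atlas",
                        key_label(ef$structure, ef$subdivision, ef$hemisphere)))
    }
    arr[sel] <- arr[sel] * ef$factor
  }
  vol <- cbf_volume(arr, atlas$affine,
                    meta = list(subject_id = espec$subject_id,
                                exam_id = espec$exam_id,
                                age_months = espec$age_months,
                                scanner = espec$scanner,
                                sedation = espec$sedation,
                                state = espec$state, group = "patient"))
  structure(list(volume = vol,
                 ground_truth = list(effects = espec$effects,
                                     mu_cortex = mu_c, ratio = ratio,
                                     subject_factor = sf,
                                     seed = espec$seed)),
            class = "synthetic_patient")
}

# ---------------------------------------------------------------------------
# Polygraphic EEG/EMG generator

eeg_montage_19 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz", "C4",
    "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

#' Central-parietal channel set
#'
#' The channels over which periodic-complex sharp waves are maximal and
#' over which back-average peak amplitudes are reported.
#'
#' @return Character vector `c("C3","Cz","C4","P3","Pz","P4")`.
#' @export
central_parietal_channels <- function() c("C3", "Cz", "C4", "P3", "Pz", "P4")

# Zero-mean sharp-wave topography: negative central-parietal maximum with
# positive phase reversal over frontal leads, so the common-average
# reference preserves the injected amplitude.
sspe_topography <- function() {
  w <- c(C3 = -1, Cz = -1, P3 = -1, Pz = -1, C4 = -0.85, P4 = -0.85,
         P7 = -0.4, P8 = -0.4, O1 = -0.25, O2 = -0.25)
  pos <- setdiff(eeg_montage_19(), names(w))
  w <- c(w, stats::setNames(rep(-sum(w) / length(pos), length(pos)), pos))
  w[eeg_montage_19()]
}

lpd_left_topography <- function() {
  w <- stats::setNames(numeric(19), eeg_montage_19())
  w[c("F3", "C3", "P3", "T7", "P7")] <- c(-0.5, -1, -1, -0.6, -0.7)
  w
}

#' EEG/EMG simulation presets
#'
#' Parameter bundles for the polygraphic generator, emulating published
#' periodic-discharge phenotypes:
#' * `SSPE_early`: generalized periodic complexes every 5-7 s, negative
#'   central-parietal sharp wave of 90 microvolts with frontal phase
#'   reversal, diamond-shaped deltoid EMG bursts following the sharp wave
#'   by a 20-60 ms latency (default 40 ms).
#' * `SSPE_late`: the same complexes at the shorter 2-3 s periodicity of
#'   advanced disease.
#' * `LPD_focal`: lateralized periodic discharges confined to
#'   left-hemisphere channels, 1.5-2.5 s intervals.
#' * `ES_cluster`: diffuse slow-wave complexes with long spasm-like EMG
#'   bursts every 8-12 s.
#' * `null_background`: background activity only, no complexes, EMG flat
#'   except noise.
#'
#' Background EEG is depressed slow activity (band-limited 1-4 Hz noise).
#' SSPE presets enforce their defining constraints (interval range inside
#' 5-7 s or 2-3 s, latency within 20-60 ms, 90 microvolt sharp-wave
#' amplitude).
#'
#' @param id Preset id.
#' @param ... Named overrides of preset fields (e.g. `latency_s = 0.05`,
#'   `background = list(noise_sd = 10)`).
#' @return A list of class `eeg_preset`.
#' @export
eeg_preset <- function(id = c("SSPE_early", "SSPE_late", "LPD_focal",
                              "ES_cluster", "null_background"), ...) {
  id <- match.arg(id)
  base <- list(
    id = id,
    sfreq = 256,
    eeg_channels = eeg_montage_19(),
    emg_channels = c("EMG_right_deltoid", "EMG_left_deltoid"),
    interval_range = c(5, 7),
    sharp = list(amplitude_uV = 90, sigma_s = 0.022,
                 topography = sspe_topography()),
    slow = list(amplitude_uV = 60, sigma_s = 0.12, delay_s = 0.25,
                topo_scale = 0.7),
    latency_s = 0.04,
    emg = list(amplitude_uV = 100, duration_s = 0.2, carrier_hz = 80,
               noise_sd = 2, scales = c(EMG_right_deltoid = 1,
                                        EMG_left_deltoid = 0.6)),
    background = list(noise_sd = 20, band = c(1, 4)))
  base <- switch(
    id,
    SSPE_early = base,
    SSPE_late = utils::modifyList(base, list(interval_range = c(2, 3))),
    LPD_focal = utils::modifyList(base, list(
      interval_range = c(1.5, 2.5),
      sharp = list(amplitude_uV = 80, sigma_s = 0.022,
                   topography = lpd_left_topography()),
      emg = utils::modifyList(base$emg,
                              list(scales = c(EMG_right_deltoid = 1,
                                              EMG_left_deltoid = 0))))),
    ES_cluster = utils::modifyList(base, list(
      interval_range = c(8, 12),
      sharp = list(amplitude_uV = 60, sigma_s = 0.05,
                   topography = sspe_topography()),
      slow = list(amplitude_uV = 120, sigma_s = 0.25, delay_s = 0.35,
                  topo_scale = 1),
      emg = utils::modifyList(base$emg, list(duration_s = 1)))),
    null_background = utils::modifyList(base, list(interval_range = NULL)))
  over <- list(...)
  if (length(over)) base <- utils::modifyList(base, over)
  validate_eeg_preset(base)
}

validate_eeg_preset <- function(p) {
  bad_ch <- setdiff(names(p$sharp$topography), p$eeg_channels)
  if (length(bad_ch)) {
    abort_cst("cst_config_error",
              sprintf("topography names channels outside the montage: %s",
                      paste(bad_ch, collapse = ", ")))
  }
  bad_emg <- setdiff(names(p$emg$scales), p$emg_channels)
  if (length(bad_emg)) {
    abort_cst("cst_config_error",
              sprintf("EMG scales name channels outside the montage: %s",
                      paste(bad_emg, collapse = ", ")))
  }
  if (startsWith(p$id, "SSPE")) {
    rng <- if (p$id == "SSPE_early") c(5, 7) else c(2, 3)
    if (is.null(p$interval_range) || p$interval_range[1] < rng[1] ||
        p$interval_range[2] > rng[2]) {
      abort_cst("cst_config_error",
                sprintf("%s intervals must lie within [%g, %g] s",
                        p$id, rng[1], rng[2]))
    }
    if (p$latency_s < 0.02 || p$latency_s > 0.06) {
      abort_cst("cst_config_error",
                "SSPE EEG-to-EMG latency must lie within 20-60 ms")
    }
    if (p$sharp$amplitude_uV != 90) {
      abort_cst("cst_config_error",
                "SSPE sharp-wave amplitude is fixed at 90 microvolts")
    }
  }
  structure(p, class = "eeg_preset")
}

# Band-limited background noise with target sd.
background_noise <- function(n, fs, band, sd_target) {
  x <- stats::rnorm(n)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, x)
  x * sd_target / stats::sd(x)
}

#' Generate a polygraphic EEG/EMG recording with periodic discharges
#'
#' Simulates a multichannel recording from an [eeg_preset()]: depressed
#' slow background activity on every EEG channel, stereotyped periodic
#' complexes (negative sharp wave followed by a slow wave, spatially
#' weighted by the preset topography), and diamond-shaped EMG bursts
#' (triangular envelope over a deterministic high-frequency carrier)
#' starting a fixed latency after each complex peak. Ground truth lists
#' every complex peak and EMG onset.
#'
#' @param preset An [eeg_preset()].
#' @param duration_s Recording duration in seconds; must be at least 10
#'   times the maximum complex interval. Ignored when `n_events` is given.
#' @param n_events Alternatively, the exact number of complexes to
#'   generate; the duration is then chosen to fit them.
#' @param seed Integer seed.
#' @return List of class `polygraphy_sim` with `recording` (a
#'   [polygraphic_recording()]), `events` (data frame `complex_time`,
#'   `emg_onset`, seconds) and `preset`.
#' @export
generate_polygraphy <- function(preset, duration_s = NULL, n_events = NULL,
                                seed = 1) {
  stopifnot(inherits(preset, "eeg_preset"))
  fs <- preset$sfreq
  has_events <- !is.null(preset$interval_range)
  set.seed(seed)
  if (has_events) {
    rng <- preset$interval_range
    if (!is.null(n_events)) {
      gaps <- stats::runif(max(n_events - 1L, 0L), rng[1], rng[2])
      tk <- 2 + c(0, cumsum(gaps))
      duration_s <- tk[length(tk)] + 2
    } else {
      if (is.null(duration_s) || duration_s < 10 * rng[2]) {
        abort_cst("cst_argument_error",
                  sprintf("duration must be at least 10 x the maximum interval (%g s)",
                          10 * rng[2]))
      }
      tk <- numeric(0)
      t_cur <- 2
      repeat {
        if (t_cur > duration_s - 2) break
        tk <- c(tk, t_cur)
        t_cur <- t_cur + stats::runif(1, rng[1], rng[2])
      }
    }
  } else {
    tk <- numeric(0)
    if (is.null(duration_s)) duration_s <- 60
  }
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  chans <- c(preset$eeg_channels, preset$emg_channels)
  dat <- matrix(0, n, length(chans), dimnames = list(NULL, chans))

  bg <- preset$background
  for (ch in preset$eeg_channels) {
    dat[, ch] <- background_noise(n, fs, bg$band, bg$noise_sd)
  }
  for (ch in preset$emg_channels) {
    dat[, ch] <- stats::rnorm(n, 0, preset$emg$noise_sd)
  }

  sharp <- preset$sharp
  slow <- preset$slow
  topo <- sharp$topography
  for (t0 in tk) {
    # sharp wave
    i_lo <- max(1L, floor((t0 - 5 * sharp$sigma_s) * fs) + 1L)
    i_hi <- min(n, ceiling((t0 + 5 * sharp$sigma_s) * fs) + 1L)
    idx <- i_lo:i_hi
    wave <- sharp$amplitude_uV * exp(-((tt[idx] - t0) / sharp$sigma_s)^2)
    # slow wave, delayed
    j_lo <- max(1L, floor((t0 + slow$delay_s - 4 * slow$sigma_s) * fs) + 1L)
    j_hi <- min(n, ceiling((t0 + slow$delay_s + 4 * slow$sigma_s) * fs) + 1L)
    jdx <- j_lo:j_hi
    swave <- slow$amplitude_uV *
      exp(-((tt[jdx] - t0 - slow$delay_s) / slow$sigma_s)^2)
    for (ch in names(topo)) {
      if (topo[[ch]] == 0) next
      dat[idx, ch] <- dat[idx, ch] + topo[[ch]] * wave
      dat[jdx, ch] <- dat[jdx, ch] + topo[[ch]] * slow$topo_scale * swave
    }
  }

  emg <- preset$emg
  onsets <- tk + preset$latency_s
  for (t0 in onsets) {
    i_lo <- floor(t0 * fs) + 1L
    i_hi <- min(n, ceiling((t0 + emg$duration_s) * fs) + 1L)
    if (i_lo > n) next
    idx <- i_lo:i_hi
    tau <- tt[idx] - t0
    env <- pmax(0, 1 - abs(2 * tau / emg$duration_s - 1))
    burst <- emg$amplitude_uV * env * sin(2 * pi * emg$carrier_hz * tau)
    for (ch in names(emg$scales)) {
      if (emg$scales[[ch]] == 0) next
      dat[idx, ch] <- dat[idx, ch] + emg$scales[[ch]] * burst
    }
  }

  rec <- polygraphic_recording(dat, fs)
  events <- data.frame(complex_time = tk, emg_onset = onsets)
  structure(list(recording = rec, events = events, preset = preset,
                 seed = as.integer(seed)),
            class = "polygraphy_sim")
}

#' Write simulated events as TSV
#'
#' @param sim A [generate_polygraphy()] result.
#' @param path File path; columns `onset_s`, `label`.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(sim, path) {
  ev <- rbind(data.frame(onset_s = sim$events$complex_time, label = "complex"),
              data.frame(onset_s = sim$events$emg_onset, label = "emg_onset"))
  ev <- ev[order(ev$onset_s), ]
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
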