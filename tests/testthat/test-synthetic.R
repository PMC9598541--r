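test_that("fixture atlases have the expected subregion structure", {
  set <- make_fixture_atlas(32)
  expect_equal(sum(set$striatum$labels$hemisphere == "left"), 7L)
  expect_equal(sum(set$striatum$labels$hemisphere == "right"), 7L)
  expect_equal(sum(set$thalamus$labels$hemisphere == "left"), 7L)
  expect_equal(sum(set$cortex$labels$hemisphere == "left"), 6L)
  # every labelled region is nonempty
  for (s in c("cortex", "striatum", "thalamus")) {
    atl <- set[[s]]
    counts <- table(factor(atl$img[atl$img != 0],
                           levels = atl$labels$label_id))
    expect_true(all(counts > 0))
  }
  expect_error(make_fixture_atlas(12), class = "cst_size_error")
})

test_that("the merged fixture atlas hosts exactly 36 compartments", {
  atl <- fixture_compartment_atlas(32)
  expect_equal(nrow(atl$labels), 36L)
  got <- atl$labels[, c("structure", "subdivision", "hemisphere")]
  rownames(got) <- NULL
  expect_identical(got, compartment_keys())
  counts <- table(factor(atl$img[atl$img != 0], levels = atl$labels$label_id))
  expect_true(all(counts > 0))
})

test_that("fixture atlases are deterministic", {
  a <- make_fixture_atlas(16, seed = 4)
  b <- make_fixture_atlas(16, seed = 4)
  expect_identical(a$striatum$img, b$striatum$img)
  expect_identical(a$cortex$labels, b$cortex$labels)
})

test_that("the ratio curve is about 1.5 in infancy and near 1 in adolescence", {
  expect_lt(abs(subcortical_ratio(6) - 1.5), 0.06)
  expect_lt(abs(subcortical_ratio(12) - 1.5), 0.06)
  expect_lt(abs(subcortical_ratio(180) - 1), 0.05)
  # monotone decay
  ages <- seq(0, 200, by = 5)
  expect_true(all(diff(subcortical_ratio(ages)) <= 0))
})

test_that("a noise-free cohort reproduces the age curves exactly", {
  cs <- cohort_spec(n_controls = 2, ages = 6, subject_cv = 0, voxel_sd = 0,
                    seed = 1)
  tab <- cohort_cbf_tables(generate_control_cohort(cs, small_atlas),
                           small_atlas)[[1]]
  wcm <- attr(tab, "whole_cortex_mean")
  expect_equal(wcm, cortical_cbf(6))
  sub <- tab$r_cbf[tab$structure != "cortex"]
  expect_equal(sub, rep(subcortical_ratio(6), length(sub)))
  # at 180 months the ratio is within 5% of 1 by construction
  cs2 <- cohort_spec(n_controls = 2, ages = 180, subject_cv = 0, voxel_sd = 0,
                     seed = 1)
  tab2 <- cohort_cbf_tables(generate_control_cohort(cs2, small_atlas),
                            small_atlas)[[1]]
  expect_lt(max(abs(tab2$r_cbf[tab2$structure != "cortex"] - 1)), 0.05)
})

test_that("the generated between-subject dispersion matches the specified CV", {
  cs <- cohort_spec(n_controls = 232, seed = 2)
  cohort <- generate_control_cohort(cs, small_atlas)
  sf <- cohort$ground_truth$subject_factor
  cv_hat <- stats::sd(sf) / mean(sf)
  expect_lt(abs(cv_hat - cs$subject_cv) / cs$subject_cv, 0.2)
  expect_equal(nrow(cohort$metadata), 232L)
})

test_that("cohort generation is seed-deterministic", {
  cs <- cohort_spec(n_controls = 3, seed = 11)
  a <- generate_control_cohort(cs, small_atlas)
  b <- generate_control_cohort(cs, small_atlas)
  expect_identical(a$volumes[[1]]$data, b$volumes[[1]]$data)
  expect_identical(a$metadata, b$metadata)
})

test_that("a unit effect leaves the patient volume at the control draw", {
  cs <- cohort_spec(seed = 3)
  base <- generate_patient(effect_spec(null_effects(), age_months = 10,
                                       seed = 12),
                           cs, small_atlas)
  unit <- generate_patient(effect_spec(cst_effects("parietal", "left", 1.0),
                                       age_months = 10, seed = 12),
                           cs, small_atlas)
  expect_identical(unit$volume$data, base$volume$data)
})

test_that("injected effects scale exactly the targeted compartments", {
  cs <- cohort_spec(subject_cv = 0, voxel_sd = 0, seed = 4)
  base <- generate_patient(effect_spec(null_effects(), age_months = 10,
                                       seed = 13),
                           cs, small_atlas)
  eff <- generate_patient(effect_spec(
    data.frame(structure = "striatum", subdivision = "occipital",
               hemisphere = "right", factor = 1.5),
    age_months = 10, seed = 13), cs, small_atlas)
  ids <- small_atlas$labels$label_id[small_atlas$labels$structure == "striatum" &
                                       small_atlas$labels$subdivision == "occipital" &
                                       small_atlas$labels$hemisphere == "right"]
  sel <- small_atlas$img %in% ids
  expect_equal(eff$volume$data[sel], base$volume$data[sel] * 1.5)
  expect_equal(eff$volume$data[!sel], base$volume$data[!sel])
})

test_that("a uniform cortical effect lowers subcortical ratios by its inverse", {
  cs <- cohort_spec(subject_cv = 0, voxel_sd = 0, seed = 5)
  cortical_all <- do.call(rbind, lapply(hemispheres(), function(h) {
    data.frame(structure = "cortex", subdivision = subdivisions(),
               hemisphere = h, factor = 1.2)
  }))
  base_tab <- build_cbf_table(
    generate_patient(effect_spec(null_effects(), age_months = 10, seed = 14),
                     cs, small_atlas)$volume, small_atlas)
  eff_tab <- build_cbf_table(
    generate_patient(effect_spec(cortical_all, age_months = 10, seed = 14),
                     cs, small_atlas)$volume, small_atlas)
  ctx <- base_tab$structure == "cortex"
  expect_equal(eff_tab$r_cbf[ctx], base_tab$r_cbf[ctx], tolerance = 1e-10)
  expect_equal(eff_tab$r_cbf[!ctx], base_tab$r_cbf[!ctx] / 1.2,
               tolerance = 1e-10)
})

test_that("unknown effect compartments are a key error", {
  expect_error(
    effect_spec(data.frame(structure = "cortex", subdivision = "limbic",
                           hemisphere = "left", factor = 1.5),
                age_months = 10),
    class = "cst_key_error")
})

test_that("end-to-end: an injected circuit effect is recovered downstream", {
  cs <- cohort_spec(n_controls = 20, ages = 12, scanners = "GE_1.5T",
                    subject_cv = 0.05, voxel_sd = 2, seed = 6)
  tabs <- cohort_cbf_tables(generate_control_cohort(cs, small_atlas),
                            small_atlas)
  pat <- generate_patient(effect_spec(cst_effects("prefrontal", "left", 1.5),
                                      age_months = 12, scanner = "GE_1.5T",
                                      sedation = TRUE, seed = 15),
                          cs, small_atlas)
  st <- classify_compartments(build_cbf_table(pat$volume, small_atlas), tabs)
  circ <- detect_circuits(st)
  hit <- circ[circ$measure == "A-CBF" & circ$subdivision == "prefrontal" &
                circ$hemisphere == "left", ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$pattern, "C-S-T")
  expect_identical(hit$direction, "increase")
})

test_that("SSPE presets enforce their defining constraints", {
  expect_error(eeg_preset("SSPE_early", interval_range = c(4, 7)),
               class = "cst_config_error")
  expect_error(eeg_preset("SSPE_late", interval_range = c(5, 7)),
               class = "cst_config_error")
  expect_error(eeg_preset("SSPE_early", latency_s = 0.1),
               class = "cst_config_error")
  expect_error(eeg_preset("SSPE_early",
                          sharp = list(amplitude_uV = 50, sigma_s = 0.022,
                                       topography = c(Cz = -1, Fz = 1))),
               class = "cst_config_error")
})

test_that("the null background preset has no complexes and a flat EMG", {
  sim <- generate_polygraphy(eeg_preset("null_background"), duration_s = 60,
                             seed = 31)
  expect_equal(nrow(sim$events), 0L)
  expect_length(detect_emg_onsets(sim$recording, "EMG_right_deltoid"), 0L)
  expect_lt(max(abs(sim$recording$data[, "EMG_right_deltoid"])), 12)
})

test_that("SSPE_early produces about one complex every six seconds", {
  sim <- generate_polygraphy(eeg_preset("SSPE_early"), duration_s = 600,
                             seed = 32)
  n <- nrow(sim$events)
  expect_gt(n, 100 * 0.8)
  expect_lt(n, 100 * 1.2)
  gaps <- diff(sim$events$complex_time)
  expect_true(all(gaps >= 5 & gaps <= 7))
  expect_true(all(diff(sim$events$emg_onset) > 0))
})

test_that("duration below ten maximal intervals is rejected", {
  expect_error(generate_polygraphy(eeg_preset("SSPE_early"), duration_s = 30),
               class = "cst_argument_error")
})

test_that("focal LPD complexes stay on the configured left-hemisphere channels", {
  sim <- generate_polygraphy(eeg_preset("LPD_focal",
                                        background = list(noise_sd = 5,
                                                          band = c(1, 4))),
                             duration_s = 60, seed = 33)
  d <- sim$recording$data
  v_left <- stats::var(d[, "C3"])
  v_right <- stats::var(d[, "C4"])
  expect_gt(v_left, 5 * v_right)
  # contralateral channels carry background power only
  expect_lt(v_right, 3 * stats::var(d[, "O2"]))
})

test_that("polygraphy generation is seed-deterministic", {
  a <- generate_polygraphy(eeg_preset("SSPE_late"), duration_s = 35, seed = 8)
  b <- generate_polygraphy(eeg_preset("SSPE_late"), duration_s = 35, seed = 8)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$events, b$events)
})

test_that("ground-truth events export to TSV", {
  sim <- generate_polygraphy(eeg_preset("SSPE_late"), duration_s = 35, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(sim, path)
  ev <- utils::read.delim(path)
  expect_setequal(unique(ev$label), c("complex", "emg_onset"))
  expect_equal(nrow(ev), 2L * nrow(sim$events))
})
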