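make_status <- function(changes = NULL) {
  # all-normal 72-row status table; `changes` is a data frame with
  # structure, subdivision, hemisphere, measure, direction
  keys <- compartment_keys()
  out <- do.call(rbind, lapply(c("A-CBF", "R-CBF"), function(m) {
    cbind(exam_id = "e1", keys, measure = m,
          data.frame(patient_value = 50, control_mean = 50, control_sd = 5,
                     n_controls = 20, t = 0, p = 1, direction = "normal",
                     note = "", stringsAsFactors = FALSE))
  }))
  if (!is.null(changes)) {
    for (i in seq_len(nrow(changes))) {
      ch <- changes[i, ]
      sel <- out$structure == ch$structure & out$subdivision == ch$subdivision &
        out$hemisphere == ch$hemisphere & out$measure == ch$measure
      out$direction[sel] <- ch$direction
    }
  }
  class(out) <- c("compartment_status", "data.frame")
  out
}

test_that("aligned changes in all three structures give one C-S-T pattern", {
  st <- make_status(data.frame(structure = c("cortex", "striatum", "thalamus"),
                               subdivision = "parietal", hemisphere = "left",
                               measure = "A-CBF", direction = "decrease"))
  circ <- detect_circuits(st)
  expect_equal(nrow(circ), 1L)
  expect_identical(circ$pattern, "C-S-T")
  expect_identical(circ$direction, "decrease")
  expect_identical(circ$subdivision, "parietal")
  expect_identical(circ$hemisphere, "left")
})

test_that("an all-normal examination has no circuit patterns", {
  expect_equal(nrow(detect_circuits(make_status())), 0L)
})

test_that("two-structure coincidences are labelled by their subset", {
  st <- make_status(data.frame(structure = c("striatum", "thalamus"),
                               subdivision = "occipital", hemisphere = "right",
                               measure = "R-CBF", direction = "increase"))
  circ <- detect_circuits(st)
  expect_identical(circ$pattern, "S-T")
})

test_that("mixed directions in a stratum are not a circuit", {
  st <- make_status(data.frame(structure = c("cortex", "striatum"),
                               subdivision = "temporal", hemisphere = "left",
                               measure = "A-CBF",
                               direction = c("increase", "decrease")))
  expect_equal(nrow(detect_circuits(st)), 0L)
})

test_that("circuit detection equals exhaustive enumeration on random tables", {
  for (seed in 1:20) {
    st <- random_status(seed)
    got <- detect_circuits(st)
    want <- circuit_oracle(st)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      key <- function(d) sort(paste(d$measure, d$subdivision, d$hemisphere,
                                    d$direction, d$pattern))
      expect_identical(key(got), key(want))
    }
    # maximality: no emitted pattern is a strict subset of another in its stratum
    strat <- paste(got$measure, got$subdivision, got$hemisphere, got$direction)
    expect_equal(anyDuplicated(strat), 0L)
  }
})

test_that("incomplete status tables are a completeness error", {
  st <- make_status()
  expect_error(detect_circuits(st[-1, ]), class = "cst_completeness_error")
})

test_that("group summaries conserve counts and denominators", {
  sts <- lapply(1:14, function(i) random_status(100 + i))
  gs <- summarize_group(sts, measure = "A-CBF")
  expect_equal(gs$total_compartments, 504L)
  manual <- sum(vapply(sts, function(s) {
    sum(s$measure == "A-CBF" & s$direction != "normal")
  }, numeric(1)))
  expect_equal(gs$changed, manual)
  expect_equal(sum(gs$by_direction), gs$changed)
  expect_equal(sum(gs$by_structure), gs$changed)
  expect_equal(gs$changed_percent, round(100 * manual / 504))
  expect_equal(summarize_group(sts[1:8], measure = "A-CBF")$total_compartments, 288L)
  expect_equal(summarize_group(sts[1:4], measure = "A-CBF")$total_compartments, 144L)
})

test_that("group summaries require an explicit measure when both are present", {
  expect_error(summarize_group(list(random_status(1))),
               class = "cst_argument_error")
  expect_s3_class(summarize_group(list(random_status(1)), measure = "R-CBF"),
                  "group_summary")
})

test_that("group summaries serialise to JSON", {
  gs <- summarize_group(list(random_status(7)), measure = "A-CBF")
  path <- withr::local_tempfile(fileext = ".json")
  write_group_summary(gs, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$total_compartments, 36L)
  expect_equal(back$changed, gs$changed)
})

test_that("Fisher's exact test matches enumeration on all tables with margins <= 8", {
  for (a in 0:8) for (b in 0:8) for (c_ in 0:8) for (d in 0:8) {
    if (a + b > 8 || c_ + d > 8 || a + c_ > 8 || b + d > 8) next
    if (a + b + c_ + d == 0) next
    got <- fisher_contrast(matrix(c(a, c_, b, d), 2))
    want <- fisher_enumeration_oracle(a, b, c_, d)
    expect_lt(abs(got$p - want), 1e-12)
  }
})

test_that("Fisher's exact test agrees with stats::fisher.test", {
  set.seed(77)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    got <- fisher_contrast(tab)
    want <- stats::fisher.test(tab)
    expect_equal(got$p, want$p.value, tolerance = 1e-8)
  }
})

test_that("degenerate and symmetric tables give p = 1", {
  expect_equal(fisher_contrast(matrix(c(0, 0, 5, 9), 2))$p, 1)
  expect_equal(fisher_contrast(matrix(c(3, 3, 3, 3), 2))$p, 1)
})

test_that("odds-ratio conventions and argument checks hold", {
  expect_equal(fisher_contrast(matrix(c(2, 1, 4, 8), 2))$odds_ratio, 4)
  expect_equal(fisher_contrast(matrix(c(5, 0, 1, 7), 2))$odds_ratio, Inf)
  expect_true(is.nan(fisher_contrast(matrix(c(0, 0, 1, 7), 2))$odds_ratio))
  expect_error(fisher_contrast(matrix(c(-1, 0, 1, 7), 2)),
               class = "cst_argument_error")
  expect_error(fisher_contrast(matrix(c(0.5, 0, 1, 7), 2)),
               class = "cst_argument_error")
})

test_that("donut models encode statuses as 18 cells per hemisphere", {
  dn <- build_donut(make_status(), "A-CBF")
  expect_equal(nrow(dn), 36L)
  for (h in hemispheres()) {
    expect_equal(sum(dn$hemisphere == h), 18L)
  }
  expect_true(all(dn$color == "green"))
  # single forced cell: left prefrontal cortex increase -> one red cell at
  # ring 1 (cortex, outer), sector 1 (prefrontal), left chart
  st <- make_status(data.frame(structure = "cortex", subdivision = "prefrontal",
                               hemisphere = "left", measure = "A-CBF",
                               direction = "increase"))
  dn2 <- build_donut(st, "A-CBF")
  red <- dn2[dn2$color == "red", ]
  expect_equal(nrow(red), 1L)
  expect_equal(red$ring, 1L)
  expect_equal(red$sector, 1L)
  expect_identical(red$hemisphere, "left")
})

test_that("donut cell colours re-derive losslessly from a status TSV", {
  st <- random_status(55)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_status_table(st, path)
  dn <- build_donut(read_status_table(path), "R-CBF")
  cmap <- c(increase = "red", decrease = "blue", normal = "green")
  for (i in seq_len(nrow(dn))) {
    src <- st[st$measure == "R-CBF" & st$structure == dn$structure[i] &
                st$subdivision == dn$subdivision[i] &
                st$hemisphere == dn$hemisphere[i], ]
    expect_identical(dn$color[i], unname(cmap[src$direction]))
    expect_identical(dn$direction[i], src$direction)
  }
})

test_that("donut rendering returns a ggplot and writes a figure", {
  dn <- build_donut(random_status(56), "A-CBF")
  p <- plot_donut(dn)
  expect_s3_class(p, "ggplot")
  path <- withr::local_tempfile(fileext = ".png")
  render_donut(dn, path)
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 0)
})
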