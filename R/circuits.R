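# Circuit-coincidence detection, group summaries, exact contrasts and the
# donut-chart model.

structure_initials <- c(cortex = "C", striatum = "S", thalamus = "T")

check_status_complete <- function(status) {
  keys <- compartment_keys()
  key_str <- paste(keys$structure, keys$subdivision, keys$hemisphere)
  for (m in unique(status$measure)) {
    sub <- status[status$measure == m, ]
    if (!all(key_str %in% paste(sub$structure, sub$subdivision, sub$hemisphere))) {
      abort_cst("cst_completeness_error",
                sprintf("status table incomplete for measure %s (need all 36 compartments)", m))
    }
  }
  invisible(TRUE)
}

#' Detect coincident circuit patterns in one examination
#'
#' A circuit pattern is a set of at least two structures (out of cortex,
#' striatum, thalamus) whose compartments share the same subdivision,
#' hemisphere, measure and direction of significant CBF change. For each
#' such stratum the maximal structure subset is emitted once, labelled
#' C-S-T, C-S, C-T or S-T; proper subsets of an emitted pattern are not
#' emitted separately. Structures changing in opposite directions within a
#' stratum are not a pattern (they would appear as two strata).
#'
#' @param status A `compartment_status` table for one examination, complete
#'   for each measure it contains.
#' @return Data frame with columns `measure`, `subdivision`, `hemisphere`,
#'   `direction`, `pattern` (e.g. `"C-S-T"`), `n_structures`; zero rows if
#'   no circuit coincidence is present.
#' @export
detect_circuits <- function(status) {
  check_status_complete(status)
  chg <- status[!is.na(status$direction) & status$direction != "normal", ,
                drop = FALSE]
  empty <- data.frame(measure = character(), subdivision = character(),
                      hemisphere = character(), direction = character(),
                      pattern = character(), n_structures = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(chg)) return(empty)
  strata <- split(chg, paste(chg$measure, chg$subdivision, chg$hemisphere,
                             chg$direction, sep = "\r"))
  rows <- lapply(strata, function(s) {
    if (nrow(s) < 2L) return(NULL)
    structs <- structures()[structures() %in% s$structure]
    data.frame(measure = s$measure[1], subdivision = s$subdivision[1],
               hemisphere = s$hemisphere[1], direction = s$direction[1],
               pattern = paste(structure_initials[structs], collapse = "-"),
               n_structures = length(structs), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(match(out$measure, c("A-CBF", "R-CBF")),
                   match(out$subdivision, subdivisions()),
                   match(out$hemisphere, hemispheres())), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise compartment changes over a group of examinations
#'
#' Aggregates one measure across the status tables of a group: the total
#' compartment denominator (36 per examination), counts of changed
#' compartments by direction and by structure, and circuit-pattern counts
#' from [detect_circuits()]. Report percentages are rounded to the nearest
#' integer; exact fractions are retained.
#'
#' @param status_list List of `compartment_status` tables, one per
#'   examination.
#' @param measure `"A-CBF"` or `"R-CBF"`; must be given explicitly when the
#'   tables carry both measures.
#' @return A list of class `group_summary`.
#' @export
summarize_group <- function(status_list, measure = NULL) {
  if (!length(status_list)) {
    abort_cst("cst_argument_error", "need at least one examination")
  }
  measures_present <- unique(unlist(lapply(status_list, function(s) s$measure)))
  if (is.null(measure)) {
    if (length(measures_present) > 1L) {
      abort_cst("cst_argument_error",
                "tables contain several measures; select one explicitly")
    }
    measure <- measures_present
  }
  if (!measure %in% c("A-CBF", "R-CBF")) {
    abort_cst("cst_argument_error", "measure must be 'A-CBF' or 'R-CBF'")
  }
  n_exam <- length(status_list)
  total <- 36L * n_exam
  per_exam <- lapply(status_list, function(s) {
    check_status_complete(s)
    s[s$measure == measure, , drop = FALSE]
  })
  all_rows <- do.call(rbind, per_exam)
  chg <- all_rows[!is.na(all_rows$direction) & all_rows$direction != "normal", ,
                  drop = FALSE]
  count_by <- function(values, levels) {
    out <- table(factor(values, levels = levels))
    stats::setNames(as.integer(out), levels)
  }
  circ <- do.call(rbind, lapply(per_exam, detect_circuits))
  circuit_counts <- if (is.null(circ) || !nrow(circ)) {
    stats::setNames(integer(4), c("C-S-T", "C-S", "C-T", "S-T"))
  } else {
    count_by(circ$pattern, c("C-S-T", "C-S", "C-T", "S-T"))
  }
  changed <- nrow(chg)
  structure(list(
    measure = measure,
    n_examinations = n_exam,
    total_compartments = total,
    changed = changed,
    changed_fraction = changed / total,
    changed_percent = round(100 * changed / total),
    by_direction = count_by(chg$direction, c("increase", "decrease")),
    by_structure = count_by(chg$structure, structures()),
    circuit_counts = circuit_counts,
    n_circuits = sum(circuit_counts)
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: %d/%d compartments changed (%d%%) over %d examinations\n",
              x$measure, x$changed, x$total_compartments, x$changed_percent,
              x$n_examinations))
  cat(sprintf("  increase %d, decrease %d; C %d, S %d, T %d\n",
              x$by_direction[["increase"]], x$by_direction[["decrease"]],
              x$by_structure[["cortex"]], x$by_structure[["striatum"]],
              x$by_structure[["thalamus"]]))
  cat(sprintf("  circuits: C-S-T %d, C-S %d, C-T %d, S-T %d\n",
              x$circuit_counts[["C-S-T"]], x$circuit_counts[["C-S"]],
              x$circuit_counts[["C-T"]], x$circuit_counts[["S-T"]]))
  invisible(x)
}

#' Write a group summary as JSON
#'
#' @param summary A `group_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value for a 2x2 contingency table of nonnegative
#' integer counts, computed by summing the hypergeometric probabilities of
#' all tables with the observed margins whose point probability does not
#' exceed the observed table's (the standard two-sided exact convention,
#' with a 1e-7 relative tie tolerance). The odds ratio is the sample
#' cross-product ratio a*d / (b*c); when b*c = 0 it is `Inf` unless a*d is
#' also 0, in which case it is `NaN`.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_contrast <- function(tab) {
  if (!is.matrix(tab) || !all(dim(tab) == c(2L, 2L))) {
    abort_cst("cst_argument_error", "tab must be a 2x2 matrix")
  }
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    abort_cst("cst_argument_error", "counts must be nonnegative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  if (n == 0) {
    abort_cst("cst_argument_error", "at least one margin must be nonzero")
  }
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  list(odds_ratio = or, p = p)
}

#' Build the donut-chart model for one examination
#'
#' Encodes the compartment statuses of one measure as a donut chart: three
#' rings (outside to inside: cortex, striatum, thalamus) by six equal
#' sectors (clockwise from the top: prefrontal, rostral motor, caudal
#' motor, parietal, occipital, temporal), one chart per hemisphere. Cell
#' colours derive solely from the status directions: red = increase,
#' blue = decrease, green = normal.
#'
#' @param status A complete `compartment_status` table for one examination.
#' @param measure `"A-CBF"` or `"R-CBF"`.
#' @return Data frame of class `donut_chart` with columns `hemisphere`,
#'   `structure`, `ring` (1 = outer), `subdivision`, `sector` (1 = first
#'   clockwise from top), `direction`, `color`; 36 rows (18 cells per
#'   hemisphere).
#' @export
build_donut <- function(status, measure = "A-CBF") {
  sub <- status[status$measure == measure, , drop = FALSE]
  if (!nrow(sub)) {
    abort_cst("cst_argument_error",
              sprintf("status table has no rows for measure %s", measure))
  }
  check_status_complete(sub)
  keys <- compartment_keys()
  idx <- match(paste(keys$structure, keys$subdivision, keys$hemisphere),
               paste(sub$structure, sub$subdivision, sub$hemisphere))
  dirs <- sub$direction[idx]
  color_map <- c(increase = "red", decrease = "blue", normal = "green")
  out <- data.frame(
    hemisphere = keys$hemisphere,
    structure = keys$structure,
    ring = match(keys$structure, structures()),
    subdivision = keys$subdivision,
    sector = match(keys$subdivision, subdivisions()),
    direction = dirs,
    color = unname(color_map[dirs]),
    stringsAsFactors = FALSE)
  attr(out, "measure") <- measure
  attr(out, "exam_id") <- sub$exam_id[1]
  class(out) <- c("donut_chart", "data.frame")
  out
}

#' Plot a donut-chart model
#'
#' Renders the [build_donut()] model as nested rings with ggplot2, one
#' panel per hemisphere.
#'
#' @param model A `donut_chart`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_donut <- function(model, title = NULL) {
  df <- as.data.frame(model)
  df$xmin <- df$sector - 1
  df$xmax <- df$sector
  df$ymin <- 4 - df$ring       # cortex (ring 1) outermost
  df$ymax <- 5 - df$ring
  df$hemisphere <- factor(df$hemisphere, levels = hemispheres())
  lab <- data.frame(x = seq_len(6) - 0.5, y = 4.6,
                    text = c("PF", "RM", "CM", "P", "O", "T"))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$direction),
                       colour = "white", linewidth = 0.4) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$text),
                       size = 3) +
    ggplot2::scale_fill_manual(values = c(increase = "#d7191c",
                                          decrease = "#2c7bb6",
                                          normal = "#1a9641"),
                               drop = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 4.8)) +
    ggplot2::coord_polar(theta = "x", start = 0, direction = 1) +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::theme_void() +
    ggplot2::labs(title = title %||% sprintf("%s, exam %s",
                                             attr(model, "measure"),
                                             attr(model, "exam_id") %||% "?"),
                  fill = NULL)
}

#' Render a donut chart to a file
#'
#' @param model A `donut_chart`.
#' @param path Output figure path (`.png` or `.svg`).
#' @param width,height Figure size in inches.
#' @param ... Passed to [plot_donut()].
#' @return `path`, invisibly.
#' @export
render_donut <- function(model, path, width = 7, height = 4, ...) {
  p <- plot_donut(model, ...)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}
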