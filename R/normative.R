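# Single-patient vs normative-cohort comparison: control matching,
# single-case t-test and compartment classification.

#' Match controls to a patient examination
#'
#' Controls must share the patient's MRI scanner and sedation status
#' exactly. Age matching starts from a window of +/- `age_factor` times the
#' patient's age (in months) and doubles the window until at least `min_n`
#' controls are found, capping at the whole scanner/sedation-matched pool.
#' Selection is deterministic given the pool.
#'
#' @param patient A list or one-row data frame with `age_months`, `scanner`
#'   and `sedation`.
#' @param pool Data frame of candidate controls with columns `subject_id`,
#'   `age_months`, `scanner`, `sedation` (one row per control subject).
#' @param min_n Minimum cohort size (default 10; below this the standard
#'   deviation that anchors the single-case test is too unstable).
#' @param age_factor Initial half-width of the age window as a fraction of
#'   the patient's age (default 0.25).
#' @return A list of class `normative_match` with `subject_ids`, the final
#'   `age_window_months`, and the matching criteria.
#' @export
match_controls <- function(patient, pool, min_n = 10, age_factor = 0.25) {
  patient <- as.list(patient)
  needed <- c("subject_id", "age_months", "scanner", "sedation")
  miss <- setdiff(needed, names(pool))
  if (length(miss)) {
    abort_cst("cst_argument_error",
              sprintf("control pool missing column(s): %s",
                      paste(miss, collapse = ", ")))
  }
  if (!nrow(pool)) abort_cst("cst_argument_error", "control pool is empty")
  hard <- pool[pool$scanner == patient$scanner &
                 pool$sedation == patient$sedation, , drop = FALSE]
  if (nrow(hard) < min_n) {
    abort_cst("cst_insufficient_controls",
              sprintf("only %d controls share scanner '%s' and sedation %s; need %d",
                      nrow(hard), patient$scanner, patient$sedation, min_n))
  }
  w <- max(age_factor * patient$age_months, 0.5)
  repeat {
    sel <- abs(hard$age_months - patient$age_months) <= w
    if (sum(sel) >= min_n || all(sel)) break
    w <- 2 * w
  }
  structure(list(subject_ids = hard$subject_id[sel],
                 age_window_months = w,
                 criteria = list(scanner = patient$scanner,
                                 sedation = patient$sedation,
                                 age_months = patient$age_months,
                                 min_n = min_n, age_factor = age_factor)),
            class = "normative_match")
}

#' @export
print.normative_match <- function(x, ...) {
  cat(sprintf("<normative_match> %d controls (scanner %s, sedation %s, age %.4g +/- %.4g mo)\n",
              length(x$subject_ids), x$criteria$scanner, x$criteria$sedation,
              x$criteria$age_months, x$age_window_months))
  invisible(x)
}

#' Single-case t-test against a control sample
#'
#' Compares one patient value with a sample of control values using the
#' pooled-variance two-sample t-test with a singleton first sample, which
#' reduces to the Crawford-Howell single-case form
#' \deqn{t = (x - \bar{m}) / (s \sqrt{1 + 1/n}), \quad df = n - 1,}
#' where \eqn{\bar{m}} and \eqn{s} are the control mean and standard
#' deviation and \eqn{n} the number of controls. The p-value is two-sided.
#'
#' @param patient_value A single numeric value.
#' @param control_values Numeric vector of at least 3 control values with
#'   nonzero standard deviation.
#' @return List with `t`, `p`, `df`, `n_controls`, `control_mean`,
#'   `control_sd`.
#' @export
single_case_t <- function(patient_value, control_values) {
  if (length(patient_value) != 1L || !is.finite(patient_value)) {
    abort_cst("cst_argument_error", "patient_value must be a single finite number")
  }
  n <- length(control_values)
  if (n < 3L) {
    abort_cst("cst_insufficient_data",
              sprintf("need at least 3 control values, got %d", n))
  }
  m <- mean(control_values)
  s <- stats::sd(control_values)
  if (s == 0) {
    abort_cst("cst_degenerate_cohort", "control values have zero variance")
  }
  tt <- (patient_value - m) / (s * sqrt(1 + 1 / n))
  df <- n - 1
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df, n_controls = n,
       control_mean = m, control_sd = s)
}

# Vectorised Crawford-Howell over rows of a control matrix (rows = keys,
# cols = control subjects). Returns a data frame; rows with zero control sd
# get NA statistics and a note.
single_case_t_rows <- function(patient_values, control_mat) {
  n <- ncol(control_mat)
  m <- rowMeans(control_mat)
  s <- apply(control_mat, 1L, stats::sd)
  tt <- (patient_values - m) / (s * sqrt(1 + 1 / n))
  p <- 2 * stats::pt(-abs(tt), n - 1)
  note <- ifelse(s == 0, "degenerate cohort (zero control sd)", "")
  tt[s == 0] <- NA_real_
  p[s == 0] <- NA_real_
  data.frame(patient_value = patient_values, control_mean = m, control_sd = s,
             n_controls = n, t = tt, p = p, note = note,
             stringsAsFactors = FALSE)
}

#' Classify all compartments of a patient examination
#'
#' Runs the single-case t-test for every compartment and both measures
#' (A-CBF and R-CBF) against the control tables, and classifies each
#' (compartment, measure) as `"increase"`, `"decrease"` or `"normal"`:
#' increase if p < alpha and the patient value exceeds the control mean,
#' decrease if p < alpha and it is below, normal otherwise. No
#' multiple-comparison correction is applied by default (matching the plain
#' alpha = 0.05 rule); `p_adjust = "BH"` optionally applies
#' Benjamini-Hochberg across the 72 tests before thresholding.
#'
#' Compartments whose control sample is degenerate are flagged in the
#' `note` column with `direction = NA`; the remaining compartments are
#' still classified.
#'
#' @param patient_table A `cbf_table` for the patient examination.
#' @param control_tables List of `cbf_table` objects, one per control
#'   subject (e.g. the tables of the cohort selected by
#'   [match_controls()]).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data frame of class `compartment_status` with 72 rows
#'   (36 compartments x 2 measures): `exam_id`, `structure`, `subdivision`,
#'   `hemisphere`, `measure`, `patient_value`, `control_mean`,
#'   `control_sd`, `n_controls`, `t`, `p`, `direction`, `note`.
#' @export
classify_compartments <- function(patient_table, control_tables,
                                  alpha = 0.05, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (length(control_tables) < 3L) {
    abort_cst("cst_insufficient_data", "need at least 3 control tables")
  }
  keys <- compartment_keys()
  key_str <- paste(keys$structure, keys$subdivision, keys$hemisphere)
  align <- function(tab) {
    idx <- match(key_str, paste(tab$structure, tab$subdivision, tab$hemisphere))
    if (anyNA(idx)) {
      abort_cst("cst_completeness_error", "CBF table does not cover all 36 compartments")
    }
    tab[idx, , drop = FALSE]
  }
  pt <- align(patient_table)
  ctrl <- lapply(control_tables, align)
  a_mat <- vapply(ctrl, function(x) x$a_cbf, numeric(36L))
  r_mat <- vapply(ctrl, function(x) x$r_cbf, numeric(36L))

  res_a <- single_case_t_rows(pt$a_cbf, a_mat)
  res_r <- single_case_t_rows(pt$r_cbf, r_mat)
  out <- rbind(
    cbind(keys, measure = "A-CBF", res_a, stringsAsFactors = FALSE),
    cbind(keys, measure = "R-CBF", res_r, stringsAsFactors = FALSE))
  p_thr <- out$p
  if (p_adjust == "BH") p_thr <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(is.na(p_thr), NA_character_,
                          ifelse(p_thr < alpha & out$patient_value > out$control_mean,
                                 "increase",
                                 ifelse(p_thr < alpha & out$patient_value < out$control_mean,
                                        "decrease", "normal")))
  out <- cbind(exam_id = pt$exam_id[1], out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("compartment_status", "data.frame")
  out
}

#' Write / read a compartment status table as TSV
#'
#' @param status A `compartment_status` data frame.
#' @param path File path.
#' @return `path` (write) or a `compartment_status` (read).
#' @export
write_status_table <- function(status, path) {
  utils::write.table(as.data.frame(status), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_status_table
#' @export
read_status_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"direction" %in% names(out)) {
    abort_cst("cst_format_error", "not a status table (no direction column)")
  }
  if (!"note" %in% names(out)) out$note <- ""
  out$note[is.na(out$note)] <- ""
  class(out) <- c("compartment_status", "data.frame")
  out
}
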