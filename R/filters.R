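# Eligibility filtering of a generic patient-level table, and the descriptive
# outputs: treatment frequency table and crude mortality rates.

# Normalize a regimen label: components separated by "+", sorted, so that
# "Memantine+Donepezil" and "Donepezil+Memantine" are the same regimen.
normalize_regimen <- function(x) {
  vapply(strsplit(x, "\\s*\\+\\s*"), function(parts)
    paste(sort(trimws(parts)), collapse = "+"), character(1))
}

# Map a normalized regimen to the strategy code 0..3, NA when outside the
# four-strategy taxonomy.
regimen_to_treatment <- function(x) {
  match(normalize_regimen(x), normalize_regimen(treatment_levels())) - 1L
}

#' Apply the study eligibility filters
#'
#' Applies, in order: (1) first diagnosis inside the date window; (2) complete
#' demographics (an explicit `"Unknown"` level is valid, a missing value is
#' not); (3) removal of treatment switchers (patients whose medication history
#' maps to more than one distinct regimen over follow-up); (4) restriction to
#' the allowed treatment strategies; (5) removal of any strategy used by less
#' than `min_treatment_share` of the post-switcher cohort. Surviving records
#' get the integer `treatment` code 0..3.
#'
#' `med_history` is a character column of regimens separated by `"|"`, each
#' regimen itself a `"+"`-joined drug combination (e.g.
#' `"Donepezil|Donepezil+Memantine"` is a switcher under the strict rule).
#'
#' @param records patient-level data.frame with columns `patient_id`,
#'   `first_dx_date` (Date), the demographic columns, and `med_history`.
#' @param dx_window length-2 Date vector, inclusive window for the first
#'   diagnosis (default calendar year 2016).
#' @param min_followup minimum follow-up in years guaranteed by the window
#'   given the data horizon (recorded in the report; default 5).
#' @param switcher_rule `"strict"` (any change of regimen, including
#'   monotherapy followed by the combination, is a switch) or
#'   `"augmentation_as_combo"` (a history confined to one monotherapy plus the
#'   combination counts as combination use).
#' @param allowed_treatments character vector of allowed regimen labels
#'   (default the four-strategy taxonomy of [treatment_levels()]).
#' @param min_treatment_share minimum fraction of the post-switcher cohort a
#'   strategy must reach (default 0.005).
#' @param demographic_cols names of the required demographic columns.
#' @return list with `records` (filtered data.frame, plus `treatment`) and
#'   `report` (a `filter_report`: data.frame of per-step in/out counts with
#'   attribute `final_n`).
#' @export
apply_study_filters <- function(records,
                                dx_window = as.Date(c("2016-01-01",
                                                      "2016-12-31")),
                                min_followup = 5,
                                switcher_rule = c("strict",
                                                  "augmentation_as_combo"),
                                allowed_treatments = treatment_levels(),
                                min_treatment_share = 0.005,
                                demographic_cols = c("age_group", "sex",
                                                     "race", "marital")) {
  switcher_rule <- match.arg(switcher_rule)
  required <- c("patient_id", "first_dx_date", "med_history", demographic_cols)
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop_drc("drc_schema", "missing required column(s): %s",
             paste(missing_cols, collapse = ", "))

  steps <- character(0)
  n_in <- integer(0)
  n_out <- integer(0)
  note <- function(name, before, after) {
    steps <<- c(steps, name)
    n_in <<- c(n_in, before)
    n_out <<- c(n_out, after)
  }

  # (1) diagnosis window (whole calendar dates, boundaries inclusive)
  n0 <- nrow(records)
  keep <- !is.na(records$first_dx_date) &
    records$first_dx_date >= dx_window[1] &
    records$first_dx_date <= dx_window[2]
  records <- records[keep, , drop = FALSE]
  note("dx_window", n0, nrow(records))

  # (2) complete demographics ("Unknown" is a level; NA / empty is absence)
  n0 <- nrow(records)
  complete <- rep(TRUE, nrow(records))
  for (cl in demographic_cols) {
    v <- records[[cl]]
    complete <- complete & !is.na(v) & trimws(as.character(v)) != ""
  }
  records <- records[complete, , drop = FALSE]
  note("complete_demographics", n0, nrow(records))

  # (3) treatment switchers
  n0 <- nrow(records)
  regimen_sets <- lapply(strsplit(as.character(records$med_history),
                                  "\\s*\\|\\s*"),
                         function(r) unique(normalize_regimen(r)))
  combo <- normalize_regimen(treatment_levels()[4])
  monos <- normalize_regimen(treatment_levels()[2:3])
  resolved <- vapply(regimen_sets, function(s) {
    if (length(s) == 1) return(s)
    if (switcher_rule == "augmentation_as_combo" &&
        combo %in% s && all(s %in% c(monos, combo)) &&
        sum(s %in% monos) <= 1)
      return(combo)
    NA_character_
  }, character(1))
  keep <- !is.na(resolved)
  records <- records[keep, , drop = FALSE]
  resolved <- resolved[keep]
  note("treatment_switchers", n0, nrow(records))

  # (4) allowed strategies
  n0 <- nrow(records)
  allowed_norm <- normalize_regimen(allowed_treatments)
  keep <- resolved %in% allowed_norm
  records <- records[keep, , drop = FALSE]
  resolved <- resolved[keep]
  note("allowed_treatments", n0, nrow(records))

  # (5) minimum strategy share, evaluated on the post-switcher cohort
  n0 <- nrow(records)
  if (nrow(records) > 0) {
    share <- table(resolved) / nrow(records)
    keep <- resolved %in% names(share)[share >= min_treatment_share]
    records <- records[keep, , drop = FALSE]
    resolved <- resolved[keep]
  }
  note("min_treatment_share", n0, nrow(records))

  records$treatment <- regimen_to_treatment(resolved)
  report <- structure(
    data.frame(step = steps, n_in = n_in, n_out = n_out,
               stringsAsFactors = FALSE),
    final_n = nrow(records),
    min_followup = min_followup,
    class = c("filter_report", "data.frame"))
  list(records = records, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> final_n =", attr(x, "final_n"), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report a `filter_report` from [apply_study_filters()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
filter_report_json <- function(report, path = NULL) {
  obj <- list(steps = as.data.frame(report), final_n = attr(report, "final_n"))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Treatment frequency table
#'
#' Counts and percent-of-total per treatment label. Percentages use two
#' decimals with half-up rounding and sum to 100 up to rounding.
#'
#' @param records data.frame with a `treatment` (0..3) or `med_history`
#'   column.
#' @return data.frame with columns `label`, `count`, `percent`.
#' @export
treatment_frequency_table <- function(records) {
  if (!is.null(records$treatment)) {
    lab <- treatment_levels()[records$treatment + 1L]
  } else if (!is.null(records$med_history)) {
    lab <- normalize_regimen(as.character(records$med_history))
  } else {
    stop_drc("drc_schema", "missing required column(s): treatment or med_history")
  }
  tab <- sort(table(lab), decreasing = TRUE)
  data.frame(label = names(tab),
             count = as.integer(tab),
             percent = round_half_up(100 * as.integer(tab) / sum(tab), 2),
             stringsAsFactors = FALSE)
}

#' Crude mortality rates per 1000 patient-years
#'
#' rate = 1000 x deaths / total follow-up years, per treatment group and in
#' total. A group with zero person-time gets an `NA` rate rather than an
#' error.
#'
#' @param records data.frame with `y5_survival`, `followup_years` and (for
#'   grouping) `treatment`.
#' @param group_by column to group by, `"treatment"` by default; `NULL` for a
#'   single overall rate.
#' @return data.frame with columns `group`, `deaths`, `person_years`, `rate`
#'   (last row `"Total"`).
#' @export
mortality_rate <- function(records, group_by = "treatment") {
  if (is.null(records$y5_survival) || is.null(records$followup_years))
    stop_drc("drc_schema",
             "missing required column(s): y5_survival, followup_years")
  one <- function(df) {
    deaths <- sum(df$y5_survival == 0)
    py <- sum(df$followup_years)
    data.frame(deaths = deaths, person_years = py,
               rate = if (py > 0) 1000 * deaths / py else NA_real_)
  }
  if (is.null(group_by)) {
    out <- cbind(group = "Total", one(records))
    return(out)
  }
  g <- records[[group_by]]
  if (group_by == "treatment") g <- treatment_levels()[g + 1L]
  parts <- lapply(split(records, g), one)
  out <- do.call(rbind, c(
    Map(function(nm, df) cbind(group = nm, df), names(parts), parts),
    list(cbind(group = "Total", one(records)))))
  rownames(out) <- NULL
  out
}
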