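# Recoding rules and CSV I/O for wide-format twin-pair tables.
#
# A pair table is a data.frame with one row per twin pair:
#   pair_id, zygosity (MZ|DZ), and per twin (_1/_2 suffix):
#   attainment, performance, tracking (immediate|delayed|blank),
#   male (0|1), birth_year.
# Centering constants (performance mean, birth-year mean) live in
# attr(, "centering") so fits are reproducible from the table alone.

.track_scores <- c(
  "VMBO-b" = 0, "VMBO-basis" = 0,
  "VMBO-k" = 1, "VMBO-kader" = 1,
  "VMBO-g/t" = 2, "VMBO-g" = 2, "VMBO-t" = 2, "VMBO-theoretisch" = 2,
  "VMBO-gemengd" = 2,
  "HAVO" = 3,
  "VWO" = 4, "Gymnasium" = 4, "VWO/Gymnasium" = 4)

#' Score reported secondary-school tracks on the 0-4 attainment scale
#'
#' Dutch secondary tracks are scored 0 = VMBO-b, 1 = VMBO-k,
#' 2 = VMBO-g/t, 3 = HAVO, 4 = VWO/Gymnasium. Some survey eras combined
#' VMBO tracks into one answer category: a bare `"VMBO"` answer scores 1.5
#' in the 2004-2008 surveys (enrolment-weighted average over all VMBO
#' tracks) and 0.5 in the 2009-2014 surveys (average of VMBO-b and VMBO-k,
#' since VMBO-theoretisch was a separate category there). When several
#' tracks are reported, the arithmetic mean of their scores is returned.
#'
#' @param reported_tracks Character vector of track labels.
#' @param survey_era One of `"2004-2008"`, `"2009-2014"`, `"age-12-survey"`
#'   (the age-12 surveys list all VMBO tracks separately, so a bare "VMBO"
#'   is not a recognised answer there).
#' @return Numeric score in `[0, 4]`; `NA` for an empty input.
#' @examples
#' score_attainment("VWO")                      # 4
#' score_attainment("VMBO", "2004-2008")        # 1.5
#' score_attainment(c("HAVO", "VWO"))           # 3.5
#' @export
score_attainment <- function(reported_tracks,
                             survey_era = c("age-12-survey", "2004-2008",
                                            "2009-2014")) {
  survey_era <- match.arg(survey_era)
  reported_tracks <- reported_tracks[!is.na(reported_tracks) &
                                       nzchar(reported_tracks)]
  if (length(reported_tracks) == 0L) return(NA_real_)
  scores <- vapply(reported_tracks, function(lab) {
    if (lab == "VMBO") {
      switch(survey_era,
             "2004-2008" = 1.5,
             "2009-2014" = 0.5,
             stop("track label 'VMBO' is not a recognised category in the ",
                  survey_era, " surveys", call. = FALSE))
    } else if (lab %in% names(.track_scores)) {
      .track_scores[[lab]]
    } else {
      stop("unrecognised track label: '", lab, "'", call. = FALSE)
    }
  }, numeric(1))
  mean(scores)
}

#' Classify tracking timing from parental class-composition reports
#'
#' A child who enters secondary school in a class combining two or more
#' track levels (a heterogeneous class) has its definitive tracking
#' delayed; a single-level class means immediate tracking. The mother's
#' report takes priority; the father's is used only when the mother's is
#' missing.
#'
#' @param mother_report,father_report Number of track levels in the child's
#'   class (>= 1), or `NA` when the parent did not respond.
#' @return `"delayed"`, `"immediate"`, or `"missing"`.
#' @examples
#' determine_tracking_timing(2, 1)    # "delayed"  (mother priority)
#' determine_tracking_timing(NA, 1)   # "immediate"
#' @export
determine_tracking_timing <- function(mother_report = NA,
                                      father_report = NA) {
  pick <- if (!is.na(mother_report)) mother_report else father_report
  if (is.na(pick)) return("missing")
  if (!is.numeric(pick) || pick < 1)
    stop("track-level count must be a positive number, got ", pick)
  if (pick >= 2) "delayed" else "immediate"
}

#' Assign a zygosity-by-concordance group label to each pair
#'
#' Pairs are grouped by zygosity crossed with the pair's tracking pattern:
#' `both-immediate`, `both-delayed`, `discordant` (one immediate, one
#' delayed), or `tracking-missing` (at least one twin's timing unknown).
#' Estimation uses each twin's own status; this label is the descriptive
#' pair-level grouping.
#'
#' @param zygosity `"MZ"` or `"DZ"` (vectorized).
#' @param tracking1,tracking2 Per-twin statuses among
#'   `"immediate"`, `"delayed"`, `"missing"` (`NA` treated as missing).
#' @return Character vector like `"MZ/both-immediate"`.
#' @export
assign_pair_group <- function(zygosity, tracking1, tracking2) {
  stopifnot(all(zygosity %in% c("MZ", "DZ")))
  t1 <- ifelse(is.na(tracking1), "missing", tracking1)
  t2 <- ifelse(is.na(tracking2), "missing", tracking2)
  ok <- c("immediate", "delayed", "missing")
  if (!all(t1 %in% ok) || !all(t2 %in% ok))
    stop("tracking status must be immediate, delayed or missing")
  conc <- ifelse(t1 == "missing" | t2 == "missing", "tracking-missing",
          ifelse(t1 == t2,
                 ifelse(t1 == "immediate", "both-immediate", "both-delayed"),
                 "discordant"))
  paste(zygosity, conc, sep = "/")
}

.pair_cols <- c("pair_id", "zygosity",
                paste0(rep(c("attainment", "performance", "tracking",
                             "male", "birth_year"), each = 2), c("_1", "_2")))

#' Read a wide-format twin-pair table from CSV
#'
#' Expects a UTF-8 CSV with header columns `pair_id`, `zygosity` and per
#' twin (`_1`/`_2`): `attainment`, `performance`, `tracking`, `male`,
#' `birth_year`. Empty cells encode missing values. Performance and birth
#' year are centered against the means of the non-missing values in the
#' loaded sample (stored in `attr(, "centering")`; pass `centering` to
#' override, e.g. to score new data against a reference sample).
#'
#' @param path CSV file path.
#' @param centering Optional list with `performance_mean` and
#'   `birth_year_mean` to use fixed centering constants.
#' @return A `pair_table` data.frame with added columns
#'   `performance_c_1/_2`, `birth_year_c_1/_2`, `group`, and attributes
#'   `centering`.
#' @export
read_pair_table <- function(path, centering = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(.pair_cols, names(raw))
  if (length(missing_cols))
    stop("pair table lacks mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  bad_zyg <- which(!raw$zygosity %in% c("MZ", "DZ"))
  if (length(bad_zyg))
    stop("unparseable zygosity in rows: ",
         paste(utils::head(bad_zyg, 10), collapse = ", "))
  dup <- raw$pair_id[duplicated(raw$pair_id)]
  if (length(dup))
    stop("duplicated pair ids: ", paste(unique(dup), collapse = ", "))
  bad_trk <- !(is.na(raw$tracking_1) |
                 raw$tracking_1 %in% c("immediate", "delayed", "missing")) |
             !(is.na(raw$tracking_2) |
                 raw$tracking_2 %in% c("immediate", "delayed", "missing"))
  if (any(bad_trk))
    stop("invalid tracking values in rows: ",
         paste(which(bad_trk), collapse = ", "))
  as_pair_table(raw, centering = centering)
}

#' Finalize a data.frame as a pair table
#'
#' Validates columns, computes centered performance/birth-year columns and
#' the pair group label. Used by [read_pair_table()] and [simulate_pairs()].
#'
#' @param df Data.frame with the pair-table columns.
#' @param centering Optional fixed centering constants (see
#'   [read_pair_table()]).
#' @return A `pair_table` data.frame.
#' @export
as_pair_table <- function(df, centering = NULL) {
  missing_cols <- setdiff(.pair_cols, names(df))
  if (length(missing_cols))
    stop("pair table lacks mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  perf <- c(df$performance_1, df$performance_2)
  yob <- c(df$birth_year_1, df$birth_year_2)
  if (is.null(centering)) {
    centering <- list(performance_mean = mean(perf, na.rm = TRUE),
                      birth_year_mean = mean(yob, na.rm = TRUE))
  }
  df$performance_c_1 <- df$performance_1 - centering$performance_mean
  df$performance_c_2 <- df$performance_2 - centering$performance_mean
  df$birth_year_c_1 <- df$birth_year_1 - centering$birth_year_mean
  df$birth_year_c_2 <- df$birth_year_2 - centering$birth_year_mean
  df$group <- assign_pair_group(df$zygosity, df$tracking_1, df$tracking_2)
  attr(df, "centering") <- centering
  class(df) <- c("pair_table", "data.frame")
  df
}

#' Write a pair table to CSV
#'
#' Writes the mandatory wide-format columns; missing values become empty
#' cells, so `write_pair_table()` then [read_pair_table()] round-trips
#' losslessly (derived columns are recomputed on read).
#'
#' @param pairs A pair table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.csv(pairs[, .pair_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.pair_table <- function(x, ...) {
  cat("Twin pair table:", nrow(x), "pairs\n")
  print(table(group = x$group))
  ctr <- attr(x, "centering")
  if (!is.null(ctr))
    cat(sprintf("centering: performance %.2f, birth year %.2f\n",
                ctr$performance_mean, ctr$birth_year_mean))
  invisible(x)
}

# Relatedness from zygosity.
.relatedness <- function(zygosity) ifelse(zygosity == "MZ", 1, 0.5)
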