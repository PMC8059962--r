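#' @title Specimen and population data model
#' @description
#' The package distinguishes three tabular levels, mirroring how museum
#' drill-hole surveys are recorded:
#' \itemize{
#'   \item \emph{traces}: one row per drill hole (diameter, outline shape,
#'     complete or incomplete penetration);
#'   \item \emph{specimens}: one row per echinoid test (surface visibility,
#'     four ordinal abrasion sub-scores, test diameter);
#'   \item \emph{populations}: one row per taxon x locality x stratigraphic
#'     unit (counts of individuals and drilled individuals, hole counts,
#'     mean taphonomic grade, drilling frequency).
#' }
#' Population rows carry a \code{source} flag: \code{"EAT"} for systematically
#' surveyed (specimen-backed) populations, \code{"LIT"} for literature-derived
#' frequencies that have no specimen backing and no taphonomic grades.
#' @name dataset-model
NULL

.outline_levels <- c("circular", "subcircular", "irregular", "rectangular",
                     "elongated", "notched", "minute")
.predatory_outlines <- setdiff(.outline_levels, "minute")

#' Read and validate a population table
#'
#' @param path CSV with columns \code{population_id, taxon, life_habit, stage,
#'   source, n_individuals, n_drilled, n_holes_complete, n_holes_incomplete,
#'   mean_taph_grade} (\code{mean_taph_grade} may be blank for LIT rows).
#' @param timescale A \code{stage_table} used to resolve stage names.
#' @return Validated data.frame with canonical stage spellings and a computed
#'   \code{drilling_frequency} column.
#' @export
read_populations <- function(path, timescale = load_timescale()) {
  df <- read_csv_checked(path)
  validate_populations(df, timescale, what = paste0("populations file '", path, "'"))
}

#' Validate a population table held in memory
#'
#' Applied by [read_populations()] and by the synthetic generator so that
#' generated data always passes the same checks as ingested data.
#'
#' @param df Population data.frame (see [read_populations()]).
#' @param timescale A \code{stage_table}.
#' @param what Label used in error messages.
#' @return The validated data.frame, stages canonicalized,
#'   \code{drilling_frequency} (re)computed.
#' @export
validate_populations <- function(df, timescale = load_timescale(),
                                 what = "population table") {
  check_cols(df, c("population_id", "taxon", "life_habit", "stage", "source",
                   "n_individuals", "n_drilled", "n_holes_complete",
                   "n_holes_incomplete"), what)
  fail_rows <- function(bad, msg) {
    if (length(bad))
      stop_ctx(what, ": ", msg, " in row(s) ", paste(bad, collapse = ", "))
  }
  fail_rows(which(!df$source %in% c("EAT", "LIT")), "source must be EAT or LIT")
  fail_rows(which(!df$life_habit %in% c("epifaunal", "infaunal")),
            "life_habit must be epifaunal or infaunal")
  fail_rows(which(is.na(df$n_individuals) | df$n_individuals < 1),
            "n_individuals must be >= 1")
  fail_rows(which(is.na(df$n_drilled) | df$n_drilled < 0 |
                  df$n_drilled > df$n_individuals),
            "n_drilled must satisfy 0 <= n_drilled <= n_individuals")
  fail_rows(which(is.na(df$n_holes_complete) | df$n_holes_complete < 0 |
                  is.na(df$n_holes_incomplete) | df$n_holes_incomplete < 0),
            "hole counts must be non-negative")
  if (!"mean_taph_grade" %in% names(df)) df$mean_taph_grade <- NA_real_
  fail_rows(which(df$source == "EAT" & is.na(df$mean_taph_grade)),
            "EAT rows must carry mean_taph_grade")
  stage_idx <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    stage_idx[i] <- tryCatch(resolve_stage(timescale, df$stage[i]),
      error = function(e) stop_ctx(what, ": row ", i, ": ", conditionMessage(e)))
  }
  df$stage <- timescale$name[stage_idx]
  df$drilling_frequency <- df$n_drilled / df$n_individuals
  df
}

#' Read a specimen table
#'
#' @param path CSV with columns \code{specimen_id, population_id,
#'   visible_fraction, subscore_ambitus, subscore_periproct,
#'   subscore_peristome, subscore_apical, test_diameter}.
#' @param scale_max Maximum value of each ordinal abrasion sub-score
#'   (default 3, giving a summed taphonomic grade in 0..12).
#' @return Validated specimen data.frame.
#' @export
read_specimens <- function(path, scale_max = 3L) {
  df <- read_csv_checked(path)
  what <- paste0("specimens file '", path, "'")
  check_cols(df, c("specimen_id", "population_id", "visible_fraction",
                   "subscore_ambitus", "subscore_periproct",
                   "subscore_peristome", "subscore_apical", "test_diameter"),
             what)
  bad <- which(is.na(df$visible_fraction) | df$visible_fraction < 0 |
               df$visible_fraction > 1)
  if (length(bad))
    stop_ctx(what, ": visible_fraction outside [0,1] in row(s) ",
             paste(bad, collapse = ", "))
  sub <- df[, c("subscore_ambitus", "subscore_periproct",
                "subscore_peristome", "subscore_apical")]
  bad <- which(apply(sub, 1L, function(s) any(is.na(s) | s < 0 | s > scale_max)))
  if (length(bad))
    stop_ctx(what, ": sub-score missing or outside 0..", scale_max,
             " in row(s) ", paste(bad, collapse = ", "))
  bad <- which(is.na(df$test_diameter) | df$test_diameter <= 0)
  if (length(bad))
    stop_ctx(what, ": test_diameter must be positive in row(s) ",
             paste(bad, collapse = ", "))
  df
}

#' Read a trace (drill hole) table
#'
#' @param path CSV with columns \code{specimen_id, diameter_mm, outline,
#'   complete} (\code{complete} coded 0/1).
#' @return Validated trace data.frame with logical \code{complete}.
#' @export
read_traces <- function(path) {
  df <- read_csv_checked(path)
  what <- paste0("traces file '", path, "'")
  check_cols(df, c("specimen_id", "diameter_mm", "outline", "complete"), what)
  bad <- which(is.na(df$diameter_mm) | df$diameter_mm <= 0)
  if (length(bad))
    stop_ctx(what, ": diameter_mm must be positive in row(s) ",
             paste(bad, collapse = ", "))
  bad <- which(!df$outline %in% .outline_levels)
  if (length(bad))
    stop_ctx(what, ": unknown outline in row(s) ", paste(bad, collapse = ", "),
             " (allowed: ", paste(.outline_levels, collapse = ", "), ")")
  df$complete <- as.logical(df$complete)
  df
}

#' Summed taphonomic grade of specimens
#'
#' Abrasion is scored separately on the ambitus, periproct, peristome and
#' apical disc on a fixed ordinal scale, then summed; higher scores mean
#' poorer preservation. No imputation: any missing sub-score is an error.
#'
#' @param specimens Specimen data.frame (see [read_specimens()]).
#' @param scale_max Per-region maximum score (default 3; grade range 0..12).
#' @return Integer vector of summed grades, one per specimen.
#' @export
taphonomic_grade <- function(specimens, scale_max = 3L) {
  cols <- c("subscore_ambitus", "subscore_periproct",
            "subscore_peristome", "subscore_apical")
  check_cols(specimens, cols, "specimen table")
  sub <- as.matrix(specimens[, cols])
  if (anyNA(sub)) {
    bad <- which(apply(sub, 1L, anyNA))
    stop_ctx("missing taphonomic sub-score in row(s) ",
             paste(bad, collapse = ", "), "; no imputation is performed")
  }
  if (any(sub < 0 | sub > scale_max))
    stop_ctx("taphonomic sub-scores must lie in 0..", scale_max)
  as.integer(rowSums(sub))
}

#' Classify drill holes as predatory, parasitic or unclassified
#'
#' Predatory (cassid-type) drill holes are diagnosed by size and outline:
#' diameter at least \code{min_predatory_mm} (traces on minute echinoid taxa
#' are exempt from the size criterion) and an outline in the predatory set
#' (circular, subcircular, irregular, rectangular, elongated, notched).
#' Sub-threshold holes on non-minute hosts are attributed to eulimid
#' gastropod parasitism and excluded from drilling frequencies. The
#' classification is total: every trace maps to exactly one class.
#'
#' @param diameter_mm Hole diameter(s), mm.
#' @param outline Outline class(es); see [read_traces()] for allowed values.
#' @param test_diameter_mm Host test diameter(s), mm.
#' @param minute_taxon_threshold Test diameter (mm) below which a host counts
#'   as a minute taxon (default 10).
#' @param min_predatory_mm Minimum predatory hole diameter on non-minute
#'   hosts (default 0.5).
#' @return Character vector in \code{{"predatory","parasitic","unclassified"}}.
#' @examples
#' classify_trace(1.2, "circular", 40)            # predatory
#' classify_trace(0.2, "circular", 40)            # parasitic (eulimid)
#' classify_trace(0.3, "circular", 8)             # predatory: minute host
#' @export
classify_trace <- function(diameter_mm, outline, test_diameter_mm,
                           minute_taxon_threshold = 10,
                           min_predatory_mm = 0.5) {
  if (any(diameter_mm <= 0) || any(test_diameter_mm <= 0))
    stop_ctx("trace and host diameters must be positive")
  if (any(!outline %in% .outline_levels))
    stop_ctx("unknown outline value(s): ",
             paste(unique(setdiff(outline, .outline_levels)), collapse = ", "))
  n <- max(length(diameter_mm), length(outline), length(test_diameter_mm))
  diameter_mm <- rep_len(diameter_mm, n)
  outline <- rep_len(outline, n)
  test_diameter_mm <- rep_len(test_diameter_mm, n)
  minute_host <- test_diameter_mm < minute_taxon_threshold
  predatory <- outline %in% .predatory_outlines &
    (diameter_mm >= min_predatory_mm | minute_host)
  parasitic <- !predatory & diameter_mm < min_predatory_mm & !minute_host
  out <- rep("unclassified", n)
  out[parasitic] <- "parasitic"
  out[predatory] <- "predatory"
  out
}

#' Retain specimens with sufficient visible test surface
#'
#' Specimens qualify for drill-hole survey only when more than
#' \code{min_visible} of the test surface is observable (strictly greater:
#' a half-visible test is excluded).
#'
#' @param specimens Specimen data.frame.
#' @param min_visible Visibility threshold as a proportion (default 0.5).
#' @return Filtered specimen data.frame.
#' @export
filter_specimens <- function(specimens, min_visible = 0.5) {
  check_cols(specimens, "visible_fraction", "specimen table")
  specimens[specimens$visible_fraction > min_visible, , drop = FALSE]
}

#' Retain populations with a minimum number of individuals
#'
#' @param populations Population data.frame.
#' @param min_n Minimum population size, inclusive (default 10).
#' @return Filtered population data.frame.
#' @export
filter_populations <- function(populations, min_n = 10L) {
  check_cols(populations, "n_individuals", "population table")
  populations[populations$n_individuals >= min_n, , drop = FALSE]
}

#' Aggregate specimens and traces into population records
#'
#' Builds one population row per \code{population_id}: \code{n_individuals}
#' counts retained specimens, \code{n_drilled} counts specimens bearing at
#' least one predatory trace (individual-based, not hole-based), hole counts
#' sum predatory traces by completeness, and \code{mean_taph_grade} averages
#' the summed taphonomic grade. Parasitic and unclassified traces never enter
#' the counts. Specimens are expected to have passed [filter_specimens()].
#'
#' @param specimens Specimen data.frame (already visibility-filtered).
#' @param traces Trace data.frame.
#' @param pop_info data.frame with one row per population: \code{population_id,
#'   taxon, life_habit, stage, source}.
#' @param timescale A \code{stage_table} for stage validation.
#' @param scale_max Taphonomic sub-score maximum (default 3).
#' @param minute_taxon_threshold Passed to [classify_trace()].
#' @return Validated population data.frame (see [read_populations()]).
#' @export
summarize_populations <- function(specimens, traces, pop_info,
                                  timescale = load_timescale(),
                                  scale_max = 3L, minute_taxon_threshold = 10) {
  check_cols(pop_info, c("population_id", "taxon", "life_habit", "stage", "source"),
             "pop_info")
  empty <- setdiff(pop_info$population_id, specimens$population_id)
  if (length(empty))
    stop_ctx("population(s) with zero retained specimens: ",
             paste(empty, collapse = ", "))
  host <- specimens$test_diameter[match(traces$specimen_id, specimens$specimen_id)]
  keep <- !is.na(host)  # traces on filtered-out specimens are not surveyed
  traces <- traces[keep, , drop = FALSE]
  host <- host[keep]
  cls <- classify_trace(traces$diameter_mm, traces$outline, host,
                        minute_taxon_threshold = minute_taxon_threshold)
  pred <- traces[cls == "predatory", , drop = FALSE]
  grade <- taphonomic_grade(specimens, scale_max = scale_max)
  pop_of <- specimens$population_id
  drilled_specs <- unique(pred$specimen_id)
  is_drilled <- specimens$specimen_id %in% drilled_specs
  pred_pop <- specimens$population_id[match(pred$specimen_id, specimens$specimen_id)]

  agg <- function(v, pops, f) {
    out <- tapply(v, factor(pops, levels = pop_info$population_id), f)
    ifelse(is.na(out), 0, out)
  }
  n_ind <- agg(rep(1L, nrow(specimens)), pop_of, sum)
  n_drl <- agg(as.integer(is_drilled), pop_of, sum)
  n_cmp <- agg(as.integer(pred$complete), pred_pop, sum)
  n_inc <- agg(as.integer(!pred$complete), pred_pop, sum)
  m_grd <- tapply(grade, factor(pop_of, levels = pop_info$population_id), mean)

  out <- data.frame(
    population_id = pop_info$population_id,
    taxon = pop_info$taxon,
    life_habit = pop_info$life_habit,
    stage = pop_info$stage,
    source = pop_info$source,
    n_individuals = as.integer(n_ind),
    n_drilled = as.integer(n_drl),
    n_holes_complete = as.integer(n_cmp),
    n_holes_incomplete = as.integer(n_inc),
    mean_taph_grade = as.numeric(m_grd),
    stringsAsFactors = FALSE
  )
  validate_populations(out, timescale, what = "summarized populations")
}
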