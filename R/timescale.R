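#' Load a pinned geologic timescale
#'
#' Reads the packaged chronostratigraphic chart and returns a validated stage
#' table spanning the Aalenian (Middle Jurassic) through the Holocene. Every
#' analysis in the package bins populations onto this table, so the chart is
#' pinned to a fixed edition rather than tracking the most recent revision:
#' reproducibility of stage midpoints takes precedence over chart currency.
#'
#' @param chart_version Chart identifier. Only \code{"ICS2013"} (boundaries
#'   consistent with a Chattian base at 28.1 Ma) is shipped.
#' @return A \code{stage_table}: a data.frame with columns \code{name},
#'   \code{older_bound}, \code{younger_bound}, \code{index} (0 = oldest) and
#'   \code{midpoint}, plus attributes \code{chart_version} and \code{aliases}.
#' @examples
#' ts <- load_timescale()
#' stage_midpoint(ts, "Ypresian")
#' @export
load_timescale <- function(chart_version = "ICS2013") {
  fname <- switch(chart_version,
    ICS2013 = "timescale_ics2013.csv",
    stop("unknown chart_version: ", chart_version, call. = FALSE)
  )
  path <- system.file("extdata", fname, package = "echinodrill", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  apath <- system.file("extdata", "stage_aliases.csv",
                       package = "echinodrill", mustWork = TRUE)
  aliases <- utils::read.csv(apath, stringsAsFactors = FALSE)
  as_stage_table(tab, chart_version = chart_version, aliases = aliases)
}

#' Build a stage table from boundary ages
#'
#' Validates the tiling invariant (stages partition time with no gaps or
#' overlaps, ordered oldest to youngest) and attaches midpoints. Exposed
#' mainly so tests and users can supply custom or truncated charts.
#'
#' @param tab data.frame with columns \code{name}, \code{older_bound_ma},
#'   \code{younger_bound_ma}, ordered oldest first.
#' @param chart_version Label recorded on the table and in all outputs.
#' @param aliases Optional data.frame with columns \code{alias},
#'   \code{canonical} used when resolving stage names.
#' @return A \code{stage_table} (see [load_timescale()]).
#' @export
as_stage_table <- function(tab, chart_version = "custom", aliases = NULL) {
  need <- c("name", "older_bound_ma", "younger_bound_ma")
  if (!all(need %in% names(tab)))
    stop("stage table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  n <- nrow(tab)
  if (n < 2L) stop("stage table needs at least two stages", call. = FALSE)
  older <- as.numeric(tab$older_bound_ma)
  younger <- as.numeric(tab$younger_bound_ma)
  bad <- which(!(older > younger) | younger < 0)
  if (length(bad))
    stop("invalid stage bounds (older <= younger or negative) for: ",
         paste(tab$name[bad], collapse = ", "), call. = FALSE)
  mism <- which(abs(younger[-n] - older[-1]) > 1e-9)
  if (length(mism))
    stop("timescale tiling violated between '", tab$name[mism[1]], "' (younger bound ",
         younger[mism[1]], ") and '", tab$name[mism[1] + 1L], "' (older bound ",
         older[mism[1] + 1L], ")", call. = FALSE)
  out <- data.frame(
    name = as.character(tab$name),
    older_bound = older,
    younger_bound = younger,
    index = seq_len(n) - 1L,
    midpoint = (older + younger) / 2,
    stringsAsFactors = FALSE
  )
  attr(out, "chart_version") <- chart_version
  attr(out, "aliases") <- aliases
  class(out) <- c("stage_table", "data.frame")
  out
}

#' @export
print.stage_table <- function(x, ...) {
  cat("Stage table [", attr(x, "chart_version"), "]: ", nrow(x), " stages, ",
      x$older_bound[1], "-", x$younger_bound[nrow(x)], " Ma\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("... and", nrow(x) - 4L, "more stages\n")
  invisible(x)
}

# Resolve a stage name against the table (case-insensitive, alias-aware).
# Returns the row index; errors with nearest-name suggestions.
resolve_stage <- function(table, name) {
  stopifnot(inherits(table, "stage_table"))
  if (length(name) != 1L || is.na(name) || !nzchar(name))
    stop("stage name must be a single non-empty string", call. = FALSE)
  key <- tolower(trimws(name))
  aliases <- attr(table, "aliases")
  if (!is.null(aliases)) {
    hit <- match(key, tolower(aliases$alias))
    if (!is.na(hit)) key <- tolower(aliases$canonical[hit])
  }
  i <- match(key, tolower(table$name))
  if (is.na(i)) {
    d <- utils::adist(key, tolower(table$name))
    near <- table$name[order(d)][seq_len(min(3L, nrow(table)))]
    stop("unknown stage '", name, "'; nearest matches: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  i
}

#' Stage midpoint age
#'
#' Arithmetic mean of a stage's boundary ages, reported to 0.1 Myr precision.
#'
#' @param table A \code{stage_table}.
#' @param name Stage name (case-insensitive; common synonyms resolved).
#' @return Midpoint age in Ma.
#' @examples
#' ts <- load_timescale()
#' stage_midpoint(ts, "Rupelian")  # 31.0
#' @export
stage_midpoint <- function(table, name) {
  vapply(name, function(nm) round(table$midpoint[resolve_stage(table, nm)], 1),
         numeric(1), USE.NAMES = length(name) > 1L)
}

#' Assign an age or stage name to a stage bin
#'
#' Numeric ages use the half-open convention: an age exactly on a stage
#' boundary belongs to the younger stage (0 Ma belongs to the terminal
#' Holocene bin). Stage names are resolved as in [stage_midpoint()].
#'
#' @param table A \code{stage_table}.
#' @param x A numeric age in Ma, or a stage name.
#' @return One row of the table (a \code{data.frame}).
#' @examples
#' ts <- load_timescale()
#' assign_bin(ts, 45.0)$name   # "Lutetian"
#' assign_bin(ts, 47.8)$name   # boundary age -> younger stage, "Lutetian"
#' @export
assign_bin <- function(table, x) {
  stopifnot(inherits(table, "stage_table"))
  if (is.character(x)) return(as.data.frame(table)[resolve_stage(table, x), ])
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("x must be a single age in Ma or a stage name", call. = FALSE)
  n <- nrow(table)
  if (x > table$older_bound[1] || x < table$younger_bound[n])
    stop("age ", x, " Ma outside the table span [",
         table$younger_bound[n], ", ", table$older_bound[1], "] Ma", call. = FALSE)
  # half-open: stage contains ages a with younger_bound < a <= older_bound;
  # the terminal bin additionally contains its younger bound (0 Ma).
  i <- which(x <= table$older_bound & (x > table$younger_bound |
         (table$index == table$index[n] & x >= table$younger_bound)))
  as.data.frame(table)[i[1], ]
}
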