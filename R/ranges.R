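# Range data: one lineage per row with known origination and extinction
# times. Times are "time before reference": non-negative reals, larger =
# older, 0 = the reference (youngest) time.

#' Construct a set of lineage ranges
#'
#' A lineage range records the origination time (`t_start`) and extinction
#' time (`t_end`) of one lineage on the time-before-reference axis
#' (non-negative, larger = older). Extant lineages have `t_end = 0`.
#'
#' @param lineage_id character vector of unique lineage identifiers.
#' @param t_start numeric vector of origination times (time before
#'   reference).
#' @param t_end numeric vector of extinction times; must satisfy
#'   `t_start >= t_end >= 0`.
#' @param extant logical vector; `TRUE` forces `t_end = 0`.
#' @return A `data.frame` of class `"lineage_ranges"` with columns
#'   `lineage_id`, `t_start`, `t_end`, `extant`.
#' @examples
#' lineage_ranges(c("a", "b"), t_start = c(10, 8), t_end = c(0, 5),
#'                extant = c(TRUE, FALSE))
#' @export
lineage_ranges <- function(lineage_id, t_start, t_end, extant) {
  n <- length(lineage_id)
  stopifnot(length(t_start) == n, length(t_end) == n, length(extant) == n)
  lineage_id <- as.character(lineage_id)
  if (anyDuplicated(lineage_id))
    lr_stop("duplicated lineage_id: ",
            paste(unique(lineage_id[duplicated(lineage_id)]), collapse = ", "))
  if (any(!is.finite(t_start)) || any(!is.finite(t_end)))
    lr_stop("non-finite range times")
  t_end[extant] <- 0
  bad <- which(t_start < t_end | t_end < 0)
  if (length(bad))
    lr_stop("invalid range (need t_start >= t_end >= 0) for lineage(s): ",
            paste(lineage_id[bad], collapse = ", "))
  out <- data.frame(lineage_id = lineage_id, t_start = as.numeric(t_start),
                    t_end = as.numeric(t_end), extant = as.logical(extant),
                    stringsAsFactors = FALSE)
  class(out) <- c("lineage_ranges", "data.frame")
  out
}

#' Read a range table
#'
#' Reads a tab-separated table with header columns `lineage_id`, `t_start`,
#' `t_end`, `status` (`status` is `"extant"` or `"extinct"`). By default
#' times are taken as time-before-reference. With `dialect = "calendar"`
#' the two time columns are calendar years (start <= end) and are converted
#' to time before `reference_year` (default: the most recent year present).
#'
#' @param path path to the TSV file.
#' @param dialect `"tbr"` (time-before-reference, default) or `"calendar"`.
#' @param reference_year reference year used for the calendar conversion;
#'   `NULL` uses the maximum year in the file.
#' @return A [lineage_ranges()] object. For `dialect = "calendar"` the
#'   chosen reference year is stored in `attr(x, "reference_year")`.
#' @export
read_range_table <- function(path, dialect = c("tbr", "calendar"),
                             reference_year = NULL) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("lineage_id", "t_start", "t_end", "status")
  if (!all(need %in% names(tab)))
    lr_stop("range table must have columns: ", paste(need, collapse = ", "))
  for (cc in c("t_start", "t_end")) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v) & !is.na(tab[[cc]]))
    if (length(bad))
      lr_stop("malformed ", cc, " in range table row(s): ",
              paste(bad, collapse = ", "))
    tab[[cc]] <- v
  }
  if (!all(tab$status %in% c("extant", "extinct")))
    lr_stop("status must be 'extant' or 'extinct'")
  extant <- tab$status == "extant"
  t_start <- tab$t_start
  t_end <- tab$t_end
  ref <- NULL
  if (dialect == "calendar") {
    bad <- which(t_start > t_end)
    if (length(bad))
      lr_stop("calendar dialect expects first year <= last year; row(s): ",
              paste(bad, collapse = ", "))
    ref <- reference_year %||% max(t_end, t_start)
    new_start <- ref - t_start
    new_end <- ref - t_end
    t_start <- new_start
    t_end <- new_end
  } else {
    bad <- which(t_start < t_end)
    if (length(bad))
      lr_stop("t_end > t_start in range table row(s): ",
              paste(bad, collapse = ", "))
  }
  out <- lineage_ranges(tab$lineage_id, t_start, t_end, extant)
  if (!is.null(ref)) attr(out, "reference_year") <- ref
  out
}

#' Write a range table
#'
#' Inverse of [read_range_table()] for the time-before-reference dialect.
#'
#' @param ranges a [lineage_ranges()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_range_table <- function(ranges, path) {
  tab <- data.frame(lineage_id = ranges$lineage_id,
                    t_start = ranges$t_start, t_end = ranges$t_end,
                    status = ifelse(ranges$extant, "extant", "extinct"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a production-year series into lineages at long gaps
#'
#' Consecutive runs of years separated by strictly more than `max_gap`
#' missing years are coded as distinct lineages (a gap of exactly
#' `max_gap` years does not split). Each output lineage spans the first to
#' the last year of its run.
#'
#' @param production_times integer-valued years in which the lineage was in
#'   production (need not be sorted or unique).
#' @param max_gap maximum tolerated number of consecutive missing years
#'   (default 3).
#' @param lineage_id stem used to label the output lineages
#'   (`"<stem>_1"`, `"<stem>_2"`, ... when more than one results).
#' @return `data.frame` with columns `lineage_id`, `first_year`,
#'   `last_year`, one row per resulting lineage, ordered by time.
#' @examples
#' split_on_gaps(c(1950, 1951, 1952, 1957, 1958), max_gap = 3)
#' @export
split_on_gaps <- function(production_times, max_gap = 3,
                          lineage_id = "lineage") {
  if (length(production_times) == 0)
    lr_stop("empty production-year set")
  yrs <- sort(unique(as.numeric(production_times)))
  # gap between consecutive produced years y1 < y2 is y2 - y1 - 1 missing
  # years; split when that exceeds max_gap
  new_run <- c(TRUE, diff(yrs) - 1 > max_gap)
  run <- cumsum(new_run)
  first <- tapply(yrs, run, min)
  last <- tapply(yrs, run, max)
  k <- length(first)
  ids <- if (k == 1) lineage_id else paste(lineage_id, seq_len(k), sep = "_")
  data.frame(lineage_id = ids, first_year = as.numeric(first),
             last_year = as.numeric(last), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Lineage richness through time
#'
#' Counts, at each grid time, the lineages whose range contains that time;
#' membership is closed on both ends (a lineage is counted at both its
#' origination and its extinction time).
#'
#' @param ranges a [lineage_ranges()] object.
#' @param grid sorted numeric vector of times before reference.
#' @return integer vector of counts, one per grid time.
#' @export
richness_through_time <- function(ranges, grid) {
  if (is.unsorted(grid) && is.unsorted(rev(grid)))
    lr_stop("grid must be sorted")
  vapply(grid, function(t)
    sum(ranges$t_start >= t & ranges$t_end <= t), integer(1))
}

#' Lineage lifespans
#'
#' @param ranges a [lineage_ranges()] object.
#' @return numeric vector `t_start - t_end`, one duration per lineage, in
#'   input order.
#' @export
lifespans <- function(ranges) {
  ranges$t_start - ranges$t_end
}
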