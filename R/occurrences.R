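# Occurrence data: per-lineage collections of dated finds. An occurrence
# carries either a fixed calendar age (time before reference, `age_type =
# "cal"`) or an uncalibrated radiocarbon age with its 1-sigma error
# (`age_type = "c14"`), to be calibrated before analysis.

#' Construct an occurrence set
#'
#' @param records `data.frame` with columns `lineage_id`, `age_type`
#'   (`"cal"` or `"c14"`), `age` (calendar age before reference for
#'   `"cal"`; uncalibrated 14C yr BP for `"c14"`), and `err` (1-sigma
#'   radiocarbon error, `NA` for `"cal"` rows, `> 0` for `"c14"` rows).
#' @param extant named logical vector, one entry per lineage id; lineages
#'   absent from `extant` default to extinct.
#' @return list of class `"occurrence_set"` with elements `records` and
#'   `extant`.
#' @export
occurrence_set <- function(records, extant = NULL) {
  need <- c("lineage_id", "age_type", "age", "err")
  if (!all(need %in% names(records)))
    lr_stop("occurrence records need columns: ", paste(need, collapse = ", "))
  records$lineage_id <- as.character(records$lineage_id)
  if (nrow(records) == 0) lr_stop("occurrence set has no records")
  if (!all(records$age_type %in% c("cal", "c14")))
    lr_stop("age_type must be 'cal' or 'c14'")
  if (any(!is.finite(records$age))) lr_stop("non-finite occurrence ages")
  c14 <- records$age_type == "c14"
  if (any(c14 & (!is.finite(records$err) | records$err <= 0)))
    lr_stop("c14 occurrences need err > 0")
  records$err[!c14] <- NA_real_
  ids <- unique(records$lineage_id)
  ext <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(extant)) {
    if (is.null(names(extant))) lr_stop("extant must be a named logical")
    keep <- intersect(names(extant), ids)
    ext[keep] <- as.logical(extant[keep])
  }
  structure(list(records = records[, need], extant = ext),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d occurrences, %d lineages (%d extant)\n",
              nrow(x$records), length(x$extant), sum(x$extant)))
  invisible(x)
}

#' Calendar ages grouped by lineage
#'
#' Requires every record to be of type `"cal"` (calibrate/resample first if
#' radiocarbon records are present).
#'
#' @param occ an [occurrence_set()].
#' @return named list of numeric age vectors, one per lineage.
#' @export
ages_by_lineage <- function(occ) {
  if (any(occ$records$age_type != "cal"))
    lr_stop("occurrence set still contains uncalibrated c14 records")
  split(occ$records$age, occ$records$lineage_id)
}

#' Read an occurrence table
#'
#' Tab-separated with header columns `lineage_id`, `age_type`, `age`,
#' `err` and optionally `status` (`extant`/`extinct` per lineage; any row
#' of a lineage marked `extant` flags the lineage extant).
#'
#' @param path path to the TSV file.
#' @return an [occurrence_set()].
#' @export
read_occurrence_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("lineage_id", "age_type", "age")
  if (!all(need %in% names(tab)))
    lr_stop("occurrence table must have columns: ",
            paste(c(need, "err"), collapse = ", "))
  if (is.null(tab$err)) tab$err <- NA_real_
  tab$age <- suppressWarnings(as.numeric(tab$age))
  tab$err <- suppressWarnings(as.numeric(tab$err))
  bad <- which(!is.finite(tab$age))
  if (length(bad))
    lr_stop("malformed age in occurrence table row(s): ",
            paste(bad, collapse = ", "))
  extant <- NULL
  if (!is.null(tab$status)) {
    st <- tapply(tab$status == "extant", tab$lineage_id, any)
    extant <- stats::setNames(as.logical(st), names(st))
  }
  occurrence_set(tab[, c("lineage_id", "age_type", "age", "err")], extant)
}

#' Write an occurrence table
#'
#' @param occ an [occurrence_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrence_table <- function(occ, path) {
  tab <- occ$records
  tab$status <- ifelse(occ$extant[tab$lineage_id], "extant", "extinct")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
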