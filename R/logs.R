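# Posterior-log serialization: tab-separated, one column per scalar
# parameter, list-valued parameters (rates, shift times, latent ts/te)
# semicolon-joined. Round-trips losslessly for finite values.

#' Write a posterior log
#'
#' @param log a `posterior_log` as returned by [run_chain()].
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_posterior_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mode=", log$mode, " window=", log$window[1], ",",
                    log$window[2]), con)
  utils::write.table(log$samples, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a posterior log
#'
#' @param path path written by [write_posterior_log()].
#' @return a `posterior_log` object.
#' @export
read_posterior_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) lr_stop("empty log file")
  meta <- NULL
  if (grepl("^#", lines[1])) {
    meta <- lines[1]
    lines <- lines[-1]
  }
  if (!length(lines)) lr_stop("log file has no header row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("iteration", "log_posterior", "log_likelihood", "lam_k",
            "lam_rates", "lam_shifts", "mu_k", "mu_rates", "mu_shifts")
  if (!all(need %in% header))
    lr_stop("log header mismatch; expected at least: ",
            paste(need, collapse = ", "))
  body <- lines[-1]
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  # empty trailing fields are legal (strsplit drops them); only rows with
  # MORE fields than the header, or truncated below the last non-optional
  # field, are malformed
  bad <- which(nf > length(header) | nf < which(header == "mu_shifts") - 1L)
  if (length(bad))
    lr_stop("truncated or malformed log row ", bad[1])
  samples <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = stats::setNames(
                                 rep("character",
                                     sum(header %in% c("lam_rates",
                                                       "lam_shifts",
                                                       "mu_rates",
                                                       "mu_shifts", "ts",
                                                       "te"))),
                                 intersect(header,
                                           c("lam_rates", "lam_shifts",
                                             "mu_rates", "mu_shifts",
                                             "ts", "te"))))
  if (nrow(samples) > 1 && any(diff(samples$iteration) <= 0))
    lr_stop("iterations must be strictly increasing")
  for (cc in intersect(c("lam_rates", "lam_shifts", "mu_rates", "mu_shifts",
                         "ts", "te"), names(samples)))
    samples[[cc]][is.na(samples[[cc]])] <- ""
  mode <- "range"
  window <- NULL
  if (!is.null(meta)) {
    mode <- sub(".*mode=(\\S+).*", "\\1", meta)
    wtxt <- sub(".*window=([^ ]+).*", "\\1", meta)
    window <- as.numeric(strsplit(wtxt, ",", fixed = TRUE)[[1]])
  }
  if (is.null(window) || any(is.na(window))) {
    shifts <- parse_semi(c(samples$lam_shifts, samples$mu_shifts))
    hi <- suppressWarnings(max(unlist(shifts), 0))
    window <- c(hi * 1.01 + 1, 0)
    if ("ts" %in% names(samples))
      window[1] <- max(window[1], max(unlist(parse_semi(samples$ts))))
  }
  structure(list(samples = samples, mode = mode, window = window,
                 acceptance = NULL, priors = NULL),
            class = "posterior_log")
}

# ";"-joined numeric fields -> list of numeric vectors
#' @noRd
parse_semi <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    if (!length(v)) numeric(0) else as.numeric(v)
  })
}
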