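# Delimited-text I/O for traces, dwell tables and event tables.
# Convention: tab separation, '.' decimal, mandatory header row; units are
# part of the column names (time_s, force_pN, height_nm, dwell_s, step_nm).

#' Write a trace to a tab-separated text file
#'
#' @param trace an [mt_trace()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "mt_trace"))
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace from a tab-separated text file
#'
#' The file must have the header `time_s force_pN height_nm` (tab
#' separated). Parsing problems are reported with the offending line
#' number.
#'
#' @param path input file
#' @param sampling_rate sampling rate in Hz; inferred from the time channel
#'   when `NULL`
#' @return an [mt_trace()]
#' @export
read_trace <- function(path, sampling_rate = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty trace file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  required <- c("time_s", "force_pN", "height_nm")
  if (!all(required %in% header))
    stop(sprintf("line 1 of '%s': header must contain %s (got: %s)",
                 path, paste(required, collapse = ", "), lines[1]))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t"),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  for (col in required) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("'%s': non-numeric value in column %s at line %d",
                   path, col, bad[1] + 1L))
    df[[col]] <- as.numeric(df[[col]])
  }
  if (is.null(sampling_rate))
    sampling_rate <- 1 / stats::median(diff(df$time_s))
  mt_trace(df$time_s, df$force_pN, df$height_nm, sampling_rate)
}

#' Write a dwell-record table
#' @param dwells a [dwell_records()] data frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dwells <- function(dwells, path) {
  utils::write.table(as.data.frame(dwells), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dwell-record table
#' @param path input file with header `force_pN dwell_s censored`
#' @return a [dwell_records()] data frame
#' @export
read_dwells <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  required <- c("force_pN", "dwell_s")
  if (!all(required %in% names(df)))
    stop(sprintf("'%s': dwell table must have columns %s",
                 path, paste(required, collapse = ", ")))
  dwell_records(df$force_pN, df$dwell_s,
                if ("censored" %in% names(df)) as.logical(df$censored) else FALSE)
}
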