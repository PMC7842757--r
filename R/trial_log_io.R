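#' Write a trial log to CSV
#'
#' Writes the interchange format used throughout the package: UTF-8 CSV with
#' a mandatory header and columns `observer_id, protocol, trial_index,
#' f1_hz, f2_hz, is_impossible, rewarded_response_draw, response, feedback`.
#' Frequencies are written with 17 significant digits so that
#' `read_trial_log(write_trial_log(x))` reproduces every field (frequencies
#' to well beyond 12 significant digits). Absent responses/feedback are
#' written as empty cells.
#'
#' @param log A `trial_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  stopifnot(inherits(log, "trial_log"))
  num <- function(x) sprintf("%.17g", x)
  opt <- function(x) ifelse(is.na(x), "", as.character(as.integer(x)))
  out <- data.frame(
    observer_id = attr(log, "observer_id"),
    protocol = attr(log, "protocol"),
    trial_index = log$trial_index,
    f1_hz = num(log$f1_hz),
    f2_hz = num(log$f2_hz),
    is_impossible = as.integer(log$is_impossible),
    rewarded_response_draw = opt(log$rewarded_response_draw),
    response = opt(log$response),
    feedback = opt(log$feedback),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.TRIAL_LOG_COLS <- c("observer_id", "protocol", "trial_index", "f1_hz",
                     "f2_hz", "is_impossible", "rewarded_response_draw",
                     "response", "feedback")

#' Read a trial log from CSV
#'
#' Inverse of [write_trial_log()]. Validation failures (missing columns,
#' non-numeric or non-positive frequencies, responses outside \{0, 1,
#' empty\}, non-contiguous trial indices) raise errors that name the
#' offending column and data row.
#'
#' @param path CSV file path.
#' @return A `trial_log`.
#' @export
read_trial_log <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  missing_cols <- setdiff(.TRIAL_LOG_COLS, names(raw))
  if (length(missing_cols)) {
    stop("trial-log file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0L) stop("trial-log file ", path, " has no data rows", call. = FALSE)

  num_col <- function(name, positive = FALSE) {
    v <- suppressWarnings(as.numeric(raw[[name]]))
    bad <- which(is.na(v) | (positive & v <= 0))
    if (length(bad)) {
      stop("column '", name, "' is not ", if (positive) "a positive number",
           if (!positive) "numeric", " at data row ", bad[1], call. = FALSE)
    }
    v
  }
  bin_col <- function(name) {
    x <- raw[[name]]
    out <- rep(NA_integer_, n)
    filled <- !(is.na(x) | x == "")
    bad <- which(filled & !x %in% c("0", "1"))
    if (length(bad)) {
      stop("column '", name, "' must be 0, 1 or empty; offending data row ",
           bad[1], call. = FALSE)
    }
    out[filled] <- as.integer(x[filled])
    out
  }

  idx <- num_col("trial_index")
  if (!identical(as.integer(idx), seq_len(n))) {
    first_bad <- which(as.integer(idx) != seq_len(n))[1]
    stop("trial_index must be contiguous 1..", n, "; data row ", first_bad,
         " has trial_index ", idx[first_bad],
         " (file has ", n, " data rows)", call. = FALSE)
  }
  f1 <- num_col("f1_hz", positive = TRUE)
  f2 <- num_col("f2_hz", positive = TRUE)
  imp_raw <- raw$is_impossible
  bad <- which(!imp_raw %in% c("0", "1", "TRUE", "FALSE"))
  if (length(bad)) {
    stop("column 'is_impossible' must be 0/1; offending data row ", bad[1],
         call. = FALSE)
  }
  imp <- imp_raw %in% c("1", "TRUE")
  mism <- which(imp != (f1 == f2))
  if (length(mism)) {
    stop("is_impossible flag disagrees with f1 == f2 at data row ", mism[1],
         call. = FALSE)
  }
  proto <- unique(raw$protocol)
  if (length(proto) != 1L) {
    stop("trial-log file mixes protocols: ", paste(proto, collapse = ", "),
         call. = FALSE)
  }
  feedback_protocol(proto)
  obs <- unique(raw$observer_id)
  if (length(obs) != 1L) {
    stop("trial-log file mixes observer_ids: ", paste(obs, collapse = ", "),
         call. = FALSE)
  }

  df <- data.frame(trial_index = seq_len(n), f1_hz = f1, f2_hz = f2,
                   is_impossible = imp,
                   rewarded_response_draw = bin_col("rewarded_response_draw"),
                   response = bin_col("response"),
                   feedback = bin_col("feedback"))
  new_trial_log(df, protocol = proto, observer_id = obs)
}
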