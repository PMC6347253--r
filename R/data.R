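#' Grouped binomial dose-response data
#'
#' Constructs a validated container for grouped binomial observations from a
#' dose-finding study: one row per dose group with the number of responders
#' and the group size. Rows are sorted by dose; duplicate doses are rejected
#' because the model treats each dose group as a single binomial observation.
#'
#' @param dose Numeric vector of dose levels (study units, e.g. mg). Must be
#'   non-negative and distinct.
#' @param responders Integer vector of event counts per group.
#' @param total Integer vector of group sizes (positive).
#'
#' @return A `data.frame` of class `"dose_response_data"` with columns
#'   `dose`, `responders`, `total`, sorted by increasing dose.
#'
#' @examples
#' dose_response_data(dose = c(0, 0.5, 1, 2, 4),
#'                    responders = c(1, 18, 34, 33, 36),
#'                    total = c(58, 60, 61, 61, 60))
#' @export
dose_response_data <- function(dose, responders, total) {
  if (length(dose) != length(responders) || length(dose) != length(total))
    stop("'dose', 'responders' and 'total' must have equal length", call. = FALSE)
  if (length(dose) < 2L)
    stop("at least two dose groups are required", call. = FALSE)
  if (!is.numeric(dose) || anyNA(dose) || any(dose < 0))
    stop("'dose' must be non-negative and free of missing values", call. = FALSE)
  if (anyDuplicated(dose))
    stop("duplicate dose levels: ", paste(dose[duplicated(dose)], collapse = ", "),
         call. = FALSE)
  if (!is.numeric(total) || anyNA(total) || any(total < 1) ||
      any(total != round(total)))
    stop("'total' must contain positive integers", call. = FALSE)
  if (!is.numeric(responders) || anyNA(responders) ||
      any(responders != round(responders)))
    stop("'responders' must contain non-negative integers", call. = FALSE)
  bad <- which(responders < 0 | responders > total)
  if (length(bad))
    stop("responders outside [0, total] in group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  ord <- order(dose)
  out <- data.frame(dose = as.numeric(dose[ord]),
                    responders = as.integer(responders[ord]),
                    total = as.integer(total[ord]))
  class(out) <- c("dose_response_data", "data.frame")
  out
}

#' @export
print.dose_response_data <- function(x, ...) {
  cat("Grouped binomial dose-response data:",
      nrow(x), "dose groups,", sum(x$total), "subjects\n")
  y <- as.data.frame(x)
  y$proportion <- round(y$responders / y$total, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Read grouped dose-response data from CSV
#'
#' Reads a CSV file with header `dose,responders,total` and returns a
#' validated [dose_response_data()] object sorted by dose. Malformed rows
#' (responders exceeding the group size, negative doses, duplicated doses)
#' raise an error naming the offending content.
#'
#' @param path Path to the CSV file.
#' @return A `dose_response_data` object.
#' @examples
#' path <- system.file("extdata", "nct02131662.csv", package = "plband")
#' read_dose_response_csv(path)
#' @export
read_dose_response_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("dose", "responders", "total")
  if (!all(needed %in% names(raw)))
    stop("expected header 'dose,responders,total' in ", path, call. = FALSE)
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  dose_response_data(raw$dose, raw$responders, raw$total)
}

#' Dose-response counts from trial NCT02131662
#'
#' The grouped binomial responder counts from the phase 2 dose-finding trial
#' NCT02131662 (clinicaltrials.gov): placebo plus four active doses, with
#' responders/total of 1/58, 18/60, 34/61, 33/61 and 36/60 at 0, 0.5, 1, 2
#' and 4 mg. These data ship with the package (also as
#' `extdata/nct02131662.csv`) and are used throughout the examples.
#'
#' @return A `dose_response_data` object with 5 groups.
#' @examples
#' trial_nct02131662()
#' @export
trial_nct02131662 <- function() {
  dose_response_data(dose = c(0, 0.5, 1, 2, 4),
                     responders = c(1L, 18L, 34L, 33L, 36L),
                     total = c(58L, 60L, 61L, 61L, 60L))
}

#' Write a pointwise CI curve to CSV
#'
#' Serializes a [profile_ci_curve()] / [wald_ci_curve()] /
#' [bootstrap_ci_curve()] result with a fixed column order
#' (`dose,estimate,lower,upper,method_lower,method_upper,converged`).
#' Missing limits (non-converged doses) are written as empty cells.
#'
#' @param curve A `pointwise_ci` object.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @seealso [read_ci_csv()] for the round-trip reader.
#' @export
write_ci_csv <- function(curve, path) {
  stopifnot(inherits(curve, "pointwise_ci"))
  cols <- c("dose", "estimate", "lower", "upper",
            "method_lower", "method_upper", "converged")
  out <- as.data.frame(curve)[, cols]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}

#' Read back a pointwise CI curve written by [write_ci_csv()]
#'
#' Empty cells are read as missing values. The numeric columns round-trip
#' exactly at the default `write.csv` precision (15 significant digits).
#'
#' @param path CSV path produced by [write_ci_csv()].
#' @return A data frame with the same columns.
#' @export
read_ci_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = "",
                  colClasses = c(dose = "numeric", estimate = "numeric",
                                 lower = "numeric", upper = "numeric",
                                 method_lower = "character",
                                 method_upper = "character",
                                 converged = "logical"))
}
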