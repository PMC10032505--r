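#' Construct a survival dataset
#'
#' Bundles a numeric feature matrix with right-censored follow-up
#' information: observed times \code{y_i > 0} and event indicators
#' \code{delta_i} (1 = event observed, 0 = right-censored).  All fitting and
#' evaluation functions in the package accept this container.
#'
#' @param features numeric matrix, n subjects x p features, no missing
#'   values (impute upstream).
#' @param times positive follow-up times, length n.
#' @param events event indicators in \{0, 1\}, length n; at least one event
#'   is required, otherwise the Cox partial likelihood is undefined.
#' @param feature_names optional character vector of p distinct names;
#'   defaults to the column names of \code{features} or \code{x1..xp}.
#' @return An object of class \code{"survdata"}: a list with elements
#'   \code{features}, \code{times}, \code{events}, \code{feature_names}.
#' @examples
#' d <- survival_dataset(matrix(rnorm(20), 10, 2), times = rexp(10) + 0.1,
#'                       events = rep(1, 10))
#' d
#' @export
survival_dataset <- function(features, times, events, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  p <- ncol(features)
  if (anyNA(features) || any(!is.finite(features)))
    stop("features must be finite with no missing values")
  times <- as.numeric(times)
  events <- as.numeric(events)
  if (length(times) != n || length(events) != n)
    stop("times and events must have one entry per row of features")
  if (any(!is.finite(times)) || any(times <= 0))
    stop("all follow-up times must be strictly positive")
  if (!all(events %in% c(0, 1)))
    stop("events must be 0 (censored) or 1 (event)")
  if (sum(events) < 1)
    stop("at least one event is required: partial likelihood undefined")
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) feature_names <- paste0("x", seq_len(p))
  }
  feature_names <- as.character(feature_names)
  if (length(feature_names) != p || anyDuplicated(feature_names))
    stop("feature_names must be ", p, " distinct strings")
  colnames(features) <- feature_names
  structure(list(features = features, times = times, events = events,
                 feature_names = feature_names),
            class = "survdata")
}

#' @export
print.survdata <- function(x, ...) {
  cat("Survival dataset: ", nrow(x$features), " subjects, ",
      ncol(x$features), " features, ", sum(x$events), " events (",
      round(100 * (1 - mean(x$events)), 1), "% censored)\n", sep = "")
  invisible(x)
}

#' Construct a labeled dataset for logistic or linear regression
#'
#' @param features numeric matrix, n x p, no missing values.
#' @param outcome numeric outcome of length n: binary in \{0,1\} for the
#'   logistic family, real-valued for the gaussian family.
#' @param feature_names optional character vector of p distinct names.
#' @return An object of class \code{"labdata"} with elements
#'   \code{features}, \code{outcome}, \code{feature_names}.
#' @export
labeled_dataset <- function(features, outcome, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  p <- ncol(features)
  if (anyNA(features) || any(!is.finite(features)))
    stop("features must be finite with no missing values")
  outcome <- as.numeric(outcome)
  if (length(outcome) != n) stop("outcome must have one entry per row")
  if (any(!is.finite(outcome))) stop("outcome must be finite")
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) feature_names <- paste0("x", seq_len(p))
  }
  feature_names <- as.character(feature_names)
  if (length(feature_names) != p || anyDuplicated(feature_names))
    stop("feature_names must be ", p, " distinct strings")
  colnames(features) <- feature_names
  structure(list(features = features, outcome = outcome,
                 feature_names = feature_names),
            class = "labdata")
}

#' Build the risk-set index for Breslow's partial likelihood
#'
#' Precomputes, for every unique failure time t_1 < ... < t_m, the set D_i of
#' subjects failing at t_i, the tie multiplicities d_i = |D_i|, and the risk
#' set R_i = \{j : y_j >= t_i\} of subjects still under observation.  Times at
#' which only censoring occurs contribute no entry.
#'
#' @param data a \code{\link{survival_dataset}}.
#' @return A list of class \code{"risk_index"} with
#'   \code{unique_failure_times}, \code{failure_sets} (list of index
#'   vectors), \code{failure_counts}, \code{risk_sets} (list of index
#'   vectors).
#' @export
build_risk_index <- function(data) {
  stopifnot(inherits(data, "survdata"))
  ev <- which(data$events == 1)
  if (length(ev) == 0) stop("no events: partial likelihood undefined")
  ft <- sort(unique(data$times[ev]))
  failure_sets <- lapply(ft, function(t) ev[data$times[ev] == t])
  risk_sets <- lapply(ft, function(t) which(data$times >= t))
  structure(list(unique_failure_times = ft,
                 failure_sets = failure_sets,
                 failure_counts = lengths(failure_sets),
                 risk_sets = risk_sets),
            class = "risk_index")
}

#' Read a delimited dataset from disk
#'
#' Expects a header row.  For the Cox family the file must contain numeric
#' columns \code{time} and \code{event}; for logistic/gaussian outcomes a
#' column \code{outcome}.  All remaining columns are taken as numeric
#' features.
#'
#' @param path file path of a CSV/TSV file.
#' @param sep field separator; default \code{","}.
#' @param type \code{"survival"} (time/event columns) or \code{"labeled"}
#'   (outcome column).
#' @return A \code{\link{survival_dataset}} or \code{\link{labeled_dataset}}.
#' @export
read_dataset <- function(path, sep = ",", type = c("survival", "labeled")) {
  type <- match.arg(type)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (type == "survival") {
    need <- c("time", "event")
  } else {
    need <- "outcome"
  }
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  feat_cols <- setdiff(names(df), need)
  if (length(feat_cols) == 0) stop("no feature columns found")
  for (cn in names(df)) {
    col <- df[[cn]]
    if (!is.numeric(col))
      stop("column '", cn, "' is not numeric")
    if (anyNA(col))
      stop("missing value in column '", cn, "', row ",
           which(is.na(col))[1])
  }
  X <- as.matrix(df[, feat_cols, drop = FALSE])
  if (type == "survival") {
    if (any(df$time <= 0))
      stop("non-positive time in row ", which(df$time <= 0)[1])
    survival_dataset(X, df$time, df$event, feat_cols)
  } else {
    labeled_dataset(X, df$outcome, feat_cols)
  }
}

#' Write a dataset as delimited text
#'
#' Numeric values are written with 17 significant digits so that a
#' write/read round trip reproduces the dataset exactly.
#'
#' @param data a \code{survdata} or \code{labdata} object.
#' @param path output file path.
#' @param sep field separator; default \code{","}.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(data, path, sep = ",") {
  if (inherits(data, "survdata")) {
    df <- data.frame(time = data$times, event = data$events,
                     check.names = FALSE)
  } else if (inherits(data, "labdata")) {
    df <- data.frame(outcome = data$outcome, check.names = FALSE)
  } else stop("data must be a survdata or labdata object")
  df <- cbind(df, as.data.frame(data$features, check.names = FALSE))
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  out <- vapply(df, fmt, character(nrow(df)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = sep), con)
  writeLines(apply(out, 1, paste, collapse = sep), con)
  invisible(path)
}
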