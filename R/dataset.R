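#' Construct a right-censored survival dataset
#'
#' Bundles observed times, event indicators and a covariate matrix into a
#' validated container used by every fitting routine in the package.
#'
#' @param time Numeric vector of strictly positive observed times (event or
#'   censoring times, in the study's time unit, e.g. years).
#' @param event Integer/numeric vector of event indicators: 1 if the event
#'   (e.g. death) was observed, 0 if the observation was right-censored.
#' @param X Numeric matrix of covariates, one row per subject.
#' @param feature_names Optional character vector of covariate labels;
#'   defaults to the column names of `X` or `x1..xp`.
#' @param groups Optional length-`p` vector of group labels mapping each
#'   covariate to a group (used by the group spike-and-slab model).
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `time`, `event`, `X`, `feature_names`, `groups`, `n`, `p`.
#' @export
survival_dataset <- function(time, event, X, feature_names = NULL,
                             groups = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("covariate matrix X must be numeric")
  n <- nrow(X)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != n || length(event) != n)
    stop("time, event and rows of X must have equal length")
  if (anyNA(time) || any(time <= 0))
    stop("observed times must be strictly positive and non-missing")
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 (censored) or 1 (event)")
  p <- ncol(X)
  if (is.null(feature_names)) {
    feature_names <- colnames(X) %||% paste0("x", seq_len(p))
  }
  if (length(feature_names) != p)
    stop("feature_names must have one entry per covariate column")
  colnames(X) <- feature_names
  if (!is.null(groups) && length(groups) != p)
    stop("groups must have one label per covariate")
  structure(
    list(time = time, event = as.integer(event), X = X,
         feature_names = feature_names, groups = groups, n = n, p = p),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("survival_dataset: n =", x$n, ", p =", x$p,
      sprintf("(%d events, %.1f%% censored)\n", sum(x$event),
              100 * mean(x$event == 0)))
  if (!is.null(x$groups))
    cat("  covariate groups:", length(unique(x$groups)), "\n")
  invisible(x)
}

#' Read a survival dataset from a delimited file
#'
#' Expects a header row with a time column, an event column coded 0/1, and
#' numeric covariate columns.  Missing values may be encoded as empty cells
#' or the string `NA`; they are kept (use [complete_case_filter()] to drop
#' incomplete rows).
#'
#' @param path Path to a CSV file.
#' @param time_col,event_col Names of the time and event columns.
#' @param group_path Optional path to a CSV with columns `feature,group`
#'   assigning covariates to groups.
#' @return A [survival_dataset()].
#' @export
read_dataset <- function(path, time_col = "time", event_col = "event",
                         group_path = NULL) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  for (col in c(time_col, event_col)) {
    if (!col %in% names(df))
      stop("required column '", col, "' missing from ", path)
  }
  covar_cols <- setdiff(names(df), c(time_col, event_col))
  bad <- covar_cols[!vapply(df[covar_cols], is.numeric, logical(1))]
  if (length(bad) > 0)
    stop("non-numeric covariate columns: ", paste(bad, collapse = ", "))
  ev_raw <- df[[event_col]]
  if (!is.numeric(ev_raw) || !all(ev_raw[!is.na(ev_raw)] %in% c(0, 1)))
    stop("event column '", event_col, "' must be coded 0/1")
  tm <- df[[time_col]]
  if (any(!is.na(tm) & tm <= 0))
    stop("column '", time_col, "' contains non-positive times")
  X <- as.matrix(df[covar_cols])
  groups <- NULL
  if (!is.null(group_path)) {
    gdf <- read.csv(group_path, check.names = FALSE)
    if (!all(c("feature", "group") %in% names(gdf)))
      stop("group file must have columns 'feature' and 'group'")
    groups <- gdf$group[match(covar_cols, gdf$feature)]
    if (anyNA(groups))
      stop("group file is missing entries for some covariates")
  }
  # validation of times/events happens in the constructor, but NA rows are
  # legal at this stage; build with placeholder checks relaxed
  new_dataset_allow_na(tm, ev_raw, X, covar_cols, groups)
}

# Internal: like survival_dataset() but tolerating NAs (pre-filter stage).
new_dataset_allow_na <- function(time, event, X, feature_names, groups) {
  ok <- !is.na(time) & !is.na(event)
  if (any(time[ok] <= 0)) stop("observed times must be strictly positive")
  if (!all(event[ok] %in% c(0, 1))) stop("event indicators must be 0/1")
  colnames(X) <- feature_names
  structure(
    list(time = as.numeric(time), event = as.integer(event), X = X,
         feature_names = feature_names, groups = groups,
         n = nrow(X), p = ncol(X)),
    class = "survival_dataset"
  )
}

#' Write a survival dataset to CSV
#'
#' Column layout is `time, event, x1..xp`; a write/read round trip is the
#' identity on valid datasets.
#'
#' @param data A [survival_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "survival_dataset"))
  df <- data.frame(time = data$time, event = data$event,
                   data$X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Drop observations with any missing value
#'
#' Complete-case analysis: every row with a missing time, event indicator
#' or covariate value is removed, and a report of the attrition is
#' attached.
#'
#' @param data A [survival_dataset()] (possibly containing `NA`s).
#' @return A list with elements `data` (the filtered dataset) and `report`
#'   (counts and percentage removed).
#' @export
complete_case_filter <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  keep <- !is.na(data$time) & !is.na(data$event) &
    stats::complete.cases(data$X)
  n_total <- data$n
  n_keep <- sum(keep)
  if (n_keep == 0)
    stop("complete-case filtering removed every observation")
  out <- survival_dataset(data$time[keep], data$event[keep],
                          data$X[keep, , drop = FALSE],
                          feature_names = data$feature_names,
                          groups = data$groups)
  report <- list(n_total = n_total, n_complete = n_keep,
                 n_removed = n_total - n_keep,
                 pct_removed = round(100 * (n_total - n_keep) / n_total, 2))
  list(data = out, report = report)
}
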