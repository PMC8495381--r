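# Disease-free survival validation of marker combinations: Kaplan-Meier
# estimation, log-rank tests, and double-positive stratification. The
# product-limit and log-rank computations are delegated to the survival
# package; this module fixes conventions (ties: events precede censorings,
# the survfit default) and the result surfaces.

#' Dichotomize a continuous marker
#'
#' High/positive status is strictly above the threshold: the median
#' (`rule = "median"`) or an explicit `cutpoint`.
#'
#' @param values Named numeric vector (>= 4 patients).
#' @param rule "median" or "cutpoint".
#' @param cutpoint Threshold when `rule = "cutpoint"`.
#' @return A list: `status` (named "positive"/"negative" vector),
#'   `threshold`.
#' @export
dichotomize <- function(values, rule = c("median", "cutpoint"),
                        cutpoint = NULL) {
  rule <- match.arg(rule)
  if (length(values) < 4) stop("need >= 4 patients", call. = FALSE)
  if (max(values) == min(values)) {
    stop("all values identical; no split possible", call. = FALSE)
  }
  threshold <- if (rule == "median") median(values) else {
    stopifnot(!is.null(cutpoint))
    cutpoint
  }
  status <- ifelse(values > threshold, "positive", "negative")
  names(status) <- names(values)
  list(status = status, threshold = threshold)
}

#' Kaplan-Meier estimate of disease-free survival
#'
#' Product-limit estimator with the standard tied-time convention (events
#' before censorings at tied times).
#'
#' @param time Positive follow-up times.
#' @param event Logical/0-1 event indicator (TRUE = recurrence).
#' @param group Optional group labels for stratified curves.
#' @return A `km_curve`: tibble-backed list with the per-time estimates and,
#'   when two or more groups are given, the log-rank chi-square and p.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  event <- as.integer(as.logical(event))
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                             conf.type = "log")
    curve <- tibble::tibble(
      group = "all", time = fit$time, n_risk = fit$n.risk,
      n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv,
      std_err = fit$std.err * fit$surv)
    test <- NULL
  } else {
    group <- as.character(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ group)
    strata <- rep(names(fit$strata), fit$strata)
    curve <- tibble::tibble(
      group = sub("^group=", "", strata), time = fit$time,
      n_risk = fit$n.risk, n_event = fit$n.event, n_censor = fit$n.censor,
      surv = fit$surv, std_err = fit$std.err * fit$surv)
    test <- if (length(unique(group)) >= 2) logrank(time, event, group)
  }
  structure(list(curve = curve, test = test,
                 n = length(time), n_event = sum(event)),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' @param time Positive follow-up times.
#' @param event Event indicator.
#' @param group Group labels (every group must be non-empty).
#' @return A list: `chi2`, `df`, `p`.
#' @export
logrank <- function(time, event, group) {
  group <- as.character(group)
  tab <- table(group)
  if (any(tab == 0) || length(tab) < 2) {
    stop("log-rank requires >= 2 non-empty groups", call. = FALSE)
  }
  event <- as.integer(as.logical(event))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(tab) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Double-positive marker stratification
#'
#' @param markers Tibble/data.frame with one status column
#'   ("positive"/"negative") per marker.
#' @param pair Character vector of the two marker column names.
#' @param four_level Return the full 4-level labelling
#'   (double-negative / single-positive per marker / double-positive)
#'   instead of the 2-level one.
#' @return Character vector of strata labels ("double-positive" vs "other",
#'   or 4 levels).
#' @export
double_positive_strata <- function(markers, pair, four_level = FALSE) {
  stopifnot(length(pair) == 2, all(pair %in% names(markers)))
  a <- markers[[pair[1]]]
  b <- markers[[pair[2]]]
  bad <- is.na(a) | is.na(b)
  if (any(bad)) {
    ids <- if ("patient_id" %in% names(markers))
      markers$patient_id[bad] else which(bad)
    stop("missing marker status for: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  pos_a <- a == "positive"
  pos_b <- b == "positive"
  if (four_level) {
    dplyr::case_when(
      pos_a & pos_b ~ "double-positive",
      pos_a & !pos_b ~ paste0(pair[1], "-positive"),
      !pos_a & pos_b ~ paste0(pair[2], "-positive"),
      TRUE ~ "double-negative")
  } else {
    ifelse(pos_a & pos_b, "double-positive", "other")
  }
}

#' Validate a marker pair against disease-free survival
#'
#' Stratifies patients into double-positive vs other and compares
#' disease-free survival with Kaplan-Meier curves and a log-rank test.
#'
#' @param clinical Tibble with columns patient_id, time_months, event, and
#'   one status column per marker.
#' @param pair The two marker columns (default PCSK1 and SMOC1).
#' @return A `km_curve` with the stratified curves and log-rank test.
#' @export
validate_marker_pair <- function(clinical, pair = c("PCSK1", "SMOC1")) {
  strata <- double_positive_strata(clinical, pair)
  km_estimate(clinical$time_months, clinical$event, strata)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> ", x$n, " subjects, ", x$n_event, " events, ",
      length(unique(x$curve$group)), " group(s)\n", sep = "")
  if (!is.null(x$test)) {
    cat("log-rank chi2 = ", format(x$test$chi2, digits = 4),
        " (df ", x$test$df, "), p = ", format(x$test$p, digits = 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' Tidiers for nettrace result objects
#'
#' `tidy()` returns the per-unit table of a result (per cell, per gene, per
#' time point); `glance()` returns a one-row summary.
#'
#' @param x A nettrace result object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) x$curve

#' @rdname tidiers
#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_event = x$n_event,
    n_groups = length(unique(x$curve$group)),
    chi2 = if (is.null(x$test)) NA_real_ else x$test$chi2,
    p = if (is.null(x$test)) NA_real_ else x$test$p)
}
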