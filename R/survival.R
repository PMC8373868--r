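#' Survival data
#'
#' Right-censored time-to-event data: for each subject the follow-up time in
#' cycles and whether the event (invasion) was observed (`TRUE`) or the
#' subject was censored (`FALSE`).
#'
#' @param times non-negative event/censoring times.
#' @param events parallel logical vector; `TRUE` = invasion observed.
#' @return an object of class `surv_data` (a tibble with columns `time`,
#'   `event`).
#' @examples
#' surv_data(c(2, 3, 3, 5, 7), c(TRUE, TRUE, TRUE, FALSE, TRUE))
#' @export
surv_data <- function(times, events) {
  if (length(times) != length(events)) {
    stop("'times' and 'events' must have equal length", call. = FALSE)
  }
  if (length(times) == 0) stop("empty survival data", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  structure(tibble::tibble(time = as.numeric(times),
                           event = as.logical(events)),
            class = c("surv_data", "tbl_df", "tbl", "data.frame"))
}

#' Extract survival data from a cohort
#'
#' Convenience accessor: the invasion-free survival data of a simulated
#' cohort (event = invasion observed, i.e. not censored).
#'
#' @param cohort a `cohort_result`.
#' @return a `surv_data` object.
#' @export
cohort_surv_data <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_result"))
  surv_data(cohort$patients$time_to_invasion_cycles,
            !cohort$patients$censored)
}

#' Kaplan-Meier product-limit estimate
#'
#' The product-limit estimator of the invasion-free survival function under
#' right censoring: at each distinct event time `t_i` with `d_i` events among
#' `n_i` subjects at risk, the survival estimate multiplies by
#' `(1 - d_i / n_i)`. Ties are grouped; censored subjects leave the risk set
#' after the events at their time.
#'
#' @param data a `surv_data` object (or anything `surv_data()` accepts via
#'   `times`/`events` columns `time`, `event`).
#' @return an object of class `km_curve`: a tibble with one row per distinct
#'   event time and columns `time`, `at_risk`, `events`, `survival`;
#'   `S(0) = 1` is implicit (attribute `n` records the sample size).
#' @examples
#' km <- km_estimate(surv_data(c(2, 3, 3, 5, 7), c(TRUE, TRUE, TRUE, FALSE, TRUE)))
#' km$survival[km$time == 3]  # 0.4
#' @export
km_estimate <- function(data) {
  if (!inherits(data, "surv_data")) {
    data <- surv_data(data$time, data$event)
  }
  n <- nrow(data)
  ord <- order(data$time)
  tm <- data$time[ord]
  ev <- data$event[ord]
  etimes <- sort(unique(tm[ev]))
  if (length(etimes) == 0) {
    curve <- tibble::tibble(time = numeric(0), at_risk = integer(0),
                            events = integer(0), survival = numeric(0))
  } else {
    at_risk <- vapply(etimes, function(t) sum(tm >= t), numeric(1))
    d <- vapply(etimes, function(t) sum(tm == t & ev), numeric(1))
    surv <- cumprod(1 - d / at_risk)
    curve <- tibble::tibble(time = etimes, at_risk = as.integer(at_risk),
                            events = as.integer(d), survival = surv)
  }
  structure(curve, class = c("km_curve", class(tibble::tibble())), n = n)
}

# Evaluate a KM step function at arbitrary times (right-continuous).
km_survival_at <- function(curve, t) {
  vapply(t, function(x) {
    i <- which(curve$time <= x)
    if (length(i)) curve$survival[max(i)] else 1
  }, numeric(1))
}

#' Restricted mean survival time
#'
#' The area under the Kaplan-Meier step function on `[0, horizon]`: the mean
#' invasion-free time restricted to the follow-up horizon. This is the
#' cohort summary used for "average time to invasion" (it handles censored
#' patients) and the output statistic of the sensitivity analysis.
#'
#' @param curve a `km_curve`.
#' @param horizon upper limit of integration (> 0), typically the censoring
#'   horizon `max_cycles`.
#' @return the restricted mean, a scalar.
#' @examples
#' km <- km_estimate(surv_data(c(2, 3, 3, 5, 7), c(TRUE, TRUE, TRUE, FALSE, TRUE)))
#' restricted_mean(km, horizon = 7)  # 4.4
#' @export
restricted_mean <- function(curve, horizon) {
  stopifnot(inherits(curve, "km_curve"))
  if (horizon < 0) stop("'horizon' must be >= 0", call. = FALSE)
  if (horizon == 0) return(0)
  tt <- curve$time[curve$time < horizon]
  ss <- curve$survival[curve$time < horizon]
  knots <- c(0, tt, horizon)
  heights <- c(1, ss)
  sum(heights * diff(knots))
}

#' Mean time to invasion over uncensored patients
#'
#' Alternative cohort summary: the arithmetic mean of the observed invasion
#' times, ignoring censored patients. Offered alongside [restricted_mean()];
#' the restricted mean is the default summary because it accounts for
#' censoring.
#'
#' @param data a `surv_data` object.
#' @return scalar mean of event times; `NA` if no events.
#' @export
mean_uncensored <- function(data) {
  stopifnot(inherits(data, "surv_data"))
  if (!any(data$event)) return(NA_real_)
  mean(data$time[data$event])
}

#' Two-group log-rank test
#'
#' The standard log-rank comparison of two right-censored samples: at each
#' distinct event time (pooled across groups), the observed number of events
#' in group A is compared with its hypergeometric expectation given the risk
#' sets; the standardized sum of observed-minus-expected is chi-square with
#' 1 df under the null of equal hazards.
#'
#' @param a,b `surv_data` objects.
#' @return an object of class `logrank_result`: list with `statistic`
#'   (chi-square, 1 df), `p_value`, `observed`, `expected` (group A).
#' @examples
#' d <- surv_data(c(2, 3, 3, 5, 7), c(TRUE, TRUE, TRUE, FALSE, TRUE))
#' logrank_test(d, d)$p_value  # 1
#' @export
logrank_test <- function(a, b) {
  stopifnot(inherits(a, "surv_data"), inherits(b, "surv_data"))
  tm <- c(a$time, b$time)
  ev <- c(a$event, b$event)
  grp <- rep(c(1L, 2L), c(nrow(a), nrow(b)))
  if (!any(ev)) {
    stop("log-rank statistic undefined: no events in either group",
         call. = FALSE)
  }
  etimes <- sort(unique(tm[ev]))
  o_a <- 0; e_a <- 0; v <- 0
  for (t in etimes) {
    at_risk <- tm >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d_t <- sum(tm == t & ev)
    d1 <- sum(tm == t & ev & grp == 1L)
    o_a <- o_a + d1
    e_a <- e_a + d_t * n1 / n_t
    if (n_t > 1) {
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  stat <- if (v > 0) (o_a - e_a)^2 / v else 0
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 observed = o_a, expected = e_a),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.4g (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' @rdname km_estimate
#' @param x a `km_curve`.
#' @param ... unused.
#' @export
tidy.km_curve <- function(x, ...) {
  tibble::tibble(time = x$time, at_risk = x$at_risk, events = x$events,
                 survival = x$survival)
}

#' @rdname km_estimate
#' @export
glance.km_curve <- function(x, ...) {
  n <- attr(x, "n")
  tibble::tibble(
    n = n,
    n_events = sum(x$events),
    final_survival = if (nrow(x)) x$survival[nrow(x)] else 1,
    median_survival = {
      i <- which(x$survival <= 0.5)
      if (length(i)) x$time[min(i)] else NA_real_
    }
  )
}

#' @rdname logrank_test
#' @param x a `logrank_result`.
#' @param ... unused.
#' @export
tidy.logrank_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = 1L, p_value = x$p_value,
                 observed = x$observed, expected = x$expected)
}
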