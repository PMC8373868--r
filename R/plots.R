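#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier curve
#'
#' Step plot of the invasion-free survival estimate.
#'
#' @param object a `km_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble::tibble(
    time = c(0, object$time),
    survival = c(1, object$survival)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (cycles)", y = "invasion-free survival") +
    ggplot2::theme_minimal()
}

#' Plot cohort survival
#'
#' Kaplan-Meier curve of a simulated cohort's time to invasion.
#'
#' @param object a `cohort_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cohort_result <- function(object, ...) {
  autoplot.km_curve(km_estimate(cohort_surv_data(object))) +
    ggplot2::labs(title = sprintf("Cohort of %d patients (master seed %d)",
                                  nrow(object$patients), object$master_seed))
}

#' Plot Morris sensitivities
#'
#' Horizontal bar chart of mu_star per parameter, ordered by sensitivity.
#'
#' @param object a `morris_result`.
#' @param top show only the `top` most sensitive parameters (default all).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.morris_result <- function(object, top = Inf, ...) {
  df <- tidy.morris_result(object)
  df <- df[order(-df$mu_star), ]
  if (is.finite(top)) df <- utils::head(df, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mu_star, y = .data$parameter)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(mu * "*"), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a patient trajectory
#'
#' Per-cycle tumor, mutant, mesenchymal and immune population sizes of one
#' simulated patient (requires `record_trajectory = TRUE`).
#'
#' @param record a `patient_record` with a trajectory.
#' @return a ggplot.
#' @export
plot_trajectory <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  if (is.null(record$trajectory)) {
    stop("record has no trajectory; simulate with record_trajectory = TRUE",
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    record$trajectory,
    cols = c("n_tumor", "n_mutant", "n_mesenchymal", "N_NK", "N_CTL",
             "N_Treg", "tau"),
    names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$value,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle (post-warmup)", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
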