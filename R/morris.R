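#' Parameter priors for sensitivity analysis
#'
#' Attaches a sampling prior to every tunable parameter in the registry:
#' literature-anchored parameters get a truncated normal N(m_e, 2 m_e)
#' restricted to the parameter's valid range (m_e the anchor estimate,
#' variance twice the estimate so sampling does not lean too heavily on
#' prior work); phenotype parameters with no prior information are uniform
#' on \[0,1\].
#'
#' @param pars a `model_params` object supplying the anchors.
#' @param registry a registry tibble ([param_registry()]); a subset of its
#'   rows may be passed to restrict the analysis to fewer parameters.
#' @return a named list of priors, each a list with `name`, `kind`,
#'   `quantile` (function mapping \[0,1\] to parameter space) and the
#'   registry fields.
#' @examples
#' pr <- build_priors(model_params())
#' pr$Delta_MIE$quantile(0.5)  # 0.5, uniform on [0,1]
#' @export
build_priors <- function(pars = model_params(), registry = param_registry(pars)) {
  stopifnot(is.data.frame(registry))
  need <- c("parameter", "kind", "mean", "sd", "lo", "hi", "integer")
  if (length(setdiff(need, names(registry)))) {
    stop("registry lacks required columns", call. = FALSE)
  }
  priors <- purrr::pmap(registry, function(parameter, kind, mean, sd, lo, hi,
                                           integer) {
    qf <- switch(kind,
      uniform = {
        force(lo); force(hi)
        function(u) lo + u * (hi - lo)
      },
      truncnorm = {
        # quantile of N(mean, sd^2) truncated to [lo, hi]; unbounded tails
        # are clipped at the 1st/99th percentile so the unit interval maps
        # to a finite range
        plo <- stats::pnorm(lo, mean, sd)
        phi <- stats::pnorm(hi, mean, sd)
        plo <- max(plo, 0.01)
        phi <- min(phi, 0.99)
        function(u) {
          q <- stats::qnorm(plo + u * (phi - plo), mean, sd)
          pmin(hi, pmax(lo, q))
        }
      },
      stop("unknown prior kind: ", kind, call. = FALSE)
    )
    if (integer) {
      qraw <- qf
      qf <- function(u) pmax(1, round(qraw(u)))
    }
    list(name = parameter, kind = kind, mean = mean, sd = sd, lo = lo,
         hi = hi, integer = integer, quantile = qf)
  })
  names(priors) <- registry$parameter
  priors
}

#' Morris one-at-a-time trajectory design
#'
#' Standard Morris elementary-effects design: `r` trajectories in the unit
#' hypercube of the `k` tunable parameters. Each trajectory starts from a
#' random base point on a grid of `levels` levels and moves one coordinate
#' at a time by the step `Delta = levels / (2 (levels - 1))`, visiting
#' `k + 1` points; the move order and directions are randomized, and every
#' point stays inside the unit cube. Unit-cube coordinates are mapped to
#' parameter space through each prior's quantile function.
#'
#' @param priors a prior list from [build_priors()].
#' @param r number of base trajectories (30 by default, as used for the full
#'   analysis; at least 10 is recommended).
#' @param levels even number of grid levels (4 by default).
#' @return an object of class `morris_design`: list with `points` (matrix,
#'   `r (k+1)` rows by `k` columns, unit-cube coordinates), `trajectory`
#'   (row grouping), `moved` (which coordinate changed entering each row;
#'   NA for base points), `delta`, `priors`.
#' @examples
#' set.seed(1)
#' d <- sample_trajectories(build_priors(), r = 2)
#' dim(d$points)  # 2 * 32 rows, 31 columns
#' @export
sample_trajectories <- function(priors, r = 30L, levels = 4L) {
  stopifnot(r >= 1, levels >= 2, levels %% 2 == 0)
  k <- length(priors)
  delta <- levels / (2 * (levels - 1))
  # base-point grid: {0, 1/(levels-1), ..., 1 - delta}
  grid <- seq(0, 1 - delta, by = 1 / (levels - 1))
  pts <- matrix(NA_real_, nrow = r * (k + 1), ncol = k,
                dimnames = list(NULL, names(priors)))
  moved <- rep(NA_integer_, r * (k + 1))
  trajectory <- rep(seq_len(r), each = k + 1)
  row <- 1L
  for (j in seq_len(r)) {
    x <- grid[sample.int(length(grid), k, replace = TRUE)]
    # direction per coordinate, flipped where a +delta step would leave [0,1]
    dir <- sample(c(-1, 1), k, replace = TRUE)
    dir <- ifelse(x + dir * delta < 0 | x + dir * delta > 1, -dir, dir)
    order_ <- sample.int(k)
    pts[row, ] <- x
    row <- row + 1L
    for (i in order_) {
      x[i] <- x[i] + dir[i] * delta
      pts[row, ] <- x
      moved[row] <- i
      row <- row + 1L
    }
  }
  structure(list(points = pts, trajectory = trajectory, moved = moved,
                 delta = delta, priors = priors),
            class = "morris_design")
}

#' Map a Morris design to parameter space
#'
#' Applies each prior's quantile function to its unit-cube column.
#'
#' @param design a `morris_design`.
#' @return a tibble with one row per design point, columns named after the
#'   parameters.
#' @export
design_points <- function(design) {
  stopifnot(inherits(design, "morris_design"))
  mapped <- purrr::imap(design$priors, function(pr, nm) {
    pr$quantile(design$points[, nm])
  })
  tibble::as_tibble(mapped)
}

#' Morris elementary-effects summary
#'
#' Given one model output per design point, each one-coordinate move yields
#' an elementary effect `(y_after - y_before) / (signed step)`, in
#' normalized (unit-cube) coordinates. Per parameter, `mu_star` is the mean
#' absolute elementary effect ("the average absolute change of the output
#' over the range of variation of the parameter") and `sigma` their standard
#' deviation (interaction/nonlinearity indicator).
#'
#' @param design a `morris_design`.
#' @param outputs numeric vector, one output per design-point row.
#' @return an object of class `morris_result`: a tibble with columns
#'   `parameter`, `mu_star`, `sigma`, `n_effects`.
#' @examples
#' set.seed(1)
#' d <- sample_trajectories(build_priors()[1:2], r = 4)
#' y <- 3 * d$points[, 1]
#' compute_mu_star(d, y)  # mu_star = 3 for the first parameter, 0 for the second
#' @export
compute_mu_star <- function(design, outputs) {
  stopifnot(inherits(design, "morris_design"))
  npts <- nrow(design$points)
  if (length(outputs) != npts || any(!is.finite(outputs))) {
    stop("'outputs' must supply one finite value per design point",
         call. = FALSE)
  }
  k <- ncol(design$points)
  effects <- vector("list", k)
  for (row in seq_len(npts)) {
    i <- design$moved[row]
    if (is.na(i)) next
    step <- design$points[row, i] - design$points[row - 1L, i]
    ee <- (outputs[row] - outputs[row - 1L]) / step
    effects[[i]] <- c(effects[[i]], ee)
  }
  res <- tibble::tibble(
    parameter = colnames(design$points),
    mu_star = vapply(effects, function(e) {
      if (length(e)) mean(abs(e)) else NA_real_
    }, numeric(1)),
    sigma = vapply(effects, function(e) {
      if (length(e) > 1) stats::sd(e) else 0
    }, numeric(1)),
    n_effects = vapply(effects, length, integer(1))
  )
  structure(res, class = c("morris_result", class(tibble::tibble())))
}

#' Run the Morris sensitivity analysis on the simulator
#'
#' Evaluates the cohort-level output statistic at every design point of a
#' Morris one-at-a-time design and aggregates elementary effects into
#' `mu_star` and `sigma` per parameter. The default output is the restricted
#' mean invasion-free survival (area under the KM curve up to `max_cycles`);
#' `output = "mean_uncensored"` uses the mean time to invasion over
#' uncensored patients instead. Design points share per-patient seed
#' streams (common random numbers) so elementary effects are differences
#' under matched randomness; set `common_rng = FALSE` for independent
#' streams per design point.
#'
#' @param pars a `model_params` object (baseline; supplies prior anchors and
#'   fixed run-control settings).
#' @param scheme an `inflammation_scheme`.
#' @param priors prior list ([build_priors()]); restrict its registry to
#'   analyze fewer parameters.
#' @param r number of trajectories.
#' @param levels Morris grid levels.
#' @param n_patients_per_eval cohort size per design point.
#' @param master_seed integer; seeds both the design and the cohorts.
#' @param output `"rmst"` or `"mean_uncensored"`.
#' @param common_rng share per-patient seeds across design points.
#' @return a `morris_result` tibble (see [compute_mu_star()]) with
#'   attributes `r`, `n_patients_per_eval`, `output`, and `outputs` (the raw
#'   per-design-point outputs).
#' @examples
#' \donttest{
#' pars <- model_params(warmup_cycles = 50, max_cycles = 100, N_0 = 10)
#' reg <- param_registry(pars)
#' pr <- build_priors(pars, reg[reg$parameter %in% c("p", "Delta_MIE"), ])
#' run_morris(pars, priors = pr, r = 2, n_patients_per_eval = 5,
#'            master_seed = 1)
#' }
#' @export
run_morris <- function(pars = model_params(), scheme = inflammation_scheme(),
                       priors = build_priors(pars), r = 30L, levels = 4L,
                       n_patients_per_eval = 100L, master_seed = 1L,
                       output = c("rmst", "mean_uncensored"),
                       common_rng = TRUE) {
  output <- match.arg(output)
  set.seed(master_seed)
  design <- sample_trajectories(priors, r = r, levels = levels)
  theta <- design_points(design)
  eval_seeds <- if (common_rng) {
    rep(master_seed, nrow(theta))
  } else {
    derive_seeds(master_seed, nrow(theta))
  }
  outputs <- vapply(seq_len(nrow(theta)), function(i) {
    pi <- pars
    for (nm in names(theta)) pi[[nm]] <- theta[[nm]][i]
    pi <- validate_params(unclass(pi))
    sch <- scheme
    if (sch$mode == "CYCLING") {
      sch$ihd <- pi$IHD
      sch$ild <- pi$ILD
    }
    co <- simulate_cohort(pi, sch, n_patients = n_patients_per_eval,
                          master_seed = eval_seeds[i])
    sd_ <- cohort_surv_data(co)
    if (output == "rmst") {
      restricted_mean(km_estimate(sd_), horizon = pi$max_cycles)
    } else {
      m <- mean_uncensored(sd_)
      if (is.na(m)) pi$max_cycles else m
    }
  }, numeric(1))
  res <- compute_mu_star(design, outputs)
  attr(res, "r") <- r
  attr(res, "n_patients_per_eval") <- n_patients_per_eval
  attr(res, "output") <- output
  attr(res, "outputs") <- outputs
  res
}

#' @rdname compute_mu_star
#' @param x a `morris_result`.
#' @param ... unused.
#' @export
tidy.morris_result <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, mu_star = x$mu_star,
                 sigma = x$sigma, n_effects = x$n_effects)
}
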