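#' Model parameters
#'
#' Constructs the full parameter set of the tumor--immune--EMT model. Tumor
#' cells are discrete agents whose per-cycle fate (proliferate, apoptose,
#' be cleared by NK cells or CTLs, or rest in G0) is drawn from probabilities
#' determined by the cell's mutational profile, its epithelial/mesenchymal
#' phenotype and the current immune state; NK, CTL and Treg populations and
#' the TGF-beta concentration evolve continuously.
#'
#' Populations are scaled: tumors of order 1e9 cells are represented at order
#' 1e2, and rate constants are scaled accordingly. Rates are per cell cycle
#' (18 h by default).
#'
#' @param ... named parameter overrides over the calibrated defaults; unknown
#'   names are an error.
#'
#' @section Parameters:
#' \describe{
#'   \item{p, d_C}{baseline per-cycle proliferation / apoptosis probabilities
#'     of an unmutated epithelial cell.}
#'   \item{Delta_P, Delta_A, Delta_IE}{proportional effect of a mutation in
#'     the proliferation, apoptosis, or immune-evasion pathway, each in
#'     \[0,1\].}
#'   \item{Delta_MGA, Delta_MIE}{mesenchymal growth arrest and mesenchymal
#'     immune evasion: proportional reduction of a mesenchymal cell's
#'     proliferation / immune-clearance probability, each in \[0,1\];
#'     1 means complete arrest / complete evasion.}
#'   \item{K_0}{tumor crowding constant; the mean-field carrying capacity of
#'     an unmutated tumor is K_0 (p / d_C - 1).}
#'   \item{K_1, K_2}{saturation constants of immune clearance: tumor-load
#'     scaling of effector engagement and Treg suppression of cytotoxicity.}
#'   \item{K_4}{TGF-beta saturation of Treg recruitment.}
#'   \item{E_NK, E_CTL}{effector efficacies (maximal per-cycle clearance
#'     probability); CTLs are more efficient than NK cells by default.}
#'   \item{sigma_NK, d_NK}{NK recruitment (constant) and death rate.}
#'   \item{sigma_CTL_low, sigma_CTL_high, d_CTL}{CTL recruitment per
#'     immune-cleared mutant cell in the low/high inflammation state; CTL
#'     death rate.}
#'   \item{sigma_Treg_low, sigma_Treg_high, d_Treg}{Treg recruitment
#'     coefficients (per cleared mutant cell, TGF-beta-saturating) and death
#'     rate.}
#'   \item{tau_MUT, tau_Treg}{TGF-beta production per mutant tumor cell and
#'     per Treg.}
#'   \item{T_MES}{EMT-score threshold: a cell whose score is strictly above
#'     T_MES is mesenchymal.}
#'   \item{emt_gain, emt_decay, K_tau}{EMT-score update constants: per-cycle
#'     saturating gain driven by TGF-beta (half-saturation K_tau) and linear
#'     decay toward the epithelial state.}
#'   \item{delta_MUT_baseline}{immunogenicity of unmutated cells (mutated
#'     cells have immunogenicity 1); 0 by default, so unmutated cells are
#'     invisible to effectors.}
#'   \item{IHD, ILD}{inflammation high / low durations in cycles for the
#'     cycling scheme.}
#'   \item{N_0}{initial number of in situ tumor cells.}
#'   \item{warmup_cycles}{pre-mutation warmup length (cycles); the tumor
#'     grows to carrying capacity with only NK cells present.}
#'   \item{max_cycles}{censoring horizon (cycles after warmup).}
#'   \item{mut_increment}{per-proliferation increment of the cell-autonomous
#'     mutation probability.}
#'   \item{cycle_hours}{length of one cell cycle in hours.}
#'   \item{progression_threshold}{mutant fraction at or above which the tumor
#'     is invasive.}
#'   \item{deactivation_per_kill_NK, deactivation_per_kill_CTL}{effectors
#'     removed (exhausted) per tumor cell cleared by that compartment.}
#'   \item{dummy}{inert parameter with no effect on the dynamics; include it
#'     in a sensitivity analysis to benchmark the Monte-Carlo noise floor of
#'     the elementary effects (its true sensitivity is exactly 0).}
#' }
#'
#' @return an object of class `model_params` (a validated named list).
#' @examples
#' pars <- model_params(Delta_MIE = 0.5)
#' pars$Delta_MIE
#' @export
model_params <- function(...) {
  pars <- default_params()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(pars))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    pars[names(dots)] <- dots
  }
  validate_params(pars)
}

# Calibrated defaults. Carrying capacity K_0 (p/d_C - 1) = 200 cells
# (populations scaled from ~1e9 to ~1e2); immune pressure on a fresh mutant
# exceeds its growth advantage, so escape requires immune-evasion mutations
# or EMT, giving times to invasion spread over the 2000-cycle horizon.
default_params <- function() {
  list(
    p = 0.3, d_C = 0.1,
    Delta_P = 0.2, Delta_A = 0.5, Delta_IE = 0.95,
    Delta_MGA = 0.2, Delta_MIE = 0.5,
    K_0 = 100, K_1 = 100, K_2 = 25, K_4 = 10,
    E_NK = 0.2, E_CTL = 0.35,
    sigma_NK = 5, d_NK = 0.1,
    sigma_CTL_low = 0.1, sigma_CTL_high = 0.5, d_CTL = 0.2,
    sigma_Treg_low = 0.05, sigma_Treg_high = 0.25, d_Treg = 0.1,
    tau_MUT = 0.05, tau_Treg = 0.2,
    T_MES = 0.5,
    emt_gain = 0.15, emt_decay = 0.02, K_tau = 2,
    delta_MUT_baseline = 0,
    dummy = 0,
    IHD = 50L, ILD = 100L,
    N_0 = 50L,
    warmup_cycles = 1000L,
    max_cycles = 2000L,
    mut_increment = 1e-4,
    cycle_hours = 18,
    progression_threshold = 0.5,
    deactivation_per_kill_NK = 1,
    deactivation_per_kill_CTL = 1
  )
}

#' Validate a model parameter set
#'
#' Checks every field's type and range (probabilities and proportional
#' effects in \[0,1\], rates and constants non-negative, strictly positive
#' where division requires it, positive integer cycle counts).
#'
#' @param pars a named list of parameters (all fields required).
#' @return the validated `model_params` object, invisibly classed.
#' @export
validate_params <- function(pars) {
  need <- names(default_params())
  missing <- setdiff(need, names(pars))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num1 <- function(nm) {
    v <- pars[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    }
    v
  }
  chk <- function(nm, lo = -Inf, hi = Inf, lo_open = FALSE, hi_open = FALSE) {
    v <- num1(nm)
    bad <- if (lo_open) v <= lo else v < lo
    bad <- bad || if (hi_open) v >= hi else v > hi
    if (bad) {
      stop(sprintf("parameter '%s' = %g outside valid range %s%g, %g%s", nm, v,
                   if (lo_open) "(" else "[", lo, hi,
                   if (hi_open) ")" else "]"),
           call. = FALSE)
    }
    v
  }
  int1 <- function(nm, lo = 1) {
    v <- chk(nm, lo = lo)
    if (v != round(v)) {
      stop("parameter '", nm, "' must be an integer", call. = FALSE)
    }
    as.integer(v)
  }
  chk("p", 0, 1); chk("d_C", 0, 1)
  for (nm in c("Delta_P", "Delta_A", "Delta_IE", "Delta_MGA", "Delta_MIE",
               "delta_MUT_baseline", "E_NK", "E_CTL",
               "progression_threshold")) chk(nm, 0, 1)
  chk("T_MES", 0, 1, lo_open = TRUE, hi_open = TRUE)
  for (nm in c("K_0", "K_1", "K_2", "K_4")) chk(nm, 0, lo_open = TRUE)
  for (nm in c("sigma_NK", "d_NK", "sigma_CTL_low", "sigma_CTL_high", "d_CTL",
               "sigma_Treg_low", "sigma_Treg_high", "d_Treg",
               "tau_MUT", "tau_Treg", "emt_gain", "emt_decay", "K_tau",
               "mut_increment", "deactivation_per_kill_NK",
               "deactivation_per_kill_CTL")) chk(nm, 0)
  chk("cycle_hours", 0, lo_open = TRUE)
  num1("dummy")  # inert by construction; any finite value
  # canonical double storage for non-count fields (stable serialization)
  for (nm in setdiff(need, c("IHD", "ILD", "N_0", "warmup_cycles",
                             "max_cycles"))) {
    pars[[nm]] <- as.numeric(pars[[nm]])
  }
  pars$IHD <- int1("IHD"); pars$ILD <- int1("ILD")
  pars$N_0 <- int1("N_0")
  pars$warmup_cycles <- int1("warmup_cycles")
  pars$max_cycles <- int1("max_cycles")
  structure(pars, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> (", length(unclass(x)), " fields)\n", sep = "")
  df <- tibble::tibble(parameter = names(x),
                       value = vapply(x, function(v) format(v), character(1)))
  print(df, n = nrow(df))
  invisible(x)
}

#' Registry of sensitivity-tunable parameters
#'
#' The 31 substantive model parameters varied in global sensitivity analysis,
#' with the prior attached to each. Parameters with a literature-anchored
#' point estimate m_e get a truncated-normal prior N(m_e, 2 m_e) restricted
#' to the parameter's valid range; the phenotype and threshold parameters
#' with no prior information (the Delta effects, efficacies, T_MES, baseline
#' immunogenicity) are uniform on \[0,1\]. Run-control settings (warmup
#' length, horizon, cell-cycle length, progression threshold, mutation
#' increment, exhaustion factors) are fixed, not tunable.
#'
#' @param pars a `model_params` object supplying the anchor values m_e.
#' @return a tibble with columns `parameter`, `kind` ("uniform" or
#'   "truncnorm"), `mean`, `sd`, `lo`, `hi`, `integer`.
#' @examples
#' nrow(param_registry(model_params()))  # 31
#' @export
param_registry <- function(pars = model_params()) {
  stopifnot(inherits(pars, "model_params"))
  unif01 <- c("Delta_P", "Delta_A", "Delta_IE", "Delta_MGA", "Delta_MIE",
              "E_NK", "E_CTL", "delta_MUT_baseline")
  # anchored parameters: name -> (lower, upper) of the valid range
  anchored <- list(
    p = c(0, 1), d_C = c(0, 1),
    K_0 = c(1e-8, Inf), K_1 = c(1e-8, Inf), K_2 = c(1e-8, Inf),
    K_4 = c(1e-8, Inf),
    sigma_NK = c(0, Inf), d_NK = c(1e-6, Inf),
    sigma_CTL_low = c(0, Inf), sigma_CTL_high = c(0, Inf),
    d_CTL = c(1e-6, Inf),
    sigma_Treg_low = c(0, Inf), sigma_Treg_high = c(0, Inf),
    d_Treg = c(1e-6, Inf),
    tau_MUT = c(0, Inf), tau_Treg = c(0, Inf),
    emt_gain = c(0, Inf), emt_decay = c(0, Inf), K_tau = c(1e-8, Inf),
    IHD = c(1, Inf), ILD = c(1, Inf), N_0 = c(1, Inf)
  )
  reg <- dplyr::bind_rows(
    tibble::tibble(parameter = unif01, kind = "uniform",
                   mean = NA_real_, sd = NA_real_, lo = 0, hi = 1),
    # T_MES lives on the open interval (0,1); sample just inside it
    tibble::tibble(parameter = "T_MES", kind = "uniform",
                   mean = NA_real_, sd = NA_real_, lo = 1e-6, hi = 1 - 1e-6),
    tibble::tibble(
      parameter = names(anchored), kind = "truncnorm",
      mean = unname(vapply(names(anchored),
                           function(nm) as.numeric(pars[[nm]]), numeric(1))),
      sd = sqrt(2 * unname(vapply(names(anchored),
                                  function(nm) as.numeric(pars[[nm]]),
                                  numeric(1)))),
      lo = unname(vapply(anchored, `[`, numeric(1), 1)),
      hi = unname(vapply(anchored, `[`, numeric(1), 2))
    )
  )
  reg$integer <- reg$parameter %in% c("IHD", "ILD", "N_0")
  stopifnot(nrow(reg) == 31L)
  reg
}

#' Resolve inflammation-dependent recruitment rates
#'
#' Recruitment of the adaptive compartments depends on the inflammatory state
#' of the tumor microenvironment: the low/high members of each paired
#' parameter are selected by the current state. Unpaired parameters are
#' state-independent.
#'
#' @param state `"LOW"` or `"HIGH"`.
#' @param pars a `model_params` object.
#' @return a list with elements `sigma_CTL` and `sigma_Treg`.
#' @examples
#' resolve_params("LOW", model_params())$sigma_CTL
#' @export
resolve_params <- function(state, pars) {
  state <- match.arg(state, c("LOW", "HIGH"))
  stopifnot(inherits(pars, "model_params"))
  if (state == "LOW") {
    list(sigma_CTL = pars$sigma_CTL_low, sigma_Treg = pars$sigma_Treg_low)
  } else {
    list(sigma_CTL = pars$sigma_CTL_high, sigma_Treg = pars$sigma_Treg_high)
  }
}

#' Convert simulation cycles to days
#'
#' One cell cycle is `cycle_hours` long (18 h by default), so `cycles`
#' cycles correspond to `cycles * cycle_hours / 24` days. Summaries report
#' the value rounded to the nearest day: 841 cycles at 18 h is 631 days.
#'
#' @param cycles non-negative cycle count(s).
#' @param pars a `model_params` object (supplies `cycle_hours`).
#' @param round_days round to the nearest whole day (default `TRUE`, the
#'   reporting convention).
#' @return days, numeric.
#' @examples
#' cycles_to_days(841)  # 631
#' @export
cycles_to_days <- function(cycles, pars = model_params(), round_days = TRUE) {
  if (any(!is.finite(cycles)) || any(cycles < 0)) {
    stop("'cycles' must be non-negative", call. = FALSE)
  }
  d <- cycles * pars$cycle_hours / 24
  if (round_days) round(d) else d
}
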