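#' Immune state
#'
#' Continuous populations of the three immune compartments plus the current
#' TGF-beta concentration. NK cells are innate and always present; CTLs and
#' Tregs are adaptive and recruited in response to immune-cleared mutant
#' tumor cells. All components are non-negative (floored at 0).
#'
#' @param N_NK,N_CTL,N_Treg population sizes (scaled cells), >= 0.
#' @param tau TGF-beta concentration (arbitrary units), >= 0.
#' @return an object of class `immune_state`.
#' @examples
#' immune_state(N_NK = 50)
#' @export
immune_state <- function(N_NK = 0, N_CTL = 0, N_Treg = 0, tau = 0) {
  v <- c(N_NK = N_NK, N_CTL = N_CTL, N_Treg = N_Treg, tau = tau)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("immune populations and tau must be finite and >= 0", call. = FALSE)
  }
  structure(list(N_NK = N_NK, N_CTL = N_CTL, N_Treg = N_Treg, tau = tau),
            class = "immune_state")
}

#' @export
print.immune_state <- function(x, ...) {
  cat(sprintf("<immune_state> NK %.4g | CTL %.4g | Treg %.4g | TGF-beta %.4g\n",
              x$N_NK, x$N_CTL, x$N_Treg, x$tau))
  invisible(x)
}

#' Inflammation scheme
#'
#' Deterministic schedule of the inflammatory state of the tumor
#' microenvironment: permanently low, permanently high, or cycling between
#' blocks of `ild` LOW cycles and `ihd` HIGH cycles starting from
#' `start_state`.
#'
#' @param mode one of `"CONSTANT_LOW"`, `"CONSTANT_HIGH"`, `"CYCLING"`.
#' @param ihd,ild inflammation high / low durations (cycles, >= 1); used by
#'   the cycling mode.
#' @param start_state `"LOW"` or `"HIGH"`: the state of the first block (and
#'   the state held during warmup).
#' @return an object of class `inflammation_scheme`.
#' @examples
#' inflammation_scheme("CYCLING", ihd = 50, ild = 100)
#' @export
inflammation_scheme <- function(mode = c("CYCLING", "CONSTANT_LOW",
                                         "CONSTANT_HIGH"),
                                ihd = 50L, ild = 100L,
                                start_state = c("LOW", "HIGH")) {
  mode <- match.arg(mode)
  start_state <- match.arg(start_state)
  ihd <- as.integer(ihd); ild <- as.integer(ild)
  if (mode == "CYCLING" && (ihd < 1L || ild < 1L)) {
    stop("cycling inflammation requires ihd >= 1 and ild >= 1", call. = FALSE)
  }
  structure(list(mode = mode, ihd = ihd, ild = ild, start_state = start_state),
            class = "inflammation_scheme")
}

#' @export
print.inflammation_scheme <- function(x, ...) {
  if (x$mode == "CYCLING") {
    cat(sprintf("<inflammation_scheme> CYCLING start %s (LOW %d / HIGH %d cycles)\n",
                x$start_state, x$ild, x$ihd))
  } else {
    cat("<inflammation_scheme>", x$mode, "\n")
  }
  invisible(x)
}

#' Inflammatory state at a given cycle
#'
#' Deterministic lookup of the LOW/HIGH state at post-warmup cycle
#' `cycle_index` (0 = first post-warmup cycle). The cycling mode alternates
#' half-open blocks `[start, start + duration)` of length `ild` (LOW) and
#' `ihd` (HIGH), beginning with `start_state`.
#'
#' @param cycle_index integer cycle index(es) >= 0.
#' @param scheme an `inflammation_scheme`.
#' @return character vector of `"LOW"` / `"HIGH"`.
#' @examples
#' sch <- inflammation_scheme("CYCLING", ihd = 50, ild = 100, start_state = "LOW")
#' inflammation_state(c(99, 100, 150), sch)  # LOW HIGH LOW
#' @export
inflammation_state <- function(cycle_index, scheme) {
  stopifnot(inherits(scheme, "inflammation_scheme"))
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0", call. = FALSE)
  switch(scheme$mode,
    CONSTANT_LOW = rep("LOW", length(cycle_index)),
    CONSTANT_HIGH = rep("HIGH", length(cycle_index)),
    CYCLING = {
      period <- scheme$ihd + scheme$ild
      pos <- cycle_index %% period
      first_len <- if (scheme$start_state == "LOW") scheme$ild else scheme$ihd
      in_first <- pos < first_len
      other <- if (scheme$start_state == "LOW") "HIGH" else "LOW"
      ifelse(in_first, scheme$start_state, other)
    }
  )
}

#' Per-cycle clearance tally
#'
#' Counts of tumor cells cleared by each effector compartment during one
#' cell cycle, and the number of those cleared cells that carried at least
#' one mutation. The mutant-clearance count is the antigenic stimulus
#' forcing adaptive recruitment (N*_MUT).
#'
#' @param cleared_by_NK,cleared_by_CTL,cleared_mutant non-negative counts;
#'   `cleared_mutant <= cleared_by_NK + cleared_by_CTL`.
#' @return an object of class `clearance_tally`.
#' @export
clearance_tally <- function(cleared_by_NK = 0L, cleared_by_CTL = 0L,
                            cleared_mutant = 0L) {
  v <- c(cleared_by_NK, cleared_by_CTL, cleared_mutant)
  if (any(v < 0) || cleared_mutant > cleared_by_NK + cleared_by_CTL) {
    stop("invalid clearance tally", call. = FALSE)
  }
  structure(list(cleared_by_NK = as.integer(cleared_by_NK),
                 cleared_by_CTL = as.integer(cleared_by_CTL),
                 cleared_mutant = as.integer(cleared_mutant)),
            class = "clearance_tally")
}

#' TGF-beta concentration
#'
#' Algebraic update: tau = tau_MUT * N_MUT + tau_Treg * N_Treg. Mutant tumor
#' cells and (more strongly) Tregs are the TGF-beta sources; the
#' concentration tracks the current populations with no memory.
#'
#' @param n_mut number of tumor cells carrying at least one mutation.
#' @param immune an `immune_state` (supplies N_Treg).
#' @param pars a `model_params` object.
#' @return tau, a non-negative scalar.
#' @examples
#' compute_tgfb(50, immune_state(N_Treg = 20),
#'              model_params(tau_MUT = 0.01, tau_Treg = 0.1))  # 2.5
#' @export
compute_tgfb <- function(n_mut, immune, pars) {
  if (n_mut < 0) stop("n_mut must be >= 0", call. = FALSE)
  pars$tau_MUT * n_mut + pars$tau_Treg * immune$N_Treg
}

# Exact one-cycle solution of N' = a - d N with constant forcing a:
# N(1) = a/d + (N0 - a/d) exp(-d). d = 0 degenerates to N0 + a.
linear_step <- function(n0, a, d) {
  if (d < 0) stop("decay rate must be >= 0", call. = FALSE)
  if (d == 0) return(n0 + a)
  eq <- a / d
  max(0, eq + (n0 - eq) * exp(-d))
}

#' Advance the immune populations over one cell cycle
#'
#' Each compartment obeys a linear ODE with forcing held constant within the
#' cycle (the clearance tally, TGF-beta and the inflammation-resolved
#' recruitment rates are frozen at their cycle-start values), so the update
#' is the exact exponential solution N(1) = a/d + (N0 - a/d) e^(-d):
#' NK: a = sigma_NK; CTL: a = sigma_CTL N*_MUT;
#' Treg: a = sigma_Treg N*_MUT tau / (1 + tau / K_4).
#' Results are floored at 0.
#'
#' @param immune an `immune_state` at cycle start (after exhaustion).
#' @param tally a `clearance_tally` for the current cycle (N*_MUT forcing).
#' @param tau TGF-beta concentration frozen at cycle start.
#' @param state `"LOW"` or `"HIGH"` inflammatory state of the cycle.
#' @param pars a `model_params` object.
#' @param adaptive if `FALSE` (warmup), CTL and Treg dynamics are frozen at
#'   zero and only the NK compartment is updated.
#' @return the advanced `immune_state` (tau unchanged; recompute with
#'   [compute_tgfb()]).
#' @examples
#' st <- step_immune(immune_state(), clearance_tally(), tau = 0, state = "LOW",
#'                   pars = model_params())
#' st$N_NK  # one cycle of NK recruitment from 0
#' @export
step_immune <- function(immune, tally, tau, state, pars, adaptive = TRUE) {
  stopifnot(inherits(immune, "immune_state"))
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (min(pars$d_NK, pars$d_CTL, pars$d_Treg) <= 0) {
    stop("immune death rates must be > 0", call. = FALSE)
  }
  eff <- resolve_params(state, pars)
  n_star <- tally$cleared_mutant
  nk <- linear_step(immune$N_NK, pars$sigma_NK, pars$d_NK)
  if (adaptive) {
    ctl <- linear_step(immune$N_CTL, eff$sigma_CTL * n_star, pars$d_CTL)
    treg <- linear_step(immune$N_Treg,
                        eff$sigma_Treg * n_star * tau / (1 + tau / pars$K_4),
                        pars$d_Treg)
  } else {
    ctl <- 0
    treg <- 0
  }
  immune_state(N_NK = nk, N_CTL = ctl, N_Treg = treg, tau = immune$tau)
}

#' Effector exhaustion after tumor-cell clearance
#'
#' Effectors deactivate (and are removed) upon successful tumor-cell
#' clearance: NK and CTL populations are reduced by the configured number of
#' effectors per kill attributed to each compartment, floored at 0. Applied
#' before the population ODE step each cycle.
#'
#' @param immune an `immune_state`.
#' @param tally a `clearance_tally` for the current cycle.
#' @param pars a `model_params` object.
#' @return the exhausted `immune_state`.
#' @examples
#' apply_deactivation(immune_state(N_NK = 20),
#'                    clearance_tally(cleared_by_NK = 5, cleared_mutant = 5),
#'                    model_params())$N_NK  # 15
#' @export
apply_deactivation <- function(immune, tally, pars) {
  stopifnot(inherits(immune, "immune_state"), inherits(tally, "clearance_tally"))
  immune_state(
    N_NK = max(0, immune$N_NK -
                 pars$deactivation_per_kill_NK * tally$cleared_by_NK),
    N_CTL = max(0, immune$N_CTL -
                  pars$deactivation_per_kill_CTL * tally$cleared_by_CTL),
    N_Treg = immune$N_Treg,
    tau = immune$tau
  )
}
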