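#' @importFrom stats runif rmultinom setNames
NULL

# --- internal population representation -------------------------------------
# The engine keeps the cell population as parallel raw vectors (one slot per
# cell) and only materializes tibbles at the API boundary.

pop_from_cells <- function(cells) {
  list(dP = cells$delta_P, dA = cells$delta_A, dIE = cells$delta_IE,
       emt = cells$emt_score, zeta = cells$zeta, mp = cells$mut_prob)
}

cells_from_pop <- function(pop) {
  tibble::tibble(delta_P = pop$dP, delta_A = pop$dA, delta_IE = pop$dIE,
                 emt_score = pop$emt, zeta = pop$zeta, mut_prob = pop$mp)
}

pop_size <- function(pop) length(pop$dP)
pop_mutant <- function(pop) pop$dP | pop$dA | pop$dIE

# One main-phase cycle on the raw representation, in algorithm order:
# (1) synchronous fate draw against cycle-start populations and application
#     (proliferation duplicates, apoptosis/clearance removes, clearances
#     tallied); (2) mutation machinery for proliferating cells (a mutation
#     acquired at division is clonal: parent and daughter both carry it;
#     daughters inherit the parent's full state including the post-division
#     mut_prob, so the cell-autonomous mutation probability counts
#     non-mutating proliferations along the ancestral lineage);
# (3) effector exhaustion then the exact-exponential immune ODE step with
#     forcing frozen at cycle start; (4) algebraic TGF-beta recomputation;
# (5) EMT-score and phenotype update for every cell.
cycle_raw <- function(pop, imm, infl_state, pars, mutation_on = TRUE) {
  n <- pop_size(pop)
  tally <- list(cleared_by_NK = 0L, cleared_by_CTL = 0L, cleared_mutant = 0L)
  births <- 0L
  deaths <- 0L
  if (n > 0) {
    pr <- fate_probs_vec(pop$dP, pop$dA, pop$dIE, pop$zeta, n,
                         imm$N_NK, imm$N_CTL, imm$N_Treg, pars)
    f <- draw_fate_codes(pr)
    nk_cl <- f == 3L
    ctl_cl <- f == 4L
    mut <- pop_mutant(pop)
    tally$cleared_by_NK <- sum(nk_cl)
    tally$cleared_by_CTL <- sum(ctl_cl)
    tally$cleared_mutant <- sum((nk_cl | ctl_cl) & mut)
    pidx <- which(f == 1L)
    births <- length(pidx)
    deaths <- sum(f == 2L)
    if (mutation_on && length(pidx)) {
      acq <- stats::runif(length(pidx)) < pop$mp[pidx]
      pop$mp[pidx] <- ifelse(acq, 0, pop$mp[pidx] + pars$mut_increment)
      if (any(acq)) {
        res <- flip_random_pathway(pop$dP, pop$dA, pop$dIE, pidx[acq])
        pop$dP <- res$dP; pop$dA <- res$dA; pop$dIE <- res$dIE
      }
    }
    keep <- f == 1L | f == 5L
    pop <- list(
      dP = c(pop$dP[keep], pop$dP[pidx]),
      dA = c(pop$dA[keep], pop$dA[pidx]),
      dIE = c(pop$dIE[keep], pop$dIE[pidx]),
      emt = c(pop$emt[keep], pop$emt[pidx]),
      zeta = c(pop$zeta[keep], pop$zeta[pidx]),
      mp = c(pop$mp[keep], pop$mp[pidx])
    )
  }
  # immune update: exhaustion, then ODE step with cycle-start forcing
  imm2 <- list(
    N_NK = max(0, imm$N_NK - pars$deactivation_per_kill_NK *
                 tally$cleared_by_NK),
    N_CTL = max(0, imm$N_CTL - pars$deactivation_per_kill_CTL *
                  tally$cleared_by_CTL),
    N_Treg = imm$N_Treg, tau = imm$tau
  )
  n_star <- tally$cleared_mutant
  eff <- if (infl_state == "LOW") {
    list(s_ctl = pars$sigma_CTL_low, s_treg = pars$sigma_Treg_low)
  } else {
    list(s_ctl = pars$sigma_CTL_high, s_treg = pars$sigma_Treg_high)
  }
  nk <- linear_step(imm2$N_NK, pars$sigma_NK, pars$d_NK)
  if (mutation_on) {
    ctl <- linear_step(imm2$N_CTL, eff$s_ctl * n_star, pars$d_CTL)
    treg <- linear_step(imm2$N_Treg,
                        eff$s_treg * n_star * imm$tau / (1 + imm$tau / pars$K_4),
                        pars$d_Treg)
  } else {
    ctl <- 0; treg <- 0
  }
  n_mut <- sum(pop_mutant(pop))
  tau <- pars$tau_MUT * n_mut + pars$tau_Treg * treg
  pop$emt <- emt_step_vec(pop$emt, tau, pars)
  pop$zeta <- pop$emt > pars$T_MES
  list(pop = pop,
       imm = list(N_NK = nk, N_CTL = ctl, N_Treg = treg, tau = tau),
       tally = tally, births = births, deaths = deaths)
}

# Warmup fast path. During warmup no mutations occur and only NK cells are
# present; all cells share one (unmutated, epithelial) state, so per-cycle
# fates are drawn as one multinomial over the population count --
# distributionally identical to per-cell draws.
warmup_raw <- function(pars, scheme, track = FALSE) {
  n <- pars$N_0
  emt <- 0
  zeta <- FALSE
  imm <- list(N_NK = pars$sigma_NK / pars$d_NK, N_CTL = 0, N_Treg = 0, tau = 0)
  infl <- scheme$start_state
  sizes <- if (track) integer(pars$warmup_cycles) else NULL
  for (t in seq_len(pars$warmup_cycles)) {
    if (n > 0) {
      pr <- fate_probs_vec(FALSE, FALSE, FALSE, zeta, n,
                           imm$N_NK, imm$N_CTL, imm$N_Treg, pars)
      counts <- stats::rmultinom(1, n, c(pr$rho_P, pr$rho_A, pr$rho_NK,
                                         pr$rho_CTL, pr$rho_R))
      cleared <- counts[3] + counts[4]
      n <- n + counts[1] - counts[2] - cleared
      nk0 <- max(0, imm$N_NK - pars$deactivation_per_kill_NK * counts[3])
    } else {
      nk0 <- imm$N_NK
    }
    imm$N_NK <- linear_step(nk0, pars$sigma_NK, pars$d_NK)
    emt <- emt_step_vec(emt, 0, pars)
    zeta <- emt > pars$T_MES
    if (track) sizes[t] <- n
  }
  list(n = n, emt = emt, zeta = zeta, imm = imm, infl = infl, sizes = sizes)
}

# --- exported surface --------------------------------------------------------

#' Tumor state
#'
#' Bundles the cell population, the cycle index (0 = first post-warmup
#' cycle), the immune state and the inflammation scheme.
#'
#' @param cells a tumor-cell tibble ([tumor_cells()]).
#' @param immune an `immune_state`.
#' @param scheme an `inflammation_scheme`.
#' @param cycle_index current post-warmup cycle index.
#' @param extinct whether the tumor went extinct.
#' @return an object of class `tumor_state`.
#' @export
tumor_state <- function(cells, immune = immune_state(),
                        scheme = inflammation_scheme(), cycle_index = 0L,
                        extinct = FALSE) {
  structure(list(cells = validate_cells(cells), immune = immune,
                 scheme = scheme, cycle_index = as.integer(cycle_index),
                 extinct = isTRUE(extinct)),
            class = "tumor_state")
}

#' @export
print.tumor_state <- function(x, ...) {
  n <- nrow(x$cells)
  cat(sprintf(
    "<tumor_state> cycle %d | %d cells (%d mutant, %d mesenchymal)%s\n",
    x$cycle_index, n,
    sum(x$cells$delta_P | x$cells$delta_A | x$cells$delta_IE),
    sum(x$cells$zeta), if (x$extinct) " | EXTINCT" else ""))
  print(x$immune)
  invisible(x)
}

#' Run the pre-mutation warmup phase
#'
#' Starts from `N_0` unmutated epithelial cells and runs `warmup_cycles`
#' cycles with mutation disabled and the adaptive compartments (CTL, Treg)
#' absent; only NK cells are present, at their recruitment/death equilibrium.
#' The tumor completes its exponential growth phase and settles at the
#' mean-field carrying capacity `K_0 (p / d_C - 1)` (when NK pressure on
#' unmutated cells is zero, i.e. `delta_MUT_baseline = 0`). Inflammation is
#' held at the scheme's start state. Extinction during warmup is flagged on
#' the returned state, not an error.
#'
#' @param pars a `model_params` object.
#' @param scheme an `inflammation_scheme`.
#' @param track_sizes record the per-cycle population sizes (attribute
#'   `warmup_sizes` of the result).
#' @return a `tumor_state` at post-warmup cycle 0.
#' @examples
#' set.seed(1)
#' st <- run_warmup(model_params(warmup_cycles = 50, N_0 = 20),
#'                  inflammation_scheme())
#' nrow(st$cells)
#' @export
run_warmup <- function(pars, scheme = inflammation_scheme(),
                       track_sizes = FALSE) {
  stopifnot(inherits(pars, "model_params"))
  w <- warmup_raw(pars, scheme, track = track_sizes)
  st <- tumor_state(
    tumor_cells(max(w$n, 0), emt_score = w$emt, zeta = w$zeta, mut_prob = 0),
    immune = immune_state(N_NK = w$imm$N_NK, N_CTL = 0, N_Treg = 0, tau = 0),
    scheme = scheme, cycle_index = 0L, extinct = w$n <= 0
  )
  if (track_sizes) attr(st, "warmup_sizes") <- w$sizes
  st
}

#' Advance the simulation by one cell cycle
#'
#' Executes one post-warmup cycle in algorithm order: synchronous fate
#' assignment and application for every cell (fates drawn against
#' cycle-start populations; daughters are not exposed to fate decisions
#' until the next cycle), mutation machinery for proliferating cells,
#' effector exhaustion followed by the immune population step, TGF-beta
#' recomputation, and the EMT-score/phenotype update.
#'
#' @param state a `tumor_state`.
#' @param pars a `model_params` object.
#' @return a list with `state` (advanced `tumor_state`), `tally`
#'   (a `clearance_tally` for the cycle), and the cycle's `births` and
#'   `deaths` (apoptoses) for exact bookkeeping: the new tumor size equals
#'   the old size + births - deaths - clearances.
#' @examples
#' set.seed(1)
#' st <- tumor_state(tumor_cells(10), immune_state(N_NK = 50))
#' step_cycle(st, model_params())$tally
#' @export
step_cycle <- function(state, pars) {
  stopifnot(inherits(state, "tumor_state"), inherits(pars, "model_params"))
  infl <- inflammation_state(state$cycle_index, state$scheme)
  res <- cycle_raw(pop_from_cells(state$cells),
                   list(N_NK = state$immune$N_NK, N_CTL = state$immune$N_CTL,
                        N_Treg = state$immune$N_Treg, tau = state$immune$tau),
                   infl, pars, mutation_on = TRUE)
  new_state <- tumor_state(
    cells_from_pop(res$pop),
    immune = immune_state(N_NK = res$imm$N_NK, N_CTL = res$imm$N_CTL,
                          N_Treg = res$imm$N_Treg, tau = res$imm$tau),
    scheme = state$scheme, cycle_index = state$cycle_index + 1L,
    extinct = pop_size(res$pop) == 0
  )
  list(state = new_state,
       tally = clearance_tally(res$tally$cleared_by_NK,
                               res$tally$cleared_by_CTL,
                               res$tally$cleared_mutant),
       births = res$births, deaths = res$deaths)
}

#' Has the tumor progressed to invasion?
#'
#' The tumor is invasive once the fraction of cells harboring at least one
#' pathway mutation reaches the progression threshold (50% by default; the
#' comparison is `>=`). An empty (extinct) tumor has not progressed.
#'
#' @param state a `tumor_state`.
#' @param pars a `model_params` object.
#' @return logical; attribute `extinct` marks the empty-tumor case.
#' @examples
#' st <- tumor_state(tumor_cells(4, delta_P = c(TRUE, TRUE, FALSE, FALSE)))
#' check_progression(st, model_params())  # 2/4 >= 0.5
#' @export
check_progression <- function(state, pars) {
  n <- nrow(state$cells)
  if (n == 0) {
    return(structure(FALSE, extinct = TRUE))
  }
  frac <- sum(state$cells$delta_P | state$cells$delta_A |
                state$cells$delta_IE) / n
  structure(frac >= pars$progression_threshold, extinct = FALSE)
}

# Trajectory recording columns.
traj_cols <- c("cycle", "n_tumor", "n_mutant", "n_mesenchymal", "N_NK",
               "N_CTL", "N_Treg", "tau", "inflammation")

#' Simulate one in-silico patient
#'
#' Runs the warmup phase, then the main loop: each cycle draws and applies
#' tumor-cell fates, runs the mutation machinery, updates the immune
#' populations, TGF-beta and EMT scores, and checks progression. The time to
#' invasion is the first post-warmup cycle at which the mutant fraction
#' reaches the progression threshold; a patient whose tumor never progresses
#' is right-censored at `max_cycles`. Extinction yields a censored record
#' with `extinct = TRUE`.
#'
#' @param pars a `model_params` object.
#' @param scheme an `inflammation_scheme`.
#' @param seed integer seed; fully determines the record.
#' @param record_trajectory keep the per-cycle state table (slower).
#' @return an object of class `patient_record`: a list with
#'   `time_to_invasion` (cycles), `censored`, `extinct`, `seed`, and
#'   optionally `trajectory` (a tibble).
#' @examples
#' rec <- simulate_patient(model_params(warmup_cycles = 50, max_cycles = 100),
#'                         inflammation_scheme(), seed = 1)
#' rec$censored
#' @export
simulate_patient <- function(pars, scheme = inflammation_scheme(), seed = 1L,
                             record_trajectory = FALSE) {
  stopifnot(inherits(pars, "model_params"))
  set.seed(seed)
  w <- warmup_raw(pars, scheme)
  pop <- list(dP = rep(FALSE, max(w$n, 0)), dA = rep(FALSE, max(w$n, 0)),
              dIE = rep(FALSE, max(w$n, 0)),
              emt = rep(w$emt, max(w$n, 0)), zeta = rep(w$zeta, max(w$n, 0)),
              mp = rep(0, max(w$n, 0)))
  imm <- w$imm
  traj <- if (record_trajectory) {
    matrix(NA_real_, nrow = pars$max_cycles, ncol = 8)
  } else NULL
  infl_traj <- if (record_trajectory) character(pars$max_cycles) else NULL
  time <- pars$max_cycles
  censored <- TRUE
  extinct <- w$n <= 0
  thr <- pars$progression_threshold
  if (!extinct) {
    # cycle 0 is the post-warmup state itself (progression can in principle
    # already hold for a seeded state; after a standard warmup it cannot)
    t <- 0L
    repeat {
      n <- pop_size(pop)
      if (n == 0) { extinct <- TRUE; break }
      if (sum(pop_mutant(pop)) / n >= thr) {
        time <- t; censored <- FALSE; break
      }
      if (t >= pars$max_cycles) break
      infl <- inflammation_state(t, scheme)
      res <- cycle_raw(pop, imm, infl, pars, mutation_on = TRUE)
      pop <- res$pop; imm <- res$imm
      t <- t + 1L
      if (record_trajectory) {
        traj[t, ] <- c(t, pop_size(pop), sum(pop_mutant(pop)),
                       sum(pop$zeta), imm$N_NK, imm$N_CTL, imm$N_Treg,
                       imm$tau)
        infl_traj[t] <- infl
      }
    }
  }
  rec <- structure(
    list(time_to_invasion = as.integer(time), censored = censored,
         extinct = extinct, seed = as.integer(seed)),
    class = "patient_record")
  if (record_trajectory) {
    keep <- !is.na(traj[, 1])
    tr <- tibble::as_tibble(setNames(as.data.frame(traj[keep, , drop = FALSE]),
                                     traj_cols[1:8]))
    tr$inflammation <- infl_traj[keep]
    rec$trajectory <- tr
  }
  rec
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> time to invasion %d cycles%s%s (seed %d)\n",
              x$time_to_invasion,
              if (x$censored) " (censored)" else "",
              if (x$extinct) " (extinct)" else "", x$seed))
  invisible(x)
}

# Deterministic per-patient seed derivation from the master seed: the master
# seed initializes R's RNG once and n seeds are drawn; patient i always gets
# the i-th seed regardless of execution order.
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

#' Simulate a cohort of in-silico patients
#'
#' Runs `n_patients` independent patient simulations. Per-patient seeds are
#' derived deterministically from the master seed (a fixed draw of `n`
#' integers), so the cohort is reproducible and independent of execution
#' order, and two cohorts sharing a master seed share their per-patient
#' random streams (common random numbers across parameter settings).
#'
#' @param pars a `model_params` object.
#' @param scheme an `inflammation_scheme`.
#' @param n_patients cohort size.
#' @param master_seed integer master seed.
#' @param record_trajectories keep per-cycle trajectories (memory-heavy).
#' @return an object of class `cohort_result` with `patients` (a tibble:
#'   `patient_id`, `seed`, `time_to_invasion_cycles`, `time_to_invasion_days`,
#'   `censored`, `extinct`), `params`, `scheme`, `master_seed`, and
#'   `trajectories` (list, if recorded).
#' @examples
#' co <- simulate_cohort(model_params(warmup_cycles = 20, max_cycles = 50,
#'                                    N_0 = 10),
#'                       n_patients = 3, master_seed = 42)
#' co$patients
#' @export
simulate_cohort <- function(pars, scheme = inflammation_scheme(),
                            n_patients = 100L, master_seed = 1L,
                            record_trajectories = FALSE) {
  stopifnot(n_patients >= 1)
  seeds <- derive_seeds(master_seed, n_patients)
  recs <- purrr::map(seeds, function(s) {
    simulate_patient(pars, scheme, seed = s,
                     record_trajectory = record_trajectories)
  })
  patients <- tibble::tibble(
    patient_id = seq_len(n_patients),
    seed = seeds,
    time_to_invasion_cycles = vapply(recs, `[[`, integer(1),
                                     "time_to_invasion"),
    censored = vapply(recs, `[[`, logical(1), "censored"),
    extinct = vapply(recs, `[[`, logical(1), "extinct")
  )
  patients$time_to_invasion_days <-
    cycles_to_days(patients$time_to_invasion_cycles, pars)
  patients <- patients[, c("patient_id", "seed", "time_to_invasion_cycles",
                           "time_to_invasion_days", "censored", "extinct")]
  out <- structure(
    list(patients = patients, params = pars, scheme = scheme,
         master_seed = as.integer(master_seed)),
    class = "cohort_result")
  if (record_trajectories) {
    out$trajectories <- purrr::map(recs, "trajectory")
  }
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "<cohort_result> %d patients (master seed %d) | %.0f%% censored | median time to invasion %s cycles\n",
    nrow(x$patients), x$master_seed, 100 * mean(x$patients$censored),
    format(stats::median(x$patients$time_to_invasion_cycles))))
  invisible(x)
}

#' @rdname simulate_cohort
#' @param x a `cohort_result`.
#' @param ... unused.
#' @export
tidy.cohort_result <- function(x, ...) x$patients

#' @rdname simulate_cohort
#' @export
glance.cohort_result <- function(x, ...) {
  km <- km_estimate(surv_data(x$patients$time_to_invasion_cycles,
                              !x$patients$censored))
  tibble::tibble(
    n_patients = nrow(x$patients),
    n_events = sum(!x$patients$censored),
    censoring_fraction = mean(x$patients$censored),
    extinction_fraction = mean(x$patients$extinct),
    median_cycles = stats::median(x$patients$time_to_invasion_cycles),
    rmst_cycles = restricted_mean(km, horizon = x$params$max_cycles)
  )
}
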