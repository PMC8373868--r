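#' Create a population of tumor cells
#'
#' Each tumor cell is an agent with three boolean pathway mutations
#' (proliferation `delta_P`, apoptosis `delta_A`, immune evasion `delta_IE`),
#' a continuous EMT score in \[0,1\], the mesenchymal phenotype flag `zeta`
#' (score strictly above `T_MES` at the last update), and a cell-autonomous
#' mutation probability `mut_prob` that grows by a fixed increment with every
#' non-mutating proliferation and resets to 0 on mutation; daughters inherit
#' it, so it counts non-mutating proliferations along the ancestral lineage
#' since the last mutation. Mutations are monotone: once acquired they are
#' faithfully passed to daughters and never revert.
#'
#' @param n number of cells.
#' @param delta_P,delta_A,delta_IE logical, recycled to length `n`.
#' @param emt_score numeric in \[0,1\], recycled.
#' @param zeta logical phenotype flag, recycled.
#' @param mut_prob numeric >= 0, recycled.
#' @return a tibble with one row per cell.
#' @examples
#' tumor_cells(3)
#' @export
tumor_cells <- function(n, delta_P = FALSE, delta_A = FALSE, delta_IE = FALSE,
                        emt_score = 0, zeta = FALSE, mut_prob = 0) {
  stopifnot(n >= 0)
  cells <- tibble::tibble(
    delta_P = rep_len(as.logical(delta_P), n),
    delta_A = rep_len(as.logical(delta_A), n),
    delta_IE = rep_len(as.logical(delta_IE), n),
    emt_score = rep_len(as.numeric(emt_score), n),
    zeta = rep_len(as.logical(zeta), n),
    mut_prob = rep_len(as.numeric(mut_prob), n)
  )
  validate_cells(cells)
}

validate_cells <- function(cells) {
  stopifnot(is.data.frame(cells))
  need <- c("delta_P", "delta_A", "delta_IE", "emt_score", "zeta", "mut_prob")
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    stop("cells table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cells) &&
      (any(cells$emt_score < 0) || any(cells$emt_score > 1))) {
    stop("emt_score must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(cells) && any(cells$mut_prob < 0)) {
    stop("mut_prob must be >= 0", call. = FALSE)
  }
  tibble::as_tibble(cells)
}

# Vectorized fate probabilities on raw columns; returns a list of five
# numeric vectors that sum to 1 elementwise. Clamp-and-rescale: if the four
# active probabilities exceed 1 (pathological parameters), they are rescaled
# proportionally and rest gets 0.
fate_probs_vec <- function(dP, dA, dIE, zeta, n_tumor, nk, ctl, treg, pars) {
  crowd <- 1 / (1 + n_tumor / pars$K_0)
  rP <- pars$p * (1 + dP * pars$Delta_P) * (1 - zeta * pars$Delta_MGA) * crowd
  rA <- pars$d_C * (1 - dA * pars$Delta_A)
  mut <- dP | dA | dIE
  dmut <- ifelse(mut, 1, pars$delta_MUT_baseline)
  evade <- (1 - dIE * pars$Delta_IE) * (1 - zeta * pars$Delta_MIE)
  load <- n_tumor / pars$K_1
  sat_nk <- if (nk > 0) nk / (load + nk) else 0
  sat_ctl <- if (ctl > 0) ctl / (load + ctl) else 0
  suppress <- 1 / (1 + treg / pars$K_2)
  rNK <- dmut * sat_nk * pars$E_NK * suppress * evade
  rCTL <- dmut * sat_ctl * pars$E_CTL * suppress * evade
  s <- rP + rA + rNK + rCTL
  over <- s > 1
  if (any(over)) {
    sc <- ifelse(over, 1 / s, 1)
    rP <- rP * sc; rA <- rA * sc; rNK <- rNK * sc; rCTL <- rCTL * sc
    s <- pmin(s, 1)
  }
  list(rho_P = rP, rho_A = rA, rho_NK = rNK, rho_CTL = rCTL,
       rho_R = pmax(0, 1 - s))
}

#' Per-cycle fate probabilities of tumor cells
#'
#' For each cell, the probability of proliferating, undergoing apoptosis,
#' being cleared by NK cells or by CTLs, or resting in G0 this cycle:
#' \deqn{\rho_P = p (1 + \delta_P \Delta_P)(1 - \zeta \Delta_{MGA}) / (1 + N_C/K_0)}
#' \deqn{\rho_A = d_C (1 - \delta_A \Delta_A)}
#' \deqn{\rho_{NK} = \delta_{MUT} \frac{N_{NK}}{N_C/K_1 + N_{NK}}
#'   \frac{E_{NK}}{1 + N_{Treg}/K_2} (1-\delta_{IE}\Delta_{IE})(1-\zeta\Delta_{MIE})}
#' with CTL clearance of the same form using \eqn{N_{CTL}} and \eqn{E_{CTL}},
#' and \eqn{\rho_R} the complement. \eqn{\delta_{MUT}} is 1 for a cell with
#' at least one mutation and `delta_MUT_baseline` otherwise (mutated cells
#' are more immunogenic). Mesenchymal cells (\eqn{\zeta = 1}) proliferate
#' less (growth arrest \eqn{\Delta_{MGA}}) and evade clearance
#' (\eqn{\Delta_{MIE}}); \eqn{\Delta_{MIE} = 1} is complete evasion.
#'
#' @param cells a tumor-cell tibble (see [tumor_cells()]).
#' @param n_tumor total tumor size N_C (>= 1; the cells themselves count).
#' @param immune an `immune_state`.
#' @param pars a `model_params` object.
#' @return a tibble with columns `rho_P`, `rho_A`, `rho_NK`, `rho_CTL`,
#'   `rho_R`, one row per cell, each row summing to 1.
#' @examples
#' compute_fate_probabilities(tumor_cells(1), 1, immune_state(),
#'                            model_params())
#' @export
compute_fate_probabilities <- function(cells, n_tumor, immune, pars) {
  cells <- validate_cells(cells)
  if (n_tumor < 1) stop("n_tumor must be >= 1", call. = FALSE)
  if (min(immune$N_NK, immune$N_CTL, immune$N_Treg) < 0) {
    stop("immune populations must be >= 0", call. = FALSE)
  }
  tibble::as_tibble(fate_probs_vec(
    cells$delta_P, cells$delta_A, cells$delta_IE, cells$zeta,
    n_tumor, immune$N_NK, immune$N_CTL, immune$N_Treg, pars
  ))
}

fate_levels <- c("PROLIFERATE", "APOPTOSE", "CLEARED_BY_NK", "CLEARED_BY_CTL",
                 "REST")

# Integer fate codes 1..5 for prob vectors; one uniform draw per cell.
draw_fate_codes <- function(pr) {
  u <- stats::runif(length(pr$rho_P))
  c1 <- pr$rho_P
  c2 <- c1 + pr$rho_A
  c3 <- c2 + pr$rho_NK
  c4 <- c3 + pr$rho_CTL
  1L + (u >= c1) + (u >= c2) + (u >= c3) + (u >= c4)
}

#' Draw cell fates
#'
#' Categorical draw of one fate per cell from its fate-probability row,
#' using the current R random stream (reproducible under `set.seed()`).
#'
#' @param probs a tibble as returned by [compute_fate_probabilities()].
#' @param tol tolerance on each row's probabilities summing to 1.
#' @return a factor with levels `PROLIFERATE`, `APOPTOSE`, `CLEARED_BY_NK`,
#'   `CLEARED_BY_CTL`, `REST`.
#' @examples
#' set.seed(1)
#' draw_fate(tibble::tibble(rho_P = 1, rho_A = 0, rho_NK = 0, rho_CTL = 0,
#'                          rho_R = 0))
#' @export
draw_fate <- function(probs, tol = 1e-9) {
  s <- probs$rho_P + probs$rho_A + probs$rho_NK + probs$rho_CTL + probs$rho_R
  if (any(abs(s - 1) > tol)) {
    stop("fate probabilities must sum to 1", call. = FALSE)
  }
  lo <- pmin(probs$rho_P, probs$rho_A, probs$rho_NK, probs$rho_CTL,
             probs$rho_R)
  if (any(lo < -tol)) stop("fate probabilities must be >= 0", call. = FALSE)
  factor(fate_levels[draw_fate_codes(probs)], levels = fate_levels)
}

# Flip one not-yet-mutated pathway, uniformly at random, for each row index
# in `idx`. Cells with all three mutations are left unchanged.
flip_random_pathway <- function(dP, dA, dIE, idx) {
  for (i in idx) {
    open <- which(!c(dP[i], dA[i], dIE[i]))
    if (!length(open)) next
    pick <- if (length(open) == 1L) open else open[sample.int(length(open), 1L)]
    if (pick == 1L) dP[i] <- TRUE else if (pick == 2L) dA[i] <- TRUE
    else dIE[i] <- TRUE
  }
  list(dP = dP, dA = dA, dIE = dIE)
}

#' Acquire a mutation in a random open pathway
#'
#' Flips exactly one currently unmutated pathway to mutated, chosen
#' uniformly among the unmutated ones. A cell already mutated in all three
#' pathways is returned unchanged (acquisition is a no-op, flagged in the
#' `saturated` attribute).
#'
#' @param cells a tumor-cell tibble; every row acquires one mutation.
#' @return the updated tibble; attribute `saturated` is a logical vector
#'   marking rows that had no open pathway.
#' @examples
#' set.seed(1)
#' choose_mutation_pathway(tumor_cells(1, delta_P = TRUE, delta_A = TRUE))
#' @export
choose_mutation_pathway <- function(cells) {
  cells <- validate_cells(cells)
  saturated <- cells$delta_P & cells$delta_A & cells$delta_IE
  res <- flip_random_pathway(cells$delta_P, cells$delta_A, cells$delta_IE,
                             which(!saturated))
  cells$delta_P <- res$dP; cells$delta_A <- res$dA; cells$delta_IE <- res$dIE
  attr(cells, "saturated") <- saturated
  cells
}

#' Mutation machinery for proliferating cells
#'
#' Called for cells whose fate this cycle is proliferation. With probability
#' `mut_prob` the cell gains one mutation in a random open pathway and its
#' cell-autonomous mutation probability resets to 0; otherwise `mut_prob`
#' increases by the fixed increment (1e-4 by default). After `k` consecutive
#' non-mutating proliferations along the lineage since the last mutation
#' (or since the founder's birth), `mut_prob = k * mut_increment`; daughters
#' inherit the parent's post-division value.
#'
#' @param cells tibble of proliferating cells.
#' @param pars a `model_params` object.
#' @return a list with `cells` (updated parents) and `acquired` (logical,
#'   which rows mutated this division).
#' @examples
#' set.seed(1)
#' update_mutation_machinery(tumor_cells(2, mut_prob = c(0, 1)),
#'                           model_params())$acquired
#' @export
update_mutation_machinery <- function(cells, pars) {
  cells <- validate_cells(cells)
  n <- nrow(cells)
  acquired <- if (n) stats::runif(n) < cells$mut_prob else logical(0)
  cells$mut_prob <- ifelse(acquired, 0, cells$mut_prob + pars$mut_increment)
  if (any(acquired)) {
    res <- flip_random_pathway(cells$delta_P, cells$delta_A, cells$delta_IE,
                               which(acquired))
    cells$delta_P <- res$dP; cells$delta_A <- res$dA; cells$delta_IE <- res$dIE
  }
  list(cells = cells, acquired = acquired)
}

# Raw EMT recurrence on score vectors.
emt_step_vec <- function(score, tgfb, pars) {
  gain <- pars$emt_gain * (tgfb / (tgfb + pars$K_tau))
  s <- score + gain * (1 - score) - pars$emt_decay * score
  pmin(1, pmax(0, s))
}

#' Update EMT scores and phenotypes
#'
#' The continuous EMT score of each cell responds to the external TGF-beta
#' concentration through a saturating (Hill-type, half-saturation `K_tau`)
#' gain toward 1 and a linear decay toward 0, clamped to \[0,1\]:
#' `score' = score + emt_gain * tgfb/(tgfb + K_tau) * (1 - score)
#'   - emt_decay * score`.
#' A cell whose updated score is strictly above `T_MES` undergoes EMT and is
#' mesenchymal (`zeta = TRUE`); otherwise it is (or reverts to, MET)
#' epithelial. Under constant TGF-beta the score converges to
#' `g / (g + emt_decay)` with `g = emt_gain * tgfb/(tgfb + K_tau)`.
#'
#' @param cells a tumor-cell tibble.
#' @param tgfb TGF-beta concentration, >= 0.
#' @param pars a `model_params` object.
#' @return the updated tibble.
#' @examples
#' update_emt_score(tumor_cells(1, emt_score = 0.4), tgfb = 10, model_params())
#' @export
update_emt_score <- function(cells, tgfb, pars) {
  cells <- validate_cells(cells)
  if (!is.finite(tgfb) || tgfb < 0) {
    stop("tgfb must be finite and >= 0", call. = FALSE)
  }
  cells$emt_score <- emt_step_vec(cells$emt_score, tgfb, pars)
  cells$zeta <- cells$emt_score > pars$T_MES
  cells
}
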