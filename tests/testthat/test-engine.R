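test_that("warmup yields a mutation-free tumor near carrying capacity", {
  pars <- model_params(N_0 = 30)
  expect_identical(pars$warmup_cycles, 1000L)
  set.seed(2)
  st <- run_warmup(pars, inflammation_scheme(), track_sizes = TRUE)
  expect_identical(st$cycle_index, 0L)
  expect_false(any(st$cells$delta_P | st$cells$delta_A | st$cells$delta_IE))
  expect_true(all(st$cells$mut_prob == 0))
  sizes <- attr(st, "warmup_sizes")
  target <- pars$K_0 * (pars$p / pars$d_C - 1)
  expect_lt(abs(mean(tail(sizes, 100)) / target - 1), 0.2)
})

test_that("a cycle with rest-only fates leaves the cell collection unchanged", {
  pars <- quick_params(p = 0, d_C = 0)
  st <- tumor_state(tumor_cells(15), immune_state())
  set.seed(4)
  out <- step_cycle(st, pars)
  expect_identical(nrow(out$state$cells), 15L)
  expect_identical(out$tally$cleared_by_NK, 0L)
  expect_identical(out$births, 0L)
})

test_that("forced apoptosis empties the tumor with zero clearances", {
  pars <- quick_params(p = 0, d_C = 1, Delta_A = 0)
  st <- tumor_state(tumor_cells(20), immune_state(N_NK = 100))
  set.seed(4)
  out <- step_cycle(st, pars)
  expect_identical(nrow(out$state$cells), 0L)
  expect_true(out$state$extinct)
  expect_identical(out$tally$cleared_by_NK + out$tally$cleared_by_CTL, 0L)
  expect_identical(out$deaths, 20L)
})

test_that("step_cycle is deterministic given the stream state", {
  pars <- quick_params()
  st <- tumor_state(tumor_cells(30, delta_IE = rep(c(TRUE, FALSE), 15),
                                mut_prob = 0.01),
                    immune_state(N_NK = 50, N_CTL = 5, N_Treg = 2, tau = 1))
  set.seed(11); a <- step_cycle(st, pars)
  set.seed(11); b <- step_cycle(st, pars)
  expect_identical(a$state$cells, b$state$cells)
  expect_identical(a$state$immune, b$state$immune)
})

test_that("tumor size obeys exact per-cycle bookkeeping", {
  pars <- quick_params(mut_increment = 1e-3)
  st <- tumor_state(tumor_cells(40, delta_P = rep(c(TRUE, FALSE), 20),
                                mut_prob = 0.05),
                    immune_state(N_NK = 50, N_CTL = 10))
  set.seed(8)
  for (i in 1:30) {
    n0 <- nrow(st$cells)
    mut0 <- sum(st$cells$delta_P | st$cells$delta_A | st$cells$delta_IE)
    out <- step_cycle(st, pars)
    cleared <- out$tally$cleared_by_NK + out$tally$cleared_by_CTL
    expect_identical(nrow(out$state$cells),
                     as.integer(n0 + out$births - out$deaths - cleared))
    # mutations never revert: mutant count can only drop via removals
    mut1 <- sum(out$state$cells$delta_P | out$state$cells$delta_A |
                  out$state$cells$delta_IE)
    expect_gte(mut1, mut0 - out$deaths - cleared)
    st <- out$state
    if (nrow(st$cells) == 0) break
  }
})

test_that("progression is a >= 50% mutant-fraction threshold", {
  pars <- model_params()
  half <- tumor_state(tumor_cells(100, delta_P = rep(c(TRUE, FALSE),
                                                     each = 50)))
  expect_true(check_progression(half, pars))
  none <- tumor_state(tumor_cells(100))
  expect_false(check_progression(none, pars))
  under <- tumor_state(tumor_cells(100, delta_P = rep(c(TRUE, FALSE),
                                                      c(49, 51))))
  expect_false(check_progression(under, pars))
  empty <- tumor_state(tumor_cells(0))
  res <- check_progression(empty, pars)
  expect_false(res)
  expect_true(attr(res, "extinct"))
})

test_that("patients without mutation are censored at the horizon", {
  pars <- quick_params(mut_increment = 0)
  rec <- simulate_patient(pars, inflammation_scheme(), seed = 3)
  expect_true(rec$censored)
  expect_identical(rec$time_to_invasion, pars$max_cycles)
})

test_that("patient records are reproducible and trajectories consistent", {
  pars <- quick_params()
  a <- simulate_patient(pars, inflammation_scheme(), seed = 17,
                        record_trajectory = TRUE)
  b <- simulate_patient(pars, inflammation_scheme(), seed = 17,
                        record_trajectory = TRUE)
  expect_identical(a, b)
  expect_identical(nrow(a$trajectory),
                   as.integer(if (a$censored && !a$extinct) pars$max_cycles
                              else a$time_to_invasion))
  expect_true(all(a$trajectory$n_mutant <= a$trajectory$n_tumor))
  expect_true(all(a$trajectory$inflammation %in% c("LOW", "HIGH")))
})

test_that("a state seeded beyond the threshold progresses at cycle 0", {
  st <- generate_fixture("forced-progression")
  pars <- model_params()
  expect_true(check_progression(st, pars))
})

test_that("cohorts are deterministic, sized, and composable", {
  pars <- quick_params()
  a <- simulate_cohort(pars, inflammation_scheme(), n_patients = 10,
                       master_seed = 5)
  b <- simulate_cohort(pars, inflammation_scheme(), n_patients = 10,
                       master_seed = 5)
  expect_identical(a$patients, b$patients)
  expect_identical(nrow(a$patients), 10L)
  expect_identical(anyDuplicated(a$patients$seed), 0L)

  off <- generate_fixture("mutation-off")
  expect_identical(mean(off$patients$censored), 1)

  g <- glance(a)
  expect_identical(g$n_patients, 10L)
  expect_identical(tidy(a), a$patients)
})
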