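test_that("inflammation schedule follows the half-open block convention", {
  expect_identical(
    inflammation_state(0:5, inflammation_scheme("CONSTANT_HIGH")),
    rep("HIGH", 6))
  sch <- inflammation_scheme("CYCLING", ihd = 50, ild = 100,
                             start_state = "LOW")
  expect_identical(inflammation_state(c(0, 99, 100, 149, 150, 249, 250), sch),
                   c("LOW", "LOW", "HIGH", "HIGH", "LOW", "LOW", "HIGH"))
  sch_hi <- inflammation_scheme("CYCLING", ihd = 50, ild = 100,
                                start_state = "HIGH")
  expect_identical(inflammation_state(0, sch_hi), "HIGH")
  expect_error(inflammation_state(-1, sch), ">= 0")
  expect_error(inflammation_scheme("CYCLING", ihd = 0), "ihd")
})

test_that("TGF-beta is the stated linear combination of its sources", {
  pars <- model_params(tau_MUT = 0.01, tau_Treg = 0.1)
  expect_identical(compute_tgfb(0, immune_state(), pars), 0)
  expect_equal(compute_tgfb(50, immune_state(N_Treg = 20), pars), 2.5)
  t1 <- compute_tgfb(30, immune_state(N_Treg = 7), pars)
  t2 <- compute_tgfb(60, immune_state(N_Treg = 14), pars)
  expect_equal(t2, 2 * t1)
  expect_error(compute_tgfb(-1, immune_state(), pars), ">= 0")
})

test_that("immune step matches the closed-form linear-ODE solution", {
  # equilibrium: sigma_NK = d_NK * N_NK leaves NK unchanged
  pars <- model_params(sigma_NK = 5, d_NK = 0.1)
  st <- step_immune(immune_state(N_NK = 50), clearance_tally(), tau = 0,
                    state = "LOW", pars = pars)
  expect_equal(st$N_NK, 50, tolerance = 1e-12)

  # growth from 0 with a = 10, d = 0.1 over one cycle
  pars2 <- model_params(sigma_NK = 10, d_NK = 0.1)
  st2 <- step_immune(immune_state(N_NK = 0), clearance_tally(), tau = 0,
                     state = "LOW", pars = pars2)
  expect_equal(st2$N_NK, 100 * (1 - exp(-0.1)), tolerance = 1e-12)

  # no antigenic stimulus: CTLs decay purely exponentially
  pars3 <- model_params(d_CTL = 0.2)
  st3 <- step_immune(immune_state(N_CTL = 40), clearance_tally(), tau = 5,
                     state = "HIGH", pars = pars3)
  expect_equal(st3$N_CTL, 40 * exp(-0.2), tolerance = 1e-12)
})

test_that("exponential update agrees with fine-step numerical integration", {
  set.seed(21)
  for (i in 1:20) {
    pars <- model_params(
      sigma_NK = runif(1, 0, 20), d_NK = runif(1, 0.01, 1),
      sigma_CTL_low = runif(1, 0, 2), d_CTL = runif(1, 0.01, 1),
      sigma_Treg_low = runif(1, 0, 2), d_Treg = runif(1, 0.01, 1),
      K_4 = runif(1, 1, 50))
    imm <- immune_state(N_NK = runif(1, 0, 100), N_CTL = runif(1, 0, 100),
                        N_Treg = runif(1, 0, 100))
    n_star <- sample(0:10, 1)
    tau <- runif(1, 0, 20)
    tally <- clearance_tally(cleared_by_NK = n_star, cleared_mutant = n_star)
    ours <- step_immune(imm, tally, tau, "LOW", pars)
    # independent oracle: adaptive ODE integration of the same constant-
    # forcing system over one cycle
    rhs <- function(t, y, parms) {
      list(c(
        pars$sigma_NK - pars$d_NK * y[1],
        pars$sigma_CTL_low * n_star - pars$d_CTL * y[2],
        pars$sigma_Treg_low * n_star * tau / (1 + tau / pars$K_4) -
          pars$d_Treg * y[3]))
    }
    num <- deSolve::ode(c(imm$N_NK, imm$N_CTL, imm$N_Treg), c(0, 1), rhs,
                        NULL, method = "lsoda", rtol = 1e-12, atol = 1e-12)
    expect_equal(ours$N_NK, unname(num[2, 2]), tolerance = 1e-8)
    expect_equal(ours$N_CTL, unname(num[2, 3]), tolerance = 1e-8)
    expect_equal(ours$N_Treg, unname(num[2, 4]), tolerance = 1e-8)
  }
})

test_that("with no stimulus the adaptive arm dies out and NK equilibrates", {
  pars <- model_params()
  imm <- immune_state(N_NK = 5, N_CTL = 30, N_Treg = 30)
  for (i in 1:400) {
    imm <- step_immune(imm, clearance_tally(), tau = 0, state = "LOW",
                       pars = pars)
  }
  expect_equal(imm$N_NK, pars$sigma_NK / pars$d_NK, tolerance = 1e-6)
  expect_lt(imm$N_CTL, 1e-10)
  expect_lt(imm$N_Treg, 1e-10)
})

test_that("Treg recruitment saturates in TGF-beta", {
  pars <- model_params(K_4 = 10, sigma_Treg_low = 1, d_Treg = 0.1)
  forcing <- function(tau) {
    st <- step_immune(immune_state(), clearance_tally(2, 0, 2), tau, "LOW",
                      pars)
    st$N_Treg
  }
  taus <- c(0.1, 1, 10, 100, 1e4)
  vals <- vapply(taus, forcing, numeric(1))
  expect_true(all(diff(vals) > 0))
  # tau -> Inf limit: forcing term -> sigma * N* * K_4
  lim <- 1 * 2 * 10 / 0.1 * (1 - exp(-0.1))  # a/d scaled over one cycle
  expect_equal(vals[length(vals)], lim, tolerance = 1e-2)
})

test_that("exhaustion removes effectors per kill and floors at zero", {
  pars <- model_params(deactivation_per_kill_NK = 1,
                       deactivation_per_kill_CTL = 1)
  imm <- immune_state(N_NK = 20, N_CTL = 10)
  same <- apply_deactivation(imm, clearance_tally(), pars)
  expect_identical(same$N_NK, 20)
  expect_identical(same$N_CTL, 10)
  hit <- apply_deactivation(imm, clearance_tally(5, 3, 8), pars)
  expect_identical(hit$N_NK, 15)
  expect_identical(hit$N_CTL, 7)
  wipe <- apply_deactivation(immune_state(N_NK = 2),
                             clearance_tally(5, 0, 5), pars)
  expect_identical(wipe$N_NK, 0)
})

test_that("clearance tally rejects inconsistent counts", {
  expect_error(clearance_tally(1, 1, 3), "invalid")
  expect_error(clearance_tally(-1, 0, 0), "invalid")
})
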