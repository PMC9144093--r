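test_that("renal markers follow their published formulas", {
  m <- covariate_table(age = 50, sex = "male", height = 170, weight = 65, scr = 0.8)
  expect_equal(m$crcl, 101.5625)
  f <- covariate_table(age = 50, sex = "female", height = 170, weight = 65, scr = 0.8)
  expect_equal(f$crcl, 0.85 * 101.5625)
  expect_equal(f$mdrd, 0.742 * 175 * 0.8^-1.154 * 50^-0.203)
  # CKD-EPI male, scr above kappa: 141 (scr/0.9)^-1.209 0.993^age
  expect_equal(
    covariate_table(age = 60, sex = "male", height = 175, weight = 80, scr = 1.2)$ckdepi,
    141 * (1.2 / 0.9)^-1.209 * 0.993^60)
  # clearance vanishes as scr grows
  big <- covariate_table(age = 50, sex = "male", height = 170, weight = 65, scr = 1e6)
  expect_lt(big$crcl, 1e-3)
  expect_error(covariate_table(age = 50, sex = "male", height = 170,
                               weight = 65, scr = 0), "positive")
  expect_error(compute_renal_markers(transform(m, scr = -1)), "positive")
})

test_that("typical values evaluate covariate functions deterministically", {
  m <- pk_model("lin", CL = ~ 3.5 * (crcl / 100), V1 = 30, Q = 5, V2 = 50,
                residual = list(add = 1, prop = 0))
  cov <- covariate_table(age = c(50, 50), sex = "male", height = 170,
                         weight = 65, scr = 0.8)
  cov$crcl <- c(100, 50)
  tv <- typical_values(m, cov)
  expect_equal(tv$CL, c(3.5, 1.75))
  expect_equal(tv$V1, c(30, 30))
  # covariate-free model: constants for every patient
  k <- pk_model("const", CL = 3, V1 = 30, Q = 5, V2 = 50,
                residual = list(add = 1, prop = 0))
  expect_equal(typical_values(k, cov), data.frame(CL = c(3, 3), V1 = 30, Q = 5, V2 = 50))
  # missing covariate named in the error
  mdrd_model <- pk_model("need_mdrd", CL = ~ 2 * (mdrd / 90), V1 = 30, Q = 5, V2 = 50,
                         residual = list(add = 1, prop = 0))
  expect_error(typical_values(mdrd_model, cov[, c("age", "sex", "weight")]), "mdrd")
})

test_that("model construction rejects invalid specs", {
  bad_omega <- matrix(c(0.1, 0.2, 0.2, 0.1), 2, dimnames = list(c("CL", "V1"), c("CL", "V1")))
  expect_error(pk_model("bad", CL = 3, V1 = 30, Q = 5, V2 = 50, omega = bad_omega,
                        residual = list(add = 1, prop = 0)), "semi-definite")
  expect_error(pk_model("bad", CL = ~ system("ls"), V1 = 30, Q = 5, V2 = 50,
                        residual = list(add = 1, prop = 0)), "disallowed")
  expect_error(pk_model("bad", CL = ~ 2 * bodyfat, V1 = 30, Q = 5, V2 = 50,
                        residual = list(add = 1, prop = 0)), "bodyfat")
  expect_error(pk_model("bad", CL = 3, V1 = 30, Q = 5, V2 = 50,
                        residual = list(add = 0, prop = 0)), "residual")
})

test_that("analytic concentration matches an independent ODE solution", {
  reg <- regimen() # 1000 mg over 1 h
  pars <- random_params(25, seed = 11)
  times <- c(0.25, 0.5, 1, 2, 3, 5, 8, 12)
  for (i in seq_len(nrow(pars))) {
    a <- concentration_profile(pars[i, ], reg, times)[1, ]
    b <- ode_conc(pars$CL[i], pars$V1[i], pars$Q[i], pars$V2[i], reg, times)
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-12)), 1e-6)
  }
})

test_that("concentration limits and edge cases", {
  reg <- regimen(doses = data.frame(time = 2, amt = 1000, dur = 1))
  p <- data.frame(CL = 4, V1 = 30, Q = 6, V2 = 50)
  # zero before any dose
  expect_equal(concentration(p, reg, c(0, 1, 2)), c(0, 0, 0))
  # Q = 0 collapses to the one-compartment infusion solution
  p1 <- data.frame(CL = 4, V1 = 30, Q = 0, V2 = 50)
  r0 <- regimen()
  t <- c(0.25, 0.75, 1)
  expect_equal(concentration(p1, r0, t),
               (1000 / 1) / 4 * (1 - exp(-(4 / 30) * t)), tolerance = 1e-12)
  # decays to zero long after the last dose
  expect_lt(concentration(p, r0, 1000), 1e-10)
  # nearly degenerate alpha ~ beta handled by the limiting form, not a crash
  pdeg <- data.frame(CL = 2, V1 = 20, Q = 1e-9, V2 = 20)
  expect_true(is.finite(concentration(pdeg, r0, 3)))
})

test_that("analytic AUC matches dense-grid quadrature and mass balance", {
  reg <- regimen()
  pars <- random_params(10, seed = 3)
  grid <- seq(12, 24, by = 0.001)
  for (i in seq_len(nrow(pars))) {
    cg <- concentration_profile(pars[i, ], reg, grid)[1, ]
    trap <- sum((cg[-1] + cg[-length(cg)]) / 2) * 0.001
    expect_lt(abs(auc_interval(pars[i, ], reg, 12, 24) - trap) / trap, 1e-4)
  }
  # steady state over one interval is exactly dose / CL
  rss <- regimen(tau = 12, steady_state = TRUE)
  expect_equal(auc_interval(pars, rss, 12, 24), 1000 / pars$CL, tolerance = 1e-8)
  expect_equal(auc_interval(pars, rss, 0, 12), 1000 / pars$CL, tolerance = 1e-8)
  # zero dose gives zero exposure
  r0 <- regimen(doses = data.frame(time = 0, amt = 0, dur = 1))
  expect_equal(auc_interval(pars[1, ], r0, 0, 24), 0)
})

test_that("AUC is additive over abutting windows", {
  pars <- random_params(5, seed = 9)
  for (reg in list(regimen(), regimen(tau = 12, steady_state = TRUE))) {
    ab <- auc_interval(pars, reg, 2, 7)
    bc <- auc_interval(pars, reg, 7, 30)
    ac <- auc_interval(pars, reg, 2, 30)
    expect_equal(ab + bc, ac, tolerance = 1e-10)
  }
})

test_that("steady-state profile equals the limit of repeated dosing", {
  p <- data.frame(CL = 3.5, V1 = 30, Q = 7, V2 = 50)
  rss <- regimen(tau = 12, steady_state = TRUE)
  many <- regimen(doses = data.frame(time = seq(0, 12 * 60, by = 12), amt = 1000, dur = 1))
  t_in <- c(1, 2, 5, 12)
  a <- concentration_profile(p, rss, t_in)[1, ]
  b <- concentration_profile(p, many, 60 * 12 + t_in)[1, ]
  expect_equal(a, b, tolerance = 1e-7)
})

test_that("residual error model has the specified variance and floor", {
  # zero sds reproduce the input exactly
  expect_equal(apply_residual_error(c(5, 10), list(add = 0, prop = 0)), c(5, 10))
  # Monte-Carlo check of the combined noise sd
  obs <- apply_residual_error(rep(10, 1e5), list(add = 1, prop = 0), seed = 1)
  expect_lt(abs(sd(obs) - 1) / 1, 0.02)
  obs2 <- apply_residual_error(rep(10, 1e5), list(add = 0.5, prop = 0.2), seed = 2)
  expect_lt(abs(sd(obs2) - sqrt(0.25 + 4)) / sqrt(4.25), 0.02)
  # floor contract: never below the floor, never negative
  low <- apply_residual_error(rep(0.05, 1e4), list(add = 5, prop = 0), seed = 3)
  expect_gte(min(low), 0.01)
})
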