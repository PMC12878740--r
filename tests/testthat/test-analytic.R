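test_that("buildup time scales match the closed-form expressions", {
  ts <- time_scales(default_params, default_implant)

  # frozen from the defining formulas evaluated by hand:
  # T1  = (1 - 1e-4) * 52.7 * 4 / 34.7
  # TMg = (1.538*3 + 0.452*2 + (6.05/0.0775)*0.3*12.3 + 4*(138/34.7)*52.7) / 10.9
  expect_equal(ts$T1, 6.074323, tolerance = 1e-6)
  expect_equal(ts$TMg, 103.8455, tolerance = 1e-6)
  expect_equal(sum(ts$shares), 1, tolerance = 1e-12)
  expect_equal(unname(ts$shares["tissue"]), 0.740638, tolerance = 1e-5)
  expect_equal(unname(ts$shares["bone"]), 0.254487, tolerance = 1e-5)

  # TMg is inversely proportional to the excretion rate
  doubled <- physiology_params(gamma = 2 * 10.9)
  expect_equal(time_scales(doubled, default_implant)$TMg, ts$TMg / 2)
})

test_that("critical release rate behaves as phiD * (Chyp* - 1) * (1 - xi)", {
  sh <- sigma_hyp(default_params, default_implant)
  expect_equal(sh, 6 * (1.05 / 0.85 - 1) * (1 - 1e-4), tolerance = 1e-12)

  # xi -> 0 limit and linearity in phiD
  tiny <- scale_implants(1, 0.05, 1e-9, default_params)
  expect_equal(sigma_hyp(default_params, tiny),
               6 * (1.05 / 0.85 - 1), tolerance = 1e-8)
  half <- physiology_params(phiD = 3)
  expect_equal(sigma_hyp(half, default_implant), sh / 2, tolerance = 1e-12)
})

test_that("hypermagnesemia onset time follows TMg * log(sigma/(sigma - sigma_hyp))", {
  ts <- time_scales(default_params, default_implant)
  sh <- sigma_hyp(default_params, default_implant)

  expect_equal(t_hyp(default_params, default_implant, sigma = 2 * sh),
               ts$TMg * log(2), tolerance = 1e-12)
  expect_equal(ts$TMg * log(2), 71.98, tolerance = 1e-3)

  # monotone decreasing in sigma, -> 0 as sigma grows
  sig <- c(1.5, 2, 3, 5, 50, 5000)
  th <- vapply(sig, function(s)
    t_hyp(default_params, default_implant, sigma = s), numeric(1))
  expect_true(all(diff(th) < 0))
  expect_lt(th[length(th)], 0.05)

  # at or below the critical rate the threshold is never reached
  expect_identical(t_hyp(default_params, default_implant, sigma = sh), Inf)
  expect_identical(t_hyp(default_params, default_implant, sigma = 0.05), Inf)
})

test_that("two-exponential approximation tracks the full solution for small xi", {
  tg <- default_time_grid(n = 120)
  for (n in c(1, 10)) {
    impl <- scale_implants(n, 0.05, 0.00527, default_params)
    ap <- approx_trajectory(default_params, impl, t_grid = tg)
    tr <- simulate_pbpk(default_params, impl, t_grid = tg,
                        method = "closed_form")
    expect_lt(max(abs(ap$Cs_star - tr$Cs_star) / tr$Cs_star), 0.01)
    expect_lt(max(abs(ap$CT_star - tr$CT_star) / tr$CT_star), 0.01)
  }

  # anchors: t = 0 and t = TMg
  ts <- time_scales(default_params, default_implant)
  ap0 <- approx_trajectory(default_params, default_implant,
                           t_grid = c(0, ts$TMg))
  expect_equal(unname(unlist(ap0[1, -1])), rep(1, 4))
  S <- 0.05 / ((1 - 1e-4) * 6)
  expect_equal(ap0$Cs_star[2], 1 + (1 - exp(-1)) * S, tolerance = 1e-12)

  expect_warning(
    approx_trajectory(default_params,
                      scale_implants(1, 10, 5, default_params),
                      t_grid = c(0, 10)),
    "xi")
})

test_that("systemic buildup time is independent of the release rate", {
  # formula level: time_scales() has no sigma argument; numeric level:
  # the 63.2%-rise time of serum agrees across release rates within 5%
  ts <- time_scales(default_params, default_implant)
  rise_time <- function(sigma) {
    impl <- scale_implants(sigma / 0.05, 0.05, 0.00527, default_params)
    ss <- steady_state(default_params, impl, rho = 1)
    target <- 1 + (1 - exp(-1)) * (ss[["Cs_star"]] - 1)
    stats::uniroot(function(t)
      cs_star_at(t, default_params, impl) - target,
      c(1, 600), tol = 1e-3)$root
  }
  times <- vapply(c(0.05, 0.5, 1.45), rise_time, numeric(1))
  expect_lt(max(times) / min(times) - 1, 0.05)
  expect_equal(times[1], ts$TMg, tolerance = 0.1)
})

test_that("serum dip under intake reduction follows 1 + (rho-1)*gamma/k1", {
  expect_identical(min_serum_normalized(default_params, 1), 1)
  m0 <- min_serum_normalized(default_params, 0)
  expect_equal(m0, 1 - 10.9 / 138, tolerance = 1e-12)
  # ~8% drop at zero intake, comfortably above hypomagnesemia (~0.76-0.88)
  expect_gt(m0, 0.88)
  expect_error(min_serum_normalized(default_params, 1.5), "rho")
})

test_that("dietary factor solves the steady-state targets", {
  inert <- scale_implants(1, 0, 0.00527, default_params)
  expect_equal(rho_for_target(default_params, inert)$rho_raw, 1)

  twenty <- scale_implants(20, 0.05, 0.00527, default_params)
  r <- rho_for_target(default_params, twenty, "homeostasis")
  expect_equal(r$rho_raw, 1 - 1 / 6)
  expect_true(r$feasible)

  rh <- rho_for_target(default_params, twenty, "avoid_hyper")
  expect_equal(rh$rho_raw, 1.05 / 0.85 - 1 / 6)

  big <- scale_implants(240, 0.05, 0.00527, default_params)  # sigma = 2*phiD
  rbig <- rho_for_target(default_params, big, "homeostasis")
  expect_equal(rbig$rho_raw, -1)
  expect_false(rbig$feasible)
  expect_equal(rbig$rho, 0)
})

test_that("minimum implant count for hypermagnesemia is found by integer scan", {
  expect_identical(min_implants_hyper(default_params), 29L)

  # bracketing: n = 28 stays below the normalized threshold, n = 29 crosses
  expect_equal(1 + 28 * 0.05 / 6, 1.23333, tolerance = 1e-5)
  expect_equal(1 + 29 * 0.05 / 6, 1.24167, tolerance = 1e-5)
  expect_lt(1 + 28 * 0.05 / 6, 1.05 / 0.85)
  expect_gt(1 + 29 * 0.05 / 6, 1.05 / 0.85)

  # a single implant at (slightly above) the critical rate suffices
  sh0 <- 6 * (1.05 / 0.85 - 1)
  expect_identical(min_implants_hyper(default_params, sigma0 = sh0 * 1.0001),
                   1L)

  # monotone non-increasing in the per-implant rate
  counts <- vapply(c(0.02, 0.05, 0.1, 0.5, 1.5),
                   function(s0) min_implants_hyper(default_params, s0),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})
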