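test_that("standard scenario: systemic compartments overlap; output is deterministic", {
  spec <- scenario_spec("standard", t_grid = grid_short)
  tab <- run_scenario(spec)
  expect_setequal(unique(tab$compartment), c("Cs", "CN", "CT", "CI"))

  wide <- split(tab$C_star, tab$compartment)
  # serum, bone and tissue curves mutually within 1% at all times
  expect_lt(max(abs(wide$CN - wide$Cs) / wide$Cs), 0.01)
  expect_lt(max(abs(wide$CT - wide$Cs) / wide$Cs), 0.01)
  # while the implant zone rises far above them
  expect_gt(max(wide$CI), 3.41)

  expect_identical(tab, run_scenario(spec))
})

test_that("plate scenario: little systemic effect in the first days despite xi ~ 0.023", {
  spec <- scenario_spec("plate", t_grid = grid_short,
                        method = "closed_form")
  tab <- run_scenario(spec)
  cs <- tab[tab$compartment == "Cs", ]
  chyp <- 1.05 / 0.85
  expect_true(all(cs$C_star[cs$t_days <= 5] < chyp))
  # but the 10 mmol/day release eventually drives hypermagnesemia
  expect_gt(max(cs$C_star), chyp)
  impl <- scale_implants(1, 10, 1.2, default_params)
  expect_equal(impl$xi, 1.2 / 52.7, tolerance = 1e-12)
  expect_equal(impl$xi, 0.023, tolerance = 0.01)
})

test_that("multi-implant scenario brackets the hypermagnesemia count", {
  spec <- scenario_spec("multi_implant", t_grid = grid_short,
                        method = "closed_form")
  tab <- run_scenario(spec)
  expect_setequal(unique(tab$sweep_value), c(1, 5, 10, 20, 29, 50))
  chyp <- 1.05 / 0.85
  longrun <- tab[tab$compartment == "Cs" & tab$t_days == max(tab$t_days), ]
  expect_lt(longrun$C_star[longrun$sweep_value == 20], chyp)
  expect_gt(longrun$C_star[longrun$sweep_value == 29], chyp)
  # serum burden increases with implant count at every time point
  cs <- tab[tab$compartment == "Cs", ]
  by_n <- split(cs$C_star, cs$sweep_value)
  ord <- order(as.numeric(names(by_n)))
  for (i in seq_len(length(ord) - 1)) {
    expect_true(all(by_n[[ord[i + 1]]] >= by_n[[ord[i]]] - 1e-12))
  }
})

test_that("diet control: rebounding intake reductions dip to the predicted minimum", {
  spec <- scenario_spec("diet_control", t_grid = grid_3yr,
                        method = "closed_form")
  tab <- run_scenario(spec)
  padj <- renal_adjust(default_params, 1 / 3)
  TMg_adj <- time_scales(padj, scale_implants(20, params = padj))$TMg

  cs <- tab[tab$compartment == "Cs", ]
  rhos <- sort(unique(cs$sweep_value), decreasing = TRUE)
  expect_equal(rhos, c(1, 1 - 1 / 6, 0.5, 0), tolerance = 1e-12)

  for (r in c(1, 1 - 1 / 6, 0.5)) {
    x <- cs$C_star[cs$sweep_value == r & cs$t_days <= TMg_adj]
    expect_equal(min(x), min_serum_normalized(padj, r), tolerance = 0.01)
  }

  # zero external intake does not rebound: the long-run level
  # rho + sigma/phiD = 0.5 lies below the dip plateau, so serum keeps
  # falling past the dip toward it on the reserve-depletion time scale
  x0 <- cs$C_star[cs$sweep_value == 0]
  expect_lt(min(x0[cs$t_days[cs$sweep_value == 0] <= TMg_adj]),
            min_serum_normalized(padj, 0) - 0.05)
  expect_gt(min(x0), 0.5)

  # intake control barely affects the implant-zone concentration
  ci <- tab[tab$compartment == "CI" & tab$t_days == max(tab$t_days), ]
  expect_lt(diff(range(ci$C_star)) / mean(ci$C_star), 0.15)
})

test_that("renal sweep: serum burden falls with Gamma, rises with implant count", {
  tab <- sweep_renal(default_params,
                     implant_counts = c(0, 1, 5, 10, 15, 20, 29))
  G0 <- 10.9 / 138

  healthy1 <- tab[abs(tab$Gamma - G0) < 1e-12 & tab$n == 1, ]
  expect_equal(healthy1$Cs_inf_star, 1 + 0.05 / 6, tolerance = 1e-9)
  expect_true(all(tab$Cs_inf_star[tab$n == 0] == 1))

  # monotone in both directions
  for (n in c(1, 10, 29)) {
    sub <- tab[tab$n == n, ]
    sub <- sub[order(sub$Gamma), ]
    expect_true(all(diff(sub$Cs_inf_star) < 0))
    expect_true(all(diff(sub$Cs_star_1yr) < 0))
  }
  one_g <- tab[abs(tab$Gamma - G0 / 3) < 1e-9, ]
  expect_true(all(diff(one_g$Cs_inf_star[order(one_g$n)]) >= 0))

  # at one-third kidney function, 10-15 screws reach hypermagnesemia
  tab3 <- sweep_renal(default_params, implant_counts = c(1, 5, 10, 15, 20, 29),
                      Gamma_grid = G0 / 3)
  crossing <- min(tab3$n[tab3$Cs_inf_star >= 1.05 / 0.85])
  expect_true(crossing %in% c(10, 15))

  expect_error(sweep_renal(default_params, Gamma_grid = -0.01), "Gamma")
})

test_that("onset-time sweep: sooner for more implants and worse kidneys, never under months", {
  tab <- sweep_thyp(default_params)

  # a single screw cannot cause hypermagnesemia in any renal state
  s1 <- tab[tab$sigma == 0.05, ]
  expect_true(all(is.infinite(s1$T_hyp)))

  # monotone decreasing in sigma within each renal state
  for (rf in unique(tab$renal_fraction)) {
    sub <- tab[tab$renal_fraction == rf, ]
    fin <- sub[is.finite(sub$T_hyp), ]
    expect_true(all(diff(fin$T_hyp[order(fin$sigma)]) < 0))
  }

  # worse kidneys: onset no later, at any release rate where both are finite
  healthy <- tab[tab$renal_fraction == 1, ]
  third <- tab[abs(tab$renal_fraction - 1 / 3) < 1e-12, ]
  m <- merge(healthy, third, by = "sigma")
  both <- is.finite(m$T_hyp.x) & is.finite(m$T_hyp.y)
  expect_true(any(both))
  expect_true(all(m$T_hyp.y[both] <= m$T_hyp.x[both] + 1e-9))

  # even large implant loads take months: every finite onset exceeds 30 days
  expect_gt(min(tab$T_hyp[is.finite(tab$T_hyp)]), 30)
})

test_that("derived-value presets reshape to the long contract", {
  tab <- run_scenario(scenario_spec("thyp_curve",
                                    sigma_grid = c(0.05, 2, 5)))
  expect_named(tab, c("scenario", "renal_fraction_or_Gamma", "n_or_sigma",
                      "quantity", "value"))
  tab2 <- run_scenario(scenario_spec("renal_sweep",
                                     implant_counts = c(1, 29),
                                     Gamma_grid = 10.9 / 138 * c(0.5, 1)))
  expect_setequal(unique(tab2$quantity), c("Cs_inf_star", "Cs_star_1yr"))
})
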