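test_that("ideal gas law gives the expected amounts", {
  expect_equal(moles_from_state(101325, 0.001, 298.15),
               101.325 / (8.314 * 298.15), tolerance = 1e-12)
  expect_equal(moles_from_state(101325, 0.001, 298.15), 0.04087, tolerance = 1e-3)
  expect_equal(moles_from_state(100000, 0.001, 293.15), 0.04103, tolerance = 1e-4)
  expect_identical(moles_from_state(101325, 0, 298.15), 0)
  expect_error(moles_from_state(-1, 0.001, 298.15), class = "bapscal_error_domain")
  expect_error(moles_from_state(101325, 0.001, 0), class = "bapscal_error_domain")
})

test_that("gas state ties species amounts to the ideal gas law", {
  s <- gas_state(101325, 293.15, 1e-3, synthetic_air())
  expect_equal(s$n_o2 + s$n_co2 + s$n_n2, s$n_total, tolerance = 1e-12)
  expect_equal(s$n_total, s$p_pa * s$v_head_m3 / (8.314 * s$t_k),
               tolerance = 1e-9)
  expect_error(gas_mixture(0.5, 0.6, 0.5), class = "bapscal_error_domain")
})

test_that("one removal/injection exchange reproduces the worked example", {
  s0 <- gas_state(100000, 293.15, 1e-3, synthetic_air())
  s1 <- apply_exchange(s0, exchange_step(1000, 1000))
  expect_equal(100 * s1$n_o2 / s1$n_total, 20.295, tolerance = 1e-10)
  expect_equal(100 * s1$n_co2 / s1$n_total, 0.205, tolerance = 1e-10)
  expect_equal(100 * s1$n_n2 / s1$n_total, 79.5, tolerance = 1e-10)
})

test_that("zero exchange is the identity and matched composition a fixed point", {
  s0 <- gas_state(100000, 293.15, 1e-3, synthetic_air())
  s1 <- apply_exchange(s0, exchange_step(0, 0))
  expect_equal(s1$n_o2, s0$n_o2)
  expect_equal(s1$n_total, s0$n_total)
  # injecting the current composition with dp_out = dp_in changes nothing
  same <- gas_mixture(0.205, 0, 0.795)
  s2 <- apply_exchange(s0, exchange_step(1500, 1500, injected = same))
  expect_equal(s2$n_total, s0$n_total, tolerance = 1e-12)
  expect_equal(s2$n_o2 / s2$n_total, s0$n_o2 / s0$n_total, tolerance = 1e-12)
})

test_that("removal exceeding the pool is an infeasible protocol", {
  s0 <- gas_state(100000, 293.15, 1e-3)
  expect_error(apply_exchange(s0, exchange_step(2e5, 0)),
               class = "bapscal_error_infeasible")
})

test_that("species are conserved across random exchange sequences", {
  set.seed(101)
  for (rep in 1:25) {
    p <- random_protocol()
    state <- gas_state(p$chamber$p_pa, p$chamber$t_k,
                       p$chamber$v_head_ml * 1e-6, p$initial)
    removed <- c(o2 = 0, co2 = 0, n2 = 0)
    injected <- c(o2 = 0, co2 = 0, n2 = 0)
    for (i in seq_len(p$n_steps)) {
      st <- exchange_step(p$dp_pa, p$dp_pa, injected = p$injected)
      n_out <- p$dp_pa * state$v_head_m3 / (8.314 * state$t_k)
      fr <- n_out / state$n_total
      removed <- removed + fr * c(o2 = state$n_o2, co2 = state$n_co2,
                                  n2 = state$n_n2)
      n_in <- n_out
      injected <- injected + n_in * c(o2 = p$injected$frac_o2,
                                      co2 = p$injected$frac_co2,
                                      n2 = p$injected$frac_n2)
      state <- apply_exchange(state, st)
    }
    s0 <- gas_state(p$chamber$p_pa, p$chamber$t_k, p$chamber$v_head_ml * 1e-6,
                    p$initial)
    expect_equal(state$n_o2 + removed[["o2"]],
                 s0$n_o2 + injected[["o2"]], tolerance = 1e-12)
    expect_equal(state$n_co2 + removed[["co2"]],
                 s0$n_co2 + injected[["co2"]], tolerance = 1e-12)
    expect_equal(state$n_n2 + removed[["n2"]],
                 s0$n_n2 + injected[["n2"]], tolerance = 1e-12)
  }
})

test_that("closed-form concentrations match the stepwise mole balance", {
  ideal <- idealized_concentrations(1, 1000, 100000)
  expect_equal(ideal$o2_volpct, 20.295, tolerance = 1e-10)
  expect_equal(ideal$co2_volpct, 0.205, tolerance = 1e-10)
  i0 <- idealized_concentrations(0, 1000, 100000)
  expect_equal(c(i0$o2_volpct, i0$co2_volpct, i0$n2_volpct), c(20.5, 0, 79.5))
  # large i converges to the injected mixture
  inf_step <- idealized_concentrations(5000, 5000, 100000)
  expect_equal(inf_step$co2_volpct, 20.5, tolerance = 1e-6)
  expect_equal(inf_step$o2_volpct, 0, tolerance = 1e-6)
  expect_error(idealized_concentrations(1, 2000, 1000),
               class = "bapscal_error_domain")

  set.seed(202)
  for (rep in 1:25) {
    p <- random_protocol()
    run <- run_protocol(p)
    cf <- idealized_concentrations(0:p$n_steps, p$dp_pa, p$chamber$p_pa,
                                   initial = p$initial, injected = p$injected)
    expect_equal(run$o2_volpct, cf$o2_volpct, tolerance = 1e-10)
    expect_equal(run$co2_volpct, cf$co2_volpct, tolerance = 1e-10)
    expect_equal(run$n2_volpct, cf$n2_volpct, tolerance = 1e-10)
    # fractions always total 100 Vol%
    expect_equal(run$o2_volpct + run$co2_volpct + run$n2_volpct,
                 rep(100, p$n_steps + 1), tolerance = 1e-9)
  }
})

test_that("standard protocol keeps N2 constant, O2 falling and CO2 rising", {
  run <- run_protocol(baps_protocol(n_steps = 8))
  expect_equal(run$n2_volpct, rep(79.5, 9), tolerance = 1e-9)
  expect_true(all(diff(run$o2_volpct) < 0))
  expect_true(all(diff(run$co2_volpct) > 0))
  expect_equal(run$p_hpa, rep(run$p_hpa[1], 9), tolerance = 1e-9)
})

test_that("Vol% and umol/mL conversions agree and round-trip", {
  expect_equal(volpct_to_umol_per_ml(100, 100000, 293.15), 41.03,
               tolerance = 1e-4)
  expect_identical(volpct_to_umol_per_ml(0, 100000, 293.15), 0)
  c0 <- c(0.3, 1.7, 3)
  back <- umol_per_ml_to_volpct(
    volpct_to_umol_per_ml(c0, 98000, 291), 98000, 291)
  expect_equal(back, c0, tolerance = 1e-12)
  # protocol output is consistent between its two CO2 columns
  run <- run_protocol(baps_protocol(n_steps = 4))
  expect_equal(run$co2_umol_ml,
               volpct_to_umol_per_ml(run$co2_volpct, run$p_hpa * 100, 293.15),
               tolerance = 1e-9)
})

test_that("volume extension recovers the headspace volume", {
  expect_equal(headspace_volume(100000, 1000, 10), 990)
  # halved pressure returns the extension volume itself
  expect_equal(headspace_volume(100000, 50000, 123), 123)
  # triplicates are averaged
  expect_equal(headspace_volume(100000, c(1000, 1000, 2000), 10),
               mean(c(990, 990, 490)))
  expect_error(headspace_volume(1000, 2000, 10), class = "bapscal_error_domain")
  expect_error(headspace_volume(1000, 0, 10),
               class = "bapscal_error_infeasible")
})

test_that("headspace-volume uncertainty is syringe-dominated at typical errors", {
  s <- vhead_uncertainty(0.01, 0.0042, 1000)
  expect_gt(s, 1); expect_lt(s, 15)   # approx 10 mL at 1000 mL
  expect_equal(s, 10, tolerance = 0.15)
  expect_identical(vhead_uncertainty(0, 0, 1000), 0)
  # doubling the dominant syringe term approximately doubles the result
  expect_equal(vhead_uncertainty(0.02, 0.0042, 1000) / s, 2, tolerance = 0.07)
})
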