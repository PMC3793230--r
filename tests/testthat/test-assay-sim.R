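# Closed-form mass-balance oracle: once all substrate is consumed, the
# endpoint amounts follow from stoichiometry alone, independent of the ODE
# integration. With urease present every urea is eventually converted.
stoich_endpoint <- function(enzyme, urease, ug0) {
  if (enzyme == "amidohydrolase") {
    list(nh3 = 2 * ug0, urea_made = 0, co2 = ug0)
  } else {
    # lyase or spontaneous decay: all substrate to urea first
    if (urease) list(nh3 = 2 * ug0, urea_made = ug0, co2 = ug0)
    else list(nh3 = 0, urea_made = ug0, co2 = 0)
  }
}

test_that("no enzyme and no decay gives a flat curve with zero readout", {
  cfg <- assay_config(enzyme = "none", k_decay = 0, horizon = 20)
  curve <- simulate_assay(cfg)
  expect_equal(max(abs(curve$ug - cfg$ug0)), 0, tolerance = 1e-9)
  expect_equal(max(curve$readout), 0, tolerance = 1e-9)
  expect_equal(max(curve$nh3_released), 0, tolerance = 1e-9)
})

test_that("the lyase releases no ammonia without urease; urea accumulates fully", {
  cfg <- assay_config(enzyme = "lyase", urease_time = Inf, k_decay = 0)
  curve <- simulate_assay(cfg)
  expect_equal(max(curve$nh3_released), 0, tolerance = 1e-9)
  last <- curve[nrow(curve), ]
  expect_equal(last$urea, cfg$ug0, tolerance = 1e-6)
  ep <- endpoint_stoichiometry(curve)
  expect_equal(ep$urea, 1, tolerance = 1e-3)
  expect_equal(ep$nh3, 0, tolerance = 1e-3)
})

test_that("ODE endpoints agree with the closed-form mass-balance oracle", {
  cases <- list(
    list(enzyme = "amidohydrolase", urease_time = Inf),
    list(enzyme = "lyase", urease_time = 0),
    list(enzyme = "lyase", urease_time = 30)
  )
  for (cs in cases) {
    cfg <- assay_config(enzyme = cs$enzyme, urease_time = cs$urease_time,
                        k_decay = 0)
    curve <- simulate_assay(cfg)
    last <- curve[nrow(curve), ]
    want <- stoich_endpoint(cs$enzyme, is.finite(cs$urease_time), cfg$ug0)
    expect_equal(last$nh3_released, want$nh3, tolerance = 1e-4 * cfg$ug0)
    expect_equal(last$urea_released, want$urea_made, tolerance = 1e-4 * cfg$ug0)
    expect_equal(last$co2, want$co2, tolerance = 1e-4 * cfg$ug0)
  }
})

test_that("mid-run urease addition shows the biphasic signature", {
  cfg <- assay_config(enzyme = "lyase", urease_time = 30)
  curve <- simulate_assay(cfg)
  before <- curve[curve$time <= 29, ]
  # before urease: urea accumulates, essentially no ammonia released
  expect_lt(max(before$nh3_released), 0.01 * cfg$ug0)
  expect_gt(max(before$urea), 0.9 * cfg$ug0)
  # after the event the full two equivalents appear
  expect_equal(curve$nh3_released[nrow(curve)], 2 * cfg$ug0,
               tolerance = 1e-3 * cfg$ug0)
})

test_that("the readout is non-decreasing and tracks captured ammonia", {
  cfg <- assay_config(enzyme = "amidohydrolase", urease_time = Inf, k_decay = 0)
  curve <- simulate_assay(cfg)
  expect_true(all(diff(curve$readout) >= 0))
  last <- curve[nrow(curve), ]
  # GDH consumes one NADH per ammonia captured; with excess NADH and time,
  # everything released is captured
  expect_equal(last$readout, last$nh3_released, tolerance = 1e-4)
})

test_that("nitrogen and carbon balances close along every trajectory", {
  for (enz in c("none", "lyase", "amidohydrolase")) {
    for (tu in c(Inf, 0, 30)) {
      cfg <- assay_config(enzyme = enz, urease_time = tu, k_decay = 0.001)
      bal <- mass_balance(simulate_assay(cfg))
      expect_lt(bal$nitrogen, 1e-6)
      expect_lt(bal$carbon, 1e-6)
    }
  }
})

test_that("activity classification recovers each configured scenario", {
  pair <- function(enzyme, k_decay = 0.001, horizon = 60) {
    list(
      wo = simulate_assay(assay_config(enzyme = enzyme, urease_time = Inf,
                                       k_decay = k_decay, horizon = horizon)),
      w = simulate_assay(assay_config(enzyme = enzyme, urease_time = 0,
                                      k_decay = k_decay, horizon = horizon))
    )
  }
  p <- pair("amidohydrolase")
  expect_identical(classify_activity(p$wo, p$w), "amidohydrolase")
  p <- pair("lyase")
  expect_identical(classify_activity(p$wo, p$w), "lyase")
  p <- pair("none", k_decay = 5e-4)
  expect_identical(classify_activity(p$wo, p$w), "none")
})

test_that("spontaneous-decay ammonia is strictly delayed relative to the lyase", {
  horizon <- 60
  lyase <- simulate_assay(assay_config(enzyme = "lyase", urease_time = 0,
                                       k_decay = 0, horizon = horizon))
  decay <- simulate_assay(assay_config(enzyme = "none", urease_time = 0,
                                       k_decay = 5e-4, horizon = horizon))
  t_lyase <- half_rise_time(lyase)
  t_decay <- half_rise_time(decay)
  expect_false(is.na(t_decay))
  expect_gt(t_decay, t_lyase)
})

test_that("configuration and endpoint guards reject unusable inputs", {
  expect_error(assay_config(urease_time = 70, horizon = 60), "horizon")
  expect_error(assay_config(ug0 = -1))
  short <- simulate_assay(assay_config(enzyme = "lyase", urease_time = Inf,
                                       vmax_enzyme = 1e-4, horizon = 10))
  expect_error(endpoint_stoichiometry(short), "horizon")
  none <- simulate_assay(assay_config(enzyme = "none", k_decay = 0, horizon = 5))
  expect_error(endpoint_stoichiometry(none), "undefined|consumed")
})

test_that("classification rejects mismatched curve pairs", {
  a <- simulate_assay(assay_config(enzyme = "lyase", urease_time = Inf))
  b <- simulate_assay(assay_config(enzyme = "amidohydrolase", urease_time = 0))
  expect_error(classify_activity(a, b), "same configuration")
  expect_error(classify_activity(a, a), "without")
})

test_that("endpoint ratios depend only on stoichiometry, not kinetics", {
  set.seed(123)
  for (i in 1:6) {
    vmax <- 10^stats::runif(1, log10(0.05), log10(5))
    km <- 10^stats::runif(1, log10(0.005), log10(0.5))
    cfg <- assay_config(enzyme = if (i %% 2) "amidohydrolase" else "lyase",
                        urease_time = 0, vmax_enzyme = vmax, km_enzyme = km,
                        k_decay = 0, horizon = 600, dt = 0.5)
    ep <- endpoint_stoichiometry(simulate_assay(cfg))
    expect_equal(ep$nh3, 2, tolerance = 1e-3)
    expect_equal(ep$co2, 1, tolerance = 1e-3)
  }
})
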