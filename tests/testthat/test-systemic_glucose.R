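baseline_drivers <- function(b) {
  list(
    PEPCK = b$liver$PEPCK0, cAMP = b$liver$cAMP0, Food = b$food$Food0,
    IRS1_ratio = 1, DRn = 0
  )
}

test_that("steady-state rates follow the printed closed forms", {
  p <- systemic_params("chronic_infusion", "saline")
  r <- steady_state_rates(p)
  expect_equal(unname(r["ks_I"]), 0.224 * 3.73, tolerance = 1e-12)
  expect_equal(unname(r["ks_F"]), 0.096 * 0.053, tolerance = 1e-12)
  expect_equal(unname(r["ks_G"]), 0.00521 * 197, tolerance = 1e-12)
  # with food modeled, production is rescaled by the baseline intake factor
  r2 <- steady_state_rates(p, list(Food = 91.7), use_food = TRUE)
  expect_equal(unname(r2["ks_G"]),
    0.00521 * 197 / (1 + 0.000346 * 91.7 / 24), tolerance = 1e-12)
})

test_that("returned rates make the baseline state an exact fixed point", {
  des <- study_design("chronic_infusion", "0.3")
  b <- resolve_bundle(des)
  st <- c(G = b$systemic$G0, I = b$systemic$I0, FFA = b$systemic$FFA0)
  d <- systemic_rhs(st, baseline_drivers(b), b$systemic, t = 0,
    rates = b$rates, use_food = TRUE)
  expect_lt(max(abs(d)), 1e-12)
})

test_that("food gain worked example reproduces the printed 0.2%", {
  expect_identical(food_glucose_gain(0), 0)
  g120 <- food_glucose_gain(120)
  expect_equal(g120, 0.000346 * 5, tolerance = 1e-12)
  expect_equal(round(100 * g120, 1), 0.2)
  expect_equal(food_glucose_gain(240), 2 * g120, tolerance = 1e-12)
})

test_that("regimen kind selects the FFA-insulin coupling variant", {
  pa <- systemic_params("circadian_nadir", "im50")
  pc <- systemic_params("chronic_infusion", "0.3")
  expect_equal(pa$S_FI, 13.3)
  expect_equal(pc$S_FI, 28.9)
  des <- study_design("chronic_infusion", "0.3")
  b <- resolve_bundle(des)
  st <- c(G = b$systemic$G0, I = b$systemic$I0, FFA = b$systemic$FFA0 + 0.1)
  dr <- baseline_drivers(b)
  d0 <- systemic_rhs(st, dr, b$systemic, t = 0, rates = b$rates, use_food = TRUE)
  dlate <- systemic_rhs(st, dr, b$systemic, t = 100, rates = b$rates, use_food = TRUE)
  # chronic: the FFA drive on insulin decays with exp(-kFI t)
  expect_gt(d0[["I"]], dlate[["I"]])
  expect_equal(
    d0[["I"]] - dlate[["I"]],
    b$rates[["ks_I"]] * 28.9 * 0.1 * (1 - exp(-0.183 * 100)),
    tolerance = 1e-9
  )
  expect_error(
    systemic_params("chronic_infusion", "0.3", regimen_kind = "weird"),
    "regimen_kind"
  )
  expect_error(systemic_params("chronic_infusion", "nope"), "unknown group")
})

test_that("insulin below baseline reduces glucose utilization (signed deviation)", {
  des <- study_design("chronic_infusion", "0.3")
  b <- resolve_bundle(des)
  dr <- baseline_drivers(b)
  low <- c(G = b$systemic$G0, I = b$systemic$I0 * 0.8, FFA = b$systemic$FFA0)
  d <- systemic_rhs(low, dr, b$systemic, t = 0, rates = b$rates, use_food = TRUE)
  expect_gt(d[["G"]], 0) # less disposal -> glucose rises
})

test_that("saline chronic simulation keeps plasma analytes near baseline for 21 days", {
  sim <- simulate_study(study_design("chronic_infusion", "saline"))
  b <- sim$bundle
  expect_lt(max(abs(sim$states$G - b$systemic$G0)) / b$systemic$G0, 0.03)
  expect_lt(max(abs(sim$states$I - b$systemic$I0)) / b$systemic$I0, 0.03)
  expect_lt(max(abs(sim$states$FFA - b$systemic$FFA0)) / b$systemic$FFA0, 0.03)
})

test_that("steady-state glucose increases with infusion rate at fixed physiology", {
  # hold the group parameters fixed (0.3-arm baselines) and vary only the rate
  ss <- sapply(c(0.1, 0.2, 0.3, 0.4), function(rate) {
    des <- study_design("chronic_infusion", "0.3", t_end = 168)
    des$regimen <- dose_regimen("sc_infusion", rate, t_stop = 168)
    sim <- simulate_study(des)
    summarize_analyte(sim, "G")$terminal
  })
  expect_true(all(diff(ss) > 0))
  expect_gt(ss[4] / 192, 1.05)
})

test_that("chronic dosing gives an early glucose dip driven by the insulin spike", {
  sim <- simulate_study(study_design("chronic_infusion", "0.3"))
  g <- summarize_analyte(sim, "G")
  i <- summarize_analyte(sim, "I")
  b <- sim$bundle
  expect_lt(g$t_nadir, 24)
  expect_lt(g$nadir, b$systemic$G0)
  expect_gt(g$terminal, b$systemic$G0) # gradual rise afterwards
  # insulin rises quickly at the start (initial spike within ~12 h)
  early <- sim$states$I[sim$times <= 12]
  expect_gt(max(early), 1.5 * b$systemic$I0)
})
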