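test_that("baseline harmonization makes every tissue exactly stationary drug-free", {
  for (tissue in c("adipose", "liver", "muscle")) {
    for (key in if (tissue == "liver") c("iv10", "iv50", "infusion") else "default") {
      p <- receptor_params(tissue, key)
      d <- receptor_rhs(receptor_init(p), 0, p)
      expect_lt(max(abs(d)), 1e-10)
    }
  }
})

test_that("harmonized rates keep the printed values where they were consistent", {
  p <- receptor_params("muscle")
  # printed muscle ks_Rm (0.416) is reproduced by kd_Rm * GRm0 to ~0.2%
  expect_equal(p$ks_Rm, 0.139 * 2.99, tolerance = 1e-12)
  expect_equal(p$ks_Rm, 0.416, tolerance = 5e-3)
  pl <- receptor_params("liver", "iv50")
  expect_equal(pl$kd_Rm, 2.90 / 25.8, tolerance = 1e-12)
})

test_that("full nuclear-complex suppression leaves pure mRNA decay", {
  p <- receptor_params("adipose")
  st <- c(GRm = 1500, R = 10, DR = 1, DRn = 1e9)
  d <- receptor_rhs(st, 0, p)
  expect_equal(d[["GRm"]], -p$kd_Rm * 1500, tolerance = 1e-6)
})

test_that("stiff trajectory matches an independent fixed-step RK4 oracle", {
  reg <- im50_regimen()
  p <- receptor_params("adipose")
  cfun <- concentration_fn(reg)
  t_out <- seq(0, 12, by = 0.5)
  oracle <- rk4_integrate(oracle_receptor_rhs(p, cfun), receptor_init(p),
    t_end = 12, h = 5e-4, t_out = t_out)
  sim <- simulate_receptor("adipose", reg, t_grid = t_out, params = p,
    rtol = 1e-11, atol = 1e-13)
  for (cn in c("GRm", "R", "DR", "DRn")) {
    scale <- max(abs(oracle[, cn]))
    expect_lt(max(abs(sim[[cn]] - oracle[, cn])) / scale, 1e-6)
  }
})

test_that("single IM dose reproduces the qualitative receptor signatures", {
  rec <- adipose_im50_receptor()
  s_grm <- summarize_trace(rec$time_h, rec$GRm)
  s_drn <- summarize_trace(rec$time_h, rec$DRn)
  # mRNA is transiently down-regulated then returns toward baseline
  expect_lt(s_grm$nadir, 0.5 * rec$GRm[1])
  expect_gt(s_grm$terminal, 0.95 * rec$GRm[1])
  # free receptor drops to near zero and recovers
  expect_lt(min(rec$R), 0.1 * rec$R[1])
  expect_gt(rec$R[nrow(rec)], 0.8 * rec$R[1])
  # nuclear complex peaks early then declines toward baseline
  expect_lt(s_drn$t_peak, 1)
  expect_lt(rec$DRn[nrow(rec)], 0.01 * s_drn$peak)
})

test_that("chronic infusion shows receptor tolerance: extremum then new steady state", {
  reg <- dose_regimen("sc_infusion", 0.3, t_stop = 168)
  rec <- simulate_receptor("adipose", reg, t_grid = dense_grid(168))
  grm <- rec$GRm
  # down-regulation with partial return to a plateau below baseline
  expect_lt(min(grm), 0.8 * grm[1])
  tail_grm <- grm[rec$time_h > 120]
  expect_lt(max(abs(diff(tail_grm))), 1e-3 * grm[1]) # plateau
  expect_lt(tail_grm[1], 0.95 * grm[1]) # below original baseline
  drn <- rec$DRn
  i_pk <- which.max(drn)
  expect_true(i_pk > 1 && rec$time_h[i_pk] < 24)
  expect_lt(drn[length(drn)], drn[i_pk]) # declined from its peak to a plateau
})

test_that("saline regimen gives a flat trajectory at baseline", {
  rec <- simulate_receptor("adipose", saline_regimen(48), t_grid = seq(0, 48, 0.5))
  expect_lt(max(abs(rec$GRm - rec$GRm[1])), 1e-8 * rec$GRm[1])
  expect_lt(max(abs(rec$DRn)), 1e-8)
})

test_that("negative state or concentration is a domain error", {
  p <- receptor_params("adipose")
  expect_error(receptor_rhs(c(GRm = -1, R = 1, DR = 0, DRn = 0), 0, p), ">= 0")
  expect_error(receptor_rhs(receptor_init(p), -5, p), ">= 0")
})
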