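# Independent fixed-step classical RK4 integrator used as an oracle against
# the adaptive stiff solver. Deliberately minimal and method-independent of
# deSolve.
rk4_integrate <- function(rhs, y0, t_end, h, t_out) {
  n_steps <- ceiling(t_end / h)
  y <- y0
  out <- matrix(NA_real_, length(t_out), length(y0))
  colnames(out) <- names(y0)
  next_out <- 1
  record <- function(tt, yy) {
    while (next_out <= length(t_out) && t_out[next_out] <= tt + h / 2) {
      out[next_out, ] <<- yy
      next_out <<- next_out + 1
    }
  }
  record(0, y)
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * h
    k1 <- rhs(t, y)
    k2 <- rhs(t + h / 2, y + h / 2 * k1)
    k3 <- rhs(t + h / 2, y + h / 2 * k2)
    k4 <- rhs(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    record(i * h, y)
  }
  out
}

# receptor equations re-stated independently for the oracle (same model,
# hand-written rather than calling the package RHS)
oracle_receptor_rhs <- function(p, cfun) {
  function(t, y) {
    C <- cfun(t)
    GRm <- y[1]; R <- y[2]; DR <- y[3]; DRn <- y[4]
    c(
      p$ks_Rm * (1 - DRn / (p$IC50_Rm + DRn)) - p$kd_Rm * GRm,
      p$ks_R * GRm + p$Rf * p$kre * DRn - p$kon * C * R - p$kd_R * R,
      p$kon * C * R - p$kT * DR,
      p$kT * DR - p$kre * DRn
    )
  }
}

# shared expensive fixtures, computed once per test run
im50_regimen <- function() dose_regimen("im_bolus", 50)

.fixture_env <- new.env()
adipose_im50_receptor <- function() {
  if (is.null(.fixture_env$rec)) {
    .fixture_env$rec <- simulate_receptor("adipose", im50_regimen(),
      t_grid = dense_grid(72))
  }
  .fixture_env$rec
}
adipose_im50_drn_fn <- function() {
  rec <- adipose_im50_receptor()
  stats::splinefun(rec$time_h, rec$DRn, method = "natural")
}
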