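# Shared test fixtures and independent oracles.

# Uniform random draws over the fitting box 0.1 <= alpha <= 0.6,
# alpha < rho_U < 2, 0.1 <= gamma_d <= 6, 1 <= tau <= 3600, optionally
# conditioned on the stability class.
rand_params <- function(n, monostable = NA) {
  out <- vector("list", n)
  k <- 0L
  while (k < n) {
    a <- runif(1, 0.1, 0.6)
    rU <- runif(1, a + 1e-6, 2)
    gd <- runif(1, 0.1, 6)
    d <- (2 - rU)^2 - 4 * gd
    if (!is.na(monostable) && monostable != (d <= 0)) next
    k <- k + 1L
    out[[k]] <- efficacy_params(a, runif(1, 1, 3600), gd, rU,
                                runif(1, 0.05, 1.5))
  }
  out
}

# Independent equilibrium finder: sign-scan of the drift on
# [alpha - 0.5, 2.5] with step `step`, then bisection to `tol`.
scan_roots <- function(params, step = 1e-3, tol = 1e-10) {
  x <- seq(params$alpha - 0.5, 2.5, by = step)
  f <- efficacy_drift(x, params)
  hits <- which(f[-length(f)] == 0 | f[-1] * f[-length(f)] < 0)
  roots <- vapply(hits, function(i) {
    if (f[i] == 0) return(x[i])
    a <- x[i]; b <- x[i + 1L]; fa <- f[i]
    while (b - a > tol) {
      m <- (a + b) / 2
      fm <- efficacy_drift(m, params)
      if (fm == 0) return(m)
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
    }
    (a + b) / 2
  }, numeric(1))
  sort(roots)
}

# Exhaustive grid-fit oracle: plain loop over every candidate, integrating
# at the adaptive solver's tolerance; returns the minimal error.
brute_force_min_ef <- function(series, cands) {
  rho_0 <- max(series$ri[1L], 1e-6)
  efs <- vapply(seq_len(nrow(cands)), function(i) {
    p <- efficacy_params(cands$alpha[i], cands$tau[i], cands$gamma_d[i],
                         cands$rho_U[i], rho_0)
    tr <- simulate_efficacy(p, seq(600, 3600, by = 600))
    sum(abs(tr$rho - series$ri))
  }, numeric(1))
  min(efs)
}

# Small grid used wherever full-grid search would be wastefully slow.
reduced_grid <- function() {
  parameter_grid(alpha_values = c(0.2, 0.35, 0.5),
                 tau_values = c(601, 1801, 3600),
                 gamma_d_values = c(0.3, 0.8, 1.5, 3, 5),
                 rho_U_values = c(0.6, 0.9, 1.2, 1.5, 1.8))
}

# Synthetic baseline peak series (pre-session, 1-min spacing ending 1 min
# before the tetanus, so the -5 min reference is always covered).
baseline_peaks <- function(amps, stim_role = "TS") {
  n <- length(amps)
  peak_series(seq(-n - 4, -5), amps, stim_role = stim_role, session = "pre")
}
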