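# shared fixtures built in code

# reference structural parameters (typical fast metabolizer)
ref_params <- function(Cl = 0.012, Vc = 1.35, Q = 0.003, Vp = 1.18,
                       F_top = 0.0784, k_top = 3e-4, Lag = 26.4,
                       F_po = 1, k_po = 0.06) {
  structural_params(Cl, Vc, Q, Vp, F_top, k_top, Lag, F_po, k_po)
}

ref_slow_params <- function() {
  link_transform(flunixin_population_model(), rep(0, 9), MET = 1)
}

# small single-route study: n subjects, one IV bolus each, optional noise
toy_iv_dataset <- function(n = 12, cl_typ = 0.008, omega_cl = 0.3, b = 0.2,
                           dose = 5, times = c(15, 60, 180, 360, 720, 1440),
                           seed = 1) {
  set.seed(seed)
  obs <- list(); dos <- list(); cov <- list()
  for (i in seq_len(n)) {
    cl_i <- cl_typ * exp(rnorm(1, 0, omega_cl))
    p <- structural_params(cl_i, 1.35, 0.003, 1.18, 0.0784, 3e-4, 26.4,
                           1, 0.06)
    d <- data.frame(subject_id = sprintf("S%02d", i), time = 0,
                    amount = dose, route = "IV", phase = 1,
                    period = NA_integer_)
    f <- solve_profile(p, d, times)
    y <- f * (1 + b * rnorm(length(f)))
    while (any(y < 0)) y[y < 0] <- (f * (1 + b * rnorm(length(f))))[y < 0]
    obs[[i]] <- data.frame(subject_id = d$subject_id, time = times,
                           conc = y, censored = FALSE, excluded = FALSE)
    dos[[i]] <- d
    cov[[i]] <- data.frame(subject_id = d$subject_id, sex = "F",
                           bodyweight = 4, MET = 0)
  }
  pk_dataset(do.call(rbind, dos), do.call(rbind, obs),
             do.call(rbind, cov), 0.002)
}

toy_iv_init <- function(cl = 0.01, omega_cl = 0.5, b = 0.3) {
  population_model(
    mu = c(Cl = cl, Vc = 1.35, Q = 0.003, Vp = 1.18, ktop = 3e-4,
           Lag = 26.4, kpo = 0.06),
    xi_Ftop = 0.0784, F_po = 1, beta_Cl_MET = 0,
    omega = c(Cl = omega_cl, Vc = 0, Q = 0, Vp = 0, Ftop = 0, ktop = 0,
              Lag = 0, kpo = 0, Fpo = 0),
    corr = NULL, b = b, fpo_fixed = TRUE)
}

toy_iv_settings <- function(...) {
  saem_settings(n_explore = 200, n_smooth = 100, estimate_beta = FALSE,
                fix_fpo = TRUE, random = "Cl", corr_block = NULL,
                n_cond_iter = 80, n_is_draws = 200, ...)
}

# fast full-study fit settings used where speed matters more than polish
quick_settings <- function(...) {
  saem_settings(n_explore = 150, n_smooth = 80, n_cond_iter = 60,
                n_is_draws = 100, ...)
}
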