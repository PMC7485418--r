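test_that("SAEM matches a brute-force quadrature MLE on a one-parameter toy", {
  ds <- toy_iv_dataset(n = 12, seed = 11)
  fit <- fit_saem(ds, init = toy_iv_init(), settings = toy_iv_settings(),
                  seed = 5)
  # brute-force marginal MLE: adaptive quadrature over the random effect,
  # joint search over (log Cl, log omega, log b)
  subs <- flunixinpk:::.prepare_subjects(ds)
  marg <- function(theta) {
    ccl <- theta[1]; om <- exp(theta[2]); bb <- exp(theta[3])
    ll <- 0
    for (s in subs) {
      g <- function(e) sapply(e, function(ei) {
        p <- structural_params(exp(ccl + ei), 1.35, 0.003, 1.18, 0.0784,
                               3e-4, 26.4, 1, 0.06)
        f <- solve_profile(p, s$doses, s$t_obs)
        exp(sum(dnorm(s$y, f, bb * pmax(f, 0.001), log = TRUE)) +
              dnorm(ei, 0, om, log = TRUE))
      })
      ll <- ll + log(integrate(g, -5 * om, 5 * om, rel.tol = 1e-9)$value)
    }
    -ll
  }
  opt <- optim(c(log(0.008), log(0.3), log(0.2)), marg,
               method = "Nelder-Mead",
               control = list(reltol = 1e-9, maxit = 400))
  cl_mle <- exp(opt$par[1])
  cl_saem <- fit$model$mu[["Cl"]]
  expect_equal(cl_saem, cl_mle, tolerance = 0.05)  # 2 significant figures
  expect_equal(fit$model$b, exp(opt$par[3]), tolerance = 0.1)
  expect_equal(fit$model$omega[["Cl"]], exp(opt$par[2]), tolerance = 0.2)
})

test_that("near-noiseless data at the truth are recovered closely", {
  truth <- flunixin_population_model()
  quiet <- population_model(
    mu = truth$mu, xi_Ftop = truth$xi_Ftop, F_po = 1,
    beta_Cl_MET = truth$beta_Cl_MET,
    omega = setNames(rep(0.02, 9), names(truth$omega)),
    corr = NULL, b = 0.02, fpo_fixed = TRUE)
  ds <- generate_study(config = generator_config(truth = quiet), seed = 31)
  fit <- fit_saem(ds, init = init_from_nca(ds),
                  settings = quick_settings(), seed = 77)
  for (nm in c("Cl", "Vc", "Q", "Vp", "ktop", "Lag", "kpo"))
    expect_equal(fit$model$mu[[nm]], truth$mu[[nm]], tolerance = 0.10)
  expect_equal(100 * fit$model$xi_Ftop, 7.84, tolerance = 0.10)
  expect_equal(fit$model$beta_Cl_MET, -0.892, tolerance = 0.1)
  expect_lt(fit$model$b, 0.05)
})

test_that("fits are reproducible bit-for-bit and satisfy the BIC identity", {
  ds <- toy_iv_dataset(n = 8, seed = 3)
  f1 <- fit_saem(ds, init = toy_iv_init(), settings = toy_iv_settings(),
                 seed = 9)
  f2 <- fit_saem(ds, init = toy_iv_init(), settings = toy_iv_settings(),
                 seed = 9)
  expect_identical(f1$model$mu, f2$model$mu)
  expect_identical(f1$model$b, f2$model$b)
  expect_identical(f1$loglik, f2$loglik)
  expect_equal(f1$BIC, -2 * f1$loglik + f1$n_params * log(8),
               tolerance = 1e-12)
  # a different seed moves the estimates, but only slightly
  f3 <- fit_saem(ds, init = toy_iv_init(), settings = toy_iv_settings(),
                 seed = 10)
  expect_false(identical(f1$model$mu[["Cl"]], f3$model$mu[["Cl"]]))
  expect_equal(f1$model$mu[["Cl"]], f3$model$mu[["Cl"]], tolerance = 0.05)
})

test_that("conditional draws agree with quadrature posteriors on the toy model", {
  ds <- toy_iv_dataset(n = 6, seed = 21)
  model <- toy_iv_init(cl = 0.008, omega_cl = 0.3, b = 0.2)
  cond <- sample_conditional(model, ds, n_iter = 400, n_burn = 50, seed = 2)
  subs <- cond$subjects
  for (i in c(1, 4)) {
    s <- subs[[i]]
    num <- function(e) sapply(e, function(ei) {
      p <- structural_params(0.008 * exp(ei), 1.35, 0.003, 1.18, 0.0784,
                             3e-4, 26.4, 1, 0.06)
      f <- solve_profile(p, s$doses, s$t_obs)
      exp(sum(dnorm(s$y, f, 0.2 * pmax(f, 0.001), log = TRUE)) +
            dnorm(ei, 0, 0.3, log = TRUE))
    })
    z <- integrate(num, -2, 2, rel.tol = 1e-10)$value
    pm <- integrate(function(e) e * num(e), -2, 2, rel.tol = 1e-10)$value / z
    eta_draws <- cond$eta[, i, "Cl"]
    expect_equal(mean(eta_draws), pm, tolerance = 0.05)
  }
})

test_that("the conditional distribution collapses for precise data and widens to the prior for BLQ-only data", {
  # subject A: low-noise informative IV data; subject B: all observations BLQ
  p <- structural_params(0.008, 1.35, 0.003, 1.18, 0.0784, 3e-4, 26.4, 1, 0.06)
  times <- c(30, 120, 480, 960, 1920)
  dA <- data.frame(subject_id = "A", time = 0, amount = 5, route = "IV",
                   phase = 1, period = NA_integer_)
  fA <- solve_profile(p, dA, times)
  dB <- dA; dB$subject_id <- "B"; dB$amount <- 1e-4  # everything below LLOQ
  obs <- rbind(
    data.frame(subject_id = "A", time = times, conc = fA, censored = FALSE,
               excluded = FALSE),
    data.frame(subject_id = "B", time = times, conc = 0.002,
               censored = TRUE, excluded = FALSE))
  cov <- data.frame(subject_id = c("A", "B"), sex = "F", bodyweight = 4,
                    MET = 0)
  ds <- pk_dataset(rbind(dA, dB), obs, cov, 0.002)
  model <- toy_iv_init(cl = 0.008, omega_cl = 0.3, b = 0.05)
  cond <- sample_conditional(model, ds, n_iter = 400, n_burn = 50, seed = 4)
  sd_A <- sd(cond$eta[, "A", "Cl"])
  sd_B <- sd(cond$eta[, "B", "Cl"])
  expect_lt(sd_A, 0.05)              # posterior concentrates on the data
  expect_equal(sd_B, 0.3, tolerance = 0.25)  # posterior is the prior
  expect_equal(mean(cond$eta[, "B", "Cl"]), 0, tolerance = 0.15)
})

test_that("degenerate datasets are rejected with clear messages", {
  ds <- toy_iv_dataset(n = 1, seed = 2)
  expect_error(fit_saem(ds, init = toy_iv_init(),
                        settings = toy_iv_settings()), "2 subjects")
  ds2 <- toy_iv_dataset(n = 3, seed = 2)
  ds2$covariates$MET <- NA
  expect_error(fit_saem(ds2, init = toy_iv_init(),
                        settings = saem_settings(estimate_beta = TRUE)),
               "MET")
})
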