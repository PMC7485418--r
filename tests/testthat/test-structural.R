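test_that("IV bolus initial concentration equals dose over central volume", {
  p <- ref_params()
  d <- data.frame(time = 0, amount = 1.35, route = "IV")
  expect_equal(solve_profile(p, d, 0), 1.0, tolerance = 1e-12)
})

test_that("no dose events give an identically zero profile", {
  p <- ref_params()
  expect_equal(solve_profile(p, data.frame(time = numeric(0),
                                           amount = numeric(0),
                                           route = character(0)),
                             seq(0, 1000, 50)),
               rep(0, 21))
})

test_that("analytic solution matches an adaptive-step ODE oracle", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  rhs <- function(t, y, pr) {
    list(c(-pr["kpo"] * y[1], -pr["ktp"] * y[2],
           pr["kpo"] * y[1] + pr["ktp"] * y[2] -
             (pr["k10"] + pr["k12"]) * y[3] + pr["k21"] * y[4],
           pr["k12"] * y[3] - pr["k21"] * y[4]))
  }
  for (rep in 1:5) {
    p <- structural_params(
      Cl = exp(runif(1, -5.5, -3.5)), Vc = exp(runif(1, -0.5, 1)),
      Q = exp(runif(1, -6.5, -5)), Vp = exp(runif(1, -0.5, 1)),
      F_top = runif(1, 0.02, 0.5), k_top = exp(runif(1, -8.5, -7)),
      Lag = runif(1, 5, 60), F_po = runif(1, 0.5, 1),
      k_po = exp(runif(1, -3.5, -2)))
    doses <- data.frame(time = c(0, 200), amount = c(10, 13),
                        route = sample(c("IV", "PO", "TD"), 2))
    times <- sort(runif(50, 1, 8000))
    dep_time <- ifelse(doses$route == "TD", doses$time + p$Lag, doses$time)
    dep_var <- c(IV = "Ac", IM = "Ac", PO = "Apo", TD = "Atd")[doses$route]
    dep_amt <- ifelse(doses$route == "TD", p$F_top * doses$amount,
                      ifelse(doses$route == "PO", p$F_po * doses$amount,
                             doses$amount))
    evt <- data.frame(var = dep_var, time = dep_time, value = dep_amt,
                      method = "add")
    parms <- c(k10 = p$Cl / p$Vc, k12 = p$Q / p$Vc, k21 = p$Q / p$Vp,
               kpo = p$k_po, ktp = p$k_top)
    ot <- deSolve::ode(c(Apo = 0, Atd = 0, Ac = 0, Ap = 0),
                       sort(unique(c(0, times, evt$time))), rhs, parms,
                       events = list(data = evt),
                       rtol = 1e-12, atol = 1e-14)
    num <- ot[match(times, ot[, "time"]), "Ac"] / p$Vc
    ana <- solve_profile(p, doses, times)
    expect_equal(ana, unname(num), tolerance = 1e-8)
  }
})

test_that("Q -> 0 limit recovers the one-compartment closed form", {
  p <- structural_params(0.01, 2, 1e-10, 1, 0.1, 3e-4, 20, 1, 0.06)
  d <- data.frame(time = 0, amount = 4, route = "IV")
  tt <- seq(0, 2000, by = 100)
  expect_equal(solve_profile(p, d, tt),
               (4 / 2) * exp(-0.01 / 2 * tt), tolerance = 1e-6)
})

test_that("profiles are linear in dose amount", {
  p <- ref_params()
  d1 <- data.frame(time = c(0, 300), amount = c(5, 10),
                   route = c("IV", "TD"))
  d2 <- d1; d2$amount <- 2 * d1$amount
  tt <- seq(10, 6000, by = 97)
  expect_equal(solve_profile(p, d2, tt), 2 * solve_profile(p, d1, tt),
               tolerance = 1e-12)
})

test_that("transdermal terminal slope is absorption-limited (flip-flop)", {
  p <- ref_slow_params()
  d <- data.frame(time = 0, amount = 13.2, route = "TD")
  tt <- c(10000, 11000, 12000, 13000)   # deep terminal phase
  cc <- solve_profile(p, d, tt)
  slope <- -coef(lm(log(cc) ~ tt))[[2]]
  expect_equal(slope, p$k_top, tolerance = 1e-3)
  expect_equal(log(2) / p$k_top, 2310, tolerance = 0.01)
  # IV terminal slope is the slow disposition exponent, not k_top
  dv <- data.frame(time = 0, amount = 8.8, route = "IV")
  cciv <- solve_profile(p, dv, tt)
  slope_iv <- -coef(lm(log(cciv) ~ tt))[[2]]
  k10 <- p$Cl / p$Vc; k12 <- p$Q / p$Vc; k21 <- p$Q / p$Vp
  s <- k10 + k12 + k21
  beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  expect_equal(slope_iv, beta, tolerance = 1e-6)
})

test_that("mass balance accounts for every milligram", {
  p <- ref_params(F_po = 0.8)
  d <- data.frame(time = c(0, 100, 400), amount = c(5, 7, 13),
                  route = c("IV", "PO", "TD"))
  for (tend in c(500, 2000, 20000)) {
    mb <- mass_balance(p, d, tend)
    expect_equal(mb$input, mb$absorbed + mb$depot_remaining,
                 tolerance = 1e-9)
    expect_equal(mb$absorbed, mb$eliminated + mb$remaining,
                 tolerance = 1e-9)
    expect_equal(mb$input + mb$pending, 5 + 0.8 * 7 + p$F_top * 13,
                 tolerance = 1e-9)
  }
  # IV only: remaining + eliminated = dose at every t
  d_iv <- data.frame(time = 0, amount = 5, route = "IV")
  mb <- mass_balance(p, d_iv, 3000)
  expect_equal(mb$eliminated + mb$remaining, 5, tolerance = 1e-9)
})

test_that("transdermal lag defers depot entry", {
  p <- ref_params()
  d <- data.frame(time = 0, amount = 10, route = "TD")
  mb <- mass_balance(p, d, p$Lag / 2)  # before the lag has elapsed
  expect_equal(mb$absorbed, 0, tolerance = 1e-12)
  expect_equal(mb$remaining, 0, tolerance = 1e-12)
  expect_equal(mb$pending, p$F_top * 10, tolerance = 1e-12)
  expect_equal(solve_profile(p, d, c(5, 15, 25)), rep(0, 3))
})

test_that("elimination is complete after ten terminal half-lives", {
  set.seed(3)
  for (rep in 1:3) {
    p <- structural_params(
      Cl = exp(runif(1, -5, -4)), Vc = exp(runif(1, -0.3, 0.7)),
      Q = exp(runif(1, -6.5, -5.5)), Vp = exp(runif(1, -0.3, 0.7)),
      F_top = 0.1, k_top = 3e-4, Lag = 25, F_po = 0.9, k_po = 0.06)
    k10 <- p$Cl / p$Vc; k12 <- p$Q / p$Vc; k21 <- p$Q / p$Vp
    s <- k10 + k12 + k21
    beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
    thalf_max <- log(2) / min(beta, p$k_top, p$k_po)
    d <- data.frame(time = 0, amount = 10, route = sample(c("IV", "PO"), 1))
    f_eff <- if (d$route == "IV") 1 else p$F_po
    mb <- mass_balance(p, d, 10 * thalf_max)
    expect_gt(mb$eliminated / (f_eff * 10), 0.999)
  }
})

test_that("crossover carry-over at the washout interval is below the LLOQ", {
  p <- ref_slow_params()
  d <- data.frame(time = 0, amount = 3.3 * 4, route = "TD")
  washout <- 216 * 60 + 216 * 60   # end of TD sampling plus 9 days
  cc <- solve_profile(p, d, washout)
  expect_lt(cc, 0.002)
  # and even at the end of the TD sampling window itself
  expect_lt(solve_profile(p, d, 216 * 60), 0.002)
})

test_that("invalid inputs are rejected", {
  p <- ref_params()
  expect_error(solve_profile(p, data.frame(time = 0, amount = 5,
                                           route = "SC"), 0:10),
               "route")
  expect_error(solve_profile(p, data.frame(time = 0, amount = -1,
                                           route = "IV"), 0:10),
               "positive")
  expect_error(solve_profile(p, data.frame(time = 0, amount = 5,
                                           route = "IV"), c(5, 1)),
               "sorted")
  expect_error(structural_params(-1, 1, 1, 1, 0.5, 1, 0, 1, 1), "Cl")
  expect_error(structural_params(1, 1, 1, 1, 1.5, 1, 0, 1, 1), "F_top")
})
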