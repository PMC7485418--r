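test_that("terminal slope is exact on monoexponential data", {
  tt <- c(10, 20, 40, 80, 160, 320, 640, 1280)
  cc <- 10 * exp(-0.01 * tt)
  lz <- estimate_lambda_z(tt, cc, extravascular = FALSE)
  expect_true(lz$estimable)
  expect_equal(lz$lambda_z, 0.01, tolerance = 1e-10)
  expect_equal(lz$adj_r2, 1, tolerance = 1e-12)
})

test_that("too few post-peak points give a not-estimable flag", {
  lz <- estimate_lambda_z(c(0, 30, 60, 120), c(0.1, 10, 6, 3),
                          extravascular = TRUE)
  expect_false(lz$estimable)
  r <- nca_single_profile(data.frame(time = c(0, 30, 60, 120),
                                     conc = c(0.1, 10, 6, 3)),
                          dose = 5, route = "PO")
  expect_true(is.na(r$t_half))
  expect_false(is.na(r$Cmax))  # partial result keeps Cmax/tmax
  expect_equal(r$Cmax, 10000)
  expect_equal(r$tmax, 0.5)
})

test_that("linear trapezoid reproduces the hand-computed toy AUC", {
  r <- nca_single_profile(data.frame(time = c(0, 60, 120),
                                     conc = c(0, 10, 5)),
                          dose = 1, route = "PO",
                          config = nca_config(trapezoid = "linear"))
  expect_equal(r$AUC_last, 12.5, tolerance = 1e-12)
})

test_that("NCA closed forms hold on dense monoexponential profiles", {
  k <- 0.002; c0 <- 8; dose <- 16  # implies V = 2 L, Cl = V*k
  tt <- seq(1, 10 * log(2) / k, length.out = 4000)
  prof <- data.frame(time = tt, conc = c0 * exp(-k * tt))
  r <- nca_single_profile(prof, dose, "IV")
  expect_equal(r$AUC_inf, (c0 / k) / 60, tolerance = 1e-3)   # mg h/L
  expect_equal(r$MRT, (1 / k) / 60, tolerance = 2e-3)
  expect_equal(r$Cl, dose * k / c0 * 60, tolerance = 1e-3)   # L/h
  expect_equal(r$Vss, dose / c0, tolerance = 2e-3)
  expect_equal(r$C0, c0 * 1000, tolerance = 1e-6)
})

test_that("noise-free transdermal profile shows the published flip-flop half-life", {
  p <- ref_slow_params()
  des <- study_design()
  sched <- des$schedule_td2[-1]
  d <- data.frame(time = 0, amount = 3.3 * 4, route = "TD")
  prof <- data.frame(time = sched, conc = solve_profile(p, d, sched))
  r <- nca_single_profile(prof, 3.3 * 4, "TD")
  expect_equal(r$t_half, 38.89, tolerance = 0.05)
  expect_equal(r$t_half, log(2) / p$k_top / 60, tolerance = 0.02)
})

test_that("noise-free IV profile reproduces the published AUCinf/Dose", {
  p <- ref_slow_params()
  thalf <- 8.86 * 60   # slow-metabolizer terminal disposition half-life
  tt <- seq(1, 7 * thalf, by = 5)
  d <- data.frame(time = 0, amount = 2.2 * 4, route = "IV")
  prof <- data.frame(time = tt, conc = solve_profile(p, d, tt))
  r <- nca_single_profile(prof, 2.2 * 4, "IV")
  expect_equal(r$AUC_over_dose, 3.4, tolerance = 0.03)
  expect_equal(r$Vss, vss(p), tolerance = 0.01)
})

test_that("NCA clearance recovers the model clearance on dense IV data", {
  set.seed(9)
  for (rep in 1:3) {
    p <- structural_params(
      Cl = exp(runif(1, -5, -4)), Vc = exp(runif(1, -0.3, 0.7)),
      Q = exp(runif(1, -6.3, -5.3)), Vp = exp(runif(1, -0.3, 0.7)),
      F_top = 0.1, k_top = 3e-4, Lag = 25, F_po = 1, k_po = 0.06)
    k10 <- p$Cl / p$Vc; k12 <- p$Q / p$Vc; k21 <- p$Q / p$Vp
    s <- k10 + k12 + k21
    beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
    tt <- seq(1, 8 * log(2) / beta, length.out = 2500)
    d <- data.frame(time = 0, amount = 10, route = "IV")
    prof <- data.frame(time = tt, conc = solve_profile(p, d, tt))
    r <- nca_single_profile(prof, 10, "IV")
    expect_equal(r$Cl, p$Cl * 60, tolerance = 0.02)
  }
})

test_that("group summaries behave at the degenerate ends", {
  p <- ref_params()
  tt <- seq(30, 4000, by = 60)
  d <- data.frame(time = 0, amount = 5, route = "IV")
  r1 <- nca_single_profile(data.frame(time = tt,
                                      conc = solve_profile(p, d, tt)),
                           5, "IV")
  r1$subject_id <- "A"
  s1 <- nca_summarize(r1)
  expect_equal(s1$Cmax[s1$stat == "Mean"], s1$Cmax[s1$stat == "Median"])
  expect_equal(s1$Cmax[s1$stat == "SD"], 0)  # sd over a single profile
  rr <- rbind(r1, r1, r1)
  rr$subject_id <- c("A", "B", "C")
  s3 <- nca_summarize(rr)
  for (m in c("Cmax", "t_half", "AUC_inf", "MRT"))
    expect_equal(s3[[m]][s3$stat == "SD"], 0, tolerance = 1e-12)
  expect_error(nca_summarize(r1[0, ]), "summarize")
})

test_that("adding a later positive sample never decreases AUC_last", {
  set.seed(21)
  p <- ref_params()
  d <- data.frame(time = 0, amount = 8, route = "PO")
  tt <- sort(runif(12, 10, 3000))
  cc <- solve_profile(p, d, tt)
  auc <- numeric(0)
  for (k in 3:12) {
    r <- nca_single_profile(data.frame(time = tt[1:k], conc = cc[1:k]),
                            8, "PO")
    auc <- c(auc, r$AUC_last)
  }
  expect_true(all(diff(auc) >= -1e-12))
})

test_that("truncated TD sampling inflates the extrapolated AUC fraction", {
  p <- ref_slow_params()
  des <- study_design()
  d <- data.frame(time = 0, amount = 13.2, route = "TD")
  s72 <- des$schedule_phase1[-1]           # through 72 h
  s216 <- des$schedule_td2[-1]             # through 216 h
  r72 <- nca_single_profile(
    data.frame(time = s72, conc = solve_profile(p, d, s72)), 13.2, "TD")
  r216 <- nca_single_profile(
    data.frame(time = s216, conc = solve_profile(p, d, s216)), 13.2, "TD")
  expect_gt(r72$AUC_extrap_pct, 30)
  expect_lt(r216$AUC_extrap_pct, 20)
  expect_gt(r72$AUC_extrap_pct, r216$AUC_extrap_pct)
})
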