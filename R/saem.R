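#' SAEM algorithm settings
#'
#' Controls the stochastic approximation EM schedule and the MCMC kernels
#' used to sample individual parameters. Defaults follow common published
#' SAEM practice: an exploratory phase with step size 1 followed by a
#' smoothing phase with step size \code{1/(k - K1)^0.7}, one chain, an
#' independence (prior) proposal plus componentwise random-walk passes
#' with acceptance-rate adaptation during exploration, and simulated
#' annealing on the variance parameters during exploration.
#'
#' @param n_explore exploratory-phase iterations (step size 1)
#' @param n_smooth smoothing-phase iterations (decreasing step)
#' @param n_rw_passes componentwise random-walk passes per iteration
#' @param n_cond_iter MCMC iterations used after estimation to sample the
#'   conditional distributions (standard errors, log-likelihood,
#'   diagnostics)
#' @param n_is_draws importance-sampling draws per subject for the
#'   log-likelihood estimate
#' @param estimate_beta estimate the slow-metabolizer effect on
#'   log-clearance (requires MET in the dataset covariates)
#' @param fix_fpo pin oral bioavailability to 1 (final-model convention)
#'   instead of estimating it freely through the logit link
#' @param fpo_var fixed random-effect variance for the oral
#'   bioavailability when it is estimated freely (its IIV is not
#'   identifiable from parallel-group data, so it is pinned small rather
#'   than estimated); \code{NULL} estimates it
#' @param random names of parameters carrying random effects (and hence
#'   estimated typical values); parameters not listed are frozen at their
#'   initial values
#' @param corr_block names of parameters whose random-effect correlations
#'   are estimated freely; \code{NULL} for a diagonal covariance
#' @param annealing exploratory-phase lower bound factor on variance
#'   shrinkage per iteration (simulated annealing); 0 disables
#' @param error_floor_frac the proportional-error SD is
#'   \code{b * max(F, error_floor_frac * LLOQ)}; keeps the censored
#'   likelihood finite when predictions approach zero
#' @param rw_init initial componentwise random-walk standard deviation
#' @return list of class \code{saem_settings}
#' @export
saem_settings <- function(n_explore = 300, n_smooth = 150, n_rw_passes = 2,
                          n_cond_iter = 150, n_is_draws = 500,
                          estimate_beta = TRUE, fix_fpo = FALSE,
                          fpo_var = 0.01,
                          random = .psi_names,
                          corr_block = .corr_block,
                          annealing = 0.95, error_floor_frac = 0.5,
                          rw_init = 0.4) {
  stopifnot(n_explore >= 1, n_smooth >= 1, n_rw_passes >= 1,
            all(random %in% .psi_names),
            is.null(corr_block) || all(corr_block %in% random))
  structure(list(n_explore = n_explore, n_smooth = n_smooth,
                 n_rw_passes = n_rw_passes, n_cond_iter = n_cond_iter,
                 n_is_draws = n_is_draws, estimate_beta = estimate_beta,
                 fix_fpo = fix_fpo, fpo_var = fpo_var,
                 random = random, corr_block = corr_block,
                 annealing = annealing, error_floor_frac = error_floor_frac,
                 rw_init = rw_init),
            class = "saem_settings")
}

## numerically stable log(sum(exp(x)))
.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## Per-subject data bundles used by the estimation machinery. Excluded
## rows are dropped here and never seen again.
.prepare_subjects <- function(dataset) {
  ids <- unique(dataset$covariates$subject_id)
  subs <- list()
  for (id in ids) {
    oo <- .subject_obs(dataset, id)
    if (nrow(oo) == 0L) next
    dd <- .subject_doses(dataset, id)
    cv <- dataset$covariates[dataset$covariates$subject_id == id, ]
    subs[[length(subs) + 1L]] <- list(
      id = id, doses = dd, t_obs = oo$time, y = oo$conc,
      cens = oo$censored, MET = cv$MET[1], bw = cv$bodyweight[1],
      sex = cv$sex[1])
  }
  subs
}

## M3 log-likelihood of one subject given structural parameters.
## Quantified points contribute a Gaussian density with SD b*g,
## g = max(F, floor); censored points contribute log Phi((LLOQ - F)/(b*g)).
.subject_loglik <- function(params, sub, b, lloq, floor) {
  f <- solve_profile(params, sub$doses, sub$t_obs)
  g <- pmax(f, floor)
  sd <- b * g
  ll <- 0
  if (any(!sub$cens))
    ll <- sum(stats::dnorm(sub$y[!sub$cens], f[!sub$cens], sd[!sub$cens],
                           log = TRUE))
  if (any(sub$cens))
    ll <- ll + sum(stats::pnorm(lloq, f[sub$cens], sd[sub$cens],
                                log.p = TRUE))
  ll
}

#' M3 censored log-likelihood of one subject
#'
#' Sum over observations of the Gaussian log-density (quantified points)
#' and the log normal-CDF mass below the LLOQ (censored points), under the
#' proportional error model with SD \code{b * max(F, floor)}.
#'
#' @param params a \code{\link{structural_params}}
#' @param doses subject dose table (columns \code{time}, \code{amount},
#'   \code{route})
#' @param observations subject observation table (columns \code{time},
#'   \code{conc}, \code{censored})
#' @param b proportional residual-error scale
#' @param lloq lower limit of quantification (mg/L)
#' @param error_floor_frac SD floor as a fraction of the LLOQ
#' @return scalar log-likelihood
#' @export
individual_loglik_m3 <- function(params, doses, observations, b, lloq,
                                 error_floor_frac = 0.5) {
  if (nrow(observations) == 0L) stop("subject has no observations")
  sub <- list(doses = doses, t_obs = observations$time,
              y = observations$conc, cens = observations$censored)
  .subject_loglik(params, sub, b, lloq, error_floor_frac * lloq)
}

#' Initial population values from noncompartmental analysis
#'
#' Seeds the typical values of the mixed-effects fit from the NCA output:
#' clearance and steady-state volume from the IV profiles (volume split
#' evenly between compartments), the transdermal absorption rate from the
#' TD terminal slope (flip-flop), transdermal bioavailability from the
#' ratio of dose-normalized AUCs, and the oral absorption rate from the
#' oral tmax. Random-effect SDs start at 0.3, correlations at 0, the
#' error scale at 0.3. Routes absent from the dataset fall back to
#' mild generic values.
#'
#' @param dataset a \code{\link{pk_dataset}}
#' @return a \code{\link{population_model}} suitable as \code{init} for
#'   \code{\link{fit_saem}}
#' @export
init_from_nca <- function(dataset) {
  res <- nca_dataset(dataset)
  med <- function(route, col, fallback) {
    x <- res[[col]][res$route == route]
    x <- x[is.finite(x)]
    if (length(x)) stats::median(x) else fallback
  }
  cl_h <- med("IV", "Cl", 0.6)                   # L/h
  vss_iv <- med("IV", "Vss", 2.5)                # L
  aucd_iv <- med("IV", "AUC_over_dose", 1 / cl_h)
  aucd_td <- med("TD", "AUC_over_dose", 0.05 * aucd_iv)
  lzn_td <- med("TD", "lambda_z", 0.018)         # 1/h
  tmax_po <- med("PO", "tmax", 1)                # h
  ftop <- min(max(aucd_td / aucd_iv, 1e-3), 0.5)
  population_model(
    mu = c(Cl = cl_h / 60, Vc = vss_iv / 2, Q = cl_h / 120, Vp = vss_iv / 2,
           ktop = lzn_td / 60, Lag = 30, kpo = min(3 / (tmax_po * 60), 0.5)),
    xi_Ftop = ftop, F_po = 0.9, beta_Cl_MET = 0,
    omega = stats::setNames(rep(0.3, length(.psi_names)), .psi_names),
    corr = NULL, b = 0.3, fpo_fixed = FALSE)
}

## Clamp logit-scale typical values to the numerical guard range.
.clamp_logit_means <- function(cmu) {
  for (nm in .logit_links)
    cmu[nm] <- min(max(cmu[nm], -.logit_cap), .logit_cap)
  cmu
}

## Structured covariance update: keep the free-correlation block, zero the
## rest of the off-diagonal, floor variances, and project the block to PSD.
.structure_omega <- function(O, random, corr_block, var_floor = 1e-4) {
  keep <- matrix(FALSE, nrow(O), ncol(O), dimnames = dimnames(O))
  diag(keep) <- TRUE
  if (length(corr_block) > 1)
    keep[corr_block, corr_block] <- TRUE
  O[!keep] <- 0
  diag(O) <- pmax(diag(O), var_floor)
  if (length(corr_block) > 1) {
    ## keep the free-correlation block safely positive definite: floor the
    ## eigenvalues of its correlation form so correlations cannot lock at
    ## +/-1 and blow up the precision matrix
    blk <- O[corr_block, corr_block]
    d <- sqrt(diag(blk))
    R <- blk / outer(d, d)
    eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
    ev <- pmax(eg$values, 1e-2)
    R <- eg$vectors %*% (ev * t(eg$vectors))
    dr <- sqrt(diag(R))
    R <- R / outer(dr, dr)
    O[corr_block, corr_block] <- R * outer(d, d)
  }
  O
}

#' Fit the population model by SAEM with M3 censored likelihood
#'
#' Stochastic approximation EM: each iteration samples the individual
#' Gaussian-scale parameters by Metropolis-Hastings (an independence
#' proposal from the current population distribution plus componentwise
#' random walks), imputes the censored observations from their truncated
#' conditional distribution, updates the sufficient statistics with the
#' stochastic-approximation step, and solves the exact M-step (generalized
#' least squares for the typical values and covariate effect, moment
#' update for the structured covariance, closed-form update for the
#' proportional error scale). After the parameter search, conditional
#' MCMC at the final estimates provides the per-subject posterior draws
#' used for standard errors (outer product of conditional expected
#' complete-data scores), the importance-sampling log-likelihood (t
#' proposal, 5 df), and diagnostics.
#'
#' @param dataset a \code{\link{pk_dataset}}
#' @param init initial \code{\link{population_model}}; default
#'   \code{\link{init_from_nca}(dataset)}
#' @param settings a \code{\link{saem_settings}}
#' @param seed integer seed; identical seeds reproduce the fit exactly
#' @return object of class \code{saem_fit}: \code{model} (the estimated
#'   \code{population_model}), \code{par_table} (estimate / SE / RSE\% /
#'   CV\% per reported parameter), \code{corr_table}, \code{loglik},
#'   \code{n_params}, \code{BIC}, \code{trace} (per-iteration fixed
#'   effects), \code{draws} (conditional psi draws, n_iter x n_subject x
#'   n_random array), and bookkeeping fields
#' @export
fit_saem <- function(dataset, init = NULL, settings = saem_settings(),
                     seed = 1L) {
  set.seed(seed)
  if (is.null(init)) init <- init_from_nca(dataset)
  subs <- .prepare_subjects(dataset)
  N <- length(subs)
  if (N < 2) stop("need at least 2 subjects with observations")
  lloq <- dataset$lloq
  floor_ <- settings$error_floor_frac * lloq
  est_beta <- settings$estimate_beta
  if (est_beta) {
    mets <- vapply(subs, `[[`, numeric(1), "MET")
    if (any(is.na(mets)))
      stop("estimate_beta = TRUE requires MET for every subject; ",
           "run classify_metabolizers() first or disable the covariate")
  }
  act <- settings$random                    # active (random) components
  if (settings$fix_fpo) act <- setdiff(act, "Fpo")  # pinned: no latent dim
  if (est_beta && !"Cl" %in% act)
    stop("estimate_beta requires 'Cl' among the random parameters")
  nact <- length(act)
  blk <- intersect(settings$corr_block, act)
  fixed_psi <- .clamp_logit_means(.psi_typical(init, MET = 0))

  ## state: current estimates
  cmu <- fixed_psi                          # Gaussian-scale typical values
  beta <- if (est_beta) init$beta_Cl_MET else 0
  Ofull <- omega_matrix(init)
  O <- .structure_omega(Ofull[act, act, drop = FALSE], act, blk)
  b <- init$b
  if (settings$fix_fpo) cmu["Fpo"] <- .logit_cap  # F_po pinned to ~1

  MET <- vapply(subs, function(s) ifelse(is.na(s$MET), 0, s$MET), numeric(1))
  e_cl <- as.numeric(act == "Cl")

  psi_full <- function(psi_act, met) {
    p <- cmu
    p["Cl"] <- p["Cl"] + beta * met
    p[act] <- psi_act
    p
  }
  lik_of <- function(psi_act, i) {
    p <- psi_full(psi_act, MET[i])
    pars <- .psi_to_params(p, settings$fix_fpo, 1)
    .subject_loglik(pars, subs[[i]], b, lloq, floor_)
  }
  mean_i <- function(i) cmu[act] + beta * MET[i] * e_cl

  ## initial latent values and caches
  PSI <- do.call(rbind, lapply(seq_len(N), mean_i))
  colnames(PSI) <- act
  cur_ll <- vapply(seq_len(N), function(i) lik_of(PSI[i, ], i), numeric(1))
  s1 <- PSI
  S2 <- array(0, c(nact, nact, N))
  for (i in seq_len(N)) S2[, , i] <- tcrossprod(PSI[i, ])
  n_obs_tot <- sum(vapply(subs, function(s) length(s$y), numeric(1)))
  stat_res <- n_obs_tot * b^2
  ## per-subject, per-component random-walk scales (posterior widths vary
  ## by orders of magnitude between routes), adapted during exploration
  rw <- matrix(settings$rw_init, N, nact)
  K1 <- settings$n_explore
  n_iter <- K1 + settings$n_smooth
  trace <- vector("list", n_iter)

  impute_cens <- function(i, psi_act) {
    s <- subs[[i]]
    p <- psi_full(psi_act, MET[i])
    pars <- .psi_to_params(p, settings$fix_fpo, 1)
    f <- solve_profile(pars, s$doses, s$t_obs)
    g <- pmax(f, floor_)
    sd <- b * g
    y <- s$y
    if (any(s$cens)) {
      fl <- f[s$cens]; sl <- sd[s$cens]
      plo <- stats::pnorm(0, fl, sl)
      phi <- stats::pnorm(lloq, fl, sl)
      u <- plo + stats::runif(sum(s$cens)) * pmax(phi - plo, 1e-300)
      yc <- stats::qnorm(pmin(pmax(u, 1e-300), 1 - 1e-16), fl, sl)
      y[s$cens] <- pmin(pmax(yc, 0), lloq)
    }
    sum(((y - f) / g)^2)
  }

  mcmc_sweep <- function(adapt) {
    chO <- tryCatch(chol(O), error = function(e) chol(O + diag(1e-8, nact)))
    W <- chol2inv(chO)
    for (i in seq_len(N)) {
      mi <- mean_i(i)
      ## independence (prior) proposal
      prop <- mi + drop(crossprod(chO, stats::rnorm(nact)))
      llp <- lik_of(prop, i)
      if (is.finite(llp) && log(stats::runif(1)) < llp - cur_ll[i]) {
        PSI[i, ] <<- prop; cur_ll[i] <<- llp
      }
      ## componentwise random walks
      for (pass in seq_len(settings$n_rw_passes)) {
        for (j in seq_len(nact)) {
          prop <- PSI[i, ]
          prop[j] <- prop[j] + rw[i, j] * stats::rnorm(1)
          d1 <- PSI[i, ] - mi; d2 <- prop - mi
          dprior <- -0.5 * (sum(d2 * (W %*% d2)) - sum(d1 * (W %*% d1)))
          llp <- lik_of(prop, i)
          acc <- is.finite(llp) &&
            log(stats::runif(1)) < llp - cur_ll[i] + dprior
          if (acc) { PSI[i, ] <<- prop; cur_ll[i] <<- llp }
          if (adapt)
            rw[i, j] <<- min(max(rw[i, j] * exp(0.3 * (acc - 0.35)),
                                 1e-3), 5)
        }
      }
    }
    invisible(NULL)
  }

  for (k in seq_len(n_iter)) {
    gamma <- if (k <= K1) 1 else 1 / (k - K1)^0.7
    mcmc_sweep(adapt = k <= K1)
    ## censored-data residual statistic at the current draws
    res_now <- sum(vapply(seq_len(N), function(i) impute_cens(i, PSI[i, ]),
                          numeric(1)))
    ## stochastic-approximation updates
    s1 <- s1 + gamma * (PSI - s1)
    for (i in seq_len(N))
      S2[, , i] <- S2[, , i] + gamma * (tcrossprod(PSI[i, ]) - S2[, , i])
    stat_res <- stat_res + gamma * (res_now - stat_res)

    ## ----- M-step -----
    chO <- tryCatch(chol(O), error = function(e) chol(O + diag(1e-8, nact)))
    W <- chol2inv(chO)
    if (est_beta) {
      A <- matrix(0, nact + 1, nact + 1)
      rhs <- numeric(nact + 1)
      We <- W %*% e_cl
      for (g in unique(MET)) {
        gi <- which(MET == g); ng <- length(gi)
        sbar <- colMeans(s1[gi, , drop = FALSE])
        A[1:nact, 1:nact] <- A[1:nact, 1:nact] + ng * W
        A[1:nact, nact + 1] <- A[1:nact, nact + 1] + ng * g * We
        A[nact + 1, 1:nact] <- A[nact + 1, 1:nact] + ng * g * t(We)
        A[nact + 1, nact + 1] <- A[nact + 1, nact + 1] +
          ng * g^2 * sum(e_cl * We)
        rhs[1:nact] <- rhs[1:nact] + ng * (W %*% sbar)
        rhs[nact + 1] <- rhs[nact + 1] + ng * g * sum(We * sbar)
      }
      sol <- solve(A, rhs)
      cmu[act] <- sol[1:nact]
      beta <- sol[nact + 1]
    } else {
      cmu[act] <- colMeans(s1)
    }
    cmu <- .clamp_logit_means(cmu)
    if (settings$fix_fpo) cmu["Fpo"] <- .logit_cap
    Onew <- matrix(0, nact, nact, dimnames = list(act, act))
    for (i in seq_len(N)) {
      mi <- mean_i(i)
      Onew <- Onew + S2[, , i] - tcrossprod(s1[i, ], mi) -
        tcrossprod(mi, s1[i, ]) + tcrossprod(mi)
    }
    Onew <- Onew / N
    Onew <- .structure_omega(Onew, act, blk)
    if ("Fpo" %in% act && !is.null(settings$fpo_var))
      Onew["Fpo", "Fpo"] <- settings$fpo_var
    b_new <- sqrt(stat_res / n_obs_tot)
    if (settings$annealing > 0 && k <= K1) {
      diag(Onew) <- pmax(diag(Onew), settings$annealing * diag(O))
      b_new <- max(b_new, sqrt(settings$annealing) * b)
    }
    O <- Onew
    b <- b_new
    ## refresh cached likelihoods under the new b
    cur_ll <- vapply(seq_len(N), function(i) lik_of(PSI[i, ], i), numeric(1))

    trace[[k]] <- c(iter = k,
                    stats::setNames(cmu[act], paste0("c_", act)),
                    beta = beta, b = b,
                    stats::setNames(sqrt(diag(O)), paste0("omega_", act)))
  }
  trace <- as.data.frame(do.call(rbind, trace))

  ## ----- conditional draws at the final estimates -----
  n_cond <- settings$n_cond_iter
  draws <- array(NA_real_, c(n_cond, N, nact),
                 dimnames = list(NULL, vapply(subs, `[[`, "", "id"), act))
  chO <- tryCatch(chol(O), error = function(e) chol(O + diag(1e-8, nact)))
  W <- chol2inv(chO)
  scb1 <- numeric(N); scb2 <- numeric(N)     # split-half scores for b
  for (it in seq_len(n_cond)) {
    mcmc_sweep(adapt = FALSE)
    draws[it, , ] <- PSI
    for (i in seq_len(N)) {
      ## conditional expected score w.r.t. b (Fisher identity)
      p <- psi_full(PSI[i, ], MET[i])
      pars <- .psi_to_params(p, settings$fix_fpo, 1)
      s <- subs[[i]]
      f <- solve_profile(pars, s$doses, s$t_obs)
      g <- pmax(f, floor_)
      scb <- 0
      if (any(!s$cens)) {
        r <- (s$y[!s$cens] - f[!s$cens]) / g[!s$cens]
        scb <- scb + sum(-1 / b + r^2 / b^3)
      }
      if (any(s$cens)) {
        z <- (lloq - f[s$cens]) / (b * g[s$cens])
        lr <- exp(stats::dnorm(z, log = TRUE) -
                    stats::pnorm(z, log.p = TRUE))
        scb <- scb + sum(-lr * z / b)
      }
      if (it %% 2 == 0) scb1[i] <- scb1[i] + scb
      else scb2[i] <- scb2[i] + scb
    }
  }
  scb1 <- scb1 / (n_cond %/% 2)
  scb2 <- scb2 / (n_cond - n_cond %/% 2)
  ## SE(b): outer product of per-subject conditional scores; the two MCMC
  ## half-estimates enter as a cross-product so the Monte-Carlo noise does
  ## not inflate the information
  info_b <- max(sum(scb1 * scb2) - sum((scb1 + scb2) / 2)^2 / N, 1e-12)
  se_b <- 1 / sqrt(info_b)

  ## SEs of the mean parameters (c, beta) by the GLS sandwich:
  ## the conditional means psi-hat have marginal covariance
  ## Omega - V_i (V_i = conditional covariance, estimated from the draws),
  ## and the M-step estimator is weighted least squares with weight W,
  ## so Var(theta) = A^-1 B A^-1 with A = sum X'WX,
  ## B = sum X'W (Omega - V_i) W X.
  npm <- nact + est_beta
  A <- matrix(0, npm, npm); B <- matrix(0, npm, npm)
  for (i in seq_len(N)) {
    Xi <- diag(nact)
    if (est_beta) Xi <- cbind(Xi, MET[i] * e_cl)
    Vi <- stats::cov(matrix(draws[, i, ], ncol = nact))
    S <- O - Vi
    eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
    S <- eg$vectors %*% (pmax(eg$values, 1e-10) * t(eg$vectors))
    WX <- W %*% Xi
    A <- A + crossprod(Xi, WX)
    B <- B + t(WX) %*% S %*% WX
  }
  covth <- tryCatch({
    Ainv <- solve(A)
    Ainv %*% B %*% Ainv
  }, error = function(e) matrix(NA_real_, npm, npm))
  se_fix <- c(sqrt(pmax(diag(covth), 0)), se_b)
  names(se_fix) <- c(paste0("c_", act), if (est_beta) "beta", "b")

  ## ----- importance-sampling log-likelihood -----
  ## Defensive mixture proposal: half multivariate t (5 df) centred on the
  ## conditional draws, half the population prior. The prior component
  ## bounds the weights in the weakly informed directions (where the
  ## conditional distribution is the prior itself), which a pure
  ## conditional-moment proposal undercovers.
  loglik <- 0
  M <- settings$n_is_draws
  ldet_O <- sum(log(diag(chO)))
  for (i in seq_len(N)) {
    D <- draws[, i, , drop = TRUE]
    if (nact == 1) D <- matrix(D, ncol = 1)
    mi <- mean_i(i)
    ## Laplace fit of the conditional: mode and curvature of
    ## prior x likelihood give a proposal whose weakly informed
    ## directions inherit the prior's spread
    negpost <- function(psi) {
      if (any(!is.finite(psi)) || max(abs(psi)) > 40) return(1e10)
      d <- psi - mi
      ll <- tryCatch(lik_of(psi, i), error = function(e) -Inf)
      if (!is.finite(ll)) return(1e10)
      0.5 * sum(d * (W %*% d)) - ll
    }
    opt <- stats::optim(colMeans(D), negpost, method = "BFGS",
                        control = list(maxit = 100), hessian = TRUE)
    H <- (opt$hessian + t(opt$hessian)) / 2
    eh <- eigen(H, symmetric = TRUE)
    Vhat <- eh$vectors %*% ((1 / pmax(eh$values, 1e-6)) * t(eh$vectors))
    mhat <- opt$par
    chV <- chol(Vhat * 1.2^2 + diag(1e-10, nact))
    Wv <- chol2inv(chV)
    ldet_V <- sum(log(diag(chV)))
    lw <- numeric(M)
    use_t <- stats::runif(M) < 0.5
    for (m in seq_len(M)) {
      if (use_t[m]) {
        z <- stats::rt(nact, df = 5)
        psi <- mhat + drop(crossprod(chV, z))
      } else {
        psi <- mi + drop(crossprod(chO, stats::rnorm(nact)))
      }
      dv <- psi - mhat
      qv <- sum(dv * (Wv %*% dv))
      ## multivariate-t density (5 df) with scale matrix Vhat
      lt <- lgamma((5 + nact) / 2) - lgamma(5 / 2) -
        nact / 2 * log(5 * pi) - ldet_V -
        (5 + nact) / 2 * log1p(qv / 5)
      d <- psi - mi
      lprior <- -0.5 * sum(d * (W %*% d)) - ldet_O -
        nact / 2 * log(2 * pi)
      lprop <- .logsumexp(c(lt, lprior)) - log(2)
      lw[m] <- lprior + lik_of(psi, i) - lprop
    }
    mx <- max(lw)
    loglik <- loglik + mx + log(mean(exp(lw - mx)))
  }

  ## ----- assemble result -----
  n_params <- nact + est_beta + 1 + nact +
    if (length(blk) > 1) choose(length(blk), 2) else 0
  if ("Fpo" %in% act && !is.null(settings$fpo_var))
    n_params <- n_params - 1              # pinned Fpo variance not free
  BIC <- -2 * loglik + n_params * log(N)

  omega_out <- stats::setNames(rep(0, length(.psi_names)), .psi_names)
  omega_out[act] <- sqrt(diag(O))
  if (settings$fix_fpo) omega_out["Fpo"] <- 0.1
  corr_out <- diag(length(.corr_block))
  dimnames(corr_out) <- list(.corr_block, .corr_block)
  if (length(blk) > 1) {
    sdb <- sqrt(diag(O)[blk])
    corr_out[blk, blk] <- O[blk, blk] / outer(sdb, sdb)
  }
  model <- population_model(
    mu = stats::setNames(exp(cmu[c("Cl", "Vc", "Q", "Vp", "ktop", "Lag",
                                   "kpo")]),
                         c("Cl", "Vc", "Q", "Vp", "ktop", "Lag", "kpo")),
    xi_Ftop = stats::plogis(cmu[["Ftop"]]),
    F_po = if (settings$fix_fpo) 1 else stats::plogis(cmu[["Fpo"]]),
    beta_Cl_MET = beta,
    omega = omega_out, corr = corr_out, b = b,
    fpo_fixed = settings$fix_fpo)

  par_table <- .build_par_table(model, cmu, beta, b, se_fix, act, est_beta,
                                settings$fix_fpo)
  corr_table <- NULL
  if (length(blk) > 1) {
    prs <- t(utils::combn(blk, 2))
    corr_table <- data.frame(pair = paste0("corr(", prs[, 1], ",",
                                           prs[, 2], ")"),
                             estimate = corr_out[prs],
                             stringsAsFactors = FALSE)
  }
  structure(list(model = model, par_table = par_table,
                 corr_table = corr_table,
                 loglik = loglik, n_params = n_params, BIC = BIC,
                 trace = trace, draws = draws, se_fix = se_fix,
                 settings = settings, subjects = subs, MET = MET,
                 lloq = lloq, seed = seed, active = act),
            class = "saem_fit")
}

## Estimate / SE / RSE% / CV% table on the reporting scale.
.build_par_table <- function(model, cmu, beta, b, se_fix, act, est_beta,
                             fix_fpo) {
  getse <- function(nm) {
    v <- se_fix[paste0("c_", nm)]
    if (nm %in% act && is.finite(v)) unname(v) else NA_real_
  }
  rows <- list()
  addrow <- function(name, est, se, cv) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, estimate = est, se = se,
      rse_pct = ifelse(is.finite(se) & est != 0, 100 * se / abs(est),
                       NA_real_),
      cv_pct = cv, stringsAsFactors = FALSE)
  }
  cv_ln <- function(nm) if (nm %in% act) .cv_from_omega(model$omega[[nm]])
           else NA_real_
  ## log-normal parameters: natural-scale SE by the delta method
  for (nm in c("Cl", "Vc", "Q", "Vp", "ktop", "Lag", "kpo")) {
    est <- model$mu[[nm]]
    addrow(nm, est, est * getse(nm), cv_ln(nm))
  }
  if (est_beta) {
    se_b <- se_fix["beta"]
    addrow("beta_Cl_MET", beta, unname(se_b), NA_real_)
  }
  ## logit-linked bioavailabilities: reported in percent
  xi <- model$xi_Ftop
  cv_ftop <- if ("Ftop" %in% act) {
    z <- stats::qlogis(xi) + model$omega[["Ftop"]] * stats::qnorm(
      seq(0.0005, 0.9995, length.out = 2001))
    fs <- stats::plogis(z)
    100 * stats::sd(fs) / mean(fs)
  } else NA_real_
  addrow("F_top_pct", 100 * xi, 100 * xi * (1 - xi) * getse("Ftop"), cv_ftop)
  addrow("F_po_pct", 100 * model$F_po,
         if (fix_fpo) NA_real_ else
           100 * model$F_po * (1 - model$F_po) * getse("Fpo"),
         if ("Fpo" %in% act && !fix_fpo) .cv_from_omega(model$omega[["Fpo"]])
         else NA_real_)
  addrow("b", b, unname(se_fix["b"]), NA_real_)
  do.call(rbind, rows)
}

#' @export
print.saem_fit <- function(x, ...) {
  cat("SAEM population fit:", length(x$subjects), "subjects, loglik",
      format(x$loglik, digits = 6), ", BIC", format(x$BIC, digits = 6),
      "(", x$n_params, "parameters )\n")
  print(x$par_table, digits = 4)
  if (!is.null(x$corr_table)) print(x$corr_table, digits = 3)
  invisible(x)
}

#' Sample the conditional distribution of individual parameters
#'
#' Runs Metropolis-Hastings at fixed population parameters and returns
#' per-subject posterior draws of the Gaussian-scale individual
#' parameters. Used for diagnostics and covariate/correlation screens in
#' place of point empirical-Bayes estimates (shrinkage mitigation). For a
#' \code{saem_fit} the draws collected at the final estimates are
#' returned directly unless \code{refresh = TRUE}.
#'
#' @param fit a \code{saem_fit}, or a \code{\link{population_model}}
#'   (with \code{dataset} supplied) to sample under known parameters
#' @param dataset a \code{\link{pk_dataset}}; required when \code{fit} is
#'   a \code{population_model}
#' @param n_iter MCMC iterations (draws kept every iteration)
#' @param n_burn burn-in iterations discarded
#' @param use_met use the dataset MET covariate in the mean structure
#' @param seed integer seed
#' @return list with \code{draws} (iterations x subjects x parameters
#'   array of psi draws), \code{eta} (same shape, centred at the
#'   population mean so entries are random effects), \code{subjects},
#'   \code{MET}
#' @export
sample_conditional <- function(fit, dataset = NULL, n_iter = 100,
                               n_burn = 20, use_met = TRUE, seed = 1L) {
  if (inherits(fit, "saem_fit")) {
    draws <- fit$draws
    act <- fit$active
    subs <- fit$subjects
    MET <- fit$MET
    model <- fit$model
    eta <- draws
    for (i in seq_along(subs)) {
      mi <- .psi_typical(model, 0)[act]
      mi["Cl"] <- mi["Cl"] + model$beta_Cl_MET * MET[i] * ("Cl" %in% act)
      eta[, i, ] <- sweep(draws[, i, , drop = FALSE], 3, mi)
    }
    return(list(draws = draws, eta = eta, subjects = subs, MET = MET,
                active = act))
  }
  stopifnot(inherits(fit, "population_model"), !is.null(dataset))
  set.seed(seed)
  model <- fit
  subs <- .prepare_subjects(dataset)
  N <- length(subs)
  act <- .psi_names
  nact <- length(act)
  lloq <- dataset$lloq
  floor_ <- 0.5 * lloq
  MET <- vapply(subs, function(s) {
    m <- if (use_met) s$MET else 0
    ifelse(is.na(m), 0, m)
  }, numeric(1))
  O <- omega_matrix(model)
  O <- O + diag(1e-8, nact)
  chO <- chol(O)
  W <- chol2inv(chO)
  mean_i <- function(i) {
    m <- .psi_typical(model, MET[i])
    m[act]
  }
  lik_of <- function(psi, i) {
    pars <- .psi_to_params(stats::setNames(psi, act), model$fpo_fixed,
                           model$F_po)
    .subject_loglik(pars, subs[[i]], model$b, lloq, floor_)
  }
  PSI <- do.call(rbind, lapply(seq_len(N), mean_i))
  cur_ll <- vapply(seq_len(N), function(i) lik_of(PSI[i, ], i), numeric(1))
  ## per-subject, per-component random-walk scales, adapted during burn-in
  ## (posterior width varies by orders of magnitude between subjects)
  rw <- matrix(0.4, N, nact)
  total <- n_burn + n_iter
  draws <- array(NA_real_, c(n_iter, N, nact),
                 dimnames = list(NULL, vapply(subs, `[[`, "", "id"), act))
  for (it in seq_len(total)) {
    for (i in seq_len(N)) {
      mi <- mean_i(i)
      prop <- mi + drop(crossprod(chO, stats::rnorm(nact)))
      llp <- lik_of(prop, i)
      if (is.finite(llp) && log(stats::runif(1)) < llp - cur_ll[i]) {
        PSI[i, ] <- prop; cur_ll[i] <- llp
      }
      for (j in seq_len(nact)) {
        prop <- PSI[i, ]
        prop[j] <- prop[j] + rw[i, j] * stats::rnorm(1)
        d1 <- PSI[i, ] - mi; d2 <- prop - mi
        dprior <- -0.5 * (sum(d2 * (W %*% d2)) - sum(d1 * (W %*% d1)))
        llp <- lik_of(prop, i)
        acc <- is.finite(llp) &&
          log(stats::runif(1)) < llp - cur_ll[i] + dprior
        if (acc) { PSI[i, ] <- prop; cur_ll[i] <- llp }
        if (it <= n_burn)
          rw[i, j] <- min(max(rw[i, j] * exp(0.3 * (acc - 0.35)),
                              1e-3), 5)
      }
    }
    if (it > n_burn) draws[it - n_burn, , ] <- PSI
  }
  eta <- draws
  for (i in seq_len(N)) eta[, i, ] <- sweep(draws[, i, , drop = FALSE], 3,
                                            mean_i(i))
  list(draws = draws, eta = eta, subjects = subs, MET = MET, active = act)
}
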