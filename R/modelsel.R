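#' Two-stage final-model fit
#'
#' The package's model-building recipe for the full study: an exploratory
#' SAEM fit with oral bioavailability estimated freely through the logit
#' link; if that estimate exceeds 0.99 the final fit pins F_po to 1 with a
#' small bookkeeping IIV variance (0.01), otherwise the exploratory fit is
#' the final one.
#'
#' @param dataset a \code{\link{pk_dataset}}
#' @param init initial \code{\link{population_model}}; default from NCA
#' @param settings a \code{\link{saem_settings}} (the \code{fix_fpo} and
#'   \code{fpo_var} fields are managed by this wrapper)
#' @param seed integer seed
#' @return the final \code{saem_fit}, with the exploratory fit attached as
#'   attribute \code{"exploratory"} when a refit happened
#' @export
fit_final_model <- function(dataset, init = NULL,
                            settings = saem_settings(), seed = 1L) {
  settings$fix_fpo <- FALSE
  settings$fpo_var <- NULL
  fit1 <- fit_saem(dataset, init = init, settings = settings, seed = seed)
  if (fit1$model$F_po > 0.99) {
    settings$fix_fpo <- TRUE
    fit2 <- fit_saem(dataset, init = fit1$model, settings = settings,
                     seed = seed + 1L)
    attr(fit2, "exploratory") <- fit1
    return(fit2)
  }
  fit1
}

## Single conditional draw per subject (Monolix-style shrinkage
## mitigation): for each subject pick one sampled eta at random.
.one_draw_per_subject <- function(cond, seed = 1L) {
  set.seed(seed)
  n_iter <- dim(cond$eta)[1]
  N <- dim(cond$eta)[2]
  idx <- sample.int(n_iter, N, replace = TRUE)
  eta <- do.call(rbind, lapply(seq_len(N),
                               function(i) cond$eta[idx[i], i, ]))
  colnames(eta) <- dimnames(cond$eta)[[3]]
  eta
}

#' Covariate screening on sampled random effects
#'
#' For every random effect, tests sex and metabolizer class by one-way
#' ANOVA and bodyweight by Pearson correlation, using one conditional
#' posterior draw per subject rather than empirical-Bayes point estimates
#' (shrinkage mitigation). Inclusion is flagged at p < 0.05, uncorrected.
#'
#' @param fit a \code{saem_fit}, or a \code{\link{population_model}} with
#'   \code{dataset}
#' @param dataset the \code{\link{pk_dataset}} (required for a
#'   \code{population_model}; used for covariate values in both cases)
#' @param cond optional precomputed \code{\link{sample_conditional}} output
#' @param seed seed for the draw selection
#' @return data frame with \code{parameter}, \code{covariate},
#'   \code{test}, \code{p_value}, \code{include}, \code{note}
#' @export
covariate_tests <- function(fit, dataset, cond = NULL, seed = 1L) {
  if (is.null(cond)) cond <- sample_conditional(fit, dataset, seed = seed)
  eta <- .one_draw_per_subject(cond, seed = seed)
  ids <- vapply(cond$subjects, `[[`, "", "id")
  cv <- dataset$covariates[match(ids, dataset$covariates$subject_id), ]
  out <- list()
  add <- function(parameter, covariate, test, p, note = "") {
    out[[length(out) + 1L]] <<- data.frame(
      parameter = parameter, covariate = covariate, test = test,
      p_value = p, include = is.finite(p) && p < 0.05, note = note,
      stringsAsFactors = FALSE)
  }
  for (nm in colnames(eta)) {
    e <- eta[, nm]
    if (length(unique(cv$sex)) < 2)
      add(nm, "sex", "anova", NA_real_, "constant covariate, skipped")
    else
      add(nm, "sex", "anova",
          stats::anova(stats::lm(e ~ factor(cv$sex)))[["Pr(>F)"]][1])
    if (all(is.na(cv$MET)) || length(unique(cv$MET)) < 2)
      add(nm, "MET", "anova", NA_real_, "constant covariate, skipped")
    else
      add(nm, "MET", "anova",
          stats::anova(stats::lm(e ~ factor(cv$MET)))[["Pr(>F)"]][1])
    if (stats::sd(cv$bodyweight) == 0)
      add(nm, "bodyweight", "pearson", NA_real_, "constant covariate, skipped")
    else
      add(nm, "bodyweight", "pearson",
          stats::cor.test(e, cv$bodyweight)$p.value)
  }
  do.call(rbind, out)
}

#' Random-effect correlation screening
#'
#' Pairwise Pearson correlation tests between sampled random effects (one
#' conditional draw per subject). Pairs with p < 0.05 are flagged for
#' inclusion as free correlations in the covariance structure.
#'
#' @inheritParams covariate_tests
#' @return data frame with \code{par1}, \code{par2}, \code{correlation},
#'   \code{p_value}, \code{include}
#' @export
correlation_tests <- function(fit, dataset, cond = NULL, seed = 1L) {
  if (is.null(cond)) cond <- sample_conditional(fit, dataset, seed = seed)
  eta <- .one_draw_per_subject(cond, seed = seed)
  if (nrow(eta) < 3) {
    warning("fewer than 3 subjects: correlation tests skipped")
    return(data.frame(par1 = character(0), par2 = character(0),
                      correlation = numeric(0), p_value = numeric(0),
                      include = logical(0)))
  }
  nms <- colnames(eta)
  ## only parameters with non-degenerate spread are testable
  nms <- nms[apply(eta, 2, stats::sd) > 1e-8]
  if (length(nms) < 2)
    return(data.frame(par1 = character(0), par2 = character(0),
                      correlation = numeric(0), p_value = numeric(0),
                      include = logical(0)))
  prs <- utils::combn(nms, 2)
  out <- lapply(seq_len(ncol(prs)), function(k) {
    ct <- stats::cor.test(eta[, prs[1, k]], eta[, prs[2, k]])
    data.frame(par1 = prs[1, k], par2 = prs[2, k],
               correlation = unname(ct$estimate), p_value = ct$p.value,
               include = ct$p.value < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify subjects as fast or slow metabolizers
#'
#' One-dimensional 2-means clustering of log-clearance proxies (NCA
#' clearances or conditional-mean clearances from a fit). The
#' higher-clearance cluster is labelled fast (MET = 0), the lower slow
#' (MET = 1). If the cluster separation is below \code{min_separation}
#' (log scale) the split is considered degenerate and every subject is
#' assigned MET = 1 with a warning.
#'
#' @param log_cl named numeric vector of per-subject log-clearance proxies
#' @param min_separation minimum distance between cluster centres on the
#'   log scale for a non-degenerate split
#' @return data frame with \code{subject_id}, \code{log_cl}, \code{MET}
#' @export
classify_metabolizers <- function(log_cl, min_separation = 0.3) {
  stopifnot(is.numeric(log_cl), !is.null(names(log_cl)))
  if (stats::sd(log_cl) < 1e-12) {
    warning("clearances are indistinguishable; all subjects assigned MET = 1")
    return(data.frame(subject_id = names(log_cl), log_cl = unname(log_cl),
                      MET = 1L, stringsAsFactors = FALSE))
  }
  km <- stats::kmeans(log_cl, centers = 2, nstart = 10)
  if (abs(diff(km$centers)) < min_separation) {
    warning("cluster separation below threshold; all subjects assigned MET = 1")
    met <- rep(1L, length(log_cl))
  } else {
    fast_cluster <- which.max(km$centers)
    met <- ifelse(km$cluster == fast_cluster, 0L, 1L)
  }
  data.frame(subject_id = names(log_cl), log_cl = unname(log_cl),
             MET = met, stringsAsFactors = FALSE)
}

#' Conditional-mean log-clearance proxies for metabolizer classification
#'
#' Per-subject posterior mean of log-clearance under a fitted (or assumed)
#' population model, via \code{\link{sample_conditional}}. The MET
#' covariate is deliberately ignored in the mean structure so the mixture
#' shows up in the proxies themselves.
#'
#' @param model a \code{\link{population_model}} (typically without the
#'   MET effect, or with it zeroed)
#' @param dataset a \code{\link{pk_dataset}}
#' @param n_iter,seed passed to \code{\link{sample_conditional}}
#' @return named vector of per-subject posterior-mean log-clearances
#' @export
clearance_proxies <- function(model, dataset, n_iter = 100, seed = 1L) {
  cond <- sample_conditional(model, dataset, n_iter = n_iter,
                             use_met = FALSE, seed = seed)
  lcl <- apply(cond$draws[, , "Cl", drop = FALSE], 2, mean)
  stats::setNames(lcl, vapply(cond$subjects, `[[`, "", "id"))
}

#' Goodness-of-fit diagnostics
#'
#' Assembles the standard diagnostic bundle from a converged fit:
#' observation vs individual-prediction pairs (predictions from one
#' conditional draw per subject), individual weighted residuals
#' IWRES = (y - F) / (b * max(F, floor)), their lag-1 autocorrelation,
#' and a prediction distribution built from Monte-Carlo replicates of the
#' whole study (quantiles 5\% to 95\% in steps of 10\% on a grid with
#' roughly 50-minute spacing, per route). The \code{log1p}-scaled axes
#' used for plotting are left to the caller.
#'
#' @param fit a \code{saem_fit}
#' @param dataset the fitted \code{\link{pk_dataset}}
#' @param n_sim number of simulated study replicates
#' @param grid_step grid spacing in minutes for the prediction
#'   distribution
#' @param seed integer seed
#' @return list with \code{obs_pred} (data frame: subject, time, dv,
#'   ipred, iwres, censored), \code{iwres_acf1}, \code{pred_dist} (data
#'   frame: route, time, quantile columns), \code{coverage} (fraction of
#'   quantified observations inside the 5-95\% band, per route)
#' @export
gof_diagnostics <- function(fit, dataset, n_sim = 500, grid_step = 50,
                            seed = 1L) {
  set.seed(seed)
  cond <- sample_conditional(fit, dataset)
  eta <- .one_draw_per_subject(cond, seed = seed)
  subs <- fit$subjects
  model <- fit$model
  act <- fit$active
  floor_ <- fit$settings$error_floor_frac * fit$lloq
  op <- list()
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    psi <- .psi_typical(model, fit$MET[i])
    psi[act] <- psi[act] + eta[i, ]
    pars <- .psi_to_params(psi, model$fpo_fixed, model$F_po)
    f <- solve_profile(pars, s$doses, s$t_obs)
    g <- pmax(f, floor_)
    op[[i]] <- data.frame(subject_id = s$id, time = s$t_obs, dv = s$y,
                          ipred = f, iwres = (s$y - f) / (model$b * g),
                          censored = s$cens, stringsAsFactors = FALSE)
  }
  obs_pred <- do.call(rbind, op)
  quant_res <- obs_pred$iwres[!obs_pred$censored]
  iwres_acf1 <- if (length(quant_res) > 2)
    stats::acf(quant_res, lag.max = 1, plot = FALSE)$acf[2] else NA_real_

  ## prediction distribution: per-route quantile bands over study replicates
  qs <- seq(0.05, 0.95, by = 0.10)
  routes <- unique(dataset$doses$route)
  ## per subject-occasion sampling horizon, per route
  sim_conc <- list()   # route -> matrix sims x grid
  grids <- list()
  for (rt in routes) {
    tmax <- 0
    for (i in seq_along(subs)) {
      dd <- subs[[i]]$doses
      for (k in seq_len(nrow(dd))) {
        if (dd$route[k] != rt) next
        t0 <- dd$time[k]
        t1 <- if (k < nrow(dd)) dd$time[k + 1] else Inf
        tt <- subs[[i]]$t_obs
        tt <- tt[tt >= t0 & tt < t1]
        if (length(tt)) tmax <- max(tmax, max(tt - t0))
      }
    }
    grids[[rt]] <- seq(0, tmax, by = grid_step)
  }
  Om <- omega_matrix(model)[act, act, drop = FALSE]
  ch <- chol(Om + diag(1e-10, length(act)))
  for (rt in routes) sim_conc[[rt]] <- list()
  for (r in seq_len(n_sim)) {
    for (i in seq_along(subs)) {
      e <- drop(crossprod(ch, stats::rnorm(length(act))))
      psi <- .psi_typical(model, fit$MET[i])
      psi[act] <- psi[act] + e
      pars <- .psi_to_params(psi, model$fpo_fixed, model$F_po)
      dd <- subs[[i]]$doses
      for (k in seq_len(nrow(dd))) {
        rt <- dd$route[k]
        gg <- grids[[rt]]
        d1 <- dd[k, , drop = FALSE]; d1$time <- 0
        f <- solve_profile(pars, d1, gg)
        ## replicate observations, not mean responses: add residual noise
        y <- pmax(f * (1 + model$b * stats::rnorm(length(f))), 0)
        sim_conc[[rt]][[length(sim_conc[[rt]]) + 1L]] <- y
      }
    }
  }
  pred_dist <- list(); coverage <- list()
  for (rt in routes) {
    mat <- do.call(rbind, sim_conc[[rt]])
    qmat <- apply(mat, 2, stats::quantile, probs = qs)
    df <- data.frame(route = rt, time = grids[[rt]], t(qmat))
    names(df)[-(1:2)] <- paste0("q", round(100 * qs))
    pred_dist[[rt]] <- df
    ## coverage of the 5-95% band at the observation times
    covered <- 0L; total <- 0L
    for (i in seq_along(subs)) {
      s <- subs[[i]]; dd <- s$doses
      for (k in seq_len(nrow(dd))) {
        if (dd$route[k] != rt) next
        t0 <- dd$time[k]
        t1 <- if (k < nrow(dd)) dd$time[k + 1] else Inf
        sel <- s$t_obs >= t0 & s$t_obs < t1 & !s$cens
        if (!any(sel)) next
        tt <- s$t_obs[sel] - t0
        yy <- s$y[sel]
        ql <- stats::approx(grids[[rt]], qmat[1, ], tt, rule = 2)$y
        qh <- stats::approx(grids[[rt]], qmat[nrow(qmat), ], tt, rule = 2)$y
        covered <- covered + sum(yy >= ql & yy <= qh)
        total <- total + length(yy)
      }
    }
    coverage[[rt]] <- if (total) covered / total else NA_real_
  }
  list(obs_pred = obs_pred, iwres_acf1 = iwres_acf1,
       pred_dist = do.call(rbind, pred_dist),
       coverage = unlist(coverage))
}
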