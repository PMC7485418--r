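#' Default trial design: two-phase flunixin study in pre-wean piglets
#'
#' Phase 1 is a parallel design (IM n = 7 at 2.2 mg/kg; PO n = 8 and TD
#' n = 8 at 3.3 mg/kg) sampled through 72 h. Phase 2 is a two-way IV/TD
#' crossover (n = 16; IV 2.2 mg/kg sampled through 60 h, TD 3.3 mg/kg
#' sampled through 216 h) with a 9-day washout between periods. The LLOQ
#' of the assay is 2 ug/L.
#'
#' @param im_n,po_n,td_n phase-1 group sizes
#' @param crossover_n phase-2 group size (half start IV, half TD)
#' @param washout_days washout between crossover periods
#' @param lloq lower limit of quantification (mg/L internal scale)
#' @return object of class \code{study_design}
#' @export
study_design <- function(im_n = 7, po_n = 8, td_n = 8, crossover_n = 16,
                         washout_days = 9, lloq = 0.002) {
  h <- 60
  phase1 <- c(0, 15, 30, 45, 60, 90, c(2, 3, 6, 12, 24, 36, 48, 60, 72) * h)
  iv2 <- c(0, 5, 15, 30, 45, 60, 90, c(2, 3, 6, 12, 24, 36, 48, 60) * h)
  td2 <- c(0, 15, 30, 45, 60, 90,
           c(2, 3, 6, 12, 24, 36, 48, 60, 72, 84, 96, 108, 120, 132, 144,
             156, 168, 180, 192, 204, 216) * h)
  stopifnot(!is.unsorted(phase1, strictly = TRUE),
            !is.unsorted(iv2, strictly = TRUE),
            !is.unsorted(td2, strictly = TRUE),
            im_n > 0, po_n > 0, td_n > 0, crossover_n > 0, lloq > 0)
  structure(list(
    im_n = im_n, po_n = po_n, td_n = td_n, crossover_n = crossover_n,
    dose_rate = c(IV = 2.2, IM = 2.2, PO = 3.3, TD = 3.3),  # mg/kg
    schedule_phase1 = phase1, schedule_iv2 = iv2, schedule_td2 = td2,
    washout_min = washout_days * 24 * 60, lloq = lloq),
    class = "study_design")
}

#' Configuration of the synthetic-study generator
#'
#' @param truth generating \code{\link{population_model}}; defaults to the
#'   reference parameterization \code{\link{flunixin_population_model}}
#' @param bw_model generating \code{\link{bodyweight_model}}
#' @param fast_fraction probability of the fast-metabolizer class
#'   (MET = 0); default 9/38 as observed in the study population
#' @param drop_po_pig emulate the excluded oral-dose subject by flagging
#'   all observations of one PO pig as excluded
#' @param drop_iv_points number of random IV observations to flag excluded
#'   (emulates unverifiable IV samples)
#' @return object of class \code{generator_config}
#' @export
generator_config <- function(truth = flunixin_population_model(),
                             bw_model = bodyweight_model(),
                             fast_fraction = 9 / 38,
                             drop_po_pig = FALSE, drop_iv_points = 0) {
  stopifnot(inherits(truth, "population_model"),
            inherits(bw_model, "bodyweight_model"),
            fast_fraction >= 0, fast_fraction <= 1, drop_iv_points >= 0)
  structure(list(truth = truth, bw_model = bw_model,
                 fast_fraction = fast_fraction, drop_po_pig = drop_po_pig,
                 drop_iv_points = drop_iv_points),
            class = "generator_config")
}

## Draw one multivariate normal vector given the Cholesky factor (upper).
.rmvnorm_chol <- function(n, chol_upper) {
  d <- ncol(chol_upper)
  matrix(stats::rnorm(n * d), n, d) %*% chol_upper
}

#' Apply LLOQ censoring to an observation table
#'
#' Concentrations strictly below the LLOQ become censored with the LLOQ
#' stored as their value; values at or above the LLOQ are untouched.
#'
#' @param observations data frame with columns \code{conc} and
#'   \code{censored}
#' @param lloq lower limit of quantification (same unit as \code{conc})
#' @return list with the modified \code{observations} and \code{n_flipped},
#'   the number of rows newly censored
#' @export
censor_lloq <- function(observations, lloq) {
  if (lloq <= 0) stop("lloq must be positive")
  flip <- !observations$censored & observations$conc < lloq
  observations$censored[flip] <- TRUE
  observations$conc[flip] <- lloq
  list(observations = observations, n_flipped = sum(flip))
}

#' Generate a complete synthetic study
#'
#' Simulates the full two-phase trial under the generating model: per
#' subject, draws sex, bodyweight (phase-appropriate Box-Cox sub-model),
#' metabolizer class, and correlated random effects; computes doses as
#' mg/kg rate times bodyweight; simulates noise-free profiles with the
#' analytic structural model (crossover period 2 by superposition on the
#' period-1 doses); adds proportional residual noise
#' \code{y = F * (1 + b * eps)} with negative draws resampled; censors at
#' the LLOQ. Pre-dose (time-0) samples are generated as BLQ and flagged
#' excluded.
#'
#' @param design a \code{\link{study_design}}
#' @param config a \code{\link{generator_config}}
#' @param seed integer seed; the same seed reproduces the dataset exactly
#' @return a \code{\link{pk_dataset}}
#' @export
generate_study <- function(design = study_design(),
                           config = generator_config(), seed = 1L) {
  set.seed(seed)
  truth <- config$truth
  Om <- omega_matrix(truth)
  ch <- chol(Om + diag(1e-12, nrow(Om)))  # guard exact-zero variances
  n1 <- design$im_n + design$po_n + design$td_n
  n2 <- design$crossover_n
  N <- n1 + n2
  ids <- sprintf("P%02d", seq_len(N))
  phase <- c(rep(1L, n1), rep(2L, n2))
  route1 <- c(rep("IM", design$im_n), rep("PO", design$po_n),
              rep("TD", design$td_n))
  ## phase 2: first half IV-first, second half TD-first
  first2 <- rep(c("IV", "TD"), each = n2 / 2, length.out = n2)
  sex <- rep(c("F", "M"), length.out = N)
  MET <- as.integer(stats::runif(N) >= config$fast_fraction)  # 0 fast, 1 slow
  bw <- numeric(N)
  bw[phase == 1] <- sample_bodyweight(config$bw_model, n1, phase = 1)$bw
  bw[phase == 2] <- sample_bodyweight(config$bw_model, n2, phase = 2)$bw
  eta <- .rmvnorm_chol(N, ch)

  doses_l <- list(); obs_l <- list()
  for (i in seq_len(N)) {
    pars <- link_transform(truth, eta[i, ], MET = MET[i])
    if (phase[i] == 1L) {
      rt <- route1[i]
      dosedf <- data.frame(subject_id = ids[i], time = 0,
                           amount = design$dose_rate[[rt]] * bw[i],
                           route = rt, phase = 1L, period = NA_integer_,
                           stringsAsFactors = FALSE)
      sched <- design$schedule_phase1
      times <- sched
    } else {
      rt1 <- first2[i - n1]
      rt2 <- setdiff(c("IV", "TD"), rt1)
      s1 <- if (rt1 == "IV") design$schedule_iv2 else design$schedule_td2
      s2 <- if (rt2 == "IV") design$schedule_iv2 else design$schedule_td2
      t2 <- max(s1) + design$washout_min
      dosedf <- data.frame(subject_id = ids[i], time = c(0, t2),
                           amount = design$dose_rate[c(rt1, rt2)] * bw[i],
                           route = c(rt1, rt2), phase = 2L, period = 1:2,
                           stringsAsFactors = FALSE)
      times <- c(s1, t2 + s2)
      sched <- times
    }
    conc <- solve_profile(pars, dosedf, times)
    ## proportional noise, negative draws resampled (truncation at zero)
    y <- conc
    idx <- which(conc > 0)
    if (truth$b > 0 && length(idx)) {
      yy <- conc[idx] * (1 + truth$b * stats::rnorm(length(idx)))
      while (any(yy < 0)) {
        bad <- which(yy < 0)
        yy[bad] <- conc[idx][bad] * (1 + truth$b * stats::rnorm(length(bad)))
      }
      y[idx] <- yy
    }
    predose <- if (phase[i] == 1L) times == 0 else times %in% c(0, t2 + 0)
    obs_l[[i]] <- data.frame(subject_id = ids[i], time = times, conc = y,
                             censored = FALSE,
                             excluded = predose, stringsAsFactors = FALSE)
    doses_l[[i]] <- dosedf
  }
  doses <- do.call(rbind, doses_l)
  obs <- do.call(rbind, obs_l)
  cen <- censor_lloq(obs, design$lloq)
  obs <- cen$observations
  ## pre-dose rows are true zeros: store as BLQ
  obs$conc[obs$excluded] <- design$lloq
  obs$censored[obs$excluded] <- TRUE

  if (config$drop_po_pig) {
    po_ids <- unique(doses$subject_id[doses$route == "PO"])
    drop <- po_ids[1]
    obs$excluded[obs$subject_id == drop] <- TRUE
  }
  if (config$drop_iv_points > 0) {
    iv_ids <- unique(doses$subject_id[doses$route == "IV"])
    iv_rows <- which(obs$subject_id %in% iv_ids & !obs$excluded)
    k <- min(config$drop_iv_points, length(iv_rows))
    obs$excluded[sample(iv_rows, k)] <- TRUE
  }
  covariates <- data.frame(subject_id = ids, sex = sex, bodyweight = bw,
                           MET = MET, stringsAsFactors = FALSE)
  pk_dataset(doses, obs, covariates, design$lloq)
}
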