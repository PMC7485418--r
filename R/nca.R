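#' Noncompartmental analysis configuration
#'
#' @param min_lambda_points minimum number of terminal points for the
#'   terminal-slope regression (at least 3)
#' @param trapezoid AUC rule: \code{"lin-up-log-down"} (log trapezoid on
#'   declining segments) or \code{"linear"}
#' @param blq_rule handling of censored observations; only
#'   \code{"exclude"} is supported (censored points are dropped entirely,
#'   never substituted)
#' @return object of class \code{nca_config}
#' @export
nca_config <- function(min_lambda_points = 3,
                       trapezoid = c("lin-up-log-down", "linear"),
                       blq_rule = "exclude") {
  if (min_lambda_points < 3) stop("min_lambda_points must be >= 3")
  trapezoid <- match.arg(trapezoid)
  blq_rule <- match.arg(blq_rule, "exclude")
  structure(list(min_lambda_points = min_lambda_points, trapezoid = trapezoid,
                 blq_rule = blq_rule), class = "nca_config")
}

#' Terminal-slope (lambda-z) estimation by best adjusted R-squared
#'
#' Log-linear regression over candidate terminal windows (the last k
#' points, k >= \code{min_lambda_points}), excluding the Cmax point for
#' extravascular routes. The window maximizing the adjusted R-squared is
#' selected; windows within 1e-4 of the best are tie-broken toward more
#' points. Works in internal units (minutes).
#'
#' @param time observation times (min), sorted ascending
#' @param conc positive concentrations (censored points already excluded)
#' @param config an \code{\link{nca_config}}
#' @param extravascular logical; if \code{TRUE} the Cmax point is excluded
#'   from every candidate window
#' @return list with \code{lambda_z} (1/min), \code{intercept} (log mg/L
#'   at time 0), \code{n_points}, \code{adj_r2}; or all-NA with
#'   \code{estimable = FALSE} when fewer than \code{min_lambda_points}
#'   usable points remain or no window has a negative slope
#' @export
estimate_lambda_z <- function(time, conc, config = nca_config(),
                              extravascular = TRUE) {
  keep <- conc > 0
  time <- time[keep]; conc <- conc[keep]
  if (extravascular && length(conc)) {
    ## terminal candidates are the points strictly after the peak
    imax <- which.max(conc)
    after <- time > time[imax]
    time <- time[after]; conc <- conc[after]
  }
  n <- length(conc)
  na <- list(lambda_z = NA_real_, intercept = NA_real_,
             n_points = NA_integer_, adj_r2 = NA_real_, estimable = FALSE)
  if (n < config$min_lambda_points) return(na)
  lc <- log(conc)
  best <- NULL
  for (k in config$min_lambda_points:n) {
    idx <- (n - k + 1):n
    ft <- stats::lm.fit(cbind(1, time[idx]), lc[idx])
    slope <- ft$coefficients[2]
    if (!is.finite(slope) || slope >= 0) next
    r2 <- 1 - sum(ft$residuals^2) / sum((lc[idx] - mean(lc[idx]))^2)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    cand <- list(lambda_z = unname(-slope),
                 intercept = unname(ft$coefficients[1]),
                 n_points = k, adj_r2 = unname(adj), estimable = TRUE)
    if (is.null(best) || adj > best$adj_r2 + 1e-4 ||
        (abs(adj - best$adj_r2) <= 1e-4 && k > best$n_points))
      best <- cand
  }
  if (is.null(best)) na else best
}

## trapezoidal AUC and AUMC over one segment
.seg_auc <- function(t1, t2, c1, c2, rule) {
  dt <- t2 - t1
  if (rule == "lin-up-log-down" && c2 < c1 && c2 > 0 && c1 > 0) {
    k <- log(c1 / c2) / dt
    auc <- (c1 - c2) / k
    aumc <- (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
  } else {
    auc <- dt * (c1 + c2) / 2
    aumc <- dt * (t1 * c1 + t2 * c2) / 2
  }
  c(auc, aumc)
}

#' Noncompartmental metrics for a single profile
#'
#' Computes the standard NCA panel from one concentration-time profile:
#' Cmax/tmax from the observed points, terminal slope by
#' \code{\link{estimate_lambda_z}}, AUC and AUMC to the last positive
#' observation by the configured trapezoid, extrapolation to infinity via
#' the terminal slope, mean residence time, and clearance and
#' steady-state volume (apparent, i.e. /F, for extravascular routes).
#' For IV profiles, the initial concentration C0 is back-extrapolated
#' log-linearly from the first two quantifiable points and the segment
#' from time 0 to the first sample is included in the AUC.
#'
#' Censored observations are excluded entirely. Inputs are in internal
#' units (min, mg/L); results are reported in hours, ug/L, and litres.
#'
#' @param profile data frame with columns \code{time} (min), \code{conc}
#'   (mg/L), and optionally \code{censored}
#' @param dose administered amount (mg)
#' @param route one of IV, IM, PO, TD
#' @param config an \code{\link{nca_config}}
#' @return one-row data frame of class \code{nca_result}: \code{lambda_z}
#'   (1/h), \code{t_half} (h), \code{Cmax} (ug/L), \code{tmax} (h),
#'   \code{C0} (ug/L, IV only), \code{AUC_last}, \code{AUC_inf} (mg h/L),
#'   \code{AUC_extrap_pct}, \code{AUC_over_dose} (h/L), \code{MRT} (h),
#'   \code{Cl} or \code{Cl_F} (L/h), \code{Vss} or \code{Vss_F} (L);
#'   metrics depending on an unestimable terminal slope are NA
#' @export
nca_single_profile <- function(profile, dose, route, config = nca_config()) {
  if (dose <= 0) stop("dose must be positive")
  if (!route %in% .known_routes) stop("unknown route: ", route)
  if ("censored" %in% names(profile))
    profile <- profile[!profile$censored, , drop = FALSE]
  profile <- profile[profile$conc >= 0, , drop = FALSE]
  profile <- profile[order(profile$time), , drop = FALSE]
  tt <- profile$time; cc <- profile$conc
  ev <- route %in% c("IM", "PO", "TD")
  out <- data.frame(subject_id = NA_character_, route = route,
                    dose = dose, n_obs = length(cc),
                    lambda_z = NA_real_, t_half = NA_real_,
                    Cmax = NA_real_, tmax = NA_real_, C0 = NA_real_,
                    AUC_last = NA_real_, AUC_inf = NA_real_,
                    AUC_extrap_pct = NA_real_, AUC_over_dose = NA_real_,
                    AUMC_inf = NA_real_, MRT = NA_real_,
                    Cl = NA_real_, Vss = NA_real_,
                    lambda_n_points = NA_integer_, lambda_adj_r2 = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("nca_result", class(out))
  if (length(cc) == 0L) return(out)
  imax <- which.max(cc)
  out$Cmax <- cc[imax] * 1000          # mg/L -> ug/L
  out$tmax <- tt[imax] / 60            # min -> h
  ## IV: back-extrapolated C0 and a leading segment from t = 0
  if (route == "IV" && length(cc) >= 2) {
    sl <- (log(cc[2]) - log(cc[1])) / (tt[2] - tt[1])
    c0 <- if (is.finite(sl) && sl < 0) exp(log(cc[1]) - sl * tt[1]) else cc[1]
    out$C0 <- c0 * 1000
    if (tt[1] > 0) { tt <- c(0, tt); cc <- c(c0, cc) }
  }
  if (length(cc) >= 2) {
    segs <- vapply(seq_len(length(cc) - 1L), function(j)
      .seg_auc(tt[j], tt[j + 1], cc[j], cc[j + 1], config$trapezoid),
      numeric(2))
    auc_last <- sum(segs[1, ]); aumc_last <- sum(segs[2, ])
  } else {
    auc_last <- 0; aumc_last <- 0
  }
  lz <- estimate_lambda_z(profile$time, profile$conc, config,
                          extravascular = ev)
  if (isTRUE(lz$estimable)) {
    ipos <- max(which(cc > 0))
    clast <- cc[ipos]; tlast <- tt[ipos]
    auc_inf <- auc_last + clast / lz$lambda_z
    aumc_inf <- aumc_last + clast * tlast / lz$lambda_z +
      clast / lz$lambda_z^2
    out$lambda_z <- lz$lambda_z * 60   # 1/min -> 1/h
    out$t_half <- log(2) / lz$lambda_z / 60
    out$lambda_n_points <- lz$n_points
    out$lambda_adj_r2 <- lz$adj_r2
    out$AUC_last <- auc_last / 60      # mg min/L -> mg h/L
    out$AUC_inf <- auc_inf / 60
    out$AUC_extrap_pct <- 100 * (auc_inf - auc_last) / auc_inf
    out$AUC_over_dose <- out$AUC_inf / dose
    out$AUMC_inf <- aumc_inf / 3600
    out$MRT <- (aumc_inf / auc_inf) / 60
    out$Cl <- dose / out$AUC_inf       # L/h (apparent, /F, if extravascular)
    out$Vss <- out$Cl * out$MRT
  } else {
    out$AUC_last <- auc_last / 60
  }
  out
}

#' Run NCA on every profile of a dataset
#'
#' Splits each subject's observations into dosing occasions (one per dose
#' event; crossover subjects contribute one profile per period, with
#' times taken relative to the period's dose), excludes censored and
#' excluded rows, and computes \code{\link{nca_single_profile}} per
#' occasion.
#'
#' @param dataset a \code{\link{pk_dataset}}
#' @param config an \code{\link{nca_config}}
#' @return data frame of per-profile NCA results, one row per dosing
#'   occasion, with \code{subject_id} and \code{route} filled in
#' @export
nca_dataset <- function(dataset, config = nca_config()) {
  out <- list()
  for (id in unique(dataset$covariates$subject_id)) {
    dd <- .subject_doses(dataset, id)
    oo <- .subject_obs(dataset, id)
    if (nrow(dd) == 0L || nrow(oo) == 0L) next
    for (k in seq_len(nrow(dd))) {
      t0 <- dd$time[k]
      t1 <- if (k < nrow(dd)) dd$time[k + 1] else Inf
      sel <- oo$time >= t0 & oo$time < t1 & !oo$censored
      if (!any(sel)) next
      prof <- data.frame(time = oo$time[sel] - t0, conc = oo$conc[sel])
      res <- nca_single_profile(prof, dose = dd$amount[k],
                                route = dd$route[k], config = config)
      res$subject_id <- id
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

#' Group summary of NCA results
#'
#' Mean, SD and median of every metric per route, missing values excluded
#' pairwise — the layout of a standard NCA parameter table with
#' Mean/SD/Median sub-rows per dosing group.
#'
#' @param results data frame from \code{\link{nca_dataset}} (or rbound
#'   \code{\link{nca_single_profile}} rows with \code{route} filled)
#' @return data frame with columns \code{route}, \code{stat}, then one
#'   column per metric
#' @export
nca_summarize <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("no NCA results to summarize")
  metrics <- c("AUC_over_dose", "AUC_inf", "Cl", "Cmax", "t_half",
               "lambda_z", "MRT", "tmax", "Vss")
  rows <- list()
  for (rt in intersect(.known_routes, unique(results$route))) {
    g <- results[results$route == rt, , drop = FALSE]
    if (nrow(g) == 0L) stop("empty route group: ", rt)
    for (st in c("Mean", "SD", "Median")) {
      f <- switch(st,
                  Mean = function(x) mean(x, na.rm = TRUE),
                  # SD of a single value is 0 by convention (not NA)
                  SD = function(x) {
                    x <- x[!is.na(x)]
                    if (length(x) <= 1) 0 else stats::sd(x)
                  },
                  Median = function(x) stats::median(x, na.rm = TRUE))
      vals <- vapply(metrics, function(mname) {
        x <- g[[mname]]
        if (all(is.na(x))) NA_real_ else f(x)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(route = rt, stat = st,
                                              t(vals), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
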