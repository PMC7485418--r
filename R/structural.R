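#' Structural parameter set for the two-compartment flunixin model
#'
#' Bundles the nine structural constants of one individual: systemic
#' clearance, central and peripheral volumes, intercompartmental clearance,
#' and the absorption parameters of the two parallel depot compartments
#' (first-order oral depot; first-order transdermal depot with a lag).
#' Internal units are minutes, milligrams, litres; concentrations are mg/L.
#'
#' @param Cl systemic clearance (L/min)
#' @param Vc central volume of distribution (L)
#' @param Q intercompartmental clearance (L/min)
#' @param Vp peripheral volume of distribution (L)
#' @param F_top transdermal bioavailability, fraction in (0, 1]
#' @param k_top transdermal first-order absorption rate (1/min)
#' @param Lag transdermal absorption lag (min), non-negative
#' @param F_po oral bioavailability, fraction in (0, 1]
#' @param k_po oral first-order absorption rate (1/min)
#' @return an object of class \code{structural_params}
#' @examples
#' p <- structural_params(Cl = 0.012, Vc = 1.35, Q = 0.003, Vp = 1.18,
#'                        F_top = 0.0784, k_top = 3e-4, Lag = 26.4,
#'                        F_po = 1, k_po = 0.06)
#' @export
structural_params <- function(Cl, Vc, Q, Vp, F_top, k_top, Lag, F_po, k_po) {
  p <- list(Cl = Cl, Vc = Vc, Q = Q, Vp = Vp, F_top = F_top, k_top = k_top,
            Lag = Lag, F_po = F_po, k_po = k_po)
  for (nm in c("Cl", "Vc", "Q", "Vp", "k_top", "k_po")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("structural parameter '", nm, "' must be a single positive number")
  }
  for (nm in c("F_top", "F_po")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0 || p[[nm]] > 1)
      stop("bioavailability '", nm, "' must lie in (0, 1]")
  }
  if (!is.numeric(Lag) || length(Lag) != 1L || !is.finite(Lag) || Lag < 0)
    stop("'Lag' must be a single non-negative number")
  structure(p, class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Two-compartment structural parameters (min / mg / L):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

## Disposition exponents (alpha >= beta) and micro constants of the
## two-compartment mammillary model.
.disposition <- function(p) {
  k10 <- p$Cl / p$Vc
  k12 <- p$Q / p$Vc
  k21 <- p$Q / p$Vp
  s <- k10 + k12 + k21
  disc <- sqrt(max(s * s - 4 * k10 * k21, 0))
  list(k10 = k10, k12 = k12, k21 = k21,
       alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

## Central-compartment concentration after a unit bolus into the central
## compartment at tau = 0 (tau >= 0), per unit dose.
.bolus_unit <- function(dsp, Vc, tau) {
  d <- dsp$alpha - dsp$beta
  A <- (dsp$alpha - dsp$k21) / d
  B <- (dsp$k21 - dsp$beta) / d
  (A * exp(-dsp$alpha * tau) + B * exp(-dsp$beta * tau)) / Vc
}

## Central-compartment concentration after a unit amount placed in a
## first-order depot (rate ka) at tau = 0, per unit depot amount.
.foral_unit <- function(dsp, Vc, ka, tau) {
  al <- dsp$alpha; be <- dsp$beta; k21 <- dsp$k21
  ## a repeated exponent makes the partial fractions singular; nudge ka
  if (abs(ka - al) < 1e-10 * ka) ka <- ka * (1 + 1e-8)
  if (abs(ka - be) < 1e-10 * ka) ka <- ka * (1 + 1e-8)
  ca <- (k21 - al) / ((ka - al) * (be - al))
  cb <- (k21 - be) / ((ka - be) * (al - be))
  ck <- (k21 - ka) / ((al - ka) * (be - ka))
  ka * (ca * exp(-al * tau) + cb * exp(-be * tau) + ck * exp(-ka * tau)) / Vc
}

.known_routes <- c("IV", "IM", "PO", "TD")

#' Predict a concentration profile for one individual
#'
#' Closed-form solution of the linear two-compartment system with parallel
#' first-order oral and lagged transdermal depot compartments, evaluated at
#' arbitrary times under an arbitrary multiple-dose schedule. IV and IM
#' doses enter the central compartment as boluses; PO doses deposit
#' \code{F_po * amount} into the oral depot at the dose time; TD doses
#' deposit \code{F_top * amount} into the transdermal depot at the dose
#' time plus \code{Lag}. Doses superpose by linearity.
#'
#' @param params a \code{\link{structural_params}} object
#' @param doses data frame with columns \code{time} (min), \code{amount}
#'   (mg) and \code{route} (one of \code{"IV"}, \code{"IM"}, \code{"PO"},
#'   \code{"TD"})
#' @param times sorted ascending numeric vector of prediction times (min)
#' @param im_depot optional list \code{list(F = , ka = )}; when supplied,
#'   IM doses are routed through their own first-order depot instead of the
#'   default central bolus (sensitivity analyses only)
#' @return numeric vector of central concentrations (mg/L), one per time
#' @examples
#' p <- structural_params(0.012, 1.35, 0.003, 1.18, 0.0784, 3e-4, 26.4, 1, 0.06)
#' d <- data.frame(time = 0, amount = 13.2, route = "TD")
#' head(solve_profile(p, d, times = seq(0, 2880, by = 60)))
#' @export
solve_profile <- function(params, doses, times, im_depot = NULL) {
  stopifnot(inherits(params, "structural_params"))
  if (is.unsorted(times)) stop("'times' must be sorted ascending")
  if (length(times) == 0L) return(numeric(0))
  conc <- numeric(length(times))
  if (is.null(doses) || nrow(doses) == 0L) return(conc)
  if (!all(doses$route %in% .known_routes))
    stop("unknown route code: ",
         paste(setdiff(unique(doses$route), .known_routes), collapse = ", "))
  if (any(doses$amount <= 0)) stop("dose amounts must be positive")
  dsp <- .disposition(params)
  for (i in seq_len(nrow(doses))) {
    rt <- doses$route[i]; amt <- doses$amount[i]; t0 <- doses$time[i]
    if (rt %in% c("IV", "IM") && is.null(im_depot) || rt == "IV") {
      idx <- times >= t0
      if (any(idx))
        conc[idx] <- conc[idx] + amt * .bolus_unit(dsp, params$Vc, times[idx] - t0)
    } else if (rt == "IM") {
      tdep <- t0
      idx <- times > tdep
      if (any(idx))
        conc[idx] <- conc[idx] + im_depot$F * amt *
          .foral_unit(dsp, params$Vc, im_depot$ka, times[idx] - tdep)
    } else if (rt == "PO") {
      idx <- times > t0
      if (any(idx))
        conc[idx] <- conc[idx] + params$F_po * amt *
          .foral_unit(dsp, params$Vc, params$k_po, times[idx] - t0)
    } else { # TD
      tdep <- t0 + params$Lag
      idx <- times > tdep
      if (any(idx))
        conc[idx] <- conc[idx] + params$F_top * amt *
          .foral_unit(dsp, params$Vc, params$k_top, times[idx] - tdep)
    }
  }
  conc
}

## Full compartment-state solution (amounts, mg) plus cumulative
## elimination, by eigen-decomposition of the augmented 5x5 rate matrix.
## States: A_po, A_td, A_c, A_p, E (eliminated). Used for mass-balance
## audits; solve_profile() is the fast path for concentrations.
.state_matrix <- function(params) {
  k10 <- params$Cl / params$Vc
  k12 <- params$Q / params$Vc
  k21 <- params$Q / params$Vp
  kpo <- params$k_po
  ktp <- params$k_top
  M <- matrix(0, 5, 5)
  M[1, 1] <- -kpo
  M[2, 2] <- -ktp
  M[3, ] <- c(kpo, ktp, -(k10 + k12), k21, 0)
  M[4, ] <- c(0, 0, k12, -k21, 0)
  M[5, 3] <- k10
  M
}

#' Compartment amounts and cumulative elimination over time
#'
#' Propagates the full state of the linear system (oral depot, transdermal
#' depot, central, peripheral amounts, and cumulative eliminated amount)
#' through the dose schedule by eigen-decomposition of the rate matrix.
#'
#' @inheritParams solve_profile
#' @return data frame with columns \code{time}, \code{A_po}, \code{A_td},
#'   \code{A_c}, \code{A_p}, \code{eliminated} (all mg)
#' @export
solve_states <- function(params, doses, times) {
  stopifnot(inherits(params, "structural_params"))
  if (is.unsorted(times)) stop("'times' must be sorted ascending")
  M <- .state_matrix(params)
  eg <- eigen(M)
  V <- Re(eg$vectors); lam <- Re(eg$values)
  Vinv <- solve(V)
  ## impulse events: (time, state-index, amount added)
  ev <- list()
  if (!is.null(doses) && nrow(doses) > 0L) {
    for (i in seq_len(nrow(doses))) {
      rt <- doses$route[i]
      ev[[i]] <- switch(rt,
        IV = , IM = c(doses$time[i], 3, doses$amount[i]),
        PO = c(doses$time[i], 1, params$F_po * doses$amount[i]),
        TD = c(doses$time[i] + params$Lag, 2, params$F_top * doses$amount[i]),
        stop("unknown route code: ", rt))
    }
  }
  ev <- if (length(ev)) do.call(rbind, ev) else matrix(numeric(0), 0, 3)
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  out <- matrix(0, length(times), 5)
  state <- numeric(5); tcur <- -Inf; k <- 1L
  prop <- function(state, dt) {
    if (dt <= 0) return(state)
    as.numeric(V %*% (exp(lam * dt) * (Vinv %*% state)))
  }
  for (j in seq_along(times)) {
    tj <- times[j]
    while (k <= nrow(ev) && ev[k, 1] <= tj) {
      if (is.finite(tcur)) state <- prop(state, ev[k, 1] - tcur)
      state[ev[k, 2]] <- state[ev[k, 2]] + ev[k, 3]
      tcur <- ev[k, 1]; k <- k + 1L
    }
    if (is.finite(tcur)) state <- prop(state, tj - tcur)
    tcur <- max(tcur, tj)
    out[j, ] <- state
  }
  data.frame(time = times, A_po = out[, 1], A_td = out[, 2],
             A_c = out[, 3], A_p = out[, 4], eliminated = out[, 5])
}

#' Mass-balance audit of a dose schedule
#'
#' Accounts for every milligram of drug at \code{t_end}: amount absorbed
#' into the body (boluses plus depot transfer), amount still in the depots,
#' amount eliminated (time integral of \code{Cl/Vc * A_c}), amount
#' remaining in central plus peripheral compartments, and depot deposits
#' whose lagged entry time has not yet been reached.
#'
#' @inheritParams solve_profile
#' @param t_end audit time (min), at or beyond the last dose time
#' @return list with components \code{dosed}, \code{input}, \code{absorbed},
#'   \code{depot_remaining}, \code{eliminated}, \code{remaining},
#'   \code{pending} (all mg); \code{input = absorbed + depot_remaining} and
#'   \code{absorbed = eliminated + remaining} up to numerical precision
#' @export
mass_balance <- function(params, doses, t_end) {
  stopifnot(inherits(params, "structural_params"))
  if (!is.null(doses) && nrow(doses) > 0L && t_end < max(doses$time))
    stop("'t_end' must not precede the last dose time")
  st <- solve_states(params, doses, t_end)
  dep_time <- function(i) {
    switch(doses$route[i], TD = doses$time[i] + params$Lag, doses$time[i])
  }
  eff <- function(i) {
    switch(doses$route[i],
           PO = params$F_po * doses$amount[i],
           TD = params$F_top * doses$amount[i],
           doses$amount[i])
  }
  n <- if (is.null(doses)) 0L else nrow(doses)
  input <- 0; pending <- 0; dosed <- 0
  for (i in seq_len(n)) {
    dosed <- dosed + doses$amount[i]
    if (dep_time(i) <= t_end) input <- input + eff(i) else pending <- pending + eff(i)
  }
  depot <- st$A_po + st$A_td
  remaining <- st$A_c + st$A_p
  list(dosed = dosed, input = input,
       absorbed = input - depot,
       depot_remaining = depot,
       eliminated = st$eliminated,
       remaining = remaining,
       pending = pending)
}

#' Volume of distribution at steady state
#'
#' For the two-compartment mammillary model this is the sum of the central
#' and peripheral volumes.
#'
#' @param params a \code{\link{structural_params}} object
#' @return Vss in litres
#' @export
vss <- function(params) params$Vc + params$Vp
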