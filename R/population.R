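## Canonical order of the Gaussian-scale individual parameter vector.
## All components use a log link except the two bioavailabilities (logit).
.psi_names <- c("Cl", "Vc", "Q", "Vp", "Ftop", "ktop", "Lag", "kpo", "Fpo")
.logit_links <- c("Ftop", "Fpo")
.corr_block <- c("Cl", "Q", "Vp", "Ftop")
## numerical guard: logit-scale typical values are kept in [-cap, cap],
## i.e. bioavailabilities in [plogis(-7), plogis(7)] ~ [0.09%, 99.91%]
.logit_cap <- 7

#' Population model for the hierarchical PK analysis
#'
#' The estimand of the nonlinear mixed-effects fit: typical values of the
#' structural parameters (log-normal link for clearances, volumes, rates
#' and the lag; logit-normal link for the bioavailabilities), an additive
#' covariate effect of the slow-metabolizer class on log-clearance, the
#' random-effect covariance (free correlations among clearance,
#' intercompartmental clearance, peripheral volume and transdermal
#' bioavailability), and the proportional residual-error scale.
#'
#' @param mu named vector of typical values for \code{Cl} (L/min),
#'   \code{Vc} (L), \code{Q} (L/min), \code{Vp} (L), \code{ktop} (1/min),
#'   \code{Lag} (min), \code{kpo} (1/min)
#' @param xi_Ftop typical transdermal bioavailability, fraction in (0, 1)
#' @param F_po typical oral bioavailability, fraction in (0, 1]
#' @param beta_Cl_MET additive effect on log-clearance for slow
#'   metabolizers (MET = 1); the reference category MET = 0 is fast
#' @param omega named vector of random-effect standard deviations on the
#'   Gaussian (log / logit) scale, over
#'   \code{Cl, Vc, Q, Vp, Ftop, ktop, Lag, kpo, Fpo}
#' @param corr correlation matrix among the random effects of
#'   \code{Cl, Q, Vp, Ftop} (dimnames required); all other random effects
#'   are independent
#' @param b proportional residual-error scale
#' @param fpo_fixed logical; if \code{TRUE}, individual oral
#'   bioavailability is pinned to \code{F_po} exactly (its variance entry
#'   is bookkeeping only)
#' @return object of class \code{population_model}
#' @export
population_model <- function(mu, xi_Ftop, F_po = 1, beta_Cl_MET = 0,
                             omega, corr = NULL, b, fpo_fixed = TRUE) {
  mu_names <- setdiff(.psi_names, .logit_links)
  if (!all(mu_names %in% names(mu)))
    stop("'mu' must name ", paste(mu_names, collapse = ", "))
  mu <- mu[mu_names]
  if (any(mu <= 0)) stop("typical values must be positive")
  if (xi_Ftop <= 0 || xi_Ftop >= 1) stop("xi_Ftop must lie in (0, 1)")
  if (F_po <= 0 || F_po > 1) stop("F_po must lie in (0, 1]")
  if (!all(.psi_names %in% names(omega)))
    stop("'omega' must name all of ", paste(.psi_names, collapse = ", "))
  omega <- omega[.psi_names]
  if (any(omega < 0)) stop("omega entries must be non-negative")
  if (is.null(corr)) {
    corr <- diag(length(.corr_block))
    dimnames(corr) <- list(.corr_block, .corr_block)
  }
  if (!identical(rownames(corr), .corr_block) ||
      !identical(colnames(corr), .corr_block))
    stop("'corr' must have dimnames ", paste(.corr_block, collapse = ", "))
  if (any(abs(corr) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("'corr' must be positive semi-definite")
  if (b <= 0) stop("residual-error scale b must be positive")
  structure(list(mu = mu, xi_Ftop = xi_Ftop, F_po = F_po,
                 beta_Cl_MET = beta_Cl_MET, omega = omega, corr = corr,
                 b = b, fpo_fixed = fpo_fixed),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model\n  typical values:\n")
  print(c(x$mu, Ftop = x$xi_Ftop, Fpo = x$F_po))
  cat("  beta_Cl_MET:", x$beta_Cl_MET, "  b:", x$b,
      if (x$fpo_fixed) " (F_po fixed)" else "", "\n  omega:\n")
  print(x$omega)
  cat("  correlations (Cl, Q, Vp, Ftop):\n")
  print(x$corr)
  invisible(x)
}

## Omega standard deviation from a log-normal coefficient of variation (%).
.omega_from_cv <- function(cv_pct) sqrt(log(1 + (cv_pct / 100)^2))

## Log-normal CV (%) from an omega standard deviation.
.cv_from_omega <- function(omega) 100 * sqrt(exp(omega^2) - 1)

#' Reference population parameterization for flunixin in pre-wean piglets
#'
#' The final-model estimates shipped with the package: typical clearance
#' 0.012 L/min (fast-metabolizer reference), slow-metabolizer effect
#' -0.892 on log-clearance, central/peripheral volumes 1.35/1.18 L,
#' intercompartmental clearance 0.003 L/min, transdermal bioavailability
#' 7.84\% with absorption rate 3e-4 1/min and 26.4 min lag, oral
#' bioavailability fixed at 1 with absorption rate 0.06 1/min, and
#' proportional residual error 0.294. Between-subject standard deviations
#' are back-computed from the reported log-normal CV\%s; the transdermal
#' bioavailability spread uses the log-normal approximation of its
#' logit-normal distribution (valid because F is small). Correlations are
#' free among Cl, Q, Vp and Ftop.
#'
#' @return a \code{\link{population_model}}
#' @export
flunixin_population_model <- function() {
  corr <- matrix(c(
    1,     0.612, 0.694, 0.853,
    0.612, 1,     0.967, 0.766,
    0.694, 0.967, 1,     0.817,
    0.853, 0.766, 0.817, 1), 4, 4,
    dimnames = list(.corr_block, .corr_block))
  population_model(
    mu = c(Cl = 0.012, Vc = 1.35, Q = 0.003, Vp = 1.18,
           ktop = 3e-4, Lag = 26.4, kpo = 0.06),
    xi_Ftop = 0.0784,
    F_po = 1,
    beta_Cl_MET = -0.892,
    omega = c(Cl = .omega_from_cv(31.9), Vc = .omega_from_cv(83.8),
              Q = .omega_from_cv(227), Vp = .omega_from_cv(106),
              Ftop = .omega_from_cv(192), ktop = .omega_from_cv(29.9),
              Lag = .omega_from_cv(148), kpo = .omega_from_cv(30.5),
              Fpo = 0.1),
    corr = corr,
    b = 0.294,
    fpo_fixed = TRUE)
}

## Full 9x9 random-effect covariance on the Gaussian scale.
omega_matrix <- function(model) {
  n <- length(.psi_names)
  O <- diag(model$omega^2, n)
  dimnames(O) <- list(.psi_names, .psi_names)
  blk <- .corr_block
  O[blk, blk] <- outer(model$omega[blk], model$omega[blk]) * model$corr
  O
}

## Gaussian-scale typical (mean) vector for a given MET value.
.psi_typical <- function(model, MET = 0) {
  m <- c(log(model$mu["Cl"]) + model$beta_Cl_MET * MET,
         log(model$mu[c("Vc", "Q", "Vp")]),
         stats::qlogis(model$xi_Ftop),
         log(model$mu[c("ktop", "Lag", "kpo")]),
         min(max(stats::qlogis(model$F_po), -.logit_cap), .logit_cap))
  names(m) <- .psi_names
  m
}

## Map a Gaussian-scale vector psi to structural parameters.
.psi_to_params <- function(psi, fpo_fixed = FALSE, F_po = 1) {
  structural_params(
    Cl = exp(psi[["Cl"]]), Vc = exp(psi[["Vc"]]), Q = exp(psi[["Q"]]),
    Vp = exp(psi[["Vp"]]),
    F_top = stats::plogis(psi[["Ftop"]]),
    k_top = exp(psi[["ktop"]]), Lag = exp(psi[["Lag"]]),
    F_po = if (fpo_fixed) F_po else stats::plogis(psi[["Fpo"]]),
    k_po = exp(psi[["kpo"]]))
}

#' Individual structural parameters from population model and random effects
#'
#' Applies the link functions: log-normal parameters are
#' \code{mu * exp(eta)}, clearance additionally carries the multiplicative
#' slow-metabolizer factor \code{exp(beta_Cl_MET * MET)}, and the
#' transdermal bioavailability passes through the logit link,
#' \code{logit(F) = logit(xi) + eta}. Oral bioavailability is pinned when
#' the model fixes it.
#'
#' @param model a \code{\link{population_model}}
#' @param eta numeric vector of random effects, length 9 in the order
#'   \code{Cl, Vc, Q, Vp, Ftop, ktop, Lag, kpo, Fpo} (or named); zeros give
#'   the typical individual
#' @param MET 0 (fast metabolizer, reference) or 1 (slow)
#' @return a \code{\link{structural_params}}
#' @examples
#' m <- flunixin_population_model()
#' link_transform(m, rep(0, 9), MET = 1)$Cl  # 0.012 * exp(-0.892)
#' @export
link_transform <- function(model, eta = rep(0, 9), MET = 0) {
  if (!is.null(names(eta))) {
    e <- stats::setNames(rep(0, length(.psi_names)), .psi_names)
    e[names(eta)] <- eta
    eta <- e
  }
  if (length(eta) != length(.psi_names))
    stop("'eta' must have length ", length(.psi_names))
  if (any(!is.finite(eta))) stop("'eta' must be finite")
  psi <- .psi_typical(model, MET) + as.numeric(eta)
  names(psi) <- .psi_names
  .psi_to_params(psi, model$fpo_fixed, model$F_po)
}
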