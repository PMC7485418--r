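#' Box-Cox bodyweight sub-model
#'
#' Bodyweight (kg) is modeled on a Box-Cox transformed scale,
#' \code{(BW^lambda - 1)/lambda = BW_pop + IPV * [phase 2] + eps},
#' \code{eps ~ N(0, sigma^2)}. The phase offset captures the growth of the
#' crossover-phase piglets relative to the parallel-phase piglets.
#'
#' @param BW_pop transformed-scale population location
#' @param IPV transformed-scale inter-phase offset (added for phase 2)
#' @param sigma transformed-scale residual standard deviation
#' @param lambda Box-Cox exponent, in [-2, 2]
#' @return object of class \code{bodyweight_model}
#' @export
bodyweight_model <- function(BW_pop = 1.31, IPV = 0.89, sigma = 0.29,
                             lambda = 0.14) {
  if (sigma <= 0) stop("sigma must be positive")
  if (lambda < -2 || lambda > 2) stop("lambda must lie in [-2, 2]")
  structure(list(BW_pop = BW_pop, IPV = IPV, sigma = sigma, lambda = lambda),
            class = "bodyweight_model")
}

## Box-Cox transform and inverse (lambda = 0 handled as the log limit).
.boxcox <- function(bw, lambda) {
  if (abs(lambda) < 1e-12) log(bw) else (bw^lambda - 1) / lambda
}
.boxcox_inv <- function(y, lambda) {
  if (abs(lambda) < 1e-12) return(exp(y))
  arg <- 1 + lambda * y
  ifelse(arg > 0, arg^(1 / lambda), NA_real_)
}

#' Deterministic bodyweight at the transformed-scale mean
#'
#' Inverse Box-Cox transform of \code{BW_pop} (+ \code{IPV} for phase 2);
#' the zero-noise limit of \code{\link{sample_bodyweight}}.
#'
#' @param model a \code{\link{bodyweight_model}}
#' @param phase study phase, 1 or 2
#' @return bodyweight in kg
#' @export
typical_bodyweight <- function(model, phase = 1) {
  y <- model$BW_pop + model$IPV * (phase == 2)
  .boxcox_inv(y, model$lambda)
}

#' Draw bodyweights from the Box-Cox sub-model
#'
#' Draws transformed-scale residuals, inverts the transform, and redraws
#' the rare residuals for which the inversion argument is non-positive
#' (extreme negative tail). All returned weights are positive.
#'
#' @param model a \code{\link{bodyweight_model}}
#' @param n number of draws
#' @param phase study phase, 1 or 2
#' @return list with \code{bw} (kg vector, length n) and \code{redraws}
#'   (count of rejected residuals)
#' @export
sample_bodyweight <- function(model, n, phase = 1) {
  if (n < 1) stop("n must be at least 1")
  mu <- model$BW_pop + model$IPV * (phase == 2)
  bw <- numeric(n)
  redraws <- 0L
  left <- seq_len(n)
  while (length(left)) {
    y <- mu + stats::rnorm(length(left), 0, model$sigma)
    v <- .boxcox_inv(y, model$lambda)
    ok <- !is.na(v) & v > 0
    bw[left[ok]] <- v[ok]
    redraws <- redraws + sum(!ok)
    left <- left[!ok]
  }
  list(bw = bw, redraws = redraws)
}

#' Fit the Box-Cox bodyweight sub-model by lambda grid search
#'
#' For each lambda on the grid -2 to 2 in steps of 0.1, transforms the
#' weights, fits the location + phase-offset model by least squares, and
#' records the sum of squared errors of the geometric-mean normalized
#' transform (the normalization makes SSE comparable across lambda and is
#' equivalent to maximizing the Box-Cox profile likelihood). The reported
#' lambda minimizes a spline interpolation of SSE over the grid.
#'
#' @param weights bodyweights (kg), all positive
#' @param phase phase labels (1 or 2), same length as \code{weights}
#' @return a \code{\link{bodyweight_model}} fitted to the data, with
#'   attributes \code{sse_grid} (data frame of lambda and normalized SSE)
#'   and \code{lambda_grid_argmin}
#' @export
fit_bodyweight_boxcox <- function(weights, phase) {
  if (any(weights <= 0)) stop("bodyweights must be positive")
  if (length(weights) != length(phase)) stop("length mismatch")
  if (length(weights) < 3 || length(unique(phase)) < 2)
    stop("need at least 3 weights spanning both phases")
  grid <- seq(-2, 2, by = 0.1)
  gm <- exp(mean(log(weights)))
  ph2 <- as.numeric(phase == 2)
  sse <- vapply(grid, function(l) {
    z <- .boxcox(weights, l) / gm^(l - 1)
    sum(stats::resid(stats::lm(z ~ ph2))^2)
  }, numeric(1))
  sp <- stats::splinefun(grid, sse)
  opt <- stats::optimize(sp, c(-2, 2))
  lambda <- opt$minimum
  ## refit location/offset/scale at the selected lambda (unnormalized scale)
  z <- .boxcox(weights, lambda)
  fit <- stats::lm(z ~ ph2)
  out <- bodyweight_model(BW_pop = unname(stats::coef(fit)[1]),
                          IPV = unname(stats::coef(fit)[2]),
                          sigma = sqrt(mean(stats::resid(fit)^2)),
                          lambda = lambda)
  attr(out, "sse_grid") <- data.frame(lambda = grid, sse = sse)
  attr(out, "lambda_grid_argmin") <- grid[which.min(sse)]
  out
}
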