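#' Compartment-model rate parameters
#'
#' Rate constants of the nested one-, two- and three-tissue compartment
#' models of tracer kinetics: `k1` (mL/min, plasma-to-tissue influx), `k2`
#' (1/min, efflux), `k3`/`k4` (1/min, specific granzyme-B binding and
#' unbinding) and `k5`/`k6` (1/min, nonspecific binding and unbinding).
#' Order reductions are enforced: a one-tissue model fixes `k3`-`k6` at
#' zero and a two-tissue model fixes `k5`-`k6` at zero.
#'
#' @param order model order, 1, 2 or 3.
#' @param k1,k2,k3,k4,k5,k6 non-negative rates; rates not used by `order`
#'   must be zero.
#' @param upper upper bound applied to every rate (default 5).
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(order, k1, k2, k3 = 0, k4 = 0, k5 = 0, k6 = 0,
                           upper = 5) {
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  k <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6)
  if (any(!is.finite(k)) || any(k < 0)) stop("rates must be non-negative")
  if (any(k > upper)) stop("rates exceed the upper bound (", upper, ")")
  if (order == 1 && any(k[3:6] != 0))
    stop("one-tissue model requires k3 = k4 = k5 = k6 = 0")
  if (order == 2 && any(k[5:6] != 0))
    stop("two-tissue model requires k5 = k6 = 0")
  structure(list(order = as.integer(order), k = k), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> %dTCM: %s\n", x$order,
              paste(sprintf("%s=%.4g", names(x$k), x$k), collapse = " ")))
  invisible(x)
}

#' Number of free parameters per model order (1TCM = 2, 2TCM = 4, 3TCM = 6)
#' @param order model order, 1, 2 or 3.
#' @return integer parameter count.
#' @export
n_free_params <- function(order) c(2L, 4L, 6L)[order]

#' Forward-simulate a tissue time-activity curve
#'
#' Solves the compartment system driven by the plasma input and returns the
#' frame-averaged total tissue concentration \eqn{C_T} (average over each
#' frame's duration, not a midpoint sample) with zero initial conditions.
#'
#' `method = "analytic"` uses the exact exponential-convolution solution
#' from the eigen-decomposition of the rate matrix (all orders; the rate
#' matrices have real spectra). `method = "ode"` integrates the ordinary
#' differential equations numerically (deSolve `lsoda`, rtol 1e-8) and also
#' accepts a sampled input curve, serving as an independent numerical route.
#'
#' @param params a `kinetic_params`.
#' @param aif an `aif_params` (closed-form input), or for `method = "ode"`
#'   also a `tac` sampled input (linearly interpolated).
#' @param schedule a `frame_schedule`.
#' @param method `"analytic"` or `"ode"`.
#' @param rtol,atol ODE tolerances (ode method only).
#' @return A `tac` of frame-averaged tissue concentrations.
#' @export
forward_model <- function(params, aif, schedule,
                          method = c("analytic", "ode"),
                          rtol = 1e-8, atol = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "frame_schedule"))
  if (method == "analytic") {
    if (!inherits(aif, "aif_params"))
      stop("the analytic route needs closed-form input parameters")
    q <- frame_quadrature(schedule, t0_min = aif$t0_s / 60)
    v <- .ct_frame_avg_cpp(unname(params$k), params$order, aif_vec(aif),
                           q$t, q$w, q$frame, q$n_frames)
  } else {
    v <- ct_frames_ode(params, aif, schedule, rtol = rtol, atol = atol)
  }
  tac(schedule, as.numeric(v), roi = "tissue", unit = "Bq_mL",
      decay_corrected = TRUE, reference_time_s = 0)
}

#' Pointwise tissue concentration from the analytic solution
#'
#' @param params a `kinetic_params`.
#' @param aif an `aif_params`.
#' @param t_s times in seconds.
#' @return total tissue concentration at each time.
#' @export
ct_points <- function(params, aif, t_s) {
  stopifnot(inherits(params, "kinetic_params"), inherits(aif, "aif_params"))
  as.numeric(.ct_points_cpp(unname(params$k), params$order, aif_vec(aif),
                            t_s / 60))
}

# Numerical route: integrate the compartment ODEs plus a running integral
# of C_T, then difference the integral at frame edges to frame-average.
ct_frames_ode <- function(params, aif, schedule, rtol = 1e-8, atol = 1e-12) {
  k <- params$k
  m <- params$order
  cp_fun <- if (inherits(aif, "aif_params")) {
    function(t_min) .aif_points_cpp(aif_vec(aif), t_min)
  } else if (inherits(aif, "tac")) {
    af <- stats::approxfun(aif$schedule$mid_s / 60, aif$values, rule = 2)
    function(t_min) af(t_min)
  } else stop("aif must be aif_params or a sampled tac")
  deriv <- function(t, y, p) {
    cp <- cp_fun(t)
    c1 <- y[1]; c2 <- if (m >= 2) y[2] else 0; c3 <- if (m >= 3) y[3] else 0
    d1 <- k["k1"] * cp - (k["k2"] + k["k3"] + k["k5"]) * c1 +
      k["k4"] * c2 + k["k6"] * c3
    d <- d1
    if (m >= 2) d <- c(d, k["k3"] * c1 - k["k4"] * c2)
    if (m >= 3) d <- c(d, k["k5"] * c1 - k["k6"] * c3)
    list(c(d, sum(y[seq_len(m)])))  # last state: integral of C_T
  }
  nf <- nrow(schedule)
  edges <- c(schedule$start_s,
             schedule$start_s[nf] + schedule$duration_s[nf]) / 60
  sol <- deSolve::lsoda(y = numeric(m + 1), times = edges, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  cum <- sol[, m + 2]
  diff(cum) / (schedule$duration_s / 60)
}

#' Fit a compartment model to a tissue time-activity curve
#'
#' Bounded multi-start nonlinear least squares: rates constrained to
#' `[0, k_upper]` /min, `n_starts` Latin-hypercube starting points (fixed
#' seed) plus any caller-supplied starts (e.g. a lower-order solution when
#' fitting nested orders), Levenberg-Marquardt descent, best residual sum
#' of squares winning with ties broken by lower `k3`. Residuals are
#' unweighted by default; `weights = "frame_duration"` weights each frame
#' by the square root of its duration.
#'
#' @param tissue_tac a `tac` sharing its schedule with the input function.
#' @param aif fitted `aif_params` (t0 is frozen during tissue fitting).
#' @param order model order, 1, 2 or 3.
#' @param n_starts Latin-hypercube multi-start count.
#' @param seed RNG seed for the start design.
#' @param k_upper upper rate bound, 1/min.
#' @param weights `"uniform"` or `"frame_duration"`.
#' @param extra_starts optional list of numeric start vectors (length 2,
#'   4 or 6 matching `order`).
#' @return A `kinetic_fit`: `order`, `params`, `k` (length 6), `fitted`,
#'   `observed`, `rss`, `n`, `npar`, `aic`, `converged`.
#' @export
fit_compartment_model <- function(tissue_tac, aif, order,
                                  n_starts = 32, seed = 20260102,
                                  k_upper = 5,
                                  weights = c("uniform", "frame_duration"),
                                  extra_starts = NULL) {
  weights <- match.arg(weights)
  stopifnot(inherits(tissue_tac, "tac"), inherits(aif, "aif_params"))
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  y <- tissue_tac$values
  schedule <- tissue_tac$schedule
  npar <- n_free_params(order)
  q <- frame_quadrature(schedule, t0_min = aif$t0_s / 60)
  av <- aif_vec(aif)
  w <- if (weights == "uniform") rep(1, length(y)) else
    sqrt(schedule$duration_s / 60)

  pad6 <- function(p) c(p, numeric(6 - length(p)))
  resid_fn <- function(p) {
    v <- .ct_frame_avg_cpp(pad6(p), order, av, q$t, q$w, q$frame,
                           q$n_frames)
    (as.numeric(v) - y) * w
  }

  design <- with_seed(seed, lhs::randomLHS(n_starts, npar))
  starts <- lapply(seq_len(n_starts), function(i) design[i, ] * k_upper)
  if (!is.null(extra_starts)) {
    for (s in extra_starts) {
      if (length(s) != npar) stop("extra start of wrong length")
      starts <- c(starts, list(pmin(pmax(s, 0), k_upper)))
    }
  }

  lo <- rep(0, npar)
  up <- rep(k_upper, npar)
  # stage 1: cheap descent from every start; stage 2: polish the winner
  lm_run <- function(p0, maxiter, tol) {
    # stage-1 runs are deliberately iteration-capped; silence the
    # maxiter-reached warning
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = unname(p0), lower = lo, upper = up,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, ftol = tol, ptol = tol))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = fit$par, rss = sum(fit$fvec^2), info = fit$info)
  }
  runs <- Filter(Negate(is.null),
                 lapply(starts, lm_run, maxiter = 100, tol = 1e-10))
  if (length(runs) == 0) stop("compartment fit failed from every start")
  rss <- vapply(runs, `[[`, numeric(1), "rss")
  k3s <- vapply(runs, function(r) if (npar >= 4) r$par[3] else 0, numeric(1))
  best <- runs[[order(rss, k3s)[1]]]
  polish <- lm_run(best$par, maxiter = 400, tol = 1e-15)
  if (!is.null(polish) && polish$rss <= best$rss) best <- polish
  kfull <- pad6(best$par)
  params <- kinetic_params(order, kfull[1], kfull[2], kfull[3], kfull[4],
                           kfull[5], kfull[6], upper = k_upper)
  fitted_v <- as.numeric(.ct_frame_avg_cpp(kfull, order, av, q$t, q$w,
                                           q$frame, q$n_frames))
  rss_u <- sum((fitted_v - y)^2)  # unweighted RSS enters the AIC
  structure(list(order = as.integer(order), params = params,
                 k = setNames(kfull, paste0("k", 1:6)),
                 fitted = fitted_v, observed = y, schedule = schedule,
                 rss = rss_u, n = length(y), npar = npar,
                 aic = compute_aic(rss_u, length(y), npar),
                 converged = best$info %in% 1:3),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %dTCM  RSS=%.4g  AIC=%.2f  converged=%s\n",
              x$order, x$rss, x$aic, x$converged))
  print(x$params)
  invisible(x)
}

#' Fit several nested model orders to one curve
#'
#' Fits the requested orders in ascending order, seeding each higher-order
#' fit with the lower-order solution (padded with zeros and with a small
#' off-boundary value) in addition to its Latin-hypercube starts, so the
#' nested-optimum property RSS(3) <= RSS(2) <= RSS(1) holds by
#' construction.
#'
#' @inheritParams fit_compartment_model
#' @param orders integer vector from \{1, 2, 3\}.
#' @return Named list of `kinetic_fit`s (`"1"`, `"2"`, `"3"`).
#' @export
fit_all_orders <- function(tissue_tac, aif, orders = 1:3,
                           n_starts = 32, seed = 20260102, k_upper = 5,
                           weights = "uniform") {
  orders <- sort(unique(as.integer(orders)))
  fits <- list()
  prev <- NULL
  for (m in orders) {
    extra <- NULL
    if (!is.null(prev)) {
      pk <- prev$k[seq_len(n_free_params(prev$order))]
      pad <- n_free_params(m) - length(pk)
      if (pad > 0)
        extra <- list(c(pk, numeric(pad)), c(pk, rep(0.01, pad)))
    }
    fits[[as.character(m)]] <- fit_compartment_model(
      tissue_tac, aif, m, n_starts = n_starts, seed = seed,
      k_upper = k_upper, weights = weights, extra_starts = extra)
    prev <- fits[[as.character(m)]]
  }
  fits
}
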