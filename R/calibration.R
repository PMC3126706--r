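# Calibration fitting and rating curves: recover the carrier resistance
# surface R(V, L) from triplicate pressure-decline measurements, then invert
# it per velocity into monotone rating curves mapping measured declines back
# to filling/lysis levels.

#' Fit the carrier resistance surface to a calibration table
#'
#' Converts each observed pressure decline to a resistance via Ohm's law and
#' fits the parametric family
#' `R = R_empty + A_scale * g(L) * (1 + V^beta)`,
#' `g(L) = expm1(k_L * (L - L_knee))` above the knee, by nonlinear least
#' squares on log-resistance. The four smooth parameters are fitted by
#' Levenberg-Marquardt on a log scale (positivity enforced); the knee is
#' profiled: a coarse scan over candidate knees followed by 1-D refinement of
#' the profiled residual sum of squares.
#'
#' @param table a [generate_calibration_data()] table (columns
#'   `velocity_mps`, `level_pct`, `replicate`, `delta_p_mmHg`).
#' @param circuit a [circuit_config()] (for the tube diameter).
#' @param knee_tol absolute tolerance of the knee refinement.
#' @return the fitted [carrier_model()] with attribute `"fit"` (list with
#'   `rss`, `sigma_log`, `n`).
#' @export
fit_calibration <- function(table, circuit = default_circuit(),
                            knee_tol = 1e-9) {
  req <- c("velocity_mps", "level_pct", "delta_p_mmHg")
  if (!all(req %in% names(table)))
    stop("calibration table must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  V <- table$velocity_mps
  L <- table$level_pct / 100
  if (length(unique(V)) < 2 || length(unique(L)) < 3)
    stop("need >= 2 velocities and >= 3 levels for identifiability",
         call. = FALSE)
  q <- velocity_to_flow(V, circuit$tube_inner_diameter)
  R <- resistance_from_ohm(table$delta_p_mmHg, q)
  if (any(R <= 0)) stop("non-positive observed resistance", call. = FALSE)
  y <- log(R)

  # starting values from the data: floor from the lowest level, amplitude
  # from the largest observed excess
  r0 <- mean(R[L == min(L)])
  above <- L > min(L) + 1e-9
  a0 <- max((max(R) - r0) / (expm1(2 * (max(L) - min(L))) * 2), r0 * 1e-3)

  inner <- function(knee) {
    df <- data.frame(y = y, V = V, L = L)
    fit <- try(minpack.lm::nlsLM(
      y ~ log(exp(lre) + exp(la) *
                ifelse(L <= knee, 0, expm1(exp(lk) * (L - knee))) *
                (1 + V^exp(lb))),
      data = df,
      start = list(lre = log(r0), la = log(a0), lk = log(2), lb = log(1)),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(list(rss = Inf))
    list(rss = sum(stats::residuals(fit)^2), fit = fit)
  }

  lev <- sort(unique(L))
  hi <- lev[length(lev) - 2L]  # keep >= 3 informative levels above the knee
  cand <- unique(pmin(pmax(c(0, lev[lev < hi],
                             seq(0, hi, length.out = 9)), 0), hi))
  rss <- vapply(cand, function(k) inner(k)$rss, numeric(1))
  k_best <- cand[which.min(rss)]
  span <- max(diff(sort(cand)))
  opt <- stats::optimize(function(k) inner(k)$rss,
                         lower = max(0, k_best - span),
                         upper = min(hi, k_best + span), tol = knee_tol)
  knee <- if (opt$objective < min(rss)) opt$minimum else k_best
  best <- inner(knee)
  if (!is.finite(best$rss))
    stop("calibration fit did not converge", call. = FALSE)
  cf <- stats::coef(best$fit)
  model <- carrier_model(R_empty = exp(cf[["lre"]]), k_L = exp(cf[["lk"]]),
                         beta = exp(cf[["lb"]]), A_scale = exp(cf[["la"]]),
                         L_knee = knee)
  attr(model, "fit") <- list(rss = best$rss,
                             sigma_log = sqrt(best$rss / length(y)),
                             n = length(y))
  model
}

#' Build per-velocity rating curves
#'
#' For each velocity, tabulates the pressure decline over a dense filling
#' grid above the knee (below it the decline is flow-independent and the map
#' is not invertible) and constructs a monotone piecewise-cubic interpolant
#' of the inverse map `dP -> L`. For pulsatile flows the mean velocity should
#' be used for lookups.
#'
#' @param model a [carrier_model()].
#' @param circuit a [circuit_config()].
#' @param velocities velocities (m/s) at which to tabulate curves.
#' @param n_grid grid points per curve.
#' @return object of class `rating_curves`.
#' @export
build_rating_curves <- function(model, circuit = default_circuit(),
                                velocities = seq(0.19, 0.95, length.out = 5),
                                n_grid = 2001L) {
  stopifnot(inherits(model, "carrier_model"))
  if (any(velocities <= 0 | velocities > 0.95))
    stop("`velocities` must lie in (0, 0.95]", call. = FALSE)
  velocities <- sort(velocities)
  Lg <- seq(model$L_knee, 1, length.out = n_grid)
  curves <- lapply(velocities, function(v) {
    dp <- pressure_decline(circuit, model, Lg, rep(v, n_grid))
    if (any(diff(dp) <= 0))
      stop("non-monotone rating tabulation (degenerate model)", call. = FALSE)
    list(velocity = v, dp_range = range(dp), dp = dp,
         forward = stats::splinefun(Lg, dp, method = "monoH.FC"),
         inverse = stats::splinefun(dp, Lg, method = "monoH.FC"))
  })
  structure(list(velocities = velocities, curves = curves, model = model,
                 L_knee = model$L_knee, L_grid = Lg),
            class = "rating_curves")
}

# invert one curve with range clipping; returns list(L, flag)
.invert_one <- function(curve, dp, L_knee) {
  lo <- curve$dp_range[1]; hi <- curve$dp_range[2]
  flag <- ifelse(dp < lo, "below_range", ifelse(dp > hi, "above_range", "ok"))
  L <- curve$inverse(pmin(pmax(dp, lo), hi))
  L <- pmin(pmax(L, L_knee), 1)
  list(L = L, flag = flag)
}

#' Convert a pressure-decline series into a lysis trajectory
#'
#' Inverts each sample's decline into a filling level using the rating curve
#' at the given mean velocity; for velocities between tabulated curves, a
#' virtual curve is built by linear interpolation of the bracketing forward
#' tabulations (in decline space, which keeps the map monotone and avoids
#' end-of-range bias) and then inverted. The lysis level is
#' `1 - L(t) / L(0)`. Out-of-range declines are clipped and flagged per
#' sample.
#'
#' @param delta_p pressure declines in mmHg (vector), e.g. an error-adjusted
#'   series.
#' @param curves a [build_rating_curves()] object.
#' @param velocity mean flow velocity of the recording, m/s.
#' @return data.frame `delta_p_mmHg`, `filling`, `lysis`, `flag`.
#' @export
decline_to_lysis <- function(delta_p, curves, velocity) {
  stopifnot(inherits(curves, "rating_curves"))
  vs <- curves$velocities
  if (velocity < min(vs) || velocity > max(vs))
    stop("`velocity` outside the tabulated curve set", call. = FALSE)
  i <- findInterval(velocity, vs, rightmost.closed = TRUE)
  if (vs[i] == velocity) {
    cu <- curves$curves[[i]]
  } else {
    w <- (velocity - vs[i]) / (vs[i + 1L] - vs[i])
    dpw <- (1 - w) * curves$curves[[i]]$dp + w * curves$curves[[i + 1L]]$dp
    cu <- list(dp_range = range(dpw),
               inverse = stats::splinefun(dpw, curves$L_grid,
                                          method = "monoH.FC"))
  }
  inv <- .invert_one(cu, delta_p, curves$L_knee)
  L <- inv$L; flag <- inv$flag
  data.frame(delta_p_mmHg = delta_p, filling = L,
             lysis = 1 - L / L[1], flag = flag)
}
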