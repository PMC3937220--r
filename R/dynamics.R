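# Right-hand sides, steady states and integration of the NFL circuit models.
#
# Model equations (X = mRNA, Y = repressor monomer, D = dimer, Y2 = second
# repressor):
#   simple: dX/dt = lambda1 / (1 + (Y/k)^n) - beta1 * X
#           dY/dt = lambda2 * X - beta2 * Y
#   dimer:  repression term uses D in place of Y;
#           dD/dt = on * Y^2 - off * D, with -2*on*Y^2 + 2*off*D added to dY/dt
#   or2:    dX/dt = lambda1 / (1 + (Y/k)^n + (Y2/kb)^nb) - beta1 * X
#           (or the product of the two denominators under multiplicative logic)

# Hill repression input raised safely: Inf^n -> Inf handled by division below
hill_denominator <- function(params, rep1, rep2 = NULL) {
  d <- 1 + (rep1 / params$k)^params$n
  if (!is.null(rep2)) {
    sr <- params$second_repressor
    term2 <- (rep2 / sr$kb)^sr$nb
    d <- if (params$or_logic == "additive") d + term2 else d * (1 + term2)
  }
  d
}

#' Time derivatives of the NFL circuit models
#'
#' Evaluates the right-hand side of the chosen model variant at a state.
#' States are named vectors: \code{c(X, Y)} for \code{"simple"},
#' \code{c(X, Y, D)} for \code{"dimer"}, \code{c(X, Y, Y2)} for \code{"or2"}.
#'
#' @param state named non-negative numeric vector (see above).
#' @param params a \code{\link{circuit_params}} object.
#' @param variant one of \code{"simple"}, \code{"dimer"}, \code{"or2"}.
#' @return Named numeric vector of derivatives, same shape as \code{state}.
#' @examples
#' p <- reference_params()
#' circuit_derivs(c(X = 0, Y = 0), p)   # dX/dt = lambda1, dY/dt = 0
#' @export
circuit_derivs <- function(state, params, variant = "simple") {
  stopifnot(inherits(params, "circuit_params"))
  variant <- check_variant(params, variant)
  nm <- state_names(variant)
  if (length(state) != length(nm))
    stop("state for variant '", variant, "' must have components ",
         paste(nm, collapse = ", "))
  if (is.null(names(state)) || !all(nm %in% names(state))) names(state) <- nm
  if (any(state < 0)) stop("negative state components are not allowed")
  d <- circuit_rhs(0, state[nm], list(p = params, variant = variant))[[1]]
  names(d) <- nm
  d
}

# deSolve-style rhs; parms = list(p = circuit_params, variant = chr)
circuit_rhs <- function(t, y, parms) {
  p <- parms$p
  switch(parms$variant,
    simple = {
      X <- y[1]; Y <- y[2]
      list(c(p$lambda1 / hill_denominator(p, Y) - p$beta1 * X,
             p$lambda2 * X - p$beta2 * Y))
    },
    dimer = {
      X <- y[1]; Y <- y[2]; D <- y[3]
      on <- p$dimer$on; off <- p$dimer$off
      list(c(p$lambda1 / hill_denominator(p, D) - p$beta1 * X,
             p$lambda2 * X - p$beta2 * Y - 2 * on * Y^2 + 2 * off * D,
             on * Y^2 - off * D))
    },
    or2 = {
      X <- y[1]; Y <- y[2]; Y2 <- y[3]
      sr <- p$second_repressor
      list(c(p$lambda1 / hill_denominator(p, Y, Y2) - p$beta1 * X,
             p$lambda2 * X - p$beta2 * Y,
             sr$lambda2b * X - sr$beta2b * Y2))
    })
}

# steady repressor input as a function of mRNA X (all species slaved to X)
steady_repressor <- function(X, params, variant) {
  Y <- params$lambda2 * X / params$beta2
  switch(variant,
         simple = Y,
         dimer  = (params$dimer$on / params$dimer$off) * Y^2,
         or2    = Y)
}

#' Open- and closed-loop steady states
#'
#' The open loop (repressor absent, equivalently \code{k = Inf}) has
#' \code{open_X = lambda1/beta1} and \code{open_Y = lambda1*lambda2 /
#' (beta1*beta2)}. The closed loop is the unique positive root of
#' \code{beta1 * X * denom(X) = lambda1}, where \code{denom} is the
#' repression denominator with every repressor species slaved to \code{X};
#' it is found by bracketed root finding on \code{(0, lambda1/beta1]}.
#'
#' @inheritParams circuit_derivs
#' @param tol relative root-finding tolerance.
#' @return List with \code{open_X}, \code{open_Y}, \code{closed_X},
#'   \code{closed_Y}, plus \code{closed_D} (dimer variant) or
#'   \code{closed_Y2} (OR variant).
#' @examples
#' steady_states(reference_params())$closed_X  # ~0.044621
#' @export
steady_states <- function(params, variant = "simple", tol = 1e-12) {
  stopifnot(inherits(params, "circuit_params"))
  variant <- check_variant(params, variant)
  open_X <- params$lambda1 / params$beta1
  open_Y <- params$lambda1 * params$lambda2 / (params$beta1 * params$beta2)
  denom <- function(X) {
    r1 <- steady_repressor(X, params, variant)
    r2 <- if (variant == "or2") {
      sr <- params$second_repressor
      sr$lambda2b * X / sr$beta2b
    }
    hill_denominator(params, r1, r2)
  }
  f <- function(X) {
    d <- denom(X)
    if (!is.finite(d)) return(-params$beta1 * X)  # overwhelming repression
    params$lambda1 / d - params$beta1 * X
  }
  lo <- open_X * 1e-300
  root <- tryCatch(
    stats::uniroot(f, lower = lo, upper = open_X, tol = tol * open_X,
                   f.lower = f(lo), f.upper = f(open_X)),
    error = function(e)
      stop("closed-loop root finding failed on (", format(lo), ", ",
           format(open_X), "]: ", conditionMessage(e)))
  closed_X <- root$root
  out <- list(open_X = open_X, open_Y = open_Y,
              closed_X = closed_X,
              closed_Y = params$lambda2 * closed_X / params$beta2)
  if (variant == "dimer")
    out$closed_D <- (params$dimer$on / params$dimer$off) * out$closed_Y^2
  if (variant == "or2") {
    sr <- params$second_repressor
    out$closed_Y2 <- sr$lambda2b * closed_X / sr$beta2b
  }
  out
}

#' Integrate an NFL circuit model
#'
#' Adaptive-step, stiffness-switching integration (\code{deSolve::ode},
#' method \code{"lsoda"}) of the chosen variant. Defaults reproduce the
#' reference numerical setup: absolute and relative tolerances 1e-10 and a
#' horizon of 1000 time units. The genome-reboot initial condition is all
#' species at exactly zero (the plasmid arrives as naked ssDNA, without
#' mRNA or regulators); \code{init = "zero"} selects it, \code{init =
#' "steady"} starts at the closed-loop fixed point, or supply a numeric
#' state vector.
#'
#' @inheritParams circuit_derivs
#' @param init \code{"zero"}, \code{"steady"}, or a numeric state vector.
#' @param horizon final time (> 0).
#' @param dt output grid spacing.
#' @param atol,rtol integrator tolerances.
#' @return A \code{circuit_trajectory}: a data frame with column \code{time}
#'   and one column per species, with the parameters and variant attached as
#'   attributes. Concentrations more negative than \code{-atol} abort;
#'   values within the tolerance band below zero are clipped to 0.
#' @examples
#' tr <- simulate_circuit(reference_params(), horizon = 50)
#' max(tr$X)
#' @export
simulate_circuit <- function(params, variant = "simple", init = "zero",
                             horizon = 1000, dt = 0.05,
                             atol = 1e-10, rtol = 1e-10) {
  stopifnot(inherits(params, "circuit_params"))
  variant <- check_variant(params, variant)
  if (!is.numeric(horizon) || horizon <= 0) stop("'horizon' must be > 0")
  nm <- state_names(variant)
  y0 <- if (is.character(init)) {
    init <- match.arg(init, c("zero", "steady"))
    if (init == "zero") stats::setNames(rep(0, length(nm)), nm)
    else {
      ss <- steady_states(params, variant)
      stats::setNames(unlist(ss[paste0("closed_", nm)], use.names = FALSE), nm)
    }
  } else {
    if (length(init) != length(nm))
      stop("numeric 'init' must have components ", paste(nm, collapse = ", "))
    if (any(init < 0)) stop("negative initial concentrations are not allowed")
    stats::setNames(as.numeric(init), nm)
  }
  times <- seq(0, horizon, by = dt)
  out <- deSolve::ode(y = y0, times = times, func = circuit_rhs,
                      parms = list(p = params, variant = variant),
                      method = "lsoda", atol = atol, rtol = rtol)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failed (istate = ", attr(out, "istate")[1],
         "); consider smaller dt or looser horizon")
  m <- as.data.frame(unclass(out))
  names(m) <- c("time", nm)
  vals <- as.matrix(m[nm])
  if (any(!is.finite(vals))) stop("non-finite state encountered during integration")
  if (any(vals < -sqrt(atol)))
    stop("state dipped below -tolerance; integration unreliable")
  vals[vals < 0] <- 0
  m[nm] <- vals
  structure(m, params = params, variant = variant,
            class = c("circuit_trajectory", "data.frame"))
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat(sprintf("NFL trajectory (%s variant): %d points over t = [%g, %g]\n",
              attr(x, "variant"), nrow(x), x$time[1], x$time[nrow(x)]))
  sp <- setdiff(names(x), "time")
  for (s in sp)
    cat(sprintf("  %-2s: final %.6g, max %.6g\n", s, x[[s]][nrow(x)], max(x[[s]])))
  invisible(x)
}

#' @export
plot.circuit_trajectory <- function(x, species = "X", log = "", ...) {
  sp <- match.arg(species, setdiff(names(x), "time"))
  graphics::plot(x$time, x[[sp]], type = "l", xlab = "time", ylab = sp,
                 log = log, ...)
  invisible(x)
}

# local extrema indices of a sampled signal (strict rise, non-strict fall
# so plateaus do not multiply-count)
local_extrema <- function(x) {
  i <- 2:(length(x) - 1L)
  list(peaks   = i[x[i] >  x[i - 1] & x[i] >= x[i + 1]],
       troughs = i[x[i] <  x[i - 1] & x[i] <= x[i + 1]])
}

#' Classify a trajectory as damped or cyclostationary
#'
#' Inspects the final half of the mRNA signal. The trajectory is called
#' oscillatory (cyclostationary) when successive peak-to-trough amplitudes
#' neither decay below a fixed fraction of their predecessor
#' (\code{retention}, default 0.9) nor fall under an absolute floor
#' (\code{floor_frac}, default 1\% of the mean mRNA level over the window).
#' The period is the mean inter-peak interval.
#'
#' @param traj a \code{circuit_trajectory} (or a data frame with columns
#'   \code{time} and \code{X}).
#' @param retention minimum allowed ratio of successive amplitudes.
#' @param floor_frac amplitude floor as a fraction of mean X.
#' @param converged_tol relative width of the terminal window under which the
#'   trajectory counts as converged (no extrema needed).
#' @return List with \code{oscillatory} (logical), \code{period} (time units
#'   or \code{NA}), and \code{relative_amplitude} (mean peak-to-trough
#'   amplitude over mean X).
#' @examples
#' t <- seq(0, 60, by = 0.01)
#' sustained <- data.frame(time = t, X = 2 + sin(2 * pi * t / 5))
#' detect_cyclostationarity(sustained)$period  # ~5
#' @export
detect_cyclostationarity <- function(traj, retention = 0.9, floor_frac = 0.01,
                                     converged_tol = 1e-6) {
  if (!all(c("time", "X") %in% names(traj)))
    stop("'traj' must have columns 'time' and 'X'")
  X <- traj$X; tt <- traj$time
  keep <- tt >= tt[length(tt)] / 2
  Xh <- X[keep]; th <- tt[keep]
  mX <- mean(Xh)
  flat <- diff(range(Xh)) <= converged_tol * max(mX, .Machine$double.eps)
  ex <- local_extrema(Xh)
  none <- list(oscillatory = FALSE, period = NA_real_,
               relative_amplitude = 0)
  if (flat) return(none)
  nex <- length(ex$peaks) + length(ex$troughs)
  if (nex < 6) {
    exfull <- local_extrema(X)
    if (length(exfull$peaks) + length(exfull$troughs) < 6)
      stop("trajectory too short to classify: fewer than 6 extrema and not ",
           "converged; integrate over a longer horizon")
    return(none)  # extrema exist but all in the first half: decayed
  }
  # successive peak -> next trough amplitudes
  amp <- vapply(ex$peaks, function(p) {
    nxt <- ex$troughs[ex$troughs > p]
    if (!length(nxt)) NA_real_ else Xh[p] - Xh[nxt[1]]
  }, numeric(1))
  amp <- amp[!is.na(amp)]
  if (length(amp) < 3) return(none)
  ratios <- amp[-1] / amp[-length(amp)]
  osc <- all(amp > floor_frac * mX) && all(ratios >= retention)
  list(oscillatory = osc,
       period = if (osc) mean(diff(th[ex$peaks])) else NA_real_,
       relative_amplitude = mean(amp) / mX)
}

#' Simulate until the dynamical regime is decided
#'
#' Integrates from the genome-reboot initial condition, doubling the horizon
#' (up to \code{max_factor} times the base horizon) until the trajectory is
#' either classified cyclostationary or has converged to the fixed point.
#'
#' @inheritParams simulate_circuit
#' @param max_factor maximum horizon extension factor (doublings stop here).
#' @param converged_tol relative tolerance on the terminal window for
#'   convergence.
#' @return List with \code{trajectory}, \code{regime} (\code{"damped"},
#'   \code{"cyclostationary"} or \code{"undecided"}), \code{classification}
#'   (the \code{\link{detect_cyclostationarity}} result) and \code{horizon}.
#' @export
simulate_to_regime <- function(params, variant = "simple", horizon = 1000,
                               dt = 0.05, max_factor = 8,
                               atol = 1e-10, rtol = 1e-10,
                               converged_tol = 1e-6) {
  h <- horizon
  repeat {
    tr <- simulate_circuit(params, variant, init = "zero", horizon = h,
                           dt = dt, atol = atol, rtol = rtol)
    cl <- tryCatch(detect_cyclostationarity(tr, converged_tol = converged_tol),
                   error = function(e) NULL)
    lastq <- tr$X[tr$time >= 0.75 * h]
    ss <- steady_states(params, variant)
    conv <- diff(range(lastq)) <
      converged_tol * max(ss$closed_X, mean(lastq), .Machine$double.eps)
    if (!is.null(cl) && cl$oscillatory)
      return(list(trajectory = tr, regime = "cyclostationary",
                  classification = cl, horizon = h))
    if (conv)
      return(list(trajectory = tr, regime = "damped",
                  classification = if (is.null(cl)) list(oscillatory = FALSE,
                    period = NA_real_, relative_amplitude = 0) else cl,
                  horizon = h))
    if (h >= horizon * max_factor)
      return(list(trajectory = tr, regime = "undecided",
                  classification = cl, horizon = h))
    h <- min(h * 2, horizon * max_factor)
  }
}
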