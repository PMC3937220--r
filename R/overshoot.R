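# Feedback gain, transcriptional overshoot, and the sweeps relating the two.

#' Feedback gain of a negative feedback loop
#'
#' The gain G is the ratio between the steady-state mRNA level of the open
#' loop (repressor absent) and that of the closed loop (repressor present),
#' all other parameters equal: \code{G = open_X / closed_X}. G >= 1, grows
#' with the transcriptional/translational strength (lambda1, lambda2) and
#' shrinks with the binding constant k.
#'
#' @inheritParams circuit_derivs
#' @return The gain (dimensionless, >= 1).
#' @examples
#' feedback_gain(reference_params())  # ~224.1
#' @export
feedback_gain <- function(params, variant = "simple") {
  ss <- steady_states(params, variant)
  ss$open_X / ss$closed_X
}

# parabolic refinement of a sampled maximum through the 3 points around it
refine_peak <- function(tt, x) {
  i <- which.max(x)
  if (i == 1L || i == length(x)) return(list(t = tt[i], x = x[i]))
  y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
  den <- y1 - 2 * y2 + y3
  if (den >= 0) return(list(t = tt[i], x = x[i]))
  d <- 0.5 * (y1 - y3) / den
  h <- tt[i + 1] - tt[i]
  list(t = tt[i] + d * h, x = y2 - 0.25 * (y1 - y3) * d)
}

#' Measure the transcriptional overshoot of a reboot trajectory
#'
#' The overshoot is \code{O = Xmax / Xss}: the global maximum of the mRNA
#' signal along the relaxation from the genome-reboot initial condition,
#' divided by the closed-loop steady state. The sampled maximum is refined
#' by local parabolic interpolation. For cyclostationary trajectories, which
#' never settle, the denominator is the mean of the terminal cycle and the
#' record is flagged.
#'
#' @param traj a \code{circuit_trajectory} started from the reboot (zero)
#'   condition and integrated past its global maximum.
#' @param converged_tol relative tolerance used to decide convergence.
#' @return List with \code{O_measured}, \code{t_peak}, \code{Xmax},
#'   \code{Xss} (steady state or terminal-cycle mean), and
#'   \code{oscillatory}.
#' @export
measure_overshoot <- function(traj, converged_tol = 1e-6) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  params <- attr(traj, "params"); variant <- attr(traj, "variant")
  ss <- steady_states(params, variant)
  pk <- refine_peak(traj$time, traj$X)
  cl <- tryCatch(detect_cyclostationarity(traj, converged_tol = converged_tol),
                 error = function(e) list(oscillatory = FALSE, period = NA_real_))
  h <- traj$time[nrow(traj)]
  lastq <- traj$X[traj$time >= 0.75 * h]
  conv <- diff(range(lastq)) <
    converged_tol * max(ss$closed_X, mean(lastq), .Machine$double.eps)
  if (cl$oscillatory) {
    cyc <- traj$X[traj$time > h - cl$period]
    denom <- mean(cyc)
  } else if (conv) {
    denom <- ss$closed_X
  } else {
    stop("trajectory neither converged nor cyclostationary; ",
         "integrate over a longer horizon")
  }
  list(O_measured = pk$x / denom, t_peak = pk$t,
       Xmax = pk$x, Xss = denom, oscillatory = cl$oscillatory)
}

#' Analytic overshoot approximation
#'
#' Before repression sets in, the mRNA follows the open loop,
#' \code{X(t) = (lambda1/beta1) * (1 - exp(-beta1 t))}; dividing by the
#' closed-loop steady state gives the approximation
#' \code{O = G * (1 - exp(-beta1 * t))}, where \code{t} is the duration of
#' the repression-free phase -- operationally the time to reach the maximal
#' value of X, since for sharply nonlinear loops the peak immediately
#' follows repression onset. In the long-delay limit \code{t -> Inf} the
#' correction vanishes and \code{O -> G}.
#'
#' @inheritParams circuit_derivs
#' @param t_peak duration of the repression-free phase (time units, >= 0).
#' @param form optional replacement for the default functional form: a
#'   function \code{f(G, beta1, t)} returning the approximate overshoot.
#' @return The approximate overshoot. Values below 1 (possible at very small
#'   \code{t_peak}) carry attribute \code{below_floor = TRUE}, since a
#'   physical overshoot cannot be smaller than 1.
#' @examples
#' p <- reference_params()
#' approx_overshoot(p, t_peak = Inf)  # equals the gain
#' @export
approx_overshoot <- function(params, t_peak, variant = "simple", form = NULL) {
  if (t_peak < 0) stop("'t_peak' must be >= 0")
  G <- feedback_gain(params, variant)
  O <- if (is.null(form)) G * (1 - exp(-params$beta1 * t_peak))
       else form(G, params$beta1, t_peak)
  if (O < 1) attr(O, "below_floor") <- TRUE
  O
}

# time at which the repressor input first crosses its half-maximal constant:
# the end of the repression-free phase used for the analytic approximation.
# Falls back to the X-peak time when the input never crosses k.
repression_onset_time <- function(traj) {
  params <- attr(traj, "params"); variant <- attr(traj, "variant")
  input <- switch(variant, simple = traj$Y, dimer = traj$D, or2 = traj$Y)
  i <- which(input >= params$k)
  if (!length(i)) return(refine_peak(traj$time, traj$X)$t)
  i <- i[1]
  if (i == 1L) return(traj$time[1])
  # linear interpolation of the crossing between the bracketing grid points
  t0 <- traj$time[i - 1]; t1 <- traj$time[i]
  y0 <- input[i - 1]; y1 <- input[i]
  t0 + (params$k - y0) / (y1 - y0) * (t1 - t0)
}

#' Sweep feedback gain against measured and approximate overshoot
#'
#' Runs one reboot simulation per grid value of the varied parameter,
#' auto-extending the horizon until the regime is decided, and assembles a
#' tidy table of gain, measured overshoot, analytic approximation, peak
#' time and flags. Grid members whose simulation fails are kept with
#' \code{failed = TRUE} rather than dropped.
#'
#' @param base_params a \code{\link{circuit_params}} object.
#' @param vary which parameter to vary: \code{"k"}, \code{"lambda1"} or
#'   \code{"n"}.
#' @param grid numeric vector (length >= 2, or length 1 with \code{Inf} for
#'   the open loop) of values for the varied parameter.
#' @param variant model variant.
#' @param horizon base integration horizon (auto-extended up to 8x).
#' @param dt output grid spacing.
#' @return Data frame with columns \code{value, G, O_measured, O_approx,
#'   t_peak, Xmax, Xss, oscillatory, failed}.
#' @export
gain_overshoot_sweep <- function(base_params, vary = c("k", "lambda1", "n"),
                                 grid, variant = "simple",
                                 horizon = 200, dt = 0.02) {
  vary <- match.arg(vary)
  if (any(grid <= 0)) stop("grid values must be positive")
  if (length(grid) < 1) stop("empty grid")
  rows <- lapply(grid, function(v) {
    res <- tryCatch({
      pl <- unclass(base_params)
      pl[[vary]] <- v
      p <- circuit_params(pl$lambda1, pl$lambda2, pl$beta1, pl$beta2,
                          pl$k, pl$n, dimer = pl$dimer,
                          second_repressor = pl$second_repressor,
                          or_logic = pl$or_logic)
      G <- feedback_gain(p, variant)
      if (!is.finite(pl$k) || G <= 1 + 1e-12) {
        # open or effectively open loop: monotone saturation, no overshoot
        data.frame(value = v, G = G, O_measured = 1, O_approx = G,
                   t_peak = Inf, Xmax = p$lambda1 / p$beta1,
                   Xss = p$lambda1 / p$beta1 / G,
                   oscillatory = FALSE, failed = FALSE)
      } else {
        sim <- simulate_to_regime(p, variant, horizon = horizon, dt = dt)
        if (sim$regime == "undecided")
          stop("regime undecided at maximal horizon")
        m <- measure_overshoot(sim$trajectory)
        t_on <- repression_onset_time(sim$trajectory)
        Oa <- as.numeric(approx_overshoot(p, t_on, variant))
        data.frame(value = v, G = G, O_measured = m$O_measured,
                   O_approx = Oa, t_peak = m$t_peak, Xmax = m$Xmax,
                   Xss = m$Xss, oscillatory = m$oscillatory, failed = FALSE)
      }
    }, error = function(e) {
      data.frame(value = v, G = NA_real_, O_measured = NA_real_,
                 O_approx = NA_real_, t_peak = NA_real_, Xmax = NA_real_,
                 Xss = NA_real_, oscillatory = NA, failed = TRUE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
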