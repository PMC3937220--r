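# Population-level bookkeeping: asynchronous conjugative invasion, bulk mRNA
# fold-changes, the conversion copy-number bound, and growth/burden analysis.

#' Mating and burden parameters for an invasion simulation
#'
#' @param donor0,recipient0 initial donor and recipient counts (cells/ml).
#' @param transfer_rate effective mass-action conjugation constant, per
#'   donor-recipient pair per unit time (ml/(cells*min)). The study system
#'   reports no measured value; the default is an order-of-magnitude
#'   placeholder and should be treated as such.
#' @param mating_duration length of the surface-mating window (min).
#' @param burden_steady relative generation-time increase of established
#'   plasmid carriers over plasmid-free cells (0.17 = 17\%).
#' @param burden_first_gen multiplier on the carrier generation time for the
#'   first generation of a new transconjugant (2.5 = two and a half times
#'   the donor generation time).
#' @param base_generation plasmid-free generation time (min).
#' @param exclusion_delay time (min) after formation before a transconjugant
#'   can itself donate (surface-exclusion deployment); default 0.
#' @return An object of class \code{mating_params}.
#' @export
mating_params <- function(donor0 = 1e6, recipient0 = 1e6,
                          transfer_rate = 1e-8, mating_duration = 30,
                          burden_steady = 0.17, burden_first_gen = 2.5,
                          base_generation = 30, exclusion_delay = 0) {
  if (donor0 < 0 || recipient0 < 0) stop("cell counts must be >= 0")
  if (transfer_rate < 0) stop("'transfer_rate' must be >= 0")
  if (burden_first_gen < 1 || burden_steady < 0)
    stop("burden multipliers must be >= 1 (first generation) and >= 0 (steady)")
  if (base_generation <= 0 || mating_duration < 0)
    stop("'base_generation' must be > 0 and 'mating_duration' >= 0")
  structure(list(donor0 = donor0, recipient0 = recipient0,
                 transfer_rate = transfer_rate,
                 mating_duration = mating_duration,
                 burden_steady = burden_steady,
                 burden_first_gen = burden_first_gen,
                 base_generation = base_generation,
                 exclusion_delay = exclusion_delay),
            class = "mating_params")
}

#' Maximal fold-increase of plasmid gene copies by conversion alone
#'
#' Without growth, conjugation can at most convert every recipient into a
#' plasmid carrier, so the number of plasmid-gene copies in the population
#' can rise at most \code{(donor0 + recipient0) / donor0}-fold. For the
#' 1:1 donor/recipient mix of a standard mating this bound is exactly 2.
#'
#' @param donor0 initial donors (> 0; the plasmid source).
#' @param recipient0 initial recipients (>= 0).
#' @return The dimensionless bound.
#' @examples
#' max_copy_fold(1e6, 1e6)  # 2
#' @export
max_copy_fold <- function(donor0, recipient0) {
  if (donor0 <= 0) stop("'donor0' must be > 0: no plasmid source otherwise")
  if (recipient0 < 0) stop("'recipient0' must be >= 0")
  (donor0 + recipient0) / donor0
}

# per-cohort count growth factor between absolute times t0 < t1 for a
# transconjugant cohort formed at time s: first generation lasts
# g1 = burden_first_gen * g_carrier (measured from s), then g_carrier.
cohort_growth_factor <- function(s, t0, t1, mating, g_carrier) {
  g1 <- mating$burden_first_gen * g_carrier
  r1 <- log(2) / g1; r2 <- log(2) / g_carrier
  dur_first <- function(a, b) max(0, min(b, s + g1) - a)
  d1 <- dur_first(t0, t1)
  exp(r1 * d1 + r2 * ((t1 - t0) - d1))
}

#' Simulate asynchronous conjugative invasion of a cell population
#'
#' Discrete-time cohort model. During the mating window, new transconjugants
#' form at rate \code{transfer_rate * (donors + eligible transconjugants) *
#' recipients}; each formation step founds a cohort whose regulatory circuit
#' restarts from the genome-reboot condition (all plasmid species zero),
#' while donors and established carriers sit at the closed-loop steady
#' state. Bulk signals are cohort sums of per-cell levels normalized to the
#' plasmid-bearing population at t = 0: the autoregulated mRNA (reboot
#' kernel X(t)), a constitutive unregulated transcript (open-loop kernel),
#' and a never-transcribed region (per-plasmid copy count 1), the last two
#' serving as normalization controls. Growth (off during mating by default:
#' the protocol resuspends into fresh medium afterwards) applies per-type
#' generation times: recipients at \code{base_generation}, carriers at
#' \code{base_generation * (1 + burden_steady)}, new transconjugants at
#' \code{burden_first_gen} times the carrier generation time for their first
#' generation.
#'
#' @param mating a \code{\link{mating_params}} object.
#' @param circuit a \code{\link{circuit_params}} object for the NFL species.
#' @param variant circuit model variant.
#' @param horizon total simulated time (min).
#' @param step time step (min); cohort formation uses one cohort per step.
#' @param growth logical: apply post-mating growth to the counts.
#' @param cohort_schedule optional data frame with columns \code{formed_at}
#'   and \code{count}: an explicit conversion schedule that replaces the
#'   mass-action formation dynamics (formation times must lie on the step
#'   grid). Useful for controlled scenarios such as instantaneous full
#'   conversion or spreading a fixed number of converts over windows of
#'   different length.
#' @param atol,rtol integrator tolerances for the reboot kernel.
#' @return An object of class \code{invasion_sim}: a data frame with columns
#'   \code{time, donors, recipients, transconjugants, bulk_fold_nfl,
#'   bulk_fold_constitutive, bulk_fold_untranscribed}, with the cohort table
#'   in attribute \code{cohorts} and the reboot kernel in attribute
#'   \code{kernel}.
#' @export
simulate_invasion <- function(mating, circuit, variant = "simple",
                              horizon = 120, step = 0.5, growth = FALSE,
                              cohort_schedule = NULL, atol = 1e-10,
                              rtol = 1e-10) {
  stopifnot(inherits(mating, "mating_params"),
            inherits(circuit, "circuit_params"))
  variant <- check_variant(circuit, variant)
  times <- seq(0, horizon, by = step)
  nT <- length(times)
  ss <- steady_states(circuit, variant)
  Xss <- ss$closed_X
  # reboot kernel on the step grid: per-cell mRNA at age a since transfer
  kern_tr <- simulate_circuit(circuit, variant, init = "zero",
                              horizon = horizon, dt = step,
                              atol = atol, rtol = rtol)
  kernel <- kern_tr$X
  open_X <- circuit$lambda1 / circuit$beta1
  const_kernel <- open_X * (1 - exp(-circuit$beta1 * times))

  D <- numeric(nT); R <- numeric(nT)
  D[1] <- mating$donor0; R[1] <- mating$recipient0
  # one potential cohort per formation step (those within the mating window)
  scheduled <- !is.null(cohort_schedule)
  if (scheduled) {
    if (!all(c("formed_at", "count") %in% names(cohort_schedule)))
      stop("'cohort_schedule' needs columns formed_at and count")
    if (!all(cohort_schedule$formed_at %in% times))
      stop("scheduled formation times must lie on the step grid")
    if (sum(cohort_schedule$count) > mating$recipient0 + 1e-9)
      stop("scheduled conversions exceed the recipient pool")
    cohort_t <- cohort_schedule$formed_at
  } else {
    cohort_t <- times[times < mating$mating_duration & times < horizon]
  }
  n_coh <- length(cohort_t)
  coh_counts <- matrix(0, nrow = max(n_coh, 1L), ncol = nT)
  cn <- numeric(n_coh)
  g_free <- mating$base_generation
  g_carrier <- g_free * (1 + mating$burden_steady)
  for (i in seq_len(nT - 1L)) {
    t <- times[i]
    newly <- 0
    j <- which(cohort_t == t)
    if (length(j)) {
      if (scheduled) {
        newly <- sum(cohort_schedule$count[j])
        cn[j] <- cohort_schedule$count[j]
      } else if (mating$transfer_rate > 0 && R[i] > 0) {
        eligible <- D[i] + sum(cn[cohort_t <= t - mating$exclusion_delay])
        newly <- mating$transfer_rate * eligible * R[i] * step
        if (newly > 0.2 * R[i])
          stop("cohort formation exceeds 20% of recipients in one step; ",
               "use a smaller 'step'")
        cn[j] <- newly
      }
    }
    growD <- growR <- 1
    grow_coh <- rep(1, n_coh)
    if (growth && times[i + 1] > mating$mating_duration) {
      a <- max(t, mating$mating_duration); b <- times[i + 1]
      if (b > a) {
        growD <- 2^((b - a) / g_carrier)
        growR <- 2^((b - a) / g_free)
        grow_coh <- vapply(cohort_t, cohort_growth_factor, numeric(1),
                           t0 = a, t1 = b, mating = mating,
                           g_carrier = g_carrier)
      }
    }
    D[i + 1] <- D[i] * growD
    R[i + 1] <- (R[i] - newly) * growR
    cn <- cn * grow_coh
    if (n_coh) coh_counts[, i + 1] <- cn
  }
  Tc <- if (n_coh) colSums(coh_counts) else numeric(nT)
  N0 <- mating$donor0  # plasmid-bearing cells at t = 0
  bulk_nfl <- bulk_const <- bulk_untr <- numeric(nT)
  for (i in seq_len(nT)) {
    ages <- times[i] - cohort_t
    active <- which(ages >= 0 & coh_counts[, i] > 0)
    kidx <- match(round(ages[active] / step), round(times / step))
    coh_n <- coh_counts[active, i]
    bulk_nfl[i] <- (D[i] * Xss + sum(coh_n * kernel[kidx])) / (N0 * Xss)
    bulk_const[i] <- (D[i] * open_X + sum(coh_n * const_kernel[kidx])) /
      (N0 * open_X)
    bulk_untr[i] <- (D[i] + sum(coh_n)) / N0
  }
  out <- data.frame(time = times, donors = D, recipients = R,
                    transconjugants = Tc,
                    bulk_fold_nfl = bulk_nfl,
                    bulk_fold_constitutive = bulk_const,
                    bulk_fold_untranscribed = bulk_untr)
  structure(out,
            cohorts = data.frame(formed_at = cohort_t,
                                 count_final = if (n_coh) coh_counts[, nT]
                                               else numeric(0)),
            kernel = data.frame(age = times, X = kernel),
            mating = mating, circuit = circuit, variant = variant,
            growth = growth,
            class = c("invasion_sim", "data.frame"))
}

#' @export
print.invasion_sim <- function(x, ...) {
  cat(sprintf("Conjugative invasion: %d time points over [%g, %g] min\n",
              nrow(x), x$time[1], x$time[nrow(x)]))
  cat(sprintf("  final donors %.4g, recipients %.4g, transconjugants %.4g\n",
              x$donors[nrow(x)], x$recipients[nrow(x)],
              x$transconjugants[nrow(x)]))
  cat(sprintf("  peak bulk folds: NFL %.3g, constitutive %.3g, untranscribed %.3g\n",
              max(x$bulk_fold_nfl), max(x$bulk_fold_constitutive),
              max(x$bulk_fold_untranscribed)))
  invisible(x)
}

#' Apparent generation time from two timed counts
#'
#' Assuming exponential growth between the two samples,
#' \code{g = (t1 - t0) * log(2) / log(count1 / count0)} minutes. When the
#' count did not increase the generation time is undefined; \code{NA} is
#' returned with attribute \code{non_growing = TRUE}.
#'
#' @param count_t0,count_t1 positive cell counts at the two times.
#' @param t0,t1 sample times (min), \code{t1 > t0}.
#' @return Apparent generation time in minutes (or flagged \code{NA}).
#' @examples
#' apparent_generation_time(1e6, 2e6, 0, 30)  # 30
#' @export
apparent_generation_time <- function(count_t0, count_t1, t0, t1) {
  if (count_t0 <= 0 || count_t1 <= 0) stop("counts must be > 0")
  if (t1 <= t0) stop("'t1' must be greater than 't0'")
  if (count_t1 <= count_t0) {
    out <- NA_real_
    attr(out, "non_growing") <- TRUE
    return(out)
  }
  (t1 - t0) * log(2) / log(count_t1 / count_t0)
}

#' Summarize a timed donor/recipient/transconjugant counts table
#'
#' Computes, per sampling interval and cell type, the apparent generation
#' time from the replicate-mean counts, and per time point the proportion of
#' plasmid-bearing cells that are transconjugants, \code{Tc / (Tc + D)},
#' with a first-order (delta-method) standard error propagated from the
#' replicate scatter of the counts. The plasmid does not conjugate in
#' liquid, so every change in the proportion is attributed to growth-rate
#' differences; the returned object carries that assumption as an
#' annotation.
#'
#' @param counts data frame with columns \code{time}, \code{type} (one of
#'   \code{"D"}, \code{"R"}, \code{"Tc"}), \code{count}, \code{replicate}.
#' @return List with \code{fraction} (data frame: time, fraction, se) and
#'   \code{generation_times} (data frame: t0, t1, type, generation_minutes),
#'   plus an \code{assumption} string.
#' @export
competition_summary <- function(counts) {
  need <- c("time", "type", "count", "replicate")
  if (!all(need %in% names(counts)))
    stop("'counts' must have columns ", paste(need, collapse = ", "))
  tps <- sort(unique(counts$time))
  types <- c("D", "R", "Tc")
  for (tp in tps)
    for (ty in types)
      if (!any(counts$time == tp & counts$type == ty))
        stop("missing type '", ty, "' at time ", tp)
  agg <- stats::aggregate(count ~ time + type, counts, mean)
  vagg <- stats::aggregate(count ~ time + type, counts,
                           function(z) stats::var(z) / length(z))
  getv <- function(tab, tp, ty) tab$count[tab$time == tp & tab$type == ty]
  frac <- do.call(rbind, lapply(tps, function(tp) {
    Dm <- getv(agg, tp, "D"); Tm <- getv(agg, tp, "Tc")
    vD <- getv(vagg, tp, "D"); vT <- getv(vagg, tp, "Tc")
    tot <- Dm + Tm
    f <- if (tot > 0) Tm / tot else 0
    se <- if (tot > 0) sqrt((Dm / tot^2)^2 * vT + (Tm / tot^2)^2 * vD) else 0
    data.frame(time = tp, fraction = f, se = se)
  }))
  gt <- do.call(rbind, lapply(seq_len(length(tps) - 1L), function(i) {
    do.call(rbind, lapply(types, function(ty) {
      g <- apparent_generation_time(getv(agg, tps[i], ty),
                                    getv(agg, tps[i + 1L], ty),
                                    tps[i], tps[i + 1L])
      data.frame(t0 = tps[i], t1 = tps[i + 1L], type = ty,
                 generation_minutes = as.numeric(g))
    }))
  }))
  list(fraction = frac, generation_times = gt,
       assumption = paste("no conjugation in liquid medium: all changes in",
                          "the transconjugant fraction reflect growth-rate",
                          "differences"))
}
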