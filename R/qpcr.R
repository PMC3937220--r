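# Measurement analytics: GFP/OD promoter activity, promoter calling and
# repression folds, network topology inference, qPCR primer efficiency,
# threshold-cycle transcriptional landscape, and growth-normalized
# conjugation fold-changes with propagated errors.

#' Steady promoter activity (GFP/OD) in the exponential window
#'
#' Detects, per replicate, the contiguous span of time points whose local
#' log-OD slope stays within 90\% of its maximum (the exponential growth
#' window), and averages GFP/OD over it. At least 4 points must fall in the
#' window. Replicate means are averaged; the replicate standard deviation is
#' reported as dispersion.
#'
#' @param table data frame with columns \code{condition}, \code{time},
#'   \code{OD}, \code{GFP}, \code{replicate}.
#' @param condition which condition id to evaluate.
#' @param slope_frac fraction of the maximal local slope that still counts
#'   as exponential (default 0.9).
#' @return List with \code{activity} (mean GFP/OD), \code{sd} (across
#'   replicates), \code{n_replicates}, and \code{window} (time range used,
#'   from the first replicate).
#' @export
steady_gfp_od <- function(table, condition, slope_frac = 0.9) {
  need <- c("condition", "time", "OD", "GFP", "replicate")
  if (!all(need %in% names(table)))
    stop("'table' must have columns ", paste(need, collapse = ", "))
  d <- table[table$condition == condition, , drop = FALSE]
  if (!nrow(d)) stop("condition '", condition, "' not found")
  if (any(d$OD <= 0)) stop("OD must be > 0 wherever GFP/OD is evaluated")
  reps <- unique(d$replicate)
  win1 <- NULL
  per_rep <- vapply(reps, function(r) {
    dr <- d[d$replicate == r, , drop = FALSE]
    dr <- dr[order(dr$time), , drop = FALSE]
    if (nrow(dr) < 5) stop("need at least 5 time points per replicate")
    lo <- log(dr$OD)
    # centred local slope of log OD
    ns <- nrow(dr)
    sl <- (lo[c(2:ns, ns)] - lo[c(1, 1:(ns - 1))]) /
      (dr$time[c(2:ns, ns)] - dr$time[c(1, 1:(ns - 1))])
    smax <- max(sl)
    if (smax <= 0) stop("no exponential window detectable: OD never grows")
    ok <- sl >= slope_frac * smax
    # contiguous run containing the slope maximum
    im <- which.max(sl)
    a <- im; while (a > 1 && ok[a - 1]) a <- a - 1
    b <- im; while (b < ns && ok[b + 1]) b <- b + 1
    if (b - a + 1 < 4)
      stop("no exponential window detectable: fewer than 4 points at ",
           ">= ", slope_frac, " of the maximal log-OD slope")
    if (is.null(win1)) win1 <<- range(dr$time[a:b])
    mean(dr$GFP[a:b] / dr$OD[a:b])
  }, numeric(1))
  list(activity = mean(per_rep),
       sd = if (length(per_rep) > 1) stats::sd(per_rep) else 0,
       n_replicates = length(per_rep),
       window = win1)
}

#' Promoter call and repression fold
#'
#' A cloned fragment is called a promoter when its activity is at least
#' two-fold above the promoter-less vector background (boundary inclusive).
#' When a paired repressed activity is supplied, the repression fold is
#' \code{activity / activity_repressed}; if the repressed activity falls at
#' or below background the fold is reported as the censored lower bound
#' \code{activity / background} with \code{censored = TRUE} (the true fold
#' is at least that large).
#'
#' @param activity promoter activity alone (GFP/OD), > 0.
#' @param vector_background promoter-less vector activity, > 0.
#' @param activity_repressed optional paired activity under repression.
#' @param fold_threshold promoter-call threshold (default 2).
#' @return List with \code{is_promoter}, and (when a repressed activity is
#'   given) \code{repression_fold} and \code{censored}.
#' @examples
#' promoter_calls(2e5, 1e3, activity_repressed = 4e4)$repression_fold  # 5
#' @export
promoter_calls <- function(activity, vector_background,
                           activity_repressed = NULL, fold_threshold = 2) {
  if (vector_background <= 0) stop("'vector_background' must be > 0")
  if (activity <= 0) stop("'activity' must be > 0")
  out <- list(is_promoter = activity >= fold_threshold * vector_background)
  if (!is.null(activity_repressed)) {
    if (activity_repressed <= 0) stop("'activity_repressed' must be > 0")
    if (activity_repressed <= vector_background) {
      out$repression_fold <- activity / vector_background
      out$censored <- TRUE
    } else {
      out$repression_fold <- activity / activity_repressed
      out$censored <- FALSE
    }
  }
  out
}

#' Infer repressor-to-promoter network topology
#'
#' For every (regulator, promoter) pair with replicated activities and a
#' matched empty-vector control, an edge is called when the one-tailed
#' Welch t test (activity with regulator < control) is significant at
#' \code{alpha} and the repression fold (control mean / regulator mean) is
#' at least \code{fold_threshold}. Output is sorted by regulator then
#' promoter.
#'
#' @param activities long data frame with columns \code{regulator} (the
#'   value \code{"control"} marks empty-vector rows), \code{promoter},
#'   \code{activity}, \code{replicate}.
#' @param alpha significance level (default 0.05).
#' @param fold_threshold minimal repression fold for an edge (default 2).
#' @param p_adjust multiple-testing correction passed to
#'   \code{\link[stats]{p.adjust}}; default \code{"none"} (per-pair calls,
#'   as the per-gene star convention reports), \code{"BH"} available.
#' @return Data frame of edges: \code{regulator, promoter, repression_fold,
#'   p_value, significant}.
#' @export
infer_topology <- function(activities, alpha = 0.05, fold_threshold = 2,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  need <- c("regulator", "promoter", "activity", "replicate")
  if (!all(need %in% names(activities)))
    stop("'activities' must have columns ", paste(need, collapse = ", "))
  regs <- setdiff(unique(activities$regulator), "control")
  proms <- unique(activities$promoter)
  rows <- list()
  for (pr in proms) {
    ctrl <- activities$activity[activities$promoter == pr &
                                activities$regulator == "control"]
    if (!length(ctrl)) stop("missing empty-vector control for promoter ", pr)
    for (rg in regs) {
      act <- activities$activity[activities$promoter == pr &
                                 activities$regulator == rg]
      if (!length(act)) next
      fold <- mean(ctrl) / mean(act)
      pv <- if (length(act) > 1 && length(ctrl) > 1 &&
                (stats::sd(act) > 0 || stats::sd(ctrl) > 0)) {
        stats::t.test(act, ctrl, alternative = "less")$p.value
      } else {
        # degenerate zero-variance fixture: decide on the means alone
        if (mean(act) < mean(ctrl)) 0 else 1
      }
      rows[[length(rows) + 1L]] <-
        data.frame(regulator = rg, promoter = pr, repression_fold = fold,
                   p_value = pv)
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_value <- stats::p.adjust(tab$p_value, method = p_adjust)
  tab$significant <- tab$p_value < alpha
  edges <- tab[tab$significant & tab$repression_fold >= fold_threshold, ,
               drop = FALSE]
  edges <- edges[order(edges$regulator, edges$promoter), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Primer-pair amplification efficiency from a dilution series
#'
#' Least-squares fit of Ct against log2(template amount) over a dilution
#' series (at least 3 amounts spanning at least a 2-fold range). The
#' per-cycle amplification factor is \code{A = 2^(-1/slope)} and the
#' fractional efficiency \code{E = A - 1} (perfect doubling: slope -1 per
#' 2-fold dilution step, A = 2, E = 1). The pair passes quantification QC
#' when \code{0.9 < E < 1.2} (open interval).
#'
#' @param amounts template amounts (ng), length >= 3.
#' @param ct threshold cycles matching \code{amounts} (replicates allowed:
#'   repeat the amount).
#' @return List with \code{E}, \code{amplification_factor}, \code{slope}
#'   (per log2 amount), \code{pass}, and \code{diagnostic}.
#' @examples
#' primer_efficiency(c(2.5, 5, 10), c(16.2, 15.2, 14.2))$E  # 1
#' @export
primer_efficiency <- function(amounts, ct) {
  if (length(amounts) != length(ct)) stop("'amounts' and 'ct' lengths differ")
  if (length(unique(amounts)) < 3)
    stop("dilution series needs >= 3 distinct amounts")
  if (max(amounts) / min(amounts) < 2)
    stop("dilution series must span at least a 2-fold range")
  fit <- stats::lm(ct ~ log2(amounts))
  slope <- unname(stats::coef(fit)[2])
  ua <- sort(unique(amounts))
  means <- vapply(ua, function(a) mean(ct[amounts == a]), numeric(1))
  if (!is.finite(slope) || slope > -1e-8 || any(diff(means) >= 0))
    return(list(E = NA_real_, amplification_factor = NA_real_, slope = slope,
                pass = FALSE,
                diagnostic = "non-monotone or flat Ct over the dilution series"))
  A <- 2^(-1 / slope)
  E <- A - 1
  list(E = E, amplification_factor = A, slope = slope,
       pass = (E > 0.9 && E < 1.2), diagnostic = "ok")
}

#' Threshold-cycle transcriptional landscape
#'
#' Per-amplicon mRNA abundance index comparing cDNA threshold cycles to a
#' genomic-DNA reference (default 5 ng): \code{index = Ct_DNA - Ct_cDNA},
#' oriented so that larger means more mRNA and one unit corresponds to one
#' template doubling. Untranscribed regions sit around -8; the most active
#' regions around +2.
#'
#' @param ct data frame with columns \code{amplicon}, \code{template}
#'   (\code{"cDNA"} or \code{"DNA"}), \code{template_amount}, \code{Ct},
#'   \code{replicate}.
#' @param dna_reference_amount template amount (ng) of the DNA reference
#'   rows (default 5).
#' @return Data frame with columns \code{amplicon, index, sd, n}.
#' @export
transcriptional_landscape <- function(ct, dna_reference_amount = 5) {
  need <- c("amplicon", "template", "Ct")
  if (!all(need %in% names(ct)))
    stop("'ct' must have columns ", paste(need, collapse = ", "))
  amps <- unique(ct$amplicon)
  out <- do.call(rbind, lapply(amps, function(a) {
    cdna <- ct$Ct[ct$amplicon == a & ct$template == "cDNA"]
    dnarows <- ct$amplicon == a & ct$template == "DNA"
    if ("template_amount" %in% names(ct))
      dnarows <- dnarows & ct$template_amount == dna_reference_amount
    dna <- ct$Ct[dnarows]
    if (!length(cdna) || !length(dna))
      stop("amplicon '", a, "' lacks cDNA or DNA-reference measurements")
    nrep <- min(length(cdna), length(dna))
    idx <- mean(dna) - cdna   # per-replicate indices vs mean reference
    data.frame(amplicon = a, index = mean(dna) - mean(cdna),
               sd = if (length(cdna) > 1) stats::sd(idx) else 0,
               n = length(cdna))
  }))
  rownames(out) <- NULL
  out
}

#' Growth-normalized expression fold-changes during conjugation
#'
#' For each post-mating time point, the relative abundance of the target
#' transcript is \code{A_target^(Ct0 - Ct_t)} with the primer pair's
#' amplification factor \code{A} (default 2), normalized by the same
#' quantity for a constitutive chromosomal reference (dxs), which absorbs
#' growth of the population. The relative error follows first-order
#' propagation on the log2 scale,
#' \code{sigma/x = ln(2) * sqrt(var(Ct) + var(Ct_ref) - 2 cov(Ct, Ct_ref))},
#' with the covariance taken over paired replicates. Significance of the
#' target rising above the reference is a one-tailed Welch t test on the
#' replicate Ct drops; stars follow the convention \code{"**"} p < 0.05,
#' \code{"*"} p < 0.1.
#'
#' @param ct data frame with columns \code{amplicon}, \code{timepoint},
#'   \code{Ct}, \code{replicate} (cDNA rows; a \code{template} column, if
#'   present, is filtered to \code{"cDNA"}).
#' @param target amplicon id of the gene of interest.
#' @param reference amplicon id of the normalizer (default \code{"dxs"}).
#' @param efficiencies named vector of per-amplicon amplification factors
#'   \code{A}; missing entries default to 2.
#' @param strict_exponent use the propagation formula exactly as printed in
#'   some protocols, with the bracket raised to -2 instead of 1/2; default
#'   \code{FALSE} (square root, the dimensionally consistent first-order
#'   form).
#' @return Data frame with one row per post-baseline timepoint:
#'   \code{timepoint, fold, rel_error, p_value, stars}.
#' @export
conjugation_response <- function(ct, target, reference = "dxs",
                                 efficiencies = NULL,
                                 strict_exponent = FALSE) {
  need <- c("amplicon", "timepoint", "Ct", "replicate")
  if (!all(need %in% names(ct)))
    stop("'ct' must have columns ", paste(need, collapse = ", "))
  if ("template" %in% names(ct)) ct <- ct[ct$template == "cDNA", , drop = FALSE]
  Afor <- function(a) {
    if (!is.null(efficiencies) && a %in% names(efficiencies))
      unname(efficiencies[a]) else 2
  }
  get <- function(a, tp) {
    d <- ct[ct$amplicon == a & ct$timepoint == tp, , drop = FALSE]
    stats::setNames(d$Ct, d$replicate)
  }
  tps <- sort(unique(ct$timepoint))
  if (!(0 %in% tps)) stop("missing t = 0 baseline measurements")
  t0_t <- get(target, 0); t0_r <- get(reference, 0)
  if (!length(t0_t) || !length(t0_r))
    stop("missing t = 0 baseline for target or reference")
  out <- do.call(rbind, lapply(setdiff(tps, 0), function(tp) {
    ct_t <- get(target, tp); ct_r <- get(reference, tp)
    if (!length(ct_t) || !length(ct_r))
      stop("missing measurements at timepoint ", tp)
    # per-replicate Ct drops (abundance-increase orientation)
    drop_t <- mean(t0_t) - ct_t
    drop_r <- mean(t0_r) - ct_r
    fold <- Afor(target)^mean(drop_t) / Afor(reference)^mean(drop_r)
    common <- intersect(names(ct_t), names(ct_r))
    if (length(common) < 2)
      stop("variance formula needs >= 2 paired replicates at timepoint ", tp)
    v_t <- stats::var(ct_t[common]); v_r <- stats::var(ct_r[common])
    cv_tr <- stats::cov(ct_t[common], ct_r[common])
    bracket <- v_t + v_r - 2 * cv_tr
    rel_error <- if (strict_exponent) log(2) * bracket^(-2)
                 else log(2) * sqrt(max(bracket, 0))
    pv <- if (stats::sd(drop_t[common]) > 0 || stats::sd(drop_r[common]) > 0)
      stats::t.test(drop_t[common], drop_r[common],
                    alternative = "greater")$p.value else 1
    stars <- if (pv < 0.05) "**" else if (pv < 0.1) "*" else ""
    data.frame(timepoint = tp, fold = fold, rel_error = rel_error,
               p_value = pv, stars = stars)
  }))
  rownames(out) <- NULL
  out
}
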