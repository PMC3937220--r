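# Seeded generators for every input the pipeline consumes: GFP/OD growth
# profiles, qPCR Ct tables (with dilution series), invasion time courses
# (Ct + plate counts), and the regulator-by-promoter activity matrix with a
# known planted topology.

#' Ground-truth repression network used by the synthetic fixtures
#'
#' The planted topology mirrors a small broad-host-range plasmid backbone:
#' six repressors and fifteen promoters. Three repressors are pure
#' self-repressors (ResP, KfrA, TrwA); ArdK controls the five maintenance
#' promoters; KorA the four conjugation promoters; StbA overlaps both sets
#' plus its own promoter (with weaker folds on the conjugation promoters
#' than KorA's). The two integron promoters (Pint, Pant) are unrepressed.
#'
#' @return List with \code{regulators}, \code{promoters}, and \code{edges}
#'   (data frame \code{regulator, promoter, fold}).
#' @export
r388_network_truth <- function() {
  promoters <- c("PresP", "PkfrA", "PardC", "Porf7", "Pssb", "Porf12",
                 "Porf14", "PstbA", "PtrwA", "PtrwH", "PkorA", "PkikA",
                 "PkorB", "Pint", "Pant")
  regulators <- c("ResP", "KfrA", "ArdK", "StbA", "TrwA", "KorA")
  e <- rbind(
    data.frame(regulator = "ResP", promoter = "PresP", fold = 5),
    data.frame(regulator = "KfrA", promoter = "PkfrA", fold = 20),
    data.frame(regulator = "TrwA", promoter = "PtrwA", fold = 12),
    data.frame(regulator = "ArdK",
               promoter = c("PardC", "Porf7", "Porf12", "Porf14", "Pssb"),
               fold = c(100, 500, 150, 120, 60)),
    data.frame(regulator = "KorA",
               promoter = c("PtrwH", "PkorA", "PkikA", "PkorB"),
               fold = c(90, 40, 30, 25)),
    data.frame(regulator = "StbA",
               promoter = c("PstbA", "PardC", "Porf7", "Porf12", "Porf14",
                            "PtrwH", "PkorA", "PkikA", "PkorB"),
               fold = c(50, 20, 15, 12, 10, 10, 6, 4, 3)))
  list(regulators = regulators, promoters = promoters, edges = e)
}

#' Configuration for the synthetic-data generators
#'
#' Defaults encode the study conditions the generators emulate: replicate
#' coefficients of variation of the threshold cycle (0.12 for cDNA, 0.034
#' for genomic DNA), plate-count dilution error (cv 0.15, the middle of the
#' reported 0.1-0.2 range), a 17\% steady generation-time burden for
#' plasmid carriers with a 2.5x first-generation penalty in fresh
#' transconjugants, and a 30-minute plasmid-free generation time.
#'
#' @param seed master integer seed; fixes all randomness end to end. Each
#'   generated table derives its own stream from (seed, table name), so
#'   tables are independently reproducible.
#' @param ct_cv_cdna,ct_cv_dna replicate cv of Ct per template type.
#' @param ct_baseline_cdna,ct_baseline_dna mean threshold cycles of the two
#'   template types (cycles).
#' @param ct_shared_frac fraction of the replicate Ct variance shared across
#'   amplicons within a replicate (extraction/RT loading), in [0, 1).
#' @param count_cv lognormal cv of plate counts.
#' @param gfp_cv lognormal cv of GFP/OD replicate noise.
#' @param burden_steady,burden_first_gen,base_generation growth burden
#'   parameters (see \code{\link{mating_params}}).
#' @param network ground-truth topology, as \code{\link{r388_network_truth}}.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1,
                         ct_cv_cdna = 0.12, ct_cv_dna = 0.034,
                         ct_baseline_cdna = 19.9, ct_baseline_dna = 14.2,
                         ct_shared_frac = 0.9,
                         count_cv = 0.15, gfp_cv = 0.1,
                         burden_steady = 0.17, burden_first_gen = 2.5,
                         base_generation = 30,
                         network = r388_network_truth()) {
  if (ct_cv_cdna <= 0 || ct_cv_cdna >= 1 || ct_cv_dna <= 0 || ct_cv_dna >= 1)
    stop("Ct cv values must lie in (0, 1)")
  if (count_cv <= 0 || count_cv >= 1) stop("'count_cv' must lie in (0, 1)")
  if (ct_shared_frac < 0 || ct_shared_frac >= 1)
    stop("'ct_shared_frac' must lie in [0, 1)")
  structure(list(seed = as.integer(seed),
                 ct_cv_cdna = ct_cv_cdna, ct_cv_dna = ct_cv_dna,
                 ct_baseline_cdna = ct_baseline_cdna,
                 ct_baseline_dna = ct_baseline_dna,
                 ct_shared_frac = ct_shared_frac,
                 count_cv = count_cv, gfp_cv = gfp_cv,
                 burden_steady = burden_steady,
                 burden_first_gen = burden_first_gen,
                 base_generation = base_generation,
                 network = network),
            class = "synth_config")
}

# deterministic per-table stream: (master seed, table name) -> integer seed
table_seed <- function(config, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(config$seed) * 1000003 + h * 7919) %% 2147483629L)
}

with_table_seed <- function(config, name, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(table_seed(config, name))
  expr
}

#' Synthetic growth + GFP reporter time series
#'
#' Logistic OD growth (rate set by \code{base_generation}) with GFP
#' accumulating proportionally to the condition's promoter activity, under
#' multiplicative lognormal noise. Conditions are supplied as a named
#' vector of true GFP/OD activities; repressed conditions are expressed by
#' scaling the activity by the planted fold upstream of this call.
#'
#' @param config a \code{\link{synth_config}}.
#' @param activities named numeric vector: true GFP/OD level per condition.
#' @param n_replicates replicates per condition (default 5).
#' @param times sampling grid in minutes.
#' @param noise_cv replicate noise cv; default from \code{config$gfp_cv};
#'   set 0 for noise-free tables.
#' @return Data frame with columns \code{condition, time, OD, GFP,
#'   replicate}.
#' @export
synth_growth_gfp <- function(config, activities, n_replicates = 5,
                             times = seq(0, 600, by = 30),
                             noise_cv = config$gfp_cv) {
  stopifnot(inherits(config, "synth_config"))
  r <- log(2) / config$base_generation
  od0 <- 0.01; K <- 1.5
  od <- K / (1 + ((K - od0) / od0) * exp(-r * times))
  with_table_seed(config, "growth_gfp", {
    rows <- lapply(names(activities), function(cond) {
      a <- activities[[cond]]
      do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
        noise <- if (noise_cv > 0)
          exp(stats::rnorm(length(times), 0, sqrt(log(1 + noise_cv^2))))
        else 1
        data.frame(condition = cond, time = times, OD = od,
                   GFP = a * od * noise, replicate = rep)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Synthetic qPCR Ct table with dilution series
#'
#' For each amplicon, emits a genomic-DNA dilution series (2.5, 5 and 10 ng)
#' following the planted per-cycle amplification factor, and cDNA rows whose
#' Ct encodes the planted relative abundance:
#' \code{Ct_cDNA = Ct_DNA(5 ng) - log2(abundance)} (so an abundance of
#' 2^-8 relative to the DNA reference lands 8 cycles late, the signature of
#' an untranscribed region). Replicate noise is normal on the cycle scale
#' with sd = cv * baseline Ct per template type; a configurable fraction of
#' the variance is shared across amplicons within a replicate (extraction
#' and loading), which is what makes the covariance term of downstream
#' error propagation meaningful.
#'
#' @param config a \code{\link{synth_config}}.
#' @param abundances named numeric vector: per-amplicon mRNA abundance
#'   relative to the 5 ng DNA reference (> 0).
#' @param amplification named vector of per-cycle amplification factors per
#'   amplicon (default 2 for all).
#' @param n_replicates replicates per row group (default 3).
#' @param noise logical; FALSE for an exact, noise-free table.
#' @param table_name stream name (change to draw an independent table).
#' @return Data frame with columns \code{amplicon, template,
#'   template_amount, replicate, Ct}.
#' @export
synth_ct_table <- function(config, abundances, amplification = NULL,
                           n_replicates = 3, noise = TRUE,
                           table_name = "ct_table") {
  stopifnot(inherits(config, "synth_config"))
  if (any(abundances <= 0)) stop("abundances must be > 0")
  amps <- names(abundances)
  Afor <- function(a) {
    if (!is.null(amplification) && a %in% names(amplification))
      unname(amplification[a]) else 2
  }
  sd_cdna <- config$ct_cv_cdna * config$ct_baseline_cdna
  sd_dna  <- config$ct_cv_dna  * config$ct_baseline_dna
  shared <- sqrt(config$ct_shared_frac)
  resid  <- sqrt(1 - config$ct_shared_frac)
  with_table_seed(config, table_name, {
    # one shared draw per (replicate, template type)
    z_shared_c <- stats::rnorm(n_replicates)
    z_shared_d <- stats::rnorm(n_replicates)
    rows <- lapply(amps, function(a) {
      A <- Afor(a)
      dna_amounts <- c(2.5, 5, 10)
      dna <- do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
        mu <- config$ct_baseline_dna - log2(dna_amounts / 5) / log2(A)
        eps <- if (noise)
          sd_dna * (shared * z_shared_d[rep] +
                    resid * stats::rnorm(length(mu))) else 0
        data.frame(amplicon = a, template = "DNA",
                   template_amount = dna_amounts, replicate = rep,
                   Ct = mu + eps)
      }))
      cdna <- do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
        mu <- config$ct_baseline_dna - log2(abundances[[a]])
        eps <- if (noise)
          sd_cdna * (shared * z_shared_c[rep] + resid * stats::rnorm(1)) else 0
        data.frame(amplicon = a, template = "cDNA",
                   template_amount = NA_real_, replicate = rep,
                   Ct = mu + eps)
      }))
      rbind(dna, cdna)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Synthetic conjugation time course: qPCR table plus plate counts
#'
#' Runs the cohort invasion model (mating continuing on the surface over
#' the sampled window) for an autoregulated gene, a constitutive
#' plasmid gene and an untranscribed region, converts the bulk abundance
#' folds at 0/30/60/90/120 min into a cDNA Ct table (with the chromosomal
#' reference gene dxs riding total-population growth), and emits a
#' replicated donor/recipient/transconjugant plate-count table from a
#' separate 30-min mating followed by outgrowth, with lognormal dilution
#' noise and the burden-modified generation times.
#'
#' @param config a \code{\link{synth_config}}.
#' @param mating a \code{\link{mating_params}}; defaults derive from
#'   \code{config} burden/generation values, with a transfer rate high
#'   enough that most recipients convert within the sampled window (surface
#'   matings of efficient conjugative systems approach full conversion).
#' @param circuit a \code{\link{circuit_params}} for the autoregulated
#'   gene; the default is a minute-calibrated loop (mRNA half-life
#'   ~3.5 min, repressor removed by dilution at a 30-min generation:
#'   \code{lambda1 = 10, lambda2 = 1, beta1 = 0.2, beta2 = 0.023,
#'   k = 0.01, n = 1}), so the population burst plays out over the tens of
#'   minutes the time course samples.
#' @param variant circuit variant.
#' @param timepoints qPCR sampling times (min).
#' @param n_replicates replicates for both tables.
#' @param noise logical; FALSE for noise-free outputs.
#' @return List with \code{ct} (qPCR table: amplicon, timepoint, replicate,
#'   template, Ct), \code{counts} (time, type, count, replicate),
#'   \code{truth} (data frame of true normalized folds per gene and
#'   timepoint), and \code{invasion} (the no-growth invasion_sim behind the
#'   qPCR table).
#' @export
synth_invasion_dataset <- function(config, mating = NULL, circuit = NULL,
                                   variant = "simple",
                                   timepoints = c(0, 30, 60, 90, 120),
                                   n_replicates = 4, noise = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(circuit))
    circuit <- circuit_params(lambda1 = 10, lambda2 = 1, beta1 = 0.2,
                              beta2 = 0.023, k = 0.01, n = 1)
  if (is.null(mating))
    mating <- mating_params(transfer_rate = 3e-8,
                            burden_steady = config$burden_steady,
                            burden_first_gen = config$burden_first_gen,
                            base_generation = config$base_generation)
  # qPCR observable: mating proceeds on the plate across the whole window;
  # growth handled by dxs normalization, so the mRNA table uses the
  # no-growth bulk folds (growth cancels in target/reference ratios).
  mat_q <- mating
  mat_q$mating_duration <- max(timepoints)
  inv <- simulate_invasion(mat_q, circuit, variant,
                           horizon = max(timepoints), step = 0.5,
                           growth = FALSE)
  at <- function(col) stats::approx(inv$time, inv[[col]], xout = timepoints)$y
  fold_nfl <- at("bulk_fold_nfl")
  fold_const <- at("bulk_fold_constitutive")
  fold_untr <- at("bulk_fold_untranscribed")
  # growth of the whole population (every cell carries dxs): generation-time
  # weighted; during surface mating growth is slow -- model total growth as
  # plasmid-free-rate growth capped at 2-fold over the window
  dxs_fold <- pmin(2^( timepoints / (2 * config$base_generation)), 2)
  truth <- data.frame(timepoint = rep(timepoints, 4),
                      gene = rep(c("nfl", "const", "untr", "dxs"),
                                 each = length(timepoints)),
                      fold = c(fold_nfl, fold_const, fold_untr,
                               rep(1, length(timepoints))))
  base_ct <- c(nfl = 20, const = 19, untr = 27, dxs = 18)
  sd_cdna <- config$ct_cv_cdna * config$ct_baseline_cdna
  shared <- sqrt(config$ct_shared_frac)
  resid <- sqrt(1 - config$ct_shared_frac)
  ctab <- with_table_seed(config, "invasion_ct", {
    rows <- list()
    for (ti in seq_along(timepoints)) {
      # shared extraction noise per (timepoint, replicate)
      z_sh <- stats::rnorm(n_replicates)
      folds <- c(nfl = fold_nfl[ti], const = fold_const[ti],
                 untr = fold_untr[ti], dxs = 1)
      for (g in names(folds)) {
        abundance <- folds[[g]] * dxs_fold[ti]
        mu <- base_ct[[g]] - log2(abundance)
        eps <- if (noise)
          sd_cdna * (shared * z_sh + resid * stats::rnorm(n_replicates))
        else rep(0, n_replicates)
        rows[[length(rows) + 1L]] <-
          data.frame(amplicon = g, timepoint = timepoints[ti],
                     replicate = seq_len(n_replicates), template = "cDNA",
                     Ct = mu + eps)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
  # plate-count experiment: 30 min mating, then liquid outgrowth (no further
  # transfer), sampled every 30 min over 5 h
  inv_g <- simulate_invasion(mating, circuit, variant,
                             horizon = 300, step = 0.5, growth = TRUE)
  sample_times <- seq(30, 300, by = 30)
  sl <- sqrt(log(1 + config$count_cv^2))
  counts <- with_table_seed(config, "invasion_counts", {
    rows <- list()
    for (tp in sample_times) {
      i <- which.min(abs(inv_g$time - tp))
      truthc <- c(D = inv_g$donors[i], R = inv_g$recipients[i],
                  Tc = inv_g$transconjugants[i])
      for (ty in names(truthc)) {
        noisef <- if (noise) exp(stats::rnorm(n_replicates, 0, sl))
                  else rep(1, n_replicates)
        rows[[length(rows) + 1L]] <-
          data.frame(time = tp, type = ty,
                     count = truthc[[ty]] * noisef,
                     replicate = seq_len(n_replicates))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
  list(ct = ctab, counts = counts, truth = truth, invasion = inv)
}

#' Synthetic regulator-by-promoter activity matrix with planted topology
#'
#' Replicated GFP/OD activities for every promoter under every regulator
#' plus the empty-vector control, with repression folds planted from the
#' ground-truth network (see \code{\link{r388_network_truth}}) and
#' multiplicative lognormal replicate noise.
#'
#' @param config a \code{\link{synth_config}}.
#' @param n_replicates replicates per cell (default 5).
#' @param baseline unrepressed promoter activity (GFP/OD units).
#' @param noise_cv replicate noise cv; default \code{config$gfp_cv}; 0 for
#'   an exact fixture.
#' @param table_name stream name; vary to draw independent fixtures.
#' @return List with \code{activities} (long data frame: regulator,
#'   promoter, activity, replicate; regulator \code{"control"} rows are the
#'   empty-vector baseline) and \code{truth} (the planted edge table).
#' @export
synth_network_fixture <- function(config, n_replicates = 5, baseline = 1e5,
                                  noise_cv = config$gfp_cv,
                                  table_name = "network_fixture") {
  stopifnot(inherits(config, "synth_config"))
  net <- config$network
  with_table_seed(config, table_name, {
    rows <- list()
    for (pr in net$promoters) {
      for (rg in c("control", net$regulators)) {
        fold <- 1
        if (rg != "control") {
          hit <- net$edges$fold[net$edges$regulator == rg &
                                net$edges$promoter == pr]
          if (length(hit)) fold <- hit
        }
        mu <- baseline / fold
        noisef <- if (noise_cv > 0)
          exp(stats::rnorm(n_replicates, 0, sqrt(log(1 + noise_cv^2))))
        else rep(1, n_replicates)
        rows[[length(rows) + 1L]] <-
          data.frame(regulator = rg, promoter = pr,
                     activity = mu * noisef,
                     replicate = seq_len(n_replicates))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    list(activities = out, truth = net$edges)
  })
}
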