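test_that("generators are byte-identical under the same seed", {
  cfg <- synth_config(seed = 11)
  a1 <- synth_growth_gfp(cfg, c(p1 = 1e5, p2 = 2e4), n_replicates = 2)
  a2 <- synth_growth_gfp(cfg, c(p1 = 1e5, p2 = 2e4), n_replicates = 2)
  expect_identical(a1, a2)
  c1 <- synth_ct_table(cfg, c(g1 = 0.5, g2 = 4))
  c2 <- synth_ct_table(cfg, c(g1 = 0.5, g2 = 4))
  expect_identical(c1, c2)
  f1 <- synth_network_fixture(cfg, n_replicates = 2)
  f2 <- synth_network_fixture(cfg, n_replicates = 2)
  expect_identical(f1, f2)
  # a different seed moves the draws
  expect_false(identical(a1, synth_growth_gfp(synth_config(seed = 12),
                                              c(p1 = 1e5, p2 = 2e4),
                                              n_replicates = 2)))
})

test_that("noise-free growth tables return the planted activity exactly", {
  cfg <- synth_config(seed = 5)
  tab <- synth_growth_gfp(cfg, c(pX = 1e5), noise_cv = 0)
  out <- steady_gfp_od(tab, "pX")
  expect_equal(out$activity, 1e5)
  expect_equal(out$sd, 0)
})

test_that("planted repression folds survive the GFP/OD round trip", {
  cfg <- synth_config(seed = 21)
  tab <- synth_growth_gfp(cfg, c(alone = 1e5, repressed = 2e4),
                          n_replicates = 5)
  alone <- steady_gfp_od(tab, "alone")
  repres <- steady_gfp_od(tab, "repressed")
  pc <- promoter_calls(alone$activity, 1e3,
                       activity_repressed = repres$activity)
  # planted fold 5, allow 2 standard errors of the replicate scatter
  se <- pc$repression_fold *
    sqrt((alone$sd / alone$activity)^2 + (repres$sd / repres$activity)^2) /
    sqrt(alone$n_replicates)
  expect_lt(abs(pc$repression_fold - 5), 2 * se + 0.5)
})

test_that("noise-free Ct tables reproduce planted abundance indices exactly", {
  cfg <- synth_config(seed = 2)
  ct <- synth_ct_table(cfg, c(oriT_like = 2^-8, integron_like = 2^2,
                              flat = 1), noise = FALSE)
  out <- transcriptional_landscape(ct)
  expect_equal(out$index[out$amplicon == "oriT_like"], -8)
  expect_equal(out$index[out$amplicon == "integron_like"], 2)
  expect_equal(out$index[out$amplicon == "flat"], 0)
  expect_equal(out$sd, rep(0, 3))
})

test_that("planted amplification factors drive the efficiency filter", {
  cfg <- synth_config(seed = 2)
  ct <- synth_ct_table(cfg, c(good = 1, poor = 1),
                       amplification = c(good = 2, poor = 1.85),
                       noise = FALSE)
  dil <- ct[ct$template == "DNA", ]
  good <- primer_efficiency(dil$template_amount[dil$amplicon == "good"],
                            dil$Ct[dil$amplicon == "good"])
  poor <- primer_efficiency(dil$template_amount[dil$amplicon == "poor"],
                            dil$Ct[dil$amplicon == "poor"])
  expect_true(good$pass)
  expect_equal(good$E, 1, tolerance = 1e-9)
  expect_false(poor$pass)
  expect_equal(poor$E, 0.85, tolerance = 1e-9)
})

test_that("replicate Ct scatter matches the configured cv at large n", {
  cfg <- synth_config(seed = 31)
  ct <- synth_ct_table(cfg, c(g = 1), n_replicates = 1000)
  cdna <- ct$Ct[ct$template == "cDNA"]
  dna5 <- ct$Ct[ct$template == "DNA" & ct$template_amount == 5]
  expect_equal(stats::sd(cdna) / cfg$ct_baseline_cdna, cfg$ct_cv_cdna,
               tolerance = 0.1)
  expect_equal(stats::sd(dna5) / cfg$ct_baseline_dna, cfg$ct_cv_dna,
               tolerance = 0.1)
})

test_that("network fixture has the documented shape and planted truth", {
  cfg <- synth_config(seed = 1)
  fx <- synth_network_fixture(cfg, n_replicates = 3)
  expect_identical(length(unique(fx$activities$promoter)), 15L)
  expect_setequal(setdiff(unique(fx$activities$regulator), "control"),
                  c("ResP", "KfrA", "ArdK", "StbA", "TrwA", "KorA"))
  # integron promoters carry no repression edge
  expect_false(any(fx$truth$promoter %in% c("Pint", "Pant")))
  # every regulator represses at least its own loop
  expect_setequal(unique(fx$truth$regulator),
                  c("ResP", "KfrA", "ArdK", "StbA", "TrwA", "KorA"))
})

test_that("default-noise fixtures are recovered exactly by topology inference", {
  cfg <- synth_config(seed = 8)
  fx <- synth_network_fixture(cfg)
  edges <- infer_topology(fx$activities)
  truth <- fx$truth[order(fx$truth$regulator, fx$truth$promoter), ]
  expect_equal(edges$regulator, truth$regulator)
  expect_equal(edges$promoter, truth$promoter)
})

test_that("invasion dataset: controls bounded, burst visible, counts honest", {
  cfg <- synth_config(seed = 13)
  ds <- synth_invasion_dataset(cfg, noise = FALSE)
  tr <- ds$truth
  peak <- function(g) max(tr$fold[tr$gene == g])
  expect_lte(peak("untr"), 2)
  expect_lte(peak("const"), 2)
  expect_gt(peak("nfl"), peak("untr"))
  expect_gt(peak("nfl"), peak("const"))
  # noise-free response recovers the planted profile exactly
  r <- conjugation_response(ds$ct, "nfl")
  expect_equal(r$fold, tr$fold[tr$gene == "nfl" & tr$timepoint > 0],
               tolerance = 1e-9)
  # noise-free counts give the exact burden-modified generation times
  cs <- competition_summary(ds$counts)
  gt <- cs$generation_times
  g_carrier <- cfg$base_generation * (1 + cfg$burden_steady)
  expect_equal(gt$generation_minutes[gt$type == "Tc" & gt$t0 == 30],
               cfg$burden_first_gen * g_carrier, tolerance = 1e-6)
  expect_equal(gt$generation_minutes[gt$type == "Tc" & gt$t0 == 240],
               g_carrier, tolerance = 1e-6)
  expect_equal(gt$generation_minutes[gt$type == "D" & gt$t0 == 30],
               g_carrier, tolerance = 1e-6)
  expect_equal(gt$generation_minutes[gt$type == "R" & gt$t0 == 30],
               cfg$base_generation, tolerance = 1e-6)
})

test_that("noisy response stays within its propagated error bars", {
  cfg <- synth_config(seed = 17)
  ds <- synth_invasion_dataset(cfg)
  truth <- ds$truth
  for (g in c("nfl", "const", "untr")) {
    r <- conjugation_response(ds$ct, g)
    tv <- truth$fold[truth$gene == g & truth$timepoint > 0]
    # propagated relative error ~ log-scale sd, pooled across the profile
    pooled <- sqrt(mean(r$rel_error^2))
    expect_true(all(abs(log(r$fold / tv)) <= 2 * pooled + 1e-9))
  }
})
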