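make_growth_table <- function(activity, times = seq(0, 300, by = 30),
                              reps = 2, noise = 0) {
  od <- 0.01 * 2^(times / 30)        # clean exponential
  do.call(rbind, lapply(seq_len(reps), function(r)
    data.frame(condition = "c1", time = times, OD = od,
               GFP = activity * od * (1 + noise), replicate = r)))
}

test_that("steady GFP/OD recovers a constant activity on clean growth", {
  tab <- make_growth_table(5000)
  out <- steady_gfp_od(tab, "c1")
  expect_equal(out$activity, 5000)
  expect_equal(out$sd, 0)            # identical replicates: zero dispersion
  expect_equal(out$n_replicates, 2)
})

test_that("zero fluorescence gives zero activity and flat OD is rejected", {
  tab <- make_growth_table(0)
  expect_equal(steady_gfp_od(tab, "c1")$activity, 0)
  flat <- data.frame(condition = "c1", time = seq(0, 120, 30), OD = 0.5,
                     GFP = 1, replicate = 1)
  expect_error(steady_gfp_od(flat, "c1"), "exponential window")
  expect_error(steady_gfp_od(tab, "nope"), "not found")
})

test_that("promoter calls use an inclusive two-fold boundary and censoring", {
  bg <- 1e3
  expect_true(promoter_calls(2 * bg, bg)$is_promoter)
  expect_false(promoter_calls(1.99 * bg, bg)$is_promoter)
  pc <- promoter_calls(5e4, bg, activity_repressed = 1e4)
  expect_equal(pc$repression_fold, 5)
  expect_false(pc$censored)
  # repressed signal at background: only a lower bound can be reported
  pc2 <- promoter_calls(6e5, bg, activity_repressed = 0.8 * bg)
  expect_equal(pc2$repression_fold, 600)
  expect_true(pc2$censored)
  expect_error(promoter_calls(-1, bg), "activity")
})

test_that("topology inference is exact on a noise-free fixture and silent on nulls", {
  cfg <- synth_config(seed = 3)
  fx <- synth_network_fixture(cfg, noise_cv = 0)
  edges <- infer_topology(fx$activities)
  truth <- fx$truth[order(fx$truth$regulator, fx$truth$promoter), ]
  expect_equal(edges$regulator, truth$regulator)
  expect_equal(edges$promoter, truth$promoter)
  expect_equal(edges$repression_fold, truth$fold, tolerance = 1e-9)
  # no regulator affects anything: empty edge list
  null_act <- fx$activities
  null_act$activity <- 1e5
  expect_identical(nrow(infer_topology(null_act)), 0L)
  expect_error(infer_topology(null_act[null_act$regulator != "control", ]),
               "control")
})

test_that("primer efficiency recovers planted amplification factors", {
  out <- primer_efficiency(c(2.5, 5, 10), c(16.2, 15.2, 14.2))
  expect_equal(out$E, 1)
  expect_equal(out$amplification_factor, 2)
  expect_true(out$pass)
  # planted per-cycle factor 1.85 sits below the QC window
  A <- 1.85
  ct <- 20 - log2(c(2.5, 5, 10) / 5) / log2(A)
  out2 <- primer_efficiency(c(2.5, 5, 10), ct)
  expect_equal(out2$E, 0.85, tolerance = 1e-9)
  expect_false(out2$pass)
  # scale invariance of the estimator
  out3 <- primer_efficiency(10 * c(2.5, 5, 10), ct)
  expect_equal(out3$E, out2$E, tolerance = 1e-12)
  # degenerate series
  bad <- primer_efficiency(c(2.5, 5, 10), c(15, 15, 15))
  expect_false(bad$pass)
  expect_true(is.na(bad$E))
  expect_error(primer_efficiency(c(5, 5, 5), c(1, 2, 3)), "distinct")
})

test_that("landscape index is abundance-oriented with one unit per doubling", {
  ct <- rbind(
    data.frame(amplicon = "a_silent", template = "cDNA",
               template_amount = NA, replicate = 1:2, Ct = 22.2),
    data.frame(amplicon = "a_silent", template = "DNA",
               template_amount = 5, replicate = 1:2, Ct = 14.2),
    data.frame(amplicon = "b_hot", template = "cDNA",
               template_amount = NA, replicate = 1:2, Ct = 12.2),
    data.frame(amplicon = "b_hot", template = "DNA",
               template_amount = 5, replicate = 1:2, Ct = 14.2),
    data.frame(amplicon = "c_even", template = "cDNA",
               template_amount = NA, replicate = 1:2, Ct = 14.2),
    data.frame(amplicon = "c_even", template = "DNA",
               template_amount = 5, replicate = 1:2, Ct = 14.2))
  out <- transcriptional_landscape(ct)
  expect_equal(out$index[out$amplicon == "a_silent"], -8)  # untranscribed
  expect_equal(out$index[out$amplicon == "b_hot"], 2)      # hottest region
  expect_equal(out$index[out$amplicon == "c_even"], 0)
  expect_error(transcriptional_landscape(ct[ct$template == "cDNA", ]),
               "lacks")
})

test_that("conjugation response normalizes Ct drops by the reference gene", {
  mk <- function(amp, tp, ct) data.frame(amplicon = amp, timepoint = tp,
                                         replicate = 1:3, Ct = ct)
  # no movement anywhere: fold 1, no stars
  flat <- rbind(mk("g", 0, 20), mk("g", 30, 20),
                mk("dxs", 0, 18), mk("dxs", 30, 18))
  r <- conjugation_response(flat, "g")
  expect_equal(r$fold, 1)
  expect_identical(r$stars, "")
  expect_equal(r$rel_error, 0)
  # target drops one cycle more than the reference: two-fold induction
  ind <- rbind(mk("g", 0, 20), mk("g", 30, 18),
               mk("dxs", 0, 18), mk("dxs", 30, 17))
  expect_equal(conjugation_response(ind, "g")$fold, 2)
  # efficiency-corrected base
  r17 <- conjugation_response(ind, "g",
                              efficiencies = c(g = 1.7, dxs = 2))
  expect_equal(r17$fold, 1.7^2 / 2)
  expect_error(conjugation_response(ind[ind$timepoint != 0, ], "g"),
               "baseline")
})

test_that("error propagation uses the paired-replicate covariance", {
  set.seed(9)
  shared <- rnorm(6, 0, 1)
  mk <- function(amp, tp, ct) data.frame(amplicon = amp, timepoint = tp,
                                         replicate = 1:6, Ct = ct)
  tab <- rbind(mk("g", 0, 20), mk("g", 30, 18 + shared),
               mk("dxs", 0, 18), mk("dxs", 30, 17 + shared))
  r <- conjugation_response(tab, "g")
  # identical shared noise cancels exactly in the covariance term
  expect_equal(r$rel_error, 0, tolerance = 1e-9)
  # independent noise adds in quadrature
  tab2 <- rbind(mk("g", 0, 20), mk("g", 30, 18 + shared),
                mk("dxs", 0, 18), mk("dxs", 30, 17 + rev(shared)))
  r2 <- conjugation_response(tab2, "g")
  v <- var(shared); cv <- cov(shared, rev(shared))
  expect_equal(r2$rel_error, log(2) * sqrt(2 * v - 2 * cv), tolerance = 1e-9)
})

test_that("significance stars follow the p < 0.1 / p < 0.05 coding", {
  set.seed(4)
  mk <- function(amp, tp, ct) data.frame(amplicon = amp, timepoint = tp,
                                         replicate = seq_along(ct), Ct = ct)
  eps <- rnorm(4, 0, 0.05)
  strong <- rbind(mk("g", 0, rep(20, 4)), mk("g", 30, 17 + eps),
                  mk("dxs", 0, rep(18, 4)), mk("dxs", 30, rep(18, 4) + eps))
  expect_identical(conjugation_response(strong, "g")$stars, "**")
  null <- rbind(mk("g", 0, rep(20, 4)), mk("g", 30, 20 + eps),
                mk("dxs", 0, rep(18, 4)), mk("dxs", 30, 18 + eps))
  expect_identical(conjugation_response(null, "g")$stars, "")
})
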