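test_that("conversion bound is pure bookkeeping on the initial mix", {
  expect_equal(max_copy_fold(1e6, 1e6), 2)
  expect_equal(max_copy_fold(5, 0), 1)
  expect_equal(max_copy_fold(1, 3), 4)
  expect_error(max_copy_fold(0, 10), "plasmid source")
})

test_that("no transfer leaves bulk signals flat at the donor steady state", {
  p <- reference_params()
  mt <- mating_params(transfer_rate = 0)
  inv <- simulate_invasion(mt, p, horizon = 30, step = 0.5)
  expect_equal(max(abs(inv$bulk_fold_nfl - 1)), 0)
  expect_equal(max(abs(inv$bulk_fold_untranscribed - 1)), 0)
  expect_equal(inv$transconjugants[nrow(inv)], 0)
})

test_that("instantaneous full conversion reduces to the single-cell kernel", {
  p <- reference_params()
  mt <- mating_params(donor0 = 1, recipient0 = 1e6, transfer_rate = 0)
  inv <- simulate_invasion(mt, p, horizon = 30, step = 0.1,
                           cohort_schedule = data.frame(formed_at = 0,
                                                        count = 1e6))
  tr <- simulate_circuit(p, horizon = 30, dt = 0.1)
  Xss <- steady_states(p)$closed_X
  # bulk - donor term is the normalized single-cell trajectory times the
  # converted-to-donor ratio
  expect_equal(inv$bulk_fold_nfl[-1], 1 + 1e6 * (tr$X[-1] / Xss),
               tolerance = 1e-9)
})

test_that("untranscribed control species never exceeds the conversion bound", {
  p <- reference_params()
  for (rate in c(1e-8, 5e-8, 2e-7)) {
    mt <- mating_params(transfer_rate = rate, mating_duration = 30)
    inv <- simulate_invasion(mt, p, horizon = 60, step = 0.2)
    expect_lte(max(inv$bulk_fold_untranscribed),
               max_copy_fold(mt$donor0, mt$recipient0) + 1e-9)
  }
})

test_that("bulk signal equals an independent per-cohort integration", {
  p <- reference_params()
  mt <- mating_params(transfer_rate = 5e-8, mating_duration = 5)
  inv <- simulate_invasion(mt, p, horizon = 15, step = 1)
  coh <- attr(inv, "cohorts")
  Xss <- steady_states(p)$closed_X
  oracle <- vapply(inv$time, function(t) {
    s <- 0
    for (j in seq_len(nrow(coh))) {
      if (t > coh$formed_at[j] && coh$count_final[j] > 0) {
        trj <- simulate_circuit(p, horizon = t - coh$formed_at[j],
                                dt = t - coh$formed_at[j])
        s <- s + coh$count_final[j] * trj$X[nrow(trj)]
      }
    }
    (mt$donor0 * Xss + s) / (mt$donor0 * Xss)
  }, numeric(1))
  expect_equal(inv$bulk_fold_nfl, oracle, tolerance = 1e-6)
})

test_that("spreading a fixed number of converts damps the bulk peak", {
  p <- reference_params()
  total <- 1e6
  peaks <- vapply(c(1, 5, 20), function(w) {
    sched <- data.frame(formed_at = seq(0, w - 0.5, by = 0.5),
                        count = total / (2 * w))
    mt <- mating_params(donor0 = 1e6, recipient0 = total, transfer_rate = 0)
    inv <- simulate_invasion(mt, p, horizon = 40, step = 0.5,
                             cohort_schedule = sched)
    max(inv$bulk_fold_nfl)
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("too-coarse cohort formation steps are refused", {
  p <- reference_params()
  mt <- mating_params(transfer_rate = 1e-6, mating_duration = 30)
  expect_error(simulate_invasion(mt, p, horizon = 30, step = 1),
               "smaller 'step'")
})

test_that("apparent generation time inverts exponential growth", {
  expect_equal(apparent_generation_time(1e6, 2e6, 0, 30), 30)
  expect_equal(apparent_generation_time(1e6, 8e6, 0, 90), 30)
  g <- apparent_generation_time(1e6, 1e6, 0, 30)
  expect_true(is.na(g) && isTRUE(attr(g, "non_growing")))
  expect_error(apparent_generation_time(0, 1e6, 0, 30), "counts")
  expect_error(apparent_generation_time(1e6, 2e6, 30, 30), "t1")
})

test_that("competition summary reports fractions, errors and growth rates", {
  mk <- function(tp, D, R, Tc)
    data.frame(time = rep(tp, 3), type = c("D", "R", "Tc"),
               count = c(D, R, Tc), replicate = 1)
  # constant equal donors and transconjugants: fraction pinned at one half
  counts <- do.call(rbind, lapply(c(0, 30, 60), mk, D = 1e6, R = 1e6,
                                  Tc = 1e6))
  counts <- rbind(counts, transform(counts, replicate = 2))
  cs <- competition_summary(counts)
  expect_equal(cs$fraction$fraction, rep(0.5, 3))
  expect_equal(cs$fraction$se, rep(0, 3))
  # zero transconjugants: fraction identically zero
  counts0 <- do.call(rbind, lapply(c(0, 30), mk, D = 1e6, R = 1e6, Tc = NA))
  counts0$count[counts0$type == "Tc"] <- 1e-12
  expect_error(competition_summary(counts0[counts0$type != "Tc", ]),
               "missing type")
  # slower-growing transconjugants dip, then recover
  tps <- c(0, 30, 60, 90)
  D <- 1e6 * 2^(tps / 30)
  Tc <- 1e6 * c(1, 1.2, 1.5, 4)   # lags, then catches up
  counts2 <- do.call(rbind, Map(mk, tps, D, 1e6, Tc))
  counts2 <- rbind(counts2, transform(counts2, replicate = 2))
  cs2 <- competition_summary(counts2)
  f <- cs2$fraction$fraction
  expect_lt(min(f[-1]), f[1])           # dip below the initial fraction
  expect_gt(f[4], f[3])                 # recovery
  gt <- cs2$generation_times
  expect_equal(gt$generation_minutes[gt$type == "D"], rep(30, 3))
})
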