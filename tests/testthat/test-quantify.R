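gauss_trace <- function(times, apex, sigma, amplitude, baseline = 0) {
  amplitude * exp(-(times - apex)^2 / (2 * sigma^2)) + baseline
}

test_that("detect_peak finds the apex of a clean Gaussian and rejects flat traces", {
  t <- seq(240, 360, by = 2)
  pk <- detect_peak(t, gauss_trace(t, 300, 5, 100))
  expect_lte(abs(pk$apex_rt - 300), 2)
  expect_true(pk$left_rt < pk$apex_rt && pk$apex_rt < pk$right_rt)
  # boundaries near the 5%-of-apex crossing (2.45 sigma), capped at 4 sigma
  expect_lte(pk$right_rt - pk$apex_rt, 4 * pk$sigma_est + 2)
  expect_gte(pk$right_rt - pk$apex_rt, 2 * 5 - 2)
  # two peaks: apex at the larger
  two <- gauss_trace(t, 260, 5, 10) + gauss_trace(t, 320, 5, 100)
  expect_lte(abs(detect_peak(t, two)$apex_rt - 320), 2)
  expect_null(detect_peak(t, rep(0, length(t))))
  expect_null(detect_peak(t, rep(7, length(t))))
  expect_error(detect_peak(1:4, c(0, 1, 0, 0)), "time points")
})

test_that("integrate_transition reproduces rectangle and Gaussian areas and is linear", {
  t <- seq(0, 100, by = 0.1)
  rect <- ifelse(t >= 40 & t <= 60, 5, 0)
  expect_equal(integrate_transition(t, rect, 40, 60), 5 * 20,
               tolerance = 0.005)
  g <- gauss_trace(t, 50, 4, 30)
  expect_equal(integrate_transition(t, g, 50 - 16, 50 + 16),
               30 * 4 * sqrt(2 * pi), tolerance = 0.01)
  expect_equal(integrate_transition(t, 2 * g, 34, 66),
               2 * integrate_transition(t, g, 34, 66))
  expect_equal(integrate_transition(t, g, 10, 10.05), 0)  # empty window
  # baseline subtraction removes a constant offset
  expect_equal(integrate_transition(t, g + 3, 34, 66, baseline = 3),
               integrate_transition(t, g, 34, 66), tolerance = 1e-9)
})

test_that("dotp is the normalized cosine with the documented edge cases", {
  expect_equal(compute_dotp(c(0.6, 0.8), c(0.6, 0.8)), 1)
  expect_equal(compute_dotp(c(1, 0), c(0, 1)), 0)
  expect_equal(compute_dotp(c(4, 3), c(3, 4)), 0.96)
  expect_equal(compute_dotp(c(0, 0), c(1, 2)), 0)
  expect_error(compute_dotp(c(1, 2), c(0, 0)), "non-zero")
  # scale invariance in both arguments, and self-similarity of 1
  set.seed(9)
  for (i in 1:10) {
    v <- runif(5); w <- runif(5)
    expect_equal(compute_dotp(3.7 * v, w), compute_dotp(v, w))
    expect_equal(compute_dotp(v, 0.2 * w), compute_dotp(v, w))
    expect_equal(compute_dotp(v, v), 1)
  }
})

test_that("co-elution is an inclusive max-pairwise-difference test", {
  expect_true(check_coelution(c(300, 300, 300), 5))
  expect_false(check_coelution(c(300, 300, 350), 5))
  expect_true(check_coelution(c(300, 302, 305), 5))  # boundary, inclusive
  expect_false(check_coelution(c(300, NA), 5))       # one apex is not enough
  expect_true(check_coelution(c(300, NA, 301), 5))
})

test_that("noiseless quantification recovers every ratio within 1% across the dynamic range", {
  cfg <- sim_config(n_proteins = 25, noise_relative_sd = 0,
                    interference_fraction = 0, seed = 21)
  ex <- quick_experiment(cfg)
  q <- quantify_run(ex$chromatograms, ex$library)
  truth <- merge(ex$truth$peptides, ex$truth$proteins)
  m <- merge(q, truth)
  expect_equal(nrow(m), nrow(q))
  rel_err <- abs(m$ratio / 2^m$true_log2_ratio - 1)
  expect_lt(max(rel_err), 0.01)
  expect_true(all(q$dotp_light >= 0.99 & q$dotp_heavy >= 0.99))
  expect_true(all(q$passed_filters))
  expect_true(all(q$failure_reason == "none"))
})

test_that("swapping channel labels inverts the ratio exactly", {
  cfg <- quick_config(noise_relative_sd = 0, interference_fraction = 0)
  ex <- quick_experiment(cfg)
  swapped <- ex$chromatograms
  swapped$channel <- ifelse(swapped$channel == "light", "heavy", "light")
  q1 <- quantify_run(ex$chromatograms, ex$library)
  q2 <- quantify_run(swapped, ex$library)
  m <- merge(q1, q2, by = "peptide_sequence")
  expect_equal(m$ratio.x * m$ratio.y, rep(1, nrow(m)), tolerance = 1e-9)
})

test_that("interference-corrupted peptides fail the gates and clean peptides pass", {
  cfg <- sim_config(n_proteins = 40, interference_fraction = 0.25, seed = 31)
  ex <- quick_experiment(cfg)
  intf <- inject_interference(ex$chromatograms, cfg)
  q <- quantify_run(intf$chromatograms, ex$library)
  corrupted <- q$peptide_sequence %in% intf$corrupted
  expect_gt(sum(corrupted), 10)
  expect_gte(mean(!q$passed_filters[corrupted]), 0.95)
  expect_gte(mean(q$passed_filters[!corrupted]), 0.99)
  expect_true(all(q$failure_reason[corrupted & !q$passed_filters] %in%
                    c("low_dotp", "no_coelution")))
})

test_that("a silent channel yields a missing_channel failure with undefined ratio", {
  cfg <- quick_config(noise_relative_sd = 0, interference_fraction = 0)
  ex <- quick_experiment(cfg)
  pep <- ex$chromatograms$peptide_sequence[1]
  chrom <- ex$chromatograms[ex$chromatograms$peptide_sequence == pep, ]
  chrom$intensity[chrom$channel == "heavy"] <- 0
  entry <- Filter(function(e) e$peptide_sequence == pep,
                  library_entries(ex$library))[[1]]
  q <- quantify_peptide(chrom, entry)
  expect_false(q$passed_filters)
  expect_equal(q$failure_reason, "missing_channel")
  expect_true(is.na(q$ratio))
})
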