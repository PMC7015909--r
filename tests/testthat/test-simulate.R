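test_that("simulation is deterministic under a fixed seed", {
  cfg <- quick_config()
  a <- quick_experiment(cfg)
  b <- quick_experiment(cfg)
  expect_identical(a$chromatograms, b$chromatograms)
  expect_identical(a$truth, b$truth)
})

test_that("noiseless chromatograms realize the true heavy/light ratio by construction", {
  cfg <- quick_config(noise_relative_sd = 0, baseline_level = 0,
                      interference_fraction = 0)
  ex <- quick_experiment(cfg)
  ch <- ex$chromatograms
  truth <- merge(ex$truth$peptides, ex$truth$proteins)
  for (pep in truth$peptide_sequence[1:5]) {
    sums <- tapply(ch$intensity[ch$peptide_sequence == pep],
                   ch$channel[ch$peptide_sequence == pep], sum)
    true_r <- 2^truth$true_log2_ratio[truth$peptide_sequence == pep]
    expect_equal(unname(sums["heavy"] / sums["light"]), true_r,
                 tolerance = 1e-9)
  }
})

test_that("forward and reverse designs realize reciprocal heavy/light ratios", {
  cfg <- quick_config(noise_relative_sd = 0, baseline_level = 0)
  lib <- generate_library(cfg)
  truth <- generate_ground_truth(lib, cfg)
  fwd <- simulate_experiment(lib, truth, "forward", cfg)
  rev_ <- simulate_experiment(lib, truth, "reverse", cfg)
  for (pep in unique(lib$peptide_sequence)) {
    rf <- with(fwd[fwd$peptide_sequence == pep, ],
               sum(intensity[channel == "heavy"]) /
                 sum(intensity[channel == "light"]))
    rr <- with(rev_[rev_$peptide_sequence == pep, ],
               sum(intensity[channel == "heavy"]) /
                 sum(intensity[channel == "light"]))
    expect_equal(rf * rr, 1, tolerance = 1e-9)
  }
})

test_that("transition peak areas follow the closed-form Gaussian integral", {
  cfg <- quick_config(noise_relative_sd = 0, baseline_level = 0,
                      cycle_time = 0.5)
  ex <- quick_experiment(cfg)
  ch <- ex$chromatograms
  pep <- ex$truth$peptides$peptide_sequence[1]
  entry <- library_entries(ex$library)[[
    which(vapply(library_entries(ex$library),
                 function(e) e$peptide_sequence == pep, logical(1)))]]
  sub <- ch[ch$peptide_sequence == pep & ch$channel == "light", ]
  frac <- entry$transitions$library_relative_intensity
  frac <- frac / sum(frac)
  truth <- merge(ex$truth$peptides, ex$truth$proteins)
  row <- truth[truth$peptide_sequence == pep, ]
  hl <- 2^row$true_log2_ratio
  light_amp <- row$abundance / (1 + hl)
  for (j in seq_along(frac)) {
    tr <- sub[sub$fragment == entry$transitions$fragment[j], ]
    area <- oracle_trapz(tr$rt_sec, tr$intensity)
    expect_equal(area, light_amp * frac[j] * cfg$peak_sigma * sqrt(2 * pi),
                 tolerance = 0.01)
  }
})

test_that("abundances span the configured dynamic range", {
  cfg <- sim_config(n_proteins = 60, seed = 5)
  lib <- generate_library(cfg)
  truth <- generate_ground_truth(lib, cfg)
  span <- log10(max(truth$peptides$abundance) / min(truth$peptides$abundance))
  expect_gte(span, cfg$abundance_log10_range - 0.5)
  expect_lte(span, cfg$abundance_log10_range)
})

test_that("ground truth shares one ratio per protein and covers all peptides", {
  cfg <- quick_config()
  lib <- generate_library(cfg)
  truth <- generate_ground_truth(lib, cfg)
  expect_setequal(truth$peptides$peptide_sequence,
                  unique(lib$peptide_sequence))
  expect_equal(nrow(truth$proteins), length(unique(lib$protein_id)))
  # dropping a peptide from the truth is rejected by name
  truncated <- truth
  dropped <- truncated$peptides$peptide_sequence[1]
  truncated$peptides <- truncated$peptides[-1, ]
  expect_error(simulate_experiment(lib, truncated, "forward", cfg), dropped)
})

test_that("interference injection is seed-deterministic and a zero fraction is a no-op", {
  cfg0 <- quick_config(interference_fraction = 0)
  ex <- quick_experiment(cfg0)
  out0 <- inject_interference(ex$chromatograms, cfg0)
  expect_identical(out0$chromatograms, ex$chromatograms)
  expect_length(out0$corrupted, 0)

  cfg <- quick_config(interference_fraction = 0.3)
  ex <- quick_experiment(cfg)
  a <- inject_interference(ex$chromatograms, cfg)
  b <- inject_interference(ex$chromatograms, cfg)
  expect_identical(a, b)
  n_pep <- length(unique(ex$chromatograms$peptide_sequence))
  expect_equal(length(a$corrupted), round(0.3 * n_pep))
  # corrupted peptides gained intensity, clean ones untouched
  changed <- tapply(
    abs(a$chromatograms$intensity - ex$chromatograms$intensity),
    a$chromatograms$peptide_sequence, sum)
  expect_setequal(names(changed)[changed > 0], a$corrupted)
})
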