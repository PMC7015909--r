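fake_quant <- function(peptides, ratios, protein = "KIN001", passed = TRUE) {
  data.frame(peptide_sequence = peptides, protein_id = protein,
             kinase_class = "protein", ratio = ratios,
             passed_filters = passed, stringsAsFactors = FALSE)
}

test_that("orientation maps measured heavy/light ratios onto metastatic/primary", {
  q <- fake_quant(c("AAK", "CCK", "DDK"), c(2, 0.5, 1))
  f <- orient_ratios(q, "forward")
  expect_equal(f$oriented_log2, c(1, -1, 0))
  r <- orient_ratios(q, "reverse")
  expect_equal(r$oriented_log2, c(-1, 1, 0))
  expect_error(orient_ratios(q, "sideways"), "design")
  # failed peptides are excluded
  q$passed_filters[2] <- FALSE
  expect_equal(nrow(orient_ratios(q, "forward")), 2)
})

test_that("orientation is an involution under a double label swap", {
  set.seed(12)
  ratios <- 2^rnorm(20)
  q <- fake_quant(sprintf("PEP%02dK", 1:20), ratios)
  fwd <- orient_ratios(q, "forward")
  # measuring the reciprocal sample under the swapped design re-derives
  # the same oriented values
  q_swapped <- fake_quant(q$peptide_sequence, 1 / ratios)
  rev_ <- orient_ratios(q_swapped, "reverse")
  expect_equal(rev_$oriented_log2, fwd$oriented_log2, tolerance = 1e-12)
})

test_that("consistency fraction counts sign agreement with zero counting as consistent", {
  f <- orient_ratios(fake_quant(c("AK", "BK", "CK", "DK"), c(2, 2, 2, 2)),
                     "forward")
  r <- orient_ratios(fake_quant(c("AK", "BK", "CK", "DK"), c(0.5, 0.5, 0.5, 2)),
                     "reverse")
  expect_equal(consistency_fraction(f, r), 0.75)
  r_zero <- orient_ratios(fake_quant("AK", 1), "reverse")
  f_one <- orient_ratios(fake_quant("AK", 2), "forward")
  expect_equal(consistency_fraction(f_one, r_zero), 1)
  disjoint <- orient_ratios(fake_quant("ZZK", 2), "reverse")
  expect_true(is.na(consistency_fraction(f_one, disjoint)))
})

test_that("forward/reverse R2 is the squared Pearson correlation of oriented ratios", {
  set.seed(13)
  vals <- rnorm(10)
  f <- orient_ratios(fake_quant(sprintf("P%02dK", 1:10), 2^vals), "forward")
  r_same <- orient_ratios(fake_quant(sprintf("P%02dK", 1:10), 2^(-vals)),
                          "reverse")
  expect_equal(forward_reverse_r2(f, r_same), 1, tolerance = 1e-12)
  r_noisy <- orient_ratios(
    fake_quant(sprintf("P%02dK", 1:10), 2^(-(vals + rnorm(10, 0, 0.3)))),
    "reverse")
  expect_equal(forward_reverse_r2(f, r_noisy),
               cor(vals, r_noisy$oriented_log2)^2, tolerance = 1e-12)
  expect_true(is.na(forward_reverse_r2(f[1:2, ], r_same[1:2, ])))
})

test_that("label-swap QC is exact in the noiseless limit", {
  cfg <- sim_config(n_proteins = 20, noise_relative_sd = 0,
                    interference_fraction = 0, seed = 3)
  lib <- generate_library(cfg)
  truth <- generate_ground_truth(lib, cfg)
  fq <- quantify_run(simulate_experiment(lib, truth, "forward", cfg), lib)
  rq <- quantify_run(simulate_experiment(lib, truth, "reverse", cfg), lib)
  f <- orient_ratios(fq, "forward")
  r <- orient_ratios(rq, "reverse")
  expect_equal(consistency_fraction(f, r), 1)
  expect_equal(forward_reverse_r2(f, r), 1, tolerance = 1e-6)
})

test_that("protein aggregation averages replicates and computes linear-scale RSD", {
  recs <- do.call(rbind, lapply(1:3, function(i) {
    orient_ratios(fake_quant("AAAK", c(8, 10, 12)[i]), "forward",
                  replicate_id = i)
  }))
  tab <- aggregate_protein(recs)
  expect_equal(tab$rsd_percent, oracle_rsd(c(8, 10, 12)))
  expect_equal(tab$rsd_percent, 20)
  expect_equal(tab$mean_log2, mean(log2(c(8, 10, 12))))
  expect_equal(tab$n_replicates, 3)
  # RSD matches the direct formula to near machine precision
  set.seed(14)
  lin <- 2^rnorm(6, 1, 0.2)
  recs2 <- do.call(rbind, lapply(seq_along(lin), function(i) {
    orient_ratios(fake_quant("AAAK", lin[i]), "forward", replicate_id = i)
  }))
  expect_equal(aggregate_protein(recs2)$rsd_percent, oracle_rsd(lin),
               tolerance = 1e-10)
})

test_that("regulation calls follow the 1.5-fold cutoff on the mean log2", {
  mk <- function(ratio) orient_ratios(fake_quant("AAAK", ratio), "forward")
  expect_equal(aggregate_protein(mk(2^0.7))$call, "up")    # 1.62-fold
  expect_equal(aggregate_protein(mk(2^-0.7))$call, "down")
  expect_equal(aggregate_protein(mk(1))$call, "unchanged")
  expect_equal(aggregate_protein(mk(2^0.55))$call, "unchanged")  # 1.46-fold
  expect_equal(aggregate_protein(mk(2^0.55), cutoff = 1.4)$call, "up")
  # single replicate: RSD undefined but the call is still made
  expect_true(is.na(aggregate_protein(mk(2))$rsd_percent))
})

test_that("dynamic range is the log10 max/min of positive areas", {
  expect_equal(dynamic_range(c(1e3, 5e4, 1e7)), 4)
  expect_equal(dynamic_range(c(7, 7, 7)), 0)
  expect_error(dynamic_range(c(1, 0)), "positive")
})

test_that("the kinome matrix is restricted to commonly quantified proteins", {
  t1 <- data.frame(protein_id = c("A", "B", "C"), kinase_class = "protein",
                   mean_log2 = c(1, 2, 3), stringsAsFactors = FALSE)
  t2 <- data.frame(protein_id = c("B", "C", "D"),
                   kinase_class = c("lipid", "protein", "protein"),
                   mean_log2 = c(4, 5, 6), stringsAsFactors = FALSE)
  km <- build_kinome_matrix(list(p1 = t1, p2 = t2))
  expect_equal(rownames(km$matrix), c("B", "C"))
  expect_equal(km$matrix["B", ], c(p1 = 2, p2 = 4))
  expect_false(anyNA(km$matrix))
  counts <- km$class_counts
  expect_equal(sum(counts$n[counts$pair_id == "p1"]), 3)
  expect_equal(counts$n[counts$pair_id == "p2" &
                          counts$kinase_class == "lipid"], 1)
  one <- build_kinome_matrix(list(only = t1))
  expect_equal(unname(one$matrix[, 1]), t1$mean_log2)
})
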