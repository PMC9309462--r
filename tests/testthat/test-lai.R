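test_that("switch probability follows the exponential map-distance model", {
  pp <- std_panels()
  hmm <- build_hmm(pp$panel)
  expect_identical(switch_prob(hmm, 0), 0)
  # g = 25, r = 1e-8, d = 1 Mb: s = 1 - exp(-0.25)
  expect_equal(switch_prob(hmm, 1e6), 1 - exp(-0.25), tolerance = 1e-12)
  expect_equal(sum(hmm$priors), 1, tolerance = 1e-12)
  expect_equal(unname(hmm$priors), c(0.30, 0.66, 0.04), tolerance = 1e-12)
  expect_error(build_hmm(pp$panel, priors = c(WB = 0.5, EUR_DP = 0.5,
                                              ASIA_DP = 0)),
               "strictly positive")
})

test_that("posterior dosages match exhaustive path enumeration on a 5-SNP instance", {
  set.seed(42)
  map <- snp_map(rep("1", 5), c(1e6, 2.5e6, 3e6, 7e6, 9e6),
                 rep("A", 5), rep("G", 5))
  freq <- matrix(runif(15, 0.05, 0.95), 5, 3,
                 dimnames = list(NULL, c("WB", "EUR_DP", "ASIA_DP")))
  panel <- ref_panel(freq, map)
  hmm <- build_hmm(panel)
  for (g in list(c(0L, 1L, 2L, NA, 1L), c(2L, 2L, 1L, 0L, 0L))) {
    gm <- genotype_matrix(matrix(g, 1, 5), map, "x")
    fld <- posterior_dosages(hmm, gm)
    oracle <- oracle_posterior(panel$freq, map$pos, unname(hmm$priors),
                               25, 1e-8, g)
    expect_lt(max(abs(oracle$dosage - fld$dosage[1, , ])), 1e-10)
    expect_equal(fld$loglik[1], oracle$loglik, tolerance = 1e-10)
  }
})

test_that("dosages are normalised and an all-missing individual gets priors", {
  pp <- std_panels()
  hmm <- build_hmm(pp$panel)
  coh <- simulate_cross("WB", "EUR_DP", 3, pp, seed = 61)
  gm <- cohort_genotypes(coh, pp$map)
  gm$geno[3, ] <- NA_integer_
  expect_warning(fld <- posterior_dosages(hmm, gm), "no observed genotypes")
  sums <- apply(fld$dosage, c(1, 2), sum)
  expect_lt(max(abs(sums - 2)), 1e-8)
  # prior marginals for the empty individual
  expect_lt(max(abs(fld$dosage[3, , "WB"] - 2 * hmm$priors[["WB"]])), 1e-8)
})

test_that("pure wild boar animals decode to near-complete wild dosage", {
  m <- population_model(n_snps = 2000,
                        divergence = c(WB = 0.2, EUR_DP = 0.2, ASIA_DP = 0.3),
                        chrom_lengths = c("15" = 140412725))
  pp <- generate_reference_panels(m, c(WB = 60, EUR_DP = 60, ASIA_DP = 40),
                                  seed = 13)
  pure <- simulate_cross("WB", "WB", 8, pp, seed = 62)
  fld <- posterior_dosages(build_hmm(pp$panel), cohort_genotypes(pure, pp$map))
  wb <- rowMeans(fld$dosage[, , "WB"])
  expect_gte(mean(wb), 1.9)
  expect_gte(min(wb), 1.8)
})

test_that("Viterbi tracts are whole chromosomes without recombination and beat the truth path", {
  pp <- chip_panels()
  f1 <- simulate_cross("WB", "EUR_DP", 2, pp, recomb_rate = 0, seed = 63,
                       missing_rate = 0)
  gm <- cohort_genotypes(f1, pp$map)
  hmm <- build_hmm(pp$panel)
  vt <- viterbi_tracts(hmm, gm)
  tr1 <- vt$tracts[vt$tracts$individual == gm$ids[1], ]
  # one tract per haplotype slot per chromosome
  expect_identical(nrow(tr1), 2L * length(unique(pp$map$chrom)))
  # Viterbi path log-likelihood is >= that of the true simulated path
  for (i in 1:2) {
    cn <- names(pp$model$chrom_lengths)
    a1 <- truth_dosages(f1[i], pp$map)$dosage[1, , ]
    # ordered truth state: slot 1 = hap1 ancestry, slot 2 = hap2
    anc1 <- apply(a1, 1, function(d) which(d > 0)[1])
    anc2 <- apply(a1, 1, function(d) rev(which(d > 0))[1])
    path <- (anc1 - 1L) * 3L + anc2
    expect_gte(vt$path_loglik[i] + 1e-9,
               path_loglik(hmm, gm$geno[i, ], path))
  }
})

test_that("recent admixed genomes decode with >= 90% per-SNP diploid accuracy", {
  pp <- chip_panels()
  set.seed(64)
  # g = 5 admixture: F1 backcrossed/intercrossed a few generations
  coh <- backcross_cohort(pp, 12, depths = c(1L, 2L, 3L), seed = 64,
                          missing_rate = 0)
  gm <- cohort_genotypes(coh, pp$map)
  hfld <- viterbi_field(build_hmm(pp$panel), gm)
  tfld <- truth_dosages(coh, pp$map)
  # unordered diploid ancestry matches when dosage vectors agree
  match_snp <- apply(hfld$dosage == tfld$dosage, c(1, 2), all)
  expect_gte(mean(match_snp), 0.90)
})

test_that("posterior dosages integrate to global ancestry", {
  pp <- chip_panels()
  coh <- backcross_cohort(pp, 30, depths = c(0L, 1L, 2L, 3L, 4L), seed = 65)
  gm <- cohort_genotypes(coh, pp$map)
  fld <- posterior_dosages(build_hmm(pp$panel), gm)
  dose_q <- global_from_dosages(fld)
  true_wb <- vapply(coh, function(i) true_q(i)[["WB"]], 0)
  # genome-wide mean dosage/2 tracks truth ...
  expect_lt(mean(abs(dose_q - true_wb)), 0.05)
  # ... and correlates strongly with the supervised global estimate
  est_wb <- vapply(seq_along(coh), function(i)
    estimate_q(gm$geno[i, ], pp$panel)$q[["WB"]], 0)
  expect_gt(stats::cor(dose_q, est_wb), 0.9)
})
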