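test_that("karyotype transmission follows Mendelian segregation of the fusion allele", {
  expect_true(all(transmit_karyotype(38L, 36L, 1000L, seed = 1) == 37L))
  expect_true(all(transmit_karyotype(36L, 36L, 200L, seed = 2) == 36L))
  expect_true(all(transmit_karyotype(38L, 38L, 200L, seed = 3) == 38L))
  k <- transmit_karyotype(37L, 37L, 4000L, seed = 4)
  p <- as.numeric(table(factor(k, levels = 36:38))) / 4000
  se <- sqrt(c(.25, .5, .25) * c(.75, .5, .75) / 4000)
  expect_true(all(abs(p - c(.25, .5, .25)) < 3 * se))
  expect_error(transmit_karyotype(35L, 37L), "36, 37 or 38")
  expect_identical(transmit_karyotype(37L, 37L, 50L, seed = 9),
                   transmit_karyotype(37L, 37L, 50L, seed = 9))
})

test_that("divergence parameter orders population differentiation in generated panels", {
  m <- population_model(n_snps = 10000,
                        divergence = c(WB = 0.1, EUR_DP = 0.1, ASIA_DP = 0.3),
                        chrom_lengths = c("1" = 2e8, "2" = 2e8))
  pp <- generate_reference_panels(m, c(WB = 10, EUR_DP = 10, ASIA_DP = 10),
                                  seed = 41)
  f <- pp$panel$freq
  expect_gt(mean(abs(f[, "WB"] - f[, "ASIA_DP"])),
            mean(abs(f[, "WB"] - f[, "EUR_DP"])))
  # deterministic under a fixed seed
  pp2 <- generate_reference_panels(m, c(WB = 10, EUR_DP = 10, ASIA_DP = 10),
                                   seed = 41)
  expect_identical(pp$panel$freq, pp2$panel$freq)
  expect_identical(pp$genotypes$WB$geno, pp2$genotypes$WB$geno)
})

test_that("degenerate panel requests fail or warn as appropriate", {
  m <- population_model(n_snps = 100)
  expect_error(generate_reference_panels(m, c(WB = 0, EUR_DP = 100, ASIA_DP = 35)),
               "WB")
  expect_error(population_model(divergence = c(WB = 0, EUR_DP = .1, ASIA_DP = .1)),
               "strictly in")
  m0 <- population_model(n_snps = 100,
                         divergence = c(WB = 1e-3, EUR_DP = 1e-3, ASIA_DP = 1e-3))
  expect_warning(generate_reference_panels(m0, c(WB = 5, EUR_DP = 5, ASIA_DP = 5),
                                           seed = 1),
                 "weakly identifiable")
})

test_that("F1 crosses are half wild by construction with 2n = 37", {
  pp <- std_panels()
  f1 <- simulate_cross("WB", "EUR_DP", 4, pp, seed = 42)
  for (ind in f1) {
    expect_identical(ind$karyotype, 37L)
    expect_equal(unname(true_q(ind)), c(0.5, 0.5, 0), tolerance = 1e-12)
  }
})

test_that("zero recombination transmits intact parental haplotypes", {
  pp <- std_panels()
  off <- simulate_cross("WB", "EUR_DP", 3, pp, recomb_rate = 0, seed = 43,
                        emit = FALSE)
  n_chrom <- length(pp$model$chrom_lengths)
  for (ind in off) {
    tr <- tracts_of(ind)
    # one whole-chromosome single-ancestry tract per haplotype per chromosome
    expect_identical(nrow(tr), 2L * n_chrom)
    expect_true(all(tr$start == 1))
    expect_equal(unname(tr$end),
                 unname(pp$model$chrom_lengths[tr$chrom]))
  }
})

test_that("backcrossing halves the domestic fraction each generation", {
  pp <- std_panels()
  coh <- backcross_cohort(pp, 200, depths = 3L, emit = FALSE, seed = 44)
  dp <- vapply(coh, function(i) 1 - true_q(i)[["WB"]], 0)
  se <- stats::sd(dp) / sqrt(length(dp))
  expect_lt(abs(mean(dp) - 2^-4), 3 * se)
})

test_that("tracts tile chromosomes, q sums to one, karyotype tracks the junction", {
  pp <- std_panels()
  coh <- sim_demo_cohort(pp, list(n_pure = 5, n_f1 = 5, n_f2 = 10, n_bc = 10,
                                  bc_depths = c(1L, 2L)), seed = 45)
  cl <- pp$model$chrom_lengths
  for (ind in coh) {
    tr <- tracts_of(ind)
    for (h in 1:2) for (ch in names(cl)) {
      t1 <- tr[tr$haplotype == h & tr$chrom == ch, ]
      t1 <- t1[order(t1$start), ]
      expect_identical(t1$start[1], 1)           # starts at chromosome start
      expect_identical(t1$end[nrow(t1)], unname(cl[[ch]]))
      if (nrow(t1) > 1)                          # contiguous, non-overlapping
        expect_true(all(t1$start[-1] == t1$end[-nrow(t1)] + 1))
    }
    expect_equal(sum(true_q(ind)), 1, tolerance = 1e-12)
    expect_identical(ind$karyotype, 36L + sum(!ind$fused))
  }
  # ancestry at the junction is wild iff the allele is fused:
  # WB dosage at junction markers equals the fused-allele count 38 - 2n
  jf <- truth_dosages(coh, junction_eval_map())
  for (i in seq_along(coh)) {
    expect_equal(unname(jf$dosage[i, "jun17", "WB"]),
                 38 - coh[[i]]$karyotype)
    expect_equal(unname(jf$dosage[i, "jun15", "WB"]),
                 38 - coh[[i]]$karyotype)
  }
})

test_that("introgression injection hits the target dosage and nothing else", {
  pp <- std_panels()
  coh <- backcross_cohort(pp, 100, depths = 4L, emit = FALSE, seed = 46)
  iv <- list(chrom = "13", start = 8.3e7, end = 8.8e7)
  expect_identical(inject_introgression(coh, iv, 0, pp), coh)
  full <- inject_introgression(coh, iv, 2, pp, seed = 47)
  tf <- truth_dosages(full, pp$map)
  in_iv <- pp$map$chrom == "13" & pp$map$pos >= iv$start & pp$map$pos <= iv$end
  expect_true(all(tf$dosage[, in_iv, "WB"] == 0))
  part <- inject_introgression(coh, iv, 0.4, pp, seed = 48)
  tp <- truth_dosages(part, pp$map)
  # injection overwrites whole haplotype segments, so average the realised
  # domestic dosage per individual over the interval and compare to 0.4
  dp_dos <- rowMeans(2 - tp$dosage[, in_iv, "WB"])
  base <- rowMeans(2 - truth_dosages(coh, pp$map)$dosage[, in_iv, "WB"])
  # each haplotype is overwritten with prob 0.2 on top of its own ancestry
  se <- 3 * stats::sd(dp_dos) / sqrt(length(dp_dos))
  expect_lt(abs(mean(dp_dos) - (0.4 + 0.8 * mean(base))), max(se, 0.05))
  expect_error(inject_introgression(coh, list(chrom = "99", start = 1, end = 2e6),
                                    1, pp), "outside map")
  expect_error(inject_introgression(coh, list(chrom = "13", start = 1, end = 2),
                                    1, pp), "at least 2 SNPs")
})

test_that("admixture-model genotype simulation matches requested proportions", {
  pp <- std_panels()
  Q <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.2, 0.3, 0.5))
  gm <- simulate_q_genotypes(pp$panel, Q, seed = 49)
  expect_identical(dim(gm$geno), c(3L, nrow(pp$map)))
  # mean alt dosage per individual tracks the mixture expectation
  expe <- 2 * (pp$panel$freq %*% t(Q))
  expect_lt(max(abs(rowMeans(gm$geno) - colMeans(expe))), 0.05)
})
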