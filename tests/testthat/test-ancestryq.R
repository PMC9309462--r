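recovery_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- population_model(n_snps = 2000,
                            divergence = c(WB = 0.1, EUR_DP = 0.1,
                                           ASIA_DP = 0.1))
      cache <<- generate_reference_panels(
        m, c(WB = 60, EUR_DP = 60, ASIA_DP = 40), seed = 3)
    }
    cache
  }
})

test_that("pure and F1 individuals are recovered by the supervised estimator", {
  pp <- recovery_panel()
  # pure wild boar: near-complete wild ancestry, 0.98 in expectation
  Q <- rbind(matrix(rep(c(1, 0, 0), 10), 10, 3, byrow = TRUE),
             c(0.5, 0.5, 0))
  gm <- simulate_q_genotypes(pp$panel, Q, seed = 51)
  qs <- vapply(1:10, function(i) estimate_q(gm$geno[i, ], pp$panel)$q[["WB"]],
               0)
  expect_gte(mean(qs), 0.98)
  expect_gte(min(qs), 0.90)
  qf <- estimate_q(gm$geno[11, ], pp$panel)$q
  expect_lt(max(abs(qf - c(0.5, 0.5, 0))), 0.05)
})

test_that("EM log-likelihood is monotone and estimates are SNP-order invariant", {
  pp <- recovery_panel()
  set.seed(52)
  Q <- t(replicate(6, { x <- -log(runif(3)); x / sum(x) }))
  gm <- simulate_q_genotypes(pp$panel, Q, seed = 53)
  for (i in 1:6) {
    e <- estimate_q(gm$geno[i, ], pp$panel)
    expect_true(all(diff(e$trace) > -1e-8))
    expect_equal(sum(e$q), 1, tolerance = 1e-10)
    expect_true(all(e$q >= 0))
  }
  perm <- sample(nrow(pp$map))
  pmap <- pp$map[perm, ]
  panel_perm <- ref_panel(pp$panel$freq[perm, , drop = FALSE],
                          structure(pmap, class = class(pp$map)))
  e0 <- estimate_q(gm$geno[1, ], pp$panel)
  e1 <- estimate_q(gm$geno[1, perm], panel_perm)
  expect_equal(e1$q, e0$q, tolerance = 1e-8)
})

test_that("degenerate estimator inputs behave as documented", {
  pp <- recovery_panel()
  # K = 1 panel: the zero-dimensional simplex
  p1 <- ref_panel(pp$panel$freq[, "WB", drop = FALSE], pp$map)
  g <- simulate_q_genotypes(pp$panel, matrix(c(1, 0, 0), 1), seed = 54)$geno[1, ]
  expect_identical(estimate_q(g, p1)$q, c(WB = 1))
  expect_error(estimate_q(rep(NA_integer_, nrow(pp$map)), pp$panel),
               "no overlap")
  g2 <- g; g2[-(1:50)] <- NA
  expect_warning(estimate_q(g2, pp$panel), "informative SNPs")
})

test_that("bootstrap SE shrinks like 1/sqrt(SNP count) and CIs are 1.96 SE wide", {
  pp <- recovery_panel()
  gm <- simulate_q_genotypes(pp$panel, matrix(c(0.6, 0.3, 0.1), 1), seed = 55)
  g <- gm$geno[1, ]
  half <- seq_len(1000)
  p_half <- ref_panel(pp$panel$freq[half, , drop = FALSE],
                      structure(pp$map[half, ], class = class(pp$map)))
  b_full <- bootstrap_q(g, pp$panel, n_boot = 120, seed = 56)
  b_half <- bootstrap_q(g[half], p_half, n_boot = 120, seed = 57)
  ratio <- stats::median(b_half$se / b_full$se)
  expect_lt(abs(ratio - sqrt(2)), 0.3 * sqrt(2))
  # untruncated CI half-width over SE is exactly 1.96
  hw <- (b_full$ci_upper_raw - b_full$q) / b_full$se
  expect_equal(unname(hw), rep(1.96, 3), tolerance = 1e-12)
  expect_true(all(b_full$ci_lower >= 0 & b_full$ci_upper <= 1))
  # bit-reproducible under the same seed
  expect_identical(bootstrap_q(g, pp$panel, n_boot = 120, seed = 56), b_full)
})

test_that("the CI-based admixture classification follows the 0.99 / 0.60 rules", {
  expect_identical(classify_admixture(0.995, 1.0), "unadmixed")
  expect_identical(classify_admixture(0.97, 0.992), "unadmixed")
  expect_identical(classify_admixture(0.94, 0.96), "admixed")
  expect_identical(classify_admixture(0.55, 0.60), "recent_hybrid_candidate")
  expect_identical(classify_admixture(0.60, 0.65), "admixed")
})

test_that("the cohort Q table classifies simulated animals sensibly", {
  pp <- recovery_panel()
  Q <- rbind(c(1, 0, 0), c(0.97, 0.03, 0), c(0.5, 0.5, 0))
  gm <- simulate_q_genotypes(pp$panel, Q, seed = 58)
  tab <- ancestry_q_table(gm, pp$panel, n_boot = 60, seed = 59)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$class[3], "recent_hybrid_candidate")
  expect_true(all(abs(rowSums(tab[, c("q_WB", "q_EUR_DP", "q_ASIA_DP")]) - 1)
                  < 1e-8))
})
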