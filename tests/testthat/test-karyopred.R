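toy_fused <- function() {
  m17 <- snp_map(rep("17", 3), c(5e6, 4e7, 63e6), "A", "G",
                 id = c("a17", "b17", "c17"))
  m15 <- snp_map(rep("15", 3), c(1L, 2e6, 9e7), "A", "G",
                 id = c("a15", "b15", "c15"))
  fuse_map(m15, m17)
}

test_that("the fused rob(15;17) map shifts chr15 by the chr17 length", {
  fm <- toy_fused()
  # first chr15 nucleotide lands at 63,494,081 + 1
  expect_equal(fm$fused_pos[fm$id == "a15"], 63494082)
  # chr17 coordinates are unchanged
  expect_equal(fm$fused_pos[fm$id == "b17"], 4e7)
  expect_true(all(diff(fm$fused_pos) > 0))
  expect_equal(attr(fm, "junction"), 63494081)
  # bijection on SNPs
  expect_setequal(fm$id, c("a17", "b17", "c17", "a15", "b15", "c15"))
  m17 <- snp_map(rep("17", 2), c(5e6, 7e7), "A", "G")
  m15 <- snp_map(rep("15", 2), c(10, 20), "A", "G")
  expect_error(fuse_map(m15, m17), "exceed")
  mix <- snp_map(c("15", "16"), c(10, 20), "A", "G")
  expect_error(fuse_map(mix, m17), "single-chromosome")
})

make_field <- function(wb_dosages, map) {
  n <- nrow(wb_dosages)
  dos <- array(0, dim = c(n, ncol(wb_dosages), 3),
               dimnames = list(paste0("i", seq_len(n)), map$id,
                               c("WB", "EUR_DP", "ASIA_DP")))
  dos[, , "WB"] <- wb_dosages
  dos[, , "EUR_DP"] <- 2 - wb_dosages
  structure(list(dosage = dos, map = map, labels = c("WB", "EUR_DP", "ASIA_DP"),
                 ids = paste0("i", seq_len(n)), source = "truth"),
            class = "lai_field")
}

test_that("the karyotype call rule maps junction dosages to 2n with ties toward 37", {
  fm <- toy_fused()
  map <- snp_map(c(rep("17", 3), rep("15", 3)),
                 c(5e6, 4e7, 63e6, 1L, 2e6, 9e7), "A", "G",
                 id = c("a17", "b17", "c17", "a15", "b15", "c15"))
  # rows: (left flank c17, right flank a15) dosage pairs
  wb <- rbind(c(0, 0, 2.0, 2.0, 0, 0),   # both flanks wild      -> 36
              c(0, 0, 1.0, 1.0, 0, 0),   # one wild allele each  -> 37
              c(0, 0, 0.0, 0.0, 0, 0),   # both domestic         -> 38
              c(0, 0, 2.0, 0.0, 0, 0),   # opposite flanks: tie  -> 37
              c(0, 0, 1.6, 1.6, 0, 0),   # 0.8 proportion        -> 36
              c(0, 0, 1.4, 1.4, 0, 0))   # 0.7 proportion        -> 37
  calls <- predict_karyotype(make_field(wb, map), fm)
  expect_identical(calls$predicted_2n, c(36L, 37L, 38L, 37L, 36L, 37L))
  expect_true(all(calls$confidence >= 0 & calls$confidence <= 1))
  # flank_window larger than available SNPs on one side errors
  expect_error(predict_karyotype(make_field(wb, map), fm, flank_window = 4),
               "flank_window")
})

test_that("concordance has the published orientation and arithmetic", {
  calls <- data.frame(id = paste0("i", 1:10),
                      predicted_2n = c(rep(36L, 4), rep(37L, 4), 38L, 38L))
  truth <- data.frame(id = paste0("i", 1:10),
                      karyotype = c(rep(36L, 4), rep(37L, 3), 36L, 38L, 37L))
  cc <- karyotype_concordance(calls, truth)
  expect_equal(cc$overall, 0.8)
  expect_identical(as.integer(cc$confusion["37", "36"]), 1L)
  expect_identical(as.integer(cc$confusion["38", "37"]), 1L)
  expect_equal(unname(cc$per_class), c(4 / 5, 3 / 4, 1 / 1))
  # perfect predictions give the identity matrix
  cc2 <- karyotype_concordance(
    data.frame(id = truth$id, predicted_2n = truth$karyotype), truth)
  expect_equal(cc2$overall, 1)
  expect_true(all(cc2$confusion[upper.tri(cc2$confusion)] == 0))
  expect_error(karyotype_concordance(calls, truth[1:9, ]), "id mismatch")
})

test_that("error-free junction ancestry reproduces every true karyotype", {
  pp <- chip_panels()
  coh <- sim_demo_cohort(pp, list(n_pure = 10, n_f1 = 10, n_f2 = 30,
                                  n_bc = 10, bc_depths = 1L), seed = 71)
  truth <- truth_table(coh)
  jmap <- junction_eval_map()
  fm <- fused_map_of(jmap)
  calls <- predict_karyotype(truth_dosages(coh, jmap), fm)
  cc <- karyotype_concordance(calls, truth)
  expect_equal(cc$overall, 1)
  # at real (off-junction) flank SNPs, rare crossovers between the flank
  # and the junction leave a small irreducible mismatch
  calls2 <- predict_karyotype(truth_dosages(coh, pp$map), fused_map_of(pp$map))
  expect_gte(karyotype_concordance(calls2, truth)$overall, 0.95)
})
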