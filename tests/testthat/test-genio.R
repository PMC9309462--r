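make_toy_gm <- function() {
  map <- snp_map(chrom = c("1", "1", "2", "2"),
                 pos = c(100L, 200L, 50L, 150L),
                 ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"))
  geno <- rbind(ind1 = c(0L, 1L, 2L, NA),
                ind2 = c(2L, 0L, 1L, 1L),
                ind3 = c(1L, 1L, 0L, 2L))
  genotype_matrix(geno, map)
}

test_that("PLINK text round-trips exactly (with counted-allele sidecar)", {
  gm <- make_toy_gm()
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_plink(gm, prefix)
  back <- read_genotypes(prefix, "ped")
  expect_identical(unname(back$geno), unname(gm$geno))
  expect_identical(back$ids, gm$ids)
  expect_identical(back$map$pos, gm$map$pos)
  expect_identical(back$map$alt, gm$map$alt)   # counted allele preserved
  # a larger simulated matrix with missingness
  pp <- std_panels()
  gm2 <- pp$genotypes$ASIA_DP
  prefix2 <- file.path(withr::local_tempdir(), "sim")
  write_plink(gm2, prefix2)
  back2 <- read_genotypes(prefix2, "ped")
  expect_identical(unname(back2$geno), unname(gm2$geno))
})

test_that("VCF round-trips; ./. becomes missing; multi-allelic sites are rejected", {
  gm <- make_toy_gm()
  path <- file.path(withr::local_tempdir(), "toy.vcf")
  write_vcf(gm, path)
  back <- read_genotypes(path, "vcf")
  expect_identical(unname(back$geno), unname(gm$geno))
  expect_true(is.na(back$geno["ind1", 4]))
  lines <- readLines(path)
  bad <- sub("\tG\t", "\tG,T\t", lines[grepl("^1\t100", lines)])
  writeLines(c(lines[startsWith(lines, "#")], bad),
             tri <- file.path(withr::local_tempdir(), "tri.vcf"))
  expect_error(read_genotypes(tri, "vcf"), "1:100")
})

test_that("duplicated individual ids are rejected on read", {
  gm <- make_toy_gm()
  prefix <- file.path(withr::local_tempdir(), "dup")
  write_plink(gm, prefix)
  ped <- readLines(paste0(prefix, ".ped"))
  ped[2] <- sub("^ind2 ind2", "ind1 ind1", ped[2])
  writeLines(ped, paste0(prefix, ".ped"))
  expect_error(read_genotypes(prefix, "ped"), "duplicated individual id")
})

test_that("SNP filter applies strict MAF and missingness thresholds, no HWE", {
  # 10 SNPs with known properties across 10 individuals
  n <- 10L
  geno <- matrix(1L, n, 10)
  geno[, 1] <- 0L                                   # monomorphic -> MAF 0
  geno[, 2] <- c(1L, rep(0L, n - 1L))               # MAF 0.05 exactly
  geno[, 3] <- c(1L, 1L, rep(0L, n - 2L))           # MAF 0.10
  geno[, 4] <- rep(c(0L, 2L), 5)                    # MAF 0.5, HWE-violating
  geno[1, 5] <- NA                                  # missing 0.10
  geno[1:2, 6] <- NA                                # missing 0.20
  geno[, 7] <- c(2L, rep(NA, 5L), rep(0L, 4L))      # missing 0.50
  geno[, 8] <- c(rep(2L, 9L), 1L)                   # MAF 0.05 exactly (alt major)
  map <- snp_map(rep("1", 10), seq(1e5, 1e6, length.out = 10), "A", "G")
  gm <- genotype_matrix(geno, map)
  kept <- filter_snps(gm, maf_min = 0.05, miss_max = 0.15)
  # hand enumeration: drop 1 (mono), 2 and 8 (MAF == 0.05, strict), 6 and 7
  # (missing >= 0.15); keep 3, 4 (no HWE rule), 5, 9, 10
  expect_identical(kept$map$id, map$id[c(3, 4, 5, 9, 10)])
  # idempotent
  expect_identical(filter_snps(kept, 0.05, 0.15)$map$id, kept$map$id)
  expect_error(filter_snps(gm, maf_min = 0.5, miss_max = 0.01),
               "review")
})

test_that("IBS thinning keeps the better-called member of each redundant pair", {
  pp <- std_panels()
  base <- pp$genotypes$WB
  g <- base$geno[1:6, ]
  g[1, ] <- g[2, ]                       # ind1 duplicates ind2 ...
  g[1, 1:100] <- NA                      # ... with a worse call rate
  gm <- genotype_matrix(g, base$map, paste0("i", 1:6))
  kept <- ibs_thin(gm, 0.95)
  expect_false("i1" %in% kept)
  expect_true("i2" %in% kept)
  # threshold 1.0 and no exact duplicates: everyone is retained
  gm2 <- genotype_matrix(base$geno[3:8, ], base$map, paste0("j", 1:6))
  expect_identical(ibs_thin(gm2, 1.0), paste0("j", 1:6))
})

test_that("IBS thinning agrees with the exhaustive oracle on toy cases", {
  pp <- std_panels()
  base <- pp$genotypes$EUR_DP
  for (seed in 1:3) {
    set.seed(seed)
    g <- base$geno[sample(nrow(base$geno), 4), ]
    g[2, ] <- g[1, ]; g[2, sample(ncol(g), 40)] <- NA
    g[4, sample(ncol(g), 300)] <- g[3, sample(ncol(g), 300)]
    gm <- genotype_matrix(g, base$map, paste0("t", 1:4))
    ib <- ibs_matrix(gm)
    expect_identical(ibs_thin(gm, 0.9),
                     oracle_ibs_thin(ib, call_rate(gm), gm$ids, 0.9))
  }
})

test_that("LD pruning keeps one representative per correlated cluster", {
  pp <- std_panels()
  base <- pp$genotypes$WB
  # duplicated SNP column: exactly one survives
  g <- base$geno[, 1:20]
  g[, 2] <- g[, 1]
  map <- base$map[1:20, ]; class(map) <- c("snp_map", "data.frame")
  gm <- genotype_matrix(g, map, base$ids)
  pruned <- ld_prune(gm, r2_cutoff = 0.1, window = 10)
  expect_true(xor(map$id[1] %in% pruned$map$id, map$id[2] %in% pruned$map$id))
  # independent SNPs at n = 500: at least 95% survive a 0.1 cutoff
  set.seed(7)
  n <- 500; M <- 200
  f <- runif(M, 0.1, 0.9)
  gi <- matrix(rbinom(n * M, 2L, rep(f, each = n)), n, M)
  mapi <- snp_map(rep("1", M), seq_len(M) * 1e4, "A", "G")
  gmi <- genotype_matrix(gi, mapi)
  expect_gte(nrow(ld_prune(gmi, 0.1, 50)$map) / M, 0.95)
})

test_that("LD pruning matches the brute-force oracle on a correlated block", {
  set.seed(8)
  n <- 80
  z <- rbinom(n, 2L, 0.5)
  flip <- function(p) ifelse(runif(n) < p, sample(0:2, n, TRUE), z)
  g <- cbind(z, flip(.05), flip(.1), rbinom(n, 2L, .5), flip(.15))
  storage.mode(g) <- "integer"
  map <- snp_map(rep("1", 5), (1:5) * 1e5, "A", "G")
  gm <- genotype_matrix(g, map)
  for (cutoff in c(0.1, 0.5, 0.9)) {
    keep_oracle <- oracle_ld_prune(gm$geno, gm$map, cutoff, 5)
    expect_identical(ld_prune(gm, cutoff, 5)$map$id, gm$map$id[keep_oracle],
                     label = paste("cutoff", cutoff))
  }
})
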