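# Shared fixtures (built once per run) and independent oracles.

# chip-density two-chromosome panel for HMM/karyotype benchmarks:
# chr15 + chr17 at ~1 SNP / 68 kb matches the density of a genome-wide
# 40k-SNP porcine array, which is what the HMM's information flow assumes.
chip_panels <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- population_model(
        n_snps = 3000,
        divergence = c(WB = 0.2, EUR_DP = 0.2, ASIA_DP = 0.3),
        chrom_lengths = c("15" = 140412725, "17" = 63494081))
      cache <<- generate_reference_panels(
        m, c(WB = 60, EUR_DP = 60, ASIA_DP = 40), seed = 11)
    }
    cache
  }
})

# small general-purpose panel on the 4-chromosome demo genome
std_panels <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- population_model(n_snps = 1200)
      cache <<- generate_reference_panels(
        m, c(WB = 40, EUR_DP = 40, ASIA_DP = 30), seed = 3)
    }
    cache
  }
})

# mixed-pedigree cohort spec used by karyotype benchmarks: F2/backcross
# heavy so every karyotype class contains recombinant animals
mixed_cohort_spec <- function(n = 300) {
  stopifnot(n == 300)
  list(n_pure = 30, n_f1 = 20, n_f2 = 175, n_bc = 75, bc_depths = c(1L, 2L))
}

# evaluation map with markers immediately flanking the rob(15;17) junction
# (last chr17 bp and first chr15 bp) plus optional extra SNPs
junction_eval_map <- function(extra_map = NULL) {
  jm <- data.frame(chrom = c("17", "15"), pos = c(63494081L, 1L),
                   ref = "A", alt = "G",
                   id = c("jun17", "jun15"), stringsAsFactors = FALSE)
  if (!is.null(extra_map))
    jm <- rbind(jm, as.data.frame(extra_map)[, names(jm)])
  jm <- jm[order(match(jm$chrom, c("17", "15")), jm$pos), ]
  jm <- jm[!duplicated(paste(jm$chrom, jm$pos)), ]
  snp_map(jm$chrom, jm$pos, jm$ref, jm$alt, jm$id)
}

fused_map_of <- function(map, chr17_length = 63494081) {
  m15 <- map[map$chrom == "15", , drop = FALSE]
  m17 <- map[map$chrom == "17", , drop = FALSE]
  class(m15) <- class(m17) <- c("snp_map", "data.frame")
  fuse_map(m15, m17, chr17_length)
}

# ---- independent HMM oracle: exhaustive sum over all K^2-state paths ----
# recomputes transitions and emissions from first principles; shares no
# code with the package implementation.
oracle_posterior <- function(freq, pos, priors, g, r, geno) {
  K <- ncol(freq); S <- K^2; M <- length(pos)
  a_of <- rep(seq_len(K), each = K); b_of <- rep(seq_len(K), times = K)
  pi2 <- priors[a_of] * priors[b_of]
  emis <- function(m, s) {
    if (is.na(geno[m])) return(1)
    fa <- freq[m, a_of[s]]; fb <- freq[m, b_of[s]]
    c((1 - fa) * (1 - fb), fa * (1 - fb) + (1 - fa) * fb, fa * fb)[geno[m] + 1]
  }
  sw <- 1 - exp(-g * r * diff(pos))
  Tm <- lapply(sw, function(s) {
    A <- (1 - s) * diag(K) + s * matrix(priors, K, K, byrow = TRUE)
    kronecker(A, A)
  })
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), M)))
  jp <- apply(paths, 1, function(p) {
    pr <- pi2[p[1]] * emis(1, p[1])
    for (m in seq_len(M)[-1])
      pr <- pr * Tm[[m - 1]][p[m - 1], p[m]] * emis(m, p[m])
    pr
  })
  post <- sapply(seq_len(M), function(m)
    vapply(seq_len(S), function(s) sum(jp[paths[, m] == s]), 0))
  post <- t(post) / sum(jp)  # M x S
  dos <- post %*% sapply(seq_len(K), function(k)
    (a_of == k) + (b_of == k))
  list(dosage = dos, loglik = log(sum(jp)))
}

# ---- independent LD-pruning oracle: literal double loop ----
oracle_ld_prune <- function(geno, map, r2_cutoff, window) {
  keep <- logical(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    kept <- integer(0)
    for (m in idx) {
      drop <- FALSE
      for (k in kept) {
        if (m - k > window) next
        r2 <- suppressWarnings(
          stats::cor(geno[, k], geno[, m], use = "pairwise.complete.obs"))^2
        if (!is.na(r2) && r2 > r2_cutoff) drop <- TRUE
      }
      if (!drop) { kept <- c(kept, m); keep[m] <- TRUE }
    }
  }
  keep
}

# ---- independent IBS-thinning oracle under the stated rule ----
oracle_ibs_thin <- function(ibs, call_rates, ids, threshold) {
  alive <- rep(TRUE, length(ids))
  pairs <- which(upper.tri(ibs) & ibs > threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-ibs[pairs], pairs[, 1], pairs[, 2])
    for (r in ord) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!alive[i] || !alive[j]) next
      if (call_rates[i] < call_rates[j]) alive[i] <- FALSE
      else if (call_rates[j] < call_rates[i]) alive[j] <- FALSE
      else alive[max(i, j)] <- FALSE
    }
  }
  ids[alive]
}

# per-SNP wild-ancestry frequency computed directly from tract tables
oracle_tract_freq <- function(individuals, map, label = "WB") {
  counts <- numeric(nrow(map))
  for (ind in individuals) {
    tr <- tracts_of(ind)
    tr <- tr[tr$ancestry == label, , drop = FALSE]
    for (r in seq_len(nrow(tr))) {
      hit <- map$chrom == tr$chrom[r] & map$pos >= tr$start[r] &
        map$pos <= tr$end[r]
      counts[hit] <- counts[hit] + 1
    }
  }
  counts / (2 * length(individuals))
}
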