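`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population model for the synthetic cohort generator
#'
#' Describes three source populations — wild boar (WB), European domestic
#' pig (EUR_DP) and Asian domestic pig (ASIA_DP) — whose per-SNP allele
#' frequencies diverge from a shared ancestral frequency under the
#' Balding–Nichols model: f_k ~ Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k), where
#' F_k is an Fst-like divergence parameter.
#'
#' @param n_snps number of autosomal SNPs.
#' @param labels population labels; the first is treated as the wild
#'   (fusion-carrying) population.
#' @param divergence named per-population divergence, each strictly in (0,1).
#' @param freq_margin ancestral frequencies are drawn uniformly on
#'   `[freq_margin, 1 - freq_margin]`.
#' @param chrom_lengths named chromosome lengths (bp) for the SNP map.
#' @param missing_rate i.i.d. genotype missingness applied on emission.
#' @param map optional fixed `snp_map` (simulated otherwise).
#' @param ancestral_freqs optional fixed per-SNP ancestral frequencies.
#' @return object of class `population_model`.
#' @export
population_model <- function(n_snps = 3000,
                             labels = c("WB", "EUR_DP", "ASIA_DP"),
                             divergence = c(WB = 0.15, EUR_DP = 0.15,
                                            ASIA_DP = 0.30),
                             freq_margin = 0.05,
                             chrom_lengths = default_chrom_lengths(),
                             missing_rate = 0.02,
                             map = NULL, ancestral_freqs = NULL) {
  divergence <- divergence[labels]
  if (anyNA(divergence))
    stop("divergence must be named for every population label")
  if (any(divergence <= 0 | divergence >= 1))
    stop("divergence must be strictly in (0, 1)")
  stopifnot(freq_margin > 0, freq_margin < 0.5,
            missing_rate >= 0, missing_rate <= 0.10)
  if (!is.null(ancestral_freqs) &&
      any(ancestral_freqs < freq_margin | ancestral_freqs > 1 - freq_margin))
    stop("ancestral_freqs must lie within the frequency margin")
  structure(list(n_snps = n_snps, labels = labels, divergence = divergence,
                 freq_margin = freq_margin, chrom_lengths = chrom_lengths,
                 missing_rate = missing_rate, map = map,
                 ancestral_freqs = ancestral_freqs),
            class = "population_model")
}

#' Generate diverged reference panels
#'
#' Draws per-population allele frequencies from the Balding–Nichols model
#' around shared ancestral frequencies and samples panel genotypes as
#' binomial(2, f) draws. Returns both the true frequencies (as a
#' [ref_panel]) and the sampled panel genotype matrices.
#'
#' @param model a [population_model].
#' @param panel_sizes named counts of reference animals per population.
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with elements `panel` (true-frequency `ref_panel`),
#'   `genotypes` (named list of `genotype_matrix`), `map`, `ancestral_freqs`,
#'   `model` and `seed`; class `sim_panels`.
#' @export
generate_reference_panels <- function(model,
                                      panel_sizes = c(WB = 60, EUR_DP = 60,
                                                      ASIA_DP = 40),
                                      seed = 1L) {
  panel_sizes <- panel_sizes[model$labels]
  if (anyNA(panel_sizes))
    stop("panel_sizes must be named for every population label")
  empty <- model$labels[panel_sizes < 1]
  if (length(empty))
    stop("panel size must be >= 1; empty panel for population: ",
         paste(empty, collapse = ", "))
  set.seed(seed)
  map <- model$map %||% sim_snp_map(model$n_snps, model$chrom_lengths)
  M <- nrow(map)
  p0 <- model$ancestral_freqs %||%
    stats::runif(M, model$freq_margin, 1 - model$freq_margin)
  if (max(model$divergence) < 0.01)
    warning("all divergence parameters are near zero: population ",
            "frequencies barely differ and ancestry is weakly identifiable")
  freq <- sapply(model$labels, function(k) {
    F <- model$divergence[[k]]
    stats::rbeta(M, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  })
  panel <- ref_panel(freq, map)
  genotypes <- list()
  for (k in model$labels) {
    n <- panel_sizes[[k]]
    g <- matrix(stats::rbinom(n * M, 2L, rep(panel$freq[, k], each = n)),
                nrow = n, ncol = M)
    if (model$missing_rate > 0)
      g[stats::runif(n * M) < model$missing_rate] <- NA_integer_
    genotypes[[k]] <- genotype_matrix(g, map,
                                      ids = sprintf("%s_%03d", k, seq_len(n)))
  }
  structure(list(panel = panel, genotypes = genotypes, map = map,
                 ancestral_freqs = p0, model = model, seed = seed),
            class = "sim_panels")
}

# ---- Robertsonian transmission ---------------------------------------------

#' Transmit the rob(15;17) karyotype from two parents
#'
#' Each parent transmits one junction-locus allele: a 2n=36 parent always
#' transmits the fused allele, a 2n=38 parent always the unfused allele and
#' a 2n=37 heterozygote transmits the fused allele with probability 1/2.
#' The offspring karyotype is 36 plus its number of unfused alleles, which
#' reproduces the classical segregation expectations (37x37 -> 25/50/25 for
#' 36/37/38; 37x36 -> 50/50; 37x38 -> 50/50; 38x36 -> all 37).
#'
#' @param kA,kB parental diploid chromosome numbers in `{36, 37, 38}`.
#' @param n_offspring number of independent offspring to draw.
#' @param seed optional integer seed.
#' @return integer vector of offspring karyotypes.
#' @export
transmit_karyotype <- function(kA, kB, n_offspring = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (k in c(kA, kB))
    if (!k %in% c(36L, 37L, 38L))
      stop("parental karyotype must be 36, 37 or 38 (got ", k, ")")
  p_unfused <- c(`36` = 0, `37` = 0.5, `38` = 1)
  uA <- stats::rbinom(n_offspring, 1L, p_unfused[[as.character(kA)]])
  uB <- stats::rbinom(n_offspring, 1L, p_unfused[[as.character(kB)]])
  as.integer(36L + uA + uB)
}

# ---- linkage layout & meiosis ----------------------------------------------

# Haplotypes are stored as numeric matrices with columns (chrom, start, end,
# anc): chrom and anc are integer codes into the individual's chrom_names and
# anc_labels. Tracts are 1-based inclusive and tile every chromosome.
COL_CHROM <- 1L; COL_START <- 2L; COL_END <- 3L; COL_ANC <- 4L

# Chromosomes 15 and 17 are joined into one meiotic linkage group mirroring
# the fused rob(15;17) coordinate system (chr17 first, chr15 offset by the
# chr17 length), so the fusion allele at the junction co-segregates with the
# haplotype segment spanning the centromere junction.
linkage_layout <- function(chrom_lengths) {
  chroms <- names(chrom_lengths)
  idx <- function(ch) match(ch, chroms)
  groups <- list(); rob_group <- NA_integer_; junction <- NA_real_
  if (all(c("15", "17") %in% chroms)) {
    groups[[length(groups) + 1L]] <- list(
      chrom = idx(c("17", "15")),
      offset = c(0, chrom_lengths[["17"]]),
      length = unname(chrom_lengths[c("17", "15")]))
    rob_group <- length(groups)
    junction <- chrom_lengths[["17"]]
    chroms_rest <- setdiff(chroms, c("15", "17"))
  } else chroms_rest <- chroms
  for (ch in chroms_rest)
    groups[[length(groups) + 1L]] <- list(chrom = idx(ch), offset = 0,
                                          length = chrom_lengths[[ch]])
  # per-chromosome-index offset lookup for group coordinate transforms
  len <- vapply(groups, function(g) sum(g$length), 0)
  list(groups = groups, len = len, rob_group = rob_group, junction = junction)
}

new_sim_individual <- function(id, hap1, hap2, fused, depth, chrom_lengths,
                               labels) {
  structure(list(id = id, hap1 = hap1, hap2 = hap2, fused = fused,
                 pedigree_depth = depth, chrom_lengths = chrom_lengths,
                 anc_labels = labels, karyotype = 36L + sum(!fused),
                 geno = NULL),
            class = "sim_individual")
}

#' @export
print.sim_individual <- function(x, ...) {
  cat("sim_individual", x$id, ": 2n =", x$karyotype,
      sprintf("(q_%s = %.3f)", x$anc_labels[1], true_q(x)[1]),
      "depth", x$pedigree_depth, "\n")
  invisible(x)
}

#' Create a pure founder individual
#'
#' Founders carry single-ancestry haplotypes across every chromosome. Wild
#' boar founders are homozygous for the fused rob(15;17) allele (2n = 36);
#' domestic pig founders are homozygous unfused (2n = 38).
#'
#' @param pop population label.
#' @param chrom_lengths named chromosome lengths.
#' @param id individual identifier.
#' @param labels the ancestry label set (first = wild, fusion-carrying).
#' @return a `sim_individual`.
#' @export
founder_individual <- function(pop, chrom_lengths = default_chrom_lengths(),
                               id = pop,
                               labels = c("WB", "EUR_DP", "ASIA_DP")) {
  anc <- match(pop, labels)
  if (is.na(anc)) stop("unknown population label: ", pop)
  nc <- length(chrom_lengths)
  hap <- cbind(seq_len(nc), rep(1, nc), unname(chrom_lengths), rep(anc, nc))
  fused <- rep(anc == 1L, 2L)
  new_sim_individual(id, hap, hap, fused, depth = 0L, chrom_lengths, labels)
}

merge_adjacent_mat <- function(tr) {
  n <- nrow(tr)
  if (n <= 1L) return(tr)
  new_run <- c(TRUE, tr[-1, COL_CHROM] != tr[-n, COL_CHROM] |
                 tr[-1, COL_ANC] != tr[-n, COL_ANC] |
                 tr[-1, COL_START] != tr[-n, COL_END] + 1)
  last <- c(which(new_run)[-1] - 1L, n)
  cbind(tr[new_run, COL_CHROM], tr[new_run, COL_START],
        tr[last, COL_END], tr[new_run, COL_ANC])
}

# One gamete: Poisson crossovers uniform on bp within each linkage group,
# no interference; returns haplotype tracts plus the transmitted fusion allele.
make_gamete <- function(ind, layout, recomb_rate) {
  frags <- vector("list", length(layout$groups)); fused_allele <- NA
  for (gi in seq_along(layout$groups)) {
    ginfo <- layout$groups[[gi]]
    L <- layout$len[[gi]]
    nxo <- if (recomb_rate > 0) stats::rpois(1L, recomb_rate * L) else 0L
    bounds <- c(0, sort(stats::runif(nxo, 0, L)), L)
    h0 <- sample.int(2L, 1L)
    # parent haplotypes in group coordinates, sorted by group start
    haps <- lapply(list(ind$hap1, ind$hap2), function(hap) {
      sel <- hap[, COL_CHROM] %in% ginfo$chrom
      tr <- hap[sel, , drop = FALSE]
      off <- ginfo$offset[match(tr[, COL_CHROM], ginfo$chrom)]
      gt <- cbind(tr[, COL_CHROM], tr[, COL_START] + off,
                  tr[, COL_END] + off, tr[, COL_ANC])
      gt[order(gt[, COL_START]), , drop = FALSE]
    })
    segs <- vector("list", length(bounds) - 1L)
    for (i in seq_len(length(bounds) - 1L)) {
      lo <- floor(bounds[i]) + 1; hi <- floor(bounds[i + 1L])
      if (hi < lo) next
      tr <- haps[[((h0 + i) %% 2L) + 1L]]
      sel <- tr[, COL_END] >= lo & tr[, COL_START] <= hi
      sub <- tr[sel, , drop = FALSE]
      sub[, COL_START] <- pmax(sub[, COL_START], lo)
      sub[, COL_END] <- pmin(sub[, COL_END], hi)
      segs[[i]] <- sub
    }
    gt <- do.call(rbind, segs)
    gt <- gt[order(gt[, COL_START]), , drop = FALSE]
    if (!is.na(layout$rob_group) && gi == layout$rob_group) {
      jseg <- findInterval(layout$junction + 0.5, bounds)
      hap_at_j <- ((h0 + jseg) %% 2L) + 1L
      fused_allele <- ind$fused[hap_at_j]
    }
    # back to chromosome coordinates, splitting at within-group boundaries
    off <- ginfo$offset[match(gt[, COL_CHROM], ginfo$chrom)]
    gt[, COL_START] <- gt[, COL_START] - off
    gt[, COL_END] <- gt[, COL_END] - off
    frags[[gi]] <- gt
  }
  hap <- do.call(rbind, frags)
  hap <- hap[order(hap[, COL_CHROM], hap[, COL_START]), , drop = FALSE]
  hap <- merge_adjacent_mat(hap)
  if (is.na(fused_allele))  # map without chromosomes 15/17: unlinked fallback
    fused_allele <- ind$fused[sample.int(2L, 1L)]
  list(hap = hap, fused = fused_allele)
}

cross_once <- function(pA, pB, id, recomb_rate) {
  if (!identical(pA$chrom_lengths, pB$chrom_lengths) ||
      !identical(pA$anc_labels, pB$anc_labels))
    stop("mismatched maps: parents were simulated on different chromosome sets")
  layout <- linkage_layout(pA$chrom_lengths)
  gA <- make_gamete(pA, layout, recomb_rate)
  gB <- make_gamete(pB, layout, recomb_rate)
  new_sim_individual(id, gA$hap, gB$hap, c(gA$fused, gB$fused),
                     depth = max(pA$pedigree_depth, pB$pedigree_depth) + 1L,
                     pA$chrom_lengths, pA$anc_labels)
}

as_parent <- function(p, panels, id) {
  if (is.character(p)) {
    founder_individual(p, panels$model$chrom_lengths, id = id,
                       labels = panels$model$labels)
  } else p
}

#' Simulate offspring of a cross
#'
#' Gametes are recombinant mosaics of the parental haplotypes with
#' Poisson-distributed crossovers (rate `recomb_rate` per bp). Ancestry
#' tracts and the rob(15;17) junction allele travel with the haplotype
#' segment spanning the centromere junction. Offspring genotypes are
#' sampled at each SNP from the tract ancestry's panel allele frequency.
#'
#' @param parentA,parentB `sim_individual` objects or population labels
#'   (labels create fresh pure founders).
#' @param n_offspring number of offspring.
#' @param panels a `sim_panels` object from [generate_reference_panels()].
#' @param recomb_rate per-bp per-meiosis crossover rate.
#' @param missing_rate i.i.d. missingness applied to emitted genotypes
#'   (defaults to the model's rate).
#' @param seed optional integer seed.
#' @param emit if `FALSE`, skip genotype emission (tracts only; fast).
#' @return list of `sim_individual` with genotypes attached.
#' @export
simulate_cross <- function(parentA, parentB, n_offspring = 1L, panels,
                           recomb_rate = 1e-8, missing_rate = NULL,
                           seed = NULL, emit = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_offspring >= 1, recomb_rate >= 0)
  missing_rate <- missing_rate %||% panels$model$missing_rate
  pA <- as_parent(parentA, panels, "parentA")
  pB <- as_parent(parentB, panels, "parentB")
  lapply(seq_len(n_offspring), function(i) {
    ind <- cross_once(pA, pB, sprintf("off_%03d", i), recomb_rate)
    if (emit) ind <- emit_genotypes(ind, panels$panel, missing_rate)
    ind
  })
}

#' Tracts of a simulated individual as a data frame
#' @param ind a `sim_individual`.
#' @return data frame: haplotype, chrom, start, end (1-based inclusive),
#'   ancestry.
#' @export
tracts_of <- function(ind) {
  do.call(rbind, lapply(1:2, function(h) {
    tr <- ind[[paste0("hap", h)]]
    data.frame(haplotype = h,
               chrom = names(ind$chrom_lengths)[tr[, COL_CHROM]],
               start = tr[, COL_START], end = tr[, COL_END],
               ancestry = ind$anc_labels[tr[, COL_ANC]],
               stringsAsFactors = FALSE)
  }))
}

# per-haplotype ancestry code at every SNP of the map (integer in 1..K)
hap_anc_at_snps <- function(hap, map, chrom_names) {
  out <- integer(nrow(map))
  map_cidx <- match(map$chrom, chrom_names)
  for (ci in unique(hap[, COL_CHROM])) {
    rows <- which(map_cidx == ci)
    if (!length(rows)) next
    tr <- hap[hap[, COL_CHROM] == ci, , drop = FALSE]
    out[rows] <- tr[findInterval(map$pos[rows], tr[, COL_START]), COL_ANC]
  }
  if (any(out == 0L))
    stop("haplotype tracts do not cover every SNP of the map")
  out
}

#' Emit genotypes for a simulated individual
#'
#' For each haplotype and SNP, an allele is drawn Bernoulli(f) from the alt
#' allele frequency of the tract's ancestry; the genotype is the allele sum,
#' masked missing i.i.d. at `missing_rate`.
#'
#' @param ind a `sim_individual`.
#' @param panel a `ref_panel` (true simulation frequencies).
#' @param missing_rate missingness probability per genotype.
#' @return the individual with a `geno` vector attached.
#' @export
emit_genotypes <- function(ind, panel, missing_rate = 0.02) {
  M <- nrow(panel$map)
  cn <- names(ind$chrom_lengths)
  a1 <- hap_anc_at_snps(ind$hap1, panel$map, cn)
  a2 <- hap_anc_at_snps(ind$hap2, panel$map, cn)
  g <- stats::rbinom(M, 1L, panel$freq[cbind(seq_len(M), a1)]) +
    stats::rbinom(M, 1L, panel$freq[cbind(seq_len(M), a2)])
  if (missing_rate > 0) g[stats::runif(M) < missing_rate] <- NA_integer_
  ind$geno <- as.integer(g)
  ind
}

#' Assemble a cohort genotype matrix from simulated individuals
#' @param individuals list of `sim_individual` with genotypes emitted.
#' @param map the `snp_map` genotypes were emitted on.
#' @return a `genotype_matrix`.
#' @export
cohort_genotypes <- function(individuals, map) {
  geno <- do.call(rbind, lapply(individuals, function(i) {
    if (is.null(i$geno)) stop("individual ", i$id, " has no emitted genotypes")
    i$geno
  }))
  genotype_matrix(geno, map, ids = vapply(individuals, `[[`, "", "id"))
}

#' True global ancestry proportions of a simulated individual
#'
#' Tract-length-weighted ancestry fractions over both haplotypes; sums to 1.
#'
#' @param ind a `sim_individual`.
#' @return named numeric vector of proportions (one per ancestry label).
#' @export
true_q <- function(ind) {
  K <- length(ind$anc_labels)
  tot <- 2 * sum(ind$chrom_lengths)
  q <- numeric(K)
  for (h in list(ind$hap1, ind$hap2)) {
    w <- h[, COL_END] - h[, COL_START] + 1
    for (k in seq_len(K)) q[k] <- q[k] + sum(w[h[, COL_ANC] == k])
  }
  stats::setNames(q / tot, ind$anc_labels)
}

#' Truth table for a simulated cohort
#' @param individuals list of `sim_individual`.
#' @return data frame with id, karyotype, pedigree depth and true q.
#' @export
truth_table <- function(individuals) {
  labels <- individuals[[1]]$anc_labels
  qs <- t(vapply(individuals, true_q, numeric(length(labels))))
  colnames(qs) <- paste0("q_", labels)
  data.frame(id = vapply(individuals, `[[`, "", "id"),
             karyotype = vapply(individuals, `[[`, 0L, "karyotype"),
             pedigree_depth = vapply(individuals, `[[`, 0L, "pedigree_depth"),
             qs, stringsAsFactors = FALSE, row.names = NULL)
}

#' True local-ancestry dosages of a simulated cohort
#'
#' Converts haplotype tracts into a per-SNP ancestry dosage field (0-2 per
#' ancestry), the same container the HMM decoder returns, for use as ground
#' truth in benchmarks.
#'
#' @param individuals list of `sim_individual`.
#' @param map `snp_map` to evaluate at (any positions on the simulated
#'   chromosomes, e.g. including extra junction-flanking markers).
#' @return a `lai_field` (see [posterior_dosages()]).
#' @export
truth_dosages <- function(individuals, map) {
  labels <- individuals[[1]]$anc_labels
  cn <- names(individuals[[1]]$chrom_lengths)
  n <- length(individuals); M <- nrow(map); K <- length(labels)
  ids <- vapply(individuals, `[[`, "", "id")
  dos <- array(0, dim = c(n, M, K), dimnames = list(ids, map$id, labels))
  for (i in seq_len(n)) {
    a1 <- hap_anc_at_snps(individuals[[i]]$hap1, map, cn)
    a2 <- hap_anc_at_snps(individuals[[i]]$hap2, map, cn)
    for (k in seq_len(K)) dos[i, , k] <- (a1 == k) + (a2 == k)
  }
  structure(list(dosage = dos, map = map, labels = labels, ids = ids,
                 source = "truth"), class = "lai_field")
}

#' Backcross pedigree cohort
#'
#' Each individual is bred as an F1 (wild x domestic founders) backcrossed
#' to fresh wild founders for `depth` further generations, so its expected
#' domestic fraction is 2^-(depth+1).
#'
#' @param panels a `sim_panels` object.
#' @param n cohort size.
#' @param depths backcross generations per individual (recycled).
#' @param dp_label domestic founder population.
#' @param recomb_rate per-bp crossover rate.
#' @param seed integer seed.
#' @param emit emit genotypes (slow part; disable for tract-only studies).
#' @param missing_rate missingness for emission.
#' @return list of `sim_individual`.
#' @export
backcross_cohort <- function(panels, n, depths = 3L, dp_label = "EUR_DP",
                             recomb_rate = 1e-8, seed = NULL, emit = TRUE,
                             missing_rate = NULL) {
  if (!is.null(seed)) set.seed(seed)
  missing_rate <- missing_rate %||% panels$model$missing_rate
  depths <- rep_len(depths, n)
  labels <- panels$model$labels
  wb <- labels[1]
  cl <- panels$model$chrom_lengths
  lapply(seq_len(n), function(i) {
    ind <- cross_once(founder_individual(wb, cl, labels = labels),
                      founder_individual(dp_label, cl, labels = labels),
                      "f1", recomb_rate)
    for (j in seq_len(depths[i]))
      ind <- cross_once(ind, founder_individual(wb, cl, labels = labels),
                        "bc", recomb_rate)
    ind$id <- sprintf("bc%d_%04d", depths[i], i)
    ind$pedigree_depth <- depths[i] + 1L
    if (emit) ind <- emit_genotypes(ind, panels$panel, missing_rate)
    ind
  })
}

#' Overwrite local ancestry in an interval (introgression injection)
#'
#' Within `interval`, each individual's haplotype tracts are overwritten to
#' domestic ancestry independently with probability `target_dp_dosage / 2`
#' per haplotype; genotypes are re-sampled inside the interval and truth
#' records update automatically (tracts carry the truth).
#'
#' @param individuals list of `sim_individual`.
#' @param interval list or vector with `chrom`, `start`, `end` (1-based bp).
#' @param target_dp_dosage expected domestic dosage in `[0, 2]`.
#' @param panels `sim_panels` (for SNP lookup and genotype re-emission).
#' @param dp_label ancestry to inject.
#' @param seed optional integer seed.
#' @return modified list of individuals.
#' @export
inject_introgression <- function(individuals, interval, target_dp_dosage,
                                 panels, dp_label = "EUR_DP", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(target_dp_dosage >= 0, target_dp_dosage <= 2)
  chrom <- as.character(interval[["chrom"]])
  start <- as.numeric(interval[["start"]]); end <- as.numeric(interval[["end"]])
  map <- panels$map
  cl <- panels$model$chrom_lengths
  if (!chrom %in% names(cl) || start < 1 || end > cl[[chrom]] || start >= end)
    stop("interval outside map: ", chrom, ":", start, "-", end)
  in_iv <- map$chrom == chrom & map$pos >= start & map$pos <= end
  if (sum(in_iv) < 2)
    stop("interval must cover at least 2 SNPs (covers ", sum(in_iv), ")")
  if (target_dp_dosage == 0) return(individuals)
  cidx <- match(chrom, names(cl))
  aidx <- match(dp_label, panels$model$labels)
  p <- target_dp_dosage / 2
  lapply(individuals, function(ind) {
    touched <- FALSE
    for (h in c("hap1", "hap2")) {
      if (stats::runif(1) < p) {
        ind[[h]] <- overwrite_tract_mat(ind[[h]], cidx, start, end, aidx)
        touched <- TRUE
      }
    }
    if (touched && !is.null(ind$geno)) {
      idx <- which(in_iv)
      cn <- names(ind$chrom_lengths)
      a1 <- hap_anc_at_snps(ind$hap1, map, cn)[idx]
      a2 <- hap_anc_at_snps(ind$hap2, map, cn)[idx]
      g <- stats::rbinom(length(idx), 1L, panels$panel$freq[cbind(idx, a1)]) +
        stats::rbinom(length(idx), 1L, panels$panel$freq[cbind(idx, a2)])
      if (panels$model$missing_rate > 0)
        g[stats::runif(length(idx)) < panels$model$missing_rate] <- NA_integer_
      ind$geno[idx] <- as.integer(g)
    }
    ind
  })
}

overwrite_tract_mat <- function(hap, cidx, start, end, aidx) {
  on_ch <- hap[, COL_CHROM] == cidx
  tr <- hap[on_ch, , drop = FALSE]
  keep <- tr[, COL_END] < start | tr[, COL_START] > end
  pieces <- list(tr[keep, , drop = FALSE])
  ov <- tr[!keep, , drop = FALSE]
  left <- ov[ov[, COL_START] < start, , drop = FALSE]
  if (nrow(left)) {
    left[, COL_END] <- pmin(left[, COL_END], start - 1)
    pieces[[length(pieces) + 1L]] <- left
  }
  right <- ov[ov[, COL_END] > end, , drop = FALSE]
  if (nrow(right)) {
    right[, COL_START] <- pmax(right[, COL_START], end + 1)
    pieces[[length(pieces) + 1L]] <- right
  }
  pieces[[length(pieces) + 1L]] <- cbind(cidx, start, end, aidx)
  new <- do.call(rbind, pieces)
  new <- new[order(new[, COL_START]), , drop = FALSE]
  new <- merge_adjacent_mat(new)
  out <- rbind(hap[!on_ch, , drop = FALSE], new)
  out[order(out[, COL_CHROM], out[, COL_START]), , drop = FALSE]
}

#' Simulate genotypes directly under the global admixture model
#'
#' Genotypes are binomial(2, sum_k q_k f_km) draws — the exact generative
#' model of the supervised ancestry likelihood — used for parameter-recovery
#' benchmarks of [estimate_q()].
#'
#' @param panel a `ref_panel`.
#' @param Q matrix of true ancestry proportions, individuals x populations.
#' @param seed optional integer seed.
#' @param missing_rate i.i.d. missingness.
#' @return a `genotype_matrix`.
#' @export
simulate_q_genotypes <- function(panel, Q, seed = NULL, missing_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  Q <- as.matrix(Q)
  stopifnot(ncol(Q) == ncol(panel$freq),
            all(abs(rowSums(Q) - 1) < 1e-8))
  M <- nrow(panel$freq); n <- nrow(Q)
  P <- panel$freq %*% t(Q)  # M x n mixture frequencies
  g <- matrix(stats::rbinom(n * M, 2L, t(P)), nrow = n, ncol = M)
  if (missing_rate > 0)
    g[stats::runif(n * M) < missing_rate] <- NA_integer_
  genotype_matrix(g, panel$map, ids = sprintf("adm_%03d", seq_len(n)))
}

#' Write truth tracts to a tab-separated file
#' @param individuals list of `sim_individual`.
#' @param path output TSV path (individual, haplotype, chrom, start, end,
#'   ancestry; 1-based inclusive).
#' @export
write_truth_tracts <- function(individuals, path) {
  rows <- lapply(individuals, function(ind)
    cbind(individual = ind$id, tracts_of(ind)))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write truth karyotypes to a two-column TSV
#' @param individuals list of `sim_individual`.
#' @param path output path.
#' @export
write_truth_karyotypes <- function(individuals, path) {
  utils::write.table(
    data.frame(individual = vapply(individuals, `[[`, "", "id"),
               karyotype = vapply(individuals, `[[`, 0L, "karyotype")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
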