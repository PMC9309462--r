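#' SNP map
#'
#' A `snp_map` is a data frame with one row per SNP and columns `chrom`
#' (character), `pos` (1-based bp, integer), `ref` and `alt` (single-letter
#' allele labels) and `id`. Allele counts throughout the package count the
#' `alt` allele. Positions must be strictly increasing within a chromosome
#' and all chromosomes must be autosomal.
#'
#' @param chrom chromosome identifiers (coerced to character).
#' @param pos 1-based base-pair positions.
#' @param ref,alt allele letters; `alt` is the counted allele.
#' @param id SNP identifiers; generated as `chrom_pos` when `NULL`.
#' @return a data frame of class `snp_map`.
#' @export
snp_map <- function(chrom, pos, ref, alt, id = NULL) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (is.null(id)) id <- paste(chrom, pos, sep = "_")
  m <- data.frame(chrom = chrom, pos = pos, ref = as.character(ref),
                  alt = as.character(alt), id = as.character(id),
                  stringsAsFactors = FALSE)
  validate_snp_map(m)
  class(m) <- c("snp_map", "data.frame")
  m
}

validate_snp_map <- function(m) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "id") %in% names(m)))
  if (any(toupper(m$chrom) %in% c("X", "Y", "MT", "M")))
    stop("snp_map must contain autosomes only")
  if (anyNA(m$pos) || any(m$pos < 1L))
    stop("snp_map positions must be positive integers")
  for (ch in unique(m$chrom)) {
    p <- m$pos[m$chrom == ch]
    if (any(diff(p) <= 0))
      stop("snp_map positions must be strictly increasing within chromosome ",
           ch)
  }
  if (anyDuplicated(m$id)) stop("duplicated SNP ids in snp_map")
  invisible(m)
}

#' Default chromosome lengths used by the simulator
#'
#' Four pig autosomes; chromosome 17's length is the assembly value used to
#' build the fused rob(15;17) map (its last nucleotide precedes the first
#' q-arm nucleotide of the fused chromosome).
#'
#' @return named numeric vector of chromosome lengths in bp.
#' @export
default_chrom_lengths <- function() {
  c("1" = 274330532, "13" = 208334590, "15" = 140412725, "17" = 63494081)
}

#' Length of pig chromosome 17 used for the fused rob(15;17) map
#' @export
CHR17_LENGTH <- 63494081L

#' Simulate a SNP map
#'
#' Places `n_snps` SNPs uniformly at random along the given chromosomes,
#' allocating SNP counts proportionally to chromosome length (at least two
#' per chromosome), with random distinct ref/alt letters.
#'
#' @param n_snps total number of SNPs.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @return a `snp_map`.
#' @export
sim_snp_map <- function(n_snps, chrom_lengths = default_chrom_lengths()) {
  stopifnot(n_snps >= 2 * length(chrom_lengths))
  n_per <- stats::setNames(pmax(2L, round(n_snps * chrom_lengths /
                                            sum(chrom_lengths))),
                           names(chrom_lengths))
  # adjust rounding drift on the largest chromosome
  n_per[which.max(chrom_lengths)] <- n_per[which.max(chrom_lengths)] +
    (n_snps - sum(n_per))
  bases <- c("A", "C", "G", "T")
  chrom <- character(0); pos <- integer(0)
  for (ch in names(chrom_lengths)) {
    p <- sort(sample.int(chrom_lengths[[ch]], n_per[[ch]], replace = FALSE))
    chrom <- c(chrom, rep(ch, length(p)))
    pos <- c(pos, p)
  }
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  snp_map(chrom, pos, ref, alt)
}

#' Genotype matrix
#'
#' Individuals by SNPs matrix of alt-allele counts (0/1/2, `NA` = missing)
#' tied to a [snp_map].
#'
#' @param geno integer matrix, individuals in rows, SNPs in columns.
#' @param map a `snp_map` with one row per column of `geno`.
#' @param ids individual identifiers (defaults to rownames).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map, ids = rownames(geno)) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (ncol(geno) != nrow(map))
    stop("genotype matrix has ", ncol(geno), " SNPs but map has ", nrow(map))
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(geno)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated individual ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotypes must be 0, 1, 2 or NA")
  rownames(geno) <- ids
  colnames(geno) <- map$id
  structure(list(geno = geno, map = map, ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "individuals x", ncol(x$geno),
      "SNPs on", length(unique(x$map$chrom)), "chromosomes;",
      sprintf("missing %.2f%%", 100 * mean(is.na(x$geno))), "\n")
  invisible(x)
}

#' Per-individual call rate
#'
#' @param gm a `genotype_matrix`.
#' @return named vector of 1 - missing fraction per individual.
#' @export
call_rate <- function(gm) rowMeans(!is.na(gm$geno))

#' Observed alt-allele frequencies
#' @param gm a `genotype_matrix`.
#' @return per-SNP alt allele frequency over non-missing genotypes.
#' @export
allele_freq <- function(gm) colMeans(gm$geno, na.rm = TRUE) / 2

subset_snps <- function(gm, keep) {
  map <- gm$map[keep, , drop = FALSE]
  class(map) <- c("snp_map", "data.frame")
  genotype_matrix(gm$geno[, keep, drop = FALSE], map, gm$ids)
}

subset_inds <- function(gm, keep) {
  if (is.character(keep)) keep <- match(keep, gm$ids)
  genotype_matrix(gm$geno[keep, , drop = FALSE], gm$map, gm$ids[keep])
}

#' Reference panel of per-population allele frequencies
#'
#' Holds, for each ancestral population, the per-SNP alt-allele frequency
#' f_km used by the supervised ancestry likelihood and by the local-ancestry
#' HMM emissions. Frequencies are clamped to `[eps, 1 - eps]` so fixed
#' differences never yield infinite log likelihoods.
#'
#' @param freq numeric matrix, SNPs x populations, column names = labels.
#' @param map the `snp_map` the rows refer to.
#' @param eps clamping bound; documented default 1e-4 for known (simulated)
#'   truth frequencies, use [panel_from_genotypes()] for estimated ones.
#' @return object of class `ref_panel`.
#' @export
ref_panel <- function(freq, map, eps = 1e-4) {
  freq <- as.matrix(freq)
  if (nrow(freq) != nrow(map)) stop("frequency rows must match map")
  if (is.null(colnames(freq))) stop("freq must have population column names")
  freq <- pmin(pmax(freq, eps), 1 - eps)
  structure(list(freq = freq, map = map, labels = colnames(freq), eps = eps),
            class = "ref_panel")
}

#' Estimate a reference panel from population genotype matrices
#'
#' Allele frequencies are estimated per population and clamped with an
#' add-one style bound eps_k = 1 / (2 n_k + 2), avoiding zero or one
#' frequencies on fixed differences.
#'
#' @param gm_list named list of `genotype_matrix`, one per population.
#' @return a `ref_panel`.
#' @export
panel_from_genotypes <- function(gm_list) {
  stopifnot(length(gm_list) >= 1, !is.null(names(gm_list)))
  map <- gm_list[[1]]$map
  freq <- sapply(gm_list, function(g) {
    if (!identical(g$map$id, map$id)) stop("population maps differ")
    f <- allele_freq(g)
    eps <- 1 / (2 * nrow(g$geno) + 2)
    pmin(pmax(f, eps), 1 - eps)
  })
  ref_panel(freq, map, eps = min(1 / (2 * vapply(gm_list, function(g) nrow(g$geno), 1) + 2)))
}
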