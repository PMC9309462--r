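# Genotype input/output and marker/sample filtering.
#
# Text formats only: PLINK-style .ped/.map (whitespace separated, alleles as
# letters, "0 0" = missing) and VCF 4.x with a GT field. A classic 4-column
# .map carries no allele labels, so the writer also emits a "<prefix>.ref"
# sidecar (SNP id, counted allele — the PLINK --reference-allele format);
# the reader uses it when present and otherwise counts the minor allele.

#' Write genotypes as PLINK-style .ped/.map text
#'
#' @param gm a `genotype_matrix`.
#' @param prefix output path prefix; writes `<prefix>.ped`, `<prefix>.map`
#'   and `<prefix>.ref` (counted-allele sidecar).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  map <- gm$map
  utils::write.table(
    data.frame(map$chrom, map$id, 0, map$pos),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(map$id, map$alt),
    paste0(prefix, ".ref"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  g <- gm$geno
  n <- nrow(g)
  # allele pairs per genotype: 0 -> ref/ref, 1 -> ref/alt, 2 -> alt/alt
  lines <- vapply(seq_len(n), function(i) {
    a1 <- ifelse(is.na(g[i, ]), "0", ifelse(g[i, ] >= 1, map$alt, map$ref))
    a2 <- ifelse(is.na(g[i, ]), "0", ifelse(g[i, ] == 2, map$alt, map$ref))
    paste(c(gm$ids[i], gm$ids[i], 0, 0, 0, -9,
            as.vector(rbind(a1, a2))), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Write genotypes as an uncompressed VCF (GT only, unphased)
#'
#' @param gm a `genotype_matrix`.
#' @param path output `.vcf` path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(gm, path) {
  map <- gm$map
  hdr <- c("##fileformat=VCFv4.2",
           "##source=boarmix",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$ids), collapse = "\t"))
  gt <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L], nrow = nrow(gm$geno))
  gt[is.na(gm$geno)] <- "./."
  body <- vapply(seq_len(nrow(map)), function(m) {
    paste(c(map$chrom[m], map$pos[m], map$id[m], map$ref[m], map$alt[m],
            ".", "PASS", ".", "GT", gt[, m]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from PLINK .ped/.map or VCF
#'
#' Allele counts are counts of the counted allele: for VCF the ALT allele;
#' for .ped the allele named in a `<prefix>.ref` sidecar when present,
#' otherwise the minor (first-listed on ties) allele. Multi-allelic sites
#' are rejected.
#'
#' @param path `.vcf` file, or a prefix / `.ped` path for PLINK input.
#' @param format `"ped"` or `"vcf"`.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("ped", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") read_vcf_gt(path) else read_plink(path)
}

read_plink <- function(prefix) {
  prefix <- sub("\\.ped$", "", prefix)
  ped_path <- paste0(prefix, ".ped"); map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stop("file not found: ", p)
  mp <- utils::read.table(map_path, header = FALSE,
                          colClasses = c("character", "character",
                                         "numeric", "integer"))
  M <- nrow(mp)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  ids <- character(n)
  alle <- matrix("0", n, 2L * M)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * M)
      stop("malformed .ped record at line ", i, ": expected ",
           6L + 2L * M, " fields, found ", length(f))
    ids[i] <- f[2]
    alle[i, ] <- f[-(1:6)]
  }
  if (anyDuplicated(ids))
    stop("duplicated individual id in .ped: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ref_path <- paste0(prefix, ".ref")
  counted <- NULL
  if (file.exists(ref_path)) {
    rf <- utils::read.table(ref_path, header = FALSE,
                            colClasses = "character")
    counted <- rf[[2]][match(mp[[2]], rf[[1]])]
  }
  geno <- matrix(NA_integer_, n, M)
  cnt <- character(M); other <- character(M)
  for (m in seq_len(M)) {
    a <- alle[, c(2L * m - 1L, 2L * m), drop = FALSE]
    obs <- a[a != "0"]
    al <- unique(obs)
    if (length(al) > 2L)
      stop("more than two alleles at site ", mp[[2]][m], " (line ", m,
           " of .map): ", paste(al, collapse = "/"))
    cnt[m] <- if (!is.null(counted) && !is.na(counted[m])) counted[m]
      else if (!length(al)) "N"
      else al[order(tabulate(match(obs, al), length(al)), seq_along(al))][1]
    gi <- (a[, 1] == cnt[m]) + (a[, 2] == cnt[m])
    gi[a[, 1] == "0" | a[, 2] == "0"] <- NA_integer_
    geno[, m] <- as.integer(gi)
    oth <- setdiff(al, cnt[m])
    other[m] <- if (length(oth)) oth[1] else "N"
  }
  map <- snp_map(mp[[1]], mp[[4]], ref = other, alt = cnt, id = mp[[2]])
  genotype_matrix(geno, map, ids = ids)
}

read_vcf_gt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-variant files come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    stop("multi-allelic site(s) not supported: ",
         paste(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]),
               collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  if (anyDuplicated(ids))
    stop("duplicated individual id in VCF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  count_alt <- function(x) {
    al <- strsplit(x, "[/|]")
    vapply(al, function(a) {
      if (any(is.na(a)) || any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  gt[is.na(gt)] <- "./."
  geno <- matrix(NA_integer_, length(ids), nrow(fix))
  for (s in seq_along(ids)) geno[s, ] <- count_alt(gt[, s])
  idcol <- fix[, "ID"]
  miss_id <- is.na(idcol) | idcol == "."
  idcol[miss_id] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[miss_id]
  map <- snp_map(fix[, "CHROM"], as.integer(fix[, "POS"]),
                 ref = fix[, "REF"], alt = fix[, "ALT"], id = idcol)
  genotype_matrix(geno, map, ids = ids)
}

#' Filter SNPs on minor allele frequency and missingness
#'
#' Retains SNPs whose minor allele frequency is strictly greater than
#' `maf_min` and whose missing fraction is strictly less than `miss_max`.
#' No Hardy–Weinberg filter is applied: admixture itself perturbs HWE, so a
#' HWE criterion would preferentially discard the signal of interest.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_min MAF threshold (strict `>`), default 0.05.
#' @param miss_max missing-fraction threshold (strict `<`), default 0.05.
#' @param autosomes_only drop non-autosomal chromosomes (maps are validated
#'   autosomal on construction; kept for interface completeness).
#' @return filtered `genotype_matrix`.
#' @export
filter_snps <- function(gm, maf_min = 0.05, miss_max = 0.05,
                        autosomes_only = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  p <- allele_freq(gm)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing column
  miss <- colMeans(is.na(gm$geno))
  # strict inequalities with a representation guard: observed fractions like
  # 19/20 are not exact in binary, which would otherwise flip ties at the
  # threshold either way
  eps <- 1e-9
  keep <- maf > maf_min + eps & miss < miss_max - eps
  if (autosomes_only)
    keep <- keep & !(toupper(gm$map$chrom) %in% c("X", "Y", "MT", "M"))
  if (!any(keep))
    stop("all SNPs removed by filtering; review maf_min/miss_max thresholds")
  subset_snps(gm, keep)
}

#' Pairwise identity-by-state matrix
#'
#' IBS between two individuals is the mean over SNPs non-missing in both of
#' (2 - |g_i - g_j|) / 2, i.e. the fraction of shared alleles.
#'
#' @param gm a `genotype_matrix`.
#' @return symmetric matrix of IBS values in `[0, 1]`.
#' @export
ibs_matrix <- function(gm) {
  g <- gm$geno
  n <- nrow(g)
  out <- matrix(1, n, n, dimnames = list(gm$ids, gm$ids))
  for (i in seq_len(n - 1L)) {
    gi <- g[i, ]
    for (j in (i + 1L):n) {
      ok <- !is.na(gi) & !is.na(g[j, ])
      v <- if (any(ok)) mean((2 - abs(gi[ok] - g[j, ok])) / 2) else NA_real_
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}

#' Thin near-duplicate individuals by identity-by-state
#'
#' All pairs with IBS above `ibs_threshold` are processed in descending IBS
#' order (ties by first id); within each pair still intact, the member with
#' the lower call rate is dropped (ties keep the earlier-listed individual).
#' Greedy and deterministic; never removes both members of a pair.
#'
#' @param gm a `genotype_matrix`.
#' @param ibs_threshold IBS above which a pair is considered redundant,
#'   in (0, 1].
#' @return character vector of retained individual ids.
#' @export
ibs_thin <- function(gm, ibs_threshold) {
  stopifnot(ibs_threshold > 0, ibs_threshold <= 1)
  ibs <- ibs_matrix(gm)
  cr <- call_rate(gm)
  n <- nrow(ibs)
  pairs <- which(upper.tri(ibs) & ibs > ibs_threshold, arr.ind = TRUE)
  if (!nrow(pairs)) return(gm$ids)
  ord <- order(-ibs[pairs], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  dropped <- logical(n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (dropped[i] || dropped[j]) next
    drop <- if (cr[i] < cr[j]) i else if (cr[j] < cr[i]) j else max(i, j)
    dropped[drop] <- TRUE
  }
  gm$ids[!dropped]
}

#' Prune SNPs in linkage disequilibrium
#'
#' Left-to-right within each chromosome: a SNP is dropped when its squared
#' genotype correlation with any retained SNP at most `window` positions
#' earlier (in map order) exceeds `r2_cutoff`, keeping one representative
#' per LD cluster.
#'
#' @param gm a `genotype_matrix`.
#' @param r2_cutoff squared-correlation cutoff in (0, 1], default 0.1.
#' @param window comparison window in SNPs, default 50.
#' @return pruned `genotype_matrix`.
#' @export
ld_prune <- function(gm, r2_cutoff = 0.1, window = 50L) {
  stopifnot(r2_cutoff > 0, r2_cutoff <= 1, window >= 1)
  keep <- logical(nrow(gm$map))
  for (ch in unique(gm$map$chrom)) {
    idx <- which(gm$map$chrom == ch)
    kept <- integer(0)
    for (m in idx) {
      recent <- kept[kept >= m - window]
      drop <- FALSE
      for (k in rev(recent)) {
        r2 <- suppressWarnings(
          stats::cor(gm$geno[, k], gm$geno[, m],
                     use = "pairwise.complete.obs"))^2
        if (!is.na(r2) && r2 > r2_cutoff) { drop <- TRUE; break }
      }
      if (!drop) {
        kept <- c(kept, m)
        keep[m] <- TRUE
      }
    }
  }
  subset_snps(gm, keep)
}
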