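# Genome scan for localised deficits of wild-boar ancestry
# (candidate adaptive introgression from domestic pigs).

#' Mean wild-boar ancestry per SNP across a cohort
#'
#' Averages the wild ancestry proportion (dosage / 2) over individuals at
#' every SNP and records the genome-wide mean and standard deviation of the
#' per-SNP series, which parameterise the SD-based flagging thresholds.
#'
#' @param field a `lai_field` with at least 2 individuals.
#' @param wild_label the wild ancestry component.
#' @return object of class `scan_result`: data frame (`chrom`, `pos`,
#'   `mean_wb`) with attributes `mu`, `sigma`, `n_individuals`.
#' @export
ancestry_scan <- function(field, wild_label = "WB") {
  n <- dim(field$dosage)[1]
  if (is.null(n) || n < 2L) stop("ancestry_scan needs at least 2 individuals")
  prop <- field$dosage[, , wild_label] / 2
  mean_wb <- colMeans(prop, na.rm = TRUE)
  out <- data.frame(chrom = field$map$chrom, pos = field$map$pos,
                    mean_wb = as.numeric(mean_wb),
                    stringsAsFactors = FALSE)
  structure(out, mu = mean(mean_wb), sigma = stats::sd(mean_wb),
            n_individuals = n, class = c("scan_result", "data.frame"))
}

#' Flag low-ancestry regions at k standard deviations below the mean
#'
#' SNPs whose cohort-mean wild ancestry falls below `mu - k_sd * sigma` are
#' flagged; runs of flagged SNPs on the same chromosome separated by at
#' most `max_gap` unflagged SNPs are merged into intervals bounded by the
#' bp positions of their first and last flagged SNP.
#'
#' @param scan a `scan_result`.
#' @param k_sd threshold multiplier, conventionally 3 or 6.
#' @param max_gap maximum number of unflagged SNPs bridged inside an
#'   interval (default 0: strictly consecutive).
#' @return data frame of sorted non-overlapping intervals: `chrom`,
#'   `start`, `end` (1-based inclusive bp), `n_snps`, `min_mean`; attribute
#'   `threshold`.
#' @export
flag_regions <- function(scan, k_sd = 6, max_gap = 0L) {
  mu <- attr(scan, "mu"); sigma <- attr(scan, "sigma")
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate scan: per-SNP ancestry series has zero standard deviation")
  thr <- mu - k_sd * sigma
  flagged <- scan$mean_wb < thr
  out <- list()
  for (ch in unique(scan$chrom)) {
    rows <- which(scan$chrom == ch)
    f <- which(flagged[rows])
    if (!length(f)) next
    grp <- cumsum(c(1L, diff(f) > max_gap + 1L))
    for (g in unique(grp)) {
      idx <- rows[f[grp == g]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = scan$pos[idx[1]], end = scan$pos[idx[length(idx)]],
        n_snps = length(idx), min_mean = min(scan$mean_wb[idx]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_snps = integer(0), min_mean = numeric(0))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  attr(res, "k_sd") <- k_sd
  res
}

#' Write flagged intervals as BED (0-based half-open) and TSV (1-based)
#' @param regions output of [flag_regions()].
#' @param bed_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_regions <- function(regions, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(regions$chrom, regions$start - 1L, regions$end)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(regions), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(regions)
}
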