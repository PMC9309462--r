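# In-silico karyotyping at the rob(15;17) centromere junction.
#
# Chromosomes 15 and 17 are acrocentric in domestic pigs and fused at
# their centromeres into one submetacentric chromosome in Western European
# wild boar. The fused in-silico map keeps chromosome 17 coordinates and
# shifts chromosome 15 by the chromosome 17 length, so the first chr15
# nucleotide becomes fused coordinate 63,494,081 + 1; the junction sits at
# the chr17 length. An individual's chromosome number follows from the
# ancestry of its two haplotypes at the SNPs flanking the junction: both
# wild -> 2n = 36, one domestic -> 37, both domestic -> 38.

#' Build the fused rob(15;17) SNP map
#'
#' @param map15,map17 single-chromosome `snp_map`s (chromosomes "15", "17").
#' @param chr17_length total chromosome 17 length in bp; the junction
#'   coordinate. Default 63,494,081.
#' @return object of class `fused_map`: data frame (`id`, `fused_pos`,
#'   `chrom`, `pos`) sorted by fused position, with attribute `junction`.
#' @export
fuse_map <- function(map15, map17, chr17_length = CHR17_LENGTH) {
  for (m in list(map15, map17))
    if (length(unique(m$chrom)) != 1L)
      stop("fuse_map expects single-chromosome maps")
  if (any(diff(map15$pos) <= 0) || any(diff(map17$pos) <= 0))
    stop("maps must be position-sorted")
  if (any(map17$pos > chr17_length))
    stop("chr17 positions exceed chr17_length; fused positions would overlap")
  fused <- data.frame(
    id = c(map17$id, map15$id),
    fused_pos = c(map17$pos, map15$pos + chr17_length),
    chrom = c(map17$chrom, map15$chrom),
    pos = c(map17$pos, map15$pos),
    stringsAsFactors = FALSE)
  if (any(diff(fused$fused_pos) <= 0))
    stop("fused positions not strictly increasing")
  structure(fused, junction = chr17_length,
            class = c("fused_map", "data.frame"))
}

#' Predict 2n karyotypes from local-ancestry dosages at the junction
#'
#' The wild-boar allelic proportion of each flank is the mean WB dosage
#' over the `flank_window` SNPs nearest the junction on that side, divided
#' by 2; the combined proportion is the mean of the two flanks. The call is
#' 36 when the implied WB allele count (2 x combined) rounds to 2, 37 when
#' it rounds to 1 and 38 when it rounds to 0; exact .5 ties resolve toward
#' 37 (the heterozygote, flagging the animal rather than clearing it).
#'
#' @param field a `lai_field` (posterior or truth dosages).
#' @param fmap a `fused_map`.
#' @param flank_window SNPs per flank, default 1 ("the first SNPs on both
#'   sides of the centromere").
#' @param wild_label the wild ancestry component.
#' @return data frame: id, predicted_2n, WB dosage per flank, confidence
#'   (1 minus the distance of the implied allele count from the call).
#' @export
predict_karyotype <- function(field, fmap, flank_window = 1L,
                              wild_label = "WB") {
  junction <- attr(fmap, "junction")
  left_ids <- fmap$id[fmap$fused_pos <= junction]
  right_ids <- fmap$id[fmap$fused_pos > junction]
  if (!length(left_ids) || !length(right_ids))
    stop("no SNP on one side of the junction")
  if (length(left_ids) < flank_window || length(right_ids) < flank_window)
    stop("fewer than flank_window SNPs on one side of the junction")
  left_use <- utils::tail(left_ids, flank_window)   # nearest below junction
  right_use <- utils::head(right_ids, flank_window) # nearest above junction
  wb <- field$dosage[, , wild_label, drop = FALSE]
  dim(wb) <- dim(field$dosage)[1:2]
  colnames(wb) <- field$map$id
  miss <- setdiff(c(left_use, right_use), colnames(wb))
  if (length(miss))
    stop("dosages missing for junction-flanking SNPs: ",
         paste(miss, collapse = ", "))
  left_dos <- rowMeans(wb[, left_use, drop = FALSE])
  right_dos <- rowMeans(wb[, right_use, drop = FALSE])
  combined <- (left_dos / 2 + right_dos / 2) / 2
  x <- 2 * combined  # implied WB allele count at the junction, in [0, 2]
  called <- ifelse(x > 1.5, 2L, ifelse(x < 0.5, 0L, 1L))
  data.frame(id = field$ids,
             predicted_2n = 38L - called,
             wb_dosage_left = left_dos,
             wb_dosage_right = right_dos,
             confidence = 1 - pmin(1, abs(x - called)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Concordance between predicted and true karyotypes
#'
#' @param calls data frame from [predict_karyotype()] (columns `id`,
#'   `predicted_2n`).
#' @param truth data frame with columns `id` (or `individual`) and
#'   `karyotype`, or a named vector of true 2n values.
#' @return list with `confusion` (3x3, rows = predicted, columns = true),
#'   `per_class` (column-normalised diagonal, i.e. recall per true class)
#'   and `overall` (trace / total).
#' @export
karyotype_concordance <- function(calls, truth) {
  if (is.data.frame(truth)) {
    idc <- if ("id" %in% names(truth)) "id" else "individual"
    truth <- stats::setNames(truth$karyotype, truth[[idc]])
  }
  missing_ids <- setdiff(calls$id, names(truth))
  extra_ids <- setdiff(names(truth), calls$id)
  if (length(missing_ids) || length(extra_ids))
    stop("id mismatch between calls and truth; missing truth for: ",
         paste(missing_ids, collapse = ", "),
         if (length(extra_ids)) paste0("; truth without calls: ",
                                       paste(extra_ids, collapse = ", ")))
  lv <- c(36, 37, 38)
  confusion <- table(
    predicted = factor(calls$predicted_2n, levels = lv),
    true = factor(truth[calls$id], levels = lv))
  per_class <- diag(confusion) / colSums(confusion)
  list(confusion = confusion,
       per_class = stats::setNames(as.numeric(per_class), lv),
       overall = sum(diag(confusion)) / sum(confusion))
}

#' Write a fused map as TSV
#' @param fmap a `fused_map`.
#' @param path output path.
#' @export
write_fused_map <- function(fmap, path) {
  utils::write.table(as.data.frame(fmap), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
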