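#!/usr/bin/env Rscript
# PCA of the cohort plus reference panels and model-based clustering of
# (PC1, PC2) to flag putative recent hybrids among the candidate animals.

suppressPackageStartupMessages({
  library(boarmix)
  library(ggplot2)
})
out <- "results/analysis"
st <- readRDS("scratch/sim_state.rds")

gm <- read_genotypes(file.path(out, "cohort_filtered"), "ped")
sc <- pca_genotypes(gm, n_components = 10)
message("PC1/PC2 explain ",
        paste(round(100 * sc$explained[1:2], 1), collapse = "% / "), "%")

oc <- detect_outliers(sc)
truth <- truth_table(st$cohort)
flagged <- oc$id[oc$is_outlier]
message(length(flagged), " animals flagged as outliers; true wild ancestry ",
        "of flagged animals: ",
        paste(round(truth$q_WB[match(flagged, truth$id)], 2), collapse = ", "))

write.table(data.frame(id = sc$ids, sc$scores), file.path(out, "pca_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(oc, file.path(out, "outlier_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

df <- data.frame(PC1 = sc$scores[, 1], PC2 = sc$scores[, 2],
                 outlier = oc$is_outlier,
                 karyotype = factor(truth$karyotype[match(sc$ids, truth$id)]))
p <- ggplot(df, aes(PC1, PC2, colour = karyotype, shape = outlier)) +
  geom_point(size = 2) +
  labs(title = "Cohort structure on PC1/PC2",
       subtitle = "shapes mark mixture-model outliers") +
  theme_minimal()
ggsave(file.path(out, "pca_outliers.pdf"), p, width = 7, height = 5)
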