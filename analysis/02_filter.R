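#!/usr/bin/env Rscript
# Marker and sample quality control: re-read the PLINK text genotypes,
# apply the MAF > 0.05 / missingness < 0.05 filters (no Hardy-Weinberg
# criterion), thin near-duplicate samples by identity-by-state and record
# what an r2 = 0.1 LD pruning would retain.

suppressPackageStartupMessages(library(boarmix))
out <- "results/analysis"

gm <- read_genotypes(file.path(out, "cohort"), "ped")
message("read ", nrow(gm$geno), " animals x ", nrow(gm$map), " SNPs; ",
        "call rates ", paste(round(range(call_rate(gm)), 3), collapse = "-"))

gm_f <- filter_snps(gm, maf_min = 0.05, miss_max = 0.05)
message("MAF/missingness filters kept ", nrow(gm_f$map), " of ",
        nrow(gm$map), " SNPs")

kept <- ibs_thin(gm_f, 0.95)
message("IBS thinning at 0.95 kept ", length(kept), " of ",
        nrow(gm_f$geno), " animals")

pruned <- ld_prune(gm_f, r2_cutoff = 0.1, window = 50)
message("LD pruning at r2 > 0.1 would retain ", nrow(pruned$map),
        " SNPs (local-ancestry input is left unpruned; the HMM models LD ",
        "through tract persistence)")

write_plink(gm_f, file.path(out, "cohort_filtered"))
write.table(data.frame(id = kept), file.path(out, "kept_individuals.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
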