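#!/usr/bin/env Rscript
# Supervised global ancestry of every cohort animal against the three
# panel frequency sets, with 200-replicate bootstrap CIs and the
# unadmixed / admixed / recent-hybrid classification.

suppressPackageStartupMessages(library(boarmix))
out <- "results/analysis"
st <- readRDS("scratch/sim_state.rds")

gm <- read_genotypes(file.path(out, "cohort_filtered"), "ped")
keep <- match(gm$map$id, st$panels$map$id)
panel <- ref_panel(st$panels$panel$freq[keep, , drop = FALSE], gm$map)

qtab <- ancestry_q_table(gm, panel, n_boot = 200, seed = 20260904L)
write.table(qtab, file.path(out, "q_matrix.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- truth_table(st$cohort)
rmse <- sqrt(mean((qtab$q_WB - truth$q_WB[match(qtab$id, truth$id)])^2))
message("classes: ",
        paste(names(table(qtab$class)), table(qtab$class),
              sep = "=", collapse = ", "),
        "; wild-ancestry RMSE vs truth ", round(rmse, 3),
        "; median bootstrap SE ", round(median(qtab$se_WB), 4))
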