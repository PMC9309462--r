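#!/usr/bin/env Rscript
# Simulate the study system: three diverged reference panels (wild boar,
# European and Asian domestic pig) and a mixed cohort of pure, F1, F2 and
# backcross animals carrying the rob(15;17) fusion, with full tract and
# karyotype truth. Writes PLINK text genotypes and truth tables.

suppressPackageStartupMessages(library(boarmix))

seed <- 20260901L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

model <- population_model(n_snps = 3000)
panels <- generate_reference_panels(model,
                                    c(WB = 60, EUR_DP = 60, ASIA_DP = 40),
                                    seed = seed)
# field-realistic survey: predominantly wild-caught animals (pure or a few
# generations of backcrossing) with a handful of recent hybrids to detect
cohort <- sim_demo_cohort(panels,
                          list(n_pure = 100L, n_f1 = 10L, n_f2 = 5L,
                               n_bc = 35L, bc_depths = c(2L, 3L, 4L)),
                          seed = seed + 1L)
gm <- cohort_genotypes(cohort, panels$map)
truth <- truth_table(cohort)

write_plink(gm, file.path(out, "cohort"))
for (k in names(panels$genotypes))
  write_plink(panels$genotypes[[k]], file.path(out, paste0("panel_", k)))
write_truth_tracts(cohort, file.path(out, "truth_tracts.tsv"))
write_truth_karyotypes(cohort, file.path(out, "truth_karyotypes.tsv"))
write.table(data.frame(snp = panels$map$id, panels$panel$freq),
            file.path(out, "panel_freqs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(list(panels = panels, cohort = cohort), "scratch/sim_state.rds")

message("simulated ", length(cohort), " animals x ", nrow(panels$map),
        " SNPs; karyotypes: ",
        paste(names(table(truth$karyotype)), table(truth$karyotype),
              sep = "=", collapse = ", "),
        "; mean true wild ancestry ", round(mean(truth$q_WB), 3))
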