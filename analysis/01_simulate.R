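#!/usr/bin/env Rscript
# Simulate the synthetic immunopeptidome study: a proteolysis cohort with
# planted ladder artifacts, benign/tumor profiling cohorts with planted
# tumor-exclusive peptides, and the bundle files downstream stages consume.

suppressMessages(library(immunopepR))

seed <- 1L
out <- "results/bundle"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
study <- gen_proteolysis_cohort(cfg, n_samples = 10L)
cfg2 <- generator_config(seed = seed + 2L)
cohorts <- gen_cohorts(cfg2)

write_bundle(study$proteome, list(proteolysis_study = study$cohort),
             lapply(study$truth, as.list), file.path(out, "proteolysis"))
write_bundle(cohorts$proteome,
             list(benign = cohorts$benign, tumor = cohorts$tumor),
             cohorts$truth, file.path(out, "profiling"))

n_pep <- sum(vapply(study$cohort$samples,
                    function(s) length(sample_union(s)), integer(1)))
cat(sprintf("proteolysis cohort: %d samples, %d sample-level peptides\n",
            length(study$cohort$samples), n_pep))
cat(sprintf("profiling cohorts: %d benign / %d tumor samples, %d planted exclusives\n",
            length(cohorts$benign$samples), length(cohorts$tumor$samples),
            nrow(cohorts$truth$planted)))
cat("bundle written under", out, "\n")
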