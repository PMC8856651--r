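#!/usr/bin/env Rscript
# Stage 2: planted-variant recovery under simulation. 100 seeded families,
# each with the causal variant transmitted per the template and 5000
# background variants at Beta(0.2, 5) founder allele frequencies; the
# co-segregation filter is scored against the generator's truth manifest,
# in both carrier-definition modes.

suppressMessages(library(famseg))
dir.create("results", showWarnings = FALSE)

n_runs <- 100
rows <- lapply(seq_len(n_runs), function(s) {
  sim <- simulate_family(family_sim_config(n_background_variants = 5000,
                                           seed = 2000 + s))
  keys <- variant_keys(sim$gm)
  v_any <- dominant_filter(sim$gm, sim$ped, detail = FALSE)
  v_het <- dominant_filter(sim$gm, sim$ped, require_het = TRUE, detail = FALSE)
  data.frame(seed = 2000 + s,
             recovered_any = sim$truth$causal_key %in% keys[v_any$segregates],
             fp_any = sum(keys[v_any$segregates] != sim$truth$causal_key),
             recovered_het = sim$truth$causal_key %in% keys[v_het$segregates],
             fp_het = sum(keys[v_het$segregates] != sim$truth$causal_key))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/02_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("any-alt mode: recovered %d/%d, mean background FPs %.3f/run",
                sum(tab$recovered_any), n_runs, mean(tab$fp_any)))
message(sprintf("het mode:     recovered %d/%d, mean background FPs %.3f/run",
                sum(tab$recovered_het), n_runs, mean(tab$fp_het)))
message("het mode is the family's inheritance model (carriers heterozygous);")
message("the any-alt mode admits rare chance co-segregations involving hom-alt calls")
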