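#!/usr/bin/env Rscript
# Step 1: generate the synthetic reference surfaces used by every later
# step — age/sex/smoking-status life table, comorbidity prevalence for
# current and former smokers, and population age weights — and export them
# as long-format CSV so real reference data could be swapped in.

library(smicea)

surfaces <- make_reference_surfaces(seed = 1)
dir.create("results", showWarnings = FALSE)
write_surfaces(surfaces, "results/surfaces")

lt <- surfaces$life_table
message("Annual death probability, male current smokers (before SMI uplift):")
for (age in c(40, 60, 80)) {
  message(sprintf("  age %d: %.4f", age, lt[as.character(age), "male", "current"]))
}
message("Current- vs former-smoker COPD prevalence at age 70 (female): ",
        sprintf("%.3f vs %.3f",
                surfaces$prevalence["copd", "70", "female", "current"],
                surfaces$prevalence["copd", "70", "female", "former"]))
message("Population weights sum to ", format(sum(surfaces$weights)),
        " across ", length(surfaces$weights), " age/sex cells")
message("Surfaces written to results/surfaces/")
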