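#!/usr/bin/env Rscript
# Stage 6: thermal stability. Simulates a two-state DSC thermogram per
# variant at its published melting temperature (unfolding enthalpy
# 500 kJ/mol, 30-90 C scan at 0.1 C) with mild noise, then extracts Tm as
# the peak of the baseline-subtracted excess heat capacity. The K5 variant
# aggregated before measurement and has no Tm. Writes results/tm.csv.

suppressPackageStartupMessages(library(fabkin))
seed <- 20180714L

tms <- published_tm()
out <- do.call(rbind, lapply(seq_len(nrow(tms)), function(i) {
  if (is.na(tms$tm_C[i]))
    return(data.frame(variant = tms$variant[i], tm_set_C = NA,
                      tm_recovered_C = NA, row.names = NULL))
  dsc <- generate_dsc_thermogram(tm = tms$tm_C[i], dH_unf = 5e5,
                                 noise_sd = 200, seed = seed + i)
  tm_hat <- tm_from_thermogram(dsc$temp_C, dsc$excess_cp)
  data.frame(variant = tms$variant[i], tm_set_C = tms$tm_C[i],
             tm_recovered_C = round(as.numeric(tm_hat), 2), row.names = NULL)
}))

dir.create("results", showWarnings = FALSE)
utils::write.csv(out, "results/tm.csv", row.names = FALSE)

cat("Tm extraction from simulated two-state thermograms:\n\n")
print(out, row.names = FALSE)
cat("\nEvery mutant melts below the 76.8 C wild type - the affinity gain\n")
cat("from charge introduction trades against thermal stability, mildest\n")
cat("for R3/R5 among the mutants with measurable transitions.\n")
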