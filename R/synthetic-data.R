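#' Experiment design for a synthetic SPR campaign
#'
#' Defaults mirror a typical multi-temperature Biacore kinetics study on a
#' sub-nanomolar Fab-antigen pair: five temperatures from 283.15 to
#' 303.15 K in 5 K steps, a two-fold concentration series 1.25-10 nM
#' around the 5 nM working concentration, 120 s association / 600 s
#' dissociation sampled at 1 Hz, and homoscedastic Gaussian read noise.
#'
#' @param temperatures Temperatures (K), distinct.
#' @param concentrations Analyte concentrations (M), >= 0 with at least two
#'   positive values.
#' @param protocol An [injection_protocol] giving the phase timing (its
#'   concentration field is ignored; the series above is used).
#' @param noise_sd Gaussian noise SD (RU).
#' @param rmax Surface capacity (RU), held constant across temperatures.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(
    temperatures = c(283.15, 288.15, 293.15, 298.15, 303.15),
    concentrations = c(1.25e-9, 2.5e-9, 5e-9, 1e-8),
    protocol = injection_protocol(t_assoc_start = 0, t_assoc_end = 120,
                                  t_end = 720, sample_interval = 1),
    noise_sd = 0, rmax = 100) {
  if (anyDuplicated(temperatures)) stop("temperatures must be distinct")
  if (any(concentrations < 0) || sum(concentrations > 0) < 2)
    stop("need non-negative concentrations with >= 2 positive values")
  structure(list(temperatures = sort(temperatures),
                 concentrations = concentrations, protocol = protocol,
                 noise_sd = noise_sd, rmax = rmax),
            class = "experiment_design")
}

#' Thermodynamically self-consistent ground truth for a variant
#'
#' Builds the per-temperature rate-constant table implied jointly by the
#' equilibrium thermodynamics and the transition-state parameters:
#' kon(T) = (kB T / h) exp(dS_act/R - dH_act/(R T)) from the Eyring
#' relation, Kd(T) = exp(dG(T)/(R T)) with dG(T) from the van't Hoff model
#' (see [predict_gibbs]), and koff(T) = kon(T) Kd(T). By construction
#' R T ln Kd(T) equals the model dG(T) exactly at every temperature, so a
#' correct analysis pipeline must recover (dH, dS, dCp, dH_act, dS_act)
#' from the simulated data.
#'
#' @param thermo A [thermo_params] for the binding equilibrium.
#' @param activation_on An [activation_params] for kon.
#' @param design An [experiment_design] (supplies the temperatures).
#' @return An object of class `ground_truth`: the inputs plus a data.frame
#'   `rates` with columns `temperature`, `kon`, `koff`, `kd`.
#' @export
consistent_ground_truth <- function(thermo, activation_on,
                                    design = experiment_design()) {
  stopifnot(inherits(thermo, "thermo_params"),
            inherits(activation_on, "activation_params"),
            inherits(design, "experiment_design"))
  Tv <- design$temperatures
  kon <- eyring_kon(activation_on, Tv)
  kd <- exp(predict_gibbs(thermo, Tv) / (phys_const$R * Tv))
  koff <- kon * kd
  if (any(kon < 1 | kon > 1e12))
    warning("implausible regime: kon outside [1, 1e12] M-1 s-1 at some temperature")
  structure(list(thermo = thermo, activation_on = activation_on,
                 rates = data.frame(temperature = Tv, kon = kon,
                                    koff = koff, kd = kd)),
            class = "ground_truth")
}

#' Association rate constant from Eyring parameters
#'
#' @param activation_on An [activation_params].
#' @param temperature Temperatures (K).
#' @return kon (M-1 s-1) at each temperature.
#' @export
eyring_kon <- function(activation_on, temperature) {
  with(phys_const,
       (kB * temperature / h) *
         exp(activation_on$dS_act / R -
             activation_on$dH_act / (R * temperature)))
}

#' Solve the activation entropy that anchors kon at one temperature
#'
#' Given an activation enthalpy, returns the dS_act for which the Eyring
#' relation reproduces the stated kon at the stated temperature. Used to
#' build ground truths anchored to published rate constants.
#'
#' @param kon Target association rate constant (M-1 s-1).
#' @param temperature Anchor temperature (K).
#' @param dH_act Activation enthalpy (J mol-1).
#' @return An [activation_params].
#' @export
activation_from_kon <- function(kon, temperature, dH_act) {
  stopifnot(kon > 0, temperature > 0)
  dS_act <- phys_const$R *
    (log(kon * phys_const$h / (phys_const$kB * temperature)) +
       dH_act / (phys_const$R * temperature))
  activation_params(dH_act, dS_act)
}

#' Solve the binding entropy that anchors Kd at one temperature
#'
#' Given dH and dCp, returns the thermo_params whose van't Hoff curve
#' passes through dG = R T ln(kd) at the anchor temperature.
#'
#' @param kd Target dissociation constant (M) at `temperature`.
#' @param temperature Anchor temperature (K).
#' @param dH Binding enthalpy at 293.15 K (J mol-1).
#' @param dCp Heat-capacity change (J mol-1 K-1).
#' @return A [thermo_params].
#' @export
thermo_from_kd <- function(kd, temperature, dH, dCp = 0) {
  dG <- gibbs_from_kd(kd, temperature)
  t0 <- phys_const$t_ref
  dS <- (dH + dCp * (temperature - t0) -
           dCp * temperature * log(temperature / t0) - dG) / temperature
  thermo_params(dH, dS, dCp)
}

#' Generate a complete synthetic SPR campaign
#'
#' Simulates one sensorgram per (temperature, concentration) pair plus one
#' blank (zero-concentration) trace per temperature, using the ground
#' truth's rate constants at each temperature. With `noise_sd = 0` the
#' traces are exact closed-form Langmuir curves; otherwise i.i.d. Gaussian
#' noise is added to every trace including the blanks. Deterministic under
#' a fixed seed. Optionally writes the trace files (CSV sensorgram
#' dialect, see [write_sensorgram]) and a YAML manifest recording the
#' ground truth, so a downstream analysis can be checked against it.
#'
#' @param truth A [ground_truth].
#' @param design An [experiment_design]; its temperatures must match the
#'   truth's rate table.
#' @param seed Integer seed for the noise.
#' @param out_dir Optional directory; when given, traces and
#'   `manifest.yaml` are written there.
#' @return Invisibly, a list with `traces` (list of [sensorgram_trace],
#'   samples then blanks), `manifest` (list), and `files` (paths, when
#'   written).
#' @export
generate_experiment <- function(truth, design = experiment_design(),
                                seed = 1L, out_dir = NULL) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(design, "experiment_design"))
  if (!isTRUE(all.equal(sort(truth$rates$temperature),
                        design$temperatures)))
    stop("design temperatures do not match the ground-truth rate table")
  prot0 <- design$protocol
  traces <- list()
  meta <- list()
  k <- 0L
  for (i in seq_along(design$temperatures)) {
    Tv <- design$temperatures[i]
    row <- truth$rates[truth$rates$temperature == Tv, ]
    kp <- kinetic_params(row$kon, row$koff, design$rmax, temperature = Tv)
    for (C in c(design$concentrations, 0)) {      # 0 = blank trace
      k <- k + 1L
      prot <- injection_protocol(prot0$t_assoc_start, prot0$t_assoc_end,
                                 prot0$t_end, C, prot0$sample_interval)
      traces[[k]] <- simulate_sensorgram(kp, prot, design$noise_sd,
                                         seed = seed + 1000L * k)
      meta[[k]] <- list(temperature_K = Tv, concentration_M = C,
                        blank = C == 0)
    }
  }
  manifest <- list(
    seed = seed, noise_sd_RU = design$noise_sd, rmax_RU = design$rmax,
    thermo = list(dH_J_mol = truth$thermo$dH, dS_J_mol_K = truth$thermo$dS,
                  dCp_J_mol_K = truth$thermo$dCp,
                  t_ref_K = truth$thermo$t_ref),
    activation_on = list(dH_act_J_mol = truth$activation_on$dH_act,
                         dS_act_J_mol_K = truth$activation_on$dS_act),
    rates = lapply(seq_len(nrow(truth$rates)), function(j)
      as.list(truth$rates[j, ])),
    traces = meta)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(length(traces))
    for (j in seq_along(traces)) {
      lab <- if (meta[[j]]$blank) "blank" else
        sprintf("c%05.0fpM", meta[[j]]$concentration_M * 1e12)
      files[j] <- file.path(out_dir, sprintf(
        "trace_T%06.2fK_%s.csv", meta[[j]]$temperature_K, lab))
      write_sensorgram(traces[[j]], files[j])
    }
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(list(traces = traces, manifest = manifest, files = files))
}

#' Simulate a two-state DSC thermogram
#'
#' Excess heat capacity of a two-state unfolding transition under the
#' van't Hoff model:
#' Cp_ex(T) = dH_unf^2 / (R T^2) * K / (1 + K)^2 with
#' K(T) = exp(-(dH_unf/R) (1/T - 1/Tm)) (temperatures in kelvin
#' internally). The peak sits at Tm up to a small, dH-dependent shift from
#' the 1/T^2 prefactor (well under 0.1 degC for realistic unfolding
#' enthalpies). Larger dH_unf gives a narrower peak. Optional Gaussian
#' noise; deterministic under a fixed seed.
#'
#' @param tm Melting temperature (degrees C); must lie inside the grid.
#' @param dH_unf Van't Hoff unfolding enthalpy (J mol-1), > 0.
#' @param grid Temperature grid (degrees C), default 30-90 at 0.1.
#' @param noise_sd Gaussian noise SD (same units as Cp_ex).
#' @param seed Integer seed for the noise.
#' @return A data.frame with columns `temp_C`, `excess_cp`.
#' @export
generate_dsc_thermogram <- function(tm, dH_unf = 5e5,
                                    grid = seq(30, 90, by = 0.1),
                                    noise_sd = 0, seed = NULL) {
  if (tm < min(grid) || tm > max(grid))
    stop("'tm' lies outside the temperature grid")
  if (dH_unf <= 0) stop("'dH_unf' must be positive")
  TK <- grid + 273.15
  tmK <- tm + 273.15
  K <- exp(-(dH_unf / phys_const$R) * (1 / TK - 1 / tmK))
  cp <- dH_unf^2 / (phys_const$R * TK^2) * K / (1 + K)^2
  if (noise_sd > 0)
    cp <- cp + local_rng(seed, stats::rnorm(length(cp), sd = noise_sd))
  data.frame(temp_C = grid, excess_cp = cp)
}

#' Ground-truth presets for the six-variant charge panel
#'
#' Self-consistent synthetic parameter sets for the wild type and the five
#' FR3 charge mutants, anchored so that kon and Kd at 298.15 K equal the
#' published 25 C rate constants (see [published_kinetics]). The enthalpy
#' choices encode the observed thermodynamic signatures: entropy-driven
#' binding with unfavorable enthalpy for the wild type and the acidic
#' mutants, favorable enthalpy and entropy for the basic mutants; in the
#' transition state the R5 preset has a favorable (negative) activation
#' enthalpy and the K5 preset an unfavorable one. The magnitudes are
#' package choices (the corresponding measured values were never published
#' as numbers) and are not used as oracle values anywhere.
#'
#' @param design An [experiment_design] supplying the temperature grid.
#' @return Named list of [consistent_ground_truth] objects.
#' @export
variant_truths <- function(design = experiment_design()) {
  kin <- published_kinetics()
  # dH (J/mol) at 293.15 K and activation enthalpy of kon (J/mol)
  dH <- c(wild_type = 15e3, R3 = -10e3, R5 = -20e3, K5 = -15e3,
          D5 = 12e3, E5 = 18e3)
  dH_act <- c(wild_type = 30e3, R3 = 25e3, R5 = -8e3, K5 = 55e3,
              D5 = 35e3, E5 = 40e3)
  dCp <- c(wild_type = -800, R3 = -1000, R5 = -1500, K5 = -1200,
           D5 = -600, E5 = -500)
  out <- lapply(kin$variant, function(v) {
    row <- kin[kin$variant == v, ]
    consistent_ground_truth(
      thermo_from_kd(row$koff / row$kon, 298.15, dH = dH[[v]],
                     dCp = dCp[[v]]),
      activation_from_kon(row$kon, 298.15, dH_act = dH_act[[v]]),
      design)
  })
  stats::setNames(out, kin$variant)
}
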