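# Shared fixtures: a wild-type-like Fab-antigen system anchored to the
# published 25 C rate constants, and small builders used across test files.

wt_params <- function(temperature = 298.15)
  kinetic_params(kon = 2.48e6, koff = 5.49e-4, rmax = 100,
                 temperature = temperature)

default_conc <- c(1.25e-9, 2.5e-9, 5e-9, 1e-8)

make_traces <- function(params = wt_params(), conc = default_conc,
                        noise_sd = 0, seed = NULL) {
  lapply(seq_along(conc), function(i)
    simulate_sensorgram(
      params,
      injection_protocol(concentration = conc[i]),
      noise_sd = noise_sd,
      seed = if (is.null(seed)) NULL else seed + i))
}

# Wild-type-like self-consistent ground truth (entropy-driven binding,
# unfavorable enthalpy, modest negative dCp).
wt_truth <- function() {
  consistent_ground_truth(
    thermo = thermo_from_kd(2.22e-10, 298.15, dH = 20e3, dCp = -1000),
    activation_on = activation_from_kon(2.48e6, 298.15, dH_act = 30e3))
}

rel_err <- function(est, truth) abs(est / truth - 1)
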