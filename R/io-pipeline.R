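#' Write a sensorgram trace in the package CSV dialect
#'
#' Plain comma-separated text with metadata in `# key=value` header lines
#' (`concentration_M`, `temperature_K`, `phase_assoc_start_s`,
#' `phase_assoc_end_s`) followed by a `time_s,response_RU` column header
#' and the data. Numbers are written with 17 significant digits so that
#' write/read round-trips are exact.
#'
#' @param trace A [sensorgram_trace].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensorgram <- function(trace, path) {
  stopifnot(inherits(trace, "sensorgram_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# concentration_M=%.17g", trace$concentration),
    sprintf("# temperature_K=%.17g", trace$temperature),
    sprintf("# phase_assoc_start_s=%.17g", trace$t_assoc_start),
    sprintf("# phase_assoc_end_s=%.17g", trace$t_assoc_end),
    "time_s,response_RU",
    sprintf("%.17g,%.17g", trace$times, trace$responses)), con)
  invisible(path)
}

#' Read a sensorgram trace from the package CSV dialect
#'
#' Parse errors (missing mandatory header key, non-numeric cell,
#' non-increasing time) name the offending key or line. Trailing blank
#' lines are tolerated.
#'
#' @param path Path to a file written by [write_sensorgram].
#' @return A [sensorgram_trace].
#' @export
read_sensorgram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && any(diff(hdr_idx) != 1))
    stop("parse error in ", path, ": header lines must be contiguous")
  hdr <- lines[hdr_idx]
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)\\s*$", hdr))
  keys <- vapply(kv, function(m) if (length(m)) m[2] else NA_character_, "")
  vals <- suppressWarnings(as.numeric(
    vapply(kv, function(m) if (length(m)) m[3] else NA_character_, "")))
  meta <- stats::setNames(vals, keys)
  for (key in c("concentration_M", "temperature_K", "phase_assoc_end_s"))
    if (!key %in% keys || !is.finite(meta[[key]]))
      stop("parse error in ", path, ": missing or non-numeric header key '",
           key, "'")
  assoc_start <- if ("phase_assoc_start_s" %in% keys)
    meta[["phase_assoc_start_s"]] else 0
  body <- lines[-hdr_idx]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2 || !grepl("^time_s\\s*,\\s*response_RU", body[1]))
    stop("parse error in ", path, ": expected 'time_s,response_RU' column header")
  cells <- strsplit(body[-1], ",")
  if (any(lengths(cells) != 2))
    stop("parse error in ", path, " at data line ",
         which(lengths(cells) != 2)[1], ": expected 2 comma-separated cells")
  num <- suppressWarnings(vapply(cells, as.numeric, numeric(2)))
  if (any(!is.finite(num)))
    stop("parse error in ", path, " at data line ",
         which(colSums(!is.finite(num)) > 0)[1], ": non-numeric cell")
  times <- num[1, ]; resp <- num[2, ]
  if (any(diff(times) <= 0))
    stop("parse error in ", path, ": time_s must be strictly increasing")
  sensorgram_trace(times, resp, meta[["concentration_M"]],
                   meta[["temperature_K"]], assoc_start,
                   meta[["phase_assoc_end_s"]])
}

#' Run the full kinetics-to-thermodynamics pipeline for a panel of variants
#'
#' For each variant, global-fits the 1:1 Langmuir model per temperature
#' (after blank subtraction when a blank is present), converts the fitted
#' Kd(T) to Gibbs energies, fits the nonlinear van't Hoff model for
#' (dH, dS, dCp) and the Eyring model for (dH_act, dS_act) of kon, and
#' reports fold changes of kon and koff relative to a designated reference
#' variant at the report temperature. With a single temperature only the
#' kinetics are reported and the thermodynamic stage is skipped with a
#' warning.
#'
#' A fit-bypass mode accepts per-variant rate constants directly (a
#' data.frame with columns `variant`, `kon`, `koff`) and produces the
#' kinetics/fold-change part of the report without sensorgrams.
#'
#' @param config Either a list (or path to a YAML file) with elements
#'   `variants` (named list; each variant a list of trace file paths or of
#'   in-memory [sensorgram_trace] lists grouped by temperature),
#'   `reference` (variant name), and optional `report_temperature_K`
#'   (default 298.15); or, for fit bypass, a data.frame of rate constants.
#' @param reference Reference variant name (fit-bypass mode, or to
#'   override the config).
#' @param report_temperature_K Temperature whose kinetics go into the
#'   report table (K).
#' @return A list of class `pipeline_report` with data.frames `kinetics`
#'   (variant, kd_M, kon, kon_se, koff, koff_se, fold_kon, fold_koff),
#'   `thermo` (variant, dH, dS, dCp, dH_act, dS_act; absent in
#'   single-temperature or bypass mode).
#' @export
run_pipeline <- function(config, reference = NULL,
                         report_temperature_K = 298.15) {
  if (is.data.frame(config))
    return(bypass_report(config, reference, report_temperature_K))
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$variants))
  if (is.null(reference)) reference <- config$reference
  if (is.null(reference) || !reference %in% names(config$variants))
    stop("config error: exactly one existing variant must be the reference")
  if (!is.null(config$report_temperature_K))
    report_temperature_K <- config$report_temperature_K

  per_variant <- lapply(names(config$variants), function(v) {
    traces <- load_variant_traces(config$variants[[v]])
    temps <- vapply(traces, `[[`, numeric(1), "temperature")
    fits <- lapply(split(traces, round(temps, 6)), function(group) {
      conc <- vapply(group, `[[`, numeric(1), "concentration")
      blanks <- group[conc == 0]
      samples <- group[conc > 0]
      if (length(blanks) >= 1)
        samples <- lapply(samples, blank_subtract, blank = blanks[[1]])
      global_fit(samples)
    })
    ft <- as.numeric(names(fits))
    list(variant = v, temps = ft, fits = fits)
  })
  names(per_variant) <- names(config$variants)

  kin <- do.call(rbind, lapply(per_variant, function(pv) {
    i <- which.min(abs(pv$temps - report_temperature_K))
    row <- fit_report(pv$fits[[i]], pv$variant)
    row$temperature_K <- pv$temps[i]
    row
  }))
  ref_row <- kin[kin$variant == reference, ]
  kin$fold_kon <- fold_change(kin$kon_M1s1, ref_row$kon_M1s1)
  kin$fold_koff <- fold_change(kin$koff_s1, ref_row$koff_s1)

  thermo <- NULL
  n_temps <- min(vapply(per_variant, function(pv) length(pv$temps), 1L))
  if (n_temps < 3) {
    warning("fewer than 3 temperatures: thermodynamic analysis skipped")
  } else {
    thermo <- do.call(rbind, lapply(per_variant, function(pv) {
      kon <- vapply(pv$fits, function(f) f$params$kon, numeric(1))
      koff <- vapply(pv$fits, function(f) f$params$koff, numeric(1))
      dG <- gibbs_from_kd(koff / kon, pv$temps)
      tp <- vant_hoff_fit(pv$temps, dG)
      ap <- eyring_fit(pv$temps, kon)
      data.frame(variant = pv$variant, dH_J_mol = tp$dH,
                 dS_J_mol_K = tp$dS, dCp_J_mol_K = tp$dCp,
                 dH_act_J_mol = ap$dH_act, dS_act_J_mol_K = ap$dS_act,
                 row.names = NULL)
    }))
  }
  structure(list(kinetics = kin, thermo = thermo, reference = reference,
                 report_temperature_K = report_temperature_K),
            class = "pipeline_report")
}

# Accept a variant's traces as file paths, a flat list of traces, or a
# nested list grouped by temperature.
load_variant_traces <- function(x) {
  if (inherits(x, "sensorgram_trace")) return(list(x))
  if (is.character(x)) return(lapply(x, read_sensorgram))
  stopifnot(is.list(x))
  out <- list()
  for (el in x) out <- c(out, load_variant_traces(el))
  out
}

bypass_report <- function(rates, reference, report_temperature_K) {
  stopifnot(all(c("variant", "kon", "koff") %in% names(rates)))
  if (is.null(reference) || !reference %in% rates$variant)
    stop("config error: exactly one existing variant must be the reference")
  kin <- do.call(rbind, lapply(seq_len(nrow(rates)), function(i)
    fit_report(kinetic_params(rates$kon[i], rates$koff[i], rmax = 100,
                              temperature = report_temperature_K),
               rates$variant[i])))
  ref <- kin[kin$variant == reference, ]
  kin$fold_kon <- fold_change(kin$kon_M1s1, ref$kon_M1s1)
  kin$fold_koff <- fold_change(kin$koff_s1, ref$koff_s1)
  kin$temperature_K <- report_temperature_K
  structure(list(kinetics = kin, thermo = NULL, reference = reference,
                 report_temperature_K = report_temperature_K),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Variant report at %.2f K (reference: %s)\n\nKinetics:\n",
              x$report_temperature_K, x$reference))
  kin <- x$kinetics
  kin$fold_kon <- format_fold_change(kin$fold_kon)
  kin$fold_koff <- format_fold_change(kin$fold_koff)
  print(kin, row.names = FALSE)
  if (!is.null(x$thermo)) {
    cat("\nThermodynamics (kJ/mol; entropies J/mol/K):\n")
    th <- x$thermo
    out <- data.frame(variant = th$variant,
                      dH_kJ = signif(th$dH_J_mol / 1e3, 3),
                      dS = signif(th$dS_J_mol_K, 3),
                      dCp_kJ = signif(th$dCp_J_mol_K / 1e3, 3),
                      dH_act_kJ = signif(th$dH_act_J_mol / 1e3, 3),
                      dS_act = signif(th$dS_act_J_mol_K, 3))
    print(out, row.names = FALSE)
  }
  invisible(x)
}

#' Published per-variant kinetic constants bundled with the package
#'
#' Reads the bundled table of per-variant rate constants at 25 degrees C
#' (wild type plus the R3/R5/K5/D5/E5 charge mutants): columns `variant`,
#' `kd_M` (printed Kd), `kon`, `kon_se`, `koff`, `koff_se`.
#'
#' @return A data.frame.
#' @export
published_kinetics <- function() {
  utils::read.csv(system.file("extdata", "table1_kinetics.csv",
                              package = "fabkin"),
                  stringsAsFactors = FALSE)
}

#' Published per-variant melting temperatures bundled with the package
#'
#' @return A data.frame with columns `variant`, `tm_C` (NA where the
#'   variant aggregated before measurement).
#' @export
published_tm <- function() {
  utils::read.csv(system.file("extdata", "table2_tm.csv",
                              package = "fabkin"),
                  stringsAsFactors = FALSE)
}
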