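#' Equilibrium thermodynamic parameters of binding
#'
#' Binding enthalpy and entropy changes defined at the fixed reference
#' temperature 293.15 K, plus the (temperature-independent) heat-capacity
#' change that curves Gibbs energy with temperature. Energies are stored in
#' J mol-1 internally; report layers convert to kJ mol-1.
#'
#' @param dH Binding enthalpy change at 293.15 K (J mol-1).
#' @param dS Binding entropy change at 293.15 K (J mol-1 K-1).
#' @param dCp Heat-capacity change of binding (J mol-1 K-1).
#' @return An object of class `thermo_params` with the fixed `t_ref`.
#' @export
thermo_params <- function(dH, dS, dCp = 0) {
  stopifnot(is.finite(dH), is.finite(dS), is.finite(dCp))
  structure(list(dH = dH, dS = dS, dCp = dCp, t_ref = phys_const$t_ref),
            class = "thermo_params")
}

#' Transition-state (activation) parameters of association
#'
#' Activation enthalpy and entropy of the association rate constant, as
#' obtained from an Eyring analysis of kon(T).
#'
#' @param dH_act Activation enthalpy (J mol-1).
#' @param dS_act Activation entropy (J mol-1 K-1).
#' @return An object of class `activation_params`.
#' @export
activation_params <- function(dH_act, dS_act) {
  stopifnot(is.finite(dH_act), is.finite(dS_act))
  structure(list(dH_act = dH_act, dS_act = dS_act),
            class = "activation_params")
}

#' Gibbs energy of binding from the dissociation constant
#'
#' The standard-state Gibbs energy change on binding,
#' `dG = R T ln(Kd)` with Kd in M: negative whenever Kd < 1 M.
#'
#' @param kd Equilibrium dissociation constant (M), > 0.
#' @param temperature Absolute temperature (K), > 0.
#' @return Gibbs energy change (J mol-1).
#' @export
#' @examples
#' gibbs_from_kd(2.22e-10, 298.15)  # about -55.1 kJ/mol
gibbs_from_kd <- function(kd, temperature) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("'kd' must be positive")
  if (any(temperature <= 0)) stop("'temperature' must be positive (K)")
  phys_const$R * temperature * log(kd)
}

#' Gibbs energy predicted by the van't Hoff model with heat capacity
#'
#' Integrated Gibbs-Helmholtz relation under constant dCp:
#' `dG(T) = dH - T dS + dCp (T - 293.15) - dCp T ln(T / 293.15)`,
#' with dH and dS defined at the 293.15 K reference, where both dCp terms
#' vanish and dG reduces to dH - T dS.
#'
#' @param params A [thermo_params] object.
#' @param temperature Absolute temperature (K), > 0; vectorised.
#' @return Gibbs energy change (J mol-1).
#' @export
predict_gibbs <- function(params, temperature) {
  stopifnot(inherits(params, "thermo_params"))
  if (any(temperature <= 0)) stop("'temperature' must be positive (K)")
  t0 <- params$t_ref
  params$dH - temperature * params$dS +
    params$dCp * (temperature - t0) -
    params$dCp * temperature * log(temperature / t0)
}

#' Nonlinear van't Hoff fit of dG(T)
#'
#' Fits the temperature dependence of the binding Gibbs energy with the
#' heat-capacity-corrected van't Hoff model (see [predict_gibbs]) by
#' unweighted least squares. The model is nonlinear in T but linear in the
#' parameters (dH, dS, dCp), so the least-squares solution is computed
#' exactly with a linear solve rather than an iterative optimiser.
#'
#' @param temperatures Temperatures (K), at least 3 distinct values.
#' @param dG Gibbs energies (J mol-1) at those temperatures.
#' @param fit_dCp Set `FALSE` to constrain dCp = 0 (classic linear van't
#'   Hoff), in which case 2 distinct temperatures suffice.
#' @return A [thermo_params] object with attributes `se` (standard errors
#'   for dH, dS, dCp when estimable) and `rss`.
#' @export
#' @examples
#' tp <- thermo_params(-30e3, 80, -1.5e3)
#' temps <- seq(283.15, 303.15, by = 5)
#' vant_hoff_fit(temps, predict_gibbs(tp, temps))
vant_hoff_fit <- function(temperatures, dG, fit_dCp = TRUE) {
  stopifnot(length(temperatures) == length(dG))
  n_par <- if (fit_dCp) 3L else 2L
  if (length(unique(temperatures)) < n_par)
    stop(sprintf("under-determined: need >= %d distinct temperatures", n_par))
  t0 <- phys_const$t_ref
  X <- cbind(dH = rep(1, length(temperatures)),
             dS = -temperatures,
             dCp = (temperatures - t0) -
                   temperatures * log(temperatures / t0))
  if (!fit_dCp) X <- X[, 1:2, drop = FALSE]
  fit <- stats::lm.fit(X, dG)
  beta <- fit$coefficients
  out <- thermo_params(dH = beta[["dH"]], dS = beta[["dS"]],
                       dCp = if (fit_dCp) beta[["dCp"]] else 0)
  rss <- sum(fit$residuals^2)
  se <- rep(NA_real_, 3)
  dof <- length(dG) - n_par
  if (dof > 0) {
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se[seq_len(n_par)] <- sqrt(diag(xtx_inv) * rss / dof)
  }
  names(se) <- c("dH", "dS", "dCp")
  attr(out, "se") <- se
  attr(out, "rss") <- rss
  out
}

#' Eyring analysis of the association rate constant
#'
#' Transition-state theory links the temperature dependence of kon to the
#' activation enthalpy and entropy:
#' `ln(kon / T) = -dH_act / (R T) + dS_act / R + ln(kB / h)`.
#' The parameters are obtained by ordinary least-squares regression of
#' ln(kon/T) on 1/T (the classical Eyring plot): the slope is -dH_act/R
#' and the intercept is dS_act/R + ln(kB/h).
#'
#' @param temperatures Temperatures (K), at least 2 distinct values.
#' @param kon Association rate constants (M-1 s-1), > 0.
#' @return An [activation_params] object with attribute `se` (standard
#'   errors of dH_act and dS_act when > 2 temperatures are supplied).
#' @export
eyring_fit <- function(temperatures, kon) {
  stopifnot(length(temperatures) == length(kon))
  if (length(unique(temperatures)) < 2)
    stop("need >= 2 distinct temperatures for an Eyring fit")
  if (any(kon <= 0)) stop("'kon' must be positive")
  y <- log(kon / temperatures)
  x <- 1 / temperatures
  X <- cbind(intercept = rep(1, length(x)), x = x)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  dH_act <- -cf[["x"]] * phys_const$R
  dS_act <- (cf[["intercept"]] - log(phys_const$kB / phys_const$h)) *
    phys_const$R
  out <- activation_params(dH_act, dS_act)
  se <- rep(NA_real_, 2)
  if (length(y) > 2) {
    sm <- sqrt(diag(chol2inv(chol(crossprod(X))) *
                      sum(fit$residuals^2) / (length(y) - 2)))
    se <- c(sm[[2]] * phys_const$R, sm[[1]] * phys_const$R)
  }
  names(se) <- c("dH_act", "dS_act")
  attr(out, "se") <- se
  out
}

#' Fold change of a kinetic constant relative to a reference variant
#'
#' @param mutant_value Value for the mutant.
#' @param wildtype_value Value for the reference (wild type), > 0.
#' @return The ratio mutant/wild-type (full precision). Report layers round
#'   to 2 significant figures (1 for ratios below 0.05), matching the
#'   conventional precision of published fold changes.
#' @export
#' @examples
#' fold_change(5.44e7, 2.48e6)  # about 22
fold_change <- function(mutant_value, wildtype_value) {
  if (any(wildtype_value <= 0)) stop("reference value must be positive")
  if (any(mutant_value < 0)) stop("mutant value must be non-negative")
  mutant_value / wildtype_value
}

#' Round a fold change to reporting precision
#'
#' @param ratio A fold change from [fold_change].
#' @return The ratio at 2 significant figures, or 1 significant figure when
#'   below 0.05.
#' @export
format_fold_change <- function(ratio) {
  ifelse(ratio < 0.05, signif(ratio, 1), signif(ratio, 2))
}

#' Classify the thermodynamic signature of binding
#'
#' Labels the enthalpic and entropic contributions to binding as favorable,
#' unfavorable or neutral. A contribution is favorable when it lowers the
#' Gibbs energy: dH < 0 for enthalpy, -T dS < 0 (i.e. dS > 0) for entropy.
#' Contributions smaller in magnitude than `tol` (default 0.1 kJ mol-1, on
#' the energy scale |dH| resp. |T dS|) are labelled neutral.
#'
#' @param dH Binding enthalpy change (J mol-1).
#' @param dS Binding entropy change (J mol-1 K-1).
#' @param temperature Temperature (K) at which -T dS is evaluated.
#' @param tol Neutrality tolerance on the energy scale (J mol-1).
#' @return A list with elements `enthalpy` and `entropy`, each one of
#'   "favorable", "unfavorable", "neutral".
#' @export
#' @examples
#' classify_signature(-20e3, 120, 298.15)  # both favorable
classify_signature <- function(dH, dS, temperature = 298.15, tol = 100) {
  stopifnot(is.finite(dH), is.finite(dS), temperature > 0)
  lab <- function(energy) {
    if (abs(energy) < tol) "neutral"
    else if (energy < 0) "favorable" else "unfavorable"
  }
  list(enthalpy = lab(dH), entropy = lab(-temperature * dS))
}

#' Melting temperature from a DSC thermogram
#'
#' Extracts Tm as the temperature of maximal baseline-subtracted excess
#' heat capacity. The instrument baseline is approximated by linear
#' interpolation between the pre- and post-transition plateaus (the mean of
#' the first and last `n_plateau` points). The peak position is refined by
#' a three-point parabolic interpolation around the grid maximum.
#'
#' @param temps Temperature grid (degrees C), >= 5 strictly increasing
#'   points spanning the transition.
#' @param excess_cp Measured excess heat capacity at each grid point.
#' @param n_plateau Number of points averaged at each end for the baseline.
#' @return The melting temperature (degrees C), with attribute
#'   `edge_warning` = TRUE when the maximum sits on the grid boundary (in
#'   which case a warning is also raised and no parabolic refinement is
#'   done).
#' @export
tm_from_thermogram <- function(temps, excess_cp, n_plateau = 5L) {
  stopifnot(length(temps) == length(excess_cp))
  if (length(temps) < 5) stop("need >= 5 grid points")
  if (any(diff(temps) <= 0)) stop("'temps' must be strictly increasing")
  n <- length(temps)
  n_plateau <- min(n_plateau, floor(n / 3))
  pre  <- mean(excess_cp[seq_len(n_plateau)])
  post <- mean(excess_cp[seq(n - n_plateau + 1L, n)])
  base <- pre + (post - pre) * (temps - temps[1]) / (temps[n] - temps[1])
  y <- excess_cp - base
  i <- which.max(y)
  peak <- y[i]
  spread <- stats::sd(y)
  if (!is.finite(peak) || peak <= 0 || spread == 0 || peak < 3 * spread / sqrt(n))
    stop("no peak: thermogram has no interior maximum above the baseline")
  edge <- i == 1L || i == n
  if (edge) {
    warning("thermogram maximum lies on the grid boundary")
    tm <- temps[i]
  } else {
    # Parabola through the three points bracketing the maximum; exact for a
    # locally quadratic peak and sub-grid accurate otherwise.
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (denom < 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    h1 <- temps[i] - temps[i - 1]; h2 <- temps[i + 1] - temps[i]
    tm <- temps[i] + delta * (h1 + h2) / 2
  }
  structure(tm, edge_warning = edge)
}
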