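#' Subtract a blank-cell trace from a sample trace
#'
#' Biacore-style referencing: the response recorded on a blank flow cell is
#' subtracted point-by-point from the sample-cell response. Both traces
#' must share the same time grid exactly; no interpolation is attempted, so
#' a grid mismatch is an error rather than a silent resampling.
#'
#' @param sample A [sensorgram_trace] from the active surface.
#' @param blank A [sensorgram_trace] from the reference (blank) surface.
#' @return A [sensorgram_trace] with referenced responses and the sample's
#'   metadata.
#' @export
blank_subtract <- function(sample, blank) {
  stopifnot(inherits(sample, "sensorgram_trace"),
            inherits(blank, "sensorgram_trace"))
  if (length(sample$times) != length(blank$times) ||
      any(sample$times != blank$times))
    stop("sample and blank traces must share an identical time grid")
  sensorgram_trace(sample$times, sample$responses - blank$responses,
                   sample$concentration, sample$temperature,
                   sample$t_assoc_start, sample$t_assoc_end)
}

#' Global 1:1 Langmuir fit across a concentration series
#'
#' Fits a single set of (kon, koff, Rmax) to all traces simultaneously by
#' Levenberg-Marquardt least squares, the standard "global fit" of Biacore
#' kinetic analysis. Parameters are optimised on the log10 scale, which
#' enforces positivity and conditions a problem whose rates span several
#' decades. Starting values are derived deterministically from the data:
#' koff from a log-linear regression of the dissociation tail, kon from a
#' linearisation of the observed association rate kobs = kon C + koff
#' across concentrations, and Rmax from 1.2 x the largest observed
#' response.
#'
#' @param traces List of [sensorgram_trace] objects recorded at one
#'   temperature; at least one must have positive analyte concentration.
#' @return An object of class `fit_result`: fields `params`
#'   ([kinetic_params] with the fitted values), `standard_errors` (named
#'   vector for kon, koff, rmax on the natural scale), `kd_se` (delta-method
#'   SE of the derived Kd), `residual_sum_of_squares`, `n_points`,
#'   `converged`, and `koff_poorly_determined` (TRUE when
#'   koff x dissociation duration < 1e-3, i.e. the tail decays too little
#'   to pin koff down).
#' @export
#' @examples
#' p <- kinetic_params(2.48e6, 5.49e-4, 100)
#' prot <- function(C) injection_protocol(concentration = C)
#' traces <- lapply(c(2.5e-9, 1e-8), function(C)
#'   simulate_sensorgram(p, prot(C)))
#' global_fit(traces)
global_fit <- function(traces) {
  if (inherits(traces, "sensorgram_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, TRUE, "sensorgram_trace")))
  temps <- vapply(traces, `[[`, numeric(1), "temperature")
  if (max(temps) - min(temps) > 1e-9)
    stop("all traces in a global fit must share one temperature")
  conc <- vapply(traces, `[[`, numeric(1), "concentration")
  if (!any(conc > 0))
    stop("non-identifiable: at least one trace must have concentration > 0")
  all_resp <- unlist(lapply(traces, `[[`, "responses"))
  if (all(abs(all_resp) < .Machine$double.eps))
    stop("non-identifiable: all responses are zero")

  start <- fit_start_values(traces)
  residual_fun <- function(p) {
    # clamp the log10-parameters so intermediate LM steps cannot overflow
    p <- pmin(pmax(p, -30), 30)
    kp <- kinetic_params(10^p[1], 10^p[2], 10^p[3], temperature = temps[1])
    unlist(lapply(traces, function(tr) {
      prot <- injection_protocol(tr$t_assoc_start, tr$t_assoc_end,
                                 max(tr$times) + 1, tr$concentration,
                                 sample_interval = 1)
      tr$responses - langmuir_response(kp, prot, tr$times)
    }))
  }
  fit <- minpack.lm::nls.lm(
    par = log10(start), fn = residual_fun,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-12, maxiter = 500))
  converged <- fit$info %in% 1:4

  p_hat <- 10^fit$par
  n <- length(fit$fvec)
  rss <- sum(fit$fvec^2)
  # Covariance of the log10-parameters from the Gauss-Newton approximation
  # J'J (nls.lm's `hessian`), scaled by the residual variance; the SEs on
  # the natural scale follow by the delta method.
  se_nat <- rep(NA_real_, 3)
  kd_se <- NA_real_
  cov_log <- try(solve(fit$hessian) * rss / max(n - 3L, 1L), silent = TRUE)
  if (!inherits(cov_log, "try-error") && all(is.finite(diag(cov_log)))) {
    se_log <- sqrt(pmax(diag(cov_log), 0))
    se_nat <- p_hat * log(10) * se_log
    # Kd = koff/kon: var(log10 Kd) = var(l_koff) + var(l_kon) - 2 cov
    v_kd_log <- cov_log[2, 2] + cov_log[1, 1] - 2 * cov_log[1, 2]
    kd_se <- (p_hat[2] / p_hat[1]) * log(10) * sqrt(max(v_kd_log, 0))
  }
  names(se_nat) <- c("kon", "koff", "rmax")

  diss_dur <- max(vapply(traces, function(tr) max(tr$times) - tr$t_assoc_end,
                         numeric(1)))
  koff_flag <- p_hat[2] * diss_dur < 1e-3
  if (koff_flag)
    warning("koff poorly determined: dissociation phase decays by < 0.1%")

  structure(
    list(params = kinetic_params(p_hat[1], p_hat[2], p_hat[3],
                                 temperature = temps[1]),
         standard_errors = se_nat, kd_se = kd_se,
         residual_sum_of_squares = rss, n_points = n,
         converged = converged, koff_poorly_determined = koff_flag),
    class = "fit_result"
  )
}

# Deterministic start values (kon, koff, rmax) for the global fit.
fit_start_values <- function(traces) {
  rmax0 <- 1.2 * max(unlist(lapply(traces, `[[`, "responses")))
  if (!is.finite(rmax0) || rmax0 <= 0) rmax0 <- 100

  # koff: pooled log-linear regression of the dissociation tail of the
  # trace with the largest end-of-association response.
  koff0 <- NA_real_
  r_end <- vapply(traces, function(tr) {
    i <- which.min(abs(tr$times - tr$t_assoc_end))
    tr$responses[i]
  }, numeric(1))
  tr <- traces[[which.max(r_end)]]
  sel <- tr$times > tr$t_assoc_end & tr$responses > 0.02 * max(tr$responses)
  if (sum(sel) >= 3) {
    sl <- stats::coef(stats::lm(log(tr$responses[sel]) ~ tr$times[sel]))[2]
    if (is.finite(sl) && sl < 0) koff0 <- -sl
  }
  if (!is.finite(koff0) || koff0 <= 0) koff0 <- 1e-3

  # kon: estimate kobs per positive-concentration trace by log-linear
  # regression of (plateau - R), then regress kobs on C.
  kobs <- conc <- numeric(0)
  for (tr in traces) {
    if (tr$concentration <= 0) next
    sel <- tr$times >= tr$t_assoc_start & tr$times <= tr$t_assoc_end
    tt <- tr$times[sel]; rr <- tr$responses[sel]
    plateau <- max(rr) * 1.02 + 1e-9
    y <- plateau - rr
    ok <- y > 0.02 * plateau
    if (sum(ok) >= 3) {
      sl <- stats::coef(stats::lm(log(y[ok]) ~ tt[ok]))[2]
      if (is.finite(sl) && sl < 0) {
        kobs <- c(kobs, -sl); conc <- c(conc, tr$concentration)
      }
    }
  }
  kon0 <- NA_real_
  if (length(kobs) >= 2) {
    sl <- stats::coef(stats::lm(kobs ~ conc))[2]
    if (is.finite(sl) && sl > 0) kon0 <- sl
  } else if (length(kobs) == 1) {
    kon0 <- max((kobs - koff0) / conc, 0.1 * kobs / conc)
  }
  if (!is.finite(kon0) || kon0 <= 0) kon0 <- 1e6
  c(kon = unname(kon0), koff = unname(koff0), rmax = unname(rmax0))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Global 1:1 Langmuir fit (%s, %d points, RSS = %.4g RU^2)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_points, x$residual_sum_of_squares))
  cat(sprintf("  kon  = %.3g +/- %.2g M-1 s-1\n", x$params$kon,
              x$standard_errors["kon"]))
  cat(sprintf("  koff = %.3g +/- %.2g s-1\n", x$params$koff,
              x$standard_errors["koff"]))
  cat(sprintf("  Rmax = %.3g +/- %.2g RU\n", x$params$rmax,
              x$standard_errors["rmax"]))
  cat(sprintf("  Kd   = %.3g M\n", x$params$kd))
  invisible(x)
}

#' Format a fit as a kinetics-table row
#'
#' Produces one row of a per-variant kinetics table in the conventional
#' layout (Kd, kon +/- SE, koff +/- SE), with values rounded to 3
#' significant figures. Kd is the ratio koff/kon of the fitted constants;
#' Rmax is an instrument-level quantity and is deliberately excluded.
#'
#' @param result A converged `fit_result`, or a [kinetic_params] object
#'   (in which case SEs are reported as NA).
#' @param variant Label for the row.
#' @return A one-row data.frame with columns `variant`, `kd_M`,
#'   `kon_M1s1`, `kon_se`, `koff_s1`, `koff_se`.
#' @export
fit_report <- function(result, variant = "variant") {
  if (inherits(result, "kinetic_params")) {
    p <- result; se <- c(kon = NA_real_, koff = NA_real_)
  } else {
    stopifnot(inherits(result, "fit_result"))
    if (!result$converged) stop("cannot report a non-converged fit")
    p <- result$params; se <- result$standard_errors
  }
  data.frame(variant = variant,
             kd_M = signif(p$koff / p$kon, 3),
             kon_M1s1 = signif(p$kon, 3), kon_se = signif(se[["kon"]], 3),
             koff_s1 = signif(p$koff, 3), koff_se = signif(se[["koff"]], 3),
             row.names = NULL)
}
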