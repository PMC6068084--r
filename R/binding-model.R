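#' Kinetic parameters of a 1:1 Langmuir interaction
#'
#' Container for the rate constants of the reversible bimolecular reaction
#' A + B <-> AB that underlies Biacore-style SPR kinetics. The equilibrium
#' dissociation constant is derived, never stored: `Kd = koff/kon`.
#'
#' @param kon Association rate constant (M-1 s-1), > 0.
#' @param koff Dissociation rate constant (s-1), > 0.
#' @param rmax Maximal analyte binding capacity of the surface (RU), > 0.
#' @param temperature Temperature at which the constants apply (K), > 0.
#' @return An object of class `kinetic_params` with fields `kon`, `koff`,
#'   `rmax`, `temperature` and derived `kd` (M).
#' @export
#' @examples
#' kinetic_params(kon = 2.48e6, koff = 5.49e-4, rmax = 100)
kinetic_params <- function(kon, koff, rmax, temperature = 298.15) {
  stopifnot(is.numeric(kon), is.numeric(koff), is.numeric(rmax),
            length(kon) == 1L, length(koff) == 1L, length(rmax) == 1L)
  if (!is.finite(kon) || kon <= 0)   stop("'kon' must be a positive finite number")
  if (!is.finite(koff) || koff <= 0) stop("'koff' must be a positive finite number")
  if (!is.finite(rmax) || rmax <= 0) stop("'rmax' must be a positive finite number")
  if (!is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be a positive finite number (K)")
  structure(
    list(kon = kon, koff = koff, rmax = rmax,
         temperature = temperature, kd = koff / kon),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("1:1 Langmuir kinetic parameters at %.2f K\n", x$temperature))
  cat(sprintf("  kon  = %.3g M-1 s-1\n  koff = %.3g s-1\n  Kd   = %.3g M\n  Rmax = %.3g RU\n",
              x$kon, x$koff, x$kd, x$rmax))
  invisible(x)
}

#' Injection protocol for one sensorgram cycle
#'
#' Phase boundaries of a single injection cycle: analyte flows over the
#' surface from `t_assoc_start` to `t_assoc_end` (association phase), then
#' running buffer alone until `t_end` (dissociation phase).
#'
#' @param t_assoc_start Start of analyte injection (s).
#' @param t_assoc_end End of injection / start of buffer wash (s).
#' @param t_end End of the monitored cycle (s).
#' @param concentration Analyte concentration during injection (M), >= 0.
#' @param sample_interval Detector sampling interval (s), > 0.
#' @return An object of class `injection_protocol`.
#' @export
injection_protocol <- function(t_assoc_start = 0, t_assoc_end = 120,
                               t_end = 720, concentration = 5e-9,
                               sample_interval = 1) {
  if (!(t_assoc_start >= 0 && t_assoc_start < t_assoc_end && t_assoc_end < t_end))
    stop("phase boundaries must satisfy 0 <= t_assoc_start < t_assoc_end < t_end")
  if (!is.finite(concentration) || concentration < 0)
    stop("'concentration' must be non-negative")
  if (!is.finite(sample_interval) || sample_interval <= 0)
    stop("'sample_interval' must be positive")
  structure(
    list(t_assoc_start = t_assoc_start, t_assoc_end = t_assoc_end,
         t_end = t_end, concentration = concentration,
         sample_interval = sample_interval),
    class = "injection_protocol"
  )
}

#' A single SPR sensorgram trace
#'
#' One injection cycle's time/response series together with the metadata
#' the downstream fits need: analyte concentration, temperature and the
#' association-phase boundaries.
#'
#' @param times Time points (s), strictly increasing, length >= 2.
#' @param responses Responses (RU), same length as `times`.
#' @param concentration Analyte concentration (M).
#' @param temperature Temperature (K).
#' @param t_assoc_start,t_assoc_end Association phase boundaries (s).
#' @return An object of class `sensorgram_trace`.
#' @export
sensorgram_trace <- function(times, responses, concentration, temperature,
                             t_assoc_start, t_assoc_end) {
  if (length(times) != length(responses) || length(times) < 2L)
    stop("'times' and 'responses' must have equal length >= 2")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (!is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be positive (K)")
  if (!is.finite(concentration) || concentration < 0)
    stop("'concentration' must be non-negative (M)")
  structure(
    list(times = as.numeric(times), responses = as.numeric(responses),
         concentration = concentration, temperature = temperature,
         t_assoc_start = t_assoc_start, t_assoc_end = t_assoc_end),
    class = "sensorgram_trace"
  )
}

#' @export
print.sensorgram_trace <- function(x, ...) {
  cat(sprintf(
    "SPR sensorgram: %d points, C = %.3g M, T = %.2f K, association %g-%g s\n",
    length(x$times), x$concentration, x$temperature,
    x$t_assoc_start, x$t_assoc_end))
  invisible(x)
}

#' Closed-form association-phase response
#'
#' Analytic solution of the 1:1 Langmuir rate equation
#' dR/dt = kon C (Rmax - R) - koff R starting from R = 0 at the injection
#' start: R(t) = Req (1 - exp(-kobs (t - t0))) with kobs = kon C + koff and
#' Req = Rmax C / (C + Kd).
#'
#' @param params A [kinetic_params] object.
#' @param protocol An [injection_protocol] (supplies C and the phase start).
#' @param t Time grid (s) within the association phase.
#' @return Response (RU) at each time point.
#' @export
#' @examples
#' p <- kinetic_params(1e6, 1e-3, 100)
#' simulate_association(p, injection_protocol(concentration = 1e-8), t = 0:120)
simulate_association <- function(params, protocol, t) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(protocol, "injection_protocol"))
  C <- protocol$concentration
  if (C < 0) stop("'concentration' must be non-negative")
  if (any(t < protocol$t_assoc_start - 1e-12) ||
      any(t > protocol$t_assoc_end + 1e-12))
    stop("time grid must lie within the association phase")
  kobs <- params$kon * C + params$koff
  req  <- params$rmax * C / (C + params$kd)
  req * (1 - exp(-kobs * (t - protocol$t_assoc_start)))
}

#' Closed-form dissociation-phase response
#'
#' After the injection stops (C = 0) the bound complex decays
#' exponentially: R(t) = R0 exp(-koff (t - t0)), with half-life ln(2)/koff.
#'
#' @param params A [kinetic_params] object.
#' @param r0 Response at the start of dissociation (RU), >= 0.
#' @param t Time grid (s); the first element is taken as the phase start t0.
#' @param t0 Start of the dissociation phase (s); defaults to `t[1]`.
#' @return Response (RU) at each time point.
#' @export
simulate_dissociation <- function(params, r0, t, t0 = t[1]) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.finite(r0) || r0 < 0) stop("'r0' must be non-negative")
  if (any(t < t0 - 1e-12)) stop("time grid must not precede the phase start")
  r0 * exp(-params$koff * (t - t0))
}

#' Simulate a full sensorgram cycle
#'
#' Composes the association and dissociation closed forms over the
#' protocol's time grid and adds i.i.d. Gaussian noise in RU. The trace is
#' continuous at the phase boundary before noise. Binding starts from
#' R = 0 (regeneration between cycles is assumed complete) and no
#' mass-transport limitation, bulk jump or baseline drift is modelled.
#'
#' @param params A [kinetic_params] object.
#' @param protocol An [injection_protocol].
#' @param noise_sd Standard deviation of additive Gaussian noise (RU), >= 0.
#' @param seed Optional integer seed; when given the trace is reproducible
#'   and the caller's random state is left untouched.
#' @param t Optional explicit time grid (s); defaults to the protocol's
#'   regular grid from `t_assoc_start` to `t_end` at `sample_interval`.
#' @return A [sensorgram_trace].
#' @export
simulate_sensorgram <- function(params, protocol, noise_sd = 0, seed = NULL,
                                t = NULL) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(protocol, "injection_protocol"))
  if (!is.finite(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (is.null(t))
    t <- seq(protocol$t_assoc_start, protocol$t_end,
             by = protocol$sample_interval)
  resp <- langmuir_response(params, protocol, t)
  if (noise_sd > 0) {
    noise <- local_rng(seed, stats::rnorm(length(t), sd = noise_sd))
    resp <- resp + noise
  }
  sensorgram_trace(t, resp, protocol$concentration, params$temperature,
                   protocol$t_assoc_start, protocol$t_assoc_end)
}

# Noiseless two-phase closed form over an arbitrary grid spanning both phases.
langmuir_response <- function(params, protocol, t) {
  assoc <- t <= protocol$t_assoc_end
  resp <- numeric(length(t))
  resp[assoc] <- simulate_association(params, protocol, t[assoc])
  if (any(!assoc)) {
    C <- protocol$concentration
    kobs <- params$kon * C + params$koff
    req  <- params$rmax * C / (C + params$kd)
    r_end <- req * (1 - exp(-kobs * (protocol$t_assoc_end - protocol$t_assoc_start)))
    resp[!assoc] <- simulate_dissociation(params, r_end, t[!assoc],
                                          t0 = protocol$t_assoc_end)
  }
  resp
}

# Evaluate `expr` under a temporary RNG state seeded with `seed` (or the
# current state when seed is NULL).
local_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Numerically integrated 1:1 Langmuir sensorgram
#'
#' Brute-force oracle for the closed forms: integrates
#' dR/dt = kon C(t) (Rmax - R) - koff R with `deSolve::lsoda`, where C(t)
#' equals the protocol concentration during the association phase and 0
#' afterwards. Used in tests to validate [simulate_association] and
#' [simulate_dissociation]; agreement is better than 1e-8 * Rmax.
#'
#' @inheritParams simulate_sensorgram
#' @param t Time grid (s) spanning the cycle.
#' @return Response (RU) at each time point.
#' @export
simulate_ode <- function(params, protocol, t) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(protocol, "injection_protocol"))
  deriv <- function(time, state, parms) {
    C <- if (time <= parms$t_assoc_end) parms$C else 0
    list(parms$kon * C * (parms$rmax - state[1]) - parms$koff * state[1])
  }
  t_ae <- protocol$t_assoc_end
  # Integrate each phase separately: the concentration drop at t_assoc_end
  # is a genuine discontinuity and must not be stepped across.
  t_a <- sort(unique(c(t[t <= t_ae], protocol$t_assoc_start, t_ae)))
  parms_a <- list(kon = params$kon, koff = params$koff, rmax = params$rmax,
                  C = protocol$concentration, t_assoc_end = Inf)
  out_a <- deSolve::lsoda(y = c(R = 0), times = t_a, func = deriv,
                          parms = parms_a, rtol = 1e-12, atol = 1e-12)
  resp <- numeric(length(t))
  resp[t <= t_ae] <- out_a[match(t[t <= t_ae], out_a[, 1]), 2]
  if (any(t > t_ae)) {
    r_ae <- unname(out_a[nrow(out_a), 2])
    t_d <- sort(unique(c(t_ae, t[t > t_ae])))
    parms_d <- list(kon = params$kon, koff = params$koff, rmax = params$rmax,
                    C = 0, t_assoc_end = Inf)
    out_d <- deSolve::lsoda(y = c(R = r_ae), times = t_d, func = deriv,
                            parms = parms_d, rtol = 1e-12, atol = 1e-12)
    resp[t > t_ae] <- out_d[match(t[t > t_ae], out_d[, 1]), 2]
  }
  resp
}
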