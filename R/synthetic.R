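# Surrogate voltage traces with known ground-truth burst structure, used
# to validate the feature extractor independently of the ODE solver.

#' Specification of a synthetic burst trace
#'
#' Describes a periodic trace: a silent phase at `baseline_V`, an active
#' phase (fraction `active_fraction` of the period) at `plateau_V`
#' carrying `n_spikes` evenly spaced raised-cosine spikes of height
#' `spike_amplitude`, plus Gaussian noise.  A matching sawtooth Ca2+
#' channel (minimum at the active-phase onset) is generated so that the
#' feature extractor's cycle segmentation is exercised.
#'
#' @param period burst period (ms).
#' @param active_fraction fraction of the period spent active, in (0, 1).
#' @param n_spikes spikes per burst (integer >= 0).
#' @param baseline_V,plateau_V silent / active voltage levels (mV).
#' @param spike_amplitude spike height above the plateau (mV).
#' @param noise_sd Gaussian noise s.d. (mV).
#' @param n_periods number of periods generated.
#' @param dt sample step (ms).
#' @param seed RNG seed; traces are deterministic for a fixed seed.
#' @return List of class `"lacto_synth_spec"`.
#' @export
synth_spec <- function(period = 1000, active_fraction = 0.4, n_spikes = 3,
                       baseline_V = -65, plateau_V = -25,
                       spike_amplitude = 10, noise_sd = 0,
                       n_periods = 6, dt = 0.5, seed = 1) {
  if (period <= 0 || dt <= 0) stop("period and dt must be positive")
  if (active_fraction <= 0 || active_fraction >= 1)
    stop("active_fraction must be in (0, 1)")
  if (n_spikes < 0 || n_spikes != round(n_spikes))
    stop("n_spikes must be a nonnegative integer")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(period = period, active_fraction = active_fraction,
                 n_spikes = as.integer(n_spikes), baseline_V = baseline_V,
                 plateau_V = plateau_V, spike_amplitude = spike_amplitude,
                 noise_sd = noise_sd, n_periods = as.integer(n_periods),
                 dt = dt, seed = as.integer(seed)),
            class = "lacto_synth_spec")
}

#' Generate a synthetic burst trace
#'
#' Spike bumps are raised cosines of width `active_phase / (2 n_spikes)`,
#' which makes their prominence exactly `spike_amplitude` and lets
#' detector thresholds be exercised deliberately.  The RNG state is
#' restored on exit.
#'
#' @param spec a [synth_spec()] object.
#' @return A `"lacto_trace"` data frame `(t, V, n, c)` (the `n` channel
#'   is a nominal constant; it is not used by the feature extractor).
#' @export
make_trace <- function(spec) {
  stopifnot(inherits(spec, "lacto_synth_spec"))
  t <- seq(0, spec$n_periods * spec$period - spec$dt, by = spec$dt)
  ph <- (t %% spec$period) / spec$period          # phase in [0, 1)
  af <- spec$active_fraction
  active <- ph < af
  V <- ifelse(active, spec$plateau_V, spec$baseline_V)
  if (spec$n_spikes > 0) {
    width <- af / (2 * spec$n_spikes)             # phase units
    centers <- af * (seq_len(spec$n_spikes) - 0.5) / spec$n_spikes
    for (ctr in centers) {
      d <- abs(ph - ctr)
      inb <- active & d < width / 2
      V[inb] <- V[inb] +
        spec$spike_amplitude * 0.5 * (1 + cos(2 * pi * d[inb] / width))
    }
  }
  if (spec$noise_sd > 0) {
    rs <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(rs)) assign(".Random.seed", rs,
                                     envir = globalenv()))
    set.seed(spec$seed)
    V <- V + stats::rnorm(length(V), sd = spec$noise_sd)
  }
  # sawtooth Ca2+: rises during the active phase, decays while silent
  cc <- ifelse(active, 0.1 + 0.3 * ph / af,
               0.4 - 0.3 * (ph - af) / (1 - af))
  tr <- data.frame(t = t, V = V, n = 0.1, c = cc)
  attr(tr, "spec") <- spec
  class(tr) <- c("lacto_trace", "data.frame")
  tr
}
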