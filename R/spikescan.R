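# Scan protocol for the burst-feature extremes of the bursting region:
# spikes per burst grow without an interior maximum toward the Hopf-side
# border, so the map is a coarse grid per gBK slice refined by bisecting
# the spiking/bursting border in gK and measuring one fixed step inside.

# rotation-counting features: like extract_features but with a prominence
# floor at the integrator noise level, so every canard rotation of the
# active phase is counted, including the near-invisible mid-burst ones
rotation_features <- function(pars, y0 = .ic_midspike, t_end = 160000,
                              transient = 40000, dt = 0.25,
                              prominence = 1e-4) {
  tr <- simulate_lacto(pars, y0, t_end, transient, dt,
                       rtol = 1e-11, atol = 1e-13)
  tryCatch(extract_features(tr, spike_prominence = prominence,
                            smooth_ms = 0),
           lacto_insufficient = function(e)
             list(regime = "insufficient", spikes_per_burst = NA,
                  active_phase = NA, period = NA))
}

#' Maximum spikes per burst over the bursting region
#'
#' Reproduces the burst-feature extreme of the two-parameter map at fixed
#' `Cm`: for each `gBK` slice the Hopf-side spiking/bursting border is
#' located (coarse outward scan from the full-system Hopf point, then
#' bisection with the mid-spike initial condition, which selects the
#' bursting attractor inside the bistable band), and the burst features
#' are measured one fixed step inside the border.  Spikes are counted as
#' canard rotations (prominence floor `rot_prominence`, above integrator
#' ripple but far below the 0.5 mV default used for regime
#' classification, since mid-burst rotation amplitudes decay to
#' micro-volt scale near the border).
#'
#' @param pars baseline parameters; `Cm` is taken from here.
#' @param gBK_values slice positions (nS).
#' @param coarse_step outward scan step from the Hopf point (nS).
#' @param coarse_span maximal outward scan distance (nS).
#' @param border_tol bisection tolerance for the border (nS).
#' @param step_in measurement offset inside the border (nS).
#' @param rot_prominence rotation-counting prominence floor (mV).
#' @return List with `max_spikes`, `max_active_ms`, and the per-slice
#'   table `slices`.
#' @export
max_spikes_scan <- function(pars = lacto_pars(Cm = 5),
                            gBK_values = c(0.5, 1, 1.5, 2, 2.5),
                            coarse_step = 0.25, coarse_span = 3,
                            border_tol = 0.01, step_in = 0.01,
                            rot_prominence = 1e-4) {
  slices <- lapply(gBK_values, function(gb) {
    out <- data.frame(gBK = gb, hb = NA_real_, border = NA_real_,
                      spikes = NA_integer_, active_ms = NA_real_)
    try({
      pb <- sweep_pars(pars, "gBK", gb)
      gg <- seq(0.2, 40, by = 0.4)
      mre <- vapply(gg, function(x) {
        eq <- full_equilibria(sweep_pars(pb, "gK", x))
        if (!nrow(eq)) return(NA_real_)
        eq$max_re[which.max(eq$V)]
      }, 0)
      k <- which(!is.na(mre[-1]) & !is.na(mre[-length(mre)]) &
                   mre[-1] * mre[-length(mre)] < 0)
      if (!length(k)) stop("no Hopf point on slice")
      hb <- full_hopf_slice(pb, "gK", c(gg[k[1]], gg[k[1] + 1]))$value
      out$hb <- hb
      is_burst <- function(gK) {
        ft <- rotation_features(sweep_pars(pb, "gK", gK))
        identical(ft$regime, "bursting")
      }
      gks <- seq(hb + coarse_step, hb + coarse_span, by = coarse_step)
      first <- NA_real_
      for (g in gks) if (is_burst(g)) { first <- g; break }
      if (is.na(first)) stop("no bursting found on slice")
      lo <- first - coarse_step; hi <- first
      while (hi - lo > border_tol) {
        mid <- (lo + hi) / 2
        if (is_burst(mid)) hi <- mid else lo <- mid
      }
      ft <- rotation_features(sweep_pars(pb, "gK", hi + step_in),
                              prominence = rot_prominence)
      out$border <- hi
      out$spikes <- ft$spikes_per_burst
      out$active_ms <- ft$active_phase
    }, silent = TRUE)
    out
  })
  slices <- do.call(rbind, slices)
  list(max_spikes = suppressWarnings(max(slices$spikes, na.rm = TRUE)),
       max_active_ms = suppressWarnings(max(slices$active_ms, na.rm = TRUE)),
       slices = slices)
}
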