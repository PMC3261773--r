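# Full-system integration (compiled right-hand side, adaptive stiff
# solver) and burst-feature extraction.

#' Simulate the full lactotroph model
#'
#' Integrates `(V, n, c)` with an adaptive stiff solver (deSolve `lsoda`,
#' compiled right-hand side).  The transient is discarded.
#'
#' @param pars a [lacto_pars()] object.
#' @param y0 initial state `(V, n, c)`; the default is a hyperpolarized
#'   cell with modest Ca2+.
#' @param t_end total integrated time (ms).
#' @param transient portion discarded from the front (ms).
#' @param dt output sampling step (ms).
#' @param rtol,atol solver tolerances.
#' @return A data frame `(t, V, n, c)` of class `"lacto_trace"` with the
#'   parameters and solver settings as attributes.
#' @export
simulate_lacto <- function(pars = lacto_pars(),
                           y0 = c(V = -60, n = 0.1, c = 0.1),
                           t_end = 60000, transient = 20000, dt = 0.5,
                           rtol = 1e-8, atol = 1e-10) {
  if (pars[["Cm"]] <= 0) stop("Cm must be positive")
  out <- deSolve::lsoda(y = c(V = y0[[1]], n = y0[[2]], c = y0[[3]]),
                        times = seq(0, t_end, by = dt),
                        func = "lacto_derivs", parms = par_vec(pars),
                        dllname = "lactoburst", initfunc = "lacto_initmod",
                        rtol = rtol, atol = atol, maxsteps = 500000)
  if (any(!is.finite(out[, 2:4])))
    stop("solver failure: non-finite state reached")
  tr <- as.data.frame(out[out[, 1] >= transient, ])
  names(tr) <- c("t", "V", "n", "c")
  attr(tr, "pars") <- pars
  attr(tr, "solver") <- list(rtol = rtol, atol = atol, dt = dt,
                             t_end = t_end, transient = transient)
  class(tr) <- c("lacto_trace", "data.frame")
  tr
}

# strict local maxima: greater than both neighbours (flat plateau tops
# are not spikes)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] > x[i + 1]]
}

# cycle boundaries from minima of the slowest variable c; minima are kept
# only if they sit in the lower quarter of the c range, which removes the
# shallow per-spike ripple minima inside the active phase
cycle_minima <- function(t, c) {
  i <- which(diff(sign(diff(c))) > 0) + 1L
  i[c[i] < min(c) + 0.25 * (max(c) - min(c))]
}

# centered moving average with edge-replication padding
smooth_v <- function(V, k) {
  if (k <= 1) return(V)
  h <- k %/% 2
  Vp <- c(rep(V[1], h), V, rep(V[length(V)], h))
  f <- stats::filter(Vp, rep(1 / k, k), sides = 2)
  as.numeric(f[(h + 1):(h + length(V))])
}

# topographic prominence: extend from each strict peak to the nearest
# strictly higher sample (or segment edge) on each side; prominence is
# the height above the higher of the two stretch minima
peak_prominence <- function(x, k) {
  h <- x[k]
  l <- k
  while (l > 1 && x[l - 1] <= h) l <- l - 1
  r <- k
  while (r < length(x) && x[r + 1] <= h) r <- r + 1
  h - max(min(x[l:k]), min(x[k:r]))
}

# prominent local V maxima inside [a, b).  Ordinary peaks are judged by
# topographic prominence (robust to noise: a ripple next to a higher
# sample has a tiny stretch).  The segment's global maximum is the burst
# envelope top, whose stretches span the whole cycle; it counts as a
# spike only if it rises above the active-phase median, so a flat (if
# noisy) plateau contributes no spike.
count_spikes <- function(t, V, a, b, v_thresh, prominence) {
  seg <- which(t >= a & t < b)
  Vs <- V[seg]
  if (length(Vs) < 3) return(0L)
  j <- local_maxima(Vs)
  j <- j[Vs[j] > v_thresh]
  if (!length(j)) return(0L)
  med <- stats::median(Vs[Vs > v_thresh])
  kmax <- j[which.max(Vs[j])]
  keep <- 0L
  for (k in j) {
    ok <- if (k == kmax) Vs[k] - med >= prominence
    else peak_prominence(Vs, k) >= prominence
    if (ok) keep <- keep + 1L
  }
  keep
}

#' Extract burst features from a voltage trace
#'
#' Cycles are delimited by minima of the slow Ca2+ variable; spikes are
#' prominent local voltage maxima above the active-phase threshold; the
#' active phase is the time per cycle spent above that threshold.
#' Regimes: `"steady"` if the voltage range is below 1 mV; `"spiking"`
#' if exactly one prominent maximum per cycle; `"bursting"` otherwise
#' (two or more spikes, or an oscillating plateau whose spikes are too
#' small to resolve at the chosen prominence).
#'
#' @param trace a `"lacto_trace"` (simulated or synthetic).
#' @param spike_prominence minimal topographic prominence of a counted
#'   spike (mV).
#' @param v_thresh active-phase voltage threshold (mV).
#' @param smooth_ms moving-average width applied to V before peak
#'   detection only (ms); suppresses measurement noise without touching
#'   the threshold-based activity measures.  Set 0 to disable.
#' @return List of class `"lacto_features"`: `regime`, `period` (ms),
#'   `active_phase` (ms), `spikes_per_burst`, `amplitude` (mV),
#'   `n_cycles`.
#' @export
extract_features <- function(trace, spike_prominence = 0.5,
                             v_thresh = -40, smooth_ms = 5) {
  tr <- as.data.frame(trace)
  t <- tr$t; V <- tr$V; cc <- tr$c
  dt <- stats::median(diff(t))
  V_pk <- smooth_v(V, as.integer(round(smooth_ms / dt)))
  amp <- max(V) - min(V)
  if (amp < 1)
    return(structure(list(regime = "steady", period = NA_real_,
                          active_phase = NA_real_, spikes_per_burst = 0L,
                          amplitude = amp, n_cycles = 0L),
                     class = "lacto_features"))
  mins <- cycle_minima(t, cc)
  if (length(mins) < 4)
    stop(structure(class = c("lacto_insufficient", "error", "condition"),
                   list(message = "fewer than 3 complete cycles in trace",
                        call = sys.call())))
  ns <- vapply(seq_len(length(mins) - 1), function(k)
    count_spikes(t, V_pk, t[mins[k]], t[mins[k + 1]], v_thresh,
                 spike_prominence), 0L)
  act <- vapply(seq_len(length(mins) - 1), function(k) {
    seg <- which(t >= t[mins[k]] & t < t[mins[k + 1]])
    sum(V[seg] > v_thresh) * dt
  }, 0)
  spb <- as.integer(round(stats::median(ns)))
  structure(list(regime = if (spb == 1L) "spiking" else "bursting",
                 period = mean(diff(t[mins])),
                 active_phase = stats::median(act),
                 spikes_per_burst = spb,
                 amplitude = amp,
                 n_cycles = length(mins) - 1L),
            class = "lacto_features")
}

#' @export
print.lacto_features <- function(x, ...) {
  cat("Burst features:", x$regime, "\n")
  if (x$regime != "steady")
    cat(sprintf("  period %.1f ms, active phase %.1f ms, %d spikes/burst\n",
                x$period, x$active_phase, x$spikes_per_burst))
  invisible(x)
}

#' Simulate and extract features, extending the run if needed
#'
#' Convenience wrapper: simulates, extracts features, and doubles the
#' integration time once if fewer than 3 cycles were found.
#'
#' @inheritParams simulate_lacto
#' @param ... passed on to [extract_features()].
#' @return A `"lacto_features"` list.
#' @export
simulate_features <- function(pars = lacto_pars(),
                              y0 = c(V = -60, n = 0.1, c = 0.1),
                              t_end = 60000, transient = 20000, dt = 0.5,
                              rtol = 1e-8, atol = 1e-10, ...) {
  tr <- simulate_lacto(pars, y0, t_end, transient, dt, rtol, atol)
  tryCatch(extract_features(tr, ...),
           lacto_insufficient = function(e) {
             tr2 <- simulate_lacto(pars, y0, 2 * t_end, transient, dt,
                                   rtol, atol)
             extract_features(tr2, ...)
           })
}

# deterministic initial conditions used for bistability probing
.ic_hyper <- c(V = -60, n = 0.1, c = 0.1)
.ic_midspike <- c(V = -20, n = 0.05, c = 0.3)

#' Burst-feature map over a conductance grid
#'
#' Runs [simulate_features()] on every `(gK, gBK)` grid point.  Each
#' point is probed from two fixed initial conditions (hyperpolarized and
#' mid-spike) to expose bistability between bursting and spiking; the
#' reported row keeps the bursting solution when the two disagree and
#' records the disagreement in `bistable`.
#'
#' @param pars baseline parameters (including `Cm`).
#' @param gK_values,gBK_values grid coordinates (nS).
#' @param both_ics probe both initial conditions?
#' @param ... passed to [simulate_features()].
#' @return Data frame `(gK, gBK, regime, period, active_phase,
#'   spikes_per_burst, bistable)`; failed points carry `NA`s.
#' @export
feature_map <- function(pars = lacto_pars(), gK_values, gBK_values,
                        both_ics = TRUE, ...) {
  grid <- expand.grid(gK = gK_values, gBK = gBK_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- set_pars(pars, gK = grid$gK[i], gBK = grid$gBK[i])
    f1 <- tryCatch(simulate_features(p, y0 = .ic_hyper, ...),
                   error = function(e) NULL)
    f2 <- if (both_ics)
      tryCatch(simulate_features(p, y0 = .ic_midspike, ...),
               error = function(e) NULL) else NULL
    pick <- f1
    bist <- FALSE
    if (!is.null(f2)) {
      if (is.null(pick)) pick <- f2
      else if (f1$regime != f2$regime) {
        bist <- TRUE
        if (f2$regime == "bursting") pick <- f2
      } else if (f2$regime == "bursting" &&
                 f2$spikes_per_burst > f1$spikes_per_burst) pick <- f2
    }
    if (is.null(pick))
      return(data.frame(gK = grid$gK[i], gBK = grid$gBK[i],
                        regime = NA, period = NA, active_phase = NA,
                        spikes_per_burst = NA, bistable = NA))
    data.frame(gK = grid$gK[i], gBK = grid$gBK[i], regime = pick$regime,
               period = pick$period, active_phase = pick$active_phase,
               spikes_per_burst = pick$spikes_per_burst, bistable = bist)
  })
  do.call(rbind, rows)
}

#' Full-system equilibria and stability
#'
#' @param pars a [lacto_pars()] object.
#' @return Data frame `(V, n, c, max_re, oscillatory, stable)`, one row
#'   per equilibrium.
#' @export
full_equilibria <- function(pars = lacto_pars()) {
  Vs <- ordinary_equilibrium_voltages(pars)
  rows <- lapply(Vs, function(V) {
    n <- boltz(V, pars[["vn"]], pars[["sn"]])
    c_eq <- -pars[["alpha"]] * i_ca(V, pars) / pars[["kc"]]
    ev <- eigen(jacobian_full(c(V, n, c_eq), pars), only.values = TRUE)$values
    imax <- which.max(Re(ev))
    data.frame(V = V, n = n, c = c_eq, max_re = Re(ev[imax]),
               oscillatory = abs(Im(ev[imax])) > 0,
               stable = max(Re(ev)) < 0)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(V = numeric(0), n = numeric(0), c = numeric(0),
               max_re = numeric(0), oscillatory = logical(0),
               stable = logical(0))
}

#' Hopf bifurcation of the full system along a parameter slice
#'
#' Bisects the largest real part of the full-system Jacobian spectrum at
#' the depolarized equilibrium (largest-V root).  The crossing pair must
#' be complex for the result to be reported as a Hopf point.
#'
#' @param pars baseline parameters (including `Cm`).
#' @param sweep `"gK"` or `"gBK"`.
#' @param bracket sweep bracket (nS).
#' @param tol bisection tolerance (nS).
#' @return List with `value` (parameter at the Hopf), `omega` (imaginary
#'   part of the crossing pair, 1/ms) and `sweep`.
#' @export
full_hopf_slice <- function(pars = lacto_pars(), sweep = "gK",
                            bracket = c(0.1, 3), tol = 1e-7) {
  mre <- function(x) {
    p <- sweep_pars(pars, sweep, x)
    eq <- full_equilibria(p)
    if (!nrow(eq)) return(NA_real_)
    eq$max_re[which.max(eq$V)]
  }
  if (mre(bracket[1]) * mre(bracket[2]) > 0)
    stop("bracket does not straddle an eigenvalue crossing")
  val <- uniroot(mre, bracket, tol = tol)$root
  p <- sweep_pars(pars, sweep, val)
  eq <- full_equilibria(p)
  i <- which.max(eq$V)
  if (!eq$oscillatory[i])
    stop("crossing eigenvalue pair is real, not a Hopf bifurcation")
  st <- c(eq$V[i], eq$n[i], eq$c[i])
  ev <- eigen(jacobian_full(st, p), only.values = TRUE)$values
  list(value = val, sweep = sweep,
       omega = max(abs(Im(ev))), equilibrium = st)
}
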