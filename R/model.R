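# Core model: activation curves, ionic currents, full right-hand side and
# its analytic Jacobian.  All voltage-dependent gates are Boltzmann
# functions; SK channel activation by Ca2+ is a Hill function of order 2.

# Boltzmann with clamped exponent (saturation is exact far outside the
# physiological range, so clamping changes nothing but avoids overflow).
boltz <- function(V, vh, s) {
  a <- pmin(pmax((vh - V) / s, -500), 500)
  1 / (1 + exp(a))
}
dboltz <- function(V, vh, s) {
  m <- boltz(V, vh, s)
  m * (1 - m) / s
}
d2boltz <- function(V, vh, s) {
  m <- boltz(V, vh, s)
  m * (1 - m) * (1 - 2 * m) / s^2
}
hill2 <- function(c, Kd) c^2 / (c^2 + Kd^2)
dhill2 <- function(c, Kd) 2 * c * Kd^2 / (c^2 + Kd^2)^2
d2hill2 <- function(c, Kd) 2 * Kd^2 * (Kd^2 - 3 * c^2) / (c^2 + Kd^2)^3

#' Steady-state activation functions
#'
#' Voltage-dependent gates (`m`, `n`, `b`) are Boltzmann curves with the
#' midpoints and slopes of the parameter set; Ca2+-dependent SK activation
#' (`s`) is a Hill function with exponent 2 and half-maximum `Kd`.
#'
#' @param x membrane potential in mV (`m`, `n`, `b`) or Ca2+ concentration
#'   in uM (`s`); vectorised.
#' @param which one of `"m"`, `"n"`, `"b"`, `"s"`.
#' @param pars a [lacto_pars()] object.
#' @return Activation value(s) in (0, 1).
#' @examples
#' activation(-20, "m", lacto_pars())  # midpoint: 0.5
#' @export
activation <- function(x, which = c("m", "n", "b", "s"), pars = lacto_pars()) {
  which <- match.arg(which)
  switch(which,
         m = boltz(x, pars[["vm"]], pars[["sm"]]),
         n = boltz(x, pars[["vn"]], pars[["sn"]]),
         b = boltz(x, pars[["vb"]], pars[["sb"]]),
         s = hill2(x, pars[["Kd"]]))
}

# I_Ca and its voltage derivative appear throughout the slow-flow algebra.
i_ca <- function(V, pars)
  pars[["gCa"]] * boltz(V, pars[["vm"]], pars[["sm"]]) * (V - pars[["VCa"]])
di_ca <- function(V, pars)
  pars[["gCa"]] * (dboltz(V, pars[["vm"]], pars[["sm"]]) * (V - pars[["VCa"]]) +
                     boltz(V, pars[["vm"]], pars[["sm"]]))
d2i_ca <- function(V, pars)
  pars[["gCa"]] * (d2boltz(V, pars[["vm"]], pars[["sm"]]) * (V - pars[["VCa"]]) +
                     2 * dboltz(V, pars[["vm"]], pars[["sm"]]))

#' Ionic currents
#'
#' The four membrane currents of the model, in pA: inward Ca2+ current
#' `ICa`, delayed-rectifier `IK`, SK-type Ca2+-activated K+ current `IKCa`
#' and fast BK-type K+ current `IBK`.
#'
#' @param V membrane potential (mV).
#' @param n delayed-rectifier activation.
#' @param c cytosolic Ca2+ (uM).
#' @param pars a [lacto_pars()] object.
#' @return Named numeric vector `(ICa, IK, IKCa, IBK)`.
#' @export
currents <- function(V, n, c, pars = lacto_pars()) {
  dvk <- V - pars[["VK"]]
  c(ICa  = i_ca(V, pars),
    IK   = pars[["gK"]] * n * dvk,
    IKCa = pars[["gKCa"]] * hill2(c, pars[["Kd"]]) * dvk,
    IBK  = pars[["gBK"]] * boltz(V, pars[["vb"]], pars[["sb"]]) * dvk)
}

#' Full-system right-hand side
#'
#' Time derivatives of the state `(V, n, c)`:
#' `C_m dV/dt = -(ICa + IK + IKCa + IBK)`,
#' `dn/dt = (n_inf(V) - n)/tau_n`,
#' `dc/dt = -f_c (alpha ICa + k_c c)`.
#'
#' @param state numeric vector `(V, n, c)` (named or positional).
#' @param pars a [lacto_pars()] object.
#' @return Numeric vector `(dV/dt, dn/dt, dc/dt)` in (mV/ms, 1/ms, uM/ms).
#' @export
rhs_full <- function(state, pars = lacto_pars()) {
  if (pars[["Cm"]] <= 0) stop("Cm must be positive")
  V <- state[[1]]; n <- state[[2]]; c <- state[[3]]
  ii <- currents(V, n, c, pars)
  c(dV = -sum(ii) / pars[["Cm"]],
    dn = (boltz(V, pars[["vn"]], pars[["sn"]]) - n) / pars[["taun"]],
    dc = -pars[["fc"]] * (pars[["alpha"]] * ii[["ICa"]] + pars[["kc"]] * c))
}

#' Analytic Jacobian of the full system
#'
#' Exact partial derivatives of [rhs_full()] with respect to `(V, n, c)`;
#' used for equilibrium stability and Hopf detection.
#'
#' @inheritParams rhs_full
#' @return A 3x3 numeric matrix.
#' @export
jacobian_full <- function(state, pars = lacto_pars()) {
  V <- state[[1]]; n <- state[[2]]; c <- state[[3]]
  dvk <- V - pars[["VK"]]
  s  <- hill2(c, pars[["Kd"]])
  fV <- -(di_ca(V, pars) + pars[["gK"]] * n + pars[["gKCa"]] * s +
            pars[["gBK"]] * (dboltz(V, pars[["vb"]], pars[["sb"]]) * dvk +
                               boltz(V, pars[["vb"]], pars[["sb"]])))
  fn <- -pars[["gK"]] * dvk
  fc_ <- -pars[["gKCa"]] * dhill2(c, pars[["Kd"]]) * dvk
  matrix(c(fV / pars[["Cm"]], fn / pars[["Cm"]], fc_ / pars[["Cm"]],
           dboltz(V, pars[["vn"]], pars[["sn"]]) / pars[["taun"]],
           -1 / pars[["taun"]], 0,
           -pars[["fc"]] * pars[["alpha"]] * di_ca(V, pars), 0,
           -pars[["fc"]] * pars[["kc"]]),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("dV", "dn", "dc"), c("V", "n", "c")))
}

#' Time constants of the three variables
#'
#' `tau_c = 1/(f_c k_c)` is closed form; `tau_n` is the parameter `taun`;
#' the voltage time constant `tau_V = C_m / g_Total` varies along a
#' trajectory with the total conductance
#' `g_Total = gK n + gBK b_inf(V) + gCa m_inf(V) + gKCa s_inf(c)`,
#' so its range is estimated from a simulated trace.
#'
#' @param pars a [lacto_pars()] object.
#' @param trace optional `"lacto_trace"` (or data frame with columns
#'   `V`, `n`, `c`) along which to bound `tau_V`.
#' @return List with `tau_c`, `tau_n` and (if a trace is given)
#'   `tau_V_range = c(min, max)` in ms.
#' @export
time_constants <- function(pars = lacto_pars(), trace = NULL) {
  out <- list(tau_c = 1 / (pars[["fc"]] * pars[["kc"]]),
              tau_n = pars[["taun"]])
  if (!is.null(trace)) {
    tr <- as.data.frame(trace)
    if (!nrow(tr)) stop("empty trace")
    gtot <- pars[["gK"]] * tr$n +
      pars[["gBK"]] * boltz(tr$V, pars[["vb"]], pars[["sb"]]) +
      pars[["gCa"]] * boltz(tr$V, pars[["vm"]], pars[["sm"]]) +
      pars[["gKCa"]] * hill2(tr$c, pars[["Kd"]])
    out$tau_V_range <- pars[["Cm"]] / c(max(gtot), min(gtot))
  }
  out
}
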