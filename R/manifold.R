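# Critical manifold f(V, c, n) = 0, its fold curves L+/- and vertical
# projections.  In the singular limit the fast variable V relaxes to this
# surface; its attracting upper/lower sheets and repelling middle sheet are
# separated by the folds, where df/dV = 0.

#' Fast nullcline function and its partial derivatives
#'
#' `f(V, c, n) = -(ICa + IK + IKCa + IBK)` is the voltage velocity scaled
#' by `C_m`; the critical manifold is its zero set.
#'
#' @param V,c,n coordinates.
#' @param pars a [lacto_pars()] object.
#' @return List with `f` and the partials `fV`, `fc`, `fn`.
#' @export
f_and_partials <- function(V, c, n, pars = lacto_pars()) {
  dvk <- V - pars[["VK"]]
  s <- hill2(c, pars[["Kd"]])
  b <- boltz(V, pars[["vb"]], pars[["sb"]])
  f <- -(i_ca(V, pars) + pars[["gK"]] * n * dvk +
           pars[["gKCa"]] * s * dvk + pars[["gBK"]] * b * dvk)
  fV <- -(di_ca(V, pars) + pars[["gK"]] * n + pars[["gKCa"]] * s +
            pars[["gBK"]] * (dboltz(V, pars[["vb"]], pars[["sb"]]) * dvk + b))
  list(f = f,
       fV = fV,
       fc = -pars[["gKCa"]] * dhill2(c, pars[["Kd"]]) * dvk,
       fn = -pars[["gK"]] * dvk)
}

f_of <- function(V, c, n, pars) f_and_partials(V, c, n, pars)$f

#' Solve the critical manifold for n
#'
#' The manifold `f = 0` is a graph over `(c, V)`:
#' `n(c, V) = -(1/gK) (gCa m_inf(V)(V - VCa)/(V - VK) + gKCa s_inf(c) +
#' gBK b_inf(V))`.
#'
#' @param c Ca2+ concentration (uM); vectorised.
#' @param V membrane potential (mV); vectorised.
#' @param pars a [lacto_pars()] object.
#' @return `n` on the manifold.
#' @export
n_of <- function(c, V, pars = lacto_pars()) {
  if (pars[["gK"]] <= 0) stop("gK must be positive to solve for n")
  if (any(V == pars[["VK"]])) stop("V = VK is singular for n(c, V)")
  -(i_ca(V, pars) / (V - pars[["VK"]]) +
      pars[["gKCa"]] * hill2(c, pars[["Kd"]]) +
      pars[["gBK"]] * boltz(V, pars[["vb"]], pars[["sb"]])) / pars[["gK"]]
}

# Scalar fold-voltage function: eliminating the lumped linear conductance
# between f = 0 and df/dV = 0 leaves
#   phi(V) = (A'(V) + B'(V)) (V - VK) - (A(V) + B(V)),
# with A = gCa m_inf (V - VCa), B = gBK b_inf (V - VK).  phi contains
# neither gK nor c, so the fold voltages are two constants.
phi_fold <- function(V, pars) {
  A <- i_ca(V, pars)
  B <- pars[["gBK"]] * boltz(V, pars[["vb"]], pars[["sb"]]) * (V - pars[["VK"]])
  dAB <- di_ca(V, pars) +
    pars[["gBK"]] * (dboltz(V, pars[["vb"]], pars[["sb"]]) * (V - pars[["VK"]]) +
                       boltz(V, pars[["vb"]], pars[["sb"]]))
  dAB * (V - pars[["VK"]]) - (A + B)
}
dphi_fold <- function(V, pars) {
  d2AB <- d2i_ca(V, pars) +
    pars[["gBK"]] * (d2boltz(V, pars[["vb"]], pars[["sb"]]) * (V - pars[["VK"]]) +
                       2 * dboltz(V, pars[["vb"]], pars[["sb"]]))
  d2AB * (V - pars[["VK"]])
}

# df/dV restricted to the manifold (n = n_of); depends on V only.
fV_manifold <- function(V, pars) -phi_fold(V, pars) / (V - pars[["VK"]])

#' Fold voltages of the critical manifold
#'
#' Solves `f = 0`, `df/dV = 0` simultaneously.  The system reduces to one
#' scalar equation in V alone, so the folds are two constant voltage levels
#' `V- < V+` independent of both `c` and `gK`.  For large `gBK` the folds
#' merge and vanish; an empty result is then a valid state.
#'
#' Roots are located by a dense sign scan on `V` in `[-75, 50]` mV followed
#' by bisection.
#'
#' @param pars a [lacto_pars()] object.
#' @return Numeric vector `c(V_minus, V_plus)`, or `numeric(0)` if the
#'   manifold has no fold.
#' @export
fold_voltages <- function(pars = lacto_pars()) {
  Vg <- seq(-75 + 1e-9, 50, length.out = 2001)
  ph <- phi_fold(Vg, pars)
  i <- which(ph[-1] * ph[-length(ph)] < 0)
  if (!length(i)) return(numeric(0))
  r <- vapply(i, function(k)
    uniroot(phi_fold, c(Vg[k], Vg[k + 1]), pars = pars, tol = 1e-10)$root, 0)
  sort(r)
}

#' Fold curves with their n-parameterisation
#'
#' Samples `L- = (V-, c, n-(c))` and `L+ = (V+, c, n+(c))` on a Ca2+ grid.
#'
#' @param pars a [lacto_pars()] object.
#' @param c_grid Ca2+ sample points (uM).
#' @return A data frame `(curve, c, V, n)` of class `"lacto_folds"`, with
#'   attribute `fold_voltages`; zero rows when the folds have merged away.
#' @export
fold_curves <- function(pars = lacto_pars(),
                        c_grid = seq(0, 1.4, length.out = 561)) {
  fv <- fold_voltages(pars)
  if (!length(fv)) {
    out <- data.frame(curve = character(0), c = numeric(0),
                      V = numeric(0), n = numeric(0))
  } else {
    out <- rbind(
      data.frame(curve = "L-", c = c_grid, V = fv[1],
                 n = n_of(c_grid, fv[1], pars)),
      data.frame(curve = "L+", c = c_grid, V = fv[2],
                 n = n_of(c_grid, fv[2], pars)))
  }
  attr(out, "fold_voltages") <- fv
  class(out) <- c("lacto_folds", "data.frame")
  out
}

#' Project a point vertically onto an attracting sheet
#'
#' Moves along the fast fibre (the V direction) at fixed `(c, n)` to the
#' root of `f` on the requested attracting sheet: above `V+` for the upper
#' sheet, below `V-` for the lower.  This realises the fold projections
#' P(L+) and P(L-) when fed fold-curve points.
#'
#' @param c,n the conserved slow coordinates.
#' @param target `"upper"` or `"lower"`.
#' @param pars a [lacto_pars()] object.
#' @return The voltage of the landing point (mV).
#' @export
project_to_sheet <- function(c, n, target = c("upper", "lower"),
                             pars = lacto_pars()) {
  target <- match.arg(target)
  fv <- fold_voltages(pars)
  if (length(fv) < 2) stop("projection requires both fold curves")
  rng <- if (target == "upper") c(fv[2] + 1e-9, 60) else c(-90, fv[1] - 1e-9)
  Vg <- seq(rng[1], rng[2], length.out = 1500)
  fg <- f_of(Vg, c, n, pars)
  i <- which(fg[-1] * fg[-length(fg)] < 0)
  if (!length(i))
    stop("no root of f on the ", target,
         " sheet: the point has left the fold regime")
  r <- vapply(i, function(k)
    uniroot(function(V) f_of(V, c, n, pars),
            c(Vg[k], Vg[k + 1]), tol = 1e-12)$root, 0)
  r <- r[vapply(r, function(V) fV_manifold(V, pars) < 0, TRUE)]
  if (!length(r))
    stop("no attracting root of f on the ", target, " sheet")
  if (target == "upper") max(r) else min(r)
}

# sheet label by V relative to the fold voltages
sheet_of <- function(V, pars) {
  fv <- fold_voltages(pars)
  if (length(fv) < 2) return(rep("unfolded", length(V)))
  ifelse(V > fv[2], "upper", ifelse(V < fv[1], "lower", "middle"))
}
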