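# Singular periodic orbits.  The orbit is pieced together from the
# desingularized flow on the attracting sheets with vertical jumps at the
# folds: lower sheet -> L- -> jump up to P(L-) -> upper sheet -> L+ (or the
# folded node, if the landing point was inside the singular funnel) -> jump
# down to P(L+) -> ...  The funnel-entry distance delta is measured along
# P(L-) as a signed Ca2+ difference between the orbit's landing point and
# the strong canard, positive inside the funnel.

# Interpolator for the projection of L- onto the upper sheet, V_P(c).
# P(L-) is a graph over c, so a spline over a dense grid is accurate and
# cheap to evaluate inside root functions.
pl_minus_spline <- function(pars, c_range = c(1e-3, 1.4), n = 400) {
  fv <- fold_voltages(pars)
  cg <- seq(c_range[1], c_range[2], length.out = n)
  Vp <- vapply(cg, function(cc)
    tryCatch(project_to_sheet(cc, n_of(cc, fv[1], pars), "upper", pars),
             error = function(e) NA_real_), 0)
  ok <- is.finite(Vp)
  if (sum(ok) < 10) stop("P(L-) could not be sampled on the upper sheet")
  list(fun = stats::splinefun(cg[ok], Vp[ok], method = "natural"),
       range = range(cg[ok]))
}

#' Integrate the reduced flow on one attracting sheet
#'
#' Integrates the desingularized system from a starting point until the
#' trajectory reaches the sheet's fold curve (or, optionally, comes within
#' `fn_tol` of a folded node, or leaves the Ca2+ window).  On the
#' attracting sheets desingularized time runs with true time, so no
#' direction flip is needed.
#'
#' @param V0,c0 starting point on the sheet.
#' @param sheet `"upper"` or `"lower"`.
#' @param pars a [lacto_pars()] object.
#' @param fn optional folded-node location `c(V, c)` used as an additional
#'   stopping set (funnel entry).
#' @param c_range Ca2+ window treated as the working region.
#' @param tau_max maximal desingularized time.
#' @param n_out number of dense-output points over the integrated span.
#' @param fn_tol stopping distance to the folded node.
#' @return List with `path` (matrix `tau, V, c`), the terminal point, and
#'   `stopped_at` in `{"fold", "folded_node", "c_range", "tau_max"}`.
#' @export
integrate_reduced <- function(V0, c0, sheet = c("upper", "lower"),
                              pars = lacto_pars(), fn = NULL,
                              c_range = c(1e-4, 1.4), tau_max = 5e5,
                              n_out = 400, fn_tol = 1e-4) {
  sheet <- match.arg(sheet)
  fv <- fold_voltages(pars)
  if (length(fv) < 2) stop("no fold curves for these parameters")
  rhs <- function(t, y, parms) list(desing_rhs(y[1], y[2], pars))
  root <- function(t, y, parms) {
    r <- c(if (sheet == "upper") y[1] - fv[2] else fv[1] - y[1],
           y[2] - c_range[1], y[2] - c_range[2])
    if (!is.null(fn))
      r <- c(r, sqrt((y[1] - fn[1])^2 + (y[2] - fn[2])^2) - fn_tol)
    r
  }
  out <- deSolve::lsodar(c(V = V0, c = c0), times = c(0, tau_max),
                         func = rhs, rootfunc = root,
                         rtol = 1e-10, atol = 1e-12)
  t_stop <- out[nrow(out), 1]
  if (t_stop > 0 && t_stop < tau_max) {
    # re-run with dense output over the actual span (extended slightly so
    # the terminating root fires strictly inside the requested window)
    out <- deSolve::lsodar(c(V = V0, c = c0),
                           times = seq(0, 1.05 * t_stop, length.out = n_out),
                           func = rhs, rootfunc = root,
                           rtol = 1e-10, atol = 1e-12)
  }
  term <- out[nrow(out), ]
  iroot <- attr(out, "iroot")
  stopped <- if (is.null(iroot) || all(iroot == 0)) "tau_max"
  else if (iroot[1] == 1) "fold"
  else if (length(iroot) >= 4 && iroot[4] == 1) "folded_node"
  else "c_range"
  list(path = out, V = unname(term[2]), c = unname(term[3]),
       stopped_at = stopped)
}

#' Strong canard of the folded node
#'
#' The singular trajectory that enters the folded node along its strong
#' eigendirection, computed by integrating the desingularized flow
#' backwards from `FN + eps * (strong eigenvector)` on the upper sheet
#' until it crosses P(L-) or leaves the Ca2+ window.
#'
#' @param pars a [lacto_pars()] object.
#' @param eps displacement from the folded node along the strong
#'   eigenvector (state units).
#' @param c_range working Ca2+ window.
#' @return List of class `"lacto_canard"`: `path`, the folded node
#'   location `fn`, the strong `eigendirection`, and `sc_c`, the Ca2+
#'   coordinate where the canard crosses P(L-) (`NA` if it exits the
#'   window first).
#' @export
strong_canard <- function(pars = lacto_pars(), eps = 1e-4,
                          c_range = c(1e-4, 1.4)) {
  fs <- find_folded_singularities(pars)
  fn_row <- fs[fs$on_curve == "L+" & fs$class == "folded_node" & fs$c > 0, ]
  if (!nrow(fn_row)) stop("no folded node on L+ for these parameters")
  fn_row <- fn_row[1, ]
  J <- desing_jacobian(fn_row$V, fn_row$c, pars)
  e <- eigen(J)
  istr <- which.max(abs(Re(e$values)))
  v <- Re(e$vectors[, istr]); v <- v / sqrt(sum(v^2))

  fv <- fold_voltages(pars)
  pl <- pl_minus_spline(pars, c(c_range[1], c_range[2]))
  rhs <- function(t, y, parms) list(-desing_rhs(y[1], y[2], pars))
  root <- function(t, y, parms) {
    gc <- min(max(y[2], pl$range[1]), pl$range[2])
    c(y[1] - pl$fun(gc), y[2] - c_range[1], y[2] - c_range[2])
  }
  best <- NULL
  for (sg in c(1, -1)) {
    y0 <- c(fn_row$V, fn_row$c) + sg * eps * v
    if (y0[1] <= fv[2]) next  # keep the branch on the upper sheet
    out <- deSolve::lsodar(c(V = y0[1], c = y0[2]), times = c(0, 5e5),
                           func = rhs, rootfunc = root,
                           rtol = 1e-10, atol = 1e-12)
    t_stop <- out[nrow(out), 1]
    if (t_stop > 0 && t_stop < 5e5)
      out <- deSolve::lsodar(c(V = y0[1], c = y0[2]),
                             times = seq(0, 1.05 * t_stop, length.out = 400),
                             func = rhs, rootfunc = root,
                             rtol = 1e-10, atol = 1e-12)
    term <- out[nrow(out), ]
    hit <- abs(term[2] - pl$fun(min(max(term[3], pl$range[1]),
                                    pl$range[2]))) < 1e-6
    cand <- list(path = out, fn = c(V = fn_row$V, c = fn_row$c),
                 eigendirection = v,
                 sc_c = if (hit) unname(term[3]) else NA_real_)
    if (hit) { best <- cand; break }
    if (is.null(best)) best <- cand
  }
  structure(best, class = "lacto_canard")
}

# Is the point on P(L-) at Ca2+ level cc inside the singular funnel?
# (Its forward reduced trajectory then reaches the folded node.)
in_funnel <- function(cc, pars, fn, pl) {
  Vu <- tryCatch(pl$fun(cc), error = function(e) NA_real_)
  if (!is.finite(Vu)) return(NA)
  r <- integrate_reduced(Vu, cc, "upper", pars, fn = fn)
  r$stopped_at == "folded_node"
}

#' Construct the singular periodic orbit
#'
#' Iterates sheet flows and vertical fold jumps until the Ca2+ coordinate
#' of the landing point on P(L+) repeats (a fixed point of the one
#' dimensional return map) or `max_cycles` is reached.  If the upper-sheet
#' segment funnels into the folded node, the downward jump is taken from
#' the folded node itself, as in the singular limit.
#'
#' @param pars a [lacto_pars()] object.
#' @param start starting point `c(V, c)` on the lower sheet.
#' @param c_range working Ca2+ window (uM).
#' @param tol return-map convergence tolerance on c (uM).
#' @param max_cycles cap on return-map iterations.
#' @return An object of class `"lacto_orbit"`: list with `segments` (data
#'   frame `segment, sheet, tau, V, c, n`), `jumps`, `landing_c` (on
#'   P(L-)), `passes_through_FN`, `converged`.
#' @export
build_singular_orbit <- function(pars = lacto_pars(),
                                 start = c(V = -70, c = 0.9),
                                 c_range = c(1e-4, 1.4), tol = 1e-8,
                                 max_cycles = 50) {
  fv <- fold_voltages(pars)
  if (length(fv) < 2) stop("no fold curves for these parameters")
  fs <- find_folded_singularities(pars)
  fn_row <- fs[fs$on_curve == "L+" & fs$class == "folded_node" & fs$c > 0, ]
  fn <- if (nrow(fn_row)) c(fn_row$V[1], fn_row$c[1]) else NULL

  landing_c <- NA_real_
  through_fn <- FALSE
  converged <- FALSE
  failed <- FALSE
  segs <- list(); jumps <- list()
  keep <- function(res, sheet, id) {
    p <- res$path
    data.frame(segment = id, sheet = sheet, tau = p[, 1],
               V = p[, 2], c = p[, 3], n = n_of(p[, 3], p[, 2], pars))
  }
  # one turn of the return map: from a point on the lower sheet (at Ca2+
  # level c_dn just after the downward jump) back to the next downward
  # jump; records the cycle's segments/jumps as a side effect
  cycle_from <- function(V0, c0) {
    lo <- integrate_reduced(V0, c0, "lower", pars, c_range = c_range)
    if (lo$stopped_at != "fold") return(NULL)
    landing_c <<- lo$c
    n_j <- n_of(lo$c, fv[1], pars)
    V_up <- project_to_sheet(lo$c, n_j, "upper", pars)
    up <- integrate_reduced(V_up, lo$c, "upper", pars, fn = fn,
                            c_range = c_range)
    if (!up$stopped_at %in% c("fold", "folded_node")) return(NULL)
    through_fn <<- up$stopped_at == "folded_node"
    c_down <- if (through_fn) fn[2] else up$c
    V_dn <- project_to_sheet(c_down, n_of(c_down, fv[2], pars),
                             "lower", pars)
    segs <<- list(keep(lo, "lower", 1L), keep(up, "upper", 2L))
    jumps <<- list(list(from = "L-", c = lo$c, n = n_j, V_land = V_up),
                   list(from = "L+", c = c_down,
                        n = n_of(c_down, fv[2], pars), V_land = V_dn))
    c(V_dn, c_down)
  }
  st <- cycle_from(start[[1]], start[[2]])
  if (is.null(st)) failed <- TRUE
  k <- 1L
  hist <- if (failed) numeric(0) else st[2]
  while (!failed && !converged && k < max_cycles) {
    nxt <- cycle_from(st[1], st[2])
    if (is.null(nxt)) { failed <- TRUE; break }
    k <- k + 1L
    hist <- c(hist, nxt[2])
    if (abs(nxt[2] - st[2]) < tol) { converged <- TRUE; st <- nxt; break }
    st <- nxt
    # Aitken acceleration of the slowly contracting 1-D map
    m <- length(hist)
    if (m >= 3 && m %% 3 == 0) {
      d1 <- hist[m] - hist[m - 1]; d2 <- hist[m - 1] - hist[m - 2]
      if (abs(d1 - d2) > 0) {
        c_acc <- hist[m] - d1^2 / (d1 - d2)
        if (is.finite(c_acc) && c_acc > c_range[1] && c_acc < c_range[2]) {
          V_acc <- tryCatch(project_to_sheet(c_acc,
                     n_of(c_acc, fv[2], pars), "lower", pars),
                     error = function(e) NA_real_)
          if (is.finite(V_acc)) st <- c(V_acc, c_acc)
        }
      }
    }
  }
  structure(list(segments = if (length(segs)) do.call(rbind, segs) else NULL,
                 jumps = jumps, landing_c = landing_c,
                 passes_through_FN = through_fn, converged = converged,
                 fold_voltages = fv, fn = fn, pars = pars),
            class = "lacto_orbit")
}

#' @export
print.lacto_orbit <- function(x, ...) {
  cat("Singular periodic orbit:",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  landing point on P(L-): c =", format(x$landing_c), "uM\n")
  cat("  passes through folded node:", x$passes_through_FN, "\n")
  invisible(x)
}

#' Funnel-entry distance of the singular orbit
#'
#' Signed Ca2+ difference, measured along P(L-), between the singular
#' orbit's landing point and the crossing point of the strong canard.
#' The sign is fixed dynamically so that landing points inside the
#' singular funnel (whose reduced trajectories pass through the folded
#' node) give `delta > 0`; `delta = 0` means the orbit lands exactly on
#' the strong canard and separates relaxation oscillation (spiking,
#' `delta < 0`) from mixed mode oscillation (bursting, `delta > 0`).
#'
#' @param orbit a `"lacto_orbit"` from [build_singular_orbit()]; may be
#'   `NULL`, in which case it is built from `pars`.
#' @param canard a `"lacto_canard"` from [strong_canard()]; built on
#'   demand when `NULL`.
#' @param pars a [lacto_pars()] object.
#' @return List with `delta` (uM), `landing_c`, `sc_c`,
#'   `passes_through_FN`, `converged`.
#' @export
delta_of <- function(orbit = NULL, canard = NULL, pars = lacto_pars()) {
  if (is.null(orbit)) orbit <- build_singular_orbit(pars)
  pars <- orbit$pars
  if (is.null(canard)) canard <- strong_canard(pars)
  if (!is.finite(canard$sc_c))
    stop("strong canard does not reach P(L-): delta undefined")
  if (!orbit$converged)
    stop("singular orbit did not converge: delta undefined")
  pl <- pl_minus_spline(pars)
  h <- 0.02
  side <- NA
  up <- in_funnel(canard$sc_c + h, pars, orbit$fn, pl)
  if (isTRUE(up)) side <- +1
  else {
    dn <- in_funnel(canard$sc_c - h, pars, orbit$fn, pl)
    if (isTRUE(dn)) side <- -1
  }
  if (is.na(side)) stop("could not determine funnel side of the strong canard")
  list(delta = side * (orbit$landing_c - canard$sc_c),
       landing_c = orbit$landing_c, sc_c = canard$sc_c,
       passes_through_FN = orbit$passes_through_FN,
       converged = orbit$converged)
}
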