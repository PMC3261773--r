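# Two-fast/one-slow comparison analysis: equilibria of the (V, n) fast
# subsystem with Ca2+ treated as a parameter (the "z-curve"), their
# stability, and the fold (limit point) and Hopf points along the branch.

fast_jacobian <- function(V, n, c, pars) {
  fp <- f_and_partials(V, c, n, pars)
  matrix(c(fp$fV / pars[["Cm"]], fp$fn / pars[["Cm"]],
           dboltz(V, pars[["vn"]], pars[["sn"]]) / pars[["taun"]],
           -1 / pars[["taun"]]),
         nrow = 2, byrow = TRUE)
}

#' Equilibria of the fast (V, n) subsystem
#'
#' With `c` frozen, fast-subsystem equilibria satisfy `n = n_inf(V)` and
#' `f(V, c, n_inf(V)) = 0`; all voltage roots are found by dense sign
#' scan plus bisection and classified by the 2x2 Jacobian.
#'
#' @param c Ca2+ concentration (uM).
#' @param pars a [lacto_pars()] object.
#' @return Data frame `(V, n, max_re, oscillatory, stable)`.
#' @export
fast_equilibria <- function(c, pars = lacto_pars()) {
  g <- function(V) f_of(V, c, boltz(V, pars[["vn"]], pars[["sn"]]), pars)
  Vg <- seq(-74.999, 49.999, length.out = 2001)
  gv <- g(Vg)
  i <- which(gv[-1] * gv[-length(gv)] < 0)
  rows <- lapply(i, function(k) {
    V <- uniroot(g, c(Vg[k], Vg[k + 1]), tol = 1e-12)$root
    n <- boltz(V, pars[["vn"]], pars[["sn"]])
    ev <- eigen(fast_jacobian(V, n, c, pars), only.values = TRUE)$values
    data.frame(V = V, n = n, max_re = max(Re(ev)),
               oscillatory = any(abs(Im(ev)) > 0),
               stable = max(Re(ev)) < 0)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(V = numeric(0), n = numeric(0), max_re = numeric(0),
               oscillatory = logical(0), stable = logical(0))
}

#' Build the z-curve of the fast subsystem
#'
#' Sweeps `c`, records all fast-subsystem equilibria with stability, and
#' locates limit points (changes in the number of equilibria) and Hopf
#' points (stability flip of the depolarized branch through a complex
#' pair) by bisection in `c`.
#'
#' @param pars a [lacto_pars()] object.
#' @param c_range swept Ca2+ interval (uM).
#' @param n number of sweep points.
#' @return List of class `"lacto_zcurve"`: `branches` (data frame
#'   `c, V, n, stable, oscillatory`), `limit_points`, `hopf_points`
#'   (each `(c, V)` data frames).
#' @export
build_zcurve <- function(pars = lacto_pars(), c_range = c(0.005, 1.4),
                         n = 301) {
  cg <- seq(c_range[1], c_range[2], length.out = n)
  eqs <- lapply(cg, fast_equilibria, pars = pars)
  branches <- do.call(rbind, lapply(seq_along(cg), function(i)
    if (nrow(eqs[[i]]))
      cbind(c = cg[i], eqs[[i]]) else NULL))

  counts <- vapply(eqs, nrow, 0L)
  limit_points <- list()
  for (i in which(diff(counts) != 0)) {
    cc <- bisect_boundary(function(x) nrow(fast_equilibria(x, pars)) ==
                            counts[i], cg[i], cg[i + 1], tol = 1e-8)
    eq <- fast_equilibria(cc, pars)
    # at a fold two roots nearly coincide; report the pair midpoint
    Vlp <- if (nrow(eq)) eq$V[which.min(abs(eq$max_re))] else NA_real_
    limit_points[[length(limit_points) + 1]] <- data.frame(c = cc, V = Vlp)
  }

  # Hopf on the depolarized (largest-V) branch
  top_re <- vapply(eqs, function(e)
    if (nrow(e)) e$max_re[which.max(e$V)] else NA_real_, 0)
  hopf_points <- list()
  for (i in which(!is.na(top_re[-1]) & !is.na(top_re[-length(top_re)]) &
                    top_re[-1] * top_re[-length(top_re)] < 0)) {
    g <- function(x) {
      e <- fast_equilibria(x, pars)
      e$max_re[which.max(e$V)]
    }
    cc <- uniroot(g, c(cg[i], cg[i + 1]), tol = 1e-10)$root
    e <- fast_equilibria(cc, pars)
    k <- which.max(e$V)
    if (e$oscillatory[k])
      hopf_points[[length(hopf_points) + 1]] <-
        data.frame(c = cc, V = e$V[k])
  }
  structure(list(branches = branches,
                 limit_points = if (length(limit_points))
                   do.call(rbind, limit_points) else
                     data.frame(c = numeric(0), V = numeric(0)),
                 hopf_points = if (length(hopf_points))
                   do.call(rbind, hopf_points) else
                     data.frame(c = numeric(0), V = numeric(0)),
                 pars = pars),
            class = "lacto_zcurve")
}

#' @export
print.lacto_zcurve <- function(x, ...) {
  cat("Fast-subsystem z-curve:",
      length(unique(round(x$branches$c, 10))), "c-slices\n")
  cat("  limit points at c =", format(x$limit_points$c, digits = 5), "\n")
  cat("  Hopf points at c =", format(x$hopf_points$c, digits = 5), "\n")
  invisible(x)
}

#' Probe sub/supercriticality of a fast-subsystem Hopf point
#'
#' Integrates the fast `(V, n)` subsystem at a Ca2+ level just on the
#' unstable side of the Hopf point, starting from a tiny perturbation of
#' the equilibrium.  A supercritical Hopf sheds a small stable limit
#' cycle there, so the oscillation saturates at small amplitude; a
#' subcritical Hopf sheds no nearby attractor and the trajectory escapes
#' to a distant state.
#'
#' @param pars a [lacto_pars()] object.
#' @param c_hopf Hopf Ca2+ location (from [build_zcurve()]).
#' @param dc probe offset in Ca2+ (uM); both sides are examined and the
#'   unstable one is used.
#' @param pert initial perturbation amplitude (mV).
#' @param t_end integration time (ms).
#' @param escape amplitude (mV) regarded as escape to a distant
#'   attractor.
#' @return `"subcritical"` or `"supercritical"`.
#' @export
probe_fast_hopf <- function(pars = lacto_pars(), c_hopf, dc = 0.02,
                            pert = 0.1, t_end = 20000, escape = 15) {
  cc <- c_hopf + dc
  e <- fast_equilibria(cc, pars)
  k <- which.max(e$V)
  if (!nrow(e) || e$stable[k]) {
    cc <- c_hopf - dc
    e <- fast_equilibria(cc, pars)
    k <- which.max(e$V)
  }
  if (!nrow(e) || e$stable[k])
    stop("no unstable depolarized equilibrium found near c = ", c_hopf)
  rhs <- function(t, y, parms) {
    f <- f_of(y[1], cc, y[2], pars)
    list(c(f / pars[["Cm"]],
           (boltz(y[1], pars[["vn"]], pars[["sn"]]) - y[2]) / pars[["taun"]]))
  }
  out <- deSolve::lsoda(c(V = e$V[k] + pert, n = e$n[k]),
                        seq(0, t_end, by = 1), rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-11)
  if (max(abs(out[, 2] - e$V[k])) > escape) "subcritical" else "supercritical"
}
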