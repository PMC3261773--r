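# One- and two-parameter bifurcation detection for the desingularized
# system.  Every boundary here is the zero of a scalar test function that
# is monotone near its zero, so all curves are traced by per-slice
# bisection on a parameter grid; no continuation machinery is used.

sweep_pars <- function(pars, name, value) {
  stopifnot(name %in% c("gK", "gBK"))
  p <- unclass(pars); p[[name]] <- value
  structure(p, class = "lacto_pars")
}

# boundary of a logical predicate by bisection; pred must differ at ends
bisect_boundary <- function(pred, lo, hi, tol = 1e-6) {
  plo <- pred(lo); phi <- pred(hi)
  if (is.na(plo) || is.na(phi) || plo == phi)
    stop("bracket endpoints do not straddle the event")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(pred(mid), plo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# signed distance of the ordinary singularity nearest a fold level from
# that fold; zero exactly at a transcritical (type II folded saddle-node)
tr_test <- function(pars, fold) {
  fv <- fold_voltages(pars)
  if (length(fv) < 2) return(NA_real_)
  Vf <- if (fold == "upper") fv[2] else fv[1]
  Vs <- ordinary_equilibrium_voltages(pars)
  if (!length(Vs)) return(NA_real_)
  Vs[which.min(abs(Vs - Vf))] - Vf
}

#' Transcritical (type II folded saddle-node) bifurcation
#'
#' Locates the parameter value at which an ordinary singularity crosses a
#' fold curve (equivalently, `df/dV` vanishes at the CN1 equilibrium) by
#' bisection on a bracket.
#'
#' @param pars baseline parameters (the non-swept values are held fixed).
#' @param sweep `"gK"` or `"gBK"`.
#' @param bracket numeric length 2; must straddle the event.
#' @param fold which fold the equilibrium crosses (`"upper"` for TR1,
#'   `"lower"` for TR2 at default parameters).
#' @param tol bisection tolerance in nS.
#' @return List of class `"lacto_bif"` with `kind`, `param`, `value`,
#'   `location` (V, c at the event) and `pars`.
#' @export
find_TR <- function(pars = lacto_pars(), sweep = "gK",
                    bracket = c(0.1, 1), fold = c("upper", "lower"),
                    tol = 1e-6) {
  fold <- match.arg(fold)
  g <- function(x) tr_test(sweep_pars(pars, sweep, x), fold)
  if (g(bracket[1]) * g(bracket[2]) > 0)
    stop("bracket endpoints do not straddle a transcritical point")
  val <- uniroot(g, bracket, tol = tol)$root
  p <- sweep_pars(pars, sweep, val)
  fv <- fold_voltages(p)
  Vf <- if (fold == "upper") fv[2] else fv[1]
  c_eq <- -p[["alpha"]] * i_ca(Vf, p) / p[["kc"]]
  structure(list(kind = paste0("TR_", fold), param = sweep, value = val,
                 location = c(V = Vf, c = c_eq), pars = p),
            class = "lacto_bif")
}

n_folded_on <- function(pars, fold, c_window = c(-1, 1.4)) {
  fv <- fold_voltages(pars)
  if (length(fv) < 2) return(0L)
  Vf <- if (fold == "upper") fv[2] else fv[1]
  length(fold_F_roots(Vf, pars, c_window = c(0, c_window[2]),
                      c_neg_window = c(c_window[1], 0)))
}

#' Saddle-node (type I folded saddle-node) of folded singularities
#'
#' Locates, by bisection on the number of `F` roots along a fold line,
#' the parameter value at which a folded node and a folded saddle
#' coalesce and disappear (double-root condition of `F` restricted to
#' the fold).
#'
#' @inheritParams find_TR
#' @param fold fold curve carrying the pair.
#' @param c_window Ca2+ window searched for folded singularities
#'   (includes the negative-c extension).
#' @return A `"lacto_bif"` list; `location` reports the coalescence
#'   point estimated just inside the existence side.
#' @export
find_SN <- function(pars = lacto_pars(), sweep = "gK",
                    bracket = c(4, 10), fold = c("upper", "lower"),
                    tol = 1e-6, c_window = c(-1, 1.4)) {
  fold <- match.arg(fold)
  pred <- function(x)
    n_folded_on(sweep_pars(pars, sweep, x), fold, c_window) >= 2
  val <- bisect_boundary(pred, bracket[1], bracket[2], tol)
  inside <- if (pred(bracket[1])) val - 5 * tol else val + 5 * tol
  p_in <- sweep_pars(pars, sweep, inside)
  fv <- fold_voltages(p_in)
  Vf <- if (fold == "upper") fv[2] else fv[1]
  r <- fold_F_roots(Vf, p_in, c_window = c(0, c_window[2]),
                    c_neg_window = c(c_window[1], 0))
  loc <- c(V = Vf, c = if (length(r) >= 2) mean(range(r)) else NA_real_)
  structure(list(kind = paste0("SN_", fold), param = sweep, value = val,
                 location = loc, pars = sweep_pars(pars, sweep, val)),
            class = "lacto_bif")
}

# discriminant tr^2 - 4 det of the desingularized Jacobian at the folded
# singularity on `fold` nearest to c_near
focus_node_test <- function(pars, fold, c_near) {
  fv <- fold_voltages(pars)
  if (length(fv) < 2) return(NA_real_)
  Vf <- if (fold == "upper") fv[2] else fv[1]
  r <- fold_F_roots(Vf, pars)
  if (!length(r)) return(NA_real_)
  cc <- r[which.min(abs(r - c_near))]
  J <- desing_jacobian(Vf, cc, pars)
  (J[1, 1] + J[2, 2])^2 - 4 * (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
}

#' Folded focus to folded node transition
#'
#' Bisection on the eigenvalue discriminant of the desingularized
#' Jacobian at a tracked folded singularity.
#'
#' @inheritParams find_TR
#' @param fold fold curve carrying the tracked singularity.
#' @param c_near initial guess for the tracked singularity's Ca2+
#'   coordinate (the root nearest this value is followed).
#' @return A `"lacto_bif"` list.
#' @export
find_focus_node <- function(pars = lacto_pars(), sweep = "gK",
                            bracket = c(30, 50), fold = "lower",
                            c_near = 0.27, tol = 1e-6) {
  g <- function(x) focus_node_test(sweep_pars(pars, sweep, x), fold, c_near)
  if (g(bracket[1]) * g(bracket[2]) > 0)
    stop("bracket endpoints do not straddle the discriminant zero")
  val <- uniroot(g, bracket, tol = tol)$root
  structure(list(kind = paste0("focus_node_", fold), param = sweep,
                 value = val, location = c(V = NA, c = NA),
                 pars = sweep_pars(pars, sweep, val)),
            class = "lacto_bif")
}

#' Fold-merge point of the critical manifold
#'
#' The fold voltages are the simple roots of a scalar function of V; at
#' the merge value of `gBK` that function has a double root (its interior
#' minimum touches zero) and the fold structure of the critical manifold
#' disappears.  Independent of `gK`.
#'
#' @param pars baseline parameters.
#' @param bracket bracket in `gBK` (nS).
#' @param tol root tolerance.
#' @return A `"lacto_bif"` list; `location` holds the merged fold
#'   voltage.
#' @export
find_fold_merge <- function(pars = lacto_pars(), bracket = c(20, 40),
                            tol = 1e-10) {
  dipmin <- function(gBK)
    optimize(function(V) phi_fold(V, sweep_pars(pars, "gBK", gBK)),
             c(-72, -40))
  g <- function(gBK) dipmin(gBK)$objective
  if (g(bracket[1]) * g(bracket[2]) > 0)
    stop("bracket does not straddle the fold-merge point")
  val <- uniroot(g, bracket, tol = tol)$root
  V0 <- dipmin(val)$minimum
  structure(list(kind = "fold_merge", param = "gBK", value = val,
                 location = c(V = V0, c = NA),
                 pars = sweep_pars(pars, "gBK", val)),
            class = "lacto_bif")
}

#' Codimension-2 point on the fold-merge line
#'
#' With `gBK` at the fold-merge value the two folds coincide in a single
#' line that still carries folded singularities (the SN3/SN4 pairs) up to
#' a codimension-2 point in `gK`, beyond which it carries none.  Located
#' by bisection on the existence of `F` roots along the merged line.
#'
#' @param pars baseline parameters.
#' @param bracket bracket in `gK` (nS).
#' @param merge optional precomputed result of [find_fold_merge()].
#' @param tol bisection tolerance (nS).
#' @return A `"lacto_bif"` list.
#' @export
find_codim2_on_merge_line <- function(pars = lacto_pars(),
                                      bracket = c(50, 120),
                                      merge = NULL, tol = 1e-6) {
  if (is.null(merge)) merge <- find_fold_merge(pars)
  V0 <- merge$location[["V"]]
  p0 <- sweep_pars(pars, "gBK", merge$value)
  pred <- function(gK)
    length(fold_F_roots(V0, sweep_pars(p0, "gK", gK),
                        c_window = c(0, 1.4), c_neg_window = c(-1, 0))) > 0
  val <- bisect_boundary(pred, bracket[1], bracket[2], tol)
  structure(list(kind = "codim2_merge", param = "gK", value = val,
                 location = c(V = V0, c = NA),
                 pars = sweep_pars(p0, "gK", val)),
            class = "lacto_bif")
}

#' @export
print.lacto_bif <- function(x, ...) {
  cat(sprintf("%s bifurcation at %s = %.6g nS\n", x$kind, x$param, x$value))
  invisible(x)
}

#' Eigenvalue-ratio profile across the folded-node window
#'
#' For `gK` between the TR1 and SN1 boundaries (at fixed `gBK`) there is
#' a folded node on L+; its eigenvalue ratio `mu` vanishes at both ends
#' (the type II and type I folded saddle-node limits) and is maximal in
#' between, with `S_max = floor((mu+1)/(2 mu))` accordingly large near
#' the ends.
#'
#' @param pars baseline parameters (fixing `gBK` etc.).
#' @param gK_range interval to profile; when `NULL`, the (TR1, SN1)
#'   interval is located automatically.
#' @param n number of grid points.
#' @return Data frame `(gK, mu, s_max)` with `NA` where no folded node
#'   exists.
#' @export
mu_profile <- function(pars = lacto_pars(), gK_range = NULL, n = 101) {
  if (is.null(gK_range)) {
    tr1 <- find_TR(pars, "gK", c(0.1, 2), "upper")$value
    sn1 <- find_SN(pars, "gK", c(tr1 + 0.1, 12), "upper")$value
    gK_range <- c(tr1, sn1)
  }
  gg <- seq(gK_range[1], gK_range[2], length.out = n + 2)
  gg <- gg[-c(1, length(gg))]       # open interval: mu undefined at ends
  mu <- vapply(gg, function(g) {
    fs <- find_folded_singularities(sweep_pars(pars, "gK", g))
    fn <- fs[fs$on_curve == "L+" & fs$class == "folded_node", ]
    if (!nrow(fn)) return(NA_real_)
    max(fn$mu)
  }, 0)
  data.frame(gK = gg, mu = mu,
             s_max = ifelse(is.na(mu) | mu <= 0, NA, floor((mu + 1) / (2 * mu))))
}

#' Trace the delta = 0 boundary of the mixed-mode-oscillation region
#'
#' For each `gBK` value, brackets the sign change of the funnel-entry
#' distance delta in `gK` inside the (TR1, SN1) folded-node window and
#' refines it by bisection.  Between this curve and TR1 the singular
#' orbit enters the funnel and the full system bursts.
#'
#' @param pars baseline parameters.
#' @param gBK_values slice positions (nS).
#' @param tol bisection tolerance in `gK` (nS).
#' @param probe number of probe points used to bracket the sign change.
#' @return Data frame `(gBK, gK)`; slices where delta has no sign change
#'   (or is undefined) are dropped with a warning.
#' @export
trace_delta_zero <- function(pars = lacto_pars(), gBK_values = 0.4,
                             tol = 1e-4, probe = 6) {
  rows <- lapply(gBK_values, function(gb) {
    pb <- sweep_pars(pars, "gBK", gb)
    val <- tryCatch({
      tr1 <- find_TR(pb, "gK", c(0.05, 3), "upper")$value
      sn1 <- find_SN(pb, "gK", c(tr1 + 0.05, 15), "upper")$value
      dsign <- function(g)
        sign(delta_of(pars = sweep_pars(pb, "gK", g))$delta)
      gg <- seq(tr1 + 0.15 * (sn1 - tr1), sn1 - 0.05 * (sn1 - tr1),
                length.out = probe)
      sg <- vapply(gg, function(g)
        tryCatch(dsign(g), error = function(e) NA_real_), 0)
      k <- which(!is.na(sg[-1]) & !is.na(sg[-length(sg)]) &
                   sg[-1] * sg[-length(sg)] < 0)
      if (!length(k)) stop("no delta sign change in the folded-node window")
      lo <- gg[k[1]]; hi <- gg[k[1] + 1]; slo <- sg[k[1]]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        sm <- tryCatch(dsign(mid), error = function(e) NA_real_)
        if (is.na(sm)) break
        if (sm == slo) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }, error = function(e) {
      warning("gBK = ", gb, ": ", conditionMessage(e)); NA_real_
    })
    data.frame(gBK = gb, gK = val)
  })
  out <- do.call(rbind, rows)
  out[is.finite(out$gK), ]
}

#' Two-parameter region map of the desingularized system
#'
#' Labels each grid point by its fold / folded-singularity inventory:
#' `"B"` folded node on L+ (the mixed-mode-oscillation substrate);
#' `"A"` depolarized stable equilibrium (upper sheet); `"C"` folded
#' node/focus on L- at positive Ca2+; `"D"` folded node on L- only at
#' negative Ca2+; `"E"` hyperpolarized stable equilibrium;
#' `"no_folds"` past the fold merge.
#'
#' @param pars baseline parameters.
#' @param gK_values,gBK_values grid coordinates (nS).
#' @return Data frame `(gK, gBK, region)`.
#' @export
build_region_map <- function(pars = lacto_pars(),
                             gK_values = seq(0.1, 150, length.out = 31),
                             gBK_values = seq(0, 35, length.out = 15)) {
  grid <- expand.grid(gK = gK_values, gBK = gBK_values)
  grid$region <- vapply(seq_len(nrow(grid)), function(i) {
    p <- sweep_pars(sweep_pars(pars, "gK", grid$gK[i]), "gBK", grid$gBK[i])
    region_label(p)
  }, "")
  grid
}

region_label <- function(p) {
  fv <- fold_voltages(p)
  if (length(fv) < 2) return("no_folds")
  fs <- find_folded_singularities(p)
  os <- find_ordinary_singularities(p)
  fn_up <- fs[fs$on_curve == "L+" & fs$class == "folded_node", ]
  if (nrow(fn_up)) return("B")
  stab <- os[os$class %in% c("stable_node", "stable_focus"), ]
  if (nrow(stab) && any(stab$V > fv[2])) return("A")
  low <- fs[fs$on_curve == "L-" & fs$class %in% c("folded_node",
                                                  "folded_focus"), ]
  if (nrow(low[low$c > 0 & low$class == "folded_node", ])) return("C")
  if (nrow(low[low$c < 0 & low$class == "folded_node", ])) return("D")
  if (nrow(low[low$c > 0, ])) return("C")
  "E"
}
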