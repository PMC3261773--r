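# Reduced and desingularized slow flow on the critical manifold.  With n
# eliminated via n(c, V), the reduced flow is singular on the folds; after
# rescaling time by -(df/dV)^(-1) the desingularized system
#   dV/dtau = F(V, c),   dc/dtau = f_c (alpha ICa + k_c c) df/dV
# is smooth there (the rescaling reverses time on the repelling middle
# sheet).  Its equilibria are the ordinary singularities (true equilibria
# of the full model) and the folded singularities on L+/-.

# P = dc/dt of the full model, negated: fc*(alpha ICa + kc c)
P_of <- function(V, c, pars)
  pars[["fc"]] * (pars[["alpha"]] * i_ca(V, pars) + pars[["kc"]] * c)

#' Desingularized voltage velocity F
#'
#' `F(V, c) = -f_c (alpha ICa + k_c c) df/dc + (n_inf(V) - n(c,V))/tau_n
#' df/dn`, with `n` eliminated through the critical manifold.  `F = 0`
#' defines the V-nullcline of the desingularized system; folded
#' singularities are its intersections with the fold curves, ordinary
#' singularities its intersections with the Ca2+ balance curve CN1.
#'
#' @param V,c coordinates on the critical manifold.
#' @param pars a [lacto_pars()] object.
#' @return Numeric value of F.
#' @export
F_of <- function(V, c, pars = lacto_pars()) {
  n <- n_of(c, V, pars)
  dvk <- V - pars[["VK"]]
  fc_ <- -pars[["gKCa"]] * dhill2(c, pars[["Kd"]]) * dvk
  fn_ <- -pars[["gK"]] * dvk
  -P_of(V, c, pars) * fc_ +
    (boltz(V, pars[["vn"]], pars[["sn"]]) - n) / pars[["taun"]] * fn_
}

#' Desingularized vector field
#'
#' @param V,c coordinates on the critical manifold.
#' @param pars a [lacto_pars()] object.
#' @return Numeric vector `(dV/dtau, dc/dtau)`.  On the attracting sheets
#'   (`df/dV < 0`) the desingularized time runs with true time; on the
#'   repelling middle sheet it is reversed.
#' @export
desing_rhs <- function(V, c, pars = lacto_pars()) {
  c(dV = F_of(V, c, pars),
    dc = P_of(V, c, pars) * fV_manifold(V, pars))
}

#' Analytic Jacobian of the desingularized system
#'
#' Exact 2x2 derivative matrix of [desing_rhs()] in `(V, c)`.  The
#' eigenvalue ratio of a folded node can be as small as a few percent, so
#' the classification of folded singularities uses these closed-form
#' partials rather than finite differences.
#'
#' @inheritParams desing_rhs
#' @return A 2x2 numeric matrix.
#' @export
desing_jacobian <- function(V, c, pars = lacto_pars()) {
  vK <- pars[["VK"]]; dvk <- V - vK
  gK <- pars[["gK"]]; gKCa <- pars[["gKCa"]]; gBK <- pars[["gBK"]]
  taun <- pars[["taun"]]; Kd <- pars[["Kd"]]

  sP  <- dhill2(c, Kd); sPP <- d2hill2(c, Kd)
  n    <- n_of(c, V, pars)
  ninf <- boltz(V, pars[["vn"]], pars[["sn"]])

  P   <- P_of(V, c, pars)
  P_V <- pars[["fc"]] * pars[["alpha"]] * di_ca(V, pars)
  P_c <- pars[["fc"]] * pars[["kc"]]

  G   <- -gKCa * sP * dvk          # df/dc on the manifold
  G_V <- -gKCa * sP
  G_c <- -gKCa * sPP * dvk

  H   <- -gK * dvk                 # df/dn
  H_V <- -gK

  # dn(c,V)/dV and /dc
  N_V <- -(di_ca(V, pars) * dvk - i_ca(V, pars)) / dvk^2 / gK -
    gBK * dboltz(V, pars[["vb"]], pars[["sb"]]) / gK
  N_c <- -(gKCa / gK) * sP

  ninfP <- dboltz(V, pars[["vn"]], pars[["sn"]])

  F_V <- -(P_V * G + P * G_V) +
    ((ninfP - N_V) * H + (ninf - n) * H_V) / taun
  F_c <- -(P_c * G + P * G_c) - N_c * H / taun

  fVm  <- fV_manifold(V, pars)
  fVmP <- -dphi_fold(V, pars) / dvk + phi_fold(V, pars) / dvk^2

  Q_V <- P_V * fVm + P * fVmP
  Q_c <- P_c * fVm

  matrix(c(F_V, F_c, Q_V, Q_c), nrow = 2, byrow = TRUE,
         dimnames = list(c("dV", "dc"), c("V", "c")))
}

# node/saddle/focus label from a 2x2 Jacobian
classify_2x2 <- function(J) {
  ev <- eigen(J, only.values = TRUE)$values
  if (is.complex(ev) && any(abs(Im(ev)) > 0)) {
    cls <- if (max(Re(ev)) < 0) "stable_focus" else "unstable_focus"
  } else {
    ev <- Re(ev)
    cls <- if (prod(ev) < 0) "saddle"
    else if (max(ev) < 0) "stable_node"
    else "unstable_node"
  }
  list(class = cls, eigenvalues = ev)
}

.sing_empty <- function() {
  data.frame(kind = character(0), on_curve = character(0),
             V = numeric(0), c = numeric(0), n = numeric(0),
             class = character(0),
             re_lambda1 = numeric(0), im_lambda1 = numeric(0),
             re_lambda2 = numeric(0), im_lambda2 = numeric(0),
             mu = numeric(0), s_max = integer(0), flags = character(0),
             stringsAsFactors = FALSE)
}

.sing_row <- function(kind, on_curve, V, c, n, cls, ev, mu = NA_real_,
                      s_max = NA_integer_, flags = "") {
  data.frame(kind = kind, on_curve = on_curve, V = V, c = c, n = n,
             class = cls,
             re_lambda1 = Re(ev[1]), im_lambda1 = Im(ev[1]),
             re_lambda2 = Re(ev[2]), im_lambda2 = Im(ev[2]),
             mu = mu, s_max = s_max, flags = flags,
             stringsAsFactors = FALSE)
}

#' Ordinary singularities of the desingularized system
#'
#' True equilibria of the full model: `f = 0`, `n = n_inf(V)`,
#' `c = -alpha ICa / k_c` (the curve CN1).  All voltage roots in
#' `[-75, 50]` mV are located by dense sign scan plus bisection and
#' classified by the eigenvalues of the desingularized Jacobian.
#' Equilibria at negative Ca2+ are flagged `"nonphysical"`.
#'
#' @param pars a [lacto_pars()] object.
#' @return A data frame of class `"lacto_sings"` (possibly empty) with one
#'   row per singularity.
#' @export
find_ordinary_singularities <- function(pars = lacto_pars()) {
  eqV <- ordinary_equilibrium_voltages(pars)
  rows <- lapply(eqV, function(V) {
    c_eq <- -pars[["alpha"]] * i_ca(V, pars) / pars[["kc"]]
    n_eq <- boltz(V, pars[["vn"]], pars[["sn"]])
    cl <- classify_2x2(desing_jacobian(V, c_eq, pars))
    .sing_row("ordinary", "CN1", V, c_eq, n_eq, cl$class, cl$eigenvalues,
              flags = if (c_eq < 0) "nonphysical" else "")
  })
  out <- if (length(rows)) do.call(rbind, rows) else .sing_empty()
  class(out) <- c("lacto_sings", "data.frame")
  out
}

# voltage roots of f(V, c_eq(V), n_inf(V)) = 0
ordinary_equilibrium_voltages <- function(pars) {
  g <- function(V) {
    c_eq <- -pars[["alpha"]] * i_ca(V, pars) / pars[["kc"]]
    f_of(V, c_eq, boltz(V, pars[["vn"]], pars[["sn"]]), pars)
  }
  Vg <- seq(-74.999, 49.999, length.out = 3001)
  gv <- g(Vg)
  i <- which(gv[-1] * gv[-length(gv)] < 0)
  vapply(i, function(k)
    uniroot(g, c(Vg[k], Vg[k + 1]), tol = 1e-12)$root, 0)
}

# c-roots of F along a fold line
fold_F_roots <- function(V_fold, pars, c_window = c(0, 1.4),
                         c_neg_window = c(-1, 0), n_scan = 4001) {
  cg <- seq(c_neg_window[1], c_window[2], length.out = n_scan)
  Fv <- F_of(V_fold, cg, pars)
  i <- which(Fv[-1] * Fv[-length(Fv)] < 0)
  vapply(i, function(k)
    uniroot(function(cc) F_of(V_fold, cc, pars),
            c(cg[k], cg[k + 1]), tol = 1e-13)$root, 0)
}

#' Folded singularities on the fold curves
#'
#' On each fold voltage level the roots of `F(V_fold, c) = 0` are folded
#' singularities (`f = 0`, `F = 0`, `df/dV = 0`).  Each is classified as a
#' folded node, folded saddle or folded focus from the eigenvalues of the
#' desingularized Jacobian; folded nodes and saddles carry the eigenvalue
#' ratio `mu` and (nodes only) the rotation bound `S_max`.
#'
#' The default search window is `c` in `[0, 1.4]` uM plus an extended
#' negative window `[-1, 0)` whose roots are flagged `"nonphysical"`
#' (folded singularities at negative Ca2+ organise part of the
#' two-parameter diagram even though no trajectory visits them).
#'
#' @param pars a [lacto_pars()] object.
#' @param c_window physical Ca2+ search window (uM).
#' @param c_neg_window extended negative window.
#' @return A data frame of class `"lacto_sings"`.
#' @export
find_folded_singularities <- function(pars = lacto_pars(),
                                      c_window = c(0, 1.4),
                                      c_neg_window = c(-1, 0)) {
  fv <- fold_voltages(pars)
  rows <- list()
  if (length(fv) == 2) {
    for (k in 1:2) {
      curve <- if (k == 1) "L-" else "L+"
      roots <- fold_F_roots(fv[k], pars, c_window, c_neg_window)
      for (cc in roots) {
        cl <- classify_2x2(desing_jacobian(fv[k], cc, pars))
        folded_cls <- switch(cl$class,
                             stable_node = "folded_node",
                             unstable_node = "folded_node",
                             saddle = "folded_saddle",
                             stable_focus = "folded_focus",
                             unstable_focus = "folded_focus")
        mu <- s_max <- NA
        if (folded_cls %in% c("folded_node", "folded_saddle")) {
          ev <- Re(cl$eigenvalues)
          mu <- ev[which.min(abs(ev))] / ev[which.max(abs(ev))]
          if (folded_cls == "folded_node") s_max <- s_max_of(mu)
        }
        rows[[length(rows) + 1]] <-
          .sing_row("folded", curve, fv[k], cc, n_of(cc, fv[k], pars),
                    folded_cls, cl$eigenvalues, mu,
                    if (is.na(s_max)) NA_integer_ else as.integer(s_max),
                    flags = if (cc < 0) "nonphysical" else "")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .sing_empty()
  class(out) <- c("lacto_sings", "data.frame")
  out
}

#' @export
print.lacto_sings <- function(x, ...) {
  cat("Singularities of the desingularized lactotroph flow:\n")
  print(as.data.frame(x)[, c("kind", "on_curve", "V", "c", "class",
                             "mu", "s_max", "flags")], ...)
  invisible(x)
}

#' Eigenvalue ratio of a folded node or saddle
#'
#' `mu = lambda_weak / lambda_strong` with `|lambda_weak| <
#' |lambda_strong|`.  `mu` lies in (0, 1] for a folded node and is
#' negative for a folded saddle; it is undefined (complex eigenvalues)
#' for a folded focus.
#'
#' @param sing one row of a `"lacto_sings"` data frame, or a numeric
#'   length-2 vector of real eigenvalues.
#' @return The eigenvalue ratio.
#' @export
mu_of <- function(sing) {
  ev <- if (is.numeric(sing)) sing
  else {
    if (any(abs(c(sing$im_lambda1, sing$im_lambda2)) > 0))
      stop("mu is undefined for complex eigenvalues (folded focus)")
    c(sing$re_lambda1, sing$re_lambda2)
  }
  ev[which.min(abs(ev))] / ev[which.max(abs(ev))]
}

#' Maximal number of small oscillations through a folded node
#'
#' `S_max = floor((mu + 1) / (2 mu))`; it diverges as `mu -> 0+` (the
#' folded saddle-node limits) and equals 1 at `mu = 1`.
#'
#' @param mu folded-node eigenvalue ratio in (0, 1].
#' @return Integer rotation bound.
#' @export
s_max_of <- function(mu) {
  if (any(mu <= 0)) stop("S_max requires mu > 0 (folded node)")
  floor((mu + 1) / (2 * mu))
}
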