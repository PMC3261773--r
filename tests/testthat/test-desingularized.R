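p0 <- lacto_pars()

# independent evaluation of F: n solved from f = 0 by bisection instead of
# the closed form, partial derivatives of f by central differences
F_independent <- function(V, c, pars) {
  n <- uniroot(function(nn) f_of_pkg(V, c, nn, pars), c(-5, 5),
               tol = 1e-14)$root
  h <- 1e-6
  dfdc <- (f_of_pkg(V, c + h, n, pars) - f_of_pkg(V, c - h, n, pars)) / (2 * h)
  dfdn <- (f_of_pkg(V, c, n + h, pars) - f_of_pkg(V, c, n - h, pars)) / (2 * h)
  ica <- currents(V, n, c, pars)[["ICa"]]
  P <- pars[["fc"]] * (pars[["alpha"]] * ica + pars[["kc"]] * c)
  ninf <- activation(V, "n", pars)
  -P * dfdc + (ninf - n) / pars[["taun"]] * dfdn
}
f_of_pkg <- function(V, c, n, pars) f_and_partials(V, c, n, pars)$f

test_that("F matches a term-by-term independent evaluation", {
  set.seed(3)
  for (k in 1:10) {
    V <- runif(1, -65, 30); cc <- runif(1, 0.05, 1.2)
    expect_equal(F_of(V, cc, p0), F_independent(V, cc, p0),
                 tolerance = 1e-6)
  }
})

test_that("desingularized flow vanishes where it must", {
  fv <- fold_voltages(p0)
  for (cc in c(0.1, 0.4, 1.0)) {
    expect_equal(desing_rhs(fv[1], cc, p0)[["dc"]], 0, tolerance = 1e-12)
    expect_equal(desing_rhs(fv[2], cc, p0)[["dc"]], 0, tolerance = 1e-12)
  }
  # on CN1 (the Ca2+ balance curve) dc/dtau also vanishes
  V <- -30
  c_eq <- -p0[["alpha"]] * currents(V, 0, 0, p0)[["ICa"]] / p0[["kc"]]
  expect_equal(desing_rhs(V, c_eq, p0)[["dc"]], 0, tolerance = 1e-14)
  # F = 0 at every reported singularity, ordinary and folded
  for (s in list(find_ordinary_singularities(p0),
                 find_folded_singularities(p0))) {
    for (i in seq_len(nrow(s)))
      expect_lt(abs(F_of(s$V[i], s$c[i], p0)), 1e-9)
  }
})

test_that("analytic desingularized Jacobian matches finite differences", {
  set.seed(5)
  for (k in 1:10) {
    V <- runif(1, -65, 30); cc <- runif(1, 0.05, 1.2)
    J <- desing_jacobian(V, cc, p0)
    J_fd <- fd_jacobian(function(x) desing_rhs(x[1], x[2], p0), c(V, cc),
                        h = 1e-5)
    expect_lt(rel_err(J, J_fd), 1e-5)
  }
})

test_that("ordinary singularities reproduce the depolarized/saddle/bottom sequence", {
  s1 <- find_ordinary_singularities(set_pars(p0, gK = 0.1))
  fv <- fold_voltages(p0)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$class, "stable_node")
  expect_gt(s1$V, fv[2])            # depolarized: upper sheet

  s2 <- find_ordinary_singularities(p0)  # gK = 4
  expect_true("saddle" %in% s2$class)

  s3 <- find_ordinary_singularities(set_pars(p0, gK = 150))
  expect_equal(nrow(s3), 1)
  expect_equal(s3$class, "stable_node")
  expect_lt(s3$V, fv[1])            # hyperpolarized: bottom sheet
})

test_that("folded singularity inventory follows the one-parameter sequence", {
  fs4 <- find_folded_singularities(p0)   # gK = 4
  up <- fs4[fs4$on_curve == "L+", ]
  expect_setequal(up$class, c("folded_node", "folded_saddle"))
  expect_true(all(fs4$class[fs4$on_curve == "L-"] == "folded_focus"))

  fs03 <- find_folded_singularities(set_pars(p0, gK = 0.3))
  expect_equal(sum(fs03$on_curve == "L+" &
                     fs03$class == "folded_saddle"), 2)
  expect_equal(sum(fs03$on_curve == "L-" &
                     fs03$class == "folded_focus"), 2)

  fs8 <- find_folded_singularities(set_pars(p0, gK = 8))  # past SN1
  expect_equal(sum(fs8$on_curve == "L+"), 0)
})

test_that("every folded singularity satisfies the defining residuals", {
  for (g in c(0.3, 4, 43, 130)) {
    fs <- find_folded_singularities(set_pars(p0, gK = g))
    for (i in seq_len(nrow(fs))) {
      fp <- f_and_partials(fs$V[i], fs$c[i], fs$n[i], set_pars(p0, gK = g))
      expect_lt(abs(fp$f), 1e-9)
      expect_lt(abs(fp$fV), 1e-9)
      expect_lt(abs(F_of(fs$V[i], fs$c[i], set_pars(p0, gK = g))), 1e-9)
    }
  }
})

test_that("folded-singularity roots agree with a dense sign-scan oracle", {
  fv <- fold_voltages(p0)
  fs <- find_folded_singularities(p0)
  for (k in 1:2) {
    curve <- c("L-", "L+")[k]
    cg <- seq(-1, 1.4, length.out = 48001)
    Fv <- F_of(fv[k], cg, p0)
    i <- which(Fv[-1] * Fv[-length(Fv)] < 0)
    oracle <- cg[i] - Fv[i] * (cg[2] - cg[1]) / (Fv[i + 1] - Fv[i])
    got <- sort(fs$c[fs$on_curve == curve])
    expect_equal(got, sort(oracle), tolerance = 1e-4)
  }
})

test_that("mu and S_max behave as the canard theory dictates", {
  expect_equal(s_max_of(1), 1)
  expect_equal(s_max_of(0.07), 7)        # floor(1.07 / 0.14)
  expect_error(s_max_of(0), "mu")
  expect_error(s_max_of(-0.2), "mu")
  mus <- seq(0.005, 1, length.out = 300)
  expect_true(all(diff(s_max_of(mus)) <= 0))   # non-increasing

  fs <- find_folded_singularities(p0)
  fn <- fs[fs$class == "folded_node" & fs$on_curve == "L+", ]
  expect_gt(fn$mu, 0); expect_lte(fn$mu, 1)
  sd_ <- fs[fs$class == "folded_saddle", ]
  expect_true(all(sd_$mu < 0))
  foc <- fs[fs$class == "folded_focus", ][1, ]
  expect_error(mu_of(foc), "complex")
  expect_equal(mu_of(fn), fn$mu)
})
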