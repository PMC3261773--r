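p0 <- lacto_pars()

test_that("bifurcation values are stable under halving the tolerance", {
  tr_a <- find_TR(p0, "gK", c(0.1, 1), tol = 1e-6)$value
  tr_b <- find_TR(p0, "gK", c(0.1, 1), tol = 5e-7)$value
  expect_lt(abs(tr_a - tr_b), 1e-6)
  sn_a <- find_SN(p0, "gK", c(4, 10), tol = 1e-6)$value
  sn_b <- find_SN(p0, "gK", c(4, 10), tol = 5e-7)$value
  expect_lt(abs(sn_a - sn_b), 1e-6)
})

test_that("the focus-node discriminant changes sign across the transition", {
  bf <- find_focus_node(p0, "gK", c(30, 50), fold = "lower", c_near = 0.27)
  fs_lo <- find_folded_singularities(set_pars(p0, gK = bf$value - 0.5))
  fs_hi <- find_folded_singularities(set_pars(p0, gK = bf$value + 0.5))
  expect_true("folded_focus" %in%
                fs_lo$class[fs_lo$on_curve == "L-" & fs_lo$c > 0])
  expect_true("folded_node" %in%
                fs_hi$class[fs_hi$on_curve == "L-" & fs_hi$c > 0])
})

test_that("fold merge removes the folds and does not depend on gK", {
  m <- find_fold_merge(p0)
  expect_length(fold_voltages(set_pars(p0, gBK = m$value + 1e-3)), 0)
  expect_length(fold_voltages(set_pars(p0, gBK = m$value - 1e-3)), 2)
  for (g in c(1, 50, 120))
    expect_equal(find_fold_merge(set_pars(p0, gK = g))$value, m$value,
                 tolerance = 1e-9)
})

test_that("the codimension-2 point splits the merged line", {
  m <- find_fold_merge(p0)
  c2 <- find_codim2_on_merge_line(p0, c(50, 120), m)
  V0 <- m$location[["V"]]
  pm <- set_pars(p0, gBK = m$value)
  below <- set_pars(pm, gK = c2$value - 1)
  above <- set_pars(pm, gK = c2$value + 1)
  n_roots <- function(p) {
    cg <- seq(-1, 1.4, length.out = 8001)
    Fv <- F_of(V0, cg, p)
    sum(Fv[-1] * Fv[-length(Fv)] < 0)
  }
  expect_gte(n_roots(below), 2)
  expect_equal(n_roots(above), 0)
})

test_that("region labels follow the two-parameter structure", {
  rl <- function(gK, gBK)
    lactoburst:::region_label(set_pars(p0, gK = gK, gBK = gBK))
  expect_equal(rl(4, 0.4), "B")      # folded node on L+: MMO substrate
  expect_equal(rl(0.1, 0.4), "A")    # depolarized steady state
  expect_equal(rl(150, 0.4), "E")    # hyperpolarized steady state
  expect_equal(rl(7.588, 33), "no_folds")
  rm <- build_region_map(p0, gK_values = c(0.1, 4, 150),
                         gBK_values = c(0.4, 33))
  expect_equal(nrow(rm), 6)
  expect_true(all(rm$region[rm$gBK == 33] == "no_folds"))
})

test_that("mu profile is consistent with S_max pointwise", {
  mp <- mu_profile(p0, gK_range = c(1, 7), n = 15)
  ok <- !is.na(mp$mu)
  expect_true(any(ok))
  expect_equal(mp$s_max[ok], s_max_of(mp$mu[ok]))
  # region-B membership equals the existence of a positive mu
  for (i in which(ok))
    expect_equal(lactoburst:::region_label(set_pars(p0, gK = mp$gK[i])), "B")
})
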