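p0 <- lacto_pars()

test_that("f and its partials are analytic and consistent", {
  # f vanishes identically when n is eliminated through the manifold
  cg <- seq(0.05, 1.3, length.out = 7)
  Vg <- seq(-70, 40, length.out = 7)
  for (cc in cg) for (V in Vg)
    expect_lt(abs(f_and_partials(V, cc, n_of(cc, V, p0), p0)$f), 1e-10)

  # df/dn is zero exactly at the K+ reversal potential
  expect_equal(f_and_partials(p0[["VK"]], 0.3, 0.2, p0)$fn, 0)

  st <- random_states(10, seed = 7)
  for (i in seq_len(nrow(st))) {
    x <- c(st$V[i], st$c[i], st$n[i])
    fp <- f_and_partials(x[1], x[2], x[3], p0)
    g_fd <- fd_jacobian(function(y)
      f_and_partials(y[1], y[2], y[3], p0)$f, x)
    expect_lt(rel_err(c(fp$fV, fp$fc, fp$fn), as.numeric(g_fd)), 1e-6)
  }
})

test_that("n(c, V) is monotone in c and degenerates correctly", {
  V <- -30
  cg <- seq(0.01, 1.4, length.out = 50)
  expect_true(all(diff(n_of(cg, V, p0)) < 0))     # V > VK
  # without the SK conductance the manifold does not depend on c
  pK <- set_pars(p0, gKCa = 0)
  expect_equal(n_of(0.1, V, pK), n_of(1.2, V, pK))
  expect_error(n_of(0.3, p0[["VK"]], p0), "singular")
})

test_that("fold voltages satisfy both defining equations and ignore gK and c", {
  fv <- fold_voltages(p0)
  expect_length(fv, 2)
  expect_lt(fv[1], fv[2])
  for (V in fv) for (cc in c(0.1, 0.5, 1.2)) {
    fp <- f_and_partials(V, cc, n_of(cc, V, p0), p0)
    expect_lt(abs(fp$f), 1e-9)
    expect_lt(abs(fp$fV), 1e-9)
  }
  for (g in c(0.3, 4, 40, 140))
    expect_equal(fold_voltages(set_pars(p0, gK = g)), fv, tolerance = 1e-10)
  # past the fold merge the manifold has no fold at all
  expect_length(fold_voltages(set_pars(p0, gBK = 32.2, gK = 7.588)), 0)
})

test_that("sheet stability signs match the fold geometry", {
  fv <- fold_voltages(p0)
  cc <- 0.4
  for (V in c(fv[2] + 1, fv[2] + 20, fv[1] - 1, fv[1] - 8)) {
    expect_lt(f_and_partials(V, cc, n_of(cc, V, p0), p0)$fV, 0)
  }
  for (V in c(mean(fv), fv[1] + 2, fv[2] - 2)) {
    expect_gt(f_and_partials(V, cc, n_of(cc, V, p0), p0)$fV, 0)
  }
})

test_that("vertical projection lands on the correct sheet", {
  fv <- fold_voltages(p0)
  # a point of L- projected to the upper sheet lies on P(L-): f = 0 there
  cc <- 0.3
  nm <- n_of(cc, fv[1], p0)
  Vp <- project_to_sheet(cc, nm, "upper", p0)
  expect_gt(Vp, fv[2])
  expect_lt(abs(f_of(Vp, cc, nm, p0)), 1e-9)

  # idempotence: a point already on the upper sheet projects to itself
  Vu <- Vp
  expect_equal(project_to_sheet(cc, n_of(cc, Vu, p0), "upper", p0), Vu,
               tolerance = 1e-8)

  # brute-force oracle: dense V grid sign scan with linear interpolation
  set.seed(11)
  for (k in 1:20) {
    cc <- runif(1, 0.1, 1.0)
    nn <- n_of(cc, runif(1, fv[1] - 5, fv[1]), p0)
    Vp <- tryCatch(project_to_sheet(cc, nn, "upper", p0),
                   error = function(e) NA)
    if (!is.finite(Vp)) next
    Vg <- seq(fv[2], 50, length.out = 40001)
    fg <- f_of(Vg, cc, nn, p0)
    i <- which(fg[-1] * fg[-length(fg)] < 0)
    expect_true(length(i) >= 1)
    Vor <- Vg[max(i)] - fg[max(i)] * (Vg[2] - Vg[1]) /
      (fg[max(i) + 1] - fg[max(i)])
    expect_equal(Vp, Vor, tolerance = 1e-3)
  }

  # projection failure is reported, not silently wrong
  expect_error(project_to_sheet(1.4, 0.9, "upper", p0), "sheet")
})
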