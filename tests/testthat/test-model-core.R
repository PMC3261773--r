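p0 <- lacto_pars()

test_that("activation curves hit their midpoints and stay inside (0,1)", {
  expect_equal(activation(p0[["vm"]], "m", p0), 0.5)
  expect_equal(activation(p0[["vn"]], "n", p0), 0.5)
  expect_equal(activation(p0[["vb"]], "b", p0), 0.5)
  expect_equal(activation(p0[["Kd"]], "s", p0), 0.5)
  expect_equal(activation(0, "s", p0), 0)
  for (w in c("m", "n", "b")) {
    v <- activation(c(-1e4, -80, 0, 80, 1e4), w, p0)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(is.finite(v)))
  }
})

test_that("currents vanish at reversal potentials and match hand evaluation", {
  expect_equal(currents(p0[["VCa"]], 0.3, 0.2, p0)[["ICa"]], 0)
  ik <- currents(p0[["VK"]], 0.3, 0.2, p0)
  expect_equal(unname(ik[c("IK", "IKCa", "IBK")]), c(0, 0, 0))

  # independent scalar evaluation of the current formulas
  V <- -40; n <- 0.1; c <- 0.2
  m_inf <- 1 / (1 + exp((-20 - V) / 12))
  b_inf <- 1 / (1 + exp((-20 - V) / 5.6))
  s_inf <- c^2 / (c^2 + 0.5^2)
  expect_equal(unname(currents(V, n, c, p0)),
               c(2 * m_inf * (V - 50),
                 4 * n * (V + 75),
                 1.7 * s_inf * (V + 75),
                 0.4 * b_inf * (V + 75)),
               tolerance = 1e-12)
})

test_that("the right-hand side vanishes exactly at equilibrium conditions", {
  os <- find_ordinary_singularities(p0)
  expect_gt(nrow(os), 0)
  for (i in seq_len(nrow(os))) {
    st <- c(os$V[i], os$n[i], os$c[i])
    expect_lt(max(abs(rhs_full(st, p0))), 1e-9)
  }
  # the c equation alone has its root at c = -alpha ICa / kc
  V <- -35; n <- 0.2
  ica <- currents(V, n, 0.1, p0)[["ICa"]]
  c_eq <- -p0[["alpha"]] * ica / p0[["kc"]]
  expect_equal(rhs_full(c(V, n, c_eq), p0)[["dc"]], 0, tolerance = 1e-14)
})

test_that("analytic full-system Jacobian matches finite differences", {
  st <- random_states(10)
  for (i in seq_len(nrow(st))) {
    x <- c(st$V[i], st$n[i], st$c[i])
    J_fd <- fd_jacobian(function(y) rhs_full(y, p0), x)
    expect_lt(rel_err(jacobian_full(x, p0), J_fd), 1e-6)
  }
  # the c row depends only on (V, c), never on n
  J <- jacobian_full(c(-40, 0.1, 0.2), p0)
  expect_identical(J["dc", "n"], 0)
  expect_true(is.finite(sum(diag(J))))
})

test_that("time constants: tau_c closed form and tau_V from a trace", {
  tc <- time_constants(p0)
  expect_equal(tc$tau_c, 625)
  expect_equal(tc$tau_n, 43)
  # tau_c has no gK or gBK in it
  expect_equal(time_constants(set_pars(p0, gK = 150, gBK = 20))$tau_c, 625)

  # a one-point trace engineered so that g_Total = 3 nS gives
  # tau_V = 5 pF / 3 nS
  V <- -40; c <- 0.3
  grest <- p0[["gBK"]] * activation(V, "b", p0) +
    p0[["gCa"]] * activation(V, "m", p0) +
    p0[["gKCa"]] * activation(c, "s", p0)
  n3 <- (3 - grest) / p0[["gK"]]
  tr <- data.frame(V = V, n = n3, c = c)
  expect_equal(time_constants(p0, tr)$tau_V_range,
               c(5 / 3, 5 / 3), tolerance = 1e-10)
  expect_equal(round(5 / 3, 1), 1.7)
})

test_that("parameter validation rejects unphysical values", {
  expect_error(lacto_pars(Cm = 0), "Cm")
  expect_error(lacto_pars(fc = 1.5), "fc")
  expect_error(lacto_pars(sm = -1), "sm")
  expect_error(lacto_pars(nonsense = 1), "unknown")
  expect_error(rhs_full(c(-60, 0.1, 0.1), set_pars(p0)), NA)
  # set_pars returns a modified copy, the original is untouched
  p1 <- set_pars(p0, gK = 10)
  expect_equal(p0[["gK"]], 4)
  expect_equal(p1[["gK"]], 10)
})
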