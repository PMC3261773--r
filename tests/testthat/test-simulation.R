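p0 <- lacto_pars()

test_that("steady parameters relax onto the depolarized equilibrium", {
  pA <- set_pars(p0, gK = 0.1, Cm = 10)
  tr <- simulate_lacto(pA, t_end = 30000, transient = 15000)
  ft <- extract_features(tr)
  expect_equal(ft$regime, "steady")
  end <- as.numeric(tail(tr, 1)[, c("V", "n", "c")])
  expect_lt(max(abs(rhs_full(end, pA))), 1e-8)
  s <- find_ordinary_singularities(pA)
  expect_equal(end[1], s$V[1], tolerance = 1e-4)
})

test_that("calcium stays nonnegative from nonnegative initial conditions", {
  tr <- simulate_lacto(set_pars(p0, Cm = 10),
                       y0 = c(V = -60, n = 0.1, c = 0),
                       t_end = 20000, transient = 0)
  expect_gte(min(tr$c), 0)
  # the c-equation pushes c upward at c = 0 whenever ICa is inward
  d <- rhs_full(c(-30, 0.1, 0), p0)
  expect_gt(d[["dc"]], 0)
})

test_that("spiking and bursting regimes at Cm = 10 pF match the delta sign", {
  ft_sp <- simulate_features(set_pars(p0, gK = 5.1, Cm = 10))
  expect_equal(ft_sp$regime, "spiking")
  expect_equal(ft_sp$spikes_per_burst, 1L)
  ft_bu <- simulate_features(set_pars(p0, gK = 4, Cm = 10))
  expect_equal(ft_bu$regime, "bursting")
  expect_gte(ft_bu$spikes_per_burst, 2L)
})

test_that("active-phase oscillation amplitude grows with Cm", {
  # interior spike prominence at the folded-node parameters, three Cm
  amp_of <- function(Cm) {
    tr <- simulate_lacto(set_pars(p0, Cm = Cm), t_end = 30000,
                         transient = 10000, dt = 0.25,
                         rtol = 1e-10, atol = 1e-12)
    # longest contiguous active-phase run = one burst
    r <- rle(tr$V > -40)
    ends <- cumsum(r$lengths)
    k <- which(r$values)[which.max(r$lengths[r$values])]
    seg <- (ends[k] - r$lengths[k] + 1):ends[k]
    Vs <- tr$V[seg]
    j <- lactoburst:::local_maxima(Vs)
    if (length(j) < 2) return(0)
    pr <- vapply(j, function(kk) lactoburst:::peak_prominence(Vs, kk), 0)
    # drop the envelope top (jump-up overshoot), keep interior rotations
    stats::median(sort(pr, decreasing = TRUE)[-1])
  }
  amps <- vapply(c(0.001, 0.1, 2), amp_of, 0)
  expect_lt(amps[1], amps[2])
  expect_lt(amps[2], amps[3])
  expect_lt(amps[1], 0.5)
})

test_that("the full-system attractor hugs the singular orbit for tiny Cm", {
  p <- set_pars(p0, gK = 5.1, Cm = 0.001)
  orb <- build_singular_orbit(set_pars(p0, gK = 5.1))
  tr <- simulate_lacto(p, t_end = 8000, transient = 7000, dt = 0.1,
                       rtol = 1e-10, atol = 1e-12)
  fv <- orb$fold_voltages
  seg <- orb$segments
  # compare in the (c, V) plane away from fold neighbourhoods
  away <- abs(tr$V - fv[1]) > 2 & abs(tr$V - fv[2]) > 2 &
    (tr$V > fv[2] + 2 | tr$V < fv[1] - 2)
  pts <- tr[away, ]
  # nearest orbit point, V in mV against 1 mV, c in uM against 0.01 uM
  for (i in seq(1, nrow(pts), by = 50)) {
    d <- sqrt(((pts$V[i] - seg$V) / 1)^2 + ((pts$c[i] - seg$c) / 0.01)^2)
    expect_lt(min(d), 1.5)
  }
})

test_that("feature map exposes bistability between bursting and spiking", {
  fm <- feature_map(set_pars(p0, Cm = 5), gK_values = 4.87,
                    gBK_values = 2, t_end = 120000, transient = 40000)
  expect_equal(fm$regime, "bursting")
  expect_true(fm$bistable)
})

test_that("full-system Hopf moves smoothly with Cm and has a complex pair", {
  hb <- vapply(c(0.01, 1, 5), function(cm)
    full_hopf_slice(set_pars(p0, Cm = cm), "gK", c(0.1, 3))$value, 0)
  expect_true(all(diff(hb) > 0))
  h <- full_hopf_slice(set_pars(p0, Cm = 5), "gK", c(0.1, 3))
  expect_gt(h$omega, 0)
})
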