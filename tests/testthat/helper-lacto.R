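# shared helpers: finite-difference derivatives and random states

fd_jacobian <- function(fun, x, h = 1e-6) {
  n <- length(fun(x))
  J <- matrix(0, n, length(x))
  for (j in seq_along(x)) {
    e <- rep(0, length(x)); e[j] <- h
    J[, j] <- (fun(x + e) - fun(x - e)) / (2 * h)
  }
  J
}

random_states <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(V = runif(n, -70, 40),
             n = runif(n, 0, 0.6),
             c = runif(n, 0.02, 1.2))
}

rel_err <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b), 1e-8)
  max(d / s)
}
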