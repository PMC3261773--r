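#' @useDynLib lactoburst
#' @importFrom stats uniroot optimize median setNames
#' @importFrom utils write.csv read.csv tail head
NULL

# Canonical parameter order; must match src/lactoburst.c.
.lacto_par_order <- c("Cm", "gCa", "VCa", "vm", "sm", "gK", "VK", "vn", "sn",
                      "taun", "gKCa", "Kd", "gBK", "vb", "sb", "fc", "alpha",
                      "kc")

.lacto_defaults <- c(
  Cm    = 5,       # pF, membrane capacitance
  gCa   = 2,       # nS, Ca2+ conductance
  VCa   = 50,      # mV, Ca2+ reversal
  vm    = -20,     # mV, m_inf midpoint
  sm    = 12,      # mV, m_inf slope
  gK    = 4,       # nS, delayed-rectifier K+ conductance
  VK    = -75,     # mV, K+ reversal
  vn    = -5,      # mV, n_inf midpoint
  sn    = 10,      # mV, n_inf slope
  taun  = 43,      # ms, n time constant
  gKCa  = 1.7,     # nS, SK (K(Ca)) conductance
  Kd    = 0.5,     # uM, Ca2+ level at s_inf half-max
  gBK   = 0.4,     # nS, BK conductance
  vb    = -20,     # mV, b_inf midpoint
  sb    = 5.6,     # mV, b_inf slope
  fc    = 0.01,    # fraction of free cytosolic Ca2+
  alpha = 0.0015,  # uM/fC, current-to-concentration conversion
  kc    = 0.16     # 1/ms, Ca2+ extrusion rate
)

#' Lactotroph model parameters
#'
#' Construct an immutable parameter set for the three-variable pituitary
#' lactotroph model.  Units are mV, ms, pF, nS, pA and uM throughout, so
#' that nS x mV = pA and pF / nS = ms and no hidden rescaling is needed.
#' Defaults are the standard published values for the lactotroph cell model
#' (`Cm` = 5 pF, `gCa` = 2 nS, `gK` = 4 nS, `gBK` = 0.4 nS, ...).
#'
#' Parameter sets are plain named numeric vectors of class `"lacto_pars"`;
#' scans always work on modified copies (see [set_pars()]), never in place.
#'
#' @param ... named overrides of the default values, e.g. `gK = 5.1`.
#' @return A named numeric vector of class `"lacto_pars"`.
#' @examples
#' p <- lacto_pars(gK = 4, gBK = 0.4)
#' p[["Cm"]]
#' @export
lacto_pars <- function(...) {
  ov <- list(...)
  p <- .lacto_defaults
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("all parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- vapply(ov, as.numeric, 0)
  }
  validate_pars(p)
  structure(p, class = "lacto_pars")
}

#' Modified copy of a parameter set
#'
#' @param pars a `"lacto_pars"` object.
#' @param ... named overrides.
#' @return A new `"lacto_pars"` object; `pars` is untouched.
#' @export
set_pars <- function(pars, ...) {
  ov <- list(...)
  if (!length(ov)) return(pars)
  do.call(lacto_pars, utils::modifyList(as.list(unclass(pars)), ov))
}

validate_pars <- function(p) {
  if (any(!is.finite(p))) stop("parameters must be finite")
  if (p[["Cm"]] <= 0) stop("Cm must be positive")
  for (g in c("gCa", "gK", "gKCa", "gBK"))
    if (p[[g]] < 0) stop(g, " must be nonnegative")
  for (s in c("sm", "sn", "sb"))
    if (p[[s]] <= 0) stop(s, " must be positive")
  if (p[["taun"]] <= 0) stop("taun must be positive")
  if (p[["Kd"]] <= 0) stop("Kd must be positive")
  if (p[["fc"]] <= 0 || p[["fc"]] > 1) stop("fc must be in (0, 1]")
  if (p[["kc"]] <= 0) stop("kc must be positive")
  invisible(p)
}

#' @export
print.lacto_pars <- function(x, ...) {
  cat("Lactotroph model parameters (mV, ms, pF, nS, uM):\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Read or write a parameter configuration file
#'
#' Flat key-value JSON with the canonical parameter names
#' (`Cm, gCa, ..., kc`).  Unknown keys are rejected; missing keys keep
#' their defaults.
#'
#' @param path file path.
#' @param pars a `"lacto_pars"` object (for writing).
#' @return `read_pars()` returns a `"lacto_pars"` object;
#'   `write_pars()` returns `path` invisibly.
#' @export
read_pars <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(lacto_pars, as.list(x))
}

#' @rdname read_pars
#' @export
write_pars <- function(pars, path) {
  jsonlite::write_json(as.list(unclass(pars)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# parameter vector in the order the compiled derivatives expect
par_vec <- function(pars) as.numeric(pars[.lacto_par_order])
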