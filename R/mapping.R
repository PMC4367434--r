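## Physical -> recombinational distance mapping.

# registry of mapping functions d (Morgans) -> c (recombination fraction)
.mapRegistry <- new.env(parent = emptyenv())

.registerBuiltins <- function() {
  assign("linear", function(d) {
    eps <- 1e-9
    if (any(d >= 0.5)) warning("linear mapping clamped at c = 0.5")
    pmin(d, 0.5 - eps)
  }, envir = .mapRegistry)
  assign("haldane", function(d) (1 - exp(-2 * d)) / 2, envir = .mapRegistry)
  assign("kosambi", function(d) tanh(2 * d) / 2, envir = .mapRegistry)
}

#' Register a mapping function
#'
#' Mapping functions convert additive map distance d (Morgans) into
#' recombination fraction c, accounting for multiple crossovers.  Built-ins
#' are \code{linear} (c = d, clamped below 0.5), \code{haldane}
#' (c = (1 - exp(-2d))/2) and \code{kosambi} (c = tanh(2d)/2).  Further
#' functions — e.g. the Sved or Sved-Feldman drift-based mappings — can be
#' plugged in here; a registered function must be monotone non-decreasing in
#' d with values in [0, 0.5).
#'
#' @param name function name used with \code{\link{mapDistance}}.
#' @param fun vectorised function of d (Morgans) returning c.
#' @export
registerMapFunction <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  probe <- fun(c(1e-6, 0.01, 0.1, 1, 10))
  if (any(probe < 0) || any(probe >= 0.5) || is.unsorted(probe))
    stop("mapping function must be monotone with values in [0, 0.5)")
  assign(name, fun, envir = .mapRegistry)
  invisible(name)
}

#' @rdname registerMapFunction
#' @return \code{mapFunctions} returns the registered function names.
#' @export
mapFunctions <- function() sort(ls(.mapRegistry))

#' Map physical distance to recombination fraction
#'
#' First infers map distance d = k * delta (Morgans), with k a per-bp
#' recombination rate (default 1e-8 Morgans/bp, i.e. 1 Mb = 1 cM), then
#' applies the chosen mapping function to obtain the recombination fraction
#' c in [0, 0.5).
#'
#' @param delta_bp physical distance(s) in bp, > 0.
#' @param method registered mapping function name (see
#'   \code{\link{registerMapFunction}}).
#' @param k recombination rate in Morgans per bp (default 1e-8).
#' @return recombination fraction(s) c.
#' @examples
#' mapDistance(1e6)                      # 0.01 (1 Mb at the default k)
#' mapDistance(5e6, method = "haldane")  # (1 - exp(-0.1))/2
#' @export
mapDistance <- function(delta_bp, method = "linear", k = 1e-8) {
  if (any(delta_bp <= 0)) stop("distances must be > 0")
  if (!is.numeric(k) || k <= 0) stop("k must be > 0")
  if (!exists(method, envir = .mapRegistry))
    stop("unknown mapping function '", method, "'; registered: ",
         paste(mapFunctions(), collapse = ", "))
  fun <- get(method, envir = .mapRegistry)
  # c lives in [0, 0.5): at extreme distances the closed forms round to
  # exactly 0.5 in double precision, so the open bound is enforced here
  pmin(fun(k * delta_bp), 0.5 - 1e-12)
}
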