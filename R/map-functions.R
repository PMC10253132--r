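#' Kosambi map function
#'
#' Convert a recombination fraction to a genetic distance under the Kosambi
#' map function, d = 25 * ln((1 + 2r) / (1 - 2r)) centiMorgan, which allows
#' for moderate positive crossover interference.
#'
#' @param r recombination fraction(s), in `[0, 0.5)`.
#' @return genetic distance(s) in cM.
#' @seealso [kosambi_inverse()], [haldane_cm()]
#' @export
#' @examples
#' kosambi_cm(0.25)          # 25 * log(3) = 27.465...
#' kosambi_inverse(kosambi_cm(0.1))
kosambi_cm <- function(r) {
  stopifnot(is.numeric(r))
  if (any(r < 0 | r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' @param d genetic distance(s) in cM, `d >= 0`.
#' @return recombination fraction(s), r = 0.5 * tanh(d / 50).
#' @export
kosambi_inverse <- function(d) {
  stopifnot(is.numeric(d))
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * tanh(d / 50)
}

#' Haldane map function and inverse
#'
#' The Haldane function assumes no crossover interference (crossovers form a
#' Poisson process along the chromosome); it is the map function implied by
#' the default meiosis simulator.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return `haldane_cm`: distance in cM; `haldane_inverse`: recombination
#'   fraction r = (1 - exp(-d/50)) / 2.
#' @export
haldane_cm <- function(r) {
  stopifnot(is.numeric(r))
  if (any(r < 0 | r >= 0.5)) stop("recombination fraction must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cm
#' @param d genetic distance(s) in cM, `d >= 0`.
#' @export
haldane_inverse <- function(d) {
  stopifnot(is.numeric(d))
  if (any(d < 0)) stop("map distance must be non-negative")
  (1 - exp(-d / 50)) / 2
}

# inter-site recombination fraction under the active crossover model
rf_from_cm <- function(d, model = c("haldane", "kosambi")) {
  model <- match.arg(model)
  switch(model, haldane = haldane_inverse(d), kosambi = kosambi_inverse(d))
}
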