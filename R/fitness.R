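#' Gaussian stabilizing-selection fitness
#'
#' Fitness of a trait value `phi` under stabilizing selection towards an
#' environmental optimum `E`:
#' \deqn{\omega = e^{-(\varphi - E)^2 / s}}
#' The same form gives microbial fitness in the environment, microbial
#' fitness within a host (with the composite within-host environment as the
#' optimum) and host fitness. Fitness is 1 exactly when `phi == E`, symmetric
#' in `phi - E`, strictly decreasing in the mismatch, and approaches 1 for
#' every trait value as `s` grows very large (neutrality).
#'
#' @param phi Trait value(s).
#' @param E Environmental optimum (scalar or vector conformable with `phi`).
#' @param s Selection parameter (> 0; smaller means stronger selection).
#' @return Fitness value(s) in `(0, 1]`.
#' @examples
#' gaussian_fitness(0, 1, s = 1) # exp(-1)
#' @export
gaussian_fitness <- function(phi, E, s) {
  if (any(s <= 0)) stop("selection parameter s must be > 0", call. = FALSE)
  exp(-((phi - E)^2) / s)
}

#' Composite within-host environment
#'
#' The environment experienced by microbes inside a host blends the host
#' genetic trait (internal conditions: gut pH, temperature, diet) with the
#' external condition: `E_tMh = I * phi_hg + (1 - I) * E_tM`. At `I = 0`
#' microbes see the external environment only; at `I = 1` only the host.
#'
#' @param phi_hg Host genetic trait value(s).
#' @param E_tM External environmental condition at the current microbial
#'   generation.
#' @param I Host weighting in `[0, 1]`.
#' @return The composite optimum for within-host microbial selection.
#' @export
internal_environment <- function(phi_hg, E_tM, I) {
  if (any(I < 0 | I > 1)) stop("I must lie in [0, 1]", call. = FALSE)
  I * phi_hg + (1 - I) * E_tM
}

#' Host phenotype
#'
#' `phi_h = G * phi_hg + (1 - G) * phi_hM`: a convex combination of the
#' host's heritable genetic trait and the mean trait value of its microbiome.
#' `G = 0` makes host fitness entirely microbiome-derived; `G = 1` removes
#' the microbiome's influence (the microbiome-independent baseline).
#'
#' @param phi_hg Host genetic trait value(s).
#' @param phi_hM Mean microbiome trait value(s).
#' @param G Genetic weighting in `[0, 1]`.
#' @return Host phenotype value(s).
#' @export
host_phenotype <- function(phi_hg, phi_hM, G) {
  if (any(G < 0 | G > 1)) stop("G must lie in [0, 1]", call. = FALSE)
  G * phi_hg + (1 - G) * phi_hM
}

#' Abundance-weighted mean microbiome trait
#'
#' The mean trait value of a host's microbiome, weighting each microbial
#' individual equally: `sum(n_m * phi_m) / sum(n_m)`.
#'
#' @param counts Non-negative integer abundance vector over taxa.
#' @param phi_m Per-taxon trait values (same length as `counts`).
#' @return The weighted mean trait value.
#' @export
mean_microbiome_trait <- function(counts, phi_m) {
  stopifnot(length(counts) == length(phi_m))
  total <- sum(counts)
  if (total <= 0) stop("community is empty", call. = FALSE)
  sum(counts * phi_m) / total
}
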