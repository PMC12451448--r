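# Stochastic community-assembly kernels. Communities are plain non-negative
# integer-valued numeric vectors over the N_M taxa with a fixed total; every
# kernel conserves that total exactly.

#' Fitness-weighted sampling probabilities
#'
#' The probability of a taxon being drawn from a source community is
#' proportional to the product of its fitness and its relative abundance in
#' that source. If every product underflows to zero (extreme trait-optimum
#' mismatch at small `s`), sampling falls back to relative abundance alone
#' with a warning, keeping the process defined without biasing among taxa.
#'
#' @param counts Source community abundance vector (total > 0).
#' @param fitness Per-taxon fitness vector (non-negative, same length).
#' @return Probability vector summing to 1.
#' @export
sampling_probabilities <- function(counts, fitness) {
  total <- sum(counts)
  if (total <= 0) stop("cannot sample from an empty community", call. = FALSE)
  if (any(fitness < 0)) stop("fitness must be non-negative", call. = FALSE)
  w <- fitness * (counts / total)
  sw <- sum(w)
  if (sw <= 0 || !is.finite(sw)) {
    warning("all fitness-by-abundance weights are zero; ",
            "falling back to relative abundance", call. = FALSE)
    return(counts / total)
  }
  w / sw
}

#' Split a community total across sources
#'
#' Converts stated source proportions (such as `P` and `1 - P`, or
#' `Z`, `Y`, `1 - Z - Y`) into integer per-source draw counts that sum to
#' `total` exactly, by largest-remainder rounding: each allocation is within
#' one individual of `total * proportion`, remainders are awarded to the
#' largest fractional parts, and ties go to the earlier source (the
#' host/parent source is listed first by convention).
#'
#' @param total Destination community size.
#' @param proportions Non-negative proportions summing to 1.
#' @return Integer-valued numeric vector summing to `total`.
#' @examples
#' allocate_counts(100, c(0.98, 0.02)) # 98, 2
#' @export
allocate_counts <- function(total, proportions) {
  if (any(proportions < 0)) stop("proportions must be non-negative", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  exact <- total * proportions
  # guard floors against representation error (e.g. 1e8 * 0.8 = 8e7 - 1e-8)
  alloc <- floor(exact + 1e-12 * max(total, 1))
  rem <- round(total - sum(alloc))
  frac <- exact - alloc
  if (rem > 0) {
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    alloc[take] <- alloc[take] + 1
  } else if (rem < 0) {
    give <- order(frac, seq_along(frac))
    give <- give[alloc[give] > 0][seq_len(-rem)]
    alloc[give] <- alloc[give] - 1
  }
  alloc
}

# Stochastic alternative to allocate_counts: multinomial split of the total.
allocate_counts_binomial <- function(total, proportions) {
  as.numeric(stats::rmultinom(1, total, proportions))
}

#' Multinomial community assembly from weighted sources
#'
#' Builds a new community by drawing, from each source, `allocation`
#' individuals multinomially with fitness-by-relative-abundance
#' probabilities, then summing the draws. The output total equals the sum of
#' allocations exactly, and a taxon absent from every source can never
#' appear.
#'
#' @param sources A list of sources, each a list with elements `counts`
#'   (community vector), `fitness` (per-taxon fitness in the destination
#'   context) and `allocation` (number of individuals to draw).
#' @return Community vector (integer-valued numeric).
#' @export
draw_from_sources <- function(sources) {
  n_taxa <- length(sources[[1]]$counts)
  out <- numeric(n_taxa)
  for (src in sources) {
    a <- src$allocation
    if (a <= 0) next
    if (sum(src$counts) <= 0) {
      stop("positive allocation from an empty source", call. = FALSE)
    }
    p <- sampling_probabilities(src$counts, src$fitness)
    out <- out + as.numeric(stats::rmultinom(1, a, p))
  }
  out
}

#' The three-way allocation of an environmental-pool renewal
#'
#' The environmental pool of size `n_ME` is renewed each microbial
#' generation from three sources: the previous pool (proportion `Z`), the
#' pooled host communities (`Y`, microbes shed from hosts), and a fixed,
#' invariant pool with all taxa equally probable (`1 - Z - Y`). This helper
#' returns the exact integer draw counts used for the three sources, in that
#' order.
#'
#' @param n_ME Environmental pool size.
#' @param Z Persistence proportion.
#' @param Y Host-shedding proportion.
#' @return Numeric vector of three allocations summing to `n_ME`.
#' @examples
#' renewal_allocations(1e8, Z = 0.8, Y = 0.05) # 8e7, 5e6, 1.5e7
#' @export
renewal_allocations <- function(n_ME, Z, Y) {
  if (Z < 0 || Y < 0 || Z + Y > 1) stop("need Z, Y >= 0 and Z + Y <= 1",
                                        call. = FALSE)
  allocate_counts(n_ME, c(Z, Y, 1 - Z - Y))
}

#' Renew the environmental microbial pool
#'
#' Assembles the next environmental pool from the previous pool, host
#' shedding and the fixed source (see [renewal_allocations()]). Every source
#' is weighted by microbial fitness in the environment,
#' `omega_m_env = gaussian_fitness(traits, E_tM, s)`; the fixed source has
#' all taxa at equal abundance, so its sampling probabilities are
#' proportional to fitness alone.
#'
#' @param env Previous environmental pool (community vector).
#' @param host_pool Pooled host communities (the element-wise sum over
#'   hosts), or a matrix of host communities (taxa in rows) to be pooled.
#' @param Z,Y Persistence and shedding proportions (`Z + Y <= 1`).
#' @param E_tM Environmental condition at this microbial generation.
#' @param traits Per-taxon microbial trait values.
#' @param s Selection parameter.
#' @param n_ME Pool size (defaults to the current pool total).
#' @param allocation `"deterministic"` largest-remainder split or
#'   `"binomial"` stochastic split.
#' @return The renewed pool (community vector of total `n_ME`).
#' @export
renew_environment <- function(env, host_pool, Z, Y, E_tM, traits, s,
                              n_ME = sum(env),
                              allocation = c("deterministic", "binomial")) {
  allocation <- match.arg(allocation)
  if (is.matrix(host_pool)) host_pool <- rowSums(host_pool)
  w <- gaussian_fitness(traits, E_tM, s)
  alloc <- if (allocation == "binomial") {
    allocate_counts_binomial(n_ME, c(Z, Y, 1 - Z - Y))
  } else {
    renewal_allocations(n_ME, Z, Y)
  }
  draw_from_sources(list(
    list(counts = env, fitness = w, allocation = alloc[1]),
    list(counts = host_pool, fitness = w, allocation = alloc[2]),
    list(counts = rep(1, length(traits)), fitness = w, allocation = alloc[3])
  ))
}

#' Within-host microbial generation
#'
#' One microbial generation inside a host: the new community of size `n_MH`
#' is drawn at proportion `P` from the host's own previous community and
#' `1 - P` from the environmental pool. Under the default destination-context
#' weighting both sources use within-host fitness
#' `omega_m_host = gaussian_fitness(traits, E_tMh, s)` — the host filters
#' environmental colonizers; passing `env_fitness` weights the environmental
#' source by its own context instead.
#'
#' @param host Host community vector.
#' @param env Environmental pool vector.
#' @param P Retention proportion in `[0, 1]`.
#' @param E_tMh Composite within-host environment (see
#'   [internal_environment()]).
#' @param traits Per-taxon trait values.
#' @param s Selection parameter.
#' @param env_fitness Optional fitness vector for the environmental source
#'   (source-context weighting); defaults to the within-host fitness.
#' @param allocation Deterministic or binomial source split.
#' @return New host community vector (total preserved).
#' @export
within_host_update <- function(host, env, P, E_tMh, traits, s,
                               env_fitness = NULL,
                               allocation = c("deterministic", "binomial")) {
  if (P < 0 || P > 1) stop("P must lie in [0, 1]", call. = FALSE)
  allocation <- match.arg(allocation)
  n_MH <- sum(host)
  w_host <- gaussian_fitness(traits, E_tMh, s)
  if (is.null(env_fitness)) env_fitness <- w_host
  alloc <- if (allocation == "binomial") {
    allocate_counts_binomial(n_MH, c(P, 1 - P))
  } else {
    allocate_counts(n_MH, c(P, 1 - P))
  }
  draw_from_sources(list(
    list(counts = host, fitness = w_host, allocation = alloc[1]),
    list(counts = env, fitness = env_fitness, allocation = alloc[2])
  ))
}

#' Assemble an offspring's microbiome at birth
#'
#' Identical mechanics to [within_host_update()] with the vertical
#' inheritance proportion `X` in place of `P` and the parent community as the
#' host source: a proportion `X` of the offspring's microbiome is sampled
#' from its parent and `1 - X` from the environment.
#'
#' @param parent Parent community vector.
#' @param env Environmental pool vector.
#' @param X Vertical inheritance proportion in `[0, 1]`.
#' @inheritParams within_host_update
#' @return Offspring community vector.
#' @export
assemble_offspring <- function(parent, env, X, E_tMh, traits, s,
                               env_fitness = NULL,
                               allocation = c("deterministic", "binomial")) {
  within_host_update(parent, env, X, E_tMh, traits, s,
                     env_fitness = env_fitness, allocation = allocation)
}

#' Fitness-free initial colonization
#'
#' The founding draw: `n` individuals multinomially over `N_M` taxa with
#' equal probabilities. Used for the initial environmental pool and the first
#' host generation; every later sampling event is fitness-weighted.
#'
#' @param n Community size.
#' @param N_M Number of taxa.
#' @return Community vector of total `n`.
#' @export
initial_colonization <- function(n, N_M) {
  stopifnot(n >= 1, N_M >= 1)
  as.numeric(stats::rmultinom(1, n, rep(1 / N_M, N_M)))
}

#' Fitness-proportional parent selection
#'
#' Wright-Fisher reproduction: each of the `N_H` offspring slots draws a
#' parent with replacement, with probability proportional to host fitness.
#' If every fitness underflows to zero, parents are drawn uniformly.
#'
#' @param host_fitnesses Non-negative fitness vector over hosts.
#' @return Integer vector of parent indices, one per offspring slot.
#' @export
select_parents <- function(host_fitnesses) {
  if (any(host_fitnesses < 0)) stop("fitness must be non-negative", call. = FALSE)
  N_H <- length(host_fitnesses)
  tot <- sum(host_fitnesses)
  if (tot <= 0 || !is.finite(tot)) {
    return(sample.int(N_H, N_H, replace = TRUE))
  }
  sample.int(N_H, N_H, replace = TRUE, prob = host_fitnesses)
}
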