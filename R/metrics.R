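#' Scaled Shannon-Wiener alpha diversity
#'
#' Shannon entropy of the taxon relative abundances, `H = -sum(p * log(p))`
#' over taxa present, normalized by its maximum over the global taxon pool,
#' `log(N_M)`. A perfectly even community over all `N_M` taxa scores 1; a
#' monoculture scores 0; losing taxa from the pool lowers the index even if
#' the survivors are even, so diversity decline under closed transmission is
#' visible.
#'
#' @param counts Community abundance vector (total > 0).
#' @param N_M Size of the global taxon pool used for scaling (>= 2);
#'   defaults to `length(counts)`.
#' @return A value in `[0, 1]`.
#' @export
scaled_shannon <- function(counts, N_M = length(counts)) {
  total <- sum(counts)
  if (total <= 0) stop("community is empty", call. = FALSE)
  if (N_M < 2) stop("N_M must be >= 2 for a non-degenerate scaling", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p)) / log(N_M)
}

#' Mean within-host microbial fitness
#'
#' Per host, the abundance-weighted mean of within-host microbial fitness
#' `omega_m_host = gaussian_fitness(traits, E_tMh, s)`; averaged over hosts.
#'
#' @param hosts A community vector, or a matrix of host communities with
#'   taxa in rows and hosts in columns.
#' @param traits Per-taxon trait values.
#' @param E_tMh Composite within-host environment, a scalar or one value per
#'   host.
#' @param s Selection parameter.
#' @return Mean fitness in `(0, 1]`.
#' @export
mean_microbial_fitness <- function(hosts, traits, E_tMh, s) {
  if (!is.matrix(hosts)) hosts <- matrix(hosts, ncol = 1)
  E_tMh <- rep_len(E_tMh, ncol(hosts))
  per_host <- vapply(seq_len(ncol(hosts)), function(h) {
    w <- gaussian_fitness(traits, E_tMh[h], s)
    sum(hosts[, h] * w) / sum(hosts[, h])
  }, numeric(1))
  mean(per_host)
}

#' Expected effective vertical inheritance
#'
#' Effective vertical inheritance is the fraction of parentally acquired
#' microbes still present in a host's microbiome when it reproduces. Under
#' neutral sampling the birth draw contributes `X` and each of the
#' `T_M - 1` within-host generations retains proportion `P` in expectation,
#' giving `X * P^(T_M - 1)`. With `P = 0.98` and 101 microbial generations,
#' even complete transmission at birth (`X = 1`) leaves only
#' `0.98^100 = 0.133` of the parental microbiome.
#'
#' @param X Vertical inheritance proportion at birth.
#' @param P Within-host retention proportion.
#' @param T_M Microbial generations per host generation (>= 1).
#' @return Expected parental-origin fraction at reproduction.
#' @export
expected_effective_vertical_inheritance <- function(X, P, T_M) {
  stopifnot(all(X >= 0 & X <= 1), all(P >= 0 & P <= 1), all(T_M >= 1))
  X * P^(T_M - 1)
}

#' Simulate realized vertical inheritance
#'
#' Tracks parental-origin tags through a host generation: the birth draw
#' tags the `X` proportion sampled from the parent, and the `T_M - 1`
#' within-host updates propagate tags by treating the tagged and untagged
#' copies of each taxon as separate sampling categories (the environmental
#' source is always untagged, so tags can only be diluted). Returns the
#' per-host tagged fraction at the moment of reproduction. The default is
#' neutral (`s` very large); under selection the realized fraction may
#' deviate from the closed form [expected_effective_vertical_inheritance()].
#'
#' @param X Vertical inheritance proportion at birth.
#' @param P Within-host retention proportion.
#' @param T_M Microbial generations per host generation.
#' @param n_hosts Number of independent host lineages to simulate.
#' @param n_MH Microbes per host.
#' @param N_M Number of taxa.
#' @param traits Per-taxon trait values (defaults to all zero).
#' @param E_tMh Within-host environmental optimum (scalar; default 0).
#' @param s Selection parameter; the default `1e12` is effectively neutral.
#' @param env Environmental pool composition (defaults to even).
#' @return Numeric vector of `n_hosts` tagged fractions in `[0, 1]`.
#' @export
realized_vertical_inheritance <- function(X, P, T_M, n_hosts = 50,
                                          n_MH = 1e4, N_M = 50,
                                          traits = rep(0, N_M), E_tMh = 0,
                                          s = 1e12, env = rep(1, N_M)) {
  stopifnot(X >= 0, X <= 1, P >= 0, P <= 1, T_M >= 1)
  w <- gaussian_fitness(traits, E_tMh, s)
  w2 <- c(w, w)                       # tagged block then untagged block
  env2 <- c(numeric(N_M), env)        # environment contributes untagged only
  parent <- initial_colonization(n_MH, N_M)
  vapply(seq_len(n_hosts), function(h) {
    alloc <- allocate_counts(n_MH, c(X, 1 - X))
    comm <- numeric(2 * N_M)
    if (alloc[1] > 0) {
      comm[seq_len(N_M)] <- draw_from_sources(list(
        list(counts = parent, fitness = w, allocation = alloc[1])
      ))
    }
    if (alloc[2] > 0) {
      comm[N_M + seq_len(N_M)] <- draw_from_sources(list(
        list(counts = env, fitness = w, allocation = alloc[2])
      ))
    }
    if (T_M > 1) {
      for (k in seq_len(T_M - 1)) {
        a <- allocate_counts(n_MH, c(P, 1 - P))
        comm <- draw_from_sources(list(
          list(counts = comm, fitness = w2, allocation = a[1]),
          list(counts = env2, fitness = w2, allocation = a[2])
        ))
      }
    }
    sum(comm[seq_len(N_M)]) / n_MH
  }, numeric(1))
}

#' Neutral coalescence of host ancestry
#'
#' Runs fitness-free Wright-Fisher reproduction with [select_parents()] under
#' uniform fitness, tracking each host's founder, and records the generation
#' at which the whole population first descends from a single founder. For a
#' haploid population of size `N_H` coalescent theory puts the mean near
#' `2 * N_H` generations — the rationale for a burn-in of 200 generations
#' when `N_H = 100`.
#'
#' @param N_H Host population size.
#' @param replicates Number of independent replicates.
#' @param max_generations Safety cap per replicate.
#' @return Integer vector of coalescence times (generations), one per
#'   replicate.
#' @export
simulate_coalescence <- function(N_H = 100, replicates = 1000,
                                 max_generations = 100L * N_H) {
  uniform <- rep(1, N_H)
  vapply(seq_len(replicates), function(r) {
    founder <- seq_len(N_H)
    g <- 0L
    while (g < max_generations) {
      g <- g + 1L
      founder <- founder[select_parents(uniform)]
      if (all(founder == founder[1L])) return(g)
    }
    g
  }, integer(1))
}

#' Write or read a tidy metrics table
#'
#' One row per (replicate, host generation), with the fixed column set
#' `replicate`, `scenario`, `X`, `T_M`, `host_generation`, `is_burn_in`,
#' `E_value`, `mean_host_fitness`, `mean_microbe_fitness`, `mean_alpha`
#' (plus any extra recorded columns). Values round-trip at full precision.
#'
#' @param records A metrics tibble (from [run_replicate()] or
#'   [run_simulation()]).
#' @param path Output path; comma- or tab-delimited by extension
#'   (`.tsv` gives tab).
#' @return `write_metrics()` returns `path` invisibly; `read_metrics()`
#'   returns the tibble.
#' @export
write_metrics <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (grepl("\\.tsv$", path)) readr::write_tsv(records, path)
  else readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (grepl("\\.tsv$", path)) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}
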