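#' Build a simulation configuration
#'
#' Assembles and validates the full parameter set of the holobiont simulator.
#' Defaults correspond to the main simulated conditions: a constant population
#' of `N_H = 100` haploid hosts, `N_M = 200` microbial taxa, communities of
#' `n_MH = 1e6` microbes per host and `n_ME = 1e8` in the environmental pool,
#' run for `T_H = 1500` host generations with a 200-generation burn-in.
#'
#' @param N_H Number of hosts (constant population size).
#' @param N_M Number of microbial taxa in the global pool.
#' @param n_MH Microbes per host community (fixed total).
#' @param n_ME Microbes in the environmental pool (fixed total).
#' @param T_H Number of host generations.
#' @param T_M Microbial generations per host generation (integer, >= 1).
#' @param burn_in Host generations of burn-in during which the environment is
#'   held at its stationary baseline (mean 0, SD `sigma0`).
#' @param X Vertical inheritance: proportion of an offspring's microbiome
#'   sampled from its parent at birth, in `[0, 1]`.
#' @param P Within-host retention: proportion of a host's microbiome resampled
#'   from its own previous microbial generation, in `[0, 1]`.
#' @param Z Environmental-pool persistence: proportion of the pool resampled
#'   from its previous state each microbial generation.
#' @param Y Host shedding: proportion of the pool sampled from the pooled host
#'   communities. The remainder `1 - Z - Y` comes from a fixed, even pool.
#' @param G Weighting of the host genetic trait in the host phenotype
#'   (`G = 0`: phenotype is the mean microbiome trait; `G = 1`: microbiome
#'   has no effect).
#' @param I Weighting of the host genetic trait in the within-host
#'   environment experienced by microbes.
#' @param s Selection parameter of the Gaussian fitness function (> 0; small
#'   values mean strong selection, very large values approach neutrality).
#' @param trait_min,trait_max Range of the uniform distribution microbial
#'   trait values are drawn from (also the clipping range for environments).
#' @param phi_hg Heritable host genetic trait value (scalar, applied to every
#'   founding host).
#' @param scenario Environmental scenario, one of `"1A"`, `"1B"`, `"2A"`,
#'   `"2B"`, `"3A"`, `"3B"`. Scenario 1 fluctuates about a constant mean,
#'   scenario 2 has a linearly increasing mean, scenario 3 a linearly
#'   increasing SD; type A is autocorrelated, type B independent draws.
#' @param rho Lag-1 autocorrelation of type-A environments, in `[0, 1)`.
#' @param sigma0 Baseline environmental SD.
#' @param mu_max Final environmental mean reached by scenario 2 at `T_H`.
#' @param sigma_max Final environmental SD reached by scenario 3 at `T_H`.
#' @param clip_env Clip environmental values to `[trait_min, trait_max]`?
#' @param fitness_context `"destination"` (default) weights every source of a
#'   sampling event by microbial fitness in the destination context (host
#'   filtering of environmental colonizers); `"source"` weights each source by
#'   fitness in that source's own context.
#' @param host_fitness_env `"final"` (default) evaluates host fitness at the
#'   last microbial-resolution environmental value of the generation;
#'   `"start"` uses the first.
#' @param allocation `"deterministic"` (default) splits each sampling event
#'   across sources by largest-remainder rounding of the stated proportions;
#'   `"binomial"` draws the split stochastically.
#' @param replicates Number of replicate simulations.
#' @param seed Master seed; per-run seeds are derived from it stably.
#'
#' @return A `holosim_config` object (a validated named list).
#' @examples
#' cfg <- holosim_config(N_H = 20, N_M = 10, n_MH = 100, n_ME = 1000,
#'                       T_H = 10, burn_in = 2)
#' cfg$X
#' @export
holosim_config <- function(N_H = 100, N_M = 200, n_MH = 1e6, n_ME = 1e8,
                           T_H = 1500, T_M = 1, burn_in = 200,
                           X = 0.5, P = 0.98, Z = 0.8, Y = 0.05,
                           G = 0, I = 0.5, s = 1,
                           trait_min = -2.5, trait_max = 2.5, phi_hg = 0,
                           scenario = "1A", rho = 0.9, sigma0 = 0.5,
                           mu_max = 2, sigma_max = 1.5, clip_env = TRUE,
                           fitness_context = c("destination", "source"),
                           host_fitness_env = c("final", "start"),
                           allocation = c("deterministic", "binomial"),
                           replicates = 1, seed = 1L) {
  cfg <- list(
    N_H = N_H, N_M = N_M, n_MH = n_MH, n_ME = n_ME,
    T_H = T_H, T_M = T_M, burn_in = burn_in,
    X = X, P = P, Z = Z, Y = Y, G = G, I = I, s = s,
    trait_min = trait_min, trait_max = trait_max, phi_hg = phi_hg,
    scenario = as.character(scenario),
    rho = rho, sigma0 = sigma0, mu_max = mu_max, sigma_max = sigma_max,
    clip_env = clip_env,
    fitness_context = match.arg(fitness_context),
    host_fitness_env = match.arg(host_fitness_env),
    allocation = match.arg(allocation),
    replicates = replicates, seed = as.integer(seed)
  )
  validate_config(cfg)
}

#' @keywords internal
validate_config <- function(cfg) {
  chk <- function(ok, name, msg) {
    if (!isTRUE(ok)) stop("invalid `", name, "`: ", msg, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  prop <- function(x) num1(x) && x >= 0 && x <= 1

  chk(num1(cfg$N_H) && cfg$N_H >= 2, "N_H", "need at least 2 hosts")
  chk(num1(cfg$N_M) && cfg$N_M >= 1, "N_M", "need at least 1 microbial taxon")
  chk(num1(cfg$n_MH) && cfg$n_MH >= 1, "n_MH", "host community size must be >= 1")
  chk(num1(cfg$n_ME) && cfg$n_ME >= 1, "n_ME", "environmental pool size must be >= 1")
  chk(num1(cfg$T_H) && cfg$T_H >= 1, "T_H", "must run at least one host generation")
  chk(num1(cfg$T_M) && cfg$T_M >= 1, "T_M",
      "microbial generations per host generation must be >= 1")
  chk(num1(cfg$burn_in) && cfg$burn_in >= 0 && cfg$burn_in < cfg$T_H,
      "burn_in", "must satisfy 0 <= burn_in < T_H")
  for (p in c("X", "P", "Z", "Y", "G", "I")) {
    chk(prop(cfg[[p]]), p, "must be a proportion in [0, 1]")
  }
  chk(cfg$Z + cfg$Y <= 1, "Z", "Z + Y must not exceed 1")
  chk(num1(cfg$s) && cfg$s > 0, "s", "selection parameter must be > 0")
  chk(num1(cfg$trait_min) && num1(cfg$trait_max) && cfg$trait_min < cfg$trait_max,
      "trait_min", "trait_min must be strictly less than trait_max")
  chk(num1(cfg$phi_hg), "phi_hg", "must be a finite scalar")
  chk(is.character(cfg$scenario) && length(cfg$scenario) == 1L &&
        cfg$scenario %in% scenario_kinds(), "scenario",
      paste("must be one of", paste(scenario_kinds(), collapse = ", ")))
  chk(num1(cfg$rho) && cfg$rho >= 0 && cfg$rho < 1, "rho", "must be in [0, 1)")
  chk(num1(cfg$sigma0) && cfg$sigma0 >= 0, "sigma0", "SD must be >= 0")
  chk(num1(cfg$sigma_max) && cfg$sigma_max >= 0, "sigma_max", "SD must be >= 0")
  chk(num1(cfg$mu_max), "mu_max", "must be a finite scalar")
  chk(is.logical(cfg$clip_env) && length(cfg$clip_env) == 1L, "clip_env",
      "must be TRUE or FALSE")
  chk(num1(cfg$replicates) && cfg$replicates >= 1, "replicates", "must be >= 1")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed", "must be an integer")
  for (n in c("N_H", "N_M", "n_MH", "n_ME", "T_H", "T_M", "burn_in", "replicates")) {
    chk(cfg[[n]] == round(cfg[[n]]), n, "must be a whole number")
  }
  structure(cfg, class = "holosim_config")
}

scenario_kinds <- function() c("1A", "1B", "2A", "2B", "3A", "3B")

#' @export
print.holosim_config <- function(x, ...) {
  cat("<holosim_config>\n")
  cat(sprintf("  hosts N_H = %g, taxa N_M = %g, n_MH = %g, n_ME = %g\n",
              x$N_H, x$N_M, x$n_MH, x$n_ME))
  cat(sprintf("  T_H = %g (burn-in %g), T_M = %g, scenario %s\n",
              x$T_H, x$burn_in, x$T_M, x$scenario))
  cat(sprintf("  X = %g, P = %g, Z = %g, Y = %g, G = %g, I = %g, s = %g\n",
              x$X, x$P, x$Z, x$Y, x$G, x$I, x$s))
  cat(sprintf("  replicates = %g, seed = %d\n", x$replicates, x$seed))
  invisible(x)
}

#' Read a configuration file
#'
#' Reads a flat key-value YAML document and returns a validated configuration.
#' Keys absent from the file take the documented defaults of
#' [holosim_config()]; an empty file yields the default configuration.
#' Unknown keys are an error, so typos do not pass silently.
#'
#' @param path Path to a YAML file of `key: value` pairs.
#' @return A `holosim_config` object.
#' @seealso [write_config()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must be a mapping of key: value pairs",
                           call. = FALSE)
  # YAML 1.1 reads the bare key `Y` as a boolean; map it back to the
  # host-shedding parameter
  names(vals)[names(vals) %in% c("TRUE", "yes")] <- "Y"
  known <- names(formals(holosim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(holosim_config, vals)
}

#' Write a configuration file
#'
#' Writes a configuration as flat YAML so that [read_config()] reproduces
#' every field exactly.
#'
#' @param config A `holosim_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "holosim_config"))
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}
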