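#' Initialize the simulation state
#'
#' Draws the per-taxon microbial trait values (uniform on
#' `[trait_min, trait_max]`), an environmental pool of `n_ME` microbes at
#' approximately equal abundances (multinomial with equal probabilities),
#' and a founding microbiome for each host acquired fitness-free from that
#' pool. All subsequent sampling events are fitness-weighted.
#'
#' @param config A `holosim_config`.
#' @param seed Optional seed set before drawing (default: leave the RNG
#'   stream as-is).
#' @return A list with elements `traits` (length `N_M`), `env` (community
#'   vector of total `n_ME`), `hosts` (`N_M` x `N_H` matrix of community
#'   columns) and `phi_hg` (length `N_H`).
#' @export
initialize_state <- function(config, seed = NULL) {
  stopifnot(inherits(config, "holosim_config"))
  if (!is.null(seed)) set.seed(seed)
  traits <- stats::runif(config$N_M, config$trait_min, config$trait_max)
  env <- initial_colonization(config$n_ME, config$N_M)
  hosts <- vapply(seq_len(config$N_H),
                  function(h) initial_colonization(config$n_MH, config$N_M),
                  numeric(config$N_M))
  hosts <- matrix(hosts, nrow = config$N_M)
  list(traits = traits, env = env, hosts = hosts,
       phi_hg = rep(config$phi_hg, config$N_H))
}

# One sampling pass over all hosts: each destination community of size n_MH
# is drawn at proportion `prop` from its own source column and `1 - prop`
# from the environmental pool. Vectorizes the environment-source draws across
# hosts when every host shares the same within-host environment.
update_hosts_batch <- function(source_mat, env, prop, E_h, traits, s,
                               env_fitness_context_E = NULL,
                               allocation = "deterministic") {
  N_M <- nrow(source_mat)
  N_H <- ncol(source_mat)
  n_MH <- sum(source_mat[, 1])
  E_h <- rep_len(E_h, N_H)
  shared <- length(unique(E_h)) == 1L

  det_alloc <- allocate_counts(n_MH, c(prop, 1 - prop))
  out <- matrix(0, N_M, N_H)

  if (shared) {
    w <- gaussian_fitness(traits, E_h[1], s)
    env_fit <- if (is.null(env_fitness_context_E)) w
               else gaussian_fitness(traits, env_fitness_context_E, s)
    if (allocation == "deterministic") {
      if (det_alloc[2] > 0) {
        p_env <- sampling_probabilities(env, env_fit)
        out <- out + stats::rmultinom(N_H, det_alloc[2], p_env)
      }
      if (det_alloc[1] > 0) {
        for (h in seq_len(N_H)) {
          p <- sampling_probabilities(source_mat[, h], w)
          out[, h] <- out[, h] + stats::rmultinom(1, det_alloc[1], p)
        }
      }
      return(out)
    }
  }
  for (h in seq_len(N_H)) {
    w <- gaussian_fitness(traits, E_h[h], s)
    env_fit <- if (is.null(env_fitness_context_E)) w
               else gaussian_fitness(traits, env_fitness_context_E, s)
    alloc <- if (allocation == "binomial") {
      allocate_counts_binomial(n_MH, c(prop, 1 - prop))
    } else det_alloc
    out[, h] <- draw_from_sources(list(
      list(counts = source_mat[, h], fitness = w, allocation = alloc[1]),
      list(counts = env, fitness = env_fit, allocation = alloc[2])
    ))
  }
  out
}

#' Run one host generation
#'
#' Executes the per-generation cycle on a state: at each of the `T_M`
#' microbial steps the environmental pool is renewed (persistence `Z`, host
#' shedding `Y`, fixed source `1 - Z - Y`) at that step's environmental
#' value; microbial steps 2..`T_M` additionally resample every host
#' community at retention `P` — the birth draw that produced this
#' generation's starting communities counts as step 1, so with `T_M = 1` no
#' within-host update occurs at all. After the final step, host phenotypes
#' and fitnesses are computed, metrics are recorded prior to reproduction,
#' parents are selected with probability proportional to fitness, and the
#' next generation's communities are assembled with vertical inheritance `X`
#' from the environment state after the final renewal.
#'
#' @param state State list as returned by [initialize_state()].
#' @param E_slice The `T_M` microbial-resolution environmental values of
#'   this host generation.
#' @param config A `holosim_config`.
#' @return A list with the updated `state` and a one-row `metrics` tibble
#'   (`E_value`, `mean_host_fitness`, `mean_microbe_fitness`, `mean_alpha`,
#'   `pool_richness`).
#' @export
run_host_generation <- function(state, E_slice, config) {
  stopifnot(length(E_slice) == config$T_M)
  if (any(!is.finite(E_slice))) stop("non-finite environmental value", call. = FALSE)
  N_M <- config$N_M
  s <- config$s
  source_E <- config$fitness_context == "source"

  for (k in seq_len(config$T_M)) {
    Ek <- E_slice[k]
    state$env <- renew_environment(state$env, rowSums(state$hosts),
                                   config$Z, config$Y, Ek, state$traits, s,
                                   n_ME = config$n_ME,
                                   allocation = config$allocation)
    if (k >= 2) {
      E_h <- internal_environment(state$phi_hg, Ek, config$I)
      state$hosts <- update_hosts_batch(
        state$hosts, state$env, config$P, E_h, state$traits, s,
        env_fitness_context_E = if (source_E) Ek else NULL,
        allocation = config$allocation
      )
    }
  }

  E_final <- E_slice[config$T_M]
  E_sel <- if (config$host_fitness_env == "start") E_slice[1] else E_final
  E_h_final <- internal_environment(state$phi_hg, E_final, config$I)

  phi_hM <- as.numeric(crossprod(state$hosts, state$traits)) / config$n_MH
  phi_h <- host_phenotype(state$phi_hg, phi_hM, config$G)
  w_h <- gaussian_fitness(phi_h, E_sel, s)

  metrics <- tibble::tibble(
    E_value = E_sel,
    mean_host_fitness = mean(w_h),
    mean_microbe_fitness = mean_microbial_fitness(state$hosts, state$traits,
                                                  E_h_final, s),
    mean_alpha = mean(apply(state$hosts, 2, scaled_shannon, N_M = N_M)),
    pool_richness = sum(rowSums(state$hosts) > 0)
  )

  parents <- select_parents(w_h)
  state$hosts <- update_hosts_batch(
    state$hosts[, parents, drop = FALSE], state$env, config$X, E_h_final,
    state$traits, s,
    env_fitness_context_E = if (source_E) E_final else NULL,
    allocation = config$allocation
  )
  state$phi_hg <- state$phi_hg[parents]
  list(state = state, metrics = metrics)
}

#' Run one replicate simulation
#'
#' Initializes a population, then runs `T_H` host generations (the first
#' `burn_in` of them under the stationary burn-in environment that is part
#' of the supplied series) and records one metrics row per host generation,
#' measured prior to reproduction. Burn-in rows are retained and flagged so
#' stabilization can be inspected.
#'
#' @param config A `holosim_config`.
#' @param E_tH Host-resolution environmental series of length `T_H`; by
#'   default generated for this configuration and replicate via
#'   [env_series_for()].
#' @param seed Seed for the run (default: derived stably from the master
#'   seed and the run's scenario/replicate/X/T_M key).
#' @param replicate Replicate index recorded in the output.
#' @return A tibble with one row per host generation: `replicate`,
#'   `scenario`, `X`, `T_M`, `host_generation`, `is_burn_in`, `E_value`,
#'   `mean_host_fitness`, `mean_microbe_fitness`, `mean_alpha`,
#'   `pool_richness`.
#' @examples
#' cfg <- holosim_config(N_H = 10, N_M = 10, n_MH = 200, n_ME = 2000,
#'                       T_H = 20, burn_in = 5, scenario = "2B")
#' run_replicate(cfg)
#' @export
run_replicate <- function(config, E_tH = NULL, seed = NULL, replicate = 1L) {
  stopifnot(inherits(config, "holosim_config"))
  if (is.null(E_tH)) E_tH <- env_series_for(config, replicate)
  if (length(E_tH) != config$T_H) {
    stop("environmental series length must equal T_H", call. = FALSE)
  }
  if (is.null(seed)) {
    seed <- derive_seed(config$seed, "run", config$scenario, replicate,
                        config$X, config$T_M)
  }
  set.seed(seed)

  state <- initialize_state(config)
  E_tM <- matrix(interpolate_series(E_tH, config$T_M), nrow = config$T_M)

  rows <- vector("list", config$T_H)
  for (t in seq_len(config$T_H)) {
    step <- run_host_generation(state, E_tM[, t], config)
    state <- step$state
    rows[[t]] <- step$metrics
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      replicate = as.integer(replicate),
      scenario = config$scenario,
      X = config$X,
      T_M = config$T_M,
      host_generation = dplyr::row_number(),
      is_burn_in = .data$host_generation <= config$burn_in,
      .before = 1
    )
}

#' Run a full simulation (all replicates of one setting)
#'
#' Runs `config$replicates` independent replicates, each with its own
#' environmental series and a stably derived seed, and returns a
#' `holosim_sim` object wrapping the combined tidy metrics. Use
#' [generics::tidy()] for the per-generation table,
#' [generics::glance()] for a one-row summary, and
#' [ggplot2::autoplot()] for trajectory plots.
#'
#' @param config A `holosim_config`.
#' @return A `holosim_sim` object (list with `metrics` and `config`).
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "holosim_config"))
  metrics <- purrr::map(seq_len(config$replicates), function(r) {
    run_replicate(config, E_tH = env_series_for(config, r), replicate = r)
  }) |>
    dplyr::bind_rows()
  structure(list(metrics = metrics, config = config), class = "holosim_sim")
}

#' Run an experiment grid
#'
#' Executes each run specification of a grid built by [build_grid()]. The
#' environmental series for a (scenario, replicate) pair is generated once
#' from its `env_seed` and reused for every (X, T_M) combination, as the
#' grid construction requires. Optionally writes one tidy metrics file per
#' run plus a manifest of resolved parameters.
#'
#' @param grid A run-specification tibble from [build_grid()].
#' @param base The base `holosim_config`.
#' @param out_dir Optional output directory for per-run metrics files and a
#'   `manifest.csv`.
#' @param progress Print a line per completed run?
#' @return The combined metrics tibble (invisibly if `out_dir` is given).
#' @export
run_grid <- function(grid, base, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(base, "holosim_config"), is.data.frame(grid))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  env_cache <- new.env(parent = emptyenv())
  results <- purrr::pmap(grid, function(scenario, replicate, X, T_M,
                                        env_seed, run_seed, ...) {
    cfg <- holosim_config(
      N_H = base$N_H, N_M = base$N_M, n_MH = base$n_MH, n_ME = base$n_ME,
      T_H = base$T_H, T_M = T_M, burn_in = base$burn_in,
      X = X, P = base$P, Z = base$Z, Y = base$Y,
      G = base$G, I = base$I, s = base$s,
      trait_min = base$trait_min, trait_max = base$trait_max,
      phi_hg = base$phi_hg, scenario = scenario,
      rho = base$rho, sigma0 = base$sigma0, mu_max = base$mu_max,
      sigma_max = base$sigma_max, clip_env = base$clip_env,
      fitness_context = base$fitness_context,
      host_fitness_env = base$host_fitness_env,
      allocation = base$allocation,
      replicates = 1, seed = base$seed
    )
    key <- paste(scenario, replicate, sep = "_")
    if (is.null(env_cache[[key]])) {
      env_cache[[key]] <- env_series_for(cfg, replicate, env_seed = env_seed)
    }
    res <- run_replicate(cfg, E_tH = env_cache[[key]], seed = run_seed,
                         replicate = replicate)
    if (!is.null(out_dir)) {
      fn <- sprintf("metrics_%s_rep%03d_X%.3f_TM%d.csv",
                    scenario, replicate, X, as.integer(T_M))
      write_metrics(res, file.path(out_dir, fn))
    }
    if (progress) {
      message(sprintf("done: %s rep %d X=%.3f T_M=%d",
                      scenario, replicate, X, T_M))
    }
    res
  })
  combined <- dplyr::bind_rows(results)
  if (!is.null(out_dir)) {
    manifest <- grid |>
      dplyr::mutate(N_H = base$N_H, N_M = base$N_M, n_MH = base$n_MH,
                    n_ME = base$n_ME, T_H = base$T_H, burn_in = base$burn_in,
                    P = base$P, Z = base$Z, Y = base$Y, G = base$G,
                    I = base$I, s = base$s, master_seed = base$seed)
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    return(invisible(combined))
  }
  combined
}
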