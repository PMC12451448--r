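#' Stable seed derivation
#'
#' Derives a 31-bit seed from a master seed and an arbitrary key, by hashing
#' the key string (FNV-1a style multiply-and-add over characters, modulo the
#' Mersenne prime 2^31 - 1). Runs are therefore reproducible independently of
#' execution order: the same (master seed, key) always yields the same seed.
#'
#' @param master Master seed (integer).
#' @param ... Key components (scenario, replicate index, X, T_M, ...);
#'   formatted and concatenated.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  parts <- c(list(master), list(...))
  key <- paste(vapply(parts, function(x) format(x, trim = TRUE, digits = 15),
                      character(1)), collapse = "|")
  h <- 2166136261 %% 2147483647
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Build an experiment grid of run specifications
#'
#' Expands the Cartesian product of vertical-inheritance values, microbial
#' generation counts, environmental scenarios and replicate indices into one
#' run specification per row. Environmental series are keyed by
#' (scenario, replicate) only, so every (X, T_M) combination of a replicate
#' reuses the identical host-resolution series: a grid over 6 scenarios and
#' 20 replicates uses 120 unique series no matter how many X/T_M settings it
#' spans. Each row carries two derived seeds: `env_seed` (shared across X and
#' T_M) for the environmental series and `run_seed` for the simulation itself.
#'
#' @param base A `holosim_config` supplying all parameters not varied.
#' @param X_values Vertical-inheritance proportions to sweep.
#' @param T_M_values Microbial generation counts to sweep.
#' @param scenarios Environmental scenario kinds.
#' @param replicates Replicates per combination.
#' @return A tibble with one row per run: `scenario`, `replicate`, `X`,
#'   `T_M`, `env_seed`, `run_seed`.
#' @examples
#' cfg <- holosim_config()
#' grid <- build_grid(cfg, X_values = c(0, 0.5, 1), T_M_values = c(1, 10),
#'                    scenarios = c("1A", "2B"), replicates = 2)
#' nrow(grid) # 3 * 2 * 2 * 2
#' @export
build_grid <- function(base,
                       X_values = sweep_X_values(),
                       T_M_values = sweep_T_M_values(),
                       scenarios = scenario_kinds(),
                       replicates = base$replicates) {
  stopifnot(inherits(base, "holosim_config"))
  if (!length(X_values) || !length(T_M_values) || !length(scenarios)) {
    stop("X_values, T_M_values and scenarios must be non-empty", call. = FALSE)
  }
  if (any(X_values < 0 | X_values > 1)) {
    stop("X_values must lie in [0, 1]", call. = FALSE)
  }
  if (any(T_M_values < 1 | T_M_values != round(T_M_values))) {
    stop("T_M_values must be whole numbers >= 1", call. = FALSE)
  }
  if (!all(scenarios %in% scenario_kinds())) {
    stop("unknown scenario kind(s): ",
         paste(setdiff(scenarios, scenario_kinds()), collapse = ", "),
         call. = FALSE)
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)

  grid <- tidyr::expand_grid(
    scenario = as.character(scenarios),
    replicate = seq_len(replicates),
    X = as.numeric(X_values),
    T_M = as.numeric(T_M_values)
  )
  grid |>
    dplyr::mutate(
      env_seed = purrr::map2_int(.data$scenario, .data$replicate,
                                 \(sc, r) derive_seed(base$seed, "env", sc, r)),
      run_seed = purrr::pmap_int(
        list(.data$scenario, .data$replicate, .data$X, .data$T_M),
        \(sc, r, x, tm) derive_seed(base$seed, "run", sc, r, x, tm)
      )
    )
}

#' Default sweep values
#'
#' The full vertical-inheritance and microbial-generation sweeps used by
#' default by [build_grid()]: 9 X values and 14 T_M values (with 6 scenarios
#' and 20 replicates these expand to 15,120 runs).
#' @return Numeric vector of sweep values.
#' @export
sweep_X_values <- function() {
  c(0, 0.167, 0.333, 0.500, 0.667, 0.933, 0.990, 0.999, 1)
}

#' @rdname sweep_X_values
#' @export
sweep_T_M_values <- function() {
  c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 20, 50, 100, 200)
}
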