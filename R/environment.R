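#' Generate a host-resolution environmental series
#'
#' Produces the environmental condition experienced at each host generation
#' under one of six scenarios. The generation-`t` marginal mean and SD follow
#' the scenario:
#'
#' * scenario 1 ("unchanging"): mean 0, SD `sigma0` throughout;
#' * scenario 2 (increasing mean): the mean ramps linearly from 0 at the end
#'   of burn-in to `mu_max` at `T_H`; SD stays `sigma0`;
#' * scenario 3 (increasing variance): mean 0; the SD ramps linearly from
#'   `sigma0` to `sigma_max`.
#'
#' Type A is an AR(1) process, `E_t = mu_t + rho * (E_{t-1} - mu_{t-1}) +
#' eps_t` with `eps_t ~ N(0, sigma_t^2 * (1 - rho^2))`, so the marginal SD is
#' `sigma_t` and successive values are predictable; type B draws each value
#' independently, `E_t = mu_t + N(0, sigma_t^2)`. During burn-in every
#' scenario behaves as scenario 1 (mean 0, SD `sigma0`): trend and variance
#' ramps begin only after burn-in, which exists to let communities stabilize.
#'
#' @param kind Scenario kind: `"1A"`, `"1B"`, `"2A"`, `"2B"`, `"3A"`, `"3B"`.
#' @param T_H Number of host generations.
#' @param burn_in Burn-in length (`0 <= burn_in < T_H`).
#' @param rho Lag-1 autocorrelation for type-A series (`0 <= rho < 1`;
#'   ignored for type B).
#' @param sigma0 Baseline SD (`>= 0`).
#' @param mu_max Final mean for scenario 2.
#' @param sigma_max Final SD for scenario 3.
#' @param trait_min,trait_max Clipping bounds (the simulated trait range).
#' @param clip Clip the series to `[trait_min, trait_max]`?
#' @return Numeric vector of length `T_H` with attributes `kind` and
#'   `burn_in`.
#' @examples
#' set.seed(1)
#' e <- generate_env_series("2B", T_H = 500, burn_in = 100)
#' @export
generate_env_series <- function(kind, T_H, burn_in = 0,
                                rho = 0.9, sigma0 = 0.5,
                                mu_max = 2, sigma_max = 1.5,
                                trait_min = -2.5, trait_max = 2.5,
                                clip = TRUE) {
  kind <- match.arg(as.character(kind), scenario_kinds())
  stopifnot(T_H >= 1, burn_in >= 0, burn_in < T_H)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (sigma0 < 0 || sigma_max < 0) stop("SDs must be >= 0", call. = FALSE)

  scen <- substr(kind, 1, 1)
  type <- substr(kind, 2, 2)
  t <- seq_len(T_H)

  # ramps start at the end of burn-in (t0) and complete at T_H
  t0 <- max(burn_in, 1)
  frac <- if (T_H > t0) pmax(0, t - t0) / (T_H - t0) else rep(0, T_H)
  mu <- if (scen == "2") mu_max * frac else rep(0, T_H)
  sigma <- if (scen == "3") sigma0 + (sigma_max - sigma0) * frac else rep(sigma0, T_H)

  if (type == "B") {
    e <- mu + stats::rnorm(T_H, 0, sigma)
  } else {
    e <- numeric(T_H)
    e[1] <- mu[1] + stats::rnorm(1, 0, sigma[1])
    innov_sd <- sigma * sqrt(1 - rho^2)
    eps <- stats::rnorm(T_H, 0, innov_sd)
    for (i in seq_len(T_H)[-1]) {
      e[i] <- mu[i] + rho * (e[i - 1] - mu[i - 1]) + eps[i]
    }
  }
  if (clip) e <- pmin(pmax(e, trait_min), trait_max)
  structure(e, kind = kind, burn_in = burn_in)
}

#' Interpolate a host-resolution series to microbial resolution
#'
#' Microbes experience environmental change at their own generation scale:
#' within host generation `t` the `T_M` microbial generations see an
#' arithmetic progression from `E[t]` towards `E[t+1]` with step
#' `(E[t+1] - E[t]) / T_M`. For example `E = (0.2, 0.24)` with `T_M = 4`
#' yields `0.2, 0.21, 0.22, 0.23` for the first host generation. With
#' `T_M = 1` the output equals the input. The final host generation has no
#' successor, so its value is held constant for its `T_M` steps.
#'
#' @param E_tH Host-resolution series (numeric).
#' @param T_M Microbial generations per host generation (integer >= 1).
#' @return Numeric vector of length `length(E_tH) * T_M`.
#' @export
interpolate_series <- function(E_tH, T_M) {
  stopifnot(is.numeric(E_tH), length(E_tH) >= 1)
  if (T_M < 1 || T_M != round(T_M)) stop("T_M must be a whole number >= 1",
                                         call. = FALSE)
  T_H <- length(E_tH)
  step <- c(diff(E_tH), 0)
  rep(as.numeric(E_tH), each = T_M) +
    rep(step, each = T_M) * rep.int((seq_len(T_M) - 1) / T_M, T_H)
}

#' Read or write an environmental series
#'
#' Environmental series are shared across every (X, T_M) combination of a
#' replicate; exporting them as two-column delimited text (generation, E)
#' lets the identical series be reused across a grid or inspected.
#'
#' @param E Numeric series (for writing).
#' @param path File path.
#' @return `write_env_series()` returns `path` invisibly;
#'   `read_env_series()` returns the numeric series.
#' @export
write_env_series <- function(E, path) {
  readr::write_tsv(tibble::tibble(generation = seq_along(E), E = as.numeric(E)),
                   path)
  invisible(path)
}

#' @rdname write_env_series
#' @export
read_env_series <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  df$E[order(df$generation)]
}

#' Generate the environmental series for a configuration
#'
#' Convenience wrapper tying [generate_env_series()] to the scenario fields
#' of a configuration and a derived seed, so that a given
#' (master seed, scenario, replicate) always yields the same series.
#'
#' @param config A `holosim_config`.
#' @param replicate Replicate index (keys the series together with the
#'   scenario).
#' @param env_seed Optional explicit seed, overriding the derived one.
#' @return Numeric series of length `config$T_H`.
#' @export
env_series_for <- function(config, replicate = 1L, env_seed = NULL) {
  stopifnot(inherits(config, "holosim_config"))
  if (is.null(env_seed)) {
    env_seed <- derive_seed(config$seed, "env", config$scenario, replicate)
  }
  withr_seed(env_seed, {
    generate_env_series(config$scenario, config$T_H, config$burn_in,
                        rho = config$rho, sigma0 = config$sigma0,
                        mu_max = config$mu_max, sigma_max = config$sigma_max,
                        trait_min = config$trait_min,
                        trait_max = config$trait_max,
                        clip = config$clip_env)
  })
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
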