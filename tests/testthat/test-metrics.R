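test_that("scaled Shannon index matches hand calculation and vegan", {
  expect_equal(scaled_shannon(rep(5, 10)), 1)
  expect_equal(scaled_shannon(c(0, 12, 0)), 0)
  h <- (-2 * 0.25 * log(0.25) - 0.5 * log(0.5)) / log(3)
  expect_equal(scaled_shannon(c(1, 1, 2)), h)
  expect_equal(h, 0.9464, tolerance = 1e-4)

  # independent oracle: vegan's Shannon entropy with the same scaling
  set.seed(21)
  for (i in 1:10) {
    counts <- rpois(12, lambda = 8)
    counts[1] <- counts[1] + 1
    expect_equal(scaled_shannon(counts),
                 vegan::diversity(counts) / log(12))
  }
  expect_error(scaled_shannon(c(0, 0)), "empty")
  expect_error(scaled_shannon(5, N_M = 1), "N_M")
})

test_that("scaled Shannon is label-invariant and penalizes missing taxa", {
  counts <- c(7, 0, 3, 12, 0)
  expect_equal(scaled_shannon(counts), scaled_shannon(rev(counts)))
  expect_lt(scaled_shannon(counts), 1)  # zeros in the pool cap it below 1
})

test_that("mean microbial fitness is the abundance-weighted host average", {
  traits <- c(0.2, 1.2)
  # single host, equal counts, fitnesses {1, exp(-1)}
  expect_equal(mean_microbial_fitness(c(1, 1), traits, E_tMh = 0.2, s = 1),
               (1 + exp(-1)) / 2)
  # monoculture at the optimum
  expect_equal(mean_microbial_fitness(c(10, 0), traits, 0.2, s = 1), 1)
  # neutrality
  expect_equal(mean_microbial_fitness(c(3, 9), traits, 0.2, s = 1e12), 1,
               tolerance = 1e-9)
  # bounded by the per-taxon fitnesses present
  w <- gaussian_fitness(traits, 0.5, 1)
  m <- mean_microbial_fitness(c(4, 6), traits, 0.5, 1)
  expect_gte(m, min(w)); expect_lte(m, max(w))
})

test_that("expected effective vertical inheritance has the closed form", {
  expect_equal(expected_effective_vertical_inheritance(0.7, 0.9, 1), 0.7)
  expect_equal(expected_effective_vertical_inheritance(0.5, 1, 500), 0.5)
  expect_equal(expected_effective_vertical_inheritance(1, 0.98, 101),
               0.98^100)
  expect_equal(0.98^100, 0.1326196, tolerance = 1e-6)
  expect_equal(expected_effective_vertical_inheritance(0, 0.98, 50), 0)
})

test_that("realized vertical inheritance hits its deterministic limits", {
  set.seed(31)
  expect_equal(realized_vertical_inheritance(0, 0.9, 5, n_hosts = 3,
                                             n_MH = 100, N_M = 5),
               rep(0, 3))
  expect_equal(realized_vertical_inheritance(1, 1, 10, n_hosts = 3,
                                             n_MH = 100, N_M = 5),
               rep(1, 3))
})

test_that("realized vertical inheritance matches the neutral closed form", {
  set.seed(32)
  fr <- realized_vertical_inheritance(0.8, 0.9, 11, n_hosts = 40,
                                      n_MH = 5000, N_M = 20)
  expected <- expected_effective_vertical_inheritance(0.8, 0.9, 11)
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - expected), 3 * se + 1e-9)
})

test_that("metrics tables round-trip through delimited text", {
  cfg <- tiny_config(T_H = 5, burn_in = 1)
  res <- run_replicate(cfg)
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_metrics(res, path)
    back <- read_metrics(path)
    expect_equal(as.data.frame(back), as.data.frame(res))
  }
  # grid output is uniquely keyed
  grid_out <- dplyr::bind_rows(
    dplyr::mutate(res, X = 0, T_M = 1),
    dplyr::mutate(res, X = 1, T_M = 1)
  )
  keys <- dplyr::distinct(grid_out, scenario, X, T_M, replicate,
                          host_generation)
  expect_equal(nrow(keys), nrow(grid_out))
})

test_that("neutral coalescence times are near twice the population size", {
  set.seed(33)
  times <- simulate_coalescence(N_H = 30, replicates = 300)
  expect_length(times, 300)
  expect_true(all(times >= 1))
  # coalescent expectation 2 * N * (1 - 1/N) = 58 for N = 30
  expect_equal(mean(times), 2 * 30 * (1 - 1 / 30), tolerance = 0.1)
})
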