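test_that("initialization draws even communities of the right sizes", {
  cfg <- tiny_config()
  st <- initialize_state(cfg, seed = 1)
  expect_length(st$traits, cfg$N_M)
  expect_true(all(st$traits >= cfg$trait_min & st$traits <= cfg$trait_max))
  expect_equal(sum(st$env), cfg$n_ME)
  expect_equal(dim(st$hosts), c(cfg$N_M, cfg$N_H))
  expect_equal(colSums(st$hosts), rep(cfg$n_MH, cfg$N_H))
  expect_gt(scaled_shannon(st$env, cfg$N_M), 0.99)

  st2 <- initialize_state(cfg, seed = 1)
  expect_identical(st, st2)

  mono <- initialize_state(tiny_config(N_M = 1), seed = 2)
  expect_equal(as.numeric(mono$hosts[1, ]), rep(200, 10))
})

test_that("replicates are deterministic in (config, series, seed)", {
  cfg <- tiny_config(T_H = 12, burn_in = 3, scenario = "2B")
  e <- env_series_for(cfg, 1)
  r1 <- run_replicate(cfg, E_tH = e, seed = 77)
  r2 <- run_replicate(cfg, E_tH = e, seed = 77)
  expect_identical(r1, r2)
  r3 <- run_replicate(cfg, E_tH = e, seed = 78)
  expect_false(identical(r1$mean_host_fitness, r3$mean_host_fitness))
})

test_that("community sizes and host count are conserved through a run", {
  cfg <- tiny_config(T_M = 3, X = 0.7)
  e <- env_series_for(cfg, 1)
  st <- initialize_state(cfg, seed = 5)
  E_tM <- matrix(interpolate_series(e, cfg$T_M), nrow = cfg$T_M)
  for (t in 1:5) {
    step <- run_host_generation(st, E_tM[, t], cfg)
    st <- step$state
    expect_equal(ncol(st$hosts), cfg$N_H)
    expect_equal(colSums(st$hosts), rep(cfg$n_MH, cfg$N_H))
    expect_equal(sum(st$env), cfg$n_ME)
  }
})

test_that("metrics rows are complete, flagged for burn-in, and bounded", {
  cfg <- tiny_config(T_H = 15, burn_in = 6, scenario = "3A")
  res <- run_replicate(cfg, replicate = 4L)
  expect_equal(nrow(res), 15)
  expect_equal(res$host_generation, 1:15)
  expect_equal(res$is_burn_in, 1:15 <= 6)
  expect_equal(unique(res$replicate), 4L)
  expect_true(all(res$mean_host_fitness > 0 & res$mean_host_fitness <= 1))
  expect_true(all(res$mean_microbe_fitness > 0 & res$mean_microbe_fitness <= 1))
  expect_true(all(res$mean_alpha >= 0 & res$mean_alpha <= 1))
})

test_that("a run of only burn-in generations is entirely flagged", {
  cfg <- tiny_config(T_H = 6, burn_in = 5)
  res <- run_replicate(cfg)
  expect_true(all(res$is_burn_in[1:5]))
  expect_false(res$is_burn_in[6])
})

test_that("near-neutral selection keeps mean host fitness at 1", {
  cfg <- tiny_config(s = 1e12, T_H = 10, scenario = "1B")
  res <- run_replicate(cfg)
  expect_true(all(res$mean_host_fitness > 0.9999))
  expect_true(all(res$mean_microbe_fitness > 0.9999))
})

test_that("with G = 1 host fitness is microbiome-independent", {
  # phi_hg = 0, so recorded host fitness must equal exp(-E_sel^2 / s)
  cfg <- tiny_config(G = 1, T_H = 8, scenario = "2B", sigma0 = 0, mu_max = 2,
                     burn_in = 0)
  e <- generate_env_series("2B", 8, 0, sigma0 = 0, mu_max = 2)
  res <- run_replicate(cfg, E_tH = e)
  expect_equal(res$mean_host_fitness, exp(-res$E_value^2), tolerance = 1e-12)
})

test_that("T_M = 1 with X = 1 can only lose taxa", {
  cfg <- tiny_config(N_H = 8, X = 1, T_M = 1, T_H = 40, burn_in = 0,
                     scenario = "2B")
  res <- run_replicate(cfg)
  expect_true(all(diff(res$pool_richness) <= 0))
})

test_that("run_simulation stacks replicates and its tidiers behave", {
  cfg <- tiny_config(T_H = 10, burn_in = 2, replicates = 3)
  sim <- run_simulation(cfg)
  td <- tidy(sim)
  expect_equal(nrow(td), 30)
  expect_equal(sort(unique(td$replicate)), 1:3)
  gl <- glance(sim)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$replicates, 3L)
  expect_true(gl$final_host_fitness > 0 && gl$final_host_fitness <= 1)
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
})

test_that("grid runs reuse the replicate's environmental series", {
  cfg <- tiny_config(T_H = 8, burn_in = 2, scenario = "1B", seed = 3L)
  grid <- build_grid(cfg, X_values = c(0, 1), T_M_values = 1,
                     scenarios = "1B", replicates = 2)
  out_dir <- withr::local_tempdir()
  res <- run_grid(grid, cfg, out_dir = out_dir)
  expect_equal(nrow(res), 4 * 8)
  # same replicate, different X: identical environmental values
  e0 <- res$E_value[res$X == 0 & res$replicate == 1]
  e1 <- res$E_value[res$X == 1 & res$replicate == 1]
  expect_identical(e0, e1)
  files <- list.files(out_dir)
  expect_length(files[grepl("^metrics_", files)], 4)
  expect_true("manifest.csv" %in% files)
})
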