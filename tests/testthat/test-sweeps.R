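test_that("the canonical seed-set catalogue lists all 35 combinations", {
  sets <- canonical_seed_sets()
  expect_equal(nrow(sets), 35L)
  expect_equal(sets$label[1], "Isabelle")
  expect_equal(sets$n_ties[1], 2L)
  expect_equal(sets$label[35], "Peter+Alyssa+Victoria")
  expect_equal(sets$n_ties[35], 12L)
  expect_equal(sets$characters[[35]], c("Peter", "Alyssa", "Victoria"))
  expect_equal(sort(sets$n_ties),
               c(2L, 3L, 3L, 4L, 4L, 5L, 5L, 5L, 6L, 6L, 6L, 7L, 7L, 7L, 7L,
                 7L, 8L, 8L, 8L, 8L, 8L, 9L, 9L, 9L, 10L, 10L, 10L, 10L, 11L,
                 11L, 11L, 11L, 11L, 12L, 12L))
})

test_that("catalogued tie counts all match the canonical fixture", {
  net <- canonical_fixture("balanced")
  sets <- canonical_seed_sets()
  observed <- vapply(sets$characters,
                     function(s) nrow(incident_edges(net, s)), integer(1))
  expect_equal(observed, sets$n_ties)
})

test_that("a fixture/catalogue tie-count mismatch is a hard error", {
  net <- canonical_fixture("balanced")
  sets <- canonical_seed_sets()[1:2, ]
  sets$n_ties[2] <- 99L
  cfg <- sweep_config(net, seed_sets = sets, replicates = 2L,
                      structural = structural_params(p_triangle = 0,
                                                     p_background = 0))
  expect_error(run_seed_sweep(cfg), "fixture/seed mismatch")
})

test_that("with no stochastic additions every seed set recalls exactly its ties", {
  net <- canonical_fixture("balanced")
  cfg <- sweep_config(net, seed_sets = canonical_seed_sets()[c(1, 6, 22), ],
                      replicates = 5L,
                      structural = structural_params(p_triangle = 0,
                                                     p_background = 0),
                      affect = affect_params(x = 0), master_seed = 3L)
  tab <- run_seed_sweep(cfg)
  expect_equal(tab$precision_mean, rep(1, 3))
  expect_equal(tab$precision_sd, rep(0, 3))
  expect_equal(tab$coverage_mean, tab$n_seed_ties / 23)
  expect_equal(tab$n_recalled_mean, as.numeric(tab$n_seed_ties))
  expect_equal(tab$quality_mean, rep(1, 3))
})

test_that("replicate streams pool identically across batch splits", {
  net <- canonical_fixture("balanced")
  params <- structural_params(p_triangle = 0.5, p_background = 0.02)
  whole <- replicate_scores(net, c("Lewis", "Alyssa"), params,
                            master_seed = 11L, block = 4L, replicates = 1:40)
  halves <- rbind(
    replicate_scores(net, c("Lewis", "Alyssa"), params,
                     master_seed = 11L, block = 4L, replicates = 1:20),
    replicate_scores(net, c("Lewis", "Alyssa"), params,
                     master_seed = 11L, block = 4L, replicates = 21:40))
  rownames(halves) <- NULL
  expect_identical(whole, halves)
})

test_that("overriding with the true closed-triplet count is a no-op", {
  net <- canonical_fixture("balanced")
  cen <- triplet_census(net)
  cfg <- sweep_config(net, replicates = 15L, master_seed = 21L)
  over <- suppressWarnings(run_tclosed_sweep(cfg, cen$T_closed))
  base <- suppressWarnings(
    replicate_scores(net, c("Lewis", "Alyssa"), cfg$structural, cfg$affect,
                     master_seed = 21L, block = 1L, replicates = 1:15))
  expect_equal(over$coverage_mean, mean(base$coverage))
  expect_equal(over$precision_mean, mean(base$precision, na.rm = TRUE))
  expect_error(run_tclosed_sweep(cfg, cen$T + 5), "must lie in")
})

test_that("x sweep rows cover each condition and grid point", {
  bal <- canonical_fixture("balanced")
  imb <- canonical_fixture("imbalanced")
  cfg <- sweep_config(bal, replicates = 8L, master_seed = 7L)
  tab <- suppressWarnings(
    run_x_sweep(cfg, x_grid = c(0, 0.3),
                targets = list(balanced = bal, imbalanced = imb)))
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$condition, c("balanced", "imbalanced"))
  expect_true(0.3 %in% tab$x)
  expect_error(run_x_sweep(cfg, x_grid = c(-0.1, 0.5)), "must lie in")
})

test_that("sweep outputs round-trip and are byte-identical across reruns", {
  net <- canonical_fixture("balanced")
  cfg <- sweep_config(net, seed_sets = canonical_seed_sets()[c(1, 22), ],
                      replicates = 10L,
                      structural = structural_params(p_triangle = 0.5,
                                                     p_background = 0.02),
                      master_seed = 13L)
  tab1 <- run_seed_sweep(cfg)
  tab2 <- run_seed_sweep(cfg)
  expect_identical(tab1, tab2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sweep(tab1, d1)
  write_sweep(tab2, d2)
  expect_identical(readBin(file.path(d1, "sweep.csv"), "raw", 1e6),
                   readBin(file.path(d2, "sweep.csv"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "sweep.json"), "raw", 1e6),
                   readBin(file.path(d2, "sweep.json"), "raw", 1e6))

  back <- read_sweep(d1)
  expect_equal(back$coverage_mean, tab1$coverage_mean)
  expect_equal(back$seed_set, tab1$seed_set)
})

test_that("delta columns appear only when experimental summaries are given", {
  net <- canonical_fixture("balanced")
  cfg <- sweep_config(net, seed_sets = canonical_seed_sets()[22, ],
                      replicates = 5L,
                      structural = structural_params(p_triangle = 0.5,
                                                     p_background = 0.02))
  tab <- run_seed_sweep(cfg)
  d <- withr::local_tempdir()
  plain <- write_sweep(tab, d)
  expect_false(any(grepl("_delta$", names(plain))))

  exp_sum <- data.frame(metric = c("precision", "coverage"),
                        mean = c(0.9, 0.5), sd = c(0.1, 0.1))
  with_delta <- write_sweep(tab, d, experimental = exp_sum)
  expect_equal(with_delta$precision_delta,
               delta(tab$precision_mean, 0.9, 0.1))
  expect_equal(with_delta$coverage_delta,
               delta(tab$coverage_mean, 0.5, 0.1))
  expect_false("quality_delta" %in% names(with_delta))
})

test_that("sweep configurations load from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "replicates: 25",
    "master_seed: 99",
    "condition: balanced",
    "structural:",
    "  census_mode: triangles",
    "affect:",
    "  x: 0.45",
    "seed_sets:",
    "  - Lewis+Alyssa",
    "  - [Peter, James]"
  ), f)
  cfg <- read_sweep_config(f, canonical_fixture("balanced"))
  expect_equal(cfg$replicates, 25L)
  expect_equal(cfg$master_seed, 99L)
  expect_equal(cfg$structural$census_mode, "triangles")
  expect_equal(cfg$affect$x, 0.45)
  expect_equal(cfg$seed_sets$characters[[1]], c("Lewis", "Alyssa"))
  expect_equal(cfg$seed_sets$characters[[2]], c("Peter", "James"))
})
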