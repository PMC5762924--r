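test_that("identical seeds give bit-identical datasets", {
  a <- simulate_dataset(sim_config(n_samples_per_period = c(6, 4, 4),
                                   n_motus = 15, seed = 99))
  b <- simulate_dataset(sim_config(n_samples_per_period = c(6, 4, 4),
                                   n_motus = 15, seed = 99))
  expect_identical(a$read_matrix, b$read_matrix)
  expect_identical(as.data.frame(a$traits), as.data.frame(b$traits))
  expect_identical(a$samples$age, b$samples$age)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  c_ <- simulate_dataset(sim_config(n_samples_per_period = c(6, 4, 4),
                                    n_motus = 15, seed = 100))
  expect_false(identical(a$read_matrix, c_$read_matrix))
})

test_that("the generator respects shapes, period counts and trait invariants", {
  ds <- simulate_dataset(sim_config(n_samples_per_period = c(10, 5, 7),
                                    n_motus = 25, seed = 1))
  expect_equal(dim(ds$read_matrix), c(22, 25))
  expect_equal(as.integer(table(ds$samples$period)), c(10, 5, 7))
  expect_equal(as.character(assign_period(ds$samples$age)),
               as.character(ds$samples$period))
  # hard trait constraints: NM coupling, no fixers among NM taxa
  expect_length(paleotrait:::.nm_conflicts(ds$traits), 0)
  expect_false(any(ds$traits$n_fix == "fixer" & ds$traits$myc_type == "NM"))
  expect_equal(length(ds$tree$tip.label), 25)
})

test_that("infeasible marginals are rejected at configuration time", {
  bad <- default_trait_marginals()
  bad$n_fix <- c(fixer = 0.5, nonfixer = 0.5)
  bad$myc_type <- c(AM = 0.2, ECM = 0.1, ERM = 0.1, NM = 0.6)
  expect_error(sim_config(trait_marginals = bad), "infeasible")
  bad2 <- default_trait_marginals()
  bad2$growth_form <- c(forb = 0.5, graminoid = 0.2, dwarf_shrub = 0.2,
                        tree_shrub = 0.2)
  expect_error(sim_config(trait_marginals = bad2), "sum to 1")
})

test_that("realized forb counts fluctuate around the configured 86/131 marginal", {
  counts <- vapply(1:200, function(s) {
    ds <- simulate_dataset(sim_config(n_samples_per_period = c(2, 1, 1),
                                      n_motus = 131, seed = s))
    sum(ds$traits$growth_form == "forb")
  }, numeric(1))
  p <- 86 / 131
  se_mean <- sqrt(131 * p * (1 - p)) / sqrt(200)
  expect_lt(abs(mean(counts) - 86), 4 * se_mean)
})

test_that("zero period effects give identical expected profiles across periods", {
  null_eff <- lapply(default_period_effects(), function(m) m * 0)
  ds <- simulate_dataset(sim_config(n_samples_per_period = c(4, 3, 3),
                                    n_motus = 20, period_effects = null_eff,
                                    spatial_sill = 0, seed = 7))
  pim <- ds$truth$pi
  expect_equal(pim["pre-LGM", ], pim["LGM", ], tolerance = 1e-12)
  expect_equal(pim["pre-LGM", ], pim["post-LGM", ], tolerance = 1e-12)
  es <- ds$truth$expected_shares$myc_type
  expect_equal(es["pre-LGM", ], es["post-LGM", ], tolerance = 1e-12)
})

test_that("calibrated AM targets are hit analytically and recovered from reads", {
  cfg <- sim_config(n_samples_per_period = c(25, 25, 25), n_motus = 40,
                    target_shares = list(myc_type = list(AM = c(0.8, 0.6, 0.4))),
                    overdispersion = 5, spatial_sill = 0, seed = 17)
  ds <- simulate_dataset(cfg)
  expect_equal(unname(ds$truth$expected_shares$myc_type[, "AM"]),
               c(0.8, 0.6, 0.4), tolerance = 1e-12)
  sh <- sample_trait_shares(ds$read_matrix, ds$traits, "myc_type", "reads")
  ci <- bootstrap_ci(sh, ds$samples, B = 500, seed = 2)
  covered <- ci$lower[, "AM"] <= c(0.8, 0.6, 0.4) &
    c(0.8, 0.6, 0.4) <= ci$upper[, "AM"]
  expect_true(all(covered))
})

test_that("per-sample read totals follow the configured lognormal", {
  cfg <- sim_config(n_samples_per_period = c(400, 300, 300), n_motus = 10,
                    reads_meanlog = 8.9, reads_sdlog = 1.5, seed = 23)
  ds <- simulate_dataset(cfg)
  tot <- rowSums(ds$read_matrix)
  ks <- suppressWarnings(stats::ks.test(tot, stats::plnorm,
                                        meanlog = 8.9, sdlog = 1.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("site effects are spatially autocorrelated up to the configured range", {
  cfg <- sim_config(n_samples_per_period = c(2, 1, 1), n_motus = 5,
                    n_sites = 80, spatial_range_km = 3000, spatial_sill = 1,
                    seed = 31)
  ds <- simulate_dataset(cfg)
  g <- ds$truth$site_effects
  d <- ds$truth$site_distance_km
  up <- upper.tri(d)
  semivar <- function(sel) mean((g[row(d)[up][sel]] - g[col(d)[up][sel]])^2) / 2
  near <- d[up] < 1500
  far <- d[up] > 6000
  expect_lt(semivar(near), semivar(far))
})

test_that("the Yule/Brownian simulator produces ultrametric binary trees deterministically", {
  sim <- simulate_tree(131, seed = 5)
  expect_equal(length(sim$tree$tip.label), 131)
  expect_equal(sim$tree$Nnode, 130)
  depths <- ape::node.depth.edgelength(sim$tree)[1:131]
  expect_lt(max(depths) - min(depths), 1e-9)
  sim2 <- simulate_tree(131, seed = 5)
  expect_identical(sim$trait, sim2$trait)
  expect_error(simulate_tree(1), "n_tips")
})
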