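test_that("the low-level OMI decomposition reproduces the hand example", {
  # 4 samples, two periods (A,A,B,B); standardized dummy z = (1,1,-1,-1)
  Z <- matrix(c(1, 1, -1, -1), ncol = 1)
  # species present only in sample 1; a second uniform species
  P <- rbind(sp1 = c(1, 0, 0, 0), sp2 = rep(0.25, 4))
  u <- c(0.5, 0.5)
  core <- omi_core(P, Z, u)
  expect_equal(core$omi[["sp1"]], 1)
  expect_equal(core$omi[["sp2"]], 0)  # uniform profile sits at the origin
  expect_equal(core$tol[["sp1"]], 0)  # point profile has no tolerance
  expect_equal(core$mean_omi, 0.5)
  expect_equal(sum(core$eigenvalues), core$mean_omi, tolerance = 1e-12)
})

test_that("OMI identities hold on random data and null axes vanish for a 3-level factor", {
  set.seed(31)
  for (i in 1:3) {
    rm <- matrix(rpois(10 * 6, 8) + 1L, 10, 6,
                 dimnames = list(paste0("s", 1:10), paste0("m", 1:6)))
    per <- factor(sample(rep(period_levels(), c(4, 3, 3))),
                  levels = period_levels())
    fit <- omi_analysis(rm, per)
    expect_equal(fit$motus$inertia, fit$motus$omi + fit$motus$tol + fit$motus$rtol,
                 tolerance = 1e-9)
    expect_equal(sum(fit$eigenvalues), sum(fit$motus$weight * fit$motus$omi),
                 tolerance = 1e-9)
    expect_true(all(abs(fit$eigenvalues[-(1:2)]) <= 1e-10))
    expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  }
})

test_that("a uniformly distributed species has zero marginality through the full interface", {
  rm <- cbind(even = rep(5L, 8), patchy = c(40L, rep(1L, 7)))
  rownames(rm) <- paste0("s", 1:8)
  per <- factor(rep(period_levels(), c(3, 3, 2)), levels = period_levels())
  fit <- omi_analysis(rm, per)
  expect_equal(fit$motus$omi[fit$motus$motu_id == "even"], 0, tolerance = 1e-12)
  expect_gt(fit$motus$omi[fit$motus$motu_id == "patchy"], 0)
})

test_that("species scores are invariant to MOTU input order and obey the sign contract", {
  ds <- structured_dataset(n_per = c(10, 6, 6), n_motus = 20, seed = 14)
  fit <- omi_analysis(ds$read_matrix, ds$samples$period)
  ord <- sample(ncol(ds$read_matrix))
  fit2 <- omi_analysis(ds$read_matrix[, ord], ds$samples$period)
  expect_equal(fit2$species_scores[rownames(fit$species_scores), 1:2],
               fit$species_scores[, 1:2], tolerance = 1e-9)
  # orientation: post-LGM centroid negative on axis 1, LGM negative on axis 2
  expect_lt(mean(fit$sample_scores[ds$samples$period == "post-LGM", 1]), 0)
  expect_lt(mean(fit$sample_scores[ds$samples$period == "LGM", 2]), 0)
})

test_that("a MOTU confined to post-LGM samples takes an extreme negative axis-1 score", {
  set.seed(15)
  rm <- matrix(rpois(12 * 6, 20) + 1L, 12, 6,
               dimnames = list(paste0("s", 1:12), paste0("m", 1:6)))
  per <- factor(rep(period_levels(), each = 4), levels = period_levels())
  rm[, "m6"] <- 0L
  rm[per == "post-LGM", "m6"] <- 50L
  fit <- omi_analysis(rm, per)
  sc1 <- fit$species_scores[, 1]
  expect_equal(names(which.min(sc1)), "m6")
  expect_lt(sc1[["m6"]], 0)
})

test_that("the randomization p matches brute-force enumeration on tiny data", {
  rm <- matrix(c(9L, 1L, 2L, 8L), 2, 2,
               dimnames = list(c("s1", "s2"), c("m1", "m2")))
  per <- factor(c("pre-LGM", "LGM"))
  rt <- omi_randtest(rm, per, exhaustive = TRUE)
  # brute force: both orderings of the two samples
  Z <- paleotrait:::.standardized_dummies(per)
  P <- t(rm) / colSums(rm)
  u <- colSums(rm) / sum(rm)
  mo <- function(Zp) sum(u * rowSums((P %*% Zp)^2))
  vals <- c(mo(Z), mo(Z[2:1, , drop = FALSE]))
  expect_equal(rt$obs, vals[1])
  expect_equal(rt$p, mean(vals >= vals[1] - 1e-12))
})

test_that("strong period structure drives the randomization p to its floor", {
  # each MOTU occurs in exactly one period: the observed labeling maximizes
  # the mean OMI over sample relabelings
  set.seed(19)
  per <- factor(rep(period_levels(), c(20, 12, 12)), levels = period_levels())
  n <- length(per)
  rm <- matrix(0L, n, 30, dimnames = list(sprintf("s%02d", 1:n),
                                          sprintf("m%02d", 1:30)))
  home <- rep_len(period_levels(), 30)
  for (k in seq_len(30))
    rm[per == home[k], k] <- as.integer(sample(50:100, sum(per == home[k]),
                                               replace = TRUE))
  rt <- omi_randtest(rm, per, n_perm = 99, seed = 4)
  expect_equal(rt$p, 1 / 100)
})

test_that("trait-on-niche models account for covariates and flag aliased traits", {
  ds <- structured_dataset(n_per = c(14, 8, 8), n_motus = 35, seed = 23,
                           overdispersion = 25)
  f <- filter_dataset(ds$read_matrix, ds$traits)
  fit <- omi_analysis(f$read_matrix, ds$samples$period)
  sc <- fit$species_scores[, 1:2]
  tnm <- trait_niche_models(sc, f$traits, n_perm = 99, seed = 2)
  s <- tnm$summary
  expect_setequal(unique(s$trait),
                  c("growth_form", "myc_type", "myc_status", "n_fix", "pollination"))
  # growth form appears only univariately; mutualist traits in all 3 designs
  expect_equal(sum(s$trait == "growth_form"), 1)
  expect_equal(sum(s$trait == "myc_status"), 3)
  expect_true(all(s$R2 >= 0 & s$R2 <= 1))
  # mycorrhizal type and status never co-occur in one model
  for (m in tnm$models) expect_false(all(c("myc_type", "myc_status") %in% m$terms))

  # focal trait identical to growth form -> zero added SS in model (ii)
  tt <- f$traits
  tt$pollination <- factor(ifelse(tt$growth_form == "forb", "insect", "wind"),
                           levels = trait_levels("pollination"))
  tt$growth_form <- factor(ifelse(tt$growth_form == "forb", "forb", "graminoid"),
                           levels = trait_levels("growth_form"))
  w <- testthat::capture_warnings(
    tnm2 <- trait_niche_models(sc, tt, n_perm = 49, seed = 2))
  expect_true(any(grepl("aliased", w)))
  s2 <- tnm2$summary
  row <- s2[s2$trait == "pollination" & s2$model == "after_growth_form", ]
  expect_equal(row$R2, 0)
  expect_equal(row$df, 0L)
})

test_that("Dunn's test matches its closed form, a brute-force tie recount, and base Kruskal-Wallis", {
  # no ties: groups {1,2,3} vs {4,5,6} -> z = 3 / sqrt(3.5 * 2/3)
  d <- dunn_test(1:6, factor(rep(c("a", "b"), each = 3)))
  expect_equal(abs(d$pairs$z), 3 / sqrt(3.5 * (2 / 3)), tolerance = 1e-9)
  expect_equal(d$pairs$p, 2 * pnorm(-abs(d$pairs$z)))

  # ties: independent recomputation from first principles
  x <- c(1, 1, 2, 2, 3, 3)
  g <- factor(rep(c("a", "b"), each = 3))
  d2 <- dunn_test(x, g)
  r <- rank(x)
  N <- 6
  Tc <- sum(sapply(table(x), function(t) t^3 - t)) / (12 * (N - 1))
  zref <- (mean(r[1:3]) - mean(r[4:6])) /
    sqrt((N * (N + 1) / 12 - Tc) * (2 / 3))
  expect_equal(d2$pairs$z, zref, tolerance = 1e-12)
  expect_equal(d2$tie_correction, Tc)
  expect_equal(d2$kw_statistic,
               unname(kruskal.test(x, g)$statistic), tolerance = 1e-12)

  # identical groups: z = 0, p = 1
  d3 <- dunn_test(rep(1, 8), factor(rep(c("a", "b"), 4)))
  expect_equal(d3$pairs$z, 0)
  expect_equal(d3$pairs$p, 1)

  # antisymmetry under group relabeling
  d4 <- dunn_test(1:6, factor(rep(c("b", "a"), each = 3)))
  expect_equal(d4$pairs$z, -d$pairs$z)
})
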