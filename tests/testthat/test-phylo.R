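test_that("single-species MOTUs relabel tips; multi-taxon MOTUs graft at the right rank", {
  bb <- simulate_backbone(n_species = 2, n_genus = 1, n_tribe = 1,
                          n_subfamily = 1, n_family = 1)
  h0 <- max(ape::node.depth.edgelength(bb$tree))
  tr <- graft_motus(bb$tree, bb$taxonomy, bb$motu_defs)
  expect_setequal(tr$tip.label, names(bb$motu_defs))
  expect_equal(length(tr$tip.label), 6)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  # grafting and pruning leave the tree height unchanged
  expect_equal(max(ape::node.depth.edgelength(tr)), h0, tolerance = 1e-9)
  pl <- attr(tr, "placements")
  ids <- sprintf("motu%03d", 1:6)
  expect_equal(pl$rank[match(ids, pl$motu_id)],
               c("species", "species", "genus", "tribe", "subfamily", "family"))
  # attachment heights follow the nesting depth of the ranks
  expect_true(all(diff(pl$height[match(ids[3:6], pl$motu_id)]) > 0))
})

test_that("a MOTU of two congeners attaches at the genus crown and stays contemporaneous", {
  txt <- "((spA:1,spB:1):3,(spC:2.5,spD:2.5):1.5);"
  tree <- ape::read.tree(text = txt)
  taxo <- data.frame(species = c("spA", "spB", "spC", "spD"),
                     genus = c("G1", "G1", "G2", "G2"),
                     tribe = "T1", subfamily = "S1", family = "F1")
  defs <- list(motuX = c("spA", "spB"), mA = "spA", mB = "spB",
               mC = "spC", mD = "spD")
  tr <- graft_motus(tree, taxo, defs)
  expect_setequal(tr$tip.label, names(defs))
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  # motuX's pendant branch equals the G1 crown height
  edge_len <- tr$edge.length[tr$edge[, 2] == match("motuX", tr$tip.label)]
  expect_equal(edge_len, 1)
})

test_that("unresolvable MOTUs are reported as an error list, not dropped", {
  bb <- simulate_backbone(n_species = 1, n_genus = 1, n_tribe = 0,
                          n_subfamily = 0, n_family = 0)
  defs <- c(bb$motu_defs, list(lost = c("nowhere1", "nowhere2")))
  expect_error(graft_motus(bb$tree, bb$taxonomy, defs), "lost")
})

test_that("grafting at the published attachment counts yields a 131-tip MOTU phylogeny", {
  bb <- simulate_backbone()  # 26 species + 75 genus + 7 tribe + 5 subfamily + 18 family
  tr <- graft_motus(bb$tree, bb$taxonomy, bb$motu_defs)
  expect_equal(length(tr$tip.label), 131)
  expect_equal(tr$Nnode, 130)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
})

test_that("on a star tree PGLS collapses to ordinary least squares with lambda at the bound", {
  set.seed(33)
  n <- 40
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n)
  names(y) <- star$tip.label
  X <- cbind(intercept = 1, x = x)
  rownames(X) <- star$tip.label
  fit <- pgls_lambda(y, X, star)
  ols <- lm(y ~ x)
  expect_true(fit$lambda_bound)
  expect_equal(fit$lambda, 0)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-9)
  expect_equal(unname(fit$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-9)
})

test_that("the profile likelihood is maximized at the reported lambda", {
  sim <- simulate_tree(60, trait_lambda = 0.6, seed = 41)
  X <- matrix(1, 60, 1, dimnames = list(sim$tree$tip.label, "intercept"))
  fit <- pgls_lambda(sim$trait, X, sim$tree)
  for (l in c(0, 0.5, 1))
    expect_gte(fit$profile(fit$lambda) + 1e-6, fit$profile(l))
})

test_that("PGLS agrees with nlme::gls under corPagel on the same data", {
  skip_if_not_installed("nlme")
  sim <- simulate_tree(50, trait_lambda = 0.7, seed = 13)
  tree <- sim$tree
  x <- rnorm(50)
  y <- sim$trait + 0.5 * x
  names(y) <- tree$tip.label
  X <- cbind(intercept = 1, x = x)
  rownames(X) <- tree$tip.label
  fit <- pgls_lambda(y, X, tree)
  df <- data.frame(y = y, x = x, row.names = tree$tip.label)
  # data is explicitly tip-ordered; corPagel's ordering notice is expected
  ref <- suppressWarnings(nlme::gls(y ~ x, data = df[tree$tip.label, ],
                                    correlation = ape::corPagel(0.5, phy = tree),
                                    method = "ML"))
  lam_ref <- unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(fit$lambda, lam_ref, tolerance = 1e-3)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(ref$logLik), tolerance = 1e-4)
})

test_that("category means coincide across models when signal is absent and diverge in precision when present", {
  # identical tip values in two categories: zero difference in both models
  sim <- simulate_tree(30, trait_lambda = 1, seed = 3)
  tree <- sim$tree
  y <- setNames(rep(c(1, 1), 15), tree$tip.label)
  g <- factor(rep(c("A", "B"), 15))
  cm <- suppressWarnings(category_niche_means(y, g, tree))
  expect_equal(cm$mean[1] - cm$mean[2], 0)
  expect_equal(cm$mean_pgls[1] - cm$mean_pgls[2], 0, tolerance = 1e-9)

  # star tree (lambda pinned at 0): phylogenetic = arithmetic means
  star <- ape::stree(30, "star"); star$edge.length <- rep(1, 30)
  yy <- setNames(rnorm(30), star$tip.label)
  gg <- factor(rep(c("A", "B"), 15))
  cm2 <- category_niche_means(yy, gg, star)
  expect_equal(cm2$mean, cm2$mean_pgls, tolerance = 1e-9)
  expect_equal(attr(cm2, "lambda"), 0)
})

test_that("phylogenetically clustered traits widen the phylogenetic standard errors", {
  wins <- 0L
  n_sims <- 100
  for (i in seq_len(n_sims)) {
    sim <- simulate_tree(80, trait_lambda = 1, seed = 500 + i)
    tree <- sim$tree
    y <- sim$trait
    # categorize tips by a second conserved character: clade membership
    g <- factor(ifelse(seq_along(tree$tip.label) %in%
                         unlist(ape::prop.part(tree)[[2]]), "A", "B"))
    if (nlevels(droplevels(g)) < 2) next
    cm <- suppressWarnings(category_niche_means(y, g, tree))
    if (mean(cm$se_pgls, na.rm = TRUE) >= mean(cm$se, na.rm = TRUE))
      wins <- wins + 1L
  }
  expect_gte(wins / n_sims, 0.9)
})
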