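test_that("trait-source merging takes the most recent defined value", {
  s1 <- data.frame(motu_id = "A", myc_type = "AM")
  s2 <- data.frame(motu_id = "A", myc_type = "ECM")
  merged <- merge_trait_sources(list(s1, s2))
  expect_equal(as.character(merged$myc_type), "AM")

  # gaps fall through to older sources, per trait independently
  s1 <- data.frame(motu_id = c("A", "B"), myc_type = c(NA, "ECM"),
                   growth_form = c("forb", NA))
  s2 <- data.frame(motu_id = c("A", "C"), myc_type = c("NM", "AM"),
                   myc_status = c("NM", "OM"))
  merged <- merge_trait_sources(list(s1, s2))
  expect_equal(as.character(merged$myc_type[merged$motu_id == "A"]), "NM")
  expect_equal(as.character(merged$myc_status[merged$motu_id == "A"]), "NM")
  expect_equal(as.character(merged$growth_form[merged$motu_id == "A"]), "forb")
  expect_equal(as.character(merged$myc_type[merged$motu_id == "B"]), "ECM")

  expect_equal(nrow(merge_trait_sources(list())), 0)
  empty <- merge_trait_sources(list(data.frame(motu_id = c("x", "y"))))
  expect_true(all(as.character(empty$myc_type) == "undefined"))
})

test_that("merging detects NM type/status conflicts and names the MOTUs", {
  s1 <- data.frame(motu_id = "A", myc_status = "OM")
  s2 <- data.frame(motu_id = "A", myc_type = "NM")
  expect_error(merge_trait_sources(list(s1, s2)), "A")
})

test_that("filtering removes rare then trait-incomplete MOTUs then emptied samples", {
  # m1 kept; m2 undefined in pollination; m3 rare (4 reads total);
  # sample s2 only holds the removed MOTUs
  rm <- matrix(c(10L, 5L, 1L,
                 0L, 7L, 3L),
               nrow = 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("m1", "m2", "m3")))
  tt <- trait_table(c("m1", "m2", "m3"),
                    growth_form = "forb", myc_type = "AM", myc_status = "OM",
                    n_fix = "nonfixer",
                    pollination = c("insect", "undefined", "wind"))
  res <- filter_dataset(rm, tt)
  expect_equal(colnames(res$read_matrix), "m1")
  expect_equal(rownames(res$read_matrix), "s1")
  expect_equal(res$report$motus_removed_rare, 1)
  expect_equal(res$report$motus_removed_undefined, 1)
  expect_equal(res$report$samples_removed_empty, 1)
  expect_equal(res$report$reads_removed, 16)
  expect_equal(res$report$reads_in - res$report$reads_removed,
               res$report$reads_out)
})

test_that("filtering is the identity on clean data and is idempotent", {
  ds <- structured_dataset(n_per = c(5, 3, 3), n_motus = 12, seed = 4)
  once <- filter_dataset(ds$read_matrix, ds$traits)
  keep <- colSums(ds$read_matrix) >= 5
  expect_identical(once$read_matrix, ds$read_matrix[, keep, drop = FALSE])
  twice <- filter_dataset(once$read_matrix, once$traits)
  expect_identical(twice$read_matrix, once$read_matrix)
  expect_identical(as.data.frame(twice$traits), as.data.frame(once$traits))
  expect_equal(twice$report$reads_removed, 0)
})

test_that("Cramer's V matches hand-computed 2x2 values and its bounds", {
  # [[8,2],[3,7]]: chi2 = N(ad-bc)^2 / row/col products = 50000/9900
  tt <- trait_table(paste0("m", 1:20),
                    myc_type = rep(c("AM", "ECM"), c(10, 10)),
                    n_fix = c(rep("fixer", 8), rep("nonfixer", 2),
                              rep("fixer", 3), rep("nonfixer", 7)))
  r <- cramers_v(tt, "myc_type", "n_fix")
  expect_equal(r$chi2, 50000 / 9900, tolerance = 1e-12)
  expect_equal(r$v, sqrt(50000 / 9900 / 20), tolerance = 1e-12)
  expect_equal(r$df, 1L)
  expect_equal(r$p, pchisq(50000 / 9900, 1, lower.tail = FALSE))

  perfect <- trait_table(paste0("m", 1:20),
                         growth_form = rep(c("forb", "graminoid"), each = 10),
                         pollination = rep(c("insect", "wind"), each = 10))
  expect_equal(cramers_v(perfect, "growth_form", "pollination")$v, 1)

  indep <- trait_table(paste0("m", 1:20),
                       growth_form = rep(c("forb", "graminoid"), each = 10),
                       pollination = rep(c("insect", "wind"), 10))
  expect_equal(cramers_v(indep, "growth_form", "pollination")$v, 0)
})

test_that("Cramer's V is symmetric and invariant to MOTU order; degenerate traits error", {
  set.seed(42)
  tt <- trait_table(paste0("m", 1:60),
                    growth_form = sample(c("forb", "graminoid", "tree_shrub"),
                                         60, replace = TRUE),
                    myc_type = sample(c("AM", "ECM"), 60, replace = TRUE))
  a <- cramers_v(tt, "growth_form", "myc_type")
  b <- cramers_v(tt, "myc_type", "growth_form")
  expect_equal(a$v, b$v)
  expect_equal(a$p, b$p)
  shuffled <- tt[sample(nrow(tt)), ]
  expect_equal(cramers_v(shuffled, "growth_form", "myc_type")$v, a$v)

  mono <- trait_table(paste0("m", 1:10), growth_form = "forb",
                      myc_type = rep(c("AM", "ECM"), 5))
  expect_error(cramers_v(mono, "growth_form", "myc_type"), "growth_form")
})

test_that("the pairwise association matrix carries V above and p below the diagonal", {
  ds <- structured_dataset(n_per = c(4, 3, 3), n_motus = 60, seed = 9)
  m <- cramers_v_matrix(ds$traits)
  expect_true(all(is.na(diag(m))))
  r <- cramers_v(ds$traits, "growth_form", "myc_type")
  expect_equal(m["growth_form", "myc_type"], r$v)
  expect_equal(m["myc_type", "growth_form"], r$p)
  expect_true(all(m[upper.tri(m)] >= 0 & m[upper.tri(m)] <= 1))
})
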