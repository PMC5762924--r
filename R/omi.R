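#' Low-level outlying mean index decomposition
#'
#' Computes the OMI decomposition for species profiles `P` against an
#' environment table `Z` that is already centered and standardized with
#' uniform sample weights. For species i with profile p_i (rows of `P`,
#' summing to 1) the marginality vector is m_i = sum_j p_ij z_j; the
#' outlying mean index is omi_i = ||m_i||^2; the tolerance is the
#' profile-weighted variance of the projections of z_j on the marginality
#' direction, tol_i = sum_j p_ij ((z_j . e_i) - ||m_i||)^2 with
#' e_i = m_i/||m_i|| (zero when m_i = 0); and the residual tolerance is
#' rtol_i = inertia_i - omi_i - tol_i with inertia_i = sum_j p_ij ||z_j||^2.
#' Ordination axes are the eigenvectors of M' U M with U = diag(u_i); the
#' eigenvalues sum to the u-weighted mean OMI.
#'
#' @param P Species x samples matrix of profiles (rows sum to 1).
#' @param Z Samples x variables standardized environment matrix.
#' @param u Species weights summing to 1 (read mass fractions).
#' @return List with `eigenvalues`, `axes` (eigenvectors), `species_scores`
#'   (M projected on the axes), `marginality` (M), and per-species `omi`,
#'   `tol`, `rtol`, `inertia`, `weight`, plus `mean_omi`.
#' @export
omi_core <- function(P, Z, u) {
  P <- as.matrix(P); Z <- as.matrix(Z)
  stopifnot(nrow(Z) == ncol(P), length(u) == nrow(P))
  stopifnot(abs(sum(u) - 1) < 1e-8)
  M <- P %*% Z
  omi <- rowSums(M * M)
  inertia <- as.numeric(P %*% rowSums(Z * Z))
  nrm <- sqrt(omi)
  E <- M / ifelse(nrm > 0, nrm, 1)           # unit marginality directions
  A <- Z %*% t(E)                            # projections, samples x species
  Dev <- sweep(A, 2, nrm, "-")^2
  tol <- colSums(Dev * t(P))
  tol[nrm == 0] <- 0
  rtol <- inertia - omi - tol
  W <- crossprod(M, M * u)
  eig <- eigen(W, symmetric = TRUE)
  list(eigenvalues = eig$values, axes = eig$vectors,
       species_scores = M %*% eig$vectors, marginality = M,
       omi = omi, tol = tol, rtol = rtol, inertia = inertia,
       weight = u, mean_omi = sum(u * omi))
}

# centered/standardized dummy coding of a factor with uniform weights 1/n
.standardized_dummies <- function(f) {
  f <- droplevels(factor(f))
  n <- length(f)
  Z <- sapply(levels(f), function(l) {
    ind <- as.numeric(f == l)
    m <- mean(ind)
    s <- sqrt(mean((ind - m)^2))
    if (s == 0) stop("degenerate period indicator for level ", l)
    (ind - m) / s
  })
  rownames(Z) <- names(f)
  Z
}

#' OMI niche ordination of MOTUs against climatic period
#'
#' Constrained ordination placing each MOTU in the climatic niche space
#' spanned by the period factor. The environment table is the centered,
#' standardized period dummy coding (uniform sample weights 1/n); species
#' profiles are the read distributions of each MOTU across samples; species
#' weights are read mass fractions u_i. For a three-level period factor the
#' environment has rank 2, so two non-null axes are produced.
#'
#' Axis orientation is fixed so that, when the factor uses the standard
#' period labels, the post-LGM sample centroid is negative on axis 1 and
#' the LGM centroid is negative on axis 2; otherwise the species score of
#' largest magnitude is made positive.
#'
#' @param rm Read-count matrix (samples x MOTUs), filtered.
#' @param periods Factor over samples (usually `samples$period`).
#' @return Object of class `paleo_omi`: the [omi_core()] decomposition plus
#'   `sample_scores` (standardized environment projected on the axes),
#'   `periods`, and per-MOTU table `motus`.
#' @export
omi_analysis <- function(rm, periods) {
  rm <- as.matrix(rm)
  periods <- droplevels(factor(periods, levels = c(period_levels(),
                                                   setdiff(unique(as.character(periods)),
                                                           period_levels()))))
  if (nlevels(periods) < 2) stop("need at least 2 periods")
  if (length(periods) != nrow(rm)) stop("periods do not align with samples")
  ytot <- colSums(rm)
  if (any(ytot == 0))
    stop("MOTU(s) with zero total reads: ",
         paste(colnames(rm)[ytot == 0], collapse = ", "))
  P <- t(rm) / ytot
  u <- ytot / sum(ytot)
  Z <- .standardized_dummies(periods)
  core <- omi_core(P, Z, u)
  sample_scores <- Z %*% core$axes
  # deterministic sign convention
  for (a in seq_len(ncol(core$axes))) {
    flip <- FALSE
    if (a == 1 && "post-LGM" %in% levels(periods)) {
      flip <- mean(sample_scores[periods == "post-LGM", 1]) > 0
    } else if (a == 2 && "LGM" %in% levels(periods)) {
      flip <- mean(sample_scores[periods == "LGM", 2]) > 0
    } else {
      ss <- core$species_scores[, a]
      flip <- ss[which.max(abs(ss))] < 0
    }
    if (flip) {
      core$axes[, a] <- -core$axes[, a]
      core$species_scores[, a] <- -core$species_scores[, a]
      sample_scores[, a] <- -sample_scores[, a]
    }
  }
  rownames(core$species_scores) <- colnames(rm)
  motus <- data.frame(motu_id = colnames(rm), omi = core$omi, tol = core$tol,
                      rtol = core$rtol, inertia = core$inertia,
                      weight = core$weight, stringsAsFactors = FALSE)
  structure(c(core, list(sample_scores = sample_scores, periods = periods,
                         motus = motus)),
            class = "paleo_omi")
}

#' @export
print.paleo_omi <- function(x, ...) {
  nn <- sum(x$eigenvalues > 1e-10)
  cat("OMI ordination:", nrow(x$species_scores), "MOTUs,",
      nlevels(x$periods), "periods,", nn, "non-null axes\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues[seq_len(nn)], 4),
                              collapse = ", "), "\n")
  cat("  u-weighted mean OMI:", signif(x$mean_omi, 4), "\n")
  invisible(x)
}

#' Monte Carlo randomization test for mean OMI
#'
#' Tests whether the read-weighted average outlying mean index is greater
#' than expected at random by permuting the sample-to-period assignment as
#' one global row permutation of the environment table (preserving the
#' among-MOTU covariance of the community table) and recomputing the mean
#' OMI; p = (#\{perm >= obs\} + 1) / (n_perm + 1).
#'
#' @inheritParams omi_analysis
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional RNG seed.
#' @param exhaustive Enumerate all n! permutations (n <= 7); the p-value is
#'   then #\{perm >= obs\} / n! including the identity.
#' @return Object of class `omi_randtest`: `obs`, `p`, `n_perm`, `perm`.
#' @export
omi_randtest <- function(rm, periods, n_perm = 999, seed = NULL,
                         exhaustive = FALSE) {
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  rm <- as.matrix(rm)
  periods <- droplevels(factor(periods))
  ytot <- colSums(rm)
  if (any(ytot == 0)) stop("MOTU(s) with zero total reads")
  P <- t(rm) / ytot
  u <- ytot / sum(ytot)
  Z <- .standardized_dummies(periods)
  mean_omi <- function(Zp) {
    M <- P %*% Zp
    sum(u * rowSums(M * M))
  }
  obs <- mean_omi(Z)
  n <- nrow(Z)
  if (exhaustive) {
    if (n > 7) stop("exhaustive enumeration limited to n <= 7")
    Pm <- .all_perms(n)
    perm <- apply(Pm, 1, function(p) mean_omi(Z[p, , drop = FALSE]))
    p <- mean(perm >= obs - 1e-12)
  } else {
    .set_seed(seed)
    perm <- vapply(seq_len(n_perm), function(i) {
      mean_omi(Z[sample.int(n), , drop = FALSE])
    }, numeric(1))
    p <- (sum(perm >= obs - 1e-12) + 1) / (n_perm + 1)
  }
  structure(list(obs = obs, p = p, n_perm = length(perm), perm = perm,
                 exhaustive = exhaustive),
            class = "omi_randtest")
}

#' @export
print.omi_randtest <- function(x, ...) {
  cat(sprintf("OMI randomization test: mean OMI = %.4g, p = %.4g (%d permutations%s)\n",
              x$obs, x$p, x$n_perm, if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' Trait-on-niche PERMANOVA model series
#'
#' Tests the power of each trait to explain MOTU niche positions (the OMI
#' species scores, Euclidean distance) in three sequential-model designs:
#' (i) the trait alone; (ii) growth form entered first, the trait second;
#' (iii) growth form and the non-confounded mutualist traits first, the
#' focal trait last. Mycorrhizal type and mycorrhizal status are strongly
#' associated and partially confounded, so they are never entered in the
#' same model; when the focal trait is pollination or nitrogen fixation,
#' mycorrhizal status represents the mycorrhizal pair among the covariates.
#' Growth form itself is only tested univariately. A focal trait perfectly
#' aliased with its covariates keeps its row with zero df and R2 = 0 (with
#' a warning).
#'
#' @param scores MOTU x axes score matrix (e.g. `fit$species_scores[, 1:2]`).
#' @param traits A `paleo_traits` table covering the MOTUs (trait-complete).
#' @param n_perm,seed Permutation settings.
#' @return Object of class `trait_niche_models`: `summary` data frame
#'   (trait, model, df, R2, F, p of the focal term) and the full
#'   `paleo_permanova` fits in `models`.
#' @export
trait_niche_models <- function(scores, traits, n_perm = 999, seed = NULL) {
  scores <- as.matrix(scores)
  tt <- traits[match(rownames(scores), traits$motu_id), , drop = FALSE]
  if (anyNA(tt$motu_id)) stop("score rows missing from trait table")
  for (tr in trait_names()) {
    if (any(as.character(tt[[tr]]) == "undefined"))
      stop("trait table must be trait-complete (filter first)")
    tt[[tr]] <- droplevels(tt[[tr]])
  }
  d <- dist(scores)
  mutual <- c("myc_type", "myc_status", "n_fix", "pollination")
  confound <- c(myc_type = "myc_status", myc_status = "myc_type")
  .set_seed(seed)
  models <- list()
  rows <- list()
  run <- function(terms, focal, model_label) {
    fit <- tryCatch(permanova(d, tt[, terms, drop = FALSE], terms = terms,
                              n_perm = n_perm),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      if (grepl("aliased", conditionMessage(fit))) {
        warning("focal trait '", focal, "' aliased in model ", model_label,
                "; reported with zero added SS")
        return(data.frame(trait = focal, model = model_label, df = 0L,
                          R2 = 0, F = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      }
      stop(fit)
    }
    models[[paste(model_label, focal, sep = ":")]] <<- fit
    data.frame(trait = focal, model = model_label,
               df = fit$tab[focal, "Df"], R2 = fit$tab[focal, "R2"],
               F = fit$tab[focal, "F"], p = fit$tab[focal, "p"],
               stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- run("growth_form", "growth_form", "univariate")
  for (tr in mutual) {
    rows[[length(rows) + 1L]] <- run(tr, tr, "univariate")
    rows[[length(rows) + 1L]] <- run(c("growth_form", tr), tr, "after_growth_form")
    others <- setdiff(mutual, c(tr, confound[tr]))
    if (!tr %in% names(confound)) others <- setdiff(others, "myc_type")
    rows[[length(rows) + 1L]] <- run(c("growth_form", others, tr), tr,
                                     "after_growth_form_and_traits")
  }
  structure(list(summary = do.call(rbind, rows), models = models),
            class = "trait_niche_models")
}

#' @export
print.trait_niche_models <- function(x, ...) {
  cat("trait-on-niche PERMANOVA series (focal-term statistics):\n")
  s <- x$summary
  s$R2 <- round(s$R2, 3)
  s$F <- signif(s$F, 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Dunn's post-hoc test on one ordination axis
#'
#' Rank-based pairwise comparisons among trait categories using pooled
#' mid-ranks with tie correction: for groups a, b,
#' z_ab = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - T)(1/n_a + 1/n_b)) with
#' T = sum(t^3 - t) / (12 (N - 1)), two-sided normal p-values. When every
#' value is tied the statistic is 0 and p = 1 for all pairs.
#'
#' @param x Numeric vector (e.g. MOTU scores on one OMI axis).
#' @param g Grouping factor (trait categories), each group non-empty.
#' @param adjust p-adjustment method (default `"none"`; `"holm"` available).
#' @return Object of class `dunn_result`: `pairs` (groupA, groupB, z, p,
#'   p_adjusted), `kw_statistic`, `kw_p`, `tie_correction`.
#' @export
dunn_test <- function(x, g, adjust = "none") {
  g <- droplevels(factor(g))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  stopifnot(length(x) == length(g))
  N <- length(x)
  r <- rank(x)  # mid-ranks
  tie_tab <- table(x)
  Tcorr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  varfac <- N * (N + 1) / 12 - Tcorr
  rbar <- tapply(r, g, mean)
  ng <- table(g)
  lv <- levels(g)
  rows <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i >= j) next
    den2 <- varfac * (1 / ng[[i]] + 1 / ng[[j]])
    z <- if (den2 <= 0) 0 else (rbar[[i]] - rbar[[j]]) / sqrt(den2)
    rows[[length(rows) + 1L]] <-
      data.frame(groupA = lv[i], groupB = lv[j], z = z,
                 p = if (z == 0) 1 else 2 * pnorm(-abs(z)),
                 stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  pairs$p_adjusted <- p.adjust(pairs$p, method = adjust)
  kw <- suppressWarnings(kruskal.test(x, g))
  structure(list(pairs = pairs, kw_statistic = as.numeric(kw$statistic),
                 kw_p = kw$p.value, tie_correction = Tcorr, adjust = adjust),
            class = "dunn_result")
}

#' @export
print.dunn_result <- function(x, ...) {
  cat(sprintf("Dunn's test (Kruskal-Wallis chi2 = %.4g, p = %.4g; adjust = %s)\n",
              x$kw_statistic, x$kw_p, x$adjust))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Per-category mean and standard error of axis scores
#'
#' Arithmetic summary used alongside [dunn_test()] to characterize where
#' trait categories sit along an ordination axis.
#'
#' @param x Numeric scores.
#' @param g Grouping factor.
#' @return Data frame with category, n, mean, se (se is `NA` for n = 1).
#' @export
category_axis_means <- function(x, g) {
  g <- droplevels(factor(g))
  data.frame(category = levels(g),
             n = as.integer(table(g)),
             mean = as.numeric(tapply(x, g, mean)),
             se = as.numeric(tapply(x, g, function(v)
               if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)),
             stringsAsFactors = FALSE)
}
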