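#' Great-circle distance matrix between samples
#'
#' Haversine distances on a sphere of radius 6371.0 km.
#'
#' @param samples A `paleo_samples` table, or a data frame with `latitude`,
#'   `longitude` (and optionally `sample_id`) columns.
#' @return Symmetric matrix of distances in km.
#' @export
haversine_matrix <- function(samples) {
  lat <- samples$latitude; lon <- samples$longitude
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude out of [-180, 180]")
  p <- cbind(lon, lat)
  m <- geosphere::distm(p, p,
                        fun = function(a, b) geosphere::distHaversine(a, b, r = 6371000)) / 1000
  ids <- if (!is.null(samples$sample_id)) as.character(samples$sample_id)
         else rownames(samples)
  dimnames(m) <- list(ids, ids)
  m
}

.pair_classes <- function(geo_vec, breaks) {
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be ascending")
  if (breaks[1] > 0) breaks <- c(0, breaks)
  if (is.finite(breaks[length(breaks)])) breaks <- c(breaks, Inf)
  cut(geo_vec, breaks = breaks, right = FALSE, include.lowest = TRUE)
}

#' Mantel correlogram of ecological distance against geographic distance
#'
#' For each geographic distance class the Mantel statistic is the (sign
#' flipped) Pearson correlation, over all sample pairs, between the class
#' indicator and the ecological distances, so that positive r means pairs
#' within the class are ecologically more similar than average (positive
#' spatial autocorrelation). Significance is assessed by joint row/column
#' relabeling of the ecological matrix; p-values receive a progressive Holm
#' adjustment across classes (class k adjusted within classes 1..k).
#'
#' @param eco_d Ecological distance matrix (`dist`/matrix), typically the
#'   residual distances from [residual_distance()].
#' @param geo_d Geographic distance matrix in km (see [haversine_matrix()]).
#' @param breaks Ascending class breaks in km; a leading 0 and trailing Inf
#'   are added if absent. Default anchors 0-200 km and > 2000 km classes.
#' @param n_perm,seed Permutation settings.
#' @return Object of class `mantel_correlogram`: data frame `classes` with
#'   lower, upper, n_pairs, mantel_r, p, p_adjusted.
#' @export
mantel_correlogram <- function(eco_d, geo_d,
                               breaks = c(0, 200, 500, 1000, 2000, Inf),
                               n_perm = 999, seed = NULL) {
  E <- as.matrix(eco_d); Gd <- as.matrix(geo_d)
  n <- nrow(E)
  stopifnot(nrow(Gd) == n)
  up <- .upper_pairs(n)
  geo_vec <- Gd[up]
  cls <- .pair_classes(geo_vec, breaks)
  lv <- levels(cls)
  IND <- sapply(lv, function(l) as.numeric(cls == l))
  eco_vec <- E[up]
  n_pairs <- colSums(IND)
  r_of <- function(v) {
    out <- rep(NA_real_, length(lv))
    for (k in seq_along(lv)) {
      if (n_pairs[k] == 0) next
      if (n_pairs[k] == length(v)) { out[k] <- 0; next }  # constant indicator
      out[k] <- -cor(IND[, k], v)
    }
    out
  }
  r_obs <- r_of(eco_vec)
  .set_seed(seed)
  ge <- numeric(length(lv))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    vp <- E[p, p][up]
    rp <- r_of(vp)
    ge <- ge + (!is.na(rp) & abs(rp) >= abs(r_obs) - 1e-12)
  }
  pval <- ifelse(n_pairs > 0 & n_pairs < length(eco_vec),
                 (ge + 1) / (n_perm + 1), NA_real_)
  tested <- which(!is.na(pval))
  p_adj <- rep(NA_real_, length(lv))
  for (idx in seq_along(tested)) {
    k <- tested[idx]
    p_adj[k] <- p.adjust(pval[tested[seq_len(idx)]], method = "holm")[idx]
  }
  lower <- as.numeric(sub("^\\[|^\\(", "", sapply(strsplit(lv, ","), `[`, 1)))
  upper <- as.numeric(sub("\\)$|\\]$", "", sapply(strsplit(lv, ","), `[`, 2)))
  structure(list(classes = data.frame(class = lv, lower = lower, upper = upper,
                                      n_pairs = as.integer(n_pairs),
                                      mantel_r = r_obs, p = pval,
                                      p_adjusted = p_adj,
                                      stringsAsFactors = FALSE),
                 n = n, n_perm = n_perm),
            class = "mantel_correlogram")
}

#' @export
print.mantel_correlogram <- function(x, ...) {
  cat("Mantel correlogram (", x$n, "samples,", x$n_perm, "permutations)\n")
  print(x$classes, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Multi-scale variance decomposition of trait composition
#'
#' Splits the multivariate variogram of per-sample trait composition into
#' explained and residual components by geographic distance class. The
#' fitted value of a sample is its period's mean composition; per class h,
#' gamma_x(h) = (1 / (2 n_pairs)) sum_(i,j in h) ||x_i - x_j||^2 is computed
#' for the total, fitted and residual parts, and the cross term
#' gamma_total - gamma_fitted - gamma_residual measures scale-dependent
#' trait-environment correlation (near zero when the trait-climate
#' relationship is scale-independent). With a single class covering all
#' pairs the decomposition reduces to the classical between/within
#' (explained/residual) variance partition and the cross term vanishes.
#'
#' @param shares Numeric matrix, samples x variables (e.g. trait shares).
#' @param periods Factor over samples.
#' @param geo_d Geographic distance matrix in km.
#' @param breaks Distance class breaks (km), as in [mantel_correlogram()].
#' @return Object of class `mso_decomposition`: data frame `classes` with
#'   n_pairs, gamma_total, gamma_explained, gamma_residual, cross_term.
#' @export
mso_decomposition <- function(shares, periods, geo_d,
                              breaks = c(0, 200, 500, 1000, 2000, Inf)) {
  X <- as.matrix(shares)
  periods <- droplevels(factor(periods))
  stopifnot(length(periods) == nrow(X))
  Gd <- as.matrix(geo_d)
  n <- nrow(X)
  fit <- apply(X, 2, function(col) ave(col, periods))
  res <- X - fit
  up <- .upper_pairs(n)
  cls <- .pair_classes(Gd[up], breaks)
  sq <- function(M) as.matrix(dist(M))[up]^2
  d2_tot <- sq(X); d2_fit <- sq(fit); d2_res <- sq(res)
  lv <- levels(cls)
  rows <- lapply(lv, function(l) {
    sel <- cls == l
    np <- sum(sel)
    if (np < 1) return(NULL)
    gt <- sum(d2_tot[sel]) / (2 * np)
    gf <- sum(d2_fit[sel]) / (2 * np)
    gr <- sum(d2_res[sel]) / (2 * np)
    data.frame(class = l, n_pairs = np, gamma_total = gt,
               gamma_explained = gf, gamma_residual = gr,
               cross_term = gt - gf - gr, stringsAsFactors = FALSE)
  })
  structure(list(classes = do.call(rbind, rows), n = n),
            class = "mso_decomposition")
}

#' @export
print.mso_decomposition <- function(x, ...) {
  cat("multi-scale variance decomposition (", x$n, "samples)\n")
  print(x$classes, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulation-based type-I error estimate under spatial autocorrelation
#'
#' Simulates null data sets (no period effect) in which each sample's
#' multivariate response is drawn from a spatial Gaussian process with
#' exponential covariance sill * exp(-d / range) plus independent unit
#' nugget noise at the observed coordinates, runs a one-factor PERMANOVA of
#' the simulated responses against the period factor, and reports the
#' fraction of simulations rejecting at `alpha`. With sill = 0 the test
#' should hold its nominal level; autocorrelation aligned with the period
#' geography inflates it.
#'
#' @param samples A `paleo_samples` table (coordinates + period).
#' @param range_km,sill Exponential covariance parameters of the simulated
#'   spatial process (sill in response-variance units; nugget fixed at 1).
#' @param n_sims Number of simulated data sets (> 0).
#' @param n_perm Permutations per PERMANOVA.
#' @param n_dims Response dimensionality.
#' @param alpha Nominal level.
#' @param seed Optional RNG seed.
#' @return Object of class `type1_inflation`: `rate`, binomial `ci`,
#'   `n_sims`, `alpha`.
#' @export
type1_inflation <- function(samples, range_km, sill, n_sims = 500,
                            n_perm = 199, n_dims = 3, alpha = 0.05,
                            seed = NULL) {
  if (n_sims < 1) stop("n_sims must be positive")
  per <- droplevels(factor(samples$period))
  n <- nrow(samples)
  geo <- haversine_matrix(samples)
  Sigma <- sill * exp(-geo / range_km) + diag(n)
  L <- tryCatch(chol(Sigma), error = function(e) {
    warning("covariance not positive definite; jittering diagonal")
    chol(Sigma + diag(1e-6 * max(diag(Sigma)), n))
  })
  .set_seed(seed)
  rej <- 0L
  for (s in seq_len(n_sims)) {
    X <- crossprod(L, matrix(rnorm(n * n_dims), n, n_dims))
    fit <- permanova(dist(X), data.frame(period = per), n_perm = n_perm)
    if (fit$tab["period", "p"] <= alpha) rej <- rej + 1L
  }
  ci <- stats::binom.test(rej, n_sims)$conf.int
  structure(list(rate = rej / n_sims, ci = as.numeric(ci), n_sims = n_sims,
                 alpha = alpha, rejections = rej),
            class = "type1_inflation")
}

#' @export
print.type1_inflation <- function(x, ...) {
  cat(sprintf("PERMANOVA type-I rate at alpha = %.2f: %.3f (95%% CI %.3f-%.3f, %d sims)\n",
              x$alpha, x$rate, x$ci[1], x$ci[2], x$n_sims))
  invisible(x)
}
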