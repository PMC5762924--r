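#' Bray-Curtis dissimilarity
#'
#' d_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk) between non-negative
#' abundance rows; entries lie in [0, 1].
#'
#' @param x Non-negative matrix, samples in rows. All-zero rows are an
#'   error (the sample should have been filtered).
#' @return A `dist` object.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative abundances")
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("all-zero row(s): ",
         paste(if (is.null(rownames(x))) which(rs == 0) else
               rownames(x)[rs == 0], collapse = ", "))
  num <- as.matrix(dist(x, method = "manhattan"))
  den <- outer(rs, rs, "+")
  as.dist(num / den)
}

# Gower-centered inner-product matrix from a distance matrix:
# G = C (-1/2 D*D) C with C = I - 11'/n
.gower_G <- function(d) {
  D <- as.matrix(d)
  A <- -0.5 * D * D
  n <- nrow(A)
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), colMeans(A)) + mean(A)
}

# cumulative hat matrices for a sequential (Type I) model:
# H0 = intercept-only, then one entry per added term
.sequential_hats <- function(data, terms) {
  n <- nrow(data)
  hats <- list(list(H = matrix(1 / n, n, n), rank = 1L))
  for (k in seq_along(terms)) {
    fml <- stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = " + ")))
    X <- model.matrix(fml, data = data)
    hats[[k + 1L]] <- .hat_matrix(X)
  }
  hats
}

#' Permutational multivariate analysis of variance
#'
#' PERMANOVA on a distance matrix with sequential (Type I) sums of squares.
#' The distance matrix is Gower-centered (G = C (-1/2 D o D) C); the sum of
#' squares added by the k-th term is tr(H_k G) - tr(H_{k-1} G) for the
#' nested hat matrices of the cumulative design, the pseudo-F is
#' (SS_term / df_term) / (SS_res / df_res), and p-values come from joint
#' row/column relabelings of D, with ties counted as at least as extreme
#' (p = (#\{F* >= F\} + 1) / (n_perm + 1)). Permutation is free (no strata).
#'
#' @param d A `dist` or symmetric matrix.
#' @param data A `data.frame` of factors/covariates, rows aligned with `d`
#'   (matched by labels when both are named).
#' @param terms Character vector giving the term order; defaults to
#'   `names(data)`.
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @param exhaustive Enumerate all n! relabelings instead of sampling
#'   (n <= 8); the p-value is then the exact fraction #\{F* >= F\} / n!.
#' @return An object of class `paleo_permanova` with an ANOVA-style table
#'   (`tab`: Df, SumOfSqs, R2, F, p per term plus Residual and Total rows).
#' @examples
#' x <- matrix(c(0, 1, 3, 4), ncol = 1)
#' f <- data.frame(g = factor(c("a", "a", "b", "b")))
#' permanova(dist(x), f, exhaustive = TRUE)
#' @export
permanova <- function(d, data, terms = NULL, n_perm = 999, seed = NULL,
                      exhaustive = FALSE) {
  D <- as.matrix(d)
  n <- nrow(D)
  data <- as.data.frame(data)
  if (nrow(data) != n) stop("design rows do not match distance matrix")
  if (!is.null(rownames(D)) && !is.null(rownames(data)) &&
      !all(rownames(data) == as.character(seq_len(n))) &&
      all(rownames(D) %in% rownames(data)))
    data <- data[rownames(D), , drop = FALSE]
  if (is.null(terms)) terms <- names(data)
  for (tm in terms) {
    v <- data[[tm]]
    if (is.character(v)) data[[tm]] <- factor(v)
    if (is.factor(data[[tm]]) && nlevels(droplevels(data[[tm]])) < 2)
      stop("term '", tm, "' has fewer than 2 levels")
  }
  G <- .gower_G(D)
  hats <- .sequential_hats(data, terms)
  ranks <- vapply(hats, `[[`, integer(1), "rank")
  dfs <- diff(ranks)
  if (any(dfs == 0))
    stop("rank-deficient design; aliased term(s): ",
         paste(terms[dfs == 0], collapse = ", "))
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1) stop("no residual degrees of freedom")

  ss_of <- function(Gm) {
    tr <- vapply(hats, function(h) .tr2(h$H, Gm), numeric(1))
    ss_terms <- diff(tr)
    ss_total <- sum(diag(Gm)) - tr[1]
    c(ss_terms, ss_total - sum(ss_terms))
  }
  obs <- ss_of(G)
  k <- length(terms)
  ss_terms <- obs[seq_len(k)]
  ss_res <- obs[k + 1L]
  ss_total <- sum(obs)
  Fobs <- (ss_terms / dfs) / (ss_res / df_res)

  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    P <- .all_perms(n)
    ge <- numeric(k)
    for (r in seq_len(nrow(P))) {
      p <- P[r, ]
      s <- ss_of(G[p, p])
      Fp <- (s[seq_len(k)] / dfs) / (s[k + 1L] / df_res)
      ge <- ge + (Fp >= Fobs - 1e-12)
    }
    pval <- ge / nrow(P)
    n_perm_used <- nrow(P)
  } else {
    .set_seed(seed)
    ge <- numeric(k)
    for (r in seq_len(n_perm)) {
      p <- sample.int(n)
      s <- ss_of(G[p, p])
      Fp <- (s[seq_len(k)] / dfs) / (s[k + 1L] / df_res)
      ge <- ge + (Fp >= Fobs - 1e-12)
    }
    pval <- (ge + 1) / (n_perm + 1)
    n_perm_used <- n_perm
  }

  tab <- data.frame(Df = c(dfs, df_res, n - 1L),
                    SumOfSqs = c(ss_terms, ss_res, ss_total),
                    R2 = c(ss_terms, ss_res, ss_total) / ss_total,
                    F = c(Fobs, NA, NA),
                    p = c(pval, NA, NA),
                    row.names = c(terms, "Residual", "Total"))
  structure(list(tab = tab, n = n, n_perm = n_perm_used, seed = seed,
                 exhaustive = exhaustive, terms = terms),
            class = "paleo_permanova")
}

#' @export
print.paleo_permanova <- function(x, digits = 4, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %s %d permutations)\n",
              if (x$exhaustive) "exhaustive," else "", x$n_perm))
  tab <- x$tab
  tab$SumOfSqs <- signif(tab$SumOfSqs, digits)
  tab$R2 <- round(tab$R2, digits)
  tab$F <- signif(tab$F, digits)
  print(tab, na.print = "")
  invisible(x)
}

#' Pairwise PERMANOVA contrasts with compact letter display
#'
#' Runs a one-factor PERMANOVA on every pair of factor levels (on the
#' corresponding sub-distance-matrix) and summarizes the pattern as a
#' compact letter display: levels share a letter when their pairwise test
#' is not significant at `alpha`. Pairwise p-values are unadjusted by
#' default; `adjust = "holm"` is available.
#'
#' @param d Distance matrix (`dist` or matrix).
#' @param f Grouping factor aligned with `d`.
#' @param n_perm,seed Permutation settings per pair.
#' @param adjust p-adjustment method (see [stats::p.adjust()]).
#' @param alpha Significance level for the letter display.
#' @return Object of class `pairwise_permanova`: `pairs` data frame
#'   (groupA, groupB, F, R2, p, p_adjusted) and `letters`.
#' @export
pairwise_permanova <- function(d, f, n_perm = 999, seed = NULL,
                               adjust = "none", alpha = 0.05) {
  D <- as.matrix(d)
  f <- droplevels(factor(f))
  lv <- levels(f)
  if (length(lv) < 2) stop("factor must have at least 2 levels")
  .set_seed(seed)
  rows <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i >= j) next
    sel <- f %in% lv[c(i, j)]
    if (sum(f == lv[i]) < 2 || sum(f == lv[j]) < 2) {
      warning("level with < 2 samples; skipping pair ", lv[i], " vs ", lv[j])
      next
    }
    sub <- permanova(D[sel, sel, drop = FALSE],
                     data.frame(g = droplevels(f[sel])),
                     n_perm = n_perm)
    rows[[length(rows) + 1L]] <-
      data.frame(groupA = lv[i], groupB = lv[j],
                 F = sub$tab["g", "F"], R2 = sub$tab["g", "R2"],
                 p = sub$tab["g", "p"], stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  pairs$p_adjusted <- p.adjust(pairs$p, method = adjust)
  letters_ <- compact_letters(lv, pairs[, c("groupA", "groupB")],
                              pairs$p_adjusted, alpha = alpha)
  structure(list(pairs = pairs, letters = letters_, alpha = alpha,
                 adjust = adjust),
            class = "pairwise_permanova")
}

#' @export
print.pairwise_permanova <- function(x, ...) {
  cat("pairwise PERMANOVA (adjust =", x$adjust, ", alpha =", x$alpha, ")\n")
  print(x$pairs, row.names = FALSE)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Compact letter display from pairwise significance
#'
#' Insert-and-absorb algorithm: groups share a letter exactly when their
#' pairwise comparison is non-significant.
#'
#' @param groups Character vector of group names.
#' @param pairs Two-column data frame/matrix of compared group pairs.
#' @param p P-value per pair.
#' @param alpha Significance threshold.
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(groups, pairs, p, alpha = 0.05) {
  cols <- list(groups)  # letter columns: sets of mutually-compatible groups
  sig <- which(p < alpha)
  for (s in sig) {
    a <- as.character(pairs[s, 1]); b <- as.character(pairs[s, 2])
    new_cols <- list()
    for (cl in cols) {
      if (a %in% cl && b %in% cl) {
        new_cols <- c(new_cols, list(setdiff(cl, a)), list(setdiff(cl, b)))
      } else new_cols <- c(new_cols, list(cl))
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(new_cols))
    for (u in seq_along(new_cols)) for (v in seq_along(new_cols)) {
      if (u != v && keep[u] && keep[v] &&
          all(new_cols[[u]] %in% new_cols[[v]]) &&
          !(all(new_cols[[v]] %in% new_cols[[u]]) && u < v)) keep[u] <- FALSE
    }
    cols <- new_cols[keep]
  }
  cols <- cols[lengths(cols) > 0]
  # order columns by first group appearance for stable letters
  ord <- order(vapply(cols, function(cl) min(match(cl, groups)), numeric(1)))
  cols <- cols[ord]
  out <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(cols)) {
    for (g in cols[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out
}

#' Residual pairwise distances after projecting out model terms
#'
#' Gower-centers the distance matrix, projects out the fitted space of the
#' design (residual G_r = (I - H) G (I - H)), and re-expresses G_r as
#' pairwise distances d_ij = sqrt(max(0, g_ii + g_jj - 2 g_ij)). Used to
#' feed residual community structure into the Mantel correlogram, mirroring
#' the residual matrix of a distance-based redundancy analysis.
#'
#' @inheritParams permanova
#' @return A `dist` of residual distances.
#' @export
residual_distance <- function(d, data, terms = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  data <- as.data.frame(data)
  if (is.null(terms)) terms <- names(data)
  G <- .gower_G(D)
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  H <- .hat_matrix(model.matrix(fml, data = data))$H
  M <- diag(n) - H
  Gr <- M %*% G %*% M
  g <- diag(Gr)
  D2 <- outer(g, rep(1, n)) + outer(rep(1, n), g) - 2 * Gr
  D2[D2 < 0] <- 0
  out <- sqrt(D2)
  dimnames(out) <- dimnames(D)
  as.dist(out)
}
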