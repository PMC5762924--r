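# tree helpers ---------------------------------------------------------------

# height above the tips of every node of an ultrametric tree
.node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_along(tree$tip.label)]) - depth
}

#' Graft MOTUs onto a backbone phylogeny
#'
#' Places each molecular taxon (MOTU) on an ultrametric backbone species
#' tree. A MOTU consisting of a single species present in the backbone
#' relabels that tip. Any other MOTU is attached as a new terminal branch at
#' the most recent common ancestor of the backbone members of the lowest
#' taxonomic rank (genus, then tribe, subfamily, family) that contains all
#' of its component taxa; the pendant branch length equals that node's
#' height, keeping all tips contemporaneous. When only one member of the
#' containing rank is present in the backbone, the MOTU is attached at the
#' midpoint of that member's terminal branch (again with a height-matching
#' pendant). After all placements, backbone species that do not themselves
#' represent a MOTU are pruned. MOTUs for which no containing rank can be
#' resolved in the tree are collected and reported as one error.
#'
#' @param backbone An ultrametric `phylo` whose tips are species names.
#' @param taxonomy Data frame with columns `species`, `genus`, `tribe`,
#'   `subfamily`, `family` covering the backbone species and the MOTU
#'   component taxa (NA allowed for unknown ranks).
#' @param motu_defs Named list: MOTU id -> character vector of component
#'   species.
#' @return A `phylo` whose tips are exactly the MOTU ids, with attribute
#'   `"placements"`: a data frame of MOTU, rank used and attachment height.
#' @export
graft_motus <- function(backbone, taxonomy, motu_defs) {
  stopifnot(inherits(backbone, "phylo"), is.list(motu_defs))
  need <- c("species", "genus", "tribe", "subfamily", "family")
  if (!all(need %in% names(taxonomy)))
    stop("taxonomy must have columns: ", paste(need, collapse = ", "))
  if (is.null(names(motu_defs)) || anyDuplicated(names(motu_defs)))
    stop("motu_defs must be a uniquely named list")
  tree <- backbone
  ranks <- c("genus", "tribe", "subfamily", "family")
  species_level <- character(0)   # motu -> backbone tip to relabel
  placements <- list()
  unplaceable <- character(0)

  for (motu in names(motu_defs)) {
    members <- as.character(motu_defs[[motu]])
    if (length(members) == 1L && members %in% backbone$tip.label) {
      species_level[motu] <- members
      placements[[motu]] <- data.frame(motu_id = motu, rank = "species",
                                       height = 0, stringsAsFactors = FALSE)
      next
    }
    placed <- FALSE
    for (rk in ranks) {
      vals <- taxonomy[[rk]][match(members, taxonomy$species)]
      if (anyNA(vals) || length(unique(vals)) != 1L) next
      group <- taxonomy$species[!is.na(taxonomy[[rk]]) &
                                  taxonomy[[rk]] == vals[1]]
      present <- intersect(group, tree$tip.label)
      if (length(present) == 0) next
      h <- .node_heights(tree)
      if (length(present) >= 2) {
        node <- ape::getMRCA(tree, present)
        att_h <- h[node]
        tree <- phytools::bind.tip(tree, motu, edge.length = att_h,
                                   where = node, position = 0)
      } else {
        tip <- match(present, tree$tip.label)
        edge_len <- tree$edge.length[tree$edge[, 2] == tip]
        att_h <- edge_len / 2
        tree <- phytools::bind.tip(tree, motu, edge.length = att_h,
                                   where = tip, position = att_h)
      }
      placements[[motu]] <- data.frame(motu_id = motu, rank = rk,
                                       height = att_h,
                                       stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) unplaceable <- c(unplaceable, motu)
  }
  if (length(unplaceable))
    stop("unplaceable MOTU(s): ", paste(unplaceable, collapse = ", "))

  # relabel species-level matches, then prune remaining backbone species
  idx <- match(unname(species_level), tree$tip.label)
  tree$tip.label[idx] <- names(species_level)
  drop <- setdiff(tree$tip.label, names(motu_defs))
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  attr(tree, "placements") <- do.call(rbind, placements)
  tree
}

# profile (ML) negative log-likelihood machinery for Pagel's lambda --------

.lambda_V <- function(C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

.gls_fit <- function(y, X, V) {
  L <- chol(V)
  # whitened regression: solve L' w = v
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  fit <- lm.fit(wX, wy)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  list(beta = beta, rss = rss, logdet = 2 * sum(log(diag(L))),
       XtViX = crossprod(wX))
}

.pgls_negll <- function(lambda, y, X, C) {
  V <- .lambda_V(C, lambda)
  f <- tryCatch(.gls_fit(y, X, V), error = function(e) NULL)
  if (is.null(f)) return(1e10)
  n <- length(y)
  sigma2 <- f$rss / n
  if (sigma2 <= 0) return(1e10)
  0.5 * (n * log(2 * pi * sigma2) + f$logdet + n)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits y = X beta + e with e ~ N(0, sigma^2 V(lambda)), where V(lambda)
#' scales the off-diagonal entries of the phylogenetic covariance matrix
#' (shared branch lengths) by lambda while leaving the diagonal unchanged.
#' lambda is estimated by maximum likelihood over [0, 1] (bounded 1-D
#' optimization of the profile log-likelihood, tolerance 1e-6, with the
#' boundary values checked explicitly). Coefficient standard errors use
#' sigma_hat^2 (X' V^-1 X)^-1 with the unbiased residual scale
#' RSS / (n - p). On a star phylogeny (no shared branches) lambda is
#' unidentifiable; the fit reports the lower bound with a flag and equals
#' ordinary least squares.
#'
#' @param y Named numeric response per tip.
#' @param X Design matrix (include the intercept column yourself), rows
#'   named by tip, or a factor/data.frame to be expanded via
#'   [stats::model.matrix()].
#' @param tree A `phylo` with branch lengths and positive depth.
#' @return Object of class `paleo_pgls`: `beta`, `se`, `lambda`,
#'   `lambda_bound`, `loglik`, `sigma2`, `n`, and `profile` (the profile
#'   log-likelihood function of lambda).
#' @export
pgls_lambda <- function(y, X, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.factor(X) || is.data.frame(X)) {
    X <- model.matrix(~ ., data = as.data.frame(X))
    rownames(X) <- names(y)
  }
  X <- as.matrix(X)
  if (is.null(names(y)) && is.null(rownames(X))) {
    if (length(y) != length(tree$tip.label)) stop("y does not match tree tips")
    names(y) <- tree$tip.label
    rownames(X) <- tree$tip.label
  }
  ord <- match(tree$tip.label, names(y))
  if (anyNA(ord)) stop("tips missing from y")
  y <- y[ord]
  X <- X[match(tree$tip.label, rownames(X)), , drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  C <- ape::vcv(tree)
  if (max(diag(C)) <= 0) stop("tree has no depth")
  n <- length(y)
  p <- ncol(X)
  offmax <- max(abs(C[upper.tri(C)]))
  star <- offmax < 1e-12 * max(diag(C))
  if (star) {
    lambda <- 0; bound <- TRUE
  } else {
    opt <- optimize(.pgls_negll, c(0, 1), y = y, X = X, C = C, tol = 1e-6)
    cand <- c(opt$minimum, 0, 1)
    val <- c(opt$objective, .pgls_negll(0, y, X, C), .pgls_negll(1, y, X, C))
    lambda <- cand[which.min(val)]
    bound <- lambda %in% c(0, 1)
  }
  V <- .lambda_V(C, lambda)
  f <- .gls_fit(y, X, V)
  sigma2_ml <- f$rss / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + f$logdet + n)
  sigma2 <- f$rss / (n - p)
  covb <- sigma2 * solve(f$XtViX)
  profile <- function(l) -.pgls_negll(l, y = y, X = X, C = C)
  structure(list(beta = setNames(as.numeric(f$beta), colnames(X)),
                 se = setNames(sqrt(diag(covb)), colnames(X)),
                 lambda = lambda, lambda_bound = bound, loglik = loglik,
                 sigma2 = sigma2, n = n, profile = profile),
            class = "paleo_pgls")
}

#' @export
print.paleo_pgls <- function(x, ...) {
  cat(sprintf("PGLS with Pagel's lambda: lambda = %.4f%s, logLik = %.3f, n = %d\n",
              x$lambda, if (x$lambda_bound) " (boundary)" else "", x$loglik,
              x$n))
  print(data.frame(estimate = x$beta, se = x$se))
  invisible(x)
}

#' @export
coef.paleo_pgls <- function(object, ...) object$beta

#' Phylogenetic and non-phylogenetic category means of niche scores
#'
#' Mean niche-axis score per trait category, estimated (a) as arithmetic
#' means with conventional standard errors and (b) as the category
#' coefficients of a [pgls_lambda()] fit (cell-means coding, no intercept)
#' under the co-estimated lambda. With lambda at 0 on an ultrametric tree
#' the two estimates coincide; when the trait is phylogenetically clustered
#' the phylogenetic standard errors are typically larger, reflecting the
#' reduced effective sample size.
#'
#' @param scores Named numeric vector of axis scores per tip.
#' @param categories Factor of trait categories aligned with `scores`.
#' @param tree A `phylo` whose tips match `names(scores)`.
#' @return Object of class `category_niche_means`: data frame with
#'   category, n, mean, se, mean_pgls, se_pgls; attribute `lambda`.
#' @export
category_niche_means <- function(scores, categories, tree) {
  g <- droplevels(factor(categories))
  stopifnot(length(scores) == length(g))
  plain <- category_axis_means(scores, g)
  if (any(plain$n == 1))
    plain$se[plain$n == 1] <- NA_real_  # flagged: undefined for n = 1
  X <- model.matrix(~ 0 + g)
  colnames(X) <- levels(g)
  rownames(X) <- names(scores)
  fit <- pgls_lambda(scores, X, tree)
  out <- data.frame(plain,
                    mean_pgls = as.numeric(fit$beta[plain$category]),
                    se_pgls = as.numeric(fit$se[plain$category]),
                    stringsAsFactors = FALSE)
  structure(out, lambda = fit$lambda, class = c("category_niche_means",
                                                "data.frame"))
}

#' @export
print.category_niche_means <- function(x, ...) {
  cat(sprintf("category niche means (lambda = %.4f)\n", attr(x, "lambda")))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
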