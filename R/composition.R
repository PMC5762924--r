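#' Per-sample trait composition
#'
#' Community-weighted trait shares for one trait in every sample. With
#' `weighting = "reads"` the share of a category is its read total divided
#' by the sample read total (a community-weighted mean with read counts as
#' the abundance proxy); with `weighting = "motus"` it is the number of
#' present MOTUs (reads > 0) in the category divided by the number of
#' present MOTUs.
#'
#' @param rm Read-count matrix (samples x MOTUs); must be filtered, i.e. all
#'   MOTUs defined for `trait` and no zero-read samples.
#' @param traits A `paleo_traits` table covering the MOTUs.
#' @param trait Trait name.
#' @param weighting `"reads"` or `"motus"`.
#' @return An object of class `trait_composition`: a samples x categories
#'   share matrix (rows sum to 1) with attributes `trait`, `weighting` and
#'   `unit = "sample"`.
#' @export
sample_trait_shares <- function(rm, traits, trait,
                                weighting = c("reads", "motus")) {
  trait <- match.arg(trait, trait_names())
  weighting <- match.arg(weighting)
  rm <- as.matrix(rm)
  tv <- as.character(traits[[trait]][match(colnames(rm), traits$motu_id)])
  if (anyNA(tv)) stop("MOTUs missing from trait table")
  if (any(tv == "undefined"))
    stop("MOTUs undefined for '", trait, "': filter the dataset first")
  cats <- trait_levels(trait, undefined = FALSE)
  memb <- sapply(cats, function(cc) as.numeric(tv == cc))
  if (weighting == "reads") {
    tot <- rowSums(rm)
    if (any(tot == 0))
      stop("zero-read sample(s): ", paste(rownames(rm)[tot == 0], collapse = ", "))
    shares <- (rm %*% memb) / tot
  } else {
    pres <- (rm > 0) * 1
    tot <- rowSums(pres)
    if (any(tot == 0))
      stop("zero-read sample(s): ", paste(rownames(rm)[tot == 0], collapse = ", "))
    shares <- (pres %*% memb) / tot
  }
  colnames(shares) <- cats
  structure(shares, trait = trait, weighting = weighting, unit = "sample",
            class = c("trait_composition", "matrix", "array"))
}

#' Per-period trait composition
#'
#' Aggregates per-sample shares to climatic periods as the unweighted mean
#' of the per-sample shares within each period (samples are the replication
#' unit, matching the bootstrap), re-normalized to sum to one.
#'
#' @param comp A per-sample `trait_composition` from [sample_trait_shares()].
#' @param samples A `paleo_samples` table assigning each sample a period.
#' @param pooled Use pooled aggregation instead (category totals pooled over
#'   the period's samples before normalizing); not the default.
#' @return A periods x categories `trait_composition` (unit `"period"`).
#' @export
period_trait_shares <- function(comp, samples, pooled = FALSE) {
  stopifnot(inherits(comp, "trait_composition"))
  per <- samples$period[match(rownames(comp), samples$sample_id)]
  if (anyNA(per)) stop("samples missing from sample table")
  per <- droplevels(per)
  if (any(table(per) == 0)) stop("empty period")
  agg <- t(sapply(levels(per), function(p) {
    rows <- comp[per == p, , drop = FALSE]
    if (pooled) colSums(rows) else colMeans(rows)
  }))
  agg <- agg / rowSums(agg)
  structure(agg, trait = attr(comp, "trait"),
            weighting = attr(comp, "weighting"), unit = "period",
            class = c("trait_composition", "matrix", "array"))
}

#' Stratified bootstrap confidence intervals for period trait shares
#'
#' Resamples sample ids with replacement within each climatic period,
#' recomputes the period shares per replicate, and returns percentile
#' intervals (2.5 and 97.5 percent by default, linear-interpolation
#' percentile definition). A period containing a single sample yields
#' degenerate width-zero intervals and is flagged.
#'
#' @param comp A per-sample `trait_composition`.
#' @param samples A `paleo_samples` table.
#' @param B Number of bootstrap replicates (>= 2).
#' @param level Confidence level.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list of class `bootstrap_ci` with matrices `point`, `lower`,
#'   `upper` (periods x categories), the replicate array `replicates`
#'   (B x periods x categories), `B`, `level` and `degenerate` flags.
#' @export
bootstrap_ci <- function(comp, samples, B = 1000, level = 0.95, seed = NULL) {
  stopifnot(inherits(comp, "trait_composition"), B >= 2)
  .set_seed(seed)
  per <- droplevels(samples$period[match(rownames(comp), samples$sample_id)])
  if (anyNA(per)) stop("samples missing from sample table")
  point <- period_trait_shares(comp, samples)
  point <- matrix(as.numeric(point), nrow(point), ncol(point),
                  dimnames = dimnames(point))
  idx_by_period <- split(seq_len(nrow(comp)), per)
  reps <- array(NA_real_, c(B, nrow(point), ncol(point)),
                dimnames = list(NULL, rownames(point), colnames(point)))
  for (b in seq_len(B)) {
    m <- t(vapply(idx_by_period, function(ix) {
      take <- ix[sample.int(length(ix), length(ix), replace = TRUE)]
      colMeans(comp[take, , drop = FALSE])
    }, numeric(ncol(point))))
    reps[b, , ] <- m / rowSums(m)
  }
  alpha <- (1 - level) / 2
  lower <- apply(reps, c(2, 3), quantile, probs = alpha, names = FALSE)
  upper <- apply(reps, c(2, 3), quantile, probs = 1 - alpha, names = FALSE)
  structure(list(point = point, lower = lower, upper = upper,
                 replicates = reps, B = B, level = level,
                 degenerate = lengths(idx_by_period) == 1L,
                 trait = attr(comp, "trait"),
                 weighting = attr(comp, "weighting")),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, digits = 3, ...) {
  cat(sprintf("stratified bootstrap (B = %d, level = %.2f) for %s shares (%s-weighted)\n",
              x$B, x$level, x$trait, x$weighting))
  for (p in rownames(x$point)) {
    cat(" ", p, ":\n")
    for (cc in colnames(x$point)) {
      cat(sprintf("    %-12s %.*f [%.*f, %.*f]\n", cc, digits,
                  x$point[p, cc], digits, x$lower[p, cc], digits,
                  x$upper[p, cc]))
    }
  }
  if (any(x$degenerate))
    cat("  note: degenerate single-sample period(s): ",
        paste(names(x$degenerate)[x$degenerate], collapse = ", "), "\n")
  invisible(x)
}

#' Long-format table of composition estimates
#'
#' @param x A `bootstrap_ci` object.
#' @param ... Unused.
#' @return A `data.frame` with columns period, trait, weighting, category,
#'   point, lower, upper.
#' @export
as.data.frame.bootstrap_ci <- function(x, ...) {
  g <- expand.grid(period = rownames(x$point), category = colnames(x$point),
                   stringsAsFactors = FALSE)
  data.frame(period = g$period, trait = x$trait, weighting = x$weighting,
             category = g$category,
             point = x$point[cbind(g$period, g$category)],
             lower = x$lower[cbind(g$period, g$category)],
             upper = x$upper[cbind(g$period, g$category)],
             stringsAsFactors = FALSE)
}
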