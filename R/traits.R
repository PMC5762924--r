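#' Merge trait tables by source precedence
#'
#' Combines partial trait tables compiled from different literature
#' databases, ordered most-recent-first: each MOTU's value for each trait is
#' taken from the first source that defines it, on the grounds that newer
#' compilations cover, update and correct older ones. Remaining gaps stay
#' `"undefined"`. After merging, the NM type/status consistency rule is
#' checked and violations raise a validation error listing the MOTUs.
#'
#' @param sources List of `data.frame`s, each with a `motu_id` column and any
#'   subset of the five trait columns; ordered most recent first.
#' @return A `paleo_traits` table covering the union of MOTU ids.
#' @export
merge_trait_sources <- function(sources) {
  stopifnot(is.list(sources))
  ids <- unique(unlist(lapply(sources, function(s) as.character(s$motu_id))))
  args <- list(motu_id = ids)
  for (tr in trait_names()) {
    val <- rep("undefined", length(ids))
    for (s in sources) {
      if (!tr %in% names(s)) next
      v <- .canonical_trait(s[[tr]], tr, where = sprintf("source column '%s'", tr))
      m <- match(ids, as.character(s$motu_id))
      cand <- as.character(v)[m]
      take <- val == "undefined" & !is.na(cand) & cand != "undefined"
      val[take] <- cand[take]
    }
    args[[tr]] <- val
  }
  # trait_table() enforces the NM invariant and errors listing the MOTUs
  do.call(trait_table, args)
}

#' Filter a read matrix and trait table for analysis
#'
#' Applies, in a fixed order: (1) removal of rare MOTUs whose total read
#' count across samples is below `min_reads` (default 5, the rare-MOTU
#' omission threshold of the source data set); (2) removal of MOTUs that are
#' `"undefined"` for any of the five traits; (3) removal of samples left
#' with zero reads. An empty result is reported with a warning rather than
#' an error. The operation is idempotent.
#'
#' @param rm Read-count matrix (samples x MOTUs) or a `paleo_dataset`.
#' @param traits A `paleo_traits` table (ignored when `rm` is a dataset).
#' @param min_reads Minimum total reads for a MOTU to be retained.
#' @return A list of class `paleo_filter` with elements `read_matrix`,
#'   `traits` and `report` (a `filter_report` of the removal counts); when
#'   called on a `paleo_dataset`, a filtered `paleo_dataset` with the report
#'   attached as attribute `"filter_report"`.
#' @export
filter_dataset <- function(rm, traits = NULL, min_reads = 5) {
  if (inherits(rm, "paleo_dataset")) {
    ds <- rm
    res <- filter_dataset(ds$read_matrix, ds$traits, min_reads = min_reads)
    tree <- ds$tree
    if (!is.null(tree)) {
      keep <- intersect(tree$tip.label, colnames(res$read_matrix))
      if (length(keep) >= 2) tree <- ape::keep.tip(tree, keep)
    }
    out <- paleo_dataset(res$read_matrix,
                         ds$samples[ds$samples$sample_id %in%
                                      rownames(res$read_matrix), , drop = FALSE],
                         res$traits, tree = tree, taxonomy = ds$taxonomy,
                         truth = ds$truth)
    attr(out, "filter_report") <- res$report
    return(out)
  }
  rm <- as.matrix(rm)
  stopifnot(!is.null(traits))
  if (!all(colnames(rm) %in% traits$motu_id))
    stop("read-matrix MOTUs missing from trait table")
  total_in <- sum(rm)

  rare <- colSums(rm) < min_reads
  rm1 <- rm[, !rare, drop = FALSE]

  tt1 <- traits[match(colnames(rm1), traits$motu_id), , drop = FALSE]
  undef <- Reduce(`|`, lapply(trait_names(),
                              function(tr) as.character(tt1[[tr]]) == "undefined"))
  if (length(undef) == 0) undef <- logical(0)
  rm2 <- rm1[, !undef, drop = FALSE]
  tt2 <- tt1[!undef, , drop = FALSE]

  empty <- rowSums(rm2) == 0
  rm3 <- rm2[!empty, , drop = FALSE]

  if (nrow(rm3) == 0 || ncol(rm3) == 0)
    warning("filtering removed every sample or MOTU")
  report <- structure(list(
    motus_removed_rare = sum(rare),
    motus_removed_undefined = sum(undef),
    samples_removed_empty = sum(empty),
    reads_removed = total_in - sum(rm3),
    motus_in = ncol(rm), motus_out = ncol(rm3),
    samples_in = nrow(rm), samples_out = nrow(rm3),
    reads_in = total_in, reads_out = sum(rm3),
    min_reads = min_reads), class = "filter_report")
  rownames(tt2) <- NULL
  structure(list(read_matrix = rm3, traits = tt2, report = report),
            class = "paleo_filter")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("dataset filter (min_reads =", x$min_reads, "):\n")
  cat(sprintf("  MOTUs: %d -> %d (%d rare, %d trait-incomplete)\n",
              x$motus_in, x$motus_out, x$motus_removed_rare,
              x$motus_removed_undefined))
  cat(sprintf("  samples: %d -> %d (%d emptied)\n", x$samples_in,
              x$samples_out, x$samples_removed_empty))
  cat(sprintf("  reads: %d -> %d (%d removed)\n", x$reads_in, x$reads_out,
              x$reads_removed))
  invisible(x)
}

#' Cramer's V association between two categorical traits
#'
#' Pearson chi-square (no continuity correction) on the contingency table of
#' two traits, scaled to Cramer's V = sqrt(chi2 / (n * (min(r, c) - 1))).
#' Undefined levels are excluded before tabulation by default, matching an
#' analysis restricted to trait-complete taxa.
#'
#' @param traits A `paleo_traits` table.
#' @param trait_a,trait_b Trait names (see [trait_names()]).
#' @param drop_undefined Exclude MOTUs undefined in either trait.
#' @return A list of class `cramer_result`: `v`, `chi2`, `df`, `p`, `n` and
#'   the underlying `table`.
#' @export
cramers_v <- function(traits, trait_a, trait_b, drop_undefined = TRUE) {
  trait_a <- match.arg(trait_a, trait_names())
  trait_b <- match.arg(trait_b, trait_names())
  a <- as.character(traits[[trait_a]])
  b <- as.character(traits[[trait_b]])
  if (drop_undefined) {
    keep <- a != "undefined" & b != "undefined"
    a <- a[keep]; b <- b[keep]
  }
  tab <- table(factor(a), factor(b))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2) stop("trait '", trait_a, "' has a single observed level")
  if (ncol(tab) < 2) stop("trait '", trait_b, "' has a single observed level")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v <- sqrt(as.numeric(ct$statistic) / (n * (min(dim(tab)) - 1)))
  structure(list(v = v, chi2 = as.numeric(ct$statistic),
                 df = as.integer(ct$parameter), p = as.numeric(ct$p.value),
                 n = n, table = tab,
                 traits = c(trait_a, trait_b)),
            class = "cramer_result")
}

#' @export
print.cramer_result <- function(x, ...) {
  cat(sprintf("Cramer's V (%s ~ %s): V = %.3f, chi2 = %.3f, df = %d, n = %d, p = %.4g\n",
              x$traits[1], x$traits[2], x$v, x$chi2, x$df, x$n, x$p))
  invisible(x)
}

#' Pairwise trait-association matrix
#'
#' All pairwise Cramer's V / p-values among the five traits, arranged with V
#' in the upper triangle and p in the lower triangle.
#'
#' @inheritParams cramers_v
#' @return A numeric matrix with traits as rows/columns, V above and p below
#'   the diagonal (`NA` on the diagonal).
#' @export
cramers_v_matrix <- function(traits, drop_undefined = TRUE) {
  tn <- trait_names()
  m <- matrix(NA_real_, length(tn), length(tn), dimnames = list(tn, tn))
  for (i in seq_along(tn)) for (j in seq_along(tn)) {
    if (i >= j) next
    r <- cramers_v(traits, tn[i], tn[j], drop_undefined = drop_undefined)
    m[i, j] <- r$v
    m[j, i] <- r$p
  }
  m
}
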