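#' Inject random classification errors into a trait table
#'
#' Emulates trait-database misclassification: for each susceptible trait
#' (mycorrhizal status, mycorrhizal type excluding ERM, and pollination
#' mode) independently, `round(rate * S)` MOTUs are drawn uniformly without
#' replacement from the eligible pool (for mycorrhizal type, ERM MOTUs are
#' ineligible and ERM is never a reassignment target) and each selected
#' MOTU's category is replaced by a uniform draw from the other permitted
#' categories. ERM assignments and N-fixation are treated as
#' phylogenetically conserved and are never altered.
#'
#' The NM type/status linkage is re-enforced by coupling: a type swap into
#' NM sets the status to NM; a type swap out of NM redraws the status from
#' OM/FM; a status swap into NM (never offered to ERM MOTUs) sets the type
#' to NM, and a status swap out of NM redraws the type from AM/ECM. These
#' coupled edits are consistency enforcement, not counted as reassignments.
#'
#' @param traits A trait-complete `paleo_traits` table.
#' @param rate Error rate in (0, 1).
#' @param seed Optional RNG seed; the perturbation is deterministic given
#'   the seed.
#' @return A perturbed `paleo_traits` table with attribute `"reassigned"`,
#'   a named integer vector of the number of direct reassignments per
#'   susceptible trait.
#' @export
perturb_traits <- function(traits, rate, seed = NULL) {
  stopifnot(rate > 0, rate < 1)
  for (tr in trait_names())
    if (any(as.character(traits[[tr]]) == "undefined"))
      stop("trait table must be trait-complete")
  .set_seed(seed)
  S <- nrow(traits)
  k <- round(rate * S)
  tt <- traits
  ty <- as.character(tt$myc_type)
  st <- as.character(tt$myc_status)
  pol <- as.character(tt$pollination)
  reassigned <- c(myc_status = 0L, myc_type = 0L, pollination = 0L)
  if (k == 0) {
    warning("round(rate * S) = 0; returning the table unchanged")
    attr(tt, "reassigned") <- reassigned
    return(tt)
  }

  # mycorrhizal type: ERM protected on both sides of the swap
  pool <- which(ty != "ERM")
  sel <- pool[sample.int(length(pool), min(k, length(pool)))]
  for (i in sel) {
    alt <- setdiff(c("AM", "ECM", "NM"), ty[i])
    new <- alt[sample.int(length(alt), 1)]
    if (new == "NM") st[i] <- "NM"
    else if (ty[i] == "NM") st[i] <- c("OM", "FM")[sample.int(2, 1)]
    ty[i] <- new
  }
  reassigned["myc_type"] <- length(sel)

  # mycorrhizal status: NM never offered to ERM MOTUs
  sel <- sample.int(S, k)
  for (i in sel) {
    alt <- setdiff(c("OM", "FM", "NM"), st[i])
    if (ty[i] == "ERM") alt <- setdiff(alt, "NM")
    new <- alt[sample.int(length(alt), 1)]
    if (new == "NM") ty[i] <- "NM"
    else if (st[i] == "NM") ty[i] <- c("AM", "ECM")[sample.int(2, 1)]
    st[i] <- new
  }
  reassigned["myc_status"] <- k

  # pollination: binary, the alternative is the other mode
  sel <- sample.int(S, k)
  pol[sel] <- ifelse(pol[sel] == "wind", "insect", "wind")
  reassigned["pollination"] <- k

  tt$myc_type <- factor(ty, levels = trait_levels("myc_type"))
  tt$myc_status <- factor(st, levels = trait_levels("myc_status"))
  tt$pollination <- factor(pol, levels = trait_levels("pollination"))
  .check_nm(tt)
  attr(tt, "reassigned") <- reassigned
  tt
}

#' Robustness of trait composition to trait-database error
#'
#' For each error rate and replicate, perturbs the trait table with
#' [perturb_traits()], recomputes the per-sample read-weighted shares of
#' all five traits, and Pearson-correlates the flattened share vector
#' against the original. Replicates whose share vector is constant are
#' flagged (`NA` correlation).
#'
#' @param rm Filtered read-count matrix.
#' @param traits Matching trait-complete `paleo_traits` table.
#' @param rates Error rates to scan (default 1-20 percent).
#' @param n_reps Replicates per rate.
#' @param seed RNG seed; replicate r at rate index q uses sub-seed
#'   `seed + 1000 * q + r`.
#' @return Object of class `sensitivity_curve`: `draws` data frame (rate,
#'   rep, correlation) and `summary` (rate, median_r, q025, q975).
#' @export
sensitivity_curve <- function(rm, traits, rates = c(0.01, 0.05, 0.1, 0.2),
                              n_reps = 1000, seed = 1) {
  stopifnot(all(rates > 0 & rates < 1), n_reps >= 1)
  orig <- .flat_shares(rm, traits)
  draws <- expand.grid(rep = seq_len(n_reps), rate = rates)[, 2:1]
  draws$correlation <- NA_real_
  for (q in seq_along(rates)) {
    for (r in seq_len(n_reps)) {
      tt <- suppressWarnings(perturb_traits(traits, rates[q],
                                            seed = seed + 1000L * q + r))
      v <- .flat_shares(rm, tt)
      row <- (q - 1L) * n_reps + r
      if (sd(v) > 0 && sd(orig) > 0)
        draws$correlation[row] <- cor(orig, v)
    }
  }
  summ <- do.call(rbind, lapply(rates, function(rt) {
    cc <- draws$correlation[draws$rate == rt]
    data.frame(rate = rt, median_r = stats::median(cc, na.rm = TRUE),
               q025 = quantile(cc, 0.025, na.rm = TRUE, names = FALSE),
               q975 = quantile(cc, 0.975, na.rm = TRUE, names = FALSE),
               n_flagged = sum(is.na(cc)))
  }))
  structure(list(draws = draws, summary = summ, n_reps = n_reps),
            class = "sensitivity_curve")
}

.flat_shares <- function(rm, traits) {
  unlist(lapply(trait_names(), function(tr)
    as.numeric(sample_trait_shares(rm, traits, tr, weighting = "reads"))))
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat("trait-error sensitivity (", x$n_reps, "replicates per rate)\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Re-run the conservative niche model under trait error
#'
#' Perturbs the trait table at the given error rate, re-fits the most
#' conservative trait-on-niche model — mycorrhizal status entered after
#' growth form and the non-confounded mutualist traits, Euclidean PERMANOVA
#' on the OMI species scores — and reports the median focal R-squared and
#' p-value across replicates. The ordination itself does not depend on the
#' traits, so the species scores are held fixed.
#'
#' @param scores MOTU x axes OMI score matrix.
#' @param traits Trait-complete `paleo_traits` table.
#' @param rate Error rate (default 10 percent, the literature estimate of
#'   mycorrhizal misclassification).
#' @param n_reps Replicates.
#' @param n_perm Permutations per PERMANOVA.
#' @param seed RNG seed (sub-seeded per replicate).
#' @return Object of class `sensitivity_rerun`: `median_R2`, `median_p`,
#'   per-replicate `R2` and `p`, `n_failed`.
#' @export
sensitivity_model_rerun <- function(scores, traits, rate = 0.1, n_reps = 100,
                                    n_perm = 199, seed = 1) {
  scores <- as.matrix(scores)
  d <- dist(scores)
  terms <- c("growth_form", "n_fix", "pollination", "myc_status")
  R2 <- p <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      tt <- suppressWarnings(perturb_traits(traits, rate, seed = seed + r))
      tt2 <- tt[match(rownames(scores), tt$motu_id), , drop = FALSE]
      fit <- permanova(d, tt2[, terms], terms = terms, n_perm = n_perm,
                       seed = seed + r)
      c(fit$tab["myc_status", "R2"], fit$tab["myc_status", "p"])
    }, error = function(e) NULL)
    if (!is.null(res)) { R2[r] <- res[1]; p[r] <- res[2] }
  }
  structure(list(median_R2 = stats::median(R2, na.rm = TRUE),
                 median_p = stats::median(p, na.rm = TRUE),
                 R2 = R2, p = p, n_failed = sum(is.na(R2)),
                 rate = rate, n_reps = n_reps),
            class = "sensitivity_rerun")
}

#' @export
print.sensitivity_rerun <- function(x, ...) {
  cat(sprintf("model re-run under %.0f%% trait error (%d reps, %d failed):\n",
              100 * x$rate, x$n_reps, x$n_failed))
  cat(sprintf("  median R2 = %.3f, median p = %.3f\n", x$median_R2,
              x$median_p))
  invisible(x)
}
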