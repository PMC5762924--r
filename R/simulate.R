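#' Marginal trait frequencies of the study taxon list
#'
#' Category probabilities for each trait, taken as the published counts of
#' the 131-MOTU taxon list divided by 131 (e.g. 86 forbs, 86 AM, 58 FM,
#' 9 N-fixers, 87 insect-pollinated).
#'
#' @return Named list of per-trait probability vectors.
#' @export
default_trait_marginals <- function() {
  list(growth_form = c(forb = 86, graminoid = 28, dwarf_shrub = 11,
                       tree_shrub = 6) / 131,
       myc_type = c(AM = 86, ECM = 7, ERM = 10, NM = 28) / 131,
       myc_status = c(OM = 45, FM = 58, NM = 28) / 131,
       n_fix = c(fixer = 9, nonfixer = 122) / 131,
       pollination = c(insect = 87, wind = 44) / 131)
}

#' Default period effects on category abundance
#'
#' Log-fold shifts of category read abundance in the LGM and post-LGM
#' relative to the pre-LGM baseline, chosen to emulate the qualitative
#' pattern of the study record: AM, forb, obligately-mycorrhizal and
#' insect-pollinated abundance declines toward the post-LGM while ECM, NM,
#' woody growth forms, facultative status, N-fixers (post-LGM) and wind
#' pollination increase; N-fixers dip during the LGM.
#'
#' @return Named list: trait -> categories x periods matrix of log effects
#'   (pre-LGM column all zero).
#' @export
default_period_effects <- function() {
  mk <- function(...) {
    v <- list(...)
    m <- do.call(rbind, v)
    colnames(m) <- period_levels()
    m
  }
  list(growth_form = mk(forb = c(0, -0.1, -0.8), graminoid = c(0, 0.1, 0.5),
                        dwarf_shrub = c(0, 0.1, 0.4), tree_shrub = c(0, 0.2, 0.9)),
       myc_type = mk(AM = c(0, -0.4, -0.9), ECM = c(0, 0.6, 1.1),
                     ERM = c(0, 0.1, -0.3), NM = c(0, 0.4, 0.8)),
       myc_status = mk(OM = c(0, -0.4, -0.5), FM = c(0, 0.4, 0.2),
                       NM = c(0, 0.4, 0.8)),
       n_fix = mk(fixer = c(0, -0.7, 0.3), nonfixer = c(0, 0, 0)),
       pollination = mk(insect = c(0, 0, -0.2), wind = c(0, 0, 0.4)))
}

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the structure of the study data set: 216 samples in
#' three climatic periods (145 pre-LGM, 32 LGM, 39 post-LGM) from 21 sites,
#' 131 MOTUs with the published trait marginal frequencies, heavily skewed
#' read counts (Dirichlet-multinomial with small concentration over
#' lognormal sequencing depths), period-dependent composition shifts, and
#' exponentially decaying site-level spatial autocorrelation.
#'
#' @param n_samples_per_period Integer vector (pre-LGM, LGM, post-LGM).
#' @param n_motus Number of MOTUs.
#' @param trait_marginals Per-trait category probabilities (each sums to 1).
#' @param period_effects Per-trait categories x periods log-fold shifts.
#' @param target_shares Optional exact calibration: named list
#'   trait -> (category -> length-3 vector of read-share targets per
#'   period); the generator rescales that category's weight per period so
#'   the expected read-weighted share equals the target exactly.
#' @param overdispersion Dirichlet concentration multiplier (> 0); small
#'   values give the skew typical of metabarcoding read tables.
#' @param reads_meanlog,reads_sdlog Lognormal parameters of per-sample read
#'   totals.
#' @param n_sites Number of sampling sites.
#' @param spatial_range_km,spatial_sill Exponential-covariance range and
#'   sill of the site-level random effect (sill 0 disables it).
#' @param tree_birth_rate,trait_lambda Yule rate and Pagel's lambda for the
#'   companion phylogeny simulation.
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_period = c(145, 32, 39),
                       n_motus = 131,
                       trait_marginals = default_trait_marginals(),
                       period_effects = default_period_effects(),
                       target_shares = NULL,
                       overdispersion = 0.3,
                       reads_meanlog = 8.9, reads_sdlog = 1.5,
                       n_sites = 21,
                       spatial_range_km = 500, spatial_sill = 0.25,
                       tree_birth_rate = 1, trait_lambda = 0.5,
                       seed = 1) {
  stopifnot(length(n_samples_per_period) == 3, all(n_samples_per_period >= 1),
            n_motus >= 2, overdispersion > 0, n_sites >= 2)
  for (tr in names(trait_marginals)) {
    pr <- trait_marginals[[tr]]
    if (abs(sum(pr) - 1) > 1e-8)
      stop("trait_marginals for ", tr, " do not sum to 1")
    if (any(pr < 0)) stop("negative marginal probability for ", tr)
  }
  # infeasible joint constraint: every fixer must be non-NM
  if (!is.null(trait_marginals$n_fix) && !is.null(trait_marginals$myc_type) &&
      trait_marginals$n_fix[["fixer"]] > 1 - trait_marginals$myc_type[["NM"]] + 1e-12)
    stop("infeasible marginals: fixer share exceeds non-NM share")
  structure(list(n_samples_per_period = setNames(as.integer(n_samples_per_period),
                                                 period_levels()),
                 n_motus = as.integer(n_motus),
                 trait_marginals = trait_marginals,
                 period_effects = period_effects,
                 target_shares = target_shares,
                 overdispersion = overdispersion,
                 reads_meanlog = reads_meanlog, reads_sdlog = reads_sdlog,
                 n_sites = as.integer(n_sites),
                 spatial_range_km = spatial_range_km,
                 spatial_sill = spatial_sill,
                 tree_birth_rate = tree_birth_rate,
                 trait_lambda = trait_lambda,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# draw a correlated trait table honouring the hard constraints:
# NM type <-> NM status, and no fixers among NM taxa
.simulate_traits <- function(n, marg) {
  gf_lv <- names(marg$growth_form)
  gf <- sample(gf_lv, n, replace = TRUE, prob = marg$growth_form)

  # mycorrhizal type conditional on growth form: woody taxa biased toward
  # ECM/ERM; forb/graminoid conditionals solved so the marginal is matched
  ty_lv <- names(marg$myc_type)
  cond <- rbind(tree_shrub  = c(AM = 0.20, ECM = 0.55, ERM = 0.20, NM = 0.05),
                dwarf_shrub = c(AM = 0.25, ECM = 0.15, ERM = 0.50, NM = 0.10))
  p_woody <- marg$growth_form[c("tree_shrub", "dwarf_shrub")]
  herb_share <- 1 - sum(p_woody)
  herb_target <- marg$myc_type -
    (p_woody[["tree_shrub"]] * cond["tree_shrub", ty_lv] +
       p_woody[["dwarf_shrub"]] * cond["dwarf_shrub", ty_lv])
  herb_target <- pmax(herb_target, 0.005)
  herb_target <- herb_target / sum(herb_target) # renormalize; herb_share cancels
  ty <- character(n)
  for (i in seq_len(n)) {
    pr <- if (gf[i] %in% rownames(cond)) cond[gf[i], ty_lv] else herb_target
    ty[i] <- sample(ty_lv, 1, prob = pr)
  }

  # status: forced NM when type is NM; otherwise OM/FM with an OM bias for
  # ECM/ERM taxa (obligate symbionts are over-represented among them)
  st <- character(n)
  nonNM <- marg$myc_status[c("OM", "FM")]
  nonNM <- nonNM / sum(nonNM)
  for (i in seq_len(n)) {
    if (ty[i] == "NM") st[i] <- "NM"
    else {
      pr <- if (ty[i] %in% c("ECM", "ERM"))
        c(OM = 0.65, FM = 0.35) else nonNM
      st[i] <- sample(c("OM", "FM"), 1, prob = pr)
    }
  }

  # N fixation: fixers drawn only among non-NM taxa
  nf <- rep("nonfixer", n)
  eligible <- which(ty != "NM")
  p_fix_eff <- marg$n_fix[["fixer"]] * n / max(length(eligible), 1)
  fix <- eligible[runif(length(eligible)) < p_fix_eff]
  nf[fix] <- "fixer"

  # pollination conditional on growth form (graminoids wind-pollinated)
  pol_cond <- c(forb = 0.15, graminoid = 0.90, dwarf_shrub = 0.50,
                tree_shrub = 0.70)  # P(wind | growth form)
  pol <- ifelse(runif(n) < pol_cond[gf], "wind", "insect")

  trait_table(sprintf("motu%03d", seq_len(n)), growth_form = gf,
              myc_type = ty, myc_status = st, n_fix = nf, pollination = pol)
}

#' Simulate a dataset with the study's statistical structure
#'
#' Draws a trait-correlated MOTU list, period-specific expected read
#' profiles (baseline lognormal MOTU weights times the exponentiated sum of
#' the per-trait period effects over each MOTU's categories), site-level
#' spatially autocorrelated tilts, and per-sample Dirichlet-multinomial
#' read counts over lognormal sequencing depths, plus a companion Yule
#' phylogeny with a Brownian trait under the configured Pagel's lambda.
#' Identical seeds give bit-identical datasets.
#'
#' @param config A [sim_config()].
#' @return A `paleo_dataset` whose `truth` element records the generative
#'   parameters: `pi` (periods x MOTUs expected profiles), per-trait
#'   `expected_shares` (periods x categories, the analytic read-weighted
#'   trait shares), site coordinates and effects, and the config.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_motus
  periods <- period_levels()
  npp <- config$n_samples_per_period

  traits <- .simulate_traits(K, config$trait_marginals)

  base_w <- rlnorm(K, 0, 1)
  logw <- matrix(rep(log(base_w), 3), nrow = 3, byrow = TRUE,
                 dimnames = list(periods, traits$motu_id))
  for (tr in names(config$period_effects)) {
    eff <- config$period_effects[[tr]]
    cat_i <- as.character(traits[[tr]])
    ok <- cat_i %in% rownames(eff)
    for (p in periods)
      logw[p, ok] <- logw[p, ok] + eff[cat_i[ok], p]
  }
  w <- exp(logw)

  # optional exact calibration of read-share targets for chosen categories
  if (!is.null(config$target_shares)) {
    for (tr in names(config$target_shares)) {
      for (cc in names(config$target_shares[[tr]])) {
        tgt <- config$target_shares[[tr]][[cc]]
        stopifnot(length(tgt) == 3, all(tgt > 0), all(tgt < 1))
        inset <- as.character(traits[[tr]]) == cc
        if (!any(inset) || all(inset))
          stop("cannot calibrate '", cc, "': category empty or universal")
        for (pi_ in seq_along(periods)) {
          p <- periods[pi_]
          s_in <- sum(w[p, inset]); s_out <- sum(w[p, !inset])
          w[p, inset] <- w[p, inset] * tgt[pi_] / (1 - tgt[pi_]) * s_out / s_in
        }
      }
    }
  }
  pi_mat <- w / rowSums(w)

  # sites on a high-latitude transect; exponential-covariance site effects
  site_lat <- runif(config$n_sites, 60, 72)
  site_lon <- runif(config$n_sites, -179, 179)
  site_d <- haversine_matrix(data.frame(sample_id = paste0("site", seq_len(config$n_sites)),
                                        latitude = site_lat, longitude = site_lon))
  if (config$spatial_sill > 0) {
    Sg <- config$spatial_sill * exp(-site_d / config$spatial_range_km) +
      diag(1e-8, config$n_sites)
    g <- as.numeric(.rmvnorm(1, Sg))
  } else g <- rep(0, config$n_sites)
  loading <- rnorm(K)

  n <- sum(npp)
  per <- factor(rep(periods, npp), levels = periods)
  site_of <- sample.int(config$n_sites, n, replace = TRUE)
  age <- numeric(n)
  age[per == "pre-LGM"] <- runif(npp[1], 25.001, 50)
  age[per == "LGM"] <- runif(npp[2], 15.001, 25)
  age[per == "post-LGM"] <- runif(npp[3], 0, 15)
  samples <- sample_table(sprintf("s%03d", seq_len(n)),
                          paste0("site", site_of),
                          site_lat[site_of], site_lon[site_of], age)

  depth <- pmax(50L, as.integer(round(rlnorm(n, config$reads_meanlog,
                                             config$reads_sdlog))))
  rmx <- matrix(0L, n, K, dimnames = list(samples$sample_id, traits$motu_id))
  for (j in seq_len(n)) {
    wj <- pi_mat[as.character(per[j]), ] * exp(g[site_of[j]] * loading)
    pj <- .rdirichlet(config$overdispersion * K * wj / sum(wj))
    rmx[j, ] <- as.integer(rmultinom(1, depth[j], pj))
  }

  sim_tree <- simulate_tree(K, birth_rate = config$tree_birth_rate,
                            trait_lambda = config$trait_lambda)
  sim_tree$tree$tip.label <- traits$motu_id[as.integer(sub("^t", "",
                                                           sim_tree$tree$tip.label))]
  taxonomy <- data.frame(species = traits$motu_id,
                         genus = paste0("genus", (seq_len(K) - 1L) %/% 3L),
                         tribe = paste0("tribe", (seq_len(K) - 1L) %/% 9L),
                         subfamily = paste0("subfam", (seq_len(K) - 1L) %/% 18L),
                         family = paste0("family", (seq_len(K) - 1L) %/% 36L),
                         stringsAsFactors = FALSE)

  expected_shares <- lapply(trait_names(), function(tr) {
    cats <- trait_levels(tr, undefined = FALSE)
    sh <- sapply(cats, function(cc)
      rowSums(pi_mat[, as.character(traits[[tr]]) == cc, drop = FALSE]))
    matrix(sh, nrow = 3, dimnames = list(periods, cats))
  })
  names(expected_shares) <- trait_names()

  truth <- list(pi = pi_mat, expected_shares = expected_shares,
                site_effects = g, site_latitude = site_lat,
                site_longitude = site_lon, site_distance_km = site_d,
                motu_loading = loading, config = unclass(config))
  paleo_dataset(rmx, samples, traits, tree = sim_tree$tree,
                taxonomy = taxonomy, truth = truth)
}

#' Simulate an ultrametric tree and a Brownian trait under Pagel's lambda
#'
#' Draws a Yule (pure-birth) tree conditioned on `n_tips` tips, then a
#' continuous character from a multivariate normal with covariance equal to
#' the lambda-transformed shared-branch-length matrix (off-diagonals scaled
#' by `trait_lambda`). With `trait_lambda = 0` tip values are independent.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate of the Yule process.
#' @param trait_lambda Pagel's lambda in [0, 1] used for the trait.
#' @param sigma2 Brownian rate.
#' @param seed Optional RNG seed.
#' @return List with `tree` (ultrametric `phylo`) and `trait` (named
#'   vector).
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, trait_lambda = 1,
                          sigma2 = 1, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  stopifnot(trait_lambda >= 0, trait_lambda <= 1)
  .set_seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  C <- ape::vcv(tree)
  V <- .lambda_V(C, trait_lambda) * sigma2
  x <- as.numeric(.rmvnorm(1, V + diag(1e-10, n_tips)))
  names(x) <- tree$tip.label
  list(tree = tree, trait = x)
}

#' Synthetic backbone tree, taxonomy and MOTU definitions for grafting
#'
#' Builds an ultrametric backbone species phylogeny with a nested
#' genus/tribe/subfamily/family taxonomy that supports a configurable
#' number of MOTUs at each attachment level: single-species matches plus
#' MOTUs whose lowest containing rank is a genus, tribe, subfamily or
#' family (two component species spanning the rank in each case). The
#' defaults are the attachment-level counts of the study phylogeny
#' (26 species-level, 75 genus, 7 tribe, 5 subfamily and 18 family MOTUs).
#' This is a synthetic stand-in for the published backbone supertree, which
#' is not shipped.
#'
#' @param n_species,n_genus,n_tribe,n_subfamily,n_family MOTU counts per
#'   attachment level.
#' @param seed Unused placeholder for interface stability (the construction
#'   is deterministic).
#' @return List with `tree` (`phylo`), `taxonomy` (data frame) and
#'   `motu_defs` (named list), ready for [graft_motus()].
#' @export
simulate_backbone <- function(n_species = 26, n_genus = 75, n_tribe = 7,
                              n_subfamily = 5, n_family = 18, seed = NULL) {
  # one family block per MOTU, each containing the species that make the
  # MOTU resolvable at exactly the intended rank
  fam_id <- 0L
  taxo <- list(); motu_defs <- list()
  blocks <- list()   # per block: newick fragment (no root edge) + crown height
  h <- c(genus = 1, tribe = 2, subfamily = 3, family = 4, root = 5)
  sp <- function(fam, k) sprintf("sp_f%03d_%d", fam, k)
  block <- function(level, motu) {
    fam_id <<- fam_id + 1L
    f <- sprintf("fam%03d", fam_id)
    s1 <- sp(fam_id, 1); s2 <- sp(fam_id, 2)
    tx <- data.frame(species = c(s1, s2),
                     genus = paste0(f, c("_g1", "_g1")),
                     tribe = paste0(f, c("_t1", "_t1")),
                     subfamily = paste0(f, c("_sf1", "_sf1")),
                     family = f, stringsAsFactors = FALSE)
    if (level == "species") {
      taxo[[length(taxo) + 1L]] <<- tx[1, ]
      motu_defs[[motu]] <<- s1
      blocks[[length(blocks) + 1L]] <<- list(nwk = s1, height = 0)
      return(invisible(NULL))
    }
    # split the two species at the first rank ABOVE the target rank's node,
    # so `level` is the lowest rank containing both
    if (level == "tribe") tx$genus <- paste0(f, c("_g1", "_g2"))
    if (level == "subfamily") {
      tx$genus <- paste0(f, c("_g1", "_g2"))
      tx$tribe <- paste0(f, c("_t1", "_t2"))
    }
    if (level == "family") {
      tx$genus <- paste0(f, c("_g1", "_g2"))
      tx$tribe <- paste0(f, c("_t1", "_t2"))
      tx$subfamily <- paste0(f, c("_sf1", "_sf2"))
    }
    join_h <- h[[level]]
    taxo[[length(taxo) + 1L]] <<- tx
    motu_defs[[motu]] <<- c(s1, s2)
    blocks[[length(blocks) + 1L]] <<- list(nwk = sprintf("(%s:%g,%s:%g)",
                                                         s1, join_h, s2, join_h),
                                           height = join_h)
    invisible(NULL)
  }
  counts <- c(species = n_species, genus = n_genus, tribe = n_tribe,
              subfamily = n_subfamily, family = n_family)
  m <- 0L
  for (lv in names(counts)) for (k in seq_len(counts[[lv]])) {
    m <- m + 1L
    block(lv, sprintf("motu%03d", m))
  }
  if (length(blocks) < 2) stop("need at least 2 MOTUs to build a backbone")
  # fold the family blocks into a balanced binary supertree, joining pairs
  # at successively greater heights so the whole tree stays ultrametric
  level_h <- h[["root"]]
  while (length(blocks) > 1) {
    nxt <- list()
    for (k in seq(1, length(blocks), by = 2)) {
      if (k == length(blocks)) { nxt[[length(nxt) + 1L]] <- blocks[[k]]; next }
      a <- blocks[[k]]; b <- blocks[[k + 1L]]
      nxt[[length(nxt) + 1L]] <-
        list(nwk = sprintf("(%s:%g,%s:%g)", a$nwk, level_h - a$height,
                           b$nwk, level_h - b$height),
             height = level_h)
    }
    blocks <- nxt
    level_h <- level_h + 1
  }
  tree <- ape::read.tree(text = paste0(blocks[[1L]]$nwk, ";"))
  list(tree = tree, taxonomy = do.call(rbind, taxo), motu_defs = motu_defs)
}
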