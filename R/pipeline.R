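#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end on a dataset (simulated from a
#' config, or read from files): filtering, trait associations, composition
#' with bootstrap intervals, PERMANOVA on each trait's composition with
#' pairwise contrasts, OMI ordination with randomization test, trait-niche
#' models and Dunn's tests, spatial diagnostics, phylogenetic category
#' means, and the trait-error sensitivity scan. Each stage writes CSV
#' outputs under `out_dir` and is checksummed into a JSON manifest; a stage
#' failure is recorded and its dependents skipped. Per-stage sub-seeds are
#' derived from the master seed as `seed + stage index`.
#'
#' @param config A list (or YAML file path) with elements: either
#'   `simulate` (arguments for [sim_config()]) or `input` (paths for
#'   [read_dataset()]); optional `stages` (character vector to run, default
#'   all); `seed`; `n_perm`; `B`; `rates`; `out_dir`.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% tempfile("paleotrait_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  n_perm <- config$n_perm %||% 999L
  B <- config$B %||% 1000L
  rates <- config$rates %||% c(0.01, 0.05, 0.1, 0.2)
  all_stages <- c("filter", "traits", "composition", "permanova", "omi",
                  "spatial", "phylo", "sensitivity")
  stages <- config$stages %||% all_stages
  manifest <- list(package = "paleotrait",
                   version = as.character(utils::packageVersion("paleotrait")),
                   seed = seed, n_perm = n_perm, B = B,
                   out_dir = out_dir, stages = list())
  state <- new.env()

  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE, eol = "\n", quote = FALSE,
              fileEncoding = "UTF-8")
    path
  }
  note <- function(stage, status, files = character(0), t0 = NULL) {
    manifest$stages[[stage]] <<- list(
      status = status,
      seconds = if (is.null(t0)) NA else
        round(as.numeric(proc.time()[3] - t0), 2),
      files = as.list(basename(files)),
      checksums = as.list(unname(tools::md5sum(files))))
  }
  run_stage <- function(stage, deps, fn) {
    if (!stage %in% stages) { note(stage, "skipped (toggled off)"); return() }
    if (!all(vapply(deps, function(d)
      identical(manifest$stages[[d]]$status, "ok"), logical(1)))) {
      note(stage, "skipped (failed dependency)")
      return()
    }
    t0 <- proc.time()[3]
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) note(stage, paste("failed:", conditionMessage(res)),
                                     t0 = t0)
    else note(stage, "ok", files = res, t0 = t0)
  }

  # input ---------------------------------------------------------------
  ds <- if (!is.null(config$input)) {
    do.call(read_dataset, config$input)
  } else {
    simulate_dataset(do.call(sim_config,
                             c(config$simulate %||% list(),
                               if (is.null(config$simulate$seed))
                                 list(seed = seed))))
  }
  write_dataset(ds, file.path(out_dir, "input"))

  run_stage("filter", character(0), function() {
    state$ds <- filter_dataset(ds)
    rep_ <- attr(state$ds, "filter_report")
    wcsv(data.frame(metric = names(unclass(rep_)),
                    value = unlist(unclass(rep_))), "filter_report.csv")
  })
  run_stage("traits", "filter", function() {
    m <- cramers_v_matrix(state$ds$traits)
    wcsv(data.frame(trait = rownames(m), m, check.names = FALSE),
         "trait_associations.csv")
  })
  run_stage("composition", "filter", function() {
    files <- character(0)
    rows <- list()
    for (tr in trait_names()) for (wt in c("reads", "motus")) {
      comp <- sample_trait_shares(state$ds$read_matrix, state$ds$traits, tr, wt)
      ci <- bootstrap_ci(comp, state$ds$samples, B = B, seed = seed + 3L)
      rows[[paste(tr, wt)]] <- as.data.frame(ci)
    }
    files <- wcsv(do.call(rbind, rows), "composition.csv")
    files
  })
  run_stage("permanova", "filter", function() {
    rows <- list(); prs <- list()
    for (tr in trait_names()) for (wt in c("reads", "motus")) {
      comp <- sample_trait_shares(state$ds$read_matrix, state$ds$traits, tr, wt)
      d <- bray_curtis(unclass(comp))
      fit <- permanova(d, data.frame(period = state$ds$samples$period),
                       n_perm = n_perm, seed = seed + 4L)
      pw <- pairwise_permanova(d, state$ds$samples$period, n_perm = n_perm,
                               seed = seed + 4L)
      rows[[paste(tr, wt)]] <- data.frame(
        trait = tr, weighting = wt,
        R2 = fit$tab["period", "R2"], p = fit$tab["period", "p"],
        letters = paste(pw$letters, collapse = "/"))
    }
    wcsv(do.call(rbind, rows), "permanova_periods.csv")
  })
  run_stage("omi", "filter", function() {
    fit <- omi_analysis(state$ds$read_matrix, state$ds$samples$period)
    state$omi <- fit
    rt <- omi_randtest(state$ds$read_matrix, state$ds$samples$period,
                       n_perm = n_perm, seed = seed + 5L)
    nax <- max(1L, sum(fit$eigenvalues > 1e-10))
    state$scores <- fit$species_scores[, seq_len(nax), drop = FALSE]
    tnm <- trait_niche_models(state$scores, state$ds$traits, n_perm = n_perm,
                              seed = seed + 5L)
    dunns <- do.call(rbind, lapply(trait_names(), function(tr) {
      dd <- dunn_test(state$scores[, 1],
                      state$ds$traits[[tr]][match(rownames(state$scores),
                                                  state$ds$traits$motu_id)])
      data.frame(trait = tr, dd$pairs)
    }))
    c(wcsv(data.frame(motu_id = rownames(fit$species_scores),
                      fit$motus[, -1], fit$species_scores[, seq_len(nax),
                                                          drop = FALSE]),
           "omi_scores.csv"),
      wcsv(data.frame(mean_omi = rt$obs, p = rt$p, n_perm = rt$n_perm),
           "omi_randtest.csv"),
      wcsv(tnm$summary, "trait_niche_models.csv"),
      wcsv(dunns, "dunn_axis1.csv"))
  })
  run_stage("spatial", "filter", function() {
    geo <- haversine_matrix(state$ds$samples)
    comp <- sample_trait_shares(state$ds$read_matrix, state$ds$traits,
                                "myc_status", "reads")
    d <- bray_curtis(state$ds$read_matrix)
    rd <- residual_distance(d, data.frame(period = state$ds$samples$period))
    mc <- mantel_correlogram(rd, geo, n_perm = n_perm, seed = seed + 6L)
    mso <- mso_decomposition(unclass(comp), state$ds$samples$period, geo)
    c(wcsv(mc$classes, "mantel_correlogram.csv"),
      wcsv(mso$classes, "mso_decomposition.csv"))
  })
  run_stage("phylo", "omi", function() {
    tree <- state$ds$tree
    if (is.null(tree)) stop("dataset has no phylogeny")
    sc <- state$scores[tree$tip.label, 1]
    g <- state$ds$traits$myc_status[match(tree$tip.label,
                                          state$ds$traits$motu_id)]
    cm <- category_niche_means(sc, g, tree)
    wcsv(data.frame(as.data.frame(cm), lambda = attr(cm, "lambda")),
         "phylo_category_means.csv")
  })
  run_stage("sensitivity", "omi", function() {
    sc <- sensitivity_curve(state$ds$read_matrix, state$ds$traits,
                            rates = rates,
                            n_reps = config$sensitivity_reps %||% 100L,
                            seed = seed + 7L)
    rr <- sensitivity_model_rerun(state$scores, state$ds$traits,
                                  n_reps = config$rerun_reps %||% 30L,
                                  n_perm = n_perm, seed = seed + 7L)
    c(wcsv(sc$summary, "sensitivity_curve.csv"),
      wcsv(data.frame(rate = rr$rate, median_R2 = rr$median_R2,
                      median_p = rr$median_p, n_failed = rr$n_failed),
           "sensitivity_rerun.csv"))
  })

  manifest$input_checksums <- as.list(unname(tools::md5sum(
    list.files(file.path(out_dir, "input"), full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
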