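#' Canonical trait vocabulary
#'
#' The package works with five categorical plant traits: growth form,
#' mycorrhizal type, mycorrhizal status, symbiotic nitrogen fixation and
#' pollination mode. Every trait carries an explicit `"undefined"` level for
#' taxa that could not be classified; undefined taxa are removed by
#' [filter_dataset()], never silently at parse time.
#'
#' @return `trait_names()` returns the five trait column names.
#'   `trait_levels()` returns the canonical levels of one trait.
#' @param trait One of `"growth_form"`, `"myc_type"`, `"myc_status"`,
#'   `"n_fix"`, `"pollination"`.
#' @param undefined Include the `"undefined"` level?
#' @export
trait_names <- function() names(.trait_levels)

.trait_levels <- list(
  growth_form = c("forb", "graminoid", "dwarf_shrub", "tree_shrub"),
  myc_type    = c("AM", "ECM", "ERM", "NM"),
  myc_status  = c("OM", "FM", "NM"),
  n_fix       = c("fixer", "nonfixer"),
  pollination = c("insect", "wind")
)

#' @rdname trait_names
#' @export
trait_levels <- function(trait, undefined = TRUE) {
  trait <- match.arg(trait, trait_names())
  lv <- .trait_levels[[trait]]
  if (undefined) c(lv, "undefined") else lv
}

#' Climatic-period labels
#'
#' Three-period classification of the last ~50 ka used throughout:
#' pre-LGM (> 25 ka BP), LGM (25 to 15 ka BP) and post-LGM (< 15 ka BP).
#'
#' @return Character vector of the period labels, oldest first.
#' @export
period_levels <- function() c("pre-LGM", "LGM", "post-LGM")

#' Assign samples to climatic periods from their age
#'
#' Ages above 25 ka BP map to pre-LGM, ages in (15, 25] to LGM and ages in
#' [0, 15] to post-LGM. The source classification states the LGM as "25 to
#' 15 ka BP" without closing the interval ends; this implementation fixes a
#' half-open convention (upper bound included) so that the map is a total,
#' monotone step function of age.
#'
#' @param age Numeric vector of sample ages in ka BP (thousand calibrated
#'   years before present); must be non-negative.
#' @return Factor with levels `period_levels()`.
#' @examples
#' assign_period(c(50, 25, 15, 0))
#' @export
assign_period <- function(age) {
  if (!is.numeric(age)) stop("`age` must be numeric (ka BP)")
  if (anyNA(age) || any(age < 0)) stop("`age` must be non-negative and non-missing")
  lab <- ifelse(age > 25, "pre-LGM", ifelse(age > 15, "LGM", "post-LGM"))
  factor(lab, levels = period_levels())
}

# normalize one vector of trait values to canonical levels; `where` is used
# in error messages to name the offending cells
.canonical_trait <- function(x, trait, where = "trait table") {
  lv <- trait_levels(trait)
  x <- as.character(x)
  x[is.na(x) | trimws(x) == ""] <- "undefined"
  xt <- trimws(x)
  idx <- match(tolower(xt), tolower(lv))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop(sprintf("unknown %s level(s) in %s: %s", trait, where,
                 paste(sprintf("row %d = '%s'", bad, xt[bad]), collapse = ", ")))
  }
  factor(lv[idx], levels = lv)
}

# NM is a level of both mycorrhizal traits and must agree wherever both are
# defined; returns character vector of offending ids (empty when consistent)
.nm_conflicts <- function(traits) {
  ty <- as.character(traits$myc_type)
  st <- as.character(traits$myc_status)
  both <- ty != "undefined" & st != "undefined"
  bad <- both & ((ty == "NM") != (st == "NM"))
  as.character(traits$motu_id[bad])
}

.check_nm <- function(traits) {
  bad <- .nm_conflicts(traits)
  if (length(bad))
    stop("NM mycorrhizal type/status conflict for MOTU(s): ",
         paste(bad, collapse = ", "))
  invisible(traits)
}

#' Construct and validate a trait table
#'
#' @param motu_id Character vector of unique MOTU identifiers.
#' @param growth_form,myc_type,myc_status,n_fix,pollination Trait values;
#'   matched case-insensitively and whitespace-trimmed against the canonical
#'   levels (see [trait_levels()]). Missing or empty cells become
#'   `"undefined"`.
#' @return A `data.frame` of class `paleo_traits` with factor columns.
#' @export
trait_table <- function(motu_id, growth_form = "undefined",
                        myc_type = "undefined", myc_status = "undefined",
                        n_fix = "undefined", pollination = "undefined") {
  motu_id <- as.character(motu_id)
  if (anyDuplicated(motu_id)) stop("duplicate motu_id values")
  n <- length(motu_id)
  tt <- data.frame(motu_id = motu_id, stringsAsFactors = FALSE)
  vals <- list(growth_form = growth_form, myc_type = myc_type,
               myc_status = myc_status, n_fix = n_fix, pollination = pollination)
  for (tr in trait_names()) {
    v <- rep_len(vals[[tr]], n)
    tt[[tr]] <- .canonical_trait(v, tr, where = sprintf("column '%s'", tr))
  }
  .check_nm(tt)
  class(tt) <- c("paleo_traits", "data.frame")
  tt
}

#' Construct a sample metadata table
#'
#' @param sample_id Unique sample identifiers.
#' @param site_id Site identifiers (samples nest within sites).
#' @param latitude,longitude Coordinates in decimal degrees.
#' @param age Sample age in ka BP; the climatic period is derived with
#'   [assign_period()] unless supplied and consistent.
#' @param period Optional period factor; validated against `age`.
#' @return A `data.frame` of class `paleo_samples`.
#' @export
sample_table <- function(sample_id, site_id, latitude, longitude, age,
                         period = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id values")
  if (any(latitude < -90 | latitude > 90)) stop("latitude out of [-90, 90]")
  if (any(longitude < -180 | longitude > 180)) stop("longitude out of [-180, 180]")
  derived <- assign_period(age)
  if (!is.null(period)) {
    period <- factor(as.character(period), levels = period_levels())
    if (anyNA(period)) stop("unknown period label")
    if (any(period != derived))
      stop("supplied period inconsistent with age for sample(s): ",
           paste(sample_id[period != derived], collapse = ", "))
  }
  out <- data.frame(sample_id = sample_id, site_id = as.character(site_id),
                    latitude = as.numeric(latitude),
                    longitude = as.numeric(longitude),
                    age = as.numeric(age), period = derived,
                    stringsAsFactors = FALSE)
  class(out) <- c("paleo_samples", "data.frame")
  out
}

#' Bundle a read matrix, sample metadata and traits into one dataset
#'
#' Validates the cross-references between the three tables: the read-matrix
#' rows must all be known samples and its columns known MOTUs, counts must be
#' non-negative integers, and labels unique.
#'
#' @param read_matrix Integer matrix, samples x MOTUs, with dimnames.
#' @param samples A `paleo_samples` table (see [sample_table()]).
#' @param traits A `paleo_traits` table (see [trait_table()]).
#' @param tree Optional `phylo` backbone/graft phylogeny for the MOTUs.
#' @param taxonomy Optional taxonomy `data.frame`.
#' @param truth Optional generative-truth record (synthetic data only).
#' @return A list of class `paleo_dataset`.
#' @export
paleo_dataset <- function(read_matrix, samples, traits, tree = NULL,
                          taxonomy = NULL, truth = NULL) {
  rm <- as.matrix(read_matrix)
  if (is.null(rownames(rm)) || is.null(colnames(rm)))
    stop("read_matrix must have sample row names and MOTU column names")
  if (anyDuplicated(rownames(rm)) || anyDuplicated(colnames(rm)))
    stop("duplicate read-matrix labels")
  if (anyNA(rm) || any(rm < 0)) stop("read counts must be non-negative")
  if (any(rm != round(rm))) stop("read counts must be integers")
  extra_s <- setdiff(rownames(rm), samples$sample_id)
  if (length(extra_s))
    stop("read-matrix samples missing from sample table: ",
         paste(extra_s, collapse = ", "))
  extra_m <- setdiff(colnames(rm), traits$motu_id)
  if (length(extra_m))
    stop("read-matrix MOTUs missing from trait table: ",
         paste(extra_m, collapse = ", "))
  storage.mode(rm) <- "integer"
  out <- list(read_matrix = rm,
              samples = samples[match(rownames(rm), samples$sample_id), ,
                                drop = FALSE],
              traits = traits[match(colnames(rm), traits$motu_id), ,
                              drop = FALSE],
              tree = tree, taxonomy = taxonomy, truth = truth)
  rownames(out$samples) <- NULL
  rownames(out$traits) <- NULL
  class(out) <- "paleo_dataset"
  out
}

#' @export
print.paleo_dataset <- function(x, ...) {
  cat("paleo_dataset:", nrow(x$read_matrix), "samples x",
      ncol(x$read_matrix), "MOTUs,", sum(x$read_matrix), "reads\n")
  cat("  periods:", paste(sprintf("%s=%d", levels(x$samples$period),
                                  table(x$samples$period)), collapse = ", "), "\n")
  if (!is.null(x$tree)) cat("  phylogeny:", length(x$tree$tip.label), "tips\n")
  invisible(x)
}

# default column mapping for the on-disk format; overridable via a YAML or
# list config (delimiters and column names)
.default_io_config <- function() {
  list(counts = list(delimiter = "\t", id_column = "sample_id"),
       samples = list(delimiter = ",",
                      columns = list(sample_id = "sample_id", site_id = "site_id",
                                     latitude = "latitude", longitude = "longitude",
                                     age = "age")),
       traits = list(delimiter = ",",
                     columns = c(list(motu_id = "motu_id"),
                                 setNames(as.list(trait_names()), trait_names()))))
}

.load_io_config <- function(config) {
  base <- .default_io_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  modifyList(base, config)
}

#' Read a dataset from delimited text files
#'
#' Reads a wide read-count table (first column = sample id), a sample
#' metadata table and a MOTU trait table, validates them and returns a
#' [paleo_dataset()]. Trait levels are whitespace-trimmed and matched
#' case-insensitively; unknown levels raise an error naming the cell.
#'
#' @param counts,samples,traits File paths.
#' @param tree Optional Newick file path.
#' @param taxonomy Optional taxonomy CSV path.
#' @param config Optional list or YAML file path overriding delimiters and
#'   column names (see package vignette).
#' @return A `paleo_dataset`.
#' @export
read_dataset <- function(counts, samples, traits, tree = NULL,
                         taxonomy = NULL, config = NULL) {
  cfg <- .load_io_config(config)
  for (f in c(counts, samples, traits)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  cw <- read.delim(counts, sep = cfg$counts$delimiter, check.names = FALSE,
                   stringsAsFactors = FALSE)
  idc <- cfg$counts$id_column
  if (!idc %in% names(cw)) stop("counts file lacks id column '", idc, "'")
  rm <- as.matrix(cw[, setdiff(names(cw), idc), drop = FALSE])
  rownames(rm) <- as.character(cw[[idc]])
  if (anyNA(rm) || any(rm < 0))
    stop("negative or missing read counts in ", counts)

  sm <- read.delim(samples, sep = cfg$samples$delimiter,
                   stringsAsFactors = FALSE)
  sc <- cfg$samples$columns
  missing_cols <- setdiff(unlist(sc), names(sm))
  if (length(missing_cols))
    stop("sample file lacks column(s): ", paste(missing_cols, collapse = ", "))
  st <- sample_table(sm[[sc$sample_id]], sm[[sc$site_id]],
                     sm[[sc$latitude]], sm[[sc$longitude]], sm[[sc$age]])

  tm <- read.delim(traits, sep = cfg$traits$delimiter,
                   stringsAsFactors = FALSE)
  tc <- cfg$traits$columns
  missing_cols <- setdiff(unlist(tc), names(tm))
  if (length(missing_cols))
    stop("trait file lacks column(s): ", paste(missing_cols, collapse = ", "))
  tt <- trait_table(tm[[tc$motu_id]],
                    growth_form = tm[[tc$growth_form]],
                    myc_type = tm[[tc$myc_type]],
                    myc_status = tm[[tc$myc_status]],
                    n_fix = tm[[tc$n_fix]],
                    pollination = tm[[tc$pollination]])

  tr <- if (!is.null(tree)) ape::read.tree(tree) else NULL
  tx <- if (!is.null(taxonomy)) read.csv(taxonomy, stringsAsFactors = FALSE) else NULL
  paleo_dataset(rm, st, tt, tree = tr, taxonomy = tx)
}

#' Write a dataset to delimited text files
#'
#' Writes `counts.tsv` (wide, first column `sample_id`), `samples.csv`,
#' `traits.csv` and, when present, `tree.nwk`, `taxonomy.csv` and
#' `truth.json` into `dir`. All files are UTF-8 with LF line endings;
#' integer counts round-trip bit-exactly through [read_dataset()].
#'
#' @param ds A `paleo_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "paleo_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.csv"),
             traits = file.path(dir, "traits.csv"))
  cw <- data.frame(sample_id = rownames(ds$read_matrix),
                   ds$read_matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(cw, paths["counts"], sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  write.csv(ds$samples[, c("sample_id", "site_id", "latitude", "longitude",
                           "age")],
            paths["samples"], row.names = FALSE, eol = "\n",
            fileEncoding = "UTF-8", quote = FALSE)
  write.csv(ds$traits, paths["traits"], row.names = FALSE, eol = "\n",
            fileEncoding = "UTF-8", quote = FALSE)
  if (!is.null(ds$tree)) {
    paths["tree"] <- file.path(dir, "tree.nwk")
    ape::write.tree(ds$tree, paths["tree"])
  }
  if (!is.null(ds$taxonomy)) {
    paths["taxonomy"] <- file.path(dir, "taxonomy.csv")
    write.csv(ds$taxonomy, paths["taxonomy"], row.names = FALSE, eol = "\n",
              fileEncoding = "UTF-8", quote = FALSE)
  }
  if (!is.null(ds$truth)) {
    paths["truth"] <- file.path(dir, "truth.json")
    jsonlite::write_json(ds$truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  invisible(paths)
}
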