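# shared fixture builders; everything is generated in code at test time

# tiny hand-checkable dataset: 3 samples, 4 MOTUs
tiny_dataset <- function() {
  rm <- matrix(c(80L, 20L, 0L, 5L,
                 10L, 10L, 10L, 10L,
                 0L, 0L, 30L, 6L),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("s1", "s2", "s3"),
                               c("m1", "m2", "m3", "m4")))
  traits <- trait_table(c("m1", "m2", "m3", "m4"),
                        growth_form = c("forb", "forb", "graminoid", "tree_shrub"),
                        myc_type = c("AM", "ECM", "NM", "ERM"),
                        myc_status = c("OM", "FM", "NM", "OM"),
                        n_fix = c("fixer", "nonfixer", "nonfixer", "nonfixer"),
                        pollination = c("insect", "insect", "wind", "wind"))
  samples <- sample_table(c("s1", "s2", "s3"), c("a", "a", "b"),
                          latitude = c(65, 66, 70),
                          longitude = c(150, 151, -140),
                          age = c(30, 20, 5))
  paleo_dataset(rm, samples, traits)
}

# low-noise, strongly period-structured simulated dataset for power checks
structured_dataset <- function(n_per = c(20, 12, 12), n_motus = 40, seed = 11,
                               overdispersion = 8, ...) {
  simulate_dataset(sim_config(n_samples_per_period = n_per, n_motus = n_motus,
                              overdispersion = overdispersion,
                              spatial_sill = 0, seed = seed, ...))
}

# null read matrix with skewed abundances and no group structure
null_read_matrix <- function(n_samples, n_motus, depth = 2000) {
  prof <- exp(rnorm(n_motus))
  prof <- prof / sum(prof)
  rm <- t(vapply(seq_len(n_samples), function(j) {
    p <- rgamma(n_motus, shape = 2 * n_motus * prof)
    as.integer(rmultinom(1, depth, p / sum(p)))
  }, integer(n_motus)))
  dimnames(rm) <- list(sprintf("s%03d", seq_len(n_samples)),
                       sprintf("m%03d", seq_len(n_motus)))
  rm[, colSums(rm) > 0, drop = FALSE]
}
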