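# Shared fixtures: tiny regions, noiseless kinetics, and a hand-rolled
# Hamming distance used by the uncertainty-localization checks.

region_A <- protease_region("A")
region_B <- protease_region("B")

# One- and two-position toy regions for brute-force checks.
region_p1 <- region_spec("X1", 5, "A")
region_p2 <- region_spec("X2", c(3, 7), "AC")

noiseless_kin <- function(...) kinetic_params(noise_sd = 0, ...)

fret_series_for_test <- function(ratio, time = seq_along(ratio) - 1) {
  fret_series(time, ratio)
}

# Mirror of the package's internal per-round seed derivation, used when a
# test reproduces a campaign round's draws externally.
derive_seed_test <- function(seed, offset = 1) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

# Ensemble whose members are all clones of member i: Thompson sampling then
# collapses to deterministic greedy selection of that member's prediction.
clone_single <- function(ens, i) {
  ens$members <- rep(ens$members[i], ens$k)
  ens
}

# Minimum Hamming distance from each identity to a set of identities.
min_hamming <- function(identities, train) {
  tm <- matrix(unlist(strsplit(train, "")), nrow = length(train),
               byrow = TRUE)
  vapply(strsplit(identities, ""), function(v) {
    min(rowSums(sweep(tm, 2, v, FUN = "!=")))
  }, numeric(1))
}

# Small plate built directly from ratio trajectories: one well per column
# of `ratios` (timepoints x wells), one blank, exact channel decomposition.
plate_from_ratios <- function(time, ratios, variant_ids,
                              replicates = NULL, signal = 1000,
                              blank = 100) {
  n <- ncol(ratios)
  wells <- sprintf("S%02d", seq_len(n))
  f520 <- blank + signal / (1 + ratios)
  f480 <- blank + signal * ratios / (1 + ratios)
  f480 <- cbind(f480, BLK = blank)
  f520 <- cbind(f520, BLK = blank)
  colnames(f480) <- colnames(f520) <- c(wells, "BLK")
  layout <- tibble::tibble(
    well = c(wells, "BLK"),
    variant_id = c(variant_ids, NA),
    replicate = c(replicates %||% rep(1L, n), NA),
    is_blank = c(rep(FALSE, n), TRUE)
  )
  fret_plate(time, f480, f520, layout)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
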