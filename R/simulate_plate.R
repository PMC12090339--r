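#' Kinetic and instrument parameters for plate simulation
#'
#' Defaults describe a cleavage assay read every minute in which the FRET
#' ratio of an uncut substrate starts near 0.40 and approaches 0.90 at
#' complete cleavage. The first-order rate constant `kappa` (per minute,
#' per unit fitness) is set so the wild type (fitness 1) crosses the 0.55
#' truncation threshold at 30 min — mid-assay for the 90 min default
#' duration, leaving headroom for variants several-fold slower or faster.
#' `signal` and `blank` fix the arbitrary-unit channel scale; `noise_sd` is
#' additive i.i.d. Gaussian noise per channel read, sized so wild-type
#' replicate fitness scatters with SD ~0.1.
#'
#' @param r0 Starting FRET ratio (default 0.40).
#' @param rmax Plateau ratio at complete cleavage (default 0.90).
#' @param kappa Rate constant per unit fitness, min^-1
#'   (default `-log(0.7)/30` ~ 0.0119).
#' @param noise_sd Channel noise SD in AU (default 150).
#' @param signal Total distributed channel signal in AU (default 10000).
#' @param blank Background level in AU (default 500).
#' @param dt Read interval in minutes (default 1).
#' @param duration Assay length in minutes (default 90).
#' @param replicates Wells per variant (default 3).
#' @param n_blanks Water-blank wells per plate (default 3).
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(r0 = 0.40, rmax = 0.90, kappa = -log(0.7) / 30,
                           noise_sd = 150, signal = 10000, blank = 500,
                           dt = 1, duration = 90, replicates = 3,
                           n_blanks = 3) {
  stopifnot(r0 < 0.55, 0.55 < rmax, noise_sd >= 0, kappa > 0,
            dt > 0, duration >= 2 * dt, replicates >= 1, n_blanks >= 1)
  structure(list(r0 = r0, rmax = rmax, kappa = kappa, noise_sd = noise_sd,
                 signal = signal, blank = blank, dt = dt,
                 duration = duration, replicates = replicates,
                 n_blanks = n_blanks),
            class = "kinetic_params")
}

# Noiseless ratio trajectory for one fitness value.
ratio_trajectory <- function(f, time, kin) {
  kin$r0 + (kin$rmax - kin$r0) * (1 - exp(-kin$kappa * f * time))
}

#' Simulate a two-channel FRET plate from a ground-truth landscape
#'
#' Realizes each variant's noiseless ratio trajectory
#' `r(t) = r0 + (rmax - r0) * (1 - exp(-kappa * f * t))` as two emission
#' channels that the scorer sees exactly as a plate reader would report
#' them: `F520 = blank + S / (1 + r) + e` and
#' `F480 = blank + S * r / (1 + r) + e` with `e ~ N(0, noise_sd)` i.i.d.
#' per read, so the blank-subtracted channel ratio recovers `r(t)`. Blank
#' wells carry background plus noise only. The initial slope of the
#' noiseless ratio is `(rmax - r0) * kappa * f`, proportional to true
#' fitness — the property the scoring pipeline is built to recover.
#'
#' @param variants Variant table or identity strings; the wild type is
#'   added automatically if absent (it must be on every plate as the
#'   normalization reference).
#' @param landscape A [make_landscape()] object supplying true fitness.
#' @param kinetics A [kinetic_params()] object.
#' @param seed Integer seed for the noise draws; the noiseless backbone is
#'   independent of it.
#' @return A [fret_plate()] whose layout carries `variant_id` values
#'   consistent with [new_variants()] naming.
#' @export
simulate_plate <- function(variants, landscape, kinetics = kinetic_params(),
                           seed = 1) {
  stopifnot(inherits(landscape, "fitness_landscape"),
            inherits(kinetics, "kinetic_params"))
  region <- landscape$region
  identities <- if (is.data.frame(variants)) variants$identities else variants
  wt <- wt_identity(region)
  if (!wt %in% identities) identities <- c(wt, identities)
  f <- true_fitness(landscape, identities)
  if (any(f < 0)) stop("negative true fitness is not physical", call. = FALSE)

  time <- seq(0, kinetics$duration, by = kinetics$dt)
  reps <- kinetics$replicates
  n_sample_wells <- length(identities) * reps
  n_wells <- n_sample_wells + kinetics$n_blanks
  well_names <- sprintf("W%03d", seq_len(n_wells))

  r <- vapply(f, ratio_trajectory, numeric(length(time)),
              time = time, kin = kinetics)        # time x variants
  r <- r[, rep(seq_along(identities), each = reps), drop = FALSE]
  s520 <- kinetics$blank + kinetics$signal / (1 + r)
  s480 <- kinetics$blank + kinetics$signal * r / (1 + r)
  bl <- matrix(kinetics$blank, nrow = length(time), ncol = kinetics$n_blanks)

  f480 <- cbind(s480, bl)
  f520 <- cbind(s520, bl)
  if (kinetics$noise_sd > 0) {
    with_seed(seed, {
      f480 <- f480 + rnorm(length(f480), sd = kinetics$noise_sd)
      f520 <- f520 + rnorm(length(f520), sd = kinetics$noise_sd)
    })
  }
  colnames(f480) <- colnames(f520) <- well_names

  layout <- tibble::tibble(
    well = well_names,
    variant_id = c(rep(variant_ids(region, identities), each = reps),
                   rep(NA_character_, kinetics$n_blanks)),
    replicate = c(rep(seq_len(reps), length(identities)),
                  rep(NA_integer_, kinetics$n_blanks)),
    is_blank = c(rep(FALSE, n_sample_wells), rep(TRUE, kinetics$n_blanks))
  )
  fret_plate(time, f480, f520, layout)
}

#' Write a ready-to-score fixture bundle
#'
#' Generates, for each landscape kind, a small simulated plate with its
#' layout, the serialized landscape, and a manifest — everything needed to
#' exercise the scoring pipeline from files. Regeneration with the same
#' seed is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_variants Library size per plate (default 48, the size of a
#'   round-1 screen: each bundle emulates one first-round plate of
#'   48 variants plus the wild-type reference and blanks).
#' @return Invisibly, a named list of per-kind file sets.
#' @export
fixture_bundle <- function(dir, seed = 1, n_variants = 48) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (kind in c("dense", "sparse", "additive")) {
    region <- if (kind == "sparse") protease_region("A")
              else protease_region("B")
    land <- make_landscape(region, kind, seed = derive_seed(seed, 1))
    lib <- random_library(region, n_variants, seed = derive_seed(seed, 2))
    plate <- simulate_plate(lib, land, kinetic_params(),
                            seed = derive_seed(seed, 3))
    files <- list(
      signals = file.path(dir, paste0(kind, "_plate.csv")),
      layout = file.path(dir, paste0(kind, "_layout.csv")),
      landscape = file.path(dir, paste0(kind, "_landscape.csv")),
      variants = file.path(dir, paste0(kind, "_variants.csv"))
    )
    write_plate_csv(plate, files$signals, files$layout)
    write_landscape(land, files$landscape)
    write_variant_table(lib, files$variants)
    out[[kind]] <- files
  }
  manifest <- file.path(dir, "MANIFEST.csv")
  write.csv(data.frame(kind = names(out),
                       signals = basename(vapply(out, `[[`, "", "signals")),
                       layout = basename(vapply(out, `[[`, "", "layout")),
                       landscape = basename(vapply(out, `[[`, "", "landscape")),
                       variants = basename(vapply(out, `[[`, "", "variants"))),
            manifest, row.names = FALSE, quote = FALSE)
  invisible(out)
}
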