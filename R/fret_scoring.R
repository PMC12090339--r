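#' Construct a two-channel fluorescence plate
#'
#' Container for a FRET kinetics read: emission at 480 nm (donor) and
#' 520 nm (acceptor) under 430 nm excitation, one column per well, one row
#' per timepoint, plus a layout mapping wells to variants and replicates.
#' Water-blank wells (layout rows with `is_blank = TRUE`) provide the
#' background subtracted from both channels.
#'
#' @param time Timepoints in minutes, strictly increasing.
#' @param f480,f520 Numeric matrices (timepoints x wells, AU) with identical
#'   well column names.
#' @param layout Data frame with columns `well`, `variant_id`, `replicate`,
#'   `is_blank`; every signal column must appear, and at least one blank
#'   well is required.
#' @return Object of class `fret_plate`.
#' @export
fret_plate <- function(time, f480, f520, layout) {
  time <- as.numeric(time)
  f480 <- as.matrix(f480); f520 <- as.matrix(f520)
  if (length(time) < 2 || any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing with at least two points",
         call. = FALSE)
  }
  if (nrow(f480) != length(time) || nrow(f520) != length(time)) {
    stop("signal matrices must have one row per timepoint", call. = FALSE)
  }
  if (!identical(colnames(f480), colnames(f520)) || is.null(colnames(f480))) {
    stop("`f480` and `f520` must share identical well column names",
         call. = FALSE)
  }
  layout <- tibble::as_tibble(layout)
  needed <- c("well", "variant_id", "replicate", "is_blank")
  if (!all(needed %in% names(layout))) {
    stop("layout must have columns well, variant_id, replicate, is_blank",
         call. = FALSE)
  }
  if (!setequal(layout$well, colnames(f480))) {
    stop("layout wells and signal columns disagree", call. = FALSE)
  }
  if (!any(layout$is_blank)) {
    stop("at least one blank (water) well is required", call. = FALSE)
  }
  structure(list(time = time, f480 = f480, f520 = f520, layout = layout),
            class = "fret_plate")
}

#' @export
print.fret_plate <- function(x, ...) {
  cat(sprintf("<fret_plate> %d wells (%d blank) x %d timepoints (%g-%g min)\n",
              ncol(x$f480), sum(x$layout$is_blank), length(x$time),
              min(x$time), max(x$time)))
  invisible(x)
}

blank_wells <- function(plate) plate$layout$well[plate$layout$is_blank]

# Per-timepoint mean blank signal for each channel.
blank_means <- function(plate) {
  b <- blank_wells(plate)
  list(b480 = rowMeans(plate$f480[, b, drop = FALSE]),
       b520 = rowMeans(plate$f520[, b, drop = FALSE]))
}

#' Compute the FRET ratio trace for one well
#'
#' Ratio of blank-subtracted donor to blank-subtracted acceptor emission,
#' `(F480 - B480) / (F520 - B520)`, where the background `B` is the
#' per-timepoint mean over the plate's blank wells. The ratio rises as the
#' substrate is cleaved and FRET is lost. Timepoints whose denominator is
#' not positive are masked (`NA`) with a warning; a fully masked trace is an
#' error.
#'
#' @param plate A [fret_plate()].
#' @param well Well id.
#' @return Object of class `fret_series`: list with `time` and `ratio`.
#' @export
fret_ratio <- function(plate, well) {
  stopifnot(inherits(plate, "fret_plate"))
  if (!well %in% colnames(plate$f480)) {
    stop(sprintf("well '%s' not on the plate", well), call. = FALSE)
  }
  b <- blank_means(plate)
  num <- plate$f480[, well] - b$b480
  den <- plate$f520[, well] - b$b520
  ratio <- num / den
  bad <- den <= 0
  if (any(bad)) {
    ratio[bad] <- NA_real_
    warning(sprintf("well '%s': %d timepoint(s) masked (non-positive denominator)",
                    well, sum(bad)), call. = FALSE)
  }
  if (all(is.na(ratio))) {
    stop(sprintf("well '%s': all timepoints masked, cannot score", well),
         call. = FALSE)
  }
  fret_series(plate$time, ratio)
}

#' Construct a FRET ratio series
#'
#' A dimensionless ratio trace paired with its timepoints (minutes) —
#' the unit on which [truncate_series()] and [fit_initial_slope()]
#' operate. Normally produced by [fret_ratio()]; exported so traces from
#' other sources can enter the scoring path.
#'
#' @param time Timepoints in minutes.
#' @param ratio Ratio values, same length; `NA` marks masked points.
#' @return Object of class `fret_series`.
#' @export
fret_series <- function(time, ratio) {
  stopifnot(length(time) == length(ratio))
  structure(list(time = as.numeric(time), ratio = as.numeric(ratio)),
            class = "fret_series")
}

#' @export
print.fret_series <- function(x, ...) {
  cat(sprintf("<fret_series> %d points, ratio %.3g-%.3g\n",
              length(x$time), min(x$ratio, na.rm = TRUE),
              max(x$ratio, na.rm = TRUE)))
  invisible(x)
}

#' Truncate a FRET trace at a ratio threshold
#'
#' Initial-rate estimation uses only the early, approximately linear part of
#' the trace: the prefix strictly before the first timepoint whose ratio
#' reaches the threshold (default 0.55). The first-crossing rule means a
#' noisy dip back below the threshold cannot re-admit late points. A trace
#' that never crosses is returned whole; a trace left with fewer than two
#' usable points is unscorable at this threshold (see [fit_initial_slope()]).
#'
#' @param series A `fret_series`.
#' @param threshold Positive ratio threshold; default 0.55.
#' @return The truncated `fret_series`.
#' @export
truncate_series <- function(series, threshold = 0.55) {
  stopifnot(inherits(series, "fret_series"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  hit <- which(!is.na(series$ratio) & series$ratio >= threshold)
  if (length(hit) == 0) return(series)
  keep <- seq_len(hit[1] - 1L)
  fret_series(series$time[keep], series$ratio[keep])
}

#' Fit the initial-rate slope of a FRET trace
#'
#' Ordinary least-squares slope of ratio against time (free intercept),
#' in ratio units per minute. Masked points are dropped; at least two
#' distinct timepoints must remain.
#'
#' @param series A `fret_series`, normally already passed through
#'   [truncate_series()].
#' @return Slope (numeric scalar).
#' @export
fit_initial_slope <- function(series) {
  stopifnot(inherits(series, "fret_series"))
  ok <- !is.na(series$ratio)
  t <- series$time[ok]; r <- series$ratio[ok]
  if (length(t) < 2) {
    stop("fewer than two usable points: slope undefined", call. = FALSE)
  }
  if (var(t) == 0) stop("zero time variance: slope undefined", call. = FALSE)
  tc <- t - mean(t)
  sum(tc * (r - mean(r))) / sum(tc^2)
}

#' Normalize replicate slopes to the wild-type reference
#'
#' Each replicate slope is divided by the wild type's mean slope; the
#' reported fitness is the mean of the normalized replicates, clipped at 0
#' (an enzyme cannot have negative activity — noise-only wells hover around
#' zero). By construction the wild type's own fitness is exactly 1.
#'
#' @param replicate_slopes Numeric vector of raw per-replicate slopes.
#' @param wt_mean_slope Mean slope of the wild-type replicates; must be
#'   positive (a failed reference is a campaign-level error).
#' @return List with `fitness` (clipped mean), `sd_fitness` (SD over
#'   normalized replicates, `NA` for a single replicate), `per_replicate`
#'   (unclipped normalized slopes) and `n`.
#' @export
normalize_fitness <- function(replicate_slopes, wt_mean_slope) {
  if (!is.numeric(wt_mean_slope) || length(wt_mean_slope) != 1 ||
      !is.finite(wt_mean_slope) || wt_mean_slope <= 0) {
    stop("wild-type mean slope must be positive: reference assay failed",
         call. = FALSE)
  }
  per <- replicate_slopes / wt_mean_slope
  list(fitness = max(0, mean(replicate_slopes) / wt_mean_slope),
       sd_fitness = if (length(per) >= 2) sd(per) else NA_real_,
       per_replicate = per,
       n = length(per))
}

#' Score a plate into wild-type-normalized fitness values
#'
#' Full scoring path for one plate: FRET ratio per well, truncation at the
#' ratio threshold, OLS initial-rate slope per replicate, and normalization
#' of every slope by the wild-type mean slope. Wells that cannot be scored
#' (trace starts above threshold, or too few usable points) are dropped with
#' a recorded reason; a variant with no scorable replicate gets `NA` fitness
#' and a flag. The result is deterministic given the plate.
#'
#' @param plate A [fret_plate()].
#' @param wt_variant_id Variant id of the wild-type reference; must be
#'   present with at least one scorable replicate.
#' @param threshold Truncation threshold passed to [truncate_series()].
#' @return Tibble with one row per non-blank variant: `variant_id`,
#'   `n_replicates`, `mean_slope`, `sd_slope` (raw slope scale), `fitness`,
#'   `sd_fitness` (normalized scale), `flag`. The per-well table (slopes,
#'   points used, drop reasons) is attached as attribute `"wells"`.
#' @export
score_plate <- function(plate, wt_variant_id, threshold = 0.55) {
  stopifnot(inherits(plate, "fret_plate"))
  lay <- plate$layout[!plate$layout$is_blank, ]
  if (nrow(lay) == 0) stop("plate has only blank wells", call. = FALSE)
  if (!wt_variant_id %in% lay$variant_id) {
    stop(sprintf("wild-type reference '%s' absent from the plate layout",
                 wt_variant_id), call. = FALSE)
  }

  wells <- lay$well
  slope <- rep(NA_real_, length(wells))
  n_points <- integer(length(wells))
  reason <- rep(NA_character_, length(wells))
  for (i in seq_along(wells)) {
    res <- tryCatch({
      s <- withCallingHandlers(
        fret_ratio(plate, wells[i]),
        warning = function(w) invokeRestart("muffleWarning"))
      s <- truncate_series(s, threshold)
      n_points[i] <- sum(!is.na(s$ratio))
      fit_initial_slope(s)
    }, error = function(e) {
      reason[i] <<- conditionMessage(e)
      NA_real_
    })
    slope[i] <- res
  }
  well_tbl <- tibble::tibble(
    well = wells, variant_id = lay$variant_id, replicate = lay$replicate,
    slope = slope, n_points = n_points, drop_reason = reason
  )

  wt_slopes <- slope[lay$variant_id == wt_variant_id & !is.na(slope)]
  if (length(wt_slopes) == 0) {
    stop("no scorable wild-type replicate on the plate", call. = FALSE)
  }
  wt_mean <- mean(wt_slopes)

  ids <- unique(lay$variant_id)
  rows <- lapply(ids, function(v) {
    s <- slope[lay$variant_id == v]
    dropped <- sum(is.na(s))
    s <- s[!is.na(s)]
    if (length(s) == 0) {
      return(tibble::tibble(variant_id = v, n_replicates = 0L,
                            mean_slope = NA_real_, sd_slope = NA_real_,
                            fitness = NA_real_, sd_fitness = NA_real_,
                            flag = "unscorable"))
    }
    nf <- normalize_fitness(s, wt_mean)
    flag <- if (dropped > 0) {
      sprintf("%d replicate(s) dropped", dropped)
    } else if (length(s) < 2) {
      "single replicate"
    } else {
      NA_character_
    }
    tibble::tibble(variant_id = v, n_replicates = length(s),
                   mean_slope = mean(s),
                   sd_slope = if (length(s) >= 2) sd(s) else NA_real_,
                   fitness = nf$fitness, sd_fitness = nf$sd_fitness,
                   flag = flag)
  })
  out <- do.call(rbind, rows)
  attr(out, "wells") <- well_tbl
  attr(out, "wt_variant_id") <- wt_variant_id
  attr(out, "wt_mean_slope") <- wt_mean
  out
}

#' Write or read a scored-variant table
#'
#' @param scores Tibble from [score_plate()].
#' @param file Path.
#' @export
write_scores <- function(scores, file) {
  write.csv(as.data.frame(scores), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_scores
#' @export
read_scores <- function(file) {
  tibble::as_tibble(read.csv(file, colClasses = c(variant_id = "character")))
}
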