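#' Configure a create-test-learn campaign
#'
#' Bundles everything a multi-round campaign needs to be reproducible:
#' the region, the per-round batch sizes, the scoring threshold, the
#' surrogate configuration, the simulated-assay kinetics and the master
#' seed. The first round is always a random combinatorial library; later
#' rounds are proposed by the acquisition policy after refitting the
#' ensemble on all accumulated data.
#'
#' @param region A [region_spec()].
#' @param round_sizes Integer vector of per-round batch sizes, e.g.
#'   `c(48, 32)`; their total must fit in the sequence space.
#' @param policy Acquisition policy for rounds after the first:
#'   `"thompson"` (default) or `"random"` (baseline control).
#' @param fret_threshold Truncation threshold for scoring (default 0.55).
#' @param activity_threshold Fitness above which a variant counts as
#'   active in round summaries (default 0.05).
#' @param ensemble Named list of overrides passed to [fit_ensemble()]
#'   (`k`, `bootstrap_fraction`, `hidden`, `decay`, `maxit`).
#' @param kinetics A [kinetic_params()] object for simulated plates.
#' @param seed Master integer seed; every per-round random draw derives
#'   from it.
#' @return Object of class `campaign_config`.
#' @export
campaign_config <- function(region, round_sizes, policy = c("thompson",
                                                            "random"),
                            fret_threshold = 0.55,
                            activity_threshold = 0.05,
                            ensemble = list(), kinetics = kinetic_params(),
                            seed = 1) {
  stopifnot(inherits(region, "region_spec"))
  policy <- match.arg(policy)
  round_sizes <- vapply(round_sizes, assert_scalar_count, integer(1),
                        name = "round_sizes")
  if (sum(round_sizes) > space_size(region) - 1) {
    stop("round sizes exceed the sequence space", call. = FALSE)
  }
  structure(
    list(region = region, round_sizes = round_sizes, policy = policy,
         fret_threshold = fret_threshold,
         activity_threshold = activity_threshold,
         ensemble = ensemble, kinetics = kinetics, seed = seed),
    class = "campaign_config"
  )
}

#' Run a multi-round campaign
#'
#' Executes the create-test-learn loop: round 1 draws a random library;
#' each later round fits the bootstrapped ensemble on all accumulated
#' (sequence, fitness) data — the wild type included once, with fitness
#' 1 — and proposes the next batch by the configured acquisition policy,
#' excluding everything already measured. Fitness comes either from
#' simulated plates scored end-to-end against a ground-truth landscape
#' (`landscape` given) or from user-supplied plate objects/files
#' (`plates` given). A missing plate for a pending round pauses the
#' campaign — the round's proposals are returned so the measurements can
#' be made — rather than failing. A completed simulated campaign is
#' bit-for-bit reproducible from its config.
#'
#' @param config A [campaign_config()].
#' @param landscape Optional [make_landscape()] ground-truth oracle.
#' @param plates Optional list of per-round plates: [fret_plate()] objects
#'   or `list(signals =, layout =)` file paths.
#' @param out_dir Optional run directory; when given, each round's
#'   proposals, scores and (simulated) plate are written under
#'   `round-<r>/`, with the ensemble fingerprint and a log.
#' @return Object of class `campaign`: list with `rounds` (one record per
#'   completed round), `training` (accumulated training tibble), `status`
#'   (`"complete"` or `"paused"`), and `pending` proposals when paused.
#' @export
run_campaign <- function(config, landscape = NULL, plates = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "campaign_config"))
  if (is.null(landscape) && is.null(plates)) {
    stop("provide a `landscape` oracle or per-round `plates`", call. = FALSE)
  }
  region <- config$region
  wt <- wt_identity(region)
  wt_id <- variant_ids(region, wt)
  space <- enumerate_space(region)
  log_lines <- sprintf("campaign region=%s seed=%d policy=%s rounds=%s",
                       region$region_id, config$seed, config$policy,
                       paste(config$round_sizes, collapse = "+"))

  training <- tibble::tibble(identities = wt, fitness = 1)
  measured <- wt
  rounds <- list()

  for (r in seq_along(config$round_sizes)) {
    n_r <- config$round_sizes[r]
    if (r == 1) {
      lib <- random_library(region, n_r, seed = derive_seed(config$seed, 1))
      proposals <- proposal_batch(region, lib$identities,
                                  rep(NA_integer_, n_r),
                                  rep(NA_real_, n_r), n_r,
                                  policy = "random")
      ensemble <- NULL
    } else {
      ts <- training_set(region, training$identities, training$fitness)
      ensemble <- do.call(fit_ensemble, c(
        list(data = ts, seed = derive_seed(config$seed, 100 + r)),
        config$ensemble))
      proposals <- if (config$policy == "thompson") {
        thompson_batch(ensemble, space, measured, n_r,
                       seed = derive_seed(config$seed, 200 + r))
      } else {
        random_batch(region, space, measured, n_r,
                     seed = derive_seed(config$seed, 200 + r))
      }
    }
    log_lines <- c(log_lines, sprintf("round %d: %d proposals (%s)",
                                      r, nrow(proposals),
                                      attr(proposals, "policy")))

    plate <- if (!is.null(landscape)) {
      simulate_plate(proposals, landscape, config$kinetics,
                     seed = derive_seed(config$seed, 300 + r))
    } else if (r <= length(plates) && !is.null(plates[[r]])) {
      p <- plates[[r]]
      if (inherits(p, "fret_plate")) p
      else read_plate_csv(p$signals, p$layout)
    } else {
      NULL
    }
    if (is.null(plate)) {
      log_lines <- c(log_lines,
                     sprintf("round %d: plate missing, campaign paused", r))
      out <- structure(list(config = config, rounds = rounds,
                            training = training, status = "paused",
                            pending = list(round_index = r,
                                           proposals = proposals)),
                       class = "campaign")
      write_campaign_artifacts(out, out_dir, log_lines)
      return(out)
    }

    scores <- score_plate(plate, wt_id, config$fret_threshold)
    sc <- scores[match(proposals$variant_id, scores$variant_id), ]
    measured_tbl <- tibble::tibble(
      variant_id = proposals$variant_id,
      identities = proposals$identities,
      fitness = sc$fitness, sd_fitness = sc$sd_fitness,
      n_replicates = sc$n_replicates, flag = sc$flag
    )
    ok <- !is.na(measured_tbl$fitness)
    record <- structure(
      list(round_index = r, policy = attr(proposals, "policy"),
           proposals = proposals, scores = measured_tbl,
           plate = if (!is.null(landscape)) NULL else plate,
           ensemble_fingerprint = if (is.null(ensemble)) NA_real_
                                  else ensemble$fingerprint),
      class = "round_record")
    record$summary <- summarize_round(record, config$activity_threshold)
    rounds[[r]] <- record

    training <- rbind(training,
                      measured_tbl[ok, c("identities", "fitness")])
    measured <- c(measured, proposals$identities)

    if (!is.null(out_dir)) {
      rd <- file.path(out_dir, sprintf("round-%d", r))
      dir.create(rd, recursive = TRUE, showWarnings = FALSE)
      write_proposals(proposals, file.path(rd, "proposals.csv"))
      write_scores(measured_tbl, file.path(rd, "scores.csv"))
      if (!is.null(landscape)) {
        write_plate_csv(plate, file.path(rd, "plate.csv"),
                        file.path(rd, "layout.csv"))
      }
      if (!is.null(ensemble)) save_ensemble(ensemble, rd)
    }
  }

  out <- structure(list(config = config, rounds = rounds,
                        training = training, status = "complete",
                        pending = NULL),
                   class = "campaign")
  write_campaign_artifacts(out, out_dir, log_lines)
  out
}

write_campaign_artifacts <- function(campaign, out_dir, log_lines) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(log_lines, file.path(out_dir, "campaign.log"))
  s <- summary(campaign)
  if (nrow(s)) write.csv(as.data.frame(s),
                         file.path(out_dir, "summary.csv"),
                         row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Summarize one campaign round
#'
#' Mean, maximum and SD of measured fitness plus the fraction of variants
#' counting as active (fitness above the activity threshold) — the
#' round-over-round quantities by which a campaign's progress is judged.
#'
#' @param record A round record from [run_campaign()].
#' @param activity_threshold Fitness cut-off for "active" (default 0.05).
#' @return One-row tibble: `round`, `policy`, `n_measured`,
#'   `mean_fitness`, `max_fitness`, `sd_fitness`, `frac_active`.
#' @export
summarize_round <- function(record, activity_threshold = 0.05) {
  stopifnot(inherits(record, "round_record"))
  f <- record$scores$fitness
  f <- f[!is.na(f)]
  tibble::tibble(
    round = record$round_index,
    policy = record$policy,
    n_measured = length(f),
    mean_fitness = mean(f),
    max_fitness = max(f),
    sd_fitness = if (length(f) >= 2) sd(f) else NA_real_,
    frac_active = mean(f > activity_threshold)
  )
}

#' @export
summary.campaign <- function(object, ...) {
  if (length(object$rounds) == 0) {
    return(tibble::tibble(round = integer(), policy = character(),
                          n_measured = integer(), mean_fitness = numeric(),
                          max_fitness = numeric(), sd_fitness = numeric(),
                          frac_active = numeric()))
  }
  do.call(rbind, lapply(object$rounds, `[[`, "summary"))
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("<campaign> region %s, %d/%d rounds, %s\n",
              x$config$region$region_id, length(x$rounds),
              length(x$config$round_sizes), x$status))
  s <- summary(x)
  if (nrow(s)) print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}

#' Total distinct variants measured in a campaign
#'
#' Counts measured proposals across completed rounds. The wild type is
#' scored on every plate as the normalization reference but is not counted
#' here, so a completed campaign's total equals the sum of its round sizes.
#'
#' @param campaign A [run_campaign()] result.
#' @return Integer count.
#' @export
n_measured <- function(campaign) {
  stopifnot(inherits(campaign, "campaign"))
  length(unique(unlist(lapply(campaign$rounds,
                              function(r) r$scores$variant_id))))
}
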