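#' Propose a batch of variants by Thompson sampling
#'
#' Fills each batch slot by drawing one ensemble member uniformly at random
#' and taking the argmax of that member's predicted fitness over all
#' candidates not yet measured and not already in the batch. Ties break to
#' the lowest enumeration index, so the procedure is deterministic given
#' the member draws; the member index used for every slot is logged in the
#' result, making the acquisition auditable. No model refit happens within
#' a batch (no interim measurements exist mid-batch).
#'
#' @param ensemble A fitted [fit_ensemble()] object.
#' @param candidates Candidate identity strings in enumeration order,
#'   normally [enumerate_space()] of the region.
#' @param measured Identity strings already measured (all prior rounds plus
#'   the wild type); never proposed again.
#' @param batch_size Number of proposals requested.
#' @param seed Optional seed for the member draws; `NULL` uses the current
#'   RNG stream.
#' @return A `proposal_batch`: tibble with `rank`, `variant_id`,
#'   `identities`, `member_index`, `predicted_fitness`, plus attributes
#'   `policy` and `batch_size`. If the candidate pool runs out the batch is
#'   short, with a warning.
#' @export
thompson_batch <- function(ensemble, candidates, measured, batch_size,
                           seed = NULL) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  batch_size <- assert_scalar_count(batch_size, "batch_size")
  if (is.data.frame(candidates)) candidates <- candidates$identities
  if (is.data.frame(measured)) measured <- measured$identities
  preds <- predict_members(ensemble, candidates)
  available <- !(candidates %in% measured)
  picks <- integer(0)
  members <- integer(0)
  with_seed(seed, {
    for (slot in seq_len(batch_size)) {
      idx <- which(available)
      if (length(idx) == 0) {
        warning(sprintf("candidate pool exhausted: short batch (%d of %d)",
                        length(picks), batch_size), call. = FALSE)
        break
      }
      j <- sample.int(ensemble$k, 1)
      best <- idx[which.max(preds[idx, j])]  # which.max -> lowest index on ties
      picks <- c(picks, best)
      members <- c(members, j)
      available[best] <- FALSE
    }
  })
  proposal_batch(ensemble$region, candidates[picks], members,
                 preds[cbind(picks, members)], batch_size,
                 policy = "thompson")
}

#' Propose a batch of variants uniformly at random
#'
#' Baseline acquisition policy: a uniform sample (without replacement) of
#' unmeasured candidates. Used as the control arm when quantifying the
#' value of model-guided acquisition.
#'
#' @inheritParams thompson_batch
#' @param region A [region_spec()] (the random policy needs no ensemble).
#' @return A `proposal_batch`; `member_index` and `predicted_fitness` are
#'   `NA` under this policy.
#' @export
random_batch <- function(region, candidates, measured, batch_size,
                         seed = NULL) {
  stopifnot(inherits(region, "region_spec"))
  batch_size <- assert_scalar_count(batch_size, "batch_size")
  if (is.data.frame(candidates)) candidates <- candidates$identities
  if (is.data.frame(measured)) measured <- measured$identities
  pool <- candidates[!(candidates %in% measured)]
  n_take <- min(batch_size, length(pool))
  if (n_take < batch_size) {
    warning(sprintf("candidate pool exhausted: short batch (%d of %d)",
                    n_take, batch_size), call. = FALSE)
  }
  picks <- with_seed(seed, {
    if (n_take == 0) character(0) else sample(pool, n_take)
  })
  proposal_batch(region, picks, rep(NA_integer_, n_take),
                 rep(NA_real_, n_take), batch_size, policy = "random")
}

proposal_batch <- function(region, identities, member_index,
                           predicted_fitness, batch_size, policy) {
  out <- tibble::tibble(
    rank = seq_along(identities),
    variant_id = variant_ids(region, identities),
    identities = identities,
    member_index = as.integer(member_index),
    predicted_fitness = as.numeric(predicted_fitness)
  )
  attr(out, "policy") <- policy
  attr(out, "batch_size") <- batch_size
  attr(out, "region_id") <- region$region_id
  out
}

#' Write a proposal table
#'
#' The hand-off artifact from the learn step to the next create step:
#' delimited text with rank, variant id, identities, the ensemble member
#' that selected each slot, and its predicted fitness.
#'
#' @param batch A `proposal_batch`.
#' @param file Path.
#' @export
write_proposals <- function(batch, file) {
  write.csv(as.data.frame(batch), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
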