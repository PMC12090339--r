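#' Assemble a training set for the surrogate model
#'
#' Pairs identity strings with normalized fitness values and enforces the
#' training-set contract: the wild type is present with fitness 1 (appended
#' automatically if missing), no duplicate variants, all fitness values
#' finite and non-negative. Inactive (fitness 0) variants are kept — a
#' mutation-intolerant region's many dead variants are informative.
#'
#' @param region A [region_spec()].
#' @param identities Character vector of identity strings.
#' @param fitness Numeric vector of wild-type-normalized fitness values.
#' @return Tibble with columns `identities`, `fitness`; attribute
#'   `"region"` carries the region.
#' @export
training_set <- function(region, identities, fitness) {
  stopifnot(inherits(region, "region_spec"),
            length(identities) == length(fitness))
  identity_matrix(identities, region)  # validates letters/width
  if (anyDuplicated(identities)) {
    stop("duplicate variants in the training set", call. = FALSE)
  }
  if (any(!is.finite(fitness)) || any(fitness < 0)) {
    stop("fitness values must be finite and non-negative", call. = FALSE)
  }
  wt <- wt_identity(region)
  if (!wt %in% identities) {
    identities <- c(wt, identities)
    fitness <- c(1, fitness)
  } else if (abs(fitness[match(wt, identities)] - 1) > 1e-8) {
    stop("wild-type fitness must be 1 (it defines the normalization)",
         call. = FALSE)
  }
  out <- tibble::tibble(identities = identities, fitness = fitness)
  attr(out, "region") <- region
  out
}

#' Fit a bootstrapped neural-network ensemble surrogate
#'
#' Trains `k` independent feed-forward neural-network regressors
#' ([nnet::nnet], linear output, squared-error loss, weight decay) on
#' one-hot encoded sequences. Each member sees its own seeded random
#' subsample of `floor(bootstrap_fraction * n)` records drawn without
#' replacement; the spread of the members' predictions is treated as
#' samples from an approximate Bayesian posterior over fitness. The whole
#' fit is reproducible from (data, seed).
#'
#' @param data Training set from [training_set()] (or any tibble with
#'   `identities` and `fitness` plus a `"region"` attribute).
#' @param k Ensemble size (default 5).
#' @param bootstrap_fraction Fraction of records per member (default 0.9).
#' @param seed Integer seed controlling both subsampling and weight
#'   initialization.
#' @param hidden Hidden-layer width (default 8 logistic units).
#' @param decay L2 weight decay (default 0). The default is deliberate:
#'   with any positive decay the optimizer drives the input weights of
#'   one-hot bits never seen in a member's subsample to zero, so all
#'   members agree far from the data and the posterior spread collapses
#'   exactly where exploration is needed. With no decay those weights
#'   retain each member's random initialization, which is the bootstrap
#'   ensemble's uncertainty signal in unexplored sequence space.
#' @param maxit Optimizer iteration cap (default 300).
#' @return Object of class `surrogate_ensemble`.
#' @export
fit_ensemble <- function(data, k = 5, bootstrap_fraction = 0.9, seed = 1,
                         hidden = 8, decay = 0, maxit = 300) {
  region <- attr(data, "region")
  stopifnot(inherits(region, "region_spec"))
  n <- nrow(data)
  if (n < 5) {
    stop("too few training records: measure a larger initial library (n >= 5)",
         call. = FALSE)
  }
  k <- assert_scalar_count(k, "k")
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (bootstrap_fraction <= 0 || bootstrap_fraction > 1) {
    stop("`bootstrap_fraction` must be in (0, 1]", call. = FALSE)
  }
  X <- encode_one_hot(data$identities, region)
  y <- data$fitness
  m <- max(2L, as.integer(floor(bootstrap_fraction * n)))
  members <- vector("list", k)
  subsamples <- vector("list", k)
  with_seed(seed, {
    for (i in seq_len(k)) {
      idx <- sort(sample.int(n, m))
      subsamples[[i]] <- idx
      members[[i]] <- nnet::nnet(
        x = X[idx, , drop = FALSE], y = y[idx],
        size = hidden, linout = TRUE, decay = decay, maxit = maxit,
        trace = FALSE, MaxNWts = 10000
      )
    }
  })
  structure(
    list(members = members, region = region, k = k,
         bootstrap_fraction = bootstrap_fraction, subsample_size = m,
         seed = seed,
         config = list(hidden = hidden, decay = decay, maxit = maxit),
         subsamples = subsamples,
         train_identities = data$identities,
         fingerprint = sum(y) + n),
    class = "surrogate_ensemble"
  )
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(
    "<surrogate_ensemble> %d members, %d/%d records per member, hidden=%d\n",
    x$k, x$subsample_size, length(x$train_identities), x$config$hidden))
  invisible(x)
}

# n_variants x k matrix of member predictions.
predict_members <- function(ensemble, identities) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  if (is.data.frame(identities)) identities <- identities$identities
  X <- encode_one_hot(identities, ensemble$region)
  preds <- vapply(ensemble$members,
                  function(m) as.numeric(predict(m, X)),
                  numeric(nrow(X)))
  matrix(preds, nrow = nrow(X), ncol = ensemble$k)
}

#' Posterior mean and spread of predicted fitness
#'
#' Mean and standard deviation over the ensemble members' predictions for
#' each variant — the exploitation and exploration signals of the
#' acquisition step.
#'
#' @param ensemble A fitted [fit_ensemble()] object.
#' @param identities Identity strings (or a variant table).
#' @return Tibble with `identities`, `mean`, `sd`.
#' @export
predict_posterior <- function(ensemble, identities) {
  if (is.data.frame(identities)) identities <- identities$identities
  preds <- predict_members(ensemble, identities)
  tibble::tibble(
    identities = identities,
    mean = rowMeans(preds),
    sd = apply(preds, 1, sd)
  )
}

#' Draw one posterior sample (one ensemble member)
#'
#' Thompson sampling optimizes a single random posterior sample; here that
#' is the prediction function of one uniformly drawn ensemble member. Uses
#' the current RNG stream, so a fixed RNG state gives a fixed member.
#'
#' @param ensemble A fitted [fit_ensemble()] object.
#' @return A function `f(identities) -> numeric` with attribute
#'   `"member_index"`.
#' @export
draw_member <- function(ensemble) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  i <- sample.int(ensemble$k, 1)
  member <- ensemble$members[[i]]
  region <- ensemble$region
  f <- function(identities) {
    if (is.data.frame(identities)) identities <- identities$identities
    as.numeric(predict(member, encode_one_hot(identities, region)))
  }
  attr(f, "member_index") <- i
  f
}

#' Save or load a fitted ensemble
#'
#' Serializes the ensemble with its config, seed and training-data
#' fingerprint into a run directory so later proposal rounds can reload it.
#'
#' @param ensemble A fitted [fit_ensemble()] object.
#' @param dir Run directory (created if needed).
#' @return `load_ensemble` returns the ensemble.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ensemble, file.path(dir, "ensemble.rds"))
  invisible(file.path(dir, "ensemble.rds"))
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  readRDS(file.path(dir, "ensemble.rds"))
}
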