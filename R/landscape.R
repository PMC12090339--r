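#' Generate a ground-truth fitness landscape
#'
#' Builds a Potts-like fitness function over a region's full `20^P`
#' sequence space from seeded per-position field terms `h_i(a)` and
#' pairwise coupling terms `J_ij(a, b)`. All terms are measured relative to
#' the wild-type letters (`h_i(wt_i) = 0`, `J_ij(wt_i, wt_j) = 0`), so the
#' wild type's fitness is exactly 1 by construction. Three kinds emulate
#' qualitatively different mutational tolerance:
#'
#' \describe{
#'   \item{`"dense"`}{`fitness = exp(score)`: every variant retains some
#'     activity and a small fraction of the space beats the wild type —
#'     a mutation-tolerant site.}
#'   \item{`"sparse"`}{non-wild-type letters carry strictly negative field
#'     penalties; `fitness = max(0, 1 + score)` and at least `gate` of the
#'     space is forced to zero (lowest-scoring variants gated first) — a
#'     mutation-intolerant site where the wild type is near-optimal.}
#'   \item{`"additive"`}{all couplings zero; `fitness = max(0, 1 + sum of
#'     field terms)` — a no-epistasis landscape for model-recovery checks.}
#' }
#'
#' @param region A [region_spec()].
#' @param kind `"dense"`, `"sparse"` or `"additive"`.
#' @param seed Integer seed for the random terms.
#' @param field_sd SD of the field terms (dense/additive) or of the
#'   half-normal penalty spread (sparse). Defaults: dense/additive 0.3,
#'   sparse 0.8.
#' @param coupling_sd SD of the pairwise couplings. Defaults: dense 0.1,
#'   sparse 0.05, additive 0.
#' @param gate Sparse kind only: minimum fraction of the space forced to
#'   zero fitness (default 0.8).
#' @return Object of class `fitness_landscape` with the full fitness vector
#'   (named by identity string), the generating terms, and the recorded
#'   maximum.
#' @export
make_landscape <- function(region, kind = c("dense", "sparse", "additive"),
                           seed = 1, field_sd = NULL, coupling_sd = NULL,
                           gate = 0.8) {
  stopifnot(inherits(region, "region_spec"))
  kind <- match.arg(kind)
  field_sd <- field_sd %||% switch(kind, dense = 0.3, sparse = 0.8,
                                   additive = 0.3)
  coupling_sd <- coupling_sd %||% switch(kind, dense = 0.1, sparse = 0.05,
                                         additive = 0)
  P <- n_positions(region)
  A <- length(region$alphabet)
  space <- enumerate_space(region)
  wt <- wt_identity(region)

  with_seed(seed, {
    # Field terms, zero at the wild-type letter of each position.
    h <- matrix(rnorm(P * A, sd = field_sd), nrow = P,
                dimnames = list(NULL, region$alphabet))
    if (kind == "sparse") h <- -(0.15 + abs(h))  # penalty per substitution
    for (j in seq_len(P)) h[j, region$wildtype[j]] <- 0
    # Pairwise couplings, zero whenever both letters are wild type.
    pairs <- if (P >= 2) utils::combn(P, 2, simplify = FALSE) else list()
    J <- lapply(pairs, function(pr) {
      m <- matrix(if (coupling_sd > 0) rnorm(A * A, sd = coupling_sd)
                  else 0,
                  nrow = A, ncol = A,
                  dimnames = list(region$alphabet, region$alphabet))
      m[region$wildtype[pr[1]], region$wildtype[pr[2]]] <- 0
      m
    })
  })

  letters_m <- identity_matrix(space, region)
  idx <- matrix(match(letters_m, region$alphabet), ncol = P)
  score <- rowSums(matrix(h[cbind(rep(seq_len(P), each = length(space)),
                                  as.vector(idx))],
                          ncol = P))
  for (g in seq_along(J)) {
    pr <- pairs[[g]]
    score <- score + J[[g]][cbind(idx[, pr[1]], idx[, pr[2]])]
  }

  fitness <- switch(kind,
    dense = exp(score),
    sparse = pmax(0, 1 + score),
    additive = pmax(0, 1 + score)
  )
  names(fitness) <- space

  if (kind == "sparse") {
    target_zero <- ceiling(gate * length(fitness))
    n_zero <- sum(fitness == 0)
    if (n_zero < target_zero) {
      ord <- order(fitness)
      ord <- ord[names(fitness)[ord] != wt]
      fitness[ord[seq_len(target_zero - n_zero)]] <- 0
    }
    if (fitness[wt] == 0) {
      # Degenerate draw: the gate swallowed the wild type. Regenerate with
      # a looser gate rather than returning an unusable reference.
      message("wild type gated to zero; regenerating with a looser gate")
      return(make_landscape(region, kind, seed = derive_seed(seed, 7),
                            field_sd = field_sd, coupling_sd = coupling_sd,
                            gate = gate - 0.05))
    }
  }
  if (kind == "dense" && mean(fitness > fitness[wt]) < 0.01) {
    # Construction requirement for the tolerant kind: at least 1% of the
    # space must beat the wild type. With zero-mean fields this draw is
    # vanishingly rare; reseed deterministically if it happens.
    return(make_landscape(region, kind, seed = derive_seed(seed, 11),
                          field_sd = field_sd, coupling_sd = coupling_sd,
                          gate = gate))
  }
  stopifnot(abs(fitness[wt] - 1) < 1e-12)

  structure(
    list(region = region, kind = kind, seed = seed,
         field_sd = field_sd, coupling_sd = coupling_sd, gate = gate,
         h = h, pairs = pairs, J = J,
         fitness = fitness, max_fitness = max(fitness)),
    class = "fitness_landscape"
  )
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf(
    "<fitness_landscape '%s'> region %s, %d variants, max fitness %.3g, %.1f%% inactive\n",
    x$kind, x$region$region_id, length(x$fitness), x$max_fitness,
    100 * mean(x$fitness == 0)))
  invisible(x)
}

#' Build a landscape from explicitly assigned fitness values
#'
#' Wraps a named fitness vector (names are identity strings) into a
#' `fitness_landscape` so that assigned values can drive
#' [simulate_plate()] directly — useful for calibration checks where the
#' true fitness of each simulated variant must be known exactly. The wild
#' type is added with fitness 1 if absent.
#'
#' @param region A [region_spec()].
#' @param fitness Named non-negative numeric vector, e.g.
#'   `c(AAA = 0.5, LQY = 2)`.
#' @return A `fitness_landscape` of kind `"manual"`.
#' @export
manual_landscape <- function(region, fitness) {
  stopifnot(inherits(region, "region_spec"), is.numeric(fitness),
            !is.null(names(fitness)), all(fitness >= 0))
  identity_matrix(names(fitness), region)  # validates
  wt <- wt_identity(region)
  if (!wt %in% names(fitness)) fitness <- c(setNames(1, wt), fitness)
  if (abs(fitness[wt] - 1) > 1e-12) {
    stop("wild-type fitness must be 1", call. = FALSE)
  }
  structure(
    list(region = region, kind = "manual", seed = NA_integer_,
         field_sd = NA_real_, coupling_sd = NA_real_, gate = NA_real_,
         h = NULL, pairs = NULL, J = NULL,
         fitness = fitness, max_fitness = max(fitness)),
    class = "fitness_landscape"
  )
}

#' Ground-truth fitness of variants
#'
#' Deterministic lookup into a landscape's fitness table; the wild type
#' always returns 1.
#'
#' @param landscape A [make_landscape()] object.
#' @param identities Identity strings (or a variant table).
#' @return Numeric vector of fitness values.
#' @export
true_fitness <- function(landscape, identities) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  if (is.data.frame(identities)) identities <- identities$identities
  out <- landscape$fitness[identities]
  if (anyNA(out)) {
    stop("variant(s) outside the landscape's region", call. = FALSE)
  }
  unname(out)
}

#' Serialize a landscape to structured text
#'
#' Writes the full fitness table as delimited text with header comment
#' lines recording kind, seed and generating parameters; `read_landscape`
#' restores a lookup-capable object (the generating terms themselves are
#' reproducible from the recorded seed via [make_landscape()]).
#'
#' @param landscape A [make_landscape()] object.
#' @param file Path.
#' @export
write_landscape <- function(landscape, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s seed=%d field_sd=%g coupling_sd=%g gate=%g",
                     landscape$kind, landscape$seed, landscape$field_sd,
                     landscape$coupling_sd, landscape$gate), con)
  writeLines(sprintf("# region=%s positions=%s wildtype=%s",
                     landscape$region$region_id,
                     paste(landscape$region$positions, collapse = "/"),
                     wt_identity(landscape$region)), con)
  writeLines("identities,fitness", con)
  writeLines(sprintf("%s,%.17g", names(landscape$fitness),
                     landscape$fitness), con)
  invisible(file)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(file, region) {
  header <- readLines(file, n = 2)
  kind <- sub(".*kind=(\\w+).*", "\\1", header[1])
  seed <- as.integer(sub(".*seed=(-?\\d+).*", "\\1", header[1]))
  df <- read.csv(file, comment.char = "#")
  fitness <- setNames(df$fitness, df$identities)
  structure(
    list(region = region, kind = kind, seed = seed,
         field_sd = NA_real_, coupling_sd = NA_real_, gate = NA_real_,
         h = NULL, pairs = NULL, J = NULL,
         fitness = fitness, max_fitness = max(fitness)),
    class = "fitness_landscape"
  )
}
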