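#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in alphabetical one-letter order. This fixed
#' order defines the lexicographic enumeration of sequence space and the
#' column layout of the one-hot encoding, so it must not be permuted between
#' a fitted model and later predictions.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Define a mutable region of a protein
#'
#' A region is a small set of residue positions that are mutated
#' simultaneously (combinatorially), together with their wild-type
#' identities. Variants are represented only over these positions, as short
#' identity strings such as `"HLF"`; full-length sequences appear only in
#' FASTA export.
#'
#' @param region_id Short label, e.g. `"A"` or `"B"`.
#' @param positions Strictly increasing 1-based residue indices in the
#'   protein's own numbering.
#' @param wildtype Character vector (or single string) of wild-type amino
#'   acids at those positions, same length as `positions`.
#' @param alphabet Ordered amino-acid alphabet; defaults to [AA_ALPHABET].
#'
#' @return An object of class `region_spec`.
#' @examples
#' region_spec("B", c(217, 218, 219), "LQE")
#' @export
region_spec <- function(region_id, positions, wildtype,
                        alphabet = AA_ALPHABET) {
  stopifnot(is.character(region_id), length(region_id) == 1, nzchar(region_id))
  positions <- as.integer(positions)
  if (length(positions) == 0) {
    stop("empty region: at least one mutable position is required",
         call. = FALSE)
  }
  if (any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  wildtype <- split_identities(wildtype)
  if (length(wildtype) == 1 && length(positions) > 1) {
    stop("`wildtype` must supply one letter per position", call. = FALSE)
  }
  wildtype <- unlist(wildtype)
  if (length(wildtype) != length(positions)) {
    stop("`wildtype` must have one letter per position", call. = FALSE)
  }
  if (length(alphabet) != 20 || anyDuplicated(alphabet)) {
    stop("`alphabet` must contain 20 unique letters", call. = FALSE)
  }
  if (!all(wildtype %in% alphabet)) {
    stop("wild-type letters must belong to the alphabet", call. = FALSE)
  }
  structure(
    list(region_id = region_id, positions = positions,
         wildtype = wildtype, alphabet = alphabet),
    class = "region_spec"
  )
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec '%s'> %d positions: %s (wild type %s)\n",
              x$region_id, length(x$positions),
              paste(x$positions, collapse = "/"),
              paste(x$wildtype, collapse = "")))
  invisible(x)
}

#' Preset mutable regions of the Con1-type protease study design
#'
#' Convenience constructor for the two three-residue regions used throughout
#' the package's examples and simulations: region A (positions 167, 169, 172;
#' wild type `HLF`), a mutation-intolerant site, and region B (positions
#' 217, 218, 219; wild type `LQE`), a mutation-tolerant site.
#'
#' @param id `"A"` or `"B"`.
#' @return A [region_spec()].
#' @export
protease_region <- function(id = c("A", "B")) {
  id <- match.arg(id)
  switch(id,
    A = region_spec("A", c(167L, 169L, 172L), "HLF"),
    B = region_spec("B", c(217L, 218L, 219L), "LQE")
  )
}

wt_identity <- function(region) paste(region$wildtype, collapse = "")

n_positions <- function(region) length(region$positions)

space_size <- function(region) length(region$alphabet)^n_positions(region)

# "HLF" -> c("H","L","F"); also accepts an already-split character vector.
split_identities <- function(x) {
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  x
}

# Matrix of single letters (n x P) from a vector of identity strings.
identity_matrix <- function(identities, region) {
  P <- n_positions(region)
  if (any(nchar(identities) != P)) {
    stop(sprintf("identities must have exactly %d letters", P), call. = FALSE)
  }
  m <- matrix(unlist(strsplit(identities, "")), ncol = P, byrow = TRUE)
  bad <- !(m %in% region$alphabet)
  if (any(bad)) {
    stop(sprintf("letter(s) outside the alphabet: %s",
                 paste(unique(m[bad]), collapse = ", ")), call. = FALSE)
  }
  m
}

variant_ids <- function(region, identities) {
  paste0(region$region_id, "_", identities)
}

#' Build a variant table
#'
#' Wraps identity strings into the standard variant table used across the
#' package: one row per variant with columns `variant_id`, `region_id`,
#' `identities`.
#'
#' @param region A [region_spec()].
#' @param identities Character vector of identity strings (one letter per
#'   mutable position, e.g. `"HLF"`).
#' @return A tibble with columns `variant_id`, `region_id`, `identities`.
#' @export
new_variants <- function(region, identities) {
  identity_matrix(identities, region)  # validates
  tibble::tibble(
    variant_id = variant_ids(region, identities),
    region_id = region$region_id,
    identities = identities
  )
}

#' Enumerate the full combinatorial sequence space of a region
#'
#' All `20^P` identity strings in deterministic lexicographic order
#' (position-major: the first position is the slowest-varying digit, letters
#' in alphabet order). The wild type always appears exactly once.
#'
#' @param region A [region_spec()].
#' @return Character vector of length `20^P`.
#' @examples
#' head(enumerate_space(protease_region("B")))
#' @export
enumerate_space <- function(region) {
  stopifnot(inherits(region, "region_spec"))
  P <- n_positions(region)
  # expand.grid varies its first factor fastest; feed positions reversed so
  # the *last* position varies fastest, giving lexicographic order.
  grid <- do.call(expand.grid,
                  c(rep(list(region$alphabet), P),
                    list(stringsAsFactors = FALSE)))
  do.call(paste0, rev(grid))
}

#' Design a random combinatorial library
#'
#' Draws `n` distinct variants, each mutable position sampled independently
#' and uniformly from the alphabet; duplicates are rejected and redrawn.
#' By default the wild type is excluded from the draw (it is measured on
#' every plate as the normalization reference, and appended to training sets
#' separately), which is flagged in the result's `"excluded_wt"` attribute.
#'
#' @param region A [region_spec()].
#' @param n Library size; must not exceed the number of eligible variants.
#' @param seed Integer seed; a fixed seed reproduces the library exactly.
#' @param exclude_wt Exclude the wild-type identity from the draw
#'   (default `TRUE`).
#' @return Variant table as from [new_variants()], `n` rows.
#' @examples
#' lib <- random_library(protease_region("B"), n = 48, seed = 1)
#' nrow(lib)
#' @export
random_library <- function(region, n, seed, exclude_wt = TRUE) {
  stopifnot(inherits(region, "region_spec"))
  n <- assert_scalar_count(n, "n")
  total <- space_size(region)
  excluded <- if (exclude_wt) wt_identity(region) else character(0)
  available <- total - length(excluded)
  if (n > available) {
    stop(sprintf(
      "infeasible library: requested %d variants but only %d are available",
      n, available), call. = FALSE)
  }
  alphabet <- region$alphabet
  P <- n_positions(region)
  chosen <- character(0)
  with_seed(seed, {
    attempts <- 0L
    repeat {
      need <- n - length(chosen)
      if (need == 0L) break
      draw <- matrix(sample(alphabet, 2L * need * P, replace = TRUE),
                     ncol = P)
      ids <- do.call(paste0, asplit(draw, 2))
      ids <- setdiff(unique(ids), c(chosen, excluded))
      chosen <- c(chosen, head(ids, need))
      attempts <- attempts + 1L
      if (attempts > 50L && length(chosen) < n) {
        # Dense request: rejection sampling crawls once most of the space is
        # taken; a uniform draw from the remaining enumeration is
        # distributionally identical.
        remaining <- setdiff(enumerate_space(region), c(chosen, excluded))
        chosen <- c(chosen, sample(remaining, n - length(chosen)))
      }
    }
  })
  out <- new_variants(region, chosen)
  attr(out, "excluded_wt") <- exclude_wt
  out
}

#' Per-position amino-acid coverage of a library
#'
#' Counts how often each amino acid occurs at each mutable position and
#' flags uncovered (position, amino-acid) pairs — the in-silico analogue of
#' checking a cloned library for complete amino-acid representation.
#'
#' @param library Variant table or character vector of identity strings.
#' @param region A [region_spec()].
#' @return Object of class `coverage_report`: a list with `counts`
#'   (P x 20 integer matrix, rows named by residue position), `uncovered`
#'   (tibble of zero-count pairs) and `n` (library size).
#' @export
coverage_report <- function(library, region) {
  stopifnot(inherits(region, "region_spec"))
  identities <- if (is.data.frame(library)) library$identities else library
  if (length(identities) == 0) {
    stop("empty library: nothing to report", call. = FALSE)
  }
  m <- identity_matrix(identities, region)
  counts <- vapply(seq_len(ncol(m)), function(j) {
    tabulate(factor(m[, j], levels = region$alphabet),
             nbins = length(region$alphabet))
  }, integer(length(region$alphabet)))
  counts <- t(counts)
  dimnames(counts) <- list(as.character(region$positions), region$alphabet)
  zero <- which(counts == 0, arr.ind = TRUE)
  uncovered <- tibble::tibble(
    position = region$positions[zero[, 1]],
    amino_acid = region$alphabet[zero[, 2]]
  )
  structure(list(counts = counts, uncovered = uncovered,
                 n = length(identities)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %d variants, %d uncovered (position, amino acid) pairs\n",
              x$n, nrow(x$uncovered)))
  print(x$counts)
  invisible(x)
}

#' One-hot encode variants
#'
#' Binary design matrix for the surrogate model: one row per variant,
#' `20 * P` columns laid out position-major (a 20-wide block per mutable
#' position, letters in alphabet order). Exactly one bit is set per block.
#' The encoding carries no physicochemical information.
#'
#' @param identities Character vector of identity strings (or a variant
#'   table, whose `identities` column is used).
#' @param region A [region_spec()].
#' @return Integer matrix, rows named by identity, columns like `"p217.A"`.
#' @seealso [decode_one_hot()] for the inverse.
#' @export
encode_one_hot <- function(identities, region) {
  stopifnot(inherits(region, "region_spec"))
  if (is.data.frame(identities)) identities <- identities$identities
  m <- identity_matrix(identities, region)
  P <- n_positions(region)
  A <- length(region$alphabet)
  out <- matrix(0L, nrow = nrow(m), ncol = P * A)
  for (j in seq_len(P)) {
    k <- match(m[, j], region$alphabet)
    out[cbind(seq_len(nrow(m)), (j - 1L) * A + k)] <- 1L
  }
  colnames(out) <- as.vector(t(outer(region$positions, region$alphabet,
                                     function(p, a) paste0("p", p, ".", a))))
  rownames(out) <- identities
  out
}

#' Decode a one-hot matrix back to identity strings
#'
#' @param bits Matrix as produced by [encode_one_hot()].
#' @param region A [region_spec()].
#' @return Character vector of identity strings.
#' @export
decode_one_hot <- function(bits, region) {
  stopifnot(inherits(region, "region_spec"))
  P <- n_positions(region)
  A <- length(region$alphabet)
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
  if (ncol(bits) != P * A) {
    stop("bit matrix width does not match the region", call. = FALSE)
  }
  unname(apply(bits, 1, function(v) {
    letters_out <- vapply(seq_len(P), function(j) {
      block <- v[((j - 1L) * A + 1L):(j * A)]
      if (sum(block == 1) != 1 || any(!block %in% c(0, 1))) {
        stop("invalid one-hot block: expected exactly one set bit",
             call. = FALSE)
      }
      region$alphabet[which(block == 1)]
    }, character(1))
    paste(letters_out, collapse = "")
  }))
}

#' Write or read a variant table
#'
#' Plain delimited text with columns `variant_id`, `region_id`,
#' `identities` — the hand-off format between design, scoring and proposal
#' steps.
#'
#' @param variants Variant table.
#' @param file Path.
#' @return `read_variant_table` returns a tibble.
#' @export
write_variant_table <- function(variants, file) {
  write.csv(as.data.frame(variants[, c("variant_id", "region_id",
                                       "identities")]),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(file) {
  tibble::as_tibble(read.csv(file, colClasses = "character"))
}

#' Export variants as full-length protein FASTA
#'
#' Applies each variant's substitutions to a full-length scaffold sequence
#' and writes one record per variant (id = `variant_id`). The scaffold must
#' carry the region's wild-type letters at the mutable positions.
#'
#' @param variants Variant table.
#' @param region A [region_spec()].
#' @param scaffold Full-length amino-acid sequence (single string) in the
#'   numbering used by `region$positions`.
#' @param file Output FASTA path.
#' @export
export_fasta <- function(variants, region, scaffold, file) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA export", call. = FALSE)
  }
  stopifnot(inherits(region, "region_spec"), is.character(scaffold),
            length(scaffold) == 1)
  chars <- strsplit(scaffold, "")[[1]]
  if (max(region$positions) > length(chars)) {
    stop("scaffold shorter than the region's residue numbering",
         call. = FALSE)
  }
  if (!identical(chars[region$positions], region$wildtype)) {
    stop("scaffold does not carry the wild-type letters at the mutable positions",
         call. = FALSE)
  }
  m <- identity_matrix(variants$identities, region)
  seqs <- apply(m, 1, function(row) {
    s <- chars
    s[region$positions] <- row
    paste(s, collapse = "")
  })
  set <- Biostrings::AAStringSet(setNames(seqs, variants$variant_id))
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}
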