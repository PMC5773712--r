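#' Residue pair scheme
#'
#' Each of the three pair functions combines a square-root contrast term on
#' one property with a cross-correlation term on a pair of properties:
#' scheme 1 contrasts hydrophobicity and correlates hydrophobicity with
#' hydrophilicity; scheme 2 contrasts hydrophilicity and correlates
#' hydrophobicity with side-chain mass; scheme 3 contrasts side-chain mass
#' and correlates hydrophilicity with side-chain mass.
#'
#' @param scheme_id 1, 2 or 3.
#' @param first_term_property optional override for the property s used in
#'   the square-root term (defaults to `scheme_id`).
#' @return A list of class `pair_scheme` with `scheme_id`,
#'   `first_term_property`, and `cross_pair` (length-2 integer vector).
#' @export
pair_scheme <- function(scheme_id, first_term_property = scheme_id) {
  scheme_id <- as.integer(scheme_id)
  stopifnot(scheme_id %in% 1:3,
            first_term_property %in% 1:3)
  cross <- switch(scheme_id, c(1L, 2L), c(1L, 3L), c(2L, 3L))
  structure(list(scheme_id = scheme_id,
                 first_term_property = as.integer(first_term_property),
                 cross_pair = cross),
            class = "pair_scheme")
}

#' Pair function between two residues
#'
#' Non-negative coupling value between residues `l` and `m`:
#' \deqn{\vartheta(l,m) = \sqrt{\Delta_s^*(l)^2\,|\Delta_s^*(l)-\Delta_s^*(m)|^2}
#'   + \frac{|(\Delta_a^*(l)-\bar\Delta_a^*)(\Delta_b^*(m)-\bar\Delta_b^*)|}
#'          {\sqrt{\sum_l(\Delta_a^*(l)-\bar\Delta_a^*)^2\,
#'                 \sum_m(\Delta_b^*(m)-\bar\Delta_b^*)^2}}}
#' where s is the scheme's contrast property, (a, b) its cross pair, and the
#' bars are means over the 20 residues. Not symmetric in general.
#'
#' @param l,m one-letter residue codes.
#' @param scheme a [pair_scheme()].
#' @param tables normalized 20 x 3 property matrix from [property_table()].
#' @return Non-negative scalar.
#' @export
theta <- function(l, m, scheme, tables = property_table()) {
  tm <- theta_matrix(scheme, tables)
  tm[aa_index(l), aa_index(m)]
}

#' Full 20 x 20 pair-function matrix for a scheme
#'
#' @inheritParams theta
#' @return 20 x 20 matrix with `theta(l, m)` at `[l, m]`.
#' @export
theta_matrix <- function(scheme, tables = property_table()) {
  stopifnot(inherits(scheme, "pair_scheme"),
            is.matrix(tables), nrow(tables) == 20L, ncol(tables) == 3L)
  ds <- tables[, scheme$first_term_property]
  a <- tables[, scheme$cross_pair[1]]
  b <- tables[, scheme$cross_pair[2]]
  ca <- a - mean(a)
  cb <- b - mean(b)
  denom <- sqrt(sum(ca^2) * sum(cb^2))
  # sqrt(x^2 |x - y|^2) = |x| * |x - y|
  first <- abs(ds) * abs(outer(ds, ds, "-"))
  cross <- abs(outer(ca, cb)) / denom
  out <- first + cross
  dimnames(out) <- list(AA_ALPHABET, AA_ALPHABET)
  out
}

#' Adjacency pair counts of a sequence
#'
#' `counts[l, m]` is the number of positions where residue l immediately
#' precedes residue m. Entries sum to N - 1.
#'
#' @param seq a [protein_sequence()] or residue string.
#' @return 20 x 20 integer matrix.
#' @examples
#' count_adjacent_pairs("ACA")
#' @export
count_adjacent_pairs <- function(seq) {
  chars <- seq_chars(seq)
  counts <- matrix(0L, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  n <- length(chars)
  if (n >= 2L) {
    from <- aa_index(chars[-n])
    to <- aa_index(chars[-1L])
    for (t in seq_along(from)) {
      counts[from[t], to[t]] <- counts[from[t], to[t]] + 1L
    }
  }
  counts
}

#' Pair-existence indicator matrix
#'
#' Binary matrix marking which directed residue pairs occur at least once.
#'
#' @param counts 20 x 20 adjacency count matrix.
#' @return 20 x 20 matrix over \{0, 1\}.
#' @export
rho_from_counts <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == 20L), all(counts >= 0))
  out <- (counts > 0) + 0L
  dimnames(out) <- list(AA_ALPHABET, AA_ALPHABET)
  out
}

#' Pair-weighted neighbour sum for one residue
#'
#' The bracket that weights every position-gap factor of the feature
#' component for residue a-hat: 1/38 times the count-weighted pair-function
#' sums over residues adjacent to a-hat, in both directions (k preceding
#' a-hat, and a-hat preceding k, k != a-hat). Absent pairs contribute zero.
#' The constant 38 counts the 2 x 19 directed pair classes.
#'
#' @param residue one-letter code of the focal residue a-hat.
#' @param counts adjacency counts from [count_adjacent_pairs()].
#' @param scheme a [pair_scheme()].
#' @param tables normalized property matrix.
#' @return Non-negative scalar.
#' @export
xy_sums <- function(residue, counts, scheme, tables = property_table()) {
  tm <- theta_matrix(scheme, tables)
  unname(xy_sums_all(counts, tm)[aa_index(residue)])
}

# Vectorized version over all 20 residues, given a precomputed theta matrix.
xy_sums_all <- function(counts, theta_mat) {
  w <- counts * theta_mat
  (colSums(w) + rowSums(w) - 2 * diag(w)) / 38
}
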