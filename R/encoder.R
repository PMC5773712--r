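#' Occurrence profile of a residue in a sequence
#'
#' @param seq a [protein_sequence()] or residue string.
#' @param residue one-letter code.
#' @return List with `residue`, `positions` (1-based, ascending) and
#'   `count`.
#' @export
occurrence_profile <- function(seq, residue) {
  chars <- seq_chars(seq)
  stopifnot(residue %in% AA_ALPHABET)
  pos <- which(chars == residue)
  list(residue = residue, positions = pos, count = length(pos))
}

#' Position-gap factors of an occurrence profile
#'
#' Splits the positional structure of a residue's occurrences into a leading
#' gap (distance from the N-terminus to the first occurrence, kept only when
#' the first occurrence is not at position 1), the internal gaps between
#' consecutive occurrences, and a trailing gap (distance from the last
#' occurrence to the C-terminus, kept only when the last occurrence is not
#' terminal).
#'
#' @param profile result of [occurrence_profile()].
#' @param n sequence length.
#' @return List with numeric `leading` (length 0 or 1), `internal`
#'   (length count - 1) and `trailing` (length 0 or 1); all empty when the
#'   residue never occurs.
#' @export
gap_terms <- function(profile, n) {
  pos <- profile$positions
  if (length(pos) == 0L) {
    return(list(leading = numeric(0), internal = numeric(0),
                trailing = numeric(0)))
  }
  stopifnot(n >= max(pos))
  leading <- if (pos[1] > 1L) pos[1] else numeric(0)
  internal <- if (length(pos) >= 2L) diff(pos) else numeric(0)
  trailing <- if (pos[length(pos)] < n) n - pos[length(pos)] else numeric(0)
  list(leading = as.numeric(leading), internal = as.numeric(internal),
       trailing = as.numeric(trailing))
}

# (count - 1)! computed via lgamma with a saturation cap so that extreme
# occurrence counts cannot overflow to Inf; inputs are capped at <= 100
# occurrences by the encoder's truncation rule, for which the factorial is
# still finite in double precision.
factorial_capped <- function(count, cap = 1e300) {
  if (count < 1L) return(0)
  min(exp(lgamma(count)), cap)
}

#' Single feature component for one residue under one pair scheme
#'
#' The component combines the occurrence count, a factorial-weighted
#' self-pair term, and every retained position-gap factor weighted by the
#' residue's pair-weighted neighbour sum ([xy_sums()]):
#' \deqn{\Pi_a = \Lambda_a + (\Lambda_a - 1)!\,\vartheta(a,a) +
#'   \sum_{g \in gaps} g \cdot XY_a}
#' A residue that never occurs contributes 0.
#'
#' @inheritParams occurrence_profile
#' @param scheme a [pair_scheme()].
#' @param tables normalized property matrix.
#' @return Scalar component value.
#' @export
residue_component <- function(seq, residue, scheme, tables = property_table()) {
  chars <- seq_chars(seq)
  prof <- occurrence_profile(paste(chars, collapse = ""), residue)
  if (prof$count == 0L) return(0)
  tm <- theta_matrix(scheme, tables)
  counts <- count_adjacent_pairs(paste(chars, collapse = ""))
  xy <- xy_sums_all(counts, tm)[aa_index(residue)]
  g <- gap_terms(prof, length(chars))
  unname(prof$count + factorial_capped(prof$count) * tm[residue, residue] +
           sum(c(g$leading, g$internal, g$trailing)) * xy)
}

# Names for the 220 feature columns, fixed layout:
# 3 property blocks x (core, lead, trail) x 20 residues, then composition
# and mean-position blocks.
feature_names <- function() {
  props <- c("hydrophobicity", "hydrophilicity", "side_chain_mass")
  prop_part <- unlist(lapply(props, function(p) {
    unlist(lapply(c("core", "lead", "trail"), function(part) {
      paste(p, part, AA_ALPHABET, sep = "_")
    }))
  }))
  c(prop_part,
    paste("comp", AA_ALPHABET, sep = "_"),
    paste("pos", AA_ALPHABET, sep = "_"))
}

#' Encode a protein sequence as a 220-element feature vector
#'
#' The vector has five named blocks. For each of the three physicochemical
#' scales (hydrophobicity, hydrophilicity, side-chain mass, each under its
#' own pair scheme) there are 60 components: for every residue a "core"
#' component (occurrence count + factorial self-pair term + internal-gap
#' weighted neighbour sum), a "lead" component (leading-gap weighted
#' neighbour sum) and a "trail" component (trailing-gap weighted neighbour
#' sum). The sum of the three equals the residue's full feature component
#' [residue_component()]. The last 40 elements are the length-normalized
#' composition (count / N) and mean position (mean(positions) / N, 0 when
#' absent) of each residue.
#'
#' Sequences longer than `truncate` residues are truncated from the
#' N-terminus first, mirroring the dataset curation rule and bounding the
#' factorial self-term.
#'
#' @param seq a [protein_sequence()] or residue string, length >= 2.
#' @param tables normalized 20 x 3 property matrix.
#' @param truncate maximum number of leading residues encoded (default 100;
#'   `Inf` disables truncation).
#' @return Named numeric vector of length 220.
#' @examples
#' v <- encode_sequence("MKWVTFISLLLLFSSAYS")
#' length(v)
#' @export
encode_sequence <- function(seq, tables = property_table(), truncate = 100) {
  chars <- seq_chars(seq)
  if (length(chars) < 2L) {
    stop("sequence must have at least 2 residues to encode", call. = FALSE)
  }
  if (length(chars) > truncate) chars <- chars[seq_len(truncate)]
  n <- length(chars)
  idx <- aa_index(chars)

  counts <- count_adjacent_pairs(paste(chars, collapse = ""))
  pos_by_res <- split(seq_len(n), factor(idx, levels = 1:20))

  lam <- lengths(pos_by_res)
  self_fact <- vapply(lam, factorial_capped, numeric(1))

  lead_gap <- trail_gap <- internal_gap <- numeric(20)
  for (r in 1:20) {
    pos <- pos_by_res[[r]]
    if (length(pos) == 0L) next
    if (pos[1] > 1L) lead_gap[r] <- pos[1]
    if (pos[length(pos)] < n) trail_gap[r] <- n - pos[length(pos)]
    if (length(pos) >= 2L) internal_gap[r] <- sum(diff(pos))
  }

  prop_blocks <- lapply(1:3, function(s) {
    tm <- theta_matrix(pair_scheme(s), tables)
    xy <- xy_sums_all(counts, tm)
    core <- ifelse(lam > 0, lam + self_fact * diag(tm) + internal_gap * xy, 0)
    c(core, lead_gap * xy, trail_gap * xy)
  })

  comp <- lam / n
  mean_pos <- vapply(pos_by_res, function(p) {
    if (length(p)) mean(p) else 0
  }, numeric(1)) / n

  out <- c(unlist(prop_blocks), comp, mean_pos)
  names(out) <- feature_names()
  out
}

#' Encode a set of sequences into a feature matrix
#'
#' @param seqs list of [protein_sequence()] objects or character vector of
#'   residue strings (names become row names).
#' @inheritParams encode_sequence
#' @return Numeric matrix, one row per sequence, 220 named columns.
#' @export
encode_set <- function(seqs, tables = property_table(), truncate = 100) {
  if (is.character(seqs)) {
    ids <- if (!is.null(names(seqs))) names(seqs) else as.character(seq_along(seqs))
    seqs <- as.list(seqs)
  } else {
    ids <- vapply(seqs, function(s) {
      if (inherits(s, "protein_sequence")) s$id else "seq"
    }, character(1))
  }
  out <- t(vapply(seqs, encode_sequence, numeric(220),
                  tables = tables, truncate = truncate))
  rownames(out) <- ids
  out
}
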