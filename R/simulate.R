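#' Background amino acid composition
#'
#' A cytoplasmic-like residue composition (approximate database-wide
#' frequencies), used as the default negative-class composition of the
#' generator and as the default expected abundance of the cleavage weight
#' matrix.
#'
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
aa_background <- function() {
  bg <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.7, F = 3.9, G = 7.1, H = 2.3,
          I = 5.9, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 3.9,
          R = 5.5, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)
  bg / sum(bg)
}

#' Specification of the synthetic signal-peptide generator
#'
#' Positives follow the three-region anatomy of signal peptides: a short
#' basic n-region (1-5 residues, at least one Lys/Arg), a central
#' hydrophobic h-region (7-15 residues), and a polar c-region (3-7 residues)
#' whose -3 and -1 positions satisfy the organism's cleavage rule, followed
#' by a mature region drawn from the background composition. The planted
#' cleavage site (the +1 position) is recorded and rule-compliant by
#' construction. Negatives are drawn from the background composition with no
#' planted structure.
#'
#' @param n_pos,n_neg numbers of positive and negative sequences.
#' @param organism `"eukaryote"` or `"prokaryote"` (selects the c-region
#'   rule residues).
#' @param n_region_len,h_region_len,c_region_len,mature_len length-2 integer
#'   ranges sampled uniformly.
#' @param seed integer seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 200L, n_neg = 200L,
                           organism = c("eukaryote", "prokaryote"),
                           n_region_len = c(1L, 5L),
                           h_region_len = c(7L, 15L),
                           c_region_len = c(3L, 7L),
                           mature_len = c(30L, 80L),
                           seed = 1L) {
  organism <- match.arg(organism)
  spec <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
               organism = organism,
               n_region_len = as.integer(n_region_len),
               h_region_len = as.integer(h_region_len),
               c_region_len = as.integer(c_region_len),
               mature_len = as.integer(mature_len),
               seed = as.integer(seed))
  if (spec$c_region_len[1] < 3L) {
    stop("c-region must be at least 3 residues to host the -3..-1 sites",
         call. = FALSE)
  }
  total_min <- spec$n_region_len[1] + spec$h_region_len[1] + spec$c_region_len[1]
  total_max <- spec$n_region_len[2] + spec$h_region_len[2] + spec$c_region_len[2]
  if (total_min < 3L || total_max > 60L) {
    stop("signal length range must lie within 3..60 residues", call. = FALSE)
  }
  class(spec) <- "synthetic_spec"
  spec
}

# Residue pools for the three signal regions.
N_REGION_POOL <- c(K = 3, R = 3, M = 1, N = 1, Q = 1, S = 1)
H_REGION_POOL <- c(L = 5, A = 3, V = 2, I = 2, F = 2, W = 1, M = 1)
# c-region: polar but uncharged, small-residue biased
C_REGION_POOL <- c(S = 3, T = 2, A = 2, G = 2, N = 1, Q = 1)

sample_pool <- function(pool, n) {
  sample(names(pool), n, replace = TRUE, prob = pool)
}

#' Generate a synthetic labelled dataset with planted cleavage sites
#'
#' @param spec a [synthetic_spec()].
#' @return List with `positives` (list of [protein_sequence()]), `negatives`
#'   (likewise), `sites` (data.frame of id and planted +1 cleavage position)
#'   and `spec`. Fully reproducible from `spec$seed`.
#' @examples
#' d <- generate_synthetic(synthetic_spec(n_pos = 5, n_neg = 5, seed = 7))
#' d$sites
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  rules <- rule_set(if (spec$organism == "eukaryote") "eukaryote" else "prokaryote")
  bg <- aa_background()

  draw_len <- function(rng) sample(rng[1]:rng[2], 1L)

  positives <- vector("list", spec$n_pos)
  sites <- integer(spec$n_pos)
  for (i in seq_len(spec$n_pos)) {
    n_len <- draw_len(spec$n_region_len)
    h_len <- draw_len(spec$h_region_len)
    c_len <- draw_len(spec$c_region_len)
    m_len <- draw_len(spec$mature_len)

    n_reg <- sample_pool(N_REGION_POOL, n_len)
    n_reg[sample.int(n_len, 1L)] <- sample(c("K", "R"), 1L)
    h_reg <- sample_pool(H_REGION_POOL, h_len)
    c_reg <- sample_pool(C_REGION_POOL, c_len)
    # plant rule compliance at -3 and -1; -2 polar and never proline
    c_reg[c_len - 2L] <- sample(setdiff(rules$allowed_minus3,
                                        rules$forbidden_minus3), 1L)
    c_reg[c_len] <- sample(rules$allowed_minus1, 1L)
    mature <- sample(AA_ALPHABET, m_len, replace = TRUE, prob = bg)
    mature[1L] <- sample(setdiff(AA_ALPHABET, "P"), 1L,
                         prob = bg[setdiff(AA_ALPHABET, "P")])
    residues <- paste(c(n_reg, h_reg, c_reg, mature), collapse = "")
    id <- sprintf("pos_%04d", i)
    positives[[i]] <- protein_sequence(residues, id = id)
    sites[i] <- n_len + h_len + c_len + 1L
  }

  negatives <- lapply(seq_len(spec$n_neg), function(i) {
    m_len <- draw_len(spec$mature_len) + draw_len(spec$h_region_len) +
      draw_len(spec$n_region_len) + draw_len(spec$c_region_len)
    residues <- c("M", sample(AA_ALPHABET, m_len - 1L, replace = TRUE, prob = bg))
    protein_sequence(paste(residues, collapse = ""),
                     id = sprintf("neg_%04d", i))
  })

  list(positives = positives, negatives = negatives,
       sites = data.frame(id = vapply(positives, `[[`, character(1), "id"),
                          site = sites),
       spec = spec)
}

#' Extract aligned cleavage windows from generated positives
#'
#' Cuts the window spanning `upstream` residues before the cleavage bond and
#' `downstream` after it (default -13..+2) from each positive, padding short
#' N-terminal context is not needed because generated signals are at least
#' 11 residues; sequences whose site is closer than `upstream` to the start
#' are skipped.
#'
#' @param dataset result of [generate_synthetic()].
#' @param upstream,downstream window extent in residues.
#' @return Character vector of equal-length windows.
#' @export
cleavage_windows <- function(dataset, upstream = 13L, downstream = 2L) {
  seqs <- vapply(dataset$positives, `[[`, character(1), "residues")
  sites <- dataset$sites$site
  keep <- sites > upstream & (sites + downstream - 1L) <= nchar(seqs)
  substr(seqs[keep], sites[keep] - upstream, sites[keep] + downstream - 1L)
}
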