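#' Residue constraints around the cleavage site: the (-3,-1) rule
#'
#' Returns the residue-identity rule set applied at the positions
#' immediately N-terminal of the cleavage bond. For eukaryotes, position -1
#' must hold Ala, Ser, Gly, Cys or Thr and position -3 one of Asp, Glu, Lys,
#' Arg, Asn, Gln (never Phe, His, Tyr, Trp). For prokaryotes, -1 holds Ala,
#' Gly, Ser or Thr and -3 one of Ala, Gly, Leu, Ser, Thr, Val; positions -7
#' and -8 additionally prefer Leu or another hydrophobic residue other than
#' Val or Phe (a preference recorded on the rule set, not enforced by
#' [rule_check()]). In every case no Pro may occur between -3 and +1.
#'
#' The eukaryotic -3 set above follows the source description verbatim; it
#' differs from the classical small-neutral-residue rule, which is available
#' as `rule_set("classic_von_heijne")`.
#'
#' @param organism `"eukaryote"`, `"prokaryote"` or `"classic_von_heijne"`.
#' @return A list of class `sp_rules` with the residue sets and the proline
#'   exclusion window (relative positions -3..+1).
#' @export
rule_set <- function(organism = c("eukaryote", "prokaryote",
                                  "classic_von_heijne")) {
  organism <- match.arg(organism)
  rs <- switch(organism,
    eukaryote = list(
      allowed_minus1 = c("A", "S", "G", "C", "T"),
      allowed_minus3 = c("D", "E", "K", "R", "N", "Q"),
      forbidden_minus3 = c("F", "H", "Y", "W"),
      hydrophobic_pref_positions = integer(0),
      hydrophobic_pref_excluded = character(0)),
    prokaryote = list(
      allowed_minus1 = c("A", "G", "S", "T"),
      allowed_minus3 = c("A", "G", "L", "S", "T", "V"),
      forbidden_minus3 = character(0),
      hydrophobic_pref_positions = c(-7L, -8L),
      hydrophobic_pref_excluded = c("V", "F")),
    classic_von_heijne = list(
      allowed_minus1 = c("A", "G", "S", "C", "T"),
      allowed_minus3 = c("A", "G", "S", "C", "T", "V", "L", "I"),
      forbidden_minus3 = character(0),
      hydrophobic_pref_positions = integer(0),
      hydrophobic_pref_excluded = character(0))
  )
  rs$organism <- organism
  rs$no_proline_window <- c(-3L, 1L)
  class(rs) <- "sp_rules"
  rs
}

#' Test a candidate cleavage site against the (-3,-1) rule
#'
#' The site is the 1-based index of the +1 residue (first residue of the
#' mature protein); the cleavage bond lies between positions site-1 and
#' site. Signal peptides span 3-60 residues, so admissible sites lie in
#' 4..min(N - 1, 61).
#'
#' @param seq a [protein_sequence()] or residue string.
#' @param site candidate +1 position.
#' @param rules a [rule_set()].
#' @return `TRUE` if the -1 and -3 residues satisfy the rule set and no
#'   proline occurs in the -3..+1 window.
#' @export
rule_check <- function(seq, site, rules = rule_set("eukaryote")) {
  chars <- seq_chars(seq)
  n <- length(chars)
  if (site < 4L || site > min(n - 1L, 61L)) {
    stop("candidate site ", site, " outside admissible range 4..",
         min(n - 1L, 61L), call. = FALSE)
  }
  minus1 <- chars[site - 1L]
  minus3 <- chars[site - 3L]
  window <- chars[(site - 3L):(site)]   # -3, -2, -1, +1
  minus1 %in% rules$allowed_minus1 &&
    minus3 %in% rules$allowed_minus3 &&
    !(minus3 %in% rules$forbidden_minus3) &&
    !("P" %in% window)
}

#' Build a cleavage-site position weight matrix
#'
#' Counts residues at every aligned column of the training windows (windows
#' are sequence fragments aligned on the cleavage bond, by default spanning
#' positions -13..+2) and converts counts to natural-log ratios against a
#' background composition:
#' \deqn{Q(a, i) = \ln\frac{P(a,i) + c}{\langle P(a)\rangle\,(n + 20c)}}
#' with pseudocount c (default 1; c = 0 yields -Inf sentinels for unseen
#' residues and is rejected unless `allow_zero_counts = TRUE`).
#'
#' @param aligned_windows character vector of equal-length residue strings.
#' @param background named numeric vector of expected residue abundances
#'   (strictly positive, summing to 1); defaults to a cytoplasmic-like
#'   composition ([aa_background()]).
#' @param pseudocount non-negative smoothing constant.
#' @param positions integer vector of relative positions labelling the
#'   window columns (0 is skipped: positions run ...,-2,-1,+1,+2,...).
#' @param allow_zero_counts permit -Inf entries when `pseudocount = 0`.
#' @return An object of class `sp_cleavage`: the `Q` matrix (20 residues x
#'   window columns), `positions`, `pseudocount`, `background`, `n_windows`.
#' @export
cleavage_model <- function(aligned_windows, background = aa_background(),
                           pseudocount = 1, positions = NULL,
                           allow_zero_counts = FALSE) {
  stopifnot(length(aligned_windows) >= 1L)
  width <- unique(nchar(aligned_windows))
  if (length(width) != 1L) {
    stop("aligned windows must all have the same length", call. = FALSE)
  }
  if (is.null(names(background)) || !setequal(names(background), AA_ALPHABET)) {
    stop("background must be named over the 20 canonical residues", call. = FALSE)
  }
  background <- background[AA_ALPHABET]
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-8) {
    stop("background must be strictly positive and sum to 1", call. = FALSE)
  }
  if (is.null(positions)) {
    # default alignment: last two columns are +1, +2 (mature side)
    positions <- c(seq.int(-(width - 2L), -1L), 1L, 2L)
  }
  stopifnot(length(positions) == width)

  mat <- do.call(rbind, strsplit(aligned_windows, "", fixed = TRUE))
  counts <- apply(mat, 2, function(col) {
    tabulate(aa_index(col), nbins = 20L)
  })
  rownames(counts) <- AA_ALPHABET
  n <- length(aligned_windows)
  q <- log((counts + pseudocount) /
             (background * (n + 20 * pseudocount)))
  if (pseudocount == 0 && any(!is.finite(q)) && !allow_zero_counts) {
    stop("zero counts with zero pseudocount produce -Inf entries; ",
         "use a positive pseudocount or allow_zero_counts = TRUE",
         call. = FALSE)
  }
  colnames(q) <- as.character(positions)
  structure(list(Q = q, positions = as.integer(positions),
                 pseudocount = pseudocount, background = background,
                 n_windows = n),
            class = "sp_cleavage")
}

#' @export
print.sp_cleavage <- function(x, ...) {
  cat(sprintf("<sp_cleavage> log-ratio weight matrix, %d windows, positions %d..%+d, pseudocount %g\n",
              x$n_windows, min(x$positions), max(x$positions), x$pseudocount))
  invisible(x)
}

# Score one candidate site: sum Q over window columns that fall inside the
# sequence (sites close to the N-terminus clip the left edge of the window).
score_site <- function(chars, site, model) {
  rel <- model$positions
  abs_pos <- ifelse(rel < 0, site + rel, site + rel - 1L)
  keep <- abs_pos >= 1L & abs_pos <= length(chars)
  sum(model$Q[cbind(aa_index(chars[abs_pos[keep]]), which(keep))])
}

#' Scan a sequence for its most likely cleavage site
#'
#' Every candidate +1 position in 4..min(61, N-1) is tested against the
#' (-3,-1) rule; compliant candidates are scored by summing the weight
#' matrix over the aligned window, non-compliant positions score 0 and are
#' never returned. The maximal-scoring compliant site wins; exact ties go to
#' the most N-terminal site.
#'
#' @param seq a [protein_sequence()] or residue string, length >= 5.
#' @param model an [cleavage_model()].
#' @param rules a [rule_set()].
#' @return List with `site` (the +1 position), `score`, and `scores`
#'   (a named vector over all candidates, 0 where non-compliant), or `NULL`
#'   when no candidate passes the rule.
#' @export
scan_cleavage <- function(seq, model, rules = rule_set("eukaryote")) {
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 5L) stop("sequence too short to scan (need >= 5 residues)", call. = FALSE)
  cand <- 4L:min(61L, n - 1L)
  ok <- vapply(cand, function(s) rule_check(paste(chars, collapse = ""), s, rules),
               logical(1))
  scores <- numeric(length(cand))
  scores[ok] <- vapply(cand[ok], score_site, numeric(1),
                       chars = chars, model = model)
  names(scores) <- cand
  if (!any(ok)) return(NULL)
  best <- cand[ok][which.max(scores[ok])]
  list(site = best, score = scores[as.character(best)][[1]], scores = scores)
}

#' Locate cleavage sites in a set of sequences
#'
#' @param object an `sp_cleavage` model.
#' @param newdata list of [protein_sequence()] objects or character vector.
#' @param rules a [rule_set()].
#' @param ... unused.
#' @return data.frame with columns `id`, `site` (NA when no compliant
#'   candidate), `score`, `signal_seq`, `mature_prefix`.
#' @export
predict.sp_cleavage <- function(object, newdata,
                                rules = rule_set("eukaryote"), ...) {
  if (is.character(newdata)) {
    ids <- if (!is.null(names(newdata))) names(newdata) else as.character(seq_along(newdata))
    seqs <- newdata
  } else {
    ids <- vapply(newdata, `[[`, character(1), "id")
    seqs <- vapply(newdata, `[[`, character(1), "residues")
  }
  rows <- lapply(seq_along(seqs), function(i) {
    hit <- scan_cleavage(seqs[i], object, rules)
    if (is.null(hit)) {
      data.frame(id = ids[i], site = NA_integer_, score = NA_real_,
                 signal_seq = NA_character_, mature_prefix = NA_character_)
    } else {
      data.frame(id = ids[i], site = hit$site, score = hit$score,
                 signal_seq = substr(seqs[i], 1, hit$site - 1),
                 mature_prefix = substr(seqs[i], hit$site,
                                        min(nchar(seqs[i]), hit$site + 9)))
    }
  })
  do.call(rbind, rows)
}

#' Write / read a cleavage weight matrix as TSV
#'
#' Rows are residues, columns the aligned relative positions.
#'
#' @param model an `sp_cleavage`.
#' @param path file path.
#' @export
write_cleavage_matrix <- function(model, path) {
  tab <- data.frame(residue = rownames(model$Q), model$Q, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cleavage_matrix
#' @param background background composition to attach on read.
#' @export
read_cleavage_matrix <- function(path, background = aa_background()) {
  tab <- utils::read.delim(path, check.names = FALSE)
  q <- as.matrix(tab[, -1, drop = FALSE])
  rownames(q) <- tab$residue
  structure(list(Q = q, positions = as.integer(colnames(q)),
                 pseudocount = NA_real_, background = background,
                 n_windows = NA_integer_),
            class = "sp_cleavage")
}
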