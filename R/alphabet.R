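#' The canonical 20-residue amino acid alphabet
#'
#' One-letter codes in alphabetical order. All feature matrices, weight
#' matrices and property tables in the package are indexed in this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Ordinal index of a residue in the canonical alphabet
#'
#' @param residue character vector of one-letter residue codes.
#' @return Integer vector of indices in 1..20.
#' @examples
#' aa_index(c("A", "Y"))
#' @export
aa_index <- function(residue) {
  idx <- match(residue, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(residue[is.na(idx)])
    stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

# Validate (and optionally repair) a residue string against the alphabet.
# Non-standard residues (B, Z, X, U, O, ...) are rejected unless a stand-in
# is supplied, because silent coercion corrupts the encoder.
validate_residues <- function(residues, nonstandard = c("error", "map"),
                              map_to = "A", id = NULL) {
  nonstandard <- match.arg(nonstandard)
  residues <- toupper(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    if (nonstandard == "error") {
      stop("non-standard residue(s) ",
           paste(unique(chars[bad]), collapse = ", "),
           if (!is.null(id)) paste0(" in record '", id, "'"),
           "; use nonstandard = \"map\" to substitute a stand-in",
           call. = FALSE)
    }
    stopifnot(map_to %in% AA_ALPHABET)
    chars[bad] <- map_to
  }
  paste(chars, collapse = "")
}

#' Construct a validated protein sequence record
#'
#' @param residues residue string over the 20-letter alphabet.
#' @param id sequence identifier.
#' @param nonstandard policy for residues outside the canonical alphabet:
#'   `"error"` (default) rejects them, `"map"` substitutes `map_to`.
#' @param map_to stand-in residue used when `nonstandard = "map"`.
#' @return A list of class `protein_sequence` with elements `id`, `residues`
#'   and `n` (sequence length).
#' @examples
#' protein_sequence("MKWVTFISLL", id = "demo")
#' @export
protein_sequence <- function(residues, id = "seq",
                             nonstandard = c("error", "map"), map_to = "A") {
  stopifnot(is.character(residues), length(residues) == 1L, nchar(residues) >= 1L)
  residues <- validate_residues(residues, nonstandard, map_to, id = id)
  structure(list(id = id, residues = residues, n = nchar(residues)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  shown <- if (x$n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<protein_sequence> %s (%d aa)\n%s\n", x$id, x$n, shown))
  invisible(x)
}

# Accept either a protein_sequence or a bare string; return residue chars.
seq_chars <- function(seq) {
  if (inherits(seq, "protein_sequence")) seq <- seq$residues
  stopifnot(is.character(seq), length(seq) == 1L)
  strsplit(seq, "", fixed = TRUE)[[1]]
}
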