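#' Read protein sequences from FASTA
#'
#' Thin wrapper over Biostrings. Duplicate identifiers are made unique by
#' suffixing (with a warning); residues are validated against the canonical
#' alphabet under the chosen non-standard-residue policy.
#'
#' @param path FASTA file.
#' @param nonstandard `"error"` (default) or `"map"`; see
#'   [protein_sequence()].
#' @param map_to stand-in residue used when `nonstandard = "map"`.
#' @return List of [protein_sequence()] objects (empty list for an empty
#'   file).
#' @export
read_fasta <- function(path, nonstandard = c("error", "map"), map_to = "A") {
  nonstandard <- match.arg(nonstandard)
  if (file.size(path) == 0) return(list())
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids made unique by suffixing", call. = FALSE)
    ids <- make.unique(ids, sep = "_")
  }
  mapply(function(s, id) protein_sequence(s, id = id,
                                          nonstandard = nonstandard,
                                          map_to = map_to),
         as.character(ss), ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein sequences to FASTA
#'
#' Lines are wrapped at 60 columns. Round-trips with [read_fasta()].
#'
#' @param records list of [protein_sequence()] objects or named character
#'   vector.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    seqs <- records
    ids <- names(records)
  } else {
    seqs <- vapply(records, `[[`, character(1), "residues")
    ids <- vapply(records, `[[`, character(1), "id")
  }
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read an annotation table
#'
#' The table is a tab-separated file with columns `id`, `oc` (organism
#' classification), `location` (subcellular location), `signal_start`,
#' `signal_end` (empty/NA when no signal-peptide feature), `keywords`
#' (semicolon-separated free text) and `sequence`. It stands in for the
#' database fields used during dataset curation; live database querying is
#' out of scope.
#'
#' @param path TSV file.
#' @return data.frame of class `annotated_records`.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "oc", "location", "signal_start", "signal_end",
            "keywords", "sequence")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("id", "oc", "location", "keywords", "sequence")) {
    tab[[col]] <- as.character(tab[[col]])
    tab[[col]][is.na(tab[[col]])] <- ""
  }
  tab$signal_start <- suppressWarnings(as.integer(tab$signal_start))
  tab$signal_end <- suppressWarnings(as.integer(tab$signal_end))
  class(tab) <- c("annotated_records", class(tab))
  tab
}

# Exclusion keywords marking ambiguous signal-peptide annotations.
CURATION_EXCLUDE_KEYWORDS <- c("potential", "probable", "fragment",
                               "by similarity")

#' Curate annotated records into a benchmark class
#'
#' For the secretory role, keeps records carrying a signal-peptide
#' annotation and none of the ambiguous keywords (potential, probable,
#' fragment, by similarity; case-insensitive substring match on the keyword
#' field), then truncates each retained sequence to its first 100 residues.
#' For the non-secretory role, keeps records located in the nucleus or
#' cytoplasm (cytoplasm only for prokaryotes); non-secretory sequences are
#' not truncated. In both roles the organism classification field is
#' filtered by substring match and exact duplicate sequences are removed
#' (first occurrence kept).
#'
#' @param records an `annotated_records` data.frame ([read_annotations()]).
#' @param role `"secretory"` or `"non_secretory"`.
#' @param organism `"eukaryote"`, `"gram_positive"` or `"gram_negative"`.
#' @param truncate_at truncation length for secretory sequences (default
#'   100).
#' @return The curated subset, same class as the input (so the operation is
#'   idempotent); convert with [as_protein_sequences()].
#' @export
curate <- function(records, role = c("secretory", "non_secretory"),
                   organism = c("eukaryote", "gram_positive", "gram_negative"),
                   truncate_at = 100L) {
  role <- match.arg(role)
  organism <- match.arg(organism)
  oc_pattern <- switch(organism,
                       eukaryote = "eukaryot",
                       gram_positive = "gram-positive",
                       gram_negative = "gram-negative")
  keep <- grepl(oc_pattern, tolower(records$oc), fixed = TRUE)

  if (role == "secretory") {
    has_signal <- !is.na(records$signal_start) & !is.na(records$signal_end)
    kw <- tolower(records$keywords)
    ambiguous <- Reduce(`|`, lapply(CURATION_EXCLUDE_KEYWORDS, function(w) {
      grepl(w, kw, fixed = TRUE)
    }))
    keep <- keep & has_signal & !ambiguous
    out <- records[keep, , drop = FALSE]
    out$sequence <- substr(out$sequence, 1L, truncate_at)
  } else {
    loc <- tolower(records$location)
    allowed <- if (organism == "eukaryote") {
      grepl("nucleus", loc, fixed = TRUE) | grepl("cytoplasm", loc, fixed = TRUE)
    } else {
      grepl("cytoplasm", loc, fixed = TRUE)
    }
    out <- records[keep & allowed, , drop = FALSE]
  }
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("curate(%s, %s): %d of %d records retained",
                  role, organism, nrow(out), nrow(records)))
  out
}

#' Convert curated records to protein sequences
#'
#' @param records an `annotated_records` data.frame.
#' @inheritParams read_fasta
#' @return List of [protein_sequence()] objects.
#' @export
as_protein_sequences <- function(records, nonstandard = c("error", "map"),
                                 map_to = "A") {
  nonstandard <- match.arg(nonstandard)
  mapply(function(s, id) protein_sequence(s, id = id,
                                          nonstandard = nonstandard,
                                          map_to = map_to),
         records$sequence, records$id, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
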