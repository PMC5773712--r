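#' Raw physicochemical property table
#'
#' Reads the property scales shipped with the package: Tanford
#' hydrophobicity, Hopp-Woods hydrophilicity and textbook side-chain masses
#' (Da), one row per residue in the canonical alphabetical order.
#'
#' @param path optional path to an alternative tab-separated table with
#'   columns `residue`, `hydrophobicity`, `hydrophilicity`,
#'   `side_chain_mass`.
#' @return A data.frame with 20 rows, rownames = residues.
#' @export
aa_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "sigscan",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "hydrophobicity", "hydrophilicity", "side_chain_mass")
  if (!all(need %in% names(tab))) {
    stop("property table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(tab$residue, AA_ALPHABET)) {
    stop("property table must cover exactly the 20 canonical residues",
         call. = FALSE)
  }
  tab <- tab[match(AA_ALPHABET, tab$residue), ]
  rownames(tab) <- tab$residue
  tab
}

#' Standardize a property scale to the interval [-R, R]
#'
#' Affine rescaling that sends the scale maximum to `R`, the minimum to
#' `-R`, and the midpoint to 0:
#' \deqn{\Delta^* = \frac{2R}{\Delta_{max}-\Delta_{min}}(\Delta-\Delta_{max}) + R}
#' Order within the scale is preserved.
#'
#' @param raw_values named numeric vector, one value per canonical residue.
#' @param R positive half-range of the standardized scale (default 1).
#' @return Named numeric vector spanning exactly \[-R, R\].
#' @examples
#' p <- aa_properties()
#' normalize_property(setNames(p$hydrophobicity, p$residue))
#' @export
normalize_property <- function(raw_values, R = 1) {
  if (!is.numeric(raw_values) || is.null(names(raw_values))) {
    stop("raw_values must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(AA_ALPHABET, names(raw_values))
  if (length(missing)) {
    stop("missing residue(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    stop("R must be a single positive number", call. = FALSE)
  }
  raw_values <- raw_values[AA_ALPHABET]
  dmax <- max(raw_values)
  dmin <- min(raw_values)
  if (dmax == dmin) {
    stop("degenerate scale: max equals min, cannot standardize", call. = FALSE)
  }
  (2 * R / (dmax - dmin)) * (raw_values - dmax) + R
}

#' Normalized property table for the three scales
#'
#' Applies [normalize_property()] to hydrophobicity, hydrophilicity and
#' side-chain mass. Property index s = 1, 2, 3 corresponds to the three
#' scales in that order throughout the package.
#'
#' @param R standardization half-range (default 1).
#' @param raw optional raw table as returned by [aa_properties()].
#' @return A 20 x 3 numeric matrix, rows = residues, columns =
#'   `hydrophobicity`, `hydrophilicity`, `side_chain_mass`, values in
#'   \[-R, R\].
#' @export
property_table <- function(R = 1, raw = aa_properties()) {
  cols <- c("hydrophobicity", "hydrophilicity", "side_chain_mass")
  out <- vapply(cols, function(cn) {
    normalize_property(stats::setNames(raw[[cn]], raw$residue), R = R)
  }, numeric(20))
  rownames(out) <- AA_ALPHABET
  out
}

#' Mean of a normalized property over the 20 residues
#'
#' @param normalized named numeric vector of 20 normalized values.
#' @return Arithmetic mean.
#' @export
property_mean <- function(normalized) {
  missing <- setdiff(AA_ALPHABET, names(normalized))
  if (length(missing)) {
    stop("missing residue(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  mean(normalized[AA_ALPHABET])
}
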