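#' Load a physicochemical property table
#'
#' The table is a TSV with one row per property scale and one column per
#' standard residue (header row of the 20 one-letter codes plus a leading
#' `property` column).  Each scale must be non-degenerate (max > min), since
#' the PCP encoding min-max normalises the sequence-average property over
#' the 20 per-residue scale values.
#'
#' @param path TSV path; defaults to the table shipped with the package,
#'   which covers the nine properties used by the predictor: hydrophobicity
#'   (Kyte-Doolittle), hydrophilicity (Hopp-Woods), polarity (Grantham),
#'   polarizability (Charton), transfer free energy (Janin), solvent contact
#'   area (Chothia), positive charge, flexibility (Bhaskaran-Ponnuswamy) and
#'   a protein-kinase-A substrate propensity.  The last scale is a synthetic
#'   default constructed for this package (no canonical published scale
#'   exists under that name); substitute your own table to change it.
#' @return matrix with properties as rows and the 20 residues as columns,
#'   class `pcp_table`.
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pcp_scales_default.tsv",
                        package = "lumipred", mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (names(tab)[1] != "property")
    stop("first column of a property table must be `property`")
  if (!setequal(names(tab)[-1], AA_ALPHABET))
    stop("property table must have exactly the 20 standard residue columns")
  mat <- as.matrix(tab[, AA_ALPHABET])
  rownames(mat) <- tab$property
  if (!all(is.finite(mat))) stop("property table contains non-finite values")
  rng <- apply(mat, 1, function(v) max(v) - min(v))
  if (any(rng <= 0))
    stop("degenerate property scale(s): ",
         paste(rownames(mat)[rng <= 0], collapse = ", "))
  structure(mat, class = c("pcp_table", "matrix"))
}

seq_chars <- function(sequence) strsplit(sequence, "")[[1]]

#' Amino-acid composition (AAC) block
#'
#' Twenty relative residue frequencies, `count(residue i) / L`, in the fixed
#' alphabetical ordering ACDEFGHIKLMNPQRSTVWY.
#'
#' @param sequence a sanitized sequence string.
#' @return named numeric vector of length 20 (names `AAC:<residue>`), summing
#'   to 1.
#' @export
#' @examples
#' aac_features("AAC")  # A = 2/3, C = 1/3
aac_features <- function(sequence) {
  chars <- seq_chars(sequence)
  if (length(chars) == 0L) stop("empty sequence")
  f <- table(factor(chars, levels = AA_ALPHABET)) / length(chars)
  stats::setNames(as.numeric(f), paste0("AAC:", AA_ALPHABET))
}

dc_names <- function() {
  paste0("DC:", rep(AA_ALPHABET, each = 20L), rep(AA_ALPHABET, times = 20L))
}

#' Dipeptide composition (DC) block
#'
#' Frequencies of the 400 ordered adjacent residue pairs,
#' `count(pair ij) / (L - 1)`, row-major over the fixed alphabet with the
#' first residue on the N-terminal side.
#'
#' @param sequence a sanitized sequence of length >= 2.
#' @return named numeric vector of length 400 (names `DC:<pair>`), summing
#'   to 1.
#' @export
dc_features <- function(sequence) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (L < 2L) stop("dipeptide composition needs at least 2 residues")
  pairs <- paste0(chars[-L], chars[-1L])
  lv <- paste0(rep(AA_ALPHABET, each = 20L), rep(AA_ALPHABET, times = 20L))
  f <- table(factor(pairs, levels = lv)) / (L - 1L)
  stats::setNames(as.numeric(f), dc_names())
}

#' Physicochemical property (PCP) block
#'
#' For each property scale, the sequence mean of the per-residue values is
#' min-max normalised by the smallest and largest of that property's 20
#' scale values, yielding a value in \[0, 1\] that depends on composition
#' only (not residue order).
#'
#' @param sequence a sanitized sequence.
#' @param table a `pcp_table` from [load_property_table()].
#' @return named numeric vector (names `PCP:<property>`), one value per
#'   property, each in \[0, 1\].
#' @export
pcp_features <- function(sequence, table = load_property_table()) {
  chars <- seq_chars(sequence)
  if (length(chars) == 0L) stop("empty sequence")
  vals <- table[, chars, drop = FALSE]
  m <- rowMeans(vals)
  lo <- apply(table, 1, min)
  hi <- apply(table, 1, max)
  stats::setNames(as.numeric((m - lo) / (hi - lo)),
                  paste0("PCP:", rownames(table)))
}

#' Assemble a full feature vector for one sequence
#'
#' Concatenates the requested blocks in the fixed order AAC, DC, MTF, PCP.
#' Feature names are stable strings (`AAC:A`, `DC:AR`, `MTF:EHH`,
#' `PCP:polarity`) so that feature-subset masks survive serialization and
#' transfer across datasets.
#'
#' @param sequence a sanitized sequence.
#' @param catalog a `motif_catalog` (required when `"MTF"` is requested).
#' @param table a `pcp_table` (required when `"PCP"` is requested).
#' @param blocks subset of `c("AAC", "DC", "MTF", "PCP")`.
#' @return named numeric vector with attribute `blocks` giving the index
#'   range of each block.
#' @export
assemble_features <- function(sequence, catalog = NULL,
                              table = load_property_table(),
                              blocks = c("AAC", "DC", "MTF", "PCP")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  blocks <- intersect(c("AAC", "DC", "MTF", "PCP"), blocks)  # fixed order
  out <- numeric(0)
  ranges <- list()
  for (b in blocks) {
    v <- switch(b,
      AAC = aac_features(sequence),
      DC  = dc_features(sequence),
      MTF = {
        if (is.null(catalog)) stop("MTF block requested without a motif catalog")
        mtf_features(sequence, catalog)
      },
      PCP = pcp_features(sequence, table))
    ranges[[b]] <- seq.int(length(out) + 1L, length(out) + length(v))
    out <- c(out, v)
  }
  attr(out, "blocks") <- ranges
  out
}

#' Feature matrix for a dataset
#'
#' Applies [assemble_features()] to every record, returning a numeric matrix
#' with record ids as row names.
#'
#' @inheritParams assemble_features
#' @param data a `blp_dataset`.
#' @return numeric matrix, rows = records, columns = named features.
#' @export
feature_matrix <- function(data, catalog = NULL,
                           table = load_property_table(),
                           blocks = c("AAC", "DC", "MTF", "PCP")) {
  rows <- lapply(data$sequence, assemble_features,
                 catalog = catalog, table = table, blocks = blocks)
  X <- do.call(rbind, rows)
  rownames(X) <- data$id
  X
}
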