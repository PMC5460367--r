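#' Gapped motif patterns
#'
#' A motif pattern is 2--4 literal residues with 0 or 1 wildcard position
#' between each pair of consecutive literals (2-literal patterns must carry
#' the wildcard, since ungapped residue pairs are already covered by the
#' dipeptide block).  The text grammar matches how such motifs are usually
#' printed: literal letters, with `-` marking one wildcard, e.g. `"EHH"`,
#' `"EH-H"`, `"L-S-GR"`, `"G-T-G-P"`.
#'
#' @param text pattern string, e.g. `"L-S-GR"`.
#' @return a `motif_pattern` with fields `literals` (character vector) and
#'   `gaps` (integer vector, one per junction).
#' @export
#' @examples
#' parse_pattern("L-S-GR")   # literals L,S,G,R; gaps 1,1,0
parse_pattern <- function(text) {
  if (length(text) != 1L || is.na(text)) stop("`text` must be a single string")
  if (!grepl("^[A-Z](-?[A-Z])*$", text))
    stop("illegal pattern string: ", shQuote(text),
         " (letters separated by at most one '-')")
  chars <- strsplit(text, "")[[1]]
  literals <- chars[chars != "-"]
  if (any(!literals %in% AA_ALPHABET))
    stop("non-standard residue in pattern: ", shQuote(text))
  k <- length(literals)
  if (k < 2L || k > 4L)
    stop("patterns must have 2 to 4 literal residues, got ", k)
  # gap between consecutive literals: 1 if a '-' sits between them
  gaps <- integer(k - 1L)
  pos <- which(chars != "-")
  for (i in seq_len(k - 1L)) gaps[i] <- pos[i + 1L] - pos[i] - 1L
  if (any(gaps > 1L)) stop("at most one wildcard per junction: ", shQuote(text))
  if (k == 2L && gaps[1] == 0L)
    stop("2-literal patterns must be gapped (ungapped pairs are dipeptides): ",
         shQuote(text))
  new_pattern(literals, gaps)
}

new_pattern <- function(literals, gaps) {
  structure(list(literals = literals, gaps = as.integer(gaps)),
            class = "motif_pattern")
}

#' Format a motif pattern back to its string form
#' @param pattern a `motif_pattern`.
#' @return the pattern string, the inverse of [parse_pattern()].
#' @export
format_pattern <- function(pattern) {
  k <- length(pattern$literals)
  out <- pattern$literals[1]
  for (i in seq_len(k - 1L))
    out <- paste0(out, strrep("-", pattern$gaps[i]), pattern$literals[i + 1L])
  out
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern>", format_pattern(x), "\n")
  invisible(x)
}

pattern_regex <- function(pattern) {
  k <- length(pattern$literals)
  out <- pattern$literals[1]
  for (i in seq_len(k - 1L))
    out <- paste0(out, strrep(".", pattern$gaps[i]), pattern$literals[i + 1L])
  out
}

pattern_span <- function(pattern)
  length(pattern$literals) + sum(pattern$gaps)

#' Does a sequence contain a motif?
#'
#' True when some window of the sequence aligns every literal exactly, with
#' wildcard positions free.  Sequences shorter than the pattern span simply
#' do not match.
#'
#' @param pattern a `motif_pattern` or pattern string.
#' @param sequences character vector of sanitized sequences.
#' @return logical vector, one element per sequence.
#' @export
motif_matches <- function(pattern, sequences) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  grepl(pattern_regex(pattern), sequences, perl = TRUE)
}

## Literal-position templates spanning the whole pattern space:
## k = 2 (forced gap), and every gap combination for k = 3 and 4.
motif_templates <- function() {
  tpls <- list(list(offsets = c(1L, 3L), gaps = 1L))
  for (g1 in 0:1) for (g2 in 0:1)
    tpls[[length(tpls) + 1L]] <-
      list(offsets = c(1L, 2L + g1, 3L + g1 + g2), gaps = c(g1, g2))
  for (g1 in 0:1) for (g2 in 0:1) for (g3 in 0:1)
    tpls[[length(tpls) + 1L]] <-
      list(offsets = c(1L, 2L + g1, 3L + g1 + g2, 4L + g1 + g2 + g3),
           gaps = c(g1, g2, g3))
  tpls
}

## All pattern strings of a sequence, unique per sequence (presence, not
## occurrence count).  Every pattern that can occur anywhere in any dataset
## is generated here, so screening occurring patterns is equivalent to
## enumerating the full space and testing each member.
sequence_patterns <- function(sequence, templates = motif_templates()) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  out <- vector("list", length(templates))
  for (t in seq_along(templates)) {
    tpl <- templates[[t]]
    span <- tpl$offsets[length(tpl$offsets)]
    n <- L - span + 1L
    if (n < 1L) next
    starts <- seq_len(n)
    parts <- chars[starts + tpl$offsets[1L] - 1L]
    for (i in seq_along(tpl$gaps))
      parts <- paste0(parts, strrep("-", tpl$gaps[i]),
                      chars[starts + tpl$offsets[i + 1L] - 1L])
    out[[t]] <- parts
  }
  unique(unlist(out, use.names = FALSE))
}

## Named integer vector: for each pattern occurring in `sequences`, the
## number of sequences containing it at least once.
presence_counts <- function(sequences) {
  templates <- motif_templates()
  all <- unlist(lapply(sequences, sequence_patterns, templates = templates),
                use.names = FALSE)
  if (length(all) == 0L) return(integer(0))
  tab <- table(all)
  stats::setNames(as.integer(tab), names(tab))
}

#' Enumerate candidate motif patterns over the positive class
#'
#' Scans the constrained gapped-pattern space (2--4 literals, per-junction
#' gaps of 0 or 1, 2-literal patterns gapped) and returns every pattern
#' whose per-sequence occurrence frequency in the positive set is strictly
#' greater than `threshold_T`.  Frequency counts sequences containing the
#' pattern at least once, never multiple occurrences.
#'
#' @param positives a `blp_dataset` (labels are not consulted; all records
#'   are treated as the positive class).
#' @param threshold_T minimum occurrence-frequency threshold (default 0.10).
#' @return data frame with columns `pattern`, `count_pos`, `freq_pos`.
#' @export
enumerate_patterns <- function(positives, threshold_T = 0.10) {
  if (nrow(positives) == 0L) stop("positive set is empty")
  counts <- presence_counts(positives$sequence)
  n <- nrow(positives)
  keep <- counts / n > threshold_T
  out <- data.frame(pattern = names(counts)[keep],
                    count_pos = unname(counts[keep]),
                    freq_pos = unname(counts[keep]) / n,
                    stringsAsFactors = FALSE)
  out[order(out$pattern), , drop = FALSE]
}

#' Difference of information gains from presence counts
#'
#' The discrimination score of a pattern P given how many positives and
#' negatives contain it.  With `H0` the base-2 entropy of the class split,
#' `IG_B` is the information gained by splitting the pooled set into
#' \{positives containing P\} vs everything else, and `IG_N` the gain for
#' \{negatives containing P\} vs everything else; the score is
#' `DIG = IG_B - IG_N`.  A pattern present in every positive and no negative
#' scores the full class entropy; one equally present in both classes scores
#' 0 by symmetry.
#'
#' @param pos_with,neg_with number of positive / negative sequences
#'   containing the pattern (vectorised).
#' @param n_pos,n_neg class sizes.
#' @return numeric vector of DIG scores.
#' @export
dig_from_counts <- function(pos_with, neg_with, n_pos, n_neg) {
  if (n_pos < 1L || n_neg < 1L) stop("both classes must be non-empty")
  N <- n_pos + n_neg
  ent2 <- function(a, b) {
    # binary entropy of a two-part count split, 0*log0 := 0
    n <- a + b
    p <- ifelse(n > 0, a / n, 0)
    q <- 1 - p
    term <- function(x) ifelse(x > 0, -x * log2(x), 0)
    ifelse(n > 0, term(p) + term(q), 0)
  }
  h0 <- ent2(n_pos, n_neg)
  ig <- function(a1, b1) {
    a2 <- n_pos - a1
    b2 <- n_neg - b1
    n1 <- a1 + b1
    n2 <- a2 + b2
    h0 - (n1 / N) * ent2(a1, b1) - (n2 / N) * ent2(a2, b2)
  }
  ig(pos_with, 0) - ig(0, neg_with)
}

#' DIG score of one pattern against labelled sequence sets
#'
#' Counts per-sequence presence of the pattern in each class and applies
#' [dig_from_counts()].
#'
#' @param pattern a `motif_pattern` or pattern string.
#' @param positives,negatives `blp_dataset`s holding the two classes.
#' @return a single DIG score.
#' @export
dig_score <- function(pattern, positives, negatives) {
  if (nrow(positives) == 0L || nrow(negatives) == 0L)
    stop("both classes must be non-empty")
  pw <- sum(motif_matches(pattern, positives$sequence))
  nw <- sum(motif_matches(pattern, negatives$sequence))
  dig_from_counts(pw, nw, nrow(positives), nrow(negatives))
}

#' Discover discriminative gapped motifs
#'
#' Runs the full discovery procedure: enumerate candidate patterns whose
#' positive-class frequency exceeds `threshold_T`, score every candidate by
#' DIG against the negative class, and keep the `top_k` highest-scoring
#' patterns (ties broken lexicographically by pattern string, for
#' reproducibility).  The procedure is deterministic — no randomness enters
#' the scoring.
#'
#' @param positives,negatives `blp_dataset`s for the two classes.
#' @param threshold_T positive-class frequency threshold (default 0.10).
#' @param top_k number of motifs to keep (default 10).
#' @return a `motif_catalog`: data frame with columns `pattern`, `dig`,
#'   `freq_pos`, `freq_neg`, sorted by `dig` descending, with attributes
#'   `threshold_T`, `top_k`, `n_pos`, `n_neg`.
#' @export
discover_motifs <- function(positives, negatives, threshold_T = 0.10,
                            top_k = 10L) {
  if (nrow(positives) == 0L || nrow(negatives) == 0L)
    stop("both classes must be non-empty")
  top_k <- as.integer(top_k)
  stopifnot(top_k >= 1L)
  cand <- enumerate_patterns(positives, threshold_T)
  if (nrow(cand) == 0L) {
    warning("no pattern exceeds the frequency threshold T = ", threshold_T)
    return(empty_catalog(threshold_T, top_k, nrow(positives), nrow(negatives)))
  }
  neg_counts <- presence_counts(negatives$sequence)
  nw <- unname(neg_counts[cand$pattern])
  nw[is.na(nw)] <- 0L
  dig <- dig_from_counts(cand$count_pos, nw, nrow(positives), nrow(negatives))
  ord <- order(-dig, cand$pattern)
  n_keep <- min(top_k, nrow(cand))
  if (nrow(cand) < top_k)
    warning("only ", nrow(cand), " candidate(s) pass the threshold; ",
            "catalog smaller than top_k = ", top_k)
  idx <- ord[seq_len(n_keep)]
  structure(
    data.frame(pattern = cand$pattern[idx],
               dig = dig[idx],
               freq_pos = cand$freq_pos[idx],
               freq_neg = unname(nw[idx]) / nrow(negatives),
               stringsAsFactors = FALSE),
    threshold_T = threshold_T, top_k = top_k,
    n_pos = nrow(positives), n_neg = nrow(negatives),
    class = c("motif_catalog", "data.frame"))
}

empty_catalog <- function(threshold_T, top_k, n_pos, n_neg) {
  structure(
    data.frame(pattern = character(0), dig = numeric(0),
               freq_pos = numeric(0), freq_neg = numeric(0),
               stringsAsFactors = FALSE),
    threshold_T = threshold_T, top_k = top_k, n_pos = n_pos, n_neg = n_neg,
    class = c("motif_catalog", "data.frame"))
}

#' Binary motif-presence (MTF) feature block
#'
#' One indicator per catalog entry, in catalog order: 1 if the sequence
#' contains the motif, else 0.
#'
#' @param sequence a sanitized sequence.
#' @param catalog a non-empty `motif_catalog`.
#' @return named numeric vector (names `MTF:<pattern>`) of catalog length.
#' @export
mtf_features <- function(sequence, catalog) {
  if (nrow(catalog) == 0L) stop("motif catalog is empty")
  v <- vapply(catalog$pattern,
              function(p) as.numeric(motif_matches(p, sequence)),
              numeric(1), USE.NAMES = FALSE)
  stats::setNames(v, paste0("MTF:", catalog$pattern))
}

#' Write / read a motif catalog as TSV
#'
#' Columns pattern, dig, freq_pos, freq_neg; threshold and class sizes are
#' carried in comment headers.
#'
#' @param catalog a `motif_catalog`.
#' @param path TSV path.
#' @return `path` (write) or a `motif_catalog` (read).
#' @export
write_catalog <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold_T=%g top_k=%d n_pos=%d n_neg=%d",
                     attr(catalog, "threshold_T"), attr(catalog, "top_k"),
                     attr(catalog, "n_pos"), attr(catalog, "n_neg")), con)
  utils::write.table(as.data.frame(catalog), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- as.numeric(regmatches(hdr, gregexpr("[0-9.]+", hdr))[[1]])
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  structure(tab, threshold_T = meta[1], top_k = as.integer(meta[2]),
            n_pos = as.integer(meta[3]), n_neg = as.integer(meta[4]),
            class = c("motif_catalog", "data.frame"))
}
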