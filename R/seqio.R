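#' Protein sequence datasets
#'
#' A `blp_dataset` is a plain `data.frame` with columns `id` (unique string
#' identifiers), `sequence` (uppercase strings over the 20 standard residues),
#' `label` (integer `1` = bioluminescent protein, `0` = non-BLP, `NA` =
#' unlabelled) and `lineage` (one of `"bacteria"`, `"eukaryota"`, `"archaea"`,
#' `"unknown"`).  All pipeline functions accept and return this container.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of sanitized sequences.
#' @param label optional integer/numeric vector of 0/1 labels (`NA` allowed).
#' @param lineage optional character vector of lineage tags.
#' @return A `blp_dataset` data frame.
#' @export
new_dataset <- function(id, sequence, label = NA_integer_, lineage = "unknown") {
  id <- as.character(id)
  sequence <- as.character(sequence)
  if (length(id) != length(sequence))
    stop("`id` and `sequence` must have the same length")
  if (anyDuplicated(id))
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequences are not allowed")
  bad <- vapply(sequence,
                function(s) any(!strsplit(s, "")[[1]] %in% AA_ALPHABET),
                logical(1), USE.NAMES = FALSE)
  if (any(bad))
    stop("non-standard residues in sequence(s): ",
         paste(utils::head(id[bad], 5), collapse = ", "),
         " (sanitize first)")
  label <- suppressWarnings(as.integer(rep_len(label, length(id))))
  if (any(!is.na(label) & !label %in% c(0L, 1L)))
    stop("labels must be 0, 1 or NA")
  lineage <- as.character(rep_len(lineage, length(id)))
  lineage[is.na(lineage)] <- "unknown"
  ok <- c("bacteria", "eukaryota", "archaea", "unknown")
  if (any(!lineage %in% ok))
    stop("lineage must be one of: ", paste(ok, collapse = ", "))
  structure(
    data.frame(id = id, sequence = sequence, label = label,
               lineage = lineage, stringsAsFactors = FALSE),
    class = c("blp_dataset", "data.frame"))
}

#' Count labelled records per class
#'
#' @param data a `blp_dataset`.
#' @return named integer vector with elements `positive` and `negative`.
#' @export
class_counts <- function(data) {
  c(positive = sum(data$label == 1L, na.rm = TRUE),
    negative = sum(data$label == 0L, na.rm = TRUE))
}

#' @export
print.blp_dataset <- function(x, n = 5L, ...) {
  cc <- class_counts(x)
  cat(sprintf("<blp_dataset> %d records (%d positive, %d negative, %d unlabelled)\n",
              nrow(x), cc[["positive"]], cc[["negative"]],
              nrow(x) - sum(cc)))
  shown <- utils::head(as.data.frame(x), n)
  shown$sequence <- paste0(substr(shown$sequence, 1, 24),
                           ifelse(nchar(shown$sequence) > 24, "...", ""))
  print(shown)
  if (nrow(x) > n) cat("# ...", nrow(x) - n, "more records\n")
  invisible(x)
}

#' Sanitize a raw protein sequence
#'
#' Uppercases the input, strips whitespace and gap characters, and applies a
#' policy to ambiguity codes and other non-standard letters
#' (B, J, O, U, X, Z): `"drop"` removes them (the number removed is attached
#' as attribute `n_removed`), `"reject"` raises an error on the first one.
#'
#' @param raw a single string.
#' @param policy `"drop"` (default) or `"reject"`.
#' @return sanitized string with attribute `n_removed`.
#' @export
#' @examples
#' sanitize_sequence("acdE")          # "ACDE"
#' sanitize_sequence("AXA")           # "AA", n_removed = 1
sanitize_sequence <- function(raw, policy = c("drop", "reject")) {
  policy <- match.arg(policy)
  if (length(raw) != 1L || is.na(raw)) stop("`raw` must be a single string")
  s <- toupper(gsub("[\\s.*-]+", "", raw, perl = TRUE))
  chars <- strsplit(s, "")[[1]]
  bad <- !chars %in% AA_ALPHABET
  if (any(bad)) {
    if (policy == "reject")
      stop("non-standard residue(s) ",
           paste(unique(chars[bad]), collapse = ", "),
           " (policy = reject)")
    chars <- chars[!bad]
  }
  if (length(chars) == 0L)
    stop("no usable residues remain after sanitization")
  structure(paste(chars, collapse = ""), n_removed = sum(bad))
}

#' Read a label/lineage sidecar table
#'
#' Tab-separated with columns `id`, `label` (1 = BLP, 0 = non-BLP) and
#' optionally `lineage`.
#'
#' @param path TSV file path.
#' @return data frame with columns id, label, lineage.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(tab)))
    stop("label table must have columns `id` and `label`")
  if (is.null(tab$lineage)) tab$lineage <- "unknown"
  tab$id <- as.character(tab$id)
  tab$label <- as.integer(tab$label)
  tab[c("id", "label", "lineage")]
}

#' Read protein sequences from FASTA
#'
#' Parses a (wrapped or unwrapped) FASTA file into a [new_dataset()]
#' container, sanitizing each sequence and optionally joining class labels
#' and lineage tags from a sidecar TSV by id.  The identifier is the first
#' whitespace-delimited token of the header.  Records whose sanitized
#' sequence is shorter than `min_length` residues are rejected (dipeptide
#' composition is undefined below length 2).
#'
#' @param path FASTA file.
#' @param labels optional label-table path (see [read_label_table()]).
#' @param policy sanitization policy, see [sanitize_sequence()].
#' @param min_length minimum sanitized length (default 2).
#' @return a `blp_dataset`.
#' @export
read_fasta <- function(path, labels = NULL, policy = c("drop", "reject"),
                       min_length = 2L) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA at line %d: expected a '>' header, got %s",
                 nonblank[1], shQuote(substr(lines[nonblank[1]], 1, 30))))
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(aa)
  n_removed <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    s <- tryCatch(sanitize_sequence(seqs[i], policy),
                  error = function(e)
                    stop("record ", ids[i], ": ", conditionMessage(e),
                         call. = FALSE))
    n_removed[i] <- attr(s, "n_removed")
    seqs[i] <- as.character(s)
  }
  if (any(n_removed > 0L))
    warning(sum(n_removed), " non-standard residue(s) dropped across ",
            sum(n_removed > 0L), " record(s)")
  short <- nchar(seqs) < min_length
  if (any(short))
    stop("record(s) shorter than ", min_length, " residues after sanitization: ",
         paste(ids[short], collapse = ", "))
  label <- rep(NA_integer_, length(ids))
  lineage <- rep("unknown", length(ids))
  if (!is.null(labels)) {
    tab <- read_label_table(labels)
    m <- match(ids, tab$id)
    hit <- !is.na(m)
    label[hit] <- tab$label[m[hit]]
    lineage[hit] <- tab$lineage[m[hit]]
  }
  new_dataset(ids, seqs, label, lineage)
}

#' Write a dataset to FASTA (and optional label TSV)
#'
#' @param data a `blp_dataset`.
#' @param path output FASTA path.
#' @param labels optional path for the sidecar label TSV.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, labels = NULL) {
  aa <- Biostrings::AAStringSet(stats::setNames(data$sequence, data$id))
  Biostrings::writeXStringSet(aa, path)
  if (!is.null(labels)) {
    utils::write.table(
      data.frame(id = data$id, label = data$label, lineage = data$lineage),
      labels, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Balanced train/test split
#'
#' Draws `round(train_fraction * n_positive)` positives at random and an
#' equal number of negatives for the training set; every remaining record
#' (including unlabelled ones) goes to the test set.  This mirrors training
#' on a balanced subsample of an imbalanced collection.
#'
#' @param data labelled `blp_dataset` with both classes.
#' @param train_fraction fraction of positives to train on (0 < f < 1).
#' @param seed integer seed; the split is fully reproducible.
#' @return list with elements `train` and `test`.
#' @export
split_train_test <- function(data, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  cc <- class_counts(data)
  if (any(cc == 0L)) stop("both classes must be present")
  n_tr <- round(train_fraction * cc[["positive"]])
  if (n_tr < 1L) stop("train fraction leaves no positive training records")
  if (cc[["negative"]] < n_tr)
    stop("not enough negatives (", cc[["negative"]],
         ") to balance ", n_tr, " training positives")
  pos_ids <- data$id[!is.na(data$label) & data$label == 1L]
  neg_ids <- data$id[!is.na(data$label) & data$label == 0L]
  train_ids <- with_seed(seed, c(sample(pos_ids, n_tr), sample(neg_ids, n_tr)))
  in_train <- data$id %in% train_ids
  list(train = data[in_train, , drop = FALSE],
       test  = data[!in_train, , drop = FALSE])
}

#' Balanced under-sampling of the majority class
#'
#' Keeps every minority-class record and a uniform random sample of the
#' majority class of equal size, so the result always has exactly
#' `2 * min(n_pos, n_neg)` records.
#'
#' @param data labelled `blp_dataset` with both classes.
#' @param seed integer seed.
#' @return a balanced `blp_dataset`.
#' @export
undersample_balanced <- function(data, seed = 1L) {
  cc <- class_counts(data)
  if (any(cc == 0L)) stop("both classes must be present")
  pos_ids <- data$id[!is.na(data$label) & data$label == 1L]
  neg_ids <- data$id[!is.na(data$label) & data$label == 0L]
  n <- min(length(pos_ids), length(neg_ids))
  keep <- with_seed(seed, {
    if (length(pos_ids) > n) pos_ids <- sample(pos_ids, n)
    if (length(neg_ids) > n) neg_ids <- sample(neg_ids, n)
    c(pos_ids, neg_ids)
  })
  data[data$id %in% keep, , drop = FALSE]
}
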