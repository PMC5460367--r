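#' Specification of a synthetic labelled sequence dataset
#'
#' Describes the statistical structure the predictor exploits: an i.i.d.
#' residue background, an optional per-residue composition shift applied to
#' the positive class (additive on the frequency scale; the remaining
#' residues are rescaled to keep the distribution proper), and planted
#' gapped motifs inserted into a Bernoulli-chosen subset of each class.
#' Lineage sub-specs override any of these fields, producing a
#' lineage-tagged combined dataset.
#'
#' @param n_pos,n_neg class sizes.
#' @param length_range integer pair (min, max) of sequence lengths, min >= 10.
#' @param background residue frequency vector (20 values, named or in the
#'   fixed alphabet order, summing to 1).  Default uniform 1/20.
#' @param composition_shift named numeric of additive per-residue frequency
#'   deltas applied to positives (e.g. `c(K = 0.05)` makes positives' K
#'   frequency exceed negatives' by 0.05 in expectation).
#' @param planted_motifs list of `list(pattern=, rate_pos=, rate_neg=)`;
#'   each pattern is planted (wildcards filled from the background) at one
#'   uniform random position in a Bernoulli(rate) subset of each class,
#'   overwriting background residues so lengths are unchanged.
#' @param lineages optional named list (`bacteria`, `eukaryota`, `archaea`)
#'   of override lists with the same fields.
#' @param seed integer seed.
#' @return a `sim_spec`.
#' @export
simulation_spec <- function(n_pos = 100L, n_neg = 100L,
                            length_range = c(100L, 200L),
                            background = NULL,
                            composition_shift = NULL,
                            planted_motifs = list(),
                            lineages = NULL,
                            seed = 1L) {
  background <- background %||% stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  if (is.null(names(background))) names(background) <- AA_ALPHABET
  stopifnot(setequal(names(background), AA_ALPHABET),
            abs(sum(background) - 1) < 1e-9,
            length(length_range) == 2L, length_range[1] >= 10L,
            length_range[1] <= length_range[2])
  for (m in planted_motifs) {
    stopifnot(!is.null(m$pattern), m$rate_pos >= 0, m$rate_pos <= 1,
              m$rate_neg >= 0, m$rate_neg <= 1)
    if (pattern_span(parse_pattern(m$pattern)) > length_range[1])
      stop("motif span exceeds minimum sequence length: ", m$pattern)
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 background = background[AA_ALPHABET],
                 composition_shift = composition_shift,
                 planted_motifs = planted_motifs,
                 lineages = lineages, seed = as.integer(seed)),
            class = "sim_spec")
}

shift_background <- function(background, shift) {
  if (is.null(shift) || length(shift) == 0L) return(background)
  stopifnot(all(names(shift) %in% AA_ALPHABET))
  p <- background
  p[names(shift)] <- p[names(shift)] + shift
  if (any(p < 0)) stop("composition shift drives a frequency below 0")
  rest <- setdiff(AA_ALPHABET, names(shift))
  # rescale unshifted residues so the distribution still sums to 1
  p[rest] <- p[rest] * (1 - sum(p[names(shift)])) / sum(background[rest])
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("composition shift is infeasible (shifted mass exceeds 1)")
  p
}

random_sequences <- function(n, length_range, freqs) {
  # sample.int keeps degenerate ranges (min == max) honest
  lens <- length_range[1] +
    sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE) - 1L
  vapply(lens, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = freqs), collapse = ""),
    character(1))
}

plant_motif <- function(sequences, pattern, rate, background) {
  pat <- parse_pattern(pattern)
  span <- pattern_span(pat)
  hit <- stats::runif(length(sequences)) < rate
  for (i in which(hit)) {
    L <- nchar(sequences[i])
    start <- sample.int(L - span + 1L, 1L)
    # realize the pattern: literals fixed, wildcards drawn from background
    chars <- character(span)
    pos <- 1L
    for (j in seq_along(pat$literals)) {
      chars[pos] <- pat$literals[j]
      if (j <= length(pat$gaps) && pat$gaps[j] == 1L) {
        chars[pos + 1L] <- sample(AA_ALPHABET, 1L, prob = background)
        pos <- pos + 2L
      } else pos <- pos + 1L
    }
    substr(sequences[i], start, start + span - 1L) <-
      paste(chars, collapse = "")
  }
  sequences
}

generate_flat <- function(spec, id_prefix, lineage) {
  pos_freq <- shift_background(spec$background, spec$composition_shift)
  pos <- random_sequences(spec$n_pos, spec$length_range, pos_freq)
  neg <- random_sequences(spec$n_neg, spec$length_range, spec$background)
  for (m in spec$planted_motifs) {
    pos <- plant_motif(pos, m$pattern, m$rate_pos, spec$background)
    neg <- plant_motif(neg, m$pattern, m$rate_neg, spec$background)
  }
  new_dataset(
    id = c(sprintf("%spos_%04d", id_prefix, seq_len(spec$n_pos)),
           sprintf("%sneg_%04d", id_prefix, seq_len(spec$n_neg))),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), c(spec$n_pos, spec$n_neg)),
    lineage = lineage)
}

#' Generate a synthetic labelled dataset
#'
#' Draws i.i.d. sequences per class from the (optionally shifted)
#' background, plants the configured motifs, and attaches labels and
#' lineage tags.  Fully reproducible from `spec$seed`.
#'
#' @param spec a `sim_spec` from [simulation_spec()].
#' @return a `blp_dataset`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    if (is.null(spec$lineages))
      return(generate_flat(spec, "", "unknown"))
    parts <- vector("list", length(spec$lineages))
    for (i in seq_along(spec$lineages)) {
      lin <- names(spec$lineages)[i]
      sub <- spec
      for (f in names(spec$lineages[[i]])) sub[[f]] <- spec$lineages[[i]][[f]]
      parts[[i]] <- generate_flat(sub, paste0(substr(lin, 1, 3), "_"), lin)
    }
    ds <- do.call(rbind, lapply(parts, as.data.frame))
    new_dataset(ds$id, ds$sequence, ds$label, ds$lineage)
  })
}

#' Fixed benchmark fixture family
#'
#' Three seeded datasets exercising the regimes the predictor is built for:
#' \describe{
#'   \item{separable}{100 + 100 sequences (length 120--180) whose positives
#'     carry both a compositional signal (+0.05 on E and K, echoing the
#'     charged-residue enrichment typical of bioluminescent proteins) and a
#'     planted `EHH` motif at 70\% vs 2\%; calibrated so that its defining
#'     property — a pipeline trained on it separates the classes strongly
#'     (five-fold CV MCC above 0.8) — holds across seeds.}
#'   \item{null}{same sizes, no class signal of any kind.}
#'   \item{lineage_heterogeneous}{three lineages (60 + 60 each, length
#'     100--140) with disjoint planted motifs (`EHH`, `G-T-G-P`, `DGW` at
#'     50\% vs 5\%) and opposing composition shifts, so pooled training
#'     blurs signals that lineage-specific training can exploit.}
#' }
#'
#' @param seed integer seed.
#' @return named list of `blp_dataset`s.
#' @export
make_benchmark_suite <- function(seed = 1L) {
  list(
    separable = simulate_dataset(simulation_spec(
      n_pos = 100L, n_neg = 100L, length_range = c(120L, 180L),
      composition_shift = c(E = 0.05, K = 0.05),
      planted_motifs = list(list(pattern = "EHH", rate_pos = 0.7,
                                 rate_neg = 0.02)),
      seed = seed)),
    null = simulate_dataset(simulation_spec(
      n_pos = 100L, n_neg = 100L, length_range = c(120L, 180L),
      seed = seed + 1L)),
    lineage_heterogeneous = simulate_dataset(simulation_spec(
      n_pos = 60L, n_neg = 60L, length_range = c(100L, 140L),
      lineages = list(
        bacteria = list(
          composition_shift = c(K = 0.05, D = -0.03),
          planted_motifs = list(list(pattern = "EHH", rate_pos = 0.5,
                                     rate_neg = 0.05))),
        eukaryota = list(
          composition_shift = c(K = -0.03, D = 0.05),
          planted_motifs = list(list(pattern = "G-T-G-P", rate_pos = 0.5,
                                     rate_neg = 0.05))),
        archaea = list(
          composition_shift = c(W = 0.05, L = -0.03),
          planted_motifs = list(list(pattern = "DGW", rate_pos = 0.5,
                                     rate_neg = 0.05)))),
      seed = seed + 2L)))
}
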