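# Shared fixture builders: everything is generated in code at test time.

# Tiny labelled dataset with a planted motif, for fast pipeline tests.
tiny_planted <- function(seed = 1L, n = 20L, len = c(50L, 80L),
                         pattern = "EHH", rate_pos = 0.8, rate_neg = 0.05) {
  simulate_dataset(simulation_spec(
    n_pos = n, n_neg = n, length_range = len,
    planted_motifs = list(list(pattern = pattern, rate_pos = rate_pos,
                               rate_neg = rate_neg)),
    seed = seed))
}

# Gaussian informative-plus-noise matrix for selection tests.
inf_noise_matrix <- function(seed, n = 100L, n_inf = 10L, n_noise = 50L,
                             effect = 1) {
  y <- rep(c(0L, 1L), each = n %/% 2L)
  X <- lumipred:::with_seed(seed, {
    inf <- sapply(seq_len(n_inf),
                  function(j) stats::rnorm(n, mean = ifelse(y == 1L, effect, 0)))
    noise <- matrix(stats::rnorm(n * n_noise), nrow = n, ncol = n_noise)
    cbind(inf, noise)
  })
  inf_names <- sprintf("inf%d", seq_len(n_inf))
  noise_names <- sprintf("noise%d", seq_len(n_noise))
  colnames(X) <- c(inf_names, noise_names)
  list(X = X, y = y, informative = inf_names, noise = noise_names)
}

# Write a FASTA file (optionally wrapped) without going through the package.
write_raw_fasta <- function(entries, path, width = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(entries)) {
    writeLines(paste0(">", id), con)
    s <- entries[[id]]
    if (is.null(width)) writeLines(s, con)
    else writeLines(substring(s, seq(1, nchar(s), width),
                              pmin(nchar(s), seq(width, nchar(s) + width - 1,
                                                 width))), con)
  }
  path
}

write_label_tsv <- function(ids, labels, lineages = "unknown", path) {
  utils::write.table(
    data.frame(id = ids, label = labels,
               lineage = rep_len(lineages, length(ids))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Config used throughout the tests: reduced grid, everything else default.
test_config <- function(...) fast_config(...)
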