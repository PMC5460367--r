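test_that("parse_pattern reads the printed motif grammar and round-trips", {
  p <- parse_pattern("L-S-GR")
  expect_equal(p$literals, c("L", "S", "G", "R"))
  expect_equal(p$gaps, c(1L, 1L, 0L))
  expect_equal(parse_pattern("EHH")$gaps, c(0L, 0L))
  expect_equal(parse_pattern("G-T-G-P")$gaps, c(1L, 1L, 1L))
  for (s in c("A-A", "EH-H", "DGW", "A-A-T-D", "S-G-G-R"))
    expect_equal(format_pattern(parse_pattern(s)), s)
})

test_that("parse_pattern rejects out-of-space patterns", {
  expect_error(parse_pattern("A--A"), "at most one")      # gap of 2
  expect_error(parse_pattern("ABCDE"), "2 to 4|non-standard")
  expect_error(parse_pattern("AGWKL"), "2 to 4")          # k = 5
  expect_error(parse_pattern("AA"), "dipeptides")         # ungapped pair
  expect_error(parse_pattern("A"), "2 to 4")
  expect_error(parse_pattern("a-a"), "illegal")
  expect_error(parse_pattern("AXA"), "non-standard")      # X is not a literal
})

test_that("motif_matches slides literals with free wildcards", {
  expect_true(motif_matches("A-A", "ACA"))
  expect_false(motif_matches("A-A", "AAG"))
  expect_true(motif_matches("EHH", "GGEHHGG"))
  expect_false(motif_matches("EHH", "EH"))            # shorter than span
  expect_equal(motif_matches("G-T-G-P", c("GATCGAP", "GATCGAA")),
               c(TRUE, FALSE))
})

test_that("enumerate_patterns screens the gapped space by positive frequency", {
  pos <- new_dataset(c("a", "b", "c"), c("ACAGGGGGGG", "AGAGGGGGGG", "ADAGGGGGGG"),
                     label = 1L)
  cand <- enumerate_patterns(pos, threshold_T = 0.1)
  expect_true("A-A" %in% cand$pattern)
  expect_equal(cand$freq_pos[cand$pattern == "A-A"], 1)
  expect_false("W-W" %in% cand$pattern)
  # reported frequencies agree with direct per-pattern matching
  d <- tiny_planted(seed = 21, n = 10, len = c(40L, 50L))
  cand2 <- enumerate_patterns(d[d$label == 1L, ], 0.2)
  refreq <- vapply(cand2$pattern, function(p)
    mean(motif_matches(p, d$sequence[d$label == 1L])), numeric(1),
    USE.NAMES = FALSE)
  expect_equal(cand2$freq_pos, refreq)
  # every candidate stays inside the constrained pattern space
  parsed <- lapply(cand2$pattern, parse_pattern)
  expect_true(all(vapply(parsed, function(p)
    length(p$literals) <= 4 && all(p$gaps <= 1), logical(1))))
})

test_that("dig_from_counts matches hand-derived extremes", {
  expect_equal(dig_from_counts(4, 0, 4, 4), 1)    # all pos, no neg: full bit
  expect_equal(dig_from_counts(0, 0, 4, 4), 0)    # absent everywhere
  expect_equal(dig_from_counts(4, 4, 4, 4), 0)    # class-symmetric
  expect_error(dig_from_counts(1, 0, 0, 4), "non-empty")
})

test_that("DIG is monotone in positive frequency at fixed negative frequency", {
  for (nw in c(0, 5, 20)) {
    digs <- dig_from_counts(0:100, nw, 100, 100)
    expect_true(all(diff(digs) > -1e-12))
  }
})

test_that("dig_score counts presence per sequence and feeds the formula", {
  pos <- new_dataset(paste0("p", 1:4),
                     c("GGEHHGG", "AEHHKKL", "EHHEHHA", "KKKEHHD"), label = 1L)
  neg <- new_dataset(paste0("n", 1:4),
                     c("GGGGGGG", "AKLMNPQ", "RSTVWYA", "CCDDEEF"), label = 0L)
  # p3 carries two occurrences but counts once: presence of 4/4 vs 0/4
  expect_equal(dig_score("EHH", pos, neg), 1)
  expect_equal(dig_score("W-W", pos, neg), 0)
})

test_that("discover_motifs ranks a planted motif first and is deterministic", {
  d <- tiny_planted(seed = 8, n = 25, len = c(60, 90),
                    rate_pos = 0.7, rate_neg = 0.02)
  pos <- d[d$label == 1L, ]
  neg <- d[d$label == 0L, ]
  cat1 <- discover_motifs(pos, neg)
  expect_s3_class(cat1, "motif_catalog")
  expect_equal(nrow(cat1), 10L)
  expect_equal(cat1$pattern[1], "EHH")
  expect_true(all(diff(cat1$dig) <= 0))
  expect_true(all(cat1$freq_pos > 0.1))
  expect_identical(as.data.frame(discover_motifs(pos, neg)),
                   as.data.frame(cat1))
  # no candidate above an impossible threshold: empty catalog with warning
  expect_warning(cat0 <- discover_motifs(pos, neg, threshold_T = 0.999),
                 "no pattern")
  expect_equal(nrow(cat0), 0L)
})

test_that("mtf_features emits catalog-ordered binary indicators", {
  d <- tiny_planted(seed = 8, n = 25, len = c(60, 90),
                    rate_pos = 0.7, rate_neg = 0.02)
  catalog <- discover_motifs(d[d$label == 1L, ], d[d$label == 0L, ])
  s <- d$sequence[1]
  v <- mtf_features(s, catalog)
  expect_length(v, nrow(catalog))
  expect_true(all(v %in% c(0, 1)))
  expect_equal(unname(v),
               as.numeric(vapply(catalog$pattern, motif_matches, logical(1),
                                 sequences = s)))
  expect_equal(unname(mtf_features("GGGGGGGGGG", catalog)),
               rep(0, nrow(catalog)))
})

test_that("motif catalogs survive a TSV round trip", {
  d <- tiny_planted(seed = 8, n = 15)
  catalog <- discover_motifs(d[d$label == 1L, ], d[d$label == 0L, ])
  path <- tempfile(fileext = ".tsv")
  write_catalog(catalog, path)
  back <- read_catalog(path)
  expect_equal(back$pattern, catalog$pattern)
  expect_equal(back$dig, catalog$dig, tolerance = 1e-12)
  expect_equal(attr(back, "threshold_T"), attr(catalog, "threshold_T"))
})
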