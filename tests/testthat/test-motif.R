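make_tiny_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), f)
  f
}

test_that("site sequences equal a direct substring oracle", {
  set.seed(13)
  chr <- random_dna(400)
  fa <- make_tiny_fasta(c(chrT = chr))
  out <- extract_site_sequences(fa, data.frame(chrom = "chrT",
                                               site = 100L), flank = 20L)
  expect_equal(out$seq, substr(chr, 81, 121))   # 0-based 80..120
  expect_equal(nchar(out$seq), 41L)
  expect_false(out$clipped)
  # clipped near the chromosome start
  out2 <- extract_site_sequences(fa, data.frame(chrom = "chrT",
                                                site = 10L), flank = 20L)
  expect_equal(out2$seq, substr(chr, 1, 31))
  expect_true(out2$clipped)
  # empty input, missing chromosome
  expect_equal(nrow(extract_site_sequences(
    fa, data.frame(chrom = character(), site = integer()))), 0L)
  expect_error(extract_site_sequences(
    fa, data.frame(chrom = "chrZ", site = 5L)), "chrZ")
})

test_that("sequences with too many Ns are dropped with a warning", {
  fa <- make_tiny_fasta(c(chrN = paste0(strrep("N", 100),
                                        random_dna(100))))
  expect_warning(
    out <- extract_site_sequences(fa, data.frame(chrom = "chrN",
                                                 site = c(50L, 150L))),
    "20% N")
  expect_equal(nrow(out), 1L)
})

test_that("ZOOPS-EM recovers a planted 9-mer and never decreases the likelihood", {
  set.seed(3)
  seqs <- planted_seqs(n = 50, n_planted = 40)
  res <- zoops_em(seqs, w = 9, n_starts = 5, seed = 1)
  d <- min(hamming(res$consensus, "TTCCGGGAA"),
           hamming(res$consensus, revcomp_chr("TTCCGGGAA")))
  expect_lte(d, 1L)
  expect_gte(res$fraction_containing, 0.6)
  expect_true(all(diff(res$ll_trace) > -1e-8))
  expect_true(all(abs(colSums(res$pssm$probs) - 1) < 1e-9))
  expect_true(all(res$posteriors >= 0 & res$posteriors <= 1))
})

test_that("EM rejects invalid widths", {
  seqs <- planted_seqs(n = 5, n_planted = 0, len = 12)
  expect_error(zoops_em(seqs, w = 3), ">= 4")
  expect_error(zoops_em(seqs, w = 15), "shortest")
})

test_that("motif acceptance thresholds at 25% inclusive", {
  res <- structure(list(fraction_containing = 0.589),
                   class = "motif_result")
  expect_true(accept_motif(res))            # the real-data fraction
  res$fraction_containing <- 0.24
  expect_false(accept_motif(res))
  res$fraction_containing <- 0.25
  expect_true(accept_motif(res))
})

test_that("exact null distribution matches exhaustive enumeration for w = 5", {
  pm <- matrix(c(.7, .1, .1, .1,
                 .1, .7, .1, .1,
                 .1, .1, .7, .1,
                 .25, .25, .25, .25,
                 .4, .3, .2, .1), 4, 5)
  ps <- pssm(pm)
  null <- pssm_null_distribution(ps)
  expect_lt(abs(sum(null$prob) - 1), 1e-6)
  words <- as.matrix(expand.grid(rep(list(1:4), 5)))
  sc <- rowSums(matrix(log(pm[cbind(as.vector(words),
                                    rep(1:5, each = nrow(words)))]) -
                         log(0.25), nrow(words)))
  for (thr in quantile(sc, c(0.05, 0.25, 0.5, 0.75, 0.95, 0.999))) {
    brute <- mean(sc >= thr - 1e-9)
    dp <- sum(null$prob[null$support >= round(thr / null$gran)])
    expect_lt(abs(brute - dp), 1e-3)
  }
})

test_that("a background-equal PSSM scores nothing", {
  ps <- pssm(matrix(0.25, 4, 5))
  hit <- scan_pvalue(ps, random_dna(200))
  expect_equal(hit$best_score, 0)
  expect_equal(hit$p1, 1)
  expect_equal(hit$p_m, 1)
})

test_that("planting the consensus always decreases the region p-value", {
  probs <- matrix(0.1 / 3, 4, 9,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- strsplit("TTCCGGGAA", "")[[1]]
  for (k in 1:9) probs[cons[k], k] <- 0.9
  ps <- pssm(probs)
  null <- pssm_null_distribution(ps)
  set.seed(99)
  worse <- 0L
  for (i in 1:100) {
    s <- random_dna(500)
    pos <- sample(491, 1)
    planted <- paste0(substr(s, 1, pos - 1), "TTCCGGGAA",
                      substr(s, pos + 9, 500))
    p0 <- scan_pvalue(ps, s, null)$p_m
    p1 <- scan_pvalue(ps, planted, null)$p_m
    if (p1 >= p0) worse <- worse + 1L
  }
  expect_equal(worse, 0L)
})

test_that("the region p-value is monotone in the best-hit score", {
  probs <- matrix(0.1 / 3, 4, 6,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in 1:6) probs["A", k] <- 0.9
  ps <- pssm(probs)
  null <- pssm_null_distribution(ps)
  m <- 100L
  p_at <- vapply(seq(-5, 10, by = 0.5), function(s) {
    p1 <- sum(null$prob[null$support >= round(s / null$gran)])
    1 - (1 - min(max(p1, .Machine$double.xmin), 1))^m
  }, 0)
  expect_true(all(diff(p_at) <= 0))
})

test_that("motif export writes MEME minimal format", {
  set.seed(3)
  res <- zoops_em(planted_seqs(n = 12, n_planted = 10), w = 9,
                  n_starts = 2, seed = 1)
  f <- tempfile(fileext = ".meme")
  write_meme_motif(res, f)
  txt <- readLines(f)
  expect_equal(txt[1], "MEME version 4")
  expect_true(any(grepl("^MOTIF ", txt)))
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 9",
                        txt)))
  mat <- read.table(text = tail(txt, 9))
  expect_true(all(abs(rowSums(mat) - 1) < 1e-4))
})
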