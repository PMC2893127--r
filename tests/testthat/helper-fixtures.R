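# Shared fixtures, built in code. The default synthetic dataset and its
# pipeline run are expensive enough to share across test files; they are
# memoized here (helpers are sourced once per test session).

.fixture_cache <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.fixture_cache$ds))
    .fixture_cache$ds <- generate_dataset(dataset_config(seed = 1))
  .fixture_cache$ds
}

default_dataset_paths <- function() {
  if (is.null(.fixture_cache$paths)) {
    dir <- file.path(tempdir(), "peaktriad-default-fixture")
    .fixture_cache$paths <- write_dataset(default_dataset(), dir)
  }
  .fixture_cache$paths
}

# full pipeline run on the default fixture (seed 1, selective motif set)
default_pipeline_run <- function() {
  if (is.null(.fixture_cache$run)) {
    paths <- default_dataset_paths()
    out <- file.path(tempdir(), "peaktriad-default-run")
    cfg <- pipeline_config(tags = paths[["tags"]],
                           genome = paths[["genome"]],
                           fasta = paths[["fasta"]], out_dir = out,
                           n_high_quality = 10L, seed = 1L)
    .fixture_cache$run <- suppressWarnings(suppressMessages(
      run_pipeline(cfg)))
  }
  .fixture_cache$run
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# sequences with a (mutated) motif planted in the first n_planted
planted_seqs <- function(n = 50L, n_planted = 40L, len = 41L,
                         motif = "TTCCGGGAA", n_mut = 2L) {
  bases <- c("A", "C", "G", "T")
  w <- nchar(motif)
  vapply(seq_len(n), function(i) {
    s <- sample(bases, len, replace = TRUE)
    if (i <= n_planted) {
      m <- strsplit(motif, "")[[1L]]
      for (j in sample(w, n_mut)) m[j] <- sample(setdiff(bases, m[j]), 1L)
      p <- sample(len - w + 1L, 1L)
      s[p:(p + w - 1L)] <- m
    }
    paste(s, collapse = "")
  }, "")
}

hamming <- function(a, b)
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])

revcomp_chr <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")

# tags for one simulated region: a centered binding site (strand-shifted
# pattern) or a flat "amplification" (symmetric enrichment, no shift)
sim_region_tags <- function(type = c("site", "amplification"),
                            region_len = 1000L, n_fragments = 3e5,
                            chrom = "sim") {
  type <- match.arg(type)
  L <- sample(150:250, n_fragments, replace = TRUE)
  start <- floor(runif(n_fragments) * (region_len - L + 1))
  site <- region_len %/% 2L
  p <- if (type == "site")
    ifelse(start <= site & site <= start + L - 1, 0.001, 0.00005)
  else 0.0003
  keep <- runif(n_fragments) < p
  start <- start[keep]; L <- L[keep]
  fwd <- runif(sum(keep)) < 0.5
  data.frame(chrom = chrom,
             pos = as.integer(ifelse(fwd, start, start + L - 1)),
             strand = ifelse(fwd, "+", "-"), stringsAsFactors = FALSE)
}
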