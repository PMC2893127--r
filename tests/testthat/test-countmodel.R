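test_that("genome binning follows the half-open window convention", {
  genome <- c(chrA = 1000)
  none <- bin_counts(data.frame(chrom = character(), pos = integer(),
                                strand = character()), genome, 250)
  expect_equal(nrow(none$bins), 4L)
  expect_true(all(none$bins$count == 0L))
  expect_equal(attr(none$hist, "N_total"), 4L)

  tags <- data.frame(chrom = "chrA", pos = c(0L, 249L),
                     strand = c("+", "-"))
  b <- bin_counts(tags, genome, 250)
  expect_equal(b$bins$count, c(2L, 0L, 0L, 0L))
  expect_error(bin_counts(tags, genome, 0), "positive")
})

test_that("binning agrees with a brute-force per-bin tally", {
  set.seed(11)
  genome <- c(chr1 = 1e6)
  tags <- data.frame(chrom = "chr1", pos = sample(0:(1e6 - 1), 1e4, TRUE),
                     strand = sample(c("+", "-"), 1e4, TRUE))
  tags <- deduplicate_tags(tags)
  b <- bin_counts(tags, genome, 250)
  brute <- vapply(seq_len(4000), function(i)
    sum(tags$pos >= (i - 1) * 250 & tags$pos < i * 250), 0L)
  expect_equal(b$bins$count, brute)
  # histogram mass equals bins; tag mass equals tags
  expect_equal(sum(b$hist$freq), 4000L)
  expect_equal(sum(b$hist$count * b$hist$freq), nrow(tags))
})

test_that("zero-truncated pmf sums to one across random parameters", {
  set.seed(3)
  for (i in 1:100) {
    m <- gp_model(runif(1, 0.1, 20), runif(1, 0.05, 0.95))
    kmax <- max(200, ceiling(m$r * (1 - m$p) / m$p^2 * 50))
    expect_lt(abs(sum(dbackground(1:kmax, m)) - 1), 1e-9)
  }
  m <- pois_model(2.5)
  expect_lt(abs(sum(dbackground(1:100, m)) - 1), 1e-9)
})

test_that("maximum likelihood recovers truncated negative binomial parameters", {
  set.seed(11)
  x <- rnbinom(1e5, size = 2, prob = 0.5)
  x <- x[x >= 1]
  fit <- fit_background(count_histogram(x, N_total = length(x)))
  expect_lt(abs(fit$gp$r - 2) / 2, 0.05)
  expect_lt(abs(fit$gp$p - 0.5), 0.02)
  # the fitted mean identity r(1-p)/p holds by construction
  expect_equal(fit$gp$r * (1 - fit$gp$p) / fit$gp$p,
               unname(coef(fit)["r"] * (1 - coef(fit)["p"]) /
                        coef(fit)["p"]))
  expect_gt(fit$report$loglik_gp, fit$report$loglik_pois)
})

test_that("estimation error shrinks with sample size", {
  err <- function(n, seed) {
    set.seed(seed)
    x <- rnbinom(n, size = 2, prob = 0.5)
    x <- x[x >= 1]
    fit <- fit_background(count_histogram(x, N_total = length(x)))
    c(abs(fit$gp$r - 2) / 2, abs(fit$gp$p - 0.5))
  }
  small <- rowMeans(vapply(1:3, function(s) err(1e3, s), c(0, 0)))
  large <- rowMeans(vapply(1:3, function(s) err(1e5, s), c(0, 0)))
  expect_lt(large[1], small[1])
  expect_lt(large[2], small[2])
})

test_that("Poisson-generated data gives near-equal model likelihoods", {
  # the likelihood-ratio statistic of the nested pair is O(1); its
  # average over replicates stays below the single-draw bound
  lr <- vapply(1:3, function(s) {
    set.seed(s)
    x <- rpois(5e4, 2)
    x <- x[x >= 1]
    fit <- fit_background(count_histogram(x, N_total = length(x)))
    abs(fit$report$loglik_gp - fit$report$loglik_pois)
  }, 0)
  expect_lt(mean(lr), 2)
})

test_that("degenerate histograms are rejected", {
  expect_error(fit_background(count_histogram(rep(3L, 50))),
               "degenerate")
})

test_that("tail probabilities match the geometric closed form at r = 1", {
  m <- gp_model(1, 0.3)
  expect_equal(gp_tail(m, 0), 1)
  expect_equal(gp_tail(m, 1:10), (1 - 0.3)^(1:10), tolerance = 1e-12)
  expect_lt(gp_tail(m, 200), 1e-12)
  k <- 0:50
  expect_true(all(diff(gp_tail(m, k)[-1]) < 0))  # strictly decreasing
})

test_that("eFDR table matches a hand-computed oracle and stays in [0,1]", {
  hist <- count_histogram(c(rep(1L, 90), rep(2L, 8), rep(10L, 2)),
                          N_total = 100L)
  m <- gp_model(2, 0.5)
  tab <- efdr_table(m, hist)
  expect_equal(tab$k, 0:10)
  # three-line hand computation of the observed exceedances
  expect_equal(tab$n_observed[c(1, 2, 3, 11)], c(100L, 10L, 2L, 0L))
  expect_equal(tab$expected, 100 * gp_tail(m, 0:10))
  expect_equal(tab$efdr[1:10],
               pmin(1, 100 * gp_tail(m, 0:9) / tab$n_observed[1:10]))
  expect_true(is.na(tab$efdr[11]))
  expect_true(all(tab$efdr <= 1, na.rm = TRUE))
  # exact agreement between expectation and observation gives eFDR 1
  h2 <- count_histogram(rep(1L, 10), N_total = 10L)
  t2 <- efdr_table(gp_model(1, 0.9), h2)
  expect_equal(t2$efdr[1], 1)
})

test_that("eFDR is invariant to integer scaling of the histogram", {
  set.seed(8)
  x <- rnbinom(2000, size = 3, prob = 0.4)
  m <- gp_model(3, 0.4)
  h1 <- count_histogram(x, N_total = 2500L)
  h3 <- h1
  h3$freq <- h3$freq * 3L
  attr(h3, "N_total") <- 7500L
  expect_equal(efdr_table(m, h1)$efdr, efdr_table(m, h3)$efdr)
})

test_that("threshold selection takes the first crossing", {
  tab <- data.frame(k = 0:3, n_observed = c(40L, 30L, 20L, 10L),
                    expected = c(36, 18, 8, 1),
                    efdr = c(0.9, 0.6, 0.4, 0.1))
  expect_equal(select_threshold(tab, 0.5), 2L)
  expect_equal(select_threshold(tab, 0.99), 0L)
  expect_error(select_threshold(tab, 0.05), "larger alpha")
  expect_error(select_threshold(tab, 1.2), "alpha")
})

test_that("threshold on the synthetic fixture equals a linear-scan oracle", {
  ds <- default_dataset()
  b <- bin_counts(deduplicate_tags(ds$tags), ds$genome, 250)
  fit <- fit_background(b$hist)
  tab <- efdr_table(fit$gp, b$hist)
  k_star <- select_threshold(tab, 0.5)
  scan <- Inf
  for (i in seq_len(nrow(tab)))
    if (!is.na(tab$efdr[i]) && tab$efdr[i] <= 0.5) { scan <- tab$k[i]; break }
  expect_equal(k_star, scan)
})

test_that("adjacent above-threshold bins merge into regions", {
  bins <- data.frame(chrom = "c", start = c(0L, 250L, 500L, 750L),
                     end = c(250L, 500L, 750L, 1000L),
                     count = c(7L, 9L, 3L, 8L))
  p <- select_pbrs(bins, 6L, 250)
  expect_equal(p$start, c(0L, 750L))
  expect_equal(p$end, c(500L, 1000L))
  expect_equal(p$tag_count, c(16L, 8L))
  expect_equal(p$source_bins, c(2L, 1L))
  expect_equal(nrow(select_pbrs(bins, 100L, 250)), 0L)
})

test_that("region boundaries equal a run-length-encoding oracle", {
  set.seed(9)
  n <- 10000L
  counts <- ifelse(runif(n) < 0.1, 10L, 0L)
  bins <- data.frame(chrom = "c", start = (seq_len(n) - 1L) * 250L,
                     end = seq_len(n) * 250L, count = counts)
  p <- select_pbrs(bins, 5L, 250)
  r <- rle(counts > 5L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  expect_equal(p$start, (starts[r$values] - 1L) * 250L)
  expect_equal(p$end, ends[r$values] * 250L)
})
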