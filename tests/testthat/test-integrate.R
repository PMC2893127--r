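test_that("high-quality selection handles ties by genomic order", {
  n <- 30L
  scores <- data.frame(chrom = "chr1", start = seq_len(n) * 1000L,
                       p_c = rep(0.5, n), d_p = rep(10, n))
  sel <- select_high_quality(scores, 12L)
  expect_equal(sel, 1:12)
  # more requested than available returns everything
  expect_equal(sort(select_high_quality(scores, 100L)), 1:30)
  expect_warning(select_high_quality(scores[1:5, ], 3L), "fewer than 10")
})

test_that("high-quality selection favours jointly strong regions", {
  set.seed(17)
  n <- 100L
  scores <- data.frame(chrom = "chr1", start = seq_len(n) * 1000L,
                       p_c = runif(n), d_p = runif(n) * 100)
  sel <- select_high_quality(scores, 20L)
  expect_length(sel, 20L)
  r1 <- rank(scores$p_c)[sel]
  r2 <- rank(scores$d_p)[sel]
  # selected regions are top-ranked in both lists, not just one
  expect_lt(max(r1 + r2), median(rank(scores$p_c) + rank(scores$d_p)))
})

test_that("most high-quality fixture regions contain a planted site", {
  run <- default_pipeline_run()
  ds <- default_dataset()
  sc <- run$ranked
  hq <- sc[order(sc$rank), ][seq_len(10L), ]
  truth <- ds$truth[ds$truth$type == "site", ]
  hit <- vapply(seq_len(nrow(hq)), function(i)
    any(truth$chrom == hq$chrom[i] & truth$site >= hq$start[i] - 250 &
          truth$site < hq$end[i] + 250), TRUE)
  expect_gte(mean(hit), 0.8)
})

test_that("rank-concordant scores reduce to the count ranking", {
  n <- 50L
  p_c <- sort(runif(n))
  scores <- data.frame(chrom = "chr1", start = seq_len(n) * 1000L,
                       end = seq_len(n) * 1000L + 250L,
                       p_c = p_c, d_p = p_c * 100, p_m = p_c^0.5)
  ranked <- integrate_and_rank(scores)
  expect_equal(ranked$p_c, p_c)             # final order = p_c order
  expect_equal(ranked$rank, 1:n)
})

test_that("a region weak on two scores falls below a jointly strong one", {
  set.seed(23)
  n <- 100L
  scores <- data.frame(chrom = "chr1", start = seq_len(n) * 1000L,
                       end = seq_len(n) * 1000L + 250L,
                       p_c = exp(-rexp(n, 1 / 15)),
                       d_p = exp(rexp(n, 1 / 2)),
                       p_m = exp(-rexp(n, 1 / 3)))
  # region 1: best count evidence, worst pattern and motif evidence
  scores$p_c[1] <- exp(log(min(scores$p_c[-1])) - 1)
  scores$d_p[1] <- max(scores$d_p[-1]) * 2
  scores$p_m[1] <- 1
  # region 2: top decile in all three
  scores$p_c[2] <- quantile(scores$p_c[-(1:2)], 0.1)
  scores$d_p[2] <- quantile(scores$d_p[-(1:2)], 0.1)
  scores$p_m[2] <- quantile(scores$p_m[-(1:2)], 0.1)
  ranked <- integrate_and_rank(scores)
  expect_lt(ranked$rank[ranked$start == 2000L],
            ranked$rank[ranked$start == 1000L])
})

test_that("quantile rescaling matches the count score's location and scale", {
  # scores whose log-transforms share a distributional shape but differ
  # in scale by an order of magnitude, like the three evidence scores
  set.seed(29)
  n <- 200L
  scores <- data.frame(chrom = "chr1", start = seq_len(n) * 1000L,
                       end = seq_len(n) * 1000L + 250L,
                       p_c = exp(-rexp(n, 1 / 15)),
                       d_p = exp(-rexp(n, 1 / 2)),
                       p_m = exp(-rexp(n, 1 / 3)))
  ranked <- integrate_and_rank(scores)
  xc <- ranked$x_c
  for (v in list(ranked$x_p_scaled, ranked$x_m_scaled)) {
    expect_lt(abs(mean(v) - mean(xc)) / abs(mean(xc)), 0.1)
    expect_lt(abs(var(v) - var(xc)) / var(xc), 0.1)
  }
})

test_that("affine score transforms leave the final ranking unchanged", {
  # the quantile-OLS rescaling absorbs affine changes of each log score
  set.seed(37)
  n <- 60L
  scores <- data.frame(chrom = "chr1", start = seq_len(n) * 1000L,
                       end = seq_len(n) * 1000L + 250L,
                       p_c = runif(n), d_p = runif(n) * 50 + 1,
                       p_m = runif(n))
  r1 <- integrate_and_rank(scores, eps = 0)
  tr <- scores
  tr$d_p <- scores$d_p^3               # affine on the log scale
  tr$p_m <- scores$p_m^2
  r2 <- integrate_and_rank(tr, eps = 0)
  expect_equal(r2$start, r1$start)
})

test_that("missing motif evidence falls back to two scores", {
  n <- 20L
  scores <- data.frame(chrom = "chr1", start = seq_len(n) * 1000L,
                       end = seq_len(n) * 1000L + 250L,
                       p_c = runif(n), d_p = runif(n) * 50,
                       p_m = NA_real_)
  expect_message(ranked <- integrate_and_rank(scores), "count and pattern")
  expect_true(all(is.na(ranked$x_m_scaled)))
  expect_equal(ranked$combined, (ranked$x_c + ranked$x_p_scaled) / 2)
  expect_warning(integrate_and_rank(scores[1:2, ]), "fewer than 3")
})

test_that("the significant count reproduces the published arithmetic", {
  expect_equal(n_significant(69809, 0.5, "half_away"), 34905L)
  expect_equal(n_significant(117479, 0.7, "floor"), 35243L)
  expect_equal(n_significant(3, 0.9, "half_away"), 0L)
  expect_error(n_significant(100, 1.5), "alpha")
})

test_that("the significant set size is independent of the scores", {
  set.seed(41)
  n <- 80L
  mk <- function() data.frame(chrom = "chr1",
                              start = seq_len(n) * 1000L,
                              end = seq_len(n) * 1000L + 250L,
                              p_c = runif(n), d_p = runif(n) * 50,
                              p_m = runif(n))
  s1 <- select_significant(integrate_and_rank(mk()), 0.4)
  s2 <- select_significant(integrate_and_rank(mk()), 0.4)
  expect_equal(sum(s1$significant), sum(s2$significant))
  expect_equal(sum(s1$significant), n_significant(n, 0.4))
})
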