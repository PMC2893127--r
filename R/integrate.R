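#' Select high-quality regions for motif discovery
#'
#' High-quality regions are those with both a low peak-count p-value
#' and a well-matched strand-shift pattern. Regions are ranked by `p_c`
#' and by `d_p` separately; the two top-q lists are intersected with q
#' grown until the intersection reaches `n_high_quality` regions (or
#' all regions are exhausted), then truncated to `n_high_quality` by
#' the sum of the two ranks, ties broken by `p_c` then genomic order.
#'
#' @param scores data.frame with columns `chrom`, `start`, `p_c`, `d_p`
#'   (one row per region, in genomic order).
#' @param n_high_quality Target number of regions (default 200, at most
#'   500 should be passed to motif discovery).
#' @return Integer row indices of the selected regions (in final
#'   selection order).
#' @export
select_high_quality <- function(scores, n_high_quality = 200L) {
  n <- nrow(scores)
  if (n < 10L) {
    warning("fewer than 10 regions; using all for motif discovery")
    return(seq_len(n))
  }
  n_high_quality <- min(n_high_quality, n)
  r1 <- rank(scores$p_c, ties.method = "min")
  r2 <- rank(scores$d_p, ties.method = "min")
  q <- n_high_quality
  repeat {
    sel <- which(r1 <= q & r2 <= q)
    if (length(sel) >= n_high_quality || q >= n) break
    q <- min(n, q + max(1L, q %/% 4L))
  }
  ord <- order((r1 + r2)[sel], scores$p_c[sel], sel)
  sel[ord][seq_len(min(n_high_quality, length(sel)))]
}

#' Integrate the three evidence scores and re-rank regions
#'
#' The three per-region scores are log-transformed (`x_c = ln p_c`,
#' `x_p = ln(d_p + 1e-6)`, `x_m = ln p_m`). Because the scales differ
#' by orders of magnitude (count p-values can reach 1e-30, motif
#' p-values rarely pass 1e-5), `x_p` and `x_m` are rescaled to the
#' level of `x_c` by quantile-matching ordinary least squares: the
#' sorted `x_c` vector is regressed on the sorted score vector and the
#' fitted affine map applied per region. The combined score is the mean
#' of `x_c` and the two rescaled scores; regions are ranked ascending
#' (most negative = most significant), ties broken by `p_c` then
#' genomic order.
#'
#' If no motif was accepted (`p_m` all `NA`), only `x_c` and rescaled
#' `x_p` are averaged, with a message. With fewer than 3 regions the
#' ranking falls back to `p_c` alone, with a warning.
#'
#' @param scores data.frame with columns `chrom`, `start`, `end`,
#'   `p_c`, `d_p`, `p_m` (rows in genomic order; `p_m` may be all
#'   `NA` when the motif stage was skipped or failed).
#' @param eps Offset inside `ln(d_p + eps)` (d_p can be 0).
#' @return The input with added columns `x_c`, `x_p_scaled`,
#'   `x_m_scaled`, `combined`, `rank`, ordered by rank.
#' @export
integrate_and_rank <- function(scores, eps = 1e-6) {
  n <- nrow(scores)
  out <- scores
  out$x_c <- log(scores$p_c)
  if (n < 3L) {
    warning("fewer than 3 regions; ranking by p_c alone")
    out$x_p_scaled <- NA_real_
    out$x_m_scaled <- NA_real_
    out$combined <- out$x_c
    ord <- order(scores$p_c, seq_len(n))
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(n)
    rownames(out) <- NULL
    return(out)
  }
  rescale_to_xc <- function(x) {
    if (stats::sd(x) == 0) return(rep(mean(out$x_c), n))
    fit <- stats::lsfit(sort(x), sort(out$x_c))
    fit$coefficients[1L] + fit$coefficients[2L] * x
  }
  out$x_p_scaled <- rescale_to_xc(log(scores$d_p + eps))
  have_motif <- !all(is.na(scores$p_m))
  if (have_motif) {
    out$x_m_scaled <- rescale_to_xc(log(scores$p_m))
    out$combined <- (out$x_c + out$x_p_scaled + out$x_m_scaled) / 3
  } else {
    message("no accepted motif: combining count and pattern evidence only")
    out$x_m_scaled <- NA_real_
    out$combined <- (out$x_c + out$x_p_scaled) / 2
  }
  ord <- order(out$combined, out$p_c, seq_len(n))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  out
}

#' Number of significant regions under the two-step empirical FDR rule
#'
#' The pre-specified eFDR `alpha` used to form the candidate regions
#' also fixes the expected true-positive rate `1 - alpha` among them;
#' re-ranking by the combined evidence does not change it, so the top
#' `(1 - alpha) * N` re-ordered regions are declared significant.
#'
#' @param n_regions Total number of ranked regions.
#' @param alpha The pre-specified eFDR in (0, 1).
#' @param rounding `"half_away"` (round half away from zero, default)
#'   or `"floor"`.
#' @return Integer number of significant regions.
#' @export
n_significant <- function(n_regions, alpha,
                          rounding = c("half_away", "floor")) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  rounding <- match.arg(rounding)
  x <- (1 - alpha) * n_regions
  as.integer(switch(rounding, half_away = floor(x + 0.5), floor = floor(x)))
}

#' Flag the significant regions in a ranked list
#'
#' @param ranked Output of [integrate_and_rank()].
#' @param alpha The pre-specified eFDR.
#' @param rounding Rounding rule, see [n_significant()].
#' @return `ranked` with a logical `significant` column.
#' @export
select_significant <- function(ranked, alpha,
                               rounding = c("half_away", "floor")) {
  ns <- n_significant(nrow(ranked), alpha, rounding)
  ranked$significant <- ranked$rank <= ns
  ranked
}

#' Write the per-region audit table as TSV
#'
#' @param ranked Ranked, flagged region table from
#'   [select_significant()].
#' @param path Output path.
#' @export
write_audit_table <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
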