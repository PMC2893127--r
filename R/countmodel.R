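#' Bin the genome and tabulate tag counts
#'
#' Divides every chromosome into non-overlapping windows of `d` bp
#' (the last, possibly partial, window is kept) and assigns each tag to
#' the window containing its 5' position, regardless of strand. The
#' count histogram covers all windows, including zero-count ones, so
#' that its total mass equals the number of windows in the genome.
#'
#' @param tags Deduplicated tag data.frame (`chrom`, `pos`, `strand`).
#' @param genome Named vector of chromosome lengths.
#' @param d Window size in bp (the maximum ChIP fragment size).
#' @return A list with `bins` (data.frame `chrom`, `start`, `end`,
#'   `count`) and `hist` (object of class `count_histogram`: a
#'   data.frame `count`, `freq` plus attribute `N_total`).
#' @export
bin_counts <- function(tags, genome, d) {
  if (d <= 0) stop("window size d must be positive")
  per <- lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    nb <- as.integer(ceiling(len / d))
    pos <- tags$pos[tags$chrom == ch]
    cnt <- if (length(pos)) tabulate(pos %/% d + 1L, nbins = nb) else
      integer(nb)
    start <- (seq_len(nb) - 1L) * d
    data.frame(chrom = ch, start = start,
               end = pmin(start + d, len), count = cnt,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per)
  rownames(bins) <- NULL
  tb <- table(bins$count)
  hist <- data.frame(count = as.integer(names(tb)), freq = as.integer(tb))
  hist <- hist[order(hist$count), , drop = FALSE]
  rownames(hist) <- NULL
  class(hist) <- c("count_histogram", "data.frame")
  attr(hist, "N_total") <- nrow(bins)
  list(bins = bins, hist = hist)
}

#' Build a count histogram directly from counts
#'
#' @param counts Integer vector of per-window counts (zeros included).
#' @param N_total Total number of windows; defaults to `length(counts)`.
#' @return A `count_histogram`.
#' @export
count_histogram <- function(counts, N_total = length(counts)) {
  tb <- table(counts)
  hist <- data.frame(count = as.integer(names(tb)), freq = as.integer(tb))
  hist <- hist[order(hist$count), , drop = FALSE]
  rownames(hist) <- NULL
  if (sum(hist$freq) > N_total)
    stop("histogram mass exceeds N_total")
  class(hist) <- c("count_histogram", "data.frame")
  attr(hist, "N_total") <- N_total
  hist
}

## Zero-truncated Gamma-Poisson (negative binomial) machinery.
## Parameterization: P(X = x) = C(x+r-1, x) p^r (1-p)^x, mean r(1-p)/p,
## dispersion r(1-p)/p^2; truncation removes x = 0 (mass p^r).

#' Probability mass of a fitted background model
#'
#' @param x Non-negative integer counts.
#' @param model A `gp_model` or `pois_model`.
#' @return P(X = x) under the model (zero-truncated if the model is).
#' @export
dbackground <- function(x, model) {
  if (inherits(model, "gp_model")) {
    base <- stats::dnbinom(x, size = model$r, prob = model$p)
    if (model$zero_truncated) {
      out <- ifelse(x >= 1, base / (1 - model$p^model$r), 0)
    } else out <- base
  } else if (inherits(model, "pois_model")) {
    base <- stats::dpois(x, model$lambda)
    if (model$zero_truncated) {
      out <- ifelse(x >= 1, base / (1 - exp(-model$lambda)), 0)
    } else out <- base
  } else stop("unknown model class")
  out
}

#' Upper-tail probability Pr(count > k) of the background model
#'
#' Under a zero-truncated model the support starts at 1, so
#' `gp_tail(model, 0) == 1`.
#'
#' @param model A `gp_model` or `pois_model`.
#' @param k Count threshold(s), `k >= 0`.
#' @return Pr(count > k), vectorized over `k`.
#' @export
gp_tail <- function(model, k) {
  if (any(k < 0)) stop("k must be >= 0")
  if (inherits(model, "gp_model")) {
    tail_raw <- stats::pnbinom(k, size = model$r, prob = model$p,
                               lower.tail = FALSE)
    if (model$zero_truncated) {
      p0 <- model$p^model$r
      pmin(1, ifelse(k < 1, 1, tail_raw / (1 - p0)))
    } else tail_raw
  } else if (inherits(model, "pois_model")) {
    tail_raw <- stats::ppois(k, model$lambda, lower.tail = FALSE)
    if (model$zero_truncated) {
      p0 <- exp(-model$lambda)
      pmin(1, ifelse(k < 1, 1, tail_raw / (1 - p0)))
    } else tail_raw
  } else stop("unknown model class")
}

#' Construct a Gamma-Poisson (negative binomial) model object
#'
#' @param r Shape parameter, > 0.
#' @param p Probability parameter in (0, 1).
#' @param zero_truncated Whether the support is restricted to x >= 1.
#' @return Object of class `gp_model`.
#' @export
gp_model <- function(r, p, zero_truncated = TRUE) {
  stopifnot(r > 0, p > 0, p < 1)
  structure(list(r = r, p = p, zero_truncated = zero_truncated),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf(
    "%sGamma-Poisson background model\n  r = %.6g, p = %.6g\n  mean r(1-p)/p = %.6g, dispersion r(1-p)/p^2 = %.6g\n",
    if (x$zero_truncated) "Zero-truncated " else "", x$r, x$p,
    x$r * (1 - x$p) / x$p, x$r * (1 - x$p) / x$p^2))
  invisible(x)
}

#' @export
coef.gp_model <- function(object, ...) c(r = object$r, p = object$p)

#' Construct a Poisson model object
#'
#' @param lambda Rate per window, > 0.
#' @param zero_truncated Whether the support is restricted to x >= 1.
#' @return Object of class `pois_model`.
#' @export
pois_model <- function(lambda, zero_truncated = TRUE) {
  stopifnot(lambda > 0)
  structure(list(lambda = lambda, zero_truncated = zero_truncated),
            class = "pois_model")
}

#' @export
print.pois_model <- function(x, ...) {
  cat(sprintf("%sPoisson model, lambda = %.6g\n",
              if (x$zero_truncated) "Zero-truncated " else "", x$lambda))
  invisible(x)
}

ztnb_negll <- function(par, k, freq) {
  r <- exp(par[1L])
  p <- stats::plogis(par[2L])
  ll <- suppressWarnings(
    sum(freq * (stats::dnbinom(k, size = r, prob = p, log = TRUE) -
                  log1p(-p^r))))
  if (!is.finite(ll)) return(1e300)
  -ll
}

#' Fit the zero-truncated background models to a count histogram
#'
#' Maximum-likelihood fit of the zero-truncated Gamma-Poisson (negative
#' binomial) and zero-truncated Poisson models to the positive part of a
#' genome-wide window count histogram. Zero-count windows are excluded:
#' zeros can arise from non-mappable sequence and do not reflect the
#' background rate. Optimization is quasi-Newton (BFGS) on the
#' unconstrained scale (log r, logit p), initialized from
#' method-of-moments on the truncated sample.
#'
#' @param hist A `count_histogram` (zeros may be present; they are
#'   ignored for fitting).
#' @return Object of class `gp_fit`: a list with `gp` (`gp_model`),
#'   `pois` (`pois_model`) and `report` (log-likelihoods, AICs,
#'   convergence, sample size).
#' @export
fit_background <- function(hist) {
  pos <- hist[hist$count >= 1 & hist$freq > 0, , drop = FALSE]
  if (nrow(pos) < 2L)
    stop("degenerate histogram: need >= 2 distinct nonzero count values")
  k <- pos$count; freq <- pos$freq
  n <- sum(freq)
  m1 <- sum(k * freq) / n
  v <- sum(freq * (k - m1)^2) / n
  p0 <- if (v > m1) m1 / v else 0.5
  p0 <- min(max(p0, 1e-3), 1 - 1e-3)
  r0 <- max(m1 * p0 / (1 - p0), 1e-2)
  opt <- stats::optim(c(log(r0), stats::qlogis(p0)), ztnb_negll,
                      k = k, freq = freq, method = "BFGS",
                      control = list(reltol = 1e-10, maxit = 500))
  if (opt$convergence != 0)
    stop("zero-truncated Gamma-Poisson fit did not converge (code ",
         opt$convergence, "); last iterate r=", exp(opt$par[1L]),
         " p=", stats::plogis(opt$par[2L]))
  gp <- gp_model(exp(opt$par[1L]), stats::plogis(opt$par[2L]))
  ll_gp <- -opt$value

  ztp_negll <- function(loglam) {
    lam <- exp(loglam)
    -sum(freq * (stats::dpois(k, lam, log = TRUE) - log1p(-exp(-lam))))
  }
  optp <- stats::optimize(ztp_negll, interval = log(c(1e-6, max(k) * 10)),
                          tol = 1e-10)
  pois <- pois_model(exp(optp$minimum))
  ll_pois <- -optp$objective

  fit <- list(
    gp = gp, pois = pois,
    report = list(n_windows_fit = n,
                  loglik_gp = ll_gp, loglik_pois = ll_pois,
                  aic_gp = -2 * ll_gp + 4, aic_pois = -2 * ll_pois + 2,
                  partial_end_bins_kept = TRUE))
  class(fit) <- "gp_fit"
  fit
}

#' @export
print.gp_fit <- function(x, ...) {
  print(x$gp)
  print(x$pois)
  cat(sprintf("  logLik: G-P %.2f, Poisson %.2f (AIC %.2f vs %.2f; n = %d windows)\n",
              x$report$loglik_gp, x$report$loglik_pois,
              x$report$aic_gp, x$report$aic_pois, x$report$n_windows_fit))
  invisible(x)
}

#' @export
logLik.gp_fit <- function(object, ...) {
  structure(object$report$loglik_gp, df = 2L,
            nobs = object$report$n_windows_fit, class = "logLik")
}

#' @export
coef.gp_fit <- function(object, ...) coef(object$gp)

#' Empirical FDR table over count thresholds
#'
#' For each threshold k, the eFDR is the theoretical number of windows
#' exceeding k by chance under the fitted background,
#' `N_total * Pr(count > k)`, divided by the observed number of windows
#' exceeding k, clipped to `[0, 1]`. Rows run from k = 0 to the maximum
#' observed count; the eFDR is `NA` where no window exceeds k.
#'
#' @param model Fitted background (`gp_model`).
#' @param hist The `count_histogram` the model was fitted on.
#' @return data.frame (class `efdr_table`) with columns `k`,
#'   `n_observed`, `expected`, `efdr`.
#' @export
efdr_table <- function(model, hist) {
  N_total <- attr(hist, "N_total")
  kmax <- max(hist$count)
  k <- 0:kmax
  n_obs <- vapply(k, function(kk) sum(hist$freq[hist$count > kk]), 0L)
  expected <- N_total * gp_tail(model, k)
  efdr <- ifelse(n_obs > 0, pmin(1, expected / n_obs), NA_real_)
  structure(data.frame(k = k, n_observed = n_obs, expected = expected,
                       efdr = efdr),
            class = c("efdr_table", "data.frame"))
}

#' Select the count threshold for a target eFDR
#'
#' @param table An `efdr_table`.
#' @param alpha Target eFDR in (0, 1), e.g. 0.5.
#' @return The smallest k whose eFDR is at or below `alpha`; windows
#'   kept downstream are those with count > k.
#' @export
select_threshold <- function(table, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  ok <- which(!is.na(table$efdr) & table$efdr <= alpha)
  if (!length(ok))
    stop("no count threshold attains eFDR <= ", alpha,
         "; consider a larger alpha")
  table$k[ok[1L]]
}

#' Merge above-threshold windows into potential binding regions
#'
#' Maximal runs of adjacent (boundary-sharing) windows whose count
#' exceeds the threshold are merged into one region each.
#'
#' @param bins Per-window counts from [bin_counts()].
#' @param k_star Count threshold from [select_threshold()].
#' @param d Window size used for binning.
#' @return data.frame of PBRs: `chrom`, `start`, `end`, `tag_count`,
#'   `source_bins`, sorted by (chrom, start) in genome order.
#' @export
select_pbrs <- function(bins, k_star, d) {
  out <- lapply(unique(bins$chrom), function(ch) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    mask <- b$count > k_star
    if (!any(mask)) return(NULL)
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(chrom = ch,
               start = b$start[starts[keep]],
               end = b$end[ends[keep]],
               tag_count = vapply(keep, function(i)
                 sum(b$count[starts[i]:ends[i]]), 0L),
               source_bins = r$lengths[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), tag_count = integer(),
                      source_bins = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write an eFDR table as TSV
#'
#' @param table An `efdr_table`.
#' @param path Output path.
#' @export
write_efdr_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export per-window counts as bedGraph
#'
#' @param bins Per-window counts from [bin_counts()].
#' @param path Output path.
#' @export
write_bedgraph <- function(bins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%d", bins$chrom, bins$start, bins$end,
                     bins$count), con)
  invisible(path)
}
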