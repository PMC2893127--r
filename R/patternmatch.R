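#' Configuration for the reference-pattern simulation
#'
#' The reference strand-shift pattern is generated by simulating a ChIP
#' experiment on a 1 kb region with one binding site at its center:
#' fragments of random length 150-250 bp are placed uniformly; a
#' fragment spanning the site is pulled down with probability 0.1%, any
#' other with probability 0.005%; each retained fragment is sequenced
#' from one of its two ends with equal probability, yielding one
#' 5'-end tag.
#'
#' @param n_fragments Number of simulated fragments.
#' @param frag_len Integer fragment length range (inclusive).
#' @param region_len Length of the simulated region in bp.
#' @param site Binding-site position (default: region center).
#' @param p_site Pull-down probability for site-spanning fragments.
#' @param p_bg Pull-down probability for all other fragments.
#' @param d Sliding-window width (the maximum fragment size).
#' @param seed Integer seed; the simulation is reproducible.
#' @return A `sim_ref_config` list.
#' @export
sim_ref_config <- function(n_fragments = 3e6, frag_len = c(150L, 250L),
                           region_len = 1000L, site = region_len %/% 2L,
                           p_site = 0.001, p_bg = 0.00005, d = 250L,
                           seed = 1L) {
  stopifnot(p_site > 0, p_site < 1, p_bg > 0, p_bg < 1,
            frag_len[1L] <= frag_len[2L], frag_len[2L] <= region_len,
            d > 0, d <= region_len)
  structure(list(n_fragments = n_fragments, frag_len = as.integer(frag_len),
                 region_len = as.integer(region_len), site = as.integer(site),
                 p_site = p_site, p_bg = p_bg, d = as.integer(d),
                 seed = as.integer(seed)),
            class = "sim_ref_config")
}

#' Exact probability that a random fragment spans the site
#'
#' Enumerates fragment lengths L over the configured range; for each L
#' the start is uniform on `0..region_len-L` and the fragment covers the
#' site iff `start <= site <= start+L-1`.
#'
#' @param config A `sim_ref_config`.
#' @return The spanning probability (averaged over lengths).
#' @export
site_spanning_probability <- function(config) {
  Ls <- config$frag_len[1L]:config$frag_len[2L]
  mean(vapply(Ls, function(L) {
    n_starts <- config$region_len - L + 1L
    lo <- max(0L, config$site - L + 1L)
    hi <- min(config$region_len - L, config$site)
    max(0L, hi - lo + 1L) / n_starts
  }, 0))
}

#' Simulate the reference strand-shift pattern
#'
#' Runs the fragment simulation of [sim_ref_config()], counts forward
#' and reverse 5'-end tags in a sliding window of width `d`, forms
#' S = F - R, wavelet-smooths it and normalizes the maximum amplitude
#' to 1. For a centered site the smoothed pattern has a single positive
#' lobe upstream of the site followed by a single negative lobe
#' downstream.
#'
#' @param config A `sim_ref_config`.
#' @return Object of class `reference_pattern`: list with `values`
#'   (normalized smoothed S over the n window starts), `n`, `raw`
#'   (unsmoothed S), `n_retained` (retained fragment count), `peak`,
#'   `trough` (indices) and `config`.
#' @export
simulate_reference <- function(config = sim_ref_config()) {
  set.seed(config$seed)
  n <- config$n_fragments
  L <- sample(config$frag_len[1L]:config$frag_len[2L], n, replace = TRUE)
  start <- floor(stats::runif(n) * (config$region_len - L + 1))
  spans <- start <= config$site & config$site <= start + L - 1
  keep <- stats::runif(n) < ifelse(spans, config$p_site, config$p_bg)
  n_ret <- sum(keep)
  if (n_ret == 0L) stop("reference simulation retained zero fragments")
  start <- start[keep]; L <- L[keep]
  fwd <- stats::runif(n_ret) < 0.5
  pos <- ifelse(fwd, start, start + L - 1)
  np <- config$region_len - config$d + 1L
  win_count <- function(p) {
    cnt <- tabulate(p + 1L, nbins = config$region_len)
    cs <- c(0L, cumsum(cnt))
    cs[(1:np) + config$d] - cs[1:np]
  }
  S <- win_count(pos[fwd]) - win_count(pos[!fwd])
  smooth <- modwt_denoise(S)
  amp <- max(abs(smooth))
  if (amp == 0) stop("reference pattern is flat; check configuration")
  values <- smooth / amp
  peak <- which.max(values)
  trough <- which.min(values)
  if (peak >= trough)
    stop("reference pattern peak does not precede its trough")
  structure(list(values = values, n = np, raw = S, n_retained = n_ret,
                 peak = peak, trough = trough, config = config),
            class = "reference_pattern")
}

#' @export
print.reference_pattern <- function(x, ...) {
  cat(sprintf(
    "reference_pattern: n = %d positions, %d retained fragments, peak @%d, trough @%d\n",
    x$n, x$n_retained, x$peak, x$trough))
  invisible(x)
}

#' Pattern dissimilarity score d_p
#'
#' Compares an observed forward-minus-reverse pattern to the reference:
#' both are amplitude-normalized to max |value| = 1; the observed
#' pattern's global peak and trough (leftmost ties) are mapped onto the
#' reference's by an affine transform of the position axis; the
#' transformed pattern is resampled at the n reference positions by
#' linear interpolation (constant beyond its ends); the score is the
#' sum of absolute differences over the n positions. A flat observed
#' pattern, or one whose trough does not come after its peak (wrong
#' orientation for a binding site), receives the maximum penalty 2n.
#'
#' @param s_obs Numeric observed pattern (already smoothed; see
#'   [modwt_denoise()]).
#' @param ref A `reference_pattern`.
#' @return The dissimilarity score `d_p >= 0`, with attribute
#'   `"penalized"` set when the 2n penalty was applied.
#' @export
dissimilarity <- function(s_obs, ref) {
  n <- ref$n
  penalty <- structure(2 * n, penalized = TRUE)
  amp <- max(abs(s_obs))
  if (!is.finite(amp) || amp == 0) return(penalty)
  v <- s_obs / amp
  peak <- which.max(v)
  trough <- which.min(v)
  if (trough <= peak) return(penalty)
  a <- (ref$trough - ref$peak) / (trough - peak)
  b <- ref$peak - a * peak
  # value of the transformed pattern at reference position i: v((i - b)/a)
  u <- (seq_len(n) - b) / a
  v_res <- stats::approx(seq_along(v), v, xout = u, rule = 2)$y
  structure(sum(abs(v_res - ref$values)), penalized = FALSE)
}

#' Score a strand profile against the reference pattern
#'
#' Convenience wrapper: forms S = F - R from a profile, wavelet-smooths
#' it when long enough, and computes [dissimilarity()]. Profiles too
#' short to smooth (< 16 positions) are compared raw.
#'
#' @param profile A `strand_profile`.
#' @param ref A `reference_pattern`.
#' @return `d_p` as in [dissimilarity()].
#' @export
pattern_score <- function(profile, ref) {
  if (isTRUE(profile$degenerate) || length(profile$F) == 0L)
    return(structure(2 * ref$n, penalized = TRUE))
  S <- profile$F - profile$R
  if (length(S) >= 16L) S <- modwt_denoise(S)
  dissimilarity(S, ref)
}

#' Cache a reference pattern to TSV (position, value)
#'
#' @param ref A `reference_pattern`.
#' @param path Output path.
#' @export
write_reference_pattern <- function(ref, path) {
  utils::write.table(data.frame(position = seq_len(ref$n),
                                value = ref$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
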