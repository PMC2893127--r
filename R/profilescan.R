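#' Sliding-window strand profiles over a region
#'
#' Scans the region extended by `d` bp on each side (clipped to the
#' chromosome) base pair by base pair with a window of width `d`,
#' counting forward- and reverse-strand tags separately. The extension
#' captures flanking tags: a fragment's 5' tag can lie up to `d` bp
#' from the binding site it covers.
#'
#' @param tags Deduplicated tag data.frame.
#' @param pbr One-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param d Window width in bp.
#' @param genome Named vector of chromosome lengths.
#' @return Object of class `strand_profile`: list with `chrom`,
#'   `start` (genomic coordinate of the first window start), `d`, and
#'   integer vectors `F` and `R` indexed by window start. If the
#'   extended region is shorter than `d` the profile is empty and
#'   `degenerate` is `TRUE`.
#' @export
window_profile <- function(tags, pbr, d, genome) {
  if (d <= 0) stop("window width d must be positive")
  len <- genome[[pbr$chrom]]
  if (is.null(len)) stop("chromosome ", pbr$chrom, " not in genome table")
  ext_start <- max(0L, as.integer(pbr$start) - as.integer(d))
  ext_end <- min(as.integer(len), as.integer(pbr$end) + as.integer(d))
  L <- ext_end - ext_start
  if (L < d) {
    return(structure(list(chrom = pbr$chrom, start = ext_start, d = d,
                          F = integer(0), R = integer(0),
                          degenerate = TRUE),
                     class = "strand_profile"))
  }
  np <- L - d + 1L
  sel <- tags$chrom == pbr$chrom & tags$pos >= ext_start & tags$pos < ext_end
  sub <- tags[sel, , drop = FALSE]
  win_counts <- function(pos) {
    cnt <- if (length(pos)) tabulate(pos - ext_start + 1L, nbins = L) else
      integer(L)
    cs <- c(0L, cumsum(cnt))
    as.integer(cs[(1:np) + d] - cs[1:np])
  }
  structure(list(chrom = pbr$chrom, start = ext_start, d = d,
                 F = win_counts(sub$pos[sub$strand == "+"]),
                 R = win_counts(sub$pos[sub$strand == "-"]),
                 degenerate = FALSE),
            class = "strand_profile")
}

#' @export
print.strand_profile <- function(x, ...) {
  cat(sprintf("strand_profile %s:%d-%d (d = %d, %d window positions)\n",
              x$chrom, x$start, x$start + length(x$F) + x$d - 1L, x$d,
              length(x$F)))
  invisible(x)
}

#' Locate peaks and estimate the binding-site position
#'
#' The combined peak is the window start maximizing F + R; the per-strand
#' peaks are the argmaxes of F and R. Ties are broken leftmost. The site
#' estimate is the rounded midpoint between the downstream edge of the
#' forward-peak window (`f_peak_pos + d`) and the start of the
#' reverse-peak window: for a true site the forward peak window ends at
#' the site and the reverse peak window begins there.
#'
#' @param profile A non-degenerate `strand_profile`.
#' @return Object of class `peak_info`: list with `peak_pos`,
#'   `peak_count`, `f_peak_pos`, `r_peak_pos`, `site_estimate`
#'   (genomic coordinates).
#' @export
locate_peaks <- function(profile) {
  if (isTRUE(profile$degenerate) || length(profile$F) == 0L)
    stop("degenerate profile: region shorter than window width")
  total <- profile$F + profile$R
  if (all(total == 0L)) stop("degenerate profile: no tags in scan range")
  i <- which.max(total)           # leftmost maximum
  fi <- which.max(profile$F)
  ri <- which.max(profile$R)
  f_peak <- profile$start + fi - 1L
  r_peak <- profile$start + ri - 1L
  structure(list(peak_pos = profile$start + i - 1L,
                 peak_count = total[i],
                 f_peak_pos = f_peak, r_peak_pos = r_peak,
                 site_estimate = as.integer(round(((f_peak + profile$d) +
                                                     r_peak) / 2))),
            class = "peak_info")
}

#' @export
print.peak_info <- function(x, ...) {
  cat(sprintf("peak_info: peak %d (count %d), F-peak %d, R-peak %d, site ~ %d\n",
              x$peak_pos, x$peak_count, x$f_peak_pos, x$r_peak_pos,
              x$site_estimate))
  invisible(x)
}

#' Peak tag-count p-value under the background model
#'
#' `p_c = Pr(X >= peak_count)` under the zero-truncated Gamma-Poisson
#' background, i.e. the probability of a window count at least as large
#' as the observed regional peak.
#'
#' @param model A fitted `gp_model`.
#' @param peak A `peak_info`, or a numeric peak count.
#' @return p-value in (0, 1].
#' @export
peak_pvalue <- function(model, peak) {
  cnt <- if (inherits(peak, "peak_info")) peak$peak_count else peak
  if (any(cnt < 1)) stop("peak count must be >= 1")
  gp_tail(model, cnt - 1)
}

#' Export a strand profile as a two-track bedGraph
#'
#' Forward counts are written as-is and reverse counts negated, one row
#' per window start, for genome-browser inspection.
#'
#' @param profile A `strand_profile`.
#' @param path Output path.
#' @export
write_profile_bedgraph <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(profile$F)) {
    s <- profile$start + seq_along(profile$F) - 1L
    writeLines(c("track type=bedGraph name=forward",
                 sprintf("%s\t%d\t%d\t%d", profile$chrom, s, s + 1L,
                         profile$F),
                 "track type=bedGraph name=reverse",
                 sprintf("%s\t%d\t%d\t%d", profile$chrom, s, s + 1L,
                         -profile$R)), con)
  }
  invisible(path)
}
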