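#' Sample-overlap report
#'
#' Summarizes how the unique reads of a ChIP sample and an input
#' (control) sample partition into ChIP-only, input-only and shared
#' reads, as percentages of their union. Very low sharing indicates the
#' input cannot serve as a representative local control.
#'
#' @param chip_only,input_only,in_both Unique-read counts.
#' @return Object of class `sample_overlap`: the three counts plus
#'   percentages (two decimals).
#' @export
overlap_report <- function(chip_only, input_only, in_both) {
  stopifnot(chip_only >= 0, input_only >= 0, in_both >= 0)
  total <- chip_only + input_only + in_both
  if (total == 0) stop("all counts are zero")
  pct <- function(x) round(x / total * 100, 2)
  structure(list(chip_only = chip_only, input_only = input_only,
                 in_both = in_both,
                 pct_chip_only = pct(chip_only),
                 pct_input_only = pct(input_only),
                 pct_in_both = pct(in_both)),
            class = "sample_overlap")
}

#' @export
print.sample_overlap <- function(x, ...) {
  cat(sprintf(
    "sample overlap: ChIP only %.4g (%.2f%%), input only %.4g (%.2f%%), in both %.4g (%.2f%%)\n",
    x$chip_only, x$pct_chip_only, x$input_only, x$pct_input_only,
    x$in_both, x$pct_in_both))
  invisible(x)
}

#' Background-noise estimate from a physically separated chromosome
#'
#' Mitochondrial DNA is physically separated from nuclear transcription
#' factors, so the ratio of ChIP to input reads on chrM estimates the
#' fraction of experimental-procedure noise carried into the ChIP
#' sample. The expected ChIP background is that ratio (rounded to four
#' decimals) times the input noise reads, truncated to an integer.
#'
#' @param chrM_chip,chrM_input Total reads on the separated chromosome
#'   in the ChIP and input samples.
#' @param input_noise_reads Noise reads in the input sample
#'   (genome-wide).
#' @return Object of class `noise_estimate` with `ratio` and
#'   `expected_chip_background`.
#' @export
background_noise_report <- function(chrM_chip, chrM_input,
                                    input_noise_reads) {
  if (chrM_input <= 0) stop("chrM input read count must be positive")
  ratio <- round(chrM_chip / chrM_input, 4)
  structure(list(chrM_chip_reads = chrM_chip,
                 chrM_input_reads = chrM_input,
                 chip_input_ratio = ratio,
                 input_noise_reads = input_noise_reads,
                 expected_chip_background = floor(ratio * input_noise_reads)),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    "noise estimate: chrM ChIP/input = %.0f/%.0f = %.4f; expected ChIP background = %.0f reads\n",
    x$chrM_chip_reads, x$chrM_input_reads, x$chip_input_ratio,
    x$expected_chip_background))
  invisible(x)
}

#' Cumulative false-discovery surrogate curve on an absent chromosome
#'
#' A chromosome known to be absent from the sample (e.g. chrY in a
#' female cell line, or a simulated decoy receiving only background
#' fragments) cannot harbour true binding sites, so findings on it
#' count as false discoveries. Returns the cumulative number of
#' surrogate-chromosome regions as a function of rank.
#'
#' @param ranked Ranked region table (columns `chrom`, `rank`).
#' @param surrogate Surrogate chromosome name.
#' @param genome Optional genome table; when given, `surrogate` must be
#'   one of its chromosomes.
#' @return Integer vector `curve` of length `nrow(ranked)`:
#'   `curve[i]` = surrogate regions among the top i.
#' @export
absent_chromosome_rate <- function(ranked, surrogate, genome = NULL) {
  if (!is.null(genome) && !surrogate %in% names(genome))
    stop("surrogate chromosome ", surrogate, " not in genome table")
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  cumsum(ranked$chrom == surrogate)
}

#' Write a diagnostics report as TSV
#'
#' Mirrors the column structure of a per-sample summary table: one row
#' per statistic, name and value.
#'
#' @param overlap A `sample_overlap` (or NULL).
#' @param noise A `noise_estimate` (or NULL).
#' @param path Output path.
#' @export
write_diagnostics <- function(overlap = NULL, noise = NULL, path) {
  rows <- list()
  if (!is.null(overlap))
    rows$overlap <- data.frame(
      statistic = c("chip_only", "input_only", "in_both",
                    "pct_chip_only", "pct_input_only", "pct_in_both"),
      value = c(overlap$chip_only, overlap$input_only, overlap$in_both,
                overlap$pct_chip_only, overlap$pct_input_only,
                overlap$pct_in_both))
  if (!is.null(noise))
    rows$noise <- data.frame(
      statistic = c("chrM_chip_reads", "chrM_input_reads",
                    "chip_input_ratio", "input_noise_reads",
                    "expected_chip_background"),
      value = c(noise$chrM_chip_reads, noise$chrM_input_reads,
                noise$chip_input_ratio, noise$input_noise_reads,
                noise$expected_chip_background))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
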