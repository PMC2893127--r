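#' Read a chromosome-length table
#'
#' Parses a two-column whitespace-separated text file (chromosome name,
#' length in bp) into a named integer vector, preserving file order.
#'
#' @param path Path to the table.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$chrom))
    stop("duplicate chromosome names in genome table: ",
         paste(unique(tab$chrom[duplicated(tab$chrom)]), collapse = ", "))
  if (any(tab$length <= 0)) stop("chromosome lengths must be > 0")
  stats::setNames(tab$length, tab$chrom)
}

#' Write a chromosome-length table
#'
#' @param genome Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @export
write_genome_table <- function(genome, path) {
  utils::write.table(data.frame(chrom = names(genome), length = as.integer(genome)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read mapped sequencing tags from a BED6 file
#'
#' Each uniquely mapped tag is reduced to its 5'-most base and strand:
#' for `+` records the 5' end is the BED start, for `-` records it is
#' `end - 1` (0-based). Coordinates are BED-native 0-based half-open.
#' `track`, `browser` and `#` comment lines are skipped. Records on
#' chromosomes absent from `genome` are dropped.
#'
#' @param path Path to a BED file with at least 6 columns.
#' @param genome Named vector of chromosome lengths (see
#'   [read_genome_table()]).
#' @return A data.frame with columns `chrom`, `pos` (0-based 5' position)
#'   and `strand` (`"+"`/`"-"`). The number of dropped off-genome records
#'   is attached as attribute `"n_dropped"`.
#' @export
read_tags <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(structure(data.frame(chrom = character(), pos = integer(),
                                strand = character(),
                                stringsAsFactors = FALSE),
                     n_dropped = 0L))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed BED line ", lineno[which(nf < 6L)[1L]],
         ": fewer than 6 columns")
  chrom  <- vapply(fields, `[[`, "", 1L)
  start  <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end    <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  strand <- vapply(fields, `[[`, "", 6L)
  bad <- which(is.na(start) | is.na(end) | start < 0L | end <= start)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]], ": bad coordinates")
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]],
         ": strand must be '+' or '-'")
  known <- chrom %in% names(genome)
  n_dropped <- sum(!known)
  chrom <- chrom[known]; start <- start[known]; end <- end[known]
  strand <- strand[known]; lineno <- lineno[known]
  pos <- ifelse(strand == "+", start, end - 1L)
  over <- which(pos >= genome[chrom] | end > genome[chrom])
  if (length(over))
    stop("BED line ", lineno[over[1L]], ": coordinate beyond length of ",
         chrom[over[1L]])
  structure(data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
                       stringsAsFactors = FALSE, row.names = NULL),
            n_dropped = n_dropped)
}

#' Remove duplicate tags
#'
#' Keeps at most one tag per (chromosome, position, strand), preserving
#' the order of first occurrence. No quality-based choice is made.
#'
#' @param tags Tag data.frame from [read_tags()].
#' @return Deduplicated tag data.frame; the number of removed duplicates
#'   is attached as attribute `"n_removed"`.
#' @export
deduplicate_tags <- function(tags) {
  key <- paste(tags$chrom, tags$pos, tags$strand, sep = "\r")
  dup <- duplicated(key)
  out <- tags[!dup, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_removed = sum(dup))
}

#' Write ranked, scored regions as BED6+3
#'
#' Output columns: chrom, start, end, name (= rank), score (= combined
#' score), strand (`.`), then the three evidence scores `p_c`, `d_p`,
#' `p_m`. Rows are ordered by rank. A `#`-prefixed header names the
#' columns.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`,
#'   `rank`, `combined`, `p_c`, `d_p`, `p_m`.
#' @param path Output path.
#' @export
write_scored_regions <- function(regions, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open ", path, " for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\trank\tcombined\tstrand\tp_c\td_p\tp_m", con)
  if (nrow(regions)) {
    stopifnot(setequal(regions$rank, seq_len(nrow(regions))))
    regions <- regions[order(regions$rank), , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%d\t%.6g\t.\t%.6g\t%.6g\t%.6g",
                     regions$chrom, as.integer(regions$start),
                     as.integer(regions$end), as.integer(regions$rank),
                     regions$combined, regions$p_c, regions$d_p, regions$p_m)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read back a scored-region BED6+3 file
#'
#' Inverse of [write_scored_regions()]; used for round-tripping and for
#' downstream inspection of pipeline output.
#'
#' @param path Path written by [write_scored_regions()].
#' @return data.frame with columns `chrom`, `start`, `end`, `rank`,
#'   `combined`, `p_c`, `d_p`, `p_m`.
#' @export
read_scored_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      rank = integer(), combined = numeric(), p_c = numeric(),
                      d_p = numeric(), p_m = numeric(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[[`, "", 1L),
             start = as.integer(vapply(f, `[[`, "", 2L)),
             end = as.integer(vapply(f, `[[`, "", 3L)),
             rank = as.integer(vapply(f, `[[`, "", 4L)),
             combined = as.numeric(vapply(f, `[[`, "", 5L)),
             p_c = as.numeric(vapply(f, `[[`, "", 7L)),
             d_p = as.numeric(vapply(f, `[[`, "", 8L)),
             p_m = as.numeric(vapply(f, `[[`, "", 9L)),
             stringsAsFactors = FALSE)
}

#' Write tags to BED6
#'
#' Tags are written as 1-bp intervals at the 5' position (the internal
#' representation discards read length).
#'
#' @param tags Tag data.frame (`chrom`, `pos`, `strand`).
#' @param path Output path.
#' @export
write_tags <- function(tags, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(tags))
    writeLines(sprintf("%s\t%d\t%d\tt%d\t0\t%s", tags$chrom,
                       as.integer(tags$pos), as.integer(tags$pos) + 1L,
                       seq_len(nrow(tags)), tags$strand), con)
  invisible(path)
}
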