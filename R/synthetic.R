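#' Configuration for the labelled synthetic ChIP-Seq dataset
#'
#' The generator emulates the four mechanisms that can enrich tags in a
#' region of ChIP-Seq data: (1) true binding sites, which produce the
#' strand-shifted tag pattern and carry a motif; (2) focal
#' amplification of genomic intervals; (3) nonspecific
#' binding/artifact hotspots, present on every chromosome including the
#' decoy; and (4) uniform procedural noise. Mechanisms 2 and 3 enrich
#' counts without the site pattern or motif, which is what the pattern
#' and motif stages must reject. A decoy chromosome carries no true
#' sites and serves as a false-discovery surrogate, the way an
#' absent-from-sample chromosome does in real data.
#'
#' Defaults place 10 binding sites on three 500 kb chromosomes plus a
#' 500 kb decoy, two focal amplifications, five hotspots (two on the
#' decoy), and 5e8 fragments with the pull-down probabilities of the
#' reference-pattern simulation (0.1% for site-spanning fragments,
#' 0.005% otherwise). That yields ~3 background tags per 250-bp window
#' and ~50 tags per site, so the genome-wide count histogram is
#' dominated by background windows (~97% with six or fewer tags) with
#' enrichment confined to the right tail — the regime the
#' empirical-FDR construction assumes. The background is additionally
#' overdispersed by a piecewise-constant Gamma rate field (mean 1,
#' shape `bg_gamma_shape`, `bg_tile`-bp tiles) emulating the
#' genome-wide nonuniformity of nonspecific binding;
#' `bg_gamma_shape = Inf` gives a homogeneous (Poisson) background.
#'
#' @param genome Named vector of chromosome lengths (the decoy
#'   included).
#' @param decoy Name of the decoy chromosome (no true sites, no
#'   amplification).
#' @param n_sites Number of planted binding sites.
#' @param motif Consensus motif written at each site.
#' @param mutation_rate Per-base probability of mutating a planted
#'   motif base.
#' @param p_site,p_bg Pull-down probabilities for site-spanning and
#'   background fragments.
#' @param frag_len Fragment length range (inclusive).
#' @param n_fragments Total simulated fragments.
#' @param amplifications data.frame `chrom`, `start`, `end`, `fold` of
#'   focal-amplification intervals (background retention probability is
#'   multiplied by `fold` for fragments overlapping the interval), or
#'   NULL. Not allowed on the decoy.
#' @param hotspots data.frame of the same shape for nonspecific
#'   binding/artifact hotspots; allowed on every chromosome, or NULL.
#' @param bg_gamma_shape Shape of the Gamma rate field modulating the
#'   background (mean 1); `Inf` for a homogeneous background.
#' @param bg_tile Tile length of the rate field in bp.
#' @param seed Integer seed.
#' @return A `dataset_config` list.
#' @export
dataset_config <- function(genome = c(chr1 = 500000L, chr2 = 500000L,
                                      chr3 = 500000L, chrD = 500000L),
                           decoy = "chrD",
                           n_sites = 10L,
                           motif = "TTCCGGGAA",
                           mutation_rate = 0.1,
                           p_site = 0.001, p_bg = 0.00005,
                           frag_len = c(150L, 250L),
                           n_fragments = 5e8,
                           amplifications = data.frame(
                             chrom = c("chr1", "chr2"),
                             start = c(350000L, 100000L),
                             end = c(350500L, 100500L),
                             fold = c(10, 10)),
                           hotspots = data.frame(
                             chrom = c("chr1", "chr2", "chr3",
                                       "chrD", "chrD"),
                             start = c(100000L, 400000L, 250000L,
                                       150000L, 380000L),
                             end = c(100500L, 400500L, 250500L,
                                     150500L, 380500L),
                             fold = c(12, 12, 12, 12, 12)),
                           bg_gamma_shape = 5,
                           bg_tile = 250L,
                           seed = 1L) {
  stopifnot(decoy %in% names(genome), p_site > 0, p_site < 1,
            p_bg > 0, p_bg < 1,
            mutation_rate >= 0, mutation_rate < 1,
            frag_len[1L] <= frag_len[2L],
            all(genome >= 2L * frag_len[2L]))
  check_intervals <- function(iv, what) {
    if (is.null(iv) || nrow(iv) == 0L) return(invisible())
    stopifnot(all(iv$chrom %in% names(genome)), all(iv$start >= 0),
              all(iv$start < iv$end),
              all(iv$end <= genome[iv$chrom]), all(iv$fold > 0))
  }
  check_intervals(amplifications, "amplifications")
  check_intervals(hotspots, "hotspots")
  if (!is.null(amplifications) && nrow(amplifications) &&
      any(amplifications$chrom == decoy))
    stop("amplifications must not lie on the decoy chromosome")
  structure(list(genome = genome, decoy = decoy,
                 n_sites = as.integer(n_sites),
                 motif = toupper(motif), mutation_rate = mutation_rate,
                 p_site = p_site, p_bg = p_bg,
                 frag_len = as.integer(frag_len),
                 n_fragments = n_fragments,
                 amplifications = amplifications,
                 hotspots = hotspots,
                 bg_gamma_shape = bg_gamma_shape,
                 bg_tile = as.integer(bg_tile),
                 seed = as.integer(seed)),
            class = "dataset_config")
}

# amplifications and hotspots act identically on fragment retention:
# one table of multiplicative intervals, labelled by mechanism
retention_intervals <- function(config) {
  iv <- NULL
  if (!is.null(config$amplifications) && nrow(config$amplifications))
    iv <- cbind(config$amplifications[c("chrom", "start", "end", "fold")],
                type = "amplification")
  if (!is.null(config$hotspots) && nrow(config$hotspots))
    iv <- rbind(iv, cbind(config$hotspots[c("chrom", "start", "end",
                                            "fold")],
                          type = "hotspot"))
  iv
}

# probability that a fragment (chrom ~ length, L ~ U(range),
# start ~ U(0..G-L)) falls in each retention class
frag_class_probs <- function(config, sites, intervals) {
  genome <- config$genome
  p_ch <- genome / sum(genome)
  Ls <- config$frag_len[1L]:config$frag_len[2L]
  site_f <- if (!is.null(sites) && nrow(sites)) vapply(
    seq_len(nrow(sites)), function(i) {
      G <- genome[[sites$chrom[i]]]
      p_ch[[sites$chrom[i]]] * mean(Ls / (G - Ls + 1))
    }, 0) else numeric(0)
  iv_f <- if (!is.null(intervals) && nrow(intervals)) vapply(
    seq_len(nrow(intervals)), function(j) {
      G <- genome[[intervals$chrom[j]]]
      n_over <- vapply(Ls, function(L)
        max(0L, min(G - L, intervals$end[j] - 1L) -
              max(0L, intervals$start[j] - L + 1L) + 1L), 0L)
      p_ch[[intervals$chrom[j]]] * mean(n_over / (G - Ls + 1))
    }, 0) else numeric(0)
  list(site = site_f, interval = iv_f,
       bg = 1 - sum(site_f) - sum(iv_f), p_ch = p_ch, Ls = Ls)
}

#' Generate a labelled synthetic ChIP-Seq dataset
#'
#' Draws an i.i.d. uniform ACGT genome, writes the (per-base mutated)
#' motif consensus at non-overlapping random site positions on the
#' non-decoy chromosomes (kept clear of amplification and hotspot
#' intervals so the truth labels stay unambiguous), and simulates the
#' ChIP step: fragments of random length are placed uniformly on the
#' genome and retained with the site pull-down probability when they
#' span a planted site, the background probability times the fold when
#' they overlap an amplification or hotspot interval, and the
#' background probability otherwise; each retained fragment
#' contributes one 5'-end tag from a uniformly chosen end. Retention
#' is simulated by its thinned equivalent — binomial retained counts
#' per probability class, placed from the class-conditional location
#' law — which coincides with per-fragment thinning in the Poisson
#' limit that holds at these retention probabilities. Fully
#' reproducible from the seed.
#'
#' @param config A `dataset_config`.
#' @return Object of class `synthetic_dataset`: list with `genome_seq`
#'   (a [Biostrings::DNAStringSet]), `tags` (tag data.frame), `truth`
#'   (data.frame of planted sites and confounders: `chrom`, `start`,
#'   `end`, `site` (motif center, NA for confounders), `type`
#'   (`site`/`amplification`/`hotspot`), `instance`), `genome` (length
#'   table) and `config`.
#' @export
generate_dataset <- function(config = dataset_config()) {
  set.seed(config$seed)
  genome <- config$genome
  chroms <- names(genome)
  w <- nchar(config$motif)
  bases <- c("A", "C", "G", "T")
  intervals <- retention_intervals(config)

  seqs <- lapply(chroms, function(ch)
    paste(sample(bases, genome[[ch]], replace = TRUE), collapse = ""))
  names(seqs) <- chroms

  # plant non-overlapping motif instances away from chromosome edges
  # and clear of confounder intervals
  site_chroms <- setdiff(chroms, config$decoy)
  margin <- config$frag_len[2L]
  sites <- NULL
  if (config$n_sites > 0L) {
    placed <- 0L
    rows <- list()
    occupied <- stats::setNames(lapply(site_chroms, function(ch) integer(0)),
                                site_chroms)
    attempts <- 0L
    while (placed < config$n_sites && attempts < 2000L) {
      attempts <- attempts + 1L
      ch <- sample(site_chroms, 1L)
      lo <- margin; hi <- genome[[ch]] - margin - w
      if (hi <= lo) next
      start <- sample(lo:hi, 1L)
      if (any(abs(occupied[[ch]] - start) < 2L * margin)) next
      if (!is.null(intervals) &&
          any(intervals$chrom == ch &
              start + w > intervals$start - margin &
              start < intervals$end + margin)) next
      occupied[[ch]] <- c(occupied[[ch]], start)
      inst <- strsplit(config$motif, "")[[1L]]
      mut <- stats::runif(w) < config$mutation_rate
      inst[mut] <- vapply(which(mut), function(j)
        sample(setdiff(bases, inst[j]), 1L), "")
      inst <- paste(inst, collapse = "")
      s <- seqs[[ch]]
      substr(s, start + 1L, start + w) <- inst
      seqs[[ch]] <- s
      placed <- placed + 1L
      rows[[placed]] <- data.frame(chrom = ch, start = start,
                                   end = start + w,
                                   site = start + w %/% 2L,
                                   type = "site", instance = inst,
                                   stringsAsFactors = FALSE)
    }
    if (placed < config$n_sites)
      stop("could not place ", config$n_sites, " non-overlapping sites")
    sites <- do.call(rbind, rows)
  }

  truth <- sites
  if (!is.null(intervals) && nrow(intervals)) {
    truth <- rbind(truth, data.frame(
      chrom = intervals$chrom, start = intervals$start,
      end = intervals$end, site = NA_integer_, type = intervals$type,
      instance = sprintf("fold=%g", intervals$fold),
      stringsAsFactors = FALSE))
  }
  if (is.null(truth))
    truth <- data.frame(chrom = character(), start = integer(),
                        end = integer(), site = integer(),
                        type = character(), instance = character(),
                        stringsAsFactors = FALSE)

  cls <- frag_class_probs(config, sites, intervals)
  n <- config$n_fragments
  Ls <- cls$Ls
  frag <- list()

  # site-spanning fragments: one class per planted site
  if (length(cls$site)) for (i in seq_along(cls$site)) {
    k <- stats::rbinom(1L, n, min(1, cls$site[i] * config$p_site))
    if (k == 0L) next
    G <- genome[[sites$chrom[i]]]
    L <- sample(Ls, k, replace = TRUE, prob = Ls / (G - Ls + 1))
    sp <- sites$site[i]
    start <- sp - L + 1L + floor(stats::runif(k) * L)   # spans sp
    frag[[length(frag) + 1L]] <-
      data.frame(chrom = sites$chrom[i], start = start, L = L)
  }

  # confounder-overlapping fragments (amplifications and hotspots)
  if (length(cls$interval)) for (j in seq_along(cls$interval)) {
    k <- stats::rbinom(1L, n,
                       min(1, cls$interval[j] * config$p_bg *
                             intervals$fold[j]))
    if (k == 0L) next
    G <- genome[[intervals$chrom[j]]]
    n_over <- vapply(Ls, function(L)
      max(0L, min(G - L, intervals$end[j] - 1L) -
            max(0L, intervals$start[j] - L + 1L) + 1L), 0L)
    L <- sample(Ls, k, replace = TRUE, prob = n_over / (G - Ls + 1))
    lo <- pmax(0L, intervals$start[j] - L + 1L)
    hi <- pmin(G - L, intervals$end[j] - 1L)
    start <- lo + floor(stats::runif(k) * (hi - lo + 1))
    frag[[length(frag) + 1L]] <-
      data.frame(chrom = intervals$chrom[j], start = start, L = L)
  }

  # background fragments: starts modulated by a per-tile Gamma rate
  # field (nonspecific-binding heterogeneity), rejecting the rare
  # proposals that span a site or overlap a confounder interval
  k_bg <- stats::rbinom(1L, n, cls$bg * config$p_bg)
  tile <- config$bg_tile
  tiles <- do.call(rbind, lapply(chroms, function(ch) {
    nt <- as.integer(ceiling(genome[[ch]] / tile))
    lens <- c(rep(tile, nt - 1L), genome[[ch]] - (nt - 1L) * tile)
    gam <- if (is.finite(config$bg_gamma_shape))
      stats::rgamma(nt, shape = config$bg_gamma_shape,
                    rate = config$bg_gamma_shape) else rep(1, nt)
    data.frame(chrom = ch, start = (seq_len(nt) - 1L) * tile,
               len = lens, weight = lens * gam, stringsAsFactors = FALSE)
  }))
  got <- 0L
  while (got < k_bg) {
    m <- max(64L, 2L * (k_bg - got))
    ti <- sample.int(nrow(tiles), m, replace = TRUE, prob = tiles$weight)
    ci <- match(tiles$chrom[ti], chroms)
    L <- sample(Ls, m, replace = TRUE)
    G <- unname(genome[ci])
    start <- pmin(tiles$start[ti] +
                    floor(stats::runif(m) * tiles$len[ti]), G - L)
    bad <- rep(FALSE, m)
    if (!is.null(sites)) for (i in seq_len(nrow(sites))) {
      sp <- sites$site[i]
      bad <- bad | (chroms[ci] == sites$chrom[i] &
                      start <= sp & sp < start + L)
    }
    if (!is.null(intervals) && nrow(intervals))
      for (j in seq_len(nrow(intervals))) {
        bad <- bad | (chroms[ci] == intervals$chrom[j] &
                        start < intervals$end[j] &
                        start + L > intervals$start[j])
      }
    ok <- which(!bad)[seq_len(min(k_bg - got, sum(!bad)))]
    if (length(ok))
      frag[[length(frag) + 1L]] <-
        data.frame(chrom = chroms[ci[ok]], start = start[ok], L = L[ok])
    got <- got + length(ok)
  }

  frag <- do.call(rbind, frag)
  if (is.null(frag) || nrow(frag) == 0L)
    stop("simulation retained zero fragments; check configuration")
  fwd <- stats::runif(nrow(frag)) < 0.5
  tags <- data.frame(chrom = frag$chrom,
                     pos = as.integer(ifelse(fwd, frag$start,
                                             frag$start + frag$L - 1L)),
                     strand = ifelse(fwd, "+", "-"),
                     stringsAsFactors = FALSE)
  tags <- tags[order(match(tags$chrom, chroms), tags$pos, tags$strand), ,
               drop = FALSE]
  rownames(tags) <- NULL

  structure(list(genome_seq = Biostrings::DNAStringSet(unlist(seqs)),
                 tags = tags, truth = truth, genome = genome,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d chromosomes (%d bp), %d tags, %d planted sites, %d confounders\n",
    length(x$genome), sum(x$genome), nrow(x$tags),
    sum(x$truth$type == "site"), sum(x$truth$type != "site")))
  invisible(x)
}

#' Materialize a synthetic dataset to files
#'
#' Writes the genome FASTA (plus a `.fai`-style index and a two-column
#' length table), the tags as BED6, and the truth table as TSV.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths.
#' @export
write_dataset <- function(dataset, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(prefix, ".fa")),
             fai = file.path(dir, paste0(prefix, ".fa.fai")),
             genome = file.path(dir, paste0(prefix, ".genome")),
             tags = file.path(dir, paste0(prefix, "_tags.bed")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  Biostrings::writeXStringSet(dataset$genome_seq, paths["fasta"],
                              width = 70L)
  # .fai: name, length, byte offset of first base, bases/bytes per line
  rec_bytes <- vapply(names(dataset$genome), function(ch)
    nchar(ch) + 2L + dataset$genome[[ch]] +
      ceiling(dataset$genome[[ch]] / 70), 0)
  offs <- cumsum(c(0, rec_bytes[-length(rec_bytes)]))
  writeLines(sprintf("%s\t%d\t%d\t70\t71", names(dataset$genome),
                     dataset$genome,
                     as.integer(offs + nchar(names(dataset$genome)) + 2L)),
             paths["fai"])
  write_genome_table(dataset$genome, paths["genome"])
  write_tags(dataset$tags, paths["tags"])
  utils::write.table(dataset$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
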