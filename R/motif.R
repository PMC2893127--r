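DNA <- c("A", "C", "G", "T")

seq_to_int <- function(s) {
  # A/C/G/T -> 1..4, anything else (N) -> NA
  m <- match(strsplit(toupper(s), "", fixed = TRUE)[[1L]], DNA)
  m
}

revcomp_int <- function(v) rev(5L - v)

#' Extract candidate-site sequences around estimated binding sites
#'
#' Retrieves the forward-strand genomic sequence `flank` bp up- and
#' downstream of each site estimate (a `2*flank + 1` bp window),
#' uppercased. Windows are clipped at chromosome ends (clipped entries
#' are flagged); sequences with more than 20% N are dropped with a
#' warning.
#'
#' @param fasta Path to a genome FASTA file, or a
#'   [Biostrings::DNAStringSet].
#' @param sites data.frame with columns `chrom` and `site` (0-based
#'   position) and optionally `id`.
#' @param flank Flank size in bp (default 20).
#' @return data.frame with columns `id`, `chrom`, `site`, `seq`,
#'   `clipped`.
#' @export
extract_site_sequences <- function(fasta, sites, flank = 20L) {
  gen <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(gen) <- sub("\\s.*$", "", names(gen))
  if (nrow(sites) == 0L)
    return(data.frame(id = character(), chrom = character(),
                      site = integer(), seq = character(),
                      clipped = logical(), stringsAsFactors = FALSE))
  missing <- setdiff(unique(sites$chrom), names(gen))
  if (length(missing))
    stop("chromosome(s) not in FASTA: ", paste(missing, collapse = ", "))
  id <- if (!is.null(sites$id)) as.character(sites$id) else
    sprintf("site%d", seq_len(nrow(sites)))
  out <- lapply(seq_len(nrow(sites)), function(i) {
    ch <- sites$chrom[i]
    len <- Biostrings::width(gen[ch])
    s0 <- sites$site[i] - flank      # 0-based inclusive
    e0 <- sites$site[i] + flank
    if (sites$site[i] < 0L || sites$site[i] >= len)
      stop("site ", sites$site[i], " outside chromosome ", ch)
    s <- max(0L, s0); e <- min(len - 1L, e0)
    seq <- toupper(as.character(Biostrings::subseq(gen[[ch]], s + 1L,
                                                   e + 1L)))
    data.frame(id = id[i], chrom = ch, site = sites$site[i], seq = seq,
               clipped = (s != s0 || e != e0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  nfrac <- vapply(out$seq, function(s)
    mean(strsplit(s, "")[[1L]] == "N"), 0, USE.NAMES = FALSE)
  if (any(nfrac > 0.2)) {
    warning(sum(nfrac > 0.2), " sequence(s) dropped: > 20% N")
    out <- out[nfrac <= 0.2, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Construct a position-specific scoring matrix object
#'
#' @param probs 4 x w probability matrix, rows A, C, G, T; columns must
#'   each sum to 1 and all entries be positive.
#' @param background Length-4 background base frequencies.
#' @param pseudocount Pseudocount used in construction (recorded).
#' @return Object of class `pssm`.
#' @export
pssm <- function(probs, background = rep(0.25, 4), pseudocount = 0.1) {
  stopifnot(nrow(probs) == 4L, all(probs > 0),
            all(abs(colSums(probs) - 1) < 1e-9),
            length(background) == 4L, all(background > 0))
  rownames(probs) <- DNA
  structure(list(probs = probs, width = ncol(probs),
                 background = background / sum(background),
                 pseudocount = pseudocount),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("pssm: width %d, consensus %s\n", x$width, consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PSSM
#'
#' @param x A `pssm`.
#' @return Character string of most probable bases per column.
#' @export
consensus <- function(x) paste(DNA[apply(x$probs, 2L, which.max)],
                               collapse = "")

# log-likelihood-ratio contributions of window positions for one strand;
# windows containing N get -Inf
window_llr <- function(codes, w, logratio) {
  m <- length(codes) - w + 1L
  if (m < 1L) return(numeric(0))
  sc <- numeric(m)
  for (k in seq_len(w)) {
    v <- logratio[codes[k:(k + m - 1L)], k]
    v[is.na(v)] <- -Inf
    sc <- sc + v
  }
  sc
}

#' Zero-or-one-occurrence-per-sequence (ZOOPS) motif discovery by EM
#'
#' Each ~40 bp input sequence is assumed to contain either one motif
#' occurrence (on either strand) or none. The hidden variable is the
#' occurrence position/strand (or absence); the E-step computes its
#' posterior under the current motif matrix, site prior and 0-order
#' background (estimated from the input); the M-step re-estimates the
#' matrix (with pseudocounts) and the prior. EM runs to a log-likelihood
#' change below `tol` or `max_iter` iterations, from `n_starts`
#' initializations each seeded from a randomly chosen w-mer; the best
#' final likelihood wins.
#'
#' @param seqs Character vector of DNA sequences (or the data.frame from
#'   [extract_site_sequences()]).
#' @param w Motif width (4-15, default 9).
#' @param n_starts Number of seeded EM starts.
#' @param seed Integer RNG seed.
#' @param pseudocount M-step pseudocount per matrix cell.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations per start.
#' @return Object of class `motif_result`: list with `pssm`,
#'   `posteriors` (per-sequence probability of containing the motif),
#'   `sites` (per-sequence best position, 1-based, and strand),
#'   `fraction_containing`, `gamma`, `loglik`, `ll_trace` (of the best
#'   start) and `consensus`.
#' @export
zoops_em <- function(seqs, w = 9L, n_starts = 5L, seed = 1L,
                     pseudocount = 0.1, tol = 1e-6, max_iter = 200L) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (w < 4L) stop("motif width must be >= 4")
  codes <- lapply(seqs, seq_to_int)
  if (any(lengths(codes) < w))
    stop("motif width ", w, " exceeds the shortest sequence")
  if (n_starts < 1L) stop("n_starts must be >= 1")
  base_counts <- tabulate(unlist(codes), 4L)
  bg <- (base_counts + 1) / sum(base_counts + 4)
  nseq <- length(codes)
  set.seed(seed)

  run_em <- function(theta0) {
    theta <- theta0
    gamma <- 0.5
    ll_trace <- numeric(0)
    ll_old <- -Inf
    z_contain <- numeric(nseq)
    for (iter in seq_len(max_iter)) {
      logratio <- log(theta) - log(bg)    # 4 x w
      counts <- matrix(0, 4L, w)
      mass <- 0
      ll <- 0
      z_contain <- numeric(nseq)
      best <- vector("list", nseq)
      for (i in seq_len(nseq)) {
        cc <- codes[[i]]
        m <- length(cc) - w + 1L
        sf <- window_llr(cc, w, logratio)
        rcc <- revcomp_int(ifelse(is.na(cc), NA_integer_, cc))
        sr <- window_llr(rcc, w, logratio)
        lr <- exp(c(sf, sr))
        prior <- gamma / (2 * m)
        denom <- (1 - gamma) + prior * sum(lr)
        z <- prior * lr / denom
        z_contain[i] <- sum(z)
        ll <- ll + log(denom)             # + constant background term
        jbest <- which.max(z)
        best[[i]] <- if (jbest <= m) c(jbest, 1L) else c(jbest - m, 2L)
        # expected base counts at each motif column, both strands
        zf <- z[seq_len(m)]; zr <- z[m + seq_len(m)]
        for (k in seq_len(w)) {
          bf <- cc[k:(k + m - 1L)]
          br <- rcc[k:(k + m - 1L)]
          for (a in 1:4)
            counts[a, k] <- counts[a, k] +
              sum(zf[which(bf == a)]) + sum(zr[which(br == a)])
        }
        mass <- mass + sum(z)
      }
      ll_trace <- c(ll_trace, ll)
      theta <- sweep(counts + pseudocount, 2L,
                     colSums(counts) + 4 * pseudocount, "/")
      gamma <- min(max(mass / nseq, 1e-6), 1 - 1e-6)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(theta = theta, gamma = gamma, ll = ll_trace[length(ll_trace)],
         ll_trace = ll_trace, z = z_contain, best = best)
  }

  init_from_wmer <- function() {
    repeat {
      i <- sample.int(nseq, 1L)
      cc <- codes[[i]]
      j <- sample.int(length(cc) - w + 1L, 1L)
      win <- cc[j:(j + w - 1L)]
      if (!anyNA(win)) break
    }
    theta <- matrix((1 - 0.5) / 3, 4L, w)
    theta[cbind(win, seq_len(w))] <- 0.5
    theta
  }

  fits <- lapply(seq_len(n_starts), function(s) run_em(init_from_wmer()))
  fit <- fits[[which.max(vapply(fits, `[[`, 0, "ll"))]]
  mat <- pssm(fit$theta, background = bg, pseudocount = pseudocount)
  sites <- data.frame(pos = as.integer(vapply(fit$best, `[`, 0, 1L)),
                      strand = c("+", "-")[vapply(fit$best, `[`, 0, 2L)])
  structure(list(pssm = mat, posteriors = fit$z, sites = sites,
                 fraction_containing = mean(fit$z > 0.5),
                 gamma = fit$gamma, loglik = fit$ll,
                 ll_trace = fit$ll_trace, consensus = consensus(mat)),
            class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf(
    "motif_result: consensus %s, fraction containing %.3f, logLik %.2f\n",
    x$consensus, x$fraction_containing, x$loglik))
  invisible(x)
}

#' Accept or reject a discovered motif
#'
#' A candidate motif must be contained by at least `min_fraction` of
#' the input sequences (default 25%, inclusive).
#'
#' @param result A `motif_result`.
#' @param min_fraction Minimum fraction of motif-containing sequences.
#' @return Logical flag.
#' @export
accept_motif <- function(result, min_fraction = 0.25) {
  result$fraction_containing >= min_fraction
}

#' Exact null distribution of the PSSM log-odds score
#'
#' Scores are discretized on a grid of width `gran`; the distribution
#' of the w-column sum under the 0-order background is computed by
#' dynamic-programming convolution of the per-column score
#' distributions.
#'
#' @param mat A `pssm`.
#' @param gran Discretization granularity (default 1e-3).
#' @return List with integer score `support` (units of `gran`) and
#'   `prob`; `sum(prob) == 1` up to numerical error.
#' @export
pssm_null_distribution <- function(mat, gran = 1e-3) {
  sc <- round((log(mat$probs) - log(mat$background)) / gran)
  dist <- c(1)          # prob vector over offset support
  lo <- 0L
  for (k in seq_len(mat$width)) {
    s <- sc[, k]
    new_lo <- lo + min(s)
    new_hi <- lo + length(dist) - 1L + max(s)
    nd <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- lo + s[b] - new_lo
      idx <- seq_along(dist) + off
      nd[idx] <- nd[idx] + mat$background[b] * dist
    }
    dist <- nd
    lo <- new_lo
  }
  list(support = lo + seq_along(dist) - 1L, prob = dist, gran = gran)
}

#' Scan a sequence with a PSSM and compute the region motif p-value
#'
#' The log-odds score (motif vs 0-order background) is computed at
#' every position on both strands; the site p-value p1 of the best
#' score comes from the exact discretized null distribution, and the
#' region p-value is `p_m = 1 - (1 - p1)^m` with m the number of
#' scanned (position, strand) pairs, clipped to (0, 1].
#'
#' @param mat A `pssm`.
#' @param seq DNA sequence (character).
#' @param null Optional precomputed [pssm_null_distribution()] (reuse it
#'   when scanning many regions).
#' @return List with `best_score` (nats), `best_pos` (1-based),
#'   `best_strand`, `p1`, `p_m`, `m`.
#' @export
scan_pvalue <- function(mat, seq, null = NULL) {
  codes <- seq_to_int(seq)
  w <- mat$width
  if (length(codes) < w) stop("sequence shorter than motif width")
  if (is.null(null)) null <- pssm_null_distribution(mat)
  logratio <- log(mat$probs) - log(mat$background)
  sf <- window_llr(codes, w, logratio)
  sr <- window_llr(revcomp_int(codes), w, logratio)
  all_sc <- c(sf, sr)
  m <- sum(is.finite(all_sc))
  if (m == 0L) stop("no scannable window (all windows contain N)")
  all_sc[!is.finite(all_sc)] <- -Inf
  jbest <- which.max(all_sc)
  best <- unname(all_sc[jbest])
  mi <- length(sf)
  best_pos <- if (jbest <= mi) jbest else {
    # reverse-strand window index back onto forward coordinates
    length(codes) - w + 1L - (jbest - mi) + 1L
  }
  disc <- round(best / null$gran)
  p1 <- sum(null$prob[null$support >= disc])
  p1 <- min(max(p1, .Machine$double.xmin), 1)
  p_m <- 1 - (1 - p1)^m
  p_m <- min(max(p_m, .Machine$double.xmin), 1)
  list(best_score = best, best_pos = best_pos,
       best_strand = if (jbest <= mi) "+" else "-",
       p1 = p1, p_m = p_m, m = m)
}

#' Write a motif in MEME minimal text format
#'
#' @param result A `motif_result`.
#' @param path Output path.
#' @param name Motif name in the file.
#' @export
write_meme_motif <- function(result, path, name = "motif1") {
  mat <- result$pssm
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA, mat$background),
                     collapse = " "), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       mat$width, max(1L, round(sum(result$posteriors))))),
             con)
  writeLines(apply(mat$probs, 2L, function(col)
    paste(sprintf("%.6f", col), collapse = " ")), con)
  invisible(path)
}
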