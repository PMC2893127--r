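#' Pipeline configuration
#'
#' @param tags Path to the BED6 tag file.
#' @param genome Path to the two-column chromosome-length table.
#' @param fasta Path to the genome FASTA (NULL disables the motif
#'   stage).
#' @param out_dir Output directory.
#' @param d Maximum ChIP fragment size in bp (window and bin width);
#'   known from the experimental procedure.
#' @param alpha Pre-specified eFDR in (0, 1).
#' @param n_high_quality Number of regions used for motif discovery
#'   (capped at 500).
#' @param motif_width Motif width for discovery (4-15).
#' @param motif Whether to run the motif stage at all.
#' @param rounding Rounding rule for the final significant count.
#' @param seed Integer seed driving every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tags, genome, fasta = NULL, out_dir = "peaks_out",
                            d = 250L, alpha = 0.5, n_high_quality = 200L,
                            motif_width = 9L, motif = !is.null(fasta),
                            rounding = c("half_away", "floor"), seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_high_quality > 500L)
    stop("n_high_quality must be <= 500 (motif discovery input cap)")
  if (motif_width < 4L || motif_width > 15L)
    stop("motif_width must be in 4..15")
  if (isTRUE(motif) && is.null(fasta))
    stop("motif stage enabled but no genome FASTA configured")
  structure(list(tags = tags, genome = genome, fasta = fasta,
                 out_dir = out_dir, d = as.integer(d), alpha = alpha,
                 n_high_quality = as.integer(n_high_quality),
                 motif_width = as.integer(motif_width),
                 motif = isTRUE(motif), rounding = match.arg(rounding),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys map one-to-one onto the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the yaml package")
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the whole peak-calling pipeline
#'
#' Executes, in order: tag loading and deduplication; genome binning;
#' zero-truncated Gamma-Poisson background fitting; eFDR thresholding;
#' region formation; per-region strand profiling, peak p-values and
#' pattern dissimilarity against the simulated reference; high-quality
#' region selection; motif discovery and genome-wide motif scanning
#' (when a FASTA is configured); evidence integration and re-ranking;
#' and the final `(1 - alpha)` significance cut. Writes the ranked
#' regions (BED6+3), an audit TSV, the eFDR table, the discovered
#' motif (MEME minimal format), the reference pattern and a JSON run
#' manifest into `out_dir`. Rerunning with identical config and inputs
#' reproduces identical outputs.
#'
#' @param config A `pipeline_config`, or the path of a YAML file for
#'   [read_pipeline_config()].
#' @return (Invisibly) a list with the ranked table, fitted background,
#'   eFDR table, threshold, motif result and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (config$motif && is.null(config$fasta))
    stop("motif stage enabled but no genome FASTA configured")
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage_msg("input", "reading genome table %s", config$genome)
  genome <- read_genome_table(config$genome)
  stage_msg("input", "reading tags %s", config$tags)
  tags <- read_tags(config$tags, genome)
  tags <- deduplicate_tags(tags)
  stage_msg("input", "%d unique tags (%d duplicates removed)",
            nrow(tags), attr(tags, "n_removed"))

  stage_msg("bin", "binning genome at d = %d", config$d)
  binned <- bin_counts(tags, genome, config$d)

  stage_msg("fit", "fitting zero-truncated background models")
  fit <- fit_background(binned$hist)
  stage_msg("fit", "G-P r = %.4g, p = %.4g (logLik %.1f vs Poisson %.1f)",
            fit$gp$r, fit$gp$p, fit$report$loglik_gp,
            fit$report$loglik_pois)

  etab <- efdr_table(fit$gp, binned$hist)
  k_star <- select_threshold(etab, config$alpha)
  stage_msg("efdr", "count threshold k* = %d at alpha = %g", k_star,
            config$alpha)
  pbrs <- select_pbrs(binned$bins, k_star, config$d)
  stage_msg("pbrs", "%d potential binding regions", nrow(pbrs))
  if (nrow(pbrs) == 0L) stop("pbrs stage: no region exceeds the threshold")

  stage_msg("pattern", "simulating reference pattern (seed %d)",
            config$seed)
  ref <- simulate_reference(sim_ref_config(d = config$d,
                                           seed = config$seed))

  stage_msg("profile", "profiling %d regions", nrow(pbrs))
  peaks <- vector("list", nrow(pbrs))
  scores <- pbrs
  scores$p_c <- NA_real_
  scores$d_p <- NA_real_
  scores$site <- NA_integer_
  for (i in seq_len(nrow(pbrs))) {
    prof <- window_profile(tags, pbrs[i, ], config$d, genome)
    pk <- locate_peaks(prof)
    peaks[[i]] <- pk
    scores$p_c[i] <- peak_pvalue(fit$gp, pk)
    scores$d_p[i] <- pattern_score(prof, ref)
    scores$site[i] <- pk$site_estimate
  }

  motif_res <- NULL
  motif_accepted <- FALSE
  scores$p_m <- NA_real_
  if (config$motif) {
    stage_msg("motif", "selecting up to %d high-quality regions",
              config$n_high_quality)
    hq <- select_high_quality(scores, config$n_high_quality)
    sites <- data.frame(id = sprintf("pbr%d", hq),
                        chrom = scores$chrom[hq], site = scores$site[hq])
    seqset <- extract_site_sequences(config$fasta, sites, flank = 20L)
    stage_msg("motif", "ZOOPS-EM on %d sequences (w = %d)",
              nrow(seqset), config$motif_width)
    motif_res <- zoops_em(seqset, w = config$motif_width,
                          seed = config$seed)
    motif_accepted <- accept_motif(motif_res)
    stage_msg("motif", "consensus %s, containing fraction %.3f -> %s",
              motif_res$consensus, motif_res$fraction_containing,
              if (motif_accepted) "accepted" else "rejected")
    if (motif_accepted) {
      gen <- Biostrings::readDNAStringSet(config$fasta)
      names(gen) <- sub("\\s.*$", "", names(gen))
      null <- pssm_null_distribution(motif_res$pssm)
      stage_msg("scan", "scanning %d regions for the motif", nrow(pbrs))
      for (i in seq_len(nrow(pbrs))) {
        s <- max(0L, pbrs$start[i] - config$d)
        e <- min(genome[[pbrs$chrom[i]]], pbrs$end[i] + config$d)
        seq <- as.character(Biostrings::subseq(gen[[pbrs$chrom[i]]],
                                               s + 1L, e))
        scores$p_m[i] <- scan_pvalue(motif_res$pssm, seq, null)$p_m
      }
    } else {
      stage_msg("motif",
                "no motif contained by >= 25%% of sequences; falling back to count + pattern evidence")
    }
  }

  stage_msg("rank", "integrating evidence for %d regions", nrow(scores))
  ranked <- integrate_and_rank(scores)
  ranked <- select_significant(ranked, config$alpha, config$rounding)
  ns <- sum(ranked$significant)
  stage_msg("rank", "%d of %d regions significant at alpha = %g", ns,
            nrow(ranked), config$alpha)

  paths <- c(regions = file.path(config$out_dir, "regions_ranked.bed"),
             audit = file.path(config$out_dir, "regions_audit.tsv"),
             efdr = file.path(config$out_dir, "efdr_table.tsv"),
             reference = file.path(config$out_dir, "reference_pattern.tsv"),
             manifest = file.path(config$out_dir, "manifest.json"))
  out_bed <- ranked
  out_bed$p_m[is.na(out_bed$p_m)] <- 1
  write_scored_regions(out_bed, paths["regions"])
  write_audit_table(ranked, paths["audit"])
  write_efdr_table(etab, paths["efdr"])
  write_reference_pattern(ref, paths["reference"])
  if (!is.null(motif_res))
    write_meme_motif(motif_res, file.path(config$out_dir, "motif.meme"))

  manifest <- list(
    config = unclass(config),
    inputs = list(tags_md5 = unname(tools::md5sum(config$tags)),
                  genome_md5 = unname(tools::md5sum(config$genome))),
    counts = list(n_tags = nrow(tags),
                  n_duplicates_removed = attr(tags, "n_removed"),
                  n_bins = attr(binned$hist, "N_total"),
                  k_star = k_star,
                  n_pbrs = nrow(pbrs),
                  n_high_quality = if (config$motif) length(hq) else 0L,
                  motif_accepted = motif_accepted,
                  motif_fraction = if (!is.null(motif_res))
                    motif_res$fraction_containing else NA,
                  n_significant = ns),
    background = list(r = fit$gp$r, p = fit$gp$p,
                      loglik_gp = fit$report$loglik_gp,
                      loglik_pois = fit$report$loglik_pois),
    seed = config$seed,
    version = as.character(utils::packageVersion("peaktriad")))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stage_msg("done", "finished in %.1f s; outputs in %s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")),
            config$out_dir)
  invisible(list(ranked = ranked, fit = fit, efdr = etab, k_star = k_star,
                 pbrs = pbrs, reference = ref, motif = motif_res,
                 manifest = manifest, paths = paths))
}
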