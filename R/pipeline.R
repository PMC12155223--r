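#' Run the full analysis pipeline on one sample
#'
#' Orchestrates the stages in order: somatic filtering, background
#' simulation, sample-dependent IMD threshold estimation, regional
#' correction, cluster detection and taxonomy, didyma and adduct-pair
#' extraction, pair-enrichment profiling, SBS96 signature refitting and
#' genomic/expression attribution. Each stage's table is written to
#' \code{out_dir} before the next begins; a JSON run log records the seed
#' and stage tallies. All randomness flows from \code{seed}.
#'
#' @param genome \code{DNAStringSet} (or FASTA path).
#' @param catalog A [mutation_catalog()] (or catalog TSV/VCF path).
#' @param models Optional gene models (or GTF path) with expression joined.
#' @param expression Optional expression table passed to
#'   [read_gene_models()] when \code{models} is a path.
#' @param signatures Signature matrix (default [example_signature_matrix()]).
#' @param out_dir Output directory (created; pass NULL to skip writing).
#' @param filter_cfg,cluster_cfg Configuration objects.
#' @param iterations Simulation iterations (default 100).
#' @param platform Burden normalisation platform or Mb size.
#' @param max_imd Enrichment profile axis (default 100).
#' @param seed Integer seed.
#' @return List with elements filtered, sims (threshold etc.), flags,
#'   events, didyma, nqo_pairs, enrichment (per pair class), fit,
#'   annotation, log.
#' @export
run_pipeline <- function(genome, catalog, models = NULL, expression = NULL,
                         signatures = example_signature_matrix(),
                         out_dir = NULL,
                         filter_cfg = somatic_filter_config(),
                         cluster_cfg = cluster_detection_config(),
                         iterations = 100, platform = "mouse_wgs",
                         max_imd = 100, seed = 1L) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(catalog)) catalog <- read_catalog(catalog)
  if (is.character(models)) models <- read_gene_models(models, expression)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir) && !is.null(df)) {
      df2 <- df
      if ("members" %in% names(df2)) {
        df2$members <- vapply(df2$members, paste, "", collapse = ",")
      }
      utils::write.table(df2, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  log <- list(seed = seed, n_input = nrow(catalog))
  filtered <- apply_somatic_filters(catalog, filter_cfg)
  log$n_filtered <- nrow(filtered)
  emit(as.data.frame(filtered), "catalog_filtered")

  sims <- simulate_catalog(filtered, genome, models,
                           simulation_config(iterations = iterations, seed = seed))
  thr <- estimate_sample_imd_threshold(filtered, sims, cluster_cfg)
  log$imd_threshold <- thr$threshold
  flags <- regional_imd_correction(filtered, sims, thr$threshold, cluster_cfg)
  emit(cbind(as.data.frame(filtered)[c("sample", "chrom", "pos")], flags),
       "clustered_flags")

  eff_thr <- if (is.na(thr$threshold)) cluster_cfg$didyma_imd_max else thr$threshold
  events <- detect_clusters(filtered, genome, pmin(eff_thr, flags$cutoff,
                                                   na.rm = TRUE),
                            cluster_cfg, flags = NULL)
  emit(events, "cluster_events")
  didyma <- extract_didyma(filtered, genome, cluster_cfg)
  nqo_same <- extract_nqo_pairs(filtered, genome, cluster_cfg$didyma_imd_max, "same")
  nqo_opp <- extract_nqo_pairs(filtered, genome, cluster_cfg$didyma_imd_max, "opposite")
  if (!is.null(models) && nrow(didyma)) {
    ann <- assign_region(didyma, models)
    didyma$region <- ann$region
    didyma$gene_ids <- ann$gene_ids
    didyma$ts_nts <- transcribed_strand(didyma, models)
  }
  emit(didyma, "didyma")
  emit(nqo_same, "nqo_pairs_same_strand")
  emit(nqo_opp, "nqo_pairs_opposite_strand")

  enrichment <- lapply(stats::setNames(PAIR_CLASSES, PAIR_CLASSES), function(pc) {
    obs <- pair_counts_by_imd(filtered, genome, pc, max_imd)
    enrichment_vs_simulation(obs, sims, pc, max_imd)
  })
  for (pc in names(enrichment)) emit(enrichment[[pc]], paste0("enrichment_", pc))

  counts <- build_sbs96(filtered, genome)
  fit <- fit_two_pass_nnls(counts, signatures)
  emit(exposure_table(fit, platform), "signature_exposures")

  annotation <- NULL
  if (!is.null(models)) {
    sizes <- region_sizes_from_models(models, genome)
    annotation <- list(
      sizes = sizes,
      didyma_density = if (nrow(didyma)) didyma_density_by_region(didyma, sizes),
      didyma_expression = if (nrow(didyma) && any(didyma$region == "genic"))
        didyma_by_expression(didyma, models))
  }
  log$n_events <- nrow(events)
  log$n_didyma <- nrow(didyma)
  if (!is.null(out_dir)) {
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(filtered = filtered, threshold = thr, flags = flags, events = events,
       didyma = didyma, nqo_pairs = list(same = nqo_same, opposite = nqo_opp),
       enrichment = enrichment, fit = fit, annotation = annotation, log = log)
}

#' Cohort summary statistics
#'
#' Per-metric group medians with two-tailed Mann-Whitney U comparisons
#' between the two groups; p-values are BH-adjusted to q-values when four
#' or more tests are present. Optional Spearman correlations between metric
#' pairs.
#'
#' @param df data.frame with a grouping column and numeric metric columns.
#' @param group Name of the grouping column (exactly two groups compared).
#' @param metrics Character vector of metric column names (default: all
#'   numeric columns).
#' @param spearman_pairs Optional list of length-2 character vectors of
#'   metric names to correlate.
#' @return data.frame (metric, median per group, p, q); Spearman results in
#'   attribute \code{spearman}.
#' @export
cohort_summary <- function(df, group = "group", metrics = NULL,
                           spearman_pairs = NULL) {
  g <- factor(df[[group]])
  if (nlevels(g) < 2) stop("need >= 2 groups")
  lv <- levels(g)[1:2]
  if (is.null(metrics)) {
    metrics <- names(df)[vapply(df, is.numeric, TRUE) & names(df) != group]
  }
  rows <- lapply(metrics, function(m) {
    x <- df[[m]][g == lv[1]]
    y <- df[[m]][g == lv[2]]
    p <- if (length(x) >= 1 && length(y) >= 1) {
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    } else NA_real_
    # all-tied comparisons carry no evidence of a difference
    if (!is.null(p) && is.nan(p)) p <- 1
    out <- data.frame(metric = m, median_1 = stats::median(x, na.rm = TRUE),
                      median_2 = stats::median(y, na.rm = TRUE), p = p)
    names(out)[2:3] <- paste0("median_", lv)
    out
  })
  res <- do.call(rbind, rows)
  res$q <- if (sum(!is.na(res$p)) >= 4) bh_adjust(ifelse(is.na(res$p), 1, res$p)) else NA_real_
  if (!is.null(spearman_pairs)) {
    sp <- do.call(rbind, lapply(spearman_pairs, function(pr) {
      ct <- suppressWarnings(stats::cor.test(df[[pr[1]]], df[[pr[2]]],
                                             method = "spearman"))
      data.frame(metric_a = pr[1], metric_b = pr[2],
                 rho = unname(ct$estimate), p = ct$p.value)
    }))
    attr(res, "spearman") <- sp
  }
  res
}
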