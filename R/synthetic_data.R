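#' Synthetic dataset configuration
#'
#' Defines the co-mutagenesis model the generator emulates: a random genome,
#' non-overlapping genes with zero-inflated log-normal expression, dispersed
#' APOBEC (TCW C>T/G) and carcinogen (G>T/G>C, GG-biased) background
#' mutations, and didyma pairs planted as two deaminations of the same
#' 24–32 nt single-stranded tract exposed by nucleotide excision repair.
#'
#' @param chrom_lengths Named integer vector of contig lengths (default one
#'   1 Mb chromosome).
#' @param gc_fraction Genome GC content (default 0.42, mouse-like).
#' @param n_genes,gene_length_range Gene count and span range.
#' @param expression_meanlog,expression_sdlog,zero_expression_fraction
#'   Log-normal expression model with a zero-inflated fraction.
#' @param n_dispersed_apobec,n_dispersed_nqo,n_didyma_pairs Mutation counts.
#' @param ner_tract_range Single-strand tract length range in nt (default
#'   24–32).
#' @param mutations_per_tract Deaminations per tract (default 2, the didyma
#'   case; 1 or 3 exercise the run-resolution rules).
#' @param nqo_gg_bias Placement weight multiplier for guanines followed by
#'   another guanine on the adduct strand (default 3).
#' @param nqo_gt_fraction Fraction of carcinogen mutations that are G>T
#'   (default 0.75; the rest are G>C outside GA contexts).
#' @param apobec_ct_fraction Fraction of APOBEC mutations that are C>T
#'   (default 0.7; the rest C>G).
#' @param vaf_mean,vaf_sd,vaf_range Truncated-normal clone VAF model.
#' @param pair_vaf_sd Within-pair VAF noise (default 0.02, so true pairs
#'   stay within the 0.1 VAF-difference bound).
#' @param depth_mean Mean sequencing depth (Poisson, floored at 12).
#' @param expression_weighting Weight genic didyma placement by gene
#'   expression (transcription-coupled damage bias).
#' @param min_tract_separation Minimum distance between planted tracts.
#' @param background_exclusion Background mutations are rejected within this
#'   distance of a planted tract (keeps truth labels unambiguous).
#' @param sample Sample identifier.
#' @param seed Master seed; each generation stage derives its stream from
#'   it.
#' @return List of class \code{synthetic_config}.
#' @export
synthetic_config <- function(chrom_lengths = c(chr1 = 1e6),
                             gc_fraction = 0.42,
                             n_genes = 40, gene_length_range = c(5000, 15000),
                             expression_meanlog = 2, expression_sdlog = 1,
                             zero_expression_fraction = 0.2,
                             n_dispersed_apobec = 200,
                             n_dispersed_nqo = 400,
                             n_didyma_pairs = 50,
                             ner_tract_range = c(24, 32),
                             mutations_per_tract = 2,
                             nqo_gg_bias = 3, nqo_gt_fraction = 0.75,
                             apobec_ct_fraction = 0.7,
                             vaf_mean = 0.35, vaf_sd = 0.1,
                             vaf_range = c(0.1, 0.6), pair_vaf_sd = 0.02,
                             depth_mean = 30,
                             expression_weighting = TRUE,
                             min_tract_separation = 200,
                             background_exclusion = 100,
                             sample = "synthetic1", seed = 1L) {
  chrom_lengths <- unlist(chrom_lengths)
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0), gc_fraction >= 0, gc_fraction <= 1,
            ner_tract_range[1] >= 2, ner_tract_range[2] >= ner_tract_range[1],
            ner_tract_range[2] <= min(chrom_lengths),
            n_dispersed_apobec >= 0, n_dispersed_nqo >= 0, n_didyma_pairs >= 0,
            mutations_per_tract >= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Canonical configuration for null-enrichment calibration
#'
#' A dense, fully dispersed APOBEC catalog (no planted pairs, no genes) on a
#' 2 Mb genome. The mutation count is chosen so that the expected
#' same-strand APOBEC pair count exceeds 500 in every IMD bin up to 100 nt,
#' which keeps the Monte-Carlo noise of the observed/simulated ratio below
#' a few percent and makes the null value of 1 testable bin by bin.
#'
#' @param seed Master seed.
#' @return A [synthetic_config()].
#' @export
synthetic_config_null <- function(seed = 1L) {
  synthetic_config(chrom_lengths = c(chr1 = 2e6), n_genes = 0,
                   n_dispersed_apobec = 50000, n_dispersed_nqo = 0,
                   n_didyma_pairs = 0, background_exclusion = 0,
                   seed = seed)
}

#' Canonical configuration for enrichment-shape experiments
#'
#' Plants 500 didyma pairs over a dispersed APOBEC/carcinogen background
#' dense enough that the 33–100 nt band of the same-strand APOBEC profile
#' carries several hundred expected background pairs. The truth-isolation
#' constraints of the default profile (tract separation, background
#' exclusion zones) are turned off here: they are what keeps recovery
#' scoring unambiguous, but they would artificially deplete observed pairs
#' in the null band of an enrichment profile.
#'
#' @param seed Master seed.
#' @return A [synthetic_config()].
#' @export
synthetic_config_enrichment <- function(seed = 1L) {
  synthetic_config(chrom_lengths = c(chr1 = 2e6), n_genes = 0,
                   n_dispersed_apobec = 5000, n_dispersed_nqo = 2000,
                   n_didyma_pairs = 500, expression_weighting = FALSE,
                   min_tract_separation = 0, background_exclusion = 0,
                   seed = seed)
}

.stage_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) * 7 + offset) %% 2147483646L) + 1L
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Generate a random genome
#'
#' I.i.d. bases at the configured GC fraction. Deterministic for a given
#' config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return \code{DNAStringSet}.
#' @export
make_genome <- function(cfg) {
  set.seed(.stage_seed(cfg, 1L))
  p <- c(A = (1 - cfg$gc_fraction) / 2, C = cfg$gc_fraction / 2,
         G = cfg$gc_fraction / 2, T = (1 - cfg$gc_fraction) / 2)
  seqs <- vapply(cfg$chrom_lengths, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, "")
  Biostrings::DNAStringSet(stats::setNames(seqs, names(cfg$chrom_lengths)))
}

#' Generate non-overlapping gene models with expression
#'
#' Genes are placed by rejection sampling on random strands; expression is
#' zero with the configured probability, otherwise log-normal.
#'
#' @param genome \code{DNAStringSet} from [make_genome()].
#' @param cfg A [synthetic_config()].
#' @return Gene model data.frame (gene_id, chrom, start, end, strand,
#'   expression).
#' @export
make_gene_models <- function(genome, cfg) {
  set.seed(.stage_seed(cfg, 2L))
  lens <- genome_lengths(genome)
  placed <- list()
  occupied <- lapply(lens, function(L) integer(0))  # start/end pairs per chrom
  tries <- 0L
  max_tries <- 1000L * max(1L, cfg$n_genes)
  glen_range <- cfg$gene_length_range
  while (length(placed) < cfg$n_genes) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not place ", cfg$n_genes, " non-overlapping genes")
    ch <- sample(names(lens), 1, prob = lens)
    gl <- sample(glen_range[1]:glen_range[2], 1)
    if (gl >= lens[[ch]]) gl <- max(2L, lens[[ch]] %/% 10L)
    st <- sample.int(lens[[ch]] - gl, 1)
    en <- st + gl - 1L
    iv <- occupied[[ch]]
    if (length(iv)) {
      m <- matrix(iv, ncol = 2, byrow = TRUE)
      if (any(st <= m[, 2] & en >= m[, 1])) next
    }
    occupied[[ch]] <- c(occupied[[ch]], st, en)
    placed[[length(placed) + 1L]] <- data.frame(
      gene_id = sprintf("gene%03d", length(placed) + 1L), chrom = ch,
      start = st, end = en, strand = sample(c("+", "-"), 1),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, placed)
  zero <- stats::runif(nrow(df)) < cfg$zero_expression_fraction
  df$expression <- ifelse(zero, 0,
                          stats::rlnorm(nrow(df), cfg$expression_meanlog,
                                        cfg$expression_sdlog))
  df[order(df$chrom, df$start), , drop = FALSE]
}

# TCW cytosine sites of one chromosome: data.frame(pos, strand) where pos is
# the forward coordinate of the (possibly minus-strand) mutated cytosine.
.tcw_sites <- function(genome, chrom) {
  s <- strsplit(.genome_string(genome, chrom), "", fixed = TRUE)[[1]]
  L <- length(s)
  if (L < 3) return(data.frame(pos = integer(0), strand = character(0)))
  p <- 2:(L - 1L)
  plus <- s[p - 1L] == "T" & s[p] == "C" & s[p + 1L] %in% c("A", "T")
  minus <- s[p + 1L] == "A" & s[p] == "G" & s[p - 1L] %in% c("T", "A")
  data.frame(pos = c(p[plus], p[minus]),
             strand = rep(c("+", "-"), c(sum(plus), sum(minus))),
             stringsAsFactors = FALSE)
}

# guanine sites: pos, strand (strand = guanine strand), gg (downstream G on
# the guanine strand), ga (downstream A on the guanine strand)
.guanine_sites <- function(genome, chrom) {
  s <- strsplit(.genome_string(genome, chrom), "", fixed = TRUE)[[1]]
  L <- length(s)
  if (L < 3) return(data.frame(pos = integer(0), strand = character(0),
                               gg = logical(0), ga = logical(0)))
  p <- 2:(L - 1L)
  plus <- s[p] == "G"
  minus <- s[p] == "C"
  data.frame(
    pos = c(p[plus], p[minus]),
    strand = rep(c("+", "-"), c(sum(plus), sum(minus))),
    gg = c(s[p + 1L][plus] == "G", s[p - 1L][minus] == "C"),
    ga = c(s[p + 1L][plus] == "A", s[p - 1L][minus] == "T"),
    stringsAsFactors = FALSE)
}

# forward-strand (ref, alt) for a pyrimidine-strand APOBEC substitution
.apobec_record <- function(strand, to) {
  if (strand == "+") c("C", to) else c("G", if (to == "T") "A" else "C")
}

# forward-strand (ref, alt) for a guanine-strand substitution
.nqo_record <- function(strand, to) {
  if (strand == "+") c("G", to) else c("C", if (to == "T") "A" else "G")
}

.read_support <- function(n, vaf, cfg) {
  depth <- pmax(12L, stats::rpois(n, cfg$depth_mean))
  alt <- pmax(3L, stats::rbinom(n, depth, vaf))
  alt <- pmin(alt, depth)
  list(depth = depth, alt = alt, callers = sample(2:4, n, replace = TRUE))
}

#' Plant didyma pairs inside NER-sized single-strand tracts
#'
#' For each pair: a strand and a tract location are chosen (genic placement
#' weighted by gene expression when models are supplied), the tract length
#' is drawn uniformly from the configured range, and two TCW cytosines of
#' that strand inside the tract are mutated (C>T or C>G, each with
#' probability one half). Both members share one clone VAF up to small
#' noise. Tracts lacking two usable TCW sites are resampled.
#'
#' @param genome \code{DNAStringSet}.
#' @param models Gene models or NULL.
#' @param cfg A [synthetic_config()].
#' @return List: \code{catalog} (data.frame of records), \code{truth}
#'   (class, pair_id, planted imd, strand, region per record).
#' @export
plant_didyma_ner <- function(genome, models, cfg) {
  set.seed(.stage_seed(cfg, 3L))
  if (cfg$n_didyma_pairs == 0) return(list(catalog = NULL, truth = NULL))
  lens <- genome_lengths(genome)
  # sorted TCW positions per chromosome and strand, for fast window slicing
  sites <- lapply(stats::setNames(names(lens), names(lens)), function(ch) {
    s <- .tcw_sites(genome, ch)
    list(`+` = sort(s$pos[s$strand == "+"]), `-` = sort(s$pos[s$strand == "-"]))
  })
  # placement weights: intergenic bp at weight 1, each gene at
  # bp * (1 + expression) when expression weighting is on
  recs <- list()
  truth <- list()
  tract_spans <- list()
  k <- cfg$mutations_per_tract
  pair_id <- 0L
  retries_left <- 200L * cfg$n_didyma_pairs
  while (pair_id < cfg$n_didyma_pairs) {
    retries_left <- retries_left - 1L
    if (retries_left < 0) stop("could not place didyma tracts (too few TCW sites?)")
    ch <- sample(names(lens), 1, prob = lens)
    tl <- sample(cfg$ner_tract_range[1]:cfg$ner_tract_range[2], 1)
    if (!is.null(models) && cfg$expression_weighting) {
      m <- models[models$chrom == ch, , drop = FALSE]
      gbp <- sum(m$end - m$start + 1)
      w_gene <- (m$end - m$start + 1) * (1 + m$expression)
      w_inter <- lens[[ch]] - gbp
      pick <- sample.int(nrow(m) + 1L, 1, prob = c(w_gene, w_inter))
      if (pick <= nrow(m)) {
        lo <- m$start[pick]; hi <- max(lo, m$end[pick] - tl)
      } else {
        lo <- 2L; hi <- lens[[ch]] - tl - 1L
      }
    } else {
      lo <- 2L; hi <- lens[[ch]] - tl - 1L
    }
    if (hi <= lo) next
    st <- lo + sample.int(hi - lo, 1)
    en <- st + tl - 1L
    # keep tracts well separated so truth pairs stay isolated
    prev <- tract_spans[[ch]]
    if (!is.null(prev)) {
      mm <- matrix(prev, ncol = 2, byrow = TRUE)
      if (any(st <= mm[, 2] + cfg$min_tract_separation &
              en >= mm[, 1] - cfg$min_tract_separation)) next
    }
    strand <- sample(c("+", "-"), 1)
    sp <- sites[[ch]][[strand]]
    s_lo <- findInterval(st - 1L, sp) + 1L
    s_hi <- findInterval(en, sp)
    cand <- if (s_hi >= s_lo) sp[s_lo:s_hi] else integer(0)
    if (length(cand) < k) next
    mut_pos <- sort(cand[sample.int(length(cand), k)])
    pair_id <- pair_id + 1L
    tract_spans[[ch]] <- c(tract_spans[[ch]], st, en)
    clone_vaf <- .rtrunc_norm(1, cfg$vaf_mean, cfg$vaf_sd,
                              cfg$vaf_range[1], cfg$vaf_range[2])
    repeat {
      vafs <- pmin(0.95, pmax(0.06, clone_vaf + stats::rnorm(k, 0, cfg$pair_vaf_sd)))
      if (max(vafs) - min(vafs) <= 0.08) break
    }
    alleles <- vapply(seq_len(k), function(i) {
      .apobec_record(strand, sample(c("T", "G"), 1))
    }, character(2))
    rs <- .read_support(k, vafs, cfg)
    recs[[pair_id]] <- data.frame(
      chrom = ch, pos = mut_pos, ref = alleles[1, ], alt = alleles[2, ],
      vaf = vafs, alt_reads = rs$alt, depth = rs$depth, callers = rs$callers,
      sample = cfg$sample, stringsAsFactors = FALSE)
    truth[[pair_id]] <- data.frame(
      chrom = ch, pos = mut_pos,
      class = if (k == 2) "didyma_member" else "tract_member",
      pair_id = pair_id, planted_imd = max(mut_pos) - min(mut_pos),
      strand = strand, stringsAsFactors = FALSE)
  }
  list(catalog = do.call(rbind, recs), truth = do.call(rbind, truth))
}

#' Plant dispersed background mutations
#'
#' APOBEC class: uniform over TCW cytosines of both strands, C>T or C>G.
#' Carcinogen class: over guanine sites with GG-context weighting, G>T in
#' the configured majority and otherwise G>C, never G>C in a GA context.
#' Placements avoid previously used positions and an exclusion zone around
#' planted tracts.
#'
#' @param genome \code{DNAStringSet}.
#' @param cfg A [synthetic_config()].
#' @param class "apobec" or "nqo".
#' @param avoid Integer positions (per chromosome list) to stay
#'   \code{background_exclusion} nt away from.
#' @param used Positions already mutated (per chromosome list).
#' @return List: \code{catalog}, \code{truth}.
#' @export
plant_dispersed <- function(genome, cfg, class = c("apobec", "nqo"),
                            avoid = list(), used = list()) {
  class <- match.arg(class)
  set.seed(.stage_seed(cfg, if (class == "apobec") 4L else 5L))
  n_want <- if (class == "apobec") cfg$n_dispersed_apobec else cfg$n_dispersed_nqo
  if (n_want == 0) return(list(catalog = NULL, truth = NULL))
  lens <- genome_lengths(genome)
  all_sites <- do.call(rbind, lapply(names(lens), function(ch) {
    s <- if (class == "apobec") .tcw_sites(genome, ch) else .guanine_sites(genome, ch)
    if (nrow(s)) s$chrom <- ch
    s
  }))
  ok <- rep(TRUE, nrow(all_sites))
  for (ch in names(avoid)) {
    av <- sort(avoid[[ch]])
    if (!length(av)) next
    rows <- which(all_sites$chrom == ch)
    p <- all_sites$pos[rows]
    near <- (findInterval(p + cfg$background_exclusion, av) -
               findInterval(p - cfg$background_exclusion - 1, av)) > 0
    ok[rows[near]] <- FALSE
  }
  for (ch in names(used)) {
    rows <- which(all_sites$chrom == ch)
    ok[rows][all_sites$pos[rows] %in% used[[ch]]] <- FALSE
  }
  sites <- all_sites[ok, , drop = FALSE]
  if (nrow(sites) < n_want) stop("not enough ", class, " sites for dispersed background")
  w <- if (class == "nqo") ifelse(sites$gg, cfg$nqo_gg_bias, 1) else rep(1, nrow(sites))
  pick <- sample.int(nrow(sites), n_want, prob = w)
  sites <- sites[pick, , drop = FALSE]
  n <- nrow(sites)
  if (class == "apobec") {
    to <- ifelse(stats::runif(n) < cfg$apobec_ct_fraction, "T", "G")
  } else {
    to <- ifelse(stats::runif(n) < cfg$nqo_gt_fraction, "T", "C")
    to[to == "C" & sites$ga] <- "T"  # honour the GA-context exclusion
  }
  alleles <- vapply(seq_len(n), function(i) {
    if (class == "apobec") .apobec_record(sites$strand[i], to[i])
    else .nqo_record(sites$strand[i], to[i])
  }, character(2))
  vafs <- .rtrunc_norm(n, cfg$vaf_mean, cfg$vaf_sd, cfg$vaf_range[1], cfg$vaf_range[2])
  rs <- .read_support(n, vafs, cfg)
  list(
    catalog = data.frame(chrom = sites$chrom, pos = sites$pos,
                         ref = alleles[1, ], alt = alleles[2, ], vaf = vafs,
                         alt_reads = rs$alt, depth = rs$depth,
                         callers = rs$callers, sample = cfg$sample,
                         stringsAsFactors = FALSE),
    truth = data.frame(chrom = sites$chrom, pos = sites$pos,
                       class = paste0("dispersed_", class), pair_id = NA_integer_,
                       planted_imd = NA_integer_, strand = sites$strand,
                       stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset
#'
#' Runs genome, gene-model, didyma and dispersed-background generation and
#' assembles a catalog plus truth table. Dispersed mutations colliding with
#' or adjacent to planted tracts are excluded by construction.
#'
#' @param cfg A [synthetic_config()].
#' @param with_genes Generate gene models and expression (default TRUE).
#' @return List of class \code{synthetic_dataset}: genome, models, catalog
#'   ([mutation_catalog()]), truth (one row per record, aligned by
#'   (chrom, pos)), config.
#' @export
synth_dataset <- function(cfg = synthetic_config(), with_genes = TRUE) {
  genome <- make_genome(cfg)
  models <- if (with_genes && cfg$n_genes > 0) make_gene_models(genome, cfg) else NULL
  planted <- plant_didyma_ner(genome, models, cfg)
  avoid <- if (!is.null(planted$catalog)) {
    split(planted$catalog$pos, planted$catalog$chrom)
  } else list()
  apo <- plant_dispersed(genome, cfg, "apobec", avoid = avoid, used = avoid)
  used2 <- c(avoid, if (!is.null(apo$catalog)) split(apo$catalog$pos, apo$catalog$chrom))
  # merge used positions per chromosome
  used2 <- tapply(unlist(used2), rep(names(used2), lengths(used2)), c, simplify = FALSE)
  nqo <- plant_dispersed(genome, cfg, "nqo", avoid = avoid, used = as.list(used2))
  cat_df <- rbind(planted$catalog, apo$catalog, nqo$catalog)
  truth <- rbind(planted$truth, apo$truth, nqo$truth)
  if (is.null(cat_df) || !nrow(cat_df)) stop("empty synthetic dataset")
  truth$sample <- cfg$sample
  ord <- order(truth$sample, truth$chrom, truth$pos)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  catalog <- mutation_catalog(cat_df, genome_build = "synthetic")
  if (!is.null(models)) {
    truth$region <- assign_region(truth, models)$region
  } else {
    truth$region <- "intergenic"
  }
  stopifnot(nrow(catalog) == nrow(truth),
            all(catalog$pos == truth$pos & catalog$chrom == truth$chrom))
  structure(list(genome = genome, models = models, catalog = catalog,
                 truth = truth, config = cfg),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits FASTA, GTF, expression TSV, catalog TSV, a minimal VCF, the truth
#' TSV and a JSON manifest holding the configuration (so the dataset can be
#' regenerated bit-identically from the manifest seed).
#'
#' @param dataset A \code{synthetic_dataset} from [synth_dataset()].
#' @param out_dir Output directory (must be empty or absent unless
#'   \code{force}).
#' @param force Overwrite a non-empty directory.
#' @return Named character vector of the file paths written.
#' @export
emit_dataset <- function(dataset, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output directory not empty: ", out_dir, " (use force = TRUE)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(out_dir, "genome.fa"),
             gtf = file.path(out_dir, "genes.gtf"),
             expression = file.path(out_dir, "expression.tsv"),
             catalog = file.path(out_dir, "catalog.tsv"),
             vcf = file.path(out_dir, "catalog.vcf"),
             truth = file.path(out_dir, "truth.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  Biostrings::writeXStringSet(dataset$genome, paths[["fasta"]])
  if (!is.null(dataset$models)) {
    m <- dataset$models
    gr <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$start, m$end),
                                 strand = m$strand)
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$source <- "didymascan"
    S4Vectors::mcols(gr)$gene_id <- m$gene_id
    rtracklayer::export(gr, paths[["gtf"]], format = "gtf")
    utils::write.table(data.frame(gene_id = m$gene_id, value = m$expression),
                       paths[["expression"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_catalog(dataset$catalog, paths[["catalog"]])
  .write_minimal_vcf(dataset$catalog, paths[["vcf"]])
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  cfg_json <- cfg[setdiff(names(cfg), character(0))]
  class(cfg_json) <- NULL
  # keep contig names through auto_unbox: a named length-1 vector would
  # otherwise serialise as a bare scalar
  cfg_json$chrom_lengths <- as.list(cfg$chrom_lengths)
  jsonlite::write_json(cfg_json, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  paths
}

# minimal single-sample VCF 4.2 with read support in INFO
.write_minimal_vcf <- function(catalog, path) {
  df <- as.data.frame(catalog)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##INFO=<ID=ALTREADS,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
               "##INFO=<ID=CALLERS,Number=1,Type=Integer,Description=\"Supporting callers\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(df)) {
    fmt_num <- function(x, digits = 6) ifelse(is.na(x), ".", formatC(x, format = "fg", digits = digits))
    info <- paste0("VAF=", fmt_num(df$vaf), ";DP=", fmt_num(df$depth, 12),
                   ";ALTREADS=", fmt_num(df$alt_reads, 12),
                   ";CALLERS=", fmt_num(df$callers, 12))
    writeLines(paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS", info,
                     sep = "\t"), con)
  }
  invisible(path)
}
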