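#' Simulation configuration
#'
#' @param iterations Number of simulated catalogs (default 100).
#' @param seed Integer seed; all randomness in the simulation flows from it.
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(iterations = 100, seed = 1L) {
  stopifnot(iterations >= 1)
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "simulation_config")
}

BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

# Per-chromosome candidate-position index: positions grouped by
# (forward trinucleotide code, genic flag). Returns list keyed
# "<code>.<region>" -> integer positions.
.position_index <- function(genome, chrom, genic_mask = NULL) {
  s <- .genome_string(genome, chrom)
  L <- nchar(s)
  if (L < 3) return(list())
  v <- BASE_CODE[strsplit(s, "", fixed = TRUE)[[1]]]
  p <- 2:(L - 1L)
  code <- 16L * v[p - 1L] + 4L * v[p] + v[p + 1L]
  ok <- !is.na(code)
  reg <- if (is.null(genic_mask)) rep(0L, length(p)) else as.integer(genic_mask[p])
  key <- paste0(code[ok], ".", reg[ok])
  split(p[ok], key)
}

.trinuc_code <- function(ctx) {
  v1 <- BASE_CODE[substr(ctx, 1, 1)]
  v2 <- BASE_CODE[substr(ctx, 2, 2)]
  v3 <- BASE_CODE[substr(ctx, 3, 3)]
  16L * v1 + 4L * v2 + v3
}

# logical genic mask of length L for one chromosome
.genic_mask <- function(models, chrom, L) {
  mask <- logical(L)
  if (is.null(models)) return(mask)
  m <- models[models$chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(m))) {
    mask[max(1L, m$start[r]):min(L, m$end[r])] <- TRUE
  }
  mask
}

#' Simulate context-preserving background catalogs
#'
#' For each iteration, every mutation is reassigned to a uniformly random
#' position on the same chromosome carrying the same forward-strand
#' trinucleotide (which preserves both the SBS96 channel and the reference
#' strand of the mutated pyrimidine) and the same region class
#' (genic/intergenic, when gene models are supplied). Alleles and VAFs are
#' carried over, so per-chromosome, per-channel, per-strand, per-region
#' counts are conserved exactly. Positions within one stratum and iteration
#' are drawn without replacement when enough candidate sites exist; a
#' stratum with no genic (or intergenic) candidate falls back to the whole
#' chromosome for that trinucleotide, with a logged tally.
#'
#' @param catalog A [mutation_catalog()].
#' @param genome A \code{DNAStringSet}.
#' @param models Optional gene models (see [read_gene_models()]) for the
#'   genic/intergenic constraint.
#' @param cfg A [simulation_config()].
#' @return Object of class \code{simulated_catalog_set}: list with
#'   \code{source} (annotated catalog), \code{positions} (n x iterations
#'   integer matrix), \code{iterations}, \code{relaxed} (tally of region
#'   relaxations), \code{seed}.
#' @export
simulate_catalog <- function(catalog, genome, models = NULL,
                             cfg = simulation_config()) {
  df <- annotate_catalog(catalog, genome)
  n <- nrow(df)
  lens <- genome_lengths(genome)
  ctx <- reference_context(catalog, genome, flank = 1L)
  code <- .trinuc_code(ctx)
  if (anyNA(code)) stop(sum(is.na(code)), " record(s) not classifiable (edge or N context)")
  set.seed(cfg$seed)
  pos_mat <- matrix(NA_integer_, nrow = n, ncol = cfg$iterations)
  relaxed <- 0L
  for (ch in unique(df$chrom)) {
    rows <- which(df$chrom == ch)
    mask <- if (is.null(models)) NULL else .genic_mask(models, ch, lens[[ch]])
    idx <- .position_index(genome, ch, mask)
    reg <- if (is.null(mask)) rep(0L, length(rows)) else as.integer(mask[df$pos[rows]])
    key <- paste0(code[rows], ".", reg)
    for (k in unique(key)) {
      krows <- rows[key == k]
      cand <- idx[[k]]
      if (is.null(cand) || !length(cand)) {
        # relax the region constraint: pool both region classes
        base_code <- sub("\\..*$", "", k)
        cand <- c(idx[[paste0(base_code, ".0")]], idx[[paste0(base_code, ".1")]])
        relaxed <- relaxed + length(krows)
      }
      if (is.null(cand) || !length(cand)) {
        pos_mat[krows, ] <- df$pos[krows]  # degenerate: keep original
        next
      }
      m <- length(krows)
      for (it in seq_len(cfg$iterations)) {
        pos_mat[krows, it] <- if (length(cand) >= m) {
          cand[sample.int(length(cand), m)]
        } else {
          cand[sample.int(length(cand), m, replace = TRUE)]
        }
      }
    }
  }
  structure(list(source = df, positions = pos_mat, iterations = cfg$iterations,
                 relaxed = relaxed, seed = cfg$seed),
            class = "simulated_catalog_set")
}

#' Materialise one simulated catalog
#'
#' @param sims A \code{simulated_catalog_set} from [simulate_catalog()].
#' @param i Iteration index.
#' @return Annotated catalog data.frame sorted by (sample, chrom, pos); the
#'   context-class columns (\code{apobec}, \code{nqo}, strands) are carried
#'   over from the source records, which is exact because the simulation
#'   preserves the forward trinucleotide.
#' @export
sim_catalog <- function(sims, i) {
  stopifnot(i >= 1, i <= sims$iterations)
  df <- sims$source
  df$pos <- sims$positions[, i]
  df[order(df$sample, df$chrom, df$pos), , drop = FALSE]
}

#' Fingerprint of a catalog for conservation checks
#'
#' Counts records per (chromosome, forward trinucleotide, region class).
#' Because the forward trinucleotide fixes the channel and strand, equality
#' of fingerprints implies conservation of all four strata.
#'
#' @param df Catalog data.frame (annotated or not).
#' @param genome A \code{DNAStringSet}.
#' @param models Optional gene models.
#' @return Named integer table.
#' @export
catalog_fingerprint <- function(df, genome, models = NULL) {
  ctx <- reference_context(df, genome, flank = 1L)
  lens <- genome_lengths(genome)
  reg <- rep(0L, nrow(df))
  if (!is.null(models)) {
    for (ch in unique(df$chrom)) {
      rows <- which(df$chrom == ch)
      mask <- .genic_mask(models, ch, lens[[ch]])
      reg[rows] <- as.integer(mask[df$pos[rows]])
    }
  }
  table(paste(df$chrom, ctx, reg, sep = "|"))
}

# cumulative counts of per-mutation IMDs over a grid
.imd_counts <- function(df, grid) {
  imd <- mutation_imd(df)
  imd <- imd[!is.na(imd)]
  gmax <- max(grid)
  tab <- tabulate(pmin(imd, gmax + 1L), nbins = gmax + 1L)
  cumsum(tab)[grid]
}

#' Estimate the sample-dependent IMD threshold
#'
#' Scans a grid of candidate IMD cutoffs. For each cutoff c the observed
#' number of mutations whose nearest-neighbour IMD is at most c is compared
#' with the simulated background: the mean simulated count across
#' iterations defines a Poisson null, and the upper-tail probability
#' P(X >= observed) is BH-adjusted across the grid. The
#' returned threshold is the largest c whose adjusted probability is below
#' \code{q_max} and for which chance accounts for at most
#' \code{1 - capture_fraction} of the observed sub-threshold mutations
#' (i.e. at least 90 percent of mutations below the cutoff are in excess of
#' the simulated background). Returns NA when no cutoff qualifies.
#'
#' @param catalog A [mutation_catalog()].
#' @param sims A \code{simulated_catalog_set}.
#' @param cfg A [cluster_detection_config()].
#' @return List with \code{threshold} (integer nt or NA), and the per-grid
#'   vectors \code{observed}, \code{expected}, \code{qvalue}.
#' @export
estimate_sample_imd_threshold <- function(catalog, sims,
                                          cfg = cluster_detection_config()) {
  df <- as.data.frame(catalog)
  grid <- cfg$imd_grid
  if (nrow(df) < 2) {
    warning("fewer than 2 mutations; no IMD threshold")
    return(list(threshold = NA_integer_, observed = NULL, expected = NULL,
                qvalue = NULL))
  }
  if (sims$iterations < 2) stop("need >= 2 simulation iterations")
  obs <- .imd_counts(df, grid)
  sim_counts <- matrix(0, nrow = sims$iterations, ncol = length(grid))
  for (it in seq_len(sims$iterations)) {
    sim_counts[it, ] <- .imd_counts(sim_catalog(sims, it), grid)
  }
  expected <- colMeans(sim_counts)
  p <- stats::ppois(obs - 1, lambda = expected, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  capture_ok <- obs > 0 & (expected / pmax(obs, 1)) <= (1 - cfg$capture_fraction)
  ok <- q < cfg$q_max & capture_ok
  threshold <- if (any(ok)) grid[max(which(ok))] else NA_integer_
  list(threshold = threshold, observed = obs, expected = expected, qvalue = q)
}

#' Regional IMD correction over sliding megabase windows
#'
#' Corrects the global IMD threshold for regional mutation density: each
#' mutation is evaluated in the 1 Mb window (by default) centred nearest to
#' it, on a grid of centres advancing in half-window steps. Where the
#' window's observed mutation count exceeds the simulated mean, the local
#' cutoff is the global threshold divided by that ratio — a region whose
#' density is explainable by regional effects alone must show
#' correspondingly shorter IMDs to count as clustered. Ratios below 1 never
#' loosen the cutoff.
#'
#' @param catalog A [mutation_catalog()].
#' @param sims A \code{simulated_catalog_set}.
#' @param threshold Global IMD threshold (from
#'   [estimate_sample_imd_threshold()] or an explicit override).
#' @param cfg A [cluster_detection_config()].
#' @return data.frame per mutation: \code{clustered} (nearest-neighbour IMD
#'   at or below the local cutoff), \code{cutoff}, \code{window_ratio}.
#' @export
regional_imd_correction <- function(catalog, sims, threshold,
                                    cfg = cluster_detection_config()) {
  df <- as.data.frame(catalog)
  n <- nrow(df)
  if (is.na(threshold)) {
    return(data.frame(clustered = rep(FALSE, n), cutoff = rep(NA_real_, n),
                      window_ratio = rep(NA_real_, n)))
  }
  step <- cfg$window / 2
  half <- cfg$window / 2
  ratio <- rep(1, n)
  src <- sims$source
  for (sm in unique(df$sample)) {
    for (ch in unique(df$chrom[df$sample == sm])) {
      rows <- which(df$sample == sm & df$chrom == ch)
      obs_pos <- sort(df$pos[rows])
      srows <- which(src$sample == sm & src$chrom == ch)
      sim_pos <- sort(as.vector(sims$positions[srows, , drop = FALSE]))
      centers <- pmax(half, round(df$pos[rows] / step) * step)
      lo <- centers - half
      hi <- centers + half
      n_obs <- findInterval(hi, obs_pos) - findInterval(lo - 1, obs_pos)
      n_sim <- (findInterval(hi, sim_pos) - findInterval(lo - 1, sim_pos)) / sims$iterations
      r <- ifelse(n_sim > 0, n_obs / n_sim, Inf)
      ratio[rows] <- r
    }
  }
  cutoff <- threshold / pmax(1, ratio)
  imd <- mutation_imd(mutation_catalog(df))
  clustered <- !is.na(imd) & imd <= cutoff
  data.frame(clustered = clustered, cutoff = cutoff, window_ratio = ratio)
}
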