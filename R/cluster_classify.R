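#' Cluster detection configuration
#'
#' Thresholds for clustered-mutation detection: the capture fraction and
#' q-value bound used to derive the sample-dependent IMD threshold, the
#' sliding-window size of the regional density correction, the maximum VAF
#' difference allowed between successive members of one event, and the
#' fixed didyma window.
#'
#' @param capture_fraction Fraction of sub-threshold mutations that must be
#'   in excess of chance (default 0.90).
#' @param q_max BH-adjusted empirical p-value bound (default 0.01).
#' @param window Regional correction window in nt (default 1e6).
#' @param vaf_max_diff Maximum VAF difference within an event (default 0.1).
#' @param didyma_imd_max Fixed didyma IMD window in nt (default 32).
#' @param imd_grid Candidate IMD cutoffs scanned when estimating the
#'   sample-dependent threshold; default is a graded grid from 1 nt to
#'   10 kb (1 nt steps to 100, 10 nt steps to 1 kb, 100 nt steps beyond).
#' @return List of class \code{cluster_detection_config}.
#' @export
cluster_detection_config <- function(capture_fraction = 0.90, q_max = 0.01,
                                     window = 1e6, vaf_max_diff = 0.1,
                                     didyma_imd_max = 32,
                                     imd_grid = c(1:100, seq(110L, 1000L, 10L),
                                                  seq(1100L, 10000L, 100L))) {
  stopifnot(capture_fraction > 0, capture_fraction < 1,
            q_max > 0, q_max < 1, window > 0, vaf_max_diff >= 0,
            didyma_imd_max >= 1)
  structure(list(capture_fraction = capture_fraction, q_max = q_max,
                 window = window, vaf_max_diff = vaf_max_diff,
                 didyma_imd_max = didyma_imd_max, imd_grid = as.integer(imd_grid)),
            class = "cluster_detection_config")
}

#' Annotate a catalog with context classes and strands
#'
#' Convenience wrapper adding columns \code{apobec}, \code{nqo},
#' \code{pyr_strand}, \code{gua_strand} to a catalog.
#'
#' @param catalog A [mutation_catalog()].
#' @param genome A \code{DNAStringSet}.
#' @return The catalog data.frame with four extra columns.
#' @export
annotate_catalog <- function(catalog, genome) {
  df <- as.data.frame(catalog)
  df$apobec <- is_apobec_context(catalog, genome)
  df$nqo <- is_nqo_context(catalog, genome)
  df$pyr_strand <- pyrimidine_strand(catalog$ref)
  df$gua_strand <- guanine_strand(catalog$ref)
  df
}

#' Intermutation distances between consecutive mutations
#'
#' The IMD between two mutations is the difference of their positions, i.e.
#' the number of nucleotide steps separating them: both cytosines of a TCC
#' motif are 1 IMD apart, the two cytosines of TCTC are 2 IMD apart. No IMD
#' is emitted across sample or chromosome boundaries.
#'
#' @param catalog A sorted [mutation_catalog()].
#' @return data.frame with columns sample, chrom, pos1, pos2, imd — one row
#'   per consecutive same-sample, same-chromosome pair.
#' @export
compute_imds <- function(catalog) {
  df <- as.data.frame(catalog)
  if (nrow(df) < 2) {
    return(data.frame(sample = character(0), chrom = character(0),
                      pos1 = integer(0), pos2 = integer(0), imd = integer(0)))
  }
  same <- df$sample[-1] == df$sample[-nrow(df)] & df$chrom[-1] == df$chrom[-nrow(df)]
  i <- which(same)
  data.frame(sample = df$sample[i], chrom = df$chrom[i],
             pos1 = df$pos[i], pos2 = df$pos[i + 1L],
             imd = df$pos[i + 1L] - df$pos[i])
}

#' Per-mutation IMD (distance to the nearest neighbour)
#'
#' @param catalog A sorted [mutation_catalog()].
#' @return Integer vector: for each record, the distance to its closest
#'   same-sample, same-chromosome neighbour (NA for singletons).
#' @export
mutation_imd <- function(catalog) {
  df <- as.data.frame(catalog)
  n <- nrow(df)
  if (!n) return(integer(0))
  same_prev <- c(FALSE, df$sample[-1] == df$sample[-n] & df$chrom[-1] == df$chrom[-n])
  gap_prev <- c(NA_integer_, df$pos[-1] - df$pos[-n])
  gap_prev[!same_prev] <- NA_integer_
  gap_next <- c(gap_prev[-1], NA_integer_)
  pmin(gap_prev, gap_next, na.rm = TRUE)
}

# All index pairs (i < j) of a sorted position vector with pos[j] - pos[i]
# <= max_d. Returns data.frame(i, j, d).
.pairs_within <- function(pos, max_d) {
  n <- length(pos)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0), d = integer(0)))
  hi <- findInterval(pos + max_d, pos)
  cnt <- hi - seq_len(n)
  cnt[cnt < 0] <- 0L
  i <- rep.int(seq_len(n), cnt)
  j <- sequence(cnt, from = seq_len(n) + 1L)
  data.frame(i = i, j = j, d = pos[j] - pos[i])
}

# Apply a function per (sample, chrom) group of an annotated catalog,
# returning row-bound results carrying global row indices.
.by_sample_chrom <- function(df, fn) {
  grp <- paste(df$sample, df$chrom, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), grp), function(idx) fn(df[idx, , drop = FALSE], idx))
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Detect clustered mutation events
#'
#' Groups consecutive mutations into candidate events: maximal runs where
#' every successive IMD is at or below the (per-mutation) threshold and
#' every member carries a clustered flag. Runs are split wherever two
#' successive members differ in VAF by more than \code{vaf_max_diff}
#' (missing VAFs never split). Events of size >= 2 are returned, classified
#' by [classify_event()].
#'
#' @param catalog A [mutation_catalog()].
#' @param genome A \code{DNAStringSet}.
#' @param threshold IMD threshold in nt (scalar), or a per-mutation numeric
#'   vector of effective cutoffs (e.g. from [regional_imd_correction()]).
#' @param cfg A [cluster_detection_config()].
#' @param flags Optional logical per-mutation clustered flags (default all
#'   TRUE).
#' @return data.frame of events: sample, chrom, start, end, size, imds
#'   (comma string), strand_coordinated, all_apobec, label, didyma_flag,
#'   max_vaf_diff, mean_vaf, plus a list column \code{members} of catalog
#'   row indices.
#' @export
detect_clusters <- function(catalog, genome, threshold, cfg = cluster_detection_config(),
                            flags = NULL) {
  df <- annotate_catalog(catalog, genome)
  n <- nrow(df)
  empty <- data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), size = integer(0),
                      imds = character(0), strand_coordinated = logical(0),
                      all_apobec = logical(0), label = character(0),
                      didyma_flag = logical(0), max_vaf_diff = numeric(0),
                      mean_vaf = numeric(0))
  if (!n) return(empty)
  if (is.null(flags)) flags <- rep(TRUE, n)
  thr <- if (length(threshold) == 1L) rep(as.numeric(threshold), n) else as.numeric(threshold)
  stopifnot(length(thr) == n, length(flags) == n)
  events <- .by_sample_chrom(df, function(g, idx) {
    m <- nrow(g)
    if (m < 2) return(NULL)
    gap <- diff(g$pos)
    gthr <- pmin(thr[idx][-m], thr[idx][-1])
    vdiff <- abs(diff(g$vaf))
    link <- gap <= gthr & flags[idx][-m] & flags[idx][-1] &
      (is.na(vdiff) | vdiff <= cfg$vaf_max_diff)
    if (!any(link)) return(NULL)
    runs <- rle(link)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    do.call(rbind, lapply(keep, function(k) {
      lo <- starts[k]
      hi <- ends[k] + 1L
      mem <- idx[lo:hi]
      data.frame(first = mem[1], last = mem[length(mem)])
    }))
  })
  if (is.null(events)) return(empty)
  out <- do.call(rbind, lapply(seq_len(nrow(events)), function(r) {
    mem <- events$first[r]:events$last[r]
    g <- df[mem, , drop = FALSE]
    imds <- diff(g$pos)
    cls <- classify_event(size = nrow(g), imds = imds,
                          strand_coordinated = length(unique(g$pyr_strand)) == 1L,
                          all_apobec = all(g$apobec %in% TRUE),
                          didyma_imd_max = cfg$didyma_imd_max)
    vd <- abs(diff(g$vaf))
    res <- data.frame(sample = g$sample[1], chrom = g$chrom[1],
                      start = g$pos[1], end = g$pos[nrow(g)], size = nrow(g),
                      imds = paste(imds, collapse = ","),
                      strand_coordinated = length(unique(g$pyr_strand)) == 1L,
                      all_apobec = all(g$apobec %in% TRUE),
                      label = cls$label, didyma_flag = cls$didyma_flag,
                      max_vaf_diff = if (all(is.na(vd))) NA_real_ else max(vd, na.rm = TRUE),
                      mean_vaf = mean(g$vaf))
    res$members <- I(list(mem))
    res
  }))
  rownames(out) <- NULL
  out
}

#' Classify a clustered event into the APOBEC cluster taxonomy
#'
#' Events that are strand-coordinated and consist entirely of
#' APOBEC-context mutations are labelled: \emph{omikli} for 2–3 mutations
#' with at least one IMD greater than 1; \emph{kataegis} for 4 or more
#' mutations with at least one IMD greater than 1. A two-mutation event
#' whose single IMD is at most \code{didyma_imd_max} additionally carries
#' the didyma mark; a pair at IMD exactly 1 fails the omikli clause and is
#' labelled \emph{didyma} outright. Everything else is \emph{other}.
#'
#' @param size Number of mutations in the event.
#' @param imds Integer vector of successive IMDs (length size - 1).
#' @param strand_coordinated Do all members share the pyrimidine strand?
#' @param all_apobec Are all members APOBEC-context?
#' @param didyma_imd_max Fixed didyma window (default 32 nt).
#' @return List with \code{label} in \{didyma, omikli, kataegis, other\} and
#'   logical \code{didyma_flag}.
#' @export
classify_event <- function(size, imds, strand_coordinated, all_apobec,
                           didyma_imd_max = 32) {
  stopifnot(length(imds) == size - 1)
  apo <- isTRUE(strand_coordinated) && isTRUE(all_apobec)
  didyma_flag <- apo && size == 2L && imds[1] <= didyma_imd_max
  label <- "other"
  if (apo) {
    if (size >= 2L && size <= 3L && any(imds > 1)) label <- "omikli"
    else if (size >= 4L && any(imds > 1)) label <- "kataegis"
    else if (didyma_flag) label <- "didyma"  # pair at IMD 1
  }
  list(label = label, didyma_flag = didyma_flag)
}

# Union-find for resolving runs of mutually clustered pairs.
.components <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(edges_i)) {
    a <- find(edges_i[k]); b <- find(edges_j[k])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), find, integer(1))
}

#' Extract didyma pairs
#'
#' Scans all same-sample, same-chromosome pairs of APOBEC-context mutations
#' whose positions differ by at most \code{didyma_imd_max}, requiring a
#' shared pyrimidine strand and a VAF difference of at most
#' \code{vaf_max_diff} (missing VAFs pass). Qualifying pairs that chain into
#' a run of three or more mutations are not decomposed into didyma — such
#' runs belong to the omikli/kataegis taxonomy — so only isolated pairs are
#' emitted.
#'
#' @param catalog A [mutation_catalog()].
#' @param genome A \code{DNAStringSet}.
#' @param cfg A [cluster_detection_config()].
#' @param flags Optional logical vector restricting the scan to
#'   clustered-flagged mutations.
#' @param decompose_runs If TRUE, emit every qualifying pair even inside
#'   larger runs (used by brute-force comparisons).
#' @return data.frame with one row per didymos: sample, chrom, pos1, pos2,
#'   imd, strand, vaf1, vaf2, i1, i2 (catalog row indices).
#' @export
extract_didyma <- function(catalog, genome, cfg = cluster_detection_config(),
                           flags = NULL, decompose_runs = FALSE) {
  df <- annotate_catalog(catalog, genome)
  keep <- df$apobec %in% TRUE
  if (!is.null(flags)) keep <- keep & flags
  empty <- data.frame(sample = character(0), chrom = character(0),
                      pos1 = integer(0), pos2 = integer(0), imd = integer(0),
                      strand = character(0), vaf1 = numeric(0), vaf2 = numeric(0),
                      i1 = integer(0), i2 = integer(0))
  if (sum(keep) < 2) return(empty)
  sub <- df[keep, , drop = FALSE]
  sub$.row <- which(keep)
  pairs <- .by_sample_chrom(sub, function(g, idx) {
    p <- .pairs_within(g$pos, cfg$didyma_imd_max)
    if (!nrow(p)) return(NULL)
    same_strand <- g$pyr_strand[p$i] == g$pyr_strand[p$j]
    vd <- abs(g$vaf[p$i] - g$vaf[p$j])
    ok <- same_strand & (is.na(vd) | vd <= cfg$vaf_max_diff)
    p <- p[ok, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    if (!decompose_runs) {
      comp <- .components(nrow(g), p$i, p$j)
      deg <- table(comp[c(p$i, p$j)])
      # a lone pair contributes its component label exactly twice
      lone <- names(deg)[deg == 2]
      p <- p[as.character(comp[p$i]) %in% lone, , drop = FALSE]
      if (!nrow(p)) return(NULL)
    }
    data.frame(sample = g$sample[p$i], chrom = g$chrom[p$i],
               pos1 = g$pos[p$i], pos2 = g$pos[p$j], imd = p$d,
               strand = g$pyr_strand[p$i],
               vaf1 = g$vaf[p$i], vaf2 = g$vaf[p$j],
               i1 = g$.row[p$i], i2 = g$.row[p$j])
  })
  if (is.null(pairs)) return(empty)
  rownames(pairs) <- NULL
  pairs
}

#' Extract carcinogen-adduct (NQO) mutation pairs
#'
#' Pairs of NQO-context mutations (G>T, and G>C outside a GA context) within
#' \code{max_imd} of each other, split by whether the two reference guanines
#' lie on the same or on opposite strands.
#'
#' @param catalog A [mutation_catalog()].
#' @param genome A \code{DNAStringSet}.
#' @param max_imd Maximum pair distance in nt (default 32).
#' @param strand_mode "same" or "opposite".
#' @param vaf_max_diff Optional VAF-difference bound (default NULL = none).
#' @return data.frame with columns sample, chrom, pos1, pos2, imd, strand1,
#'   strand2, i1, i2.
#' @export
extract_nqo_pairs <- function(catalog, genome, max_imd = 32,
                              strand_mode = c("same", "opposite"),
                              vaf_max_diff = NULL) {
  strand_mode <- match.arg(strand_mode)
  df <- annotate_catalog(catalog, genome)
  keep <- df$nqo %in% TRUE
  empty <- data.frame(sample = character(0), chrom = character(0),
                      pos1 = integer(0), pos2 = integer(0), imd = integer(0),
                      strand1 = character(0), strand2 = character(0),
                      i1 = integer(0), i2 = integer(0))
  if (sum(keep) < 2) return(empty)
  sub <- df[keep, , drop = FALSE]
  sub$.row <- which(keep)
  pairs <- .by_sample_chrom(sub, function(g, idx) {
    p <- .pairs_within(g$pos, max_imd)
    if (!nrow(p)) return(NULL)
    same <- g$gua_strand[p$i] == g$gua_strand[p$j]
    ok <- if (strand_mode == "same") same else !same
    if (!is.null(vaf_max_diff)) {
      vd <- abs(g$vaf[p$i] - g$vaf[p$j])
      ok <- ok & (is.na(vd) | vd <= vaf_max_diff)
    }
    p <- p[ok, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    data.frame(sample = g$sample[p$i], chrom = g$chrom[p$i],
               pos1 = g$pos[p$i], pos2 = g$pos[p$j], imd = p$d,
               strand1 = g$gua_strand[p$i], strand2 = g$gua_strand[p$j],
               i1 = g$.row[p$i], i2 = g$.row[p$j])
  })
  if (is.null(pairs)) return(empty)
  rownames(pairs) <- NULL
  pairs
}
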