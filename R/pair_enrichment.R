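PAIR_CLASSES <- c("apobec_same_strand", "apobec_opposite_strand",
                  "nqo_same_strand", "nqo_opposite_strand")

#' Count mutation pairs at each exact intermutation distance
#'
#' Counts all qualifying pairs (any two mutations of the class in the same
#' sample and chromosome, not just consecutive ones) at each exact IMD from
#' 1 to \code{max_imd}. APOBEC classes pair TCW-context mutations by their
#' pyrimidine strand; NQO classes pair adduct-context mutations by their
#' guanine strand.
#'
#' @param catalog A [mutation_catalog()] or an already [annotate_catalog()]ed
#'   data.frame (e.g. a simulated catalog).
#' @param genome A \code{DNAStringSet}; may be NULL when \code{catalog} is
#'   pre-annotated.
#' @param pair_class One of \code{"apobec_same_strand"},
#'   \code{"apobec_opposite_strand"}, \code{"nqo_same_strand"},
#'   \code{"nqo_opposite_strand"}.
#' @param max_imd Largest IMD counted (default 100 nt).
#' @return Integer vector of length \code{max_imd}, element d holding the
#'   number of pairs at IMD exactly d.
#' @export
pair_counts_by_imd <- function(catalog, genome = NULL,
                               pair_class = "apobec_same_strand",
                               max_imd = 100) {
  pair_class <- match.arg(pair_class, PAIR_CLASSES)
  df <- if ("apobec" %in% names(catalog)) as.data.frame(catalog)
        else annotate_catalog(catalog, genome)
  is_apo <- grepl("^apobec", pair_class)
  same <- grepl("same", pair_class)
  keep <- if (is_apo) df$apobec %in% TRUE else df$nqo %in% TRUE
  counts <- integer(max_imd)
  if (sum(keep) < 2) return(counts)
  sub <- df[keep, , drop = FALSE]
  strand_col <- if (is_apo) "pyr_strand" else "gua_strand"
  res <- .by_sample_chrom(sub, function(g, idx) {
    p <- .pairs_within(g$pos, max_imd)
    if (!nrow(p)) return(NULL)
    eq <- g[[strand_col]][p$i] == g[[strand_col]][p$j]
    p <- p[if (same) eq else !eq, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    data.frame(d = p$d)
  })
  if (is.null(res)) return(counts)
  d <- res$d[res$d >= 1 & res$d <= max_imd]
  counts + tabulate(d, nbins = max_imd)
}

#' Enrichment of observed pair counts over simulated backgrounds
#'
#' The simulated mean at each IMD is the arithmetic mean of the pair counts
#' across iterations; enrichment is observed divided by that mean, and is
#' left undefined (NA) where the simulated mean is zero.
#'
#' @param observed Integer count vector from [pair_counts_by_imd()], or a
#'   catalog (counted with the same class/axis; supply \code{genome} unless
#'   it is pre-annotated).
#' @param sims A \code{simulated_catalog_set} from [simulate_catalog()].
#' @param pair_class See [pair_counts_by_imd()].
#' @param max_imd IMD axis length (default 100).
#' @param genome Optional \code{DNAStringSet}, used when \code{observed} is
#'   an unannotated catalog.
#' @return data.frame of class \code{enrichment_profile}: imd, observed,
#'   simulated_mean, enrichment; attribute \code{pair_class}.
#' @export
enrichment_vs_simulation <- function(observed, sims,
                                     pair_class = "apobec_same_strand",
                                     max_imd = 100, genome = NULL) {
  if (is.data.frame(observed)) {
    observed <- pair_counts_by_imd(observed, genome = genome,
                                   pair_class = pair_class,
                                   max_imd = max_imd)
  }
  stopifnot(length(observed) == max_imd, sims$iterations >= 1)
  sim_counts <- matrix(0, nrow = sims$iterations, ncol = max_imd)
  for (it in seq_len(sims$iterations)) {
    sim_counts[it, ] <- pair_counts_by_imd(sim_catalog(sims, it),
                                           pair_class = pair_class,
                                           max_imd = max_imd)
  }
  sim_mean <- colMeans(sim_counts)
  enr <- ifelse(sim_mean > 0, observed / sim_mean, NA_real_)
  structure(data.frame(imd = seq_len(max_imd), observed = as.numeric(observed),
                       simulated_mean = sim_mean, enrichment = enr),
            pair_class = pair_class, class = c("enrichment_profile", "data.frame"))
}

#' Average enrichment profiles across samples
#'
#' Per-IMD arithmetic mean of the per-sample enrichment values, skipping
#' undefined entries; the number of samples contributing to each IMD is
#' recorded.
#'
#' @param profiles List of \code{enrichment_profile} objects sharing the
#'   same IMD axis and pair class.
#' @return data.frame: imd, enrichment (mean), n (profiles contributing).
#' @export
cohort_average <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  classes <- vapply(profiles, function(p) attr(p, "pair_class") %||% NA_character_, "")
  if (length(unique(classes)) != 1) stop("profiles mix pair classes")
  axes <- vapply(profiles, nrow, 0L)
  if (length(unique(axes)) != 1) stop("profiles have different IMD axes")
  enr <- sapply(profiles, function(p) p$enrichment)
  if (is.null(dim(enr))) enr <- matrix(enr, ncol = length(profiles))
  structure(data.frame(imd = profiles[[1]]$imd,
                       enrichment = rowMeans(enr, na.rm = TRUE),
                       n = rowSums(!is.na(enr))),
            pair_class = classes[1],
            class = c("enrichment_profile", "data.frame"))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control (delegates to
#' \code{stats::p.adjust}) with input validation.
#'
#' @param pvalues Numeric vector of p-values in [0,1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0,1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
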