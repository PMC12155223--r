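#' Genic / intergenic territory sizes in megabases
#'
#' Mouse defaults: genic regions (exons plus introns) cover 1,139 Mb and the
#' remaining intergenic territory 1,584 Mb. Override or compute from
#' supplied gene models with [region_sizes_from_models()].
#'
#' @param genic,intergenic Sizes in Mb.
#' @return Named numeric vector c(genic=, intergenic=).
#' @export
region_sizes <- function(genic = 1139, intergenic = 1584) {
  stopifnot(genic > 0, intergenic > 0)
  c(genic = genic, intergenic = intergenic)
}

#' Compute genic/intergenic territory from gene models
#'
#' Genic territory is the union (merged intervals) of gene spans, so
#' overlapping genes are not double-counted; intergenic is the remainder of
#' the genome.
#'
#' @param models Gene model data.frame (see [read_gene_models()]).
#' @param genome A \code{DNAStringSet}.
#' @return Named numeric vector of sizes in Mb.
#' @export
region_sizes_from_models <- function(models, genome) {
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    models$chrom, IRanges::IRanges(models$start, models$end)))
  genic_bp <- sum(as.numeric(GenomicRanges::width(gr)))
  total_bp <- sum(as.numeric(genome_lengths(genome)))
  region_sizes(genic = genic_bp / 1e6, intergenic = (total_bp - genic_bp) / 1e6)
}

#' Read gene models from GTF/GFF and join expression
#'
#' One model per gene spanning min(feature starts)..max(feature ends)
#' (exons and introns). Expression values are joined by gene_id; genes
#' absent from the expression table are treated as non-expressed (NA).
#'
#' @param path GTF/GFF file path.
#' @param expression Optional: path to a TSV with columns gene_id, value, or
#'   a data.frame/named vector of normalised expression.
#' @return data.frame: gene_id, chrom, start, end, strand, expression.
#' @export
read_gene_models <- function(path, expression = NULL) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else as.character(md$ID)
  keep <- !is.na(gid)
  if ("type" %in% names(md)) {
    ty <- as.character(md$type)
    if (any(ty == "gene")) keep <- keep & ty == "gene"
  }
  if (!any(keep)) stop("no gene features with gene_id in ", path)
  gr <- gr[keep]
  gid <- gid[keep]
  df <- data.frame(gene_id = gid,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  # collapse multi-row genes to one span
  sp <- split(seq_len(nrow(df)), df$gene_id)
  df <- do.call(rbind, lapply(sp, function(i) {
    data.frame(gene_id = df$gene_id[i[1]], chrom = df$chrom[i[1]],
               start = min(df$start[i]), end = max(df$end[i]),
               strand = df$strand[i[1]], stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df$expression <- NA_real_
  if (!is.null(expression)) {
    if (is.character(expression)) {
      expression <- utils::read.table(expression, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
    }
    if (is.data.frame(expression)) {
      ev <- stats::setNames(as.numeric(expression[[2]]), expression[[1]])
    } else {
      ev <- expression
    }
    df$expression <- unname(ev[df$gene_id])
  }
  df[order(df$chrom, df$start), , drop = FALSE]
}

.models_granges <- function(models) {
  GenomicRanges::GRanges(models$chrom,
                         IRanges::IRanges(models$start, models$end),
                         strand = models$strand)
}

#' Assign mutations (or positions) to genic/intergenic space
#'
#' A position is genic iff it falls within any gene span (1-based
#' inclusive, so a position equal to a gene's end coordinate is genic).
#'
#' @param catalog A catalog data.frame (columns chrom, pos) or a didyma
#'   pair table (columns chrom, pos1 — pairs are assigned by their first
#'   member).
#' @param models Gene model data.frame.
#' @return data.frame: region ("genic"/"intergenic") and gene_ids
#'   (comma-joined ids of all overlapping genes, "" if none).
#' @export
assign_region <- function(catalog, models) {
  pos <- if ("pos" %in% names(catalog)) catalog$pos else catalog$pos1
  gr <- GenomicRanges::GRanges(catalog$chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(gr, .models_granges(models), ignore.strand = TRUE)
  n <- length(gr)
  gene_ids <- character(n)
  if (length(hits)) {
    by_q <- split(models$gene_id[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
    gene_ids[as.integer(names(by_q))] <- vapply(by_q, paste, "", collapse = ",")
  }
  data.frame(region = ifelse(gene_ids == "", "intergenic", "genic"),
             gene_ids = gene_ids, stringsAsFactors = FALSE)
}

#' Transcribed vs non-transcribed strand of didyma pairs
#'
#' For a gene transcribed from mRNA-sense strand S, a pair whose shared
#' pyrimidine strand equals S carries its mutated cytosines on the coding
#' (non-transcribed) strand; the opposite orientation places them on the
#' template (transcribed) strand. Pairs outside genes, or overlapping genes
#' annotated on both strands, are NA.
#'
#' @param pairs Didyma pair table from [extract_didyma()] (columns chrom,
#'   pos1, strand).
#' @param models Gene model data.frame.
#' @return Character vector: "transcribed", "non_transcribed", or NA.
#' @export
transcribed_strand <- function(pairs, models) {
  n <- nrow(pairs)
  out <- rep(NA_character_, n)
  if (!n) return(out)
  gr <- GenomicRanges::GRanges(pairs$chrom, IRanges::IRanges(pairs$pos1, pairs$pos1))
  hits <- GenomicRanges::findOverlaps(gr, .models_granges(models), ignore.strand = TRUE)
  if (!length(hits)) return(out)
  strands <- split(models$strand[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits))
  for (q in names(strands)) {
    s <- unique(strands[[q]])
    if (length(s) != 1) next  # ambiguous: opposite-strand overlapping genes
    qi <- as.integer(q)
    out[qi] <- if (pairs$strand[qi] == s) "non_transcribed" else "transcribed"
  }
  out
}

#' Didyma density per megabase of genic and intergenic territory
#'
#' @param pairs Didyma pair table with a \code{region} column (see
#'   [assign_region()]).
#' @param sizes Named sizes in Mb from [region_sizes()].
#' @return Named numeric vector: pairs per Mb for genic and intergenic.
#' @export
didyma_density_by_region <- function(pairs, sizes = region_sizes()) {
  if (any(sizes <= 0)) stop("region sizes must be positive")
  cnt <- c(genic = sum(pairs$region == "genic"),
           intergenic = sum(pairs$region == "intergenic"))
  cnt / sizes[names(cnt)]
}

#' Expression bins: quartiles of positive expression plus a zero bin
#'
#' Genes with zero or missing expression form the \code{non_expressed} bin;
#' the remaining genes are split into quartiles Q1 (lowest) to Q4 (highest)
#' of the positive-expression distribution using nearest-rank (type 1)
#' quantile boundaries. Ties share a bin by value.
#'
#' @param models Gene model data.frame with an \code{expression} column.
#' @return Factor (levels non_expressed, Q1..Q4) aligned with \code{models}
#'   rows.
#' @export
expression_bins <- function(models) {
  e <- models$expression
  bin <- rep("non_expressed", nrow(models))
  pos <- which(!is.na(e) & e > 0)
  if (length(pos)) {
    qs <- stats::quantile(e[pos], probs = c(0.25, 0.5, 0.75), type = 1)
    bin[pos] <- c("Q1", "Q2", "Q3", "Q4")[
      findInterval(e[pos], qs, left.open = TRUE) + 1L]
  }
  factor(bin, levels = c("non_expressed", "Q1", "Q2", "Q3", "Q4"))
}

#' Percentage of genic didyma per expression bin
#'
#' @param pairs Didyma pair table with \code{region} and \code{gene_ids}
#'   columns (first listed gene is used).
#' @param models Gene model data.frame with expression.
#' @return Named numeric vector of percentages over the five bins (sums to
#'   100 when any genic pair exists; all zero with a warning otherwise).
#' @export
didyma_by_expression <- function(pairs, models) {
  bins <- expression_bins(models)
  names(bins) <- models$gene_id
  lev <- levels(bins)
  genic <- pairs[pairs$region == "genic" & pairs$gene_ids != "", , drop = FALSE]
  if (!nrow(genic)) {
    warning("no genic didyma")
    return(stats::setNames(numeric(5), lev))
  }
  first_gene <- sub(",.*$", "", genic$gene_ids)
  tab <- table(factor(as.character(bins[first_gene]), levels = lev))
  stats::setNames(100 * as.numeric(tab) / sum(tab), lev)
}
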