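CATALOG_COLUMNS <- c("sample", "chrom", "pos", "ref", "alt", "vaf",
                     "alt_reads", "depth", "callers")

#' Construct a mutation catalog
#'
#' A mutation catalog is a plain \code{data.frame} of somatic single-base
#' substitutions with one row per (sample, chrom, pos), sorted by
#' (sample, chrom, pos). Columns: \code{sample}, \code{chrom}, \code{pos}
#' (1-based), \code{ref}, \code{alt} (single bases), \code{vaf} (variant
#' allele fraction in [0,1]), \code{alt_reads}, \code{depth}, \code{callers}
#' (number of callers supporting the call). The read-support columns may be
#' \code{NA} when the source does not provide them.
#'
#' @param df data.frame with at least chrom, pos, ref, alt; missing optional
#'   columns are added as NA.
#' @param genome_build Optional label stored as an attribute.
#' @return Validated, sorted catalog data.frame of class
#'   \code{mutation_catalog}.
#' @export
mutation_catalog <- function(df, genome_build = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog lacks columns: ", paste(miss, collapse = ", "))
  if (!"sample" %in% names(df)) df$sample <- "sample1"
  for (col in c("vaf", "alt_reads", "depth", "callers")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  df <- df[, CATALOG_COLUMNS, drop = FALSE]
  df$chrom <- as.character(df$chrom)
  df$sample <- as.character(df$sample)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  if (nrow(df)) {
    bad <- !(df$ref %in% c("A", "C", "G", "T")) | !(df$alt %in% c("A", "C", "G", "T"))
    if (any(bad)) stop(sum(bad), " record(s) with ref/alt outside {A,C,G,T}")
    if (any(df$ref == df$alt)) stop("record(s) with ref == alt")
    if (any(df$pos < 1L)) stop("record(s) with pos < 1")
    v <- df$vaf[!is.na(df$vaf)]
    if (any(v < 0 | v > 1)) stop("VAF outside [0,1]")
    ok <- !is.na(df$alt_reads) & !is.na(df$depth)
    if (any(df$alt_reads[ok] > df$depth[ok])) stop("alt_reads > depth")
    df <- df[order(df$sample, df$chrom, df$pos), , drop = FALSE]
    key <- paste(df$sample, df$chrom, df$pos, df$alt)
    if (anyDuplicated(key)) stop("duplicate (sample, chrom, pos, alt) records")
  }
  rownames(df) <- NULL
  attr(df, "genome_build") <- genome_build
  class(df) <- c("mutation_catalog", "data.frame")
  df
}

#' Read a mutation catalog from TSV or VCF
#'
#' TSV input must carry a header with at least
#' \code{chrom pos ref alt} and may add \code{vaf alt_reads depth callers
#' sample}; '.' denotes missing. VCF input (4.x) is parsed with
#' \pkg{vcfR}: multi-allelic rows are split into one record per ALT, non-SNV
#' alleles are skipped with a tally, and VAF / read support are taken from
#' INFO keys \code{VAF}, \code{DP}, \code{ALTREADS}, \code{CALLERS} when
#' present, else from the named sample's \code{AD}/\code{DP} FORMAT fields.
#'
#' @param path Path to a .tsv/.txt or .vcf file (format chosen by extension,
#'   override with \code{format}).
#' @param sample Sample identifier to assign (TSV rows lacking a sample
#'   column, and all VCF records); for multi-sample VCFs, also selects the
#'   genotype column used for read support.
#' @param format "auto", "tsv" or "vcf".
#' @return A [mutation_catalog()]; the number of skipped non-SNV records is
#'   stored in attribute \code{skipped}.
#' @export
read_catalog <- function(path, sample = NULL, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("catalog file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") .read_catalog_vcf(path, sample) else .read_catalog_tsv(path, sample)
}

.read_catalog_tsv <- function(path, sample) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = c(".", "NA"),
                          check.names = FALSE, quote = "", comment.char = "")
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("TSV catalog lacks columns: ", paste(miss, collapse = ", "))
  bad_pos <- which(is.na(suppressWarnings(as.integer(df$pos))))
  if (length(bad_pos)) {
    stop("malformed pos at data line ", bad_pos[1], " of ", path)
  }
  df$pos <- as.integer(df$pos)
  for (col in c("vaf", "alt_reads", "depth", "callers")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  if (!is.null(sample)) df$sample <- sample
  snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    toupper(df$ref) %in% c("A", "C", "G", "T") &
    toupper(df$alt) %in% c("A", "C", "G", "T") &
    toupper(df$ref) != toupper(df$alt)
  out <- mutation_catalog(df[snv, , drop = FALSE])
  attr(out, "skipped") <- sum(!snv)
  out
}

.read_catalog_vcf <- function(path, sample) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(mutation_catalog(data.frame(chrom = character(), pos = integer(),
                                       ref = character(), alt = character())))
  }
  alt_split <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  row_id <- rep(seq_len(nrow(fix)), n_alt)
  rec <- data.frame(
    chrom = fix$CHROM[row_id],
    pos = as.integer(fix$POS[row_id]),
    ref = toupper(fix$REF[row_id]),
    alt = toupper(unlist(alt_split)),
    stringsAsFactors = FALSE
  )
  info_num <- function(key) {
    v <- vcfR::extract.info(vcf, element = key, as.numeric = TRUE)
    if (is.null(v) || all(is.na(v))) NULL else v[row_id]
  }
  rec$vaf <- info_num("VAF")
  rec$depth <- info_num("DP")
  rec$alt_reads <- info_num("ALTREADS")
  rec$callers <- info_num("CALLERS")
  # fall back to per-sample FORMAT AD/DP for read support
  if ((is.null(rec$vaf) || is.null(rec$depth)) && nrow(vcf@gt %||% matrix(nrow = 0, ncol = 0))) {
    gt_samples <- colnames(vcf@gt)[-1]
    col <- if (!is.null(sample) && sample %in% gt_samples) sample else gt_samples[1]
    ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD")[, col], error = function(e) NULL)
    dp <- tryCatch(as.numeric(vcfR::extract.gt(vcf, element = "DP")[, col]),
                   error = function(e) NULL)
    if (!is.null(ad)) {
      parts <- strsplit(ad, ",", fixed = TRUE)
      refd <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
      altd <- suppressWarnings(as.numeric(vapply(parts, function(p) p[min(2L, length(p))], "")))
      if (is.null(rec$alt_reads)) rec$alt_reads <- altd[row_id]
      if (is.null(rec$depth)) {
        rec$depth <- if (!is.null(dp)) dp[row_id] else (refd + altd)[row_id]
      }
      if (is.null(rec$vaf)) rec$vaf <- rec$alt_reads / rec$depth
    } else if (!is.null(dp) && is.null(rec$depth)) {
      rec$depth <- dp[row_id]
    }
  }
  rec$sample <- if (is.null(sample)) "sample1" else sample
  snv <- nchar(rec$ref) == 1L & nchar(rec$alt) == 1L &
    rec$ref %in% c("A", "C", "G", "T") & rec$alt %in% c("A", "C", "G", "T") &
    rec$ref != rec$alt
  out <- mutation_catalog(rec[snv, , drop = FALSE])
  attr(out, "skipped") <- sum(!snv)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Somatic confidence filter configuration
#'
#' Defaults follow the consensus-calling confidence rules used for murine
#' whole-genome tumor data: at least 3 reads supporting the variant, at
#' least 10 reads of depth at the site, VAF strictly over 0.05, and support
#' from at least 2 independent callers. Setting any threshold to 0 disables
#' that criterion (records with missing values then pass it).
#'
#' @param min_alt_reads,min_depth,min_callers Integer thresholds (>=, records
#'   with NA fail unless the threshold is 0).
#' @param min_vaf VAF threshold; the comparison is strict (\code{vaf > min_vaf}).
#' @return A list of class \code{somatic_filter_config}.
#' @export
somatic_filter_config <- function(min_alt_reads = 3, min_depth = 10,
                                  min_vaf = 0.05, min_callers = 2) {
  stopifnot(min_alt_reads >= 0, min_depth >= 0, min_vaf >= 0, min_callers >= 0)
  structure(list(min_alt_reads = min_alt_reads, min_depth = min_depth,
                 min_vaf = min_vaf, min_callers = min_callers),
            class = "somatic_filter_config")
}

#' Apply somatic confidence filters to a catalog
#'
#' Retains records with \code{alt_reads >= min_alt_reads},
#' \code{depth >= min_depth}, \code{vaf > min_vaf} (strict) and
#' \code{callers >= min_callers}. Records lacking a value fail the
#' corresponding criterion unless its threshold is set to 0.
#'
#' @param catalog A [mutation_catalog()].
#' @param cfg A [somatic_filter_config()].
#' @return Filtered catalog (subset of the input, order preserved).
#' @export
apply_somatic_filters <- function(catalog, cfg = somatic_filter_config()) {
  if (!nrow(catalog)) return(catalog)
  pass_num <- function(x, thr, strict = FALSE) {
    if (thr == 0 && !strict) return(rep(TRUE, length(x)))
    v <- ifelse(is.na(x), -Inf, x)
    if (strict) v > thr else v >= thr
  }
  keep <- pass_num(catalog$alt_reads, cfg$min_alt_reads) &
    pass_num(catalog$depth, cfg$min_depth) &
    pass_num(catalog$vaf, cfg$min_vaf, strict = TRUE) &
    pass_num(catalog$callers, cfg$min_callers)
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(catalog)
  attr(out, "genome_build") <- attr(catalog, "genome_build", exact = TRUE)
  out
}

#' Write a mutation catalog as TSV
#'
#' Writes the standard tab-separated catalog dialect (header
#' \code{chrom pos ref alt vaf alt_reads depth callers sample}, '.' for
#' missing values). [read_catalog()] of the written file reproduces the
#' records exactly.
#'
#' @param catalog A [mutation_catalog()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  df <- df[, c("chrom", "pos", "ref", "alt", "vaf", "alt_reads", "depth",
               "callers", "sample"), drop = FALSE]
  for (col in names(df)) {
    x <- df[[col]]
    df[[col]] <- ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE, digits = 15))
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write catalog to ", path, ": ", conditionMessage(e)))
  invisible(path)
}
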