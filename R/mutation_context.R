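#' Strand carrying the pyrimidine of the reference base pair
#'
#' For a single-base substitution the mutated base pair is identified by its
#' pyrimidine: records with reference C or T carry the pyrimidine on the
#' plus (forward) strand, records with reference A or G carry it on the
#' minus strand. Strand coordination of clustered APOBEC mutations is
#' defined on this strand.
#'
#' @param ref Character vector of reference bases (A/C/G/T), or a catalog
#'   data.frame (its \code{ref} column is used).
#' @return Character vector, "+" or "-".
#' @export
pyrimidine_strand <- function(ref) {
  if (is.data.frame(ref)) ref <- ref$ref
  ifelse(ref %in% c("C", "T"), "+", "-")
}

#' Strand carrying the guanine of the reference base pair
#'
#' Complement of [pyrimidine_strand()]: the guanine (adduct-bearing) strand
#' used to orient carcinogen-associated G>T / G>C mutations.
#'
#' @inheritParams pyrimidine_strand
#' @return Character vector, "+" or "-".
#' @export
guanine_strand <- function(ref) {
  if (is.data.frame(ref)) ref <- ref$ref
  ifelse(ref %in% c("A", "G"), "+", "-")
}

#' The 96 standard SBS channel labels
#'
#' COSMIC ordering: substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each
#' over the 16 upstream x downstream flank combinations in alphabetical
#' order.
#'
#' @return Character vector of 96 labels like \code{"A[C>T]A"}.
#' @export
sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    alt <- substr(s, 3, 3)
    for (up in bases) for (dn in bases) {
      out <- c(out, paste0(up, "[", ref, ">", alt, "]", dn))
    }
  }
  out
}

# Pyrimidine-normalised (up, ref, alt, down) for each record; NA rows where
# the trinucleotide window leaves the contig or contains N.
.pyr_context <- function(catalog, genome) {
  ctx <- reference_context(catalog, genome, flank = 1L)
  up <- substr(ctx, 1, 1)
  mid <- substr(ctx, 2, 2)
  dn <- substr(ctx, 3, 3)
  bad_ref <- !is.na(mid) & mid != catalog$ref
  if (any(bad_ref)) {
    i <- which(bad_ref)[1]
    stop("reference mismatch at ", catalog$chrom[i], ":", catalog$pos[i],
         " (catalog ", catalog$ref[i], ", genome ", mid[i], ")")
  }
  ref <- catalog$ref
  alt <- catalog$alt
  pur <- ref %in% c("A", "G")
  n_up <- ifelse(pur, .comp_base(dn), up)
  n_dn <- ifelse(pur, .comp_base(up), dn)
  n_ref <- ifelse(pur, .comp_base(ref), ref)
  n_alt <- ifelse(pur, .comp_base(alt), alt)
  usable <- !is.na(ctx) & up %in% c("A", "C", "G", "T") & dn %in% c("A", "C", "G", "T")
  data.frame(up = n_up, ref = n_ref, alt = n_alt, dn = n_dn,
             usable = usable, stringsAsFactors = FALSE)
}

#' SBS96 channel of each record
#'
#' Assigns the standard trinucleotide substitution channel, reverse
#' complementing purine-reference records so every channel is expressed on
#' the pyrimidine strand.
#'
#' @param catalog A [mutation_catalog()].
#' @param genome A \code{DNAStringSet}; the base at each position must match
#'   the record's ref (error otherwise).
#' @return Character vector of channel labels (\code{"A[C>T]A"} style); NA
#'   for records whose flank leaves the contig or contains N (these are
#'   tallied in attribute \code{excluded}).
#' @export
sbs96_channel <- function(catalog, genome) {
  if (!nrow(catalog)) return(character(0))
  px <- .pyr_context(catalog, genome)
  out <- rep(NA_character_, nrow(catalog))
  ok <- px$usable
  out[ok] <- paste0(px$up[ok], "[", px$ref[ok], ">", px$alt[ok], "]", px$dn[ok])
  attr(out, "excluded") <- sum(!ok)
  out
}

#' Is each record an APOBEC-context (TCW) mutation?
#'
#' TRUE iff, after normalisation to the strand carrying the mutated
#' cytosine, the mutation is C>T or C>G with an upstream T and a downstream
#' A or T (the T[C>T/G]W motif of APOBEC3 deamination).
#'
#' @inheritParams sbs96_channel
#' @return Logical vector (NA where context is unavailable).
#' @export
is_apobec_context <- function(catalog, genome) {
  if (!nrow(catalog)) return(logical(0))
  px <- .pyr_context(catalog, genome)
  res <- px$ref == "C" & px$alt %in% c("T", "G") & px$up == "T" & px$dn %in% c("A", "T")
  res[!px$usable] <- NA
  res
}

#' Is each record a carcinogen-adduct (NQO) context mutation?
#'
#' TRUE iff, after normalisation to the strand carrying the mutated guanine,
#' the mutation is G>T, or G>C with a downstream base other than A. The
#' G>C-in-GA exclusion removes exactly the class that is an opposite-strand
#' T[C>G] APOBEC event, so no mutation can be counted both as an APOBEC
#' didyma member and as an adduct-pair member.
#'
#' @inheritParams sbs96_channel
#' @return Logical vector (NA where context is unavailable).
#' @export
is_nqo_context <- function(catalog, genome) {
  if (!nrow(catalog)) return(logical(0))
  ctx <- reference_context(catalog, genome, flank = 1L)
  up <- substr(ctx, 1, 1)
  dn <- substr(ctx, 3, 3)
  ref <- catalog$ref
  alt <- catalog$alt
  # guanine-strand downstream base: forward dn for ref G, complement of
  # forward up for minus-strand guanines (ref C)
  g_dn <- ifelse(ref == "G", dn, .comp_base(up))
  g2t <- (ref == "G" & alt == "T") | (ref == "C" & alt == "A")
  g2c <- (ref == "G" & alt == "C") | (ref == "C" & alt == "G")
  res <- g2t | (g2c & g_dn != "A")
  res[!(ref %in% c("G", "C"))] <- FALSE
  usable <- !is.na(ctx) & up %in% c("A", "C", "G", "T") & dn %in% c("A", "C", "G", "T")
  res[!usable] <- NA
  res
}

#' Pentanucleotide mutation spectrum adjusted by genome-wide context counts
#'
#' Tallies mutations by their 5-mer reference context (normalised to the
#' pyrimidine or guanine strand) and alt allele, and divides each count by
#' the number of genome-wide occurrences of that 5-mer (counted on both
#' strands, i.e. strand-collapsed). Records whose 5-mer window leaves the
#' contig or contains N are excluded and tallied.
#'
#' @param catalog A [mutation_catalog()].
#' @param genome A \code{DNAStringSet}.
#' @param subset Optional logical vector selecting records (e.g. an NQO
#'   class mask); NA entries are dropped.
#' @param normalize_strand "pyrimidine" (default) or "guanine": the strand
#'   the context is expressed on.
#' @return data.frame with columns context, alt, count, genome_count,
#'   adjusted; attribute \code{excluded} tallies edge/N records.
#' @export
pentanucleotide_spectrum <- function(catalog, genome, subset = NULL,
                                     normalize_strand = c("pyrimidine", "guanine")) {
  normalize_strand <- match.arg(normalize_strand)
  if (!is.null(subset)) {
    keep <- !is.na(subset) & subset
    catalog <- catalog[keep, , drop = FALSE]
  }
  empty <- data.frame(context = character(0), alt = character(0),
                      count = numeric(0), genome_count = numeric(0),
                      adjusted = numeric(0))
  if (!nrow(catalog)) return(structure(empty, excluded = 0L))
  ctx <- reference_context(catalog, genome, flank = 2L)
  usable <- !is.na(ctx) & !grepl("[^ACGT]", ctx)
  excluded <- sum(!usable)
  ctx <- ctx[usable]
  ref <- catalog$ref[usable]
  alt <- catalog$alt[usable]
  flip <- if (normalize_strand == "pyrimidine") ref %in% c("A", "G") else ref %in% c("C", "T")
  if (any(flip)) {
    ctx[flip] <- revcomp(ctx[flip])
    alt[flip] <- .comp_base(alt[flip])
  }
  if (!length(ctx)) return(structure(empty, excluded = excluded))
  tab <- as.data.frame(table(context = ctx, alt = alt), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  gw <- genome_pentamer_counts(genome)
  tab$genome_count <- unname(gw[tab$context])
  tab$genome_count[is.na(tab$genome_count)] <- 0
  out <- data.frame(context = tab$context, alt = tab$alt, count = tab$Freq,
                    genome_count = tab$genome_count,
                    adjusted = ifelse(tab$genome_count > 0,
                                      tab$Freq / tab$genome_count, NA_real_))
  out <- out[order(out$context, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, excluded = excluded)
}

#' Genome-wide 5-mer occurrence counts (both strands)
#'
#' @param genome A \code{DNAStringSet}.
#' @return Named numeric vector over all 1024 5-mers; each value is the
#'   number of occurrences on the forward plus the reverse strand.
#' @export
genome_pentamer_counts <- function(genome) {
  fwd <- colSums(Biostrings::oligonucleotideFrequency(genome, width = 5))
  rc <- fwd[revcomp(names(fwd))]
  fwd + unname(rc)
}
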