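#' Read a reference genome from FASTA
#'
#' Loads a FASTA file into a \code{DNAStringSet}. Sequence names are taken as
#' the token before the first whitespace of each header, and sequences are
#' uppercased so that downstream context lookups are case-insensitive.
#'
#' @param path Path to a FASTA file.
#' @return A \code{Biostrings::DNAStringSet} with one entry per contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(seqs) <- nm
  # toupper: DNAStringSet is already uppercase by construction, but soft-masked
  # lowercase input is normalised when we cache character vectors later.
  seqs
}

#' Contig lengths of a genome
#'
#' @param genome A \code{DNAStringSet} as returned by [read_genome()].
#' @return Named integer vector of contig lengths.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

# Per-contig character string (uppercased). Context classification does
# many random-access substring lookups; one as.character() per contig and
# call is far cheaper than repeated XString subsetting.
.genome_string <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("contig not in genome: ", chrom)
  toupper(as.character(genome[[chrom]]))
}

#' Extract reference context around catalog positions
#'
#' Returns, for each record, the forward-strand sequence from
#' \code{pos - flank} to \code{pos + flank}. Windows overrunning a contig end
#' yield \code{NA}.
#'
#' @param catalog A mutation catalog (see [mutation_catalog()]).
#' @param genome A \code{DNAStringSet}.
#' @param flank Number of bases on each side (1 for trinucleotide, 2 for
#'   pentanucleotide contexts).
#' @return Character vector of contexts (length \code{2*flank + 1}), NA where
#'   the window leaves the contig.
#' @export
reference_context <- function(catalog, genome, flank = 1L) {
  out <- rep(NA_character_, nrow(catalog))
  lens <- genome_lengths(genome)
  for (ch in unique(catalog$chrom)) {
    idx <- which(catalog$chrom == ch)
    s <- .genome_string(genome, ch)
    p <- catalog$pos[idx]
    ok <- p - flank >= 1L & p + flank <= lens[[ch]]
    if (any(ok)) out[idx[ok]] <- substring(s, p[ok] - flank, p[ok] + flank)
  }
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement a sequence string (vectorised)
#' @param x Character vector of DNA strings.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.comp_base <- function(b) unname(COMPLEMENT[b])

#' Reverse complement a whole dataset
#'
#' Mirrors the genome and a catalog through reverse complementation: each
#' contig is reverse-complemented, every record is mapped to position
#' \code{L - pos + 1} with complemented alleles, and (optionally) gene model
#' strands are flipped with their spans mirrored. Used to check strand
#' symmetry of context classification and didyma extraction.
#'
#' @param genome A \code{DNAStringSet}.
#' @param catalog A mutation catalog.
#' @param models Optional gene model data.frame (see [read_gene_models()]).
#' @param flip_gene_strands Flip gene strand labels along with the mirror
#'   (default TRUE, the full physical mirror under which all strand-aware
#'   results are invariant). With FALSE the gene annotations keep their
#'   original sense, so transcribed/non-transcribed labels swap exactly.
#' @return List with elements \code{genome}, \code{catalog} and, when models
#'   are supplied, \code{models}.
#' @export
revcomp_dataset <- function(genome, catalog, models = NULL,
                            flip_gene_strands = TRUE) {
  lens <- genome_lengths(genome)
  rc_genome <- Biostrings::reverseComplement(genome)
  names(rc_genome) <- names(genome)
  cat2 <- catalog
  cat2$pos <- unname(lens[as.character(cat2$chrom)]) - cat2$pos + 1L
  cat2$ref <- .comp_base(cat2$ref)
  cat2$alt <- .comp_base(cat2$alt)
  out <- list(genome = rc_genome, catalog = mutation_catalog(cat2))
  if (!is.null(models)) {
    m2 <- models
    L <- unname(lens[as.character(m2$chrom)])
    new_start <- L - m2$end + 1L
    new_end <- L - m2$start + 1L
    m2$start <- new_start
    m2$end <- new_end
    if (flip_gene_strands) m2$strand <- ifelse(m2$strand == "+", "-", "+")
    out$models <- m2
  }
  out
}
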