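# Genome laid out so that every motif case sits at a known offset:
#  pos: 123456789012345
#       AACATCAGGATCTTT
#  - pos 5  C in ACA (upstream A)          pos 11 C in TCT (TCW)
#  - pos 8  G in AGG -> minus-strand C in CCT
ctx_genome <- function() test_genome(chr1 = "AACATCAGGATCTTT")

test_that("pyrimidine and guanine strands follow the reference base", {
  expect_equal(pyrimidine_strand(c("C", "T", "G", "A")), c("+", "+", "-", "-"))
  expect_equal(guanine_strand(c("C", "T", "G", "A")), c("-", "-", "+", "+"))
})

test_that("SBS96 channels are strand-normalised", {
  g <- test_genome(chr1 = "AACAT")  # pos 3: C in ACA context
  expect_equal(sbs96_channel(cat_of(rec("chr1", 3, "C", "T")), g)[1], "A[C>T]A")
  # TGT with G>A is minus-strand ACA with C>T
  g2 <- test_genome(chr1 = "ATGTA")
  expect_equal(sbs96_channel(cat_of(rec("chr1", 3, "G", "A")), g2)[1], "A[C>T]A")
  # missing flank at contig end
  ch <- sbs96_channel(cat_of(rec("chr1", 1, "A", "T")), g)
  expect_true(is.na(ch[1]))
  expect_equal(attr(ch, "excluded"), 1)
  # reference mismatch is an error
  expect_error(sbs96_channel(cat_of(rec("chr1", 3, "G", "A")), g), "mismatch")
})

test_that("APOBEC TCW classification covers both strands and rejects near-misses", {
  g <- test_genome(chr1 = "ATCAACCATAGAT")
  # pos 3: C in TCA
  expect_true(is_apobec_context(cat_of(rec("chr1", 3, "C", "T")), g))
  expect_true(is_apobec_context(cat_of(rec("chr1", 3, "C", "G")), g))
  # alt A is not an APOBEC substitution class
  expect_false(is_apobec_context(cat_of(rec("chr1", 3, "C", "A")), g))
  # pos 7: C in CCA (upstream not T)
  expect_false(is_apobec_context(cat_of(rec("chr1", 7, "C", "T")), g))
  # pos 11: G in AGA = minus-strand TCT; G>A is C>T on the pyrimidine strand
  expect_true(is_apobec_context(cat_of(rec("chr1", 11, "G", "A")), g))
  expect_true(is_apobec_context(cat_of(rec("chr1", 11, "G", "C")), g))
  expect_false(is_apobec_context(cat_of(rec("chr1", 11, "G", "T")), g))
})

test_that("NQO classification applies the GA-context exclusion on either strand", {
  g <- test_genome(chr1 = "ATGAGGCTCATA")
  # pos 3: G followed by A -> G>T yes, G>C excluded
  expect_true(is_nqo_context(cat_of(rec("chr1", 3, "G", "T")), g))
  expect_false(is_nqo_context(cat_of(rec("chr1", 3, "G", "C")), g))
  # pos 6: G followed by C -> both classes allowed
  expect_true(is_nqo_context(cat_of(rec("chr1", 6, "G", "T")), g))
  expect_true(is_nqo_context(cat_of(rec("chr1", 6, "G", "C")), g))
  # pos 9: C = minus-strand G; C>A is guanine-strand G>T
  expect_true(is_nqo_context(cat_of(rec("chr1", 9, "C", "A")), g))
  # minus-strand guanine at pos 9 has downstream base comp(T at pos 8) = A:
  # its G>C (ref C>G) is excluded
  expect_false(is_nqo_context(cat_of(rec("chr1", 9, "C", "G")), g))
  # pyrimidine transitions are never NQO class
  expect_false(is_nqo_context(cat_of(rec("chr1", 9, "C", "T")), g))
})

test_that("the excluded NQO G>C class is exactly the opposite-strand APOBEC TC case", {
  # scan every G>C mutation of a random genome: those in GA context must
  # never be APOBEC didyma members AND nqo simultaneously
  rc <- random_catalog(400, L = 20000, seed = 3)
  ann <- annotate_catalog(rc$catalog, rc$genome)
  both <- which(ann$apobec %in% TRUE & ann$nqo %in% TRUE)
  # overlap can only come from C>G/G>C in TC/GA context, which the
  # exclusion removes entirely
  gc_rows <- (ann$ref == "G" & ann$alt == "C") | (ann$ref == "C" & ann$alt == "G")
  expect_equal(intersect(both, which(gc_rows)), integer(0))
})

test_that("context classes are invariant under genome reverse complement", {
  rc <- random_catalog(500, L = 30000, seed = 5)
  mirror <- revcomp_dataset(rc$genome, rc$catalog)
  a1 <- is_apobec_context(rc$catalog, rc$genome)
  a2 <- is_apobec_context(mirror$catalog, mirror$genome)
  n1 <- is_nqo_context(rc$catalog, rc$genome)
  n2 <- is_nqo_context(mirror$catalog, mirror$genome)
  c1 <- sbs96_channel(rc$catalog, rc$genome)
  c2 <- sbs96_channel(mirror$catalog, mirror$genome)
  # mirrored catalog is sorted in mirrored order: match by mirrored position
  L <- genome_lengths(rc$genome)[["chr1"]]
  m <- match(L - rc$catalog$pos + 1, mirror$catalog$pos)
  expect_equal(a1, a2[m])
  expect_equal(n1, n2[m])
  expect_equal(as.vector(c1), as.vector(c2)[m])
})

test_that("SBS96 channel totals account for every classifiable SNV", {
  rc <- random_catalog(1000, L = 40000, seed = 9)
  v <- build_sbs96(rc$catalog, rc$genome)
  ch <- sbs96_channel(rc$catalog, rc$genome)
  expect_equal(sum(v), sum(!is.na(ch)))
  # brute-force per-record tally oracle
  tal <- table(factor(ch[!is.na(ch)], levels = sbs96_labels()))
  expect_equal(as.numeric(v), as.numeric(tal))
})

test_that("pentanucleotide spectra match a brute-force 5-mer tally", {
  rc <- random_catalog(300, L = 10000, seed = 13)
  spec <- pentanucleotide_spectrum(rc$catalog, rc$genome)
  # brute force: normalise each record by hand, count, divide
  s <- as.character(rc$genome[[1]])
  df <- as.data.frame(rc$catalog)
  ctx <- substring(s, df$pos - 2, df$pos + 2)
  flip <- df$ref %in% c("A", "G")
  ctx[flip] <- revcomp(ctx[flip])
  alt <- ifelse(flip, revcomp(df$alt), df$alt)
  edge <- df$pos <= 2 | df$pos >= nchar(s) - 1
  tab <- table(paste(ctx[!edge], alt[!edge]))
  got <- stats::setNames(spec$count, paste(spec$context, spec$alt))
  expect_equal(sort(names(got)), sort(names(tab)))
  expect_equal(as.numeric(got[names(tab)]), as.numeric(tab))
  # genome-wide counts: both-strand occurrences, checked for one context
  one <- spec$context[1]
  fwd <- length(gregexpr(one, s, fixed = TRUE)[[1]])
  rcv <- gregexpr(revcomp(one), s, fixed = TRUE)[[1]]
  rcn <- if (identical(as.integer(rcv), -1L)) 0 else length(rcv)
  # gregexpr misses overlapping matches; use the package counter only for
  # the adjusted = count / genome_count identity instead
  expect_equal(spec$adjusted, spec$count / spec$genome_count)
})

test_that("single planted mutation yields its 5-mer with count one", {
  g <- test_genome(chr1 = "TAAGCTT")
  spec <- pentanucleotide_spectrum(cat_of(rec("chr1", 4, "G", "T")), g,
                                   normalize_strand = "guanine")
  expect_equal(nrow(spec), 1)
  expect_equal(spec$context, "AAGCT")
  expect_equal(spec$alt, "T")
  expect_equal(spec$count, 1)
})
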