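test_that("IMD follows the motif worked examples", {
  # TCC with both cytosines mutated: positions p and p+1 -> IMD 1
  g <- test_genome(chr1 = "ATCCA")
  cat <- cat_of(rec("chr1", 3, "C", "T"), rec("chr1", 4, "C", "T"))
  expect_equal(compute_imds(cat)$imd, 1)
  # TCTC with the two cytosines mutated: positions p and p+2 -> IMD 2
  g2 <- test_genome(chr1 = "ATCTCA")
  cat2 <- cat_of(rec("chr1", 3, "C", "T"), rec("chr1", 5, "C", "T"))
  expect_equal(compute_imds(cat2)$imd, 2)
  # no IMD for singletons or across chromosomes/samples
  expect_equal(nrow(compute_imds(cat_of(rec("chr1", 3, "C", "T")))), 0)
  cross <- cat_of(rec("chr1", 3, "C", "T"), rec("chr2", 4, "C", "T"))
  expect_equal(nrow(compute_imds(cross)), 0)
})

test_that("per-mutation IMD is the nearest-neighbour gap", {
  cat <- cat_of(rec("chr1", c(100, 110, 500), "C", "T"))
  expect_equal(mutation_imd(cat), c(10, 10, 390))
})

test_that("cluster events respect IMD threshold and VAF splitting", {
  g <- test_genome(chr1 = paste(rep("ATCA", 300), collapse = ""))
  # TCA cytosines at positions 3, 7, 11, ...
  ev <- detect_clusters(cat_of(rec("chr1", 3, "C", "T", vaf = 0.40),
                               rec("chr1", 23, "C", "T", vaf = 0.45)),
                        g, threshold = 32)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$size, 2)
  expect_true(ev$didyma_flag)
  # VAF gap of 0.2 splits the pair: no event
  ev2 <- detect_clusters(cat_of(rec("chr1", 3, "C", "T", vaf = 0.40),
                                rec("chr1", 23, "C", "T", vaf = 0.20)),
                         g, threshold = 32)
  expect_equal(nrow(ev2), 0)
  # four members at successive IMDs 4 form one event
  ev3 <- detect_clusters(cat_of(rec("chr1", c(3, 7, 11, 15), "C", "T")),
                         g, threshold = 32)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$size, 4)
  expect_equal(ev3$label, "kataegis")
})

test_that("taxonomy labels follow size and IMD rules", {
  expect_equal(classify_event(2, 30, TRUE, TRUE)$label, "omikli")
  expect_true(classify_event(2, 30, TRUE, TRUE)$didyma_flag)
  expect_equal(classify_event(2, 40, TRUE, TRUE)$label, "omikli")
  expect_false(classify_event(2, 40, TRUE, TRUE)$didyma_flag)
  expect_equal(classify_event(3, c(5, 9), TRUE, TRUE)$label, "omikli")
  expect_equal(classify_event(5, c(2, 3, 2, 4), TRUE, TRUE)$label, "kataegis")
  # a pair 1 bp apart is didyma but fails the omikli IMD>1 clause
  cls <- classify_event(2, 1, TRUE, TRUE)
  expect_equal(cls$label, "didyma")
  expect_true(cls$didyma_flag)
  # non-APOBEC or discordant events are other
  expect_equal(classify_event(2, 10, FALSE, TRUE)$label, "other")
  expect_equal(classify_event(2, 10, TRUE, FALSE)$label, "other")
  expect_equal(classify_event(4, c(1, 1, 1), TRUE, TRUE)$label, "other")
})

test_that("didyma extraction honours motif, strand, VAF and window clauses", {
  # plus-strand TCA at 3; TCT at 30 (IMD 27); minus-strand site AGA
  s <- paste0("ATCA", strrep("A", 24), "TCTT", strrep("A", 10), "AAGAA",
              strrep("A", 10))
  g <- test_genome(chr1 = s)
  # satisfied pair
  d <- extract_didyma(cat_of(rec("chr1", 3, "C", "T", vaf = 0.4),
                             rec("chr1", 30, "C", "G", vaf = 0.42)), g)
  expect_equal(nrow(d), 1)
  expect_equal(d$imd, 27)
  expect_equal(d$strand, "+")
  # opposite strands: plus C>T at 3 vs minus-strand APOBEC G>A at 45
  d2 <- extract_didyma(cat_of(rec("chr1", 30, "C", "T"),
                              rec("chr1", 45, "G", "A")), g)
  expect_equal(nrow(d2), 0)
  # VAF difference above 0.1 disqualifies
  d3 <- extract_didyma(cat_of(rec("chr1", 3, "C", "T", vaf = 0.40),
                              rec("chr1", 30, "C", "T", vaf = 0.55)), g)
  expect_equal(nrow(d3), 0)
  # beyond 32 nt no pair; and monotone in the window
  far <- cat_of(rec("chr1", 3, "C", "T"), rec("chr1", 43, "G", "A"))
  expect_equal(nrow(extract_didyma(cat_of(rec("chr1", 3, "C", "T", vaf = .4),
                                          rec("chr1", 30, "C", "T", vaf = .4)),
                                   g, cluster_detection_config(didyma_imd_max = 20))), 0)
})

test_that("runs of three or more qualifying mutations yield no didyma", {
  # three TCA cytosines within one 32 nt window, same strand
  s <- paste0("ATCATTTCATTTCAT", strrep("A", 40))
  g <- test_genome(chr1 = s)
  cat3 <- cat_of(rec("chr1", 3, "C", "T"), rec("chr1", 8, "C", "T"),
                 rec("chr1", 13, "C", "T"))
  expect_equal(nrow(extract_didyma(cat3, g)), 0)
  # decompose_runs recovers the three constituent pairs
  expect_equal(nrow(extract_didyma(cat3, g, decompose_runs = TRUE)), 3)
  # and the run classifies as one omikli event
  ev <- detect_clusters(cat3, g, threshold = 32)
  expect_equal(ev$label, "omikli")
})

test_that("didyma sweep equals the brute-force pair scan on random catalogs", {
  for (seed in c(2, 23)) {
    rc <- random_catalog(600, L = 20000, seed = seed)
    fast <- extract_didyma(rc$catalog, rc$genome)
    slow <- brute_didyma(rc$catalog, rc$genome)
    expect_equal(nrow(fast), nrow(slow))
    if (nrow(fast)) {
      expect_equal(fast$pos1, slow$pos1)
      expect_equal(fast$pos2, slow$pos2)
    }
  }
})

test_that("didyma counts are preserved under whole-dataset reverse complement", {
  rc <- random_catalog(800, L = 30000, seed = 41)
  mirror <- revcomp_dataset(rc$genome, rc$catalog)
  d1 <- extract_didyma(rc$catalog, rc$genome)
  d2 <- extract_didyma(mirror$catalog, mirror$genome)
  expect_equal(nrow(d1), nrow(d2))
  # member strands flip
  expect_equal(sort(table(factor(d1$strand, c("+", "-"))), method = "radix"),
               sort(table(factor(ifelse(d2$strand == "+", "-", "+"), c("+", "-"))),
                    method = "radix"))
})

test_that("didyma window widening is monotone", {
  rc <- random_catalog(800, L = 20000, seed = 43)
  d32 <- extract_didyma(rc$catalog, rc$genome, decompose_runs = TRUE)
  d64 <- extract_didyma(rc$catalog, rc$genome,
                        cluster_detection_config(didyma_imd_max = 64),
                        decompose_runs = TRUE)
  k32 <- paste(d32$chrom, d32$pos1, d32$pos2)
  k64 <- paste(d64$chrom, d64$pos1, d64$pos2)
  expect_true(all(k32 %in% k64))
})

test_that("NQO pairs respect strand mode and the GA exclusion", {
  # G at 3 (followed by T), G at 18 (followed by C), C at 30 (minus-strand G)
  s <- paste0("AGGTA", strrep("T", 12), "AGCTA", strrep("T", 6), "TACTA",
              strrep("T", 20))
  g <- test_genome(chr1 = s)
  p1 <- extract_nqo_pairs(cat_of(rec("chr1", 3, "G", "T"),
                                 rec("chr1", 19, "G", "C")), g, 32, "same")
  expect_equal(nrow(p1), 1)
  expect_equal(p1$imd, 16)
  # opposite strand: plus G>T with minus-strand G (ref C>A)
  p2 <- extract_nqo_pairs(cat_of(rec("chr1", 19, "G", "T"),
                                 rec("chr1", 31, "C", "A")), g, 32, "opposite")
  expect_equal(nrow(p2), 1)
  expect_equal(nrow(extract_nqo_pairs(cat_of(rec("chr1", 19, "G", "T"),
                                             rec("chr1", 31, "C", "A")),
                                      g, 32, "same")), 0)
  # G>C in GA context never pairs: G at 2 is followed by G? build explicit GA
  s2 <- paste0("TGATA", strrep("T", 10), "AGCTA", strrep("T", 20))
  g2 <- test_genome(chr1 = s2)
  p3 <- extract_nqo_pairs(cat_of(rec("chr1", 2, "G", "C"),
                                 rec("chr1", 17, "G", "T")), g2, 32, "same")
  expect_equal(nrow(p3), 0)
})

test_that("taxonomy partition arithmetic holds on randomised clustered catalogs", {
  for (seed in c(3, 7)) {
    set.seed(seed)
    cfg <- synthetic_config(n_dispersed_apobec = 150, n_dispersed_nqo = 0,
                            n_didyma_pairs = 30, n_genes = 0,
                            background_exclusion = 40, seed = seed)
    ds <- synth_dataset(cfg, with_genes = FALSE)
    ev <- detect_clusters(ds$catalog, ds$genome, threshold = 32)
    expect_true(all(ev$label %in% c("didyma", "omikli", "kataegis", "other")))
    omikli <- ev[ev$label == "omikli", ]
    with_mark <- sum(omikli$didyma_flag)
    without <- sum(!omikli$didyma_flag)
    expect_equal(nrow(omikli), with_mark + without)
    # didyma marks only on size-2 events within the window
    expect_true(all(ev$size[ev$didyma_flag] == 2))
  }
})
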