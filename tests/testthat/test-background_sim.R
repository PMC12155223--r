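test_that("simulation conserves the per-stratum fingerprint exactly", {
  rc <- random_catalog(500, L = 30000, seed = 19)
  sims <- simulate_catalog(rc$catalog, rc$genome,
                           cfg = simulation_config(iterations = 10, seed = 2))
  fp0 <- catalog_fingerprint(as.data.frame(rc$catalog), rc$genome)
  for (it in c(1, 5, 10)) {
    fp1 <- catalog_fingerprint(sim_catalog(sims, it), rc$genome)
    expect_equal(sort(names(fp0)), sort(names(fp1)))
    expect_equal(as.vector(fp1[names(fp0)]), as.vector(fp0))
  }
})

test_that("genic/intergenic placement is conserved when models are supplied", {
  ds <- synth_dataset(synthetic_config(seed = 6))
  sims <- simulate_catalog(ds$catalog, ds$genome, ds$models,
                           simulation_config(iterations = 5, seed = 3))
  fp0 <- catalog_fingerprint(as.data.frame(ds$catalog), ds$genome, ds$models)
  fp1 <- catalog_fingerprint(sim_catalog(sims, 3), ds$genome, ds$models)
  expect_equal(as.vector(fp1[names(fp0)]), as.vector(fp0))
})

test_that("a single-mutation catalog simulates to single identical-channel records", {
  g <- test_genome(chr1 = paste(rep("ATCA", 50), collapse = ""))
  cat <- cat_of(rec("chr1", 23, "C", "T"))
  sims <- simulate_catalog(cat, g, cfg = simulation_config(iterations = 5, seed = 1))
  for (it in 1:5) {
    sc <- sim_catalog(sims, it)
    expect_equal(nrow(sc), 1)
    expect_equal(as.vector(sbs96_channel(mutation_catalog(sc), g)),
                 as.vector(sbs96_channel(cat, g)))
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  rc <- random_catalog(200, L = 10000, seed = 29)
  s1 <- simulate_catalog(rc$catalog, rc$genome, cfg = simulation_config(10, seed = 77))
  s2 <- simulate_catalog(rc$catalog, rc$genome, cfg = simulation_config(10, seed = 77))
  expect_identical(s1$positions, s2$positions)
  s3 <- simulate_catalog(rc$catalog, rc$genome, cfg = simulation_config(10, seed = 78))
  expect_false(identical(s1$positions, s3$positions))
})

test_that("planted clustering yields a threshold at or above the planted scale", {
  cfg <- synthetic_config(n_dispersed_apobec = 30, n_dispersed_nqo = 30,
                          n_didyma_pairs = 50, n_genes = 0, seed = 3)
  ds <- synth_dataset(cfg, with_genes = FALSE)
  sims <- simulate_catalog(ds$catalog, ds$genome,
                           cfg = simulation_config(iterations = 50, seed = 4))
  thr <- estimate_sample_imd_threshold(ds$catalog, sims)
  expect_false(is.na(thr$threshold))
  expect_gte(thr$threshold, 20)
  # doubling iterations moves the estimate by at most one grid step
  sims2 <- simulate_catalog(ds$catalog, ds$genome,
                            cfg = simulation_config(iterations = 100, seed = 4))
  thr2 <- estimate_sample_imd_threshold(ds$catalog, sims2)
  grid <- cluster_detection_config()$imd_grid
  i1 <- match(thr$threshold, grid)
  i2 <- match(thr2$threshold, grid)
  expect_lte(abs(i1 - i2), 1)
})

test_that("random catalogs yield no threshold in almost all replicates", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- synthetic_config(chrom_lengths = c(chr1 = 1e6), n_genes = 0,
                            n_dispersed_apobec = 400, n_dispersed_nqo = 0,
                            n_didyma_pairs = 0, background_exclusion = 0,
                            seed = s)
    ds <- synth_dataset(cfg, with_genes = FALSE)
    sims <- simulate_catalog(ds$catalog, ds$genome,
                             cfg = simulation_config(iterations = 20, seed = s + 100))
    if (!is.na(estimate_sample_imd_threshold(ds$catalog, sims)$threshold)) {
      hits <- hits + 1L
    }
  }
  expect_lte(hits, 0.05 * 10)
})

test_that("fewer than two mutations yields no threshold, with a warning", {
  g <- test_genome(chr1 = paste(rep("ATCA", 50), collapse = ""))
  cat <- cat_of(rec("chr1", 23, "C", "T"))
  sims <- simulate_catalog(cat, g, cfg = simulation_config(iterations = 3, seed = 1))
  expect_warning(res <- estimate_sample_imd_threshold(cat, sims), "fewer")
  expect_true(is.na(res$threshold))
})

test_that("regional correction leaves uniform-density catalogs untouched and demotes hotspots", {
  # uniform case: flags equal the global-threshold flags
  rc <- random_catalog(400, L = 2e6, seed = 31)
  sims <- simulate_catalog(rc$catalog, rc$genome,
                           cfg = simulation_config(iterations = 10, seed = 5))
  fl <- regional_imd_correction(rc$catalog, sims, threshold = 1000)
  imd <- mutation_imd(rc$catalog)
  global <- !is.na(imd) & imd <= 1000
  # regional flags are a subset of the global-threshold flags, and identical
  # wherever the window density does not exceed the simulated background
  expect_true(all(!fl$clustered | global))
  calm <- fl$window_ratio <= 1
  expect_equal(fl$clustered[calm], global[calm])
  expect_true(all(abs(fl$window_ratio - 1) < 0.5))
  # hotspot case: a dense 50 kb block embedded in a sparse background gets a
  # tighter cutoff than the global threshold
  set.seed(9)
  hot <- sort(sample(1000000:1050000, 300))
  cold <- sort(sample(1:900000, 100))
  L <- 2e6
  s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  pos <- sort(unique(c(hot, cold)))
  base <- substring(s, pos, pos)
  alt <- vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  cat <- mutation_catalog(data.frame(chrom = "chr1", pos = pos, ref = base,
                                     alt = unname(alt), vaf = 0.4, alt_reads = 10,
                                     depth = 30, callers = 3, sample = "s1"))
  sims2 <- simulate_catalog(cat, g, cfg = simulation_config(iterations = 10, seed = 6))
  fl2 <- regional_imd_correction(cat, sims2, threshold = 500)
  in_hot <- cat$pos >= 1000000 & cat$pos <= 1050000
  # 300 of 400 mutations in one window vs a uniform simulated background of
  # ~200 expected: ratio approaches (300 + spill) / 200
  expect_true(mean(fl2$window_ratio[in_hot]) > 1.4)
  expect_true(all(fl2$cutoff[in_hot] < 500))
  expect_true(mean(fl2$cutoff[!in_hot]) > mean(fl2$cutoff[in_hot]))
})
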