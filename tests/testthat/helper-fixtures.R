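# In-code fixtures: tiny genomes and catalogs built deterministically.

test_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

rec <- function(chrom, pos, ref, alt, vaf = 0.4, alt_reads = 12, depth = 30,
                callers = 3, sample = "s1") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, vaf = vaf,
             alt_reads = alt_reads, depth = depth, callers = callers,
             sample = sample, stringsAsFactors = FALSE)
}

cat_of <- function(...) mutation_catalog(do.call(rbind, list(...)))

# random SNV catalog on a random genome; used by oracle-equivalence tests
random_catalog <- function(n, L = 50000, seed = 1, n_samples = 1) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  pos <- sort(sample(2:(L - 1), n))
  base <- substring(s, pos, pos)
  alt <- vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  df <- data.frame(chrom = "chr1", pos = pos, ref = base, alt = unname(alt),
                   vaf = round(runif(n, 0.1, 0.6), 3), alt_reads = 10,
                   depth = 30, callers = 3,
                   sample = paste0("s", sample.int(n_samples, n, replace = TRUE)),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("sample", "chrom", "pos")]), ]
  list(genome = genome, catalog = mutation_catalog(df))
}

# brute-force O(n^2) didyma pair scan (full outer enumeration, independent
# of the sweep path)
brute_didyma <- function(catalog, genome, max_imd = 32, vaf_max_diff = 0.1,
                         decompose_runs = FALSE) {
  df <- annotate_catalog(catalog, genome)
  n <- nrow(df)
  d <- abs(outer(df$pos, df$pos, "-"))
  qual <- upper.tri(d) &
    outer(df$sample, df$sample, "==") &
    outer(df$chrom, df$chrom, "==") &
    d >= 1 & d <= max_imd &
    outer(df$apobec %in% TRUE, df$apobec %in% TRUE, "&") &
    outer(df$pyr_strand, df$pyr_strand, "==")
  vd <- abs(outer(df$vaf, df$vaf, "-"))
  qual <- qual & (is.na(vd) | vd <= vaf_max_diff)
  pairs <- which(qual, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(pairs) <- c("row", "col")
  pairs <- pairs[, c("row", "col"), drop = FALSE]
  if (!decompose_runs && nrow(pairs)) {
    # drop pairs in connected components larger than two
    adj <- qual | t(qual)
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (v in seq_len(n)) {
      if (!is.na(comp[v])) next
      cid <- cid + 1L
      queue <- v
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[u])) next
        comp[u] <- cid
        queue <- c(queue, which(adj[u, ] & is.na(comp)))
      }
    }
    sizes <- table(comp[unique(c(pairs[, 1], pairs[, 2]))])
    memb <- as.integer(names(sizes)[sizes == 2])
    pairs <- pairs[comp[pairs[, 1]] %in% memb, , drop = FALSE]
  }
  if (!nrow(pairs)) {
    return(data.frame(pos1 = integer(0), pos2 = integer(0)))
  }
  out <- data.frame(pos1 = df$pos[pairs[, 1]], pos2 = df$pos[pairs[, 2]],
                    sample = df$sample[pairs[, 1]], chrom = df$chrom[pairs[, 1]])
  out[order(out$sample, out$chrom, out$pos1, out$pos2), ]
}

# brute-force per-IMD pair counts for a class
brute_pair_counts <- function(catalog, genome, pair_class, max_imd = 100) {
  df <- annotate_catalog(catalog, genome)
  is_apo <- grepl("^apobec", pair_class)
  same <- grepl("same", pair_class)
  keep <- if (is_apo) df$apobec %in% TRUE else df$nqo %in% TRUE
  df <- df[keep, , drop = FALSE]
  strand <- if (is_apo) df$pyr_strand else df$gua_strand
  counts <- integer(max_imd)
  n <- nrow(df)
  if (n < 2) return(counts)
  d <- abs(outer(df$pos, df$pos, "-"))
  ok <- upper.tri(d) &
    outer(df$sample, df$sample, "==") &
    outer(df$chrom, df$chrom, "==") &
    d >= 1 & d <= max_imd &
    (outer(strand, strand, "==") == same)
  tabulate(d[ok], nbins = max_imd)
}

# brute-force NNLS by active-set enumeration (exact for small k)
brute_nnls <- function(A, b) {
  k <- ncol(A)
  best <- NULL
  best_rss <- Inf
  for (bits in 0:(2^k - 1)) {
    S <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
    x <- numeric(k)
    if (length(S)) {
      cf <- tryCatch(stats::coef(stats::lm.fit(A[, S, drop = FALSE], b)),
                     error = function(e) NULL)
      if (is.null(cf) || anyNA(cf) || any(cf < -1e-9)) next
      x[S] <- pmax(0, cf)
    }
    rss <- sum((b - A %*% x)^2)
    if (rss < best_rss - 1e-9) {
      best_rss <- rss
      best <- x
    }
  }
  best
}
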