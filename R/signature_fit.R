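#' Build an SBS96 mutation count vector
#'
#' @param catalog A [mutation_catalog()].
#' @param genome A \code{DNAStringSet}.
#' @return Named numeric vector of length 96 (names from [sbs96_labels()]),
#'   summing to the number of classifiable SNVs.
#' @export
build_sbs96 <- function(catalog, genome) {
  labs <- sbs96_labels()
  counts <- stats::setNames(numeric(96), labs)
  if (!nrow(catalog)) return(counts)
  ch <- sbs96_channel(catalog, genome)
  tab <- table(factor(ch[!is.na(ch)], levels = labs))
  counts[labs] <- as.numeric(tab)
  counts
}

#' Read a COSMIC-style signature definition matrix
#'
#' First column \code{Type} holds the 96 channel labels (\code{"A[C>A]A"}
#' style); each further column is one signature. Profiles are renormalised
#' to sum to 1.
#'
#' @param path TSV/CSV path.
#' @return Numeric 96 x k matrix, rows ordered as [sbs96_labels()].
#' @export
read_signature_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "", comment.char = "")
  type_col <- which(tolower(names(df)) %in% c("type", "mutationtype", "mutation_type"))[1]
  if (is.na(type_col)) stop("no Type column in signature matrix ", path)
  rn <- as.character(df[[type_col]])
  m <- as.matrix(df[, -type_col, drop = FALSE])
  rownames(m) <- rn
  labs <- sbs96_labels()
  if (!all(labs %in% rn)) stop("signature matrix lacks some of the 96 SBS channels")
  m <- m[labs, , drop = FALSE]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative entries in signature matrix")
  sweep(m, 2, colSums(m), "/")
}

#' A small built-in signature matrix for testing and examples
#'
#' Five synthetic 96-channel profiles shaped after well-known signature
#' classes: an aging-like C>T at CpG profile ("SBS1L"), an APOBEC C>T at TCW
#' profile ("SBS2L"), a tobacco-like C>A profile with transcription-free GG
#' bias ("SBS4L"), a flat clock-like profile ("SBS5L"), and an APOBEC C>G at
#' TCW profile ("SBS13L"). These are stand-ins built from the classes'
#' defining channels, not COSMIC profiles.
#'
#' @return Numeric 96 x 5 matrix with columns summing to 1.
#' @export
example_signature_matrix <- function() {
  labs <- sbs96_labels()
  up <- substr(labs, 1, 1)
  ref <- substr(labs, 3, 3)
  alt <- substr(labs, 5, 5)
  dn <- substr(labs, 7, 7)
  mk <- function(w) w / sum(w)
  sbs1 <- mk(ifelse(ref == "C" & alt == "T" & dn == "G", 1, 0.002))
  sbs2 <- mk(ifelse(ref == "C" & alt == "T" & up == "T" & dn %in% c("A", "T"), 1, 0.002))
  sbs4 <- mk(ifelse(ref == "C" & alt == "A", ifelse(up == "C", 1.5, 0.8), 0.01))
  sbs5 <- mk(rep(1, 96) + 0.3 * (alt == "T"))
  sbs13 <- mk(ifelse(ref == "C" & alt == "G" & up == "T" & dn %in% c("A", "T"), 1, 0.002))
  m <- cbind(SBS1L = sbs1, SBS2L = sbs2, SBS4L = sbs4, SBS5L = sbs5, SBS13L = sbs13)
  rownames(m) <- labs
  m
}

#' Two-pass non-negative least squares signature refitting
#'
#' Pass 1 solves \eqn{\min \|counts - S x\|_2, x \ge 0} over all signatures.
#' Signatures whose relative contribution \eqn{x_i / \sum x} falls strictly
#' below \code{cutoff} are removed, and pass 2 re-solves the NNLS problem
#' over the retained set. Exposures are reported in mutation counts.
#' If pass 1 prunes every signature, the single best pass-1 signature is
#' retained and the result flagged.
#'
#' @param counts Numeric 96-vector of channel counts.
#' @param sigs Numeric 96 x k signature matrix (columns sum to 1).
#' @param cutoff Relative-contribution pruning threshold (default 0.015);
#'   contributions exactly at the cutoff are retained.
#' @return List of class \code{signature_exposure}: \code{exposures} (named,
#'   zero for pruned signatures), \code{relative} (exposure shares),
#'   \code{retained} (names surviving pass 1), \code{residual} (pass-2
#'   L2 reconstruction error), \code{pass1_exposures}, \code{fallback}
#'   (TRUE when all signatures were pruned).
#' @export
fit_two_pass_nnls <- function(counts, sigs, cutoff = 0.015) {
  stopifnot(length(counts) == nrow(sigs), all(counts >= 0), ncol(sigs) >= 1,
            cutoff >= 0, cutoff < 1)
  if (is.null(colnames(sigs))) colnames(sigs) <- paste0("S", seq_len(ncol(sigs)))
  x1 <- .nnls(sigs, counts)
  names(x1) <- colnames(sigs)
  rel1 <- if (sum(x1) > 0) x1 / sum(x1) else x1
  # ties exactly at the cutoff are retained; the epsilon guards the tie
  # against solver round-off
  retained <- names(x1)[rel1 >= cutoff - 1e-9 & x1 > 0]
  fallback <- FALSE
  if (!length(retained)) {
    retained <- names(which.max(x1))
    fallback <- TRUE
  }
  x2 <- .nnls(sigs[, retained, drop = FALSE], counts)
  exposures <- stats::setNames(numeric(ncol(sigs)), colnames(sigs))
  exposures[retained] <- x2
  resid <- sqrt(sum((counts - sigs %*% exposures)^2))
  rel <- if (sum(exposures) > 0) exposures / sum(exposures) else exposures
  structure(list(exposures = exposures, relative = rel, retained = retained,
                 residual = resid, pass1_exposures = x1, fallback = fallback),
            class = "signature_exposure")
}

.nnls <- function(A, b) {
  fit <- pracma::lsqnonneg(as.matrix(A), as.numeric(b))
  fit$x
}

#' Genome/exome size constants for per-megabase burden normalisation
#'
#' Assumed callable territory: 2,723 Mb for mouse whole genomes, 2,800 Mb
#' for human whole genomes, 30 Mb for human whole exomes.
#'
#' @format Named numeric vector (megabases).
#' @export
genome_size_mb <- c(mouse_wgs = 2723, human_wgs = 2800, human_wes = 30)

#' Mutation burden per megabase
#'
#' @param count Non-negative mutation count(s).
#' @param platform One of \code{"mouse_wgs"}, \code{"human_wgs"},
#'   \code{"human_wes"}, or a positive number of megabases.
#' @return \code{count / megabases}.
#' @export
mutations_per_mb <- function(count, platform = "mouse_wgs") {
  stopifnot(all(count >= 0))
  if (is.character(platform)) {
    if (!platform %in% names(genome_size_mb)) {
      stop("unknown platform '", platform, "'; use one of ",
           paste(names(genome_size_mb), collapse = ", "), " or a numeric Mb size")
    }
    mb <- genome_size_mb[[platform]]
  } else {
    stopifnot(is.numeric(platform), platform > 0)
    mb <- platform
  }
  count / mb
}

#' Tabulate a signature fit as a per-sample exposure table
#'
#' @param fit A \code{signature_exposure} from [fit_two_pass_nnls()].
#' @param platform Passed to [mutations_per_mb()].
#' @return data.frame with columns signature, exposure_count,
#'   exposure_per_mb, relative_contribution, retained.
#' @export
exposure_table <- function(fit, platform = "mouse_wgs") {
  data.frame(
    signature = names(fit$exposures),
    exposure_count = unname(fit$exposures),
    exposure_per_mb = unname(mutations_per_mb(fit$exposures, platform)),
    relative_contribution = unname(fit$relative),
    retained = names(fit$exposures) %in% fit$retained,
    row.names = NULL
  )
}
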