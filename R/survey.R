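## Saturation (rarefaction) of gene/transcript discovery and multi-rater
## agreement of genotype-group assignments.

#' Rarefaction curve of feature discovery
#'
#' Subsamples the read-to-feature assignments without replacement at
#' \code{interval}, \code{2*interval}, ... reads and records the mean and sd
#' of the number of distinct features seen over \code{iterations} draws.
#' Seeded and reproducible; the final point at the full read count is exact
#' (sd 0) when it falls on the grid.
#'
#' @param features character vector: the feature (gene or transcript) id of
#'   each full-length read
#' @param interval subsampling step in reads (default 10000)
#' @param iterations draws per subsample size (default 100)
#' @param seed RNG seed
#' @return data.frame: \code{size}, \code{mean_features}, \code{sd_features}
#' @export
rarefy <- function(features, interval = 10000L, iterations = 100L, seed = 1L) {
  stopifnot(interval >= 1, iterations >= 1)
  N <- length(features)
  f <- as.integer(factor(features))
  sizes <- seq.int(interval, N, by = interval)
  set.seed(seed)
  out <- data.frame(size = sizes, mean_features = NA_real_,
                    sd_features = NA_real_)
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    vals <- vapply(seq_len(iterations), function(it) {
      idx <- sample.int(N, s)
      length(unique(f[idx]))
    }, 0L)
    out$mean_features[i] <- mean(vals)
    out$sd_features[i] <- sd(vals)
  }
  out
}

#' Closed-form expected distinct features under subsampling
#'
#' For a feature with \code{n_f} of the \code{N} reads, the chance it is
#' missed by a subsample of size \code{s} is \code{choose(N-n_f, s) /
#' choose(N, s)}; the expectation sums the complements. Used as an
#' independent check of [rarefy()].
#'
#' @param feature_counts reads per feature
#' @param s subsample size
#' @return expected number of distinct features
#' @export
expectedDistinct <- function(feature_counts, s) {
  N <- sum(feature_counts)
  miss <- exp(lchoose(N - feature_counts, s) - lchoose(N, s))
  miss[feature_counts > N - s] <- 0
  sum(1 - miss)
}

#' Fleiss' kappa for multi-rater agreement
#'
#' Standard formula over an n x r table of category labels (subjects x
#' raters): kappa = (Pbar - Pe) / (1 - Pe), with per-subject pairwise
#' agreement and chance agreement from the squared marginal category
#' proportions. Perfect observed agreement returns 1. When every rater
#' always uses one single category the margins are degenerate (Pe = 1) and
#' an error is raised.
#'
#' @param t matrix or data.frame of category labels, rows = subjects,
#'   columns = raters
#' @return kappa
#' @export
fleissKappa <- function(t) {
  t <- as.matrix(t)
  n <- nrow(t); r <- ncol(t)
  stopifnot(n >= 1, r >= 2)
  cats <- sort(unique(as.vector(t)))
  if (length(cats) < 2)
    stop("degenerate margins: all raters use a single category")
  ## subject x category count table
  cnt <- vapply(cats, function(k) rowSums(t == k), numeric(n))
  cnt <- matrix(cnt, nrow = n)
  P_i <- (rowSums(cnt^2) - r) / (r * (r - 1))
  Pbar <- mean(P_i)
  if (Pbar == 1) return(1)
  p_j <- colSums(cnt) / (n * r)
  Pe <- sum(p_j^2)
  if (Pe >= 1) stop("degenerate margins: all raters use a single category")
  (Pbar - Pe) / (1 - Pe)
}

#' Genotype-group membership labels per feature
#'
#' A feature counts as expressed in a sample when it has at least one
#' full-length read. Within a tissue, each feature's category is the subset
#' of genotypes (strains) expressing it, e.g. \code{"B73+B73xKi11"}. These
#' labels are the per-rater categories compared across datasets with
#' [fleissKappa()].
#'
#' @param counts matrix of FL read counts, features x samples
#' @param sheet a [SampleSheet-class]
#' @param tissue tissue to evaluate
#' @return character vector of group labels, one per feature
#' @export
genotypeGroups <- function(counts, sheet, tissue) {
  e <- sheetEntries(sheet)
  e <- e[e$tissue == tissue & e$sample_id %in% colnames(counts), , drop = FALSE]
  strains <- sort(unique(e$strain))
  lab <- character(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    on <- vapply(strains, function(s)
      sum(counts[i, e$sample_id[e$strain == s], drop = FALSE]) >= 1, NA)
    lab[i] <- if (any(on)) paste(strains[on], collapse = "+") else "none"
  }
  lab
}
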