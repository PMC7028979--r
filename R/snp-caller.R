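## Per-gene pileup construction and substitution SNP calling.
##
## At every position with enough pooled coverage the observed count of the
## top non-reference base is tested against the count expected from residual
## sequencing error with a one-sided Fisher's exact test; p values are
## Bonferroni-corrected per gene (the number of positions actually tested).

#' Parameters of the substitution SNP caller
#'
#' @param min_coverage minimum pooled aligned-base coverage to test a
#'   position (default 10)
#' @param alpha significance cutoff on the Bonferroni-adjusted p (default
#'   0.01)
#' @param error_rate residual per-base substitution error rate of the
#'   full-length consensus reads; sets the expected error count
#'   \code{E = max(1, round(N * error_rate))} of the null (default 0.005,
#'   the scale of >= 99\%-accuracy consensus transcripts)
#' @param min_gene_fl_reads minimum full-length reads over the gene for it to
#'   be eligible for calling and phasing (default 40)
#' @return a parameter list
#' @export
snpCallerParams <- function(min_coverage = 10L, alpha = 0.01,
                            error_rate = 0.005, min_gene_fl_reads = 40L) {
  stopifnot(alpha > 0, alpha < 1, error_rate > 0, error_rate < 0.5,
            min_coverage >= 1, min_gene_fl_reads >= 0)
  list(min_coverage = as.integer(min_coverage), alpha = alpha,
       error_rate = error_rate,
       min_gene_fl_reads = as.integer(min_gene_fl_reads))
}

.BASES <- c("A", "C", "G", "T")

#' Build a per-gene base pileup
#'
#' Pools the aligned bases of all reads (all samples together) over a gene
#' region. Only match/mismatch columns contribute: insertions are ignored and
#' a read with a deletion at a position adds nothing there, so coverage is
#' exactly A+C+G+T.
#'
#' @param reads a [FLReadSet-class]
#' @param region list/data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and optionally \code{gene_id}
#' @param genome a \code{DNAStringSet} supplying the reference base per
#'   position
#' @return a [Pileup-class]
#' @export
buildPileup <- function(reads, region, genome) {
  w <- region$end - region$start
  counts <- matrix(0L, w, 4, dimnames = list(NULL, .BASES))
  keep <- which(reads@chrom == region$chrom)
  if (length(keep)) {
    pos <- unlist(reads@pos[keep], use.names = FALSE)
    base <- unlist(strsplit(reads@bases[keep], "", fixed = TRUE), use.names = FALSE)
    inr <- pos >= region$start & pos < region$end
    pos <- pos[inr]; base <- base[inr]
    ok <- base %in% .BASES
    if (any(ok)) {
      idx <- cbind(pos[ok] - region$start + 1L, match(base[ok], .BASES))
      tab <- table(factor(idx[, 1], levels = seq_len(w)),
                   factor(idx[, 2], levels = 1:4))
      counts <- counts + matrix(as.integer(tab), w, 4,
                                dimnames = list(NULL, .BASES))
    }
  }
  refseq <- Biostrings::subseq(genome[[region$chrom]],
                               region$start + 1L, region$end)
  new("Pileup",
      gene_id = if (is.null(region$gene_id)) "" else region$gene_id,
      chrom = region$chrom, start = as.integer(region$start),
      ref = strsplit(as.character(refseq), "")[[1]],
      counts = counts)
}

#' Test one pileup position for a substitution SNP
#'
#' The alternative allele is the most frequent non-reference base (ties go to
#' the lexicographically smallest). Its count \code{n_alt} is compared with
#' the expected error count \code{E = max(1, round(N * error_rate))} by a
#' one-sided Fisher's exact test on the 2x2 table
#' \code{[[n_alt, N - n_alt], [E, N - E]]}: the returned \code{p_raw} is the
#' hypergeometric probability of observing at least \code{n_alt} under the
#' table's margins.
#'
#' @param counts named integer vector (A, C, G, T) at the position
#' @param ref_base the reference base
#' @param error_rate residual error rate
#' @param min_coverage positions with lower pooled coverage are skipped
#' @return list(alt, n_alt, p_raw, messy) or NULL when the position is
#'   skipped (low coverage) or has no alternative base
#' @export
testPosition <- function(counts, ref_base, error_rate = 0.005,
                         min_coverage = 10L) {
  N <- sum(counts)
  if (N < min_coverage) return(NULL)
  alt_counts <- counts[setdiff(.BASES, ref_base)]
  n_alt <- max(alt_counts)
  if (n_alt == 0) return(NULL)
  alt <- names(alt_counts)[alt_counts == n_alt][1]  # lexicographic tie-break
  E <- max(1L, as.integer(round(N * error_rate)))
  ## P(X >= n_alt), X ~ Hypergeometric(white = n_alt+E, black = 2N-n_alt-E, drawn = N)
  p <- phyper(n_alt - 1, m = n_alt + E, n = 2L * N - n_alt - E, k = N,
              lower.tail = FALSE)
  third <- sum(alt_counts) - n_alt
  list(alt = alt, n_alt = as.integer(n_alt), p_raw = p,
       messy = third > n_alt / 2)
}

#' Call substitution SNPs over a gene pileup
#'
#' Tests every position with coverage at least \code{min_coverage} and a
#' non-zero alternative count, Bonferroni-corrects within the gene
#' (\code{p_adj = min(1, p_raw * n_tests)}) and emits the positions with
#' \code{p_adj < alpha}, sorted. Genes with fewer than
#' \code{min_gene_fl_reads} full-length reads are not called and get status
#' \code{"insufficient-coverage"}. Sites where a third base exceeds half the
#' alternative count are flagged \code{messy} and excluded from phasing.
#'
#' @param pileup a [Pileup-class]
#' @param params a [snpCallerParams()] list
#' @param n_fl_reads number of full-length reads over the gene (used for the
#'   eligibility gate)
#' @return a [SNPCallSet-class]
#' @export
callSnps <- function(pileup, params = snpCallerParams(),
                     n_fl_reads = NULL) {
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), nA = integer(), nC = integer(),
                      nG = integer(), nT = integer(), coverage = integer(),
                      p_raw = double(), p_adj = double(), messy = logical())
  if (!is.null(n_fl_reads) && n_fl_reads < params$min_gene_fl_reads)
    return(new("SNPCallSet", calls = empty, n_tests = 0L,
               status = "insufficient-coverage", params = params))
  W <- nrow(pileup@counts)
  res <- vector("list", W)
  tested <- 0L
  for (i in seq_len(W)) {
    t <- testPosition(pileup@counts[i, ], pileup@ref[i],
                      params$error_rate, params$min_coverage)
    if (is.null(t)) next
    tested <- tested + 1L
    res[[i]] <- data.frame(
      chrom = pileup@chrom, pos = pileup@start + i - 1L,
      ref = pileup@ref[i], alt = t$alt,
      nA = pileup@counts[i, "A"], nC = pileup@counts[i, "C"],
      nG = pileup@counts[i, "G"], nT = pileup@counts[i, "T"],
      coverage = sum(pileup@counts[i, ]), p_raw = t$p_raw,
      p_adj = NA_real_, messy = t$messy)
  }
  calls <- do.call(rbind, res)
  if (is.null(calls)) calls <- empty
  if (nrow(calls)) {
    calls$p_adj <- pmin(1, calls$p_raw * tested)
    calls <- calls[calls$p_adj < params$alpha, , drop = FALSE]
    calls <- calls[order(calls$pos), , drop = FALSE]
    rownames(calls) <- NULL
  }
  new("SNPCallSet", calls = calls, n_tests = tested,
      status = if (nrow(calls)) "ok" else "no-SNP", params = params)
}
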