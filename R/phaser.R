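## Haplotype reconstruction from read base-vectors over called SNP sites.
##
## The two allele strings are the pair (h0, h1) minimising the summed
## read-to-nearest-allele mismatch distance, subject to the per-site
## complementarity constraint that h0 and h1 jointly use exactly the site's
## reference and alternative allele. Distances are Hamming counts over each
## read's non-missing sites: reads are anchored by alignment, so the sites
## are fixed coordinates and no indel alignment is involved.

#' Extract the read x SNP base matrix of a gene
#'
#' One row per full-length read, one column per (non-messy) called SNP.
#' Entries are the read's aligned base at the site; \code{NA} where the read
#' does not cover the position or has a deletion there. Bases outside
#' \{ref, alt\} are recorded verbatim (they count as mismatches to both
#' alleles). Reads covering no site are dropped.
#'
#' @param reads a [FLReadSet-class] (reads of one gene)
#' @param calls a [SNPCallSet-class] or its calls data.frame
#' @param isoform optional character vector parallel to \code{reads} carrying
#'   each read's isoform id
#' @return list with \code{mat} (character matrix, rows = reads), \code{qname},
#'   \code{sample}, \code{isoform}, \code{positions}, \code{ref}, \code{alt}
#' @export
extractReadHaplotypes <- function(reads, calls, isoform = NULL) {
  cl <- if (is(calls, "SNPCallSet")) snpCalls(calls) else calls
  if ("messy" %in% names(cl)) cl <- cl[!cl$messy, , drop = FALSE]
  stopifnot(nrow(cl) > 0, !is.unsorted(cl$pos))
  n <- length(reads)
  mat <- matrix(NA_character_, n, nrow(cl))
  for (i in seq_len(n)) mat[i, ] <- baseAt(reads, i, cl$pos)
  keep <- rowSums(!is.na(mat)) > 0
  list(mat = mat[keep, , drop = FALSE],
       qname = reads@qname[keep], sample = reads@sample[keep],
       isoform = if (is.null(isoform)) NULL else isoform[keep],
       positions = cl$pos, ref = cl$ref, alt = cl$alt)
}

## mismatch-to-h0 and -to-h1 distances for assignment matrix A (k x nA, 0 =
## site carries ref on h0). Returns list(D0, D1) of reads x nA matrices.
.pair_distances <- function(M0, M1, O, A) {
  D0 <- M0 %*% A + M1 %*% (1 - A) + O
  D1 <- M0 %*% (1 - A) + M1 %*% A + O
  list(D0 = D0, D1 = D1)
}

.hap_strings <- function(a, ref, alt) {
  h0 <- ifelse(a == 0, ref, alt)
  h1 <- ifelse(a == 0, alt, ref)
  c(paste(h0, collapse = ""), paste(h1, collapse = ""))
}

#' Reconstruct the two dominant haplotypes of a gene
#'
#' Chooses the per-site allele assignment minimising
#' \eqn{\sum_r \min(d(r,h_0), d(r,h_1))} over the reads, where \eqn{d} is the
#' mismatch count over the read's non-missing sites. Up to
#' \code{max_exhaustive} SNPs the \eqn{2^{k-1}} phasings are searched
#' exhaustively; beyond that a greedy search seeded from the two most
#' frequent complete read patterns with per-site majority refinement is used.
#' Ties are broken by higher total assigned-read support, then by the
#' lexicographically smaller haplotype pair. If the best pair still leaves
#' more than 20\% of reads at distance above 20\% of their informative sites
#' the gene is flagged \code{possible-paralog}.
#'
#' @param m a matrix bundle from [extractReadHaplotypes()]
#' @param max_exhaustive SNP-count bound for the exhaustive search
#'   (default 12)
#' @param max_mismatch_frac reads above this mismatch fraction stay
#'   unassigned when computing supports (default 0.5)
#' @return a [HaplotypePair-class] (labels unassigned; see
#'   [labelParentalAlleles()])
#' @export
reconstructTwoHaplotypes <- function(m, max_exhaustive = 12L,
                                     max_mismatch_frac = 0.5) {
  mat <- m$mat
  k <- ncol(mat); n <- nrow(mat)
  stopifnot(k >= 1, n >= 1)
  refm <- matrix(m$ref, n, k, byrow = TRUE)
  altm <- matrix(m$alt, n, k, byrow = TRUE)
  cov <- !is.na(mat)
  M0 <- (mat == refm) & cov; M0[is.na(M0)] <- FALSE
  M1 <- (mat == altm) & cov; M1[is.na(M1)] <- FALSE
  O <- rowSums(cov & !M0 & !M1)
  storage.mode(M0) <- "double"; storage.mode(M1) <- "double"

  if (k <= max_exhaustive) {
    ## all assignments with site 1 fixed to ref on h0 (pair symmetry)
    nA <- 2^(k - 1)
    A <- matrix(0, k, nA)
    if (k > 1) {
      combos <- as.matrix(expand.grid(rep(list(0:1), k - 1)))
      A[2:k, ] <- t(combos)
    }
    d <- .pair_distances(M0, M1, O, A)
    obj <- colSums(pmin(d$D0, d$D1))
    cand <- which(obj == min(obj))
  } else {
    a <- .greedy_phase(mat, m$ref, m$alt, M0, M1, O, cov)
    A <- matrix(a, k, 1)
    cand <- 1L
    d <- .pair_distances(M0, M1, O, A)
  }

  pick <- cand[1]
  if (length(cand) > 1) {
    ## tie-break: total support, then lexicographic pair
    supp <- vapply(cand, function(j) {
      d0 <- d$D0[, j]; d1 <- d$D1[, j]
      inf <- rowSums(cov)
      assigned <- d0 != d1 & inf > 0 & pmin(d0, d1) / pmax(inf, 1) <= max_mismatch_frac
      sum(assigned)
    }, 0)
    cand <- cand[supp == max(supp)]
    if (length(cand) > 1) {
      keys <- vapply(cand, function(j) {
        hs <- sort(.hap_strings(A[, j], m$ref, m$alt))
        paste(hs, collapse = "|")
      }, "")
      cand <- cand[order(keys)]
    }
    pick <- cand[1]
  }
  a <- A[, pick]
  hs <- .hap_strings(a, m$ref, m$alt)
  if (hs[2] < hs[1]) { hs <- rev(hs); a <- 1 - a }

  pair <- new("HaplotypePair",
              positions = as.integer(m$positions), ref = m$ref, alt = m$alt,
              hap0 = hs[1], hap1 = hs[2],
              support0 = 0L, support1 = 0L,
              label0 = "unassigned", label1 = "unassigned",
              flags = character(0))
  asg <- assignReads(m, pair, max_mismatch_frac)
  pair@support0 <- sum(asg$allele == 0L, na.rm = TRUE)
  pair@support1 <- sum(asg$allele == 1L, na.rm = TRUE)
  flags <- character(0)
  if ((pair@support0 == 0L || pair@support1 == 0L) && sum(asg$mismatches) == 0)
    flags <- c(flags, "monomorphic-reads")
  inf <- asg$informative
  far <- inf > 0 & asg$mismatches > 0.2 * inf
  if (mean(far) > 0.2) flags <- c(flags, "possible-paralog")
  pair@flags <- flags
  pair
}

## greedy phasing for many sites: seed from the two most frequent complete
## observed rows, refine by per-site majority among currently assigned reads
.greedy_phase <- function(mat, ref, alt, M0, M1, O, cov) {
  k <- ncol(mat)
  complete <- rowSums(cov) == k & O == 0
  a <- NULL
  if (sum(complete) >= 2) {
    pats <- apply(mat[complete, , drop = FALSE], 1, paste, collapse = "")
    top <- names(sort(table(pats), decreasing = TRUE))
    if (length(top) >= 1) {
      b <- strsplit(top[1], "")[[1]]
      a <- as.numeric(b != ref)
    }
  }
  if (is.null(a)) {
    votes1 <- colSums(M1); votes0 <- colSums(M0)
    a <- as.numeric(votes1 > votes0)
  }
  for (iter in 1:50) {
    A <- matrix(a, k, 1)
    D0 <- (M0 %*% A + M1 %*% (1 - A) + O)[, 1]
    D1 <- (M0 %*% (1 - A) + M1 %*% A + O)[, 1]
    to0 <- D0 < D1; to1 <- D1 < D0
    newa <- a
    for (s in seq_len(k)) {
      v_ref <- sum(M0[to0, s]) + sum(M1[to1, s])
      v_alt <- sum(M1[to0, s]) + sum(M0[to1, s])
      if (v_ref + v_alt > 0) newa[s] <- as.numeric(v_alt > v_ref)
    }
    if (all(newa == a)) break
    a <- newa
  }
  if (a[1] == 1) a <- 1 - a
  a
}

#' Assign each read to its nearer allele
#'
#' A read goes to the haplotype with fewer mismatches over its informative
#' (non-missing) sites. Equidistant reads, reads with no informative site,
#' and reads whose mismatch fraction exceeds \code{max_mismatch_frac} stay
#' unassigned.
#'
#' @param m a bundle from [extractReadHaplotypes()]
#' @param pair a [HaplotypePair-class]
#' @param max_mismatch_frac unassignment threshold (default 0.5)
#' @return data.frame: \code{qname}, \code{sample}, \code{allele} (0, 1 or
#'   NA), \code{mismatches}, \code{informative} (+ \code{isoform} when known)
#' @export
assignReads <- function(m, pair, max_mismatch_frac = 0.5) {
  mat <- m$mat
  n <- nrow(mat); k <- ncol(mat)
  h0 <- strsplit(pair@hap0, "")[[1]]
  h1 <- strsplit(pair@hap1, "")[[1]]
  cov <- !is.na(mat)
  d0 <- rowSums(cov & (mat != matrix(h0, n, k, byrow = TRUE)), na.rm = TRUE)
  d1 <- rowSums(cov & (mat != matrix(h1, n, k, byrow = TRUE)), na.rm = TRUE)
  inf <- rowSums(cov)
  allele <- ifelse(d0 < d1, 0L, ifelse(d1 < d0, 1L, NA_integer_))
  mm <- pmin(d0, d1)
  allele[inf == 0L] <- NA_integer_
  allele[inf > 0L & mm / inf > max_mismatch_frac] <- NA_integer_
  out <- data.frame(qname = m$qname, sample = m$sample,
                    allele = allele, mismatches = as.integer(mm),
                    informative = as.integer(inf))
  if (!is.null(m$isoform)) out$isoform <- m$isoform
  out
}

#' Label the two alleles with their parent of origin
#'
#' Each homozygous parent expresses only its own allele, so the reads of the
#' parent samples vote: the allele with a strict majority of a parent's
#' assigned reads takes that parent's label. If both parents majority-vote
#' the same allele, or a voting parent is tied, the gene is flagged
#' \code{ambiguous-parentage}; if only one parent has assigned reads the
#' other allele is labelled by elimination; with no parental reads at all the
#' pair is flagged \code{hybrid-only} (phasing stays valid, parent-of-origin
#' statistics are skipped).
#'
#' @param pair a [HaplotypePair-class]
#' @param assignments data.frame from [assignReads()]
#' @param sheet a [SampleSheet-class]
#' @return the pair with \code{label0}/\code{label1} set and flags updated
#' @export
labelParentalAlleles <- function(pair, assignments, sheet) {
  e <- sheetEntries(sheet)
  role_of <- setNames(e$role, e$sample_id)
  asg <- assignments[!is.na(assignments$allele), , drop = FALSE]
  asg$role <- role_of[asg$sample]
  votes <- function(r) {
    x <- asg[asg$role == r, , drop = FALSE]
    c(sum(x$allele == 0L), sum(x$allele == 1L))
  }
  vA <- votes("parentA"); vB <- votes("parentB")
  choice <- function(v) {
    if (sum(v) == 0) return(NA_integer_)
    if (v[1] == v[2]) return(-1L)      # tie
    which.max(v) - 1L
  }
  cA <- choice(vA); cB <- choice(vB)
  if (is.na(cA) && is.na(cB)) {
    pair@flags <- union(pair@flags, "hybrid-only")
    return(pair)
  }
  tie <- (!is.na(cA) && cA == -1L) || (!is.na(cB) && cB == -1L)
  same <- !is.na(cA) && !is.na(cB) && cA >= 0 && cB >= 0 && cA == cB
  if (tie || same) {
    pair@flags <- union(pair@flags, "ambiguous-parentage")
    return(pair)
  }
  if (is.na(cA)) cA <- 1L - cB          # by elimination
  if (is.na(cB)) cB <- 1L - cA
  lab <- c("unassigned", "unassigned")
  lab[cA + 1L] <- "parentA"
  lab[cB + 1L] <- "parentB"
  pair@label0 <- lab[1]; pair@label1 <- lab[2]
  pair
}

#' Phase one gene end to end
#'
#' Runs SNP calling, haplotype reconstruction, read assignment and parental
#' labelling for the reads of one gene region.
#'
#' @param reads a [FLReadSet-class] restricted to the gene's reads
#' @param region list with \code{chrom}, \code{start}, \code{end},
#'   \code{gene_id}
#' @param genome a \code{DNAStringSet}
#' @param sheet a [SampleSheet-class]
#' @param params a [snpCallerParams()] list
#' @param isoform optional per-read isoform ids
#' @return a [PhasedGene-class]; status is one of \code{phased},
#'   \code{insufficient-coverage}, \code{no-SNP}, \code{ambiguous-parentage},
#'   \code{hybrid-only}
#' @export
phaseGene <- function(reads, region, genome, sheet,
                      params = snpCallerParams(), isoform = NULL) {
  empty_asg <- data.frame(qname = character(), sample = character(),
                          allele = integer(), mismatches = integer(),
                          informative = integer())
  empty_pair <- new("HaplotypePair", positions = integer(0),
                    ref = character(0), alt = character(0),
                    hap0 = "", hap1 = "", support0 = 0L, support1 = 0L,
                    label0 = "unassigned", label1 = "unassigned",
                    flags = character(0))
  gid <- if (is.null(region$gene_id)) "" else region$gene_id
  pl <- buildPileup(reads, region, genome)
  snps <- callSnps(pl, params, n_fl_reads = length(reads))
  if (snps@status == "insufficient-coverage")
    return(new("PhasedGene", gene_id = gid, pair = empty_pair,
               assignments = empty_asg, status = "insufficient-coverage"))
  usable <- snpCalls(snps)
  usable <- usable[!usable$messy, , drop = FALSE]
  if (!nrow(usable))
    return(new("PhasedGene", gene_id = gid, pair = empty_pair,
               assignments = empty_asg, status = "no-SNP"))
  m <- extractReadHaplotypes(reads, usable, isoform)
  pair <- reconstructTwoHaplotypes(m)
  asg <- assignReads(m, pair)
  pair <- labelParentalAlleles(pair, asg, sheet)
  status <- if ("ambiguous-parentage" %in% pair@flags) "ambiguous-parentage"
    else if ("hybrid-only" %in% pair@flags) "hybrid-only"
    else "phased"
  new("PhasedGene", gene_id = gid, pair = pair, assignments = asg,
      status = status)
}

#' Phase a set of gene regions
#'
#' Driver over [phaseGene()]: selects each region's overlapping reads and
#' phases them in turn.
#'
#' @param reads a [FLReadSet-class] for the whole dataset
#' @param regions data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} (0-based half-open)
#' @param genome a \code{DNAStringSet}
#' @param sheet a [SampleSheet-class]
#' @param params a [snpCallerParams()] list
#' @return named list of [PhasedGene-class], one per region
#' @export
phaseGenes <- function(reads, regions, genome, sheet,
                       params = snpCallerParams()) {
  span_s <- vapply(reads@blocks, function(b) b[1, 1], 0L)
  span_e <- vapply(reads@blocks, function(b) b[nrow(b), 2], 0L)
  out <- vector("list", nrow(regions))
  names(out) <- regions$gene_id
  for (g in seq_len(nrow(regions))) {
    sel <- which(reads@chrom == regions$chrom[g] &
                   span_s < regions$end[g] & span_e > regions$start[g])
    out[[g]] <- phaseGene(reads[sel],
                          list(chrom = regions$chrom[g],
                               start = regions$start[g],
                               end = regions$end[g],
                               gene_id = regions$gene_id[g]),
                          genome, sheet, params)
  }
  out
}
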