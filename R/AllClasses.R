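#' @import methods
#' @importFrom stats phyper pbinom fisher.test binom.test t.test rbinom
#'   rmultinom rnorm rgeom runif setNames sd
#' @importFrom utils read.delim write.table head tail
NULL

#' Sample sheet for a reciprocal-hybrid design
#'
#' Maps each multiplexed sample to its strain, tissue, replicate and role in
#' the cross. The design has two homozygous parents and the two reciprocal F1
#' hybrids; role \code{"hybridAB"} means the \code{parentA} strain is the
#' maternal parent, \code{"hybridBA"} the reverse.
#'
#' @slot entries a \code{data.frame} with columns \code{sample_id},
#'   \code{strain}, \code{tissue}, \code{replicate}, \code{role}. Roles are
#'   one of \code{parentA}, \code{parentB}, \code{hybridAB}, \code{hybridBA}.
#'
#' @seealso [readSampleSheet()], [defaultSampleSheet()]
#' @export
setClass("SampleSheet", representation(entries = "data.frame"))

.valid_roles <- c("parentA", "parentB", "hybridAB", "hybridBA")

setValidity("SampleSheet", function(object) {
  e <- object@entries
  need <- c("sample_id", "strain", "tissue", "replicate", "role")
  if (!all(need %in% names(e)))
    return(paste("missing columns:", paste(setdiff(need, names(e)), collapse = ", ")))
  if (anyDuplicated(e$sample_id))
    return("sample_ids must be unique")
  if (!all(e$role %in% .valid_roles))
    return(paste("invalid role(s):", paste(setdiff(e$role, .valid_roles), collapse = ", ")))
  for (r in c("parentA", "parentB")) {
    st <- unique(e$strain[e$role == r])
    if (length(st) > 1)
      return(sprintf("role %s maps to more than one strain (%s)", r, paste(st, collapse = ", ")))
  }
  TRUE
})

#' Set of aligned full-length reads
#'
#' One record per primary alignment of a full-length transcript read.
#' Coordinates are 0-based half-open throughout. For each read the object
#' stores its alignment blocks (match segments on the reference), the derived
#' splice-junction chain, and the aligned base at every reference position
#' covered by a match/mismatch column -- insertions and deletions contribute
#' no base, so a position under a deletion is simply absent from \code{pos}.
#'
#' @slot qname read identifiers
#' @slot sample sample of origin (resolved from the RG tag or read-name prefix)
#' @slot chrom,strand alignment location
#' @slot blocks list of two-column integer matrices (start, end), 0-based
#'   half-open, one row per alignment block
#' @slot pos list of integer vectors: reference positions with an aligned base
#' @slot bases character vector of base strings, parallel to \code{pos}
#' @export
setClass("FLReadSet", representation(
  qname = "character", sample = "character", chrom = "character",
  strand = "character", blocks = "list", pos = "list", bases = "character"))

setValidity("FLReadSet", function(object) {
  n <- length(object@qname)
  lens <- c(length(object@sample), length(object@chrom), length(object@strand),
            length(object@blocks), length(object@pos), length(object@bases))
  if (!all(lens == n)) return("slot lengths differ")
  if (n && !all(nchar(object@bases) == lengths(object@pos)))
    return("bases string length must equal number of aligned positions")
  TRUE
})

#' Non-redundant transcript models from junction-chain collapse
#'
#' @slot info per-model table: \code{id} (PB.X.Y), \code{gene_id} (PB.X),
#'   \code{chrom}, \code{strand}, \code{start}, \code{end}, \code{n_exons}
#' @slot exons list of two-column matrices (start, end), 0-based half-open
#' @slot counts integer matrix of full-length read support, models x samples
#' @export
setClass("TranscriptModelSet", representation(
  info = "data.frame", exons = "list", counts = "matrix"))

setValidity("TranscriptModelSet", function(object) {
  n <- nrow(object@info)
  if (length(object@exons) != n || nrow(object@counts) != n)
    return("info, exons and counts must agree in length")
  for (i in seq_len(n)) {
    ex <- object@exons[[i]]
    if (any(ex[, 2] <= ex[, 1])) return(sprintf("model %d has an empty exon", i))
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2]))
      return(sprintf("model %d exons overlap or are unsorted", i))
  }
  if (any(object@counts < 0)) return("negative FL counts")
  TRUE
})

#' Per-gene base pileup over aligned full-length reads
#'
#' Counts only match/mismatch-aligned bases, pooled across all samples;
#' insertions are ignored and deletion columns contribute nothing, so
#' coverage at a position is exactly A+C+G+T.
#'
#' @slot gene_id gene locus identifier
#' @slot chrom,start region location (start 0-based)
#' @slot ref reference base per position
#' @slot counts integer matrix, positions x 4 (columns A, C, G, T)
#' @export
setClass("Pileup", representation(
  gene_id = "character", chrom = "character", start = "integer",
  ref = "character", counts = "matrix"))

setValidity("Pileup", function(object) {
  if (nrow(object@counts) != length(object@ref))
    return("counts rows must match ref length")
  if (!identical(colnames(object@counts), c("A", "C", "G", "T")))
    return("counts columns must be A, C, G, T")
  if (any(object@counts < 0)) return("negative counts")
  TRUE
})

#' Substitution SNP calls for one gene
#'
#' @slot calls data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}, \code{nA}, \code{nC}, \code{nG}, \code{nT},
#'   \code{coverage}, \code{p_raw}, \code{p_adj}, \code{messy}
#' @slot n_tests number of positions actually tested in the gene (the
#'   Bonferroni denominator)
#' @slot status \code{"ok"}, \code{"insufficient-coverage"} or \code{"no-SNP"}
#' @slot params the [snpCallerParams()] used
#' @export
setClass("SNPCallSet", representation(
  calls = "data.frame", n_tests = "integer", status = "character",
  params = "list"))

setValidity("SNPCallSet", function(object) {
  cl <- object@calls
  if (nrow(cl)) {
    if (any(cl$ref == cl$alt)) return("ref and alt must differ")
    bad <- abs(cl$p_adj - pmin(1, cl$p_raw * object@n_tests)) > 1e-12
    if (any(bad)) return("p_adj must equal min(1, p_raw * n_tests)")
    if (is.unsorted(cl$pos)) return("calls must be sorted by position")
  }
  TRUE
})

#' The two reconstructed allele haplotypes of a gene
#'
#' \code{hap0}/\code{hap1} are strings over the called SNP positions. At every
#' site the pair jointly uses exactly the site's reference and alternative
#' allele, so one haplotype determines the other.
#'
#' @slot positions SNP positions (0-based), ascending
#' @slot ref,alt site alleles
#' @slot hap0,hap1 allele strings, length = number of SNPs
#' @slot support0,support1 reads assigned to each haplotype
#' @slot label0,label1 parent-of-origin labels: \code{parentA},
#'   \code{parentB} or \code{unassigned}
#' @slot flags diagnostic flags (\code{monomorphic-reads},
#'   \code{ambiguous-parentage}, \code{hybrid-only}, \code{possible-paralog})
#' @export
setClass("HaplotypePair", representation(
  positions = "integer", ref = "character", alt = "character",
  hap0 = "character", hap1 = "character",
  support0 = "integer", support1 = "integer",
  label0 = "character", label1 = "character", flags = "character"))

setValidity("HaplotypePair", function(object) {
  k <- length(object@positions)
  if (nchar(object@hap0) != k || nchar(object@hap1) != k)
    return("haplotype length must equal number of SNP positions")
  if (k > 0) {
    h0 <- strsplit(object@hap0, "")[[1]]
    h1 <- strsplit(object@hap1, "")[[1]]
    if (identical(h0, h1)) return("hap0 and hap1 must differ")
    ok <- (h0 == object@ref & h1 == object@alt) |
          (h0 == object@alt & h1 == object@ref)
    if (!all(ok)) return("each site must use exactly the ref and alt alleles")
  }
  if (object@label0 != "unassigned" && object@label0 == object@label1)
    return("parental labels must be distinct")
  TRUE
})

#' A fully phased gene: haplotype pair, read assignments and status
#'
#' @slot gene_id gene locus identifier
#' @slot pair the [HaplotypePair-class]
#' @slot assignments data.frame: \code{qname}, \code{sample}, \code{allele}
#'   (0, 1 or NA), \code{mismatches}, \code{informative}
#' @slot status one of \code{phased}, \code{insufficient-coverage},
#'   \code{no-SNP}, \code{ambiguous-parentage}, \code{hybrid-only}
#' @export
setClass("PhasedGene", representation(
  gene_id = "character", pair = "HaplotypePair",
  assignments = "data.frame", status = "character"))

#' Allelic full-length read counts per feature and sample
#'
#' @slot table data.frame keyed by (\code{feature_id}, \code{sample_id}) with
#'   \code{level} (gene/isoform), \code{tissue}, \code{role},
#'   \code{n_parentA}, \code{n_parentB}, \code{n_unassigned}
#' @slot labeled whether alleles carry parent-of-origin labels; when FALSE the
#'   columns are allele0/allele1 counts and parent-of-origin statistics are
#'   disabled
#' @export
setClass("AllelicCounts", representation(table = "data.frame", labeled = "logical"))

setValidity("AllelicCounts", function(object) {
  t <- object@table
  need <- c("feature_id", "level", "sample_id", "tissue", "role",
            "n_parentA", "n_parentB", "n_unassigned")
  if (!all(need %in% names(t)))
    return(paste("missing columns:", paste(setdiff(need, names(t)), collapse = ", ")))
  if (nrow(t) && any(t$n_parentA < 0 | t$n_parentB < 0 | t$n_unassigned < 0))
    return("negative counts")
  TRUE
})
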