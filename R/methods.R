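#' @describeIn SampleSheet-class number of samples
#' @param x a \code{SampleSheet}
#' @export
setMethod("length", "SampleSheet", function(x) nrow(x@entries))

#' Sample identifiers
#' @param x a \code{SampleSheet} or \code{FLReadSet}
#' @return character vector of sample ids
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SampleSheet", function(x) x@entries$sample_id)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "FLReadSet", function(x) unique(x@sample))

#' Sheet entries as a data.frame
#' @param x a \code{SampleSheet}
#' @export
setGeneric("sheetEntries", function(x) standardGeneric("sheetEntries"))

#' @rdname sheetEntries
#' @export
setMethod("sheetEntries", "SampleSheet", function(x) x@entries)

#' Strain playing a given role
#' @param x a \code{SampleSheet}
#' @param role \code{"parentA"} or \code{"parentB"}
#' @export
strainOfRole <- function(x, role) {
  stopifnot(is(x, "SampleSheet"))
  st <- unique(x@entries$strain[x@entries$role == role])
  if (!length(st)) NA_character_ else st
}

#' Maternal parent role of a hybrid role
#'
#' By convention \code{hybridAB} has \code{parentA} as the maternal strain.
#' @param role \code{"hybridAB"} or \code{"hybridBA"}
#' @return \code{"parentA"} or \code{"parentB"}
#' @export
maternalRole <- function(role) {
  stopifnot(all(role %in% c("hybridAB", "hybridBA")))
  ifelse(role == "hybridAB", "parentA", "parentB")
}

setMethod("show", "SampleSheet", function(object) {
  e <- object@entries
  cat(sprintf("SampleSheet with %d samples (%s)\n", nrow(e),
              paste(sprintf("%s=%d", .valid_roles, tabulate(factor(e$role, .valid_roles), 4)),
                    collapse = ", ")))
  cat(sprintf("  strains: parentA=%s parentB=%s; tissues: %s\n",
              strainOfRole(object, "parentA"), strainOfRole(object, "parentB"),
              paste(unique(e$tissue), collapse = ", ")))
})

#' @describeIn FLReadSet-class number of reads
#' @param x a \code{FLReadSet}
#' @export
setMethod("length", "FLReadSet", function(x) length(x@qname))

#' @describeIn FLReadSet-class subset reads
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "FLReadSet", function(x, i, j, ..., drop = FALSE) {
  new("FLReadSet", qname = x@qname[i], sample = x@sample[i],
      chrom = x@chrom[i], strand = x@strand[i], blocks = x@blocks[i],
      pos = x@pos[i], bases = x@bases[i])
})

setMethod("show", "FLReadSet", function(object) {
  cat(sprintf("FLReadSet with %d reads from %d sample(s) on %s\n",
              length(object), length(unique(object@sample)),
              paste(unique(object@chrom), collapse = ",")))
})

#' Splice-junction chain of one read
#'
#' Introns implied by the gaps between alignment blocks, as a two-column
#' matrix (start, end), 0-based half-open over the intron.
#' @param x a \code{FLReadSet}
#' @param i read index
#' @export
readJunctions <- function(x, i) {
  b <- x@blocks[[i]]
  if (nrow(b) < 2) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  cbind(start = b[-nrow(b), 2], end = b[-1, 1])
}

#' Aligned base of a read at a reference position
#' @param x a \code{FLReadSet}
#' @param i read index
#' @param at 0-based reference position(s)
#' @return one character per position; \code{NA} where the read has no aligned
#'   base (not covered, or a deletion)
#' @export
baseAt <- function(x, i, at) {
  idx <- match(at, x@pos[[i]])
  out <- rep(NA_character_, length(at))
  hit <- !is.na(idx)
  if (any(hit)) out[hit] <- substring(x@bases[i], idx[hit], idx[hit])
  out
}

#' @describeIn TranscriptModelSet-class number of models
#' @param x a \code{TranscriptModelSet}
#' @export
setMethod("length", "TranscriptModelSet", function(x) nrow(x@info))

#' Model metadata table
#' @param x a \code{TranscriptModelSet}
#' @export
setGeneric("modelInfo", function(x) standardGeneric("modelInfo"))

#' @rdname modelInfo
#' @export
setMethod("modelInfo", "TranscriptModelSet", function(x) x@info)

#' Per-sample full-length read support
#' @param x a \code{TranscriptModelSet}
#' @export
setGeneric("flCounts", function(x) standardGeneric("flCounts"))

#' @rdname flCounts
#' @export
setMethod("flCounts", "TranscriptModelSet", function(x) x@counts)

#' Exon structure of one model
#' @param x a \code{TranscriptModelSet}
#' @param i model index or id
#' @export
modelExons <- function(x, i) {
  if (is.character(i)) i <- match(i, x@info$id)
  x@exons[[i]]
}

setMethod("show", "TranscriptModelSet", function(object) {
  cat(sprintf("TranscriptModelSet: %d models over %d loci, %d FL reads\n",
              length(object), length(unique(object@info$gene_id)),
              sum(object@counts)))
})

#' Per-position coverage of a pileup
#' @param x a \code{Pileup}
#' @export
pileupCoverage <- function(x) rowSums(x@counts)

setMethod("show", "Pileup", function(object) {
  cov <- pileupCoverage(object)
  cat(sprintf("Pileup for %s (%s:%d-%d): median coverage %g\n",
              object@gene_id, object@chrom, object@start,
              object@start + length(object@ref), stats::median(cov)))
})

#' @describeIn SNPCallSet-class number of calls
#' @param x a \code{SNPCallSet}
#' @export
setMethod("length", "SNPCallSet", function(x) nrow(x@calls))

#' SNP calls as a data.frame
#' @param x a \code{SNPCallSet}
#' @export
setGeneric("snpCalls", function(x) standardGeneric("snpCalls"))

#' @rdname snpCalls
#' @export
setMethod("snpCalls", "SNPCallSet", function(x) x@calls)

setMethod("show", "SNPCallSet", function(object) {
  cat(sprintf("SNPCallSet: %d substitution call(s), %d position(s) tested, status %s\n",
              nrow(object@calls), object@n_tests, object@status))
})

#' Haplotype strings of a pair
#' @param x a \code{HaplotypePair}
#' @return character(2)
#' @export
haplotypes <- function(x) c(x@hap0, x@hap1)

#' Parental labels of a pair
#' @param x a \code{HaplotypePair} or \code{PhasedGene}
#' @export
parentalLabels <- function(x) {
  if (is(x, "PhasedGene")) x <- x@pair
  c(x@label0, x@label1)
}

setMethod("show", "HaplotypePair", function(object) {
  cat(sprintf("HaplotypePair over %d SNP site(s)\n", length(object@positions)))
  cat(sprintf("  hap0 %s  support %d  label %s\n", object@hap0, object@support0, object@label0))
  cat(sprintf("  hap1 %s  support %d  label %s\n", object@hap1, object@support1, object@label1))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "PhasedGene", function(object) {
  cat(sprintf("PhasedGene %s [%s]: %d reads, %d assigned\n",
              object@gene_id, object@status, nrow(object@assignments),
              sum(!is.na(object@assignments$allele))))
})

#' Allelic count table as a data.frame
#' @param x an \code{AllelicCounts}
#' @export
setGeneric("countTable", function(x) standardGeneric("countTable"))

#' @rdname countTable
#' @export
setMethod("countTable", "AllelicCounts", function(x) x@table)

setMethod("show", "AllelicCounts", function(object) {
  cat(sprintf("AllelicCounts: %d feature x sample rows (%s, %s alleles)\n",
              nrow(object@table),
              paste(unique(object@table$level), collapse = "/"),
              if (object@labeled) "parent-labeled" else "unlabeled"))
})
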