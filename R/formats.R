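#' Read a sample sheet
#'
#' Tab-separated file with header columns \code{sample_id}, \code{strain},
#' \code{tissue}, \code{replicate}, \code{role}. Validity (unique ids, one
#' strain per parent role, known roles) is enforced by the
#' [SampleSheet-class] validity method.
#'
#' @param path TSV file
#' @return a [SampleSheet-class]
#' @export
readSampleSheet <- function(path) {
  e <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  SampleSheet(e)
}

#' Construct a sample sheet from a data.frame
#' @param entries data.frame with the sheet columns
#' @rdname readSampleSheet
#' @export
SampleSheet <- function(entries) {
  entries$sample_id <- as.character(entries$sample_id)
  entries$strain <- as.character(entries$strain)
  entries$tissue <- as.character(entries$tissue)
  entries$role <- as.character(entries$role)
  new("SampleSheet", entries = entries)
}

#' The standard 12-sample reciprocal-hybrid design
#'
#' Two inbred parents and their two reciprocal F1 hybrids, each sampled in
#' three tissues (embryo, endosperm, root): 12 samples.
#'
#' @param strainA,strainB parent strain names
#' @param tissues tissue names
#' @return a [SampleSheet-class]
#' @export
defaultSampleSheet <- function(strainA = "B73", strainB = "Ki11",
                               tissues = c("embryo", "endosperm", "root")) {
  roles <- c("parentA", "parentB", "hybridAB", "hybridBA")
  strains <- c(strainA, strainB,
               paste0(strainA, "x", strainB), paste0(strainB, "x", strainA))
  e <- expand.grid(role = roles, tissue = tissues, stringsAsFactors = FALSE)
  e$strain <- strains[match(e$role, roles)]
  e$replicate <- 1L
  e$sample_id <- paste(e$strain, e$tissue, sep = ".")
  SampleSheet(e[, c("sample_id", "strain", "tissue", "replicate", "role")])
}

.resolve_sample <- function(qname, rg, sheet) {
  ids <- sampleIds(sheet)
  smp <- rg
  miss <- is.na(smp) | !(smp %in% ids)
  if (any(miss)) {
    pref <- sub("/.*$", "", qname[miss])
    smp[miss] <- ifelse(pref %in% ids, pref, NA_character_)
  }
  bad <- is.na(smp) | !(smp %in% ids)
  if (any(bad))
    stop("cannot resolve sample for read(s): ",
         paste(head(qname[bad], 5), collapse = ", "),
         if (sum(bad) > 5) sprintf(" (and %d more)", sum(bad) - 5))
  smp
}

#' Read full-length transcript alignments
#'
#' Loads primary alignments from a SAM or BAM file and resolves each read to a
#' sample in the sheet, via the \code{RG} tag when present, else a
#' \code{"sample_id/"} read-name prefix. Secondary and supplementary
#' alignments are dropped; unmapped reads are skipped with a message. The
#' splice-junction chain is taken from the alignment \code{N} gap operations,
#' and aligned bases are recorded only for match/mismatch columns, so
#' deletions leave no base at their reference positions.
#'
#' @param path SAM or BAM file (SAM is converted on the fly)
#' @param sheet a [SampleSheet-class]
#' @return a [FLReadSet-class]; coordinates 0-based half-open
#' @export
readAlignments <- function(path, sheet) {
  stopifnot(is(sheet, "SampleSheet"))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  flag0 <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  n_unmapped <- Rsamtools::countBam(
    path, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))$records
  if (n_unmapped > 0)
    message(n_unmapped, " unmapped read(s) skipped")
  param <- Rsamtools::ScanBamParam(flag = flag0, what = c("qname", "seq"),
                                   tag = "RG")
  gal <- GenomicAlignments::readGAlignments(path, param = param)
  n <- length(gal)
  mc <- S4Vectors::mcols(gal)
  rg <- if ("RG" %in% names(mc)) as.character(mc$RG) else rep(NA_character_, n)
  smp <- .resolve_sample(mc$qname, rg, sheet)

  cig <- GenomicAlignments::cigar(gal)
  starts <- BiocGenerics::start(gal)
  # parallel decomposition of aligned (M/=/X) segments on reference and query
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = starts, ops = c("M", "=", "X"))
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = c("M", "=", "X"))
  seqs <- as.character(mc$seq)

  jl <- GenomicAlignments::junctions(gal)
  pos <- vector("list", n)
  bases <- character(n)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    rs <- BiocGenerics::start(rr[[i]]); re <- BiocGenerics::end(rr[[i]])
    qs <- BiocGenerics::start(qr[[i]]); qe <- BiocGenerics::end(qr[[i]])
    pos[[i]] <- unlist(Map(seq.int, rs, re), use.names = FALSE) - 1L
    bases[i] <- paste(substring(seqs[i], qs, qe), collapse = "")
    js <- jl[[i]]
    bs <- c(starts[i], BiocGenerics::end(js) + 1L)
    be <- c(BiocGenerics::start(js) - 1L, BiocGenerics::end(gal)[i])
    blocks[[i]] <- cbind(start = bs - 1L, end = be)
  }
  new("FLReadSet",
      qname = as.character(mc$qname), sample = smp,
      chrom = as.character(GenomeInfoDb::seqnames(gal)),
      strand = as.character(BiocGenerics::strand(gal)),
      blocks = blocks, pos = pos, bases = bases)
}

#' Write substitution SNP calls as VCF 4.2
#'
#' Internal 0-based positions become 1-based \code{POS}. INFO carries the
#' pooled coverage and per-base counts; when per-sample allele depths are
#' supplied a \code{FORMAT/AD} column per sample is added.
#'
#' @param x a [SNPCallSet-class] or the \code{calls} data.frame of one
#' @param reference_name name of the reference assembly for the header
#' @param path output file
#' @param sample_ad optional character matrix of "ref,alt" allele depths,
#'   rows parallel to the calls, columns named by sample
#' @export
writeSnpVcf <- function(x, reference_name, path, sample_ad = NULL) {
  calls <- if (is(x, "SNPCallSet")) snpCalls(x) else x
  n_tests <- if (is(x, "SNPCallSet")) x@n_tests else unique(calls$n_tests)
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls))))
      stop("calls must be sorted by (chrom, position)")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=isohap-", as.character(utils::packageVersion("isohap"))),
    paste0("##reference=", reference_name),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pooled FL read coverage\">",
    "##INFO=<ID=BASECOUNTS,Number=4,Type=Integer,Description=\"Aligned base counts A,C,G,T\">",
    "##INFO=<ID=PRAW,Number=1,Type=Float,Description=\"Raw one-sided Fisher p\">",
    "##INFO=<ID=PADJ,Number=1,Type=Float,Description=\"Bonferroni-adjusted p (per gene)\">",
    "##INFO=<ID=NTESTS,Number=1,Type=Integer,Description=\"Positions tested in the gene\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(sample_ad)) {
    hdr <- c(hdr,
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"FL read depth per allele\">")
    cols <- c(cols, "FORMAT", colnames(sample_ad))
  }
  lines <- c(hdr, paste(cols, collapse = "\t"))
  if (nrow(calls)) {
    info <- sprintf("DP=%d;BASECOUNTS=%d,%d,%d,%d;PRAW=%.6g;PADJ=%.6g;NTESTS=%d",
                    calls$coverage, calls$nA, calls$nC, calls$nG, calls$nT,
                    calls$p_raw, calls$p_adj,
                    if (length(n_tests)) rep(n_tests, nrow(calls)) else calls$n_tests)
    body <- paste(calls$chrom, calls$pos + 1L, ".", calls$ref, calls$alt,
                  ".", "PASS", info, sep = "\t")
    if (!is.null(sample_ad))
      body <- paste(body, "AD", apply(sample_ad, 1, paste, collapse = "\t"),
                    sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a VCF written by [writeSnpVcf()]
#'
#' @param path VCF file
#' @return data.frame with 0-based \code{pos}, alleles, base counts and p
#'   values
#' @export
readSnpVcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), nA = integer(), nC = integer(),
                      nG = integer(), nT = integer(), coverage = integer(),
                      p_raw = double(), p_adj = double(), n_tests = integer())
  if (!length(body)) return(empty)
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, `[[`, "", 8L)
  g1 <- function(key, conv) conv(sub(sprintf(".*%s=([^;]+).*", key), "\\1", info))
  bc <- strsplit(g1("BASECOUNTS", identity), ",", fixed = TRUE)
  bc <- matrix(as.integer(unlist(bc)), ncol = 4, byrow = TRUE)
  data.frame(
    chrom = vapply(f, `[[`, "", 1L),
    pos = as.integer(vapply(f, `[[`, "", 2L)) - 1L,
    ref = vapply(f, `[[`, "", 4L), alt = vapply(f, `[[`, "", 5L),
    nA = bc[, 1], nC = bc[, 2], nG = bc[, 3], nT = bc[, 4],
    coverage = g1("DP", as.integer),
    p_raw = g1("PRAW", as.numeric), p_adj = g1("PADJ", as.numeric),
    n_tests = g1("NTESTS", as.integer))
}

#' Read a gene x sample expression matrix
#'
#' First column gene id, remaining columns \code{sample.rep} identifiers.
#' Rejects duplicate gene ids, missing cells and negative values, naming the
#' offending record.
#'
#' @param path TSV file
#' @return numeric matrix with gene rownames
#' @export
readExpressionMatrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                  check.names = FALSE)
  genes <- as.character(d[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene id: ", genes[duplicated(genes)][1])
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/non-numeric value at gene %s, column %s",
                 genes[bad[1]], colnames(m)[bad[2]]))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at gene %s, column %s",
                 genes[bad[1]], colnames(m)[bad[2]]))
  }
  m
}

#' Write an expression matrix in the format [readExpressionMatrix()] accepts
#' @param m numeric matrix with gene rownames
#' @param path output TSV
#' @export
writeExpressionMatrix <- function(m, path) {
  d <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a short-read splice-junction support table
#'
#' TSV with columns chrom, start, end, strand, count; intron coordinates
#' 0-based half-open. Counts below 1 are rejected.
#'
#' @param path TSV file
#' @return data.frame with a precomputed lookup key
#' @export
readJunctionSupport <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#",
                  col.names = c("chrom", "start", "end", "strand", "count"))
  if (nrow(d) && is.na(suppressWarnings(as.integer(d$start[1]))))
    d <- d[-1, , drop = FALSE]                   # tolerate a header line
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  d$count <- as.integer(d$count)
  if (any(d$count < 1))
    stop("junction support counts must be >= 1 (offending intron ",
         d$chrom[d$count < 1][1], ":", d$start[d$count < 1][1], ")")
  d$key <- junctionKey(d$chrom, d$start, d$end, d$strand)
  d
}

#' @rdname readJunctionSupport
#' @param chrom,start,end,strand intron coordinates (0-based half-open)
#' @export
junctionKey <- function(chrom, start, end, strand) {
  paste(chrom, start, end, strand, sep = ":")
}

#' Write a headered TSV
#'
#' All tabular outputs carry a leading '#' line naming the tool version and
#' the parameters used.
#'
#' @param d data.frame
#' @param path output file
#' @param params named list echoed into the header
#' @export
writeHeaderedTsv <- function(d, path, params = list()) {
  p <- if (length(params))
    paste(names(params), vapply(params, function(v) paste(v, collapse = ","), ""),
          sep = "=", collapse = " ") else ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# isohap %s %s",
                     as.character(utils::packageVersion("isohap")), p), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
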