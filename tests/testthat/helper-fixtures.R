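# Small in-code fixtures shared across the suite.

# one-tissue four-sample reciprocal design
four_sample_sheet <- function() {
  SampleSheet(data.frame(
    sample_id = c("pA", "pB", "hAB", "hBA"),
    strain = c("A", "B", "AxB", "BxA"),
    tissue = "embryo", replicate = 1L,
    role = c("parentA", "parentB", "hybridAB", "hybridBA")))
}

# build a FLReadSet by hand from exon-block specs; bases default to "A" runs
make_reads <- function(blocks, samples, bases = NULL, chrom = "chr1",
                       strand = "+", qname = NULL) {
  n <- length(blocks)
  pos <- lapply(blocks, function(b)
    unlist(Map(seq.int, b[, 1], b[, 2] - 1L), use.names = FALSE))
  if (is.null(bases))
    bases <- vapply(pos, function(p) paste(rep("A", length(p)), collapse = ""), "")
  if (is.null(qname)) qname <- sprintf("r%03d", seq_len(n))
  new("FLReadSet", qname = qname,
      sample = rep_len(samples, n), chrom = rep_len(chrom, n),
      strand = rep_len(strand, n), blocks = blocks, pos = pos, bases = bases)
}

blk <- function(...) {
  v <- c(...)
  matrix(as.integer(v), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("start", "end")))
}

# minimal annotation catalog built from explicit transcript exon structures
make_catalog <- function(txs) {
  # txs: list of list(id, gene, chrom, strand, exons = blk(...))
  feats <- GenomicRanges::GRanges()
  for (t in txs) {
    tx <- GenomicRanges::GRanges(t$chrom,
      IRanges::IRanges(min(t$exons[, 1]) + 1L, max(t$exons[, 2])),
      strand = t$strand)
    S4Vectors::mcols(tx) <- S4Vectors::DataFrame(type = "mRNA", ID = t$id,
                                                 Parent = t$gene)
    ex <- GenomicRanges::GRanges(t$chrom,
      IRanges::IRanges(t$exons[, 1] + 1L, t$exons[, 2]), strand = t$strand)
    S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
      type = "exon", ID = paste0(t$id, ".e", seq_along(ex)), Parent = t$id)
    feats <- c(feats, tx, ex)
  }
  indexAnnotation(feats)
}
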