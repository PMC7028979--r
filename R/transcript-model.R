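## Collapse of aligned full-length reads into non-redundant transcript models,
## structural classification against a reference annotation, and the artifact
## retention rules. All coordinates 0-based half-open.

.junctions_of <- function(exons) {
  if (nrow(exons) < 2)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  cbind(start = exons[-nrow(exons), 2], end = exons[-1, 1])
}

.chain_str <- function(jmat) {
  if (!nrow(jmat)) return("")
  paste(jmat[, 1], jmat[, 2], sep = "-", collapse = ",")
}

#' Coverage/identity filter for transcript alignments
#'
#' Keeps an alignment iff aligned query bases / query length meets the
#' coverage bound and matches / aligned columns meets the identity bound,
#' both inclusive. Defaults 0.99 and 0.95.
#'
#' @param query_length full read length(s)
#' @param aligned_query_bases query bases consumed by the alignment
#' @param matches matching columns
#' @param aligned_columns total aligned (match + mismatch) columns
#' @param min_coverage,min_identity inclusive thresholds
#' @return logical vector: keep
#' @export
filterAlignment <- function(query_length, aligned_query_bases, matches,
                            aligned_columns, min_coverage = 0.99,
                            min_identity = 0.95) {
  if (any(query_length <= 0)) stop("zero-length query")
  (aligned_query_bases / query_length >= min_coverage) &
    (matches / aligned_columns >= min_identity)
}

#' Collapse aligned transcripts into non-redundant models by junction chain
#'
#' Multi-exon transcripts sharing an identical splice-junction chain on the
#' same strand merge into one model whose terminal exons take the union span.
#' With \code{merge_5prime_shorter = FALSE} (the default) a transcript whose
#' chain is a strict 5'-truncated suffix of a longer chain stays a separate
#' model. Mono-exon transcripts merge by same-strand overlap. Locus ids
#' (\code{PB.X}) are same-strand overlap connected components of the models;
#' isoform ids within a locus are assigned by descending total FL count, ties
#' broken by leftmost start then lexicographic chain.
#'
#' @param reads a [FLReadSet-class] of kept alignments (one count each)
#' @param merge_5prime_shorter merge 5'-truncated chains into their parent
#' @param samples sample universe for the count matrix columns (defaults to
#'   the samples present)
#' @return a [TranscriptModelSet-class]
#' @export
collapseByJunctions <- function(reads, merge_5prime_shorter = FALSE,
                                samples = NULL) {
  n <- length(reads)
  if (is.null(samples)) samples <- sort(unique(reads@sample))
  nj <- vapply(seq_len(n), function(i) nrow(reads@blocks[[i]]), 0L) - 1L
  chains <- vapply(seq_len(n), function(i) .chain_str(.junctions_of(reads@blocks[[i]])), "")
  key <- paste(reads@chrom, reads@strand, chains, sep = "|")

  members <- list()   # list of integer vectors of read indices
  ## multi-exon: exact chain identity
  multi <- which(nj > 0)
  if (length(multi))
    members <- c(members, split(multi, key[multi]))
  ## optionally fold 5'-truncated chains into their longest parent
  if (merge_5prime_shorter && length(members) > 1) {
    ord <- order(-vapply(members, function(ix) nj[ix[1]], 0L))
    members <- members[ord]
    keep <- rep(TRUE, length(members))
    for (i in seq_along(members)[-1]) {
      ix <- members[[i]][1]
      jm <- .junctions_of(reads@blocks[[ix]])
      for (j in seq_len(i - 1)) {
        if (!keep[j]) next
        jx <- members[[j]][1]
        if (reads@chrom[ix] != reads@chrom[jx] || reads@strand[ix] != reads@strand[jx]) next
        JM <- .junctions_of(reads@blocks[[jx]])
        if (nrow(jm) >= nrow(JM)) next
        part <- if (reads@strand[ix] == "+")
          JM[(nrow(JM) - nrow(jm) + 1):nrow(JM), , drop = FALSE]
        else JM[seq_len(nrow(jm)), , drop = FALSE]
        if (identical(unname(part), unname(jm))) {
          members[[j]] <- c(members[[j]], members[[i]])
          keep[i] <- FALSE
          break
        }
      }
    }
    members <- members[keep]
  }
  ## mono-exon: same-strand overlap components
  mono <- which(nj == 0)
  if (length(mono)) {
    gr <- GenomicRanges::GRanges(
      reads@chrom[mono],
      IRanges::IRanges(vapply(mono, function(i) reads@blocks[[i]][1, 1], 0L) + 1L,
                       vapply(mono, function(i) reads@blocks[[i]][1, 2], 0L)),
      strand = reads@strand[mono])
    red <- GenomicRanges::reduce(gr)
    grp <- GenomicRanges::findOverlaps(gr, red, select = "first")
    members <- c(members, split(mono, grp))
  }
  if (!length(members))
    return(new("TranscriptModelSet",
               info = data.frame(id = character(), gene_id = character(),
                                 chrom = character(), strand = character(),
                                 start = integer(), end = integer(),
                                 n_exons = integer()),
               exons = list(),
               counts = matrix(0L, 0, length(samples),
                               dimnames = list(NULL, samples))))

  m <- length(members)
  ex <- vector("list", m)
  info <- data.frame(chrom = character(m), strand = character(m),
                     start = integer(m), end = integer(m), n_exons = integer(m))
  counts <- matrix(0L, m, length(samples), dimnames = list(NULL, samples))
  chain_of <- character(m)
  for (g in seq_len(m)) {
    ix <- members[[g]]
    ch <- unique(reads@chrom[ix]); st <- unique(reads@strand[ix])
    stopifnot(length(ch) == 1, length(st) == 1)  # grouping guarantees this
    lead <- ix[which.max(vapply(ix, function(i) nrow(reads@blocks[[i]]), 0L))]
    jm <- .junctions_of(reads@blocks[[lead]])
    s0 <- min(vapply(ix, function(i) reads@blocks[[i]][1, 1], 0L))
    e0 <- max(vapply(ix, function(i) reads@blocks[[i]][nrow(reads@blocks[[i]]), 2], 0L))
    bnd <- c(s0, t(jm), e0)
    ex[[g]] <- matrix(bnd, ncol = 2, byrow = TRUE,
                      dimnames = list(NULL, c("start", "end")))
    info$chrom[g] <- ch; info$strand[g] <- st
    info$start[g] <- s0; info$end[g] <- e0
    info$n_exons[g] <- nrow(ex[[g]])
    chain_of[g] <- .chain_str(jm)
    tab <- table(factor(reads@sample[ix], levels = samples))
    counts[g, ] <- counts[g, ] + as.integer(tab)
  }
  ## locus assignment: same-strand overlap connected components
  gr <- GenomicRanges::GRanges(info$chrom,
                               IRanges::IRanges(info$start + 1L, info$end),
                               strand = info$strand)
  red <- GenomicRanges::reduce(gr)
  comp <- GenomicRanges::findOverlaps(gr, red, select = "first")
  locus_order <- order(as.character(GenomeInfoDb::seqnames(red)),
                       BiocGenerics::start(red))
  locus_rank <- match(comp, locus_order)
  ## isoform numbering: descending total count, then leftmost, then chain
  tot <- rowSums(counts)
  ord <- order(locus_rank, -tot, info$start, chain_of)
  iso <- integer(m)
  iso[ord] <- unlist(lapply(split(seq_len(m), locus_rank[ord])[
    as.character(unique(locus_rank[ord]))], seq_along), use.names = FALSE)
  ## reorder rows by (locus, isoform)
  ro <- order(locus_rank, iso)
  info <- info[ro, , drop = FALSE]
  iso <- iso[ro]; locus_rank <- locus_rank[ro]
  info$gene_id <- paste0("PB.", locus_rank)
  info$id <- paste0(info$gene_id, ".", iso)
  rownames(info) <- info$id
  new("TranscriptModelSet",
      info = info[, c("id", "gene_id", "chrom", "strand", "start", "end", "n_exons")],
      exons = ex[ro],
      counts = `rownames<-`(counts[ro, , drop = FALSE], info$id))
}

#' Index a reference annotation for structural classification
#'
#' Accepts a GFF3/GTF path or a GRanges as imported by
#' \code{rtracklayer::import}. Builds the transcript junction chains, the
#' per-strand donor/acceptor site catalogs and the gene extents used by
#' [classifyIsoform()].
#'
#' @param gff path to a GFF3/GTF file, or a GRanges with \code{type},
#'   \code{ID}/\code{transcript_id} and \code{Parent}/\code{gene_id} metadata
#' @return an \code{annotationIndex} list
#' @export
indexAnnotation <- function(gff) {
  gr <- if (is.character(gff)) rtracklayer::import(gff) else gff
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  is_tx <- type %in% c("mRNA", "transcript")
  is_ex <- type == "exon"
  get1 <- function(v) vapply(v, function(x) if (length(x)) as.character(x)[1] else NA_character_, "")
  tx_id <- if ("ID" %in% names(mc)) get1(mc$ID[is_tx]) else get1(mc$transcript_id[is_tx])
  tx_parent <- if ("Parent" %in% names(mc)) get1(mc$Parent[is_tx]) else get1(mc$gene_id[is_tx])
  ex_parent <- if ("Parent" %in% names(mc)) get1(mc$Parent[is_ex]) else get1(mc$transcript_id[is_ex])

  exd <- data.frame(tx = ex_parent,
                    start = BiocGenerics::start(gr)[is_ex] - 1L,
                    end = BiocGenerics::end(gr)[is_ex])
  ex_by_tx <- lapply(split(exd[, c("start", "end")], exd$tx), function(d) {
    m <- as.matrix(d[order(d$start), , drop = FALSE])
    dimnames(m) <- list(NULL, c("start", "end")); m
  })
  txs <- data.frame(
    tx_id = tx_id, gene_id = tx_parent,
    chrom = as.character(GenomeInfoDb::seqnames(gr))[is_tx],
    strand = as.character(BiocGenerics::strand(gr))[is_tx],
    start = BiocGenerics::start(gr)[is_tx] - 1L,
    end = BiocGenerics::end(gr)[is_tx])
  txs <- txs[txs$tx_id %in% names(ex_by_tx), , drop = FALSE]
  ex_by_tx <- ex_by_tx[txs$tx_id]

  jmats <- lapply(ex_by_tx, .junctions_of)
  chains <- vapply(jmats, .chain_str, "")
  chain_key <- paste(txs$chrom, txs$strand, chains, sep = "|")
  donors <- acceptors <- character(0)
  for (i in seq_along(jmats)) {
    jm <- jmats[[i]]
    if (!nrow(jm)) next
    ## donor = transcript-5' end of the intron
    if (txs$strand[i] == "+") {
      donors <- c(donors, paste(txs$chrom[i], "+", jm[, 1]))
      acceptors <- c(acceptors, paste(txs$chrom[i], "+", jm[, 2]))
    } else {
      donors <- c(donors, paste(txs$chrom[i], "-", jm[, 2]))
      acceptors <- c(acceptors, paste(txs$chrom[i], "-", jm[, 1]))
    }
  }
  gene_tab <- do.call(rbind, lapply(split(seq_len(nrow(txs)), txs$gene_id), function(ix)
    data.frame(gene_id = txs$gene_id[ix[1]], chrom = txs$chrom[ix[1]],
               strand = txs$strand[ix[1]],
               start = min(txs$start[ix]), end = max(txs$end[ix]))))
  genes <- GenomicRanges::GRanges(gene_tab$chrom,
                                  IRanges::IRanges(gene_tab$start + 1L, gene_tab$end),
                                  strand = gene_tab$strand)
  names(genes) <- gene_tab$gene_id
  structure(list(transcripts = txs, exons = ex_by_tx, junctions = jmats,
                 chains = chains, chain_key = chain_key,
                 donors = unique(donors), acceptors = unique(acceptors),
                 genes = genes),
            class = "annotationIndex")
}

#' Structural classification of transcript models against an annotation
#'
#' Assigns each model exactly one category:
#' \describe{
#'   \item{FSM}{junction chain identical to a reference transcript's}
#'   \item{ISM}{chain is a strict 5'-truncated suffix of a reference chain
#'     (3'-truncated sub-chains are treated as novel combinations)}
#'   \item{NIC}{every donor and acceptor site individually annotated, but the
#'     chain is novel}
#'   \item{NNC}{at least one novel splice site}
#'   \item{genic}{mono-exon inside a same-strand gene without a match}
#'   \item{antisense}{overlaps annotated genes only on the opposite strand}
#'   \item{intergenic}{overlaps no annotated gene}
#' }
#' Mono-exon models match FSM against mono-exon reference transcripts by
#' same-strand overlap.
#'
#' @param models a [TranscriptModelSet-class]
#' @param catalog an [indexAnnotation()] result
#' @return data.frame with \code{id}, \code{category},
#'   \code{matched_reference}
#' @export
classifyIsoform <- function(models, catalog) {
  info <- modelInfo(models)
  n <- nrow(info)
  gr <- GenomicRanges::GRanges(info$chrom,
                               IRanges::IRanges(info$start + 1L, info$end),
                               strand = info$strand)
  same <- GenomicRanges::findOverlaps(gr, catalog$genes)
  anti <- GenomicRanges::findOverlaps(gr, catalog$genes, ignore.strand = TRUE)
  has_same <- seq_len(n) %in% S4Vectors::queryHits(same)
  has_any <- seq_len(n) %in% S4Vectors::queryHits(anti)

  mono_ref <- which(vapply(catalog$exons, nrow, 0L) == 1L)
  mono_gr <- if (length(mono_ref))
    GenomicRanges::GRanges(catalog$transcripts$chrom[mono_ref],
                           IRanges::IRanges(catalog$transcripts$start[mono_ref] + 1L,
                                            catalog$transcripts$end[mono_ref]),
                           strand = catalog$transcripts$strand[mono_ref])
  else GenomicRanges::GRanges()

  category <- character(n)
  matched <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    jm <- .junctions_of(models@exons[[i]])
    if (nrow(jm) == 0) {  # mono-exon
      hit <- GenomicRanges::findOverlaps(gr[i], mono_gr, select = "first")
      if (!is.na(hit)) {
        category[i] <- "FSM"
        matched[i] <- catalog$transcripts$tx_id[mono_ref[hit]]
      } else if (has_same[i]) category[i] <- "genic"
      else if (has_any[i]) category[i] <- "antisense"
      else category[i] <- "intergenic"
      next
    }
    key <- paste(info$chrom[i], info$strand[i], .chain_str(jm), sep = "|")
    hit <- match(key, catalog$chain_key)
    if (!is.na(hit)) {
      category[i] <- "FSM"; matched[i] <- catalog$transcripts$tx_id[hit]
      next
    }
    ## ISM: strict contiguous sub-chain missing only 5' junctions
    ism <- NA_character_
    for (j in seq_along(catalog$junctions)) {
      if (catalog$transcripts$chrom[j] != info$chrom[i] ||
          catalog$transcripts$strand[j] != info$strand[i]) next
      JM <- catalog$junctions[[j]]
      if (nrow(JM) <= nrow(jm)) next
      part <- if (info$strand[i] == "+")
        JM[(nrow(JM) - nrow(jm) + 1):nrow(JM), , drop = FALSE]
      else JM[seq_len(nrow(jm)), , drop = FALSE]
      if (identical(unname(part), unname(jm))) { ism <- catalog$transcripts$tx_id[j]; break }
    }
    if (!is.na(ism)) { category[i] <- "ISM"; matched[i] <- ism; next }
    if (!has_same[i]) {
      category[i] <- if (has_any[i]) "antisense" else "intergenic"
      next
    }
    if (info$strand[i] == "+") {
      dn <- paste(info$chrom[i], "+", jm[, 1]); ac <- paste(info$chrom[i], "+", jm[, 2])
    } else {
      dn <- paste(info$chrom[i], "-", jm[, 2]); ac <- paste(info$chrom[i], "-", jm[, 1])
    }
    category[i] <- if (all(dn %in% catalog$donors) && all(ac %in% catalog$acceptors))
      "NIC" else "NNC"
  }
  data.frame(id = info$id, category = category, matched_reference = matched)
}

.revcomp <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))

#' Splice-junction motifs of a model
#'
#' Donor+acceptor dinucleotides on the transcript strand, e.g. "GTAG".
#' @param models a [TranscriptModelSet-class]
#' @param i model index
#' @param genome a \code{DNAStringSet}
#' @return character vector, one motif per junction
#' @export
junctionMotifs <- function(models, i, genome) {
  info <- modelInfo(models)
  jm <- .junctions_of(models@exons[[i]])
  if (!nrow(jm)) return(character(0))
  chr <- genome[[info$chrom[i]]]
  L <- as.character(Biostrings::extractAt(chr, IRanges::IRanges(jm[, 1] + 1L, jm[, 1] + 2L)))
  R <- as.character(Biostrings::extractAt(chr, IRanges::IRanges(jm[, 2] - 1L, jm[, 2])))
  if (info$strand[i] == "+") paste0(L, R) else paste0(.revcomp(R), .revcomp(L))
}

.CANONICAL <- c("GTAG", "GCAG", "ATAC")

#' Detect intra-priming (genomic A-stretch) artifacts
#'
#' Flags a model when the fraction of adenines, read on the transcript
#' strand, in the \code{window} genomic bases immediately downstream of its
#' 3' end reaches \code{a_fraction}. The window truncates at the chromosome
#' edge.
#'
#' @param models a [TranscriptModelSet-class]
#' @param genome a \code{DNAStringSet}
#' @param window bases downstream of the 3' end (default 20)
#' @param a_fraction inclusive A-fraction threshold (default 0.6)
#' @return logical vector per model
#' @export
detectIntraPriming <- function(models, genome, window = 20L, a_fraction = 0.6) {
  info <- modelInfo(models)
  out <- logical(nrow(info))
  for (i in seq_len(nrow(info))) {
    chr <- genome[[info$chrom[i]]]
    if (info$strand[i] == "+") {
      s <- info$end[i] + 1L
      e <- min(info$end[i] + window, length(chr))
      if (e < s) next
      seg <- Biostrings::subseq(chr, s, e)
      nA <- Biostrings::countPattern("A", seg)
    } else {
      e <- info$start[i]
      s <- max(1L, info$start[i] - window + 1L)
      if (e < s) next
      seg <- Biostrings::subseq(chr, s, e)
      nA <- Biostrings::countPattern("T", seg)  # A on the minus strand
    }
    out[i] <- nA / length(seg) >= a_fraction
  }
  out
}

#' Full classification table with artifact flags
#'
#' Combines [classifyIsoform()], [detectIntraPriming()], the canonical-motif
#' and short-read-support junction flags, and an optional RT-switching
#' predicate (default: never flagged; a direct-repeat heuristic can be
#' plugged in).
#'
#' @param models a [TranscriptModelSet-class]
#' @param catalog an [indexAnnotation()] result
#' @param genome a \code{DNAStringSet}
#' @param support optional [readJunctionSupport()] table
#' @param rt_predicate function(models, i, genome) -> logical, or NULL
#' @param window,a_fraction intra-priming parameters
#' @return data.frame, one row per model, with the category, the flags and
#'   the [retainIsoform()] verdict in column \code{keep}
#' @export
classifyModels <- function(models, catalog, genome, support = NULL,
                           rt_predicate = NULL, window = 20L, a_fraction = 0.6) {
  cls <- classifyIsoform(models, catalog)
  info <- modelInfo(models)
  cls$intra_priming <- detectIntraPriming(models, genome, window, a_fraction)
  n <- nrow(info)
  canon <- supp <- logical(n)
  rt <- logical(n)
  for (i in seq_len(n)) {
    motifs <- junctionMotifs(models, i, genome)
    canon[i] <- all(motifs %in% .CANONICAL)     # vacuously TRUE for mono-exon
    jm <- .junctions_of(models@exons[[i]])
    supp[i] <- if (!nrow(jm)) TRUE else
      all(junctionKey(info$chrom[i], jm[, 1], jm[, 2], info$strand[i]) %in%
            (if (is.null(support)) character(0) else support$key))
    if (!is.null(rt_predicate)) rt[i] <- isTRUE(rt_predicate(models, i, genome))
  }
  cls$junctions_all_canonical <- canon
  cls$junctions_all_supported <- supp
  cls$rt_switching <- rt
  cls$keep <- retainIsoform(cls)
  cls
}

#' Retention rule for classified isoforms
#'
#' An isoform is retained iff (1) it is FSM/ISM/NIC without intra-priming; or
#' (2) it is NNC without intra-priming or RT switching and every junction is
#' canonical or short-read supported; or (3) it is antisense/intergenic/genic
#' under the same conditions as (2). The junction condition is evaluated
#' per junction (canonical OR supported), vacuously true for mono-exon
#' models.
#'
#' @param cls a classification data.frame as from [classifyModels()] with
#'   columns \code{category}, \code{intra_priming}, \code{rt_switching},
#'   \code{junctions_all_canonical}, \code{junctions_all_supported}
#' @return logical vector: keep
#' @export
retainIsoform <- function(cls) {
  junc_ok <- cls$junctions_all_canonical | cls$junctions_all_supported
  trusted <- cls$category %in% c("FSM", "ISM", "NIC")
  other <- cls$category %in% c("NNC", "antisense", "intergenic", "genic")
  (trusted & !cls$intra_priming) |
    (other & !cls$intra_priming & !cls$rt_switching & junc_ok)
}

#' Direct-repeat RT-switching heuristic
#'
#' Optional predicate for [classifyModels()]: flags a model when any of its
#' introns shows an exact repeat of at least \code{min_repeat} bases between
#' the sequence starting at the donor site and the sequence starting at the
#' acceptor's downstream exon, the classic template-switching signature.
#'
#' @param min_repeat minimum exact repeat length (default 8)
#' @return a predicate function suitable for \code{rt_predicate}
#' @export
rtSwitchingRepeat <- function(min_repeat = 8L) {
  function(models, i, genome) {
    info <- modelInfo(models)
    jm <- .junctions_of(models@exons[[i]])
    if (!nrow(jm)) return(FALSE)
    chr <- genome[[info$chrom[i]]]
    for (r in seq_len(nrow(jm))) {
      s <- jm[r, 1]; e <- jm[r, 2]
      if (s + min_repeat > length(chr) || e + min_repeat > length(chr)) next
      a <- Biostrings::subseq(chr, s + 1L, s + min_repeat)
      b <- Biostrings::subseq(chr, e + 1L, e + min_repeat)
      if (as.character(a) == as.character(b)) return(TRUE)
    }
    FALSE
  }
}

#' Export transcript models as GFF3 plus an abundance table
#'
#' @param models a [TranscriptModelSet-class]
#' @param gff_path output GFF3 (1-based coordinates at the boundary)
#' @param abundance_path output per-sample FL-count TSV
#' @export
writeModels <- function(models, gff_path, abundance_path = NULL) {
  info <- modelInfo(models)
  rows <- GenomicRanges::GRangesList(lapply(seq_len(nrow(info)), function(i) {
    ex <- models@exons[[i]]
    g <- GenomicRanges::GRanges(info$chrom[i],
                                IRanges::IRanges(ex[, 1] + 1L, ex[, 2]),
                                strand = info$strand[i])
    g
  }))
  names(rows) <- info$id
  ## flatten: transcript + exon features
  feats <- GenomicRanges::GRanges()
  for (i in seq_len(nrow(info))) {
    tx <- GenomicRanges::GRanges(info$chrom[i],
                                 IRanges::IRanges(info$start[i] + 1L, info$end[i]),
                                 strand = info$strand[i])
    S4Vectors::mcols(tx) <- S4Vectors::DataFrame(type = "transcript",
                                                 ID = info$id[i],
                                                 Parent = info$gene_id[i])
    exg <- rows[[i]]
    S4Vectors::mcols(exg) <- S4Vectors::DataFrame(
      type = "exon", ID = paste0(info$id[i], ".exon", seq_along(exg)),
      Parent = info$id[i])
    feats <- c(feats, tx, exg)
  }
  S4Vectors::mcols(feats)$source <- "isohap"
  rtracklayer::export(feats, gff_path, format = "gff3")
  if (!is.null(abundance_path)) {
    ab <- data.frame(id = info$id, gene_id = info$gene_id, flCounts(models),
                     check.names = FALSE)
    writeHeaderedTsv(ab, abundance_path, list(what = "fl_abundance"))
  }
  invisible(gff_path)
}
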