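## Fully synthetic, truth-annotated inputs: two-haplotype genes with planted
## substitution SNPs on a synthetic chromosome, multiplexed full-length reads
## with substitution errors and 5' truncation, and the count/expression
## regimes the downstream statistics are scored against. Everything is
## deterministic under the seed.

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

#' Simulate a synthetic chromosome with two-haplotype genes
#'
#' Lays out \code{n_genes} random multi-exon genes on one synthetic
#' chromosome. Haplotype A is the reference; haplotype B differs by planted
#' substitutions at randomly chosen exonic SNP positions. Additional
#' isoforms, when requested, are 5'-truncated exon chains of the full model.
#'
#' @param n_genes number of genes
#' @param snps_per_gene integer range (or single value) of SNPs per gene
#' @param exons_per_gene integer range of exon counts
#' @param exon_len,intron_len integer ranges of exon/intron lengths (bases)
#' @param n_isoforms isoforms per gene (1 = full model only); capped at the
#'   exon count
#' @param gap intergenic gap (bases)
#' @param seed RNG seed (mandatory)
#' @return a \code{simGenome} list: \code{genome} (DNAStringSet),
#'   \code{genes}, \code{exons}, \code{isoforms}, \code{snps} (the truth)
#' @export
simulateGenes <- function(n_genes = 10L, snps_per_gene = c(2L, 10L),
                          exons_per_gene = c(2L, 5L),
                          exon_len = c(150L, 400L), intron_len = c(80L, 300L),
                          n_isoforms = 1L, gap = 300L, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  rint <- function(rg) as.integer(if (length(rg) == 1) rg else sample(rg[1]:rg[2], 1))
  genes <- data.frame(gene_id = character(n_genes), chrom = "chrS",
                      strand = character(n_genes), start = integer(n_genes),
                      end = integer(n_genes), n_exons = integer(n_genes))
  exons <- vector("list", n_genes)
  isoforms <- vector("list", n_genes)
  snps <- list()
  cursor <- gap
  for (g in seq_len(n_genes)) {
    ne <- rint(exons_per_gene)
    lens <- vapply(seq_len(ne), function(i) rint(exon_len), 0L)
    gaps <- if (ne > 1) vapply(seq_len(ne - 1), function(i) rint(intron_len), 0L) else integer(0)
    starts <- cursor + c(0L, cumsum(lens[-ne] + gaps))
    ex <- cbind(start = starts, end = starts + lens)
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("simG%03d", g)
    genes$gene_id[g] <- gid
    genes$strand[g] <- strand
    genes$start[g] <- ex[1, 1]; genes$end[g] <- ex[ne, 2]
    genes$n_exons[g] <- ne
    exons[[g]] <- ex
    ## isoforms: full chain first, then 5'-truncated chains
    ni <- min(n_isoforms, ne)
    iso <- vector("list", ni)
    for (j in seq_len(ni)) {
      keep <- if (strand == "+") j:ne else 1:(ne - j + 1)
      iso[[j]] <- ex[keep, , drop = FALSE]
    }
    names(iso) <- sprintf("%s.i%d", gid, seq_len(ni))
    isoforms[[g]] <- iso
    ## SNPs on exonic positions
    k <- rint(snps_per_gene)
    ex_pos <- unlist(Map(seq.int, ex[, 1], ex[, 2] - 1L), use.names = FALSE)
    if (k > length(ex_pos))
      stop("gene ", gid, ": SNP count exceeds exonic length")
    if (k > 0) {
      pos <- sort(sample(ex_pos, k))
      snps[[g]] <- data.frame(gene_id = gid, pos = pos,
                              ref = NA_character_, alt = NA_character_)
    }
    cursor <- ex[ne, 2] + gap
  }
  seqlen <- cursor + gap
  chrom_seq <- .rand_dna(seqlen)
  snps <- if (length(snps)) do.call(rbind, snps) else
    data.frame(gene_id = character(), pos = integer(),
               ref = character(), alt = character())
  if (nrow(snps)) {
    snps$ref <- substring(chrom_seq, snps$pos + 1L, snps$pos + 1L)
    snps$alt <- vapply(snps$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  }
  genome <- Biostrings::DNAStringSet(chrom_seq)
  names(genome) <- "chrS"
  structure(list(genome = genome, genes = genes, exons = exons,
                 isoforms = isoforms, snps = snps),
            class = "simGenome")
}

#' Default per-(gene, isoform, sample, allele) read counts
#'
#' Parents receive reads only from their own allele (A for parentA, B for
#' parentB); hybrids from both. Counts are per isoform.
#'
#' @param sim a \code{simGenome}
#' @param sheet a [SampleSheet-class]
#' @param per_parent FL reads per parent sample and isoform (default 10)
#' @param per_hybrid_allele FL reads per hybrid sample, allele and isoform
#'   (default 5)
#' @return data.frame: gene_id, isoform, sample_id, allele, n
#' @export
defaultReadCounts <- function(sim, sheet, per_parent = 10L,
                              per_hybrid_allele = 5L) {
  e <- sheetEntries(sheet)
  out <- list()
  for (g in seq_len(nrow(sim$genes))) {
    gid <- sim$genes$gene_id[g]
    for (iso in names(sim$isoforms[[g]])) for (i in seq_len(nrow(e))) {
      role <- e$role[i]
      rows <- switch(role,
        parentA = data.frame(allele = "A", n = per_parent),
        parentB = data.frame(allele = "B", n = per_parent),
        data.frame(allele = c("A", "B"), n = per_hybrid_allele))
      rows$gene_id <- gid; rows$isoform <- iso
      rows$sample_id <- e$sample_id[i]
      out[[length(out) + 1L]] <- rows
    }
  }
  do.call(rbind, out)[, c("gene_id", "isoform", "sample_id", "allele", "n")]
}

#' Simulate aligned full-length reads
#'
#' Emits reads born aligned (their CIGARs follow from the known isoform
#' structure): haplotype bases at the planted SNP sites, i.i.d. substitution
#' errors at \code{error_rate}, optional 5' truncation (geometric length,
#' producing 5'-incomplete reads) and an optional small deletion rate used
#' only to exercise the substitution-only contract of the callers.
#'
#' @param sim a \code{simGenome}
#' @param sheet a [SampleSheet-class]
#' @param counts count table as from [defaultReadCounts()] (the default)
#' @param error_rate per-base substitution error probability (default 0.005,
#'   the residual error scale of >= 99\%-accuracy consensus reads)
#' @param trunc_prob probability a read is 5'-truncated (default 0.2)
#' @param trunc_mean mean geometric truncation length in bases (default 100)
#' @param del_rate per-read probability of a 1-base deletion (default 0)
#' @param seed RNG seed (mandatory)
#' @return list: \code{reads} (a [FLReadSet-class]) and \code{truth}
#'   (data.frame qname, sample_id, gene_id, isoform, allele, n_errors)
#' @export
simulateReads <- function(sim, sheet, counts = NULL, error_rate = 0.005,
                          trunc_prob = 0.2, trunc_mean = 100, del_rate = 0,
                          seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  if (is.null(counts)) counts <- defaultReadCounts(sim, sheet)
  chrom_seq <- as.character(sim$genome[[1]])
  gene_idx <- match(counts$gene_id, sim$genes$gene_id)
  qname <- sample_v <- strand_v <- character(0)
  blocks <- pos_l <- list()
  bases_v <- character(0)
  truth <- list()
  ctr <- 0L
  for (r in seq_len(nrow(counts))) {
    g <- gene_idx[r]
    iso_ex <- sim$isoforms[[g]][[counts$isoform[r]]]
    strand <- sim$genes$strand[g]
    gsnps <- sim$snps[sim$snps$gene_id == counts$gene_id[r], , drop = FALSE]
    for (cp in seq_len(counts$n[r])) {
      ex <- iso_ex
      ## 5' truncation in transcript coordinates
      if (trunc_prob > 0 && runif(1) < trunc_prob) {
        L <- rgeom(1, 1 / trunc_mean)
        tlen <- sum(ex[, 2] - ex[, 1])
        L <- min(L, max(tlen - 50L, 0L))
        while (L > 0 && nrow(ex) > 0) {
          i5 <- if (strand == "+") 1L else nrow(ex)
          w <- ex[i5, 2] - ex[i5, 1]
          if (L >= w) { ex <- ex[-i5, , drop = FALSE]; L <- L - w }
          else {
            if (strand == "+") ex[i5, 1] <- ex[i5, 1] + L else ex[i5, 2] <- ex[i5, 2] - L
            L <- 0L
          }
        }
      }
      p <- unlist(Map(seq.int, ex[, 1], ex[, 2] - 1L), use.names = FALSE)
      b <- strsplit(substring(chrom_seq, ex[, 1] + 1L, ex[, 2]), "")
      b <- unlist(b, use.names = FALSE)
      if (counts$allele[r] == "B" && nrow(gsnps)) {
        hit <- match(gsnps$pos, p)
        ok <- !is.na(hit)
        b[hit[ok]] <- gsnps$alt[ok]
      }
      nerr <- 0L
      if (error_rate > 0) {
        flip <- which(runif(length(b)) < error_rate)
        for (i in flip) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
        nerr <- length(flip)
      }
      if (del_rate > 0 && runif(1) < del_rate && length(p) > 2) {
        i <- sample(2:(length(p) - 1), 1)
        p <- p[-i]; b <- b[-i]
      }
      ctr <- ctr + 1L
      qn <- sprintf("%s/%s_r%06d", counts$sample_id[r], counts$gene_id[r], ctr)
      qname <- c(qname, qn)
      sample_v <- c(sample_v, counts$sample_id[r])
      strand_v <- c(strand_v, strand)
      blocks[[length(blocks) + 1L]] <- ex
      pos_l[[length(pos_l) + 1L]] <- p
      bases_v <- c(bases_v, paste(b, collapse = ""))
      truth[[length(truth) + 1L]] <- data.frame(
        qname = qn, sample_id = counts$sample_id[r],
        gene_id = counts$gene_id[r], isoform = counts$isoform[r],
        allele = counts$allele[r], n_errors = nerr)
    }
  }
  reads <- new("FLReadSet", qname = qname, sample = sample_v,
               chrom = rep("chrS", length(qname)), strand = strand_v,
               blocks = blocks, pos = pos_l, bases = bases_v)
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Write simulated reads as SAM
#'
#' CIGARs are reconstructed from each read's aligned positions: runs of
#' consecutive positions become M segments; within-block gaps become D,
#' between-block gaps N. Read groups carry the sample ids.
#'
#' @param reads a [FLReadSet-class]
#' @param genome a \code{DNAStringSet} (for the @SQ header)
#' @param path output SAM file
#' @export
writeSimSam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), BiocGenerics::width(genome)),
           sprintf("@RG\tID:%s\tSM:%s", unique(reads@sample), unique(reads@sample)))
  lines <- character(length(reads))
  for (i in seq_along(lines)) {
    p <- reads@pos[[i]]
    bl <- reads@blocks[[i]]
    runs_end <- c(which(diff(p) != 1L), length(p))
    runs_start <- c(1L, head(runs_end, -1) + 1L)
    ops <- character(0)
    for (r in seq_along(runs_start)) {
      ops <- c(ops, sprintf("%dM", runs_end[r] - runs_start[r] + 1L))
      if (r < length(runs_start)) {
        gap_s <- p[runs_end[r]] + 1L
        gap_e <- p[runs_start[r + 1L]]
        ## junction if the gap matches an inter-block gap, else deletion
        is_junc <- any(bl[-nrow(bl), 2] == gap_s & bl[-1, 1] == gap_e)
        ops <- c(ops, sprintf("%d%s", gap_e - gap_s, if (is_junc) "N" else "D"))
      }
    }
    flag <- if (reads@strand[i] == "-") 16L else 0L
    lines[i] <- paste(reads@qname[i], flag, reads@chrom[i], p[1] + 1L, 60L,
                      paste(ops, collapse = ""), "*", 0L, 0L,
                      reads@bases[i], "*",
                      paste0("RG:Z:", reads@sample[i]), sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a simulated genome, annotation and truth tables
#'
#' @param sim a \code{simGenome}
#' @param dir output directory: genome.fasta, annotation.gff3, truth TSVs
#' @export
writeSimGenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fasta"))
  feats <- GenomicRanges::GRanges()
  for (g in seq_len(nrow(sim$genes))) {
    gi <- sim$genes[g, ]
    gene <- GenomicRanges::GRanges(gi$chrom,
                                   IRanges::IRanges(gi$start + 1L, gi$end),
                                   strand = gi$strand)
    S4Vectors::mcols(gene) <- S4Vectors::DataFrame(type = "gene", ID = gi$gene_id,
                                                   Parent = NA_character_)
    feats <- c(feats, gene)
    for (iso in names(sim$isoforms[[g]])) {
      ex <- sim$isoforms[[g]][[iso]]
      tx <- GenomicRanges::GRanges(gi$chrom,
                                   IRanges::IRanges(min(ex[, 1]) + 1L, max(ex[, 2])),
                                   strand = gi$strand)
      S4Vectors::mcols(tx) <- S4Vectors::DataFrame(type = "mRNA", ID = iso,
                                                   Parent = gi$gene_id)
      exg <- GenomicRanges::GRanges(gi$chrom,
                                    IRanges::IRanges(ex[, 1] + 1L, ex[, 2]),
                                    strand = gi$strand)
      S4Vectors::mcols(exg) <- S4Vectors::DataFrame(
        type = "exon", ID = paste0(iso, ".e", seq_along(exg)), Parent = iso)
      feats <- c(feats, tx, exg)
    }
  }
  S4Vectors::mcols(feats)$source <- "isohap-sim"
  rtracklayer::export(feats, file.path(dir, "annotation.gff3"), format = "gff3")
  write.table(sim$snps, file.path(dir, "truth_snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$genes, file.path(dir, "truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate downstream count/expression regimes with known truth
#'
#' \describe{
#'   \item{imprinting}{per-gene maternal:paternal FL counts in both
#'     reciprocal hybrids drawn binomially around the regime ratio: MEG 10:1,
#'     PEG 1:10, none 1:1.}
#'   \item{cistrans}{parental and pooled-hybrid allelic counts under the five
#'     regulatory regimes with \code{fold}-sized effects: conserved (1:1
#'     everywhere), cis-only (parents and hybrid share the allelic fold),
#'     trans-only (parents diverge, hybrid balanced), cis+trans (hybrid shows
#'     the cis fold, parents amplify it), cisxtrans (hybrid and parents fold
#'     in opposite directions).}
#'   \item{additive}{inbred and hybrid expression replicates; non-additive
#'     genes have the hybrid at twice the expected additive level.}
#' }
#'
#' @param kind \code{"imprinting"}, \code{"cistrans"} or \code{"additive"}
#' @param n_genes genes per regime (default 200)
#' @param seed RNG seed (mandatory)
#' @param tissue tissue label (imprinting/additive; default "endosperm")
#' @param fold effect size: imprinting active:repressed ratio (default 10),
#'   cis/trans allelic fold (default 4)
#' @param total FL counts per hybrid (imprinting, default 50) or per count
#'   margin (cistrans, default 400)
#' @param n_reps replicates per sample (additive, default 2)
#' @param cv replicate coefficient of variation (additive, default 0.05)
#' @return list(\code{data}, \code{truth}); \code{data} is an
#'   [AllelicCounts-class] for imprinting, a count data.frame for cistrans,
#'   and per-gene replicate sets for additive
#' @export
simulateRegimes <- function(kind = c("imprinting", "cistrans", "additive"),
                            n_genes = 200L, seed, tissue = "endosperm",
                            fold = NULL, total = NULL, n_reps = 2L, cv = 0.05) {
  kind <- match.arg(kind)
  stopifnot(!missing(seed))
  set.seed(seed)
  sheet <- defaultSampleSheet()
  e <- sheetEntries(sheet)
  if (kind == "imprinting") {
    if (is.null(fold)) fold <- 10
    if (is.null(total)) total <- 50L
    regimes <- rep(c("MEG", "PEG", "none"), length.out = n_genes)
    p_mat <- c(MEG = fold / (fold + 1), PEG = 1 / (fold + 1), none = 0.5)
    rows <- list()
    sid <- function(role) e$sample_id[e$role == role & e$tissue == tissue]
    for (g in seq_len(n_genes)) {
      gid <- sprintf("regG%04d", g)
      for (role in c("hybridAB", "hybridBA")) {
        nm <- rbinom(1, total, p_mat[regimes[g]])
        ## maternal allele is parentA in hybridAB, parentB in hybridBA
        nA <- if (role == "hybridAB") nm else total - nm
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = gid, level = "gene", sample_id = sid(role),
          tissue = tissue, role = role,
          n_parentA = nA, n_parentB = total - nA, n_unassigned = 0L)
      }
    }
    data <- new("AllelicCounts", table = do.call(rbind, rows), labeled = TRUE)
    truth <- data.frame(gene = sprintf("regG%04d", seq_len(n_genes)),
                        status = regimes)
    return(list(data = data, truth = truth))
  }
  if (kind == "cistrans") {
    if (is.null(fold)) fold <- 4
    if (is.null(total)) total <- 400L
    regimes <- rep(c("conserved", "cis-only", "trans-only", "cis+trans",
                     "cisxtrans"), length.out = n_genes)
    hi <- fold / (fold + 1)
    p <- list("conserved" = c(0.5, 0.5),
              "cis-only"  = c(hi, hi),
              "trans-only" = c(hi, 0.5),
              "cis+trans" = c(fold^2 / (fold^2 + 1), hi),
              "cisxtrans" = c(1 - hi, hi))   # c(parents, hybrid)
    aP <- rbinom(n_genes, total, vapply(regimes, function(r) p[[r]][1], 0))
    aH <- rbinom(n_genes, total, vapply(regimes, function(r) p[[r]][2], 0))
    data <- data.frame(gene = sprintf("ctG%04d", seq_len(n_genes)),
                       a_P = aP, b_P = total - aP, a_H = aH, b_H = total - aH)
    return(list(data = data, truth = data.frame(gene = data$gene,
                                                category = regimes)))
  }
  ## additive
  if (is.null(fold)) fold <- 2
  regimes <- rep(c("additive", "non-additive"), length.out = n_genes)
  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    mu_m <- exp(rnorm(1, log(20), 0.5))
    mu_p <- exp(rnorm(1, log(20), 0.5))
    expct <- if (tissue == "endosperm") (2 * mu_m + mu_p) / 3 else (mu_m + mu_p) / 2
    mu_h <- if (regimes[g] == "additive") expct else fold * expct
    genes[[g]] <- list(
      maternal = rnorm(n_reps, mu_m, cv * mu_m),
      paternal = rnorm(n_reps, mu_p, cv * mu_p),
      hybrid = rnorm(n_reps, mu_h, cv * mu_h))
  }
  names(genes) <- sprintf("adG%04d", seq_len(n_genes))
  list(data = genes, truth = data.frame(gene = names(genes), status = regimes))
}
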