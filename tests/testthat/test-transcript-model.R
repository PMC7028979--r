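test_that("coverage/identity filter applies inclusive bounds", {
  # coverage 0.995, identity 0.97 -> keep; coverage 0.98 -> drop
  expect_true(filterAlignment(1000, 995, 970, 1000))
  expect_false(filterAlignment(1000, 980, 990, 1000))
  # identity exactly at the 0.95 bound is kept
  expect_true(filterAlignment(1000, 990, 950, 1000))
  expect_error(filterAlignment(0, 0, 0, 0), "zero-length")
})

test_that("identical junction chains collapse into one model", {
  reads <- make_reads(
    list(blk(100, 200, 300, 400, 500, 600, 700, 800),     # full chain
         blk(150, 200, 300, 400, 500, 600, 700, 820),     # same chain, shorter 5'
         blk(300, 400, 500, 600, 700, 800)),               # 5'-truncated suffix chain
    samples = c("pA", "pA", "pB"))
  m <- collapseByJunctions(reads)
  expect_equal(length(m), 2L)
  info <- modelInfo(m)
  full <- which(info$n_exons == 4)
  expect_equal(sum(flCounts(m)[full, ]), 2)           # two reads merged
  expect_equal(info$start[full], 100L)                 # union span
  expect_equal(info$end[full], 820L)
  # same gene locus (overlapping, same strand)
  expect_equal(length(unique(info$gene_id)), 1L)

  # with merge_5prime_shorter the truncated chain folds into its parent
  m2 <- collapseByJunctions(reads, merge_5prime_shorter = TRUE)
  expect_equal(length(m2), 1L)
  expect_equal(sum(flCounts(m2)), 3)
})

test_that("mono-exon reads merge by same-strand overlap only", {
  reads <- make_reads(
    list(blk(100, 300), blk(250, 500), blk(800, 900)),
    samples = "pA")
  m <- collapseByJunctions(reads)
  expect_equal(length(m), 2L)
  opp <- make_reads(list(blk(100, 300), blk(150, 350)), samples = "pA",
                    strand = c("+", "-"))
  expect_equal(length(collapseByJunctions(opp)), 2L)
})

test_that("collapse conserves reads and is idempotent on planted isoforms", {
  sheet <- four_sample_sheet()
  sim <- simulateGenes(n_genes = 2, snps_per_gene = 0, exons_per_gene = 4,
                       n_isoforms = 3, seed = 91)
  counts <- expand.grid(gene_id = sim$genes$gene_id, iso = 1:3,
                        stringsAsFactors = FALSE)
  counts$isoform <- sprintf("%s.i%d", counts$gene_id, counts$iso)
  counts$sample_id <- "pA"; counts$allele <- "A"; counts$n <- 40L
  rd <- simulateReads(sim, sheet, counts = counts, error_rate = 0,
                      trunc_prob = 0, seed = 92)
  m <- collapseByJunctions(rd$reads)
  expect_equal(length(m), 6L)                            # 3 isoforms x 2 genes
  expect_true(all(rowSums(flCounts(m)) == 40L))          # planted support
  expect_equal(sum(flCounts(m)), length(rd$reads))       # conservation
  expect_equal(length(unique(modelInfo(m)$gene_id)), 2L)
  # isoform numbering is deterministic: PB.X.Y with Y dense per locus
  expect_setequal(sub("^PB\\.\\d+\\.", "", modelInfo(m)$id), c("1", "2", "3"))
})

test_that("structural classification assigns the expected categories", {
  ref <- make_catalog(list(
    list(id = "tx1", gene = "gene1", chrom = "chr1", strand = "+",
         exons = blk(100, 200, 300, 400, 500, 600, 700, 800, 900, 1000)),
    list(id = "tx2", gene = "gene2", chrom = "chr1", strand = "+",
         exons = blk(5000, 5400))))
  models <- collapseByJunctions(make_reads(list(
    blk(120, 200, 300, 400, 500, 600, 700, 800, 900, 980),  # FSM: same chain
    blk(520, 600, 700, 800, 900, 1000),                      # ISM: last 2 junctions
    blk(100, 200, 300, 400, 700, 800, 900, 1000),            # NIC: known sites, novel chain
    blk(100, 200, 311, 400, 500, 600, 700, 800, 900, 1000),  # NNC: novel acceptor 311
    blk(5100, 5300),                                         # FSM: mono-exon overlap
    blk(150, 250),                                           # genic mono-exon
    blk(7000, 7200),                                         # intergenic
    blk(7000, 7100, 7150, 7200)),                            # intergenic multi-exon
    samples = "pA"))
  # antisense needs opposite strand
  anti <- collapseByJunctions(make_reads(list(blk(150, 450)), samples = "pA",
                                         strand = "-"))
  cls <- classifyIsoform(models, ref)
  got <- setNames(cls$category, modelInfo(models)$start)
  expect_equal(unname(got[c("120", "520", "100", "5100", "150", "7000")]),
               c("FSM", "ISM", "NIC", "FSM", "genic", "intergenic"))
  starts <- modelInfo(models)$start
  expect_equal(cls$category[starts == 100 & modelInfo(models)$n_exons == 4], "NIC")
  expect_equal(cls$category[starts == 100 & modelInfo(models)$n_exons == 5], "NNC")
  expect_true(all(cls$category[starts == 7000] == "intergenic"))
  expect_equal(cls$matched_reference[cls$category == "ISM"], "tx1")
  expect_equal(classifyIsoform(anti, ref)$category, "antisense")
  # partition: exactly one category per model
  expect_false(anyNA(cls$category))
})

test_that("simulated data with no novelty classifies FSM/ISM only", {
  sheet <- four_sample_sheet()
  sim <- simulateGenes(n_genes = 4, snps_per_gene = 0, exons_per_gene = c(3, 5),
                       n_isoforms = 2, seed = 13)
  rd <- simulateReads(sim, sheet, error_rate = 0, trunc_prob = 0.3,
                      trunc_mean = 60, seed = 14)
  d <- tempfile(); writeSimGenome(sim, d)
  cat <- indexAnnotation(file.path(d, "annotation.gff3"))
  m <- collapseByJunctions(rd$reads)
  cls <- classifyIsoform(m, cat)
  expect_true(all(cls$category %in% c("FSM", "ISM")))
})

test_that("intra-priming flags A-rich downstream windows on either strand", {
  seqs <- Biostrings::DNAStringSet(c(
    chrA = paste0(paste(rep("C", 100), collapse = ""),
                  paste(rep("A", 20), collapse = ""),
                  paste(rep("C", 50), collapse = "")),
    chrB = paste0(paste(rep("G", 50), collapse = ""),
                  paste(rep("T", 20), collapse = ""),
                  paste(rep("G", 100), collapse = ""))))
  plusA <- collapseByJunctions(make_reads(list(blk(20, 100)), samples = "pA",
                                          chrom = "chrA"))
  expect_true(detectIntraPriming(plusA, seqs))          # downstream 20-mer all A
  # 11 of 20 A (0.55) stays below the 0.6 default
  seqs2 <- Biostrings::DNAStringSet(c(chrA = paste0(
    paste(rep("C", 100), collapse = ""),
    paste(rep(c("A", "C"), c(11, 9)), collapse = ""),
    paste(rep("C", 50), collapse = ""))))
  expect_false(detectIntraPriming(plusA, seqs2))
  # minus strand: all-T reference window upstream is an A-stretch on the read
  minusB <- collapseByJunctions(make_reads(list(blk(70, 150)), samples = "pA",
                                           chrom = "chrB", strand = "-"))
  expect_true(detectIntraPriming(minusB, seqs))
})

test_that("retention applies the three category-dependent rules", {
  base <- data.frame(category = "NIC", intra_priming = FALSE,
                     rt_switching = FALSE, junctions_all_canonical = FALSE,
                     junctions_all_supported = FALSE)
  expect_true(retainIsoform(base))                       # trusted category
  expect_false(retainIsoform(transform(base, intra_priming = TRUE)))
  nnc <- transform(base, category = "NNC")
  expect_false(retainIsoform(nnc))                       # non-canonical, unsupported
  expect_true(retainIsoform(transform(nnc, junctions_all_canonical = TRUE)))
  expect_true(retainIsoform(transform(nnc, junctions_all_supported = TRUE)))
  expect_false(retainIsoform(transform(nnc, junctions_all_supported = TRUE,
                                       rt_switching = TRUE)))
  # mono-exon intergenic: junction condition is vacuous
  ig <- transform(base, category = "intergenic", junctions_all_canonical = TRUE)
  expect_true(retainIsoform(ig))
})

test_that("classifyModels wires motifs, support and intra-priming together", {
  # gene with one GT..AG intron and one CC..GG (non-canonical) intron
  left <- paste(rep("C", 100), collapse = "")
  ex1 <- paste(rep("A", 50), collapse = "")
  i1 <- paste0("GT", paste(rep("C", 46), collapse = ""), "AG")
  ex2 <- paste(rep("G", 50), collapse = "")
  i2 <- paste0("CC", paste(rep("A", 46), collapse = ""), "GG")
  ex3 <- paste(rep("T", 50), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(left, ex1, i1, ex2, i2, ex3,
                                                     paste(rep("C", 60), collapse = ""))))
  cat <- make_catalog(list(list(id = "t1", gene = "g1", chrom = "chr1",
                                strand = "+", exons = blk(100, 150, 200, 250, 300, 350))))
  good <- collapseByJunctions(make_reads(list(blk(100, 150, 200, 250)),
                                         samples = "pA"))
  expect_equal(junctionMotifs(good, 1, genome), "GTAG")
  novel <- collapseByJunctions(make_reads(list(blk(100, 150, 200, 250, 300, 340)),
                                          samples = "pA"))
  cls <- classifyModels(novel, cat, genome)
  expect_false(cls$junctions_all_canonical)             # CC..GG intron present
  sup <- data.frame(chrom = "chr1", start = c(150, 250), end = c(200, 300),
                    strand = "+", count = c(9, 4))
  sup$key <- junctionKey(sup$chrom, sup$start, sup$end, sup$strand)
  cls2 <- classifyModels(novel, cat, genome, support = sup)
  expect_true(cls2$junctions_all_supported)
})
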