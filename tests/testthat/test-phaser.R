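calls_df <- function(pos, ref, alt) {
  data.frame(chrom = "chr1", pos = as.integer(pos), ref = ref, alt = alt,
             messy = FALSE)
}

# matrix bundle straight from strings ("." = missing)
bundle <- function(rows, ref, alt, samples = "hAB") {
  mat <- do.call(rbind, strsplit(rows, ""))
  mat[mat == "."] <- NA_character_
  list(mat = mat, qname = sprintf("r%03d", seq_along(rows)),
       sample = rep_len(samples, length(rows)), isoform = NULL,
       positions = seq_len(ncol(mat)) * 10L, ref = ref, alt = alt)
}

test_that("read haplotype matrix reflects coverage, deletions and truth", {
  genome_row <- c("C", "G", "T")
  reads <- make_reads(list(blk(10, 40), blk(10, 25), blk(10, 40)),
                      samples = "pA",
                      bases = c(paste(rep("C", 30), collapse = ""),
                                paste(rep("C", 15), collapse = ""),
                                paste(rep("C", 30), collapse = "")))
  reads@pos[[3]] <- setdiff(reads@pos[[3]], 20L)   # deletion at SNP 2
  reads@bases[3] <- paste(rep("C", 29), collapse = "")
  cl <- calls_df(c(10, 20, 30), ref = c("C", "C", "C"), alt = c("G", "G", "G"))
  m <- extractReadHaplotypes(reads, cl)
  expect_equal(dim(m$mat), c(3L, 3L))
  expect_equal(unname(m$mat[2, ]), c("C", "C", NA))     # partial span
  expect_true(is.na(m$mat[3, 2]))                        # deletion -> missing

  # with no errors the matrix equals the simulator's planted bases
  sheet <- four_sample_sheet()
  sim <- simulateGenes(n_genes = 1, snps_per_gene = 5, seed = 61)
  rd <- simulateReads(sim, sheet, error_rate = 0, trunc_prob = 0, seed = 62)
  tr <- sim$snps
  m2 <- extractReadHaplotypes(rd$reads,
                              calls_df(tr$pos, tr$ref, tr$alt))
  truth_allele <- rd$truth$allele[match(m2$qname, rd$truth$qname)]
  want <- ifelse(matrix(truth_allele == "A", nrow(m2$mat), 5),
                 matrix(tr$ref, nrow(m2$mat), 5, byrow = TRUE),
                 matrix(tr$alt, nrow(m2$mat), 5, byrow = TRUE))
  expect_equal(unname(m2$mat), unname(want))
})

test_that("clean half-and-half reads reconstruct the planted pair", {
  m <- bundle(c(rep("CT", 30), rep("GA", 30)), ref = c("C", "A"), alt = c("G", "T"))
  pair <- reconstructTwoHaplotypes(m)
  expect_setequal(haplotypes(pair), c("CT", "GA"))
  expect_equal(sort(c(pair@support0, pair@support1)), c(30L, 30L))
  expect_length(pair@flags, 0)
})

test_that("reconstruction attains the exhaustive-search optimum", {
  set.seed(73)
  for (rep in 1:30) {
    k <- sample(2:6, 1)
    nr <- sample(10:50, 1)
    ref <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    truth_a <- rbinom(k, 1, 0.5)
    h <- rbind(ifelse(truth_a == 0, ref, alt), ifelse(truth_a == 0, alt, ref))
    mat <- h[sample(1:2, nr, replace = TRUE), , drop = FALSE]
    flip <- matrix(runif(nr * k) < 0.05, nr, k)
    for (i in which(flip)) mat[i] <- sample(setdiff(c("A", "C", "G", "T"), mat[i]), 1)
    mat[matrix(runif(nr * k) < 0.1, nr, k)] <- NA   # missing sites
    keep <- rowSums(!is.na(mat)) > 0
    mat <- mat[keep, , drop = FALSE]
    m <- list(mat = mat, qname = as.character(seq_len(nrow(mat))),
              sample = rep("hAB", nrow(mat)), isoform = NULL,
              positions = seq_len(k), ref = ref, alt = alt)
    pair <- reconstructTwoHaplotypes(m)
    asg <- assignReads(m, pair, max_mismatch_frac = 1)
    got_obj <- sum(asg$mismatches)
    expect_equal(got_obj, oracle_phase_objective(mat, ref, alt), info = rep)
  }
})

test_that("reconstruction and labels are read-order invariant", {
  set.seed(11)
  m <- bundle(c(rep("CCT", 20), rep("GAA", 25), "C.T", "GA."),
              ref = c("C", "C", "T"), alt = c("G", "A", "A"),
              samples = c(rep("pA", 20), rep("pB", 25), "hAB", "hBA"))
  perm <- sample(nrow(m$mat))
  m2 <- list(mat = m$mat[perm, , drop = FALSE], qname = m$qname[perm],
             sample = m$sample[perm], isoform = NULL,
             positions = m$positions, ref = m$ref, alt = m$alt)
  p1 <- reconstructTwoHaplotypes(m)
  p2 <- reconstructTwoHaplotypes(m2)
  expect_identical(haplotypes(p1), haplotypes(p2))
  sheet <- four_sample_sheet()
  l1 <- labelParentalAlleles(p1, assignReads(m, p1), sheet)
  l2 <- labelParentalAlleles(p2, assignReads(m2, p2), sheet)
  expect_identical(parentalLabels(l1), parentalLabels(l2))
  expect_equal(parentalLabels(l1)[match("CCT", haplotypes(l1))], "parentA")
})

test_that("reads regenerated from the pair re-assign with zero mismatches", {
  m <- bundle(c(rep("CTG", 15), rep("GAC", 15)), ref = c("C", "A", "C"),
              alt = c("G", "T", "G"))
  pair <- reconstructTwoHaplotypes(m)
  regen <- bundle(c(rep(pair@hap0, 10), rep(pair@hap1, 10)),
                  ref = m$ref, alt = m$alt)
  asg <- assignReads(regen, pair)
  expect_true(all(asg$mismatches == 0))
  expect_false(anyNA(asg$allele))
})

test_that("monomorphic read sets return the per-site complement", {
  m <- bundle(rep("CT", 25), ref = c("C", "T"), alt = c("A", "G"))
  pair <- reconstructTwoHaplotypes(m)
  expect_setequal(haplotypes(pair), c("CT", "AG"))
  expect_true("monomorphic-reads" %in% pair@flags)
  expect_equal(min(pair@support0, pair@support1), 0L)
})

test_that("assignment rules: exact match, uninformative, high-mismatch", {
  m <- bundle(c("CTCT", "....", "A...", "GAGA", "CTGA"),
              ref = c("C", "T", "C", "T"), alt = c("G", "A", "G", "A"))
  pair <- reconstructTwoHaplotypes(bundle(c(rep("CTCT", 10), rep("GAGA", 10)),
                                          ref = m$ref, alt = m$alt))
  asg <- assignReads(m, pair)
  expect_equal(asg$allele[1], asg$allele[4] - 1L)        # opposite alleles
  expect_equal(asg$mismatches[1], 0L)
  expect_true(is.na(asg$allele[2]))                      # spans no site
  expect_true(is.na(asg$allele[3]))                      # base outside {ref, alt}
  expect_true(is.na(asg$allele[5]))                      # equidistant
})

test_that("parental labelling handles ties, elimination and hybrid-only", {
  sheet <- four_sample_sheet()
  mk <- function(samples, rows) bundle(rows, ref = c("C", "T"), alt = c("G", "A"),
                                       samples = samples)
  base <- mk(c(rep("pA", 35), rep("hAB", 30)), c(rep("CT", 35), rep("GA", 30)))
  pair <- reconstructTwoHaplotypes(base)
  lab <- labelParentalAlleles(pair, assignReads(base, pair), sheet)
  hap_lab <- setNames(parentalLabels(lab), haplotypes(lab))
  expect_equal(unname(hap_lab["CT"]), "parentA")         # by majority
  expect_equal(unname(hap_lab["GA"]), "parentB")         # by elimination

  tie <- mk(c(rep("pA", 20), rep("pB", 10)),
            c(rep("CT", 10), rep("GA", 10), rep("GA", 10)))
  pt <- reconstructTwoHaplotypes(tie)
  lt <- labelParentalAlleles(pt, assignReads(tie, pt), sheet)
  expect_true("ambiguous-parentage" %in% lt@flags)
  expect_equal(parentalLabels(lt), c("unassigned", "unassigned"))

  hyb <- mk(rep(c("hAB", "hBA"), 20), rep(c("CT", "GA"), 20))
  ph <- reconstructTwoHaplotypes(hyb)
  lh <- labelParentalAlleles(ph, assignReads(hyb, ph), sheet)
  expect_true("hybrid-only" %in% lh@flags)
})

test_that("greedy search above the exhaustive bound still recovers truth", {
  set.seed(19)
  k <- 15
  ref <- rep("C", k); alt <- rep("G", k)
  a <- rbinom(k, 1, 0.5)
  h0 <- paste(ifelse(a == 0, "C", "G"), collapse = "")
  h1 <- paste(ifelse(a == 0, "G", "C"), collapse = "")
  rows <- c(rep(h0, 40), rep(h1, 40))
  mat <- do.call(rbind, strsplit(rows, ""))
  flip <- matrix(runif(80 * k) < 0.02, 80, k)
  mat[flip] <- ifelse(mat[flip] == "C", "G", "C")
  m <- list(mat = mat, qname = as.character(1:80), sample = rep("hAB", 80),
            isoform = NULL, positions = seq_len(k), ref = ref, alt = alt)
  pair <- reconstructTwoHaplotypes(m, max_exhaustive = 12L)
  expect_setequal(haplotypes(pair), c(h0, h1))
})

test_that("ISM-like reads vote only on their covered sites", {
  sheet <- four_sample_sheet()
  sim <- simulateGenes(n_genes = 1, snps_per_gene = 6, exons_per_gene = 3,
                       seed = 81)
  rd <- simulateReads(sim, sheet, error_rate = 0.02, trunc_prob = 0.5,
                      trunc_mean = 150, seed = 82)
  region <- list(chrom = "chrS", start = sim$genes$start[1],
                 end = sim$genes$end[1], gene_id = sim$genes$gene_id[1])
  pg <- phaseGene(rd$reads, region, sim$genome, sheet,
                  snpCallerParams(error_rate = 0.02))
  expect_equal(pg@status, "phased")
  asg <- pg@assignments
  truth_allele <- rd$truth$allele[match(asg$qname, rd$truth$qname)]
  hapA <- paste(sim$snps$ref[sim$snps$pos %in% pg@pair@positions], collapse = "")
  alleleA <- match(hapA, haplotypes(pg@pair)) - 1L
  ok <- !is.na(asg$allele) &
    asg$allele == ifelse(truth_allele == "A", alleleA, 1L - alleleA)
  expect_gte(mean(ok), 0.98)
})
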