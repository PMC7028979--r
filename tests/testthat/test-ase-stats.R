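ac_table <- function(rows) {
  # rows: list of c(gene, tissue, role, sample, nA, nB, nun)
  t <- do.call(rbind, lapply(rows, function(r)
    data.frame(feature_id = r[[1]], level = "gene", sample_id = r[[4]],
               tissue = r[[2]], role = r[[3]],
               n_parentA = as.integer(r[[5]]), n_parentB = as.integer(r[[6]]),
               n_unassigned = as.integer(r[[7]]))))
  new("AllelicCounts", table = t, labeled = TRUE)
}

test_that("allelic counts tally assigned reads per sample and conserve totals", {
  sheet <- four_sample_sheet()
  sim <- simulateGenes(n_genes = 2, snps_per_gene = 4, seed = 21)
  rd <- simulateReads(sim, sheet, error_rate = 0, trunc_prob = 0, seed = 22)
  phased <- lapply(seq_len(2), function(g) {
    region <- list(chrom = "chrS", start = sim$genes$start[g],
                   end = sim$genes$end[g], gene_id = sim$genes$gene_id[g])
    idx <- which(rd$truth$gene_id == sim$genes$gene_id[g])
    phaseGene(rd$reads[idx], region, sim$genome, sheet)
  })
  ac <- allelicCounts(phased, sheet)
  t <- countTable(ac)
  expect_true(ac@labeled)
  # parent samples express only their own allele (error-free simulation)
  expect_true(all(t$n_parentB[t$role == "parentA"] == 0))
  expect_true(all(t$n_parentA[t$role == "parentB"] == 0))
  # conservation: every simulated read lands in exactly one cell
  per <- aggregate(cbind(n = rep(1, nrow(rd$truth))),
                   rd$truth[, c("gene_id", "sample_id")], sum)
  tot <- t$n_parentA + t$n_parentB + t$n_unassigned
  expect_equal(sum(tot), nrow(rd$truth))
  i <- match(paste(t$feature_id, t$sample_id), paste(per$gene_id, per$sample_id))
  expect_equal(tot, per$n[i])
})

test_that("monoallelic detection distinguishes strain and parent-of-origin frames", {
  rows <- function(g, ab, ba) list(
    c(g, "embryo", "hybridAB", "hAB", ab[1], ab[2], 0),
    c(g, "embryo", "hybridBA", "hBA", ba[1], ba[2], 0))
  ac <- ac_table(c(
    rows("gA", c(30, 0), c(25, 1)),       # strain-A monoallelic
    rows("gNo", c(30, 0), c(15, 15)),     # inconsistent -> none
    rows("gMat", c(30, 0), c(1, 29)),     # maternal in both hybrids
    rows("gLow", c(5, 0), c(6, 0))))      # below min_total
  hit <- detectMonoallelic(ac)
  expect_equal(hit$allele[hit$gene == "gA"], "parentA")
  expect_equal(hit$allele[hit$gene == "gMat"], "maternal")
  expect_false(any(hit$gene %in% c("gNo", "gLow")))
})

test_that("balanced allelic counts almost never look monoallelic", {
  set.seed(33)
  n <- 1000
  rows <- list()
  for (g in seq_len(n)) {
    for (role in c("hybridAB", "hybridBA")) {
      tot <- 10L + rpois(1, 15)
      a <- rbinom(1, tot, 0.5)
      rows[[length(rows) + 1L]] <- c(sprintf("g%04d", g), "embryo", role,
                                     ifelse(role == "hybridAB", "hAB", "hBA"),
                                     a, tot - a, 0)
    }
  }
  hit <- detectMonoallelic(ac_table(rows))
  expect_lte(nrow(hit) / n, 0.01)
})

test_that("imprinting thresholds reproduce the dosage formula exactly", {
  thr <- imprintingThresholds(2, 1, 5)
  expect_identical(unname(thr["maternal"]), 10 / 11)
  expect_identical(unname(thr["paternal"]), 5 / 7)
  expect_equal(unname(imprintingThresholds(1, 1, 1)), c(0.5, 0.5))
  # swapping dosages exchanges the roles
  a <- imprintingThresholds(3, 2, 5); b <- imprintingThresholds(2, 3, 5)
  expect_equal(unname(a["maternal"]), unname(b["paternal"]))
  # limits: infinite stringency pushes both thresholds to 1
  expect_equal(unname(imprintingThresholds(1, 1, 1e12)), c(1, 1),
               tolerance = 1e-10)
  expect_error(imprintingThresholds(0, 1, 5), ">= 1")
})

test_that("imprinting calls separate parent-of-origin from strain effects", {
  ac <- ac_table(list(
    # MEG: maternal-biased in both reciprocal hybrids (endosperm example)
    c("gMEG", "endosperm", "hybridAB", "hAB", 40, 2, 0),
    c("gMEG", "endosperm", "hybridBA", "hBA", 3, 45, 0),
    # strain effect: parentA allele dominant in both -> not imprinting
    c("gStr", "endosperm", "hybridAB", "hAB", 40, 2, 0),
    c("gStr", "endosperm", "hybridBA", "hBA", 45, 3, 0),
    # missing reciprocal
    c("gHalf", "endosperm", "hybridAB", "hAB", 30, 1, 0)))
  res <- callImprinting(ac, "endosperm")
  expect_equal(res$status[res$gene == "gMEG"], "MEG")
  expect_equal(res$Bm_hybridAB[res$gene == "gMEG"], 40 / 42)
  expect_equal(res$Bm_hybridBA[res$gene == "gMEG"], 45 / 48)
  expect_equal(res$status[res$gene == "gStr"], "none")
  expect_equal(res$status[res$gene == "gHalf"], "unevaluable")
})

test_that("a 10:1 paternal regime clears the endosperm PEG threshold", {
  r <- simulateRegimes("imprinting", n_genes = 90, seed = 7)
  res <- callImprinting(r$data, "endosperm")
  res <- res[match(r$truth$gene, res$gene), ]
  peg <- r$truth$status == "PEG"
  expect_gte(mean(res$status[peg] == "PEG"), 0.9)   # Bp ~ 10/11 > 5/7
  bal <- r$truth$status == "none"
  expect_true(all(res$status[bal] == "none"))
  # MEG truth genes are never mistaken for PEGs
  expect_false(any(res$status[r$truth$status == "MEG"] == "PEG"))
})

test_that("regulatory categories match the three-test pattern and its oracle", {
  # no signal anywhere
  expect_equal(classifyRegulatory(100, 100, 50, 50)$category, "conserved")
  # parents 200:50, hybrid 160:40 -> parental divergence + cis, no trans
  r1 <- classifyRegulatory(200, 50, 160, 40)
  expect_equal(r1$category, "cis-only")
  expect_equal(r1$p_parental, oracle_binom_two_sided(200, 250, 0.5), tolerance = 1e-9)
  expect_equal(r1$p_cis, oracle_binom_two_sided(160, 200, 0.5), tolerance = 1e-9)
  expect_equal(r1$p_trans, oracle_fisher_two_sided(200, 50, 160, 40), tolerance = 1e-7)
  # parents 200:50, hybrid 52:48 -> divergence + trans, no cis
  r2 <- classifyRegulatory(200, 50, 52, 48)
  expect_equal(r2$category, "trans-only")
  expect_equal(r2$p_trans, oracle_fisher_two_sided(200, 50, 52, 48), tolerance = 1e-7)
  # empty margin
  expect_equal(classifyRegulatory(0, 0, 50, 50)$category, "unevaluable")
})

test_that("regulatory classification is symmetric under allele swap", {
  set.seed(9)
  for (i in 1:20) {
    a <- rbinom(4, 300, runif(4, 0.2, 0.8)) + 1
    r <- classifyRegulatory(a[1], a[2], a[3], a[4])
    s <- classifyRegulatory(a[2], a[1], a[4], a[3])
    expect_identical(r$category, s$category)
    if (!r$category %in% c("unevaluable")) {
      expect_equal(r$dir_parental, -s$dir_parental)
      expect_equal(r$dir_hybrid, -s$dir_hybrid)
    }
  }
})

test_that("additive expectation uses the 2m:1p endosperm weights", {
  r <- additiveTest(c(6, 6), c(3, 3), c(5, 5), tissue = "endosperm")
  expect_equal(unique(r$expected), 5)                   # (2*6 + 3)/3
  expect_equal(r$t, 0)
  expect_equal(r$status, "additive")
  r2 <- additiveTest(c(6, 6), c(3, 3), c(4.5, 4.5), tissue = "embryo")
  expect_equal(unique(r2$expected), 4.5)                # midparent
  expect_equal(additiveTest(6, 3, c(5, 5))$status, "unevaluable")
})

test_that("additive test detects 2x deviations and keeps its size at n = 2", {
  r <- simulateRegimes("additive", n_genes = 200, seed = 15)
  calls <- vapply(names(r$data), function(g) {
    d <- r$data[[g]]
    additiveTest(d$maternal, d$paternal, d$hybrid, tissue = "endosperm")$status
  }, "")
  nonadd <- r$truth$status == "non-additive"
  expect_gte(mean(calls[nonadd] == "non-additive"), 0.95)
  expect_lte(mean(calls[!nonadd] == "non-additive"), 0.10)
})

test_that("additiveCalls pairs inbred replicates from the sheet", {
  sheet <- defaultSampleSheet()
  sid <- sheetEntries(sheet)
  cols <- unlist(lapply(sid$sample_id[sid$tissue == "endosperm"],
                        paste0, ".", 1:2))
  m <- matrix(10, 2, length(cols), dimnames = list(c("g1", "g2"), cols))
  pa <- grep("^B73\\.endosperm", cols); pb <- grep("^Ki11\\.endosperm", cols)
  m["g1", pa] <- 9; m["g1", pb] <- 3                     # expected AB = 7
  m["g1", grep("^B73xKi11", cols)] <- 7                  # additive
  m["g2", pa] <- 9; m["g2", pb] <- 3
  m["g2", grep("^B73xKi11", cols)] <- c(14.2, 13.8)      # ~2x expected
  res <- additiveCalls(m, sheet, "endosperm")
  ab <- res[res$hybrid == "hybridAB", ]
  expect_equal(ab$status[ab$gene == "g1"], "additive")
  expect_equal(ab$status[ab$gene == "g2"], "non-additive")
})
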