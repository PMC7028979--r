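## Downstream allelic statistics: allelic count tables, monoallelic
## expression, genomic imprinting under endosperm dosage, cis/trans
## regulatory classification, and additive vs non-additive hybrid expression.

#' Allelic full-length read counts per feature and sample
#'
#' Tallies the assigned reads of phased genes per allele, sample and feature
#' (gene or isoform). When the alleles carry parental labels, counts are
#' reported as parentA/parentB; otherwise as allele0/allele1 with a warning
#' and parent-of-origin statistics disabled.
#'
#' @param phased a [PhasedGene-class] or list of them
#' @param sheet a [SampleSheet-class]
#' @param level \code{"gene"} or \code{"isoform"} (isoform requires the
#'   assignments to carry an \code{isoform} column)
#' @return an [AllelicCounts-class]
#' @export
allelicCounts <- function(phased, sheet, level = c("gene", "isoform")) {
  level <- match.arg(level)
  if (is(phased, "PhasedGene")) phased <- list(phased)
  e <- sheetEntries(sheet)
  rows <- list()
  labeled_all <- TRUE
  for (pg in phased) {
    if (pg@status %in% c("insufficient-coverage", "no-SNP")) next
    asg <- pg@assignments
    labels <- parentalLabels(pg)
    labeled <- !any(labels == "unassigned")
    labeled_all <- labeled_all && labeled
    idxA <- if (labeled) which(labels == "parentA") - 1L else 0L
    feat <- if (level == "gene") rep(pg@gene_id, nrow(asg)) else {
      if (is.null(asg$isoform))
        stop("isoform-level counts need isoform ids in the assignments")
      asg$isoform
    }
    d <- data.frame(feature_id = feat, sample_id = asg$sample,
                    allele = asg$allele)
    for (key in unique(paste(d$feature_id, d$sample_id, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      x <- d[d$feature_id == parts[1] & d$sample_id == parts[2], ]
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = parts[1], level = level, sample_id = parts[2],
        n_parentA = sum(x$allele == idxA, na.rm = TRUE),
        n_parentB = sum(x$allele == (1L - idxA), na.rm = TRUE),
        n_unassigned = sum(is.na(x$allele)))
    }
  }
  t <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(), level = character(),
               sample_id = character(), n_parentA = integer(),
               n_parentB = integer(), n_unassigned = integer())
  i <- match(t$sample_id, e$sample_id)
  t$tissue <- e$tissue[i]
  t$role <- e$role[i]
  t <- t[, c("feature_id", "level", "sample_id", "tissue", "role",
             "n_parentA", "n_parentB", "n_unassigned")]
  if (!labeled_all)
    warning("unlabeled alleles: counts keyed allele0/allele1; ",
            "parent-of-origin statistics disabled")
  new("AllelicCounts", table = t, labeled = labeled_all)
}

.hyb_sums <- function(t, gene, tissue, role) {
  x <- t[t$feature_id == gene & t$tissue == tissue & t$role == role, , drop = FALSE]
  if (!nrow(x)) return(NULL)
  c(A = sum(x$n_parentA), B = sum(x$n_parentB))
}

#' Detect monoallelically expressed genes
#'
#' A gene is monoallelic in a tissue when, in both reciprocal hybrids, the
#' total assigned count reaches \code{min_total} and the same allele carries
#' at least \code{min_fraction} of it. The dominant allele may agree in the
#' strain frame (the same parental strain in both hybrids) or in the
#' parent-of-origin frame (the maternal, or the paternal, allele in both),
#' and the reported \code{allele} says which.
#'
#' @param counts an [AllelicCounts-class] with parental labels
#' @param min_total minimum assigned reads per hybrid (default 10)
#' @param min_fraction dominant-allele fraction (default 0.95)
#' @return data.frame: \code{gene}, \code{tissue}, \code{allele} in
#'   \{parentA, parentB, maternal, paternal\}
#' @export
detectMonoallelic <- function(counts, min_total = 10L, min_fraction = 0.95) {
  stopifnot(is(counts, "AllelicCounts"))
  if (!counts@labeled) stop("parent-labeled counts required")
  t <- countTable(counts)
  out <- list()
  for (g in unique(t$feature_id)) for (ti in unique(t$tissue[t$feature_id == g])) {
    ab <- .hyb_sums(t, g, ti, "hybridAB")
    ba <- .hyb_sums(t, g, ti, "hybridBA")
    if (is.null(ab) || is.null(ba)) next
    if (sum(ab) < min_total || sum(ba) < min_total) next
    fab <- ab["A"] / sum(ab); fba <- ba["A"] / sum(ba)
    allele <- if (fab >= min_fraction && fba >= min_fraction) "parentA"
      else if (fab <= 1 - min_fraction && fba <= 1 - min_fraction) "parentB"
      ## maternal allele is parentA in hybridAB, parentB in hybridBA
      else if (fab >= min_fraction && fba <= 1 - min_fraction) "maternal"
      else if (fab <= 1 - min_fraction && fba >= min_fraction) "paternal"
      else NA_character_
    if (!is.na(allele))
      out[[length(out) + 1L]] <- data.frame(gene = g, tissue = ti, allele = allele)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), tissue = character(), allele = character())
}

#' Imprinting thresholds under parental genome dosage
#'
#' With maternal dosage \code{d_m}, paternal dosage \code{d_p} and a
#' required fold \code{f} between the active and the repressed allele, the
#' maternal fraction must exceed \code{f*d_m / (f*d_m + d_p)} for a
#' maternally expressed gene and the paternal fraction
#' \code{f*d_p / (f*d_p + d_m)} for a paternally expressed one. Triploid
#' endosperm (2m:1p) at fold 5 gives 10/11 and 5/7.
#'
#' @param d_m,d_p maternal and paternal genome dosage (integers >= 1)
#' @param f fold requirement (default 5)
#' @return named numeric: \code{maternal}, \code{paternal}
#' @export
imprintingThresholds <- function(d_m, d_p, f = 5) {
  if (d_m < 1 || d_p < 1 || f < 1) stop("d_m, d_p and f must be >= 1")
  c(maternal = f * d_m / (f * d_m + d_p),
    paternal = f * d_p / (f * d_p + d_m))
}

#' Call imprinted genes from allelic counts
#'
#' Per gene and tissue, computes the maternal fraction Bm in each reciprocal
#' hybrid (the maternal allele is the parentA allele in hybridAB and the
#' parentB allele in hybridBA: parent of origin, not strain). A gene is MEG
#' when Bm exceeds the maternal threshold in both hybrids with at least
#' \code{min_total} assigned reads each, PEG when Bp = 1 - Bm exceeds the
#' paternal threshold in both. Endosperm uses 2m:1p dosage; other tissues
#' 1:1. Genes missing a reciprocal hybrid are reported \code{unevaluable}.
#'
#' @param counts an [AllelicCounts-class] with parental labels
#' @param tissue tissue to evaluate
#' @param f fold requirement (default 5)
#' @param min_total minimum assigned reads per hybrid (default 10)
#' @return data.frame: \code{gene}, \code{tissue}, \code{Bm_hybridAB},
#'   \code{Bm_hybridBA}, \code{status} in \{MEG, PEG, none, unevaluable\}
#' @export
callImprinting <- function(counts, tissue, f = 5, min_total = 10L) {
  stopifnot(is(counts, "AllelicCounts"))
  if (!counts@labeled) stop("parent-labeled counts required")
  dm <- if (tissue == "endosperm") 2L else 1L
  dp <- 1L
  thr <- imprintingThresholds(dm, dp, f)
  t <- countTable(counts)
  t <- t[t$tissue == tissue, , drop = FALSE]
  out <- list()
  for (g in unique(t$feature_id)) {
    ab <- .hyb_sums(t, g, tissue, "hybridAB")
    ba <- .hyb_sums(t, g, tissue, "hybridBA")
    if (is.null(ab) || is.null(ba) || sum(ab) == 0 || sum(ba) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        gene = g, tissue = tissue, Bm_hybridAB = NA_real_,
        Bm_hybridBA = NA_real_, status = "unevaluable")
      next
    }
    bm_ab <- ab["A"] / sum(ab)          # maternal = parentA strain
    bm_ba <- ba["B"] / sum(ba)          # maternal = parentB strain
    enough <- sum(ab) >= min_total && sum(ba) >= min_total
    status <- if (enough && bm_ab > thr["maternal"] && bm_ba > thr["maternal"]) "MEG"
      else if (enough && (1 - bm_ab) > thr["paternal"] && (1 - bm_ba) > thr["paternal"]) "PEG"
      else "none"
    out[[length(out) + 1L]] <- data.frame(
      gene = g, tissue = tissue, Bm_hybridAB = unname(bm_ab),
      Bm_hybridBA = unname(bm_ba), status = status)
  }
  do.call(rbind, out)
}

#' Classify cis/trans regulatory divergence of a gene
#'
#' Compares the expression ratio of the two parental alleles in the
#' homozygous parents with the allelic ratio inside the F1 hybrids. Three
#' exact tests at level \code{alpha}: parental divergence (two-sided binomial
#' of the parentA count against the library-size ratio), cis effect
#' (two-sided binomial of the hybrid parentA-allele count against 1/2), and
#' trans effect (two-sided Fisher's exact test comparing the parental with
#' the hybrid ratio). Categories: \emph{cis-only} (P and C, not T),
#' \emph{trans-only} (P and T, not C), \emph{cis+trans} (C and T, parental
#' and hybrid log-ratios same sign), \emph{cis x trans} (C and T, opposite
#' signs), \emph{conserved} (none significant), else \emph{ambiguous}.
#'
#' @param a_P,b_P gene-level FL counts in the parentA / parentB samples,
#'   library-size normalised to effective counts
#' @param a_H,b_H allelic FL counts in the hybrids (pooled over the
#'   reciprocal hybrids), parentA / parentB allele
#' @param alpha significance level (default 0.05)
#' @param null_ratio expected parentA share under equal expression, i.e. the
#'   parents' library-size ratio (default 0.5)
#' @return data.frame with one row per gene: \code{category},
#'   \code{p_parental}, \code{p_cis}, \code{p_trans}, \code{dir_parental},
#'   \code{dir_hybrid}
#' @export
classifyRegulatory <- function(a_P, b_P, a_H, b_H, alpha = 0.05,
                               null_ratio = 0.5) {
  n <- length(a_P)
  stopifnot(length(b_P) == n, length(a_H) == n, length(b_H) == n)
  out <- data.frame(category = character(n), p_parental = NA_real_,
                    p_cis = NA_real_, p_trans = NA_real_,
                    dir_parental = NA_real_, dir_hybrid = NA_real_)
  for (i in seq_len(n)) {
    NP <- a_P[i] + b_P[i]; NH <- a_H[i] + b_H[i]
    if (NP == 0 || NH == 0) { out$category[i] <- "unevaluable"; next }
    pP <- binom.test(round(a_P[i]), round(NP), p = null_ratio)$p.value
    pC <- binom.test(round(a_H[i]), round(NH), p = 0.5)$p.value
    pT <- fisher.test(matrix(round(c(a_P[i], b_P[i], a_H[i], b_H[i])),
                             2, 2, byrow = TRUE))$p.value
    sP <- pP < alpha; sC <- pC < alpha; sT <- pT < alpha
    ## direction: log allelic ratio, parental one centred on the null ratio
    dP <- log((a_P[i] / b_P[i]) / (null_ratio / (1 - null_ratio)))
    dH <- log(a_H[i] / b_H[i])
    cat <- if (sP && sC && !sT) "cis-only"
      else if (sP && sT && !sC) "trans-only"
      else if (sC && sT && sign(dP) == sign(dH)) "cis+trans"
      else if (sC && sT && sign(dP) != sign(dH)) "cisxtrans"
      else if (!sP && !sC && !sT) "conserved"
      else "ambiguous"
    out$category[i] <- cat
    out$p_parental[i] <- pP; out$p_cis[i] <- pC; out$p_trans[i] <- pT
    out$dir_parental[i] <- sign(dP); out$dir_hybrid[i] <- sign(dH)
  }
  out
}

#' Test a hybrid for additive expression
#'
#' The expected additive value is computed replicate-by-replicate from the
#' inbred parents: \code{(2*maternal + paternal)/3} in endosperm (2m:1p
#' dosage) and the midparent \code{(maternal + paternal)/2} elsewhere. The
#' hybrid replicates are compared with the expected values by a two-tailed
#' pooled-variance (homoscedastic) t test; \code{p < alpha} is called
#' non-additive. Each reciprocal hybrid is tested independently.
#'
#' @param maternal,paternal inbred expression replicates of the maternal and
#'   paternal parent (equal length, >= 2)
#' @param hybrid hybrid expression replicates (>= 2)
#' @param tissue tissue name; \code{"endosperm"} switches the 2m:1p weights
#' @param alpha significance level (default 0.05)
#' @return list: \code{expected} (per-replicate expected values),
#'   \code{t}, \code{p}, \code{status} in \{additive, non-additive,
#'   unevaluable\}
#' @export
additiveTest <- function(maternal, paternal, hybrid, tissue = "embryo",
                         alpha = 0.05) {
  if (length(maternal) != length(paternal) || length(maternal) < 2 ||
      length(hybrid) < 2)
    return(list(expected = NA_real_, t = NA_real_, p = NA_real_,
                status = "unevaluable"))
  expected <- if (tissue == "endosperm") (2 * maternal + paternal) / 3
    else (maternal + paternal) / 2
  tt <- tryCatch(t.test(hybrid, expected, var.equal = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) {  # both sides constant
    same <- isTRUE(all.equal(mean(hybrid), mean(expected)))
    tt <- list(statistic = if (same) 0 else Inf, p.value = if (same) 1 else 0)
  }
  list(expected = expected, t = unname(tt$statistic), p = tt$p.value,
       status = if (tt$p.value < alpha) "non-additive" else "additive")
}

#' Additive-expression calls over an expression matrix
#'
#' Columns must be named \code{<sample_id>.<replicate>} with sample ids from
#' the sheet. For each hybrid role and tissue the maternal and paternal
#' inbred replicates are paired and [additiveTest()] applied per gene.
#'
#' @param expr numeric gene x sample_rep matrix ([readExpressionMatrix()])
#' @param sheet a [SampleSheet-class]
#' @param tissue tissue to evaluate
#' @param alpha significance level
#' @return data.frame: gene, hybrid role, tissue, t, p, status
#' @export
additiveCalls <- function(expr, sheet, tissue, alpha = 0.05) {
  e <- sheetEntries(sheet)
  cols_of <- function(role) {
    sid <- e$sample_id[e$role == role & e$tissue == tissue]
    grep(paste0("^(", paste(sid, collapse = "|"), ")\\."), colnames(expr))
  }
  out <- list()
  for (role in c("hybridAB", "hybridBA")) {
    hyb <- cols_of(role)
    mat_role <- maternalRole(role)
    pat_role <- setdiff(c("parentA", "parentB"), mat_role)
    mcols <- cols_of(mat_role); pcols <- cols_of(pat_role)
    if (!length(hyb) || !length(mcols) || !length(pcols)) next
    for (g in rownames(expr)) {
      r <- additiveTest(expr[g, mcols], expr[g, pcols], expr[g, hyb],
                        tissue, alpha)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, hybrid = role, tissue = tissue,
        t = r$t, p = r$p, status = r$status)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), hybrid = character(), tissue = character(),
               t = double(), p = double(), status = character())
}
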