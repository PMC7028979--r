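---
title: "Isoform-level haplotype phasing and allelic statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-level haplotype phasing and allelic statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isohap)
```

## The problem

In an F1 hybrid of two inbred lines, every gene carries two parental
alleles. Full-length cDNA reads from long-read sequencing cover a transcript
end to end, so a single read observes every heterozygous site of its
molecule at once — an ideal substrate for phasing a gene into its two
alleles and counting molecule-level allele-specific expression. `isohap`
implements that pipeline for a multiplexed design of two homozygous parents
and their two reciprocal hybrids (A×B and B×A, maternal parent first),
sampled across tissues: upstream transcript-model construction and
filtering, per-gene SNP calling, haplotype reconstruction, parent-of-origin
labelling, and the downstream allelic statistics (monoallelic expression,
genomic imprinting under endosperm dosage, cis/trans regulatory
classification, additive versus non-additive hybrid expression), plus
rarefaction and multi-rater agreement utilities.

All internal coordinates are 0-based half-open; conversion happens only at
the format boundaries (GFF3 and VCF are 1-based). Alignments are inputs —
the package consumes SAM/BAM produced by a splice-aware aligner and never
aligns reads itself.

## Transcript models and artifact filtering

Aligned full-length reads are first gated on alignment quality (query
coverage ≥ 0.99 and identity ≥ 0.95, both inclusive) and then collapsed by
their splice-junction chain: multi-exon reads with identical intron chains
on one strand become one model whose terminal exons take the union span;
mono-exon reads merge by same-strand overlap. By default a read whose chain
is a strict 5′-truncated suffix of a longer chain is kept as its own model
(the degradation-aware behaviour of junction-chain collapse with 5′ merging
disabled), because 5′-incomplete molecules are common in full-length cDNA
and deserve separate accounting. Locus identifiers are connected components
of same-strand model overlap; isoform numbers within a locus follow
descending full-length read support, with ties broken by leftmost start and
then lexicographic chain so the numbering is deterministic.

Each model is classified against a reference annotation: FSM (chain
identical to a reference transcript), ISM (strict 5′-truncated suffix of a
reference chain), NIC (all donor and acceptor sites individually annotated
but the chain novel), NNC (at least one novel splice site), and genic /
antisense / intergenic for models without same-strand structural support.
Two deliberate readings of category edges: ISM is restricted to 5′
truncation — a 3′-truncated sub-chain is treated as a novel combination —
and NIC/NNC require same-strand overlap with an annotated gene, so novel
chains in unannotated space fall to antisense/intergenic. Mono-exon models
match FSM only against mono-exon reference transcripts.

Retention mirrors standard long-read QC practice: FSM/ISM/NIC survive
unless intra-primed; all other categories additionally require no
RT-switching and every junction canonical (GT–AG, GC–AG, AT–AC on the
transcript strand) or supported by a short-read junction table. The
intra-priming test flags a model whose 20 genomic bases downstream of the
3′ end are ≥ 60% adenine on the transcript strand; both the window and the
fraction are exposed because they are conventional defaults rather than
derived quantities. RT-switching has no agreed operational definition, so
the default predicate never fires; an optional direct-repeat heuristic
(exact ≥ 8 bp repeat at donor and acceptor) can be plugged in — we prefer
an explicit opt-in over silently inventing a filter.

## SNP calling

For each gene, aligned bases of all samples are pooled into a pileup.
Only match/mismatch columns count: insertions are ignored and deletions
contribute nothing, so the caller is substitution-only by construction.
At every position with coverage N ≥ 10, the most frequent non-reference
base (count $n_{alt}$, ties to the lexicographically smallest) is compared
with the count expected from residual sequencing error,
$E = \max(1, \mathrm{round}(N\varepsilon))$, by a one-sided Fisher's exact
test on the table $[[n_{alt}, N-n_{alt}], [E, N-E]]$; the p value is the
hypergeometric upper tail at the table's margins. The residual error rate
$\varepsilon$ defaults to 0.005, the scale left in consensus transcripts
polished to ≥ 99% predicted accuracy, and should be set to the data's
actual error level. Bonferroni correction is applied per gene — the
denominator is the number of positions actually tested in that gene
(coverage ≥ 10 and $n_{alt} > 0$) — because phasing is a per-gene
procedure; calls require adjusted p < 0.01. Genes with fewer than 40
full-length reads are not called at all. Sites where a third base exceeds
half the alternative count are flagged "messy" and kept out of phasing:
they usually indicate collapsed paralogs or alignment artifacts rather
than a clean biallelic site.

A consequence worth knowing: with the error-count null, a site whose minor
allele is carried by only ~10 reads has a raw p around $3\text{–}5\times
10^{-3}$, which cannot survive a per-gene Bonferroni over tens of tested
positions at α = 0.01. Reliable calling needs the minor allele on roughly
15–20 reads — naturally satisfied in this design, where a gene passing the
40-read gate has each allele on about half its reads.

## Haplotype reconstruction and parental labelling

Over the called SNP sites, each read contributes its aligned base per site
(missing where it does not cover the site or has a deletion; bases outside
{ref, alt} are kept verbatim and count as mismatches to both alleles). The
two allele strings are the pair $(h_0, h_1)$ minimising
$\sum_r \min(d(r,h_0), d(r,h_1))$, where $d$ is the Hamming distance over
the read's non-missing sites, under the constraint that the pair uses
exactly {ref, alt} at every site. "Edit distance" reduces to Hamming
distance here because sites are fixed reference coordinates — reads are
anchored by alignment and indels are excluded upstream. The constraint
makes one haplotype the per-site complement of the other, so with $k$ sites
there are $2^{k-1}$ phasings; up to $k = 12$ (a flag) the search is
exhaustive, beyond that a greedy search seeded from the most frequent
complete read pattern with per-site majority refinement takes over. Ties
are broken by larger assigned-read support, then lexicographically — the
result is deterministic and invariant to read order.

Reads are then assigned to their nearer allele over their informative
sites; equidistant reads, reads with no informative site, and reads with
mismatch fraction above 0.5 stay unassigned. 5′-truncated (ISM-like) reads
are first-class: they simply vote on fewer sites. If the best pair still
leaves more than 20% of reads at distance above 20% of their informative
sites, the gene is flagged `possible-paralog` instead of being phased
silently — a third haplotype in the pileup is the usual cause. Parent
labels come from the homozygous parents, which each express exactly one
allele: each parent's assigned reads vote, a strict majority labels the
allele, a missing parent is labelled by elimination, and contradictions or
ties flag `ambiguous-parentage` (no parental reads at all:
`hybrid-only`).

## Downstream allelic statistics

**Allelic counts.** Per gene (or isoform) and sample, assigned reads are
tallied per labelled allele, with unassigned reads tracked separately.

**Monoallelic expression.** A gene is monoallelic in a tissue when both
reciprocal hybrids have ≥ 10 assigned reads and the same allele carries
≥ 95% of them. The dominant allele may agree in the strain frame or in the
parent-of-origin frame (maternal/paternal), and the call reports which —
the reciprocal cross is exactly what separates the two. The thresholds are
package choices (the analysis needs *some* operational rule) and are
exposed as arguments.

**Imprinting.** With maternal dosage $d_m$, paternal dosage $d_p$ and a
required fold $f$ between active and repressed allele, the maternal
fraction must exceed $f d_m / (f d_m + d_p)$ for an MEG and the paternal
fraction $f d_p / (f d_p + d_m)$ for a PEG. Triploid endosperm (2m:1p) at
the default $f = 5$ gives 10/11 and 5/7; diploid tissues give 5/6 both
ways. Bm is computed per gene from summed haplotype read counts, per
reciprocal hybrid, with the maternal allele resolved by parent of origin
(parentA's allele in A×B, parentB's in B×A); a call requires the threshold
exceeded in *both* hybrids with ≥ 10 assigned reads each, which is what
distinguishes imprinting from a strain effect. Note a boundary fact: a
maternal:paternal ratio of exactly 10:1 sits *at* the endosperm MEG
threshold (10/11), so genes simulated at that ratio are detected only when
sampling noise pushes them above it; the calibration checks therefore
assess fold-10 detection in diploid tissue, where 10:1 clears 5/6 with
room, and use the endosperm for the PEG direction (10:1 ≫ 5/7).

**Cis/trans classification.** Per gene, three exact tests at α = 0.05
compare (i) the parental counts against the library-size ratio (parental
divergence, exact binomial), (ii) the hybrid allelic counts against 1/2
(cis effect, exact binomial), and (iii) the parental against the hybrid
ratio (trans effect, Fisher's exact). Categories follow the significance
pattern: cis-only (P ∧ C ∧ ¬T), trans-only (P ∧ T ∧ ¬C), cis+trans (C ∧ T,
parental and hybrid log-ratios same sign), cis×trans (C ∧ T, opposite
signs), conserved (nothing significant), else ambiguous. The test
machinery is a package decision — count-exact tests without a dispersion
model, unadjusted α — appropriate for low molecule-level counts; a
Benjamini–Hochberg screen can be applied by the caller to the returned p
values. The endosperm dosage deliberately does **not** move the cis null
off 1/2: dosage is a parent-of-origin phenomenon and is owned by the
imprinting module; mixing it into the strain-level cis test would
conflate the two. Because "conserved" requires three simultaneous
non-rejections, its per-gene accuracy under calibration sits near
$0.965^3 \approx 0.90$ — it is the marginal regime by construction, while
the effect regimes classify at 0.95–1.0.

**Additive expression.** The expected additive value is built replicate by
replicate from the inbred parents — $(2m_i + p_i)/3$ in endosperm to honour
the 2m:1p genome dosage, the midparent $(m_i + p_i)/2$ elsewhere — and
compared with the hybrid replicates by a two-tailed pooled-variance
(homoscedastic) t test at α = 0.05, each reciprocal hybrid independently.
With two replicates a side the test has df = 2 and little power; it is
reproduced as defined rather than "improved", and the calibration suite
documents its behaviour at that n.

## Rarefaction and agreement

Discovery saturation is assessed by subsampling the read-to-feature map
without replacement at 10,000-read intervals, 100 draws per size, under a
fixed seed. The mean distinct-feature count has the closed form
$\sum_f \left(1 - \binom{N-n_f}{s}/\binom{N}{s}\right)$, which the package
also exposes (`expectedDistinct`) and the tests use as an oracle. Fleiss'
kappa is implemented from its definition (per-subject pairwise agreement
against squared marginal proportions); genotype-group labels treat a
feature as expressed in a sample at ≥ 1 full-length read and categorise it
by the set of genotypes expressing it within a tissue.

## The synthetic-data generator

`simulateGenes`/`simulateReads` build a synthetic chromosome of multi-exon
genes whose haplotype B differs from the reference haplotype A by planted
exonic substitutions, then emit multiplexed full-length reads *born
aligned* (CIGARs follow from the known isoform structure): parents receive
reads from their own allele only, hybrids from both; errors are i.i.d.
substitutions (default 0.005, the consensus-read scale); 5′ truncation with
geometric length models degradation and produces ISM-like reads; an
optional deletion rate exists solely to exercise the substitution-only
contract. The default design is the 12-sample sheet (2 parents + 2
reciprocal hybrids × 3 tissues). `simulateRegimes` generates the
downstream count/expression regimes with known truth: imprinting ratios
10:1 / 1:10 / 1:1 at 50 counts per hybrid, the five regulatory regimes at
4-fold effects and 400-count margins, and additive/non-additive expression
with two replicates at 5% CV and a 2× deviation.

What the generator deliberately does **not** model: realistic long-read
error profiles (homopolymer indels dominate real data; the caller excludes
indels by design, so i.i.d. substitutions are the relevant stressor),
alignment ambiguity and mapping errors, reference bias, barcode
misassignment beyond a simple mislabeling option, and multi-gene families
collapsing onto one locus. Passing tests therefore demonstrate the
statistical machinery under its stated model, not robustness to
misalignment — on real data the `messy`-site and `possible-paralog` guards
are the first line of defence.

## Problem sizes and numerical choices

The validation suites run at sizes chosen to make their binomial margins
meaningful on a single CPU in minutes: 500 phased genes (2–10 SNPs, ≥ 40
reads) for end-to-end recovery, 200 SNP-free genes (100 reads × 500 bp) for
caller calibration, 200 genes per regulatory regime, 30,000 reads over
5,000 features for rarefaction, and exhaustive Fisher-oracle comparison
over all tables up to 200× coverage. Exact-test p values are computed with
`phyper`/`binom.test`/`fisher.test`; the test oracles re-enumerate the same
quantities from `lchoose` sums so that the two routes stay independent.
Degenerate inputs have defined behaviour throughout: empty pileups return
empty call sets, one observed haplotype returns its per-site complement
flagged `monomorphic-reads`, constant t-test inputs return t = 0 (equal
means) rather than an error, and perfect rater agreement returns κ = 1
while single-category tables raise a degenerate-margins error.

## Known limitations

* Phasing assumes exactly two haplotypes; polyploid genes and collapsed
  paralogs are flagged, not resolved.
* Multi-mapping reads are dropped with their secondary alignments; genes in
  recently duplicated regions will be under-covered.
* The Bonferroni scope is per gene; a genome-wide correction is a caller
  option but changes the coverage needed per SNP (see the power note
  above).
* Bm is gene-level from haplotype counts; a per-SNP Bm variant would
  behave differently at genes with internal recombination or isoform-
  specific imprinting.
* The additive test at two replicates has the low power inherent to its
  definition.
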