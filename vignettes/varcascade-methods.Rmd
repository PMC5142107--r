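---
title: "Methods: recessive variant prioritization and splice-consequence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive variant prioritization and splice-consequence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcascade)
```

# Scope

varcascade implements the analysis path by which a recessive disease gene is
identified from whole-exome data of a handful of unrelated families: a
four-step variant filtering cascade, pedigree segregation tests with phase
inference under partial parental genotyping, and transcript-coordinate
arithmetic that converts aberrant splicing events into protein-level HGVS
consequences. A synthetic cohort generator produces exome-scale fixtures
with planted causal configurations so that the entire path is exercisable
and testable without access to any real exome. The motivating use case is
anterior segment dysgenesis caused by biallelic *CPAMD8* mutations in three
families (one homozygous missense genotype, two compound-heterozygous
genotypes involving splice-site and frameshift alleles), but every
component is generic.

# The filtering cascade

**Step 1 — rarity.** A variant is retained iff its allele frequency is at
or below the threshold (default MAF 0.005, inclusive) in *every* population
source: 1000 Genomes, the NHLBI EVS, ExAC, and an internal exome panel.
The aggregation rule is the maximum over sources — a variant common in any
one database is removed. This is the conservative reading of a filter
described over several databases jointly; a mean- or single-source rule
would retain strictly more variants. Absence from a source is treated as
an observed zero count (population tables print explicit "0/1,980"-style
zeros), with the panel sizes 5,008 / 12,000 / 120,000 / 1,980 alleles used
as denominators for absent entries. Threshold comparisons are exact
rational arithmetic on the stored counts (`ac/an <= p/q` decided as
`ac*q <= p*an` in integers), so a variant at exactly the boundary is kept
regardless of floating-point representation.

Retained variants are partitioned by proband zygosity (homozygous /
heterozygous / hemizygous) and cross-referenced against a known
disease-gene list (packaged default: FOXC1, PITX2, PAX6, PITX3, FOXE3,
BMP4, CHRDL1, LTBP2, CYP1B1). A companion screen flags — but never
removes — variants with homozygous carriers in any population database,
since a fully penetrant recessive allele should have none.

**Step 2 — X-linked screen.** For male probands, rare hemizygous
X-chromosome variants are listed with their in-silico annotations for
manual review. The step is a report, not a filter.

**Step 3 — recessive models.** Per family, autosomal genes qualify under
the homozygous model (at least one hom-alt rare variant in the proband) or
as potential compound heterozygotes (at least two distinct rare
heterozygous variants). A single heterozygous variant never qualifies.

**Step 4 — cross-family intersection.** Genes qualifying in every family
are the candidates. Two failure modes are handled explicitly:

* *Coverage gaps.* `coverage_gap_report()` projects a candidate gene's
  exons against a sample's covered intervals and lists coding exons with
  zero coverage — the exons needing targeted (Sanger) follow-up. A rescue
  table of recovered genotypes can be merged before step 3.
* *Singleton-het fallback.* When the intersection is empty, genes
  qualifying in all but one family are re-ranked by the missing family's
  rare singleton heterozygous variants in that gene. This formalizes the
  manual re-analysis of a proband's rare heterozygotes that recovers a
  second allele hidden by missing coverage: the pipeline reports the gene
  with its single supporting allele rather than silently failing.

In-silico predictions (SIFT < 0.05 damaging, PolyPhen-2 ≥ 0.85 probably
damaging, PhyloP > 0.95 conserved) are exposed as a support score for
ranking only — candidate genes are demoted, never deleted, on prediction
grounds, because predictions are supporting evidence rather than filters.

# Segregation and phase

`check_homozygous()` requires every genotyped parent to carry the allele
and forbids unaffected homozygotes, under complete penetrance.
`check_compound_het()` is consistent iff no genotyped unaffected
individual carries both alleles, genotyped affected siblings carry both,
and each allele is attributable to a parent when both are genotyped.
Phase certainty is capped by the data:

* `confirmed_trans` — both parents genotyped, each carrying exactly one
  of the two alleles;
* `inferred_trans` — exactly one parent genotyped and carrying exactly
  one allele, the other allele imputed to the missing parent;
* `unphased` — anything weaker.

Missing genotypes never render a verdict inconsistent; they only limit the
phase claim. This encodes precisely the inference available when one
parent's DNA is unavailable: a sibling pair sharing two alleles whose
mother carries exactly one supports — but cannot confirm — a trans
configuration. The test suite checks the verdicts against a brute-force
enumeration of parental allele configurations on fully genotyped trios.

# Transcript arithmetic and splice consequences

All splicing work is done in cDNA (c.) coordinates, with c.1 the first
base of the start codon and codon *i* spanning c.(3i−2)..c.(3i); genomic
projection and minus-strand handling are deliberately out of scope.
`site_of_variant()` maps c.N+1/+2 positions to the donor of the intron
after the exon ending at c.N, and c.N−1/−2 to the acceptor of the intron
before the exon starting at c.N. Aberrant events (single and multi-exon
skips, intron retention, cryptic donors/acceptors at ±k) are pure sequence
edits whose length change always equals the affected base count.

`consequence()` translates reference and mutant (standard nuclear code,
stopping at the first stop codon; `Biostrings::translate` with
`no.init.codon = TRUE`, so alternative initiator codons are not
special-cased) and classifies the difference. A change is in-frame iff
the cDNA length change is a multiple of 3 *and* the mutant carries no
premature stop; in-frame boundaries are located by maximal common prefix
then maximal common suffix, which is exactly the HGVS 3′-most
normalization. Frameshifts are written `p.(Ref)(pos)(New)fs*N`, counting
the first altered residue as position 1, with `fs*?` (flagged) when the
mutant never reaches a stop. Insertions are reported with the inserted
residue count (`p.Ala1516_Ile1517ins26`); delins descriptions spell out
the inserted residues. An independent naive translate-and-diff oracle —
its own codon table, block placement by exhaustive enumeration — must
agree with the engine on category, boundary, residue counts and fs*N over
hundreds of randomized (transcript, event) trials.

Cryptic-site search is bare GT/AG dinucleotide matching within a window
(default 500 nt) of the lost site, on the *mutant* intron — the
splice-site point mutation is applied to the stored intron sequence before
search and simulation, which matters: a donor +1 G>T both destroys the
canonical site and supplies the T of the first retained codon. No
splice-strength scoring is attempted; observed cryptic sites in the
motivating study were identified empirically, not predicted.

## The packaged transcript fixture

`cpamd8_transcript()` loads a synthetic reconstruction of the CPAMD8-1a
coding transcript (42 exons, 1,932 residues plus stop). The exon
boundaries that the documented variants touch are fixed by their printed
HGVS coordinates — exon 7 ends at c.700, exon 29 is c.3928..c.4002
(codon arithmetic: residue Gly1310 starts at 3×1310−2 = 3928), exon 33 is
c.4393..c.4548, exon 34 is c.4549..c.4611 — and the remaining boundaries
are arbitrary contiguous tilings. The base-level sequence is synthetic:
background codons are drawn from an {A,C,G} alphabet (no stop codon can
arise in any reading frame without a T), and the bases that the documented
variants and their aberrant products read through are pinned so that every
published consequence is reproduced: the Ser1451 codon is TCT (T>C gives
Pro), the Arg785 codon is AGG (an inserted C creates CAG, Gln, and the +1
frame terminates 23 codons later), intron 33 is 78 nt with no stop in the
retained frame (26 inserted residues), and intron 7 carries a cryptic GT
at +143/+144 with a stop placed so the +142 retention terminates at
fs*30, 87 nt downstream of the exon. The real intron sequences are not
recoverable from published coordinates alone, so the fixture encodes the
published *constraints* rather than the true bases; the file is labelled
synthetic and any consequence depending on un-pinned bases has no claim to
biological accuracy.

# The synthetic cohort generator

The generator emulates the study conditions: three families (a
consanguineous trio with a homozygous missense genotype; a trio compound
heterozygous for a frameshift and a splice-acceptor allele; two affected
siblings compound heterozygous for two splice-donor alleles, with an
unavailable father, an unaffected carrier mother and granddaughter, and a
six-exon coverage gap over the proband's second allele). Planted variants
carry the published population counts, all below MAF 0.005 with zero
homozygotes.

Each proband receives 25,000 background exonic variants (the study's
per-exome order of magnitude) with a two-mode frequency spectrum: a
common mode uniform on [0.01, 0.5] and a rare mode exponential with mean
0.001, truncated at 0.005, making up fraction 0.006 of the table. The
rare fraction was chosen once so that a proband carries on the order of
110–160 rare heterozygotes, matching the study's re-analysis pool of 116;
intermediate per-step counts are otherwise not calibrated, only endpoint
behaviour. Database counts are binomial draws per source at the true
frequency with the four panel sizes above; genotypes of relatives follow
Mendelian transmission given the proband's genotype, with untransmitted
alleles drawn at the population frequency.

Deliberate decoys exercise each filter: common variants inside the causal
gene (removed at step 1), a decoy gene with rare heterozygous pairs in
exactly two of three families (removed at step 4), and a single benign
rare hemizygous X variant in the male proband (the step-2 report).
Simplifications, chosen for a clean testing contract and documented here:
rare background variants are confined to autosomal genes outside the
known-disease list and the causal gene, so the known-gene cross-reference
is empty and the X screen reports exactly the planted candidate, as in the
study; X-chromosome background genotypes are independent Hardy–Weinberg
draws rather than transmitted; common variants are generated per family
rather than shared across families (they are removed at step 1 either
way); and no linkage disequilibrium, sequencing error, or read-level
detail is modelled. Passing the recovery property therefore shows the
cascade's set logic is correct under realistic variant loads — it does not
validate caller error modes or population structure.

Everything is deterministic given the seed: the same seed reproduces
byte-identical VCF/PED/TSV/BED output.

# Conservation utilities

`global_align()` is a textbook Needleman–Wunsch global aligner with
match/mismatch scores and a linear gap penalty (defaults 1/−1/−2; the
motivating figures do not state a method, so the defaults are ordinary
and configurable) and a deterministic tie-break: diagonal preferred over
up over left. Percent identity divides matches by *all* alignment
columns, gap columns included ("full-length identity"); tools that divide
by aligned columns or the shorter sequence will report higher numbers.
Published full-length identity percentages for this protein family were
produced with an unstated aligner and unstated sequence versions, so they
are treated as qualitative; the packaged tests validate the aligner
against exhaustive enumeration and an independent implementation instead.
`column_conserved()` reports the residue multiset of an alignment column
and whether it is invariant (a single residue type across non-gap rows;
all-gap columns are not invariant). Loop-based dynamic programming in R
is adequate for the sequence lengths used here; for thousands of long
proteins, use a compiled aligner.

# Numerical and design choices

* Genomic positions are 1-based inclusive (VCF convention); coverage
  intervals are 0-based half-open (BED convention); conversion lives at
  the I/O boundary only.
* Indels are trimmed to minimal representation (shared suffix, then
  shared prefix) before annotation keying, so differently padded VCF
  encodings of the same event match the annotation table. Full
  left-alignment against a reference genome is out of scope.
* Multi-allelic sites decompose into one record per alternate allele,
  conserving total ALT observations; `|`-phased genotypes are read as
  unphased; `./.` maps to missing and is non-excluding everywhere.
* A missing genotype never removes a candidate: the family whose father
  is ungenotyped still reaches a compound-het verdict, with phase capped
  at `inferred_trans`.
* Problem sizes in the test suite: 20 seeded full-scale cohorts (25,000
  variants per proband) for planted-gene recovery, 500 randomized
  oracle-equivalence trials for the consequence engine, exhaustive
  enumeration for short-peptide alignment and for trio segregation.
  These sizes make the suite complete in about a minute on a laptop
  while leaving the generator at the study's scale.

# Known limitations

* The transcript fixture is a constraint-faithful synthetic object, not
  the real sequence; only consequences anchored to printed coordinates
  are biologically meaningful.
* De novo dominant models are outside the cascade (the motivating
  analysis considered and discarded them once recessive candidates
  emerged); so are CNV calling, linkage/LOD computation, and
  splice-strength prediction.
* The generator's realism is bounded as described above; in particular
  it cannot reproduce real per-step attrition counts, which depend on
  unreleased exomes.

# Worked example

```{r example, eval = FALSE}
library(varcascade)
tx <- cpamd8_transcript()

# simulate the aberrant products of the intron-33 acceptor loss
splice_outcomes(tx, "c.4549-1G>A")

# full pipeline on a synthetic cohort
co  <- generate_cohort(seed = 7)
res <- run_cascade(as_variant_set(co), co$pedigree,
                   transcript = tx, coverage = co$coverage,
                   rescue = rescue_table(co))
res
classify_inheritance(res$reports, res$rare, co$pedigree, res$probands)
```
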