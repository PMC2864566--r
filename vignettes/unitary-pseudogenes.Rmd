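---
title: "Detecting and dating unitary pseudogenes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating unitary pseudogenes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unipseudo)
```

## The comparative model

A unitary pseudogene is a gene disabled in place with no surviving
functional paralog. Its detection is necessarily comparative: the signal is
the *absence* of an ortholog in one species for a gene that is demonstrably
functional in another, combined with the *presence*, at the positionally
orthologous locus, of sequence that still resembles the functional gene but
carries a coding disruption. The package therefore always works with a
reference gene set (models + proteome + genome) and a query genome, linked
by an ortholog table whose reference and query id universes are explicit —
absence of a pair is meaningful only against a declared universe.

Four disruption classes are recognised: premature stop codons; frameshifts
(indels of length not divisible by 3); splice-site mutations (any departure
from donor `GT` / acceptor `AG` in an inferred intron); and truncations
(missing terminal exons). An in-frame indel is *not* a disruption, and a
stop within 10 codons of the annotated terminus (configurable
`near_terminal_tol`) is flagged but not counted, so that ordinary
stop-codon drift is not mistaken for pseudogenization.

## Mapping and alignment

The protein-to-genome mapper is a deliberately small stand-in for a
translated aligner, with the same contract: exact amino-acid 5-mer seeds
(`seed_len`) against a six-frame translation, chained when colinear on one
strand within a 50 kb gap bound, with chain score = residues covered minus
a span cost of 1e-3 residues per nucleotide of gap. The span cost matters
in tandem gene clusters: a chain stitched across two adjacent paralogous
copies can cover as many residues as a chain confined to one copy, and the
compactness term is what makes the single-locus chain win deterministically.
Windows are ranked by chain score, then leftmost coordinate; a protein
whose best window covers less than `min_coverage = 0.5` of its residues is
unalignable and classified as a reference-lineage gain (or a deleted
locus — the two are indistinguishable from mapping alone, and the scoring
helper pools them as `ABSENT_FROM_QUERY`).

The aligner does not predict genes ab initio: the reference gene model is
always in hand, so each reference exon's protein segment is locally aligned
near its expected position (previous block end + reference intron length,
with a 200 nt margin) and introns are inferred between consecutive exon
blocks. The per-exon alignment is a three-state affine dynamic program in
compiled code: a residue may consume 3 nt (substitution-scored with
BLOSUM62), 1–2 nt (a frameshift slip, cost `frameshift_penalty = 20`), or
4–5 nt (codon preceded by 1–2 slipped nt); residues may be deleted and
whole in-frame codons inserted under affine costs (`gap_open = 11`,
`gap_extend = 1`). Alignment *through* a stop codon is allowed at a fixed
score of −4 rather than forbidden: a pseudogene alignment must pass through
its own disruptions for them to be observable. The published tool this
step emulates ran with unstated parameters; these defaults are standard
protein-alignment values and are all exposed in `pipeline_config()`.

Two consequences of this design are worth spelling out. First, after a
frameshift the DP re-synchronises immediately (the remaining nucleotides of
the disrupted codon are absorbed by the slip state and downstream codons
match again), so a single indel produces exactly one frameshift transition,
not a cascade of mismatches. Second, the optimal placement of an indel can
be ambiguous when the codon before the indel site can recombine with the
remaining bases into an equally well-scoring codon — the codon-level
analogue of indel sliding in homopolymers.

## Gene-structure similarity and processed copies

`score = 0.5 × protein coverage + 0.5 × fraction of reference introns
recovered within ±10 bp (of their reference length)`, pass at ≥ 0.6. A
full-length intronless copy of a multi-exon gene — the retrotransposition
signature — scores exactly 0.5 and fails, which is how processed copies are
excluded without a named pipeline stage. For a single-exon reference gene
the intron term is vacuous (set to 1 when anything aligns), so processed
copies of single-exon genes are undetectable by structure alone; the
generator therefore only plants processed copies of multi-exon genes.
Loci within 0.05 of the threshold are marked `borderline` in the report —
the machine-checkable replacement for the manual review step a curated
annotation effort would apply.

## The filter cascade

Clustering is single-linkage over same-chromosome, same-strand intervals
overlapping by ≥ 1 bp; a locus inherits the best annotation evidence class
among its contributing genes (`NAMED_GENE` > `SPLICED_CDNA` >
`UNSPLICED_CDNA` > `PREDICTED`), and loci supported only by the last two
classes are discarded with a logged reason. Tandem-family loci (family of
≥ `min_family_size = 3` with ≥ 2 members within `max_cluster_span` =
100 kb in the reference) are reported separately rather than called
unitary, because copy-number dynamics make orthology within such clusters
unreliable. The synteny rule checks, on each side of the locus, the
`synteny_k = 3` nearest *ortholog-bearing* reference neighbours for a query
ortholog on the same chromosome and side; neighbours without orthologs are
skipped as uninformative rather than counted against the locus (a locus in
a run of consecutive gene losses would otherwise fail synteny spuriously),
and a contig edge passes vacuously. A locus is polymorphic when at least
one transcript maps across a genomic disruption and carries the functional
state at every disruption it spans (a non-stop codon over a planted stop; a
net local length difference congruent to the indel's shift modulo 3 over a
frameshift); splice-site disruptions are intronic and unspannable by mRNA.

## Dating

Shared disruptions are placed by Dollo parsimony: the event maps to the
stem of the minimal clade containing all carriers; species with missing
data are uninformative; a non-carrier inside the clade flags the pattern as
homoplasic with a warning instead of failing. Ancestral sequences are
reconstructed by per-site Fitch parsimony with a stated deterministic
tie-break (parent's state if admissible, else alphabetical), and per-branch
K_A/K_S uses NG86 counting — fractional synonymous sites per codon
position, pathway averaging over substitution orders for multi-hit codons
(paths through stop codons excluded unless all are), changes to stop codons
counted as nonsynonymous — with the Jukes–Cantor correction
`d = −(3/4)·ln(1 − (4/3)p)`. Proportions ≥ 3/4 return a flagged `NA`
(saturation), never a silent value; `omega` is flagged undefined when
`K_S = 0`. Codon columns containing a stop in any node sequence are masked
before rate estimation (`mask_stops = TRUE`), since rates must be measured
away from the disruptions themselves.

The nonfunctionalization-time estimator assumes synonymous sites are always
neutral while nonsynonymous sites evolve at `omega_bar · r_S` before
inactivation and at `r_S` after, so
`K_A1 = r_S1·[omega_bar·(T − T_N) + T_N]` and
`T_N = T·(omega_1 − omega_bar)/(1 − omega_bar)`. Estimates are clamped to
`[0, T]` with a flag, and a caution flag is set when few species inform the
reconstruction. `omega_bar` defaults to the unweighted mean of defined
non-focal branch omegas; a fixed constrained background (for instance the
0.12 median for mammalian protein-coding genes) can be supplied instead —
both conventions are supported because either is defensible and they
coincide in expectation under the simulation model.

## Population genetics

The Hardy–Weinberg test is the plain chi-square goodness of fit against
`(np², 2npq, nq²)` with `p` estimated from the sample. Two
degrees-of-freedom conventions circulate for this test; the package
defaults to df = 2 (three genotype classes, one constraint) for
compatibility with analyses reported under that convention, while the
textbook df = 1 (the allele frequency is itself estimated) is available as
`df_convention = "standard1"` and is what the calibration tests use, since
only it is expected to be uniform under the null. F_ST is
Nei's gene-diversity form `(H_T − H_S)/H_T` with unweighted population
means. For subdivision testing, genotype counts are pooled within each
subdivision (individual-level pooling — the alternative, averaging
population frequencies, weights small samples up; pooling was chosen
because the permutation unit is the population label and pooling keeps the
statistic a plain two-sample F_ST). The null permutes population labels
across subdivisions with sizes preserved, `p = (1 + #{F_ST* ≥ F_ST})/(1 +
n_perm)`; with fewer than 20 distinct label assignments the test enumerates
all of them exactly, with a warning. Population trees are UPGMA on the
F_ST matrix, cut at the largest gap between successive merge heights (one
subdivision when all heights are equal).

## Enrichment

Annotations are closed under `is_a` ancestors (true-path propagation)
before testing; the test universe is every term carried by at least one
study gene; per term the one-sided hypergeometric upper tail equals the
one-sided Fisher exact p (asserted to 1e-12 in the tests); FDR control is
Benjamini–Hochberg.

## What the generators emulate — and what they do not

`simulate_reference_geneset` builds multi-exon genes with phase-0
(codon-aligned) exon boundaries, canonical `GT…AG` introns, ATG-led CDSs
free of internal stops, on random strands with fixed intergenic spacers.
`evolve_query_genome` then plants fates: background divergence is
substitution-only and *purifying-safe* (it never creates an in-frame stop
nor touches a splice dinucleotide), so planted disruptions are provably the
only ORF-breaking events and recovery can be scored exactly. Frameshift
plants are verified at generation time to have a unique optimal alignment
placement (the codon-sliding ambiguity above) and are re-sited otherwise;
premature stops are kept ≥ 3 codons inside an exon so the local aligner
cannot clip them off a block edge. Tandem families are created by inserting
two diverged (5%/site) paralogs next to the focal gene in the *reference*
genome, because the family filter reasons over reference paralog
clustering. Processed copies are planted with one premature stop: a
pristine retrocopy would be binned "aligned, no disruption" before the
structure stage, and decayed retrocopies are the realistic case.

Real data differ in ways the generators deliberately ignore: non-zero exon
phases, alternative transcripts, segmental duplications, assembly gaps and
sequencing errors (a documented source of false polymorphic calls),
GC-content and codon-usage structure, indel-length distributions, and
recombination. Passing the planted-truth tests therefore demonstrates the
*logic* of the cascade — that each filter removes exactly what it claims to
— not robustness to annotation noise. The codon-phylogeny simulator
likewise uses uniform per-site proposals with acceptance probability
`omega` for nonsynonymous changes (so realized K_A/K_S equals `omega` by
construction), a neutral rate of 0.002 substitutions/site/MY (a standard
mammalian value), and stop-permitting neutrality after the planted switch;
it does not model transition/transversion bias or rate heterogeneity.

## Problem sizes and reproducibility

Every generator is a pure function of one integer seed. The shipped test
suite and `scripts/acceptance.R` use: a 200-gene reference genome with 20
planted unitary, 5 tandem-family, 5 processed and 5 gained genes for
pipeline recovery; 9 genes with explicit stop / 8-bp-deletion /
donor-`GT→AT` plants for exact-position disruption recovery; 50 replicates
× 5,000 codons at each planted T_N ∈ {1.65, 3.3, 4.95} MY on a
human/chimp/rhesus/marmoset tree for estimator recovery (mean absolute
error ≈ 0.3 MY, well inside the ±0.7 MY target); 2,000 null replicates for
Hardy–Weinberg calibration; 500 null replicates × 199 permutations (12
populations) for permutation-p uniformity; and 100 draws for the planted
five-fold enrichment (background carrier frequency 0.1, so the planted term
reaches half the study set). The whole acceptance run completes in about a
minute on one CPU.

## Known limitations

* Gains and deletions in the query are both simply "unalignable"; telling
  them apart needs an outgroup, which is out of scope here.
* The per-exon local alignment can clip one or two terminal residues of an
  exon when background divergence lands there; coverage, not truncation
  calls, absorbs this.
* The permutation test is conservative when very few populations (and hence
  few distinct label assignments) exist; it switches to exact enumeration
  below 20 assignments but cannot manufacture resolution.
* Dollo placement trusts the presence/absence calls; genuine homoplasy
  (recurrent disruption) is flagged, not resolved.
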