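---
title: "Methods: retroduplication, LTR dating and the tandem-duplication follow-up"
author: "retrodup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retroduplication, LTR dating and the tandem-duplication follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
the assumptions they lean on, the parameters that matter, what the
synthetic-genome generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open.

## Coordinate and sequence conventions

All stored coordinates are 1-based inclusive on the forward strand — the
native convention of GFF3, `GRanges` and R itself — and strand is applied
only when sequence is spliced out. Using a single convention end to end
(rather than a 0-based internal system) removes the usual off-by-one
conversions; GFF3 I/O is the identity on coordinates and round-trips
byte-exactly. One representative transcript per gene is kept (the mRNA with
the longest total CDS), the common convention for paralog analysis when the
transcript choice is not otherwise specified. `N` bases are allowed and
mismatch everything, including `N`.

## Retrogene calling

The caller operationalises the classic intron-loss signal in four screens.

1. **Candidates.** All-vs-all Smith–Waterman protein comparison (BLOSUM62,
   gap open 11 / extend 1), filtered at e-value ≤ 1e-7, alignment length
   strictly greater than 100 aa, and c-score (bit score over the query's
   best bit score) ≥ 0.3. Bit scores use fixed Karlin–Altschul parameters
   (λ = 0.267, K = 0.041 for proteins); because the search space here is a
   genome's worth of proteins rather than a calibrated database, e-values
   are approximate by design and the length and c-score screens carry the
   discrimination. Pairs with equal exon counts carry no intron-loss signal
   and are dropped. A shared-5-mer prescreen skips hopeless pairs; a pair
   must share one exact amino-acid 5-mer to be aligned, which a pair above
   ~50 % identity essentially always does — copies near Ks ≈ 0.6 sit at the
   edge of this bound, and an occasional heavily diverged copy dropping out
   is the expected failure mode.
2. **DNA-level duplicates.** The two genomic loci (introns included) are
   aligned; the pair is discarded as a DNA-based duplication when a single
   contiguous segment — no gap run longer than 19 bp on either side —
   covers ≥ 80 % of the shorter locus at ≥ 70 % identity. The segment
   criterion mirrors how BLAST-style extension breaks at introns: conserved
   introns keep the alignment in one piece at any divergence this pipeline
   considers, while true retrocopies fragment into per-exon segments. A
   column-identity criterion was rejected because it ties the decision to
   the pair's age: at Ks ≈ 0.3 an intron-preserving duplicate falls below
   any identity threshold tight enough to catch single-small-intron
   retrocopies. Identical single-exon pairs satisfy the rule and are
   conservatively excluded — with no intron, the two origins are
   indistinguishable.
3. **Junction evidence.** The copy's genomic locus is aligned to the
   parent's spliced transcript; alignment segments again break at gap runs
   longer than the 19 bp tolerance, and a parent exon–exon junction counts
   as *spanned* when one segment covers both its flanking bases. "At least
   two parental exons connect in one exon of the retrogene" therefore means
   `junctions_spanned >= 1`, with up to 19 bp of exon-boundary slop
   absorbed inside a segment. Both orientations of the locus are tried, so
   strand conventions cannot break the count. One consequence worth knowing
   about: an exon-skipping copy of a 3-exon parent has no spannable
   junction left (both junctions abut the skipped exon), so recoverable
   exon-skipping events need parents with ≥ 4 exons; the generator draws
   them accordingly.
4. **Tandem-with-parent exclusion and classification.** Copies at gene-rank
   distance ≤ 2 from their own parent are discarded (indistinguishable from
   tandem duplication). Each surviving copy keeps its best-bit-score parent
   (ties broken by lower Ks) and is classified: *intron retention* when ≥
   40 bp of a parent intron survives in the copy at ≥ 80 % identity
   (checked first, including when the retained intron was re-annotated as
   an intron of the copy); *exon skipping* when an internal parent exon (≥
   30 bp) is absent while both flanks are present (≥ 50 % coverage at ≥
   60 % identity); single-exon copies are *clean*; remaining multi-exon
   copies are *intron gain*. The 40 bp/80 %, 30 bp and 50 %/60 % numbers
   are this package's operational choices — the underlying publications do
   not print them — and are exposed as arguments.

A retrogene may itself seed later tandem copies; only the copy-with-its-own-
parent arrangement is excluded, so retro-derived tandem duplicates are
called as retrogenes, which is precisely the biology the grouping analysis
quantifies.

## Intact LTR elements and insertion ages

The detector is a simplified structural scan, not a reimplementation of the
full suffix-array machinery of the standard tools: exact 20-mer seed
matching finds direct-repeat candidates at compatible spacing; extension
along the repeat diagonal (substitution-only — the generator plants no
indels, and the detector documents this as a fidelity gap) delimits the
repeat by a windowed identity profile; boundaries are then refined so the
5′ copy starts `TG`, the 3′ copy ends `CA`, and an exact 4–6 bp target-site
duplication flanks the element; length bounds (LTR 100–3500 bp, element
1–15 kb) and the 90 % LTR-identity floor follow standard intact-element
practice. Overlapping candidates keep the higher-identity, then longer,
then leftmost element. The seed for each candidate cluster is taken at the
cluster's *median* position, which sits safely inside the repeat — seeds at
the repeat edge see a half-outside identity window and would be missed.

Divergence K between the two repeats is the p-distance over ungapped
columns of a global alignment, Jukes–Cantor corrected
(K = −(3/4)·ln(1 − 4p/3)); whether to correct at all is a switch, JC69 by
default. Ages follow **T = K/2μ** with μ = 9.1 × 10⁻⁹ substitutions
site⁻¹ yr⁻¹ by default and 7 × 10⁻⁹ for *Arabidopsis*-like inputs, always
overridable. p ≥ 3/4 is reported saturated with no age. At LTR length 300
the binomial sampling noise on K is large for young elements (sd ≈ 60 % of
K at K = 0.01), so calibration statements are about means over replicates,
not single elements.

Genes are flagged **contained** when fully inside an element interval
(1 bp of overhang fails — strict containment) and **flank_pair** when a
windowed re-scan of the gene ± 8 kb finds an element whose repeats bracket
the gene; containment takes precedence. RT-domain cassettes are located by
aligning the bundled exemplar set (synthetic sequences, one per clade
label) against each element's internal region (≥ 200 aligned bases);
families form by single linkage at ≥ 80 % nucleotide identity over
alignments covering ≥ 80 % of the shorter domain, named
`{chrom}_{start}_{end}_FAM{k}` after the leftmost member. Single linkage
matches hit-based family assignment practice; the 80 % coverage floor is
our reading of an "80 % similarity of the domain" rule that does not state
its denominator.

## Ka/Ks and duplicate typing

`ng86_kaks()` implements Nei–Gojobori (1986) exactly as specified by the
method: per-position synonymous-site fractions (mutations to stop codons
count as nonsynonymous), equal-weight averaging over all orderings of
multi-substitution codons with stop-passing pathways excluded (all
pathways reinstated only if every one is blocked), Jukes–Cantor correction
of pS and pN, saturation flagged at pS ≥ 3/4. Codon pairs containing
stops, gaps or `N` are skipped. The codon alignment is a back-translation
of a global protein alignment, and the implementation is tested to 1e-9
against an independent pathway-enumeration oracle. NG86 was chosen because
it is fully specifiable from first principles and adequate for the Ks < 1
regime this analysis lives in; ML codon models are out of scope.

Duplicate typing reads the rank rules literally: "adjacent or separated by
one gene" ⇒ tandem at rank distance ≤ 2; "separated by 2–19 genes" ⇒
proximal at distance 3–20; collinear blocks (DP chaining, ≥ 5 anchors,
rank gaps ≤ 25 on both axes, both orientations, longest chain extracted
first across orientations) mark WGD pairs; precedence
wgd > tandem > proximal > dispersed. In self-comparison the pipeline
removes same-chromosome anchors at rank distance ≤ 20 before chaining:
tandem and proximal pairs sit on the self-diagonal and would otherwise
chain into spurious "blocks" that steal their labels.

Ks-distribution modes use a Gaussian KDE over [0, 3] with Silverman's
bandwidth by default; a mode is *stable* when its prominence ratio exceeds
the 95th percentile of the maximum prominence ratio over uniform resamples
of the same size (plus a 5 %-of-maximum height floor against numerically
empty tail wiggles). This null-calibrated rule, rather than a fixed ratio,
is what lets a flat sample report no stable mode without suppressing real
peaks.

## The expansion test

Family evolution follows a linear birth–death model with equal birth and
death rates and a single global λ:
P(i→j) = Σₖ C(i,k)·C(i+j−k−1, i−1)·α^{i+j−2k}·(1−2α)^k with
α = λt/(1+λt), absorbing at zero. λ is estimated by maximising the
product over families of the pruning-computed likelihood of tip counts
under a uniform root-size prior over 1..max(observed); the search is
1-D and bounded so that α < 1/2 on the longest branch. Monte-Carlo
p-values compare each family's marginal likelihood with `nsim = 1000`
families simulated from the same prior and λ; *expanded* additionally
requires the focal tip count to exceed the posterior-mean size of every
ancestral node on its root-to-tip path (inside–outside over the truncated
state space, capped at max(observed)+10). No multiplicity correction is
applied, matching raw "P < 0.05" practice for this test. Calibration under
the null is conservative (flagged fraction ≪ α, because likelihood ties
among unchanged families inflate p-values), and a 10-fold focal expansion
is flagged essentially always.

In the pipeline the family-size matrix sets the focal species' count to
the orthogroup size and every sister species to 1 — the synthetic genome
simulates one species, so sisters are modelled as retaining the single
ancestral copy. This makes "expanded" mean "larger than a one-copy
ancestral family can plausibly drift to", which is the planted design.

## What the generator emulates — and what it does not

`simulate_genome()` builds a multi-chromosome genome of CDS-only genes
(ATG + sense codons + stop; exons 165–300 bp in codon multiples, introns
70–180 bp, single-exon genes ~15 %) separated by 4–10 kb of uniform-random
intergenic sequence, then plants, with one RNG stream per seed
(byte-identical reruns):

* clean / intron-retention / exon-skipping / intron-gain retrocopies at
  target Ks 0.15, never within rank distance 2 of their parent (such a
  placement is indistinguishable from tandem duplication and the caller
  rightly discards it);
* intact LTR elements with twin `TG…CA` repeats at planted divergence
  (free elements 0.005–0.06; cargo-bearing ones 0.005–0.03 — young,
  confidently detectable insertions consistent with the recent-activity
  regime the analysis targets), exact 5 bp TSDs, an RT cassette from the
  bundled exemplars, and optionally a cargo gene strictly inside: a
  retrocopy (`ltr_retro`) or a copy of a single-exon gene
  (`ltr_contained`);
* serial tandem arrays — each copy derives from the previous one, so every
  adjacent pair carries the target Ks — seeded either on retrocopies
  (3 arrays of 3, Ks 0.05: young, retro-seeded) or on plain genes
  (3 arrays of 3, Ks 0.3, each diluted by two dispersed DNA-level copies
  so its tandem fraction is 0.6 rather than 1.0);
* proximal duplicates (planted last, with ≤ 16 intervening genes, so no
  later insertion can push a pair beyond the 19-gene bound) and dispersed
  intron-preserving DNA-level duplicates as negative controls.

Mutations are applied at the p-distance whose JC69 correction equals the
target, so planted values match the estimators' corrected scale in
expectation; CDS mutations revert codons that would become premature stops
(a ≲ 2 % Ks deficit at Ks = 0.6, inside the ±0.05 recovery bound). Domain
annotations give every gene family a generic domain; contained cargo genes
get `RT`, and half of them (by default) an extra non-RT domain — so the
TE-like filter genuinely removes some genes while category A3 stays
populated.

Passing the recovery tests therefore shows the callers work when the
signal is clean: no nested or solo LTRs, no indel divergence, no UTRs or
alternative transcripts, uniform base composition, no recombination, no
annotation noise. Real genomes violate all of these; the recovery numbers
are upper bounds, and the published genome-scale counts (hundreds of
retrogenes, hundreds of SEOs) are not reproduction targets at this scale.

## Default study conditions and problem sizes

The default configuration — 5 chromosomes, 140 base genes (≈ 196 after
planting), ~1.3 Mb — is the condition under which the acceptance checks
run: planted-truth precision/recall per event class, estimator calibration
(K within 20 % of planted divergence in the mean over 100 replicate
300 bp repeats at d ∈ {0.01…0.2}; median NG86 Ks within 0.05 of targets up
to 0.6 over 25 replicate 600 bp CDSs), expansion calibration (500 null
families, nsim 1000; power over 20 seeds), and the group contrasts
(A-group median tandem fraction > B1; A-group tandem Ks < B1; ordering
fraction ≥ 0.9 with retro events planted older than their arrays). These
sizes keep a full run at a couple of minutes on one CPU while leaving
every class with enough planted events for precision and recall to be
meaningful.

## Known limitations

* The homology stage is exact Smith–Waterman behind a shared-k-mer
  prescreen — fine at desk scale, not a seeded heuristic search; copies
  beyond Ks ≈ 0.6 can drop out of the graph.
* Orthogroups are connected components over all filtered hits (single
  linkage). The reciprocal-best-hit graph alone provably cannot keep a
  tandem array of three plus its retrocopy in one orthogroup (the seed has
  a single best hit), so components-over-hits is the default and
  `edges = "rbh"` the literal alternative; over-merging through chains of
  borderline hits is the known cost of single linkage.
* The LTR detector assumes substitution-only repeat divergence and exact
  TSDs; nested elements, solo LTRs and recombinant structures are out of
  scope, as is phylogenetic clade assignment (clade labels ride along as
  exemplar metadata).
* Monte-Carlo SEO p-values are conservative under the null; the test's
  judgement day is the planted-expansion power, not the nominal α.
* Group comparisons are descriptive medians and means; no significance
  test is invented where the underlying analysis reports none.
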