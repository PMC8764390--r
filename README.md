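# retrodup

Desk-scale analysis of **retroduplication and its downstream tandem
duplication** in plant genomes, modelled on the kind of study done for the
field pennycress (*Thlaspi arvense*) genome: identify retrogenes from
intron-loss and exon-junction evidence, detect intact LTR retrotransposons
and the genes they carry, date insertions from terminal-repeat divergence,
classify duplicate genes, test orthogroups for expansion, and quantify
whether retro-seeded gene families accumulate younger, more numerous tandem
duplicates than families without retroduplication.

Every caller in the package is benchmarked against a built-in synthetic
genome generator that plants all the event classes with a machine-readable
truth table, so precision and recall are measured, not assumed.

## The models at the core

* **Retrogene calling.** A retrogene is a gene copy made by reverse
  transcription of a parent's mRNA. Candidates are protein-similar pairs
  with unequal exon counts; intron-preserving (DNA-level) duplicates are
  excluded when a single contiguous alignment segment covers ≥ 80 % of the
  shorter locus; the remaining pairs must show *exon-junction evidence* —
  at least two parental exons joined inside one exon of the copy, with ±19
  bp of boundary slop — and copies tandem with their own parent are
  discarded. Calls are classified as clean, intron-retention,
  exon-skipping or intron-gain copies.
* **LTR insertion ages.** An intact LTR retrotransposon has two terminal
  repeats that are identical at insertion. With K the JC69-corrected
  divergence between the repeats and μ the substitution rate (default
  9.1 × 10⁻⁹ site⁻¹ yr⁻¹; 7 × 10⁻⁹ for *Arabidopsis*-like inputs), the
  insertion age is **T = K / 2μ**.
* **Ka/Ks.** Nei–Gojobori (1986): per-codon synonymous-site fractions,
  equal-weight averaging over minimal mutational pathways, Jukes–Cantor
  correction; pS ≥ 3/4 is reported as saturated, never extrapolated.
* **Duplicate typing.** Same-orthogroup pairs on one chromosome are tandem
  at gene-rank distance ≤ 2, proximal at 3–20; anchors chain into collinear
  blocks (≥ 5 anchors, rank gaps ≤ 25) for WGD labelling; precedence
  wgd > tandem > proximal > dispersed.
* **Expansion test.** A linear birth–death model with equal birth and death
  rates (one global λ, estimated by maximum likelihood with pruning over
  the species tree) and a uniform root-size prior; Monte-Carlo p-values
  flag significantly expanded orthogroups (SEOs) at p < 0.05 when the
  focal count also exceeds every ancestral posterior expectation on its
  root-to-tip path.
* **Groups A1/A2/A3/B1.** A1 = retrogene flanked by LTRs, A2 = free
  retrogene, A3 = non-retrogene inside/flanked by LTRs, B1 = neither. SEOs
  are grouped by the categories they contain (B1 groups contain *only* B1
  genes), compared on per-SEO tandem fractions and tandem-pair Ks, and —
  for SEOs with > 40 % tandem duplicates — each tandem-duplicated retrogene
  is tested for ordering: retroduplication first iff
  Ks(retro, parent) > Ks(retro, nearest tandem partner).

## Worked example

```r
library(retrodup)
run <- run_pipeline(sim_config(seed = 1), seed = 1)
summary(run)
```

```
retrodup pipeline run
  genes: 196  kept after TE filter: 194
  retrogenes called: 29
  intact LTR elements: 15  LTR-flagged genes: 7
  orthogroups: 140  SEOs: 6

Group summary (per-SEO tandem fractions / tandem-pair Ks):
 group n_seos td_fraction_median td_fraction_mean td_ks_median td_ks_mean
    A1      3               0.75             0.75   0.06407309  0.0710293
    A2      3               0.75             0.75   0.06407309  0.0710293
    B1      3               0.60             0.60   0.33455706  0.3737524

retro-before-tandem ordering fraction: 1
```

Reading this: the simulated 1.3 Mb genome carries 196 genes; 2 are
reverse-transcriptase-only (TE-like) and are dropped. 29 retrogene calls
cover the 20 planted retrocopies, the 3 copies carried inside LTR elements
and the 6 tandem copies of retro seeds — retro-derived tandem duplicates
are genuine retrogenes, which is the point of the study design. SEOs seeded
by retroduplication (Groups A1/A2) have a higher median tandem fraction
(0.75 vs 0.60) and much younger tandem pairs (Ks ≈ 0.064 vs 0.335) than
SEOs of plain genes (Group B1), and every tandem-duplicated retrogene shows
Ks(retro, parent) > Ks(tandem pair): the retroduplication came first.

Dating the detected elements:

```r
age <- ltr_age(run$elements, mu = 9.1e-9)
head(age[order(age$T_mya), c("element_id", "K", "T_mya")], 3)
```

```
         element_id           K     T_mya
 chr2_114277_119405 0.005736166 0.3151739
 chr1_157176_162070 0.008620785 0.4736695
   chr3_77700_81281 0.008620785 0.4736695
```

The planted-truth recovery table (`run$recovery`) reports precision and
recall per event class; under the default conditions every class is
recovered at 1.0/1.0 and all 12 intron-preserving negative controls are
rejected.

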