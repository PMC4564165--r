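---
title: "Recessive variant prioritization in consanguineous IRD pedigrees: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recessive variant prioritization in consanguineous IRD pedigrees: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Inherited retinal degenerations (IRD) in highly consanguineous pedigrees are
overwhelmingly autosomal recessive, and the causal allele is expected to be
*autozygous*: homozygous by descent, both copies tracing through a
consanguinity loop to a common ancestor. `irdprior` implements the
candidate-discovery procedure built on that presumption. For each pedigree
with one to three exome-sequenced members, variants pass through a fixed
sequence of stages, each recorded in a per-variant `FilterTrace`:

1. **Site QC** — every non-missing call among the exome-sequenced samples
   must have read depth strictly greater than 10, mapping quality strictly
   greater than 30, and no strand-bias flag. The inequalities are strict by
   design: a call at exactly depth 10 fails. Only exome samples are
   assessed; Sanger-typed relatives carry no meaningful depth.
2. **Recessive filter** — every sequenced affected member with a non-missing
   call must be homozygous for the alternate allele; a sequenced unaffected
   sibling must not be.
3. **Homozygote frequency** — the variant is eliminated if any configured
   population database (HapMap, 1000 Genomes, ESP6500 by default) reports a
   *homozygous genotype frequency* (not allele frequency) strictly greater
   than 0.5%. Each database is tested separately; a frequency of exactly
   0.005 is retained, and presence in a database without a frequency
   (dbSNP-style listings) never triggers this rule.
4. **Region dispatch** — exactly one branch applies, by region class:
   * outside any transcribed region: eliminated;
   * 5'UTR: retained only within 6 bases upstream of the start codon;
   * 3'UTR: retained only inside a miRNA-targeted region;
   * missense SNV: retained unless the predictor consensus calls it benign
     (see below);
   * nonsense, frameshift and in-frame indels: retained with no predictor
     gate;
   * synonymous: retained only if predicted splice-altering;
   * intronic: eliminated at 15 or more bases from the nearest splice site,
     otherwise retained only if predicted splice-altering.
5. **Biotype** — transcripts with biotype "nonsense mediated decay",
   "retained intron" or "pseudogene", and 5'- or 3'-incomplete transcripts,
   are eliminated.

Survivors are intersected with a curated panel of known IRD genes
(off-panel survivors are routed to a separate report section, never
silently dropped), then every candidate is checked for **co-segregation**
across all genotyped pedigree members, and novel segregating candidates are
screened against 96 ethnicity-matched unrelated controls. Cohort-wide, all
QC-passing SNVs are tabulated by pedigree and the recurrent variants absent
from every configured database form the population-unique catalog.

# Design choices that were genuinely open

**Predictor consensus direction.** The four missense tools (MutationTaster,
PolyPhen, PROVEAN, SIFT) are consumed as annotations, never recomputed. We
eliminate a missense variant only when *all four* verdicts are benign: a
2-damaging/2-benign pattern and a 3-damaging/1-benign pattern both survive,
which is the only direction consistent with split-verdict variants reaching
candidacy and with segregation — not the annotation cascade — being the
stage that resolves them. An absent verdict never counts as benign, so a
variant unseen by a tool cannot be eliminated by it. Alternative rules
(`any_benign_drops`, `majority`) are available via
`cascade_config(predictor_rule = )`.

**UTR rules as class-conditional retention.** Read literally, "eliminate
all variants not within six bases upstream of the start codon" would
eliminate every coding variant. The UTR rules are therefore implemented as
retention conditions *within* their own region class: they only decide the
fate of 5'UTR and 3'UTR variants. This is the only reading under which
coding and intronic candidates can exist at all.

**Synonymous variants.** A synonymous change not predicted to alter
splicing is eliminated (configurable via `synonymous_splice_gate`); its
elimination is recorded in the trace, so such variants remain auditable
as "observed" without being candidates.

**Frequency rule across databases.** The databases are tested
independently ("each-database-separately"); a variant common in any one of
them is eliminated. Pooling was the alternative reading; testing separately
is the stricter and simpler contract and the database list is
configuration, not code.

**Recurrence threshold.** The population-unique catalog keeps variants
seen in *five or more* pedigrees (`min_pedigrees = 5`, inclusive), the
reading consistent with a recurrent causal variant observed in exactly
five pedigrees; the threshold is configurable.

**Transcript choice.** When a variant overlaps several transcripts and the
annotation designates none, the transcript whose region outcome is most
favorable to retention is used (deterministic tie-break on transcript id),
so borderline variants survive to segregation rather than dying to an
arbitrary transcript pick.

**Segregation model.** Complete penetrance, no phenocopies: one genotyped
unaffected homozygote refutes a candidate, one non-homozygous genotyped
affected member does too. Members with unknown affection (the "?" icons of
clinical pedigree drawings) or missing genotypes are excluded from the
verdict and from the informative count. An `allow_nonpenetrant` escape
hatch exists but defaults to 0. Control screening distinguishes
heterozygous carriers (tolerated by default — the allele is recessive and
rare, a carrier among 96 controls is unremarkable) from homozygotes (always
refuting); the strict no-carriers policy is available.

**"Solved"** means: at least one candidate that passes the cascade, lies in
a panel gene, co-segregates, and (if novel) passes the control screen.
Pedigrees with several such candidates count once. When two candidates
co-segregate and causality cannot be resolved from the data, an explicit
`causality` assignment can flag one *uncertain*: it stays in every report
but is excluded from the causal-variant count.

# Coordinate and distance conventions

Internally all intervals are 0-based half-open; the VCF and report
surfaces are 1-based. Splice distance is counted so the first intronic
base adjacent to an exon has distance 1, hence "15 or more bases from the
splice site" eliminates distance ≥ 15. The 5'UTR distance is counted in
spliced transcript coordinates, in transcript orientation: distance 1 is
the base immediately 5' of the A of the start codon (on the minus strand,
genomically *after* the CDS end). Multi-allelic VCF records are split into
one variant per alternate allele before anything else, with genotypes
re-expressed against the split allele; chromosome names are normalized by
stripping a leading `chr`.

A coding SNV whose consequence annotation is missing is classed
`coding_unknown` and eliminated: absent annotation states never pass a
filter that needs them.

# The synthetic cohort generator

No patient exomes accompany the procedure, so `generate_cohort()` emits a
complete synthetic cohort whose *structure* mirrors the study conditions:
26 pedigrees, 1–6 consanguineous marriages each, 3–12 affected and 5–16
genotyped members, one to three exome-sequenced members per pedigree
(occasionally including an unaffected sibling), one causal variant
recurring in 5 pedigrees, and unique causal variants (missense, nonsense,
frameshift) elsewhere. Decoy variants cover every elimination class — QC
failure, heterozygous-in-affected, high population frequency,
nontranscribed, far 5'UTR, non-miRNA 3'UTR, all-benign missense, deep
intronic, near-splice non-altering, NMD biotype, non-segregating,
off-panel, and control-homozygous — and a truth manifest records each
decoy's expected first failing stage.

Genotypes are produced by **Mendelian gene-dropping** from a single
ancestral founder carrier. Rather than rejection-sampling whole pedigrees
until the affected count is met (intractable for 12 affected under a
1/4 autozygosity probability), transmissions along the founder-to-
loop-couple paths are *constrained*: each forced transmission still draws
one of the parent's own two alleles, so every genotype remains Mendelian —
a property the test suite verifies with an independent trio-consistency
oracle — and unaffected loop children are rejection-sampled away from
homozygosity individually. Loop couples are first cousins, so their
children's inbreeding coefficient is at least 1/16, verified against a
recursive kinship computation.

Per-call depth is drawn as 11 plus a negative binomial with mean ≈ 63
(so clean sites always clear the depth threshold; QC-failure decoys get one
deliberately broken call), mapping quality uniformly in 40–60. Predictor
noise `p` flips each tool's damaging verdict to benign independently, so a
missense causal variant is lost only with probability p⁴ under the default
consensus rule — the recovery-rate property the tests check against
binomial error.

The scaffold is a small fictitious genome (20 genes, three 300-bp exons
each, 400-bp introns, on three chromosomes); the pipeline is
coordinate-agnostic. What the generator deliberately does **not** emulate:
linkage disequilibrium, realistic allele-frequency spectra, read-level
data, capture bias, annotation errors (annotations are internally
consistent by construction), population substructure among control
panels. Passing tests therefore demonstrate the *logic* of the pipeline —
not robustness to noisy or inconsistent real-world annotation.

One RNG stream per pedigree is derived from (master seed, pedigree index),
so cohorts are byte-reproducible and stable under partial regeneration.

# The bundled reference cohort

`reference_cohort()` materializes a code-built encoding of the reported
candidate patterns of a published 26-pedigree consanguineous IRD cohort:
13 pedigrees resolved by homozygous variants in RPE65, LCA5, USH2A, CNGB1,
FAM161A, ALMS1 and GUCY2D (the RPE65 variant recurring in five pedigrees,
one of which is typed only by targeted screening), the competing
candidates those pedigrees also carried (e.g. a 2-damaging/2-benign BEST1
missense refuted by segregation), and 13 pedigrees whose variants all fail
the cascade. Pedigree structures are *synthetic minimal reconstructions* —
only the genotype patterns that drive filtering, segregation and
recurrence are encoded; cDNA/protein labels are carried as annotations.
The one pedigree with two co-segregating candidates resolves via the
causality assignment, which flags the ALMS1 variant uncertain.

# Problem sizes used by the test suite

The unit suite runs the generator at reduced scale (2–3 pedigrees, 1–2
decoys per class) for speed; the property suite uses 52 noise-free
pedigrees for the recovery check, 60 missense-causal pedigrees at
predictor noise 0.3 for the 1−p⁴ check, 10,000 randomized annotation
bundles for the cascade-versus-oracle equivalence, and the full 4⁶
zygosity enumeration of a six-member pedigree for the segregation oracle.
The acceptance script runs the generator at its full default conditions
(26 pedigrees, 20 decoys per class).

# Known limitations

* Compound heterozygosity, X-linked and dominant models are out of scope;
  the recessive-homozygous presumption is the model.
* Annotation quality is trusted: the pipeline consumes predictor verdicts,
  splice predictions and database frequencies as given and cannot detect
  contradictory annotations.
* The control screen uses aggregate counts, not individual genotypes, and
  assumes the control panel is ethnicity-matched.
* Linkage disequilibrium between co-segregating candidates in nearby genes
  cannot be resolved by segregation alone; such pairs are reported, and
  causality assignment is explicit configuration.
* HGVS labels are passed through as annotations, never computed or
  validated; no liftover between genome builds is attempted.
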