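---
title: "Auditing genome-wide editing specificity in clonal haploid plants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing genome-wide editing specificity in clonal haploid plants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editaudit)
library(dplyr)
```

## The audit model

`editaudit` attributes every whole-genome variant observed in a clonal
haploid editing experiment to its most plausible origin. The experimental
unit is a *pedigree*: one wild-type plant propagated in vitro, from whose
protoplasts a set of clonal regenerants is derived — untreated controls,
PEG-transfected plants (with or without DNA), or nuclease-edited plants.
Three facts about this design carry all the inferential weight:

1. **Haploidy.** A true variant fixed in a clonal plant should be supported
   by essentially all reads at its site. The allele fraction (VAF) therefore
   separates fixed variants (VAF ≥ 0.8) from chimeric, subclonal ones
   (low VAF) and from caller noise.
2. **Clonal lineage structure.** A variant fixed in *every* sample predates
   the experiment (reference polymorphism); one fixed in a wild type *and
   all its derived plants* predates the pedigree split (lineage
   polymorphism); one recurring in independently regenerated plants, or
   echoed subclonally in the matched wild type, existed in the protoplast
   population before treatment (spontaneous).
3. **Positional prediction.** Nuclease activity is localised: the on-target
   window is known, and candidate off-target loci are enumerable from
   sequence homology, so nuclease-attributable variants must coincide with
   one of these positions.

What remains after these rules — variants private to PEG-exposed plants —
is attributed to the transfection treatment. The pipeline cannot
distinguish mutations induced by PEG itself from mutations induced by DNA
uptake; the two PEG roles are modelled identically (and the simulator
treats them identically by default), which mirrors the biology as far as
the design can resolve it.

## Filtering parameters

| parameter | default | meaning |
|---|---|---|
| `min_qual` | 20 (strict) | phred call quality floor |
| `min_depth` | 3 (strict) | total read depth floor, also the covered/uncovered boundary |
| `min_alt_depth` | 1 (strict) | reads supporting the alternate allele |
| `fixed_min` | 0.8 | VAF at/above which a haploid call is fixed |
| `chimera_floor` | 0.05 | VAF below which evidence is discarded as noise |
| large-InDel bound | 50 bp | \|len(ref) − len(alt)\| > 50 marks `size_class = "large"` |

All three hard filters are strict inequalities. `chimera_floor` separates
usable subclonal evidence from caller noise; it is not part of the hard
filters and only affects which low-VAF calls may serve as wild-type "echo"
evidence in attribution. Large InDels flow through the same matrix and
decision tree as small ones — the classification logic is identical, only
the size class differs. Sites not covered (depth > 3) in every non-excluded
sample are set aside in a QC sidecar rather than classified, because an
uncovered sample makes presence/absence undecidable.

## Attribution precedence

The decision tree is an ordered partition; first match wins:

1. fixed in all samples → `ref_polymorphism`
2. fixed in exactly one pedigree (wild type + derived plants) →
   `lineage_polymorphism`
3. carried by an edited plant within its nuclease's target window (span
   ± 50 bp) → `on_target`
4. carried by an edited plant within 50 bp of a predicted off-target site
   for its nuclease → `predicted_off_target_hit`
5. shared by ≥ 2 plants of a group, echoed subclonally in the matched wild
   type, or present in an untreated control → `spontaneous`
6. carried only by PEG-exposed plants → `treatment_associated`
7. otherwise `unattributed`

Two deliberate choices. First, lineage evidence outranks positional
evidence: a variant fixed across a whole pedigree that happens to overlap a
predicted site is a polymorphism, because shared ancestry is stronger
evidence than positional coincidence. Second, sharing across *different*
groups (short of all samples) also maps to `spontaneous`, flagged
`cross_group`: plants from different pedigrees cannot share a
treatment-induced variant, so recurrence implies pre-existing origin.
Chimeric states never count as carriers — per-plant count tables tally only
fixed variants — they act purely as attribution evidence.

The on-target window is the nuclease target span padded by 50 bp, and the
same 50 bp default pads predicted off-target sites, chosen to cover the
spread of microhomology-collapsing deletions around a cut site while
staying far smaller than the mean distance between random background
variants at realistic mutation loads.

## Repair-signature classification

For a deletion of span *[s, e)*, the junction microhomology is the largest
*m* for which the *m* bases before the span equal the last *m* deleted
bases, or the first *m* deleted bases equal the *m* bases after the span —
the two equivalent placements of a deletion that collapses one copy of a
flanking repeat. The definition is symmetric (left- and right-aligned
representations give the same *m*, and it is invariant under reverse
complement); the comparison on each side is capped by the available flank.
Whether the original analysis used a one-sided or junction-spanning
definition is not recorded anywhere we could find; the symmetric definition
is used and documented here.

Classification: pure deletion with *m* ≥ `min_mh` → `alt_ej_compatible`;
with exactly one junction substitution (complex indels are decomposed into
a deletion block plus residual substitutions by exhaustive alignment over
block offsets, minimising substitutions) → `alt_ej_with_substitution`;
insertions and everything else → `c_nhej_like`. `min_mh` defaults to 2 bp
because a 1-bp "microhomology" arises by chance at every other junction and
carries no signal.

## The synthetic-experiment generator

`simulate_experiment()` emulates the study design at desk scale. Defaults:
a 250-kb genome in three chromosomes of 120/80/50 kb (unequal, so
length-proportional placement is testable); 150 reference and 40
per-pedigree lineage polymorphisms; Poisson(1.5) fixed spontaneous
mutations per regenerant — consistent with the observation that untreated
clonal regenerants carry very few fixed variants — of which 30% are echoed
subclonally in the matched wild type and 15% shared with a sibling plant;
Poisson(0.5) chimeric mutations per plant at VAF uniform on (0.05, 0.5);
Poisson(15) induced SNVs and Poisson(19) induced InDels per PEG-exposed
plant, matching the observed per-plant count scale; depth
negative-binomial with mean 25× (the middle of the 14–39× range a real
experiment of this kind produces) and size 8, making depth-dropout a rare
but present failure mode for the coverage rule; true-call QUAL fixed at 60
against Poisson(3) injected noise calls per sample with QUAL uniform on
(0, 30) and low VAF, so the QUAL > 20 boundary does real work in tests.

Every draw comes from an RNG stream keyed on `(seed, stream-name)` — one
stream per plant, per wild type, and for genome, reference polymorphisms
and read emission — so output is byte-identical across runs and adding a
sample leaves the others' events untouched. On-target edits are drawn from
the microhomology-deletion model: target loci are planted with a 3-bp
microhomology pair straddling the expected cut (in the downstream flank for
CRISPR, inside the 16-bp spacer for a TALEN), the generator picks the
maximal-microhomology pair spanning the cut within ±25 bp, and the
`alt_ej_subst` mode substitutes one retained junction base, re-aligning to
verify the substitution cannot be explained away as a shifted pure
deletion — so the generated label is guaranteed by construction.

What the generator does **not** emulate: read-level artefacts (mapping
bias, strand bias, indel realignment errors), linked or structural events,
sequencing-error models beyond the DP/AD/QUAL sampling, and GC- or
repeat-dependent coverage. Passing the closed-loop tests therefore shows
the audit logic is correct given reasonable calls; it does not certify
robustness to upstream calling artefacts in real data.

## Statistical choices

Group comparisons use the Kruskal–Wallis tie-corrected H. With 2–5 plants
per group the chi-square approximation is unreliable, so for total n ≤ 8 an
exhaustive permutation null (all distinct label assignments) supplies the
p-value; note that with groups of 2+2+2 the smallest achievable exact p is
6/90 ≈ 0.067, so no omnibus result on such a design can clear α = 0.05 —
the α for the `distinguishable` flag is configurable for exactly this
reason. No multiple-comparison adjustment is applied by default because the
primary report is a single omnibus test; pairwise contrasts are labelled as
exploratory. Spearman correlation (via `stats::cor.test`) quantifies
length-proportionality of per-chromosome counts.

## Problem sizes

The shipped tests run the full audit on 14-sample experiments with ~650
variant sites over a 250-kb genome, verify the search and pairing
primitives against brute-force sliding-window oracles on one hundred 10-kb
random genomes, and check generator calibration over 60 replicates of a
reduced configuration — sizes chosen so the complete suite exercises every
code path in about a minute on one core while keeping all statistical
checks comfortably powered.

## Known limitations

* The pipeline consumes VCF; read trimming, mapping and primary calling are
  upstream concerns, and calling artefacts propagate in.
* Off-target search is substitution-only (no bulges), mirroring a
  5-mismatch ungapped homology criterion; RNA:DNA bulge-tolerant sites are
  out of scope, as is activity scoring (CFD/MIT).
* Whether the 5-mismatch tolerance should count PAM positions is left to
  the caller: the default counts mismatches uniformly over the full query,
  and a PAM-aware mode (NGG required, protospacer-only mismatches) is one
  flag away. Neither is asserted as canonical.
* Attribution of a variant private to a single PEG-exposed plant is
  intrinsically ambiguous between treatment-induced and spontaneous; the
  tree resolves it as treatment-associated and reports the two categories
  jointly where totals are compared.
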