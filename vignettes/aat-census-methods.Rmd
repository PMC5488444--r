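---
title: "Methods: counting amino acid transporter loci and testing life-history effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counting amino acid transporter loci and testing life-history effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aatcensus)
```

## The problem

Sap-feeding insects move amino acids across gut, bacteriocyte and symbiont
membranes with two transporter families: the amino acid/polyamine/
organocation superfamily (APC, TC 2.A.3) and the amino acid/auxin permease
family (AAAP, TC 2.A.18). How many distinct transporter *loci* a species
keeps is informative about its nutritional ecology — in particular whether
it induces nutrient-enriched galls on its host plant or feeds free-living
on unmanipulated tissue. Estimating that number from de novo transcriptome
assemblies is not trivial: one locus is typically represented by several
transcripts (splice variants, truncated assemblies, alleles, barely
overlapping fragments), and hit tables contain plant contaminants and
look-alike transporters. This package implements the full census:
candidate selection, transcript-to-locus coalescing, counting, group
summaries, and a phylogenetically controlled test of the life-history
effect.

## Candidate selection

A transcript is a candidate when three conditions hold:

1. a profile-HMM domain hit to the APC (PF03024) or AAAP (PF01490)
   accession with e-value `< 1e-3` (`classify_config(domain_evalue = )`);
2. its *best* BLAST hit — minimum e-value, ties broken by maximum
   bitscore, then lexicographic subject id — has e-value `< 1e-3`,
   a subject annotated APC or AAAP, and the required subject taxon group
   (default `hemiptera`). This one rule removes plant contaminants and
   non-transporter look-alikes such as Na-K-Cl cotransporters. Best-hit is
   strict (`best_k = 1`); a top-k relaxation is configurable because the
   underlying convention ("best hits were hemipteran") is ambiguous;
3. a qualifying ORF: ATG-initiated, stop- or sequence-end-terminated,
   longest over all six frames, at least `min_orf_aa = 50` residues. Ties
   on protein length prefer forward frames, then the lower frame index,
   then the smaller start — purely for determinism. Codons containing
   ambiguous bases disqualify a span by default because the downstream Ks
   arithmetic needs unambiguous codons.

Transcripts with a qualifying domain hit but no BLAST rows are rejected:
the verification step is mandatory, mirroring the annotate-then-verify
workflow the census emulates.

## From transcripts to loci

De novo mode applies three collapse rules within each taxon and family:

* **Shared assembly component.** Trinity-style component ids group splice
  variants of one locus; each component keeps the member with the longest
  ORF as its representative.
* **Low synonymous divergence.** Every pair of component representatives
  is aligned (protein level, BLOSUM62, gap open 11 / extend 1), the
  alignment is mapped back onto codons, and the pairwise synonymous rate
  Ks is computed by Nei–Gojobori (1986) counting: fractional synonymous
  sites per codon (mutations to stop codons excluded from numerator and
  denominator), pathway-averaged synonymous/nonsynonymous differences
  (pathways through stops excluded, with an all-pathways fallback), and a
  Jukes–Cantor correction \(K_s = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p_S)\).
  Pairs with defined Ks `< 0.25` collapse. Saturated pairs
  (\(p_S \ge 3/4\)) never collapse — saturation means deep divergence.
  The reference census used PAML for this number without naming the model;
  NG86 is the simplest published method, deterministic, and oracle-testable,
  and the 0.25 threshold is method-tolerant at this divergence scale.
* **Short overlap.** Pairs whose aligned overlap is under 50 bp collapse:
  two non-overlapping fragments of one gene cannot be told apart, so the
  rule conservatively counts them once. The same 50 bp is the minimum
  overlap for a pair to be Ks-comparable at all, so every pair is either
  comparable or collapsible.

Pairwise rules define edges of a graph; loci are its connected components
(transitive closure), which is deterministic and matches the "collapse
into one" semantics. All within-family pairs are tested — families are
small, so the O(n²) stage is cheap and no similarity pre-filter can drop a
true edge.

**Alignment flavour.** One deliberate deviation from a strict global
(Needleman–Wunsch) alignment: `pair_decision()` uses the same scoring with
*free end gaps* (`align_proteins(type = "overlap")`). A strict global
alignment of two barely-overlapping fragments force-aligns their
non-homologous regions, inflating the measured overlap far past 50 bp and
silently disabling the short-overlap rule; with free end gaps the aligned
region is the homologous window, the overlap measurement means what the
rule intends, and full-length pairs are scored identically to the global
variant. The strict global alignment remains implemented and is verified
against a brute-force enumeration oracle.

Genome-guided mode replaces the sequence rules with mapped location: each
candidate's best-scoring mapping interval is taken, and intervals on the
same scaffold and strand that overlap or lie within `merge_gap_bp = 5000`
merge into one locus. The 5 kb default captures partial and
non-overlapping fragments of one gene without fusing tandem paralogs; the
underlying convention ("mapping to the same location") leaves the distance
unspecified, so the value is configurable and logged. Candidates without a
passing mapping hit fall back to the de novo rules (logged).

## Counts, summaries, and the PGLS test

`build_counts()` tabulates loci per taxon and family (family-agnostic: any
label gets a column; APC and AAAP are always present) and joins
life-history labels. `summarize_groups()` reports per-group arithmetic
means *truncated toward zero*, and a group total equal to the sum of the
truncated family means — the only convention that reproduces the published
average rows from the published per-species integers (the truncated mean
of totals differs). The inquiline (a gall-inhabiting non-galler) is
grouped with the gallers by default; the mapping is a configurable
argument.

The life-history test is generalized least squares under a Brownian-motion
tree covariance: \(C_{ij}\) is the shared root-to-MRCA path length of tips
i and j. The fit whitens with the Cholesky factor of C, estimates
\(\hat\beta = (X^\top C^{-1}X)^{-1}X^\top C^{-1}y\), and tests the
life-history term by a nested-model F test,
\(F = \frac{(RSS_0 - RSS_1)/q}{RSS_1/(n-p)}\), with the p-value from
\(F_{q,\,n-p}\). With \(C = I\) this is ordinary one-way ANOVA, which is
the identity the tests pin to machine precision. Counts are treated as
Gaussian responses, matching the analysis being reproduced; a count GLM is
out of scope. Degenerate inputs are handled explicitly: a non-positive
definite C gets a small configurable ridge with a warning; a constant
response returns F = 0, p = 1; a single-level predictor errors.

The published statistics (F = 32.3 for APC, F = 21.4 for AAAP) depend on
mitochondrial-tree branch lengths that are not published, so they cannot
be recomputed from in-paper data. The package instead demonstrates the
*direction* of the effect: on the packaged published counts and a
synthetic unit-branch-length stand-in topology (labelled synthetic; built
from the relationships described in the source text), the free-living
coefficient is positive for both families. That is the check; the
magnitude is not reproducible by design.

## What the synthetic generator states, and what a green test means

The generator's defaults are a stated world shaped like the published
census: galling baselines of 10 APC and 14 AAAP loci, a free-living effect
of +7 per family (the published group means are 10 vs 17 and 14 vs 21),
Brownian rate 1.5 on a unit-rate pure-birth tree of 16 taxa, one third of
taxa free-living. Per locus: a stop-free CDS of 100–500 codons (300–1500
nt, spanning the Pfam-domain regime) wrapped in ATG-free UTRs with an
in-frame terminal stop; 1–3 isoforms sharing a component id (some
3'-truncated); with probability 0.15 an allelic copy under its own
component at Ks ≈ 0.1; with probability 0.15 (per family) one locus
represented only by two fragments overlapping 3–10 codons (< 50 bp);
paralogs diverged to targets drawn from Ks 0.5–0.9. Contaminants (10% of
loci) get passing domain hits but plant best-BLAST hits; background
transcripts get no domain hits. Hit tables are exactly consistent with
the truth at the default `label_noise = 0`.

Divergence is produced by iterating single-nucleotide substitutions
(synonymous draws from precomputed synonymous-neighbour lists; a 10%
nonsynonymous admixture for paralogs) and re-measuring with the package's
own Ks calculator until the target is met — generator and estimator agree
by construction, which is what makes the 0.25 threshold testable. Because
a single substitution moves Ks in steps of roughly \(1/S\), small targets
are matched to the nearest achievable step, never above
`target * (1 + tol)`. The start codon is never mutated (mutating it
relocates the ORF), and every emitted transcript is validated so that the
package's own ORF finder recovers exactly the designed CDS; when a random
sequence carries a longer spurious ORF in another frame, the CDS is
jittered with nonsynonymous substitutions (which leave Ks untouched) until
the designed ORF wins. This keeps truth tables exact without touching any
analysis threshold.

Two honest limitations of the stated world. First, at most one locus per
taxon/family is fragmented: the short-overlap rule cannot distinguish
non-overlapping fragments of *different* loci — it would merge them, by
design, as the conservative reading of the rule — so a world with
multi-locus fragmentation is one where truth is unrecoverable by any
implementation of the rule. Second, the generator does not emulate
read-level noise, assembly chimeras, or expression-dependent transcript
absence; a green recovery test establishes that the collapse rules invert
the generator's isoform/fragment/allele/paralog structure, not that real
assemblies are this clean. The recovery study draws 2–6 true loci per
family: the collapse rules act pairwise, so recovery does not depend on
family size, and small families keep the quadratic pair stage inside the
stated runtime budget.

One test interpretation is worth recording: "synonymous-only evolution has
Nd = 0" holds exactly only when each codon is struck at most once. With
multiple hits, NG86 pathway averaging between the end codons can route
through nonsynonymous intermediates (TTA→TTG→CTG, observed as TTA vs CTG,
averages a path through TTC), so the multi-hit regime is tested by
bounding Nd at 5% of differences and requiring the Jukes–Cantor-corrected
Ks to recover the applied synonymous load within 15% *on average* over
replicates; a per-replicate 15% band is not attainable at small
substitution counts, where one coincident double hit moves a single
estimate by ~10%.

## Numerical and formatting conventions

* Coordinates are 0-based half-open internally (`longest_orf` start/end on
  the reported frame's source strand); exported tables are 1-based
  inclusive, matching BLAST conventions.
* Mapping-hit strand is derived from subject coordinate orientation, and
  coordinates are normalised so start ≤ end.
* Gap costs are `open + length × extend` (a length-L gap costs 11 + L).
* All tie-breaks (ORF frames, best hits, equal-length representatives,
  interval sweeps) are lexicographic and documented at the function level;
  every stage is a pure function of inputs and configuration, so reruns
  are byte-identical (checksummed in the bundle manifest and run report).
* Seeds are mandatory for every stochastic step; derived seeds stay below
  2^31.
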