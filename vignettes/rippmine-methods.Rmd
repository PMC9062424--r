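---
title: "Mining rSAM-anchored RiPP pathways: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining rSAM-anchored RiPP pathways: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radical-SAM (rSAM) enzymes — especially the SPASM-domain subfamilies that bind
auxiliary iron–sulfur clusters — are strongly associated with the maturation
of ribosomally synthesized and post-translationally modified peptides (RiPPs).
That association makes the enzyme family a search handle: partition the family
into a sequence similarity network (SSN), walk the genome neighborhood of each
cluster's members, and look for the small, often unannotated, precursor
peptide gene that the tailoring enzyme acts on. The signature of a real
precursor is *sequence consensus*: independent genomes of one enzyme cluster
carry small ORFs whose cores align, repeat, or share residue-class motifs
(e.g. a TVGG tandem array, an Asp-Cys dipeptide repeat, Aro-Xaa-Xaa-Asn).

`rippmine` implements that workflow as deterministic offline code, plus the
mass-spectrometric arithmetic used to verify the downstream chemistry: the
formation of cyclopropylglycine (CPG) from valine costs two hydrogen atoms per
ring, so every modification state of a peptide sits 2 Da (at charge z:
2·m~H~/z m/z units) below the previous one, and shifted b/y fragment ladders
localize which Val carries a ring.

## Pipeline model, stage by stage

### Sequence similarity network

Pairwise scores are Smith–Waterman local alignments under BLOSUM62 with affine
gaps (open 11, extend 1; a gap of length L costs 11 + L), computed by
`Biostrings::pairwiseAlignment`. Bit scores use the Karlin–Altschul form
$\mathrm{bits} = (\lambda S - \ln K)/\ln 2$ with the gapped-BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$, and the E-value is $E = m\,n\,2^{-\mathrm{bits}}$
with $m,n$ the two full sequence lengths. These are *self-contained, documented*
conventions: absolute E-values will differ from any particular BLAST release
(different composition corrections and search-space conventions), which is why
both thresholds are parameters of `ssn_params()` rather than constants. The
defaults are the standard analysis values: $E \le 10^{-80}$, identity
$\ge 40\%$, sequence lengths 340–450 aa.

Percent identity divides identities by *alignment columns including gaps*; the
upstream web tools do not document their denominator, so this choice is fixed
here and exposed through the same edge record that carries the raw score.

Clusters are connected components of the thresholded graph (isolated nodes are
singletons), ranked by member count with ties broken by the lexicographically
smallest member id — the source analysis assigned arbitrary cluster numbers,
so size rank is this package's convention. Each node is one sequence; UniRef90
style deduplication or repnode collapsing is assumed to have happened upstream.
The representative of a cluster is its medoid (maximal summed percent identity
over incident within-cluster edges). Analysis keeps clusters with rank ≤ 118,
≥ 2 nodes, and more than three sequences, read strictly as ≥ 4.

### Gene neighborhoods

`extract_neighborhood()` takes up to k CDS features on each side of the anchor
(default k = 10) in genomic order, ignoring strand — the convention that
matches genome-neighborhood diagrams, which draw both strands. Whether the
source protocol counted all genes or CDS only is not documented; CDS-only is
the documented choice here. The cluster span is the permissive
`[min start, max end)` envelope of the context; no operon or co-orientation
requirement is imposed, because the original pathway calls were manual and the
span only seeds the flank scan.

### Flanking-ORF scan

`scan_flanks()` scans the two windows `[span_start − w, span_start)` and
`[span_end, span_end + w)` (default w = 1000 bp, measured from the cluster
edge; the alternative anchor-relative reading is available by passing a
one-gene neighborhood) in all six frames. Rules, each of which matters for the
oracle tests:

* accepted start codons default to ATG/GTG/TTG (bacterial translation table
  11); GTG/TTG initiators translate as Met;
* an ORF must have its start codon inside a window but may run past the
  window edge — a precursor straddling the boundary should not be lost;
* start codons outside the windows are invisible: nested ORFs sharing a stop
  collapse to the longest *visible* one. This ordering is essential — an
  in-frame upstream start inside the adjacent gene would otherwise swallow a
  genuine flank ORF into a representative the scan never reports;
* length bounds (default 20–120 aa) apply after the collapse;
* codons containing N are never starts or stops, and an ORF whose span
  contains N is dropped (its translation is undefined).

The 20 aa minimum is a package choice (no documented minimum exists); it
admits short precursors while bounding noise, and it is a parameter.

### Consensus and motifs

Pooled candidates (annotated beats ORF-scan on the same interval; exact
duplicate peptides deduplicate with provenance kept) are aligned by a
progressive MSA: single-linkage guide tree on pairwise global identities,
profile–profile Needleman–Wunsch under BLOSUM62 (open 10, extend 0.5), ties
resolved by input order so runs are deterministic. Column conservation is the
fraction of non-gap residues equal to the column's modal residue; the
consensus string emits the modal residue at conservation ≥ 0.8 (a parameter —
the source analysis never quantified "consensus").

Tandem repeats are exact and maximal: `find_tandem_repeats()` reports arrays
with period 2–6 and ≥ 2 full copies that extend neither left nor right by a
full unit. Units are primitive — `DCDCDCDCDCDC` is one hit (`DC` × 6), not
also `DCDC` × 3 — and rotated phases of one array collapse to the leftmost
start. Degenerate (inexact) repeats are expected to surface through
residue-class patterns instead; the built-in patterns are Aro-Xaa-Xaa-Asn
(Aro = {W, Y} by default, Phe by a flag), Asp-Cys, Tyr-Asn-Arg-Xaa-(His-Asn-Arg)₂
and His-Xaa-Ser.

Candidate ranking formalizes what was a manual call. The score is
$w_1 \cdot \text{support} + w_2 \cdot \min(\text{max copies}, 6) + w_3 \cdot
\text{pattern hits}$ with default weights (1, 0.25, 0.5). The support term
averages, over the candidate's non-gap columns, conservation × column
occupancy × agreement with the column's modal residue. The two extra factors
are deliberate refinements of plain "mean conservation": a column occupied
only by the candidate itself is trivially conserved and carries no consensus
evidence, and in a gap-free pool plain column conservation is identical for
every row, so only modal agreement distinguishes a consensus-supported
candidate from a decoy. Known limitation: for short peptides a couple of
chance pattern hits (0.5 each) can rival the support term, so in a focused
analysis the pattern set should be restricted to the motifs relevant to the
cluster at hand; the weights are configurable.

### Mass engine

Residue masses derive from elemental compositions with monoisotopic atomic
masses (H 1.0078250319, C 12, N 14.0030740, O 15.9949146, S 31.9720707);
proton 1.0072765 Da. C-terminal amidation substitutes NH₂ for OH (−0.98402 Da).
Isotope labels are per-residue formula deltas (e.g. ¹³C₅¹⁵N-Val: +6.013810 Da).
A CPG ring is a neutral −H₂ delta tied to a Val position — modeled as a
formula event, not a residue replacement, because that matches the "loss of
2 Da" bookkeeping and composes over n sites. Fragment conventions: b~i~ is the
first-i residue sum plus one proton per charge; y~j~ adds water and the amide
adjustment; internal b/y fragments are bare residue sums plus proton;
a modification or label is contained in a fragment exactly when its position
lies inside it. Charge carriers are protons only; monoisotopic peaks only.

Δppm is reported *truncated* (not rounded) to one decimal — the only
convention consistent with all four printed reference errors (3.2, 1.7, 1.1,
2.7) simultaneously — with full precision retained.

`localize_modifications()` enumerates every assignment of rings to Val
positions and compares predicted ladders with the observed ions at a ppm
tolerance (default 10). Two tiers are reported: *consistent* assignments
explain every observed ion (noiseless data yields exactly the planted one),
and *best* assignments maximize matched ions. The second tier is what makes
localization robust: with 5 ppm Gaussian noise and a 10 ppm gate, the chance
that at least one of ~30 ions drifts past the gate is large, so demanding
strict consistency would usually return nothing — whereas a wrong site
mispredicts several ions by ~2 Da and can essentially never win the count.
The mixture (nonprocessivity) flag is raised when no single assignment is
consistent but every ion is explained by some assignment: the spectrum then
requires at least two co-existing modification states, the hallmark of a
nonprocessive enzyme acting across the repeats.

### Assay arithmetic

Beer–Lambert conversions are kept in mM and cm throughout because the three
extinction coefficients are given in mM⁻¹cm⁻¹ (ferrozine–iron 27.9 at 562 nm,
methylene-blue sulfide 34.5 at 670 nm, peptide A₂₈₀ 5.6). Equivalents are a
plain ratio to a reference (enzyme monomer) concentration. The published
iron/sulfide equivalents are wet-lab measurements whose raw absorbances are
not printed; they are not recomputable targets, only the arithmetic is.

## The synthetic world

`simulate_bundle()` emulates the statistical shape of the real analysis, not
its biology:

* **Families** have block-structured identity: members of a block derive from
  a block ancestor by independent per-site substitutions at rate
  $1 - \sqrt{t/100}$, so expected pairwise identity equals the target t
  (default 90 within, ~random between; substitutions only — identity, not
  phylogeny, is the controlled variable). Lengths (360–430 aa) sit inside the
  SSN length filter.
* **Genomes** back-translate the anchor (uniform synonymous codons — no codon
  usage model), place 50–200 bp intergenic gaps and random-strand neighbor
  genes, and plant the precursor either as an annotated CDS beside the anchor
  or hidden at a fixed offset past the outermost cluster gene. Three planted
  motif archetypes rotate across blocks: hidden TVGG×4, annotated (Asp-Cys)×6,
  hidden Aro-Xaa-Xaa-Asn twins, with a one-residue leader variation per
  genome so pooling and alignment are exercised.
* **Flank hygiene**: the guarantee that flanks contain no spurious ORF is met
  by bounded constructive repair, not blind rejection — a random kilobase
  essentially always contains a ≥ 20 aa ORF (the chance a given start codon
  runs 20 codons without a stop is $(61/64)^{20} \approx 0.38$, and there are
  dozens of start codons per window), so resampling whole flanks cannot
  terminate. Instead, offending start codons are disabled by a middle-base
  substitution, ORFs starting inside the protected precursor get an early
  in-frame stop planted outside every protected interval (repairs themselves
  become protected so overlapping-frame repairs cannot clobber each other),
  and unrepairable layouts trigger a full redraw, all bounded and seeded.
* **Ladders** perturb theoretical fragment m/z by Gaussian ppm noise under a
  seed, with planted sites recorded.

What a green test does establish: thresholding, clustering, neighborhood,
scanning, pooling, motif detection and localization recover planted structure
exactly or at the stated rates. What it does not: behavior on real databases —
pseudogenes, frameshifts, contig breaks, GC-biased codon usage, paralogs,
domain-level homology below the identity cutoff, or real instrument noise
structure. The published census numbers of the original analysis (node and
cluster counts) are snapshots of a live database and are out of desk scope by
design.

## Numerical and convention choices

* Genomic intervals are 0-based half-open internally; GFF3/GenBank convert at
  the I/O boundary. Result tables for ORFs, repeats and pattern matches use
  0-based starts; peptide residue positions (labels, modification sites,
  fragment indices) are 1-based, matching b/y ion nomenclature.
* Configs, truths and manifests are JSON (no YAML parser in the supported
  dependency set).
* All randomness flows from one integer seed per generator call; generators
  restore the caller's RNG state.
* Tie-breaks are total and documented: cluster rank (size, then smallest id),
  medoid (summed identity, then smallest id), guide-tree merges (input
  order), score ranking (score, then peptide id).
* GenBank reading is a minimal flat-file parser (simple and `complement()`
  locations, `/product`, `/locus_tag`, `/translation`); `join()` locations are
  rejected. GFF3 goes through `rtracklayer`, FASTA through `Biostrings`.

## Limitations

* E-values are internally consistent but not BLAST-identical; port thresholds,
  not absolute values, when comparing with web-tool output.
* The MSA is a small-n progressive aligner meant for peptide pools (tens of
  sequences, ≲ 100 columns), not a general MSA replacement.
* Localization enumerates ring assignments over Val sites ($2^{n_{Val}}$) and
  is capped at 14 sites.
* No leader/core cleavage prediction, RBS scoring, HMM construction, isotope
  envelopes, or raw LC-MS file parsing.
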