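---
title: "Methods: homology-based miRNA discovery and EST-SSR marker design"
author: "mirssr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based miRNA discovery and EST-SSR marker design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Scope and scientific background

`mirssr` mines de novo transcriptome assemblies of non-model plants for
two kinds of functional sequence: conserved microRNA precursors and
microsatellite (EST-SSR) marker loci. Both screens are classical
desk-scale protocols — a homology scan against known mature miRNAs
followed by hairpin-structure filtering, and a MISA-style repeat scan
followed by PCR primer design — implemented here as one tested, seeded,
fully reproducible package. A synthetic-transcriptome generator with a
machine-readable truth table stands in for a raw assembly, so every
stage of both cascades can be scored against known ground truth without
any external downloads.

# The miRNA discovery cascade

The pipeline mirrors the established homology-first protocol:

1. **Reference deduplication.** Mature miRNA references are clustered at
   100% identity: a retained sequence is never identical to, nor a
   full-length substring of, another retained one. On containment ties
   the longer sequence wins; among identical sequences the
   lexicographically smallest id wins, making the operation idempotent
   and order-independent.
2. **Exact homology hits.** Because the screen demands zero mismatches,
   zero gaps and an alignment length of at least 20 nt, every acceptable
   hit is an exact substring of the transcript. The implementation
   therefore searches for exact full-length occurrences of each mature
   reference (T/U equivalent) rather than running a seeded heuristic
   aligner — the accepted set is identical and a significance threshold
   becomes vacuous. Only the forward strand is searched by default
   (assembled transcripts are oriented mRNA surrogates); a
   `both_strands` switch exists.
3. **Precursor windows.** Each hit seeds a window from 200 nt upstream
   of the mature start to 200 nt downstream of its end (about 400 nt in
   total), clipped at transcript boundaries. Clipped windows are marked
   `truncated` and continue through the cascade.
4. **Coding filter.** Windows overlapping an open reading frame of at
   least 100 codons in any of the six frames are removed before folding.
   ORFs may be complete (ATG to stop) or open-ended at either transcript
   boundary (a 5'-partial stop-free run, or an ATG run reaching the 3'
   edge), the convention of transcriptome ORF predictors. This heuristic
   stands in for a protein-database search and is deliberately
   conservative: flagging more is safer than folding coding sequence.
5. **MFE folding** (below) and **four-criterion evaluation**.
6. **Window deduplication.** When several references hit the same
   window, the evaluation with the best MFEI represents that window.

## The folding model

Secondary structures are predicted by an internal dynamic-programming
minimum-free-energy folder (Rcpp), pseudoknot-free, with deterministic
traceback: ties are broken toward the pairing with the smallest 5'
index, then the smallest 3' index, so identical inputs always give
identical structures.

Two scoring models share one DP:

* **stacking** (default): nearest-neighbor stack free energies
  (kcal/mol at 37 °C; Watson–Crick values from the Xia 1998 unified set,
  GU wobble values following the Mathews 1999 extension, approximated
  where the published motif tables are non-additive), logarithmic loop
  penalties (`hairpin(n) = 5.4 + 1.078 ln(n/3)`,
  `bulge(1) = 3.8`, `bulge(n) = 2.8 + 1.078 ln n`,
  `interior(n1,n2) = 1.7 + 1.078 ln((n1+n2)/2) + min(0.6 |n1−n2|, 3)`),
  and an affine multiloop cost `3.4 + 0.4 × (branches + 1)`. Interior
  loops are capped at 30 unpaired bases; hairpin loops need ≥ 3 unpaired
  bases; there are no dangling ends and no coaxial stacking. This is the
  smallest model that yields kcal/mol-scaled free energies, which keeps
  AMFE and MFEI on the scale conventional for precursor screening.
* **pair_count**: each pair scores −1 and loops are free (base-pair
  maximization). Its optimum is cheap to verify exhaustively, so it is
  the reference model for oracle tests.

Correctness is established structurally rather than by comparison with
an external folder: an exhaustive enumerator generates *every* nested,
constraint-respecting pairing of sequences up to 14 nt and scores them
with an independent loop-decomposition scorer; the DP must attain the
enumeration optimum under both models (500 random sequences in the
acceptance suite, plus per-commit property tests). Reported ΔG values
from web-server folders are model-specific and are treated as metadata,
never as folding acceptance values.

## The four criteria and MFEI

For a folded window and its mature span, with the **terminal loop**
defined as the hairpin loop reached by walking inward from the longest
helix (ties toward the 5'-most helix) through single-branch loops:

1. **Arm** — the mature must avoid the terminal loop and every paired
   mature base must pair across the loop to the opposite arm; a mature
   whose bases pair into two different stems has no arm.
2. **MFEI** — `AMFE = |ΔG| / window length × 100`,
   `MFEI = AMFE / GC%`. The default threshold is 0.70: the screen's own
   accepted examples lie at 0.71–0.83, while typical mRNA sits at
   0.62–0.66, rRNA near 0.59 and tRNA near 0.64, so 0.70 admits every
   accepted example while excluding the typical-mRNA band. |ΔG| and AMFE
   are reported but not independently thresholded; no published ΔG
   cutoff exists for this screen.
3. **Star mismatches** — the number of mature bases unpaired in the MFE
   structure (bulges count) must be ≤ 6. This is the only
   structure-derivable reading of "mismatches with the opposite miRNA*"
   when the star sequence itself is not reported.
4. **Loop/break integrity** — the mature must not intersect the terminal
   loop and must contain no unpaired run longer than 3 nt
   (configurable).

The verdict is the conjunction of the four flags. Accepted-set
monotonicity in each threshold (raising the MFEI cutoff, lowering the
mismatch cap or the gap limit can only shrink the set) is covered by
tests. A window with GC = 0 has undefined MFEI and auto-fails
criterion 2. The MFEI summary reports the mean to two decimals with
round-half-up, matching the convention of published candidate tables:

```{r}
library(mirssr)
summarize_mfei(reported_mirna_table()$mfei)
#> n = 9, mean 0.76, min 0.71, max 0.83
```

# The EST-SSR cascade

## Scanner semantics

`scan_ssrs()` reports every maximal tandem run whose primitive unit
(1–6 nt) meets the MISA-style repeat thresholds {10, 6, 5, 5, 5, 5} for
unit sizes 1–6. Three conventions pin down edge cases deterministically:

* runs are credited to the **primitive** unit only — never `(ATAT)n`
  when `(AT)2n` applies;
* a locus spans **complete repeats** from the leftmost position of the
  maximal run (a trailing partial unit neither extends the span nor
  shifts it);
* a locus wholly contained in a locus of a different unit size is
  suppressed; overlapping loci of different unit sizes are otherwise
  both reported.

Motif classes use the field's `AG/CT` notation: a motif, its cyclic
rotations and the rotations of its reverse complement form one class,
represented by the lexicographically smallest member. Loci separated by
at most 100 intervening bases (the common MISA compound default) share a
compound id. Distribution summaries exclude mononucleotide runs by
default because in EST assemblies they are confounded with sequencing
and assembly error.

## Melting temperatures and primer design

Primer Tm uses two-state nearest-neighbor thermodynamics with the
SantaLucia 1998 unified parameter table: dimer ΔH/ΔS terms, terminal
A/T and G/C initiation corrections, the symmetry correction for
self-complementary oligos, the entropic salt correction
`ΔS + 0.368 (N−1) ln[Na+]`, and
`Tm = 1000 ΔH / (ΔS + R ln(Ct/x)) − 273.15` with `x = 4` for
non-self-complementary sequences. Default assay conditions are 50 mM
monovalent salt and 50 nM total strand concentration. Published marker
tables built with other engines report Tm under their own (unpinned)
parameter sets; those values are treated as schema examples, not
calibration targets. The test suite instead checks agreement with an
independently coded calculator over the same published table, duplex
symmetry (`Tm(s) = Tm(revcomp(s))`) and thermodynamic orderings.

`design_primer_pairs()` enumerates every primer of length 18–25 nt lying
wholly in the flanks (never overlapping the repeat), keeps those with Tm
in 55–62 °C, pairs them under the 100–300 bp product constraint, and
ranks pairs by distance of the mean Tm from the 57 °C optimum, then by
the Tm difference within the pair. One candidate per 3' position (the
one closest to the optimum) bounds the search without losing good
designs. The stated optimum of 57 °C is kept as the ranking target even
though published marker tables often cluster near 60 °C; the objective
is configurable. Infeasible geometry (e.g. a repeat too close to a
transcript end) yields an empty result with a logged reason rather than
an error.

# The synthetic-transcriptome generator

## What it emulates

The generator's default configuration is the package's standard study
condition: three true precursors (5p and 3p arms, 0/2/4 star
mismatches, 65-nt perfect stem extensions giving ~180-nt precursors of
realistic size), five decoys each violating exactly one criterion, five
SSR loci spanning unit sizes 1–3 at and above the thresholds, and
i.i.d. background at 42% GC, a typical plant transcriptome composition.
Hosts are 600–1200 nt so precursor windows are unclipped and SSR flanks
are ample. Mature sequences come from the packaged reference set of
nine conserved plant miRNA families.

Star arms are reverse complements of the mature with substitutions at
the declared mismatch positions, chosen from bases that can pair with
neither the mature base nor (for runs) any base of the run — so the
designed duplex register is locked in by the nesting constraint and the
realized unpaired count equals the requested one. Two further
construction rules keep the designed structure thermodynamically
optimal: mismatch runs never exceed 3 nt unless a bulge is the goal,
and at least 3 paired anchor bases remain between any run and either
duplex end (shorter anchor helices are not worth their loop penalties
and would open in the MFE structure). Terminal loops are random A/C
strings, which cannot pair internally.

The decoys:

* **arm** — the mature straddles two adjacent long hairpins, each half
  pairing into its own stem: fully paired (criteria 3 and 4 hold),
  strongly folding (criterion 2 holds), but no single arm hosts it.
* **star-mismatch** — seven substitutions in runs of ≤ 3 with ≥ 3-bp
  helices between them: every other criterion holds, the count fails.
* **loop/break** — four contiguous substitutions: one 4-nt internal
  bulge, count 4 ≤ 6, arm and MFEI intact.
* **MFEI** — an intact minimal duplex (mature + loop + perfect star,
  no stem extension) in a GC-rich (60%) host: criteria 1/3/4 hold but
  the 421-nt window folds far too weakly for its GC content.
* **coding** — a structurally perfect precursor placed just downstream
  of a planted 180-codon ORF so its window overlaps the ORF; it is
  removed by the coding filter before folding.

Every planted transcript is validated by running the package's own
screen on it and re-drawn with fresh background until it exhibits
exactly its intended criterion profile (bounded retries; in practice
one or two draws suffice). Fixtures are therefore valid under *any*
seed — the recovery properties are consequences of the construction,
not of a blessed random draw. Background transcripts are exact-GC
shuffles verified to contain no qualifying SSR runs and no 20-nt mature
matches; planted SSR runs get guard bases so they cannot extend by
chance.

## What it does not emulate

No read-level error, no coverage variation, no chimeric or fragmented
contigs, no expression levels, no paralogous miRNA families differing
by one or two bases, and background is i.i.d. rather than
Markov-structured genomic sequence. Perfect precision/recall on the
fixture therefore demonstrates the correctness of the cascade's logic
and coordinate bookkeeping — not the screen's sensitivity on real
assemblies, where homology coverage of the reference set is the
limiting factor.

# Numerical and design choices

* Coordinates are 1-based inclusive in every report (TSV, GFF3, truth
  table); sequence slicing uses the same convention internally.
* Ties in the folding traceback, dedup retention, mismatch-layout
  placement and primer ranking are all broken deterministically;
  rerunning any pipeline on identical inputs reproduces every output
  file byte for byte.
* MFEI is reported to two decimals with round-half-up; Tm to three.
* The reference set is deduplicated; transcripts are not, unless
  `dedupe_transcripts` is set (deduplicating the assembly is an
  upstream assembler concern, and which side the original protocol
  clustered is ambiguous).
* Published screens of this kind sometimes count more contributing
  sequences than distinct candidate miRNAs; that many-to-one
  bookkeeping is ambiguous and is not modeled — this package reports
  one evaluation per (window, best reference) pair and plain counts per
  stage.
* Configuration files are flat key-value YAML; unknown keys are hard
  errors so typos cannot silently revert to defaults.
* Validation problem sizes: enumeration oracle on 500 random sequences
  of 8–14 nt; SSR regex oracle on 200 random 10-kb sequences; homology
  oracle on ~100 kb of fixtures; the standard fixture (17 transcripts,
  ~14 kb) for end-to-end recovery. These sizes give the oracles real
  discriminating power while keeping the full suite to a couple of
  minutes on one CPU.

# Known limitations

The stacking model omits dangles, coaxial stacks, special hairpin
tetraloops and full interior-loop tables, so its ΔG values are not
comparable to full Turner-model folders to better than ~20%; MFEI
consumers should use one folding engine consistently. The coding filter
is a heuristic: it can flag long spurious ORFs in UTR-containing
windows and cannot detect coding regions shorter than the threshold.
Primer design does not screen for self-dimers, hairpins or
template-wide uniqueness; designs are ranked by Tm geometry only.
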