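---
title: "Assembling protein sequences from de novo peptides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling protein sequences from de novo peptides: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepnexus)
```

## The problem

Antibodies, nanobodies and other engineered binders are absent from
sequence databases, so their primary structure must be read directly from
the protein. Multiprotease mass spectrometry produces thousands of short
(7–20 residue) peptide reads with per-read confidence estimates; assembly
must stitch these into full-length candidate sequences despite substitution
errors, systematic N→D / Q→E deamidation, spurious identifications, and
the fundamental inability of standard fragmentation to distinguish leucine
from isoleucine. `pepnexus` implements this assembly pipeline end to end,
with a digestion simulator that makes every stage testable against known
ground truth.

## Preprocessing model

PSM confidences arrive as natural-log probabilities and are exponentiated
to [0, 1]. Filtering applies, in order: removal of rows with missing
mandatory fields, a 7–20 residue length window (shorter peptides are
uninformative for overlap detection, longer ones are rarely reliable de
novo calls), a q-value threshold (default 0.10 — permissive, because
assembly itself averages out residual errors), an optional
minimum-confidence gate (disabled by default; the q-value is the primary
gate because it has a calibrated interpretation), and contaminant
exclusion by L/I-insensitive substring containment against a user-supplied
FASTA. A small, clearly synthetic contaminant file ships with the package
(`contaminants_synthetic.fasta`) as a placeholder for a real contaminant
database. A missing q-value column is an error unless explicitly waived,
since silently skipping FDR control would silently change results. Both
`(...)` and `[...]` modification dialects are stripped, as tool outputs
vary.

## Greedy assembly

The greedy assembler merges exact suffix–prefix overlaps
longest-overlap-first, after collapsing duplicates (multiplicity is
retained as support) and absorbing sequences contained in longer ones.
Overlaps are exact: the underlying reads are short and abundant, so
mismatch-tolerant overlaps would mostly manufacture chimeras. L and I are
distinct during assembly; their equivalence is applied only when mapping
against a reference, where it reflects a measurement limitation rather
than sequence identity.

The minimum overlap defaults to 3 residues and warns below that: with a
20-letter alphabet, 1–2 residue overlaps occur constantly by chance.
Determinism is guaranteed by a fixed tie-break: among equal-length
overlaps, prefer the merge producing the longest result, then lexicographic
order of the two sequences. Iterative scaffolding repeats
assemble-then-deduplicate until the contig set is unchanged (a fixed
point), capped at 10 rounds.

Greedy assembly is a heuristic; the test suite compares it against an
exhaustive merge-order oracle on peptide sets of up to 8 sequences and
requires coverage equality in at least 90 % of trials, with the greedy
result never exceeding the oracle.

## Weighted de Bruijn graph assembly

Peptides are decomposed into k-mers (default k = 7; 6 performs comparably,
other values markedly worse at peptide scale — k must be short enough that
7-residue peptides contribute, long enough that k-mers are mostly unique
in a ~100–700 residue protein). Edges join k-mers overlapping by k−1
residues. The edge weight is the number of occurrences of the spanning
(k+1)-mer across the peptide multiset: this makes duplicate reads count,
keeps path statistics well defined, and conserves total weight (the sum of
edge weights equals the number of (k+1)-mer occurrences over all
peptides — a property the tests assert). Peptides shorter than k are
skipped with a logged count, never padded.

Unitigs — maximal paths through nodes of in- and out-degree one — are
spelled into contigs; traversal stops at the first revisited node, so
repeats (e.g. His-tags) terminate cleanly instead of looping. Contigs
below the size threshold (default 15) are dropped. An
overlap–layout–consensus (OLC) phase then merges contigs on exact
suffix–prefix overlaps (default minimum 5), with the same tie-breaks as
the greedy assembler; merged scaffolds concatenate their edge-weight lists
and recompute the mean and minimum. On containment absorption the
container's weight list is kept — the contained contig's path is a
sub-path whose weights would otherwise be double-counted.

Each scaffold is scored S = α·ln(L) + β·w̄ + 0.2·w_min. The logarithm
makes length's marginal reward decay, so contiguity is rewarded without
favoring over-extended chimeras; the mean weight rewards scaffolds backed
by many spectral observations; the fixed 0.2 penalty on the minimum edge
weight demands continuous support with no single tenuous link. α and β
default to 1 and are exposed in configuration; only the 0.2 coefficient is
fixed by the scoring definition.

### The edge-weight floor under deep coverage

`min_edge_weight` defaults to 1 (no filtering), appropriate for shallow
data. Under deep simulated coverage the picture changes: a recurrent
artifact such as deamidation at 5 % of reads creates genuine side-branches
("bubbles") whose arms carry ≈ 5 % of the local path depth, and greedy OLC
re-joining of bubble-split unitigs can pick the wrong arm. Because bubble
popping is deliberately out of scope (the edge filter is the only
error-control mechanism), the correct response is an edge-weight floor
scaled to depth. On the package's noisy simulation fixture (mean edge
weight around 40–60), the package's own grid search selects
`min_edge_weight = 9` with k = 7, and that configuration is what the noisy
end-to-end tests use. The rule of thumb is a floor around 10–20 % of the
expected edge depth.

Raising the floor shrinks the surviving edge set monotonically, and the
tests assert that the total number of edges traversed by unitigs shrinks
with it. The total *spelled* length of contigs is deliberately not
asserted monotone: splitting a path duplicates the k−1 residues at the
cut, so spelled length can transiently grow as edges are removed.

## Clustering, alignment and consensus

Scaffolds are clustered by greedy centroid clustering in descending length
order: each scaffold joins the first cluster whose representative (its
longest member) it matches at ≥ 85 % identity over the aligned region,
with at least 80 % of the shorter sequence aligned; otherwise it founds a
new cluster. Measuring coverage on the shorter sequence is what lets a
partially assembled scaffold merge with its near-identical superstring —
the intended "coverage mode" for redundancy removal. The 0.85 identity
threshold preserves sequence specificity; the 0.8 coverage default is a
configuration value. A 4-mer sharing prefilter (≥ 15 % of the shorter
sequence's 4-mers) rejects hopeless pairs before alignment; a pair at the
acceptance thresholds necessarily shares far more than that, so the
prefilter cannot change results, only cost. Clustering and alignment are
internal and deterministic rather than delegated to external binaries,
keeping tests hermetic; thresholds match the external tools' settings.

Each cluster is aligned by representative-anchored progressive alignment:
every member is globally aligned to the representative and the pairwise
alignments are merged positionally, inserting the maximal observed gap run
after each representative position. For the near-identical members a
cluster contains, this is effectively optimal; it would be a poor general
MSA. The position-specific scoring matrix records per-column residue
frequencies among non-gap characters (columns sum to 1 within 1e-9;
all-gap columns are marked empty and omitted from the consensus), and the
consensus takes the per-column argmax with alphabetical tie-breaking for
determinism. Consensus sequences are ranked by cluster member count, then
summed scaffold score.

## Evaluation metrics

Mapping uses best local alignment with documented constants: match +2
(L/I equivalent), mismatch −1, deamidation pairs (reference N vs scaffold
D, reference Q vs E) 0, affine gaps costing 4 for the first residue and 1
thereafter. The neutral deamidation score reflects that these are
systematic chemical artifacts, not read errors, and keeps the alignment
from clipping around them; they still count as mismatches for identity but
are reported separately as `deamidation_sub` columns. All constants are
overridable via `mapping_scoring()`. Coordinates are 1-based inclusive
throughout, the R/Bioconductor convention.

Coverage is the union of aligned spans of qualifying mappings divided by
reference length — at ≥ 90 % identity for high-confidence coverage, ≥ 40 %
for permissive coverage. N50 is the shortest length at which the
descending cumulative sum of scaffold lengths reaches half the total.
Precision is the fraction of scaffolds mapping at ≥ 40 % identity (low
enough to retain homologous segments, high enough to exclude noise); mean
identity averages over ≥ 70 % mappings and is defined as 0 when none
qualify, keeping the composite score total rather than undefined.

The composite score is the dot product of Min–Max-normalized metrics with
weights 0.35 (coverage), 0.25 (N50), 0.25 (inverted scaffold count) and
0.15 (mean identity); normalization is computed across the set of
assemblies compared in one call, so the score is relative to that
comparison set by construction. When a metric is constant across the set,
all its values map to 1 (degenerate rule, documented). The AQS,
100·(C·I·P)/log10(N+9), uses the high-confidence coverage, mean identity
and precision directly as its normalized inputs — they are already 0–1
fractions — and N the scaffold count; the +9 makes the fragmentation
penalty exactly 1 at N = 1.

## Hyperparameter search

`run_grid()` enumerates the full Cartesian product of candidate values for
k, OLC minimum overlap, size threshold, edge-weight floor, FDR threshold
and refinement rounds, runs the filter–assemble–evaluate pipeline per
configuration, normalizes the composite score across the whole grid, and
ranks (ties: fewer scaffolds, then higher coverage). The pipeline is
deterministic, so results are identical for any worker count — parallelism
is purely an execution detail. The shipped default grid is illustrative,
not canonical: sensible ranges depend on data depth. A failing
configuration records its error and ranks last rather than aborting the
grid.

## What the simulator emulates — and what it does not

`simulate_psm_table()` models: a 10-protease panel with standard cleavage
specificities (trypsin after K/R not before P, LysC after K, GluC after E,
chymotrypsin after F/W/Y, elastase after A/V/S/G/L/I, thermolysin before
I/L/V/A/M/F, pepsin after F/L, and papain / proteinase K / legumain as
low-specificity enzymes via a per-site nonspecific cleavage rate — all
overridable); up to 2 missed cleavages (the conventional search setting);
sampling with replacement from a 5–25 residue fragment window, so the
downstream 7–20 filter is genuinely exercised and spectral multiplicity
feeds de Bruijn edge weights; per-residue substitution noise (default
0.01); N→D / Q→E deamidation (default 0.05); spurious random-sequence PSMs
(default 0.10); occasional `(ox)` tokens; and Beta-distributed confidences,
high-centered for true PSMs and low-centered for false ones. The default
noise rates are illustrative choices of realistic magnitude, not measured
values.

q-values are *oracle* q-values: the running false fraction along the
confidence ranking, made monotone by taking the minimum over all looser
thresholds. They are calibrated by construction — filtering at threshold t
retains a set whose realized false fraction is at most t — which is
precisely the property the FDR-filter tests assert. A real rescoring model
estimates this quantity with error; simulating that estimation error is
out of scope.

The simulator does not model spectra, retention times, intensity-dependent
confidence, position-dependent error rates, chimeric spectra, or PTMs
beyond oxidation tokens and deamidation. Tests passing on simulated data
therefore demonstrate the correctness and robustness of the assembly
logic under the stated error model, not performance on real instrument
output.

### Reconstruction fixtures and the tiling condition

Exact reconstruction is only information-theoretically possible when the
digest retains every junction of the reference: if no peptide spans some
(k+1)-residue window, no assembler can recover the sequence across it.
Test fixtures therefore draw random repeat-free references *conditioned on
their digest tiling the sequence at k* (`random_tiled_protein()`), using a
four-protease panel (elastase, thermolysin, chymotrypsin, trypsin) whose
complementary specificities make the condition cheap to satisfy by
redrawing. Noiseless fixtures use the exhaustive digest — every fragment
emitted once — rather than random sampling, which is what "the complete
digest" means; sampled fixtures are reserved for the noise-robustness
tests, where multiplicity matters.

## Problem sizes and numerical choices

The test suite runs at deliberately modest sizes chosen to exercise every
code path: 150-residue references with four proteases (≈ 500–900 exhaustive
fragments) for reconstruction, 120-residue references with the 10-protease
panel at 300 PSMs per protease (3 000 PSMs, mean edge depth ≈ 40–60) for
noise robustness, 200 trials of ≤ 8 peptides for the oracle comparison,
and 2^5-configuration grids. Score recomputation tolerances are 1e-9;
PSSM column sums are checked to 1e-9; oracle/greedy coverage equality to
1e-12. All randomness flows through explicit seeds, and the pipeline
itself is seed-free (fully deterministic), so byte-identical reruns are a
tested invariant rather than an aspiration.

## Known limitations

* L/I ambiguity is intrinsic to the data; consensus sequences can be wrong
  at every L/I position without any detectable signal. Downstream
  validation must treat L and I as a single symbol.
* Greedy assembly can be suboptimal on adversarial overlap structures; the
  oracle-equivalence test bounds, but does not eliminate, this gap.
* The de Bruijn assembler has no bubble popping or tip clipping; its only
  error control is the edge-weight floor, which requires adequate depth to
  separate signal from artifact.
* Repeats at scale k (e.g. poly-A runs, His-tags) terminate unitigs and
  fragment assemblies; this is inherent to the graph representation at
  fixed k.
* The composite score is relative to its comparison set; scores from
  different invocations are not comparable.
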