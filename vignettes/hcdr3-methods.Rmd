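---
title: "Profiling H-CDR3 loops: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling H-CDR3 loops: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcdr3)
```

## The analysis in one paragraph

The third complementarity-determining region of the antibody heavy chain
(H-CDR3) spans the V(D)J junction and is the principal antigen-contact
loop. Because the junction is assembled by random gene-segment joining with
exonuclease trimming and non-templated (N) nucleotide additions, its
length, reading frame and amino-acid chemistry vary widely, and developing
B cells are normally selected against loops that are too short, too
hydrophobic or too basic. `hcdr3` implements the downstream analysis of
annotated heavy-chain rearrangement tables: extraction of the loop from
the IMGT junction, clonotype grouping and expansion classification with
treemap landscapes, D-segment reading-frame (RF) assignment,
physicochemical profiling (net charge, GRAVY hydropathy, six-factor
descriptors), population statistics and PCA — plus a seeded V(D)J
simulator that generates annotated repertoires with ground truth so every
step can be validated end to end.

## The loop and its boundaries

The IMGT junction runs from the conserved Cys codon at position 104
through the conserved Trp/Phe codon at position 118. The loop is the
junction minus its three N-terminal residues (104--106, typically `C-x-x`)
and its single C-terminal residue (118):

```{r}
extract_loop(c("CTTIRYW", "CARGRFDYW"))
```

A four-residue junction leaves an empty loop. Such degenerate records are
retained in length histograms at length 0 — real repertoires under
impaired selection contain loops as short as 2 aa, and dropping the
boundary case silently would bias the short end of the distribution — but
they are excluded from chemical profiling, where properties of an empty
peptide are undefined.

## Clones, expansion categories and treemaps

Sequences sharing 100% amino-acid identity of the loop form a clone;
the key can be refined with the V and/or J gene call
(`group_clones(key = c("loop", "v_gene"))`). Refining the key can only
split clones, so the clone count and the number of sequences in
singleton clones are non-decreasing under refinement — a property the
test suite checks on simulated tables.

Expansion categories follow the three-way rule: a clone of one sequence
is *single*; a clone with two or more sequences is *expanded* and, when
its frequency reaches the `he_threshold` (default 1% of all productive
sequences in the compartment), *highly expanded* (HE). Two deliberate
edge decisions:

* the frequency denominator is the number of productive sequences in the
  compartment, not the number of clones;
* a singleton is always *single*, even when `1/total` exceeds the
  threshold in a tiny data set, because "expanded" requires more than one
  identical sequence.

`min_he_clone_size(total, threshold)` returns the smallest clone size
reaching the threshold, `ceiling(threshold * total)` computed with a
`1e-9` guard so that floating-point overshoot (e.g. `0.01 * 300 =
3.0000000000000004`) cannot inflate the answer by one.

Landscapes use a squarified treemap: clones are pre-sorted by descending
size with lexicographic tie-breaks, rows are packed along the shorter side
of the remaining rectangle, and a clone is added to the current row only
while the worst tile aspect ratio does not deteriorate. The layout is
deterministic given the clone ordering, tile areas are exactly
proportional to clone sizes (relative tolerance 1e-9), tiles never
overlap and together cover the canvas; all three are property-tested over
random stratifications.

## Reading-frame assignment

A germline D segment can be read in three frames. Following the
established I/II/III nomenclature, RFI is the tyrosine-enriched frame
thought to be favoured in normal repertoires, while RFII/III encode
hydrophobic (valine/leucine) and basic (arginine) residues or stop codons
and are normally counter-selected.

Internally the junction is codon-aligned starting at the Cys-104 codon, so
the translation offset into the germline D is

```
frame_offset = (d_germline_start - d_junction_start) mod 3
```

with both coordinates 0-based (the AIRR 1-based convention is converted at
the I/O boundary, and only there, so that this arithmetic stays free of
off-by-one cases; the conversion pair is exported and tested as an
involution). The offset is invariant to re-anchoring the alignment, since
equal shifts of both coordinates cancel.

The offset-to-label correspondence is gene-specific and stored in a
versioned JSON anchor map. For the two bundled mouse D genes the anchors
were calibrated from their germline translations: offset 2 yields the
tyrosine-rich frame (`YYYGSSY` for D1-1, `YYGYD` for D2-2) and is
anchored to RFI; offset 0 yields the valine-bearing hydrophobic frame
(RFII); offset 1 yields the leucine/arginine/stop frame (RFIII). Genes
absent from the map fall back to a documented default (offset 0 → RFI);
supplying a custom map without a default turns an unknown gene into an
error naming it.

Records whose D alignment is absent (fully trimmed or unannotated D —
common in very short loops) cannot be assigned; they are excluded from RF
distributions and disclosed as a separate no-D fraction rather than
being forced into a frame. When a whole clone is reduced to one RF vote
(`rf_distribution_per_clone()`), discordant members are resolved by
majority with a warning, ties towards the lower frame label; discordance
cannot arise from coordinates alone and signals annotation noise.

## Physicochemical profiling

All properties are computed on the loop, never the full junction.

**Net charge** at pH 7 (default) uses the Henderson--Hasselbalch
protonation fractions with the Lehninger pKa table: basic groups (Arg,
Lys, His side chains and the free amino terminus) contribute
$1/(1+10^{\mathrm{pH}-pK_a})$, acidic groups (Asp, Glu, Cys, Tyr and the
free carboxyl terminus) contribute $-1/(1+10^{pK_a-\mathrm{pH}})$. Net
charge is strictly decreasing in pH and bounded by the ionizable-group
counts; both are tested. Whether terminal groups should count for an
excised loop is chemically debatable — the loop is an internal fragment —
so `include_termini` is exposed; it defaults to `TRUE`, matching the
default behaviour of common peptide-property software, and the toggle
only shifts every loop by the same constant at fixed pH, leaving
between-population contrasts untouched.

**GRAVY** is the arithmetic mean of Kyte--Doolittle hydropathy values;
positive means hydrophobic.

**Six-factor descriptors.** Loops are summarised as 6-vectors of
per-residue factor means, in the style of factor-analysis amino-acid
scales, with factor semantics F1 hydrophobicity, F2 alpha/turn propensity,
F3 bulk, F4 composition, F5 flexibility, F6 electronic properties. The
bundled table (`fasgai_factors()`) is a **synthetic reconstruction**: each
factor is a single well-established property scale (Kyte--Doolittle;
Chou--Fasman P-alpha; Zamyatnin side-chain volume; Grantham composition;
side-chain rotatable-bond count; side-chain charge at pH 7 under the
Lehninger table), standardised to mean 0 / sd 1 over the 20 residues. The
published factor matrix is not redistributed here; since every downstream
operation is a per-residue lookup followed by means and PCA, the
machinery is identical and only absolute factor values differ. Users with
access to the published matrix can pass it via the `table` argument.

All three property functions are permutation-invariant (they are means)
and satisfy the weighted-mean identity under concatenation; both are
property-tested.

## Statistics

**Mann--Whitney U.** The U statistic is computed by rank sum with
midranks. The two-sided p-value is exact (from the null U distribution)
when $n_1+n_2 \le 12$ without ties, otherwise a normal approximation with
tie correction and continuity correction. The exact path is verified
against brute-force enumeration of all $\binom{n_1+n_2}{n_1}$ labelings,
and the approximation stays within 0.02 of enumeration at $n_1=n_2=8$.
`stats::wilcox.test` serves as an additional cross-check in the tests,
not as the implementation.

**Bonferroni.** `p_adj = min(1, m p)` with an explicit family size `m`.
In `compare_populations()` the family is the number of population pairs
tested per property; families are not pooled across properties, matching
how per-panel adjusted p-values are conventionally reported for this kind
of figure.

**Per-length short-loop comparison.** For the 2--7 aa range the
per-length test is a two-sided Fisher exact test on the 2x2 table (length
k vs not-k, group A vs B), Bonferroni-corrected over the lengths tested.
The test behind published per-length significance marks of this kind is
usually unnamed; the exact two-proportion test is the conservative
default at these counts.

**PCA.** `pca_profiles()` decomposes the small matrix of
population-mean 6-vectors (one row per population, as in repertoire-level
factor plots), column-centred, unscaled by default — the descriptors are
already standardised scales, and scaling a 6-column matrix of means would
let a near-constant factor dominate through noise amplification; `scale.`
is exposed for sensitivity analysis. Components come from
`stats::prcomp`; each loading vector is signed so its largest-magnitude
element is positive, making scores platform- and run-stable. Variance
fractions sum to 1, loadings are orthonormal, and scores-times-loadings
reconstructs the centred input to 1e-9; a zero-variance matrix yields
all-zero fractions with a warning rather than `NaN`s.

## The simulator: what it emulates, and what it does not

`simulate_repertoire()` is a structural stand-in for annotated
sequencing data, not a biological model. Per founder clone it samples V,
D, J segments (configurable weights), trims the D on both ends and the J
head with truncated geometric draws, inserts N nucleotides with truncated
Poisson lengths and uniform bases, assembles the junction starting at the
Cys-104 codon (the V tail contributes the first three residues, the J
head ends in the Trp codon, so the conserved bounds hold by
construction), and rejection-samples until the junction is in frame and
stop-free. Reading-frame and loop-shape selection is a second rejection
stage with acceptance weight

```
w = rf_weight[RF] * short_loop_penalty^[loop < cutoff] * min(1, exp(-charge_coef * charge))
```

normalised by the maximum RF weight. Founders are expanded to clone sizes
drawn from a rank-frequency (Zipf) law or given explicitly; members of
expanded clones receive somatic point mutations. With
`preserve_clone_key = TRUE` (default) mutations are confined to the V
region outside the junction, so a clone's loop amino-acid sequence — its
clone key — is never altered and per-sequence true mutation counts stay
exactly recoverable; with the flag off, junction sites mutate too,
productivity is recomputed, and downstream clone splitting can be
stress-tested. Isotypes are drawn per compartment from configurable
probabilities.

Defaults are chosen once as plausible study conditions: geometric
trimming with mean about 2 nt per end and Poisson N-additions with mean
2.5 per joint (typical annotation-scale magnitudes for murine junctions),
Zipf exponent 1.5 and 300 founder clones per 3000 sequences (a
heavy-tailed landscape in which the top clones clear the 1% threshold),
and per-compartment isotype skews dominated by IgG2b (spleen) and IgG2c
(bone marrow) with minority IgG1/IgG3 fractions of 2%/8% (spleen) and
6%/5% (bone marrow). The paired scenario (`scenario_wt_vs_ko()`) gives
the selected arm RF weights `I = 1, II = 0.35, III = 0.25`, a short-loop
penalty of 0.3 below 8 aa and a positive-charge coefficient of 0.15,
and the unselected arm no selection at all; the contrasts these induce
(more RFI, fewer very short loops, lower charge and hydropathy in the
selected arm) are directional emulations, and no published effect sizes
are asserted from them.

The construction distribution of the reading frame — the probability of
each frame given segment sets, trimming and N-addition laws, conditioned
on productivity — is computed exactly in the test suite by enumerating
every (D gene, trim, N-length, J-trim) layout and multiplying per-codon
no-stop probabilities (N positions are uniform over the four bases and
codons are disjoint, so stop events are independent across codons). The
simulator's empirical frame distribution must sit inside the binomial 99%
interval of that enumeration, and configured acceptance weights are
re-identified from emitted repertoires as selected-to-baseline proportion
ratios, in which per-frame construction probabilities cancel. The same
ratio design identifies D sampling weights, because per-gene productivity
acceptance (genes differ in length and stop-codon content) cancels
against a uniform-weight baseline run.

What the simulator does **not** capture: correlated isotypes within a
clone, insertion/deletion hypermutation, biased N-nucleotide composition,
allelic variation, convergent recombination producing identical loops
from distinct events, or any fitting to real sequencing data. Tests that
pass on simulated repertoires therefore validate the analysis machinery
— definitions, arithmetic, classification rules — not the biological
realism of the generator.

## Numerical and interface decisions

* Coordinates are 0-based half-open internally, 1-based closed (AIRR
  style) on disk; conversion happens only at the I/O boundary.
* "Unique sequences" deduplication (identical nucleotide junction within
  a population) is exposed as a `dedupe` flag, default off, because the
  published per-compartment counts do not state the rule precisely
  enough to hard-wire it.
* The productive filter requires the flag (when present), a stop-free
  junction, a nucleotide length divisible by three and the conserved
  C...W/F bounds; it is idempotent and order-preserving.
* Clone ordering (descending size, lexicographic key) is the single
  source of determinism for treemaps and output files;
  `run_pipeline()` reruns are byte-identical at fixed configuration and
  seed.
* Test problem sizes are deliberately modest — repertoires of a few
  hundred to ten thousand sequences, enumeration oracles on reduced
  single-V/single-J segment sets with N-additions capped at 4 — chosen
  so the whole validation suite runs in minutes while keeping every
  check exact or CI-bounded at 99%.

## Known limitations

* RF anchors are bundled for the two attested mouse D genes only; other
  genes use the default anchor unless the user supplies a calibrated map.
* The six-factor table is a synthetic reconstruction (above); absolute
  factor values are not comparable with analyses run on the published
  matrix, though separations driven by charge, hydrophobicity and bulk
  are preserved by construction.
* No de-novo D alignment: reading frames are inferred from annotation
  coordinates (or simulator truth), never from sequence search.
* Subclone splitting by C-terminal loop variation is approximated by the
  loop+V/J key mechanism; no further heuristic is attempted.
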