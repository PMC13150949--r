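# hcdr3

Analysis of immunoglobulin heavy-chain CDR3 (H-CDR3) repertoires from
AIRR-style rearrangement tables, aimed at studies of B-cell selection and
plasma-cell clonal expansion: which loops survive developmental
checkpoints, which clones expand, and what their chemistry looks like.

The H-CDR3 spans the V(D)J junction — from the conserved Cys-104 codon to
the conserved Trp/Phe-118 codon in IMGT numbering — and is the antibody's
principal antigen-contact loop. `hcdr3` implements the downstream half of
a repertoire study, starting from annotated tables (e.g. IMGT/HighV-QUEST
output or the built-in simulator):

* **Loop extraction** — the loop is the junction minus residues 104–106
  and 118: `loop = junction[4 : (L−1)]`.
* **Clonotypes and expansion** — clones are sets of sequences with 100%
  amino-acid loop identity (optionally refined by V/J gene); a clone is
  *single* (n = 1), *expanded <1%*, or *highly expanded* when
  `n / total ≥ 1%`; landscapes are drawn as squarified treemaps with tile
  area proportional to clone size.
* **Reading frames** — the D-segment translation frame is
  `(d_germline_start − d_junction_start) mod 3`, mapped to the I/II/III
  nomenclature through a per-gene anchor map (RFI = tyrosine-enriched
  frame; RFII/III = hydrophobic / arginine- and stop-bearing frames).
* **Physicochemistry** — Henderson–Hasselbalch net charge at pH 7
  (Lehninger pKa set), GRAVY (mean Kyte–Doolittle hydropathy), and
  six-factor descriptor vectors (a synthetic FASGAI-style table; see the
  methods vignette).
* **Statistics** — Mann–Whitney U (exact for small tie-free samples,
  tie- and continuity-corrected normal approximation otherwise) with
  explicit-family Bonferroni correction; PCA of population-mean
  6-vectors with a deterministic sign convention.
* **Simulation** — a seeded V(D)J generator (trimming, N-additions,
  productivity and selection by rejection, Zipf clone sizes, SHM,
  compartment-skewed isotypes) that emits AIRR-style tables plus ground
  truth for every derived quantity.

## Worked example

```r
library(hcdr3)

sim <- simulate_repertoire(sim_config(seed = 2026, n_sequences = 3000,
                                      n_clones = 300,
                                      populations = c("PC_SPL", "PC_BM")))
tbl <- annotate_physchem(annotate_loops(filter_productive(sim$table)))

spl <- classify_expansion(group_clones(tbl[tbl$population == "PC_SPL", ]))
glance(spl)
#>   n_clones total_sequences key   n_single expanded_share
#> 1      299            3099 loop       213          0.931
head(tidy(spl), 3)
#>   clone_id loop_aa           n frequency category
#> 1        1 SLLWLRPHYAMDY  1201    0.388  highly_expanded
#> 2        2 FYYGLRFAY       425    0.137  highly_expanded
#> 3        3 FTTVVATLFDY     231    0.0745 highly_expanded
```

93% of this simulated compartment sits in expanded clones, and the top
clone alone holds 39% of all sequences — the kind of skewed landscape
`plot_treemap(spl)` draws, with singles, expanded <1% and highly
expanded tiles in increasing shades.

```r
rf_distribution(assign_rf(tbl))
#>   rf        n proportion
#> 1 I      2498      0.403
#> 2 II     1562      0.252
#> 3 III    2137      0.345
```

Without selection, all three D reading frames are well represented;
`scenario_wt_vs_ko()` contrasts this with a selected arm that favours
RFI and penalises short, positively charged loops.

```r
extract_loop("CTTIRYW")
#>   junction_aa loop_aa loop_length degenerate
#> 1 CTTIRYW     IRY               3 FALSE
net_charge("IRY")   # 0.997  — one arginine, net positive at pH 7
gravy("IRY")        # -0.433 — mean Kyte-Doolittle hydropathy
```

Population-mean profiles feed the PCA (`pca_profiles()`), whose `tidy()`
scores and `glance()` variance fractions drive `autoplot()`.

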