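# rleinhib

Analysis of the regulatory role of **rate-limiting enzymes (RLEs)** in
metabolic inhibitory networks, across multiple organisms.

Metabolic products of one enzyme can act as in-vivo inhibitors of another.
Joining enzyme–product annotations with compound–inhibition annotations
within one organism yields **inhibiting enzyme pairs**: the first enzyme of a
pair is the *inhibitor provider* (it produces the inhibitory compound), the
second is the *target*. RLEs — enzymes catalysing the slowest, flux-controlling
step of a pathway — turn out to dominate this network: they provide a majority
of in-vivo inhibitors, their products reach most inhibited targets within and
across the six KEGG pathway categories (Carbohydrate, Lipid, Nucleotide,
AminoAcid, CofactorVitamin, Others), and pairs involving RLEs show elevated
functional linkage during evolution.

`rleinhib` implements that analysis as a tested, reusable pipeline for anyone
studying enzyme-level regulation in metabolic networks:

- **Network construction** — the within-organism compound join of product and
  inhibition tables into a pair edge list (`build_pairs()`), with
  distinct-entity coverage statistics (`coverage_report()`), inhibitor
  production summaries (`inhibitor_production_stats()`) and cross-pathway
  matrices (`cross_pathway_matrix()`).
- **Enrichment** — one-sided hypergeometric tests
  (`hypergeometric_tail()`): for a sample of n draws from a population of N
  containing K successes, `P(X ≥ k) = Σ_{i≥k} C(K,i) C(N−K,n−i) / C(N,n)`.
- **Phylogenetic profiling** — each enzyme gets a 0/1 presence profile over an
  82-genome reference panel (23 prokaryotes + 59 eukaryotes); pair similarity
  is the Jaccard coefficient `J = M11 / (M01 + M10 + M11)`, which ignores
  joint absences; nested pair classes (all pairs ⊇ RLE-provider pairs ⊇
  both-RLE pairs) are compared with one-sided Welch t-tests
  (`profile_similarity_analysis()`).
- **Conservation** — pairs occurring in ≥ 3 organisms
  (`find_conservative_pairs()`) and compound-initiation comparisons such as
  ADP (C00008) versus AMP (C00020) (`compound_preference_test()`).
- **Synthetic data** — a parameterised generator (`simulate_dataset()`) that
  plants known enrichment, profile-coupling and conservation structure, so
  every stage is testable with ground truth and calibrated on a null model.

All functions take tibbles and return tibbles; `run_full_analysis()` chains
every stage and optionally writes a TSV + JSON report bundle.

## Worked example

```r
library(rleinhib)

ds <- simulate_dataset(simulate_config(seed = 42))   # 5 organisms, planted structure
report <- run_full_analysis(ds)

report$production_stats
#> # A tibble: 5 × 5
#>   organism n_inhibitors n_rle_produced fraction percent
#>   <chr>           <int>          <int>    <dbl>   <int>
#> 1 eco                62             26    0.419      42
#> 2 hsa                61             29    0.475      48
#> 3 mmu                60             20    0.333      33
#> 4 rno                60             21    0.35       35
#> 5 sce                58             26    0.448      45
```

Per organism: the number of distinct in-vivo inhibitor compounds, how many
are produced by at least one rate-limiting enzyme, and that fraction (also
as an integer percentage). With the default planted `inhibitor_boost = 3`,
RLEs — 20% of enzymes — provide 33–48% of inhibitors here.

```r
pa <- report$profile_analysis
pa$comparisons[pa$comparisons$organism == "hsa", ]
#> # A tibble: 2 × 8
#>   group_a      group_b        n_a   n_b mean_a mean_b t_statistic p_value
#> 1 rle_provider common          45    95  0.344  0.290        2.95 0.00208
#> 2 rle_both     rle_provider    17    45  0.389  0.344        1.46 0.0778
```

Mean Jaccard profile similarity is higher for pairs with a rate-limiting
provider than for all pairs (one-sided Welch p ≈ 0.002 in this run),
recovering the planted profile coupling (`rho_pair = 0.3`).

The compound-initiation test works directly from a conservative-pair table;
on the counts 317 ADP-initiated pairs (171 from RLEs) versus 234 AMP-initiated
pairs (32 from RLEs):

```r
compound_preference_test(
  tibble::tibble(compound = "C00008", n_pairs = 317L, n_rle_pairs = 171L),
  tibble::tibble(compound = "C00020", n_pairs = 234L, n_rle_pairs = 32L))
#>   compound_a compound_b     k     n     K     N  p_value
#> 1 C00008     C00020       171   317   203   551 1.29e-23
```

so rate-limiting providers strongly prefer ADP over AMP as the mediating
inhibitor.

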