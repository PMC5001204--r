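# pinmod

Detection of drug-response functional modules in protein interaction
networks, with miRNA integration.

When a compound perturbs a cell, the transcriptional response is rarely a
list of isolated genes: the affected genes tend to sit close together in
the protein interaction network (PIN), forming *functional modules* whose
members are collectively differentially expressed. `pinmod` implements a
complete, testable pipeline for finding such modules from two-condition
expression data and a PIN, annotating them against pathway gene sets, and
linking them to differentially expressed miRNAs whose direction of change
opposes that of their target genes. It was built with drug-treatment
studies of hepatocytes in mind (drug-metabolizing enzymes, PXR-driven
induction), but every stage is generic.

## The model

Per-gene p-values from a two-sample test are modelled as a beta-uniform
mixture (BUM),

    f(p) = λ + (1 − λ) a p^(a−1),   p ∈ (0, 1],  a ∈ (0, 1),

uniform noise of weight λ plus a Beta(a, 1) signal component. For a chosen
false discovery rate, the noise upper bound π = λ + (1 − λ)a yields the
threshold

    τ(FDR) = [ (π − FDR·λ) / (FDR·(1 − λ)) ]^(1/(a−1)),

and each network node receives the signed score

    s(p) = (a − 1) (ln p − ln τ),

positive below τ, negative above. The *maximally scoring module* is the
connected subgraph maximizing the sum of member scores (the maximum-weight
connected subgraph problem): solved exactly by exhaustive enumeration on
small networks and by a deterministic positive-component-contraction /
cheapest-bridge heuristic on large ones. Because the FDR dials τ and hence
the module size, the pipeline scans a grid of FDRs and reports
true-positive rate and precision against ground truth when it is known.
A complementary *active-modules* search aggregates z = Φ⁻¹(1 − p) over
candidate sets as z_A = Σz/√k, calibrated against Monte-Carlo random sets,
growing several disjoint modules within a fixed depth of their start
nodes. Modules are then enriched by the hypergeometric test against GMT
pathway sets, focal terms are picked by keyword (GO) and rank (KEGG), and
miRNA–gene target pairs are retained when the gene is in the module, the
miRNA is significant, and the pair is anti-correlated (miRNA fold change
on the opposite side of 1 from the gene's log fold-change sign).

A first-class synthetic-data generator plants a connected module in a
scale-free network, realizes the BUM assumption (or full two-arm log2
expression with 7 replicates per arm), and adds a miRNA layer and pathway
sets with known truth, so the whole pipeline is validated by
planted-module recovery.

## Worked example

```r
library(pinmod)
bundle <- run_pipeline(pipeline_config(seed = 1))
glance(bundle$scan)
#> # A tibble: 1 × 4
#>   selected_fdr module_size lambda_mix a_shape
#>          <dbl>       <int>      <dbl>   <dbl>
#> 1        0.001          25      0.961  0.0781
bundle$evaluation
#> # A tibble: 1 × 3
#>   tp_rate precision    f1
#>     <dbl>     <dbl> <dbl>
#> 1       1         1     1
```

The default synthetic scenario (1000-gene scale-free network, planted
25-gene module, log2 shift 4 at replicate noise 0.5) yields 33 genes at
p < 0.01, a 33-node induced subnetwork, a BUM fit of λ = 0.961,
a = 0.078, and an FDR scan whose selected module recovers the planted
module exactly (true-positive rate, precision and F1 all 1): the module
search denoises the loose p < 0.01 pre-selection. `write_report(bundle)`
prints the full funnel; `autoplot(bundle$scan)`, `autoplot(bundle$module)`
and `plot_relative_abundance(bundle$relative_abundance)` draw the scan,
the module and the module-vs-SDG pathway concentration.

Bundled worked-example tables from a rifampin-treated human hepatocyte
study (`hepatocyte_*()`) demonstrate the table-level operations: the seven
focal enrichment terms, their 19 key genes, the 20 significant miRNAs, and
the 8-gene / 14-miRNA anti-correlated miRNA-regulated PIN.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full pipeline on the default synthetic scenario from scratch
with the given seed, prints the recovered module size and its F1 against
the planted truth, and writes the machine-readable result file.
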