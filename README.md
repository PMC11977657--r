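# seedscape

Detecting microRNA target signatures in ranked gene lists through
seed-complementary-region (SCR) enrichment landscapes, change-point cut
selection, target-set algebra, and DNA-methylation scoring.

## The problem

When a microRNA is replenished in (or lost from) a cell, its hundreds of
targets shift expression only subtly; the signal lives in the *global*
distribution of seed-matching genes along a ranked differential-expression
list, not in any single gene. `seedscape` quantifies that signal. It was
built for miRNA replenishment experiments of the miR-99a/100-5p and
miR-125b-5p type — tumour-suppressor miRNAs silenced by promoter
hypermethylation in germ cell tumours — but every function is generic over
miRNAs, gene universes and designs. Intended users are computational
biologists analysing miRNA perturbation or de-repression experiments who
want a transparent, scriptable alternative to web tooling.

## What it computes

Given a mature miRNA, its **SCR element words** are the DNA reverse
complements of the contiguous 6–8 nt sub-spans of the 1–8 seed (six words;
the canonical 2–7 element of miR-100-5p is `ACGGGT`, of miR-125b-5p
`TCAGGG`). For a ranked list of `N` genes, a word carried by `K` of them,
and the leading `n = kB` genes (bins of `B = 200`) containing `x` carriers,
the landscape score at bin `k` is the signed smaller tail of
`X ~ Hypergeometric(N, K, n)`:

    score(k) = ±(−log10 p),  p = P(X ≥ x) (enrichment, +) or P(X ≤ x) (depletion, −)

Per miRNA, the **SSSS** (single summed significance score) sums the six
element scores per bin. The leading-edge cut is selected by **CPDV**
(change-point delta value): `CPDV_i = L_i − min(L_{i+1..i+5})`, argmax over
bins, leading edge = `selected_bin × B` genes. Targets are leading-edge
genes carrying the canonical SCR; set summaries use inclusion–exclusion;
`ora()` adds hypergeometric over-representation with BH adjustment.
Companion modules cover probe detection filtering against negative
controls, gene-level collapse and ranking, ΔΔCt relative quantification,
cumulative pyrosequencing methylation scores (`Σ` per-site mean %,
maximum `100 × n_sites`), beta→M conversion `M = log2(β/(1−β))`, and
region probe-count filtering. A seeded synthetic-data module generates
3'UTR universes with spiked words, ranked experiments, methylation tables
and Ct panels with known truth.

## Worked example

```r
library(seedscape)
library(dplyr)

mirnas <- mirna_table(
  c("miR-100-5p", "miR-125b-5p"),
  c("AACCCGUAGAUCCGAACUUGUG", "UCCCUGAGACCCUAACUUGUGA")
)
canonical_scr_words(mirnas)
#>  miR-100-5p miR-125b-5p
#>    "ACGGGT"    "TCAGGG"

derive_scr_elements(mirnas) |> filter(mirna == "miR-100-5p")
#> # A tibble: 6 × 5
#>   mirna      label seed_start seed_end word
#>   <chr>      <chr>      <int>    <int> <chr>
#> 1 miR-100-5p m1-6           1        6 CGGGTT
#> 2 miR-100-5p m2-7           2        7 ACGGGT
#> 3 miR-100-5p m3-8           3        8 TACGGG
#> 4 miR-100-5p m1-7           1        7 ACGGGTT
#> 5 miR-100-5p m2-8           2        8 TACGGGT
#> 6 miR-100-5p m1-8           1        8 TACGGGTT

# a full synthetic experiment: 4000 genes, 1400 responders shifted by
# -1.5 log2 units, the miR-100-5p SCR spiked into 60% of responders
cfg <- synth_config(seed = 42)
sim <- simulate_scr_experiment(cfg)
res <- run_pipeline(pipeline_config(
  utrs = sim$utrs, mirnas = mirnas, expr = sim$expr,
  probe_info = sim$probe_info, sample_info = sim$sample_info,
  annotation = sim$annotation, seed = 42
))
res
#> <scr_pipeline>
#>   ranked genes: 4000
#>   cut: bin 8 (1600 genes)
#>   target union: 1041 (65.1% of leading edge)

glance(res$cutpoint)
#> # A tibble: 1 × 5
#>   selected_bin n_leading  cpdv lookahead bin_width
#>          <int>     <int> <dbl>     <int>     <int>
#> 1            8      1600  115.         5       200

res$target_summary
#> # A tibble: 1 × 9
#>   mirna_a    mirna_b   n_a   n_b n_overlap n_total n_union list_length union_pct
#>   <chr>      <chr>   <int> <int>     <int>   <int>   <int>       <int>     <dbl>
#> 1 miR-100-5p miR-12…   950   242       151    1192    1041        1600      65.1
```

Reading the output: the change-point lands one bin right of the 1400
spiked responders (bin 8 = 1600 genes; the SSSS peak itself sits at bin 7
— see the methods vignette for why the change point trails the peak under
ranking noise). Of those 1600 leading genes, 950 carry the miR-100-5p SCR
(the spiked word, strongly enriched) and 242 the miR-125b-5p SCR (chance
occurrences only in this simulation); their de-duplicated union covers
65.1% of the leading edge. `plot_landscape(res$landscape)`,
`plot_ssss(res$ssss)` and `plot_cpdv(res$cutpoint)` draw the corresponding
curves; `background_presence_rate(res$occurrences, "ACGGGT")` reports the
universe-wide carrier rate the enrichment is judged against.

The methods vignette (`vignettes/scr-enrichment-landscapes.Rmd`) documents
the model, parameter defaults, generator design and known limitations.

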