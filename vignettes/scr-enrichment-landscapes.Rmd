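---
title: "Detecting microRNA target signatures with SCR enrichment landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microRNA target signatures with SCR enrichment landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscape)
library(dplyr)
```

## The problem

A microRNA (miRNA) represses hundreds of mRNAs, each only subtly, so the
fingerprint of a miRNA perturbation is rarely visible in any single gene.
What is visible is a *global* shift: after replenishing a lost miRNA, the
genes whose 3'UTRs can pair with the miRNA seed drift towards the
downregulated end of a ranked differential-expression list. seedscape detects
and quantifies that drift, and turns it into concrete target gene lists.

The recognition element is the **seed complementary region (SCR)**: the DNA
word in an mRNA 3'UTR complementary to the 5' seed (nucleotides 1--8,
canonically 2--7) of a mature miRNA. For miR-100-5p
(`AACCCGUAGAUCCGAACUUGUG`) the canonical 2--7 SCR is `ACGGGT`; for
miR-125b-5p it is `TCAGGG`.

## The model

Let the ranked list hold $N$ genes, ordered from most down- to most
upregulated (treated vs control, per-gene statistic: plain log2 fold change
after collapsing probes to genes). For a word $w$ carried by $K$ of the $N$
genes, consider the leading set of the first $n = kB$ genes at every bin
boundary ($B = 200$ genes per bin). With $x$ carriers among the leading
genes and

$$X \sim \mathrm{Hypergeometric}(N, K, n),$$

the enrichment p-value is $P(X \ge x)$ and the depletion p-value
$P(X \le x)$. The **signed score** at each bin is $-\log_{10}$ of the
smaller tail, positive for enrichment among the downregulated genes and
negative for depletion. Plotting the score along the list gives the
enrichment *landscape*.

Carrier status is binary presence of the word (at least one overlapping
occurrence; `N` bases never match). An occurrence-count threshold is exposed
via `min_count` for users who want to demand multiple sites, but a per-gene
indicator is the statistic the downstream set arithmetic uses, so it is the
default; no composition correction is applied (the landscape is judged
against its own background rate, not a sequence model).

### Six SCR elements and the SSSS

Seed pairing is not confined to one hexamer, so each miRNA is represented by
the set of words complementary to every contiguous 6--8 nt sub-span of its
1--8 seed: three 6-mers, two 7-mers and the 8-mer
(`derive_scr_elements()`). The **single summed significance score (SSSS)**
of a miRNA at a bin is the sum of the six signed scores. The element spans
are fully configurable, and a Fisher combination
(`ssss_integration(method = "fisher")`) is available as a p-scaled
alternative.

A calibration warning follows directly from this definition and is borne out
by the package's null simulations: the summed SSSS is *not* a
$-\log_{10}$ p-value. The six element words are nested (a gene carrying the
1--7 word necessarily carries the 1--6 and 2--7 words), their scores are
strongly positively correlated, and under a null ranking the summed curve
routinely reaches magnitudes that would look like $p < 10^{-4}$ if misread
as a single test. The per-element scores are exactly calibrated
hypergeometric tails (the test suite verifies that under the null they stay
below the $10^{-4}$ scale in essentially every run); SSSS magnitudes should
only ever be compared *between bins of the same curve*, which is all the cut
selection below requires. Even the Fisher variant inherits some inflation
from the inter-element correlation, so no SSSS variant should be quoted as a
p-value.

### Change-point cut selection (CPDV)

To convert a landscape peak into a gene list, the **change-point delta
value** of bin $i$ on a curve $L$ is

$$\mathrm{CPDV}_i = L_i - \min(L_{i+1}, \ldots, L_{i+5}),$$

progressing left to right, with the window truncated at the end of the curve
and the final bin (empty window) assigned $-\infty$. The selected bin is the
CPDV argmax (first bin on ties; a flat curve selects bin 1), and the leading
edge is `selected_bin * B` genes. By default the pipeline applies CPDV to
each miRNA's SSSS curve, and, when several miRNAs are configured (the
two-miRNA replenishment design), to the bin-wise sum of their SSSS curves;
per-miRNA cuts are reported alongside. Both the SSSS curve and any
single-element curve are accepted, since the field's practice varies and the
change-point arithmetic is agnostic to its substrate.

A known limitation, quantified by the package's seeded parameter-recovery
experiments: when ranking noise lets a tail of true responders leak past the
responder boundary, the post-peak decline of the curve starts shallow and
steepens, and the CPDV argmax then sits at the onset of the *steepest*
descent -- typically one bin to the right of the peak, occasionally two. In
the default recovery experiment (below) the selected cut lands within one
bin of the true boundary in roughly three quarters of runs and one bin right
of it in most of the remainder, while the SSSS *peak* is within one bin of
the boundary in effectively every run. Users who need the peak rather than
the change point should read it off the SSSS curve directly.

### Target lists and set algebra

At the selected cut, `select_down_targets()` intersects the leading-edge
genes with the carriers of each miRNA's canonical 2--7 SCR word (the
six-element union is available by passing other words). In clinical-style
data where the miRNAs are lost, `select_up_targets()` instead takes
de-repressed genes -- log2 fold change strictly greater than 0.5 -- carrying
the word. `summarize_targets()` applies inclusion--exclusion
($|A \cup B| = |A| + |B| - |A \cap B|$) and reports the union as a
percentage of the reference list; `summarize_target_counts()` does the same
arithmetic from bare counts. `ora()` provides a network-free hypergeometric
over-representation analysis against user-supplied (GMT) gene sets with
Benjamini--Hochberg adjustment.

## Expression preparation

Array probes are kept only if detected above background:
the detection p-value of a probe is the fraction of pooled negative-control
intensities (all negative-control probes, all samples) at or above the
probe's mean intensity, and probes with $p > 0.01$ are removed. Pooling
across samples keeps the p-value granularity fine enough for the 0.01
threshold with a ~100-probe control set; negative-control probes themselves
are retained (flagged), which makes the filter idempotent. Intensities are
transformed as $\log_2(x + 1)$; no array normalisation is performed --
this package starts where a normalised matrix ends. Genes are represented by
their probe of largest absolute log2 fold change (ties by probe id), genes
without full-length 3'UTR annotation are dropped, and ties in the ranking
statistic are broken lexicographically so the ranked list is a pure function
of its inputs.

`ddct_relative_expression()` implements relative qPCR quantification:
replicate Cts are averaged per sample and assay,
$\Delta Ct = Ct_{target} - \overline{Ct}_{references}$ (arithmetic mean over
a multi-assay normaliser panel, equivalent to a geometric mean of linear
quantities -- stated explicitly because multi-normaliser panels are common
and the combination rule rarely is), and expression relative to a designated
reference sample is $2^{-\Delta\Delta Ct}$.

## Methylation scoring

Bisulphite-pyrosequencing panels are scored cumulatively: per CpG site,
replicate percent-methylation values (duplicate assays on independently
prepared bisulphite conversions) are averaged arithmetically -- chosen for
linearity, since the cumulative score is itself a sum -- and the per-site
means are summed. A panel of $n$ sites has maximum score $100n$ (2300 for a
23-site panel, 1200 for 12 sites, 3500 for the 35-site union), and the
overall percentage is the mean per-site methylation. Array beta values are
converted by $M = \log_2\!\bigl(\beta/(1-\beta)\bigr)$ with $\beta$ clipped
to $[10^{-6}, 1-10^{-6}]$ so fully (un)methylated probes stay finite.
Regions are considered only when at least five probes fall inside them;
coordinates are 0-based half-open internally (BED convention) and 1-based
inclusive in human-facing summaries, with exact inverse converters at the
boundary. Group differences use an unpaired two-sided Student's t test
(Welch by flag); when both groups are constant, identical means give
$t = 0, p = 1$ and different means are flagged as degenerate with an
undefined p-value rather than silently erroring.

## The synthetic-data generators

Every stage is testable without downloads because `synth_config()` fans a
single root seed into independent substreams (design, sequences,
expression, methylation, Ct) and the generators emulate the statistical
structure the analysis assumes:

* **3'UTR universe** -- i.i.d. background sequence at 40% GC with log-normal
  lengths (median 1 kb, log-SD 0.5), matching the broad shape of human
  3'UTR annotation. The spike word replaces (never lengthens) a uniformly
  placed window in designated carriers, keeping the length distribution
  exact. Because real hexamers also occur by chance, designed carrier rates
  understate realised presence rates (a 6-mer appears by chance in roughly
  one in eight 1-kb background sequences at these settings); the truth table
  records designed carriers, the scanner reports realised presence.
* **Ranked experiment** -- 1400 of 4000 genes are responders with true log2
  fold change $-1.5$ and Gaussian noise of SD $0.5$; responders carry the
  spike word with probability 0.6 versus 0.1 in the background, echoing the
  contrast between an SCR's leading-edge and background presence rates in
  real replenishment data. Probe intensities are constructed so
  `collapse_and_rank()` recovers the simulated fold changes exactly, and
  negative-control probes are drawn from a low-intensity null so the
  detection filter has real work to do.
* **Methylation** -- two groups of five samples, 23 sites, per-site means
  70% (malignant-like) versus 20% (control-like), replicate SD 5, values
  clamped (not renormalised) to $[0, 100]$.
* **Ct panels** -- target Cts are baseline $-\log_2(\text{relative
  quantity})$ plus noise over a three-assay reference panel, so
  $\Delta\Delta Ct$ recovery is exact at zero noise.

What the generators deliberately do **not** emulate: bead-level array noise,
probe cross-hybridisation, real 3'UTR base composition and repeat structure,
and conservation. Green simulation tests therefore certify the statistical
machinery, not performance on any particular real data set.

## Numerical choices and degenerate inputs

* Tail p-values are floored at $10^{-300}$ before the log transform.
* A word absent from every ranked gene yields a flat zero landscape (with a
  message), not an error.
* Ties in the CPDV argmax resolve to the smaller bin; the final bin is never
  selected.
* Matching is DNA-space only: RNA input is converted U to T on ingestion,
  sequences are uppercased, `N` is a hard mismatch.
* The de-repression threshold is strict (`log2fc > 0.5`): a gene exactly at
  0.5 is excluded.
* Empty p-value vectors, empty annotation collections and cut = 0 all return
  empty results rather than errors; misconfiguration (missing files,
  out-of-range thresholds, absent negative controls) aborts before any
  computation with a `seedscape_config_error`.

## Problem sizes used by the test suite

The packaged experiments run at the defaults above (4000 genes, 50 seeded
replicates for the recovery and null-calibration experiments, 200 draws for
the ORA and power calibrations, exhaustive enumeration on universes of up to
12 genes where a combinatorial oracle is feasible). These sizes were chosen
so the Monte-Carlo tolerances quoted in the tests (binomial 99% intervals,
3-SE bounds) are meaningful for a desk-scale run; all of them are plain
function arguments, so larger replications are one edit away.

## Known limitations

* The six-element default is a convention over the contiguous 6--8-mer
  sub-spans of the 1--8 seed; other element sets are accepted but not
  auto-derived from pairing thermodynamics.
* The ranking statistic is an unmoderated log2 fold change; a moderated
  statistic can be substituted by ranking upstream and supplying the list.
* SSSS magnitudes are scores, not p-values (see above).
* The CPDV cut inherits a rightward bias of up to one bin under ranking
  noise; treat the reported leading edge as a floor-adjacent estimate of the
  responder boundary, and consult the SSSS peak when the boundary itself is
  of interest.
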