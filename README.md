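# formulapair

Quantitative "formula pair" analysis for Traditional Chinese Medicine (TCM)
formulae: positional overlap scoring between formulae, five-component
attribute similarity between herbs, ontology-based similarity between the
diseases two formulae treat, and — built on those three scores — two
decision engines: **rare-herb replacement** (find a common herb that can
stand in for an endangered one) and **formula simplification** (merge two
overlapping formulae into a smaller one). A hypergeometric
over-representation stage against GMT pathway collections supports
mechanism inspection of the resulting formulae.

The package is aimed at TCM informatics and network-pharmacology
researchers working with curated formula/herb databases. Everything is
tidyverse-native: readers return tibbles with list-columns, every scoring
function takes the data frame first, result objects carry `tidy()` /
`glance()` methods and ggplot2 plot helpers.

## The scores

- **Combinational degree (CD).** The herb at 1-based position *m* of an
  *L*-herb formula weighs *W* = 1 + (1 − *m*)/*L* (the Master herb weighs 1,
  the last herb 1/*L*). The raw CD of two formulae sums the mean of the two
  positional weights over their shared herbs, is normalized by a scale
  constant (default 7.5, the self-pair score of a 14-herb formula) and
  banded: 0 none, (0, 0.3] low, (0.3, 0.7] middle, (0.7, 1] high.
- **Attribute similarity (AS).** Five components, each in [0, 1]: min/max
  ratios of the nature, taste and channel-tropism intensity vectors, and
  Dice coefficients of the function and indication phrase sets. AS is their
  sum in [0, 5]; AS > 3 (strict) flags a highly similar herb pair.
- **Disease similarity (Sim).** Mean pairwise semantic similarity (Wang's
  method by default) over all DOID pairs of the two formulae, banded at 0.3
  and 0.7.

A replacement proposal requires low CD, high Sim, AS > 3 and a positional
weight ratio min/max > 0.8; a simplification requires middle CD and high
Sim, keeps the shared herbs plus greedily matched AS > 3 herbs, and decides
which side survives by the "least herbs, then higher weights" rule. The
methods vignette (`vignettes/formula-pair-methods.Rmd`) derives all of this
in detail.

## Worked example

The bundled case-study database (`fixture_case_study()`) ships two
published case studies with synthetic attribute annotations (see the
vignette for what that does and does not reproduce).

```r
library(formulapair)
fx <- fixture_case_study()

pair_score(fx$formulae, "ssjy", "skt", dag = fx$ontology)
#> # A tibble: 1 × 9
#>   f1    f2    n_shared cd_raw    cd cd_band   sim sim_band shared
#>   <chr> <chr>    <int>  <dbl> <dbl> <fct>   <dbl> <fct>    <list>
#> 1 ssjy  skt          3   1.44 0.192 low         1 high     <tibble [3 × 5]>
```

SSJY and SKT (8 herbs each, both treating chronic bronchitis) share 3
herbs, giving a low CD of 0.192, and treat the same mapped disease, giving
Sim = 1 (high). That is exactly the regime for replacing SSJY's rare herb:

```r
tidy(find_replacements(fx$formulae, "forsythia suspensa", fx$herbs, fx$ontology))
#> # A tibble: 1 × 10
#>   rare_formula donor_formula rare_herb          rare_weight donor_herb
#> 1 ssjy         skt           forsythia suspensa        0.75 thunberg fritillary bulb
#>   donor_weight    cd   sim as_total weight_ratio
#> 1         0.75 0.192     1     3.61            1
```

Both herbs sit at position 3 of 8 (weight 0.75, ratio 1) and their AS of
3.61 clears the threshold: the proposal swaps thunberg fritillary bulb into
SSJY, reproducing the 8-herb formula SJZBY. The simplification engine runs
on the middle-CD pair FDHJST (15 herbs) and FFT (8 herbs):

```r
simplify_pair(fx$formulae, "fdhjst", "fft", fx$herbs, fx$ontology)
#> <tcm_simplification> fdhjst + fft
#>   cd = 0.373, sim = 1.000, K = 5 shared, P = 1, Q = 1
#>   sum W_p = 1.000, sum W_q = 0.375 -> branch new_F1
#>   rrctl simplified: radix gentianae macrophyllae | radix saposhnikoviae |
#>     chinese angelica | tuckahoe | liquorice | root of doubleteeth pubescent angelica
```

One unshared pair clears AS 3 (doubleteeth angelica / notopterygium root,
P = Q = 1); the F1 herb carries more weight (1 > 0.375), so the new 6-herb
formula keeps the 5 shared herbs plus doubleteeth angelica — the published
simplified formula. Mechanism inspection uses the 78 targets the two source
formulae share:

```r
g <- shared_targets(fx$formulae, "ssjy", "skt", fx$targets)
length(g)
#> [1] 78
overrepresentation(g, fx$pathways)
#> # A tibble: 4 × 7
#>   pathway         overlap pathway_size query_size universe_size p_value p_adjust
#> 3 cytokines and …       6            8         78           343 0.00222  0.00592
#> ...
```

`autoplot()` on the enrichment result, `plot_cd_heatmap()` on a formula
table and `plot_as_components()` on AS scores give the matching figures.
`generate_fixture(fixture_spec(seed = 1))` builds seeded synthetic
databases of any size for testing and benchmarking, and `exec/formulapair`
exposes the whole workflow as a shell command (`score cd|as|sim`,
`replace`, `simplify`, `enrich`, `fixture`).

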