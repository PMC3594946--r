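---
title: "Formula-pair scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formula-pair scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formulapair)
```

## The problem

A Traditional Chinese Medicine (TCM) formula is an ordered collection of
herbs; order encodes the Master/Adviser/Soldier/Guild importance hierarchy.
Some herbs in classical formulae (rhinoceros horn, *Cordyceps sinensis*,
*Forsythia suspensa*) are endangered or scarce, and many formulae carry more
herbs than their effect requires. formulapair implements a quantitative
"formula pair" workflow that addresses both problems: it proposes a common
herb to replace a rare one, and merges two overlapping formulae into a
smaller one, in each case under explicit score thresholds.

## The three scores

**Combinational degree (CD).** The herb at 1-based position $m$ of an
$L$-herb formula gets weight $W = 1 + (1 - m)/L$, so the Master herb weighs
exactly 1 and the last herb $1/L$. For two formulae the raw CD sums, over
their shared herbs (matched by normalized label), the mean of the two
positional weights:

$$\mathrm{CD}(F_1, F_2) = \sum_{i=1}^{n} \frac{W_{1i} + W_{2i}}{2}.$$

Raw CD is normalized by a scale constant (default 7.5, the self-pair score
of a 14-herb formula, the ceiling over the reference database) and banded:
0 means no shared herb, $(0, 0.3]$ low, $(0.3, 0.7]$ middle, $(0.7, 1]$
high, all intervals closed on the right. The self-pair of a duplicate-free
$L$-herb formula scores exactly $(L+1)/2$, which is how the 7.5 ceiling
arises at $L = 14$. Because user databases may hold longer formulae, values
above the scale clamp to 1 with a warning rather than erroring.

**Attribute similarity (AS).** Each herb carries five attributes. Nature
(cold/cool/warm/hot intensities, with "ping" spreading 0.25 over all four,
"slight" scoring 0.8 and "severe" 1.2), taste (five intensities, with
"tasteless" adding 0.5 to sweet and "pucker" 0.5 to sour) and channel
tropism (0/1 over twelve organs) are compared by the min/max ratio
$\sum_k \min(x_{ki}, x_{kj}) / \sum_k \max(x_{ki}, x_{kj})$; functions and
indications (phrase sets) by the Dice coefficient $2|A \cap B|/(|A|+|B|)$.
AS is the sum of the five components, so it lives in $[0, 5]$; a strict
$\mathrm{AS} > 3$ marks a highly similar pair. Each component is bounded by
1 even with intensities above 1, since the min sum never exceeds the max
sum.

**Disease similarity (Sim).** Treated diseases are grounded in a disease
ontology (DOIDs over an is_a DAG). Pairwise term similarity uses Wang's
structure-only measure by default; the Sim of two formulae with $p$ and $q$
mapped diseases is the mean of all $p \times q$ pairwise values, banded as
$[0, 0.3]$ none, $(0.3, 0.7]$ significant, $(0.7, 1]$ high.

## The two decision engines

**Rare-herb replacement.** For a rare herb $i$ in formula $F_1$ and a
candidate $j$ in another formula $F_2$, a proposal requires: the pair's CD
in the low band (so the two formulae share few herbs and the rare herb
cannot be recommended to replace itself), Sim in the high band, AS$(i,j)$
strictly above 3, and weight ratio $\min(W_{1i}, W_{2j}) / \max(W_{1i},
W_{2j}) > 0.8$ so the swap preserves the importance hierarchy. All three
conditions are re-asserted on the emitted proposals, which are sorted by AS,
then weight ratio, then donor label.

**Formula simplification.** For a pair with middle CD and high Sim, the
common effect is attributed to the $K$ shared herbs plus unshared herbs that
pair at AS $> 3$. All $(N-K)(M-K)$ unshared cross pairs are scored and
reduced to a one-to-one matching by greedy selection in descending AS (ties
by label), so the matched counts $P$ and $Q$ per side are well defined and
the output formula never holds duplicates. The branch rule is "least herbs":
$P > Q$ keeps the $F_2$ side, $P < Q$ the $F_1$ side; at $P = Q$ the side
with the greater total positional weight of its matched herbs wins, and a
tie emits both reduced formulae. Note that the greedy matching forces
$P = Q$, so the $P \ne Q$ branches only fire for caller-supplied matchings
(`simplify_pair(..., matched = )`), which is why that hook exists.

## Over-representation stage

Mechanism inspection uses formula target sets (union over herbs of a
herb-to-gene table; intersection across formulae for shared effects, lifted
to compound level when the table carries a compound column) tested against a
GMT pathway collection with the one-sided hypergeometric tail
$P(X \ge k)$. Raw p-values are thresholded at 0.01 and the 20 best rows
reported, matching the workflow this package emulates; a Benjamini–Hochberg
column is emitted alongside for users who prefer a corrected criterion, but
is deliberately not used for filtering. The universe is the union of all
pathway genes, since no external universe is assumed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `scale` | 7.5 | raw-CD normalization constant (self-pair score at L = 14) |
| CD bands | 0.3 / 0.7 | low/middle/high cut points, right-closed |
| Sim bands | 0.3 / 0.7 | none/significant/high cut points |
| `as_threshold` | 3 | strict AS cutoff for "highly similar" herbs |
| `ratio_threshold` | 0.8 | strict weight-ratio cutoff for replacement |
| `decay` | 0.5 | Wang edge decay, strictly in (0, 1) |
| `alpha`, `top` | 0.01, 20 | ORA reporting threshold and row cap |

All are dimensionless. Thresholds are part of the method definition and are
exposed rather than hidden, but the defaults are the published operating
point and the bundled fixtures are only meaningful under them.

## Numerical and degenerate-input choices

- **Both-empty denominators.** A min/max ratio over two all-zero vectors, or
  a Dice over two empty sets, returns 0, not an error or NaN. Missing
  annotations therefore can never push AS over the replacement threshold.
- **Modifier stacking.** "tasteless"/"pucker" bonuses add to any existing
  intensity (sour 1.0 + pucker = 1.5) with no cap: the source rules state a
  bonus, not a ceiling, and the min/max ratio stays bounded regardless.
  Whether sweet should cap at 1.0 when "tasteless" accompanies an explicit
  "sweet" is genuinely open; stacking was chosen for rule uniformity.
- **Term-similarity method.** Wang's measure is the default because it needs
  no annotation corpus. The `resnik_norm` and `lin` variants estimate
  information content from descendant counts inside the DAG (a corpus-free
  surrogate); all methods return exactly 1 on the diagonal and are
  symmetric. Multiple parents take the max S-value over all upward paths.
- **Unmappable formulae.** A formula without DOIDs cannot be Sim-scored;
  direct calls error, and database sweeps skip such pairs with a reported
  count, mirroring the heavy attrition real disease-name-to-DOID mapping
  shows.
- **Tie-breaks.** Greedy AS matching breaks ties by herb label; ORA rows
  tie-break by pathway name; replacement proposals sort by AS, ratio, donor.
  All outputs are deterministic functions of their inputs.
- **Phrase matching.** Function/indication phrases match exactly after label
  normalization (lowercase, whitespace collapse, punctuation trim). No fuzzy
  matching: shared-phrase counts are defined by equality, and a synonym
  table is the supported way to unify variant vocabularies.

## The bundled case study and the synthetic generator

`fixture_case_study()` ships a small database containing the worked-example
abstract pair (raw CD 1.475, normalized 0.197), the chronic-bronchitis trio
SSJY/SKT/SJZBY, and the rheumatoid-arthritis trio FDHJST/FFT/FFDHT. Two
points deserve honesty. First, the original attribute annotations are not
redistributable, so the bundled attributes are synthetic: they are
engineered so that the case-study pairs (forsythia suspensa / thunberg
fritillary bulb; doubleteeth pubescent angelica / notopterygium root;
rhinoceros / buffalo horn; walnut kernel / cordyceps sinensis) exceed AS 3
while every other relevant cross pair stays below — the *decisions*
reproduce, the historical AS values do not, and the package asserts only
threshold relations, never the historical totals. Second, the FFT herb
order is encoded so that notopterygium root sits at position 6 of 8 (weight
0.375), the order the published weights imply, which differs from a naive
row-major reading of the printed table.

`generate_fixture(fixture_spec(...))` builds arbitrary-size synthetic
databases: herbs with annotation mixes that exercise every lexicon path
(ping, slight, severe, tasteless, pucker), duplicate-free formulae of 3–14
herbs, a rooted is_a tree, target tables and GMT collections. Generation is
a pure function of the spec; each artifact draws from its own seeded stream
so adding one never perturbs another. The generator emulates the *shape* of
a curated database, not its statistics: real attribute annotations are
correlated (herbs that share functions share indications), real formula
membership is far from uniform, and real ontologies are unbalanced. Passing
property tests on generated data therefore demonstrates algebraic
correctness (symmetry, bounds, oracle agreement), not clinical validity of
any proposal.

Test and example problem sizes (a 40-formula/60-herb generated database,
1,000 sampled pairs per property, DAGs of at most 10 terms for the
path-enumeration oracle, universes of at most 20 genes for the exhaustive
hypergeometric oracle) were chosen so the whole suite re-derives every
oracle from scratch in well under a minute on one core.

## Known limitations

- Herb identity is name-based. Two spellings of one herb are two herbs
  unless a synonym table says otherwise; no botanical resolution is done.
- Disease-name-to-DOID mapping is accepted as input, never inferred.
- The ORA stage is a generic hypergeometric test over a user-supplied GMT;
  it does not reproduce any specific enrichment tool's internal statistics,
  grouping or curated universes, so p-values are comparable within a run,
  not against published tables.
- Compound-level target sharing requires a three-column target table; with
  two columns, herb-level intersection is a documented approximation.
- The replacement and simplification engines are screens, not validations:
  every proposal needs pharmacological review before any real-world use.
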