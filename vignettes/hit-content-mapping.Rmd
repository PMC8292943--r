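---
title: "Mapping health demand, informatics supply and technological applications with MeSH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping health demand, informatics supply and technological applications with MeSH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hitmapper)
library(dplyr)
```

## The model

Medical informatics sits between a *demand* side (diseases and population
health), a *supply* side (informatics concepts and techniques) and the
*technological applications* that connect the two. hitmapper measures this
interplay on publication corpora through the Medical Subject Headings
(MeSH) hierarchy. Three branches of the MeSH tree act as category
definitions:

| Category | Branches | Default prefixes |
|---|---|---|
| Health demand (H) | Diseases; Health; Public Health | `C`, `N01.400`, `N06.850`, `H02.403.720` |
| Informatics supply (I) | Information Science | `L` |
| Technological applications (T) | Techniques and Equipment | `E` |

The `H02.403.720` branch is Public Health as a medical *discipline*
(Epidemiology, Preventive Medicine and kin); the descriptor "Public
Health" owns tree numbers in both `N06.850` and `H02.403.720`, so the
discipline branch is kept inside H by default and can be toggled off with
`hit_scheme(public_health_discipline = FALSE)`.

Only **major topics** — headings starred at the descriptor or at any
MeSH/subheading combination — enter the computation; they carry the core
content of an article, while unstarred headings are indexing context.

For one article, every tree number of every major-topic descriptor is
classified into H, I, T or none. A descriptor occupying several branches
contributes one count per code (three terms can become six codes). With
category counts $(n_H, n_I, n_T)$ the fractional score is

$$ (h, i, t) = \left(\frac{n_H}{n}, \frac{n_I}{n}, \frac{n_T}{n}\right),
\qquad n = n_H + n_I + n_T , $$

so $h + i + t = 1$ for every scorable article and the score lives on the
two-dimensional probability simplex. Articles with $n = 0$ are
unscorable; they are kept in the score table with `NA` fractions and
dropped before any triangle placement.

Whether a descriptor whose several codes fall in the *same* category
should count once or multiply is genuinely open: the worked examples the
scoring reproduces convert terms to codes before counting, which is why
per-code counting is the default, but `hit_counts(count_by =
"descriptor")` gives the once-per-category variant for sensitivity
analysis.

### Corpus construction

A publication belongs to the medical-informatics corpus when its major
topics put at least one code in H **and** one in I (`includes_h_and_i()`).
Before that, `exclusion_reason()` removes secondary-research records:
articles majoring on "Systematic Reviews as Topic" or "Meta-Analysis as
Topic" (these sit inside the Public Health and Information Science
branches without representing demand or supply), Review and Retracted
Publication types, and titles containing "bibliometric" (case-insensitive
substring; no casing convention is established for that filter, so the
broadest reading is used). Both filters are per-record predicates, so
their order cannot change membership — a property the tests assert.

```{r}
tree <- read_mesh_table(system.file("extdata", "mesh_synthetic.tsv",
                                    package = "hitmapper"),
                        year = "synthetic-2020-subset")
corpus <- read_corpus_jsonl(system.file("extdata",
                                        "corpus_synthetic.jsonl",
                                        package = "hitmapper"))
scored <- score_corpus(corpus, tree)
scored |> select(pmid, n_h:t, included) |> head(4)
```

The vocabulary year travels with the tree (`mesh_year()`) and is stamped
on scored tables, tribin grids, interaction matrices and run manifests:
corpora and vocabularies are versioned independently, and major-topic
names that do not resolve in the loaded vocabulary are logged and
ignored rather than fatal.

## The ternary tribin display

A score is a barycentric point in the H-I-T triangle: vertices are pure
categories, the centroid is the balanced $(1/3, 1/3, 1/3)$ article.
Because articles usually carry 5–10 major terms, scores repeat heavily
and raw point clouds saturate. The triangle is therefore cut into $N$
equal parts in the three coordinate directions, giving $N^2$ congruent
sub-triangles ("tribins") — upward cells whose coordinate floors sum to
$N-1$, downward cells summing to $N-2$ — and articles are *counted* per
cell:

```{r, fig.width = 5, fig.height = 4.5}
sim <- generate_corpus(sim_config(n_articles = 2000, seed = 7))
ftree <- make_fixture_tree(sim_config())
scores <- hit_score(hit_counts(sim$records, ftree))
autoplot(tribin_grid(scores, n = 10))
```

### Numerical choices

Fractional scores are rationals with small denominators ($2/3$, $1/2$,
$1/3$...) and often sit exactly on the internal lattice lines of the
grid. The binning rule is deterministic and documented:

* values of $x N$ within $10^{-9}$ of an integer are snapped to it before
  flooring, so floating-point representations of exact rationals behave
  like the rationals themselves;
* a point on a lattice *vertex* (all three coordinates exact, floors
  summing to $N$) is resolved by nudging the T coordinate down one index
  first, then I, then H — always producing an upward cell whose closed
  triangle contains the point. Under this rule triangle vertices belong
  to their corner cells and the $(1/3,1/3,1/3)$ centroid at $N = 3$ falls
  in the central cell of the base row.

The tests verify cell assignment against an independent geometric
containment oracle (barycentric coordinates within each candidate cell)
on 1,000 random points for $N \in \{2, 3, 5, 8\}$, count conservation for
$N \le 12$, and statistical uniformity of the cell histogram under
uniform simplex sampling (the $N^2$ cells are congruent, hence
equal-area). The default $N = 10$ balances spatial resolution against
count stability for corpora in the $10^3$–$10^5$ range; it is exposed
everywhere the grid is built.

Rendering is an adapter (`autoplot()`, `write_tribin_tsv()`); the binning
core is pure geometry. Density-contour display is a recognised
alternative but is not implemented.

## Interaction profiles

For interaction maps, deep codes are rolled up to ancestor labels
(`rollup_scheme()`): depth 1 for Diseases and Techniques (their
first-level classes are informative), depth 2 for Information Science,
whose single first-level node would otherwise swallow the useful groups
(Computing Methodologies, Informatics, Communications Media). The
Health and Public Health subtrees — population-level demand rather than
specific disease management — merge into one "Population Health" label.

`cooccurrence_matrix()` counts, per article, each unordered pair of
rolled labels across two axes (`HxI`, `HxT`, `IxT`) **once**: an article
with three cardiovascular codes and one telemedicine code adds 1, not 3.
Co-occurrence multiplicity has no established convention, so the
conservative per-article count is the default and `count_by = "code"`
gives the multiplicative variant. `sankey_edges()` exports thresholded
edge lists for flow displays, and `subset_by_subtree()` builds topical
sub-corpora (e.g. everything under "Artificial Intelligence", analysed
with rollup depth one level below the subtree root).

## Disease burden versus research effort

`read_icd_mesh_table()` consumes an ICD-10-to-MeSH correspondence table
(semicolon-separated multi-code cells). An article maps to a disease
when some major-topic code lies under a matched subtree *and* under no
excluded subtree — exclusion always wins, carving out, say,
pregnancy-induced hypertension from hypertensive heart disease. Matching
covers whole subtrees, so "Diabetic Nephropathies" reaches a "Kidney
Diseases" entry without the parent term being assigned.

Per-disease publication counts are regressed on DALYs through the
origin: slope $\sum xy / \sum x^2$, with $R^2$ by the **uncentered**
total sum of squares — the standard convention for zero-intercept fits
(a centered variant sits behind `centered = TRUE`, since the convention
is not always stated when such fits are reported). The units of the
burden axis follow whatever the supplied DALY table uses; the slope is
therefore only comparable within one table's units. The packaged DALY
table is synthetic (labelled so in its filename): real GBD estimates are
inputs the user supplies.

## The synthetic-corpus generator

`make_fixture_tree()` and `generate_corpus()` stand in for the
vocabulary and corpus downloads so the full pipeline runs offline. The
fixture tree has a fixed skeleton — named internal nodes, parent/child
chains for subtree queries, a descriptor with two tree numbers in one
category, distractor branches — plus configurable pools of single-code
leaf descriptors. Articles draw their topic count from
$1 + \mathrm{Poisson}(\bar m - 1)$ with $\bar m = 6$ by default (typical
major-topic depth is 5–10 terms), assign each topic's category i.i.d.
from a mixture defaulting to $(0.45, 0.27, 0.28)$ — the composition
observed for large health-informatics corpora — and sample distinct pool
descriptors per category. One seeded stream drives a run; the seed is
recorded in the config and manifest.

Because pool descriptors carry exactly one code, the generator's
ground-truth counts must equal `hit_counts()` on its own records
code-for-code; this generator/scorer agreement is the strongest
end-to-end test in the suite. Mean scores recover the mixture within
binomial standard error ($\mathrm{SE} =
\sqrt{p(1-p)\,\overline{1/m}\,/\,N}$); the suite checks 3 SE at
$N = 10{,}000$ with a fixed seed.

What the generator does **not** emulate: realistic term frequencies and
MeSH indexing depth, vocabulary drift across years, multi-category
descriptors in the sampling pools, country/journal structure beyond
uniform labels. Passing tests therefore demonstrate the pipeline's
correctness on records of the right *shape*, not distributional realism
of MEDLINE.

`included_only = TRUE` resamples articles until they satisfy the H-I
rule; that conditioning biases the realised mixture towards H and I, so
parameter-recovery checks always run with it off.

## Scope and limitations

* Corpus-scale published figures (country tables, mean-score tables,
  triangle and Sankey figures for specific corpora) require the full
  MEDLINE corpus and are out of reach of an offline package; the suite
  instead pins the worked scoring examples, printed-table arithmetic and
  the method's structural invariants. Test problem sizes — 10,000
  articles for mixture recovery, 1,000 points per subdivision for the
  binning oracle — are the package's chosen balance of statistical power
  against suite runtime.
* The shipped vocabulary subset is synthetic: tree numbers printed in
  the published category and correspondence tables are kept verbatim,
  the remaining positions are stand-ins. Term counts against the
  official vocabulary (e.g. the 419 Information Science descriptors of
  MeSH 2020) run only when the user supplies the official descriptor
  XML.
* Country attribution has no single convention; the default parses the
  first author's affiliation against a configurable gazetteer
  (`default_gazetteer()`), keeping records with unresolvable countries.
  Language is never a filter.
* Qualifier hierarchies, supplementary concept records and entry-term
  synonymy are out of scope; descriptor names are matched as preferred
  terms.
* The CLI (`run_hitmapper()`, `inst/cli/hitmapper`) reads YAML configs;
  flags override file values, and every run writes a manifest with input
  hashes, the effective config and the vocabulary version.
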