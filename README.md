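# hitmapper

Content mapping of the biomedical literature along three MeSH branches:
**H**ealth demand (Diseases `[C]`, Health `[N01.400]`, Public Health
`[N06.850]` and its discipline branch `[H02.403.720]`), **I**nformatics
supply (Information Science `[L]`) and **T**echnological applications
(Techniques and Equipment `[E]`). It is aimed at scientometricians and
health-informatics researchers who want to ask, for a publication corpus:
which health needs is informatics research addressing, through which
techniques, and in what proportion?

For one article with major-topic MeSH codes counting `(n_H, n_I, n_T)`
across the three categories, the fractional score is

    (h, i, t) = (n_H, n_I, n_T) / (n_H + n_I + n_T),     h + i + t = 1.

Around that core the package provides:

* loaders for MeSH descriptor XML / a tabular dialect, and MEDLINE/PubMed
  citation XML / a JSONL dialect, with segment-wise tree-number queries
  (`is_under()`, `mesh_descendants()`);
* the corpus filters (exclusion of secondary-research records; inclusion
  by H-and-I co-indexing) and per-article scoring (`score_corpus()`);
* ternary placement and N×N **tribin** binning of scores on the H-I-T
  simplex (`tribin_grid()`, `autoplot()`);
* first-level rollups with the population-health merge and co-occurrence
  interaction matrices / Sankey edge lists (`cooccurrence_matrix()`,
  `sankey_edges()`), plus topical sub-corpora (`subset_by_subtree()`);
* ICD-10→MeSH subtree mapping with exclusion precedence and the
  through-origin burden-vs-effort regression (`assign_diseases()`,
  `fit_through_origin()` with `tidy()`/`glance()` methods);
* a seeded synthetic-corpus generator with exact ground truth
  (`generate_corpus()`), so the whole pipeline is testable offline;
* a CLI (`inst/cli/hitmapper`) with `score`, `triangle`, `interactions`,
  `burden` and `simulate` subcommands.

## Worked example

Using the vocabulary subset and demonstration corpus shipped with the
package (tree positions not printed in published tables are synthetic
stand-ins):

```r
library(hitmapper)
library(dplyr)

tree   <- read_mesh_table(system.file("extdata", "mesh_synthetic.tsv",
                                      package = "hitmapper"),
                          year = "synthetic-2020-subset")
corpus <- read_corpus_jsonl(system.file("extdata", "corpus_synthetic.jsonl",
                                        package = "hitmapper"))
score_corpus(corpus, tree) |>
  filter(pmid %in% c("28117445", "25981148")) |>
  select(pmid, n_h, n_i, n_t, h, i, t)
#> # A tibble: 2 × 7
#>   pmid       n_h   n_i   n_t     h     i     t
#>   <chr>    <int> <int> <int> <dbl> <dbl> <dbl>
#> 1 28117445     2     1     0 0.667 0.333   0
#> 2 25981148     2     2     6 0.2   0.2     0.6
```

The first article's three major topics expand to six MeSH codes of which
two classify H and one I, hence the score (2/3, 1/3, 0): a pure
demand-supply link with no technique involved. The second article's six
topics expand to ten H-I-T codes split (2, 2, 6) — score (0.2, 0.2, 0.6),
a device-heavy telemonitoring study where techniques dominate. Articles
failing the filters come back with `included = FALSE` and, where
applicable, an `exclusion_reason`.

Binning a corpus on the triangle and profiling interactions:

```r
scores <- score_corpus(corpus, tree) |> filter(included)
tribin_grid(scores, n = 10)              # 100-cell count grid
cooccurrence_matrix(corpus, tree, axis = "HxI")
```

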