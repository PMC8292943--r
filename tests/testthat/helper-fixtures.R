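# fixtures and independent oracles shared across the suite

example_tree <- function() {
  read_mesh_table(system.file("extdata", "mesh_synthetic.tsv",
                              package = "hitmapper"),
                  year = "synthetic-2020-subset")
}

example_corpus <- function() {
  read_corpus_jsonl(system.file("extdata", "corpus_synthetic.jsonl",
                                package = "hitmapper"))
}

icd_table_path <- function() {
  system.file("extdata", "icd10_mesh_map.tsv", package = "hitmapper")
}

mk_headings <- function(names, major = TRUE) {
  dplyr::bind_rows(lapply(names, mesh_heading, major = major))
}

one_article <- function(topics, pmid = "T1", title = "t",
                        publication_types = "Journal Article") {
  article_record(pmid, title, 2015, "eng", NA_character_,
                 publication_types, mk_headings(topics))
}

# segment-list prefix oracle, independent of is_under's string logic
oracle_is_under <- function(code, prefix) {
  cs <- strsplit(code, ".", fixed = TRUE)[[1]]
  ps <- strsplit(prefix, ".", fixed = TRUE)[[1]]
  if (length(ps) == 1 && grepl("^[A-Z]$", ps)) {
    return(substr(cs[1], 1, 1) == ps)
  }
  length(ps) <= length(cs) && all(ps == cs[seq_along(ps)])
}

# geometric containment oracle: all cells whose closed triangle contains
# the barycentric point, via barycentric coordinates within each cell.
# The per-cell 3x3 systems are inverted once per subdivision.
oracle_cell_solvers <- function(n) {
  cells <- tribin_cells(n)
  inv <- lapply(seq_len(nrow(cells)), function(k) {
    solve(t(tribin_vertices(cells$row[k], cells$position[k], n)))
  })
  list(cells = cells, inv = inv)
}

oracle_containing_cells <- function(h, i, t, n,
                                    solvers = oracle_cell_solvers(n),
                                    tol = 1e-9) {
  p <- c(h, i, t)
  hit <- vapply(solvers$inv, function(m) all(m %*% p >= -tol), logical(1))
  solvers$cells[hit, , drop = FALSE]
}

# uniform simplex points (Dirichlet(1,1,1))
runif_simplex <- function(m) {
  e <- matrix(-log(runif(3 * m)), ncol = 3)
  e / rowSums(e)
}
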