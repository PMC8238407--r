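# Fixture builders shared by the suite. All fixtures are generated in code;
# nothing is read from disk except files the helpers themselves write to
# tempdir().

write_expr_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene_id\tvalue", rows), path)
  path
}

expr_tbl <- function(values, platform = "short_read", sample = "s1",
                     batch = "b1", unit = "RPKM") {
  tibble::tibble(gene_id = names(values), value = unname(values),
                 platform = platform, sample = sample, batch = batch,
                 unit = unit)
}

# Random gene-set instances over a small alphabet, with per-element
# inclusion probability p.
random_sets <- function(n_sets, universe, p = 0.5) {
  sets <- lapply(seq_len(n_sets), function(i) {
    universe[stats::runif(length(universe)) < p]
  })
  names(sets) <- paste0("S", seq_len(n_sets))
  sets
}

# Independent per-element oracle for the Tanimoto index: walk the universe
# and count membership element by element.
oracle_tanimoto <- function(a, b, universe) {
  in_both <- 0L
  in_either <- 0L
  for (g in universe) {
    ina <- g %in% a
    inb <- g %in% b
    if (ina && inb) in_both <- in_both + 1L
    if (ina || inb) in_either <- in_either + 1L
  }
  if (in_either == 0L) 1.0 else in_both / in_either
}
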