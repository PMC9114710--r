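# small programmatic fixtures shared across test files

tiny_table <- function() {
  otu_tibble(
    matrix(c(5, 0, 3, 2,
             1, 4, 0, 5,
             2, 2, 2, 2), nrow = 3, byrow = TRUE,
           dimnames = list(NULL, paste0("OTU", 1:4))),
    sample_ids = c("s1", "s2", "s3"),
    taxonomy = tibble::tibble(
      otu_id = paste0("OTU", 1:4),
      taxonomy = paste0("Bacteria;Phylum", 1:4, ";c;o;f;g")
    )
  )
}

random_table <- function(n_samples, n_otus, lambda = 10, seed = 1) {
  set.seed(seed)
  otu_tibble(matrix(rpois(n_samples * n_otus, lambda), n_samples,
                    dimnames = list(NULL, sprintf("OTU%03d", seq_len(n_otus)))),
             sample_ids = sprintf("s%02d", seq_len(n_samples)))
}

labelled_dm <- function(values, ids) {
  dimnames(values) <- list(ids, ids)
  values
}

# graph of two planted modules: an 8-node star (hub a1) and a 4-node star
# (hub b9), bridged by a2-b10; roles hand-computed in test-network.R
planted_module_graph <- function() {
  g <- igraph::make_graph(~ a1-a2, a1-a3, a1-a4, a1-a5, a1-a6, a1-a7, a1-a8,
                          b9-b10, b9-b11, b9-b12, a2-b10)
  mem <- c(a1 = 1, a2 = 1, a3 = 1, a4 = 1, a5 = 1, a6 = 1, a7 = 1, a8 = 1,
           b9 = 2, b10 = 2, b11 = 2, b12 = 2)
  list(graph = g, membership = mem)
}
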