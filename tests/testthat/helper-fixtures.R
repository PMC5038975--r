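# Hand-built fixtures shared across tests.

# 9-term toy hierarchy:
#   R -> {A, B}; A -> {A1, A2}; B -> {B1}; A1 -> {A1a, A1b}; B1 -> {B1a}
# Leaves: A2, A1a, A1b, B1a.
toy_ontology_records <- function() {
  data.frame(
    term_id    = c("R", "A", "B", "A1", "A2", "B1", "A1a", "A1b", "B1a"),
    parent_ids = c("",  "R", "R", "A",  "A",  "B",  "A1",  "A1",  "B1"),
    level      = c(1, 2, 2, 3, 3, 3, 4, 4, 4),
    stringsAsFactors = FALSE
  )
}

toy_ontology <- function(...) load_ontology(toy_ontology_records(), ...)

# 4-drug corpus over the toy leaves; chosen so that the weight examples are
# easy to verify: A1a on 1/4 drugs, A1b on 2/4, B1a on all 4
toy_drug_records <- function() {
  data.frame(
    entity_id = c("D1", "D1", "D2", "D2", "D3", "D3", "D4", "D4"),
    term_id   = c("A1a", "B1a", "A1b", "B1a", "A1b", "B1a", "A2", "B1a"),
    stringsAsFactors = FALSE
  )
}

toy_gene_records <- function() {
  data.frame(
    entity_id = c("G1", "G1", "G2", "G2", "G3"),
    term_id   = c("A1a", "A2", "A1b", "B1a", "B1a"),
    stringsAsFactors = FALSE
  )
}

toy_corpora <- function(ontology = toy_ontology()) {
  list(drug = load_corpus(toy_drug_records(), ontology, "drug"),
       gene = load_corpus(toy_gene_records(), ontology, "gene"))
}

# random multi-parent DAG over n terms: term i (i > 1) draws 1-2 parents
# among terms 1..(i-1), giving a single root and plenty of diamond shapes
random_dag_records <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n))
  parent_ids <- c("", vapply(2:n, function(i) {
    k <- min(sample(1:2, 1), i - 1L)
    paste(sample(ids[seq_len(i - 1L)], k), collapse = "|")
  }, character(1)))
  data.frame(term_id = ids, parent_ids = parent_ids, stringsAsFactors = FALSE)
}

# random annotation corpus over a given ontology's terms
random_corpus_records <- function(ontology, n_entities, prefix, seed,
                                  profile_range = c(2L, 5L)) {
  set.seed(seed)
  terms <- ontology$terms$term_id
  ents <- sprintf("%s%02d", prefix, seq_len(n_entities))
  do.call(rbind, lapply(ents, function(e) {
    k <- sample(seq(profile_range[1], profile_range[2]), 1L)
    data.frame(entity_id = e, term_id = sample(terms, k),
               stringsAsFactors = FALSE)
  }))
}

planted_labels <- function(score_table, truth) {
  key <- paste(score_table$drug_id, score_table$gene_id)
  as.integer(key %in% paste(truth$planted_pairs$drug_id,
                            truth$planted_pairs$gene_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
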