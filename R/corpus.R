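#' Load an entity-to-term annotation corpus
#'
#' Builds the annotation index for one entity class (drugs annotated with
#' side-effect terms, or genes annotated with phenotypic trait terms) together
#' with its inverted term-to-entity index. Duplicate entity-term rows are
#' deduplicated. Terms must exist in the companion ontology: in `"strict"`
#' mode (default) an unknown term is an error listing the offending ids; in
#' `"lenient"` mode offending rows are dropped with a message.
#'
#' @param records data.frame with columns `entity_id`, `term_id`, one
#'   annotation per row.
#' @param ontology the `phenosim_ontology` the terms refer to.
#' @param entity_class `"drug"` or `"gene"`.
#' @param mode `"strict"` or `"lenient"` handling of unknown terms.
#' @return An object of class `phenosim_corpus`: list with `entity_class`,
#'   `annotations` (named list entity -> sorted term ids), `inverted` (named
#'   list term -> sorted entity ids), `n_entities`.
#' @export
load_corpus <- function(records, ontology, entity_class = c("drug", "gene"),
                        mode = c("strict", "lenient")) {
  entity_class <- match.arg(entity_class)
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records))
  if (!all(c("entity_id", "term_id") %in% names(records))) {
    stop("records must have columns 'entity_id' and 'term_id'")
  }
  if (nrow(records) < 1L) stop("empty annotation records")
  records <- data.frame(entity_id = as.character(records$entity_id),
                        term_id = as.character(records$term_id),
                        stringsAsFactors = FALSE)
  unknown <- setdiff(unique(records$term_id), ontology$terms$term_id)
  if (length(unknown)) {
    if (mode == "strict") {
      stop("unknown term id(s) in annotations: ", paste(unknown, collapse = ", "))
    }
    n_before <- nrow(records)
    records <- records[!records$term_id %in% unknown, , drop = FALSE]
    message("dropped ", n_before - nrow(records),
            " annotation row(s) with unknown terms")
    if (!nrow(records)) stop("no usable annotation rows left")
  }
  records <- unique(records)
  annotations <- lapply(split(records$term_id, records$entity_id), function(x) sort(unique(x)))
  inverted <- lapply(split(records$entity_id, records$term_id), function(x) sort(unique(x)))
  structure(
    list(entity_class = entity_class,
         annotations = annotations,
         inverted = inverted,
         n_entities = length(annotations)),
    class = "phenosim_corpus"
  )
}

#' @export
print.phenosim_corpus <- function(x, ...) {
  cat("phenosim corpus (", x$entity_class, "): ", x$n_entities,
      " entities, ", length(x$inverted), " distinct terms, ",
      sum(lengths(x$annotations)), " annotations\n", sep = "")
  invisible(x)
}

#' Frequency weight of a term within a corpus
#'
#' The negative natural logarithm of the fraction of entities (drugs or
#' genes) the term is annotated to: `f = -ln(k / n_entities)`. A term that
#' annotates every entity carries zero weight; rare terms carry large weight.
#'
#' @param corpus a `phenosim_corpus`.
#' @param term term id; must be annotated to at least one entity here.
#' @return Non-negative weight.
#' @export
frequency_weight <- function(corpus, term) {
  k <- length(corpus$inverted[[term]])
  if (k == 0L) stop("frequency weight undefined: term '", term,
                    "' annotates no entity in this corpus")
  -log(k / corpus$n_entities)
}

#' Co-occurrence weight of a term pair within a corpus
#'
#' The negative natural logarithm of the Jaccard index of the two terms'
#' entity sets, `J = |A n B| / |A u B|`, so term pairs that always co-occur
#' (including a term with itself, J = 1) carry zero weight. When the terms
#' never co-occur (J = 0, including `term_b` being absent from this corpus)
#' the weight is capped at the finite value `-ln(1 / (|A u B| + 1))`, i.e.
#' never-co-occurring pairs are maximally but finitely informative, growing
#' only logarithmically with corpus support.
#'
#' @param corpus a `phenosim_corpus`.
#' @param term_a focal term; must be annotated in this corpus.
#' @param term_b partner term; may be absent from this corpus.
#' @return Non-negative finite weight.
#' @export
cooccurrence_weight <- function(corpus, term_a, term_b) {
  A <- corpus$inverted[[term_a]]
  if (is.null(A) || !length(A)) {
    stop("co-occurrence weight undefined: term '", term_a,
         "' annotates no entity in this corpus")
  }
  B <- corpus$inverted[[term_b]]
  if (is.null(B)) B <- character(0)
  u <- length(union(A, B))
  j <- length(intersect(A, B)) / u
  if (j > 0) -log(j) else -log(1 / (u + 1))
}

#' Combined frequency x co-occurrence weight of a focal term against another
#'
#' Composes [frequency_weight()] of the focal term with
#' [cooccurrence_weight()] of the (focal, other) pair inside one corpus; the
#' product `f * c` is one side of the min() in the term-pair similarity.
#'
#' @inheritParams cooccurrence_weight
#' @param focal,other term ids; `focal` must be annotated in `corpus`.
#' @return List with `f`, `c` and `product`.
#' @export
pair_weight <- function(corpus, focal, other) {
  f <- frequency_weight(corpus, focal)
  cw <- cooccurrence_weight(corpus, focal, other)
  list(f = f, c = cw, product = f * cw)
}

#' Per-entity annotation counts and quantiles
#'
#' @param corpus a `phenosim_corpus`.
#' @param probs quantile probabilities (linear-interpolation rule, the default
#'   type-7 quantile); may be empty for counts only.
#' @return List with `counts` (sorted ascending, named by entity) and
#'   `quantiles`.
#' @export
corpus_summary <- function(corpus, probs = c(0.25, 0.5, 0.75)) {
  counts <- sort(vapply(corpus$annotations, length, integer(1)))
  qs <- if (length(probs)) stats::quantile(counts, probs = probs, type = 7) else numeric(0)
  list(counts = counts, quantiles = qs)
}
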