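#' Build a phenotype ontology from term/parent records
#'
#' Constructs a multi-parent directed acyclic graph of phenotype terms (an
#' adapted MedDRA-like hierarchy, or any DAG) and precomputes, for every term,
#' its transitive/direct descendant counts, its intrinsic information content
#' and its self-inclusive ancestor set.
#'
#' The information content of a term is structure-based (it does not depend on
#' annotation frequency):
#' \deqn{IC(t) = 1 - \frac{\ln(\mathrm{desc}(t) + 1)}{\ln N}}
#' where \eqn{\mathrm{desc}(t)} is the number of descendants of \eqn{t}
#' (transitive by default) and \eqn{N} the total number of terms. A term with
#' fewer descendants is more specific: IC is exactly 1 at leaves and exactly 0
#' at a root that dominates all other \eqn{N - 1} terms. IC is invariant to
#' the logarithm base, so natural logarithms are used throughout.
#'
#' Extra grouping ancestors (SMQ-like cross-hierarchy classes) are accepted as
#' ordinary additional parent links; nothing restricts a term to one parent.
#'
#' @param term_records data.frame with columns `term_id`, `parent_ids`
#'   (pipe-separated string of parent term ids, `""`/`NA` for roots) and
#'   optionally `label` and `level` (1 = most general).
#' @param descendant_mode `"transitive"` (default) counts all distinct
#'   descendants; `"direct"` counts immediate children only. Controls the
#'   descendant count used by the IC formula.
#'
#' @return An object of class `phenosim_ontology`: a list with elements
#'   `terms` (data.frame of term_id/label/level), `parents` (named list of
#'   parent id vectors), `n_terms`, `descendant_counts`, `direct_counts`,
#'   `ic` (named numeric in \[0,1\]), `ancestors` (named list of
#'   self-inclusive ancestor id vectors), `roots` and `descendant_mode`.
#' @examples
#' ont <- load_ontology(data.frame(
#'   term_id = c("R", "A", "B"),
#'   parent_ids = c("", "R", "R")))
#' information_content(ont, "A") # 1: A is a leaf
#' @seealso [information_content()], [mica()], [read_ontology_tsv()]
#' @export
load_ontology <- function(term_records, descendant_mode = c("transitive", "direct")) {
  descendant_mode <- match.arg(descendant_mode)
  stopifnot(is.data.frame(term_records))
  if (!all(c("term_id", "parent_ids") %in% names(term_records))) {
    stop("term_records must have columns 'term_id' and 'parent_ids'")
  }
  if (nrow(term_records) < 1L) stop("ontology needs at least one term")
  ids <- as.character(term_records$term_id)
  if (anyDuplicated(ids)) {
    stop("duplicate term_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  parents <- lapply(as.character(term_records$parent_ids), function(p) {
    if (is.na(p) || !nzchar(p)) character(0)
    else unique(strsplit(p, "|", fixed = TRUE)[[1]])
  })
  names(parents) <- ids
  dangling <- setdiff(unlist(parents), ids)
  if (length(dangling)) {
    stop("parent reference to unknown term(s): ", paste(dangling, collapse = ", "))
  }

  # child -> parent edge graph; reachability along it yields ancestors
  edge_child <- rep(ids, lengths(parents))
  edge_parent <- unlist(parents, use.names = FALSE)
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (length(edge_child)) {
    g <- igraph::add_edges(g, rbind(edge_child, edge_parent))
  }
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership == which(comp$csize > 1)[1]]
    stop("cycle detected in parent links, e.g. involving edge ",
         bad[1], " -> ", parents[[bad[1]]][parents[[bad[1]]] %in% bad][1])
  }

  ancestors <- lapply(ids, function(t) {
    sort(names(igraph::subcomponent(g, t, mode = "out")))
  })
  names(ancestors) <- ids
  desc_trans <- vapply(ids, function(t) {
    length(igraph::subcomponent(g, t, mode = "in")) - 1L
  }, integer(1))
  direct_counts <- table(factor(edge_parent, levels = ids))
  direct_counts <- stats::setNames(as.integer(direct_counts), ids)

  n <- length(ids)
  counts <- if (descendant_mode == "transitive") desc_trans else direct_counts
  if (n == 1L) {
    warning("degenerate ontology with a single term: IC defined as 1")
    ic <- stats::setNames(1, ids)
  } else {
    ic <- stats::setNames(1 - log(counts + 1) / log(n), ids)
  }

  terms <- data.frame(
    term_id = ids,
    label = if ("label" %in% names(term_records)) as.character(term_records$label) else ids,
    level = if ("level" %in% names(term_records)) as.integer(term_records$level) else NA_integer_,
    stringsAsFactors = FALSE
  )
  structure(
    list(terms = terms, parents = parents, n_terms = n,
         descendant_counts = desc_trans, direct_counts = direct_counts,
         ic = ic, ancestors = ancestors,
         roots = ids[lengths(parents) == 0L],
         descendant_mode = descendant_mode),
    class = "phenosim_ontology"
  )
}

#' @export
print.phenosim_ontology <- function(x, ...) {
  cat("phenosim ontology:", x$n_terms, "terms,",
      length(x$roots), "root(s),",
      sum(x$descendant_counts == 0L), "leaves;",
      "descendant mode:", x$descendant_mode, "\n")
  invisible(x)
}

.check_term <- function(ontology, term) {
  if (!term %in% ontology$terms$term_id) stop("unknown term: ", term)
  invisible(term)
}

#' Number of descendants of an ontology term
#'
#' @param ontology a `phenosim_ontology`.
#' @param term term id.
#' @param mode `"transitive"` (all distinct descendants, default) or
#'   `"direct"` (immediate children).
#' @return Integer count; 0 for a leaf in either mode.
#' @export
descendant_count <- function(ontology, term, mode = c("transitive", "direct")) {
  mode <- match.arg(mode)
  .check_term(ontology, term)
  if (mode == "transitive") ontology$descendant_counts[[term]]
  else ontology$direct_counts[[term]]
}

#' Intrinsic information content of a term
#'
#' `IC(t) = 1 - ln(desc(t) + 1)/ln(N)` with the descendant count taken in the
#' mode the ontology was built with. Bounded in \[0,1\]; 1 at leaves; 0 at a
#' root dominating all other terms.
#'
#' @inheritParams descendant_count
#' @return Numeric score in \[0,1\].
#' @export
information_content <- function(ontology, term) {
  .check_term(ontology, term)
  ontology$ic[[term]]
}

#' Most informative common ancestor (MICA) of two terms
#'
#' Ancestor sets are self-inclusive, so `mica(t, t)` returns `t` itself and
#' identical terms compare at maximal IC. Among all common ancestors the one
#' with maximal IC is returned; ties are broken by the lexicographically
#' smallest term id, making the result deterministic.
#'
#' @param ontology a `phenosim_ontology`.
#' @param a,b term ids.
#' @return A list with `term_id` (NA if the terms share no ancestor, e.g. in
#'   a rootless forest), `ic_value` (0 in that case) and `found` (logical).
#' @export
mica <- function(ontology, a, b) {
  .check_term(ontology, a)
  .check_term(ontology, b)
  common <- intersect(ontology$ancestors[[a]], ontology$ancestors[[b]])
  if (!length(common)) {
    return(list(term_id = NA_character_, ic_value = 0, found = FALSE))
  }
  ics <- ontology$ic[common]
  best <- common[ics == max(ics)]
  best <- sort(best)[1L]  # lexicographic tie-break
  list(term_id = best, ic_value = unname(ontology$ic[[best]]), found = TRUE)
}

#' IC-of-MICA matrix for two term sets
#'
#' Vectorised helper used by the scoring engine: returns the matrix of
#' `mica()$ic_value` for every pair of `terms_a` (rows) by `terms_b`
#' (columns).
#'
#' @param ontology a `phenosim_ontology`.
#' @param terms_a,terms_b character vectors of term ids.
#' @return Numeric matrix with dimnames `terms_a` x `terms_b`.
#' @keywords internal
#' @export
mica_ic_matrix <- function(ontology, terms_a, terms_b) {
  ids <- ontology$terms$term_id
  # boolean ancestor incidence: A[t, u] = TRUE iff u is an ancestor of t
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (t in ids) A[t, ontology$ancestors[[t]]] <- TRUE
  out <- matrix(0, length(terms_a), length(terms_b),
                dimnames = list(terms_a, terms_b))
  ic <- ontology$ic
  for (i in seq_along(terms_a)) {
    ai <- A[terms_a[i], ]
    for (j in seq_along(terms_b)) {
      common <- ai & A[terms_b[j], ]
      if (any(common)) out[i, j] <- max(ic[common])
    }
  }
  out
}
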