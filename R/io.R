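#' @keywords internal
.read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(required) && !all(required %in% names(df))) {
    stop("file ", path, " lacks required column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "),
         " (found: ", paste(names(df), collapse = ", "), ")")
  }
  df
}

#' Read an ontology from its TSV dialect
#'
#' Columns `term_id`, `label`, `level`, `parent_ids` (pipe-separated;
#' empty for roots), UTF-8 encoded, with `#` comment lines.
#'
#' @param path file path.
#' @inheritParams load_ontology
#' @return A `phenosim_ontology`.
#' @export
read_ontology_tsv <- function(path, descendant_mode = "transitive") {
  df <- .read_tsv(path, required = c("term_id", "parent_ids"))
  load_ontology(df, descendant_mode = descendant_mode)
}

#' Write an ontology in the TSV dialect read by [read_ontology_tsv()]
#' @param ontology a `phenosim_ontology`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ontology_tsv <- function(ontology, path) {
  df <- ontology$terms
  df$parent_ids <- vapply(ontology$parents[df$term_id], paste,
                          character(1), collapse = "|")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OBO-format subset into an ontology
#'
#' Parses only `[Term]` stanzas with `id:`, `name:` and `is_a:` tags (the
#' subset sufficient for a parent-link DAG); everything else is ignored.
#'
#' @inheritParams read_ontology_tsv
#' @return A `phenosim_ontology`.
#' @export
read_obo <- function(path, descendant_mode = "transitive") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <<- cur
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(is_a = character(0)); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_a:", ln)) {
      cur$is_a <- c(cur$is_a, trimws(sub("^is_a:", "", ln)))
    }
  }
  flush()
  if (!length(terms)) stop("no [Term] stanzas found in ", path)
  load_ontology(data.frame(
    term_id = vapply(terms, `[[`, character(1), "id"),
    label = vapply(terms, function(t) t$name %||% t$id, character(1)),
    parent_ids = vapply(terms, function(t) paste(t$is_a, collapse = "|"), character(1)),
    stringsAsFactors = FALSE
  ), descendant_mode = descendant_mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read entity-term annotations (plain dialect or gene-side mapping dialect)
#'
#' The plain dialect has columns `entity_id`, `term_id`, one pair per row.
#' The `"mapping"` dialect mirrors the mouse-to-human phenotype mapping file:
#' columns `mouse_gene`, `human_gene`, `mpo_term`, `mapped_superclass_mpo`,
#' `meddra_code`, `meddra_level`; entity = human gene symbol, term = the
#' mapped code.
#'
#' @param path file path.
#' @param dialect `"plain"` (default) or `"mapping"`.
#' @return data.frame with columns `entity_id`, `term_id` (the mapping
#'   dialect keeps its extra columns too).
#' @export
read_annotations_tsv <- function(path, dialect = c("plain", "mapping")) {
  dialect <- match.arg(dialect)
  if (dialect == "plain") {
    .read_tsv(path, required = c("entity_id", "term_id"))
  } else {
    df <- .read_tsv(path, required = c("mouse_gene", "human_gene", "mpo_term",
                                       "mapped_superclass_mpo", "meddra_code",
                                       "meddra_level"))
    df$entity_id <- df$human_gene
    df$term_id <- df$meddra_code
    df
  }
}

#' Read labeled positive gene-drug pairs
#'
#' Columns `drug_id`, `gene_id`, optional `evidence`. A row whose `drug_id`
#' cell names several drugs separated by `|` is split into one positive per
#' drug.
#'
#' @param path file path.
#' @return data.frame `drug_id`, `gene_id` (plus `evidence` if present).
#' @export
read_positives_tsv <- function(path) {
  df <- .read_tsv(path, required = c("drug_id", "gene_id"))
  pieces <- strsplit(as.character(df$drug_id), "|", fixed = TRUE)
  idx <- rep(seq_len(nrow(df)), lengths(pieces))
  out <- df[idx, , drop = FALSE]
  out$drug_id <- unlist(pieces, use.names = FALSE)
  rownames(out) <- NULL
  unique(out)
}

#' Read an undirected PPI edge list, optionally filtering by confidence
#'
#' Columns `protein_a`, `protein_b`, optional `confidence`; edges below
#' `min_confidence` are dropped (the conventional high-confidence cutoff is
#' 0.7).
#'
#' @param path file path.
#' @param min_confidence minimum confidence kept (default `NULL`: keep all).
#' @return data.frame of edges.
#' @export
read_ppi_tsv <- function(path, min_confidence = NULL) {
  df <- .read_tsv(path, required = c("protein_a", "protein_b"))
  if (!is.null(min_confidence)) {
    if (!"confidence" %in% names(df)) {
      stop("confidence filtering requested but file has no 'confidence' column")
    }
    df <- df[df$confidence >= min_confidence, , drop = FALSE]
  }
  df
}

#' Read known causal gene-side-effect pairs
#' @param path file path to a TSV with columns `gene_id`, `term_id`.
#' @return data.frame.
#' @export
read_causal_tsv <- function(path) {
  .read_tsv(path, required = c("gene_id", "term_id"))
}

#' Write an evaluation curve as TSV
#' @param curve a [confusion_curve()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_curve_tsv <- function(curve, path) {
  utils::write.table(curve$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.supp_dialects <- list(
  s1_pairs = c("drug_name", "gene_symbol", "score"),
  s2_biologicals = c("drug_name", "gene_symbol", "score"),
  s3_toxcast = c("drug_name", "gene_symbol", "score", "hit"),
  s4_mapping = c("mouse_gene", "human_gene", "mpo_term",
                 "mapped_superclass_mpo", "meddra_code", "meddra_level"),
  s5_targets = c("cid", "drug_name", "ensembl_gene_id", "gene_name")
)

#' Read a supplementary-table dialect and summarise it
#'
#' Parses one of the published supplementary-file dialects and computes the
#' verification counts: number of rows, unique drugs, unique genes, and (for
#' the in-vitro assay dialect) the number of hit-flagged rows. Rows whose
#' column count differs from the dialect are reported with their line
#' numbers.
#'
#' @param path file path.
#' @param dialect one of `"s1_pairs"` (high-scoring drug-gene pairs),
#'   `"s2_biologicals"`, `"s3_toxcast"` (pairs with in-vitro hit flags),
#'   `"s4_mapping"` (mouse-to-human phenotype term mapping), `"s5_targets"`
#'   (direct drug-target pairs).
#' @return List with `table` (data.frame), `summary` (named list: `rows`,
#'   `drugs`, `genes`, and `hits` for `s3_toxcast`) and `malformed`
#'   (integer line numbers of rows with a wrong column count).
#' @export
read_supplementary_table <- function(path, dialect = names(.supp_dialects)) {
  dialect <- match.arg(dialect)
  expected <- .supp_dialects[[dialect]]
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines_keep <- !grepl("^#", lines) & nzchar(lines)
  body <- lines[lines_keep]
  lineno <- which(lines_keep)
  if (!length(body)) stop("empty file: ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, expected)) {
    stop("header mismatch for dialect '", dialect, "': expected [",
         paste(expected, collapse = ", "), "], found [",
         paste(header, collapse = ", "), "]")
  }
  cells <- strsplit(body[-1], "\t", fixed = TRUE)
  ok <- lengths(cells) == length(expected)
  malformed <- lineno[-1][!ok]
  if (length(malformed)) {
    warning("skipping ", length(malformed), " malformed row(s) at line(s): ",
            paste(malformed, collapse = ", "))
  }
  tab <- as.data.frame(do.call(rbind, cells[ok]), stringsAsFactors = FALSE)
  names(tab) <- expected
  drug_col <- intersect(c("drug_name", "cid"), expected)[1]
  gene_col <- intersect(c("gene_symbol", "human_gene", "ensembl_gene_id"), expected)[1]
  summary <- list(rows = nrow(tab),
                  drugs = length(unique(tab[[drug_col]])),
                  genes = length(unique(tab[[gene_col]])))
  if (dialect == "s3_toxcast") summary$hits <- sum(tab$hit %in% c("1", "TRUE"))
  list(table = tab, summary = summary, malformed = malformed)
}
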