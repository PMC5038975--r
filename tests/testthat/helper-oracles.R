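# Independent brute-force oracles. These reimplement each quantity from the
# raw records with naive loops and recursion, sharing no code with the
# package internals they check.

oracle_parent_list <- function(records) {
  p <- lapply(as.character(records$parent_ids), function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else strsplit(x, "|", fixed = TRUE)[[1]]
  })
  names(p) <- as.character(records$term_id)
  p
}

# self-inclusive ancestors by recursive climb
oracle_ancestors <- function(parents, term) {
  seen <- character(0)
  climb <- function(t) {
    if (t %in% seen) return(invisible(NULL))
    seen <<- c(seen, t)
    for (p in parents[[t]]) climb(p)
  }
  climb(term)
  sort(seen)
}

oracle_descendants <- function(parents, term) {
  ids <- names(parents)
  ids[vapply(ids, function(u) u != term && term %in% oracle_ancestors(parents, u),
             logical(1))]
}

oracle_ic <- function(parents, term) {
  n <- length(parents)
  1 - log(length(oracle_descendants(parents, term)) + 1) / log(n)
}

# exhaustive MICA with lexicographic tie-break
oracle_mica <- function(parents, a, b) {
  common <- intersect(oracle_ancestors(parents, a), oracle_ancestors(parents, b))
  if (!length(common)) return(list(term_id = NA_character_, ic_value = 0))
  ics <- vapply(common, function(t) oracle_ic(parents, t), numeric(1))
  best <- sort(common[ics == max(ics)])[1]
  list(term_id = best, ic_value = max(ics))
}

# entity sets per term from raw annotation records
oracle_inverted <- function(records) {
  recs <- unique(records[, c("entity_id", "term_id")])
  lapply(split(recs$entity_id, recs$term_id), unique)
}

oracle_freq_weight <- function(records, term) {
  inv <- oracle_inverted(records)
  -log(length(inv[[term]]) / length(unique(records$entity_id)))
}

oracle_cooc_weight <- function(records, a, b) {
  inv <- oracle_inverted(records)
  A <- inv[[a]]; B <- inv[[b]]
  if (is.null(B)) B <- character(0)
  u <- length(union(A, B))
  j <- length(intersect(A, B)) / u
  if (j > 0) -log(j) else -log(1 / (u + 1))
}

# term-pair score from raw records, including the self-match convention
oracle_term_pair <- function(ont_records, drug_records, gene_records, se, tr) {
  parents <- oracle_parent_list(ont_records)
  micic <- oracle_mica(parents, se, tr)$ic_value
  dinv <- oracle_inverted(drug_records); ginv <- oracle_inverted(gene_records)
  if (is.null(dinv[[se]]) || is.null(ginv[[tr]])) return(0)
  cd <- if (se == tr) log(length(dinv[[se]]) + 1) else oracle_cooc_weight(drug_records, se, tr)
  cg <- if (se == tr) log(length(ginv[[tr]]) + 1) else oracle_cooc_weight(gene_records, tr, se)
  pd <- oracle_freq_weight(drug_records, se) * cd
  pg <- oracle_freq_weight(gene_records, tr) * cg
  micic * min(pd, pg)
}

# full quadruple-loop reference for the all-pairs score table
oracle_score_all_pairs <- function(ont_records, drug_records, gene_records,
                                   top_k = 20, burden_weights = c(1, 0.66, 0.33)) {
  drug_prof <- lapply(split(unique(drug_records)$term_id,
                            unique(drug_records)$entity_id), function(x) sort(unique(x)))
  gene_prof <- lapply(split(unique(gene_records)$term_id,
                            unique(gene_records)$entity_id), function(x) sort(unique(x)))
  drugs <- sort(names(drug_prof)); genes <- sort(names(gene_prof))
  counts <- vapply(drug_prof, length, integer(1))[drugs]
  q <- stats::quantile(counts, c(1, 2) / 3, type = 7)
  burden <- ifelse(counts <= q[1], burden_weights[1],
                   ifelse(counts <= q[2], burden_weights[2], burden_weights[3]))
  s_cache <- new.env()
  s_of <- function(se, tr) {
    k <- paste(se, tr)
    if (is.null(s_cache[[k]])) {
      s_cache[[k]] <- oracle_term_pair(ont_records, drug_records, gene_records, se, tr)
    }
    s_cache[[k]]
  }
  rows <- list()
  for (d in drugs) for (g in genes) {
    dt <- drug_prof[[d]]; gt <- gene_prof[[g]]
    dvals <- vapply(dt, function(se) max(vapply(gt, function(tr) s_of(se, tr), numeric(1))),
                    numeric(1))
    gvals <- vapply(gt, function(tr) max(vapply(dt, function(se) s_of(se, tr), numeric(1))),
                    numeric(1))
    ord <- order(-dvals, dt)[seq_len(min(top_k, length(dvals)))]
    raw <- mean(c(gvals, dvals[ord]))
    rows[[paste(d, g)]] <- data.frame(
      drug_id = d, gene_id = g, raw = raw,
      scaled = raw * log(length(gt)) * unname(burden[d]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  gmax <- max(out$scaled)
  out$normalized <- if (gmax > 0) out$scaled / gmax else 0
  out <- out[order(out$drug_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

# exhaustive confusion counts for the classifier "score >= threshold"
oracle_confusion <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  c(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
    TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1))
}

# pairwise Mann-Whitney probability P(s+ > s-) + 0.5 P(tie)
oracle_pairwise_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# brute-force U statistic of sample x over sample y
oracle_u_stat <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# hop distances by naive breadth-first search over an edge data.frame
oracle_bfs_distance <- function(edges, from, to_set) {
  if (from %in% to_set) return(0)
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]; b <- edges$protein_b[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  if (is.null(adj[[from]])) return(Inf)
  frontier <- from; seen <- from; d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    if (any(nxt %in% to_set)) return(d)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  Inf
}

planted_auc <- function(cfg, top_k = 20) {
  st <- generate_study(cfg)
  sc <- suppressWarnings(score_all_pairs(st$ontology, st$drug_corpus,
                                         st$gene_corpus,
                                         scoring_config(top_k = top_k)))
  confusion_curve(sc$normalized, planted_labels(sc, st$truth))$auc
}
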