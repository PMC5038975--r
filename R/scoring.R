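#' Scoring configuration
#'
#' Collects the tunable parameters of the gene-drug phenotypic similarity
#' score.
#'
#' @param top_k number of best-scoring side effects kept per drug-gene
#'   comparison (polypharmacology correction). Default 20; use `Inf` for the
#'   uncorrected score. If a drug has fewer side effects than `top_k`, all of
#'   them are used.
#' @param combine_mode how the two directional best-match value lists are
#'   combined into one raw score: `"pooled"` (default; arithmetic mean of the
#'   concatenated lists, i.e. the mean of the <= top_k drug-side values and
#'   all gene-side values together) or `"mean_of_means"` (average of the two
#'   directional means).
#' @param burden_weights ordered weights for the low/medium/high drug
#'   side-effect burden tertiles. Default `c(1, 0.66, 0.33)`.
#' @param gene_scale_mode `"ln_n"` (default): multiply by `ln(#gene terms)`,
#'   so single-annotation genes are zeroed out; `"ln_n_plus_1"` retains them.
#' @param cooccurrence_mode `"per_corpus"` (default): the drug-side
#'   co-occurrence weight is the Jaccard of the term pair over drugs and the
#'   gene-side one over genes; `"pooled"`: one shared Jaccard over the pooled
#'   drug+gene entity universe.
#' @return A list of class `phenosim_config`.
#' @export
scoring_config <- function(top_k = 20,
                           combine_mode = c("pooled", "mean_of_means"),
                           burden_weights = c(1, 0.66, 0.33),
                           gene_scale_mode = c("ln_n", "ln_n_plus_1"),
                           cooccurrence_mode = c("per_corpus", "pooled")) {
  stopifnot(top_k >= 1, length(burden_weights) == 3,
            all(burden_weights > 0), all(burden_weights <= 1))
  structure(list(top_k = top_k,
                 combine_mode = match.arg(combine_mode),
                 burden_weights = burden_weights,
                 gene_scale_mode = match.arg(gene_scale_mode),
                 cooccurrence_mode = match.arg(cooccurrence_mode)),
            class = "phenosim_config")
}

# Jaccard matrix of terms_a x terms_b entity sets within one corpus, mapped
# to co-occurrence weights (-ln J, with the finite J=0 cap -ln(1/(|AuB|+1))).
# Terms absent from the corpus have empty entity sets.
.cooc_matrix <- function(inverted, terms_a, terms_b) {
  all_terms <- union(terms_a, terms_b)
  entities <- unique(unlist(inverted[intersect(names(inverted), all_terms)],
                            use.names = FALSE))
  X <- matrix(0L, length(all_terms), max(length(entities), 1L),
              dimnames = list(all_terms, if (length(entities)) entities else "."))
  for (t in all_terms) {
    e <- inverted[[t]]
    if (!is.null(e) && length(e)) X[t, e] <- 1L
  }
  inter <- X %*% t(X)
  sizes <- rowSums(X)
  un <- outer(sizes, sizes, "+") - inter
  J <- ifelse(un > 0, inter / un, 1)
  W <- ifelse(J > 0, -log(J), -log(1 / (un + 1)))
  W[terms_a, terms_b, drop = FALSE]
}

#' Precompute a term-pair scorer for a drug/gene corpus pair
#'
#' Computes the full matrix of term-pair similarity scores
#' `s_ij = IC(MICA(i, j)) * min(f_i c_i, f_j c_j)` for every side-effect term
#' `i` annotated in the drug corpus (rows) against every trait term `j`
#' annotated in the gene corpus (columns). All granular and all-pairs scoring
#' operations are thin lookups into this matrix.
#'
#' @param ontology a `phenosim_ontology`.
#' @param drug_corpus,gene_corpus `phenosim_corpus` objects sharing the
#'   ontology.
#' @param config a [scoring_config()].
#' @return A list of class `phenosim_scorer` with the score matrix `S`
#'   (dimnames: drug terms x gene terms) and its ingredients.
#' @export
make_scorer <- function(ontology, drug_corpus, gene_corpus,
                        config = scoring_config()) {
  stopifnot(inherits(ontology, "phenosim_ontology"),
            inherits(drug_corpus, "phenosim_corpus"),
            inherits(gene_corpus, "phenosim_corpus"))
  D <- sort(names(drug_corpus$inverted))
  G <- sort(names(gene_corpus$inverted))
  mic <- mica_ic_matrix(ontology, D, G)
  f_d <- vapply(D, function(t) frequency_weight(drug_corpus, t), numeric(1))
  f_g <- vapply(G, function(t) frequency_weight(gene_corpus, t), numeric(1))
  if (config$cooccurrence_mode == "per_corpus") {
    c_d <- .self_match_cap(.cooc_matrix(drug_corpus$inverted, D, G),
                           drug_corpus$inverted)
    c_g <- t(.self_match_cap(.cooc_matrix(gene_corpus$inverted, G, D),
                             gene_corpus$inverted))
  } else {
    pooled <- drug_corpus$inverted
    for (t in names(gene_corpus$inverted)) {
      pooled[[t]] <- union(pooled[[t]], paste0("gene::", gene_corpus$inverted[[t]]))
    }
    c_d <- .self_match_cap(.cooc_matrix(pooled, D, G), pooled)
    c_g <- c_d
  }
  prod_d <- f_d * c_d              # recycles f_d down rows
  prod_g <- sweep(c_g, 2, f_g, "*")
  S <- mic * pmin(prod_d, prod_g)
  structure(list(S = S, mic = mic, f_drug = f_d, f_gene = f_g,
                 c_drug = c_d, c_gene = c_g,
                 drug_terms = D, gene_terms = G, config = config),
            class = "phenosim_scorer")
}

#' Similarity score of one side-effect / trait term pair
#'
#' `s_ij = IC(MICA(i, j)) * min(f_i c_i, f_j c_j)`: the information content of
#' the most informative common ancestor of side effect `i` and trait `j`,
#' scaled by the smaller of the two frequency-times-co-occurrence weight
#' products, so that only effects specific in both annotation sets score
#' high. If the side effect is not annotated in the drug corpus or the trait
#' not in the gene corpus, the score is 0 by contract (not an error).
#'
#' When `se_term` and `trait_term` are the same term, the co-occurrence
#' penalty (which targets redundant pairs of distinct terms) is waived: the
#' self-match takes the maximally informative capped weight
#' `-ln(1/(|A| + 1))` in each corpus, so that identical specific effects are
#' the strongest evidence of shared mechanism and identical profiles are
#' most similar to themselves. A universal term still scores 0 through its
#' zero frequency weight.
#'
#' @inheritParams make_scorer
#' @param se_term side-effect term id (drug side).
#' @param trait_term phenotypic trait term id (gene side).
#' @return List with `se_term`, `trait_term`, `mica` (see [mica()]),
#'   `drug_side_product`, `gene_side_product` and the score `s`.
#' @export
term_pair_score <- function(ontology, drug_corpus, gene_corpus,
                            se_term, trait_term,
                            config = scoring_config()) {
  .check_term(ontology, se_term)
  .check_term(ontology, trait_term)
  m <- mica(ontology, se_term, trait_term)
  in_drug <- !is.null(drug_corpus$inverted[[se_term]])
  in_gene <- !is.null(gene_corpus$inverted[[trait_term]])
  if (!in_drug || !in_gene) {
    return(list(se_term = se_term, trait_term = trait_term, mica = m,
                drug_side_product = NA_real_, gene_side_product = NA_real_,
                s = 0))
  }
  if (config$cooccurrence_mode == "per_corpus") {
    if (identical(se_term, trait_term)) {
      # self-match convention: see .self_match_cap
      kd <- length(drug_corpus$inverted[[se_term]])
      kg <- length(gene_corpus$inverted[[trait_term]])
      pd <- frequency_weight(drug_corpus, se_term) * -log(1 / (kd + 1))
      pg <- frequency_weight(gene_corpus, trait_term) * -log(1 / (kg + 1))
    } else {
      pd <- pair_weight(drug_corpus, se_term, trait_term)$product
      pg <- pair_weight(gene_corpus, trait_term, se_term)$product
    }
  } else {
    pooled <- drug_corpus$inverted
    for (t in union(se_term, trait_term)) {
      pooled[[t]] <- union(pooled[[t]], paste0("gene::", gene_corpus$inverted[[t]]))
    }
    pooled_corpus <- structure(list(inverted = pooled), class = "phenosim_corpus")
    cw <- if (identical(se_term, trait_term)) {
      -log(1 / (length(pooled[[se_term]]) + 1))
    } else cooccurrence_weight(pooled_corpus, se_term, trait_term)
    pd <- frequency_weight(drug_corpus, se_term) * cw
    pg <- frequency_weight(gene_corpus, trait_term) * cw
  }
  list(se_term = se_term, trait_term = trait_term, mica = m,
       drug_side_product = pd, gene_side_product = pg,
       s = m$ic_value * min(pd, pg))
}

# Self-match convention: a term compared against itself trivially has
# Jaccard 1, but the co-occurrence penalty targets redundant pairs of
# distinct terms; a shared specific term is the strongest possible evidence
# of shared mechanism, so self-matches take the maximally informative capped
# weight -ln(1/(|A|+1)) instead of 0.
.self_match_cap <- function(W, inverted) {
  both <- intersect(rownames(W), colnames(W))
  for (t in both) {
    k <- length(inverted[[t]])
    W[t, t] <- -log(1 / (k + 1))
  }
  W
}

# look up scores for anchor terms vs partner terms from a scorer matrix;
# direction decides which axis the anchors live on
.score_block <- function(scorer, anchor_terms, partner_terms, direction) {
  if (direction == "drug_to_gene") {
    rows <- intersect(anchor_terms, scorer$drug_terms)
    cols <- intersect(partner_terms, scorer$gene_terms)
    M <- matrix(0, length(anchor_terms), length(partner_terms),
                dimnames = list(anchor_terms, partner_terms))
    if (length(rows) && length(cols)) M[rows, cols] <- scorer$S[rows, cols]
  } else {
    rows <- intersect(anchor_terms, scorer$gene_terms)
    cols <- intersect(partner_terms, scorer$drug_terms)
    M <- matrix(0, length(anchor_terms), length(partner_terms),
                dimnames = list(anchor_terms, partner_terms))
    if (length(rows) && length(cols)) M[rows, cols] <- t(scorer$S)[rows, cols]
  }
  M
}

#' Best-matching partner term for every anchor term
#'
#' For each term of the anchor profile, finds the partner-profile term with
#' the highest term-pair score. Ties between partners are broken by the
#' lexicographically smallest partner id; rows are ordered by descending best
#' score, then anchor term id.
#'
#' @param anchor_profile,partner_profile character vectors of term ids; both
#'   non-empty.
#' @param scorer a [make_scorer()] result.
#' @param direction `"drug_to_gene"` if the anchors are side effects (drug
#'   side), `"gene_to_drug"` if the anchors are traits (gene side).
#' @return data.frame with columns `anchor_term`, `best_partner`,
#'   `best_score`.
#' @export
best_matches <- function(anchor_profile, partner_profile, scorer,
                         direction = c("drug_to_gene", "gene_to_drug")) {
  direction <- match.arg(direction)
  if (!length(anchor_profile) || !length(partner_profile)) {
    stop("best_matches requires non-empty profiles")
  }
  anchor_profile <- sort(unique(anchor_profile))
  partner_profile <- sort(unique(partner_profile))
  M <- .score_block(scorer, anchor_profile, partner_profile, direction)
  best_j <- apply(M, 1, which.max)  # first max = lexicographically smallest
  res <- data.frame(anchor_term = anchor_profile,
                    best_partner = partner_profile[best_j],
                    best_score = M[cbind(seq_along(anchor_profile), best_j)],
                    stringsAsFactors = FALSE)
  res[order(-res$best_score, res$anchor_term), , drop = FALSE]
}

#' Gene-to-drug directional similarity
#'
#' Arithmetic mean, over all phenotypic traits of the gene, of the best
#' side-effect match score.
#'
#' @param gene_profile,drug_profile term id vectors (non-empty).
#' @inheritParams best_matches
#' @return List with `mean` and `values` (one best-match score per trait,
#'   descending).
#' @export
gene_to_drug_similarity <- function(gene_profile, drug_profile, scorer) {
  bm <- best_matches(gene_profile, drug_profile, scorer, "gene_to_drug")
  list(mean = mean(bm$best_score), values = bm$best_score)
}

#' Drug-to-gene directional similarity with top-K polypharmacology correction
#'
#' Computes the best trait match for every side effect of the drug, then
#' keeps only the `top_k` highest-scoring side effects (all of them if the
#' drug has fewer), reflecting that a polypharmacological drug's full
#' side-effect profile mixes the effects of several targets while a single
#' gene explains only a subset. The selection is made per gene comparison, so
#' the contributing side effects may differ between genes.
#'
#' @inheritParams gene_to_drug_similarity
#' @param top_k number of best-scoring side effects retained (default from
#'   the scorer's config; `Inf` disables the correction).
#' @return List with `mean`, `values` (the selected scores, descending) and
#'   `contributing` (their side-effect term ids).
#' @export
drug_to_gene_similarity <- function(drug_profile, gene_profile, scorer,
                                    top_k = scorer$config$top_k) {
  stopifnot(top_k >= 1)
  bm <- best_matches(drug_profile, gene_profile, scorer, "drug_to_gene")
  k <- min(top_k, nrow(bm))
  sel <- bm[seq_len(k), , drop = FALSE]  # already (score desc, term asc)
  list(mean = mean(sel$best_score), values = sel$best_score,
       contributing = sel$anchor_term)
}

#' Combine the two directional similarities into one raw score
#'
#' @param gene_values gene-direction best-match scores (one per trait).
#' @param drug_values the selected (<= top_k) drug-direction best-match
#'   scores.
#' @param mode `"pooled"`: mean of the concatenated lists; `"mean_of_means"`:
#'   average of the two directional means.
#' @return Raw combined score.
#' @export
combine_directions <- function(gene_values, drug_values,
                               mode = c("pooled", "mean_of_means")) {
  mode <- match.arg(mode)
  if (mode == "pooled") mean(c(gene_values, drug_values))
  else (mean(gene_values) + mean(drug_values)) / 2
}

#' Side-effect burden weights for drugs
#'
#' Drugs are binned into tertiles of their side-effect count and the final
#' score multiplied by 1 (low burden, count <= 33% quantile), 0.66 (medium,
#' <= 66% quantile) or 0.33 (high), reducing the advantage of drugs with very
#' many side effects. Quantiles use the linear-interpolation (type 7) rule;
#' ties at a boundary fall into the lower bin.
#'
#' @param drug_corpus a `phenosim_corpus` of drugs.
#' @param config a [scoring_config()] supplying the three weights.
#' @return Named numeric vector drug_id -> weight.
#' @export
drug_burden_weights <- function(drug_corpus, config = scoring_config()) {
  counts <- vapply(drug_corpus$annotations, length, integer(1))
  q <- stats::quantile(counts, c(1, 2) / 3, type = 7)
  w <- ifelse(counts <= q[1], config$burden_weights[1],
              ifelse(counts <= q[2], config$burden_weights[2],
                     config$burden_weights[3]))
  stats::setNames(w, names(counts))
}

#' Score all gene-drug pairs
#'
#' The all-pairs driver: for every (drug, gene) pair it computes the raw
#' combined best-match score, scales it by `ln(#gene terms)` (downweighting
#' genes with little phenotypic information) and by the drug's side-effect
#' burden weight, and finally max-normalizes the scaled scores over the
#' scored set to \[0,1\].
#'
#' @inheritParams make_scorer
#' @return data.frame (one row per drug x gene combination, ordered by
#'   drug_id then gene_id) with columns `drug_id`, `gene_id`, `raw`,
#'   `gene_scale`, `burden_weight`, `scaled`, `normalized`, `n_gene_terms`,
#'   `n_drug_terms`, `contributing_side_effects` (pipe-separated). The global
#'   scaled maximum and the config are attached as attributes `global_max`
#'   and `config`.
#' @export
score_all_pairs <- function(ontology, drug_corpus, gene_corpus,
                            config = scoring_config()) {
  if (!length(drug_corpus$annotations) || !length(gene_corpus$annotations)) {
    stop("score_all_pairs requires non-empty corpora")
  }
  scorer <- make_scorer(ontology, drug_corpus, gene_corpus, config)
  drugs <- sort(names(drug_corpus$annotations))
  genes <- sort(names(gene_corpus$annotations))
  S <- scorer$S
  # per-drug column maxima over the drug's side effects (gene-direction), and
  # per-gene row maxima over the gene's traits (drug-direction)
  colmax_by_drug <- lapply(drugs, function(d) {
    rows <- drug_corpus$annotations[[d]]
    apply(S[rows, , drop = FALSE], 2, max)
  })
  names(colmax_by_drug) <- drugs
  rowmax_by_gene <- lapply(genes, function(g) {
    cols <- gene_corpus$annotations[[g]]
    apply(S[, cols, drop = FALSE], 1, max)
  })
  names(rowmax_by_gene) <- genes

  burden <- drug_burden_weights(drug_corpus, config)
  n_gene_terms <- vapply(gene_corpus$annotations, length, integer(1))
  gene_scale <- if (config$gene_scale_mode == "ln_n") log(n_gene_terms)
                else log(n_gene_terms + 1)
  if (config$gene_scale_mode == "ln_n" && any(n_gene_terms == 1L)) {
    warning(sum(n_gene_terms == 1L), " gene(s) with a single annotation get ",
            "scaled score 0 under gene_scale_mode 'ln_n'")
  }

  out <- vector("list", length(drugs))
  for (di in seq_along(drugs)) {
    d <- drugs[di]
    d_terms <- drug_corpus$annotations[[d]]  # sorted lexicographically
    cm <- colmax_by_drug[[d]]
    raw <- numeric(length(genes))
    contrib <- character(length(genes))
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      g_terms <- gene_corpus$annotations[[g]]
      dvals <- rowmax_by_gene[[g]][d_terms]
      ord <- order(-dvals, d_terms)[seq_len(min(config$top_k, length(dvals)))]
      gvals <- cm[g_terms]
      raw[gi] <- combine_directions(gvals, dvals[ord], config$combine_mode)
      contrib[gi] <- paste(d_terms[ord], collapse = "|")
    }
    out[[di]] <- data.frame(
      drug_id = d, gene_id = genes, raw = raw,
      gene_scale = unname(gene_scale[genes]),
      burden_weight = unname(burden[d]),
      scaled = raw * unname(gene_scale[genes]) * unname(burden[d]),
      n_gene_terms = unname(n_gene_terms[genes]),
      n_drug_terms = length(d_terms),
      contributing_side_effects = contrib,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  gmax <- max(res$scaled)
  res$normalized <- if (gmax > 0) res$scaled / gmax else 0
  res <- res[order(res$drug_id, res$gene_id),
             c("drug_id", "gene_id", "raw", "gene_scale", "burden_weight",
               "scaled", "normalized", "n_gene_terms", "n_drug_terms",
               "contributing_side_effects")]
  rownames(res) <- NULL
  attr(res, "global_max") <- gmax
  attr(res, "config") <- config
  res
}
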