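#' Build a labeled benchmark set from known positive pairs
#'
#' Mirrors the construction used for drug-target benchmarks: the positives
#' are the reported gene-drug associations and the negatives all other
#' combinations of the drugs and genes that each appear in at least one
#' positive (`universe_mode = "cross"`). Positives referencing entities not
#' present in the score table are logged and dropped.
#'
#' @param positives data.frame with columns `drug_id`, `gene_id`.
#' @param score_table result of [score_all_pairs()] (or any data.frame with
#'   `drug_id`, `gene_id` and a score column).
#' @param universe_mode `"cross"` (default, see above) or `"all_scored"` (the
#'   whole score table is the universe).
#' @param score_column column of `score_table` used as the score (default
#'   `"normalized"`).
#' @return List of class `phenosim_benchmark` with `pairs` (data.frame
#'   `drug_id`, `gene_id`, `score`, `label` in 0/1), `n_pos`, `n_neg`.
#' @export
build_benchmark <- function(positives, score_table,
                            universe_mode = c("cross", "all_scored"),
                            score_column = "normalized") {
  universe_mode <- match.arg(universe_mode)
  stopifnot(all(c("drug_id", "gene_id") %in% names(positives)),
            score_column %in% names(score_table))
  key <- function(d, g) paste(d, g, sep = "\r")
  pos <- unique(data.frame(drug_id = as.character(positives$drug_id),
                           gene_id = as.character(positives$gene_id),
                           stringsAsFactors = FALSE))
  scored_drugs <- unique(score_table$drug_id)
  scored_genes <- unique(score_table$gene_id)
  usable <- pos$drug_id %in% scored_drugs & pos$gene_id %in% scored_genes
  if (any(!usable)) {
    message("dropping ", sum(!usable), " positive pair(s) not covered by the score table")
    pos <- pos[usable, , drop = FALSE]
  }
  if (!nrow(pos)) stop("no usable positive pairs")
  if (universe_mode == "cross") {
    keep <- score_table$drug_id %in% unique(pos$drug_id) &
      score_table$gene_id %in% unique(pos$gene_id)
    uni <- score_table[keep, , drop = FALSE]
  } else {
    uni <- score_table
  }
  lab <- as.integer(key(uni$drug_id, uni$gene_id) %in% key(pos$drug_id, pos$gene_id))
  pairs <- data.frame(drug_id = uni$drug_id, gene_id = uni$gene_id,
                      score = uni[[score_column]], label = lab,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, n_pos = sum(lab == 1L), n_neg = sum(lab == 0L)),
            class = "phenosim_benchmark")
}

#' Threshold-ordered confusion counts with derived performance measures
#'
#' Sweeps the score thresholds from high to low, classifying a pair positive
#' when `score >= threshold`, with one point per distinct score so that
#' equally-scored pairs always cross the threshold together. At every point:
#' precision = TP/(TP+FP), true positive rate (recall) = TP/P, false positive
#' rate = FP/N, accuracy = (TP+TN)/(P+N), and lift = precision / (P/(P+N)) --
#' the enrichment of correct positive calls over the random-choice
#' expectation. The ROC area (AUC) is computed by the trapezoidal rule over
#' (FPR, TPR) with the (0,0) and (1,1) endpoints.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) labels, same length; both classes must be
#'   present.
#' @return List of class `phenosim_curve` with `points` (data.frame
#'   `threshold`, `TP`, `FP`, `TN`, `FN`, `precision`, `tpr`, `fpr`,
#'   `accuracy`, `lift`, thresholds descending), `auc`, `n_pos`, `n_neg`.
#' @export
confusion_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L) stop("confusion_curve requires both classes")
  thr <- sort(unique(scores), decreasing = TRUE)
  pos_by_thr <- vapply(split(labels, factor(scores, levels = thr)), sum, integer(1))
  tot_by_thr <- vapply(split(labels, factor(scores, levels = thr)), length, integer(1))
  TP <- cumsum(pos_by_thr)
  called <- cumsum(tot_by_thr)
  FP <- called - TP
  FN <- P - TP
  TN <- N - FP
  prevalence <- P / (P + N)
  pts <- data.frame(
    threshold = thr, TP = TP, FP = FP, TN = TN, FN = FN,
    precision = TP / (TP + FP), tpr = TP / P, fpr = FP / N,
    accuracy = (TP + TN) / (P + N),
    lift = (TP / (TP + FP)) / prevalence,
    row.names = NULL
  )
  fpr <- c(0, pts$fpr); tpr <- c(0, pts$tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = P, n_neg = N),
            class = "phenosim_curve")
}

#' @export
print.phenosim_curve <- function(x, ...) {
  cat("phenosim evaluation curve:", nrow(x$points), "thresholds, P =", x$n_pos,
      ", N =", x$n_neg, ", AUC =", round(x$auc, 4), "\n")
  invisible(x)
}

#' Lift at a given score threshold
#'
#' Returns the lift of the classifier "score >= threshold", i.e. the lift at
#' the curve point with the smallest distinct score >= `threshold` (NA if no
#' score reaches it).
#'
#' @param curve a [confusion_curve()] result.
#' @param threshold score cutoff.
#' @return Lift value (precision / prevalence), or NA.
#' @export
lift_at <- function(curve, threshold) {
  pts <- curve$points
  i <- which(pts$threshold >= threshold)
  if (!length(i)) return(NA_real_)
  pts$lift[max(i)]
}

#' Lowest score threshold reaching a precision target
#'
#' Scans the curve from the highest threshold down and returns the lowest
#' distinct score whose precision is at least `min_precision` (used e.g. to
#' split associations into high and low scoring at the precision-10% score).
#' If no threshold qualifies, returns NA with attribute `found = FALSE`.
#'
#' @inheritParams lift_at
#' @param min_precision target precision in (0, 1].
#' @return The threshold score (attribute `found` says whether one exists).
#' @export
threshold_at_precision <- function(curve, min_precision) {
  if (!is.numeric(min_precision) || min_precision <= 0 || min_precision > 1) {
    stop("min_precision must be in (0, 1]")
  }
  pts <- curve$points
  ok <- which(pts$precision >= min_precision)
  if (!length(ok)) return(structure(NA_real_, found = FALSE))
  structure(pts$threshold[max(ok)], found = TRUE)
}

#' Lift and pair counts per score bin
#'
#' Bins pairs by score (left-open, right-closed intervals over the given
#' edges; the lowest edge is included in the first bin) and reports per-bin
#' precision (fraction of positives), lift over the overall prevalence, the
#' natural logarithm of the pair count, and an `empty` flag for bins without
#' pairs (sparse high-score bins are a known caveat).
#'
#' @param scores,labels as in [confusion_curve()].
#' @param bin_edges increasing numeric vector of bin boundaries.
#' @return data.frame with `bin`, `lower`, `upper`, `n_pairs`, `n_pos`,
#'   `precision`, `lift`, `ln_count`, `empty`.
#' @export
binned_lift <- function(scores, labels, bin_edges) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), !is.unsorted(bin_edges, strictly = TRUE))
  prevalence <- mean(labels)
  bins <- cut(scores, breaks = bin_edges, include.lowest = TRUE, right = TRUE)
  n <- as.integer(table(bins))
  npos <- as.integer(tapply(labels, bins, sum, default = 0L))
  prec <- ifelse(n > 0, npos / n, NA_real_)
  data.frame(
    bin = levels(bins),
    lower = utils::head(bin_edges, -1), upper = utils::tail(bin_edges, -1),
    n_pairs = n, n_pos = npos, precision = prec,
    lift = prec / prevalence,
    ln_count = ifelse(n > 0, log(n), NA_real_),
    empty = n == 0L,
    stringsAsFactors = FALSE
  )
}

#' Fraction of causal gene-side-effect links among contributing side effects
#'
#' For a scored gene-drug pair, the fraction of the (at most top-K) side
#' effects that contributed to its similarity score which are independently
#' known to be caused via the gene's protein.
#'
#' @param contributing character vector of contributing side-effect term ids
#'   (non-empty).
#' @param gene_id the gene of the pair.
#' @param known_gene_se data.frame of known causal links with columns
#'   `gene_id`, `term_id`.
#' @return Fraction in \[0, 1\].
#' @export
causal_se_fraction <- function(contributing, gene_id, known_gene_se) {
  if (!length(contributing)) stop("empty contributing side-effect set")
  known <- known_gene_se$term_id[known_gene_se$gene_id == gene_id]
  mean(contributing %in% known)
}

#' One-sided rank-sum comparison of high- vs low-scoring groups
#'
#' Wilcoxon/Mann-Whitney rank-sum test (normal approximation with tie
#' correction) of the alternative that values in the high-scoring group are
#' stochastically larger than in the low-scoring group.
#'
#' @param values_high,values_low numeric samples (each of size >= 3).
#' @return List with `statistic` (the Mann-Whitney U of the high group) and
#'   `p_value` (one-sided, high > low). Degenerate all-equal samples give
#'   p = 0.5 with a warning.
#' @export
compare_high_low <- function(values_high, values_low) {
  stopifnot(length(values_high) >= 3, length(values_low) >= 3)
  if (length(unique(c(values_high, values_low))) == 1L) {
    warning("all values identical; rank-sum comparison is degenerate")
    return(list(statistic = length(values_high) * length(values_low) / 2,
                p_value = 0.5))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_high, values_low,
                                            alternative = "greater",
                                            exact = FALSE, correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Minimum PPI-network distance from a gene to any known drug target
#'
#' Breadth-first shortest hop distance in an undirected protein-protein
#' interaction network from the gene's protein to the closest known target
#' of the drug. Distance 0 means the gene itself is a known target; 1 a
#' direct interactor; genes that are neither targets nor connected to one
#' get `Inf`.
#'
#' @param network data.frame of undirected edges with columns `protein_a`,
#'   `protein_b` (an optional `confidence` column can be pre-filtered with
#'   [read_ppi_tsv()]).
#' @param gene_id protein/gene identifier.
#' @param target_ids non-empty character vector of known target identifiers.
#' @return Non-negative integer hop count, or `Inf` if unreachable.
#' @export
ppi_min_distance <- function(network, gene_id, target_ids) {
  if (!length(target_ids)) stop("empty target set")
  if (gene_id %in% target_ids) return(0)
  g <- igraph::graph_from_data_frame(
    network[, c("protein_a", "protein_b")], directed = FALSE)
  nodes <- igraph::V(g)$name
  reachable_targets <- intersect(target_ids, nodes)
  if (!gene_id %in% nodes || !length(reachable_targets)) return(Inf)
  d <- igraph::distances(g, v = gene_id, to = reachable_targets)
  min(d)
}

#' Fraction of annotations mapped, by term-frequency bin
#'
#' Bins terms by how often they are used as an annotation (left-open,
#' right-closed intervals; the first bin holds frequency exactly 1) and
#' reports the fraction of mapped terms per bin, quantifying how mapping
#' coverage changes with annotation frequency. Default gene-side edges put
#' frequencies into bins 1, (1,5], (5,10], (10,50], (50,100], >100; for the
#' drug side add 500 to extend with (100,500], >500.
#'
#' @param term_annotation_counts positive integer vector: per-term annotation
#'   frequency.
#' @param mapped_flags logical vector, same length: whether the term could be
#'   mapped.
#' @param bin_edges upper interior edges of the bins (default
#'   `c(1, 5, 10, 50, 100)`; the final bin is open-ended).
#' @return data.frame with `bin`, `n_terms`, `n_mapped`, `fraction_mapped`.
#' @export
mapping_coverage_by_frequency <- function(term_annotation_counts, mapped_flags,
                                          bin_edges = c(1, 5, 10, 50, 100)) {
  stopifnot(length(term_annotation_counts) == length(mapped_flags),
            all(term_annotation_counts >= 1))
  breaks <- c(0, bin_edges, Inf)
  labs <- c(as.character(bin_edges[1]),
            paste0("(", utils::head(bin_edges, -1), ",", utils::tail(bin_edges, -1), "]"),
            paste0(">", bin_edges[length(bin_edges)]))
  bins <- cut(term_annotation_counts, breaks = breaks, right = TRUE, labels = labs)
  n <- as.integer(table(bins))
  nm <- as.integer(tapply(as.logical(mapped_flags), bins, sum, default = 0L))
  data.frame(bin = labs, n_terms = n, n_mapped = nm,
             fraction_mapped = ifelse(n > 0, nm / n, NA_real_),
             stringsAsFactors = FALSE)
}
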