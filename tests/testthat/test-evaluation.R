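test_that("benchmark universe is the cross product of positive drugs and genes", {
  score_table <- expand.grid(drug_id = sprintf("D%d", 1:4),
                             gene_id = sprintf("G%d", 1:4),
                             stringsAsFactors = FALSE)
  score_table$normalized <- seq_len(nrow(score_table)) / nrow(score_table)

  pos <- data.frame(drug_id = c("D1", "D2"), gene_id = c("G1", "G2"))
  b <- build_benchmark(pos, score_table)
  expect_equal(nrow(b$pairs), 4L)   # 2 drugs x 2 genes
  expect_equal(b$n_pos, 2L)
  expect_equal(b$n_neg, 2L)

  # positives sharing one gene: universe = drugs x {gene}
  pos2 <- data.frame(drug_id = c("D1", "D2"), gene_id = c("G1", "G1"))
  b2 <- build_benchmark(pos2, score_table)
  expect_equal(nrow(b2$pairs), 2L)
  expect_true(all(b2$pairs$gene_id == "G1"))

  # unmatched positives are dropped with a message; none usable errors
  expect_message(build_benchmark(rbind(pos, data.frame(drug_id = "DX",
                                                       gene_id = "G1")),
                                 score_table), "dropping 1")
  expect_error(suppressMessages(build_benchmark(
    data.frame(drug_id = "DX", gene_id = "GX"), score_table)), "no usable")

  # synthetic planted truth: universe equals the brute-force cross product
  st <- generate_study(sim_config(seed = 5, n_genes = 8L, n_drugs = 5L))
  sc <- score_all_pairs(st$ontology, st$drug_corpus, st$gene_corpus)
  bs <- build_benchmark(st$truth$planted_pairs, sc)
  pd <- unique(st$truth$planted_pairs$drug_id)
  pg <- unique(st$truth$planted_pairs$gene_id)
  expect_equal(nrow(bs$pairs), length(pd) * length(pg))
  expect_equal(bs$n_pos, nrow(unique(st$truth$planted_pairs)))
})

test_that("confusion curve counts agree with exhaustive counting at every threshold", {
  scores <- c(0.9, 0.8, 0.8, 0.5, 0.3, 0.1)
  labels <- c(1, 1, 0, 0, 1, 0)
  cv <- confusion_curve(scores, labels)
  expect_equal(cv$points$threshold, c(0.9, 0.8, 0.5, 0.3, 0.1))
  for (i in seq_len(nrow(cv$points))) {
    want <- oracle_confusion(scores, labels, cv$points$threshold[i])
    expect_equal(cv$points$TP[i], unname(want["TP"]))
    expect_equal(cv$points$FP[i], unname(want["FP"]))
    expect_equal(cv$points$TN[i], unname(want["TN"]))
    expect_equal(cv$points$FN[i], unname(want["FN"]))
    # conservation and derived rates
    expect_equal(cv$points$TP[i] + cv$points$FN[i], 3)
    expect_equal(cv$points$FP[i] + cv$points$TN[i], 3)
    expect_equal(cv$points$precision[i],
                 cv$points$TP[i] / (cv$points$TP[i] + cv$points$FP[i]))
    expect_equal(cv$points$lift[i], cv$points$precision[i] / 0.5)
    expect_equal(cv$points$accuracy[i],
                 (cv$points$TP[i] + cv$points$TN[i]) / 6)
  }
  # monotone tpr/fpr as the threshold decreases
  expect_true(all(diff(cv$points$tpr) >= 0))
  expect_true(all(diff(cv$points$fpr) >= 0))

  # perfect separation
  cvp <- confusion_curve(c(3, 2, 1, 0), c(1, 1, 0, 0))
  expect_equal(cvp$auc, 1)
  expect_equal(max(cvp$points$precision), 1)

  expect_error(confusion_curve(1:3, c(1, 1, 1)), "both classes")
})

test_that("trapezoid AUC equals the pairwise Mann-Whitney probability", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 60
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    cv <- confusion_curve(scores, labels)
    expect_equal(cv$auc, oracle_pairwise_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- rnorm(200); labels <- rbinom(200, 1, 0.3)
  cv <- confusion_curve(scores, labels)
  ref <- suppressMessages(pROC::auc(labels, scores, direction = "<"))
  expect_equal(cv$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("labels independent of scores give chance-level AUC and unit lift", {
  set.seed(1234)
  n <- 10000
  scores <- runif(n)
  labels <- rbinom(n, 1, 0.1)
  cv <- confusion_curve(scores, labels)
  expect_equal(cv$auc, 0.5, tolerance = 0.02)
  # lift at a mid threshold is ~1 for a random scorer
  expect_equal(lift_at(cv, 0.5), 1, tolerance = 0.1)
  # the all-positive classifier has lift exactly 1 at the lowest threshold
  expect_equal(cv$points$lift[nrow(cv$points)], 1)
})

test_that("lift and precision-threshold lookups follow their definitions", {
  # prevalence 0.1, precision 0.5 at the top threshold: lift 5
  scores <- c(rep(0.9, 10), rep(0.1, 90))
  labels <- c(rep(c(1, 0), each = 5), c(rep(1, 5), rep(0, 85)))
  cv <- confusion_curve(scores, labels)
  expect_equal(lift_at(cv, 0.9), 0.5 / 0.1)
  expect_true(is.na(lift_at(cv, 2)))

  thr <- threshold_at_precision(cv, 0.5)
  expect_equal(as.numeric(thr), 0.9)
  expect_true(attr(thr, "found"))
  miss <- threshold_at_precision(cv, 0.9)
  expect_true(is.na(miss))
  expect_false(attr(miss, "found"))
  expect_error(threshold_at_precision(cv, 0), "min_precision")
  expect_error(threshold_at_precision(cv, 1.5), "min_precision")
})

test_that("binned lift reports per-bin enrichment, counts and empty flags", {
  scores <- c(0.05, 0.1, 0.2, 0.9, 0.95)
  labels <- c(0, 0, 0, 1, 1)
  # single bin: overall lift = precision / prevalence = 1
  one <- binned_lift(scores, labels, c(0, 1))
  expect_equal(one$lift, 1)
  expect_equal(one$n_pairs, 5L)
  # all positives in the top bin: lift = 1 / prevalence
  three <- binned_lift(scores, labels, c(0, 0.3, 0.6, 1))
  expect_equal(three$lift[3], 1 / 0.4)
  expect_true(three$empty[2])
  expect_true(is.na(three$lift[2]))
  expect_equal(three$ln_count[1], log(3))
})

test_that("causal side-effect fractions count known links among contributors", {
  known <- data.frame(gene_id = c("G1", "G1", "G2"),
                      term_id = c("t1", "t2", "t9"))
  expect_equal(causal_se_fraction(c("t5", "t6"), "G1", known), 0)
  expect_equal(causal_se_fraction(c("t1", "t2"), "G1", known), 1)
  expect_equal(causal_se_fraction(sprintf("t%d", 1:20), "G1", known), 0.1)
  contributing <- c("t1", "t2", "t3", "t4")   # 2 of 4 known for G1
  expect_equal(causal_se_fraction(contributing, "G1", known), 0.5)
  expect_equal(causal_se_fraction(contributing, "G2", known), 0)
  expect_error(causal_se_fraction(character(0), "G1", known), "empty")
})

test_that("high-low rank-sum comparison matches brute-force U and handles ties", {
  hi <- c(5, 6, 7, 8, 9, 10, 11, 12, 13, 14)
  lo <- c(1, 2, 3, 4, 4.5, 4.2, 4.8, 3.5, 2.5, 1.5)
  res <- compare_high_low(hi, lo)
  expect_equal(res$statistic, oracle_u_stat(hi, lo))  # fully separated: 100
  expect_equal(res$statistic, 100)
  expect_lt(res$p_value, 0.001)

  # agreement with the normal-approximation rank-sum (tie-corrected)
  set.seed(77)
  a <- sample(1:6, 15, replace = TRUE); b <- sample(2:8, 12, replace = TRUE)
  res2 <- compare_high_low(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, alternative = "greater",
                                             exact = FALSE, correct = FALSE))
  expect_equal(res2$p_value, ref$p.value)
  expect_equal(res2$statistic, oracle_u_stat(a, b))

  # identical samples are symmetric: p near one half
  set.seed(3); x <- rnorm(30)
  expect_equal(compare_high_low(x, x)$p_value, 0.5, tolerance = 1e-6)
  expect_warning(deg <- compare_high_low(rep(1, 5), rep(1, 5)), "degenerate")
  expect_equal(deg$p_value, 0.5)
})

test_that("PPI distance is the minimum hop count to any known target", {
  chain <- data.frame(protein_a = c("g", "x"), protein_b = c("x", "t"))
  expect_equal(ppi_min_distance(chain, "g", "g"), 0)      # gene is a target
  expect_equal(ppi_min_distance(chain, "g", "t"), 2)      # g - x - t
  expect_equal(ppi_min_distance(chain, "g", "x"), 1)      # direct interactor
  expect_equal(ppi_min_distance(chain, "orphan", "t"), Inf)
  expect_error(ppi_min_distance(chain, "g", character(0)), "empty")

  # random graphs against the naive BFS oracle
  for (seed in c(2, 4)) {
    set.seed(seed)
    nodes <- sprintf("n%d", 1:12)
    edges <- unique(data.frame(
      protein_a = sample(nodes, 18, replace = TRUE),
      protein_b = sample(nodes, 18, replace = TRUE)))
    edges <- edges[edges$protein_a != edges$protein_b, ]
    targets <- sample(nodes, 2)
    for (g in nodes) {
      expect_equal(ppi_min_distance(edges, g, targets),
                   oracle_bfs_distance(edges, g, targets),
                   label = paste("seed", seed, "gene", g))
    }
  }
})

test_that("mapping coverage bins use left-open right-closed frequency intervals", {
  counts <- c(1, 1, 2, 5, 6, 10, 11, 50, 51, 100, 101, 500)
  all_mapped <- mapping_coverage_by_frequency(counts, rep(TRUE, length(counts)))
  expect_equal(all_mapped$fraction_mapped, rep(1, 6))
  none <- mapping_coverage_by_frequency(counts, rep(FALSE, length(counts)))
  expect_equal(none$fraction_mapped, rep(0, 6))

  # counts straddling the 5 and 10 edges land per the interval notation:
  # bin1 = {1}, bin2 = (1,5], bin3 = (5,10], bin4 = (10,50], bin5 = (50,100],
  # bin6 = >100
  cov <- mapping_coverage_by_frequency(counts, counts <= 5)
  expect_equal(cov$n_terms, c(2L, 2L, 2L, 2L, 2L, 2L))
  expect_equal(cov$n_mapped, c(2L, 2L, 0L, 0L, 0L, 0L))

  # drug-side edge extension adds (100,500] and >500 bins
  drugside <- mapping_coverage_by_frequency(
    c(1, 200, 501, 700), rep(TRUE, 4), bin_edges = c(1, 5, 10, 50, 100, 500))
  expect_equal(drugside$bin,
               c("1", "(1,5]", "(5,10]", "(10,50]", "(50,100]", "(100,500]", ">500"))
  expect_equal(drugside$n_terms, c(1L, 0L, 0L, 0L, 0L, 1L, 2L))
})

test_that("enlarging the universe with low-scoring never-positive genes raises AUC", {
  # benchmark-composition effect: unlabeled entities added to the universe
  # tend to populate the low-score region (here: decoy genes carrying little
  # phenotypic information), adding easy true negatives and inflating AUC on
  # the same positives
  st <- generate_study(sim_config(seed = 13, n_genes = 20L, n_drugs = 12L))
  leaves <- st$ontology$terms$term_id[st$ontology$descendant_counts == 0]
  set.seed(99)
  decoys <- do.call(rbind, lapply(sprintf("GX%02d", 1:20), function(g) {
    data.frame(entity_id = g, term_id = sample(leaves, 2))
  }))
  gene_corpus <- load_corpus(rbind(st$gene_annotations, decoys),
                             st$ontology, "gene")
  sc <- score_all_pairs(st$ontology, st$drug_corpus, gene_corpus)
  pos <- st$truth$planted_pairs
  cross <- build_benchmark(pos, sc, universe_mode = "cross")
  full <- build_benchmark(pos, sc, universe_mode = "all_scored")
  auc_cross <- confusion_curve(cross$pairs$score, cross$pairs$label)$auc
  auc_full <- confusion_curve(full$pairs$score, full$pairs$label)$auc
  expect_gt(auc_full, auc_cross)
})
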