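#' Configuration of a synthetic gene-drug phenotype study
#'
#' Fixes the generative conditions under which the scoring scheme is
#' exercised without any licensed or downloaded data. The generator emulates
#' the structure the method assumes: a layered multi-parent phenotype
#' hierarchy; genes annotated with a handful of specific (leaf) phenotypic
#' traits; drugs that hit one or more target genes (polypharmacology) and
#' echo part of each target's traits as side effects -- usually blurred to a
#' sibling term, as cross-species phenotype mapping rarely lands on the
#' identical term -- plus unrelated noise side effects whose popularity is
#' Zipf-skewed, mimicking ubiquitous nuisance side effects such as headache
#' or nausea.
#'
#' @param seed integer seed; all randomness flows through it, with
#'   sub-streams per artifact so e.g. adding drugs does not perturb gene
#'   sampling.
#' @param depth,branching complete-tree shape of the generated ontology
#'   (default 4 levels, branching 3: 40 terms, 27 leaves).
#' @param n_genes,n_drugs entity counts (defaults 50 and 30).
#' @param traits_per_gene inclusive range of traits sampled per gene
#'   (default exactly 4). Profiles are spread over distinct leaf sibling
#'   groups where possible, emulating knockout phenotypes spanning different
#'   organ systems.
#' @param targets_per_drug inclusive range of planted target genes per drug
#'   (default 1..2; >1 models polypharmacology).
#' @param copy_fraction probability that a target's trait is echoed into the
#'   drug's side-effect profile (default 1).
#' @param sibling_swap_prob probability that an echoed trait is replaced by a
#'   sibling leaf, modelling the cross-species phenotype blur of mapping a
#'   mouse trait to a near-identical human side-effect term (default 0.25).
#' @param noise_side_effects inclusive range of unrelated noise side effects
#'   per drug; only used when `drug_profile_size` is `NULL`.
#' @param drug_profile_size when non-NULL (default 8), noise side effects
#'   fill every drug profile up to this common size, reflecting that label
#'   side-effect lists are of comparable length whatever the number of
#'   targets; a larger target load then means a larger share of
#'   target-driven side effects, not a longer list.
#' @param noise_zipf exponent of the Zipf weights used to sample noise terms
#'   over a study-specific random leaf order (default 2.5; 0 = uniform).
#'   Heavily skewed noise emulates ubiquitous nuisance side effects (the
#'   published drug data binned side effects occurring in >500 drugs), which
#'   the frequency weighting is designed to discount.
#' @param cross_link_rate fraction of leaves given an extra SMQ-like
#'   cross-hierarchy parent (default 0).
#' @param n_decoy_proteins,ppi_extra_edges interaction-network size knobs for
#'   the synthetic PPI graph (defaults 20 and 30).
#' @param causal_pair_prob probability that a planted pair contributes its
#'   echoed side effects to the known causal gene-side-effect set
#'   (default 0.5).
#'
#' @details Defaults are calibrated as a positive-control benchmark: a
#' correctly implemented scorer should recover the planted gene-drug pairs
#' with high ranking AUC under these conditions, while the `copy_fraction =
#' 0` control carries no signal. The methods vignette discusses which
#' features of real drug/phenotype data the generator does and does not
#' emulate.
#'
#' @return List of class `phenosim_simconfig`.
#' @export
sim_config <- function(seed = 7L, depth = 4L, branching = 3L,
                       n_genes = 50L, n_drugs = 30L,
                       traits_per_gene = c(4L, 4L),
                       targets_per_drug = c(1L, 2L),
                       copy_fraction = 1,
                       sibling_swap_prob = 0.25,
                       noise_side_effects = c(2L, 6L),
                       drug_profile_size = 8L,
                       noise_zipf = 2.5,
                       cross_link_rate = 0,
                       n_decoy_proteins = 20L,
                       ppi_extra_edges = 30L,
                       causal_pair_prob = 0.5) {
  stopifnot(depth >= 2, branching >= 2, n_genes >= 1, n_drugs >= 1,
            length(traits_per_gene) == 2, traits_per_gene[1] >= 1,
            length(targets_per_drug) == 2, targets_per_drug[1] >= 1,
            copy_fraction >= 0, copy_fraction <= 1,
            sibling_swap_prob >= 0, sibling_swap_prob <= 1,
            length(noise_side_effects) == 2, noise_side_effects[1] >= 0,
            cross_link_rate >= 0, cross_link_rate <= 1)
  structure(as.list(environment()), class = "phenosim_simconfig")
}

# run code under a derived seed without disturbing the caller's RNG state
.with_substream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  force(code)
}

#' Generate a complete layered phenotype ontology
#'
#' Builds a complete tree of the configured depth and branching factor
#' (term count `sum(branching^(level-1))`), optionally adding SMQ-like
#' cross-hierarchy parents to a random fraction of leaves.
#'
#' @param config a [sim_config()].
#' @return A `phenosim_ontology`.
#' @export
generate_ontology <- function(config = sim_config()) {
  stopifnot(inherits(config, "phenosim_simconfig"))
  ids <- "P0"; levels <- 1L; parents <- list(character(0))
  prev <- "P0"
  for (lv in seq_len(config$depth - 1L)) {
    nxt <- character(0)
    for (p in prev) {
      kids <- paste0(p, ".", seq_len(config$branching))
      ids <- c(ids, kids); levels <- c(levels, rep(lv + 1L, length(kids)))
      parents <- c(parents, rep(list(p), length(kids)))
      nxt <- c(nxt, kids)
    }
    prev <- nxt
  }
  names(parents) <- ids
  if (config$cross_link_rate > 0) {
    leaves <- prev
    internal <- ids[levels == 2L]
    .with_substream(config$seed, 5L, {
      chosen <- leaves[stats::runif(length(leaves)) < config$cross_link_rate]
      for (l in chosen) {
        extra <- sample(setdiff(internal, parents[[l]]), 1L)
        parents[[l]] <- c(parents[[l]], extra)
      }
    })
  }
  load_ontology(data.frame(
    term_id = ids,
    label = ids,
    level = levels,
    parent_ids = vapply(parents, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE
  ))
}

# draw one integer uniformly from an inclusive range (safe for a == b,
# where sample() would misread a scalar as 1:a)
.draw_count <- function(range) {
  if (range[1] == range[2]) as.integer(range[1])
  else sample(seq(range[1], range[2]), 1L)
}

# leaves of a generated ontology, and a sibling lookup (same primary parent)
.leaves_of <- function(ontology) {
  ontology$terms$term_id[ontology$descendant_counts == 0L]
}

#' Generate a full synthetic study with planted gene-drug ground truth
#'
#' Samples gene trait profiles uniformly from ontology leaves; gives each
#' drug 1..T planted target genes whose traits are echoed (with probability
#' `copy_fraction`, sibling-swapped with probability `sibling_swap_prob`)
#' into its side-effect profile, plus Zipf-weighted unrelated noise side
#' effects drawn from leaves outside the echoed set; derives the implied
#' positive gene-drug labels, a synthetic PPI network connecting targets and
#' decoy proteins, and a known causal gene-side-effect set from a random
#' subset of planted pairs. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List of class `phenosim_study`: `ontology`, `gene_annotations` and
#'   `drug_annotations` (data.frames `entity_id`/`term_id`), `gene_corpus`,
#'   `drug_corpus`, `truth` (list with `planted_pairs` data.frame
#'   `drug_id`/`gene_id`, `targets` named list, `echoed` named list keyed
#'   `drug|gene`), `ppi` (data.frame `protein_a`/`protein_b`/`confidence`),
#'   `causal` (data.frame `gene_id`/`term_id`), `config`.
#' @export
generate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "phenosim_simconfig"))
  ontology <- generate_ontology(config)
  leaves <- .leaves_of(ontology)
  if (length(leaves) < config$traits_per_gene[2]) {
    stop("leaf pool too small for the requested trait profile size")
  }
  siblings <- lapply(leaves, function(l) {
    p <- ontology$parents[[l]][1]
    setdiff(ontology$terms$term_id[vapply(ontology$parents, function(x) p %in% x,
                                          logical(1))], l)
  })
  names(siblings) <- leaves

  genes <- sprintf("G%03d", seq_len(config$n_genes))
  drugs <- sprintf("D%03d", seq_len(config$n_drugs))

  # trait profiles spread over distinct leaf sibling groups where possible:
  # a knockout's phenotypes span different organ systems rather than
  # near-duplicate terms, and sibling co-traits would co-occur and so be
  # nullified by the co-occurrence weighting
  leaf_group <- vapply(leaves, function(l) ontology$parents[[l]][1], character(1))
  groups <- unique(leaf_group)
  gene_traits <- .with_substream(config$seed, 1L, {
    lapply(seq_len(config$n_genes), function(i) {
      k <- .draw_count(config$traits_per_gene)
      if (k <= length(groups)) {
        gs <- sample(groups, k)
        sort(vapply(gs, function(gp) {
          cand <- leaves[leaf_group == gp]
          if (length(cand) == 1L) cand else sample(cand, 1L)
        }, character(1), USE.NAMES = FALSE))
      } else {
        sort(sample(leaves, k))
      }
    })
  })
  names(gene_traits) <- genes

  # Zipf popularity order of leaves for noise sampling (study-wide)
  noise_order <- .with_substream(config$seed, 4L, sample(leaves))
  noise_w <- stats::setNames(1 / seq_along(noise_order)^config$noise_zipf,
                             noise_order)

  targets <- vector("list", config$n_drugs)
  echoed <- list()
  drug_terms <- vector("list", config$n_drugs)
  for (i in seq_len(config$n_drugs)) {
    .with_substream(config$seed, 1000L + i, {
      t_n <- .draw_count(config$targets_per_drug)
      tg <- sample(genes, t_n)
      targets[[i]] <- tg
      se <- character(0)
      for (g in tg) {
        traits <- gene_traits[[g]]
        keep <- traits[stats::runif(length(traits)) < config$copy_fraction]
        if (!length(keep) && config$copy_fraction > 0) keep <- sample(traits, 1L)
        ech <- vapply(keep, function(tr) {
          sib <- siblings[[tr]]
          if (length(sib) && stats::runif(1) < config$sibling_swap_prob) {
            sample(sib, 1L)
          } else tr
        }, character(1))
        echoed[[paste(drugs[i], g, sep = "|")]] <- unique(unname(ech))
        se <- union(se, ech)
      }
      pool <- setdiff(leaves, se)
      n_noise <- if (!is.null(config$drug_profile_size)) {
        max(config$drug_profile_size - length(se), 0L)
      } else .draw_count(config$noise_side_effects)
      n_noise <- min(n_noise, length(pool))
      if (n_noise > 0) {
        se <- union(se, sample(pool, n_noise, prob = noise_w[pool]))
      }
      if (!length(se)) se <- sample(leaves, 1L)
      drug_terms[[i]] <- sort(se)
    })
  }
  names(targets) <- drugs
  names(drug_terms) <- drugs

  gene_annotations <- data.frame(
    entity_id = rep(genes, lengths(gene_traits)),
    term_id = unlist(gene_traits, use.names = FALSE),
    stringsAsFactors = FALSE)
  drug_annotations <- data.frame(
    entity_id = rep(drugs, lengths(drug_terms)),
    term_id = unlist(drug_terms, use.names = FALSE),
    stringsAsFactors = FALSE)

  planted <- data.frame(
    drug_id = rep(drugs, lengths(targets)),
    gene_id = unlist(targets, use.names = FALSE),
    stringsAsFactors = FALSE)
  planted <- planted[order(planted$drug_id, planted$gene_id), , drop = FALSE]
  rownames(planted) <- NULL

  # synthetic PPI: targets wired to decoys, plus random background edges
  ppi <- .with_substream(config$seed, 2L, {
    decoys <- sprintf("X%03d", seq_len(config$n_decoy_proteins))
    edges <- do.call(rbind, lapply(genes, function(g) {
      data.frame(protein_a = g,
                 protein_b = sample(decoys, sample(1:3, 1L)),
                 stringsAsFactors = FALSE)
    }))
    nodes <- c(genes, decoys)
    extra <- data.frame(protein_a = sample(nodes, config$ppi_extra_edges, replace = TRUE),
                        protein_b = sample(nodes, config$ppi_extra_edges, replace = TRUE),
                        stringsAsFactors = FALSE)
    edges <- rbind(edges, extra[extra$protein_a != extra$protein_b, ])
    edges <- unique(edges)
    edges$confidence <- round(stats::runif(nrow(edges), 0.7, 1), 3)
    edges
  })

  causal <- .with_substream(config$seed, 3L, {
    keys <- names(echoed)
    chosen <- keys[stats::runif(length(keys)) < config$causal_pair_prob]
    if (!length(chosen)) {
      data.frame(gene_id = character(0), term_id = character(0))
    } else {
      do.call(rbind, lapply(chosen, function(k) {
        g <- strsplit(k, "|", fixed = TRUE)[[1]][2]
        terms <- echoed[[k]]
        if (!length(terms)) return(NULL)
        data.frame(gene_id = g, term_id = terms, stringsAsFactors = FALSE)
      }))
    }
  })
  if (is.null(causal)) causal <- data.frame(gene_id = character(0), term_id = character(0))

  structure(list(
    ontology = ontology,
    gene_annotations = gene_annotations,
    drug_annotations = drug_annotations,
    gene_corpus = load_corpus(gene_annotations, ontology, "gene"),
    drug_corpus = load_corpus(drug_annotations, ontology, "drug"),
    truth = list(planted_pairs = planted, targets = targets, echoed = echoed),
    ppi = ppi, causal = unique(causal), config = config
  ), class = "phenosim_study")
}

#' @export
print.phenosim_study <- function(x, ...) {
  cat("phenosim synthetic study: seed", x$config$seed, "-",
      x$ontology$n_terms, "terms,",
      x$config$n_genes, "genes,", x$config$n_drugs, "drugs,",
      nrow(x$truth$planted_pairs), "planted pairs\n")
  invisible(x)
}

#' Write a synthetic study to disk in the package's TSV dialects
#'
#' Emits `ontology.tsv`, `gene_annotations.tsv`, `drug_annotations.tsv`,
#' `positives.tsv`, `ppi.tsv`, `causal.tsv` and a `manifest.yaml` carrying
#' the configuration and seed. Identical seeds and configuration give
#' byte-identical files.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "phenosim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ontology_tsv(study$ontology, file.path(dir, "ontology.tsv"))
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(study$gene_annotations, "gene_annotations.tsv")
  wt(study$drug_annotations, "drug_annotations.tsv")
  wt(study$truth$planted_pairs, "positives.tsv")
  wt(study$ppi, "ppi.tsv")
  wt(study$causal, "causal.tsv")
  manifest <- list(
    generator = "phenosim synthetic study",
    config = lapply(unclass(study$config), function(x) if (is.numeric(x)) unname(x) else x),
    files = c("ontology.tsv", "gene_annotations.tsv", "drug_annotations.tsv",
              "positives.tsv", "ppi.tsv", "causal.tsv")
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
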