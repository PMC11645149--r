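# Composite signature scoring, clustering, group statistics, ROC-AUC
# refinement, perturbation recapitulation and over-representation analysis.

# Per-gene z-score across samples (sample sd, n-1); zero-variance genes
# contribute a row of zeros.
.zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  z <- (m - mu) / sd
  z[sd == 0, ] <- 0
  z
}

.composite <- function(values, genes, context = "signature") {
  present <- intersect(genes, rownames(values))
  if (length(present) == 0L)
    stop("no ", context, " gene present in the matrix", call. = FALSE)
  dropped <- setdiff(genes, present)
  if (length(dropped) > 0L)
    message(length(dropped), " ", context, " gene(s) absent from matrix, skipped")
  z <- .zscore_rows(values[present, , drop = FALSE])
  colMeans(z)
}

#' Composite signature score per sample
#'
#' Each signature gene is z-scored across samples (sample standard
#' deviation; zero-variance genes contribute 0); a sample's score is the
#' unweighted mean of the available gene z-scores. Signature genes absent
#' from the matrix are skipped with a message.
#'
#' @param mat log2cpm-scale [ExpressionMatrix].
#' @param sig A [gene_set].
#' @return Data frame of class `SignatureScoreSet` with columns
#'   `sample_id`, `score`, `group` (the sample's condition label);
#'   attribute `signature` holds the set name.
#' @export
composite_score <- function(mat, sig) {
  .assert(inherits(mat, "ExpressionMatrix"), "mat must be an ExpressionMatrix")
  sc <- .composite(mat$values, .as_genes(sig))
  out <- data.frame(sample_id = colnames(mat$values), score = unname(sc),
                    group = mat$annotations$condition,
                    stringsAsFactors = FALSE)
  attr(out, "signature") <- if (inherits(sig, "GeneSet")) sig$name else "signature"
  class(out) <- c("SignatureScoreSet", "data.frame")
  out
}

#' Hierarchical clustering of samples on signature-gene z-scores
#'
#' Agglomerative (average-linkage, UPGMA) clustering of samples over the
#' z-scored signature genes. The default distance is Euclidean on the
#' z-scores: a signature panel moves largely in one direction, so the
#' group signal lives in the magnitude of the common shift, which
#' column-centered correlation distance cancels. `distance = "pearson"`
#' (1 - Pearson between sample profiles) is available for shape-based
#' clustering. Ties are resolved deterministically by input sample order
#' (the behavior of [stats::hclust] on a fixed input ordering).
#'
#' @param mat An [ExpressionMatrix] with at least two samples.
#' @param sig A [gene_set].
#' @param k Number of flat clusters to cut (default 2).
#' @param distance `"euclidean"` (default) or `"pearson"`.
#' @return List with `hclust` (the tree), `clusters` (named integer
#'   vector), and `newick` (the dendrogram serialized as a Newick string).
#' @export
hierarchical_cluster <- function(mat, sig, k = 2L,
                                 distance = c("euclidean", "pearson")) {
  distance <- match.arg(distance)
  .assert(ncol(mat$values) >= 2L, "need at least two samples to cluster")
  present <- intersect(.as_genes(sig), rownames(mat$values))
  .assert(length(present) > 0L, "no signature gene present in the matrix")
  z <- .zscore_rows(mat$values[present, , drop = FALSE])
  if (distance == "pearson") {
    z <- z[apply(z, 1L, stats::sd) > 0, , drop = FALSE]
    .assert(nrow(z) >= 2L, "need >= 2 informative signature genes to correlate")
    co <- suppressWarnings(stats::cor(z))
    co[!is.finite(co)] <- 0
    d <- stats::as.dist(1 - co)
  } else {
    d <- stats::dist(t(z))
  }
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc,
       clusters = stats::cutree(hc, k = k),
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param scores A `SignatureScoreSet` (or any data frame with `score` and
#'   `group` columns); needs >= 2 groups with >= 2 samples each.
#' @return List with `F`, `p`, and `pairwise` (data frame `comparison`,
#'   `diff`, `adj_p`). When residual variance is exactly zero but group
#'   means differ, `p` is reported as the smallest representable double and
#'   pairwise comparisons with unequal means likewise.
#' @export
anova_tukey <- function(scores) {
  g <- factor(scores$group)
  y <- scores$score
  .assert(nlevels(g) >= 2L, "need at least two groups")
  .assert(all(table(g) >= 2L), "every group needs >= 2 samples")
  grand <- mean(y)
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  pairs_ <- utils::combn(levels(g), 2L)
  comparison <- paste(pairs_[2L, ], pairs_[1L, ], sep = "-")
  diffs <- apply(pairs_, 2L, function(pr) mean(y[g == pr[2L]]) - mean(y[g == pr[1L]]))
  eps <- 1e-12 * max(1, sum((y - grand)^2))
  if (ss_between <= eps) {
    return(list(F = 0, p = 1,
                pairwise = data.frame(comparison = comparison, diff = diffs,
                                      adj_p = rep(1, length(diffs)))))
  }
  if (ss_within <= eps) {
    adj <- ifelse(abs(diffs) > sqrt(eps), .Machine$double.xmin, 1)
    return(list(F = Inf, p = .Machine$double.xmin,
                pairwise = data.frame(comparison = comparison, diff = diffs,
                                      adj_p = adj)))
  }
  fit <- stats::aov(y ~ g)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$g
  list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
       pairwise = data.frame(comparison = rownames(tk),
                             diff = tk[, "diff"],
                             adj_p = tk[, "p adj"],
                             row.names = NULL))
}

#' ROC AUC of a score separating two groups
#'
#' Computed through the Mann-Whitney U identity on ranks; ties count 0.5.
#'
#' @param values_pos Scores of the positive class (non-empty).
#' @param values_neg Scores of the negative class (non-empty).
#' @return AUC in `[0, 1]`: the probability a random positive exceeds a
#'   random negative.
#' @export
roc_auc <- function(values_pos, values_neg) {
  .assert(length(values_pos) > 0L && length(values_neg) > 0L,
          "both groups must be non-empty")
  np <- length(values_pos); nn <- length(values_neg)
  r <- rank(c(values_pos, values_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Per-gene ROC AUC table for one labeled dataset
#'
#' @param mat An [ExpressionMatrix].
#' @param pos_samples,neg_samples Sample ids of the two classes.
#' @param genes Genes to evaluate (default: all genes in `mat`).
#' @param dataset Label recorded in the output.
#' @return Data frame with columns `gene`, `auc`, `dataset`.
#' @export
auc_table <- function(mat, pos_samples, neg_samples, genes = NULL,
                      dataset = "dataset") {
  genes <- intersect(.as_genes(genes %||% rownames(mat$values)),
                     rownames(mat$values))
  P <- mat$values[genes, pos_samples, drop = FALSE]
  N <- mat$values[genes, neg_samples, drop = FALSE]
  auc <- vapply(seq_along(genes),
                function(i) roc_auc(P[i, ], N[i, ]), numeric(1L))
  data.frame(gene = genes, auc = auc, dataset = dataset,
             stringsAsFactors = FALSE)
}

#' Cross-dataset refinement of candidates by per-gene ROC AUC
#'
#' Keeps candidates whose per-gene AUC (positive class above negative)
#' exceeds `threshold` in every supplied dataset. Candidates absent from
#' any dataset are excluded with a warning.
#'
#' @param candidates [gene_set] of candidate genes.
#' @param datasets List of datasets, each a list with elements `mat`
#'   ([ExpressionMatrix]), `pos` and `neg` (sample-id vectors; e.g. contact
#'   vs monoculture samples).
#' @param threshold Strict AUC cutoff in `(0.5, 1]` (default 0.85).
#' @return A [gene_set] of retained genes; attribute `auc` holds the full
#'   per-dataset AUC table.
#' @export
refine_by_auc <- function(candidates, datasets, threshold = 0.85) {
  .assert(length(datasets) >= 1L, "need at least one validation dataset")
  .assert(threshold > 0.5 && threshold <= 1, "threshold must be in (0.5, 1]")
  cand <- .as_genes(candidates)
  tabs <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    auc_table(d$mat, d$pos, d$neg, genes = cand,
              dataset = d$name %||% paste0("dataset", i))
  })
  all_auc <- do.call(rbind, tabs)
  counts <- table(all_auc$gene)
  absent <- setdiff(cand, names(counts)[counts == length(datasets)])
  if (length(absent) > 0L)
    warning(length(absent), " candidate(s) absent from >=1 dataset, excluded")
  evaluable <- setdiff(cand, absent)
  passes <- tapply(all_auc$auc > threshold, all_auc$gene, all)
  kept <- evaluable[unname(passes[evaluable])]
  out <- gene_set("auc_refined", kept,
                  description = sprintf("AUC>%g in all %d datasets",
                                        threshold, length(datasets)))
  attr(out, "auc") <- all_auc
  out
}

#' Fraction of each triage bin recapitulated by a perturbation
#'
#' For each gene in the borrowed and intrinsic bins, computes the per-gene
#' ROC AUC separating perturbed from control samples; genes reaching
#' `auc_threshold` (default 1, "perfect classification") are counted as
#' recapitulated.
#'
#' @param mat [ExpressionMatrix] holding control and perturbed samples.
#' @param control_samples,perturbed_samples Sample-id vectors.
#' @param partition A `TriagePartition`.
#' @param auc_threshold Inclusive AUC cutoff (default 1.0).
#' @return List with `recap_borrowed`, `recap_intrinsic` gene sets and
#'   `fractions` (named numeric; `NA` for an empty bin).
#' @export
recapitulation_fraction <- function(mat, control_samples, perturbed_samples,
                                    partition, auc_threshold = 1.0) {
  recap_bin <- function(bin) {
    genes <- intersect(bin$genes, rownames(mat$values))
    if (length(genes) == 0L) return(character())
    tab <- auc_table(mat, perturbed_samples, control_samples, genes = genes)
    tab$gene[tab$auc >= auc_threshold]
  }
  rb <- recap_bin(partition$borrowed)
  ri <- recap_bin(partition$intrinsic)
  frac <- function(hit, bin) {
    if (length(bin$genes) == 0L) NA_real_ else length(hit) / length(bin$genes)
  }
  list(recap_borrowed = gene_set("recap_borrowed", rb),
       recap_intrinsic = gene_set("recap_intrinsic", ri),
       fractions = c(borrowed = frac(rb, partition$borrowed),
                     intrinsic = frac(ri, partition$intrinsic)))
}

#' Over-representation analysis against gene-set collections
#'
#' Upper-tail hypergeometric test of the overlap between a query set and
#' each collection set, within a stated gene universe; BH adjustment across
#' collections. Query genes outside the universe are dropped with a
#' warning.
#'
#' @param query A [gene_set].
#' @param collections List of [gene_set]s.
#' @param universe A [gene_set] (or character) defining the background.
#' @return Data frame with columns `set`, `set_k`, `overlap_k`, `p`,
#'   `adj_p`, ordered as supplied.
#' @export
ora_enrichment <- function(query, collections, universe) {
  uni <- .as_genes(universe)
  .assert(length(uni) > 0L, "universe is empty")
  q <- .as_genes(query)
  outside <- setdiff(q, uni)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe, dropped")
    q <- intersect(q, uni)
  }
  if (inherits(collections, "GeneSet")) collections <- list(collections)
  rows <- lapply(collections, function(s) {
    sk <- intersect(.as_genes(s), uni)
    k <- length(intersect(sk, q))
    data.frame(set = s$name, set_k = length(sk), overlap_k = k,
               p = hypergeom_upper(k, length(q), length(sk), length(uni)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out
}
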