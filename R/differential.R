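# Two-group differential expression on log2-CPM with BH adjustment.
# The DEG engine is a vectorized Welch unequal-variance t test per gene,
# the standard triage workhorse for small-replicate bulk designs.

#' Normalize raw counts to log2 counts-per-million
#'
#' `log2(count / library_size * 1e6 + pseudocount)` per cell, where
#' `library_size` is the sample's column sum.
#'
#' @param mat Counts-scale [ExpressionMatrix].
#' @param pseudocount Positive offset added before the log (default 1).
#' @return A log2cpm-scale [ExpressionMatrix].
#' @export
normalize_log2cpm <- function(mat, pseudocount = 1) {
  .assert(inherits(mat, "ExpressionMatrix") && mat$scale == "counts",
          "normalize_log2cpm expects a counts-scale ExpressionMatrix")
  .assert(pseudocount > 0, "pseudocount must be > 0")
  libs <- colSums(mat$values)
  if (any(libs == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(mat$values)[libs == 0], collapse = ", "), call. = FALSE)
  v <- log2(sweep(mat$values, 2L, libs, "/") * 1e6 + pseudocount)
  ExpressionMatrix(v, mat$annotations, scale = "log2cpm")
}

#' Two-group differential expression on log2-CPM
#'
#' `log2_fc = mean(group_b) - mean(group_a)` (pass the reference/control
#' group as `group_a`). Two ranking engines are available:
#' * `"moderated"` (default): limma linear fit with empirical-Bayes
#'   variance moderation, which pools information across genes and is the
#'   appropriate choice at the 2-3 replicates typical of co-culture
#'   designs.
#' * `"welch"`: per-gene Welch unequal-variance t test, dependency-free
#'   and exactly reproducible by hand; underpowered at very small n
#'   because each gene's variance is estimated from its own few
#'   replicates.
#'
#' P-values are BH-adjusted across genes. With a single replicate in
#' either group only the fold change is meaningful and p is set to 1
#' (flagged `single_replicate`); under `"welch"`, genes with zero variance
#' in both groups and unequal means are flagged `degenerate_variance` with
#' p set to the smallest representable double.
#'
#' @param mat log2cpm-scale [ExpressionMatrix].
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @param method `"moderated"` or `"welch"`.
#' @return A data frame of class `DEResult` with columns `gene`, `log2_fc`,
#'   `p_value`, `adj_p`, `mean_a`, `mean_b`, `flag`.
#' @export
de_test <- function(mat, group_a, group_b,
                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  .assert(inherits(mat, "ExpressionMatrix") && mat$scale == "log2cpm",
          "de_test expects a log2cpm-scale ExpressionMatrix")
  all_s <- colnames(mat$values)
  unknown <- setdiff(c(group_a, group_b), all_s)
  if (length(unknown) > 0L)
    stop("unknown sample(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  ov <- intersect(group_a, group_b)
  if (length(ov) > 0L)
    stop("groups overlap in sample(s): ", paste(ov, collapse = ", "),
         call. = FALSE)
  A <- mat$values[, group_a, drop = FALSE]
  B <- mat$values[, group_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  .assert(na >= 1L && nb >= 1L, "each group needs at least one sample")
  ma <- rowMeans(A); mb <- rowMeans(B)
  lfc <- mb - ma
  flag <- rep("", nrow(A))
  if (na < 2L || nb < 2L) {
    p <- rep(1, nrow(A))
    flag[] <- "single_replicate"
  } else if (method == "moderated") {
    grp <- factor(rep(c("a", "b"), c(na, nb)), levels = c("a", "b"))
    design <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(cbind(A, B), design))
    p <- fit$p.value[, 2L]
    p[!is.finite(p)] <- 1
  } else {
    va <- rowSums((A - ma)^2) / (na - 1)
    vb <- rowSums((B - mb)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    tstat <- lfc / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    zero <- se2 == 0
    p[zero & lfc == 0] <- 1
    degen <- zero & lfc != 0
    p[degen] <- .Machine$double.xmin
    flag[degen] <- "degenerate_variance"
  }
  res <- data.frame(gene = rownames(mat$values), log2_fc = lfc,
                    p_value = p, adj_p = bh_adjust(p),
                    mean_a = ma, mean_b = mb, flag = flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output order matches input
#' order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  .assert(all(is.finite(p_values)) && all(p_values >= 0 & p_values <= 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Threshold a DE result into a gene set
#'
#' Keeps genes with `adj_p < adj_p_max` whose fold change meets the
#' direction: `up` requires `log2_fc >= lfc_min`, `down` requires
#' `log2_fc <= -lfc_min`, `both` requires `|log2_fc| >= lfc_min`.
#'
#' @param res A `DEResult` from [de_test].
#' @param lfc_min Minimum absolute log2 fold change (default 2).
#' @param adj_p_max Exclusive adjusted-p cutoff (default 0.05).
#' @param direction One of `"up"`, `"down"`, `"both"`.
#' @param name Name for the resulting set.
#' @return A [gene_set].
#' @export
filter_deg <- function(res, lfc_min = 2, adj_p_max = 0.05,
                       direction = c("up", "down", "both"), name = "DEG") {
  direction <- match.arg(direction)
  .assert(lfc_min >= 0 && adj_p_max >= 0, "thresholds must be non-negative")
  keep <- switch(direction,
                 up = res$log2_fc >= lfc_min,
                 down = res$log2_fc <= -lfc_min,
                 both = abs(res$log2_fc) >= lfc_min)
  keep <- keep & res$adj_p < adj_p_max
  gene_set(name, res$gene[keep],
           description = sprintf("|log2FC|>=%g, adjP<%g, %s",
                                 lfc_min, adj_p_max, direction))
}

#' Write a DE table as TSV, with a pass/fail column at given thresholds
#' @param res A `DEResult`.
#' @param path Output path.
#' @param lfc_min,adj_p_max Thresholds recorded in `passed_filter`.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(res, path, lfc_min = 2, adj_p_max = 0.05) {
  out <- res
  out$passed_filter <- abs(out$log2_fc) >= lfc_min & out$adj_p < adj_p_max
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
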