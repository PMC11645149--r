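# Typed containers and readers/writers for every external artifact.
# All downstream modules consume these validated in-memory objects only.

#' Expression matrix with sample annotations
#'
#' A gene-by-sample numeric matrix plus a per-sample annotation table.
#' Gene identifiers are uppercase HGNC-style symbols; duplicate symbols are
#' collapsed at load time (summed on the counts scale, max-collapsed on the
#' log scale). The `scale` tag records whether values are raw counts or
#' log2 counts-per-million.
#'
#' @param values Numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample ids).
#' @param annotations Data frame with one row per sample; must contain a
#'   `condition` column, optionally `cell_line` and `batch`. Row names (or a
#'   `sample_id` column) identify the sample.
#' @param scale Either `"counts"` (non-negative raw counts) or `"log2cpm"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `annotations`, `scale`.
#' @export
ExpressionMatrix <- function(values, annotations, scale = c("counts", "log2cpm")) {
  scale <- match.arg(scale)
  .assert(is.matrix(values) && is.numeric(values),
          "values must be a numeric matrix")
  rownames(values) <- .up(rownames(values))
  .assert(!anyDuplicated(rownames(values)),
          "duplicate gene ids in expression matrix after uppercasing")
  .assert(!anyDuplicated(colnames(values)), "duplicate sample ids")
  if (!is.null(annotations$sample_id)) {
    rownames(annotations) <- annotations$sample_id
    annotations$sample_id <- NULL
  }
  missing <- setdiff(colnames(values), rownames(annotations))
  if (length(missing) > 0L)
    stop("missing annotation for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  annotations <- annotations[colnames(values), , drop = FALSE]
  .assert("condition" %in% names(annotations),
          "annotations must contain a 'condition' column")
  for (col in c("cell_line", "batch"))
    if (is.null(annotations[[col]])) annotations[[col]] <- NA_character_
  .assert(all(is.finite(values)), "expression values must be finite")
  if (scale == "counts")
    .assert(all(values >= 0), "counts-scale values must be >= 0")
  structure(list(values = values, annotations = annotations, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(table(x$annotations$condition)),
                    table(x$annotations$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Genes of an ExpressionMatrix
#' @param mat An `ExpressionMatrix`.
#' @return Character vector of gene symbols.
#' @export
em_genes <- function(mat) rownames(mat$values)

#' Samples of an ExpressionMatrix, optionally restricted to a condition
#' @param mat An `ExpressionMatrix`.
#' @param condition Optional condition label to filter on.
#' @return Character vector of sample ids.
#' @export
em_samples <- function(mat, condition = NULL) {
  s <- colnames(mat$values)
  if (is.null(condition)) return(s)
  s[mat$annotations$condition %in% condition]
}

#' Named gene set
#'
#' @param name Non-empty set name.
#' @param genes Character vector of gene symbols (uppercased, deduplicated).
#' @param description Free-text description.
#' @return An object of class `GeneSet` with elements `name`, `genes`,
#'   `description`.
#' @export
gene_set <- function(name, genes, description = "") {
  .assert(is.character(name) && nzchar(name), "gene set name must be non-empty")
  genes <- unique(.up(genes))
  genes <- genes[nzchar(genes)]
  structure(list(name = name, genes = genes, description = description),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$genes)

.as_genes <- function(x) {
  if (inherits(x, "GeneSet")) x$genes else unique(.up(x))
}

#' Undirected protein-interaction edge table
#'
#' Canonicalizes an edge list: symbols uppercased, self-loops dropped with a
#' warning, symmetric duplicates merged keeping the maximum confidence, and
#' edges stored with `a < b` lexicographically.
#'
#' @param a,b Character vectors of interacting symbols.
#' @param confidence Numeric confidence in `[0, 1]`.
#' @return Data frame of class `EdgeTable` with columns `a`, `b`,
#'   `confidence`.
#' @export
edge_table <- function(a, b, confidence) {
  a <- .up(a); b <- .up(b)
  confidence <- as.numeric(confidence)
  .assert(all(is.finite(confidence)) && all(confidence >= 0 & confidence <= 1),
          "edge confidence must lie in [0, 1]")
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped")
    a <- a[!loops]; b <- b[!loops]; confidence <- confidence[!loops]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (length(key) > 0L) {
    conf <- tapply(confidence, key, max)
    parts <- strsplit(names(conf), "\r", fixed = TRUE)
    out <- data.frame(a = vapply(parts, `[`, "", 1L),
                      b = vapply(parts, `[`, "", 2L),
                      confidence = as.numeric(conf),
                      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(out$a, out$b), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(a = character(), b = character(),
                      confidence = numeric(), stringsAsFactors = FALSE)
  }
  class(out) <- c("EdgeTable", "data.frame")
  out
}

#' Patient cohort with survival outcomes and expression
#'
#' @param patients Data frame with columns `patient_id`, `time`
#'   (non-negative, months), `event` (0/1).
#' @param expression Numeric matrix, genes x patients (colnames must match
#'   `patient_id`).
#' @return An object of class `CohortTable`.
#' @export
cohort_table <- function(patients, expression) {
  .assert(all(c("patient_id", "time", "event") %in% names(patients)),
          "patients needs columns patient_id, time, event")
  .assert(all(patients$time >= 0), "survival times must be >= 0")
  .assert(all(patients$event %in% c(0, 1)), "event indicator must be 0/1")
  .assert(!anyDuplicated(patients$patient_id), "duplicate patient ids")
  rownames(expression) <- .up(rownames(expression))
  .assert(identical(sort(colnames(expression)), sort(as.character(patients$patient_id))),
          "expression columns must match patient ids")
  expression <- expression[, as.character(patients$patient_id), drop = FALSE]
  structure(list(patients = patients, expression = expression),
            class = "CohortTable")
}

# ---- readers ---------------------------------------------------------------

#' Read an expression table plus sample annotations
#'
#' The expression file has gene symbols in the first column and one column
#' per sample; the annotation file maps every sample to at least a
#' `condition` label. Delimiters (tab or comma) are sniffed. Duplicate gene
#' rows are collapsed: summed on the counts scale, max-collapsed on the log
#' scale, with a warning.
#'
#' @param path Expression table (TSV/CSV).
#' @param annotation_path Annotation table (TSV/CSV) with a `sample_id`
#'   column (or sample ids as first column) and a `condition` column.
#' @param scale `"counts"` or `"log2cpm"` (caller-declared).
#' @return An [ExpressionMatrix].
#' @export
read_expression <- function(path, annotation_path, scale = c("counts", "log2cpm")) {
  scale <- match.arg(scale)
  tab <- .read_delim(path)
  .assert(ncol(tab) >= 2L, "expression table needs a gene column plus samples")
  genes <- .up(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(sprintf("non-numeric expression value '%s' at row %d, column '%s'",
                   v[bad], bad, names(vals)[j]), call. = FALSE)
    }
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric expression value 'NA' at row %d, column '%s'",
                   bad, names(vals)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    warning("collapsing ", sum(duplicated(genes)), " duplicate gene row(s) by ",
            if (scale == "counts") "sum" else "max")
    f <- factor(genes, levels = unique(genes))
    m <- do.call(rbind, lapply(split(seq_along(genes), f), function(i) {
      blk <- m[i, , drop = FALSE]
      if (scale == "counts") colSums(blk) else apply(blk, 2L, max)
    }))
    rownames(m) <- levels(f)
  }
  ann <- .read_delim(annotation_path)
  if (!"sample_id" %in% names(ann)) names(ann)[1L] <- "sample_id"
  ann$sample_id <- as.character(ann$sample_id)
  ExpressionMatrix(m, ann, scale = scale)
}

#' Write an ExpressionMatrix (and its annotations) to TSV
#' @param mat An [ExpressionMatrix].
#' @param path Output path for the expression table.
#' @param annotation_path Optional output path for the annotation table.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, annotation_path = NULL) {
  df <- data.frame(gene = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- data.frame(sample_id = rownames(mat$annotations), mat$annotations,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then genes. Duplicate genes within a line are deduplicated.
#'
#' @param path GMT file.
#' @return List of [gene_set] objects, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(f)), call. = FALSE)
    out[[i]] <- gene_set(f[1L], f[-c(1L, 2L)], description = f[2L])
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets A [gene_set] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  empty <- vapply(sets, function(s) length(s$genes) == 0L, TRUE)
  if (any(empty)) {
    warning("skipping empty gene set(s): ",
            paste(vapply(sets[empty], function(s) s$name, ""), collapse = ", "))
    sets <- sets[!empty]
  }
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else ".", s$genes),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-style interaction edge table
#'
#' Expects columns `protein1`, `protein2`, `combined_score`. Scores may be
#' on STRING's 0-1000 convention or already in `[0, 1]`; any score above 1
#' triggers division of all scores by 1000. Self-loops are dropped with a
#' warning; symmetric duplicates are merged keeping the maximum confidence;
#' edges below `min_confidence` are removed.
#'
#' @param path TSV/CSV edge file.
#' @param min_confidence Minimum retained confidence (default 0).
#' @return An [edge_table].
#' @export
read_edge_table <- function(path, min_confidence = 0) {
  tab <- .read_delim(path)
  need <- c("protein1", "protein2", "combined_score")
  .assert(all(need %in% names(tab)),
          "edge table needs columns protein1, protein2, combined_score")
  score <- as.numeric(tab$combined_score)
  .assert(all(is.finite(score)), "non-numeric combined_score")
  if (any(score > 1)) score <- score / 1000
  et <- edge_table(tab$protein1, tab$protein2, score)
  et[et$confidence >= min_confidence, , drop = FALSE]
}

#' Write an EdgeTable in STRING-export style
#' @param edges An [edge_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  out <- data.frame(protein1 = edges$a, protein2 = edges$b,
                    combined_score = edges$confidence)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a patient cohort CSV
#'
#' Columns: `patient_id`, `time`, `event`, then one column per gene.
#'
#' @param path CSV/TSV cohort file.
#' @return A [cohort_table].
#' @export
read_cohort <- function(path) {
  tab <- .read_delim(path)
  need <- c("patient_id", "time", "event")
  .assert(all(need %in% names(tab)),
          "cohort table needs columns patient_id, time, event")
  expr_cols <- setdiff(names(tab), need)
  .assert(length(expr_cols) > 0L, "cohort table has no expression columns")
  expr <- t(as.matrix(tab[, expr_cols, drop = FALSE]))
  colnames(expr) <- as.character(tab$patient_id)
  cohort_table(tab[, need], expr)
}

#' Write a cohort to CSV
#' @param cohort A [cohort_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cbind(cohort$patients,
               as.data.frame(t(cohort$expression), check.names = FALSE))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration (YAML or JSON)
#' @param path Config file; `.json` is parsed as JSON, anything else as YAML.
#' @return Nested list of settings.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
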