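# Three-way triage of contact-induced molecules.
#
# The co-culture design has four arms: donor (stromal) monoculture,
# recipient (tumor) monoculture, recipient contact culture, recipient
# conditioned-media culture. Molecules induced in the recipient by contact
# are partitioned by whether the donor expresses them highly:
#   borrowed  = induced in contact AND high in donor  (candidate transfer)
#   intrinsic = induced in contact, NOT high in donor (recipient's response)
#   cm_unique = induced by conditioned media only     (soluble-factor route)

#' Catalog of genes expressed highly in the donor but not the recipient
#'
#' Filters a donor-vs-recipient monoculture DE result for genes upregulated
#' in the donor. This catalog is the denominator of candidate transferable
#' molecules: everything a recipient cell lacks but could acquire.
#'
#' @param de_donor_vs_recipient `DEResult` from [de_test] with the recipient
#'   monoculture as `group_a` and the donor monoculture as `group_b` (so
#'   positive `log2_fc` means donor-high).
#' @param lfc_min,adj_p_max Thresholds as in [filter_deg].
#' @return A [gene_set] named `"msc_high"`; empty results warn.
#' @export
build_msc_high_catalog <- function(de_donor_vs_recipient, lfc_min = 2,
                                   adj_p_max = 0.05) {
  gs <- filter_deg(de_donor_vs_recipient, lfc_min, adj_p_max,
                   direction = "up", name = "msc_high")
  if (length(gs$genes) == 0L)
    warning("donor-high catalog is empty at the given thresholds")
  gs
}

#' Merge RNA- and protein-level induction evidence
#'
#' Unions the two evidence sets and records per-gene provenance
#' (`rna`, `protein`, or `both`).
#'
#' @param rna,protein [gene_set]s of induced genes from each platform.
#' @return List with `genes` (a [gene_set] named `"induced"`) and
#'   `provenance` (named character vector).
#' @export
union_evidence <- function(rna, protein) {
  r <- .as_genes(rna); p <- .as_genes(protein)
  all <- union(r, p)
  prov <- ifelse(all %in% r & all %in% p, "both",
                 ifelse(all %in% r, "rna", "protein"))
  names(prov) <- all
  list(genes = gene_set("induced", all), provenance = prov)
}

#' Partition contact-induced molecules into borrowed / intrinsic / CM bins
#'
#' Given the union of contact-culture inductions (`up_cc`), the
#' conditioned-media inductions (`up_cm`) and the donor-high catalog,
#' computes:
#' * `borrowed  = up_cc` intersected with `msc_high`
#' * `intrinsic = up_cc` minus `msc_high`
#' * `cm_unique = up_cm` minus `up_cc`
#'
#' Genes induced in both contact culture and conditioned media stay in
#' their contact-derived bin and are flagged `cm_shared` rather than being
#' excluded.
#'
#' @param up_cc [gene_set] (or character) of contact-culture inductions
#'   (union of RNA and protein evidence).
#' @param up_cm [gene_set] of conditioned-media inductions.
#' @param msc_high Donor-high catalog from [build_msc_high_catalog].
#' @param provenance Optional named character vector (gene ->
#'   `"rna"`/`"protein"`/`"both"`) from [union_evidence].
#' @return An object of class `TriagePartition`: list with `msc_high`,
#'   `borrowed`, `intrinsic`, `cm_unique` gene sets, the `cm_shared` flag
#'   vector and the `provenance` map.
#' @export
classify_induced <- function(up_cc, up_cm, msc_high, provenance = NULL) {
  cc <- .as_genes(up_cc); cm <- .as_genes(up_cm); hi <- .as_genes(msc_high)
  part <- structure(list(
    msc_high = gene_set("msc_high", hi),
    borrowed = gene_set("borrowed", intersect(cc, hi)),
    intrinsic = gene_set("intrinsic", setdiff(cc, hi)),
    cm_unique = gene_set("cm_unique", setdiff(cm, cc)),
    cm_shared = intersect(cc, cm),
    provenance = provenance %||% stats::setNames(rep("rna", length(cc)), cc)
  ), class = "TriagePartition")
  validate_partition(part)
  part
}

#' Assert the structural invariants of a TriagePartition
#' @param part A `TriagePartition`.
#' @return `part`, invisibly; errors if any invariant fails.
#' @export
validate_partition <- function(part) {
  b <- part$borrowed$genes; i <- part$intrinsic$genes
  .assert(length(intersect(b, i)) == 0L, "borrowed and intrinsic overlap")
  .assert(all(b %in% part$msc_high$genes), "borrowed not within donor catalog")
  .assert(length(intersect(i, part$msc_high$genes)) == 0L,
          "intrinsic genes found in donor catalog")
  invisible(part)
}

#' @export
print.TriagePartition <- function(x, ...) {
  cat(sprintf(paste0("TriagePartition: %d donor-high / %d borrowed / ",
                     "%d intrinsic / %d CM-unique (%d CM-shared flagged)\n"),
              length(x$msc_high$genes), length(x$borrowed$genes),
              length(x$intrinsic$genes), length(x$cm_unique$genes),
              length(x$cm_shared)))
  invisible(x)
}

#' Genes induced on both the RNA and the protein platform
#'
#' @param rna_borrowed,protein_borrowed [gene_set]s derived from the same
#'   contact-culture comparison on each platform.
#' @param name Name for the intersection set.
#' @return A [gene_set] with provenance `"both"` recorded in its
#'   description.
#' @export
cross_platform_overlap <- function(rna_borrowed, protein_borrowed,
                                   name = "rna_protein_overlap") {
  gene_set(name,
           intersect(.as_genes(rna_borrowed), .as_genes(protein_borrowed)),
           description = "provenance=both")
}

#' Export a TriagePartition as GMT plus a per-gene TSV
#' @param part A `TriagePartition`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
export_partition <- function(part, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gmt(list(part$msc_high, part$borrowed, part$intrinsic, part$cm_unique),
            file.path(dir, "triage_partition.gmt"))
  rows <- rbind(
    data.frame(gene = part$borrowed$genes,
               bin = rep("borrowed", length(part$borrowed$genes))),
    data.frame(gene = part$intrinsic$genes,
               bin = rep("intrinsic", length(part$intrinsic$genes))),
    data.frame(gene = part$cm_unique$genes,
               bin = rep("cm_unique", length(part$cm_unique$genes))))
  rows$provenance <- unname(part$provenance[rows$gene])
  rows$provenance[is.na(rows$provenance)] <- "rna"
  rows$cm_shared <- rows$gene %in% part$cm_shared
  utils::write.table(rows, file.path(dir, "triage_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
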