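# Synthetic-data generators with planted ground truth.
#
# The generators emulate the four-arm co-culture design: a donor (stromal)
# population expressing a planted "transfer" gene set highly, a recipient
# (tumor) population lacking it, contact-culture recipients acquiring the
# transfer set plus a distinct intrinsic response, and conditioned-media
# recipients acquiring almost nothing. Counts are negative-binomial; the
# proteome layer applies abundance-biased detection dropout; the cohort
# ties hazard to a latent signature state. Every generator is a pure
# function of (truth, size parameters); all randomness derives from
# `truth$seed` plus a fixed per-generator offset, so the caller's RNG
# stream is never disturbed.

#' Define the planted ground truth of a simulation
#'
#' @param n_genes Total genes in the universe.
#' @param n_transfer,n_intrinsic,n_cm Sizes of the planted transfer,
#'   intrinsic-response and conditioned-media gene sets (pairwise
#'   disjoint).
#' @param lfc_transfer Log2 fold change of transfer genes in
#'   contact-cultured recipients over recipient monoculture.
#' @param lfc_intrinsic Log2 fold change of intrinsic (and CM) inductions.
#' @param donor_extra_lfc Additional log2 excess of transfer genes in the
#'   donor over the contact-culture level; donors express transfer genes
#'   highly while recipients lack them, so the donor-vs-recipient contrast
#'   is stronger than the contact-induction contrast.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param proteome_detection List with `midpoint` and `slope` of the
#'   logistic detection model in log2 mean-abundance units.
#' @param cohort List with `hazard_ratio` (high- vs low-signature state)
#'   and `censoring_rate` (expected censored fraction).
#' @param seed Integer master seed recorded in every output.
#' @return An object of class `SimulationTruth` with the planted gene-name
#'   vectors `transfer_genes`, `intrinsic_genes`, `cm_genes`.
#' @export
simulation_truth <- function(n_genes = 2000L, n_transfer = 150L,
                             n_intrinsic = 80L, n_cm = 10L,
                             lfc_transfer = 2.5, lfc_intrinsic = 2.5,
                             donor_extra_lfc = 2, nb_dispersion = 0.1,
                             proteome_detection = list(midpoint = 6, slope = 1),
                             cohort = list(hazard_ratio = 2,
                                           censoring_rate = 0.4),
                             seed = 7L) {
  n_planted <- n_transfer + n_intrinsic + n_cm
  .assert(n_genes >= n_planted + 100L,
          "n_genes must exceed the planted sets by at least 100")
  .assert(lfc_transfer > 0 && lfc_intrinsic > 0, "planted lfc must be > 0")
  gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
  structure(list(
    n_genes = n_genes,
    transfer_genes = gene_ids[seq_len(n_transfer)],
    intrinsic_genes = gene_ids[n_transfer + seq_len(n_intrinsic)],
    cm_genes = gene_ids[n_transfer + n_intrinsic + seq_len(n_cm)],
    gene_ids = gene_ids,
    lfc_transfer = lfc_transfer, lfc_intrinsic = lfc_intrinsic,
    donor_extra_lfc = donor_extra_lfc, nb_dispersion = nb_dispersion,
    proteome_detection = proteome_detection, cohort = cohort,
    seed = as.integer(seed)), class = "SimulationTruth")
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat(sprintf(paste0("SimulationTruth (seed %d): %d genes; planted ",
                     "%d transfer / %d intrinsic / %d CM; lfc %.2g/%.2g\n"),
              x$seed, x$n_genes, length(x$transfer_genes),
              length(x$intrinsic_genes), length(x$cm_genes),
              x$lfc_transfer, x$lfc_intrinsic))
  invisible(x)
}

.rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate the four-arm co-culture count experiment
#'
#' Groups: `donor_mono`, `recipient_mono`, `recipient_cc` (contact),
#' `recipient_cm` (conditioned media). Transfer genes sit at a low-moderate
#' recipient baseline, are elevated by `lfc_transfer` only in
#' `recipient_cc`, and by `lfc_transfer + donor_extra_lfc` in the donor.
#' Intrinsic genes rise by `lfc_intrinsic` in `recipient_cc` only; CM genes
#' rise in both `recipient_cm` and `recipient_cc`; all remaining genes
#' share one mean across groups.
#'
#' @param truth A [simulation_truth].
#' @param reps_per_group Replicates per arm (>= 2, default 3).
#' @return A counts-scale [ExpressionMatrix] with condition annotations.
#' @export
simulate_coculture <- function(truth, reps_per_group = 3L) {
  .assert(reps_per_group >= 2L, "need >= 2 replicates per group")
  sets <- list(truth$transfer_genes, truth$intrinsic_genes, truth$cm_genes)
  .assert(sum(lengths(sets)) == length(unique(unlist(sets))),
          "planted gene sets overlap")
  .with_seed(truth$seed, {
    n <- truth$n_genes
    ids <- truth$gene_ids
    base <- stats::rlnorm(n, meanlog = log(500), sdlog = 1)
    planted <- ids %in% unlist(sets)
    # planted genes get a moderate, well-measurable recipient baseline;
    # keeping their library-size footprint small limits the compositional
    # bias of CPM normalization on the contact-culture arm
    base[planted] <- 2^stats::runif(sum(planted), 7, 9)
    mu <- matrix(base, nrow = n, ncol = 4,
                 dimnames = list(ids, c("donor_mono", "recipient_mono",
                                        "recipient_cc", "recipient_cm")))
    tr <- ids %in% truth$transfer_genes
    mu[tr, "recipient_cc"] <- base[tr] * 2^truth$lfc_transfer
    mu[tr, "donor_mono"] <- base[tr] * 2^(truth$lfc_transfer + truth$donor_extra_lfc)
    ig <- ids %in% truth$intrinsic_genes
    mu[ig, "recipient_cc"] <- base[ig] * 2^truth$lfc_intrinsic
    cg <- ids %in% truth$cm_genes
    mu[cg, "recipient_cc"] <- base[cg] * 2^truth$lfc_intrinsic
    mu[cg, "recipient_cm"] <- base[cg] * 2^truth$lfc_intrinsic
    groups <- rep(colnames(mu), each = reps_per_group)
    sample_ids <- paste(groups, rep(seq_len(reps_per_group), times = 4), sep = "_")
    counts <- matrix(0, nrow = n, ncol = length(sample_ids),
                     dimnames = list(ids, sample_ids))
    for (j in seq_along(sample_ids))
      counts[, j] <- .rnb(n, mu[, groups[j]], truth$nb_dispersion)
    ann <- data.frame(
      sample_id = sample_ids, condition = groups,
      cell_line = ifelse(groups == "donor_mono", "DONOR", "RECIPIENT"),
      batch = "sim", stringsAsFactors = FALSE)
    ExpressionMatrix(counts, ann, scale = "counts")
  })
}

#' Simulate a TMT-style protein differential-abundance table
#'
#' Models the abundance bias of isobaric-tag proteomics: each gene is
#' detected with probability `plogis(slope * (log2(mean abundance) -
#' midpoint))` computed over the recipient mono + contact samples. Detected
#' genes inherit the RNA-level contact-vs-mono fold change of the planted
#' mean structure plus Gaussian noise -- the proteome is an independent
#' measurement of the same underlying induction, not a re-measurement of
#' the RNA sampling noise. Undetected genes are absent from the table.
#'
#' @param expr Counts-scale [ExpressionMatrix] from [simulate_coculture].
#' @param truth The matching [simulation_truth].
#' @param noise_sd Standard deviation of the protein-level fold-change
#'   noise (default 0.3).
#' @return A `DEResult`-style data frame (`gene`, `log2_fc`, `p_value`,
#'   `adj_p`, `mean_a`, `mean_b`, `flag`) restricted to detected genes.
#' @export
simulate_proteome <- function(expr, truth, noise_sd = 0.3) {
  mono <- em_samples(expr, "recipient_mono")
  cc <- em_samples(expr, "recipient_cc")
  .assert(length(mono) > 0L && length(cc) > 0L,
          "expr must contain recipient_mono and recipient_cc samples")
  .with_seed(truth$seed + 1L, {
    abund <- log2(rowMeans(expr$values[, c(mono, cc), drop = FALSE]) + 1)
    det <- truth$proteome_detection
    p_det <- stats::plogis(det$slope * (abund - det$midpoint))
    detected <- stats::runif(length(abund)) < p_det
    ids <- rownames(expr$values)
    rna_lfc <- stats::setNames(numeric(length(ids)), ids)
    rna_lfc[ids %in% truth$transfer_genes] <- truth$lfc_transfer
    rna_lfc[ids %in% c(truth$intrinsic_genes, truth$cm_genes)] <-
      truth$lfc_intrinsic
    lfc <- rna_lfc[detected] + stats::rnorm(sum(detected), 0, noise_sd)
    p <- 2 * stats::pnorm(-abs(lfc) / noise_sd)
    res <- data.frame(gene = names(rna_lfc)[detected], log2_fc = unname(lfc),
                      p_value = unname(p), adj_p = bh_adjust(p),
                      mean_a = unname(abund[detected]),
                      mean_b = unname(abund[detected]),
                      flag = rep("", sum(detected)), stringsAsFactors = FALSE)
    class(res) <- c("DEResult", "data.frame")
    res
  })
}

#' Simulate an interaction network with planted inter-layer wiring
#'
#' A scale-free background graph is grown over the planted genes plus
#' `n_extra_nodes` fillers; `n_inter_edges` excess edges are then added
#' between random transfer-intrinsic gene pairs. With
#' `wiring = "rewired_control"` the planted graph is degree-preservingly
#' rewired, destroying the inter-layer excess while keeping every node's
#' degree.
#'
#' @param truth A [simulation_truth].
#' @param n_extra_nodes Background nodes beyond the planted genes.
#' @param wiring `"planted"` or `"rewired_control"`.
#' @param n_inter_edges Number of excess transfer-intrinsic edges.
#' @return An [edge_table] with confidences drawn uniformly in
#'   `[0.6, 0.99]`.
#' @export
simulate_network <- function(truth, n_extra_nodes = 400L,
                             wiring = c("planted", "rewired_control"),
                             n_inter_edges = 150L) {
  wiring <- match.arg(wiring)
  .assert(n_extra_nodes >= 0L, "n_extra_nodes must be >= 0")
  .with_seed(truth$seed + 2L, {
    planted <- c(truth$transfer_genes, truth$intrinsic_genes, truth$cm_genes)
    extras <- setdiff(truth$gene_ids, planted)[seq_len(n_extra_nodes)]
    nodes <- sample(c(planted, extras))
    g <- igraph::sample_pa(length(nodes), power = 1, m = 2, directed = FALSE)
    igraph::V(g)$name <- nodes
    inter <- cbind(sample(truth$transfer_genes, n_inter_edges, replace = TRUE),
                   sample(truth$intrinsic_genes, n_inter_edges, replace = TRUE))
    g <- igraph::add_edges(g, t(inter))
    g <- igraph::simplify(g)
    if (wiring == "rewired_control")
      g <- igraph::rewire(g, igraph::keeping_degseq(niter = 20 * igraph::ecount(g)))
    el <- igraph::as_edgelist(g)
    edge_table(el[, 1L], el[, 2L],
               stats::runif(nrow(el), 0.6, 0.99))
  })
}

#' Simulate a patient cohort whose hazard tracks a signature state
#'
#' Each patient carries a latent high/low signature state (probability
#' 0.5). Signature genes are shifted up by `effect` log2 units in high
#' patients; `n_noise_genes` additional genes are pure noise. Survival
#' times are exponential with hazard `log(2)/60` per month in the low
#' state, multiplied by `truth$cohort$hazard_ratio` in the high state;
#' censoring is an independent exponential calibrated so the expected
#' censored fraction equals `truth$cohort$censoring_rate`.
#'
#' @param truth A [simulation_truth].
#' @param sig A [gene_set] of signature genes to plant.
#' @param n_patients Cohort size (>= 20).
#' @param effect Log2 shift of signature genes in high-state patients.
#' @param n_noise_genes Extra uninformative genes.
#' @return A [cohort_table]; the latent state is recorded in the attribute
#'   `latent_state` (simulation sidecar, not a pipeline input).
#' @export
simulate_cohort <- function(truth, sig, n_patients = 200L, effect = 2,
                            n_noise_genes = 50L) {
  .assert(n_patients >= 20L, "need >= 20 patients")
  genes <- .as_genes(sig)
  .with_seed(truth$seed + 3L, {
    state <- stats::rbinom(n_patients, 1L, 0.5)
    ids <- sprintf("PT%04d", seq_len(n_patients))
    noise_ids <- sprintf("NOISE%03d", seq_len(n_noise_genes))
    expr <- rbind(
      matrix(stats::rnorm(length(genes) * n_patients, 8, 1),
             nrow = length(genes), dimnames = list(genes, ids)) +
        matrix(effect * state, nrow = length(genes), ncol = n_patients,
               byrow = TRUE),
      matrix(stats::rnorm(n_noise_genes * n_patients, 8, 1),
             nrow = n_noise_genes, dimnames = list(noise_ids, ids)))
    base_rate <- log(2) / 60
    rate <- base_rate * truth$cohort$hazard_ratio^state
    t_event <- stats::rexp(n_patients, rate)
    r <- truth$cohort$censoring_rate
    if (r > 0) {
      c_rate <- mean(rate) * r / (1 - r)
      t_cens <- stats::rexp(n_patients, c_rate)
    } else t_cens <- rep(Inf, n_patients)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    ct <- cohort_table(
      data.frame(patient_id = ids, time = time, event = event,
                 stringsAsFactors = FALSE), expr)
    attr(ct, "latent_state") <- stats::setNames(state, ids)
    ct
  })
}

#' Score a triage partition against planted simulation truth
#'
#' Precision and recall of the borrowed bin against the planted transfer
#' set, and of the intrinsic bin against the planted intrinsic set. Genes
#' flagged `cm_shared` are excluded from the intrinsic bin before scoring:
#' conditioned-media-shared inductions are genuinely contact-induced,
#' carry an explicit flag, and are planted as a separate category.
#'
#' @param partition A `TriagePartition`.
#' @param truth The [simulation_truth] that generated the data.
#' @return Named numeric vector: `borrowed_precision`, `borrowed_recall`,
#'   `intrinsic_precision`, `intrinsic_recall`.
#' @export
score_triage_recovery <- function(partition, truth) {
  pr <- function(got, want) {
    c(precision = if (length(got) == 0L) NA_real_ else
        length(intersect(got, want)) / length(got),
      recall = length(intersect(got, want)) / length(want))
  }
  b <- pr(partition$borrowed$genes, truth$transfer_genes)
  i <- pr(setdiff(partition$intrinsic$genes, partition$cm_shared),
          truth$intrinsic_genes)
  c(borrowed_precision = unname(b["precision"]),
    borrowed_recall = unname(b["recall"]),
    intrinsic_precision = unname(i["precision"]),
    intrinsic_recall = unname(i["recall"]))
}

#' Write a simulation's planted truth as a machine-readable sidecar
#' @param truth A [simulation_truth].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  jsonlite::write_json(
    list(seed = truth$seed, n_genes = truth$n_genes,
         transfer_genes = truth$transfer_genes,
         intrinsic_genes = truth$intrinsic_genes,
         cm_genes = truth$cm_genes,
         lfc_transfer = truth$lfc_transfer,
         lfc_intrinsic = truth$lfc_intrinsic,
         donor_extra_lfc = truth$donor_extra_lfc,
         nb_dispersion = truth$nb_dispersion,
         proteome_detection = truth$proteome_detection,
         cohort = truth$cohort),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
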