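# End-to-end orchestration: simulate/load -> DEG -> triage -> network ->
# refine -> score -> survival, from a single config, with a run manifest.

.default_config <- function() {
  list(
    seed = 7L,
    simulate = list(n_genes = 2000L, n_transfer = 150L, n_intrinsic = 80L,
                    n_cm = 10L, lfc_transfer = 2.5, lfc_intrinsic = 2.5,
                    nb_dispersion = 0.1, reps_per_group = 3L),
    thresholds = list(lfc_min = 2, adj_p_max = 0.05, min_confidence = 0.4,
                      hops = 1L, auc_threshold = 0.85),
    stages = c("deg", "triage", "network", "score")
  )
}

.merge_config <- function(user, defaults) {
  for (k in names(defaults)) {
    if (is.null(user[[k]])) user[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]) && is.list(user[[k]]))
      user[[k]] <- .merge_config(user[[k]], defaults[[k]])
  }
  user
}

.log_line <- function(log, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  c(log, line)
}

#' Run the full co-culture borrowed-gene analysis
#'
#' Stages, in dependency order: input acquisition (synthetic simulation or
#' file paths from the config), log2-CPM normalization, the three DEG
#' comparisons (donor vs recipient monoculture; contact vs monoculture;
#' conditioned media vs monoculture), protein evidence, triage into
#' borrowed / intrinsic / CM bins with the RNA-protein overlap, the
#' seed-expanded interaction network with layer projection and
#' connectivity test, composite signature scoring with ANOVA/Tukey, and
#' (when a cohort is configured) survival stratification. Artifacts are
#' written under `outdir`; a manifest records every set size, each
#' asserted against the written artifact.
#'
#' @param config Nested list (see `.default_config` in the sources) or a
#'   path readable by [read_config]. When `config$simulate` is present the
#'   inputs are generated with planted truth; otherwise
#'   `config$inputs$expression` / `annotations` / `protein_de` / `edges` /
#'   `cohort` name input files.
#' @param outdir Output directory for artifacts, manifest and log.
#' @param seed Optional override of `config$seed`.
#' @return The run manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("coborrow_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  defaults <- .default_config()
  sim_defaults <- defaults$simulate
  defaults$simulate <- NULL
  config <- .merge_config(config, defaults)
  # synthetic mode unless the config names input files
  if (is.null(config$inputs))
    config$simulate <- .merge_config(config$simulate %||% list(), sim_defaults)
  else config$simulate <- NULL
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if ("refine" %in% config$stages && is.null(config$simulate) &&
      is.null(config$inputs$validation))
    stop("refinement requested without validation datasets", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  sizes <- list()
  timings <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- code
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    log <<- .log_line(log, sprintf("stage %s done (%.2fs)", name,
                                   timings[[name]]))
    res
  }

  # ---- inputs ----
  simulated <- !is.null(config$simulate)
  truth <- NULL
  if (simulated) {
    sim <- config$simulate
    truth <- simulation_truth(
      n_genes = sim$n_genes, n_transfer = sim$n_transfer,
      n_intrinsic = sim$n_intrinsic, n_cm = sim$n_cm,
      lfc_transfer = sim$lfc_transfer, lfc_intrinsic = sim$lfc_intrinsic,
      nb_dispersion = sim$nb_dispersion, seed = config$seed)
    expr <- stage("simulate", {
      e <- simulate_coculture(truth, reps_per_group = sim$reps_per_group)
      write_expression(e, file.path(outdir, "expression.tsv"),
                       file.path(outdir, "annotations.tsv"))
      write_truth_sidecar(truth, file.path(outdir, "truth_sidecar.json"))
      e
    })
    protein_de <- simulate_proteome(expr, truth)
    edges <- simulate_network(truth, wiring = "planted")
  } else {
    ins <- config$inputs
    for (k in c("expression", "annotations"))
      if (is.null(ins[[k]]))
        stop("config$inputs is missing required key '", k, "'", call. = FALSE)
    expr <- read_expression(ins$expression, ins$annotations, scale = "counts")
    protein_de <- NULL
    edges <- if (!is.null(ins$edges))
      read_edge_table(ins$edges, config$thresholds$min_confidence) else NULL
  }

  th <- config$thresholds
  lg <- normalize_log2cpm(expr)
  mono <- em_samples(expr, "recipient_mono")
  donor <- em_samples(expr, "donor_mono")
  cc <- em_samples(expr, "recipient_cc")
  cm <- em_samples(expr, "recipient_cm")

  # ---- DEG ----
  degs <- stage("deg", {
    d <- list(donor_vs_recipient = de_test(lg, mono, donor),
              cc_vs_mono = de_test(lg, mono, cc),
              cm_vs_mono = de_test(lg, mono, cm))
    for (nm in names(d))
      write_deg_table(d[[nm]], file.path(outdir, paste0("deg_", nm, ".tsv")),
                      th$lfc_min, th$adj_p_max)
    d
  })

  # ---- triage ----
  triage <- stage("triage", {
    msc_high <- build_msc_high_catalog(degs$donor_vs_recipient,
                                       th$lfc_min, th$adj_p_max)
    rna_cc <- filter_deg(degs$cc_vs_mono, th$lfc_min, th$adj_p_max,
                         "up", name = "rna_cc_up")
    rna_cm <- filter_deg(degs$cm_vs_mono, th$lfc_min, th$adj_p_max,
                         "up", name = "rna_cm_up")
    prot_cc <- if (!is.null(protein_de))
      filter_deg(protein_de, th$lfc_min, th$adj_p_max, "up",
                 name = "protein_cc_up")
    else gene_set("protein_cc_up", character())
    ev <- union_evidence(rna_cc, prot_cc)
    part <- classify_induced(ev$genes, rna_cm, msc_high, ev$provenance)
    overlap <- cross_platform_overlap(rna_cc, prot_cc)
    export_partition(part, outdir)
    write_gmt(overlap, file.path(outdir, "rna_protein_overlap.gmt"))
    list(partition = part, overlap = overlap, rna_cc = rna_cc,
         prot_cc = prot_cc)
  })
  part <- triage$partition
  sizes$msc_high <- length(part$msc_high$genes)
  sizes$borrowed <- length(part$borrowed$genes)
  sizes$intrinsic <- length(part$intrinsic$genes)
  sizes$cm_unique <- length(part$cm_unique$genes)
  sizes$rna_protein_overlap <- length(triage$overlap$genes)

  # ---- network ----
  connectivity <- NULL
  if (!is.null(edges) && length(triage$overlap$genes) > 0L) {
    net <- stage("network", {
      n <- build_seed_network(triage$overlap, edges,
                              min_confidence = th$min_confidence,
                              hops = th$hops)
      n <- project_layer(n, part$borrowed, "borrowed")
      n <- project_layer(n, part$intrinsic, "intrinsic")
      export_network(n, file.path(outdir, "network"))
      n
    })
    connectivity <- layer_connectivity_test(net)
    sizes$network_nodes <- igraph::vcount(net$graph)
    sizes$network_edges <- igraph::ecount(net$graph)
    sizes$borrowed_layer <- connectivity$layer1_k
    sizes$intrinsic_layer <- connectivity$layer2_n
    sizes$layer_overlap <- connectivity$overlap_k
  }

  # ---- scoring ----
  scores <- NULL
  if (length(triage$overlap$genes) > 0L) {
    scores <- stage("score", {
      s <- composite_score(lg, triage$overlap)
      utils::write.table(s, file.path(outdir, "signature_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      s
    })
  }

  # ---- survival (optional) ----
  surv_res <- NULL
  if (!is.null(config$inputs$cohort) || (simulated && "survive" %in% config$stages)) {
    surv_res <- stage("survive", {
      cohort <- if (!is.null(config$inputs$cohort))
        read_cohort(config$inputs$cohort)
      else simulate_cohort(truth, triage$overlap)
      stratified_survival(cohort, triage$overlap, method = "step")
    })
    sizes$cohort_high <- surv_res$n_high
    sizes$cohort_low <- surv_res$n_low
  }

  # manifest sizes must equal the written artifacts
  gmt_sets <- read_gmt(file.path(outdir, "triage_partition.gmt"))
  gmt_size <- function(nm) {
    hit <- Filter(function(s) s$name == nm, gmt_sets)
    if (length(hit) == 0L) 0L else length(hit[[1L]]$genes)
  }
  stopifnot(gmt_size("borrowed") == sizes$borrowed,
            gmt_size("intrinsic") == sizes$intrinsic)
  manifest <- list(
    config = config, seed = config$seed, simulated = simulated,
    sizes = sizes,
    connectivity = if (!is.null(connectivity))
      connectivity[c("universe_n", "layer1_k", "layer2_n", "overlap_k",
                     "p_value")],
    logrank_p = if (!is.null(surv_res)) surv_res$logrank$p,
    timings = timings)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log, file.path(outdir, "run.log"))
  invisible(manifest)
}

#' Verify printed set and network sizes against supplied tables
#'
#' Recomputes each expected count from user-supplied tables by the same
#' set operations the triage and network stages use, and reports
#' match/mismatch per target. Targets whose inputs are missing are marked
#' not evaluable rather than failing.
#'
#' Recognized targets and the tables they need:
#' * `msc_high` — `tables$msc_high`
#' * `borrowed` = `up_cc` intersect `msc_high`
#' * `intrinsic` = `up_cc` minus `msc_high`
#' * `cm_unique` = `up_cm` minus `up_cc`
#' * `rna_protein_overlap` = `rna_induced` intersect `protein_induced`
#' * `network_nodes` — `tables$network_nodes` (character vector of node ids)
#' * `borrowed_layer` / `intrinsic_layer` / `layer_overlap` —
#'   `tables$borrowed_layer_nodes`, `tables$intrinsic_layer_nodes`
#'
#' @param expected Named list/vector of expected integer counts.
#' @param tables Named list of character vectors (or [gene_set]s).
#' @return Data frame `target`, `expected`, `computed`, `match`,
#'   `evaluable`.
#' @export
verify_supplementary <- function(expected, tables) {
  gv <- function(k) if (is.null(tables[[k]])) NULL else .as_genes(tables[[k]])
  compute <- list(
    msc_high = function() length(gv("msc_high")),
    borrowed = function() length(intersect(gv("up_cc"), gv("msc_high"))),
    intrinsic = function() length(setdiff(gv("up_cc"), gv("msc_high"))),
    cm_unique = function() length(setdiff(gv("up_cm"), gv("up_cc"))),
    rna_protein_overlap = function()
      length(intersect(gv("rna_induced"), gv("protein_induced"))),
    network_nodes = function() length(gv("network_nodes")),
    borrowed_layer = function() length(gv("borrowed_layer_nodes")),
    intrinsic_layer = function() length(gv("intrinsic_layer_nodes")),
    layer_overlap = function()
      length(intersect(gv("borrowed_layer_nodes"), gv("intrinsic_layer_nodes"))))
  needs <- list(
    msc_high = "msc_high", borrowed = c("up_cc", "msc_high"),
    intrinsic = c("up_cc", "msc_high"), cm_unique = c("up_cm", "up_cc"),
    rna_protein_overlap = c("rna_induced", "protein_induced"),
    network_nodes = "network_nodes",
    borrowed_layer = "borrowed_layer_nodes",
    intrinsic_layer = "intrinsic_layer_nodes",
    layer_overlap = c("borrowed_layer_nodes", "intrinsic_layer_nodes"))
  rows <- lapply(names(expected), function(tg) {
    if (!tg %in% names(compute))
      return(data.frame(target = tg, expected = as.integer(expected[[tg]]),
                        computed = NA_integer_, match = NA,
                        evaluable = FALSE))
    ok <- all(vapply(needs[[tg]], function(k) !is.null(tables[[k]]), TRUE))
    if (!ok)
      return(data.frame(target = tg, expected = as.integer(expected[[tg]]),
                        computed = NA_integer_, match = NA,
                        evaluable = FALSE))
    got <- compute[[tg]]()
    data.frame(target = tg, expected = as.integer(expected[[tg]]),
               computed = got, match = got == as.integer(expected[[tg]]),
               evaluable = TRUE)
  })
  do.call(rbind, rows)
}
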