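#' Configuration for a full batch-effect audit run
#'
#' Bundles input paths and every stage parameter. Referenced files are
#' checked at validation time.
#'
#' @param vcf_dir Directory of `<sample>.<caller>.vcf` files.
#' @param meta Metadata TSV path.
#' @param genes BED12 gene-model path.
#' @param out_dir Output directory for tables, figures and the JSON
#'   summary.
#' @param survival Optional survival TSV (sample_id, time, event).
#' @param mutations Optional mutation TSV (sample_id, gene_id); defaults to
#'   the merged call table's gene assignments.
#' @param mode,min_callers,min_qual Ingest parameters ([merge_callers()],
#'   [filter_snv()]).
#' @param min_k Minimum collection size per KS side ([pairwise_ks()]).
#' @param design `"reference"` or `"generalized"` ([pair_design()]).
#' @param decile Extreme gene-set fraction ([rank_and_partition()]).
#' @param kde_window KDE bandwidth in nt.
#' @param make_plots Render figures (PNG) alongside the tables.
#' @param seed Seed echoed into the report (the audit itself is
#'   deterministic).
#' @return A validated `audit_config` list.
#' @export
audit_config <- function(vcf_dir, meta, genes, out_dir,
                         survival = NULL, mutations = NULL,
                         mode = "consensus", min_callers = 2L,
                         min_qual = 30, min_k = 3L,
                         design = c("reference", "generalized"),
                         decile = 0.10, kde_window = 100,
                         make_plots = TRUE, seed = 1L) {
  design <- match.arg(design)
  for (p in c(vcf_dir, meta, genes, survival, mutations)) {
    if (!is.null(p) && !file.exists(p))
      abort_config(paste("input path does not exist:", p))
  }
  if (min_qual < 0 || min_callers < 1L || min_k < 1L ||
      decile <= 0 || decile > 0.5 || kde_window <= 0)
    abort_config("audit parameters out of documented ranges")
  structure(list(vcf_dir = vcf_dir, meta = meta, genes = genes,
                 out_dir = out_dir, survival = survival,
                 mutations = mutations, mode = mode,
                 min_callers = as.integer(min_callers), min_qual = min_qual,
                 min_k = as.integer(min_k), design = design,
                 decile = decile, kde_window = kde_window,
                 make_plots = isTRUE(make_plots), seed = as.integer(seed)),
            class = "audit_config")
}

#' Run the complete batch-effect audit
#'
#' Chains every stage on one input set: ingest (filter + merge +
#' annotate), per-sample metrics with ANOVA, per-gene density and sample
#' correlation structure, within-gene KS / r_g analysis with ranking and
#' decile gene sets, bi-clustering and per-pair p-value summaries, and —
#' when a survival table is supplied — the carrier contrast of the top
#' versus bottom gene sets. All tables are written as TSV, figures as PNG,
#' and headline numbers as a machine-readable JSON summary; the run is
#' deterministic given config + seed. A stage failure halts with an error
#' naming the stage; outputs of completed stages are preserved on disk.
#'
#' @param config An [audit_config()].
#' @return Invisibly, a list with every stage's tables and the summary.
#' @export
run_full_audit <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  models <- stage("ingest", read_gene_models(config$genes))
  meta <- stage("ingest", read_metadata(config$meta))
  calls <- stage("ingest", ingest_cohort(
    config$vcf_dir, models, mode = config$mode,
    min_callers = config$min_callers, min_qual = config$min_qual))
  tsv(calls, "calls.tsv")

  summaries <- stage("metrics",
                     summarize_samples(calls, all_samples = meta$sample_id))
  gs_center <- stage("metrics", group_summary(summaries, meta, by = "center"))
  tsv(summaries, "sample_metrics.tsv")
  tsv(gs_center, "group_summary_center.tsv")
  if (config$make_plots) {
    ggplot2::ggsave(file.path(out, "counts_by_group.png"),
                    plot_sample_metric(summaries, meta, "n_variants"),
                    width = 8, height = 5)
    ggplot2::ggsave(file.path(out, "titv_by_group.png"),
                    plot_sample_metric(summaries, meta, "titv"),
                    width = 8, height = 5)
  }

  dm <- stage("density", density_matrix(calls, models,
                                        samples = meta$sample_id))
  corr <- stage("density", sample_correlation(dm))
  oh <- stage("density", ordered_heatmap(
    corr, meta,
    file = if (config$make_plots) file.path(out, "correlation_heatmap.png")))
  cc <- stage("density", correlation_contrast(corr, meta))
  tsv(tibble::as_tibble(dm, rownames = "sample_id"), "density_matrix.tsv")
  tsv(tibble::as_tibble(oh$matrix, rownames = "sample_id"),
      "correlation_ordered.tsv")

  coll <- stage("withingene", build_location_collections(calls, meta))
  ks_tbl <- stage("withingene", pairwise_ks(
    coll, groups = sort(unique(meta$group)), min_k = config$min_k))
  design <- stage("withingene", pair_design(
    unique(meta[, c("group", "center")]), type = config$design))
  sens <- stage("withingene", batch_ratio(ks_tbl, design))
  tsv(ks_tbl[, c("gene_id", "pair", "k1", "k2", "d", "p", "evaluable")],
      "ks_pairs.tsv")
  tsv(sens, "batch_sensitivity.tsv")
  sens_ok <- sens[sens$evaluable, , drop = FALSE]
  parts <- NULL
  if (nrow(sens_ok) >= 1 / config$decile) {
    parts <- stage("withingene", rank_and_partition(sens_ok,
                                                    decile = config$decile))
    tsv(parts$ranked, "genes_ranked.tsv")
  }
  violin <- stage("withingene", pairwise_violin_summary(
    ks_tbl, meta,
    file = if (config$make_plots) file.path(out, "pair_violins.png")))
  tsv(violin, "pair_pvalues.tsv")
  if (config$make_plots && nrow(sens_ok) >= 2L &&
      length(unique(ks_tbl$pair[ks_tbl$evaluable])) >= 2L) {
    stage("withingene", bicluster_logp(
      ks_tbl[ks_tbl$gene_id %in% sens_ok$gene_id, ],
      file = file.path(out, "bicluster_logp.png")))
  }

  surv_report <- NULL
  if (!is.null(config$survival) && !is.null(parts)) {
    records <- stage("survival", tibble::as_tibble(
      utils::read.delim(config$survival)))
    mutations <- if (!is.null(config$mutations)) {
      tibble::as_tibble(utils::read.delim(config$mutations))
    } else {
      unique(calls[!is.na(calls$gene_id), c("sample_id", "gene_id")])
    }
    surv_report <- stage("survival", gene_set_contrast(
      records, mutations, parts$top, parts$bottom,
      labels = c("top_decile", "bottom_decile")))
  }

  anova <- attr(gs_center, "anova")
  summary <- list(
    seed = config$seed,
    parameters = config[c("mode", "min_callers", "min_qual", "min_k",
                          "design", "decile", "kde_window")],
    n_samples = nrow(meta),
    n_calls = nrow(dplyr::distinct(calls, .data$sample_id, .data$contig,
                                   .data$position, .data$ref, .data$alt)),
    group_means = stats::setNames(
      as.list(gs_center$mean_n_variants), gs_center$center),
    group_titv = stats::setNames(
      as.list(gs_center$mean_titv), gs_center$center),
    anova_log10p_counts = if (!is.null(anova$n_variants))
      anova$n_variants$log10_p,
    anova_log10p_titv = if (!is.null(anova$titv)) anova$titv$log10_p,
    correlation_within = cc$within,
    correlation_between = cc$between,
    n_genes_evaluable = nrow(sens_ok),
    affected_fraction = if (nrow(sens_ok) > 0) mean(sens_ok$affected),
    top_genes = if (!is.null(parts)) parts$top,
    bottom_genes = if (!is.null(parts)) parts$bottom,
    logrank_p_top = if (!is.null(surv_report) &&
                          !is.null(surv_report$top_decile$logrank))
      surv_report$top_decile$logrank$p,
    logrank_p_bottom = if (!is.null(surv_report) &&
                             !is.null(surv_report$bottom_decile$logrank))
      surv_report$bottom_decile$logrank$p
  )
  jsonlite::write_json(summary, file.path(out, "audit_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(calls = calls, summaries = summaries,
                 group_summary = gs_center, density = dm, correlation = corr,
                 ks = ks_tbl, sensitivity = sens, partition = parts,
                 survival = surv_report, summary = summary))
}
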