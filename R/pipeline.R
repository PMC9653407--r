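pipeline_defaults <- list(
  manifest = NULL, expression = NULL, distances = NULL,
  halflife = NULL, lr_pairs = NULL, coding_genes = NULL,
  min_expressed_genes = 2000, gene_min_value = 5, gene_min_cells = 10,
  hvg_k = 2000, rho_threshold = 0.25, k_modules = 4,
  cluster_linkage = "ward.D2", cluster_metric = "cosine",
  timepoint_policy = "pre-exchange", n_timepoints = 13,
  top_frac = 0.5, cid_threshold = 0.4, single_threshold = 0.4,
  lr_ruleout = "singlet-low", alpha = 0.05, lfc = 1, n_min = 5,
  halflife_units = "hours", batch_corrected = FALSE, figures = TRUE,
  seed = 1)

#' Pipeline configuration
#'
#' Collects input paths and every stage threshold into a validated list.
#' Unknown keys are rejected; thresholds are checked against their documented
#' ranges.
#'
#' @param ... named values overriding the defaults.  Inputs: \code{manifest},
#'   \code{expression}, \code{distances}, \code{halflife}, \code{lr_pairs}
#'   (file paths), optional \code{coding_genes} allow-list path.  Thresholds:
#'   \code{min_expressed_genes}, \code{gene_min_value},
#'   \code{gene_min_cells}, \code{hvg_k}, \code{rho_threshold},
#'   \code{k_modules}, \code{timepoint_policy}, \code{n_timepoints},
#'   \code{top_frac}, \code{cid_threshold}, \code{single_threshold},
#'   \code{lr_ruleout}, \code{alpha}, \code{lfc}, \code{n_min},
#'   \code{halflife_units}, \code{batch_corrected}, \code{figures},
#'   \code{seed}.
#' @return object of class \code{cidmem_config}.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(pipeline_defaults))
  if (length(unknown))
    stop("validation error: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(pipeline_defaults, over, keep.null = TRUE)
  check_range <- function(field, lo, hi, lo_open = FALSE) {
    v <- cfg[[field]]
    bad <- !is.numeric(v) || length(v) != 1 || is.na(v) ||
      (if (lo_open) v <= lo else v < lo) || v > hi
    if (bad) stop("validation error: ", field, " must be in ",
                  if (lo_open) "(" else "[", lo, ", ", hi, "]")
  }
  check_range("rho_threshold", 0, 1, lo_open = TRUE)
  check_range("top_frac", 0, 1, lo_open = TRUE)
  check_range("alpha", 0, 1, lo_open = TRUE)
  check_range("cid_threshold", -1, 1)
  check_range("single_threshold", -1, 1)
  check_range("min_expressed_genes", 0, Inf)
  check_range("gene_min_value", 0, Inf)
  check_range("gene_min_cells", 0, Inf)
  check_range("hvg_k", 1, Inf)
  check_range("k_modules", 1, Inf)
  check_range("lfc", 0, Inf)
  check_range("n_min", 2, Inf)
  if (!cfg$timepoint_policy %in% c("pre-exchange", "post-exchange",
                                   "all-hours"))
    stop("validation error: timepoint_policy must be pre-exchange, ",
         "post-exchange or all-hours")
  if (!cfg$lr_ruleout %in% c("singlet-low", "cid-only"))
    stop("validation error: lr_ruleout must be singlet-low or cid-only")
  if (!cfg$halflife_units %in% c("hours", "minutes"))
    stop("validation error: halflife_units must be hours or minutes")
  structure(cfg, class = "cidmem_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match \code{\link{pipeline_config}}
#'   arguments; unknown keys are rejected.
#' @return object of class \code{cidmem_config}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full doublet-memory pipeline
#'
#' Executes preprocess, correlate, modules, half-life, ligand-receptor and
#' differential-expression stages in sequence, writing every tabular output,
#' a provenance record (resolved configuration, per-stage counts, md5 hashes
#' of every output file) and, optionally, the figures.  Input files are
#' validated before any stage runs.
#'
#' @param config a \code{\link{pipeline_config}} (or path to a YAML config).
#' @param outdir output directory, created if needed.
#' @return invisibly, a list of stage results (class \code{cidmem_run}):
#'   classification, filtering counts, bundle, corrmap, memory_genes,
#'   modules, halflife, lr, de, provenance, paths.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "cidmem_config"))

  required <- c("manifest", "expression", "distances")
  optional <- c("halflife", "lr_pairs", "coding_genes")
  for (f in required)
    if (is.null(config[[f]]))
      stop("fatal: required input '", f, "' not configured")
  for (f in c(required, optional)) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("fatal: input file for '", f, "' does not exist: ", p)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[cidmem] ", ...)

  log_stage("preprocess")
  manifest <- read_manifest(config$manifest)
  expr <- read_expression_tsv(config$expression)
  distances <- read_distances(config$distances)
  classification <- classify_chambers(manifest)
  if (!is.null(config[["coding_genes"]])) {
    allow <- readLines(config[["coding_genes"]])
    expr <- expr[rownames(expr) %in% allow, , drop = FALSE]
  }
  retained <- classification$chamber_id[!classification$excluded]
  expr <- expr[, colnames(expr) %in% retained, drop = FALSE]
  n_cells_pre <- ncol(expr); n_genes_pre <- nrow(expr)
  expr <- filter_cells(expr, config$min_expressed_genes)
  expr <- filter_genes(expr, config$gene_min_value, config$gene_min_cells)
  groups <- setNames(classification$category,
                     classification$chamber_id)[colnames(expr)]

  log_stage("correlate")
  bundle <- align_inputs(expr, distances, classification)
  frames_used <- timepoint_policy(bundle$frames, config$timepoint_policy,
                                  config$n_timepoints)
  hvg <- select_variable_genes(bundle$expr_cid, config$hvg_k)
  corrmap <- correlate_distance_expression(
    bundle$expr_cid[hvg, , drop = FALSE],
    bundle$dist[, frames_used, drop = FALSE], n_min = config$n_min)
  memory_genes <- select_memory_genes(corrmap, config$rho_threshold)

  log_stage("modules")
  modules <- if (length(memory_genes) >= config$k_modules)
    cluster_modules(corrmap, memory_genes, k = config$k_modules,
                    linkage = config$cluster_linkage,
                    metric = config$cluster_metric) else NULL

  log_stage("halflife")
  halflife <- NULL
  if (!is.null(config[["halflife"]]) && !is.null(modules)) {
    hl_table <- read_halflife(config[["halflife"]], config$halflife_units)
    halflife <- halflife_module_test(modules$assignment$gene, hl_table)
  }

  log_stage("lr")
  lr <- NULL
  if (!is.null(config[["lr_pairs"]])) {
    lr_db <- read_lr_pairs(config[["lr_pairs"]])
    lr <- lr_screen(expr, lr_db, groups, top_frac = config$top_frac,
                    cid_threshold = config$cid_threshold,
                    single_threshold = config$single_threshold,
                    ruleout = config$lr_ruleout, n_min = config$n_min)
  }

  log_stage("de")
  de <- NULL
  if (sum(groups == "CID_NK_only") >= 3 && sum(groups == "CID") >= 3)
    de <- differential_expression(expr, groups, alpha = config$alpha,
                                  lfc = config$lfc)

  log_stage("write outputs")
  p <- function(f) file.path(outdir, f)
  write.table(classification, p("exclusion_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_expression_tsv(expr, p("filtered_expression.tsv"))
  write.table(data.frame(gene = rownames(corrmap$rho), corrmap$rho,
                         check.names = FALSE),
              p("rho_matrix.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(memory_genes, p("memory_genes.txt"))
  if (!is.null(modules))
    write.table(modules$assignment, p("modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(halflife) && halflife$status == "ok")
    jsonlite::write_json(halflife$test, p("halflife_test.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(lr))
    write.table(lr$results, p("lr_results.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(de)) {
    write.table(de, p("de_results.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    signature_export(de, outdir)
  }

  if (isTRUE(config$figures)) {
    figdir <- p("figures")
    dir.create(figdir, showWarnings = FALSE)
    if (!is.null(modules))
      plot_module_heatmap(corrmap, modules,
                          file.path(figdir, "modules_heatmap.png"))
    if (!is.null(halflife) && halflife$status == "ok") {
      bg <- setdiff(read_halflife(config[["halflife"]],
                                  config$halflife_units)$gene,
                    modules$assignment$gene)
      hl_table <- read_halflife(config[["halflife"]], config$halflife_units)
      plot_halflife_boxplot(
        halflife$join$matched$half_life_hours,
        hl_table$half_life_hours[hl_table$gene %in% bg],
        file.path(figdir, "halflife_boxplot.png"))
    }
    if (!is.null(lr) && lr$n_qualified > 0) {
      qr <- lr$results[lr$results$qualified, , drop = FALSE]
      for (i in seq_len(nrow(qr)))
        plot_lr_pair(qr[i, ], file.path(
          figdir, paste0("lr_", qr$gene_A[i], "_", qr$gene_B[i], ".png")))
    }
  }

  counts <- list(
    n_chambers = nrow(manifest),
    n_excluded = sum(classification$excluded),
    n_retained = sum(!classification$excluded),
    category_counts = as.list(attr(classification, "counts")),
    n_cells_before_filter = n_cells_pre,
    n_cells_after_filter = ncol(expr),
    n_genes_before_filter = n_genes_pre,
    n_genes_after_filter = nrow(expr),
    n_analysis_cids = bundle$n_c,
    n_hvg = length(hvg),
    n_memory_genes = length(memory_genes),
    module_sizes = if (!is.null(modules))
      as.list(table(modules$assignment$module)) else NULL,
    halflife = if (!is.null(halflife) && halflife$status == "ok")
      halflife$test[c("t", "df", "p", "n_module", "n_background")] else NULL,
    n_lr_candidates = if (!is.null(lr)) lr$n_candidates else NULL,
    n_lr_qualified = if (!is.null(lr)) lr$n_qualified else NULL,
    n_de_tested = if (!is.null(de)) nrow(de) else NULL,
    n_de_significant = if (!is.null(de)) sum(de$significant) else NULL)

  outputs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "provenance.json"]
  provenance <- list(
    config = unclass(config),
    counts = counts,
    timepoints_used = frames_used,
    missing_rho_imputed_for_clustering =
      if (!is.null(modules)) modules$n_imputed else NULL,
    batch_corrected = isTRUE(config$batch_corrected),
    output_hashes = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(provenance, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  res <- list(classification = classification, expr = expr, groups = groups,
              bundle = bundle, corrmap = corrmap,
              memory_genes = memory_genes, modules = modules,
              halflife = halflife, lr = lr, de = de, counts = counts,
              provenance = provenance, outdir = outdir)
  class(res) <- "cidmem_run"
  invisible(res)
}

#' @export
print.cidmem_run <- function(x, ...) {
  cat("cidmem pipeline run ->", x$outdir, "\n")
  cat(sprintf("  %d chambers: %d excluded, %d retained; |C| = %d\n",
              x$counts$n_chambers, x$counts$n_excluded,
              x$counts$n_retained, x$counts$n_analysis_cids))
  cat(sprintf("  %d memory genes", x$counts$n_memory_genes))
  if (!is.null(x$modules))
    cat(" in", x$modules$k, "modules (",
        paste(table(x$modules$assignment$module), collapse = "/"), ")")
  cat("\n")
  invisible(x)
}

#' Render a Markdown summary of a pipeline run
#'
#' Pure function of the saved results: regenerating the report from the same
#' run directory yields an identical file.  Stages that did not run are
#' marked as skipped.
#'
#' @param run a \code{\link{run_pipeline}} result (or its output directory,
#'   from which \code{provenance.json} is read).
#' @param file output Markdown path (default \code{report.md} in the run
#'   directory).
#' @return invisibly, the report path.
#' @export
render_report <- function(run, file = NULL) {
  if (is.character(run)) {
    prov <- jsonlite::read_json(file.path(run, "provenance.json"))
    outdir <- run
  } else {
    prov <- run$provenance
    outdir <- run$outdir
  }
  if (is.null(file)) file <- file.path(outdir, "report.md")
  cnt <- prov$counts
  # JSON round-trips drop NULLs or turn them into empty lists; treat both as
  # a skipped stage
  blank <- function(x) is.null(x) || length(x) == 0
  fmt <- function(x) if (blank(x)) "stage skipped" else x
  lines <- c(
    "# Doublet transcriptional-memory pipeline report", "",
    "## Chamber bookkeeping",
    sprintf("- chambers: %s; excluded: %s; retained: %s",
            cnt$n_chambers, cnt$n_excluded, cnt$n_retained),
    sprintf("- retained categories: %s",
            paste(names(cnt$category_counts)[6:9],
                  unlist(cnt$category_counts[6:9]), sep = "=",
                  collapse = ", ")),
    "",
    "## Filtering",
    sprintf("- cells %s -> %s (min expressed genes %s)",
            cnt$n_cells_before_filter, cnt$n_cells_after_filter,
            prov$config$min_expressed_genes),
    sprintf("- genes %s -> %s (value > %s in >= %s cells)",
            cnt$n_genes_before_filter, cnt$n_genes_after_filter,
            prov$config$gene_min_value, prov$config$gene_min_cells),
    "",
    "## Distance-expression correlation map",
    sprintf("- analysis doublets |C| = %s; %s variable genes; timepoints: %s",
            cnt$n_analysis_cids, cnt$n_hvg,
            paste(unlist(prov$timepoints_used), collapse = " ")),
    sprintf("- memory genes (|rho| >= %s at >= 1 timepoint): %s",
            prov$config$rho_threshold, cnt$n_memory_genes),
    sprintf("- modules: %s",
            if (blank(cnt$module_sizes)) "stage skipped"
            else paste(names(cnt$module_sizes),
                       unlist(cnt$module_sizes), sep = "=",
                       collapse = ", ")),
    "",
    "## mRNA half-life (module vs background)",
    if (blank(cnt$halflife)) "- stage skipped" else
      sprintf("- Welch t = %.4g, df = %.4g, p = %.4g (n = %s vs %s)",
              cnt$halflife$t, cnt$halflife$df, cnt$halflife$p,
              cnt$halflife$n_module, cnt$halflife$n_background),
    "",
    "## Ligand-receptor screen",
    sprintf("- candidate pairs: %s; qualified (rho_CID > %s): %s",
            fmt(cnt$n_lr_candidates), prov$config$cid_threshold,
            fmt(cnt$n_lr_qualified)),
    "",
    "## Differential expression (killing vs non-killing doublets)",
    sprintf("- genes tested: %s; significant at p_adj < %s & |log2FC| >= %s: %s",
            fmt(cnt$n_de_tested), prov$config$alpha, prov$config$lfc,
            fmt(cnt$n_de_significant)))
  writeLines(lines, file)
  invisible(file)
}
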