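# Figure helpers.  All writers go through save_figure(), which degrades to a
# warning when no png device is usable on the host.

save_figure <- function(draw, file, width = 7, height = 5, res = 150) {
  ok <- tryCatch({
    grDevices::png(file, width = width * res, height = height * res,
                   res = res)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
    TRUE
  }, error = function(e) {
    warning("figure skipped (", conditionMessage(e), "): ", file)
    FALSE
  })
  invisible(ok)
}

#' Module heatmap of the correlation map
#'
#' Fig. 2b-style heatmap of rho for the retained genes, rows ordered by
#' module, purple (low) to yellow (high) colour scale, with a module row
#' annotation.  Exchange-hour columns keep their frame labels (T5/T10 or
#' T5p/T10p) so the medium-change timepoints are visible.
#'
#' @param corrmap a \code{\link{correlate_distance_expression}} result.
#' @param modules a \code{\link{cluster_modules}} result.
#' @param file optional png path; when given the plot is written to disk.
#' @return the pheatmap object (invisibly when writing to file).
#' @export
plot_module_heatmap <- function(corrmap, modules, file = NULL) {
  asn <- modules$assignment
  rows <- corrmap$rho[asn$gene, , drop = FALSE]
  rows[is.na(rows)] <- 0
  ann <- data.frame(module = asn$module, row.names = asn$gene)
  pal <- grDevices::hcl.colors(101, "Viridis")
  draw <- function() pheatmap::pheatmap(
    rows, cluster_rows = FALSE, cluster_cols = FALSE, color = pal,
    annotation_row = ann, show_rownames = nrow(rows) <= 60,
    main = "distance-expression correlation (rho)")
  if (is.null(file)) draw() else save_figure(draw, file, width = 7,
                                             height = 6)
}

#' Boxplot of module vs background mRNA half-lives
#'
#' @param module_hl,background_hl numeric half-life vectors (hours).
#' @param file optional png path.
#' @return a ggplot object (invisibly when writing to file).
#' @export
plot_halflife_boxplot <- function(module_hl, background_hl, file = NULL) {
  df <- data.frame(
    group = rep(c("module", "background"),
                c(length(module_hl), length(background_hl))),
    half_life = c(module_hl, background_hl))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = group, y = half_life,
                                        fill = group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "mRNA half-life (h)") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    save_figure(function() print(p), file, width = 4, height = 4)
    return(invisible(p))
  }
  p
}

#' Grouped barplot of per-group correlations for one ligand-receptor pair
#'
#' @param rho_row one row of a \code{\link{group_pair_correlations}} result.
#' @param file optional png path.
#' @return a ggplot object (invisibly when writing to file).
#' @export
plot_lr_pair <- function(rho_row, file = NULL) {
  rho_cols <- grep("^rho_", names(rho_row), value = TRUE)
  df <- data.frame(group = sub("^rho_", "", rho_cols),
                   rho = as.numeric(rho_row[rho_cols]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = group, y = rho,
                                        fill = group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0.4, linetype = 2) +
    ggplot2::labs(title = paste(rho_row$gene_A, "/", rho_row$gene_B),
                  x = NULL, y = "Pearson rho") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    save_figure(function() print(p), file, width = 5, height = 4)
    return(invisible(p))
  }
  p
}
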