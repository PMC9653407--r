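#' Differential expression between killing and non-killing doublets
#'
#' A transparent two-group test at the published decision thresholds: per
#' gene, the log2 fold change of group means on the log2(1 + x) scale, a
#' two-sided Welch t-test, and Benjamini-Hochberg adjustment across tested
#' genes.  A gene is flagged significant when adjusted p < \code{alpha} and
#' |log2FC| >= \code{lfc}.  Genes with zero variance in both groups are
#' excluded from testing and reported.
#'
#' @param expr genes-x-cells matrix of non-negative values.
#' @param labels per-cell group labels (named by cell id or aligned with
#'   columns).
#' @param group_test,group_ref the two labels to compare; log2FC is
#'   test minus reference (killing vs non-killing by convention).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc absolute log2-fold-change cutoff (default 1).
#' @return data.frame: gene, mean_test, mean_ref, log2FC, t, df, p, p_adj,
#'   direction, significant; attribute \code{excluded_genes}.
#' @export
differential_expression <- function(expr, labels, group_test = "CID_NK_only",
                                    group_ref = "CID", alpha = 0.05,
                                    lfc = 1) {
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  if (length(labels) != ncol(expr))
    stop("labels must cover every cell of the expression matrix")
  i1 <- which(labels == group_test)
  i2 <- which(labels == group_ref)
  if (length(i1) < 3 || length(i2) < 3)
    stop("each group needs at least 3 cells (", group_test, ": ",
         length(i1), ", ", group_ref, ": ", length(i2), ")")
  x <- log2(1 + expr[, i1, drop = FALSE])
  y <- log2(1 + expr[, i2, drop = FALSE])
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, var); v2 <- apply(y, 1, var)

  testable <- !(v1 == 0 & v2 == 0)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)

  out <- data.frame(gene = rownames(expr), mean_test = m1, mean_ref = m2,
                    log2FC = m1 - m2, t = t_stat, df = df, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[testable, , drop = FALSE]
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$log2FC >= 0, "up", "down")
  out$significant <- out$p_adj < alpha & abs(out$log2FC) >= lfc
  out <- out[order(out$p_adj, out$p, out$gene), ]
  rownames(out) <- NULL
  attr(out, "excluded_genes") <- rownames(expr)[!testable]
  attr(out, "groups") <- c(test = group_test, ref = group_ref)
  out
}

#' Export up/down gene signatures
#'
#' Writes the significant up- and down-regulated gene lists as plain-text
#' files for external tools (e.g. survival portals); no survival computation
#' is performed here.
#'
#' @param de_table result of \code{\link{differential_expression}}.
#' @param dir output directory.
#' @return invisibly, named character vector of the two file paths.
#' @export
signature_export <- function(de_table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  up <- de_table$gene[de_table$significant & de_table$direction == "up"]
  down <- de_table$gene[de_table$significant & de_table$direction == "down"]
  if (length(up) + length(down) == 0)
    warning("no significant genes; writing empty signature files")
  up_path <- file.path(dir, "signature_up.txt")
  down_path <- file.path(dir, "signature_down.txt")
  writeLines(up, up_path)
  writeLines(down, down_path)
  invisible(c(up = up_path, down = down_path))
}
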