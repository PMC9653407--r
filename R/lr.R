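#' Select the most highly expressed genes
#'
#' Ranks genes by mean expression across all cells and keeps the top
#' fraction; ties are broken by gene id.
#'
#' @param expr genes-x-cells matrix (typically the full filtered matrix, all
#'   retained cells).
#' @param top_frac fraction of genes to keep, in (0, 1] (default 0.5; the top
#'   \code{ceiling(top_frac * G)} genes).
#' @return character vector of selected gene ids.
#' @export
select_top_expressed <- function(expr, top_frac = 0.5) {
  if (top_frac <= 0 || top_frac > 1)
    stop("configuration error: top_frac must be in (0, 1]")
  means <- rowMeans(expr)
  ord <- order(-means, rownames(expr))
  rownames(expr)[ord[seq_len(ceiling(top_frac * nrow(expr)))]]
}

#' Candidate ligand-receptor pairs among selected genes
#'
#' Keeps database pairs whose two genes are both in the selected gene set.
#' Self-pairs and duplicate unordered pairs are dropped; pairs naming a gene
#' absent from the expression universe (when given) are dropped with a
#' warning.
#'
#' @param selected_genes character vector (from
#'   \code{\link{select_top_expressed}}).
#' @param lr_db data.frame with gene_A, gene_B and optional category.
#' @param universe optional vector of genes present in the expression matrix.
#' @return the qualifying subset of \code{lr_db}.
#' @export
find_lr_pairs <- function(selected_genes, lr_db, universe = NULL) {
  if (is.null(lr_db$gene_A) || is.null(lr_db$gene_B))
    stop("ligand-receptor table needs columns gene_A and gene_B")
  db <- lr_db[lr_db$gene_A != lr_db$gene_B, , drop = FALSE]
  key <- paste(pmin(db$gene_A, db$gene_B), pmax(db$gene_A, db$gene_B))
  db <- db[!duplicated(key), , drop = FALSE]
  if (!is.null(universe)) {
    known <- db$gene_A %in% universe & db$gene_B %in% universe
    if (any(!known))
      warning(sum(!known), " pair(s) dropped: gene absent from the ",
              "expression matrix")
    db <- db[known, , drop = FALSE]
  }
  out <- db[db$gene_A %in% selected_genes & db$gene_B %in% selected_genes, ,
            drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group co-expression of ligand-receptor pairs
#'
#' For every pair and every cell group with at least \code{n_min} cells, the
#' Pearson correlation between the two genes' expression across that group's
#' cells.  Groups below \code{n_min} and zero-variance genes give missing
#' entries.
#'
#' @param pairs data.frame with gene_A and gene_B.
#' @param expr genes-x-cells matrix containing both genes of every pair.
#' @param groups factor or character vector of group labels, named by cell id
#'   or aligned with \code{colnames(expr)}.
#' @param n_min minimum cells per group (default 5).
#' @return data.frame: gene_A, gene_B, then one \code{rho_<group>} column per
#'   group; attribute \code{group_sizes}.
#' @export
group_pair_correlations <- function(pairs, expr, groups, n_min = 5) {
  if (!is.null(names(groups))) groups <- groups[colnames(expr)]
  if (length(groups) != ncol(expr))
    stop("groups must label every cell of the expression matrix")
  groups <- as.character(groups)
  levels <- unique(groups[!is.na(groups)])
  missing_genes <- setdiff(unique(c(pairs$gene_A, pairs$gene_B)),
                           rownames(expr))
  if (length(missing_genes))
    stop("pair gene(s) absent from the expression matrix: ",
         paste(head(missing_genes, 5), collapse = ", "))
  out <- pairs[, c("gene_A", "gene_B"), drop = FALSE]
  sizes <- setNames(integer(length(levels)), levels)
  for (g in levels) {
    cols <- which(groups == g)
    sizes[g] <- length(cols)
    rho <- rep(NA_real_, nrow(pairs))
    if (length(cols) >= n_min) {
      for (i in seq_len(nrow(pairs))) {
        a <- expr[pairs$gene_A[i], cols]
        b <- expr[pairs$gene_B[i], cols]
        if (sd(a) > 0 && sd(b) > 0) rho[i] <- cor(a, b)
      }
    }
    out[[paste0("rho_", g)]] <- rho
  }
  rownames(out) <- NULL
  attr(out, "group_sizes") <- sizes
  out
}

#' Qualify doublet-specific co-expressed pairs
#'
#' A pair qualifies when its correlation in the primary doublet group
#' strictly exceeds \code{cid_threshold}.  The default rule-out
#' (\code{ruleout = "singlet-low"}) additionally requires that no singlet
#' group (NK-only or cancer-only chambers) exceeds \code{single_threshold},
#' so that co-expression attributable to one cell type alone is discarded;
#' \code{ruleout = "cid-only"} applies the doublet threshold alone.  Raw
#' per-group correlations are always carried along so other conventions can
#' be applied downstream.
#'
#' @param rho_table result of \code{\link{group_pair_correlations}}.
#' @param cid_threshold doublet-group correlation threshold, exceeded
#'   strictly (default 0.4).
#' @param single_threshold singlet-group threshold for the rule-out (default
#'   0.4).
#' @param cid_group primary doublet group (default \code{"CID"}; falls back
#'   to \code{"CID_NK_only"} for pairs missing there).
#' @param singlet_groups singlet group names (default NK and cancer).
#' @param ruleout \code{"singlet-low"} (default) or \code{"cid-only"}.
#' @return \code{rho_table} with an added logical \code{qualified} column.
#' @export
qualify_pairs <- function(rho_table, cid_threshold = 0.4,
                          single_threshold = 0.4, cid_group = "CID",
                          singlet_groups = c("NK", "cancer"),
                          ruleout = c("singlet-low", "cid-only")) {
  ruleout <- match.arg(ruleout)
  col <- function(g) rho_table[[paste0("rho_", g)]]
  rho_cid <- col(cid_group)
  if (is.null(rho_cid))
    stop("no rho_", cid_group, " column in the correlation table")
  fallback <- col("CID_NK_only")
  if (!is.null(fallback)) rho_cid[is.na(rho_cid)] <- fallback[is.na(rho_cid)]
  qualified <- !is.na(rho_cid) & rho_cid > cid_threshold
  if (ruleout == "singlet-low") {
    for (g in singlet_groups) {
      rg <- col(g)
      if (!is.null(rg))
        qualified <- qualified & !(!is.na(rg) & rg > single_threshold)
    }
  }
  rho_table$qualified <- qualified
  rho_table
}

#' Ligand-receptor co-expression screen
#'
#' End-to-end screen: selects the top-expressed half of the genes across all
#' retained cells, intersects the ligand-receptor database with that set,
#' computes per-group Pearson correlations, and qualifies doublet-specific
#' pairs.
#'
#' @param expr filtered genes-x-cells matrix (all retained cells).
#' @param lr_db ligand-receptor table (gene_A, gene_B, category).
#' @param groups per-cell group labels (named by cell id).
#' @param top_frac,cid_threshold,single_threshold,ruleout,n_min passed to the
#'   stage functions.
#' @return list: \code{selected_genes}, \code{candidates}, \code{results}
#'   (per-group rho + qualified flag), \code{n_candidates},
#'   \code{n_qualified}.
#' @export
lr_screen <- function(expr, lr_db, groups, top_frac = 0.5,
                      cid_threshold = 0.4, single_threshold = 0.4,
                      ruleout = "singlet-low", n_min = 5) {
  selected <- select_top_expressed(expr, top_frac)
  candidates <- find_lr_pairs(selected, lr_db, universe = rownames(expr))
  if (nrow(candidates) == 0)
    return(list(selected_genes = selected, candidates = candidates,
                results = candidates, n_candidates = 0L, n_qualified = 0L))
  rho <- group_pair_correlations(candidates, expr, groups, n_min = n_min)
  res <- qualify_pairs(rho, cid_threshold, single_threshold,
                       ruleout = ruleout)
  if (!is.null(candidates$category)) res$category <- candidates$category
  list(selected_genes = selected, candidates = candidates, results = res,
       n_candidates = nrow(res), n_qualified = sum(res$qualified))
}
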