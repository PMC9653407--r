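#' Select highly variable genes
#'
#' Ranks genes by the variance of log(1 + x) across cells and keeps the top
#' \code{k}.  Ties are broken by rank then lexicographic gene id, so the
#' selection is deterministic.
#'
#' @param expr genes-x-cells matrix.
#' @param k number of genes to keep (default 2000).  If \code{k} is at least
#'   the number of available genes, all are returned (with a warning when
#'   strictly larger).
#' @return character vector of selected gene ids, in decreasing dispersion
#'   order.
#' @export
select_variable_genes <- function(expr, k = 2000) {
  if (k < 1) stop("configuration error: k must be >= 1")
  disp <- apply(log1p(expr), 1, var)
  ord <- order(-disp, rownames(expr))
  if (k > nrow(expr)) {
    warning("k = ", k, " exceeds the ", nrow(expr),
            " available genes; using all")
    k <- nrow(expr)
  }
  rownames(expr)[ord[seq_len(k)]]
}

#' Gene-by-timepoint distance-expression correlation map
#'
#' For every gene g and timepoint t, the Pearson correlation across doublets
#' between the terminal expression of g and the cell-cell distance measured
#' at t.  Correlations are computed over pairwise-complete doublets (killing
#' events truncate trajectories); entries with fewer than \code{n_min}
#' complete pairs or with zero variance are set missing.
#'
#' @param expr_cid genes x doublets expression matrix.
#' @param dist_mat doublets x timepoints distance matrix (same doublets, in
#'   the same order; typically \code{align_inputs()$dist} subset by
#'   \code{\link{timepoint_policy}}).
#' @param n_min minimum complete pairs per entry (default 5).
#' @return object of class \code{cidmem_corrmap}: list with \code{rho}
#'   (genes x timepoints), \code{n_used} (same shape), \code{n_min}.
#' @export
correlate_distance_expression <- function(expr_cid, dist_mat, n_min = 5) {
  if (ncol(expr_cid) != nrow(dist_mat))
    stop("expression and distance matrices disagree on the number of ",
         "doublets (", ncol(expr_cid), " vs ", nrow(dist_mat), ")")
  n_complete <- crossprod(!is.na(t(expr_cid)), !is.na(dist_mat))
  if (max(n_complete) < 3)
    stop("fatal: fewer than 3 complete doublet pairs at every ",
         "gene-timepoint combination")
  rho <- suppressWarnings(cor(t(expr_cid), dist_mat,
                              use = "pairwise.complete.obs"))
  rho[n_complete < n_min] <- NA_real_
  dimnames(rho) <- list(rownames(expr_cid), colnames(dist_mat))
  dimnames(n_complete) <- dimnames(rho)
  structure(list(rho = rho, n_used = n_complete, n_min = n_min),
            class = "cidmem_corrmap")
}

#' @export
print.cidmem_corrmap <- function(x, ...) {
  cat("cidmem correlation map:", nrow(x$rho), "genes x", ncol(x$rho),
      "timepoints;", sum(is.na(x$rho)), "missing entries\n")
  invisible(x)
}

#' Retain memory genes from the correlation map
#'
#' A gene is retained when |rho| meets \code{threshold} (inclusive) at one or
#' more timepoints, i.e. its terminal expression still reflects the distance
#' measured at some earlier hour.
#'
#' @param corrmap a \code{\link{correlate_distance_expression}} result.
#' @param threshold absolute-correlation cutoff in (0, 1] (default 0.25).
#' @return character vector of retained gene ids.
#' @export
select_memory_genes <- function(corrmap, threshold = 0.25) {
  stopifnot(inherits(corrmap, "cidmem_corrmap"))
  if (threshold <= 0 || threshold > 1)
    stop("configuration error: threshold must be in (0, 1]")
  max_abs <- apply(abs(corrmap$rho), 1, function(r)
    if (all(is.na(r))) -Inf else max(r, na.rm = TRUE))
  rownames(corrmap$rho)[max_abs >= threshold]
}

#' Cluster memory genes into modules
#'
#' Agglomerative hierarchical clustering of the retained genes' correlation
#' profiles, cut into exactly \code{k} modules.  The default dissimilarity
#' is the angular (uncentered-cosine) distance between rho profiles: genes
#' are grouped by where in the time course their correlation mass sits and
#' by its sign, not by its amplitude, so an induced early module, a
#' repressed mid-course module and weak bystander genes all point in
#' different directions instead of pooling into amplitude shells.
#' Centered-correlation and Euclidean dissimilarities are available as
#' alternatives.  Missing rho entries are imputed as 0 for clustering only
#' (the count is recorded).  Modules are renamed M1..Mk by their median
#' member peak timepoint, earliest first, so labels are stable across runs.
#'
#' @param corrmap a \code{\link{correlate_distance_expression}} result.
#' @param genes retained gene ids (from \code{\link{select_memory_genes}}).
#' @param k number of modules (default 4).
#' @param linkage \code{hclust} method (default \code{"ward.D2"}, which
#'   resists chaining when bystander genes pass the retention threshold).
#' @param metric \code{"cosine"} (default), \code{"correlation"} or
#'   \code{"euclidean"}.
#' @return object of class \code{cidmem_modules}: list with
#'   \code{assignment} (data.frame gene, module, peak_timepoint),
#'   \code{tree} (hclust), \code{k}, \code{n_imputed}.
#' @export
cluster_modules <- function(corrmap, genes, k = 4, linkage = "ward.D2",
                            metric = c("cosine", "correlation",
                                       "euclidean")) {
  stopifnot(inherits(corrmap, "cidmem_corrmap"))
  metric <- match.arg(metric)
  genes <- intersect(genes, rownames(corrmap$rho))
  if (k < 1) stop("configuration error: k must be >= 1")
  if (k > length(genes))
    stop("k = ", k, " exceeds the ", length(genes), " retained genes")
  rows <- corrmap$rho[genes, , drop = FALSE]
  n_imputed <- sum(is.na(rows))
  rows[is.na(rows)] <- 0
  d <- switch(metric,
    cosine = {
      nrm <- sqrt(rowSums(rows^2))
      unit <- rows / ifelse(nrm > 0, nrm, 1)  # all-zero rows stay at origin
      stats::as.dist(sqrt(pmax(2 - 2 * tcrossprod(unit), 0)))
    },
    correlation = {
      rv <- apply(rows, 1, sd)
      safe <- rows
      safe[rv == 0, ] <- safe[rv == 0, , drop = FALSE] +
        1e-12 * seq_len(ncol(rows))           # constant-profile guard
      stats::as.dist(1 - cor(t(safe)))
    },
    euclidean = dist(rows))
  tree <- hclust(d, method = linkage)
  raw <- cutree(tree, k = k)

  peak_of <- apply(abs(rows), 1, which.max)
  cluster_peak <- vapply(seq_len(k), function(cl)
    median(peak_of[raw == cl]), numeric(1))
  # earliest median peak becomes M1; ties broken by first member gene id
  first_gene <- vapply(seq_len(k), function(cl)
    min(names(raw)[raw == cl]), character(1))
  new_order <- order(cluster_peak, first_gene)
  relabel <- setNames(seq_len(k), new_order)
  module <- paste0("M", relabel[as.character(raw)])

  assignment <- data.frame(gene = names(raw), module = module,
                           peak_timepoint = colnames(rows)[peak_of],
                           stringsAsFactors = FALSE, row.names = NULL)
  assignment <- assignment[order(assignment$module, assignment$gene), ]
  rownames(assignment) <- NULL
  structure(list(assignment = assignment, tree = tree, k = k,
                 n_imputed = n_imputed),
            class = "cidmem_modules")
}

#' @export
print.cidmem_modules <- function(x, ...) {
  cat("cidmem modules:", nrow(x$assignment), "genes in", x$k, "modules (",
      paste(table(x$assignment$module), collapse = "/"), ")\n")
  invisible(x)
}
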