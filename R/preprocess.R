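chamber_categories <- c("excluded_empty", "excluded_cancer_to_empty",
                        "excluded_nk_to_empty", "excluded_nk_start_cid",
                        "excluded_cid_to_cancer",
                        "NK", "cancer", "CID", "CID_NK_only")

#' Classify chambers from their start and end composition
#'
#' Applies the exclusion rules of the experimental bookkeeping: chambers that
#' started empty, singlet chambers that ended empty (cell lost), doublet
#' chambers that started with a single NK cell, and doublet chambers that
#' ended with the cancer cell alone are excluded.  Doublets that ended with
#' the NK cell alone are retained as killing events (\code{CID_NK_only});
#' everything else retains its composition category.
#'
#' @param manifest data.frame with chamber_id, start_composition and
#'   end_composition (values in \code{empty}, \code{NK}, \code{cancer},
#'   \code{CID}).
#' @return data.frame (chamber_id, category, excluded) with attribute
#'   \code{counts} (category table); categories form a partition.
#' @export
#' @examples
#' man <- simulate_manifest(sim_config())
#' table(classify_chambers(man)$category)
classify_chambers <- function(manifest) {
  if (nrow(manifest) == 0)
    return(structure(data.frame(chamber_id = character(0),
                                category = character(0),
                                excluded = logical(0)),
                     counts = table(factor(character(0),
                                           levels = chamber_categories))))
  comp <- c("empty", "NK", "cancer", "CID")
  bad <- which(!(manifest$start_composition %in% comp) |
                 !(manifest$end_composition %in% comp))
  if (length(bad))
    stop("parse error: unknown composition label in manifest row(s) ",
         paste(head(bad, 5), collapse = ", "),
         " (chamber ", manifest$chamber_id[bad[1]], ")")
  s <- manifest$start_composition
  e <- manifest$end_composition
  category <- rep(NA_character_, nrow(manifest))
  category[s == "empty"] <- "excluded_empty"
  category[s == "cancer" & e == "empty"] <- "excluded_cancer_to_empty"
  category[s == "NK" & e == "empty"] <- "excluded_nk_to_empty"
  category[s == "NK" & e == "CID"] <- "excluded_nk_start_cid"
  category[s == "CID" & e == "cancer"] <- "excluded_cid_to_cancer"
  category[s == "NK" & e == "NK"] <- "NK"
  category[s == "cancer" & e == "cancer"] <- "cancer"
  category[s == "CID" & e == "CID"] <- "CID"
  category[s == "CID" & e == "NK"] <- "CID_NK_only"
  un <- which(is.na(category))
  if (length(un))
    stop("parse error: unclassifiable composition ", s[un[1]], " -> ",
         e[un[1]], " in manifest row ", un[1],
         " (chamber ", manifest$chamber_id[un[1]], ")")
  out <- data.frame(chamber_id = manifest$chamber_id,
                    category = category,
                    excluded = startsWith(category, "excluded_"),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(category, levels = chamber_categories))
  out
}

#' Remove low-complexity cells
#'
#' Discards cells expressing (strictly positive value) fewer than
#' \code{min_expressed_genes} genes; a cell with exactly the threshold count
#' is retained.  Column order of survivors is preserved.
#'
#' @param expr genes-x-cells matrix of non-negative values.
#' @param min_expressed_genes minimum number of expressed genes (default
#'   2000).
#' @return the filtered matrix, with attribute \code{removed_cells}.
#' @export
filter_cells <- function(expr, min_expressed_genes = 2000) {
  if (min_expressed_genes < 0)
    stop("configuration error: min_expressed_genes must be >= 0")
  if (nrow(expr) == 0 || ncol(expr) == 0) stop("empty expression matrix")
  n_expressed <- colSums(expr > 0, na.rm = TRUE)
  keep <- n_expressed >= min_expressed_genes
  out <- expr[, keep, drop = FALSE]
  attr(out, "removed_cells") <- colnames(expr)[!keep]
  out
}

#' Remove rarely expressed genes
#'
#' Retains a gene only if its value exceeds \code{min_value} (strictly) in at
#' least \code{min_cells} cells.  Intended to run after
#' \code{\link{filter_cells}}; the pipeline applies cells first, then genes.
#'
#' @param expr genes-x-cells matrix.
#' @param min_value expression threshold, exceeded strictly (default 5).
#' @param min_cells minimum number of cells above threshold (default 10).
#' @return the filtered matrix, with attribute \code{removed_genes}.
#' @export
filter_genes <- function(expr, min_value = 5, min_cells = 10) {
  if (min_value < 0 || min_cells < 0)
    stop("configuration error: gene-filter thresholds must be >= 0")
  n_above <- rowSums(expr > min_value, na.rm = TRUE)
  keep <- n_above >= min_cells
  out <- expr[keep, , drop = FALSE]
  attr(out, "removed_genes") <- rownames(expr)[!keep]
  out
}

#' Z-score normalize staining-channel intensities
#'
#' Each channel is independently centred to mean 0 and scaled to sample
#' standard deviation 1.
#'
#' @param intensities data.frame with a \code{cell_id} column and one numeric
#'   column per fluorescence channel.
#' @return data.frame of the same shape with normalized channels.
#' @export
#' @examples
#' zscore_channels(data.frame(cell_id = c("a", "b", "c"),
#'                            nk_channel = c(1, 2, 3)))
zscore_channels <- function(intensities) {
  channels <- setdiff(names(intensities), "cell_id")
  if (nrow(intensities) < 2) stop("need at least 2 cells per channel")
  for (ch in channels) {
    v <- intensities[[ch]]
    if (!all(is.finite(v))) stop("non-finite intensities in channel ", ch)
    s <- sd(v)
    if (s == 0) stop("zero-variance channel: ", ch)
    intensities[[ch]] <- (v - mean(v)) / s
  }
  intensities
}

#' Pair doublet expression with distance trajectories
#'
#' Restricts the expression matrix to doublet libraries of the requested
#' categories, joins them with the distance table on identifier, sorts both to
#' a common order, and reports ids present on only one side (dropped with a
#' warning).
#'
#' @param expr filtered genes-x-cells matrix.
#' @param distances data.frame from \code{\link{read_distances}} or
#'   \code{\link{simulate_distances}}.
#' @param classification result of \code{\link{classify_chambers}}.
#' @param categories doublet categories to include (default \code{CID} and
#'   \code{CID_NK_only}).
#' @return list: \code{expr_cid} (genes x C), \code{dist} (C x frames
#'   matrix), \code{cid_ids}, \code{n_c}, \code{dropped_expr},
#'   \code{dropped_dist}, \code{frames}.
#' @export
align_inputs <- function(expr, distances, classification,
                         categories = c("CID", "CID_NK_only")) {
  doublets <- classification$chamber_id[classification$category %in%
                                          categories]
  expr_ids <- intersect(colnames(expr), doublets)
  common <- sort(intersect(expr_ids, distances$cid_id))
  if (length(common) == 0)
    stop("fatal join error: no doublet is present in both the expression ",
         "matrix and the distance table")
  dropped_expr <- setdiff(expr_ids, common)
  dropped_dist <- setdiff(distances$cid_id, common)
  if (length(dropped_expr))
    warning(length(dropped_expr),
            " doublet(s) with expression but no distance record dropped")
  if (length(dropped_dist))
    warning(length(dropped_dist),
            " distance trajectory(ies) without expression dropped")
  frames <- attr(distances, "frames") %||% setdiff(names(distances), "cid_id")
  dmat <- as.matrix(distances[match(common, distances$cid_id), frames,
                              drop = FALSE])
  rownames(dmat) <- common
  list(expr_cid = expr[, common, drop = FALSE], dist = dmat,
       cid_ids = common, n_c = length(common),
       dropped_expr = dropped_expr, dropped_dist = dropped_dist,
       frames = frames)
}
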