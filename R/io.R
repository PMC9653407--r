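#' Read and write expression matrices
#'
#' Tab-separated genes-x-cells tables (gene ids in the first column, cell ids
#' in the header) and MatrixMarket sparse triplets with sidecar
#' \code{genes.txt}/\code{cells.txt} name files are both supported.
#'
#' @param path file to read or write. For MTX the gene/cell name files default
#'   to \code{genes.txt} and \code{cells.txt} next to it.
#' @param genes_file,cells_file sidecar name files for the MTX variant.
#' @return \code{read_*} return a numeric matrix (genes x cells);
#'   \code{write_*} return the path invisibly.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values in ", path)
  m
}

#' @rdname expression_io
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @param mat numeric genes-x-cells matrix with dimnames.
#' @export
write_expression_mtx <- function(mat, path,
                                 genes_file = file.path(dirname(path),
                                                        "genes.txt"),
                                 cells_file = file.path(dirname(path),
                                                        "cells.txt")) {
  Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
  writeLines(rownames(mat), genes_file)
  writeLines(colnames(mat), cells_file)
  invisible(path)
}

#' @rdname expression_io
#' @export
read_expression_mtx <- function(path,
                                genes_file = file.path(dirname(path),
                                                       "genes.txt"),
                                cells_file = file.path(dirname(path),
                                                       "cells.txt")) {
  m <- as.matrix(Matrix::readMM(path))
  rn <- readLines(genes_file)
  cn <- readLines(cells_file)
  if (nrow(m) != length(rn) || ncol(m) != length(cn))
    stop("MTX dimensions do not match the gene/cell name files")
  dimnames(m) <- list(rn, cn)
  m
}

#' Read the chamber manifest
#'
#' @param path TSV with header columns chamber_id, start_composition,
#'   end_composition, run_id, sequenced.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chamber_id", "start_composition", "end_composition")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(man$chamber_id)) stop("duplicate chamber_id in ", path)
  if (!is.null(man$sequenced)) man$sequenced <- as.logical(man$sequenced)
  man
}

#' Read a distance table
#'
#' @param path CSV with a \code{cid_id} column followed by one column per
#'   image frame (T0..T13 plus T5p/T10p); empty cells are missing distances.
#' @return data.frame with attribute \code{frames}.
#' @export
read_distances <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "cid_id") stop("first column of ", path,
                                    " must be cid_id")
  frames <- names(d)[-1]
  frame_hours(frames)  # validates labels
  for (j in frames) d[[j]] <- as.numeric(d[[j]])
  vals <- as.matrix(d[, frames, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) stop("negative distances in ", path)
  attr(d, "frames") <- frames
  d
}

#' Read an mRNA half-life table
#'
#' @param path TSV with columns gene and half_life_hours (or half_life plus
#'   \code{units}).
#' @param units \code{"hours"} or \code{"minutes"}; minutes are divided by 60.
#' @return data.frame with columns gene, half_life_hours.
#' @export
read_halflife <- function(path, units = c("hours", "minutes")) {
  units <- match.arg(units)
  hl <- read.delim(path, stringsAsFactors = FALSE)
  val_col <- intersect(c("half_life_hours", "half_life"), names(hl))[1]
  if (is.na(val_col) || is.null(hl$gene))
    stop("half-life table needs columns gene and half_life(_hours)")
  out <- data.frame(gene = hl$gene,
                    half_life_hours = as.numeric(hl[[val_col]]),
                    stringsAsFactors = FALSE)
  if (units == "minutes") out$half_life_hours <- out$half_life_hours / 60
  if (any(!is.finite(out$half_life_hours)) || any(out$half_life_hours <= 0))
    stop("half-life values must be positive and finite")
  if (anyDuplicated(out$gene)) stop("duplicate genes in half-life table")
  out
}

#' Read a ligand-receptor pair table
#'
#' @param path TSV with columns gene_A, gene_B and optional category.
#' @return data.frame.
#' @export
read_lr_pairs <- function(path) {
  db <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(db$gene_A) || is.null(db$gene_B))
    stop("ligand-receptor table needs columns gene_A and gene_B")
  if (is.null(db$category)) db$category <- NA_character_
  db
}
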