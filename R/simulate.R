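#' Ground truth of the synthetic experiment
#'
#' Draws everything downstream recovery tests need to know: module membership
#' and peak timepoints, per-gene mRNA half-lives (module genes with a longer
#' mean than background), the planted coordinated ligand-receptor pairs, the
#' killing-upregulated gene set, lineage marker genes, and the kill hour of
#' each killing-event doublet.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{cidmem_truth}: list with elements
#'   \code{genes} (data.frame: gene_id, module, peak_time, half_life,
#'   low_expressed, nk_marker, cancer_marker, de_up), \code{lr_pairs}
#'   (data.frame: gene_A, gene_B, coordinated) and \code{kill_times}
#'   (hours, one per killing event).
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "cidmem_sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  gene_id <- sprintf("G%04d", seq_len(G))
  k <- length(config$module_sizes)

  module <- rep("background", G)
  peak <- rep(NA_real_, G)
  csign <- rep(0, G)
  mod_idx <- sample.int(G, sum(config$module_sizes))
  off <- 0L
  for (m in seq_len(k)) {
    idx <- mod_idx[(off + 1L):(off + config$module_sizes[m])]
    module[idx] <- paste0("M", m)
    peak[idx] <- config$module_peaks[m]
    csign[idx] <- config$module_signs[m]
    off <- off + config$module_sizes[m]
  }

  # lognormal half-lives; modules drawn around a longer mean than background
  sdlog <- config$halflife_log_sd
  meanlog <- function(m) log(m) - sdlog^2 / 2
  half_life <- rlnorm(G, meanlog(config$halflife_background_mean), sdlog)
  half_life[module != "background"] <-
    rlnorm(sum(module != "background"), meanlog(config$halflife_module_mean),
           sdlog)

  bg <- setdiff(seq_len(G), mod_idx)
  n_low <- round(config$frac_low_expressed * length(bg))
  low_idx <- sample(bg, n_low)
  healthy_bg <- setdiff(bg, low_idx)

  n_lr_genes <- 2L * (config$n_lr_pairs_coordinated + config$n_lr_pairs_null)
  n_special <- n_lr_genes + config$n_de_genes + 80L
  if (length(healthy_bg) < n_special)
    stop("configuration error: too few background genes for planted ",
         "ligand-receptor pairs, DE genes and lineage markers")
  special <- sample(healthy_bg, n_special)
  lr_genes <- special[seq_len(n_lr_genes)]
  de_idx <- special[n_lr_genes + seq_len(config$n_de_genes)]
  marker_idx <- special[n_lr_genes + config$n_de_genes + seq_len(80L)]
  nk_idx <- marker_idx[1:40]
  ca_idx <- marker_idx[41:80]

  lr_mat <- matrix(gene_id[lr_genes], ncol = 2, byrow = TRUE)
  lr_pairs <- data.frame(
    gene_A = lr_mat[, 1], gene_B = lr_mat[, 2],
    coordinated = rep(c(TRUE, FALSE),
                      c(config$n_lr_pairs_coordinated,
                        config$n_lr_pairs_null)),
    stringsAsFactors = FALSE)

  kill_times <- if (config$n_killed > 0)
    sample(3:max(3L, config$n_timepoints - 1L), config$n_killed,
           replace = TRUE) else integer(0)

  genes <- data.frame(gene_id = gene_id, module = module, peak_time = peak,
                      coupling_sign = csign, half_life = half_life,
                      low_expressed = seq_len(G) %in% low_idx,
                      nk_marker = seq_len(G) %in% nk_idx,
                      cancer_marker = seq_len(G) %in% ca_idx,
                      de_up = seq_len(G) %in% de_idx,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, lr_pairs = lr_pairs,
                 kill_times = kill_times),
            class = "cidmem_truth")
}

#' Simulate the chamber manifest
#'
#' Emits one row per chamber library with its start and end composition,
#' run/batch label and a \code{sequenced} flag.  The default configuration
#' reproduces the printed composition of the motivating experiment: 336
#' chambers of which 46 fall in excluded categories (4 start-empty, 8
#' cancer-to-empty, 10 NK-to-empty, 2 NK-start doublets, 22
#' doublet-to-cancer-only) and 290 are retained (77 NK singlets, 71 cancer
#' singlets, 132 intact doublets, 10 killing-event doublets).  Among the
#' intact doublets, \code{n_cid - n_killed} are flagged as sequenced for the
#' distance-correlation analysis; which ones is drawn uniformly per seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame: chamber_id, start_composition, end_composition,
#'   run_id, sequenced.
#' @export
simulate_manifest <- function(config) {
  stopifnot(inherits(config, "cidmem_sim_config"))
  set.seed(config$seed + 1L)
  ex <- config$excluded_counts
  block <- function(start, end, n) if (n > 0)
    data.frame(start_composition = rep(start, n),
               end_composition = rep(end, n), stringsAsFactors = FALSE)
  rows <- rbind(block("empty", "empty", ex[["empty"]]),
                block("cancer", "empty", ex[["cancer_to_empty"]]),
                block("NK", "empty", ex[["nk_to_empty"]]),
                block("NK", "CID", ex[["nk_start_cid"]]),
                block("CID", "cancer", ex[["cid_to_cancer"]]),
                block("NK", "NK", config$n_single_nk),
                block("cancer", "cancer", config$n_single_cancer),
                block("CID", "CID", config$n_cid_tracked),
                block("CID", "NK", config$n_killed))
  n <- nrow(rows)
  width <- max(3L, nchar(n))
  man <- data.frame(chamber_id = sprintf(paste0("CH%0", width, "d"),
                                         seq_len(n)),
                    rows,
                    run_id = sample(paste0("R", seq_len(config$n_runs)), n,
                                    replace = TRUE),
                    sequenced = TRUE,
                    stringsAsFactors = FALSE)
  tracked <- which(man$start_composition == "CID" &
                     man$end_composition == "CID")
  n_seq <- config$n_cid - config$n_killed
  unseq <- sample(tracked, length(tracked) - n_seq)
  man$sequenced[unseq] <- FALSE
  rownames(man) <- NULL
  man
}

# fold a displacement into [0, d_max] by reflection at both walls
reflect_bound <- function(x, d_max) {
  y <- x %% (2 * d_max)
  ifelse(y > d_max, 2 * d_max - y, y)
}

#' Simulate cell-cell distance trajectories
#'
#' Each doublet follows a reflected mean-reverting Gaussian diffusion in
#' [0, d_max] over the hourly frames T0..T13: every hour the distance takes a
#' Gaussian step and is pulled a fraction \code{ar_revert} of the way back
#' toward the doublet's starting distance (its tether).  With
#' \code{ar_revert = 0} this reduces to a reflected random walk; the default
#' reversion makes distances a few hours apart nearly independent, so a gene
#' coupled to the distance at one hour is not trivially coupled to every
#' other hour.  At the post-medium-exchange frames T5p and T10p an extra
#' perturbation jump is applied, and the following hour continues from the
#' post-exchange position.  Killing-event doublets have distances set to
#' missing from their kill hour onward.  With zero step and jump sizes every
#' trajectory stays constant at its start value.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth optional \code{\link{simulate_ground_truth}} result supplying
#'   kill hours; generated from \code{config} when omitted.
#' @param cid_ids optional doublet identifiers (default \code{CID001..}),
#'   length \code{config$n_cid}.
#' @param killed_ids which of \code{cid_ids} are killing events (default the
#'   last \code{n_killed}).
#' @return data.frame with column \code{cid_id} and one numeric column per
#'   frame (16 frames at defaults); attributes \code{kill_times} (named hours)
#'   and \code{frames}.
#' @export
simulate_distances <- function(config, truth = NULL, cid_ids = NULL,
                               killed_ids = NULL) {
  stopifnot(inherits(config, "cidmem_sim_config"))
  if (config$d_max <= 0) stop("configuration error: d_max must be positive")
  if (is.null(truth)) truth <- simulate_ground_truth(config)
  n <- config$n_cid
  if (is.null(cid_ids)) cid_ids <- sprintf("CID%03d", seq_len(n))
  if (length(cid_ids) != n) stop("cid_ids must have length n_cid = ", n)
  if (is.null(killed_ids))
    killed_ids <- utils::tail(cid_ids, config$n_killed)
  if (!all(killed_ids %in% cid_ids))
    stop("killed_ids must be a subset of cid_ids")

  set.seed(config$seed + 2L)
  frames <- cid_frames(config$n_timepoints)
  hrs <- frame_hours(frames)
  D <- matrix(NA_real_, n, length(frames), dimnames = list(cid_ids, frames))
  tether <- runif(n, config$start_range[1] * config$d_max,
                  config$start_range[2] * config$d_max)
  D[, 1] <- tether
  for (j in 2:length(frames)) {
    post <- grepl("p$", frames[j])
    sd_j <- if (post) config$exchange_jump_sd else config$step_sd
    pull <- if (post) 0 else config$ar_revert   # the jump is a perturbation
    drift <- D[, j - 1] + pull * (tether - D[, j - 1])
    D[, j] <- reflect_bound(drift + rnorm(n, 0, sd_j), config$d_max)
  }

  kill_times <- setNames(truth$kill_times[seq_along(killed_ids)], killed_ids)
  for (id in killed_ids) D[id, hrs >= kill_times[[id]]] <- NA_real_

  out <- data.frame(cid_id = cid_ids, D, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  attr(out, "kill_times") <- kill_times
  attr(out, "frames") <- frames
  out
}

# memory kernel: weight of the distance at hour t on terminal expression of a
# gene peaking at t* with half-life tau (hours); width is half-life limited
memory_kernel <- function(peak, tau, hours) {
  exp(-abs(hours - peak) * log(2) / tau)
}

#' Simulate terminal expression for every chamber library
#'
#' Generates an RSEM-like non-negative gene-by-cell matrix on a lognormal
#' scale.  Module genes in distance-tracked doublets receive a contribution
#' \code{coupling_strength} times the standardized kernel-weighted distance
#' history, with kernel width set by the gene's mRNA half-life; background
#' genes are distance-independent noise.  NK and cancer singlets carry
#' lineage-marker offsets, killing-event doublets carry the planted
#' upregulated genes, coordinated ligand-receptor pairs share a latent factor
#' across doublet libraries only, and chambers that ended empty yield
#' near-empty low-complexity libraries.
#'
#' @param config a \code{\link{sim_config}}.
#' @param manifest result of \code{\link{simulate_manifest}}.
#' @param distances result of \code{\link{simulate_distances}} whose ids are
#'   manifest chamber ids.
#' @param truth result of \code{\link{simulate_ground_truth}}.
#' @return numeric matrix (genes x cells) with dimnames.
#' @export
simulate_expression <- function(config, manifest, distances, truth) {
  stopifnot(inherits(config, "cidmem_sim_config"),
            inherits(truth, "cidmem_truth"))
  cells <- manifest$chamber_id
  if (!all(distances$cid_id %in% cells))
    stop("input error: distance ids are not manifest chamber ids")
  if (nrow(distances) != config$n_cid)
    stop("input error: distance table has ", nrow(distances),
         " trajectories, config expects ", config$n_cid)
  cls <- classify_chambers(manifest)
  category <- setNames(cls$category, cls$chamber_id)[cells]

  set.seed(config$seed + 3L)
  G <- config$n_genes
  C <- length(cells)
  gene_id <- truth$genes$gene_id

  b <- rnorm(G, config$baseline_log_mean, config$baseline_log_sd)
  b[truth$genes$low_expressed] <- b[truth$genes$low_expressed] - 3.5
  lr_gene <- gene_id %in% unlist(truth$lr_pairs[, c("gene_A", "gene_B")])
  b[lr_gene] <- b[lr_gene] + 1.2   # keep planted pairs in the top-half mean
  s <- runif(G, config$log_dispersion[1], config$log_dispersion[2])

  z <- matrix(rnorm(G * C, 0, config$noise_sd), G, C)

  # distance coupling for module genes in tracked doublets
  hours <- seq_len(config$n_timepoints)
  dcols <- timepoint_policy(attr(distances, "frames") %||% colnames(distances),
                            "pre-exchange", config$n_timepoints)
  Dm <- as.matrix(distances[, dcols, drop = FALSE])
  rownames(Dm) <- distances$cid_id
  Dstd <- scale(Dm)
  Dstd[is.na(Dstd)] <- 0
  mod <- which(truth$genes$module != "background")
  if (length(mod)) {
    W <- t(vapply(mod, function(i)
      memory_kernel(truth$genes$peak_time[i], truth$genes$half_life[i], hours),
      numeric(length(hours))))
    U <- W %*% t(Dstd)                         # module genes x tracked cids
    U <- t(scale(t(U)))
    U[is.na(U)] <- 0
    U <- U * truth$genes$coupling_sign[mod]    # induced vs repressed modules
    cid_cols <- match(distances$cid_id, cells)
    z[mod, cid_cols] <- z[mod, cid_cols] + config$coupling_strength * U
  }

  # shared latent factor of coordinated LR pairs, doublet libraries only
  doublet <- which(category %in% c("CID", "CID_NK_only"))
  coord <- truth$lr_pairs[truth$lr_pairs$coordinated, , drop = FALSE]
  if (nrow(coord) && length(doublet)) {
    for (p in seq_len(nrow(coord))) {
      f <- rnorm(length(doublet)) * config$lr_latent_sd
      ia <- match(coord$gene_A[p], gene_id)
      ib <- match(coord$gene_B[p], gene_id)
      z[ia, doublet] <- z[ia, doublet] + f
      z[ib, doublet] <- z[ib, doublet] + f
    }
  }

  L <- b + s * z

  add_offset <- function(gene_sel, cell_sel, delta) {
    if (any(gene_sel) && length(cell_sel))
      L[gene_sel, cell_sel] <<- L[gene_sel, cell_sel] + delta
  }
  nk_cells <- which(category == "NK")
  ca_cells <- which(category %in% c("cancer", "excluded_cid_to_cancer"))
  db_cells <- which(category %in% c("CID", "CID_NK_only",
                                    "excluded_nk_start_cid"))
  add_offset(truth$genes$nk_marker, nk_cells, 1.5)
  add_offset(truth$genes$nk_marker, db_cells, 1.0)
  add_offset(truth$genes$cancer_marker, ca_cells, 1.5)
  add_offset(truth$genes$cancer_marker, db_cells, 1.0)
  add_offset(truth$genes$de_up, which(category == "CID_NK_only"),
             config$de_log2fc * log(2))

  empty_cells <- which(category %in% c("excluded_empty",
                                       "excluded_cancer_to_empty",
                                       "excluded_nk_to_empty"))
  if (length(empty_cells)) L[, empty_cells] <- L[, empty_cells] - 5

  expr <- exp(L)
  # expression-dependent library dropout: weak transcripts vanish, abundant
  # ones rarely do (near-empty chambers lose almost everything naturally)
  drop_p <- exp(-expr / config$dropout_scale)
  expr[matrix(runif(G * C), G, C) < drop_p] <- 0
  dimnames(expr) <- list(gene_id, cells)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the ligand-receptor database and the mRNA half-life table
#'
#' The pair table mixes the planted coordinated pairs with null pairs (the
#' table itself does not reveal which is which; that lives in the ground
#' truth).  The half-life table covers \code{halflife_coverage} of all genes,
#' so downstream joins exercise missing-gene handling.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth result of \code{\link{simulate_ground_truth}}.
#' @return list with data.frames \code{lr_pairs} (gene_A, gene_B, category)
#'   and \code{halflife} (gene, half_life_hours).
#' @export
simulate_lr_inputs <- function(config, truth) {
  stopifnot(inherits(config, "cidmem_sim_config"),
            inherits(truth, "cidmem_truth"))
  set.seed(config$seed + 4L)
  lp <- truth$lr_pairs
  lr_pairs <- data.frame(
    gene_A = lp$gene_A, gene_B = lp$gene_B,
    category = sample(c("cytokine", "growth factor", "checkpoint",
                        "adhesion"), nrow(lp), replace = TRUE),
    stringsAsFactors = FALSE)
  lr_pairs <- lr_pairs[sample.int(nrow(lr_pairs)), , drop = FALSE]
  rownames(lr_pairs) <- NULL

  n_cov <- round(config$halflife_coverage * config$n_genes)
  covered <- sort(sample.int(config$n_genes, n_cov))
  halflife <- data.frame(gene = truth$genes$gene_id[covered],
                         half_life_hours = truth$genes$half_life[covered],
                         stringsAsFactors = FALSE)
  list(lr_pairs = lr_pairs, halflife = halflife)
}

#' Simulate a complete doublet experiment
#'
#' Orchestrates the individual generators into a coherent experiment: the
#' distance trajectories are attached to the sequenced intact doublets plus
#' all killing-event chambers of the manifest, and the expression matrix
#' covers every chamber library.
#'
#' @param config a \code{\link{sim_config}} (default configuration if
#'   omitted).
#' @return object of class \code{cidmem_sim}: list with elements
#'   \code{config}, \code{truth}, \code{manifest}, \code{distances},
#'   \code{expression}, \code{halflife}, \code{lr_pairs}.
#' @export
#' @examples
#' sim <- simulate_cid_experiment(sim_config(seed = 1, n_genes = 300))
#' dim(sim$expression)
simulate_cid_experiment <- function(config = sim_config()) {
  truth <- simulate_ground_truth(config)
  manifest <- simulate_manifest(config)
  cls <- classify_chambers(manifest)
  intact_seq <- manifest$chamber_id[cls$category == "CID" & manifest$sequenced]
  killed <- manifest$chamber_id[cls$category == "CID_NK_only"]
  cid_ids <- c(intact_seq, killed)
  distances <- simulate_distances(config, truth, cid_ids = cid_ids,
                                  killed_ids = killed)
  expression <- simulate_expression(config, manifest, distances, truth)
  lr <- simulate_lr_inputs(config, truth)
  structure(list(config = config, truth = truth, manifest = manifest,
                 distances = distances, expression = expression,
                 halflife = lr$halflife, lr_pairs = lr$lr_pairs),
            class = "cidmem_sim")
}

#' @export
print.cidmem_sim <- function(x, ...) {
  cat("cidmem simulated experiment:",
      ncol(x$expression), "chamber libraries x", nrow(x$expression),
      "genes;", nrow(x$distances), "distance trajectories over",
      ncol(x$distances) - 1L, "frames\n")
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Writes \code{manifest.tsv}, \code{expression.tsv} (genes x cells;
#' optionally also MatrixMarket \code{expression.mtx} with sidecar
#' \code{genes.txt}/\code{cells.txt}), \code{distances.csv},
#' \code{halflife.tsv}, \code{lr_pairs.tsv} and \code{truth.json}.
#'
#' @param sim a \code{\link{simulate_cid_experiment}} result.
#' @param dir output directory (created if needed).
#' @param mtx also write the MatrixMarket variant of the expression matrix.
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir, mtx = FALSE) {
  stopifnot(inherits(sim, "cidmem_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write.table(sim$manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_expression_tsv(sim$expression, p("expression.tsv"))
  write.csv(sim$distances, p("distances.csv"), row.names = FALSE, quote = FALSE)
  write.table(sim$halflife, p("halflife.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$lr_pairs, p("lr_pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(
    module_membership = setNames(as.list(sim$truth$genes$module),
                                 sim$truth$genes$gene_id),
    peak_time = setNames(as.list(sim$truth$genes$peak_time),
                         sim$truth$genes$gene_id),
    half_life = setNames(as.list(sim$truth$genes$half_life),
                         sim$truth$genes$gene_id),
    coordinated_lr_pairs =
      sim$truth$lr_pairs[sim$truth$lr_pairs$coordinated,
                         c("gene_A", "gene_B")],
    de_up_genes = sim$truth$genes$gene_id[sim$truth$genes$de_up],
    kill_times = attr(sim$distances, "kill_times"))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(manifest = p("manifest.tsv"), expression = p("expression.tsv"),
             distances = p("distances.csv"), halflife = p("halflife.tsv"),
             lr_pairs = p("lr_pairs.tsv"), truth = p("truth.json"))
  if (mtx) {
    write_expression_mtx(sim$expression, p("expression.mtx"))
    paths <- c(paths, mtx = p("expression.mtx"))
  }
  invisible(paths)
}
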