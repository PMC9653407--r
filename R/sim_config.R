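#' Configuration for the synthetic doublet experiment
#'
#' Builds a validated parameter set for \code{\link{simulate_cid_experiment}}
#' and the individual \code{simulate_*} generators.  Defaults reproduce the
#' design of the motivating study: 336 chamber libraries whose composition
#' partitions into 46 excluded chambers and retained groups of 77 single NK
#' cells, 71 single cancer cells, 132 intact doublets (CIDs) and 10
#' killing-event doublets; 102 doublets carry a distance trajectory over 16
#' image frames (hours T0..T13 plus post-medium-exchange duplicates T5'/T10');
#' and four planted gene modules whose terminal expression remembers earlier
#' cell-cell distance through an mRNA-half-life-limited kernel.
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param n_cid number of doublets with distance trajectories (the analysis
#'   doublets), killing events included.
#' @param n_killed number of killing events among \code{n_cid}; these
#'   trajectories end in missing values from the kill frame onward.
#' @param n_cid_tracked chambers that remain intact doublets end-to-end.
#' @param n_single_nk,n_single_cancer retained singlet chamber counts.
#' @param excluded_counts named integer vector giving the excluded-chamber
#'   composition: start-empty, cancer-to-empty, NK-to-empty, NK-start doublet,
#'   doublet-to-cancer-only.
#' @param n_genes total simulated genes.
#' @param module_sizes sizes of the planted distance-coupled gene modules.
#' @param module_peaks peak timepoint (hour index in 1..n_timepoints) of each
#'   module's memory kernel; default spreads the modules across the course.
#' @param module_signs coupling sign of each module (+1 proximity-repressed /
#'   distance-induced, -1 distance-repressed); default alternates, since an
#'   interaction stimulus induces some programs and shuts others down.
#' @param n_timepoints hourly distance timepoints entering the analysis.
#' @param d_max chamber-scale distance bound in micrometres.
#' @param step_sd per-hour diffusion innovation standard deviation (um).
#' @param ar_revert per-hour mean-reversion rate in [0, 1): each hour the
#'   distance is pulled this fraction of the way back toward the doublet's
#'   starting distance (its tether).  0 gives a pure random walk; the default
#'   0.5 decorrelates trajectories over a few hours, which is what makes the
#'   recovered modules time-localized.
#' @param exchange_jump_sd extra displacement at the post-exchange frames
#'   T5'/T10' (um).
#' @param start_range fraction of \code{d_max} bounding the starting distance
#'   (also the tether of the mean-reverting motion).
#' @param coupling_strength latent effect size of the standardized
#'   kernel-weighted distance on a module gene's terminal expression.
#' @param noise_sd latent expression noise standard deviation (same scale as
#'   \code{coupling_strength}).
#' @param log_dispersion range of per-gene log-scale dispersion multipliers.
#' @param baseline_log_mean,baseline_log_sd natural-log baseline abundance.
#' @param frac_low_expressed fraction of background genes planted at very low
#'   abundance (exercises the gene filter).
#' @param dropout_scale expression scale of library dropout: an entry with
#'   value x becomes an exact zero with probability exp(-x / dropout_scale),
#'   so weakly expressed transcripts drop out and abundant ones rarely do.
#' @param halflife_module_mean,halflife_background_mean mean mRNA half-life in
#'   hours for module and background genes (lognormal draws).
#' @param halflife_log_sd lognormal sdlog of half-life draws.
#' @param halflife_coverage fraction of genes covered by the emitted half-life
#'   table (exercises missing-gene joins).
#' @param n_lr_pairs_coordinated,n_lr_pairs_null planted ligand-receptor pairs
#'   with and without a shared doublet-specific latent factor.
#' @param lr_latent_sd standard deviation of the shared latent factor injected
#'   into coordinated pairs across doublet libraries only.
#' @param n_de_genes,de_log2fc genes upregulated in killing-event doublets and
#'   their planted log2 fold change.
#' @param n_runs number of run/batch labels assigned to chambers.
#'
#' @return an object of class \code{cidmem_sim_config} (a validated list).
#' @seealso \code{\link{simulate_cid_experiment}}
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$n_cid
sim_config <- function(seed = 1L,
                       n_cid = 102L,
                       n_killed = 10L,
                       n_cid_tracked = 132L,
                       n_single_nk = 77L,
                       n_single_cancer = 71L,
                       excluded_counts = c(empty = 4L, cancer_to_empty = 8L,
                                           nk_to_empty = 10L, nk_start_cid = 2L,
                                           cid_to_cancer = 22L),
                       n_genes = 3000L,
                       module_sizes = c(30L, 25L, 20L, 15L),
                       module_peaks = NULL,
                       module_signs = NULL,
                       n_timepoints = 13L,
                       d_max = 80,
                       step_sd = 12,
                       ar_revert = 0.5,
                       exchange_jump_sd = 12,
                       start_range = c(0.3, 0.7),
                       coupling_strength = 2,
                       noise_sd = 1,
                       log_dispersion = c(0.35, 0.65),
                       baseline_log_mean = log(20),
                       baseline_log_sd = 0.7,
                       frac_low_expressed = 0.05,
                       dropout_scale = 4,
                       halflife_module_mean = 1.05,
                       halflife_background_mean = 0.6,
                       halflife_log_sd = 0.5,
                       halflife_coverage = 0.65,
                       n_lr_pairs_coordinated = 6L,
                       n_lr_pairs_null = 18L,
                       lr_latent_sd = 1.2,
                       n_de_genes = 20L,
                       de_log2fc = 2,
                       n_runs = 4L) {
  if (is.null(module_peaks)) {
    module_peaks <- unique(round(seq(2, max(2, n_timepoints - 1),
                                     length.out = length(module_sizes))))
    if (length(module_peaks) < length(module_sizes))
      stop("cannot place ", length(module_sizes),
           " distinct module peaks in ", n_timepoints, " timepoints")
  }
  if (is.null(module_signs))
    module_signs <- rep_len(c(1, -1), length(module_sizes))
  cfg <- list(seed = as.integer(seed),
              n_cid = as.integer(n_cid), n_killed = as.integer(n_killed),
              n_cid_tracked = as.integer(n_cid_tracked),
              n_single_nk = as.integer(n_single_nk),
              n_single_cancer = as.integer(n_single_cancer),
              excluded_counts = excluded_counts,
              n_genes = as.integer(n_genes),
              module_sizes = as.integer(module_sizes),
              module_peaks = as.integer(module_peaks),
              module_signs = as.numeric(module_signs),
              n_timepoints = as.integer(n_timepoints),
              d_max = d_max, step_sd = step_sd, ar_revert = ar_revert,
              exchange_jump_sd = exchange_jump_sd, start_range = start_range,
              coupling_strength = coupling_strength, noise_sd = noise_sd,
              log_dispersion = log_dispersion,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              frac_low_expressed = frac_low_expressed,
              dropout_scale = dropout_scale,
              halflife_module_mean = halflife_module_mean,
              halflife_background_mean = halflife_background_mean,
              halflife_log_sd = halflife_log_sd,
              halflife_coverage = halflife_coverage,
              n_lr_pairs_coordinated = as.integer(n_lr_pairs_coordinated),
              n_lr_pairs_null = as.integer(n_lr_pairs_null),
              lr_latent_sd = lr_latent_sd,
              n_de_genes = as.integer(n_de_genes), de_log2fc = de_log2fc,
              n_runs = as.integer(n_runs))
  validate_sim_config(cfg)
  class(cfg) <- "cidmem_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(n_cid = cfg$n_cid, n_killed = cfg$n_killed,
              n_cid_tracked = cfg$n_cid_tracked,
              n_single_nk = cfg$n_single_nk,
              n_single_cancer = cfg$n_single_cancer,
              n_genes = cfg$n_genes, n_timepoints = cfg$n_timepoints,
              n_runs = cfg$n_runs)
  bad <- names(counts)[counts <= 0L]
  if (length(bad)) stop("configuration error: non-positive count(s): ",
                        paste(bad, collapse = ", "))
  if (any(cfg$module_sizes <= 0L))
    stop("configuration error: module_sizes must be positive")
  if (sum(cfg$module_sizes) >= cfg$n_genes)
    stop("configuration error: module_sizes must sum to less than n_genes")
  if (length(cfg$module_peaks) != length(cfg$module_sizes))
    stop("configuration error: one module_peak per module is required")
  if (any(cfg$module_peaks < 1L | cfg$module_peaks > cfg$n_timepoints))
    stop("configuration error: module_peaks must lie in 1..n_timepoints")
  if (length(cfg$module_signs) != length(cfg$module_sizes) ||
      !all(cfg$module_signs %in% c(-1, 1)))
    stop("configuration error: module_signs must be +/-1, one per module")
  if (cfg$d_max <= 0) stop("configuration error: d_max must be positive")
  if (cfg$step_sd < 0 || cfg$exchange_jump_sd < 0)
    stop("configuration error: step sizes must be non-negative")
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  if (cfg$halflife_module_mean <= 0 || cfg$halflife_background_mean <= 0)
    stop("configuration error: half-life means must be positive")
  if (cfg$n_killed > cfg$n_cid)
    stop("configuration error: n_killed cannot exceed n_cid")
  if (cfg$n_cid - cfg$n_killed > cfg$n_cid_tracked)
    stop("configuration error: fewer tracked chambers than sequenced doublets")
  if (cfg$halflife_coverage < 0 || cfg$halflife_coverage > 1)
    stop("configuration error: halflife_coverage must be in [0, 1]")
  if (cfg$dropout_scale <= 0)
    stop("configuration error: dropout_scale must be positive")
  if (cfg$ar_revert < 0 || cfg$ar_revert >= 1)
    stop("configuration error: ar_revert must be in [0, 1)")
  invisible(cfg)
}

#' @export
print.cidmem_sim_config <- function(x, ...) {
  cat("cidmem simulation config\n")
  cat("  chambers:", total_chambers(x),
      sprintf("(%d NK, %d cancer, %d CID tracked, %d killed, %d excluded)\n",
              x$n_single_nk, x$n_single_cancer, x$n_cid_tracked, x$n_killed,
              sum(x$excluded_counts)))
  cat("  genes:", x$n_genes, "with modules",
      paste(x$module_sizes, collapse = "/"), "peaking at hours",
      paste(x$module_peaks, collapse = "/"), "\n")
  cat("  analysis doublets:", x$n_cid, "over", x$n_timepoints, "timepoints\n")
  invisible(x)
}

total_chambers <- function(cfg) {
  sum(cfg$excluded_counts) + cfg$n_single_nk + cfg$n_single_cancer +
    cfg$n_cid_tracked + cfg$n_killed
}
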