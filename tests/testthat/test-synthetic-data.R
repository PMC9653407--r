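test_that("identical configuration gives bit-identical simulations", {
  cfg <- small_cfg(seed = 7)
  expect_identical(simulate_cid_experiment(cfg), simulate_cid_experiment(cfg))
  cfg2 <- small_cfg(seed = 8)
  expect_false(identical(simulate_distances(cfg), simulate_distances(cfg2)))
})

test_that("zero step and jump sizes freeze every trajectory at its start", {
  cfg <- small_cfg(step_sd = 0, exchange_jump_sd = 0)
  d <- simulate_distances(cfg)
  vals <- as.matrix(d[, -1])
  alive <- apply(vals, 1, function(r) !anyNA(r))
  expect_true(all(vals[alive, ] == vals[alive, 1]))
  # killed trajectories are constant too, up to their kill frame
  for (i in which(!alive)) {
    r <- vals[i, ]
    expect_true(all(r[!is.na(r)] == r[1]))
  }
})

test_that("trajectories stay within [0, d_max] and exactly n_killed have missing tails", {
  cfg <- sim_config(seed = 3)           # study-scale conditions
  d <- simulate_distances(cfg)
  vals <- as.matrix(d[, -1])
  expect_true(all(vals >= 0 & vals <= cfg$d_max, na.rm = TRUE))
  has_na <- apply(vals, 1, anyNA)
  expect_identical(sum(has_na), 10L)
  # missingness begins at the kill hour and never ends
  hrs <- cidmem:::frame_hours(attr(d, "frames"))
  kt <- attr(d, "kill_times")
  for (id in names(kt)) {
    row <- vals[d$cid_id == id, ]
    expect_identical(unname(is.na(row)), hrs >= kt[[id]])
  }
})

test_that("a point-mass kernel with zero noise couples a gene affinely to one frame", {
  cfg <- small_cfg(noise_sd = 0, module_sizes = c(3, 3), module_peaks = c(4, 9),
                   dropout_scale = 1e-6, frac_low_expressed = 0)
  truth <- simulate_ground_truth(cfg)
  truth$genes$half_life[truth$genes$module != "background"] <- 0.01
  man <- simulate_manifest(cfg)
  cls <- classify_chambers(man)
  cids <- c(man$chamber_id[cls$category == "CID" & man$sequenced],
            man$chamber_id[cls$category == "CID_NK_only"])
  d <- simulate_distances(cfg, truth, cid_ids = cids,
                          killed_ids = man$chamber_id[cls$category == "CID_NK_only"])
  expr <- simulate_expression(cfg, man, d, truth)
  g <- truth$genes$gene_id[which(truth$genes$module == "M1")[1]]
  peak <- truth$genes$peak_time[truth$genes$gene_id == g]
  dist_mat <- as.matrix(d[, timepoint_policy(attr(d, "frames"))])
  rownames(dist_mat) <- d$cid_id
  # log restores the latent affine relation the generator encodes
  cm <- correlate_distance_expression(rbind(g = log(expr[g, cids])),
                                      dist_mat[cids, ])
  expect_equal(abs(cm$rho["g", paste0("T", peak)]), 1, tolerance = 1e-10)
})

test_that("with zero coupling the correlation map is a null map", {
  cfg <- small_cfg(coupling_strength = 0, n_genes = 500)
  sim <- simulate_cid_experiment(cfg)
  cls <- classify_chambers(sim$manifest)
  bundle <- suppressWarnings(align_inputs(sim$expression, sim$distances, cls))
  cm <- correlate_distance_expression(
    bundle$expr_cid, bundle$dist[, timepoint_policy(bundle$frames)])
  expect_lt(abs(mean(cm$rho, na.rm = TRUE)), 0.05)
  # with 24 doublets the null sd of rho is ~0.21; |rho| > 0.7 is a >3 sigma event
  expect_lt(mean(abs(cm$rho) > 0.7, na.rm = TRUE), 0.005)
})

test_that("lr_latent_sd = 0 removes the planted pair coordination", {
  cfg <- small_cfg(lr_latent_sd = 0)
  sim <- simulate_cid_experiment(cfg)
  cls <- classify_chambers(sim$manifest)
  groups <- setNames(cls$category, cls$chamber_id)
  co <- sim$truth$lr_pairs[sim$truth$lr_pairs$coordinated, , drop = FALSE]
  rho <- group_pair_correlations(co, sim$expression, groups)
  expect_true(all(abs(rho$rho_CID) < 0.45))
})

test_that("the half-life table covers the configured fraction of genes", {
  cfg <- small_cfg(halflife_coverage = 0.5)
  truth <- simulate_ground_truth(cfg)
  lr <- simulate_lr_inputs(cfg, truth)
  expect_identical(nrow(lr$halflife), as.integer(round(0.5 * cfg$n_genes)))
  expect_true(all(lr$halflife$half_life_hours > 0))
  # table values agree with the ground truth they were drawn from
  expect_identical(lr$halflife$half_life_hours,
                   truth$genes$half_life[match(lr$halflife$gene,
                                               truth$genes$gene_id)])
})

test_that("module half-lives are drawn longer than background on average", {
  cfg <- sim_config(seed = 11)
  truth <- simulate_ground_truth(cfg)
  mod <- truth$genes$module != "background"
  expect_gt(mean(truth$genes$half_life[mod]),
            mean(truth$genes$half_life[!mod]))
})

test_that("written simulations round-trip through the readers", {
  cfg <- small_cfg()
  sim <- simulate_cid_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir, mtx = TRUE)
  expect_true(all(file.exists(paths)))
  back <- read_expression_tsv(paths[["expression"]])
  expect_equal(back, sim$expression, tolerance = 1e-6)
  back_mtx <- read_expression_mtx(paths[["mtx"]])
  expect_equal(back_mtx, sim$expression, tolerance = 1e-12)
  d <- read_distances(paths[["distances"]])
  expect_equal(as.matrix(d[, -1]), as.matrix(sim$distances[, -1]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(read_manifest(paths[["manifest"]]), sim$manifest)
})

test_that("invalid configurations are rejected with configuration errors", {
  expect_error(sim_config(d_max = 0), "d_max")
  expect_error(sim_config(n_genes = 50, module_sizes = c(30, 30)),
               "module_sizes")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_killed = 200), "n_killed")
  expect_error(sim_config(module_signs = c(1, 2, 1, -1)), "module_signs")
  expect_error(sim_config(halflife_module_mean = 0), "half-life")
})
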