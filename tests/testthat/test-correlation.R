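test_that("timepoint policies pick the documented frames", {
  frames <- cid_frames()
  pre <- timepoint_policy(frames)
  expect_identical(pre, paste0("T", 1:13))
  expect_false(any(c("T0", "T5p", "T10p") %in% pre))
  post <- timepoint_policy(frames, "post-exchange")
  expect_true(all(c("T5p", "T10p") %in% post))
  expect_false(any(c("T5", "T10") %in% post))
  expect_identical(timepoint_policy(frames, "all-hours"), paste0("T", 0:13))
  expect_error(timepoint_policy(setdiff(frames, "T7")), "T7")
})

test_that("variable-gene selection sorts by log1p variance with stated ties", {
  m <- matrix(1, 5, 6, dimnames = list(c("d", "a", "e", "b", "c"), NULL))
  m["a", ] <- c(0, 50, 0, 50, 0, 50)       # dominant dispersion
  m["b", ] <- c(1, 2, 1, 2, 1, 2)
  expect_identical(select_variable_genes(m, k = 1), "a")
  expect_setequal(select_variable_genes(m, k = 5), rownames(m))
  expect_warning(all_g <- select_variable_genes(m, k = 10), "using all")
  expect_identical(length(all_g), 5L)
  # tie-break among the three identical constant rows is lexicographic
  expect_identical(select_variable_genes(m, k = 4)[3:4], c("c", "d"))

  set.seed(9)
  r <- matrix(rpois(50 * 20, 6), 50, 20,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  disp <- apply(log1p(r), 1, var)
  expect_identical(select_variable_genes(r, k = 12),
                   rownames(r)[order(-disp, rownames(r))][1:12])
})

test_that("the correlation map equals an elementwise Pearson oracle", {
  set.seed(31)
  G <- 20; C <- 8; T_ <- 5
  expr <- matrix(rlnorm(G * C), G, C,
                 dimnames = list(sprintf("g%02d", 1:G), sprintf("c%d", 1:C)))
  dmat <- matrix(runif(C * T_, 0, 80), C, T_,
                 dimnames = list(colnames(expr), paste0("T", 1:T_)))
  dmat[1, 4:5] <- NA; dmat[2, 5] <- NA     # killing-style missing tails
  cm <- correlate_distance_expression(expr, dmat, n_min = 3)
  for (g in rownames(expr)) for (t in colnames(dmat))
    expect_equal(cm$rho[g, t], pearson_oracle(expr[g, ], dmat[, t]),
                 tolerance = 1e-10)
})

test_that("affine relations and degenerate rows behave as Pearson dictates", {
  set.seed(5)
  C <- 12
  dmat <- matrix(runif(C * 3, 0, 50), C, 3,
                 dimnames = list(sprintf("c%d", 1:C), c("T1", "T2", "T3")))
  expr <- rbind(affine = 3 * dmat[, "T2"] + 7,
                anti = -2 * dmat[, "T3"],
                flat = rep(4, C))
  colnames(expr) <- rownames(dmat)
  cm <- correlate_distance_expression(expr, dmat)
  expect_equal(cm$rho["affine", "T2"], 1, tolerance = 1e-12)
  expect_equal(cm$rho["anti", "T3"], -1, tolerance = 1e-12)
  expect_true(all(is.na(cm$rho["flat", ])))
})

test_that("rho is invariant to affine rescaling up to the sign of the scale", {
  set.seed(6)
  expr <- matrix(rlnorm(10 * 9), 10, 9,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("c%d", 1:9)))
  dmat <- matrix(runif(9 * 4), 9, 4,
                 dimnames = list(colnames(expr), paste0("T", 1:4)))
  base <- correlate_distance_expression(expr, dmat)
  scaled <- correlate_distance_expression(5.5 * expr + 2, dmat)
  expect_equal(scaled$rho, base$rho, tolerance = 1e-10)
  flipped <- correlate_distance_expression(expr, -3 * dmat + 100)
  expect_equal(flipped$rho, -base$rho, tolerance = 1e-10)
})

test_that("entries with too few complete pairs are masked", {
  expr <- matrix(rlnorm(4 * 6), 4, 6,
                 dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  dmat <- matrix(runif(6 * 2), 6, 2,
                 dimnames = list(colnames(expr), c("T1", "T2")))
  dmat[1:3, "T2"] <- NA                    # only 3 complete pairs at T2
  cm <- correlate_distance_expression(expr, dmat, n_min = 5)
  expect_true(all(is.na(cm$rho[, "T2"])))
  expect_false(anyNA(cm$rho[, "T1"]))
  expect_identical(unname(cm$n_used[1, ]), c(6, 3))
})

test_that("memory-gene retention is inclusive at the threshold and monotone", {
  rho <- rbind(at = rep(0.25, 5), under = rep(0.249, 5),
               onehigh = c(0, 0, -0.9, 0, 0), null = rep(0.01, 5))
  colnames(rho) <- paste0("T", 1:5)
  cm <- structure(list(rho = rho, n_used = rho * 0 + 50, n_min = 5),
                  class = "cidmem_corrmap")
  expect_setequal(select_memory_genes(cm, 0.25), c("at", "onehigh"))
  expect_error(select_memory_genes(cm, 0), "configuration")
  expect_error(select_memory_genes(cm, 1.2), "configuration")
  set.seed(12)
  rr <- matrix(runif(200, -1, 1), 40, 5,
               dimnames = list(sprintf("g%02d", 1:40), paste0("T", 1:5)))
  cm2 <- structure(list(rho = rr, n_used = rr * 0 + 50, n_min = 5),
                   class = "cidmem_corrmap")
  thresholds <- sort(runif(8, 0.05, 0.95))
  sets <- lapply(thresholds, function(th) select_memory_genes(cm2, th))
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("clustering separates orthogonal patterns and is deterministic", {
  rho <- rbind(matrix(rep(c(0.8, 0.8, 0, 0, 0), each = 6), 6, 5, byrow = FALSE))
  rho <- rbind(t(replicate(6, c(0.8, 0.8, 0, 0, 0) + rnorm(5, 0, 0.01))),
               t(replicate(6, c(0, 0, 0, -0.8, -0.8) + rnorm(5, 0, 0.01))))
  dimnames(rho) <- list(sprintf("g%02d", 1:12), paste0("T", 1:5))
  cm <- structure(list(rho = rho, n_used = rho * 0 + 50, n_min = 5),
                  class = "cidmem_corrmap")
  mods <- cluster_modules(cm, rownames(rho), k = 2)
  asn <- setNames(mods$assignment$module, mods$assignment$gene)
  expect_identical(unname(asn[sprintf("g%02d", 1:6)]), rep("M1", 6))
  expect_identical(unname(asn[sprintf("g%02d", 7:12)]), rep("M2", 6))
  expect_identical(mods$assignment,
                   cluster_modules(cm, rownames(rho), k = 2)$assignment)
  singles <- cluster_modules(cm, rownames(rho), k = 12)
  expect_identical(length(unique(singles$assignment$module)), 12L)
  expect_error(cluster_modules(cm, rownames(rho), k = 13), "exceeds")
})

test_that("module labels follow peak-timepoint order", {
  rho <- rbind(t(replicate(4, c(0, 0, 0, 0.9, 0) + rnorm(5, 0, 0.01))),
               t(replicate(4, c(0.9, 0, 0, 0, 0) + rnorm(5, 0, 0.01))))
  dimnames(rho) <- list(sprintf("g%d", 1:8), paste0("T", 1:5))
  cm <- structure(list(rho = rho, n_used = rho * 0 + 50, n_min = 5),
                  class = "cidmem_corrmap")
  asn <- cluster_modules(cm, rownames(rho), k = 2)$assignment
  # the early-peaking group (genes 5-8) must be M1
  expect_true(all(asn$module[asn$gene %in% sprintf("g%d", 5:8)] == "M1"))
  expect_true(all(asn$module[asn$gene %in% sprintf("g%d", 1:4)] == "M2"))
})
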