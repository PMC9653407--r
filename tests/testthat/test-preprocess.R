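test_that("chamber classification is a partition and counts sum to the manifest", {
  set.seed(1)
  combos <- data.frame(
    s = c("empty", "cancer", "NK", "NK", "CID", "NK", "cancer", "CID", "CID"),
    e = c("empty", "empty", "empty", "CID", "cancer", "NK", "cancer", "CID",
          "NK"))
  idx <- sample.int(nrow(combos), 60, replace = TRUE)
  man <- data.frame(chamber_id = sprintf("c%02d", 1:60),
                    start_composition = combos$s[idx],
                    end_composition = combos$e[idx])
  cls <- classify_chambers(man)
  expect_false(anyNA(cls$category))
  expect_identical(sum(attr(cls, "counts")), 60L)
  expect_identical(cls$excluded, startsWith(cls$category, "excluded_"))
})

test_that("unknown composition labels raise a parse error naming the chamber", {
  man <- data.frame(chamber_id = c("a", "b"),
                    start_composition = c("NK", "weird"),
                    end_composition = c("NK", "empty"))
  expect_error(classify_chambers(man), "parse error.*b")
})

test_that("an empty manifest classifies to an empty report", {
  cls <- classify_chambers(data.frame(chamber_id = character(0),
                                      start_composition = character(0),
                                      end_composition = character(0)))
  expect_identical(nrow(cls), 0L)
  expect_identical(sum(attr(cls, "counts")), 0L)
})

test_that("cell filter applies a strict less-than rule at the threshold", {
  n_genes <- 2100
  m <- matrix(1, n_genes, 3,
              dimnames = list(sprintf("g%04d", 1:n_genes), c("at", "below", "rich")))
  m[2001:n_genes, "at"] <- 0      # exactly 2000 expressed genes
  m[2000:n_genes, "below"] <- 0   # 1999 expressed genes
  out <- filter_cells(m)          # default threshold 2000
  expect_identical(colnames(out), c("at", "rich"))
  expect_identical(attr(out, "removed_cells"), "below")
  expect_error(filter_cells(m, min_expressed_genes = -1), "configuration")
})

test_that("gene filter requires value strictly above 5 in at least 10 cells", {
  m <- matrix(0, 3, 12, dimnames = list(c("at5", "just_over", "nine_cells"),
                                        sprintf("c%02d", 1:12)))
  m["at5", 1:10] <- 5.0           # not strictly above 5 -> removed
  m["just_over", 1:10] <- 5.1     # boundary: exactly 10 cells above 5
  m["nine_cells", 1:9] <- 100     # only 9 qualifying cells
  out <- filter_genes(m)
  expect_identical(rownames(out), "just_over")
})

test_that("both filters match brute-force evaluation and are idempotent", {
  set.seed(20)
  m <- matrix(rpois(60 * 40, 3) * rbinom(60 * 40, 1, 0.6), 60, 40,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("c%02d", 1:40)))
  fc <- filter_cells(m, min_expressed_genes = 25)
  keep_cells <- vapply(seq_len(ncol(m)),
                       function(j) sum(m[, j] > 0) >= 25, logical(1))
  expect_identical(colnames(fc), colnames(m)[keep_cells])
  fg <- filter_genes(fc, min_value = 4, min_cells = 8)
  keep_genes <- vapply(seq_len(nrow(fc)),
                       function(i) sum(fc[i, ] > 4) >= 8, logical(1))
  expect_identical(rownames(fg), rownames(fc)[keep_genes])
  expect_identical(unclass(filter_cells(fc, 25))[, ], unclass(fc)[, ])
  expect_identical(unclass(filter_genes(fg, 4, 8))[, ], unclass(fg)[, ])
})

test_that("the pipeline order is cells first, then genes, and the reverse differs", {
  # cell A expresses only gene X; removing low-complexity cell A first
  # deprives X of its last qualifying cell, so the orders disagree
  m <- matrix(0, 12, 11,
              dimnames = list(c("X", sprintf("g%02d", 1:11)),
                              c("A", sprintf("c%02d", 1:10))))
  m[sprintf("g%02d", 1:11), sprintf("c%02d", 1:10)] <- 10
  m["X", "A"] <- 10
  m["X", sprintf("c%02d", 1:9)] <- 10
  cells_first <- filter_genes(filter_cells(m, min_expressed_genes = 5),
                              min_value = 5, min_cells = 10)
  genes_first <- filter_cells(filter_genes(m, min_value = 5, min_cells = 10),
                              min_expressed_genes = 5)
  expect_false("X" %in% rownames(cells_first))
  expect_true("X" %in% rownames(genes_first))
})

test_that("z-scoring centres and scales each channel exactly", {
  z <- zscore_channels(data.frame(cell_id = c("a", "b", "c"),
                                  nk_channel = c(1, 2, 3)))
  expect_equal(z$nk_channel, c(-1, 0, 1))
  set.seed(4)
  df <- data.frame(cell_id = sprintf("c%02d", 1:50),
                   nk_channel = rnorm(50, 100, 20),
                   cancer_channel = runif(50))
  zz <- zscore_channels(df)
  for (ch in c("nk_channel", "cancer_channel")) {
    expect_equal(mean(zz[[ch]]), 0, tolerance = 1e-12)
    expect_equal(sd(zz[[ch]]), 1, tolerance = 1e-12)
  }
  df$cancer_channel <- 7
  expect_error(zscore_channels(df), "zero-variance channel: cancer_channel")
})

test_that("align_inputs joins on id, ignores row order, and reports drops", {
  cfg <- small_cfg()
  sim <- simulate_cid_experiment(cfg)
  cls <- classify_chambers(sim$manifest)
  b1 <- suppressWarnings(align_inputs(sim$expression, sim$distances, cls))
  shuffled <- sim$distances[sample.int(nrow(sim$distances)), ]
  attr(shuffled, "frames") <- attr(sim$distances, "frames")
  perm <- sample.int(ncol(sim$expression))
  b2 <- suppressWarnings(align_inputs(sim$expression[, perm], shuffled, cls))
  expect_identical(b1$cid_ids, b2$cid_ids)
  expect_identical(b1$expr_cid, b2$expr_cid)
  expect_identical(b1$dist, b2$dist)
  expect_identical(b1$n_c, cfg$n_cid)

  rogue <- sim$distances
  rogue$cid_id[1] <- "NOT_A_CHAMBER"
  attr(rogue, "frames") <- attr(sim$distances, "frames")
  expect_warning(
    expect_warning(b3 <- align_inputs(sim$expression, rogue, cls),
                   "without expression"),
    "no distance record")
  expect_identical(b3$n_c, cfg$n_cid - 1L)

  none <- sim$distances
  none$cid_id <- paste0("zz", seq_len(nrow(none)))
  expect_error(align_inputs(sim$expression, none, cls), "fatal join error")
})
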