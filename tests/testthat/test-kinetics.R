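# Initial rates, fold changes, and the kinetic dataset workflow.

test_that("initial_rate fits the early-phase OLS slope", {
  expect_equal(initial_rate(c(50, 50, 50), c(0, 1, 2)), 0)
  expect_equal(initial_rate(100 + 12 * (0:3), 0:3), 12)

  # noisy line against an independent least-squares fit (QR via lm)
  set.seed(7)
  t <- seq(0, 9, 1)
  y <- 5 + 8 * t + stats::rnorm(10, 0, 0.5)
  expect_equal(initial_rate(y, t, rate_window(minutes = 10)),
               unname(stats::coef(stats::lm(y ~ t))[2]), tolerance = 1e-9)

  # replicates are averaged pointwise before fitting
  reps <- rbind(100 + 10 * (0:3), 100 + 14 * (0:3))
  expect_equal(initial_rate(reps, 0:3), 12)

  # window: first `minutes` minutes, or `min_points` points if larger
  t2 <- c(0, 1, 2, 50, 60)
  y2 <- c(0, 1, 2, 10, 10)
  expect_equal(initial_rate(y2, t2, rate_window(minutes = 2, min_points = 2)),
               1)
  expect_error(initial_rate(c(1), c(0), rate_window()), "insufficient")
  expect_error(initial_rate(c(1, NA, NA), c(0, 1, 2),
                            rate_window(minutes = 2, min_points = 2)),
               "insufficient")
})

test_that("fold_change follows the background policy", {
  expect_equal(fold_change(c(100, 100, 100), c(0, 30, 60)), 1)
  expect_equal(fold_change(c(100, 200, 350), c(0, 30, 60)), 3.5)
  # blank-well subtraction: (370 - 20) / (120 - 20)
  expect_equal(fold_change(c(120, 250, 370), c(0, 30, 60),
                           background = "blank", blank_value = 20), 3.5)
  # evaluation at an interior (interpolated) time point
  expect_equal(fold_change(c(100, 200, 400), c(0, 30, 60), t_eval = 45), 3)
  expect_error(fold_change(c(100, 200), c(0, 30), t_eval = 90,
                           interpolate = FALSE), "not a sampled")
  expect_error(fold_change(c(0, 10), c(0, 30)), "baseline")

  # scale invariance: multiplying a series by c > 0 changes nothing
  set.seed(8)
  y <- cumsum(stats::runif(6, 1, 5)) + 50
  t <- seq(0, 50, 10)
  expect_equal(fold_change(3.7 * y, t), fold_change(y, t))
})

test_that("kinetic datasets recover generator ground truth", {
  # 1 substrate x 1 condition linear series -> 1x1 tables
  kr <- kinetic_raw(0:3, matrix(100 + 12 * (0:3), 1), "S1", "P1")
  ds <- build_kinetic_dataset(kr)
  expect_equal(dim(ds$rate_table), c(1L, 1L))
  expect_equal(unname(as.matrix(ds$rate_table)[1, 1]), 12)

  # noiseless synthetic screen: rates within 1% of true A*k over an early
  # window (first 2 of 20 minutes, k <= 0.008 per minute)
  g <- gen_kinetic_screen(4, 3, time_points = seq(0, 20, 0.25),
                          noise_sd = 0, n_replicates = 1, seed = 11)
  cfg <- kinetic_config(rate_window = rate_window(minutes = 2,
                                                  min_points = 3))
  ds2 <- build_kinetic_dataset(g$raw, cfg)
  est <- as.matrix(ds2$rate_table)
  truth <- matrix(g$truth$true_rate, 4, 3)
  expect_lt(max(abs(est / truth - 1)), 0.01)

  # derived tables share the raw labels and persist via write_table
  expect_equal(rownames(est), paste0("S", 1:4))
  out <- withr::local_tempdir()
  build_kinetic_dataset(g$raw, cfg, out_dir = out)
  expect_true(all(file.exists(file.path(out, c("rate_table.csv",
                                               "fold_table.csv",
                                               "sve.csv")))))
  back <- read_screen_matrix(file.path(out, "rate_table.csv"),
                             measurement_kind = "initial_rate")
  expect_equal(back$values, est, tolerance = 1e-9)

  # determinism: identical inputs and config give identical tables
  ds3 <- build_kinetic_dataset(g$raw, cfg)
  expect_identical(ds2$rate_table$values, ds3$rate_table$values)
})

test_that("SvE scores standardize each axis with a zero-variance guard", {
  # 1x1 -> single record (0, 0)
  one <- screen_matrix(matrix(4, 1, 1, dimnames = list("S1", "P1")),
                       "o", "fold_change")
  s1 <- sve_table(one)
  expect_equal(s1$efficiency_z, 0)
  expect_equal(s1$specificity_z, 0)

  # 3x3 with one dominant cell: that cell attains the maximum of both
  m <- matrix(1.2, 3, 3, dimnames = list(paste0("S", 1:3), paste0("P", 1:3)))
  m["S3", "P1"] <- 9
  sv <- sve_table(screen_matrix(m, "t", "fold_change"))
  top <- sv[which.max(sv$efficiency_z), ]
  expect_equal(top$substrate, "S3")
  expect_equal(top$protease, "P1")
  expect_equal(which.max(sv$specificity_z), which.max(sv$efficiency_z))
  # hand-computed z for the dominant cell
  expect_equal(top$efficiency_z, (9 - mean(m[, 1])) / stats::sd(m[, 1]))

  # per-column / per-row mean 0 and sample SD 1 on a random table
  set.seed(9)
  r <- matrix(stats::runif(30, 0.2, 6), 5, 6,
              dimnames = list(paste0("S", 1:5), paste0("P", 1:6)))
  svr <- sve_table(screen_matrix(r, "r", "fold_change"))
  for (p in colnames(r)) {
    ez <- svr$efficiency_z[svr$protease == p]
    expect_equal(mean(ez), 0, tolerance = 1e-12)
    expect_equal(stats::sd(ez), 1, tolerance = 1e-12)
  }
  for (s in rownames(r)) {
    sz <- svr$specificity_z[svr$substrate == s]
    expect_equal(mean(sz), 0, tolerance = 1e-12)
    expect_equal(stats::sd(sz), 1, tolerance = 1e-12)
  }
})

test_that("bidirectional clustering merges identical profiles first", {
  m <- matrix(c(1, 5, 9, 1, 5, 9, 8, 2, 4), 3, 3,
              dimnames = list(paste0("S", 1:3), c("A", "B", "C")))
  bc <- cluster_bidirectional(m)
  ord <- match(c("A", "B"), bc$col_order)
  expect_equal(abs(diff(ord)), 1L)  # identical columns adjacent

  # 3-row toy: merge order equals hand-computed average linkage
  r <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2,
              dimnames = list(c("a", "b", "far"), c("x", "y")))
  bc2 <- cluster_bidirectional(r)
  expect_setequal(rownames(r)[-bc2$row_hclust$merge[1, ]], c("a", "b"))
  # average linkage height of the second merge: mean of d(a,far), d(b,far)
  expect_equal(bc2$row_hclust$height[2],
               mean(c(stats::dist(r)[2], stats::dist(r)[3])))

  # row permutation leaves the topology unchanged
  set.seed(10)
  big <- matrix(stats::rnorm(40), 8, 5,
                dimnames = list(paste0("S", 1:8), paste0("P", 1:5)))
  b1 <- cluster_bidirectional(big)
  b2 <- cluster_bidirectional(big[sample(8), ])
  c1 <- as.matrix(stats::cophenetic(b1$row_hclust))
  c2 <- as.matrix(stats::cophenetic(b2$row_hclust))[rownames(c1),
                                                    rownames(c1)]
  expect_equal(c1, c2, tolerance = 1e-12)
  expect_error(cluster_bidirectional(m[1, , drop = FALSE]), "at least 2")
})

test_that("spearman_matrix equals rank-transform-then-Pearson", {
  set.seed(12)
  m <- matrix(stats::runif(18), 6, 3,
              dimnames = list(paste0("S", 1:6), paste0("P", 1:3)))
  sp <- spearman_matrix(m)
  oracle <- stats::cor(apply(m, 2L, rank))
  expect_equal(sp, oracle, tolerance = 1e-12)
  expect_equal(diag(sp), stats::setNames(rep(1, 3), colnames(m)))
  expect_equal(sp, t(sp))

  # invariance under strictly monotone transforms of a column
  m2 <- m; m2[, 2] <- m2[, 2]^3
  expect_equal(spearman_matrix(m2), sp, tolerance = 1e-12)

  # constant column: undefined correlation -> NA with warning, diagonal 1
  m3 <- m; m3[, 1] <- 2
  expect_warning(sp3 <- spearman_matrix(m3), "constant")
  expect_true(is.na(sp3[1, 2]))
  expect_equal(unname(diag(sp3)), rep(1, 3))
})

test_that("class_summary counts cleaving proteases per catalytic class", {
  m <- matrix(c(3, 1, 3, 1, 1, 1), 2, 3,
              dimnames = list(c("S1", "S2"), c("Pm", "Ps", "Px")))
  cls <- c(Pm = "metallo", Ps = "serine")
  cs <- class_summary(m, cls, threshold = 1.5)
  expect_equal(cs["S1", "metallo"], 1L)
  expect_equal(cs["S1", "serine"], 1L)
  expect_equal(cs["S1", "other"], 0L)   # unannotated Px below threshold
  expect_equal(unname(cs["S2", ]), rep(0L, 3))

  # a planted metallo-dominant substrate has the strictly largest count
  m2 <- matrix(1, 2, 4, dimnames = list(c("S1", "S2"),
                                        c("M1", "M2", "Se1", "Cy1")))
  m2["S1", c("M1", "M2")] <- 4
  m2["S1", "Se1"] <- 2
  cs2 <- class_summary(m2, c(M1 = "metallo", M2 = "metallo",
                             Se1 = "serine", Cy1 = "cysteine"))
  expect_true(cs2["S1", "metallo"] > max(cs2["S1", c("serine", "cysteine")]))
})

test_that("every plot kind writes a nonempty figure file", {
  g <- gen_kinetic_screen(4, 3, time_points = seq(0, 30, 5), noise_sd = 1,
                          n_replicates = 2, seed = 13)
  cls <- stats::setNames(c("metallo", "serine", "cysteine"), paste0("P", 1:3))
  ds <- build_kinetic_dataset(g$raw, classes = cls)
  out <- withr::local_tempdir()
  for (kind in c("raw_lines", "fold_lines", "heatmap", "sve", "pie",
                 "correlation")) {
    f <- plot_kinetics(ds, kind, out_dir = out)
    expect_true(file.exists(f))
    expect_gt(file.size(f), 0)
  }
  expect_error(plot_kinetics(ds, "nope", out_dir = out), "arg")
})
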