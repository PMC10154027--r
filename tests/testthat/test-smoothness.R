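test_that("pca projection captures rank-1 data in one component", {
  set.seed(1)
  t_par <- rnorm(12)
  v <- rnorm(20)
  m <- outer(t_par, v) + 3
  rownames(m) <- sprintf("K%02d", 1:12)
  tab <- representation_table("t", "correlation_centered", m)
  pr <- pca_project(tab, rownames(m), pca_config(n_components = 5))
  ev <- attr(pr, "explained_variance")
  expect_gt(ev[1], 1 - 1e-10)
  expect_true(all(abs(pr[, -1]) < 1e-8))
})

test_that("pca preserves pairwise distances at full effective rank", {
  tab <- small_embedding_table(10, 6, seed = 3)
  keys <- rownames(tab$vectors)
  pr <- pca_project(tab, keys, pca_config(n_components = 64))
  expect_equal(ncol(pr), 6)   # min(64, 9, 6)
  d_full <- as.matrix(dist(tab$vectors))
  d_proj <- as.matrix(dist(pr))
  expect_equal(unname(d_proj), unname(d_full), tolerance = 1e-9)
  ev <- attr(pr, "explained_variance")
  expect_lte(sum(ev), 1 + 1e-12)
  expect_true(all(diff(ev) <= 1e-12))
  expect_error(pca_project(tab, keys[1:2]), "3 keys")
})

test_that("smoothness ratio follows the segment geometry", {
  expect_equal(smoothness_ratio(c(0, 0), c(1, 0), c(2, 0)), 1)
  expect_equal(smoothness_ratio(c(0, 0), c(1, 1), c(2, 0)), 1 / sqrt(2))
  expect_error(smoothness_ratio(c(0, 0), c(1, 1), c(0, 0)), "coincide")
})

test_that("smoothness is invariant under rotation and translation", {
  set.seed(4)
  for (i in 1:25) {
    pts <- matrix(rnorm(9), 3, 3)
    q <- random_rotation(3, seed = i)
    shift <- rnorm(3)
    moved <- sweep(pts %*% q, 2, shift, "+")
    expect_equal(
      smoothness_ratio(pts[1, ], pts[2, ], pts[3, ]),
      smoothness_ratio(moved[1, ], moved[2, ], moved[3, ]),
      tolerance = 1e-9)
  }
})

test_that("score_pathways emits one record per intermediate", {
  tab <- small_embedding_table(8, 10, seed = 5)
  keys <- rownames(tab$vectors)
  paths <- list(p1 = keys[1:5], p2 = keys[4:8])
  rec <- score_pathways(paths, tab)
  expect_equal(nrow(rec), 3 + 3)
  expect_true(all(rec$smoothness > 0 & rec$smoothness <= 1 + 1e-12))
  expect_true(all(rec$start[rec$pathway_id == "p1"] == keys[1]))
  # consecutive mode scores rolling triplets instead
  rec_c <- score_pathways(paths, tab, mode = "consecutive")
  expect_equal(nrow(rec_c), 6)
  expect_identical(rec_c$start[1:3], keys[1:3])
  expect_error(score_pathways(list(keys[1:2]), tab), "fewer than 3")
  expect_error(score_pathways(list(c(keys[1:2], "zz")), tab), "zz")
})

test_that("records equal a brute-force recomputation from coordinates", {
  tab <- small_embedding_table(9, 7, seed = 6)
  keys <- rownames(tab$vectors)
  paths <- list(a = keys[1:6], b = keys[c(7, 8, 9, 1)])
  cfg <- pca_config(n_components = 4)
  rec <- score_pathways(paths, tab, cfg)
  proj <- pca_project(tab, unique(unlist(paths)), cfg)
  eu <- function(a, b) sqrt(sum((a - b)^2))
  for (k in seq_len(nrow(rec))) {
    s <- proj[rec$start[k], ]; m <- proj[rec$intermediate[k], ]
    e <- proj[rec$end[k], ]
    expect_equal(rec$smoothness[k], eu(s, e) / (eu(s, m) + eu(m, e)),
                 tolerance = 1e-12)
  }
})

test_that("collinear ordered projections give smoothness exactly 1", {
  t_par <- seq(0, 1, length.out = 6)
  m <- outer(t_par, c(3, -1, 2, 5))
  rownames(m) <- sprintf("K%02d", 1:6)
  tab <- representation_table("t", "correlation_centered", m)
  rec <- score_pathways(list(p = rownames(m)), tab)
  expect_equal(rec$smoothness, rep(1, 4), tolerance = 1e-9)
})

test_that("whole-pipeline smoothness is invariant to rigid motions", {
  tab <- small_embedding_table(10, 8, seed = 7)
  keys <- rownames(tab$vectors)
  paths <- list(p = keys[1:7])
  q <- random_rotation(8, seed = 9)
  moved <- sweep(tab$vectors %*% q, 2, rnorm(8), "+")
  rownames(moved) <- keys
  tab2 <- representation_table("t2", "correlation_centered", moved)
  expect_equal(score_pathways(paths, tab)$smoothness,
               score_pathways(paths, tab2)$smoothness, tolerance = 1e-9)
})

test_that("paired t-test matches the closed form and stats::t.test", {
  d <- c(1, 2, 3)
  res <- paired_t_test(d + c(10, 20, 30), c(10, 20, 30))
  expect_equal(res$t_statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$mean_diff, 2)
  set.seed(8)
  a <- rnorm(15)
  b <- rnorm(15)
  mine <- paired_t_test(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  g <- paired_t_test(a, b, sided = "greater")
  ref_g <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  expect_equal(g$p_value, ref_g$p.value, tolerance = 1e-12)
  expect_error(paired_t_test(a, a + 1), "zero")
  perturbed <- a
  perturbed[1] <- perturbed[1] + 0.5
  ok <- paired_t_test(a, perturbed)
  expect_true(is.finite(ok$t_statistic))
  expect_true(ok$p_value > 0 && ok$p_value < 1)
})

test_that("a table smoothed along pathways scores smoother than raw", {
  met <- make_metabolome(generator_config(n_metabolites = 120, seed = 9))
  cfp <- metabolome_fp_table(met)
  paths <- met$pathways[lengths(met$pathways) >= 5]
  # synthetic smoothing: move intermediates onto the straight segment
  # between their pathway's endpoint vectors
  sm <- cfp$vectors * 1.0
  for (p in paths) {
    len <- length(p)
    for (i in 2:(len - 1)) {
      w <- (i - 1) / (len - 1)
      sm[p[i], ] <- (1 - w) * sm[p[1], ] + w * sm[p[len], ]
    }
  }
  smooth_tab <- representation_table("smoothed", "l1", sm)
  rec_raw <- score_pathways(paths, cfp)
  rec_sm <- score_pathways(paths, smooth_tab)
  expect_gte(nrow(rec_raw), 30)
  expect_gt(mean(rec_sm$smoothness), mean(rec_raw$smoothness))
  tt <- paired_t_test(rec_sm$smoothness, rec_raw$smoothness,
                      sided = "greater")
  expect_lt(tt$p_value, 0.01)
})

test_that("view coordinates are the leading two components", {
  tab <- small_embedding_table(7, 5, seed = 10)
  keys <- rownames(tab$vectors)
  pr <- pca_project(tab, keys, pca_config(n_components = 4))
  vc <- view_coordinates(pr, keys[1:6])
  expect_equal(vc$pc1, unname(pr[keys[1:6], 1]))
  expect_equal(vc$pc2, unname(pr[keys[1:6], 2]))
  f <- withr::local_tempfile(fileext = ".png")
  plot_pathway_trajectory(pr, keys[1:6], path = f)
  expect_gt(file.size(f), 0)
})
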