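# Screen statistics: intensity ratios, Dunnett, BCa bootstrap, matrices,
# clustering and population classification.

test_that("mitochondrial intensity ratio pools ROI pixels", {
  pre <- matrix(10, 20, 20); post <- matrix(10, 20, 20)
  rois <- list(roi(0, 0, 5), roi(10, 10, 5))
  expect_equal(mito_intensity_ratio(pre, post, rois), 1)
  expect_equal(mito_intensity_ratio(pre, post * 3, rois), 3)
  # pooled pixels, not mean of per-ROI ratios: pre means (10, 20),
  # post means (30, 30) -> 30 / 15 = 2
  pre2 <- matrix(10, 20, 20); pre2[11:15, 11:15] <- 20
  post2 <- matrix(30, 20, 20)
  expect_equal(mito_intensity_ratio(pre2, post2, rois), 2)
  # homogeneity: scaling post scales the ratio
  expect_equal(mito_intensity_ratio(pre2, post2 * 2.5, rois), 5)
  expect_error(mito_intensity_ratio(matrix(0, 5, 5), matrix(1, 5, 5),
                                    list(roi(0, 0, 2))), "zero")
  expect_error(mito_intensity_ratio(pre, matrix(1, 3, 3), rois), "shape")
})

test_that("one-comparison Dunnett equals the pooled-variance t-test", {
  set.seed(14)
  for (i in 1:3) {
    a <- rnorm(12); b <- rnorm(15, 0.5)
    dn <- dunnett_vs_control(list(control = a, trt = b), "control")
    tt <- t.test(b, a, var.equal = TRUE)
    expect_equal(dn$p_adj, tt$p.value, tolerance = 1e-6)
    expect_equal(dn$t, unname(tt$statistic), tolerance = 1e-9)
  }
})

test_that("Dunnett adjustment is conservative and handles edge cases", {
  set.seed(15)
  groups <- c(list(control = rnorm(10)),
              setNames(lapply(1:4, function(i) rnorm(8 + i, 0.3 * i)),
                       paste0("g", 1:4)))
  dn <- dunnett_vs_control(groups, "control")
  # adjusted p >= unadjusted pooled t p for every comparison
  df <- attr(dn, "df"); s <- attr(dn, "pooled_sd")
  for (i in seq_len(nrow(dn))) {
    p_raw <- 2 * pt(-abs(dn$t[i]), df)
    expect_gte(dn$p_adj[i] + 1e-12, p_raw)
  }
  # a group identical to the control has p ~ 1
  g <- list(control = c(1, 2, 3, 4), same = c(1, 2, 3, 4), other = c(5, 6, 7, 8))
  dn <- dunnett_vs_control(g, "control")
  expect_equal(dn$p_adj[dn$group == "same"], 1, tolerance = 1e-9)
  expect_error(dunnett_vs_control(g, "missing"), "not found")
})

test_that("Dunnett critical value matches the quadrature CDF", {
  crit <- dunnett_critical(ns = rep(20, 4), n_control = 20, alpha = 0.05)
  # classic tables give ~2.44-2.55 for 4 comparisons at these sizes
  expect_gt(crit, 2.3); expect_lt(crit, 2.7)
  # consistency: adjusted p at the critical value is alpha
  lambda <- sqrt(20 / 40)
  p <- 1 - invquant:::pdunnett_abs(crit, rep(lambda, 4), 95)
  expect_equal(p, 0.05, tolerance = 1e-6)
})

test_that("BCa bootstrap: degenerate, symmetric and reproducible cases", {
  # identical constant samples: degenerate CI at 0
  est <- bootstrap_bca_diff(rep(3, 5), rep(3, 5), n_boot = 500, seed = 1)
  expect_true(est$degenerate)
  expect_equal(c(est$ci_low, est$mean_difference, est$ci_high), c(0, 0, 0))

  # symmetric normal samples: BCa ~ percentile interval
  set.seed(22)
  g <- rnorm(200); ctrl <- rnorm(200)
  est <- bootstrap_bca_diff(g, ctrl, n_boot = 20000, seed = 5)
  qs <- with_seed_boot_percentile(g, ctrl, 20000, 5)
  sd_stat <- sqrt(var(g) / 200 + var(ctrl) / 200)
  expect_lt(abs(est$ci_low - qs[1]), 0.05 * sd_stat)
  expect_lt(abs(est$ci_high - qs[2]), 0.05 * sd_stat)
  expect_true(est$ci_low <= est$mean_difference &&
              est$mean_difference <= est$ci_high)

  # bit-for-bit reproducibility under a fixed seed
  e1 <- bootstrap_bca_diff(g, ctrl, n_boot = 1000, seed = 77)
  e2 <- bootstrap_bca_diff(g, ctrl, n_boot = 1000, seed = 77)
  expect_identical(e1, e2)
  expect_error(bootstrap_bca_diff(1, 1:3), "n >= 2")
})

test_that("screen matrix averaging and Z-scores", {
  # 3 rabs x 2 constructs hand case
  tab <- expand.grid(rab = c("r1", "r2", "r3"), construct = c("A", "B"),
                     cell = 1:2, stringsAsFactors = FALSE)
  ratios <- c(r1A = 1, r2A = 2, r3A = 3, r1B = 2, r2B = 2, r3B = 5)
  tab$F_pre <- 100
  tab$F_post <- 100 * ratios[paste0(tab$rab, tab$construct)]
  sm <- build_screen_matrix(tab)
  expect_equal(unname(sm$values[, "A"]), c(1, 2, 3))
  hand_z <- (c(1, 2, 3) - 2) / sd(c(1, 2, 3))
  expect_equal(unname(sm$zscores[, "A"]), hand_z)
  expect_equal(unname(colMeans(sm$zscores)), c(0, 0))
  expect_equal(unname(apply(sm$zscores, 2, sd)), c(1, 1))
  # constant column: informative error pointing to global mode
  tab2 <- tab; tab2$F_post[tab2$construct == "A"] <- 100
  expect_error(build_screen_matrix(tab2), "global")
  sm2 <- build_screen_matrix(tab2, standardize = "global")
  expect_equal(mean(sm2$zscores), 0)
  # missing combination errors explicitly
  expect_error(build_screen_matrix(tab[tab$rab != "r1" | tab$construct != "A", ]),
               "missing")
})

test_that("clustering merges near rows first and recovers planted blocks", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  cl <- cluster_screen(m, k = 2)
  expect_equal(cl$hclust$height[1], 0)         # identical rows merge at 0
  expect_equal(cl$clusters[["a"]], cl$clusters[["b"]])
  expect_false(cl$clusters[["a"]] == cl$clusters[["c"]])
  # three rows at mutual distances 1, 1, ~10: close pair merges first
  m2 <- rbind(p = 0, q = 1, r = 10)
  cl2 <- cluster_screen(m2, k = 2)
  expect_equal(cl2$clusters[["p"]], cl2$clusters[["q"]])
  expect_error(cluster_screen(rbind(c(NA, 1), c(1, 2))), "NA")

  # planted two-block screen recovered with adjusted Rand = 1
  truth <- rep(1:2, each = 6)
  ratios <- matrix(1, 12, 3, dimnames = list(sprintf("rab%02d", 1:12),
                                             c("TPD52", "TPD53", "TPD54")))
  ratios[truth == 2, ] <- 2.5
  tab <- simulate_screen(constructs = colnames(ratios), rabs = rownames(ratios),
                         true_ratio = ratios, cell_noise_sd = 0.15,
                         n_cells_per_condition = 15, seed = 31)
  sm <- build_screen_matrix(tab)
  cl3 <- cluster_screen(sm, k = 2)
  expect_equal(adjusted_rand_index(cl3$clusters[rownames(sm$values)], truth), 1)
})

test_that("INV population classification by screen membership", {
  hits <- data.frame(
    construct = rep(c("TPD52", "TPD53", "TPD54"), each = 3),
    rab = rep(c("Rab30", "Rab10", "RabX"), 3),
    p_adj = c(0.01, 0.02, 0.9,   0.03, 0.9, 0.9,   0.04, 0.9, 0.9))
  cls <- classify_inv_populations(hits)
  expect_equal(cls$class[cls$rab == "Rab30"], "TPD52+TPD53+TPD54")
  expect_equal(cls$class[cls$rab == "Rab10"], "TPD52")
  expect_false("RabX" %in% cls$rab)  # significant nowhere: excluded
  # planted memberships recovered from a simulated screen end-to-end
  rabs <- c("GFP", "Rab30", "Rab10", "RabNull")
  ratios <- matrix(1, 4, 2, dimnames = list(rabs, c("TPD52", "TPD54")))
  ratios["Rab30", ] <- 2.5
  ratios["Rab10", "TPD52"] <- 2.5
  tab <- simulate_screen(constructs = colnames(ratios), rabs = rabs,
                         true_ratio = ratios, cell_noise_sd = 0.2,
                         n_cells_per_condition = 20, seed = 41)
  ratio <- tab$F_post / tab$F_pre
  calls <- do.call(rbind, lapply(colnames(ratios), function(con) {
    sub <- tab$construct == con
    dn <- dunnett_vs_control(split(ratio[sub], tab$rab[sub]), "GFP")
    data.frame(construct = con, rab = dn$group, p_adj = dn$p_adj)
  }))
  cls2 <- classify_inv_populations(calls)
  expect_equal(cls2$class[cls2$rab == "Rab30"], "TPD52+TPD54")
  expect_equal(cls2$class[cls2$rab == "Rab10"], "TPD52")
  expect_false("RabNull" %in% cls2$rab)
})
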