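# recombination fractions, grouping, ordering, map summaries

test_that("recombination fraction estimation: limits and EM-vs-grid oracle", {
  g <- sample(0:2, 100, replace = TRUE)
  same <- estimate_rf(g, g)
  expect_equal(same$r, 0, tolerance = 1e-8)
  expect_gt(same$lod, 10)

  set.seed(32)
  ga <- sample(0:2, 2000, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  gb <- sample(0:2, 2000, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  unl <- estimate_rf(ga, gb)
  expect_gt(unl$r, 0.45)
  expect_lt(unl$lod, 2)

  expect_error(estimate_rf(c(0L, NA), c(NA, 0L)), "informative")

  # EM equals grid-search ML to 1e-4; mean estimate near truth
  for (r_true in c(0.01, 0.05, 0.1, 0.2)) {
    est <- replicate(25, {
      m <- sim_map(data.frame(group = "g", length_cm = 50, length_bp = 1e6,
                              n_sites = 2),
                   site_positions = list(c(10, 10 + haldane_cm(r_true))))
      pop <- simulate_f2(m, 196)
      em <- estimate_rf(pop$geno[1, ], pop$geno[2, ])$r
      grid <- rf_grid_oracle(pop$geno[1, ], pop$geno[2, ])
      expect_lt(abs(em - grid), 1e-4)
      em
    })
    mc_sd <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - r_true), 3 * mc_sd + 0.002)
  }
})

test_that("the vectorized pairwise estimator agrees with the single-pair EM", {
  pop <- simulate_f2(one_group_map(length_cm = 50, n_sites = 8), 150,
                     seed = 33)
  rf <- rf_matrix(pop$geno)
  for (i in 1:7) {
    single <- estimate_rf(pop$geno[i, ], pop$geno[i + 1, ])
    expect_equal(rf$r[i, i + 1], single$r, tolerance = 1e-10)
    expect_equal(rf$lod[i, i + 1], single$lod, tolerance = 1e-10)
  }
  expect_true(isSymmetric(rf$r))
})

test_that("linkage grouping recovers the simulated chromosomes", {
  map <- default_map(n_sites = 95)   # 2-8 markers per group
  pop <- simulate_f2(map, 150, seed = 34)
  rf <- rf_matrix(pop$geno)
  grp <- group_markers(rf)
  expect_equal(length(unique(grp)), 19)
  expect_equal(length(unique(paste(map$sites$group, grp))), 19)

  # two unlinked markers fall in separate groups; singletons stand alone
  rf2 <- rf_matrix(rbind(pop$geno[1, ], pop$geno[95, ]))
  expect_equal(length(unique(group_markers(rf2))), 2)
  rf1 <- rf_matrix(pop$geno[1, , drop = FALSE])
  expect_equal(group_markers(rf1), 1L)
})

test_that("marker ordering is exact on three points and matches brute force to eight", {
  d3 <- kosambi_cm(matrix(c(0, 0.01, 0.0199,
                            0.01, 0, 0.01,
                            0.0199, 0.01, 0), 3))
  ord <- order_markers(d3)
  expect_true(identical(ord, c(1L, 2L, 3L)) || identical(ord, c(3L, 2L, 1L)))

  path_len <- function(ord, d)
    sum(d[cbind(ord[-length(ord)], ord[-1])])
  set.seed(35)
  for (trial in 1:10) {
    m <- sample(4:8, 1)
    mp <- sim_map(data.frame(group = "g", length_cm = 40, length_bp = 1e6,
                             n_sites = m))
    pop <- simulate_f2(mp, 120)
    d <- kosambi_cm(pmin(rf_matrix(pop$geno)$r, 0.49))
    ord <- order_markers(d)
    perms <- perms_of(m)
    lens <- rowSums(vapply(seq_len(m - 1), function(k)
      d[cbind(perms[, k], perms[, k + 1])], numeric(nrow(perms))))
    expect_equal(path_len(ord, d), min(lens), tolerance = 1e-10)
  }
})

test_that("noiseless map building recovers order, groups and length", {
  map <- two_group_map(n_sites = 30)   # 30 markers per group
  pop <- simulate_f2(map, 196, seed = 36)
  # perfect genotypes through the bin machinery
  bg <- list(bins = data.frame(bin = sprintf("m%02d", 1:60),
                               chrom = map$sites$group,
                               start = map$sites$bp, end = map$sites$bp,
                               stringsAsFactors = FALSE),
             geno = pop$geno)
  gm <- build_map(bg)
  expect_equal(length(unique(gm$group)), 2)
  for (g in unique(gm$group)) {
    s <- gm[gm$group == g, ]
    rho <- stats::cor(s$cm, s$start, method = "spearman")
    expect_equal(abs(rho), 1)
  }

  # length recovery: a single replicate's length has MC sd of about
  # sqrt(100 L / 2n) ~ 4 cM, so the 10% check applies to the replicate mean
  lens <- sapply(36:39, function(seed) {
    p <- simulate_f2(map, 196, seed = seed)
    b <- list(bins = bg$bins, geno = p$geno)
    g <- build_map(b)
    sort(tapply(g$cm, g$group, max))
  })
  true_lens <- sort(tapply(map$sites$cm, map$sites$group,
                           function(x) diff(range(x))))
  expect_true(all(abs(rowMeans(lens) - true_lens) < 0.1 * true_lens))
  # reversal invariance of length: reverse genotype row order within a group
  idx <- c(30:1, 31:60)
  bg_rev <- list(bins = bg$bins[idx, ], geno = bg$geno[idx, ])
  gm_rev <- build_map(bg_rev)
  expect_equal(sort(tapply(gm_rev$cm, gm_rev$group, max)),
               sort(tapply(gm$cm, gm$group, max)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("map summaries follow the length/(n-1) and unweighted-mean conventions", {
  gm <- structure(data.frame(group = "g1", marker = c("a", "b", "c"),
                             cm = c(0, 1, 3), chrom = "c1",
                             start = 1:3, end = 1:3),
                  class = c("genetic_map", "data.frame"))
  s <- map_summary(gm)
  expect_equal(s$length_cm[1], 3)
  expect_equal(s$mean_interval[1], 1.5)
  expect_equal(s$max_interval[1], 2)

  # two groups: whole mean interval is the unweighted mean of group means
  tab <- data.frame(group = c("g1", "g2"), length_cm = c(10, 90),
                    n_markers = c(11, 10), max_interval = c(2, 30))
  s2 <- map_summary(tab)
  whole <- s2[s2$group == "Whole", ]
  expect_equal(whole$mean_interval, mean(c(1, 10)))
  expect_equal(whole$length_cm, 100)
  expect_equal(whole$max_interval, 16)
  expect_equal(whole$global_interval, 100 / (21 - 2))
  # single-marker group flagged with zero interval
  s3 <- map_summary(data.frame(group = "g", length_cm = 0, n_markers = 1))
  expect_true(s3$single_marker_group[1])
  expect_equal(s3$mean_interval[1], 0)
})

test_that("collinearity diagnostics flag inversions and suppressed regions", {
  gm <- structure(data.frame(group = "g1",
                             marker = sprintf("m%02d", 1:10),
                             cm = 0:9, chrom = "c1",
                             start = c(1:8, 10, 9) * 1e6,
                             end = c(1:8, 10, 9) * 1e6),
                  class = c("genetic_map", "data.frame"))
  res <- collinearity(gm)
  expect_equal(res$per_group$rho,
               stats::cor(0:9, c(1:8, 10, 9), method = "spearman"))
  expect_equal(res$per_group$discordant, 1)

  perfect <- gm
  perfect$start <- perfect$end <- (1:10) * 1e6
  expect_equal(collinearity(perfect)$per_group$rho, 1)

  # 15 Mb with ~0 genetic distance -> suppression flag
  supp <- structure(data.frame(group = "g1", marker = sprintf("m%02d", 1:6),
                               cm = c(0, 1, 1.2, 1.4, 1.6, 20),
                               chrom = "c1",
                               start = c(1, 2, 6, 12, 17, 18) * 1e6,
                               end = c(1, 2, 6, 12, 17, 18) * 1e6),
                    class = c("genetic_map", "data.frame"))
  res2 <- collinearity(supp)
  expect_gt(nrow(res2$suppressed), 0)
  expect_error(collinearity(transform(gm, start = NA, end = NA)), "anchor")
})
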