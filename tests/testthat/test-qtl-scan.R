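# conditional genotype probabilities, CIM scan, permutations, peaks

test_that("genotype probabilities collapse, marginalize and match enumeration", {
  # at a marker (zero distance) the observed genotype is certain
  pr <- genotype_probs(c(0L, 1L, 2L), c(0L, 1L, 2L), 0, 12)
  expect_equal(pr[1, ], c(p_aa = 1, p_ab = 0, p_bb = 0), tolerance = 1e-12)
  # both flanks missing: the 1:2:1 prior
  pr_na <- genotype_probs(NA_integer_, NA_integer_, 5, 5)
  expect_equal(unname(pr_na[1, ]), c(0.25, 0.5, 0.25))
  expect_error(genotype_probs(0L, 0L, -1, 2), "outside")

  # brute-force enumeration oracle, written as an explicit loop over the
  # eight ordered allele triples per gamete
  enum_oracle <- function(gl, gr, rl, rr) {
    tally <- array(0, c(3, 3, 3))
    for (l1 in 0:1) for (q1 in 0:1) for (r1 in 0:1)
      for (l2 in 0:1) for (q2 in 0:1) for (r2 in 0:1) {
        p <- prod(0.5,
                  ifelse(l1 == q1, 1 - rl, rl), ifelse(q1 == r1, 1 - rr, rr),
                  0.5,
                  ifelse(l2 == q2, 1 - rl, rl), ifelse(q2 == r2, 1 - rr, rr))
        tally[l1 + l2 + 1, q1 + q2 + 1, r1 + r2 + 1] <-
          tally[l1 + l2 + 1, q1 + q2 + 1, r1 + r2 + 1] + p
      }
    tally[gl + 1, , gr + 1] / sum(tally[gl + 1, , gr + 1])
  }
  set.seed(37)
  for (i in 1:10) {
    dl <- stats::runif(1, 0.5, 15); dr <- stats::runif(1, 0.5, 15)
    gl <- sample(0:2, 1); gr <- sample(0:2, 1)
    ours <- genotype_probs(gl, gr, dl, dr)[1, ]
    ref <- enum_oracle(gl, gr, kosambi_inverse(dl), kosambi_inverse(dr))
    expect_equal(unname(ours), ref, tolerance = 1e-12)
  }

  # scaffold codes agree with genotype_probs at an off-marker grid position
  map <- two_group_map(n_sites = 20)
  pop <- simulate_f2(map, 50, seed = 38)
  mk <- truth_marker_map(map)
  scaf <- scan_scaffold(pop$geno, mk, 1, "kosambi")
  rows <- which(mk$group == "chr1")
  cm <- mk$cm[rows]
  i <- which(scaf$pos$group == "chr1" &
               !scaf$pos$cm %in% cm)[3]
  p <- scaf$pos$cm[i]
  li <- findInterval(p, cm)
  pr2 <- genotype_probs(pop$geno[rows[li], ], pop$geno[rows[li + 1], ],
                        p - cm[li], cm[li + 1] - p)
  expect_equal(scaf$xa[i, ], unname(pr2[, 3] - pr2[, 1]), tolerance = 1e-12)
  expect_equal(scaf$xd[i, ], unname(pr2[, 2]), tolerance = 1e-12)
})

test_that("cofactor selection is deterministic and finds a planted locus first", {
  map <- two_group_map(n_sites = 40)
  pop <- simulate_f2(map, 196, seed = 39)
  mk <- truth_marker_map(map)
  qtl <- data.frame(group = "chr2", cm = 40, a = 1, d = 0, h2 = 0.4)
  ph <- simulate_phenotypes(pop, qtl, sim_config(n = 196), seed = 40)
  cof <- select_cofactors(pop$geno, ph$R, 5)
  expect_gte(length(cof), 1)
  expect_lte(length(cof), 5)
  expect_equal(cof, select_cofactors(pop$geno, ph$R, 5))  # deterministic
  # first pick is a marker flanking the planted QTL
  expect_equal(mk$group[cof[1]], "chr2")
  expect_lt(abs(mk$cm[cof[1]] - 40), 2.2)
  expect_equal(select_cofactors(pop$geno, ph$R, 0), integer(0))
  expect_error(select_cofactors(pop$geno, ph$R, 1e6), "cofactors")
})

test_that("scan degenerate cases and the single-marker identity", {
  map <- two_group_map(n_sites = 15)
  pop <- simulate_f2(map, 100, seed = 41)
  mk <- truth_marker_map(map)
  const <- rep(1.7, 100)
  sc <- cim_scan(pop$geno, mk, const, cim_config(step = 5, n_cofactors = 0))
  expect_true(all(sc$lod == 0))
  expect_error(cim_scan(pop$geno, mk, letters[1:100]), "numeric")

  # at a fully informative marker, LOD equals the regression identity
  set.seed(42)
  y <- stats::rnorm(100) + pop$geno[8, ]
  sc2 <- cim_scan(pop$geno, mk, y, cim_config(step = 5, n_cofactors = 0))
  i <- which(sc2$group == mk$group[8] & abs(sc2$cm - mk$cm[8]) < 1e-9)
  xa <- pop$geno[8, ] - 1; xd <- as.numeric(pop$geno[8, ] == 1)
  rss1 <- sum(stats::resid(stats::lm(y ~ xa + xd))^2)
  rss0 <- sum((y - mean(y))^2)
  expect_equal(sc2$lod[i], (100 / 2) * log10(rss0 / rss1), tolerance = 1e-8)
  expect_equal(sc2$r2_raw[i], 100 * (1 - rss1 / rss0), tolerance = 1e-8)

  # LOD is invariant under affine transformation of the phenotype
  sc3 <- cim_scan(pop$geno, mk, 3 * y + 7,
                  cim_config(step = 5, n_cofactors = 0))
  expect_equal(sc3$lod, sc2$lod, tolerance = 1e-9)
})

test_that("planted-QTL LOD matches its closed-form expectation", {
  # E[peak LOD] ~ -(n/2) log10(1 - h2) for h2 = 0.2095, n = 196 (~10.0)
  map <- default_map(n_sites = 400)
  mk <- truth_marker_map(map)
  qtl <- data.frame(group = "A09", cm = 81.91, a = 1, d = 0, h2 = 0.2095)
  lods <- vapply(1:12, function(s) {
    pop <- simulate_f2(map, 196, seed = 400 + s)
    ph <- simulate_phenotypes(pop, qtl, sim_config(n = 196), seed = 500 + s)
    sc <- cim_scan(pop$geno, mk, ph$R, cim_config(step = 2, n_cofactors = 0))
    max(sc$lod)
  }, numeric(1))
  expected <- -(196 / 2) * log10(1 - 0.2095)
  expect_lt(abs(mean(lods) - expected),
            3 * stats::sd(lods) / sqrt(length(lods)) + 0.5)
})

test_that("permutation thresholds are reproducible with quantile edge cases", {
  map <- two_group_map(n_sites = 20)
  pop <- simulate_f2(map, 80, seed = 43)
  mk <- truth_marker_map(map)
  set.seed(44)
  y <- stats::rnorm(80)
  cfg <- cim_config(step = 2, n_cofactors = 0, n_perm = 100)
  p1 <- permutation_threshold(pop$geno, mk, y, cfg, seed = 45)
  p2 <- permutation_threshold(pop$geno, mk, y, cfg, seed = 45)
  expect_equal(p1$threshold, p2$threshold)
  expect_length(p1$max_lods, 100)

  cfg_all <- cim_config(step = 2, n_cofactors = 0, n_perm = 100, alpha = 1)
  p3 <- permutation_threshold(pop$geno, mk, y, cfg_all, seed = 45)
  expect_equal(p3$threshold, min(p1$max_lods))
})

test_that("peak calling: support intervals, physical projection, empty case", {
  map <- two_group_map(n_sites = 60)
  pop <- simulate_f2(map, 196, seed = 46)
  mk <- truth_marker_map(map)
  qtl <- data.frame(group = "chr1", cm = 30, a = 1, d = 0, h2 = 0.35)
  ph <- simulate_phenotypes(pop, qtl, sim_config(n = 196), seed = 47)
  sc <- cim_scan(pop$geno, mk, ph$R, cim_config(step = 1))
  pk <- call_peaks(sc, 4, map = mk, trait = "R")
  expect_gt(nrow(pk), 0)
  top <- pk[which.max(pk$lod), ]
  expect_equal(top$group, "chr1")
  expect_lt(abs(top$cm - 30), 10)
  expect_true(top$ci_lo <= top$cm && top$cm <= top$ci_hi)
  expect_true(top$phys_lo <= top$phys_hi)
  expect_gt(top$add, 0)   # high allele raises the trait

  expect_equal(nrow(call_peaks(sc, 1e6)), 0)
})

test_that("major and minor QTLs are detected with the expected power ordering", {
  map <- default_map(n_sites = 400)
  mk <- truth_marker_map(map)
  hits <- t(vapply(1:8, function(s) {
    pop <- simulate_f2(map, 196, seed = 600 + s)
    ph <- simulate_phenotypes(pop, default_qtls(), sim_config(n = 196),
                              seed = 700 + s)
    sc <- cim_scan(pop$geno, mk, ph$R, cim_config(step = 2))
    pk <- call_peaks(sc, 4, map = mk, trait = "R")
    c(major = "A09" %in% pk$group, minor = "C03" %in% pk$group)
  }, logical(2)))
  expect_equal(mean(hits[, "major"]), 1)
  expect_gte(mean(hits[, "minor"]), 0.25)
})
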