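# the meiosis / variant-call / phenotype / expression generators

test_that("default map reproduces the 19-group template geometry", {
  m <- default_map()
  expect_equal(nrow(m$groups), 19)
  expect_equal(sum(m$groups$n_sites), 4148)
  expect_equal(sum(m$groups$length_cm), 1618.329)
  expect_true(all(tapply(m$sites$cm, m$sites$group,
                         function(x) !is.unsorted(x, strictly = TRUE))))
  # collinear physical positions
  expect_true(all(tapply(m$sites$bp, m$sites$group,
                         function(x) !is.unsorted(x))))
})

test_that("crossover counts and recombination fractions match the process", {
  expect_length(binmapqtl:::draw_crossovers(0, "haldane"), 0)
  set.seed(42)
  n_xo <- replicate(8000, length(binmapqtl:::draw_crossovers(100, "haldane")))
  # Poisson(1): mean 1, MC se = 1/sqrt(8000)
  expect_lt(abs(mean(n_xo) - 1), 3 / sqrt(8000))

  # two sites 1 cM apart: recombinant fraction ~ inverse map function (~0.01)
  m <- sim_map(data.frame(group = "g", length_cm = 10, length_bp = 1e6,
                          n_sites = 2), site_positions = list(c(4, 5)))
  gam <- simulate_meiosis(m, 20000, seed = 7)
  al <- vapply(seq_len(20000), function(j) {
    a <- binmapqtl:::gamete_allele(gam$g$start[j], gam$g$xo[[j]], c(4, 5))
    a[1] != a[2]
  }, logical(1))
  r_true <- haldane_inverse(1)
  expect_lt(abs(mean(al) - r_true), 3 * sqrt(r_true * (1 - r_true) / 20000))
  expect_error(simulate_meiosis(sim_map(data.frame(
    group = character(0), length_cm = numeric(0), length_bp = numeric(0),
    n_sites = integer(0))), 5), "empty")
})

test_that("interference mode tracks the Kosambi map function at 20 cM", {
  m <- sim_map(data.frame(group = "g", length_cm = 40, length_bp = 4e7,
                          n_sites = 2), site_positions = list(c(10, 30)))
  gam <- simulate_meiosis(m, 20000, seed = 2, model = "kosambi")
  rec <- vapply(seq_len(20000), function(j) {
    a <- binmapqtl:::gamete_allele(gam$g$start[j], gam$g$xo[[j]], c(10, 30))
    a[1] != a[2]
  }, logical(1))
  r_k <- kosambi_inverse(20)
  mc_sd <- sqrt(r_k * (1 - r_k) / 20000)
  # gamma-renewal is only approximately Kosambi: 3 MC sd plus a small model
  # margin, but clearly distinct from the no-interference value (0.165)
  expect_lt(abs(mean(rec) - r_k), 3 * mc_sd + 0.008)
  expect_gt(mean(rec), haldane_inverse(20) + 3 * mc_sd)
})

test_that("F2 genotypes segregate 1:2:1 and respect the crossover truth", {
  m <- one_group_map(n_sites = 20)
  pop1 <- simulate_f2(m, 1, seed = 5)
  expect_equal(dim(pop1$geno), c(20, 1))
  expect_true(all(pop1$geno %in% 0:2))

  pop <- simulate_f2(m, 5000, seed = 6)
  counts <- table(factor(pop$geno[10, ], levels = 0:2))
  p <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.001)

  # effectively coincident sites carry identical genotype columns
  m2 <- sim_map(data.frame(group = "g", length_cm = 50, length_bp = 1e6,
                           n_sites = 2),
                site_positions = list(c(25, 25 + 1e-9)))
  pop2 <- simulate_f2(m2, 200, seed = 8)
  expect_equal(pop2$geno[1, ], pop2$geno[2, ])

  # true_genotype agrees with the stored site genotypes
  expect_equal(true_genotype(pop1, m$sites$group, m$sites$cm), pop1$geno)
  expect_error(simulate_f2(m, 0))
})

test_that("variant calls recover truth in the noiseless limit and match the het-undercall analysis", {
  m <- one_group_map(n_sites = 60)
  pop <- simulate_f2(m, 40, seed = 9)
  vm <- simulate_variant_calls(pop, depth = 1e4, error = 0, missing = 0,
                               seed = 10)
  expect_identical(vm$geno, pop$geno)
  vm_miss <- simulate_variant_calls(pop, depth = 5, error = 0, missing = 1,
                                    seed = 11)
  expect_true(all(is.na(vm_miss$geno)))

  # P(het called homozygous) = sum_k Pois(k; 4.8) * 2 * 0.5^k over k >= 1
  k <- 1:200
  p_analytic <- sum(stats::dpois(k, 4.8) * 2 * 0.5^k)
  pop_h <- simulate_f2(one_group_map(n_sites = 500), 100, seed = 12)
  vm_h <- simulate_variant_calls(pop_h, depth = 4.8, error = 0.01,
                                 missing = 0, seed = 13)
  het <- pop_h$geno == 1L
  called_hom <- vm_h$geno[het] %in% c(0L, 2L)
  n_het <- sum(het)
  expect_lt(abs(mean(called_hom) - p_analytic),
            3 * sqrt(p_analytic * (1 - p_analytic) / n_het) + 0.002)
  expect_error(simulate_variant_calls(pop, depth = -1), "depth")
})

test_that("phenotypes realize the planted variance shares and trait structure", {
  m <- default_map(n_sites = 190)
  pop <- simulate_f2(m, 10000, seed = 14)
  qtl <- data.frame(group = "A09", cm = 81.91, a = 1, d = 0, h2 = 0.2095)
  ph <- simulate_phenotypes(pop, qtl, sim_config(n = 10000), seed = 15)
  share <- stats::var(attr(ph, "genetic")) / stats::var(attr(ph, "latent"))
  expect_lt(abs(share - 0.2095), 0.02)

  # no QTLs: pure noise, zero genetic variance
  ph0 <- simulate_phenotypes(pop, qtl[0, ], sim_config(n = 10000), seed = 16)
  expect_equal(stats::var(attr(ph0, "genetic")), 0)

  # correlated colour traits (|r| >= 0.9 by construction)
  cc <- stats::cor(ph[, c("R", "G", "B", "l", "a", "b")])
  expect_true(all(abs(cc) >= 0.9))
  expect_true(all(cc["R", c("a", "b")] < 0))
  expect_setequal(unique(ph$visual), 0:1)
  expect_equal(ph$visual, as.integer(ph$R > 67))

  expect_error(simulate_phenotypes(
    pop, data.frame(group = "A09", cm = 10, a = 1, d = 0, h2 = 1.2)), "< 1")
})

test_that("a clearly separated major locus produces a density valley between classes", {
  # at high variance share the two visual classes separate; the kernel
  # density at the between-class midpoint is below both class modes
  m <- default_map(n_sites = 190)
  pop <- simulate_f2(m, 2000, seed = 17)
  qtl <- data.frame(group = "A09", cm = 81.91, a = 1, d = 0.5, h2 = 0.75)
  ph <- simulate_phenotypes(pop, qtl, sim_config(n = 2000), seed = 18)
  g <- true_genotype(pop, "A09", 81.91)[1, ]
  d <- stats::density(ph$R)
  m_lo <- mean(ph$R[g == 0]); m_hi <- mean(ph$R[g != 0])
  between <- d$x > m_lo & d$x < m_hi
  valley <- min(d$y[between])
  x_valley <- d$x[between][which.min(d$y[between])]
  left_peak <- max(d$y[d$x <= x_valley])
  right_peak <- max(d$y[d$x >= x_valley])
  expect_lt(valley, 0.9 * left_peak)
  expect_lt(valley, 0.9 * right_peak)
})

test_that("expression simulation plants modules, replicate agreement and DEGs", {
  ex <- simulate_expression(seed = 19)
  expect_equal(dim(ex$fpkm), c(400, 18))

  # replicate correlation on module genes within each condition
  mod_genes <- names(ex$truth$module)[ex$truth$module > 0]
  cond <- paste(ex$samples$genotype, ex$samples$stage)
  reps <- split(seq_len(18), cond)
  rr <- unlist(lapply(reps, function(ix) {
    cc <- stats::cor(ex$log2[mod_genes, ix])
    cc[upper.tri(cc)]
  }))
  expect_true(all(rr >= 0.96))

  # zero noise: perfect within-module correlation
  ex0 <- simulate_expression(rep_sd = 0, gene_sd = 0, seed = 20)
  m1 <- names(ex0$truth$module)[ex0$truth$module == 1]
  cc <- stats::cor(t(ex0$log2[m1[1:5], ]))
  expect_equal(max(abs(cc) - 1), 0, tolerance = 1e-12)

  # planted flavonoid down-regulation is recovered by the stand-in DE test
  de <- de_by_stage(ex$fpkm, ex$samples)
  flagged <- deg_filter(de, stages = 25)
  expect_true(all(ex$truth$flavonoid %in% flagged$gene_id))
  expect_true(all(flagged$direction[flagged$gene_id %in%
                                      ex$truth$flavonoid] == "down"))
  expect_error(simulate_expression(module_sizes = c(100)), "2 modules")
})
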