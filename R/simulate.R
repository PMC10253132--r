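# F2 simulator: meiosis, low-coverage variant calls, phenotypes, expression.
#
# Genotypes are coded 0 = aa (parent-1 homozygote), 1 = ab, 2 = bb
# (parent-2 homozygote), NA = missing, throughout the package.

# crossover positions (cM) for one gamete on one group
draw_crossovers <- function(len, model = c("haldane", "kosambi")) {
  model <- match.arg(model)
  if (len <= 0) return(numeric(0))
  if (model == "haldane") {
    k <- stats::rpois(1, len / 100)
    if (k == 0) return(numeric(0))
    sort(stats::runif(k, 0, len))
  } else {
    # gamma-renewal (chiasma interference) process, shape nu, mean spacing
    # 100 cM between crossovers on the gamete; stationary start via burn-in
    nu <- 2.63
    pos <- -1000
    out <- numeric(0)
    while (pos <= len) {
      pos <- pos + stats::rgamma(1, shape = nu, rate = nu / 100)
      if (pos > 0 && pos <= len) out <- c(out, pos)
    }
    out
  }
}

#' Simulate gametes from an F1 meiosis
#'
#' Draws gamete haplotypes along each linkage group of a map. Under the
#' default `"haldane"` model crossover counts are Poisson with mean
#' length/100 Morgans and positions are uniform (no interference); the
#' `"kosambi"` mode uses a gamma-renewal process (shape 2.63) with positive
#' interference, consistent with the Kosambi map function used downstream.
#'
#' @param map a [sim_map()].
#' @param n_gametes number of gametes to draw.
#' @param seed optional RNG seed.
#' @param model crossover process, `"haldane"` (default) or `"kosambi"`.
#' @return list with one element per group: `start` (integer vector, founder
#'   haplotype 0/1 at the group start for each gamete) and `xo` (list of
#'   crossover position vectors, cM).
#' @export
simulate_meiosis <- function(map, n_gametes, seed = NULL,
                             model = c("haldane", "kosambi")) {
  if (!inherits(map, "sim_map")) stop("map must be a sim_map")
  if (nrow(map$groups) == 0) stop("empty map")
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nrow(map$groups)), function(i) {
    len <- map$groups$length_cm[i]
    list(start = sample(0:1, n_gametes, replace = TRUE),
         xo = replicate(n_gametes, draw_crossovers(len, model),
                        simplify = FALSE))
  })
  names(out) <- map$groups$group
  out
}

# founder allele (0/1) carried by a gamete at positions cm
gamete_allele <- function(start, xo, cm) {
  (start + findInterval(cm, xo)) %% 2L
}

#' Simulate an F2 population
#'
#' Each individual is formed from two independent F1 gametes; genotypes
#' therefore segregate 1:2:1 at every locus. Crossover positions are kept as
#' the truth track, so the true genotype at any map position (not only at
#' marker sites) can be queried with [true_genotype()].
#'
#' @param map a [sim_map()].
#' @param n number of F2 individuals (>= 1).
#' @param seed optional RNG seed.
#' @param model crossover process passed to [simulate_meiosis()].
#' @return an `f2_pop` object: list with `map`, `n`, `gam1`/`gam2` (meiosis
#'   tracks) and `geno` (sites x individuals integer matrix, 0/1/2).
#' @export
simulate_f2 <- function(map, n, seed = NULL,
                        model = c("haldane", "kosambi")) {
  if (n < 1) stop("n must be >= 1")
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  gam1 <- simulate_meiosis(map, n, model = model)
  gam2 <- simulate_meiosis(map, n, model = model)
  pop <- structure(list(map = map, n = n, gam1 = gam1, gam2 = gam2),
                   class = "f2_pop")
  pop$geno <- true_genotype(pop, map$sites$group, map$sites$cm)
  pop
}

#' True F2 genotypes at arbitrary map positions
#'
#' @param pop an `f2_pop` from [simulate_f2()].
#' @param group character vector of group ids (recycled against `cm`).
#' @param cm numeric vector of positions in cM.
#' @return integer matrix, length(cm) x n, coded 0/1/2.
#' @export
true_genotype <- function(pop, group, cm) {
  stopifnot(inherits(pop, "f2_pop"))
  k <- max(length(group), length(cm))
  group <- rep_len(group, k); cm <- rep_len(cm, k)
  out <- matrix(NA_integer_, k, pop$n)
  for (g in unique(group)) {
    idx <- which(group == g)
    g1 <- pop$gam1[[g]]; g2 <- pop$gam2[[g]]
    if (is.null(g1)) stop("unknown group: ", g)
    for (j in seq_len(pop$n)) {
      out[idx, j] <- gamete_allele(g1$start[j], g1$xo[[j]], cm[idx]) +
        gamete_allele(g2$start[j], g2$xo[[j]], cm[idx])
    }
  }
  out
}

#' Simulate low-coverage variant calls from true genotypes
#'
#' Per site and individual, the read depth is Poisson with the given mean;
#' each read samples one of the two chromosomes and is mis-read with
#' probability `error`. The genotype call is `aa`/`bb` when all reads carry
#' one allele, `ab` when both alleles are seen, and missing at depth 0 (or
#' with probability `missing`, emulating failed sites). Parents are included
#' as noiseless-truth homozygotes sequenced under the same depth model.
#'
#' @param pop an `f2_pop`.
#' @param depth mean sequencing depth (default 4.8).
#' @param error per-read allele miscall rate.
#' @param missing probability a genotype is dropped outright.
#' @param seed optional RNG seed.
#' @param parent_depth mean depth for the two parents (default 30).
#' @return a `variant_matrix`: list with `chrom`, `pos`, `cm`,
#'   parent calls/depths, and F2 `geno`, `depth`, `ad_ref`, `ad_alt`
#'   matrices (sites x individuals).
#' @export
simulate_variant_calls <- function(pop, depth = 4.8, error = 0.005,
                                   missing = 0.02, seed = NULL,
                                   parent_depth = 30) {
  if (depth <= 0) stop("depth must be positive")
  if (error < 0 || error >= 1 || missing < 0 || missing > 1) {
    stop("error in [0,1) and missing in [0,1] required")
  }
  if (!is.null(seed)) set.seed(seed)
  sites <- pop$map$sites
  m <- nrow(sites); n <- pop$n
  g <- pop$geno

  k <- matrix(stats::rpois(m * n, depth), m, n)
  # P(read shows alt allele) given genotype
  p_alt <- (g / 2) * (1 - error) + (1 - g / 2) * error
  alt <- matrix(stats::rbinom(m * n, as.vector(k), as.vector(p_alt)), m, n)
  ref <- k - alt
  call <- matrix(NA_integer_, m, n)
  call[ref > 0 & alt == 0] <- 0L
  call[ref > 0 & alt > 0] <- 1L
  call[ref == 0 & alt > 0] <- 2L
  if (missing > 0) {
    drop <- matrix(stats::runif(m * n) < missing, m, n)
    call[drop] <- NA_integer_
    k[drop] <- 0L; ref[drop] <- 0L; alt[drop] <- 0L
  }

  p_dep <- matrix(stats::rpois(2 * m, parent_depth), m, 2)
  structure(list(
    chrom = sites$group, pos = sites$bp, cm = sites$cm,
    p1_call = rep.int(0L, m), p1_depth = p_dep[, 1],
    p2_call = rep.int(2L, m), p2_depth = p_dep[, 2],
    geno = call, depth = k, ad_ref = ref, ad_alt = alt
  ), class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat("variant_matrix:", length(x$pos), "sites x", ncol(x$geno),
      "individuals;", sprintf("%.1f%% missing\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Default seed-colour QTL template
#'
#' Two quantitative trait loci emulating the study system: a major locus on
#' A09 at 81.91 cM (variance share 20.95%) and a minor locus on C03 at
#' 0.31 cM (6.25%), both with partial dominance d/a = 0.5 toward the
#' light-seed allele.
#'
#' @return data.frame with columns `group`, `cm`, `a`, `d`, `h2`.
#' @export
default_qtls <- function() {
  data.frame(group = c("A09", "C03"), cm = c(81.91, 0.31),
             a = c(1, 1), d = c(0.5, 0.5), h2 = c(0.2095, 0.0625),
             stringsAsFactors = FALSE)
}

#' Simulation configuration for phenotypes and calls
#'
#' @param n population size.
#' @param depth mean F2 sequencing depth.
#' @param error per-read miscall rate.
#' @param missing genotype drop rate.
#' @param visual_threshold R value splitting visual score 0 (dark) from 1.
#' @param seed RNG seed recorded with fixtures.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n = 196, depth = 4.8, error = 0.005, missing = 0.02,
                       visual_threshold = 67, seed = 1) {
  stopifnot(n >= 2, depth > 0, error >= 0, error < 1,
            missing >= 0, missing < 1)
  structure(list(n = n, depth = depth, error = error, missing = missing,
                 visual_threshold = visual_threshold, seed = seed),
            class = "sim_config")
}

#' Simulate correlated seed-colour phenotypes
#'
#' A standardized latent colour value is the sum of QTL genotype effects and
#' a Gaussian residual. Each QTL's effects (a, d) are rescaled so that its
#' marginal variance share equals its `h2` (theoretical 1:2:1 variance
#' a^2/2 + d^2/4); the residual variance is 1 - sum(h2). The six colour
#' traits are affine transforms of the latent value: R, G, B and l increase
#' with lightness, a and b decrease, with trait-specific noise tuned so
#' pairwise |correlations| stay at or above 0.9. The binary visual score is
#' `R > visual_threshold`.
#'
#' @param pop an `f2_pop`.
#' @param qtls data.frame like [default_qtls()].
#' @param config a [sim_config()].
#' @param seed optional RNG seed (defaults to `config$seed`).
#' @return data.frame `id, R, G, B, l, a, b, visual` with attributes
#'   `genetic` (latent genetic values) and `latent` (full latent value).
#' @export
simulate_phenotypes <- function(pop, qtls = default_qtls(),
                                config = sim_config(n = pop$n),
                                seed = NULL) {
  if (sum(qtls$h2) >= 1) stop("sum of QTL variance shares must be < 1")
  if (any(qtls$h2 <= 0)) stop("h2 must be in (0,1)")
  if (any(abs(qtls$d / qtls$a) > 1)) stop("|d/a| must be <= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- pop$n
  gvals <- numeric(n)
  for (i in seq_len(nrow(qtls))) {
    g <- true_genotype(pop, qtls$group[i], qtls$cm[i])[1, ]
    raw_var <- qtls$a[i]^2 / 2 + qtls$d[i]^2 / 4
    s <- sqrt(qtls$h2[i] / raw_var)
    a <- s * qtls$a[i]; d <- s * qtls$d[i]
    gvals <- gvals + a * (g - 1) + d * (g == 1)
  }
  z <- gvals + stats::rnorm(n, 0, sqrt(1 - sum(qtls$h2)))

  aff <- function(b0, b1, noise_frac) {
    b0 + b1 * z + stats::rnorm(n, 0, abs(b1) * noise_frac)
  }
  R <- 82 + 36 * z                      # latent trait itself, on the R scale
  out <- data.frame(
    id = sprintf("F2_%03d", seq_len(n)),
    R = R,
    G = aff(70, 28, 0.30),
    B = aff(45, 20, 0.30),
    l = aff(55, 14, 0.30),
    a = aff(12, -5, 0.30),
    b = aff(20, -6, 0.30),
    visual = as.integer(R > config$visual_threshold),
    stringsAsFactors = FALSE
  )
  attr(out, "genetic") <- gvals
  attr(out, "latent") <- z
  out
}

#' Simulate a structured expression matrix
#'
#' Emulates a 2-genotype x 3-stage x `n_reps` seed-coat expression design on
#' the log2 scale. Genes belong to latent-factor modules (each module has a
#' condition-level mean profile shared by its genes); a designated
#' "flavonoid" gene set is additionally down-regulated in the light-seed
#' genotype at stages 2 and 3. Values are returned as FPKM-like 2^log2.
#'
#' @param n_genes total genes (>= sum of module sizes).
#' @param module_sizes integer vector (>= 2 modules, >= 3 genes each).
#' @param flavonoid_lfc log2 fold change applied to the flavonoid set in the
#'   light genotype at stages 2-3 (negative = down-regulated).
#' @param n_flavonoid number of flavonoid genes (drawn from module 2).
#' @param genotype_module index of a module given a genotype-specific boost
#'   (`+2.5` in the dark genotype at 25 daf, emulating a pigmentation
#'   module); 0 disables it. Other modules are genotype-neutral, so the
#'   planted differential expression is exactly the flavonoid set plus this
#'   module.
#' @param rep_sd replicate noise sd (log2 scale).
#' @param gene_sd per-gene residual sd (log2 scale).
#' @param n_reps replicates per genotype-stage.
#' @param profiles optional modules x conditions matrix of latent condition
#'   means (columns ordered black 15/25/35, yellow 15/25/35), overriding the
#'   default stage-driven profiles; lets callers plant orthogonal modules.
#' @param seed optional RNG seed.
#' @return list with `fpkm` (genes x samples), `log2` matrix, `samples`
#'   data.frame (`sample`, `genotype`, `stage`, `rep`), and `truth` (module
#'   labels, flavonoid gene ids, planted lfc).
#' @export
simulate_expression <- function(n_genes = 400,
                                module_sizes = c(100, 100, 100),
                                flavonoid_lfc = -2, n_flavonoid = 40,
                                genotype_module = min(3, length(module_sizes)),
                                rep_sd = 0.1, gene_sd = 0.2,
                                n_reps = 3, profiles = NULL, seed = NULL) {
  if (length(module_sizes) < 2) stop("need at least 2 modules")
  if (any(module_sizes < 3)) stop("each module needs >= 3 genes")
  if (n_genes < sum(module_sizes)) stop("n_genes smaller than module total")
  if (n_reps < 2) stop("need >= 2 replicates per condition")
  if (!is.null(seed)) set.seed(seed)

  genotypes <- c("black", "yellow")
  stages <- c(15, 25, 35)
  samples <- expand.grid(rep = seq_len(n_reps), stage = stages,
                         genotype = genotypes, stringsAsFactors = FALSE)
  samples <- samples[, c("genotype", "stage", "rep")]
  samples$sample <- sprintf("%s_%02ddaf_r%d", samples$genotype,
                            samples$stage, samples$rep)
  ns <- nrow(samples)
  cond <- paste(samples$genotype, samples$stage)
  conds <- unique(cond)

  k <- length(module_sizes)
  module <- rep(0L, n_genes)
  module[seq_len(sum(module_sizes))] <- rep(seq_len(k), module_sizes)
  gene_id <- sprintf("gene%04d", seq_len(n_genes))

  if (!is.null(profiles)) {
    stopifnot(nrow(profiles) == k, ncol(profiles) == length(conds))
    prof <- profiles
    colnames(prof) <- conds
  } else {
    # stage-driven condition profiles per module (amplitude ~2 on the log2
    # scale), genotype-neutral except for the designated genotype module
    stage_eff <- matrix(stats::rnorm(k * length(stages), 0, 2), k,
                        dimnames = list(NULL, as.character(stages)))
    cond_stage <- vapply(strsplit(conds, " "), `[`, character(1), 2)
    prof <- stage_eff[, cond_stage, drop = FALSE]
    colnames(prof) <- conds
    if (genotype_module >= 1 && genotype_module <= k) {
      prof[genotype_module, conds == "black 25"] <-
        prof[genotype_module, conds == "black 25"] + 2.5
    }
  }
  base <- stats::rnorm(n_genes, 6, 2)
  log2e <- matrix(base, n_genes, ns) +
    matrix(stats::rnorm(n_genes * ns, 0, gene_sd), n_genes, ns)
  for (m in seq_len(k)) {
    idx <- which(module == m)
    latent <- prof[m, cond] + stats::rnorm(ns, 0, rep_sd)
    load <- stats::runif(length(idx), 0.8, 1.2)
    log2e[idx, ] <- log2e[idx, ] + outer(load, latent)
  }

  flav <- gene_id[which(module == 2L)[seq_len(min(n_flavonoid,
                                                  sum(module == 2L)))]]
  down <- samples$genotype == "yellow" & samples$stage %in% c(25, 35)
  log2e[gene_id %in% flav, down] <- log2e[gene_id %in% flav, down] +
    flavonoid_lfc

  dimnames(log2e) <- list(gene_id, samples$sample)
  list(fpkm = 2^log2e, log2 = log2e, samples = samples,
       truth = list(module = stats::setNames(module, gene_id),
                    flavonoid = flav, lfc = flavonoid_lfc))
}

#' Toy gene annotation along a simulation map
#'
#' Places equally spaced gene models along each group's physical axis; used
#' to exercise interval -> gene lookup on simulated QTLs.
#'
#' @param map a [sim_map()].
#' @param genes_per_group genes per linkage group.
#' @param width gene width in bp.
#' @return data.frame `gene_id, chrom, start, end, strand` (1-based closed).
#' @export
simulate_genes <- function(map, genes_per_group = 50, width = 2000) {
  out <- lapply(seq_len(nrow(map$groups)), function(i) {
    g <- map$groups[i, ]
    start <- round(seq(1, g$length_bp - width, length.out = genes_per_group))
    data.frame(
      gene_id = sprintf("%s_g%03d", g$group, seq_len(genes_per_group)),
      chrom = g$group, start = start, end = start + width - 1L,
      strand = rep_len(c("+", "-"), genes_per_group),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
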