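# Composite interval mapping by Haley-Knott regression on expected genotype
# codes, with forward-stepwise cofactor selection, permutation LOD
# thresholds and 1-LOD support intervals.

#' Composite interval mapping configuration
#'
#' @param step scan step in cM (default 0.5); marker positions are always
#'   included.
#' @param n_cofactors background markers selected by forward stepwise
#'   regression (default 5).
#' @param window exclusion window in cM: cofactors within this distance of
#'   the test position (same group) are dropped from the model (default 10).
#' @param n_perm permutations for the genome-wide threshold (default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param map_function map function for pseudo-position recombination
#'   fractions, `"kosambi"` (default) or `"haldane"`.
#' @return a list of class `cim_config`.
#' @export
cim_config <- function(step = 0.5, n_cofactors = 5, window = 10,
                       n_perm = 1000, alpha = 0.05,
                       map_function = c("kosambi", "haldane")) {
  stopifnot(step > 0, n_cofactors >= 0, window >= 0, n_perm >= 100,
            alpha > 0, alpha <= 1)
  structure(list(step = step, n_cofactors = n_cofactors, window = window,
                 n_perm = n_perm, alpha = alpha,
                 map_function = match.arg(map_function)),
            class = "cim_config")
}

# joint F2 genotype distribution at a locus between two flanking markers,
# by enumeration of the 2^3 x 2 gamete configurations; returns the 9 x 3
# conditional table P(gQ | gL, gR), rows indexed 3*gL + gR + 1
f2_prob_table <- function(rl, rr) {
  t_step <- function(x, y, r) ifelse(x == y, 1 - r, r)
  joint <- array(0, c(3, 3, 3))
  for (l1 in 0:1) for (q1 in 0:1) for (r1 in 0:1) {
    p1 <- 0.5 * t_step(l1, q1, rl) * t_step(q1, r1, rr)
    for (l2 in 0:1) for (q2 in 0:1) for (r2 in 0:1) {
      p2 <- 0.5 * t_step(l2, q2, rl) * t_step(q2, r2, rr)
      gl <- l1 + l2 + 1L; gq <- q1 + q2 + 1L; gr <- r1 + r2 + 1L
      joint[gl, gq, gr] <- joint[gl, gq, gr] + p1 * p2
    }
  }
  cond <- matrix(0, 9, 3)
  for (gl in 1:3) for (gr in 1:3) {
    marg <- sum(joint[gl, , gr])
    cond[3 * (gl - 1) + gr, ] <- joint[gl, , gr] / marg
  }
  cond
}

# single-flank version: P(gQ | gflank), 3 x 3, rows = flank genotype
f2_prob_single <- function(r) {
  p_gam <- rbind(c(1 - r, r), c(r, 1 - r))   # P(q allele | flank allele)
  cond <- matrix(0, 3, 3)
  for (f1 in 0:1) for (f2 in 0:1) {
    gf <- f1 + f2 + 1L
    for (q1 in 0:1) for (q2 in 0:1) {
      gq <- q1 + q2 + 1L
      cond[gf, gq] <- cond[gf, gq] +
        0.25 * p_gam[f1 + 1, q1 + 1] * p_gam[f2 + 1, q2 + 1]
    }
  }
  cond / rowSums(cond) * 1   # rows already sum to 1; normalize defensively
}

#' Conditional QTL genotype probabilities at a pseudo-position
#'
#' Probabilities of aa/ab/bb at a position between two flanking markers,
#' assuming no interference between the flanks; recombination fractions are
#' obtained from the distances with the configured map function. A missing
#' flank is marginalized out; with both flanks missing the 1:2:1 prior is
#' returned. At zero distance from an observed marker the probabilities
#' collapse to the observed genotype.
#'
#' @param gl,gr integer genotypes at the left/right flanking markers
#'   (0/1/2/NA).
#' @param dl,dr distances (cM) from the position to the flanks (>= 0).
#' @param map_function `"kosambi"` or `"haldane"`.
#' @return matrix (individuals x 3) of probabilities `p_aa, p_ab, p_bb`.
#' @export
genotype_probs <- function(gl, gr, dl, dr,
                           map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (dl < 0 || dr < 0) stop("position outside the flanked interval")
  inv <- if (map_function == "kosambi") kosambi_inverse else haldane_inverse
  rl <- inv(dl); rr <- inv(dr)
  both <- f2_prob_table(rl, rr)
  left_only <- f2_prob_single(rl)
  right_only <- f2_prob_single(rr)
  prior <- c(0.25, 0.5, 0.25)
  n <- max(length(gl), length(gr))
  gl <- rep_len(gl, n); gr <- rep_len(gr, n)
  out <- matrix(prior, n, 3, byrow = TRUE)
  has_l <- !is.na(gl); has_r <- !is.na(gr)
  out[has_l & has_r, ] <- both[3 * gl[has_l & has_r] + gr[has_l & has_r] + 1, ,
                               drop = FALSE]
  out[has_l & !has_r, ] <- left_only[gl[has_l & !has_r] + 1, , drop = FALSE]
  out[!has_l & has_r, ] <- right_only[gr[!has_l & has_r] + 1, , drop = FALSE]
  colnames(out) <- c("p_aa", "p_ab", "p_bb")
  out
}

# align a genotype matrix with a map: when the map carries marker names and
# the matrix has rownames, rows are matched by name (build_map reorders
# markers); otherwise positional alignment is required
align_markers <- function(geno, map) {
  if (!is.null(map$marker) && !is.null(rownames(geno))) {
    if (!all(map$marker %in% rownames(geno))) {
      stop("map markers missing from the genotype matrix")
    }
    return(geno[map$marker, , drop = FALSE])
  }
  if (nrow(geno) != nrow(map)) {
    stop("genotype matrix and map have different marker counts")
  }
  geno
}

# the 64 gamete-pair configurations underlying the two-flank conditional
# genotype table, tabulated once: indicator of allele agreement on each
# gamete segment, the joint flank-genotype class (1..9) and the QTL genotype
config64 <- local({
  cfg <- expand.grid(l1 = 0:1, q1 = 0:1, r1 = 0:1,
                     l2 = 0:1, q2 = 0:1, r2 = 0:1)
  list(el1 = cfg$l1 == cfg$q1, er1 = cfg$q1 == cfg$r1,
       el2 = cfg$l2 == cfg$q2, er2 = cfg$q2 == cfg$r2,
       key9 = 3L * (cfg$l1 + cfg$l2) + (cfg$r1 + cfg$r2) + 1L,
       gq = cfg$q1 + cfg$q2 + 1L)
})

# vectorized two-flank conditional tables: for vectors rl, rr returns
# list(paa, pab, pbb), each 9 x P indexed by 3*gL + gR + 1
flank_tables <- function(rl, rr) {
  cf <- config64
  w <- 0.25 *
    (outer(cf$el1, 1 - rl) + outer(!cf$el1, rl)) *
    (outer(cf$er1, 1 - rr) + outer(!cf$er1, rr)) *
    (outer(cf$el2, 1 - rl) + outer(!cf$el2, rl)) *
    (outer(cf$er2, 1 - rr) + outer(!cf$er2, rr))
  idx27 <- (cf$gq - 1L) * 9L + cf$key9
  J <- rowsum(w, idx27)                      # 27 x P, classes in order
  marg <- J[1:9, , drop = FALSE] + J[10:18, , drop = FALSE] +
    J[19:27, , drop = FALSE]
  list(paa = J[1:9, , drop = FALSE] / marg,
       pab = J[10:18, , drop = FALSE] / marg,
       pbb = J[19:27, , drop = FALSE] / marg)
}

# single-flank tables: 3 x P rows indexed by the flank genotype
single_tables <- function(r) {
  list(paa = rbind((1 - r)^2, r * (1 - r), r^2),
       pab = rbind(2 * r * (1 - r), (1 - r)^2 + r^2, 2 * r * (1 - r)),
       pbb = rbind(r^2, r * (1 - r), (1 - r)^2))
}

#' Precompute a scan scaffold
#'
#' Per-group position grid (the step grid plus every marker) with the
#' expected additive (`P(bb) - P(aa)`) and dominance (`P(ab)`) genotype codes
#' for every individual at every position. [cim_scan()] and
#' [permutation_threshold()] accept the result through their `scaffold`
#' argument so repeated scans of the same genotypes skip this step.
#'
#' @param geno markers x individuals genotype matrix (0/1/2/NA).
#' @param map data.frame with `group` and `cm` aligned to `geno` rows.
#' @param step scan step in cM.
#' @param map_function `"kosambi"` or `"haldane"`.
#' @return list: `pos` (data.frame `group`, `cm`), `xa`, `xd` (positions x
#'   individuals code matrices).
#' @export
scan_scaffold <- function(geno, map, step, map_function = "kosambi") {
  geno <- align_markers(geno, map)
  n <- ncol(geno)
  inv <- if (map_function == "kosambi") kosambi_inverse else haldane_inverse
  out_pos <- list(); out_xa <- list(); out_xd <- list()
  for (g in unique(map$group)) {
    rows <- which(map$group == g)
    rows <- rows[order(map$cm[rows])]
    cm <- map$cm[rows]
    M <- length(cm)
    grid <- sort(unique(c(seq(min(cm), max(cm), by = step), cm)))
    P <- length(grid)
    li <- findInterval(grid, cm)
    at_marker <- grid <= cm[li] + 1e-9
    # flank marker indices (within the group; NA when absent)
    lf <- ifelse(at_marker, li - 1L, li)
    rt <- ifelse(at_marker, li + 1L, li + 1L)
    lf[lf < 1] <- NA; rt[rt > M] <- NA
    dl <- ifelse(is.na(lf), 0, grid - cm[pmax(lf, 1L)])
    dr <- ifelse(is.na(rt), 0, cm[pmin(rt, M)] - grid)
    rl <- inv(dl); rr <- inv(dr)
    tb <- flank_tables(rl, rr)
    sl <- single_tables(rl)
    sr <- single_tables(rr)

    xa <- matrix(0, P, n); xd <- matrix(0.5, P, n)
    for (j in seq_len(P)) {
      gl <- if (is.na(lf[j])) rep(NA_integer_, n) else geno[rows[lf[j]], ]
      gr <- if (is.na(rt[j])) rep(NA_integer_, n) else geno[rows[rt[j]], ]
      has_l <- !is.na(gl); has_r <- !is.na(gr)
      b <- has_l & has_r
      if (any(b)) {
        key <- 3L * gl[b] + gr[b] + 1L
        xa[j, b] <- tb$pbb[key, j] - tb$paa[key, j]
        xd[j, b] <- tb$pab[key, j]
      }
      lo <- has_l & !has_r
      if (any(lo)) {
        xa[j, lo] <- sl$pbb[gl[lo] + 1L, j] - sl$paa[gl[lo] + 1L, j]
        xd[j, lo] <- sl$pab[gl[lo] + 1L, j]
      }
      ro <- !has_l & has_r
      if (any(ro)) {
        xa[j, ro] <- sr$pbb[gr[ro] + 1L, j] - sr$paa[gr[ro] + 1L, j]
        xd[j, ro] <- sr$pab[gr[ro] + 1L, j]
      }
      if (at_marker[j]) {
        g_here <- geno[rows[li[j]], ]
        obs <- !is.na(g_here)
        xa[j, obs] <- g_here[obs] - 1
        xd[j, obs] <- as.numeric(g_here[obs] == 1L)
      }
    }
    out_pos[[g]] <- data.frame(group = g, cm = grid, stringsAsFactors = FALSE)
    out_xa[[g]] <- xa; out_xd[[g]] <- xd
  }
  pos <- do.call(rbind, out_pos)
  rownames(pos) <- NULL
  list(pos = pos, xa = do.call(rbind, out_xa), xd = do.call(rbind, out_xd))
}

#' Select CIM background cofactors by forward stepwise regression
#'
#' Greedy forward selection of up to `k` markers by residual-sum-of-squares
#' reduction of the phenotype regression (additive codes, missing genotypes
#' mean-imputed). Selection stops early when the best remaining candidate is
#' not significant at `p_enter` (partial F-test), so `k` is a ceiling, not a
#' forced count — forcing cofactors onto markers linked to the tested region
#' distorts the scan near the exclusion-window edges. Deterministic given
#' its inputs.
#'
#' @param geno markers x individuals matrix (0/1/2/NA).
#' @param pheno numeric phenotype vector.
#' @param k maximum number of cofactors (0 gives plain interval mapping).
#' @param p_enter entry significance threshold for the stepwise F-test
#'   (default 0.01).
#' @return integer vector of selected marker row indices (length <= k).
#' @export
select_cofactors <- function(geno, pheno, k, p_enter = 0.01) {
  if (k > nrow(geno)) stop("more cofactors requested than markers")
  if (k == 0) return(integer(0))
  n <- ncol(geno)
  X <- t(geno) - 1                       # individuals x markers, additive
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  e <- pheno - mean(pheno)
  Xr <- scale(X, center = TRUE, scale = FALSE)
  chosen <- integer(0)
  for (s in seq_len(k)) {
    ss <- colSums(Xr^2)
    score <- ifelse(ss > 1e-10, colSums(Xr * e)^2 / ss, -Inf)
    score[chosen] <- -Inf
    if (all(!is.finite(score))) break
    j <- which.max(score)
    df2 <- n - 2 - length(chosen)
    rss_after <- sum(e^2) - score[j]
    f_stat <- score[j] / (rss_after / df2)
    if (stats::pf(f_stat, 1, df2, lower.tail = FALSE) > p_enter) break
    chosen <- c(chosen, j)
    q <- Xr[, j] / sqrt(sum(Xr[, j]^2))
    e <- e - q * sum(q * e)
    Xr <- Xr - q %*% crossprod(q, Xr)    # residualize remaining candidates
  }
  chosen
}

# core scan: LOD (and effects) at every scaffold position for one or more
# phenotype columns; cofactors within `window` cM of the test position on
# the same group are excluded via position zones (Frisch-Waugh-Lovell)
scan_core <- function(scaf, geno, map, Y, cof_idx, window) {
  n <- ncol(geno)
  P <- nrow(scaf$pos)
  K <- ncol(Y)
  lod <- matrix(0, P, K)
  addv <- domv <- rss_full1 <- rss_red1 <- numeric(P)

  cof_codes <- NULL
  if (length(cof_idx)) {
    xa_c <- t(geno[cof_idx, , drop = FALSE]) - 1
    xd_c <- t(geno[cof_idx, , drop = FALSE]) == 1
    storage.mode(xd_c) <- "double"
    for (j in seq_len(ncol(xa_c))) {
      nas <- is.na(xa_c[, j])
      if (any(nas)) {
        xa_c[nas, j] <- mean(xa_c[, j], na.rm = TRUE)
        xd_c[nas, j] <- mean(xd_c[, j], na.rm = TRUE)
      }
    }
    cof_codes <- cbind(xa_c, xd_c)
  }

  active_of <- function(i) {
    if (!length(cof_idx)) return(integer(0))
    same <- map$group[cof_idx] == scaf$pos$group[i]
    far <- abs(map$cm[cof_idx] - scaf$pos$cm[i]) > window
    which(!same | far)
  }
  keys <- vapply(seq_len(P), function(i) paste(active_of(i), collapse = ","),
                 character(1))

  for (key in unique(keys)) {
    rows <- which(keys == key)
    act <- active_of(rows[1])
    C <- cbind(rep(1, n),
               if (length(act)) cof_codes[, c(act, act + length(cof_idx)),
                                          drop = FALSE])
    qr_c <- qr(C)
    Yr <- qr.resid(qr_c, Y)
    rss_red <- colSums(Yr^2)
    ok_y <- rss_red > 1e-12

    # residualized additive/dominance codes for the whole zone at once,
    # then closed-form 2-regressor RSS reduction per (position, phenotype)
    UA <- qr.resid(qr_c, t(scaf$xa[rows, , drop = FALSE]))
    UD <- qr.resid(qr_c, t(scaf$xd[rows, , drop = FALSE]))
    uu <- colSums(UA^2); vv <- colSums(UD^2); uv <- colSums(UA * UD)
    det <- uu * vv - uv^2
    AtY <- crossprod(UA, Yr)                 # zone positions x K
    DtY <- crossprod(UD, Yr)
    full_rank <- det > 1e-10 * pmax(uu * vv, 1e-300) & uu > 1e-10 & vv > 1e-10
    expl <- matrix(0, length(rows), K)
    if (any(full_rank)) {
      f <- full_rank
      expl[f, ] <- (AtY[f, , drop = FALSE]^2 * vv[f] -
                      2 * AtY[f, , drop = FALSE] * DtY[f, , drop = FALSE] *
                      uv[f] +
                      DtY[f, , drop = FALSE]^2 * uu[f]) / det[f]
    }
    r1 <- !full_rank & (uu > 1e-10 | vv > 1e-10)  # rank-1: best single code
    if (any(r1)) {
      ea <- ifelse(uu[r1] > 1e-10, 1, 0) * AtY[r1, , drop = FALSE]^2 /
        pmax(uu[r1], 1e-300)
      ed <- ifelse(vv[r1] > 1e-10, 1, 0) * DtY[r1, , drop = FALSE]^2 /
        pmax(vv[r1], 1e-300)
      expl[r1, ] <- pmax(ea, ed)
    }
    rss_full <- pmax(rep(rss_red, each = length(rows)) - expl, 0)
    dim(rss_full) <- c(length(rows), K)
    lod[rows, ok_y] <- (n / 2) *
      log10(rep(rss_red[ok_y], each = length(rows)) /
              pmax(rss_full[, ok_y, drop = FALSE], 1e-300))
    # effects for the first phenotype column
    ba <- ifelse(full_rank, (vv * AtY[, 1] - uv * DtY[, 1]) /
                   ifelse(full_rank, det, 1),
                 ifelse(uu > 1e-10, AtY[, 1] / pmax(uu, 1e-300), 0))
    bd <- ifelse(full_rank, (uu * DtY[, 1] - uv * AtY[, 1]) /
                   ifelse(full_rank, det, 1), 0)
    addv[rows] <- ba
    domv[rows] <- bd
    rss_full1[rows] <- rss_full[, 1]
    rss_red1[rows] <- rss_red[1]
  }
  list(lod = lod, add = addv, dom = domv,
       rss_full = rss_full1, rss_red = rss_red1)
}

#' Composite interval mapping scan
#'
#' Haley-Knott regression of the phenotype on expected additive and dominance
#' genotype codes at each scan position, with selected background cofactors
#' (excluded within `window` cM of the test position);
#' LOD = (n/2) log10(RSS_reduced / RSS_full). The per-position `r2`
#' columns come from the single-QTL model against the null (no cofactors):
#' `r2` is the small-sample-adjusted proportion of variance and `r2_raw` the
#' uncorrected ratio, both in percent.
#'
#' @param geno markers x individuals genotype matrix (0/1/2/NA), e.g. a
#'   `bin_geno$geno`.
#' @param map data.frame aligned with `geno` rows: columns `group` and `cm`
#'   (a `genetic_map` works).
#' @param pheno numeric phenotype vector (binary 0/1 traits are scanned as
#'   numeric).
#' @param config a [cim_config()].
#' @param cofactors optional preselected cofactor marker indices; by default
#'   [select_cofactors()] picks `config$n_cofactors` of them.
#' @param scaffold optional precomputed scaffold (internal; lets repeated
#'   scans of the same genotypes share the genotype-probability grid).
#' @return a `scan_result` data.frame: `group`, `cm`, `lod`, `add`, `dom`,
#'   `r2`, `r2_raw`, with the configuration and cofactors as attributes.
#' @export
cim_scan <- function(geno, map, pheno, config = cim_config(),
                     cofactors = NULL, scaffold = NULL) {
  if (!is.numeric(pheno)) stop("phenotype must be numeric")
  stopifnot(length(pheno) == ncol(geno))
  geno <- align_markers(geno, map)
  scaf <- if (is.null(scaffold)) {
    scan_scaffold(geno, map, config$step, config$map_function)
  } else scaffold
  if (is.null(cofactors)) {
    cofactors <- select_cofactors(geno, pheno, config$n_cofactors)
  }
  Y <- matrix(pheno, ncol = 1)
  full <- scan_core(scaf, geno, map, Y, cofactors, config$window)
  plain <- if (length(cofactors)) {
    scan_core(scaf, geno, map, Y, integer(0), config$window)
  } else full
  n <- ncol(geno)
  r2_raw <- 1 - plain$rss_full / plain$rss_red
  r2_adj <- 1 - (plain$rss_full / (n - 3)) / (plain$rss_red / (n - 1))
  out <- data.frame(group = scaf$pos$group, cm = scaf$pos$cm,
                    lod = full$lod[, 1], add = full$add, dom = full$dom,
                    r2 = 100 * r2_adj, r2_raw = 100 * r2_raw,
                    stringsAsFactors = FALSE)
  out$r2[plain$rss_red <= 1e-12] <- 0
  out$r2_raw[plain$rss_red <= 1e-12] <- 0
  attr(out, "config") <- config
  attr(out, "cofactors") <- cofactors
  attr(out, "n") <- n
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Genome-wide permutation LOD threshold
#'
#' The phenotype is shuffled across individuals `n_perm` times; each
#' permutation's genome-wide maximum LOD is recorded and the threshold is the
#' (1 - alpha) quantile of that distribution. Cofactors selected on the
#' observed phenotype are reused across permutations.
#'
#' @inheritParams cim_scan
#' @param seed RNG seed for the shuffles.
#' @return list: `threshold`, `max_lods` (the permutation distribution),
#'   `alpha`, `n_perm`.
#' @export
permutation_threshold <- function(geno, map, pheno, config = cim_config(),
                                  seed = NULL, cofactors = NULL,
                                  scaffold = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geno <- align_markers(geno, map)
  scaf <- if (is.null(scaffold)) {
    scan_scaffold(geno, map, config$step, config$map_function)
  } else scaffold
  if (is.null(cofactors)) {
    cofactors <- select_cofactors(geno, pheno, config$n_cofactors)
  }
  Y <- vapply(seq_len(config$n_perm), function(i) sample(pheno),
              numeric(length(pheno)))
  res <- scan_core(scaf, geno, map, Y, cofactors, config$window)
  max_lods <- apply(res$lod, 2, max)
  list(threshold = unname(stats::quantile(max_lods, 1 - config$alpha)),
       max_lods = max_lods, alpha = config$alpha, n_perm = config$n_perm)
}

#' Call QTL peaks with 1-LOD support intervals
#'
#' Peaks are local maxima above the threshold, at least one exclusion window
#' apart; each peak's support interval extends from the peak to the last
#' contiguous positions with LOD >= peak - 1, and is projected onto physical
#' coordinates through the markers it covers.
#'
#' @param scan a `scan_result` from [cim_scan()].
#' @param threshold LOD threshold (e.g. from [permutation_threshold()]).
#' @param map optional `genetic_map`-style data.frame (`group`, `cm`,
#'   `start`, `end`) for the physical projection.
#' @param trait trait label carried into the output.
#' @return data.frame of peaks: `trait`, `group`, `chrom` (majority physical
#'   chromosome of the interval's markers), `cm`, `lod`, `r2`, `r2_raw`,
#'   `add`, `dom`, `ci_lo`, `ci_hi`, `phys_lo`, `phys_hi`.
#' @export
call_peaks <- function(scan, threshold, map = NULL, trait = "trait") {
  window <- attr(scan, "config")$window
  if (is.null(window)) window <- 10
  out <- list()
  for (g in unique(scan$group)) {
    s <- scan[scan$group == g, ]
    s <- s[order(s$cm), ]
    avail <- s$lod >= threshold
    while (any(avail)) {
      i <- which(avail)[which.max(s$lod[avail])]
      # contiguous 1-LOD support interval around the peak
      drop_lo <- which(s$lod[seq_len(i)] < s$lod[i] - 1)
      lo <- if (length(drop_lo)) s$cm[max(drop_lo) + 1L] else s$cm[1]
      drop_hi <- which(s$lod[i:nrow(s)] < s$lod[i] - 1)
      hi <- if (length(drop_hi)) s$cm[i + min(drop_hi) - 2L] else
        s$cm[nrow(s)]
      phys <- c(NA_real_, NA_real_)
      chrom <- NA_character_
      if (!is.null(map) && all(c("start", "end") %in% names(map))) {
        mg <- map[map$group == g, ]
        # markers inside the support interval plus its bracketing markers
        inside <- mg$cm >= lo & mg$cm <= hi
        below <- which(mg$cm < lo); above <- which(mg$cm > hi)
        if (length(below)) inside[below[which.max(mg$cm[below])]] <- TRUE
        if (length(above)) inside[above[which.min(mg$cm[above])]] <- TRUE
        mk <- mg[inside, ]
        if (nrow(mk) && !all(is.na(mk$start))) {
          phys <- c(min(mk$start, na.rm = TRUE), max(mk$end, na.rm = TRUE))
        }
        if ("chrom" %in% names(mk) && nrow(mk)) {
          chrom <- names(which.max(table(mk$chrom)))
        }
      }
      out[[length(out) + 1]] <- data.frame(
        trait = trait, group = g, chrom = chrom, cm = s$cm[i], lod = s$lod[i],
        r2 = s$r2[i], r2_raw = s$r2_raw[i], add = s$add[i], dom = s$dom[i],
        ci_lo = lo, ci_hi = hi, phys_lo = phys[1], phys_hi = phys[2],
        stringsAsFactors = FALSE)
      avail <- avail & abs(s$cm - s$cm[i]) > window
    }
  }
  if (!length(out)) {
    return(data.frame(trait = character(0), group = character(0),
                      chrom = character(0),
                      cm = numeric(0), lod = numeric(0), r2 = numeric(0),
                      r2_raw = numeric(0), add = numeric(0), dom = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0),
                      phys_lo = numeric(0), phys_hi = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # a satellite shoulder whose support interval contains a stronger peak on
  # the same group is the same QTL, not a second one
  keep <- vapply(seq_len(nrow(res)), function(i) {
    !any(res$group == res$group[i] & res$lod > res$lod[i] &
           res$cm >= res$ci_lo[i] & res$cm <= res$ci_hi[i])
  }, logical(1))
  res <- res[keep, , drop = FALSE]
  res[order(res$group, -res$lod), ]
}
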