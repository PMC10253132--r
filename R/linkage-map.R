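# Recombination-fraction estimation (EM for the F2 intercross), marker
# grouping, MST seriation ordering, Kosambi map construction, summaries.

# collapse a pair of genotype vectors into the sufficient class counts:
# N0 = 0 recombinant gametes, N1 = 1, N2 = 2, D = double heterozygote
rf_counts <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  cls <- 3L * ga + gb                 # 0..8
  tab <- tabulate(cls + 1L, 9)
  list(N0 = tab[1] + tab[9],          # (aa,aa), (bb,bb)
       N1 = tab[2] + tab[4] + tab[6] + tab[8],
       N2 = tab[3] + tab[7],          # (aa,bb), (bb,aa)
       D = tab[5], n = length(ga))
}

rf_em <- function(N0, N1, N2, D, tol = 1e-12, max_iter = 500) {
  n <- N0 + N1 + N2 + D
  r <- rep(0.25, length(n))
  for (i in seq_len(max_iter)) {
    exp_d <- 2 * r^2 / ((1 - r)^2 + r^2)   # E[rec gametes | double het]
    r_new <- (N1 + 2 * N2 + D * exp_d) / (2 * n)
    r_new <- pmin(r_new, 0.5)
    if (all(abs(r_new - r) < tol)) { r <- r_new; break }
    r <- r_new
  }
  r
}

rf_loglik <- function(r, N0, N1, N2, D) {
  lg <- function(x) ifelse(x > 0, log10(x), 0)   # 0*log(0) = 0 convention
  N0 * lg((1 - r)^2) + N1 * lg(r * (1 - r)) + N2 * lg(r^2) +
    D * lg((1 - r)^2 + r^2)
}

#' Estimate the recombination fraction between two F2 markers
#'
#' Maximum-likelihood estimate for two codominant markers in an intercross;
#' the double-heterozygote class (phase-ambiguous) is handled by EM. The LOD
#' of linkage is log10 L(r-hat) - log10 L(0.5).
#'
#' @param ga,gb integer genotype vectors (0/1/2, NA missing) over shared
#'   individuals.
#' @return list `r`, `lod`, `n` (informative individuals).
#' @export
estimate_rf <- function(ga, gb) {
  cc <- rf_counts(ga, gb)
  if (cc$n < 2) stop("fewer than 2 shared informative individuals")
  r <- rf_em(cc$N0, cc$N1, cc$N2, cc$D)
  lod <- rf_loglik(r, cc$N0, cc$N1, cc$N2, cc$D) -
    rf_loglik(0.5, cc$N0, cc$N1, cc$N2, cc$D)
  list(r = r, lod = max(lod, 0), n = cc$n)
}

#' Pairwise recombination fractions for a marker matrix
#'
#' Vectorized over all marker pairs: the 9 joint-genotype class counts are
#' accumulated with indicator cross-products, then the EM update runs on all
#' pairs simultaneously.
#'
#' @param geno markers x individuals integer matrix (0/1/2/NA).
#' @return list of symmetric matrices `r`, `lod`, `n`.
#' @export
rf_matrix <- function(geno) {
  ind <- lapply(0:2, function(v) {
    x <- geno == v
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "double"
    x
  })
  cnt <- function(a, b) tcrossprod(ind[[a + 1]], ind[[b + 1]])
  N0 <- cnt(0, 0) + cnt(2, 2)
  N1 <- cnt(0, 1) + cnt(1, 0) + cnt(1, 2) + cnt(2, 1)
  N2 <- cnt(0, 2) + cnt(2, 0)
  D <- cnt(1, 1)
  n <- N0 + N1 + N2 + D
  r <- rf_em(N0, N1, N2, D)
  lod <- pmax(rf_loglik(r, N0, N1, N2, D) - rf_loglik(0.5, N0, N1, N2, D), 0)
  diag(r) <- 0; diag(lod) <- 0
  dimnames(r) <- dimnames(lod) <- list(rownames(geno), rownames(geno))
  list(r = r, lod = lod, n = n)
}

#' Group markers into linkage groups
#'
#' Connected components of the graph whose edges join marker pairs with
#' linkage LOD at or above `lod_min` and estimated r at or below `r_max`.
#'
#' @param rf output of [rf_matrix()].
#' @param lod_min LOD threshold (default 6).
#' @param r_max recombination-fraction ceiling (default 0.35).
#' @return integer vector of group memberships (1, 2, ...), ordered by
#'   decreasing group size.
#' @export
group_markers <- function(rf, lod_min = 6, r_max = 0.35) {
  adj <- rf$lod >= lod_min & rf$r <= r_max
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  as.integer(factor(comp, levels = order(-tabulate(comp))))
}

# sum of adjacent distances along an order
path_length <- function(ord, d) {
  if (length(ord) < 2) return(0)
  sum(d[cbind(ord[-length(ord)], ord[-1])])
}

# segment-reversal polish with O(1) move evaluation
two_opt <- function(ord, d) {
  m <- length(ord)
  if (m < 3) return(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        a <- if (i > 1) d[ord[i - 1], ord[i]] else 0
        b <- if (j < m) d[ord[j], ord[j + 1]] else 0
        a2 <- if (i > 1) d[ord[i - 1], ord[j]] else 0
        b2 <- if (j < m) d[ord[i], ord[j + 1]] else 0
        if (a2 + b2 < a + b - 1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
  }
  ord
}

#' Order markers within a linkage group
#'
#' Minimum-spanning-tree seriation (the MST's diameter path seeds the order;
#' off-path markers are inserted at their cheapest position) followed by
#' 2-opt polishing of the sum of adjacent distances. The orientation is made
#' canonical by physical anchors when available (positive rank correlation
#' with bp position).
#'
#' @param d symmetric distance matrix (e.g. Kosambi distances from pairwise
#'   r estimates).
#' @param anchor_bp optional physical positions used to orient the order.
#' @return integer permutation of `seq_len(nrow(d))`.
#' @export
order_markers <- function(d, anchor_bp = NULL) {
  m <- nrow(d)
  if (m == 1) return(1L)
  # epsilon keeps zero-distance pairs as real edges (igraph drops 0 weights)
  g <- igraph::graph_from_adjacency_matrix(d + 1e-9, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  # diameter path of the MST as the seriation backbone
  far <- igraph::farthest_vertices(mst)$vertices
  backbone <- as.integer(igraph::shortest_paths(
    mst, from = far[1], to = far[2])$vpath[[1]])
  ord <- backbone
  for (v in setdiff(seq_len(m), backbone)) {
    L <- length(ord)
    delta <- c(d[v, ord[1]],                       # prepend
               if (L > 1) d[ord[-L], v] + d[v, ord[-1]] -
                 d[cbind(ord[-L], ord[-1])] else numeric(0),
               d[ord[L], v])                       # append
    k <- which.min(delta) - 1L
    ord <- append(ord, v, after = k)
  }
  ord <- two_opt(ord, d)
  if (!is.null(anchor_bp)) {
    rho <- suppressWarnings(stats::cor(seq_along(ord), anchor_bp[ord],
                                       method = "spearman"))
    if (!is.na(rho) && rho < 0) ord <- rev(ord)
  }
  ord
}

#' Build a genetic map from a bin genotype matrix
#'
#' Estimates pairwise recombination fractions, groups markers, orders each
#' group by MST seriation + 2-opt, and accumulates adjacent-pair Kosambi
#' distances into cM positions.
#'
#' @param bg a `bin_geno` (or list with `bins` data.frame and `geno` matrix).
#' @param lod_min,r_max grouping thresholds (see [group_markers()]).
#' @param r_cap adjacent r estimates are capped below 0.5 before the Kosambi
#'   transform (default 0.49).
#' @return a `genetic_map`: data.frame `group, marker, cm, chrom, start, end`.
#' @export
build_map <- function(bg, lod_min = 6, r_max = 0.35, r_cap = 0.49) {
  geno <- bg$geno
  rownames(geno) <- bg$bins$bin
  rf <- rf_matrix(geno)
  grp <- group_markers(rf, lod_min, r_max)
  out <- lapply(sort(unique(grp)), function(k) {
    idx <- which(grp == k)
    sub_r <- rf$r[idx, idx, drop = FALSE]
    d <- kosambi_cm(pmin(sub_r, r_cap))
    ord <- order_markers(d, anchor_bp = bg$bins$start[idx])
    idx <- idx[ord]
    adj_r <- pmin(sub_r[cbind(ord[-length(ord)], ord[-1])], r_cap)
    cm <- c(0, cumsum(kosambi_cm(adj_r)))
    data.frame(group = sprintf("LG%02d", k), marker = bg$bins$bin[idx],
               cm = cm, chrom = bg$bins$chrom[idx],
               start = bg$bins$start[idx], end = bg$bins$end[idx],
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("genetic_map", "data.frame"))
}

#' Map summary (per-group lengths, marker counts, intervals)
#'
#' For a built `genetic_map`, lengths and intervals come from the cM
#' positions. A data.frame with `group`, `length_cm` and `n_markers` columns
#' (optionally `max_interval`) is also accepted, so printed map tables can be
#' summarised directly. The whole-map mean interval is the unweighted mean of
#' the per-group mean intervals; `global_interval` (total length divided by
#' total marker count minus the number of groups) is reported alongside.
#'
#' @param x a `genetic_map` or a per-group summary data.frame.
#' @return data.frame: one row per group plus a `Whole` row, with columns
#'   `group`, `length_cm`, `n_markers`, `mean_interval`, `max_interval`,
#'   `global_interval` (Whole row only).
#' @export
map_summary <- function(x) {
  if (inherits(x, "genetic_map") ||
      (is.data.frame(x) && all(c("group", "marker", "cm") %in% names(x)))) {
    per <- do.call(rbind, lapply(split(x, x$group), function(s) {
      s <- s[order(s$cm), ]
      dd <- diff(s$cm)
      data.frame(group = s$group[1], length_cm = max(s$cm) - min(s$cm),
                 n_markers = nrow(s),
                 max_interval = if (length(dd)) max(dd) else 0,
                 stringsAsFactors = FALSE)
    }))
  } else {
    stopifnot(all(c("group", "length_cm", "n_markers") %in% names(x)))
    per <- x
    if (is.null(per$max_interval)) per$max_interval <- NA_real_
  }
  single <- per$n_markers < 2
  per$mean_interval <- ifelse(single, 0,
                              per$length_cm / pmax(per$n_markers - 1, 1))
  per$single_marker_group <- single
  whole <- data.frame(
    group = "Whole", length_cm = sum(per$length_cm),
    n_markers = sum(per$n_markers),
    max_interval = mean(per$max_interval),
    mean_interval = mean(per$mean_interval),
    single_marker_group = FALSE, stringsAsFactors = FALSE)
  out <- rbind(per[, names(whole)], whole)
  out$global_interval <- c(rep(NA_real_, nrow(per)),
                           whole$length_cm /
                             (whole$n_markers - nrow(per)))
  rownames(out) <- NULL
  out
}

#' Collinearity between genetic and physical marker order
#'
#' Per group: Spearman rank correlation between genetic position and the
#' physical anchor, adjacent discordant pairs, and flagged
#' recombination-suppressed spans (long physical stretches with almost no
#' genetic distance).
#'
#' @param map a `genetic_map` (needs `start` anchors).
#' @param bp_min physical span that triggers a suppression flag (default
#'   10 Mb).
#' @param cm_max genetic span a suppressed region must stay under (default
#'   2 cM).
#' @return list: `per_group` (group, rho, n discordant adjacent pairs) and
#'   `suppressed` (group, cM and bp spans of flagged runs).
#' @export
collinearity <- function(map, bp_min = 1e7, cm_max = 2) {
  if (all(is.na(map$start))) stop("no physical anchors present")
  per <- lapply(split(map, map$group), function(s) {
    s <- s[order(s$cm), ]
    rho <- suppressWarnings(stats::cor(rank(s$cm), rank(s$start),
                                       method = "spearman"))
    disc <- sum(diff(s$start) < 0)
    sup <- NULL
    i <- 1
    while (i < nrow(s)) {
      j <- max(which(s$cm - s$cm[i] <= cm_max))
      if (j > i && abs(s$start[j] - s$start[i]) > bp_min) {
        sup <- rbind(sup, data.frame(
          group = s$group[1], cm_lo = s$cm[i], cm_hi = s$cm[j],
          bp_span = abs(s$start[j] - s$start[i]), stringsAsFactors = FALSE))
        i <- j
      }
      i <- i + 1
    }
    list(stats = data.frame(group = s$group[1], rho = rho,
                            discordant = disc, stringsAsFactors = FALSE),
         suppressed = sup)
  })
  list(per_group = do.call(rbind, lapply(per, `[[`, "stats")),
       suppressed = do.call(rbind, lapply(per, `[[`, "suppressed")))
}
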