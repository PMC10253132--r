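# Weighted coexpression network: soft-threshold adjacency, topological
# overlap, average-linkage module detection with eigengene merging.

#' Soft-threshold adjacency from a correlation matrix
#'
#' Unsigned network: `a_ij = |cor_ij|^beta`, diagonal set to 0.
#'
#' @param cors correlation matrix (entries in `[-1, 1]`).
#' @param beta soft-threshold power (default 8).
#' @return adjacency matrix.
#' @export
soft_adjacency <- function(cors, beta = 8) {
  if (beta <= 0) stop("beta must be positive")
  if (any(abs(cors) > 1 + 1e-8, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  a <- abs(cors)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k = rowSums(a)`; entries lie in `[0, 1]` and the diagonal is 1.
#'
#' @param adj symmetric adjacency with zero diagonal, entries in `[0, 1]`.
#' @return the TOM.
#' @export
topological_overlap <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency diagonal must be zero")
  k <- rowSums(adj)
  num <- adj %*% adj + adj
  den <- outer(k, k, pmin) + 1 - adj
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# first principal component of a module's standardized expression, oriented
# to correlate positively with the module's mean expression profile
module_eigengene <- function(expr_mod) {
  xs <- t(scale(t(expr_mod)))                 # standardize each gene
  xs[is.na(xs)] <- 0                          # constant genes
  sv <- svd(xs, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  if (stats::cor(eg, colMeans(expr_mod)) < 0) eg <- -eg
  eg
}

#' Detect coexpression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' (1 - TOM) with a static tree cut; clusters below `min_module_size` are
#' left unassigned (module 0). Module eigengenes (first principal component
#' of the standardized module expression, oriented positively with the mean
#' profile) are computed and modules whose eigengene correlation is at least
#' `1 - merge_cut_height` are merged iteratively.
#'
#' @param tom topological overlap matrix.
#' @param expr genes x samples expression matrix (log scale recommended),
#'   rows aligned with `tom`.
#' @param min_module_size smallest retained module (default 100).
#' @param merge_cut_height eigengene-dissimilarity merge threshold
#'   (default 0.25: merge at correlation >= 0.75).
#' @param cut_height static tree-cut height on 1 - TOM (default 0.99).
#' @return list: `module` (integer per gene, 0 = unassigned), `eigengenes`
#'   (samples x modules), `merges` (number of merge steps performed).
#' @export
detect_modules <- function(tom, expr, min_module_size = 100,
                           merge_cut_height = 0.25, cut_height = 0.99) {
  stopifnot(nrow(tom) == nrow(expr))
  if (nrow(expr) < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(list(module = stats::setNames(rep(0L, nrow(expr)),
                                         rownames(expr)),
                eigengenes = NULL, merges = 0L))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  module <- ifelse(cl %in% keep, match(cl, keep), 0L)

  eigen_all <- function(module) {
    ids <- sort(unique(module[module > 0]))
    eg <- vapply(ids, function(m) module_eigengene(expr[module == m, ,
                                                        drop = FALSE]),
                 numeric(ncol(expr)))
    colnames(eg) <- paste0("ME", ids)
    eg
  }
  merges <- 0L
  repeat {
    ids <- sort(unique(module[module > 0]))
    if (length(ids) < 2) break
    eg <- eigen_all(module)
    cc <- stats::cor(eg)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) < 1 - merge_cut_height) break
    module[module == ids[top[2]]] <- ids[top[1]]
    module <- ifelse(module > 0,
                     match(module, sort(unique(module[module > 0]))), 0L)
    merges <- merges + 1L
  }
  eg <- if (any(module > 0)) eigen_all(module) else NULL
  if (!is.null(eg)) rownames(eg) <- colnames(expr)
  list(module = stats::setNames(module, rownames(expr)),
       eigengenes = eg, merges = merges)
}

#' Correlate module eigengenes with sample indicators
#'
#' Spearman correlation of each eigengene with the indicator of each
#' genotype-stage condition, with test p-values.
#'
#' @param eigengenes samples x modules matrix from [detect_modules()].
#' @param samples data.frame with `genotype` and `stage` per sample (rows
#'   aligned with eigengene rows).
#' @return data.frame: `module`, `condition`, `rho`, `p`; constant
#'   eigengenes are flagged with NA correlations.
#' @export
module_trait_correlation <- function(eigengenes, samples) {
  stopifnot(nrow(eigengenes) == nrow(samples), nrow(samples) >= 3)
  cond <- paste(samples$genotype, samples$stage, sep = "_")
  out <- list()
  for (m in colnames(eigengenes)) {
    eg <- eigengenes[, m]
    for (cn in unique(cond)) {
      ind <- as.numeric(cond == cn)
      if (stats::sd(eg) < 1e-12) {
        rho <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(stats::cor.test(eg, ind, method = "spearman"))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1]] <- data.frame(module = m, condition = cn,
                                           rho = rho, p = p,
                                           stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Retain coexpression edges above a weight floor
#'
#' Strictly-greater-than filter on the (undirected, deduplicated) edges of a
#' weighted network.
#'
#' @param adj adjacency (or TOM) matrix with gene names.
#' @param floor weight floor (default 0.2; an edge at exactly the floor is
#'   dropped).
#' @return data.frame: `gene1`, `gene2`, `weight`.
#' @export
retain_edges <- function(adj, floor = 0.2) {
  idx <- which(upper.tri(adj) & adj > floor, arr.ind = TRUE)
  nm <- rownames(adj)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(adj)))
  data.frame(gene1 = nm[idx[, 1]], gene2 = nm[idx[, 2]],
             weight = adj[idx], stringsAsFactors = FALSE)[
               order(-adj[idx]), , drop = FALSE]
}
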