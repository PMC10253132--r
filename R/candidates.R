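# Candidate-gene integration: QTL interval -> gene lookup, differential
# expression filtering, and the three-step candidate selection that combines
# QTL intervals, key-stage DEGs and flavonoid coexpression; plus the
# delta-delta-Ct qPCR utility.

#' Genes overlapping a physical interval
#'
#' Any-overlap on closed 1-based intervals (GFF3 convention): a gene is
#' returned when `gene_end >= start` and `gene_start <= end`.
#'
#' @param annotation data.frame `gene_id, chrom, start, end` (e.g. from
#'   [read_gff3()]).
#' @param chrom chromosome id.
#' @param start,end interval bounds (bp, `start <= end`).
#' @return the overlapping annotation rows, sorted by start.
#' @export
genes_in_interval <- function(annotation, chrom, start, end) {
  if (start > end) stop("start must be <= end")
  hit <- annotation$chrom == chrom & annotation$end >= start &
    annotation$start <= end
  out <- annotation[hit, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Filter a differential-expression table to DEGs
#'
#' A gene is retained when, at any of the requested stages,
#' `|log2 fold change| > lfc_min` and `FDR < fdr_max`.
#'
#' @param de data.frame with columns `gene_id`, `stage`, `log2fc`, `fdr`.
#' @param stages stages to consider (default the key stages 25 and 35 daf).
#' @param lfc_min log2 fold-change threshold (default 1, i.e. fold change
#'   above 2 or below 0.5).
#' @param fdr_max FDR ceiling (default 0.05, strict).
#' @param log2 set `FALSE` if the table's fold-change column is on the raw
#'   scale; it is then log2-transformed before filtering.
#' @return the retained DEG rows, with a `direction` column (up/down).
#' @export
deg_filter <- function(de, stages = c(25, 35), lfc_min = 1, fdr_max = 0.05,
                       log2 = TRUE) {
  req <- c("gene_id", "stage", "log2fc", "fdr")
  if (!all(req %in% names(de))) {
    stop("DE table must have columns: ", paste(req, collapse = ", "))
  }
  lfc <- if (log2) de$log2fc else log2(de$log2fc)
  keep <- de$stage %in% stages & abs(lfc) > lfc_min & de$fdr < fdr_max
  keep[is.na(keep)] <- FALSE
  out <- de[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out
}

#' Two-group stand-in differential expression test
#'
#' Per-gene Welch t-test on log2(x + 1) values between two sample groups;
#' the log2 fold change is the difference of group means of the log2 values
#' and p-values are Benjamini-Hochberg adjusted to FDRs. A deliberately
#' simple stand-in for a count-model DE analysis, adequate for the
#' simulator's Gaussian log-scale data.
#'
#' @param mat genes x samples expression matrix (FPKM-like, non-negative).
#' @param group two-level factor/character over samples; the *second* level
#'   is the control (fold changes are level1 - control). A character vector
#'   is treated in order of first appearance.
#' @return data.frame: `gene_id`, `log2fc`, `p`, `fdr`.
#' @export
standin_de_test <- function(mat, group) {
  if (!is.factor(group)) group <- factor(group, levels = unique(group))
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (any(table(group) < 2)) stop("each group needs >= 2 replicates")
  lg <- log2(mat + 1)
  g1 <- lg[, group == levels(group)[1], drop = FALSE]
  g2 <- lg[, group == levels(group)[2], drop = FALSE]
  lfc <- rowMeans(g1) - rowMeans(g2)
  p <- vapply(seq_len(nrow(mat)), function(i) {
    if (stats::sd(g1[i, ]) < 1e-12 && stats::sd(g2[i, ]) < 1e-12) {
      return(if (abs(lfc[i]) < 1e-12) 1 else 0)
    }
    stats::t.test(g1[i, ], g2[i, ])$p.value
  }, numeric(1))
  data.frame(gene_id = rownames(mat), log2fc = lfc, p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Stage-wise stand-in DE analysis of a genotype x stage design
#'
#' Runs [standin_de_test()] (test genotype vs control genotype) separately at
#' each stage of an expression design.
#'
#' @param mat genes x samples matrix.
#' @param samples data.frame with `genotype` and `stage` per sample.
#' @param test,control genotype labels; fold changes are test vs control.
#' @return data.frame `gene_id, stage, log2fc, p, fdr`.
#' @export
de_by_stage <- function(mat, samples, test = "yellow", control = "black") {
  out <- lapply(unique(samples$stage), function(st) {
    sel <- samples$stage == st & samples$genotype %in% c(test, control)
    grp <- factor(samples$genotype[sel], levels = c(test, control))
    cbind(standin_de_test(mat[, sel, drop = FALSE], grp), stage = st)
  })
  do.call(rbind, out)[, c("gene_id", "stage", "log2fc", "p", "fdr")]
}

#' Select candidate genes for a QTL
#'
#' The three-step candidate procedure: (1) genes inside any QTL peak's
#' physical interval; (2) of those, the differentially expressed genes at the
#' key stages; (3) of those, the genes that are themselves in the
#' flavonoid-related set or have a retained coexpression edge to a
#' flavonoid-related DEG (optionally restricted to key modules).
#'
#' @param peaks data.frame from [call_peaks()] (`group` as chromosome,
#'   `phys_lo`, `phys_hi`).
#' @param annotation gene models (`gene_id, chrom, start, end`).
#' @param de DE table (`gene_id, stage, log2fc, fdr`).
#' @param flavonoid character vector of flavonoid-related gene ids.
#' @param edges retained edge list from [retain_edges()].
#' @param modules optional named module assignment (from [detect_modules()]).
#' @param key_modules module ids considered relevant; edge partners outside
#'   them are ignored (only used when `modules` is given).
#' @param key_stages stages at which differential expression counts
#'   (default 25 and 35 daf).
#' @param ... further arguments passed to [deg_filter()].
#' @return data.frame (one row per candidate): `gene_id`, `qtl`, `de_stages`,
#'   `is_flavonoid`, `partners`, `n_partners`, `rationale`.
#' @export
select_candidates <- function(peaks, annotation, de, flavonoid, edges,
                              modules = NULL, key_modules = NULL,
                              key_stages = c(25, 35), ...) {
  empty <- data.frame(gene_id = character(0), qtl = character(0),
                      de_stages = character(0), is_flavonoid = logical(0),
                      partners = character(0), n_partners = integer(0),
                      rationale = character(0), stringsAsFactors = FALSE)
  if (is.null(peaks) || nrow(peaks) == 0) return(empty)

  degs <- deg_filter(de, stages = key_stages, ...)
  deg_ids <- unique(degs$gene_id)
  flav_degs <- intersect(flavonoid, deg_ids)
  if (!is.null(modules) && !is.null(key_modules)) {
    flav_degs <- flav_degs[modules[flav_degs] %in% key_modules]
  }

  out <- list()
  for (i in seq_len(nrow(peaks))) {
    if (is.na(peaks$phys_lo[i])) next
    chr <- if (!is.null(peaks$chrom) && !is.na(peaks$chrom[i])) {
      peaks$chrom[i]
    } else peaks$group[i]
    inside <- genes_in_interval(annotation, chr,
                                peaks$phys_lo[i], peaks$phys_hi[i])
    cand <- intersect(inside$gene_id, deg_ids)
    for (gid in cand) {
      partners <- unique(c(edges$gene2[edges$gene1 == gid],
                           edges$gene1[edges$gene2 == gid]))
      partners <- intersect(partners, setdiff(flav_degs, gid))
      is_flav <- gid %in% flavonoid
      if (!is_flav && length(partners) == 0) next
      st <- sort(unique(degs$stage[degs$gene_id == gid]))
      out[[length(out) + 1]] <- data.frame(
        gene_id = gid,
        qtl = paste0(peaks$trait[i], ":", peaks$group[i]),
        de_stages = paste(st, collapse = ","),
        is_flavonoid = is_flav,
        partners = paste(partners, collapse = ","),
        n_partners = length(partners),
        rationale = if (is_flav) "flavonoid gene, DE in QTL interval" else
          "DE in QTL interval, coexpressed with flavonoid DEG(s)",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[!duplicated(res$gene_id), , drop = FALSE]
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target,sample - Ct_ref,sample) -
#'         (Ct_target,control - Ct_ref,control)`; relative expression is
#' `2^(-ddCt)`.
#'
#' @param ct data.frame with columns `gene`, `sample`, `ct`.
#' @param reference_gene internal reference gene id.
#' @param control_sample calibrator sample id.
#' @return data.frame: `gene`, `sample`, `ddct`, `rel_expr` for all
#'   non-reference genes and non-control samples.
#' @export
delta_delta_ct <- function(ct, reference_gene, control_sample) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  if (!reference_gene %in% ct$gene) stop("reference gene not in Ct table")
  if (!control_sample %in% ct$sample) stop("control sample not in Ct table")
  ref <- ct[ct$gene == reference_gene, ]
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  tgt <- ct[ct$gene != reference_gene, ]
  out <- lapply(split(tgt, tgt$gene), function(s) {
    if (!control_sample %in% s$sample) return(NULL)
    dct <- s$ct - ref_ct[s$sample]
    dct_c <- s$ct[s$sample == control_sample] -
      ref_ct[control_sample]
    keep <- s$sample != control_sample
    data.frame(gene = s$gene[keep], sample = s$sample[keep],
               ddct = dct[keep] - dct_c, rel_expr = 2^(-(dct[keep] - dct_c)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
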