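# Marker retention rules for an aa x bb F2 resequencing panel:
# parental polymorphism -> depth/missing masking -> MAF -> segregation chi2.

#' Filtering criteria for F2 variant sites
#'
#' @param min_parent_depth minimum parent sequencing depth (default 2).
#' @param min_f2_depth minimum F2 depth; lower-depth calls are masked
#'   (default 3).
#' @param maf_floor minor allele frequency must exceed this (default 0.30,
#'   strict).
#' @param max_missing maximum fraction of missing F2 calls per site
#'   (default 0.5: a site must be called in at least half the plants).
#' @param seg_p_floor sites pass the 1:2:1 segregation chi-square test iff
#'   p >= this floor (default 0.001).
#' @param ratio expected genotype ratio aa:ab:bb.
#' @param per_allele_depth if `TRUE`, the depth floors apply to each observed
#'   allele's depth rather than to the total site depth.
#' @return a list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_parent_depth = 2, min_f2_depth = 3,
                            maf_floor = 0.30, max_missing = 0.5,
                            seg_p_floor = 0.001, ratio = c(1, 2, 1),
                            per_allele_depth = FALSE) {
  stopifnot(min_parent_depth >= 0, min_f2_depth >= 0,
            maf_floor >= 0, maf_floor <= 0.5,
            max_missing >= 0, max_missing <= 1,
            seg_p_floor >= 0, seg_p_floor <= 1,
            length(ratio) == 3, all(ratio >= 0), sum(ratio) > 0)
  structure(list(min_parent_depth = min_parent_depth,
                 min_f2_depth = min_f2_depth, maf_floor = maf_floor,
                 max_missing = max_missing, seg_p_floor = seg_p_floor,
                 ratio = ratio, per_allele_depth = per_allele_depth),
            class = "filter_criteria")
}

# subset a variant_matrix to a set of site indices
vm_subset <- function(vm, idx) {
  out <- vm
  for (f in c("chrom", "pos", "cm", "p1_call", "p1_depth", "p2_call",
              "p2_depth")) {
    out[[f]] <- vm[[f]][idx]
  }
  for (f in c("geno", "depth", "ad_ref", "ad_alt")) {
    out[[f]] <- vm[[f]][idx, , drop = FALSE]
  }
  out
}

#' Retain sites polymorphic between the parents (aa x bb)
#'
#' A site is kept when the two parents carry opposite homozygous calls and
#' both parent depths meet the parental depth floor.
#'
#' @param vm a `variant_matrix`.
#' @param criteria a [filter_criteria()].
#' @return logical vector, one element per site.
#' @export
select_parental_polymorphisms <- function(vm, criteria = filter_criteria()) {
  if (is.null(vm$p1_call) || is.null(vm$p2_call)) {
    stop("variant matrix lacks parental columns")
  }
  opposite <- !is.na(vm$p1_call) & !is.na(vm$p2_call) &
    ((vm$p1_call == 0L & vm$p2_call == 2L) |
       (vm$p1_call == 2L & vm$p2_call == 0L))
  opposite & vm$p1_depth >= criteria$min_parent_depth &
    vm$p2_depth >= criteria$min_parent_depth
}

#' Mask low-depth F2 calls and drop high-missingness sites
#'
#' F2 calls below the depth floor are set missing; sites whose resulting call
#' rate falls below `1 - max_missing` are flagged for dropping.
#'
#' @param vm a `variant_matrix`.
#' @param criteria a [filter_criteria()].
#' @return list: `variants` (masked matrix) and `keep` (logical per site).
#' @export
apply_depth_and_missing <- function(vm, criteria = filter_criteria()) {
  k <- criteria$min_f2_depth
  if (criteria$per_allele_depth) {
    low <- (vm$geno == 1L & (vm$ad_ref < k | vm$ad_alt < k)) |
      (vm$geno != 1L & vm$depth < k)
  } else {
    low <- vm$depth < k
  }
  low[is.na(low)] <- FALSE
  vm$geno[low] <- NA_integer_
  called <- rowSums(!is.na(vm$geno))
  keep <- called >= ceiling((1 - criteria$max_missing) * ncol(vm$geno))
  list(variants = vm, keep = keep)
}

#' Minor allele frequency of a genotype call vector
#'
#' @param calls integer calls (0/1/2, NA missing).
#' @return `min(p, 1 - p)` where `p = (2 n_aa + n_ab) / (2 n_called)`.
#' @export
minor_allele_frequency <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) stop("all calls missing")
  p <- (2 * sum(calls == 0L) + sum(calls == 1L)) / (2 * length(calls))
  min(p, 1 - p)
}

#' Segregation chi-square test against an expected genotype ratio
#'
#' @param counts integer vector `c(n_aa, n_ab, n_bb)`.
#' @param ratio expected ratio, default 1:2:1.
#' @return list with `chi2` and `p` (upper tail, df = 2, no continuity
#'   correction).
#' @export
segregation_chi2 <- function(counts, ratio = c(1, 2, 1)) {
  stopifnot(length(counts) == 3, length(ratio) == 3)
  n <- sum(counts)
  if (n == 0) stop("zero genotype calls")
  expd <- n * ratio / sum(ratio)
  chi2 <- sum((counts - expd)^2 / expd)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 2, lower.tail = FALSE))
}

#' Run the full marker-retention filter
#'
#' Applies, in order: parental aa x bb polymorphism, F2 depth masking and
#' missingness ceiling, minor allele frequency floor, and the 1:2:1
#' segregation chi-square test. The per-rule drop counts plus retained sites
#' sum to the input site count.
#'
#' @param vm a `variant_matrix`.
#' @param criteria a [filter_criteria()].
#' @return list: `variants` (filtered, masked), `report` (data.frame of
#'   per-rule drop counts), and `site_table` (per-site statistics and
#'   verdicts for all input sites).
#' @export
run_filter <- function(vm, criteria = filter_criteria()) {
  m <- length(vm$pos)
  verdict <- rep("retained", m)

  poly <- select_parental_polymorphisms(vm, criteria)
  verdict[!poly] <- "not_polymorphic"

  dm <- apply_depth_and_missing(vm, criteria)
  vm_masked <- dm$variants
  verdict[poly & !dm$keep] <- "too_missing"

  stats_of <- function(i) {
    calls <- vm_masked$geno[i, ]
    calls <- calls[!is.na(calls)]
    counts <- c(sum(calls == 0L), sum(calls == 1L), sum(calls == 2L))
    if (sum(counts) == 0) return(c(counts, NA, NA, NA))
    maf <- minor_allele_frequency(vm_masked$geno[i, ])
    sg <- segregation_chi2(counts, criteria$ratio)
    c(counts, maf, sg$chi2, sg$p)
  }
  st <- t(vapply(seq_len(m), stats_of, numeric(6)))
  colnames(st) <- c("n_aa", "n_ab", "n_bb", "maf", "chi2", "p")

  live <- verdict == "retained"
  fail_maf <- live & (is.na(st[, "maf"]) | st[, "maf"] <= criteria$maf_floor)
  verdict[fail_maf] <- "low_maf"
  live <- verdict == "retained"
  fail_seg <- live & (is.na(st[, "p"]) | st[, "p"] < criteria$seg_p_floor)
  verdict[fail_seg] <- "distorted_segregation"

  report <- data.frame(
    rule = c("not_polymorphic", "too_missing", "low_maf",
             "distorted_segregation", "retained"),
    sites = c(sum(verdict == "not_polymorphic"),
              sum(verdict == "too_missing"),
              sum(verdict == "low_maf"),
              sum(verdict == "distorted_segregation"),
              sum(verdict == "retained")),
    stringsAsFactors = FALSE)

  site_table <- data.frame(chrom = vm$chrom, pos = vm$pos,
                           as.data.frame(st), verdict = verdict,
                           stringsAsFactors = FALSE)
  list(variants = vm_subset(vm_masked, which(verdict == "retained")),
       report = report, site_table = site_table)
}
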