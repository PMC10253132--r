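# Sliding-window genotyping of F2 individuals and recombination-bin merging.
#
# A 15-site window is called homozygous for an individual when >= 11 of its
# informative sites carry one parent's allele; otherwise heterozygous.
# Windows with more than 2/3 of their sites missing are left unknown. The
# homozygosity threshold is pro-rated, ceil(11/15 * informative), for
# windows with missing data or short terminal windows.

#' Call the genotype of one marker window
#'
#' @param calls integer site calls (0/1/2, NA missing) inside the window.
#' @param window nominal window size (for the threshold ratio).
#' @param homo_threshold homozygosity count threshold at full size.
#' @return list: counts `n_aa`, `n_het`, `n_bb`, `n_missing` and `genotype`
#'   (0/1/2, or NA for unknown).
#' @export
call_window <- function(calls, window = 15, homo_threshold = 11) {
  if (length(calls) == 0) stop("empty window")
  n_aa <- sum(calls == 0L, na.rm = TRUE)
  n_het <- sum(calls == 1L, na.rm = TRUE)
  n_bb <- sum(calls == 2L, na.rm = TRUE)
  n_missing <- sum(is.na(calls))
  informative <- n_aa + n_het + n_bb
  geno <- if (n_missing > 2 / 3 * length(calls) || informative == 0) {
    NA_integer_
  } else {
    thr <- ceiling(homo_threshold / window * informative)
    if (n_aa >= thr) 0L else if (n_bb >= thr) 2L else 1L
  }
  list(n_aa = n_aa, n_het = n_het, n_bb = n_bb, n_missing = n_missing,
       genotype = geno)
}

# absorb single-window states flanked by identical states (double-recombinant
# smoothing for isolated miscalled windows)
smooth_states <- function(g) {
  if (length(g) < 3) return(g)
  repeat {
    iso <- which(!is.na(g[-c(1, length(g))]) &
                   !is.na(g[-((length(g) - 1):length(g))]) &
                   !is.na(g[-(1:2)]) &
                   g[-c(1, length(g))] != g[-((length(g) - 1):length(g))] &
                   g[-((length(g) - 1):length(g))] == g[-(1:2)]) + 1L
    if (length(iso) == 0) break
    g[iso] <- g[iso - 1L]
  }
  g
}

#' Slide genotyping windows along one individual's site calls
#'
#' @param calls integer site calls (0/1/2/NA), sorted by position.
#' @param pos_bp physical positions (bp), strictly increasing.
#' @param chrom chromosome id.
#' @param window window size in sites (default 15).
#' @param homo_threshold homozygous-call count threshold (default 11).
#' @param step window step in sites; 1 (default) gives maximally overlapping
#'   windows, `step = window` gives non-overlapping windows.
#' @param smooth absorb isolated single-window states (default TRUE).
#' @return a `window_track`: list with the `windows` data.frame (per window:
#'   site span, counts, genotype), the site `calls`/`pos_bp`, and the
#'   parameters used.
#' @export
slide_windows <- function(calls, pos_bp, chrom = "chr", window = 15,
                          homo_threshold = 11, step = 1, smooth = TRUE) {
  n <- length(calls)
  stopifnot(length(pos_bp) == n, n >= 1)
  if (is.unsorted(pos_bp, strictly = TRUE)) {
    stop("sites must be sorted by position")
  }
  starts <- seq(1L, n, by = step)
  # clamp the span so windows stay full-size at the chromosome tail
  # (short windows only when fewer sites than the window size exist)
  starts <- pmin(starts, max(1L, n - window + 1L))
  w <- lapply(starts, function(s) {
    e <- min(s + window - 1L, n)
    c(s, e, unlist(call_window(calls[s:e], window, homo_threshold)))
  })
  w <- as.data.frame(do.call(rbind, w))
  names(w) <- c("first_site", "last_site", "n_aa", "n_het", "n_bb",
                "n_missing", "genotype")
  w$first_bp <- pos_bp[w$first_site]
  w$last_bp <- pos_bp[w$last_site]
  w <- cbind(window = seq_len(nrow(w)), w)
  if (smooth) w$genotype <- smooth_states(w$genotype)
  structure(list(windows = w, calls = calls, pos_bp = pos_bp, chrom = chrom,
                 window_size = window, homo_threshold = homo_threshold,
                 step = step),
            class = "window_track")
}

# changepoint refinement: boundary (site index) maximizing agreement with
# left state before it and right state after it; exact on clean data
refine_breakpoint <- function(calls, lo, hi, from, to) {
  idx <- lo:(hi - 1L)
  score <- vapply(idx, function(b) {
    sum(calls[lo:b] == from, na.rm = TRUE) +
      sum(calls[(b + 1L):hi] == to, na.rm = TRUE)
  }, numeric(1))
  best <- idx[score == max(score)]
  best[ceiling(length(best) / 2)]
}

#' Detect recombination breakpoints in a window track
#'
#' Each transition between window genotypes is localized by a changepoint
#' scan of the underlying site calls; the reported interval is the span
#' between the last site assigned to the left state and the first site of
#' the right state. On clean dense data this interval brackets the true
#' crossover exactly.
#'
#' @param track a `window_track` from [slide_windows()].
#' @return data.frame: `chrom`, site indices (`left_site`, `right_site`),
#'   bp interval (`left_bp`, `right_bp`), `from` and `to` genotypes.
#' @export
detect_breakpoints <- function(track) {
  stopifnot(inherits(track, "window_track"))
  w <- track$windows
  known <- !is.na(w$genotype)
  empty <- data.frame(chrom = character(0), left_site = integer(0),
                      right_site = integer(0), left_bp = numeric(0),
                      right_bp = numeric(0), from = integer(0),
                      to = integer(0), stringsAsFactors = FALSE)
  if (!any(known)) return(empty)
  g <- w$genotype[known]
  wi <- which(known)
  ch <- which(g[-1] != g[-length(g)])
  if (length(ch) == 0) return(empty)
  out <- list()
  prev <- 0L
  for (i in ch) {
    from <- g[i]; to <- g[i + 1]
    # search region: from the start of the last left-state window to the end
    # of the first right-state window, kept after the previous boundary so
    # boundaries stay strictly increasing
    lo <- max(w$first_site[wi[i]], prev + 1L)
    hi <- min(w$last_site[wi[i + 1]], length(track$calls))
    if (hi <= lo) next
    b <- refine_breakpoint(track$calls, lo, hi, from, to)
    prev <- b
    out[[length(out) + 1]] <- data.frame(
      chrom = track$chrom, left_site = b, right_site = b + 1L,
      left_bp = track$pos_bp[b], right_bp = track$pos_bp[b + 1L],
      from = from, to = to, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Merge window tracks into recombination bins
#'
#' The chromosome is partitioned at the union of all individuals'
#' breakpoints; within a bin every individual's window genotype is constant,
#' and adjacent bins differ for at least one individual. Bin coordinates are
#' 1-based inclusive bp.
#'
#' @param tracks list (one `window_track` per individual) sharing the same
#'   site scaffold.
#' @param chrom chromosome id recorded in the output.
#' @return a `bin_geno` object: list with `bins` (data.frame `bin`, `chrom`,
#'   `start`, `end`, site span) and `geno` (bins x individuals matrix).
#' @export
merge_bins <- function(tracks, chrom = tracks[[1]]$chrom) {
  stopifnot(length(tracks) >= 1)
  pos <- tracks[[1]]$pos_bp
  if (!all(vapply(tracks, function(t) identical(t$pos_bp, pos), logical(1)))) {
    stop("tracks do not share a common site scaffold")
  }
  n_sites <- length(pos)
  bps <- lapply(tracks, detect_breakpoints)
  bounds <- sort(unique(unlist(lapply(bps, function(b) b$left_site))))
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n_sites)

  # per-individual segment states, expanded to bins
  geno <- matrix(vapply(seq_along(tracks), function(j) {
    b <- bps[[j]]
    w <- tracks[[j]]$windows
    g0 <- w$genotype[!is.na(w$genotype)][1]
    if (length(g0) == 0) g0 <- NA_integer_
    seg_states <- c(g0, b$to)
    seg_idx <- findInterval(starts, c(1L, b$left_site + 1L))
    as.integer(seg_states[seg_idx])
  }, integer(length(starts))), nrow = length(starts))

  rownames(geno) <- sprintf("%s_bin%04d", chrom, seq_along(starts))
  structure(list(
    bins = data.frame(bin = rownames(geno),
                      chrom = chrom, start = pos[starts], end = pos[ends],
                      first_site = starts, last_site = ends,
                      stringsAsFactors = FALSE),
    geno = geno
  ), class = "bin_geno")
}

#' @export
print.bin_geno <- function(x, ...) {
  cat("bin_geno:", nrow(x$bins), "bins x", ncol(x$geno), "individuals on",
      length(unique(x$bins$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Genotype an F2 population into bins, chromosome by chromosome
#'
#' Convenience wrapper: slides windows over every individual on every
#' chromosome of a (filtered) variant matrix, detects breakpoints and merges
#' population-wide bins.
#'
#' @param vm a `variant_matrix` (ideally the output of [run_filter()]).
#' @inheritParams slide_windows
#' @return a `bin_geno` spanning all chromosomes.
#' @export
bin_genotype <- function(vm, window = 15, homo_threshold = 11, step = 1,
                         smooth = TRUE) {
  chroms <- unique(vm$chrom)
  per <- lapply(chroms, function(ch) {
    idx <- which(vm$chrom == ch)
    idx <- idx[order(vm$pos[idx])]
    tracks <- lapply(seq_len(ncol(vm$geno)), function(j) {
      slide_windows(vm$geno[idx, j], vm$pos[idx], chrom = ch,
                    window = window, homo_threshold = homo_threshold,
                    step = step, smooth = smooth)
    })
    merge_bins(tracks, chrom = ch)
  })
  structure(list(
    bins = do.call(rbind, lapply(per, function(b) b$bins)),
    geno = do.call(rbind, lapply(per, function(b) b$geno))
  ), class = "bin_geno")
}
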