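#' Construct a simulation map
#'
#' A `sim_map` describes the genome geometry the simulator operates on: one or
#' more linkage groups, each with a genetic length (cM), a physical length
#' (bp) and a set of marker sites placed collinearly on both scales.
#'
#' @param groups data.frame with columns `group` (id), `length_cm` (> 0),
#'   `length_bp` (> 0) and `n_sites` (>= 1).
#' @param site_positions optional list (one element per group) of strictly
#'   increasing cM positions; by default sites are spaced uniformly over
#'   `[0, length_cm]`.
#' @return an object of class `sim_map`: a list with `groups` and a `sites`
#'   data.frame (`group`, `site`, `cm`, `bp`), with bp positions the collinear
#'   (linear) image of the cM positions.
#' @export
#' @examples
#' m <- sim_map(data.frame(group = "chr1", length_cm = 100,
#'                         length_bp = 5e7, n_sites = 50))
#' head(m$sites)
sim_map <- function(groups, site_positions = NULL) {
  req <- c("group", "length_cm", "length_bp", "n_sites")
  if (!all(req %in% names(groups))) {
    stop("groups must have columns: ", paste(req, collapse = ", "))
  }
  if (any(groups$length_cm <= 0) || any(groups$length_bp <= 0)) {
    stop("group lengths must be positive")
  }
  if (any(groups$n_sites < 1)) stop("each group needs at least one site")
  groups$group <- as.character(groups$group)
  if (anyDuplicated(groups$group)) stop("duplicate group ids")

  sites <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    if (is.null(site_positions)) {
      cm <- if (g$n_sites == 1) g$length_cm / 2 else
        seq(0, g$length_cm, length.out = g$n_sites)
    } else {
      cm <- site_positions[[i]]
      if (is.unsorted(cm, strictly = TRUE)) {
        stop("site positions must be strictly increasing within a group")
      }
      if (any(cm < 0 | cm > g$length_cm)) stop("site position outside group")
    }
    data.frame(group = g$group, site = seq_along(cm), cm = cm,
               bp = pmax(1, round(cm / g$length_cm * g$length_bp)),
               stringsAsFactors = FALSE)
  })
  structure(list(groups = groups, sites = do.call(rbind, sites)),
            class = "sim_map")
}

#' @export
print.sim_map <- function(x, ...) {
  cat("sim_map:", nrow(x$groups), "linkage group(s),",
      nrow(x$sites), "sites,",
      sprintf("%.1f cM total\n", sum(x$groups$length_cm)))
  invisible(x)
}

# Published 19-group Brassica napus template geometry: per-group genetic
# lengths (cM) and marker counts; physical lengths use a uniform 736 kb/cM
# collinear scale (places the 81.91 cM point of A09 near 60.3 Mb).
bnapus_groups <- function() {
  data.frame(
    group = c(paste0("A0", 1:9), "A10", paste0("C0", 1:9)),
    length_cm = c(84.693, 71.058, 89.030, 65.910, 100.404, 90.317, 72.777,
                  90.235, 93.434, 60.582, 80.946, 82.514, 111.315, 99.501,
                  98.286, 90.109, 77.757, 77.850, 81.611),
    n_markers = c(226, 195, 295, 168, 228, 258, 180, 149, 276, 194, 236,
                  175, 303, 224, 241, 183, 207, 199, 211),
    stringsAsFactors = FALSE
  )
}

#' Default 19-group simulation map
#'
#' The default genome geometry emulated by the simulator: 19 linkage groups
#' totalling 1618.3 cM, with marker sites allocated per group. With
#' `n_sites = NA` the per-group site counts follow the template's 4148-marker
#' allocation; passing a total reallocates sites proportionally to group
#' length (minimum 2 per group).
#'
#' @param n_sites total number of marker sites, or `NA` for the template
#'   allocation (4148).
#' @return a [sim_map()].
#' @export
#' @examples
#' default_map(n_sites = 190)
default_map <- function(n_sites = NA) {
  g <- bnapus_groups()
  if (is.na(n_sites)) {
    n <- g$n_markers
  } else {
    n <- pmax(2, round(n_sites * g$length_cm / sum(g$length_cm)))
  }
  sim_map(data.frame(group = g$group, length_cm = g$length_cm,
                     length_bp = round(g$length_cm * 736000),
                     n_sites = n, stringsAsFactors = FALSE))
}

#' Marker-scale truth map of a simulation geometry
#'
#' The simulated sites as a `genetic_map`-style table (`marker`, `group`,
#' `cm`, `chrom`, `start`, `end`), aligned row-for-row with the genotype
#' matrices the simulator produces. Useful for running scans directly on true
#' genotypes, i.e. the noiseless limit of the filter + bin-map chain.
#'
#' @param map a [sim_map()].
#' @return data.frame with one row per site.
#' @export
truth_marker_map <- function(map) {
  s <- map$sites
  data.frame(marker = sprintf("%s_s%04d", s$group, s$site), group = s$group,
             cm = s$cm, chrom = s$group, start = s$bp, end = s$bp,
             stringsAsFactors = FALSE)
}
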