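# shared fixtures: tiny maps, hand-built variant matrices, ARI

one_group_map <- function(length_cm = 100, n_sites = 200, length_bp = 5e7) {
  sim_map(data.frame(group = "chr1", length_cm = length_cm,
                     length_bp = length_bp, n_sites = n_sites))
}

two_group_map <- function(n_sites = 150) {
  sim_map(data.frame(group = c("chr1", "chr2"), length_cm = c(60, 80),
                     length_bp = c(3e7, 4e7), n_sites = n_sites))
}

# build a variant_matrix by hand from a genotype matrix (sites x individuals)
make_vm <- function(geno, depth = NULL, chrom = "chr1",
                    pos = seq_len(nrow(geno)) * 1000,
                    p1_call = rep(0L, nrow(geno)),
                    p2_call = rep(2L, nrow(geno)),
                    p1_depth = rep(10L, nrow(geno)),
                    p2_depth = rep(10L, nrow(geno))) {
  if (is.null(depth)) depth <- matrix(10L, nrow(geno), ncol(geno))
  ref <- matrix(0L, nrow(geno), ncol(geno))
  alt <- ref
  hom0 <- !is.na(geno) & geno == 0L
  hom2 <- !is.na(geno) & geno == 2L
  ref[hom0] <- depth[hom0]
  alt[hom2] <- depth[hom2]
  het <- !is.na(geno) & geno == 1L
  ref[het] <- depth[het] %/% 2L
  alt[het] <- depth[het] - ref[het]
  structure(list(chrom = rep_len(chrom, nrow(geno)), pos = pos,
                 cm = rep(NA_real_, nrow(geno)),
                 p1_call = p1_call, p1_depth = p1_depth,
                 p2_call = p2_call, p2_depth = p2_depth,
                 geno = geno, depth = depth, ad_ref = ref, ad_alt = alt),
            class = "variant_matrix")
}

# adjusted Rand index between two labelings (independent small implementation)
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expd <- sum_a * sum_b / comb2(n)
  (sum_ij - expd) / ((sum_a + sum_b) / 2 - expd)
}

# multinomial log10-likelihood of the two-marker F2 class counts, written
# directly from the nine class probabilities (grid-search oracle for the EM)
rf_grid_oracle <- function(ga, gb, grid = seq(0.00005, 0.49995, by = 5e-5)) {
  ok <- !is.na(ga) & !is.na(gb)
  cnt <- tabulate(3L * ga[ok] + gb[ok] + 1L, 9)
  ll <- cnt[1] * log10((1 - grid)^2 / 4) + cnt[9] * log10((1 - grid)^2 / 4) +
    cnt[3] * log10(grid^2 / 4) + cnt[7] * log10(grid^2 / 4) +
    (cnt[2] + cnt[4] + cnt[6] + cnt[8]) * log10(grid * (1 - grid) / 2) +
    cnt[5] * log10(((1 - grid)^2 + grid^2) / 2)
  grid[which.max(ll)]
}

# all permutations of 1..m (factorial oracle for marker ordering)
perms_of <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(m - 1L)
  do.call(rbind, lapply(seq_len(m), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
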