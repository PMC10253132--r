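# Readers/writers for the standard interchange formats: VCF v4.2 (GT:AD),
# phenotype/expression TSV, GFF3 gene models, truth JSON.

geno_to_gt <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 2L] <- "1/1"
  out
}

gt_to_geno <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[gt == "0/0"] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt == "1/1"] <- 2L
  out
}

#' Write a variant matrix to VCF v4.2
#'
#' Emits GT and AD fields; the two parents are the first two sample columns
#' (`P1`, `P2`). Parent allele depths are written on the allele each parent
#' carries.
#'
#' @param vm a `variant_matrix` (see [simulate_variant_calls()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vm, path) {
  n <- ncol(vm$geno)
  ids <- colnames(vm$geno)
  if (is.null(ids)) ids <- sprintf("F2_%03d", seq_len(n))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=binmapqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "P1", "P2", ids), collapse = "\t")
  )
  m <- length(vm$pos)
  p1 <- paste0(geno_to_gt(vm$p1_call), ":", vm$p1_depth, ",0")
  p2 <- paste0(geno_to_gt(vm$p2_call), ":0,", vm$p2_depth)
  f2 <- matrix(paste0(geno_to_gt(vm$geno), ":", vm$ad_ref, ",", vm$ad_alt),
               m, n)
  rows <- paste(vm$chrom, vm$pos, sprintf("site%05d", seq_len(m)),
                "A", "T", ".", "PASS", ".", "GT:AD", p1, p2,
                apply(f2, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a VCF into a variant matrix
#'
#' Parses GT and AD via vcfR. The samples named in `parents` become the two
#' parental columns; all remaining samples are the F2 individuals.
#'
#' @param path VCF file (v4.2, GT and AD fields).
#' @param parents names of the two parent samples.
#' @return a `variant_matrix`.
#' @export
read_vcf <- function(path, parents = c("P1", "P2")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  if (!all(parents %in% colnames(gt))) {
    stop("parent samples not found in VCF: ", paste(parents, collapse = ", "))
  }
  f2 <- setdiff(colnames(gt), parents)
  ref <- vapply(strsplit(ad, ","), function(x) as.integer(x[1]), integer(1))
  alt <- vapply(strsplit(ad, ","), function(x) as.integer(x[2]), integer(1))
  ref <- matrix(ref, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  alt <- matrix(alt, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  geno <- matrix(gt_to_geno(gt[, f2, drop = FALSE]), nrow(gt),
                 dimnames = list(NULL, f2))
  structure(list(
    chrom = as.character(v@fix[, "CHROM"]),
    pos = as.integer(v@fix[, "POS"]),
    cm = rep(NA_real_, nrow(gt)),
    p1_call = gt_to_geno(gt[, parents[1]]),
    p1_depth = ref[, parents[1]] + alt[, parents[1]],
    p2_call = gt_to_geno(gt[, parents[2]]),
    p2_depth = ref[, parents[2]] + alt[, parents[2]],
    geno = geno,
    depth = ref[, f2, drop = FALSE] + alt[, f2, drop = FALSE],
    ad_ref = ref[, f2, drop = FALSE],
    ad_alt = alt[, f2, drop = FALSE]
  ), class = "variant_matrix")
}

#' Write / read a phenotype table
#'
#' One row per F2 plant: `id, R, G, B, l, a, b, visual`, tab-separated.
#'
#' @param pheno data.frame from [simulate_phenotypes()].
#' @param path file path.
#' @return `path` / the data.frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a GFF3 gene annotation
#'
#' @param genes data.frame `gene_id, chrom, start, end, strand`.
#' @param path file path.
#' @return `path` / a data.frame in the same layout (reading uses
#'   rtracklayer and keeps `gene` features only).
#' @export
write_gff3 <- function(genes, path) {
  genes <- genes[order(genes$chrom, genes$start), ]
  lines <- sprintf("%s\tbinmapqtl\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, genes$start, genes$end, genes$strand,
                   genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(gene_id = gr$ID,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write / read an expression matrix (genes x samples TSV)
#'
#' @param mat numeric matrix with gene row names and sample column names.
#' @param path file path.
#' @return `path` / the matrix.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write a complete synthetic fixture set
#'
#' Generates an F2 population with phenotypes, variant calls, a toy gene
#' annotation and an expression matrix, and writes VCF + phenotype TSV +
#' GFF3 + expression TSV + a truth JSON (crossovers, QTLs, seeds) into a
#' directory. All files round-trip through this package's own readers.
#'
#' @param outdir output directory (created if needed).
#' @param map a [sim_map()]; default a small two-group geometry.
#' @param config a [sim_config()].
#' @param qtls QTL truth table (see [default_qtls()]).
#' @param genes_per_group toy annotation density.
#' @return named list of file paths, invisibly; the generated objects are
#'   attached as the `"objects"` attribute.
#' @export
write_fixtures <- function(outdir,
                           map = default_map(n_sites = 200),
                           config = sim_config(n = 50),
                           qtls = default_qtls(),
                           genes_per_group = 20) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  pop <- simulate_f2(map, config$n)
  vm <- simulate_variant_calls(pop, depth = config$depth,
                               error = config$error,
                               missing = config$missing)
  colnames(vm$geno) <- sprintf("F2_%03d", seq_len(config$n))
  pheno <- simulate_phenotypes(pop, qtls, config)
  genes <- simulate_genes(map, genes_per_group)
  expr <- simulate_expression(seed = config$seed)

  paths <- list(
    vcf = file.path(outdir, "variants.vcf"),
    pheno = file.path(outdir, "phenotypes.tsv"),
    gff3 = file.path(outdir, "genes.gff3"),
    expression = file.path(outdir, "expression.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_vcf(vm, paths$vcf)
  write_phenotypes(pheno, paths$pheno)
  write_gff3(genes, paths$gff3)
  write_expression(expr$fpkm, paths$expression)

  xo <- lapply(names(pop$gam1), function(g) list(
    group = g,
    gamete1 = lapply(pop$gam1[[g]]$xo, function(v) round(v, 4)),
    gamete2 = lapply(pop$gam2[[g]]$xo, function(v) round(v, 4))
  ))
  truth <- list(seed = config$seed, config = unclass(config), qtls = qtls,
                crossovers = xo,
                genetic_values = round(attr(pheno, "genetic"), 6),
                expression_truth = list(
                  module = unname(expr$truth$module),
                  gene_id = names(expr$truth$module),
                  flavonoid = expr$truth$flavonoid,
                  lfc = expr$truth$lfc))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  attr(paths, "objects") <- list(pop = pop, variants = vm, pheno = pheno,
                                 genes = genes, expression = expr)
  invisible(paths)
}
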