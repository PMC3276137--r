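# Small in-code fixtures shared across test files.

# 6 samples x 4 SNPs, haploid calls, one missing cell, one SNP coded on
# the major allele (snp3) to exercise re-orientation at load.
toy_genotype_tsv <- function(path = tempfile(fileext = ".tsv")) {
  tab <- data.frame(
    sample = paste0("s", 1:6),
    snp1 = c(0, 0, 1, 1, 0, 0),
    snp2 = c(0, 1, 0, NA, 0, 0),
    snp3 = c(1, 1, 1, 0, 1, 1),   # major-allele coded
    snp4 = c(0, 0, 0, 0, 0, 1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("s", 1:4)), collapse = "\t"),
    paste(c("1", "100", "v1", "A", "T", ".", "PASS", ".", "GT",
            "0", "0", "1", "1"), collapse = "\t"),
    paste(c("1", "200", "v2", "C", "G", ".", "PASS", ".", "GT",
            "0", "1", "0", "."), collapse = "\t"),
    paste(c("1", "300", "v3", "G", "A,C", ".", "PASS", ".", "GT",
            "0", "1", "2", "0"), collapse = "\t"))
  writeLines(lines, path)
  path
}

# Fragment panel with known rare/common composition: frag_r has 4 rare
# SNPs, frag_c has 3 common SNPs, frag_mix has 3 rare + 2 common.
toy_panel <- function(n = 60, seed = 101) {
  set.seed(seed)
  rare_col <- function(k) { x <- rep(0, n); x[sample(n, k)] <- 1; x }
  common_col <- function(p) rare_col(round(p * n))
  calls <- cbind(
    r1 = rare_col(1), r2 = rare_col(2), r3 = rare_col(2), r4 = rare_col(1),
    c1 = common_col(0.3), c2 = common_col(0.45), c3 = common_col(0.2),
    m1 = rare_col(2), m2 = rare_col(1), m3 = rare_col(2),
    m4 = common_col(0.25), m5 = common_col(0.4))
  g <- genotype_matrix(calls, samples = sprintf("s%02d", 1:n),
                       snps = colnames(calls))
  fragments <- list(frag_r = c("r1", "r2", "r3", "r4"),
                    frag_c = c("c1", "c2", "c3"),
                    frag_mix = c("m1", "m2", "m3", "m4", "m5"))
  list(g = g, fragments = fragments, maf = compute_maf(g))
}

# Annotation table matching toy_panel SNP ids.
toy_annotations <- function() {
  variant_annotation(
    snp_id = c("r1", "r2", "r3", "r4", "c1", "c2", "c3",
               "m1", "m2", "m3", "m4", "m5"),
    fragment_id = c(rep("frag_r", 4), rep("frag_c", 3), rep("frag_mix", 5)),
    gene_id = c(rep("geneR", 4), rep("geneC", 3), rep("geneM", 5)),
    site_class = c("nonsynonymous", "nonsynonymous", "nonsynonymous",
                   "synonymous", "nonsynonymous", "intronic", "synonymous",
                   "nonsynonymous", "nonsynonymous", "nonsynonymous",
                   "intergenic", "synonymous"),
    nonsense = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, FALSE, FALSE, FALSE, FALSE),
    polyphen = c("probably_damaging", "possibly_damaging", "benign", "none",
                 "benign", "none", "none",
                 "none", "probably_damaging", "possibly_damaging",
                 "none", "none"),
    sift = c("intolerant", "tolerant", "tolerant", "none",
             "tolerant", "none", "none",
             "tolerant", "intolerant", "intolerant", "none", "none"))
}

# Bins generated exactly from a power curve at the 20 standard midpoints.
power_curve_bins <- function(a, b, units_percent = TRUE) {
  mids <- (1:20 - 0.5) * 0.025
  p <- if (units_percent) mids * 100 else mids
  data.frame(midpoint = mids, n_total = 100L,
             n_functional = NA_integer_, proportion = a * p^b)
}

# Correlation matrix usable as a known kinship for recovery tests.
block_kinship <- function(n, n_blocks = 5, rho = 0.5) {
  block <- rep_len(seq_len(n_blocks), n)
  K <- outer(block, block, function(a, b) ifelse(a == b, rho, 0))
  diag(K) <- 1
  K
}
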