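#' Construct a genotype matrix
#'
#' Container for minor-allele counts of a panel of samples at biallelic SNPs.
#' For inbred accessions calls are haploid-style 0/1 (`ploidy = 1`);
#' `ploidy = 2` admits heterozygous calls in 0/1/2.
#'
#' @param calls numeric matrix, samples in rows, SNPs in columns; entries are
#'   minor-allele counts in `0:ploidy` or `NA` for missing.
#' @param samples character vector of unique sample identifiers (defaults to
#'   rownames of `calls`).
#' @param snps character vector of unique SNP identifiers (defaults to
#'   colnames of `calls`).
#' @param chrom,pos optional per-SNP chromosome labels and 1-based positions.
#' @param ploidy 1 (default, inbred panel) or 2.
#'
#' @return An object of class `genotype_matrix`: the calls matrix with
#'   dimnames set and attributes `ploidy`, `chrom`, `pos`.
#' @export
genotype_matrix <- function(calls, samples = rownames(calls),
                            snps = colnames(calls),
                            chrom = NULL, pos = NULL, ploidy = 1L) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(samples) || is.null(snps))
    stop("sample and SNP identifiers are required")
  samples <- as.character(samples)
  snps <- as.character(snps)
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")
  if (anyDuplicated(snps)) stop("duplicated SNP identifiers")
  if (nrow(calls) != length(samples) || ncol(calls) != length(snps))
    stop("dimensions of calls do not match identifier lengths")
  if (nrow(calls) < 2L) stop("need at least 2 samples")
  if (ncol(calls) < 1L) stop("need at least 1 SNP")
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  ok <- is.na(calls) | (calls >= 0 & calls <= ploidy & calls == round(calls))
  if (!all(ok))
    stop("calls must be missing or integers in [0, ploidy]")
  dimnames(calls) <- list(samples, snps)
  structure(calls,
            ploidy = as.integer(ploidy),
            chrom = chrom, pos = pos,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (ploidy %d, %.1f%% missing)\n",
              nrow(x), ncol(x), attr(x, "ploidy"),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Read a genotype matrix from TSV or VCF
#'
#' TSV format: header row of SNP identifiers, first column sample id, cells
#' in 0/1/2/NA. VCF: biallelic records with a GT field; multi-allelic
#' records are rejected and reported. In either format each SNP is
#' re-oriented so the *minor* allele is counted (MAF <= 0.5).
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param ploidy expected ploidy (1 for inbred accessions).
#' @return A [genotype_matrix()]. Rejected multi-allelic site identifiers
#'   are attached as attribute `rejected_sites`.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), ploidy = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("parse error: TSV needs sample column + >=1 SNP")
    samples <- as.character(tab[[1L]])
    calls <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(calls) <- "double"
    g <- genotype_matrix(calls, samples = samples, snps = colnames(tab)[-1L],
                         ploidy = ploidy)
    g <- orient_minor(g)
    attr(g, "rejected_sites") <- character(0)
    return(g)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  rejected <- character(0)
  if (any(multi)) {
    ids <- fix[multi, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"])[is.na(ids) | ids == "."]
    rejected <- unname(ids)
    message(length(rejected), " non-biallelic site(s) rejected: ",
            paste(utils::head(rejected, 5L), collapse = ", "),
            if (length(rejected) > 5L) ", ..." else "")
    vcf <- vcf[!multi, ]
    fix <- vcfR::getFIX(vcf)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1L]]) > 0)
  }
  calls <- apply(gt, c(1L, 2L), count_alt)
  ids <- fix[, "ID"]
  bad <- is.na(ids) | ids == "."
  ids[bad] <- paste0(fix[bad, "CHROM"], ":", fix[bad, "POS"])
  g <- genotype_matrix(t(calls), samples = colnames(gt), snps = ids,
                       chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                       ploidy = ploidy)
  g <- orient_minor(g)
  attr(g, "rejected_sites") <- rejected
  g
}

# Flip SNPs coded on the major allele so every column counts the minor one.
orient_minor <- function(g) {
  ploidy <- attr(g, "ploidy")
  freq <- colMeans(g, na.rm = TRUE) / ploidy
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) g[, flip] <- ploidy - g[, flip]
  g
}

#' Per-SNP minor allele frequency
#'
#' Computed over non-missing calls only; values lie in \[0, 0.5\] because
#' the stored counts are minor-allele oriented.
#'
#' @param g a [genotype_matrix()].
#' @return named numeric vector of MAFs.
#' @export
compute_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  nobs <- colSums(!is.na(g))
  if (any(nobs == 0L))
    stop("all calls missing for SNP(s): ",
         paste(colnames(g)[nobs == 0L], collapse = ", "))
  maf <- colMeans(g, na.rm = TRUE) / attr(g, "ploidy")
  pmin(maf, 1 - maf)
}

#' Classify SNPs as rare or common by MAF
#'
#' Rare means MAF strictly below `threshold`; the boundary value is common.
#' Monomorphic SNPs (MAF 0) are flagged `"monomorphic"` and excluded from
#' all tests.
#'
#' @param maf numeric vector of minor allele frequencies in \[0, 0.5\].
#' @param threshold rarity cutoff (default 0.05).
#' @return factor with levels `monomorphic`, `rare`, `common`.
#' @export
classify_rarity <- function(maf, threshold = 0.05) {
  stopifnot(all(maf >= 0 & maf <= 0.5 + 1e-12))
  out <- ifelse(maf == 0, "monomorphic",
                ifelse(maf < threshold, "rare", "common"))
  factor(out, levels = c("monomorphic", "rare", "common"))
}
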