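#' Construct a per-SNP variant annotation table
#'
#' Holds fragment/gene membership, functional site class, PolyPhen and SIFT
#' categories and the PolyPhen delta score for every SNP the pipeline may
#' test. Prediction categories other than `"none"` are only meaningful for
#' nonsynonymous sites; nonsense changes are recorded via `nonsense`.
#'
#' @param snp_id,fragment_id character vectors (fragment required for every
#'   SNP that enters fragment-level tests).
#' @param gene_id optional character vector (`NA` allowed).
#' @param site_class one of `intergenic`, `intronic`, `synonymous`,
#'   `nonsynonymous` per SNP.
#' @param nonsense logical; premature-stop changes (always treated as
#'   functional downstream).
#' @param polyphen one of `benign`, `possibly_damaging`, `probably_damaging`,
#'   `none`.
#' @param sift one of `tolerant`, `intolerant`, `none`.
#' @param delta_score optional nonnegative PolyPhen delta score (`NA` allowed).
#' @return a `data.frame` of class `variant_annotation`.
#' @export
variant_annotation <- function(snp_id, fragment_id, gene_id = NA_character_,
                               site_class, nonsense = FALSE,
                               polyphen = "none", sift = "none",
                               delta_score = NA_real_) {
  n <- length(snp_id)
  df <- data.frame(
    snp_id = as.character(snp_id),
    fragment_id = as.character(rep_len(fragment_id, n)),
    gene_id = as.character(rep_len(gene_id, n)),
    site_class = rep_len(as.character(site_class), n),
    nonsense = rep_len(as.logical(nonsense), n),
    polyphen = rep_len(as.character(polyphen), n),
    sift = rep_len(as.character(sift), n),
    delta_score = rep_len(as.numeric(delta_score), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$snp_id)) stop("duplicated snp_id in annotation")
  ok_class <- c("intergenic", "intronic", "synonymous", "nonsynonymous")
  if (!all(df$site_class %in% ok_class))
    stop("site_class must be one of ", paste(ok_class, collapse = ", "))
  if (!all(df$polyphen %in% c("benign", "possibly_damaging",
                              "probably_damaging", "none")))
    stop("invalid polyphen category")
  if (!all(df$sift %in% c("tolerant", "intolerant", "none")))
    stop("invalid sift category")
  pred <- df$polyphen != "none" | df$sift != "none"
  if (any(pred & df$site_class != "nonsynonymous"))
    stop("prediction categories require site_class = nonsynonymous")
  if (any(!is.na(df$delta_score) & df$delta_score < 0))
    stop("delta_score must be >= 0")
  class(df) <- c("variant_annotation", "data.frame")
  df
}

#' Read a variant annotation table from TSV
#'
#' Expected columns: snp_id, fragment_id, gene_id, site_class, nonsense,
#' polyphen, sift, delta_score.
#' @param path file path.
#' @return a [variant_annotation()].
#' @export
read_annotations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("snp_id", "fragment_id", "site_class")
  if (!all(need %in% colnames(tab)))
    stop("annotation TSV must contain columns: ",
         paste(need, collapse = ", "))
  variant_annotation(
    snp_id = tab$snp_id, fragment_id = tab$fragment_id,
    gene_id = if ("gene_id" %in% names(tab)) tab$gene_id else NA,
    site_class = tab$site_class,
    nonsense = if ("nonsense" %in% names(tab)) as.logical(tab$nonsense) else FALSE,
    polyphen = if ("polyphen" %in% names(tab)) ifelse(is.na(tab$polyphen), "none", tab$polyphen) else "none",
    sift = if ("sift" %in% names(tab)) ifelse(is.na(tab$sift), "none", tab$sift) else "none",
    delta_score = if ("delta_score" %in% names(tab)) tab$delta_score else NA
  )
}

#' Read an a priori candidate gene list
#'
#' One gene identifier per line; duplicates are collapsed.
#' @param path file path.
#' @param source_label free-text provenance label stored on the result.
#' @return character vector of unique gene ids with attribute `source`.
#' @export
read_candidate_genes <- function(path, source_label = basename(path)) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- unique(ids[nzchar(ids)])
  structure(ids, source = source_label)
}
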