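#' The 18-gene T-cell-inflamed gene expression profile
#'
#' Gene symbols of the pan-tumor T-cell-inflamed GEP signature covering
#' antigen presentation, chemokine expression, cytolytic activity and
#' adaptive immune resistance. `TIGIT` is the canonical symbol; the
#' variant spelling `TIGTT` occasionally seen in print is accepted on
#' input.
#' @format character vector of 18 gene symbols.
#' @export
gep_genes <- c("CCL5", "CD27", "CD274", "CD276", "CD8A", "CMKLR1", "CXCL9",
               "CXCR6", "HLA-DQA1", "HLA-DRB1", "HLA-E", "IDO1", "LAG3",
               "NKG7", "PDCD1LG2", "PSMB10", "STAT1", "TIGIT")

# map matrix columns to requested symbols, accepting TIGTT for TIGIT
match_signature_genes <- function(x, genes) {
  cols <- colnames(x)
  idx <- match(genes, cols)
  tig <- which(genes == "TIGIT" & is.na(idx))
  if (length(tig) > 0) idx[tig] <- match("TIGTT", cols)
  alt <- which(genes == "TIGTT" & is.na(idx))
  if (length(alt) > 0) idx[alt] <- match("TIGIT", cols)
  idx
}

zscore_cols <- function(x) {
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  sweep(sweep(x, 2, colMeans(x)), 2, scl, `/`)
}

#' T-cell-inflamed GEP score
#'
#' Weighted sum of per-gene z-scores (z computed across samples within the
#' cohort). Default weights are all 1; the originally published weights
#' can be supplied instead.
#'
#' @param x expression matrix (samples x genes, log-scale normalised).
#' @param genes signature genes (default [gep_genes]).
#' @param weights per-gene weights aligned with `genes` (default 1).
#' @param allow_missing drop absent genes with a warning instead of
#'   erroring.
#' @return per-sample numeric score.
#' @export
gep_score <- function(x, genes = gep_genes, weights = NULL,
                      allow_missing = FALSE) {
  x <- as.matrix(x)
  if (is.null(weights)) weights <- rep(1, length(genes))
  stopifnot(length(weights) == length(genes))
  idx <- match_signature_genes(x, genes)
  if (any(is.na(idx))) {
    miss <- genes[is.na(idx)]
    if (!allow_missing)
      stop("missing signature genes: ", paste(miss, collapse = ", "))
    warning("dropping missing signature genes: ", paste(miss, collapse = ", "))
    weights <- weights[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  z <- zscore_cols(x[, idx, drop = FALSE])
  drop(z %*% weights)
}

#' Thyroid differentiation score and its reporting bins
#'
#' The TDS is the mean z-score over a configured list of thyroid-function
#' genes (the 16-gene list lives in the TCGA reference and is supplied by
#' the caller, not hard-coded). `bin_tds` applies the reporting bins
#' `"< -1"`, `"-1 to 0"`, `"> 0"`; the boundary values -1 and 0 both fall
#' in the middle bin.
#'
#' @param x expression matrix (samples x genes).
#' @param genes thyroid-function gene ids.
#' @return `tds_score`: per-sample numeric score. `bin_tds`: factor over
#'   the three bins.
#' @export
tds_score <- function(x, genes) {
  if (length(genes) == 0) stop("empty signature")
  x <- as.matrix(x)
  idx <- match_signature_genes(x, genes)
  if (any(is.na(idx)))
    stop("missing signature genes: ", paste(genes[is.na(idx)], collapse = ", "))
  rowMeans(zscore_cols(x[, idx, drop = FALSE]))
}

#' @rdname tds_score
#' @param score numeric TDS values.
#' @export
bin_tds <- function(score) {
  cut(score, breaks = c(-Inf, -1, 0, Inf),
      labels = c("< -1", "-1 to 0", "> 0"),
      right = FALSE, include.lowest = TRUE) -> b
  # cut(right = FALSE) puts -1 in the middle bin but 0 in the upper one;
  # the convention here sends both boundaries to the middle bin
  b[score == 0] <- "-1 to 0"
  b
}

#' BRAF-RAS score and class
#'
#' Similarity of a sample's profile to RAS-mutant vs BRAF-V600E-mutant
#' expression centroids: `(cor(sample, ras) - cor(sample, braf)) / 2`,
#' bounded in [-1, 1]. Positive scores are RAS-like; ties (score 0) are
#' classified BRAF-like.
#'
#' @param x expression matrix (samples x genes) covering the centroid
#'   genes.
#' @param braf_centroid,ras_centroid named numeric centroid profiles over
#'   the BRS genes (supplied via configuration; they come from the TCGA
#'   reference, not this package).
#' @return `brs_score`: per-sample numeric score in [-1, 1].
#'   `classify_brs`: factor with levels "BRAF-like", "RAS-like".
#' @export
brs_score <- function(x, braf_centroid, ras_centroid) {
  x <- as.matrix(x)
  stopifnot(!is.null(names(braf_centroid)),
            identical(names(braf_centroid), names(ras_centroid)))
  if (stats::sd(braf_centroid) < 1e-12 || stats::sd(ras_centroid) < 1e-12)
    stop("degenerate centroid (zero variance)")
  idx <- match_signature_genes(x, names(braf_centroid))
  if (any(is.na(idx)))
    stop("missing BRS genes: ",
         paste(names(braf_centroid)[is.na(idx)], collapse = ", "))
  sub <- x[, idx, drop = FALSE]
  (apply(sub, 1, stats::cor, y = ras_centroid) -
     apply(sub, 1, stats::cor, y = braf_centroid)) / 2
}

#' @rdname brs_score
#' @param score numeric BRS values.
#' @export
classify_brs <- function(score) {
  factor(ifelse(score > 0, "RAS-like", "BRAF-like"),
         levels = c("BRAF-like", "RAS-like"))
}

#' Read or write a gene-signature JSON description
#'
#' Schema: `{name, aggregation, genes: [{id, weight}, ...]}`.
#'
#' @param path JSON file path.
#' @return list with `name`, `aggregation`, `gene_ids`, `weights`.
#' @export
read_signature_json <- function(path) {
  s <- jsonlite::fromJSON(path)
  list(name = s$name, aggregation = s$aggregation,
       gene_ids = s$genes$id, weights = s$genes$weight)
}

#' @rdname read_signature_json
#' @param signature list as returned by [read_signature_json()].
#' @export
write_signature_json <- function(signature, path) {
  jsonlite::write_json(
    list(name = signature$name, aggregation = signature$aggregation,
         genes = data.frame(id = signature$gene_ids,
                            weight = signature$weights)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
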