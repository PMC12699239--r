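#' Extract a samples x assays slice from an expression container
#'
#' @param x a \linkS4class{MiRExperiment}.
#' @param assays assay ids to keep (default: all).
#' @return numeric matrix, samples in rows.
#' @export
expressionSlice <- function(x, assays = rownames(x)) {
    missing <- setdiff(assays, rownames(x))
    if (length(missing))
        stop("assay(s) not in the matrix: ",
             paste(missing, collapse = ", "))
    t(relExpr(x)[assays, , drop = FALSE])
}

#' Impute missing entries with per-assay means
#'
#' Undetected wells are replaced by the column (assay) mean so that
#' distance-based views can run; an assay missing everywhere cannot be
#' imputed and is an error.
#'
#' @param mat samples x assays numeric matrix.
#' @return matrix without `NA`.
#' @export
imputeAssayMeans <- function(mat) {
    for (j in seq_len(ncol(mat))) {
        miss <- is.na(mat[, j])
        if (all(miss))
            stop("assay ", colnames(mat)[j] %||% j,
                 " is entirely missing; drop it before embedding")
        mat[miss, j] <- mean(mat[!miss, j])
    }
    mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal component embedding of samples
#'
#' PCA of the (typically significant-assay) expression slice on the log2
#' scale convention of heatmaps: each assay is centered and, by default,
#' z-scaled before projecting samples onto the leading eigenvectors of the
#' covariance. Missing entries are imputed with assay means first.
#'
#' @param mat samples x assays numeric matrix (e.g. from
#'   [expressionSlice()], usually after `log2`).
#' @param nComponents components to retain (default 2); at most
#'   `min(nrow - 1, ncol)`.
#' @param scale z-scale each assay (default `TRUE`).
#' @return an \linkS4class{EmbeddingResult}; `explainedVariance` covers all
#'   components and sums to 1.
#' @export
pcaEmbed <- function(mat, nComponents = 2L, scale = TRUE) {
    mat <- imputeAssayMeans(as.matrix(mat))
    vars <- apply(mat, 2L, var)
    if (all(vars == 0))
        stop("matrix has zero variance; nothing to embed")
    if (scale && any(vars == 0))
        mat <- mat[, vars > 0, drop = FALSE]
    nComponents <- as.integer(nComponents)
    stopifnot(nComponents >= 1L,
              nComponents <= min(nrow(mat) - 1L, ncol(mat)))
    pc <- prcomp(mat, center = TRUE, scale. = scale)
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    new("EmbeddingResult",
        sampleIds = rownames(mat) %||% as.character(seq_len(nrow(mat))),
        coordinates = pc$x[, seq_len(nComponents), drop = FALSE],
        explainedVariance = ev)
}

setMethod("show", "EmbeddingResult", function(object) {
    k <- ncol(object@coordinates)
    cat(sprintf("EmbeddingResult: %d samples, %d components (%s)\n",
                length(object@sampleIds), k,
                paste(sprintf("PC%d %.1f%%", seq_len(k),
                              100 * object@explainedVariance[seq_len(k)]),
                      collapse = ", ")))
})

#' Agglomerative hierarchical clustering of samples
#'
#' Standard bottom-up clustering over a Euclidean or correlation
#' (1 - Pearson) distance, with average (default), complete, or Ward
#' linkage — the usual heatmap companion view. Missing entries are imputed
#' with assay means; a non-finite distance is reported with the offending
#' sample pair.
#'
#' @param mat samples x assays numeric matrix.
#' @param metric `"euclidean"` or `"correlation"`.
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward.D2).
#' @param scale z-scale each assay first (default `TRUE`, matching
#'   [pcaEmbed()]).
#' @return an [stats::hclust] merge tree over the samples.
#' @export
hierarchicalCluster <- function(mat,
                                metric = c("euclidean", "correlation"),
                                linkage = c("average", "complete", "ward"),
                                scale = TRUE) {
    metric <- match.arg(metric)
    linkage <- match.arg(linkage)
    mat <- imputeAssayMeans(as.matrix(mat))
    stopifnot(nrow(mat) >= 2L)
    if (scale) {
        vars <- apply(mat, 2L, var)
        mat <- mat[, vars > 0, drop = FALSE]
        mat <- base::scale(mat)
    }
    d <- if (metric == "euclidean") dist(mat)
         else as.dist(1 - cor(t(mat)))
    if (any(!is.finite(d))) {
        dm <- as.matrix(d)
        bad <- which(!is.finite(dm), arr.ind = TRUE)[1L, ]
        stop("non-finite distance between samples ",
             rownames(dm)[bad[1L]] %||% bad[1L], " and ",
             colnames(dm)[bad[2L]] %||% bad[2L])
    }
    hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
}

#' Write a sample dendrogram as Newick
#'
#' @param hc an [stats::hclust] tree (e.g. from [hierarchicalCluster()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(hc, path) {
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}
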