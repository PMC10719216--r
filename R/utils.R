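# Internal helpers shared across modules.

# Coerce a SingleCellExperiment (genes x cells) or a plain cells x genes
# matrix into the (X, y) pair the model layer works with. For an SCE the
# preferred assay is "scaled" (post-preprocessing), falling back to the
# first assay; labels come from colData(x)$cell_type.
.xy <- function(x, labels = NULL, assay_name = NULL) {
    if (methods::is(x, "SummarizedExperiment")) {
        an <- assay_name
        if (is.null(an))
            an <- if ("scaled" %in% assayNames(x)) "scaled" else assayNames(x)[1L]
        X <- t(as.matrix(assay(x, an)))
        if (is.null(labels)) {
            if (!"cell_type" %in% colnames(colData(x)))
                stop("no 'cell_type' column in colData and no labels supplied")
            labels <- colData(x)$cell_type
        }
    } else {
        X <- as.matrix(x)
        if (is.null(rownames(X)) && nrow(X) > 0L)
            rownames(X) <- paste0("cell", seq_len(nrow(X)))
        if (is.null(colnames(X)) && ncol(X) > 0L)
            colnames(X) <- paste0("gene", seq_len(ncol(X)))
    }
    if (!is.null(labels)) labels <- as.character(labels)
    list(X = X, y = labels)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream; `seed = NULL` leaves the current stream untouched.
.with_seed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    withr::with_seed(as.integer(seed), expr)
}

.assert_fraction <- function(x, name, ge = 0, lt = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < ge || x >= lt)
        stop(sprintf("'%s' must be a number in [%g, %g)", name, ge, lt),
             call. = FALSE)
    invisible(x)
}

.one_hot <- function(y, classes) {
    idx <- match(y, classes)
    if (anyNA(idx))
        stop("labels contain classes unknown to the model: ",
             paste(unique(y[is.na(idx)]), collapse = ", "), call. = FALSE)
    Y <- matrix(0, length(y), length(classes))
    Y[cbind(seq_along(y), idx)] <- 1
    Y
}

# Row-wise k-nearest-neighbour index sets under Euclidean distance,
# computed with the Gram-matrix expansion so BLAS does the heavy lifting.
# Self is excluded. Returns an n x k integer matrix.
.knn_indices <- function(X, k) {
    n <- nrow(X)
    if (k <= 0L) stop("'k' must be a positive integer", call. = FALSE)
    if (k >= n) stop("'k' must be smaller than the number of cells", call. = FALSE)
    sq <- rowSums(X^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
    diag(D2) <- Inf
    t(apply(D2, 1L, function(d) order(d)[seq_len(k)]))
}
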