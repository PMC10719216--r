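#' Depth-normalize, log-transform and per-gene scale expression counts
#'
#' The three standard steps in the standard order: counts are scaled per
#' cell to the median sequencing depth, \code{log1p}-transformed, and then
#' each gene is centered and scaled to unit variance. Genes with zero
#' variance are left at zero after centering and flagged in the report.
#'
#' When a \code{fit} from a previous call is supplied, its median depth
#' and per-gene center/scale are applied unchanged. This is how test data
#' must be normalized: parameters are estimated on the training split
#' only, so there is no information leakage (and test-set gene means need
#' not be zero).
#'
#' @param x a \code{SingleCellExperiment} carrying a \code{"counts"}
#'   assay, or a non-negative cells x genes matrix.
#' @param fit optional normalization parameters returned by an earlier
#'   call (element \code{fit} of the result).
#' @return list with elements \code{data} (the input with a
#'   \code{"scaled"} assay added, or a plain matrix if a matrix came in),
#'   \code{report} (genes total/flagged, per-gene center and scale,
#'   median depth) and \code{fit} (the reusable parameters).
#' @examples
#' sce <- simulateDataset(simConfig(n_cells = 60, n_genes = 30, n_types = 3,
#'                                  n_key_genes = 6))
#' norm <- normalizeLogScale(sce)
#' range(rowMeans(SummarizedExperiment::assay(norm$data, "scaled")))
#' @export
normalizeLogScale <- function(x, fit = NULL) {
    is_sce <- methods::is(x, "SummarizedExperiment")
    counts <- if (is_sce) t(as.matrix(assay(x, "counts"))) else as.matrix(x)
    if (any(counts < 0))
        stop("counts must be non-negative", call. = FALSE)

    depth <- rowSums(counts)
    depth[depth == 0] <- 1  # empty cells stay all-zero after scaling
    med <- if (is.null(fit)) stats::median(rowSums(counts)) else fit$depth_median
    logn <- log1p(counts / depth * med)

    if (is.null(fit)) {
        center <- colMeans(logn)
        scale_ <- apply(logn, 2L, stats::sd)
    } else {
        center <- fit$center
        scale_ <- fit$scale
    }
    zero_var <- !is.finite(scale_) | scale_ < .Machine$double.eps^0.5
    safe_scale <- ifelse(zero_var, 1, scale_)
    scaled <- sweep(sweep(logn, 2L, center), 2L, safe_scale, "/")
    scaled[, zero_var] <- 0

    fit_out <- list(depth_median = med, center = center, scale = scale_,
                    zero_variance = zero_var)
    report <- list(n_genes = ncol(counts),
                   n_zero_variance = sum(zero_var),
                   zero_variance_genes = colnames(counts)[zero_var],
                   depth_median = med,
                   center = center, scale = scale_)
    if (is_sce) {
        assay(x, "scaled") <- t(scaled)
        list(data = x, report = report, fit = fit_out)
    } else {
        list(data = scaled, report = report, fit = fit_out)
    }
}

#' Select highly variable genes after a minimum-count filter
#'
#' Genes with fewer than \code{min_counts} total counts are removed first;
#' the survivors are ranked by dispersion (variance over mean of the
#' \code{log1p} depth-normalized values) and the top \code{n_top} are
#' retained. The filter precedes the ranking, so a highly dispersed gene
#' below the count threshold is never kept. Ties at the boundary are
#' broken by input gene order, and the retained genes keep their input
#' order. If fewer than \code{n_top} genes qualify, all of them are kept
#' with a warning.
#'
#' @param x a \code{SingleCellExperiment} with a \code{"counts"} assay or
#'   a cells x genes count matrix.
#' @param n_top number of genes to retain (default 2500).
#' @param min_counts minimum total expressed counts per gene (default 30).
#' @return list with \code{data} (the input restricted to the retained
#'   genes) and \code{report} (counts of genes passing the filter and
#'   retained, plus the retained index).
#' @examples
#' sce <- simulateDataset(simConfig(n_cells = 60, n_genes = 50, n_types = 3,
#'                                  n_key_genes = 6))
#' sel <- selectHVG(sce, n_top = 10, min_counts = 5)
#' sel$report$n_retained
#' @export
selectHVG <- function(x, n_top = 2500L, min_counts = 30L) {
    if (!is.numeric(n_top) || n_top <= 0)
        stop("'n_top' must be a positive integer", call. = FALSE)
    is_sce <- methods::is(x, "SummarizedExperiment")
    counts <- if (is_sce) t(as.matrix(assay(x, "counts"))) else as.matrix(x)

    totals <- colSums(counts)
    passing <- which(totals >= min_counts)
    if (length(passing) == 0L)
        stop("no gene reaches 'min_counts' total counts", call. = FALSE)

    depth <- rowSums(counts)
    depth[depth == 0] <- 1
    logn <- log1p(counts / depth * stats::median(rowSums(counts)))
    m <- colMeans(logn[, passing, drop = FALSE])
    v <- apply(logn[, passing, drop = FALSE], 2L, stats::var)
    dispersion <- ifelse(m > 0, v / m, 0)

    n_keep <- min(as.integer(n_top), length(passing))
    if (n_keep < n_top)
        warning(sprintf("only %d genes pass the count filter; keeping all of them",
                        length(passing)), call. = FALSE)
    ranked <- passing[order(-dispersion, seq_along(dispersion))]
    retained <- sort(ranked[seq_len(n_keep)])  # input order preserved

    report <- list(n_genes = ncol(counts),
                   n_passing = length(passing),
                   n_retained = n_keep,
                   retained_index = retained,
                   retained_genes = colnames(counts)[retained],
                   dispersion = stats::setNames(dispersion,
                                                colnames(counts)[passing]))
    data <- if (is_sce) x[retained, ] else counts[, retained, drop = FALSE]
    list(data = data, report = report)
}

#' Stratified train/test split
#'
#' Partitions the cells into disjoint, exhaustive train and test sets,
#' stratified by cell type so every type appears in both partitions with
#' (to within one cell) the requested proportion.
#'
#' @param x a labeled dataset (SingleCellExperiment with
#'   \code{colData(x)$cell_type}).
#' @param train_fraction fraction of each type assigned to training,
#'   strictly between 0 and 1 (default 0.8).
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test}.
#' @examples
#' sce <- simulateDataset(simConfig(n_cells = 60, n_genes = 30, n_types = 3,
#'                                  n_key_genes = 6))
#' sp <- splitTrainTest(sce, 0.8, seed = 1)
#' c(ncol(sp$train), ncol(sp$test))
#' @export
splitTrainTest <- function(x, train_fraction = 0.8, seed = 1L) {
    if (!is.numeric(train_fraction) || train_fraction <= 0 ||
        train_fraction >= 1)
        stop("'train_fraction' must lie strictly between 0 and 1",
             call. = FALSE)
    labels <- as.character(colData(x)$cell_type)
    sizes <- table(labels)
    if (any(sizes < 2L))
        stop("every cell type needs at least 2 cells to stratify: ",
             paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
    train_idx <- .with_seed(seed, {
        unlist(lapply(unique(labels), function(tp) {
            idx <- which(labels == tp)
            n_train <- round(train_fraction * length(idx))
            n_train <- max(1L, min(length(idx) - 1L, n_train))
            sample(idx, n_train)
        }), use.names = FALSE)
    })
    train_idx <- sort(train_idx)
    list(train = x[, train_idx],
         test = x[, setdiff(seq_len(ncol(x)), train_idx)])
}
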