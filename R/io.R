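# Shared readers, writers and configuration handling.

#' Write a labeled expression matrix to disk
#'
#' Two plain-text layouts are supported. \code{"mtx"} writes the counts
#' as Matrix Market coordinate format with cells in rows and 1-based
#' indices (\code{matrix.mtx}) plus \code{genes.tsv} and
#' \code{cells.tsv} index files; \code{"tsv"} writes a dense table with a
#' header row of gene ids and the cell id as first column
#' (\code{matrix.tsv}). Cell labels go to \code{labels.tsv}
#' (cell id TAB cell type) and, when present, the key-gene truth to
#' \code{key_genes.tsv} (gene TAB cell type).
#'
#' @param x a labeled \code{SingleCellExperiment} (assay
#'   \code{"counts"}).
#' @param dir output directory, created if needed.
#' @param format \code{"mtx"} (sparse) or \code{"tsv"} (dense).
#' @return \code{dir}, invisibly.
#' @export
writeExpressionMatrix <- function(x, dir, format = c("mtx", "tsv")) {
    format <- match.arg(format)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    counts <- t(as.matrix(assay(x, "counts")))  # cells in rows
    if (format == "mtx") {
        Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"),
                        file.path(dir, "matrix.mtx"))
        writeLines(colnames(counts), file.path(dir, "genes.tsv"))
        writeLines(rownames(counts), file.path(dir, "cells.tsv"))
    } else {
        df <- data.frame(cell_id = rownames(counts), counts,
                         check.names = FALSE)
        utils::write.table(df, file.path(dir, "matrix.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    utils::write.table(
        data.frame(cell_id = colnames(x),
                   cell_type = colData(x)$cell_type),
        file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    kg <- metadata(x)$key_genes
    if (!is.null(kg))
        utils::write.table(as.data.frame(kg),
                           file.path(dir, "key_genes.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Read a labeled expression matrix from disk
#'
#' Reads the layouts produced by [writeExpressionMatrix()]. Dimension
#' mismatches between the matrix and its index files raise a format error
#' stating both sizes; negative counts are rejected.
#'
#' @param dir directory holding \code{matrix.mtx} + index files or
#'   \code{matrix.tsv}, plus \code{labels.tsv} and optionally
#'   \code{key_genes.tsv}.
#' @return a labeled \code{SingleCellExperiment}.
#' @export
readExpressionMatrix <- function(dir) {
    mtx <- file.path(dir, "matrix.mtx")
    if (file.exists(mtx)) {
        counts <- withCallingHandlers(
            tryCatch(as.matrix(Matrix::readMM(mtx)),
                error = function(e) stop(sprintf(
                    "malformed Matrix Market file '%s': %s", mtx,
                    conditionMessage(e)), call. = FALSE)),
            # readMM only warns when the declared entry count disagrees
            # with the file body; treat that as a format error
            warning = function(w) stop(sprintf(
                "malformed Matrix Market file '%s': %s", mtx,
                conditionMessage(w)), call. = FALSE))
        genes <- readLines(file.path(dir, "genes.tsv"))
        cells <- readLines(file.path(dir, "cells.tsv"))
        if (ncol(counts) != length(genes))
            stop(sprintf("matrix has %d gene columns but genes.tsv lists %d",
                         ncol(counts), length(genes)), call. = FALSE)
        if (nrow(counts) != length(cells))
            stop(sprintf("matrix has %d cell rows but cells.tsv lists %d",
                         nrow(counts), length(cells)), call. = FALSE)
        dimnames(counts) <- list(cells, genes)
    } else {
        df <- utils::read.table(file.path(dir, "matrix.tsv"), sep = "\t",
                                header = TRUE, check.names = FALSE)
        counts <- as.matrix(df[, -1L, drop = FALSE])
        rownames(counts) <- df[[1L]]
    }
    if (any(counts < 0))
        stop("negative counts are not valid raw expression values",
             call. = FALSE)
    lab <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                             header = TRUE)
    if (!identical(as.character(lab$cell_id), rownames(counts)))
        stop("labels.tsv cell ids do not match the matrix rows",
             call. = FALSE)
    sce <- SingleCellExperiment(
        assays = list(counts = t(counts)),
        colData = S4Vectors::DataFrame(cell_type = lab$cell_type,
                                       row.names = lab$cell_id))
    kg_path <- file.path(dir, "key_genes.tsv")
    if (file.exists(kg_path)) {
        kg <- utils::read.table(kg_path, sep = "\t", header = TRUE)
        metadata(sce)$key_genes <- S4Vectors::DataFrame(kg)
    }
    sce
}

# Nested default experiment configuration; the single source of truth
# for what runFullExperiment does.
.default_config <- function() {
    list(
        seed = 1L,
        out_dir = NULL,
        simdata = list(n_cells = 2700L, n_genes = 1200L, n_types = 9L,
                       n_key_genes = 65L, baseline_mean = 2,
                       fold_elevation = 5, propagation_strength = 0.5,
                       nb_dispersion = 2, dropout_rate = 0.1,
                       targets_per_regulator = 5L),
        imbalance = list(enabled = FALSE, types = NULL, fraction = 0.8),
        preprocess = list(hvg = FALSE, n_top = 2500L, min_counts = 30L,
                          train_fraction = 0.8),
        classifier = list(hidden = c(256L, 128L), epochs = 30L,
                          batch_size = 64L, learning_rate = 1e-3),
        attacks = list(method = "fgsm", epsilon = 1.2, n_iter = 10L,
                       mode = "static", sweep = TRUE,
                       sweep_grid = seq(0, 3.2, by = 0.4),
                       k_neighbors = 15L),
        interpret = list(methods = c("saliency", "actmax", "deeplift",
                                     "expgrad", "kernelshap", "lime"),
                         cells_per_type = 5L, n_baseline_samples = 25L),
        consensus = list(n_top = 20L, overlap_top = 100L)
    )
}

.merge_config <- function(defaults, user, path = "") {
    for (key in names(user)) {
        full <- if (nzchar(path)) paste0(path, ".", key) else key
        if (!key %in% names(defaults))
            stop("unknown configuration key: ", full, call. = FALSE)
        if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
            if (!is.list(user[[key]]))
                stop("configuration key '", full, "' must be a section",
                     call. = FALSE)
            defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                             full)
        } else {
            defaults[key] <- list(user[[key]])  # preserves NULL values
        }
    }
    defaults
}

.validate_config <- function(cfg) {
    do.call(simConfig, c(cfg$simdata, list(seed = cfg$seed)))  # validates
    .assert_fraction(cfg$preprocess$train_fraction, "preprocess.train_fraction",
                     ge = 1e-9)
    if (cfg$preprocess$train_fraction <= 0 || cfg$preprocess$train_fraction >= 1)
        stop("preprocess.train_fraction must be in (0, 1)", call. = FALSE)
    if (!cfg$attacks$method %in% c("fgsm", "pgd"))
        stop("attacks.method must be 'fgsm' or 'pgd'", call. = FALSE)
    if (cfg$attacks$epsilon < 0)
        stop("attacks.epsilon must be >= 0", call. = FALSE)
    if (cfg$imbalance$enabled &&
        !(cfg$imbalance$fraction >= 0 && cfg$imbalance$fraction <= 1))
        stop("imbalance.fraction must lie in [0, 1]", call. = FALSE)
    bad <- setdiff(cfg$interpret$methods,
                   c("saliency", "actmax", "deeplift", "expgrad",
                     "kernelshap", "lime"))
    if (length(bad))
        stop("unknown attribution method(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    cfg
}

#' Experiment configuration
#'
#' \code{experimentConfig} builds the full nested configuration of
#' [runFullExperiment()], overriding defaults with any named sections
#' supplied; \code{loadExperimentConfig} reads overrides from a YAML or
#' JSON file. Unknown keys are rejected rather than ignored, and invalid
#' values raise an error naming the field. An empty file yields the
#' documented defaults.
#'
#' @param ... named configuration sections (\code{simdata},
#'   \code{preprocess}, \code{classifier}, \code{attacks},
#'   \code{interpret}, \code{consensus}, \code{imbalance}) or top-level
#'   scalars (\code{seed}, \code{out_dir}).
#' @return validated nested configuration list of class
#'   \code{ExperimentConfig}.
#' @examples
#' cfg <- experimentConfig(simdata = list(n_cells = 300L, n_genes = 100L,
#'                                        n_types = 3L, n_key_genes = 6L))
#' cfg$simdata$n_cells
#' @export
experimentConfig <- function(...) {
    user <- list(...)
    cfg <- .validate_config(.merge_config(.default_config(), user))
    class(cfg) <- "ExperimentConfig"
    cfg
}

#' @rdname experimentConfig
#' @param path YAML (\code{.yaml}/\code{.yml}) or JSON file of overrides.
#' @export
loadExperimentConfig <- function(path) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else
        yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    do.call(experimentConfig, user)
}

#' @rdname experimentConfig
#' @param config an \code{ExperimentConfig}.
#' @param file output path; format chosen by extension as in
#'   \code{loadExperimentConfig}.
#' @export
writeExperimentConfig <- function(config, file) {
    cfg <- unclass(config)
    if (grepl("\\.json$", file, ignore.case = TRUE))
        jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA,
                             null = "null")
    else
        yaml::write_yaml(cfg, file)
    invisible(file)
}
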