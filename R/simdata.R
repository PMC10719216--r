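#' Simulation configuration
#'
#' Parameters of the ground-truth expression simulator. The defaults match
#' the simulated study design used throughout the package: 2700 cells and
#' 1200 genes over nine cell types with 65 designated key genes.
#'
#' The generator draws steady-state expression rather than integrating
#' regulatory dynamics: each cell type elevates the mean of its key
#' (master-regulator) genes by \code{fold_elevation}, elevation propagates
#' to each regulator's target genes scaled by \code{propagation_strength}
#' and the edge effect, and counts are drawn from a negative binomial with
#' the configured overdispersion followed by Bernoulli dropout.
#'
#' @param n_cells total number of cells, allocated as evenly as possible
#'   across cell types.
#' @param n_genes number of genes.
#' @param n_types number of cell types.
#' @param n_key_genes number of key genes (one defining cell type each),
#'   split as evenly as possible over the types.
#' @param baseline_mean baseline negative-binomial mean count per gene.
#' @param fold_elevation multiplicative elevation (> 1) of a key gene's
#'   mean in its own cell type.
#' @param propagation_strength scaling of the regulatory effect passed
#'   from a key gene to its targets (dimensionless, >= 0).
#' @param nb_dispersion negative-binomial size parameter; smaller values
#'   give more overdispersed counts.
#' @param dropout_rate probability in [0, 1) that any count is zeroed.
#' @param targets_per_regulator number of target genes wired to each key
#'   gene in the default regulatory network.
#' @param seed integer seed making the draw reproducible.
#'
#' @return a validated list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(n_cells = 90, n_genes = 40, n_types = 3, n_key_genes = 6)
#' @export
simConfig <- function(n_cells = 2700L, n_genes = 1200L, n_types = 9L,
                      n_key_genes = 65L, baseline_mean = 2,
                      fold_elevation = 5, propagation_strength = 0.5,
                      nb_dispersion = 2, dropout_rate = 0.1,
                      targets_per_regulator = 5L, seed = 1L) {
    cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                n_types = as.integer(n_types),
                n_key_genes = as.integer(n_key_genes),
                baseline_mean = baseline_mean,
                fold_elevation = fold_elevation,
                propagation_strength = propagation_strength,
                nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
                targets_per_regulator = as.integer(targets_per_regulator),
                seed = as.integer(seed))
    if (cfg$n_key_genes > cfg$n_genes)
        stop("n_key_genes must not exceed n_genes", call. = FALSE)
    if (cfg$n_types < 2L) stop("need at least 2 cell types", call. = FALSE)
    if (cfg$n_cells < cfg$n_types)
        stop("need at least one cell per type", call. = FALSE)
    if (cfg$baseline_mean <= 0) stop("baseline_mean must be > 0", call. = FALSE)
    if (cfg$fold_elevation <= 1) stop("fold_elevation must be > 1", call. = FALSE)
    if (cfg$propagation_strength < 0)
        stop("propagation_strength must be >= 0", call. = FALSE)
    if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
    .assert_fraction(cfg$dropout_rate, "dropout_rate")
    class(cfg) <- "SimConfig"
    cfg
}

#' Default gene regulatory network specification
#'
#' Builds the packaged default regulatory wiring for a configuration: the
#' key genes are split as evenly as possible over the cell types (65 genes
#' over 9 types gives eight types with 7 regulators and one with 9), and
#' each key gene regulates \code{targets_per_regulator} disjoint target
#' genes with effect +1. Remaining genes are unregulated background.
#'
#' @param config a [simConfig()] object.
#' @return a list of class \code{GRNSpec} with elements
#'   \code{regulators_by_type} (list of key-gene indices per type),
#'   \code{edges} (data.frame regulator/target/effect) and
#'   \code{key_genes} (data.frame gene index and cell type).
#' @examples
#' grn <- defaultGRN(simConfig())
#' nrow(grn$key_genes)  # 65
#' @export
defaultGRN <- function(config = simConfig()) {
    nt <- config$n_types
    nk <- config$n_key_genes
    per <- rep(nk %/% nt, nt)
    extra <- nk %% nt
    if (extra > 0L)  # spread the remainder, last type takes what is left
        per[nt] <- per[nt] + extra
    stopifnot(sum(per) == nk)
    tpr <- config$targets_per_regulator
    need <- nk + nk * tpr
    if (need > config$n_genes)
        stop(sprintf(
            "n_genes = %d too small for %d regulators with %d targets each",
            config$n_genes, nk, tpr), call. = FALSE)
    reg_idx <- seq_len(nk)
    types <- rep(seq_len(nt), times = per)
    tgt_idx <- nk + seq_len(nk * tpr)
    edges <- data.frame(
        regulator = rep(reg_idx, each = tpr),
        target    = tgt_idx,
        effect    = 1)
    grn <- list(
        regulators_by_type = split(reg_idx, types),
        edges = edges,
        key_genes = data.frame(gene = reg_idx, cell_type = types))
    class(grn) <- "GRNSpec"
    grn
}

# Closed-form mean count per (gene, type) before dropout. Key genes carry
# the fold elevation in their own type; targets inherit
# propagation_strength * effect * (fold - 1) from elevated parents.
.expected_mu <- function(config, grn) {
    mu <- matrix(config$baseline_mean, config$n_genes, config$n_types)
    fold <- config$fold_elevation
    for (t in seq_len(config$n_types)) {
        regs <- grn$regulators_by_type[[t]]
        mu[regs, t] <- config$baseline_mean * fold
        e <- grn$edges[grn$edges$regulator %in% regs, , drop = FALSE]
        if (nrow(e)) {
            bump <- tapply(e$effect, e$target, sum) *
                config$propagation_strength * (fold - 1)
            idx <- as.integer(names(bump))
            mu[idx, t] <- config$baseline_mean * (1 + as.numeric(bump))
        }
    }
    mu
}

#' Expected expression under the simulator
#'
#' Closed-form expectation of the simulated counts for every (gene, cell
#' type) pair, including the dropout thinning. Used by the package's own
#' calibration checks.
#'
#' @param config a [simConfig()].
#' @param grn a \code{GRNSpec}; defaults to [defaultGRN()] of the config.
#' @return numeric matrix, genes x cell types.
#' @export
expectedExpression <- function(config, grn = defaultGRN(config)) {
    .expected_mu(config, grn) * (1 - config$dropout_rate)
}

#' Simulate a labeled expression dataset with known key genes
#'
#' Draws a cells x genes count matrix with per-cell type labels from the
#' steady-state regulatory model described in [simConfig()], and records
#' the ground-truth key-gene list. The same configuration (including its
#' seed) always reproduces the identical dataset.
#'
#' @param config a [simConfig()].
#' @param grn a \code{GRNSpec} consistent with the configuration; defaults
#'   to [defaultGRN()].
#' @param seed optional integer overriding \code{config$seed}.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   \code{"counts"} (genes x cells), \code{colData(x)$cell_type}, and the
#'   key-gene truth table in \code{metadata(x)$key_genes}
#'   (see [keyGeneTruth()]).
#' @examples
#' sce <- simulateDataset(simConfig(n_cells = 90, n_genes = 60, n_types = 3,
#'                                  n_key_genes = 6))
#' table(SummarizedExperiment::colData(sce)$cell_type)
#' @export
simulateDataset <- function(config = simConfig(), grn = defaultGRN(config),
                            seed = NULL) {
    if (!inherits(config, "SimConfig")) stop("config must be a SimConfig")
    if (!inherits(grn, "GRNSpec")) stop("grn must be a GRNSpec")
    if (length(grn$regulators_by_type) != config$n_types)
        stop("grn has a different number of cell types than the config",
             call. = FALSE)
    all_regs <- unlist(grn$regulators_by_type, use.names = FALSE)
    if (length(all_regs) != config$n_key_genes ||
        anyDuplicated(all_regs) ||
        max(c(all_regs, grn$edges$target, 0L)) > config$n_genes)
        stop("grn is inconsistent with n_genes/n_key_genes", call. = FALSE)
    if (any(!is.finite(grn$edges$effect)))
        stop("grn edge effects must be finite", call. = FALSE)
    if (is.null(seed)) seed <- config$seed

    nt <- config$n_types
    n_per <- rep(config$n_cells %/% nt, nt)
    rem <- config$n_cells %% nt
    if (rem > 0L) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
    type_names <- paste0("type_", seq_len(nt))
    gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
    cell_ids <- sprintf("cell_%04d", seq_len(config$n_cells))
    labels <- rep(type_names, times = n_per)

    mu <- .expected_mu(config, grn)
    counts <- .with_seed(seed, {
        blocks <- lapply(seq_len(nt), function(t) {
            n <- n_per[t]
            m <- matrix(
                stats::rnbinom(n * config$n_genes,
                               mu = rep(mu[, t], each = n),
                               size = config$nb_dispersion),
                nrow = n, ncol = config$n_genes)
            if (config$dropout_rate > 0)
                m <- m * matrix(
                    stats::rbinom(n * config$n_genes, 1L,
                                  1 - config$dropout_rate),
                    nrow = n)
            m
        })
        do.call(rbind, blocks)
    })
    dimnames(counts) <- list(cell_ids, gene_ids)

    truth <- S4Vectors::DataFrame(
        gene = gene_ids[grn$key_genes$gene],
        cell_type = type_names[grn$key_genes$cell_type])
    sce <- SingleCellExperiment(
        assays = list(counts = t(counts)),
        colData = S4Vectors::DataFrame(cell_type = labels,
                                       row.names = cell_ids))
    metadata(sce)$key_genes <- truth
    metadata(sce)$sim_config <- config
    sce
}

#' Ground-truth key genes of a simulated dataset
#'
#' @param x a dataset produced by [simulateDataset()].
#' @return \code{DataFrame} with columns \code{gene} and \code{cell_type}.
#' @export
keyGeneTruth <- function(x) {
    kg <- metadata(x)$key_genes
    if (is.null(kg)) stop("no key-gene truth recorded in metadata(x)")
    kg
}

#' Remove a fraction of cells from selected cell types
#'
#' Emulates class imbalance by downsampling the named cell types:
#' \code{ceiling((1 - fraction) * n)} cells of each named type are kept
#' (so a type is never silently emptied), all other types are untouched,
#' and the relative order of retained cells is preserved.
#'
#' @param x a labeled dataset (SingleCellExperiment with
#'   \code{colData(x)$cell_type}).
#' @param types character vector of cell-type labels to downsample.
#' @param fraction fraction of cells to remove, in [0, 1].
#' @param seed integer seed for the sampling of removed cells.
#' @return the downsampled dataset.
#' @examples
#' sce <- simulateDataset(simConfig(n_cells = 90, n_genes = 40, n_types = 3,
#'                                  n_key_genes = 6))
#' sub <- subsampleCellTypes(sce, "type_1", fraction = 0.8, seed = 7)
#' table(SummarizedExperiment::colData(sub)$cell_type)
#' @export
subsampleCellTypes <- function(x, types, fraction, seed = 1L) {
    if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
        stop("'fraction' must lie in [0, 1]", call. = FALSE)
    labels <- as.character(colData(x)$cell_type)
    unknown <- setdiff(types, unique(labels))
    if (length(unknown))
        stop("unknown cell type(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    if (fraction == 0) return(x)
    keep <- rep(TRUE, ncol(x))
    .with_seed(seed, {
        for (tp in types) {
            idx <- which(labels == tp)
            # epsilon guards against floating-point noise in (1 - fraction)
            n_keep <- as.integer(ceiling((1 - fraction) * length(idx) - 1e-9))
            retained <- if (n_keep == 0L) integer(0) else
                sort(sample(idx, n_keep))
            keep[setdiff(idx, retained)] <- FALSE
        }
    })
    x[, keep]
}
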