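# Consensus voting across attribution methods, key-gene recovery against
# the simulator's ground truth, and the rank-sum DGE baseline.

# Top-n genes of one column of a score matrix; ties broken by input
# (row) order so rankings are deterministic.
.top_genes <- function(scores, type, n) {
    o <- order(-scores[, type], seq_len(nrow(scores)))
    rownames(scores)[o[seq_len(min(n, nrow(scores)))]]
}

#' Consensus importance votes
#'
#' Combines the gene x cell-type score matrices of several attribution
#' methods into a single vote table: the vote of (gene, type) is the
#' number of methods that place the gene among their top \code{n_top}
#' genes for that type. Genes with equal votes are ordered secondarily by
#' their mean max-normalized score across methods.
#'
#' @param attributions list of [AttributionMatrix-class] objects sharing
#'   the same gene and cell-type index.
#' @param n_top the N of the top-N membership rule (default 20).
#' @return a [ConsensusTable-class].
#' @export
consensusImportance <- function(attributions, n_top = 20L) {
    if (!length(attributions))
        stop("need at least one attribution matrix", call. = FALSE)
    mats <- lapply(attributions, attributionScores)
    genes <- rownames(mats[[1L]]); types <- colnames(mats[[1L]])
    for (m in mats)
        if (!identical(rownames(m), genes) || !identical(colnames(m), types))
            stop("attribution matrices must share gene and cell-type indices",
                 call. = FALSE)
    votes <- matrix(0L, length(genes), length(types),
                    dimnames = list(genes, types))
    norm_sum <- matrix(0, length(genes), length(types),
                       dimnames = list(genes, types))
    for (m in mats) {
        for (t in seq_along(types)) {
            top <- .top_genes(m, t, n_top)
            votes[top, t] <- votes[top, t] + 1L
            mx <- max(m[, t])
            norm_sum[, t] <- norm_sum[, t] +
                if (mx > 0) m[, t] / mx else 0
        }
    }
    methods::new("ConsensusTable", votes = votes,
                 meanScore = norm_sum / length(mats),
                 nTop = as.integer(n_top),
                 methods = vapply(attributions, attributionMethod, ""))
}

#' Ranked gene list for one cell type
#'
#' Orders genes for a cell type: for a [ConsensusTable-class] by
#' descending vote, then mean normalized score, then input order; for an
#' [AttributionMatrix-class] by descending score, then input order.
#'
#' @param x a \code{ConsensusTable} or \code{AttributionMatrix}.
#' @param type cell-type name or column position.
#' @return character vector of gene names, most important first.
#' @export
rankedGenes <- function(x, type) {
    if (methods::is(x, "ConsensusTable")) {
        o <- order(-x@votes[, type], -x@meanScore[, type],
                   seq_len(nrow(x@votes)))
        rownames(x@votes)[o]
    } else if (methods::is(x, "AttributionMatrix")) {
        s <- attributionScores(x)
        s[order(-s[, type], seq_len(nrow(s))), type, drop = FALSE]
        rownames(s)[order(-s[, type], seq_len(nrow(s)))]
    } else stop("x must be a ConsensusTable or AttributionMatrix")
}

#' Key-gene recovery against the simulator's ground truth
#'
#' Counts, per cell type, how many of the ground-truth key genes appear
#' among the top \code{n_top} genes of a ranking source (one attribution
#' method or the consensus vote).
#'
#' @param x a [ConsensusTable-class] or [AttributionMatrix-class].
#' @param truth key-gene truth table with columns \code{gene} and
#'   \code{cell_type} (see [keyGeneTruth()]).
#' @param n_top list length considered (default 20).
#' @param condition optional label (e.g. \code{"standard"} or
#'   \code{"adversarial"}) recorded in the report.
#' @return data.frame with one row per cell type: \code{cell_type},
#'   \code{detected}, \code{total}, \code{method}, \code{condition}.
#' @export
keyGeneRecovery <- function(x, truth, n_top = 20L, condition = "standard") {
    truth <- as.data.frame(truth)
    score_mat <- if (methods::is(x, "ConsensusTable")) x@votes else
        attributionScores(x)
    missing <- setdiff(truth$gene, rownames(score_mat))
    if (length(missing))
        stop("truth genes absent from the ranking index: ",
             paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    method <- if (methods::is(x, "ConsensusTable")) "consensus" else
        attributionMethod(x)
    types <- colnames(score_mat)
    rows <- lapply(types, function(tp) {
        key <- truth$gene[truth$cell_type == tp]
        top <- rankedGenes(x, tp)[seq_len(min(n_top, nrow(score_mat)))]
        data.frame(cell_type = tp,
                   detected = length(intersect(top, key)),
                   total = length(key),
                   method = method, condition = condition)
    })
    do.call(rbind, rows)
}

# Vectorized one-vs-rest rank-sum tests for one grouping, matching
# wilcox.test(correct = TRUE, exact = FALSE): normal approximation with
# tie correction and continuity correction.
.ranksum_block <- function(ranks, tie_term, in_group) {
    n <- nrow(ranks)
    n1 <- sum(in_group); n2 <- n - n1
    W <- colSums(ranks[in_group, , drop = FALSE]) - n1 * (n1 + 1) / 2
    z <- W - n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1))))
    zc <- (z - sign(z) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(zc))
    p[sigma == 0] <- 1  # constant gene: every value tied
    p <- pmin(p, 1)
    list(W = W, p = p)
}

#' Wilcoxon rank-sum differential expression, one type vs rest
#'
#' The standard differential-expression baseline: for every cell type,
#' each gene is tested with a two-sided Wilcoxon rank-sum test of that
#' type's cells against all remaining cells, p-values are
#' Benjamini-Hochberg adjusted within the type, and genes with adjusted
#' p < \code{alpha} are flagged significant. Small datasets (at most
#' \code{exact_limit} cells) use [stats::wilcox.test()] directly, with
#' exact p-values where available; larger ones use the identical normal
#' approximation with tie and continuity correction computed from a
#' single ranking per gene.
#'
#' @param x labeled expression data (SCE or cells x genes matrix). Any
#'   per-gene monotone normalization yields identical results.
#' @param labels per-cell labels when \code{x} is a matrix.
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param exact_limit cell-count cutoff below which
#'   [stats::wilcox.test()] is called per gene (default 200).
#' @return data.frame with columns \code{gene}, \code{cell_type},
#'   \code{statistic}, \code{p_value}, \code{p_adjusted},
#'   \code{significant}.
#' @export
wilcoxonDGE <- function(x, labels = NULL, alpha = 0.05, exact_limit = 200L) {
    d <- .xy(x, labels)
    X <- d$X; y <- d$y
    types <- sort(unique(y))
    if (any(table(y) < 2L))
        stop("every cell type needs at least 2 cells", call. = FALSE)
    genes <- colnames(X)
    out <- list()
    if (nrow(X) <= exact_limit) {
        for (tp in types) {
            grp <- y == tp
            res <- lapply(seq_along(genes), function(g) {
                a <- X[grp, g]; b <- X[!grp, g]
                if (stats::sd(c(a, b)) == 0)
                    return(c(length(a) * length(b) / 2, 1))
                wt <- suppressWarnings(stats::wilcox.test(a, b))
                c(unname(wt$statistic), wt$p.value)
            })
            res <- do.call(rbind, res)
            out[[tp]] <- data.frame(gene = genes, cell_type = tp,
                                    statistic = res[, 1L],
                                    p_value = res[, 2L])
        }
    } else {
        ranks <- apply(X, 2L, rank)
        tie_term <- apply(X, 2L, function(v) {
            nt <- table(v); sum(nt^3 - nt)
        })
        for (tp in types) {
            rs <- .ranksum_block(ranks, tie_term, y == tp)
            out[[tp]] <- data.frame(gene = genes, cell_type = tp,
                                    statistic = rs$W, p_value = rs$p)
        }
    }
    res <- do.call(rbind, c(out, make.row.names = FALSE))
    res$p_adjusted <- stats::ave(res$p_value, res$cell_type,
                                 FUN = function(p) stats::p.adjust(p, "BH"))
    res$significant <- res$p_adjusted < alpha
    res
}

#' Overlap between consensus and DGE top genes
#'
#' Compares, per cell type, the top \code{n_top} genes of the consensus
#' ranking with the top \code{n_top} differentially expressed genes
#' (ordered by adjusted then raw p-value).
#'
#' @param consensus a [ConsensusTable-class].
#' @param dge result of [wilcoxonDGE()] on the same gene index.
#' @param n_top list length compared (default 100; must not exceed the
#'   number of genes).
#' @return list with \code{counts} (data.frame: cell_type, overlap,
#'   n_top) and \code{genes} (per type: shared, consensus_only,
#'   dge_only).
#' @export
overlapReport <- function(consensus, dge, n_top = 100L) {
    genes <- rownames(consensus@votes)
    if (n_top > length(genes))
        stop("'n_top' exceeds the number of genes", call. = FALSE)
    types <- colnames(consensus@votes)
    counts <- list(); gene_sets <- list()
    for (tp in types) {
        top_c <- rankedGenes(consensus, tp)[seq_len(n_top)]
        sub <- dge[dge$cell_type == tp, ]
        sub <- sub[order(sub$p_adjusted, sub$p_value,
                         match(sub$gene, genes)), ]
        top_d <- sub$gene[seq_len(n_top)]
        shared <- intersect(top_c, top_d)
        counts[[tp]] <- data.frame(cell_type = tp,
                                   overlap = length(shared), n_top = n_top)
        gene_sets[[tp]] <- list(shared = shared,
                                consensus_only = setdiff(top_c, top_d),
                                dge_only = setdiff(top_d, top_c))
    }
    list(counts = do.call(rbind, c(counts, make.row.names = FALSE)),
         genes = gene_sets)
}
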