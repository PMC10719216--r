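make_attr <- function(scores, method = "m") {
    methods::new("AttributionMatrix", method = method, scores = scores,
                 nCells = rep(1L, ncol(scores)), baseline = "test")
}

rand_scores <- function(g, t, seed) {
    withr::with_seed(seed,
        matrix(runif(g * t), g, t,
               dimnames = list(sprintf("g%02d", seq_len(g)),
                               paste0("t", seq_len(t)))))
}

test_that("votes count top-N membership across methods", {
    g <- 10; scores <- rand_scores(g, 2, 1)
    # make g01 the unanimous top gene and g02 never in any top list
    s1 <- scores; s1["g01", ] <- 10; s1["g02", ] <- -10
    s2 <- s1 + 0.01; s3 <- s1 * 2
    ct <- consensusImportance(list(make_attr(s1, "a"), make_attr(s2, "b"),
                                   make_attr(s3, "c")), n_top = 3)
    expect_equal(unname(consensusVotes(ct)["g01", ]), c(3L, 3L))
    expect_equal(unname(consensusVotes(ct)["g02", ]), c(0L, 0L))
    expect_true(all(consensusVotes(ct) <= 3L))
})

test_that("votes equal brute-force set-membership counting", {
    mats <- lapply(1:3, function(s) rand_scores(30, 3, s))
    ct <- consensusImportance(lapply(seq_along(mats), function(i)
        make_attr(mats[[i]], paste0("m", i))), n_top = 5)
    genes <- rownames(mats[[1]])
    for (t in 1:3) {
        oracle <- rowSums(vapply(mats, function(m) {
            top <- genes[order(-m[, t])[1:5]]
            genes %in% top
        }, logical(30)))
        expect_equal(unname(consensusVotes(ct)[, t]), unname(oracle))
    }
})

test_that("votes are equivariant under method order", {
    attrs <- lapply(1:4, function(s) make_attr(rand_scores(20, 2, s),
                                               paste0("m", s)))
    a <- consensusImportance(attrs, 5)
    b <- consensusImportance(rev(attrs), 5)
    expect_identical(consensusVotes(a), consensusVotes(b))
})

test_that("recovery counts detected key genes per type", {
    scores <- rand_scores(30, 2, 9)
    truth <- data.frame(gene = c("g01", "g02", "g03", "g04"),
                        cell_type = c("t1", "t1", "t2", "t2"))
    # perfect recovery: put the truth genes on top
    s <- scores
    s[c("g01", "g02"), "t1"] <- c(100, 99)
    s[c("g03", "g04"), "t2"] <- c(100, 99)
    rec <- keyGeneRecovery(make_attr(s), truth, n_top = 2)
    expect_equal(rec$detected, rec$total)
    expect_true(all(rec$detected <= pmin(2, rec$total)))
    expect_error(keyGeneRecovery(make_attr(s),
                                 data.frame(gene = "nope", cell_type = "t1"),
                                 2), "absent")
})

test_that("random rankings recover keys at the hypergeometric rate", {
    G <- 40; N <- 10; K <- 4
    truth <- data.frame(gene = sprintf("g%02d", 1:K), cell_type = "t1")
    detected <- vapply(1:200, function(s) {
        keyGeneRecovery(make_attr(rand_scores(G, 1, 100 + s)), truth,
                        n_top = N)$detected
    }, 0L)
    expected <- N * K / G
    se <- sd(detected) / sqrt(length(detected))
    expect_lt(abs(mean(detected) - expected), 4 * se + 0.05)
})

test_that("rank-sum tests on a tiny case match exhaustive enumeration", {
    X <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1, dimnames = list(NULL, "g1"))
    res <- wilcoxonDGE(X, labels = rep(c("a", "b"), each = 3))
    a_row <- res[res$cell_type == "a", ]
    # enumeration oracle: all 20 assignments of ranks 1..6 into two triples
    combos <- combn(6, 3)
    stats <- apply(combos, 2, function(idx) sum(idx) - 3 * 4 / 2)
    observed <- sum(1:3) - 6  # group a holds ranks 1,2,3 -> W = 0
    p_exact <- mean(stats <= observed | stats >= (9 - observed))
    expect_equal(a_row$statistic, observed)
    expect_equal(a_row$p_value, p_exact)  # = 0.1
    expect_equal(a_row$p_value, wilcox.test(1:3, 4:6)$p.value)
})

test_that("the vectorized rank-sum path matches wilcox.test", {
    withr::with_seed(31, {
        X <- matrix(rpois(300 * 4, 5), 300, 4,
                    dimnames = list(NULL, paste0("g", 1:4)))
        y <- sample(rep(c("a", "b", "c"), each = 100))
    })
    res <- wilcoxonDGE(X, y, exact_limit = 10L)  # force the vectorized path
    for (g in paste0("g", 1:4)) {
        wt <- wilcox.test(X[y == "b", g], X[y != "b", g])
        row <- res[res$cell_type == "b" & res$gene == g, ]
        expect_equal(row$statistic, unname(wt$statistic))
        expect_equal(row$p_value, wt$p.value, tolerance = 1e-12)
    }
})

test_that("null data give uniform p-values and calibrated flags", {
    withr::with_seed(32, {
        X <- matrix(rnorm(240 * 50), 240, 50,
                    dimnames = list(NULL, sprintf("g%02d", 1:50)))
        y <- rep(c("a", "b"), each = 120)
    })
    res <- wilcoxonDGE(X, y)
    pa <- res$p_value[res$cell_type == "a"]
    expect_gt(ks.test(pa, "punif")$p.value, 0.01)
    expect_identical(res$significant, res$p_adjusted < 0.05)
    expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
    # constant gene: p = 1 by the tie-handling rule
    Xc <- cbind(X, const = 7)
    resc <- wilcoxonDGE(Xc, y)
    expect_equal(resc$p_value[resc$gene == "const"], c(1, 1))
})

test_that("BH adjustment is applied within each cell type and is monotone", {
    withr::with_seed(33, {
        X <- matrix(rnorm(90 * 6), 90, 6,
                    dimnames = list(NULL, paste0("g", 1:6)))
        X[1:30, 1] <- X[1:30, 1] + 3
    })
    y <- rep(c("a", "b", "c"), each = 30)
    res <- wilcoxonDGE(X, y)
    for (tp in c("a", "b", "c")) {
        sub <- res[res$cell_type == tp, ]
        expect_equal(sub$p_adjusted, p.adjust(sub$p_value, "BH"))
        o <- order(sub$p_value)
        expect_true(all(diff(sub$p_adjusted[o]) >= -1e-12))
    }
})

test_that("overlap reports agree with direct set intersections", {
    scores <- rand_scores(30, 2, 41)
    attrs <- lapply(1:2, function(s) make_attr(rand_scores(30, 2, 50 + s),
                                               paste0("m", s)))
    ct <- consensusImportance(attrs, 10)
    dge <- data.frame(
        gene = rep(rownames(scores), 2),
        cell_type = rep(c("t1", "t2"), each = 30),
        statistic = 1,
        p_value = withr::with_seed(42, runif(60)))
    dge$p_adjusted <- ave(dge$p_value, dge$cell_type,
                          FUN = function(p) p.adjust(p, "BH"))
    dge$significant <- dge$p_adjusted < 0.05
    rep10 <- overlapReport(ct, dge, n_top = 10)
    for (tp in c("t1", "t2")) {
        top_c <- rankedGenes(ct, tp)[1:10]
        sub <- dge[dge$cell_type == tp, ]
        top_d <- sub$gene[order(sub$p_adjusted, sub$p_value)][1:10]
        expect_equal(rep10$counts$overlap[rep10$counts$cell_type == tp],
                     length(intersect(top_c, top_d)))
        expect_setequal(rep10$genes[[tp]]$shared, intersect(top_c, top_d))
    }
    # identical rankings overlap completely
    same <- overlapReport(ct, data.frame(
        gene = rep(rankedGenes(ct, "t1"), 2),
        cell_type = rep(c("t1", "t2"), each = 30),
        statistic = 1, p_value = rep(seq(0, 1, length.out = 30), 2),
        p_adjusted = rep(seq(0, 1, length.out = 30), 2),
        significant = FALSE), n_top = 10)
    expect_equal(same$counts$overlap[same$counts$cell_type == "t1"], 10L)
    expect_error(overlapReport(ct, dge, n_top = 100), "exceeds")
})

test_that("random DGE rankings overlap the consensus at about K^2/G genes", {
    G <- 120; K <- 10
    ct <- consensusImportance(list(make_attr(rand_scores(G, 1, 71))), K)
    overlaps <- vapply(1:200, function(s) {
        p <- withr::with_seed(600 + s, runif(G))
        dge <- data.frame(gene = rownames(consensusVotes(ct)),
                          cell_type = "t1", statistic = 1, p_value = p,
                          p_adjusted = p.adjust(p, "BH"),
                          significant = FALSE)
        overlapReport(ct, dge, n_top = K)$counts$overlap
    }, 0L)
    expect_lt(abs(mean(overlaps) - K^2 / G), 0.2)
})
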