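make_cohort <- function(n_analytes = 30, n_part = 12, shift_tp = NULL,
                        shift_sd = 1, seed = 1) {
    ## null cohort on the log2 scale; optionally shift one timepoint upward
    set.seed(seed)
    tp <- c(0, 30, 60, 120, 240)
    pid <- sprintf("S%02d", seq_len(n_part))
    v <- matrix(rnorm(n_analytes * n_part * 5), n_analytes,
                dimnames = list(sprintf("a%03d", seq_len(n_analytes)),
                                paste0(rep(pid, each = 5), "_t",
                                       rep(tp, n_part))))
    tps <- as.character(rep(tp, n_part))
    if (!is.null(shift_tp)) v[, tps == shift_tp] <- v[, tps == shift_tp] + shift_sd
    OmicsTimeCourse(2^v, "metabolite",
                    participant = rep(pid, each = 5),
                    timestamp_min = rep(tp, n_part), timepoint = tps)
}

test_that("paired Wilcoxon screen flags a planted shift and matches BH step-up", {
    co <- make_cohort(n_analytes = 20, n_part = 28, shift_tp = "60",
                      shift_sd = 1.5, seed = 4)
    res <- wilcoxonVsBaseline(log2Autoscale(co))
    expect_true(all(res$sig_60))
    expect_true(mean(res$sig_120) < 0.2)
    expect_true(all(res$padj_30 >= res$p_30, na.rm = TRUE))
    expect_equal(res$padj_30, bh_oracle(res$p_30))

    ## a timepoint identical to baseline is a non-finding
    v <- omicsValues(co)
    tp <- timepoints(co)
    v[, tp == "240"] <- v[, tp == "0"]
    assay(co, "values") <- v
    res2 <- wilcoxonVsBaseline(log2Autoscale(co))
    expect_true(all(res2$p_240 == 1))
    expect_false(any(res2$sig_240))
})

test_that("vectorized ANOVA equals stats::aov and the permutation test calibrates", {
    co <- make_cohort(n_analytes = 10, seed = 2)
    v <- log2(omicsValues(co))
    tp <- timepoints(co)
    p_pkg <- anovaPerm(co, n_perm = 5, seed = 1)$p
    p_aov <- vapply(seq_len(nrow(v)), function(i)
        summary(aov(v[i, ] ~ factor(tp)))[[1]][["Pr(>F)"]][1], numeric(1))
    ## anovaPerm works on raw assay values; recompute on the same scale
    p_raw <- vapply(seq_len(nrow(v)), function(i)
        summary(aov(omicsValues(co)[i, ] ~ factor(tp)))[[1]][["Pr(>F)"]][1],
        numeric(1))
    expect_equal(unname(p_pkg), p_raw, tolerance = 1e-12)

    ## null cohort: permutation p is not small, fixed seed is reproducible
    con <- make_cohort(n_analytes = 60, n_part = 20, seed = 5)
    a1 <- anovaPerm(con, n_perm = 50, seed = 3)
    a2 <- anovaPerm(con, n_perm = 50, seed = 3)
    expect_identical(a1$perm_p, a2$perm_p)
    expect_gt(a1$perm_p, 0.2)
    expect_gte(a1$perm_p, 1 / 51)
})

test_that("screening is invariant to analyte ordering", {
    co <- make_cohort(n_analytes = 15, shift_tp = "30", seed = 7)
    co_l <- log2Autoscale(co)
    perm <- sample(nrow(co_l))
    r1 <- wilcoxonVsBaseline(co_l)
    r2 <- wilcoxonVsBaseline(co_l[perm, ])
    expect_equal(r2$p_30, r1$p_30[perm])
    a1 <- anovaPerm(co_l, n_perm = 3, seed = 2)
    a2 <- anovaPerm(co_l[perm, ], n_perm = 3, seed = 2)
    expect_equal(unname(a2$p), unname(a1$p[perm]))
})

test_that("fuzzy c-means recovers archetypes, merges duplicates, memberships sum to 1", {
    sh <- simShakeCohort(n_participants = 8, noise_sd = 0, seed = 2,
                         kinetic_speeds = c(fast = 1, slow = 1))
    prof <- shake_profiles(sh$omics)[1:60, ]   # the three planted archetypes
    prof <- t(scale(t(prof)))
    fc <- suppressWarnings(fuzzyCMeans(prof, k_range = 2:8, seed = 1))
    expect_identical(fc$k, 3L)
    expect_equal(ari(fc$cluster, rep(1:3, each = 20)), 1)
    expect_true(all(apply(fc$membership, 1, max) > 0.99))
    expect_equal(unname(rowSums(fc$membership)), rep(1, 60), tolerance = 1e-6)
    expect_true(all(fc$retained))

    ## two identical planted centres are merged and logged
    m2 <- rbind(prof[1:20, ], prof[1:20, ] + matrix(rnorm(100, 0, 1e-5), 20))
    rownames(m2) <- paste0("x", 1:40)
    fc2 <- fuzzyCMeans(m2, k_range = 2:4, seed = 1)
    expect_identical(fc2$k, 1L)
    expect_gt(fc2$k_initial, fc2$k)

    ## k_range truncation warning (6 rows, 3 distinct profiles)
    expect_warning(fc3 <- fuzzyCMeans(prof[c(1, 2, 21, 22, 41, 42), ],
                                      k_range = 2:10, seed = 1), "truncated")
    expect_lte(fc3$k, 3L)
})

test_that("consensus clustering separates planted groups; matrix is well-formed", {
    set.seed(4)
    m <- rbind(matrix(rnorm(14 * 4, 0), 14), matrix(rnorm(14 * 4, 4), 14))
    rownames(m) <- paste0("P", 1:28)
    cc <- consensusCluster(m, k_range = 2:5, n_resample = 200, seed = 2)
    expect_identical(cc$k, 2L)
    expect_equal(ari(cc$groups, rep(1:2, each = 14)), 1)
    expect_true(isSymmetric(cc$consensus))
    expect_equal(unname(diag(cc$consensus)), rep(1, 28))
    off <- cc$consensus[upper.tri(cc$consensus)]
    expect_true(all(off %in% c(0, 1) | off > 0.95 | off < 0.05))

    ## identical participants co-cluster always
    mi <- matrix(1, 12, 3, dimnames = list(paste0("P", 1:12), NULL))
    ci <- consensusCluster(mi, k_range = 2:3, n_resample = 20, seed = 1)
    expect_true(all(ci$consensus == 1))
    expect_error(consensusCluster(m[1:5, ], k_range = 2:6), "participants")
})

test_that("response magnitude separates kinetic groups and handles null groups", {
    sh <- simShakeCohort(n_participants = 10, noise_sd = 0.05, seed = 3)
    co <- sh$omics
    assay(co, "values") <- log2(omicsValues(co))
    grp <- setNames(sh$participant_truth$kinetic_group,
                    sh$participant_truth$participant)
    rm_ <- responseMagnitude(co, grp)
    expect_identical(dim(rm_), c(2L, 4L))
    ## fast kinetics reach their largest mean |change| earlier than slow
    expect_lte(which.max(rm_["fast", ]), which.max(rm_["slow", ]))

    ## zero-response cohort is flat near zero
    nul <- simShakeCohort(n_participants = 10, magnitude = 0, noise_sd = 0.05,
                          seed = 5)
    con <- nul$omics
    assay(con, "values") <- log2(omicsValues(con))
    rn <- responseMagnitude(con, grp)
    expect_lt(max(rn), 0.15)
})

test_that("hypergeometric enrichment equals closed form and brute force", {
    universe <- paste0("g", 1:100)
    set1 <- paste0("g", 1:10)
    hits <- set1
    res <- enrichHypergeometric(hits, universe, list(s1 = set1))
    expect_equal(res$p, 1 / choose(100, 10))

    ## disjoint set: no evidence
    res2 <- enrichHypergeometric(paste0("g", 11:20), universe,
                                 list(s1 = set1))
    expect_gt(res2$p, 0.6)

    ## exhaustive enumeration for a 12-element universe
    uni <- letters[1:12]
    st <- letters[1:4]
    hi <- letters[c(1, 2, 5)]
    obs <- length(intersect(hi, st))
    draws <- combn(12, 3)
    frac <- mean(apply(draws, 2, function(d)
        sum(uni[d] %in% st) >= obs))
    res3 <- enrichHypergeometric(hi, uni, list(s = st))
    expect_equal(res3$p, frac)

    expect_error(enrichHypergeometric(hi, character(), list(s = st)),
                 "empty universe")
    expect_error(enrichHypergeometric(c(hi, "zz"), uni, list(s = st)),
                 "subset")
})
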