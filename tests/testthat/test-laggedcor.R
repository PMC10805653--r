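test_that("alignAtShift matches a hand enumeration and handles edge cases", {
    ## identical grids, tiny window: every point pairs with itself
    s <- list(t = seq(0, 100, 10), v = rnorm(11))
    al <- alignAtShift(s, s, shift = 0, window = 5)
    expect_identical(al$n, 11L)
    expect_equal(al$x, al$y)

    ## toy case: x at 0/60/120, y at 10/70; Ts=0, Tw=30
    ## y@10 window [-5,25) -> x@0; y@70 window [55,85) -> x@60
    x <- list(t = c(0, 60, 120), v = c(1, 2, 3))
    y <- list(t = c(10, 70), v = c(5, 6))
    al2 <- alignAtShift(x, y, shift = 0, window = 30)
    expect_identical(al2$n, 2L)
    expect_equal(al2$x, c(1, 2))
    expect_equal(al2$y, c(5, 6))

    ## several x points in one window are averaged
    x3 <- list(t = c(8, 12), v = c(1, 3))
    y3 <- list(t = c(10), v = c(7))
    expect_equal(alignAtShift(x3, y3, 0, 30)$x, 2)

    ## half-open window: x exactly at the upper edge is excluded
    x4 <- list(t = c(25), v = c(9))
    expect_identical(alignAtShift(x4, y3, 0, 30)$n, 0L)
    expect_identical(alignAtShift(list(t = 0, v = 1), y3, 5000, 30)$n, 0L)
})

test_that("a densely sampled shifted copy is recovered at the planted lag", {
    set.seed(1)
    t5 <- seq(0, 2000, 5)
    base <- as.numeric(stats::filter(rnorm(length(t5) + 40), rep(1, 12),
                                     sides = 1))[-(1:40)]
    x <- list(t = t5, v = base)
    y <- list(t = t5, v = c(base[-(1:2)], base[1:2]))  # y(t) = x(t + 10)...
    ## construct y(t) = x(t - 10): value at index i equals base[i - 2]
    y <- list(t = t5, v = c(base[1:2], base[seq_len(length(t5) - 2)]))
    sc <- laggedCorrelation(x, y, shifts = seq(-60, 60, 5), window = 5,
                            min_pairs = 10)
    ## x leads y, so the pinned sign convention puts the best shift at -10
    expect_lte(abs(bestShift(sc) - (-10)), 5)
    expect_gt(abs(bestCor(sc)), 0.95)

    ## swapping the roles negates the recovered shift
    sc2 <- laggedCorrelation(y, x, shifts = seq(-60, 60, 5), window = 5,
                             min_pairs = 10)
    expect_lte(abs(bestShift(sc2) - 10), 5)

    ## all shifts starved of pairs is an explicit error
    expect_error(laggedCorrelation(list(t = 1:3, v = 1:3), y,
                                   shifts = seq(-60, 60, 5), window = 5),
                 "insufficient overlap")
    expect_error(laggedCorrelation(x, y, shifts = 0:10), "symmetric")
})

test_that("factorial lag sweep recovers every planted shift within one grid step", {
    set.seed(3)
    t5 <- seq(0, 5000, 5)
    n <- length(t5)
    smooth <- function(z) as.numeric(stats::filter(z, rep(1 / 8, 8),
                                                   sides = 2))
    errs <- vapply(c(-60, -30, -10, 0, 10, 30, 60), function(delta) {
        base <- smooth(rnorm(n + 60))
        idx <- seq_len(n) + 30
        x <- base[idx]
        y <- 0.8 * base[idx - delta / 5] + rnorm(n, 0, 0.4 * sd(x, na.rm = TRUE))
        ok <- !is.na(x) & !is.na(y)
        sc <- laggedCorrelation(list(t = t5[ok], v = x[ok]),
                                list(t = t5[ok], v = y[ok]),
                                shifts = seq(-120, 120, 5), window = 5)
        ## y carries x delayed by delta: x leads, convention gives -delta
        abs(bestShift(sc) - (-delta))
    }, numeric(1))
    expect_lte(median(errs), 5)
    expect_lte(max(errs), 10)
})

test_that("independent noise yields weak, low-quality lagged correlations", {
    set.seed(9)
    hits <- replicate(100, {
        x <- list(t = seq(0, 8040, 60), v = rnorm(135))
        y <- list(t = seq(0, 8040, 10), v = rnorm(805))
        sc <- laggedCorrelation(x, y, shifts = seq(-120, 120, 10),
                                window = 10, min_pairs = 10)
        c(abs(bestCor(sc)), qualityScore(sc))
    })
    expect_gte(mean(hits[1, ] < 0.3), 0.95)
    expect_gte(mean(hits[2, ] < 0.5), 0.80)
    expect_lt(quantile(hits[2, ], 0.95), 0.8)
})

test_that("the correlation curve is invariant to monotone transforms", {
    set.seed(5)
    t5 <- seq(0, 2000, 5)
    base <- as.numeric(stats::filter(rnorm(length(t5)), rep(1, 10),
                                     sides = 1))
    ok <- !is.na(base)
    x <- list(t = t5[ok], v = base[ok])
    y <- list(t = t5[ok], v = base[ok] + rnorm(sum(ok), 0, 0.5))
    s1 <- laggedCorrelation(x, y, shifts = seq(-30, 30, 5), window = 5)
    x2 <- list(t = x$t, v = exp(x$v / max(abs(x$v))))
    s2 <- laggedCorrelation(x2, y, shifts = seq(-30, 30, 5), window = 5)
    expect_equal(s2@cor, s1@cor, tolerance = 1e-12)
})

test_that("quality score reads the Gaussianness of the shift curve", {
    sh <- seq(-100, 100, 10)
    gauss <- 0.7 * exp(-(sh - 20)^2 / (2 * 30^2)) + 0.1
    gq <- gaussianCurveQuality(sh, gauss)
    expect_true(gq$converged)
    expect_equal(gq$quality, 1)

    ## offset invariance
    gq2 <- gaussianCurveQuality(sh, gauss + 0.15)
    expect_equal(gq2$quality, gq$quality, tolerance = 1e-6)

    ## flat curves with jitter: quality stays low across seeded nulls
    set.seed(11)
    q_null <- replicate(100,
        gaussianCurveQuality(sh, 0.2 + rnorm(length(sh), 0, 0.01))$quality)
    expect_lt(quantile(q_null, 0.95), 0.8)

    ## too few points: flagged, quality 0
    expect_false(gaussianCurveQuality(sh[1:4], gauss[1:4])$converged)
})

test_that("steps lead HR with a negative best shift (pinned sign convention)", {
    w <- simWearables(days = 2, seed = 5)
    sc <- laggedCorrelation(w$steps, w$HR, shifts = seq(-10, 10, 1),
                            window = 1, min_pairs = 30)
    expect_lt(bestShift(sc), 0)
    expect_lte(abs(bestShift(sc) - (-1)), 1)
})

test_that("lagged network recovers planted molecules with controlled false edges", {
    w <- simWearables(days = 7, seed = 13)
    om <- simOmics247(w, blocks = list(
        omicsBlock("lagged", 12, driver = "HR", lag_min = 30, coupling = 1,
                   noise_sd = 0.4),
        omicsBlock("noise", 48, noise_sd = 1)), days = 7, seed = 13)
    la <- log2Autoscale(om$omics)
    ## window on the order of the shift step keeps the peak sharp; the scan
    ## range covers the peak with modest tails so the quality score reads
    ## the bump rather than the pedestal
    net <- laggedCorNetwork(w["HR"], la, shifts = seq(-60, 60, 10),
                            window = 10, quality_min = 0.7, min_pairs = 8)
    ed <- igraph::as_data_frame(net)
    lagged_ids <- om$truth$analyte[om$truth$mechanism == "lagged"]
    recall <- mean(lagged_ids %in% ed$to)
    n_false <- sum(!ed$to %in% lagged_ids)
    expect_gte(recall, 0.9)
    expect_lte(n_false, max(1, ceiling(0.05 * nrow(ed) +
                                       2 * sqrt(0.05 * nrow(ed)))))
    ## recovered shifts sit at the planted lag (one grid step slack)
    expect_lte(max(abs(ed$shift[ed$to %in% lagged_ids] - 30)), 10)

    ## edge attributes survive subnetwork extraction
    sub <- subnetwork(net, "HR")
    expect_setequal(igraph::E(sub)$quality, igraph::E(net)$quality)

    ## empty wearable panel gives an empty graph
    empty <- laggedCorNetwork(list(), la)
    expect_equal(igraph::ecount(empty), 0)
})

test_that("subnetwork extracts the first neighbourhood faithfully", {
    g <- igraph::make_star(6, mode = "undirected", center = 1)
    igraph::V(g)$name <- paste0("n", 1:6)
    igraph::E(g)$w <- seq_len(5)
    sub <- subnetwork(g, "n1")
    expect_equal(igraph::vcount(sub), 6)
    expect_setequal(igraph::E(sub)$w, 1:5)

    g2 <- igraph::add_vertices(g, 1)
    igraph::V(g2)$name[7] <- "iso"
    sub2 <- subnetwork(g2, "iso")
    expect_equal(igraph::vcount(sub2), 1)
    expect_equal(igraph::ecount(sub2), 0)
    expect_error(subnetwork(g, "absent"), "not in graph")
})
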