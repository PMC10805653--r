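test_that("day-wise LOESS is exact on polynomial days and never bridges the night", {
    tt <- simSamplingTimes(days = 3, seed = 4)
    m <- rbind(lin = 0.01 * tt + 2,
               const = rep(5, length(tt)))
    sm <- loessSmooth(m, times = tt)
    g <- smoothedGrid(sm)
    expect_identical(length(unique(g$day)), 3L)
    expect_lt(max(abs(smoothedValues(sm)["lin", ] - (0.01 * g$time + 2))),
              1e-6)
    expect_equal(unname(smoothedValues(sm)["const", ]),
                 rep(5, nrow(g)), tolerance = 1e-9)

    ## grid step is exactly 30 within days; across days the gap exceeds 4 h
    d <- diff(g$time); same <- diff(g$day) == 0
    expect_true(all(d[same] == 30))
    expect_true(all(d[!same] > 240))
    ## every grid point lies inside its day's sampled range
    day_in <- cumsum(c(1, diff(tt) > 240))
    for (dd in 1:3) {
        r <- range(tt[day_in == dd])
        expect_true(all(g$time[g$day == dd] >= r[1] &
                        g$time[g$day == dd] <= r[2]))
    }
})

test_that("cross-validated span beats the worst span on held-out data", {
    tt <- simSamplingTimes(days = 3, seed = 9)
    set.seed(2)
    y <- sin(2 * pi * tt / 1440) + rnorm(length(tt), 0, 0.3)
    sm <- loessSmooth(matrix(y, 1, dimnames = list("s", NULL)), times = tt)
    chosen <- sm@span[["s"]]
    expect_true(chosen %in% seq(0.3, 0.9, 0.1))
    ## recompute the CV criterion per span with an independent loop
    day <- cumsum(c(1, diff(tt) > 240))
    cvm <- sapply(seq(0.3, 0.9, 0.1), function(sp) {
        se <- 0
        for (dd in unique(day)) {
            t <- tt[day == dd]; yy <- y[day == dd]
            fold <- cut(seq_along(t), 5, labels = FALSE)
            for (f in 1:5) {
                tr <- fold != f
                df <- data.frame(tx = t[tr], yx = yy[tr])
                fit <- try(suppressWarnings(loess(
                    yx ~ tx, data = df, span = sp, degree = 2,
                    control = loess.control(surface = "direct"))),
                    silent = TRUE)
                if (inherits(fit, "try-error")) { se <- se + 1e6; next }
                pr <- predict(fit, data.frame(tx = t[!tr]))
                se <- se + sum((pr - yy[!tr])^2, na.rm = TRUE)
            }
        }
        se
    })
    expect_lt(cvm[match(chosen, seq(0.3, 0.9, 0.1))], max(cvm))

    ## a day with too few points is skipped with a warning
    t2 <- c(tt[day == 1], 1440 + c(600, 700), tt[day == 3] + 1440)
    y2 <- matrix(rnorm(length(t2)), 1, dimnames = list("x", NULL))
    expect_warning(sm2 <- loessSmooth(y2, times = t2), "skipped")
    expect_identical(length(unique(smoothedGrid(sm2)$day)), 2L)
})

test_that("time-course clustering separates day- from night-peaking molecules", {
    tt <- simSamplingTimes(days = 4, seed = 3)
    set.seed(5)
    day_peak <- t(replicate(15, sin(2 * pi * (tt - 360) / 1440) +
                                rnorm(length(tt), 0, 0.2)))
    night_peak <- t(replicate(15, sin(2 * pi * (tt - 1080) / 1440) +
                                  rnorm(length(tt), 0, 0.2)))
    m <- rbind(day_peak, night_peak)
    rownames(m) <- paste0("m", 1:30)
    cl <- clusterTimecourses(m, k_range = 2:6, seed = 2)
    expect_identical(cl$k, 2L)
    expect_equal(ari(cl$cluster, rep(1:2, each = 15)), 1)

    ## single-mechanism input collapses to one effective cluster after merge
    cl1 <- suppressWarnings(clusterTimecourses(day_peak, k_range = 2:4,
                                               seed = 2))
    expect_identical(cl1$k, 1L)

    ## pure-noise molecules are dropped by the membership filter; pinned at a
    ## soft fuzzifier (on a dense grid the dimension-based estimate is ~1.1,
    ## i.e. near-crisp, and memberships saturate regardless of fit)
    third <- t(replicate(15, sin(2 * pi * (tt - 720) / 1440) +
                             rnorm(length(tt), 0, 0.2)))
    noise <- t(replicate(40, rnorm(length(tt), 0, 2)))
    m2 <- rbind(day_peak, night_peak, third, noise)
    rownames(m2) <- paste0("m", seq_len(nrow(m2)))
    cl2 <- clusterTimecourses(m2, k_range = 2:8, seed = 2, fuzzifier = 2)
    expect_gt(mean(!cl2$retained[46:85]), 0.9)
    expect_gt(mean(cl2$retained[1:45]), 0.9)
})

test_that("correlation network applies both thresholds and is order invariant", {
    set.seed(7)
    base <- sin(seq(0, 6 * pi, length.out = 60))
    m <- rbind(a = base, b = base + rnorm(60, 0, 0.05),
               c = rnorm(60), d = rnorm(60))
    g <- correlationNetwork(m)
    expect_equal(igraph::ecount(g), 1)
    e <- igraph::as_data_frame(g)
    expect_setequal(unlist(e[, c("from", "to")]), c("a", "b"))
    expect_gt(e$rho, 0.9)

    ## independent noise: expect (essentially) no edges among 100 pairs
    noise <- matrix(rnorm(15 * 60), 15, dimnames = list(paste0("n", 1:15), NULL))
    gn <- correlationNetwork(noise)
    expect_lte(igraph::ecount(gn), 1L)

    ## order invariance of the edge set
    g2 <- correlationNetwork(m[c(3, 1, 4, 2), ])
    e2 <- igraph::as_data_frame(g2)
    expect_setequal(paste(pmin(e$from, e$to), pmax(e$from, e$to)),
                    paste(pmin(e2$from, e2$to), pmax(e2$from, e2$to)))
})

test_that("fast greedy communities recover planted structure", {
    ## two disjoint 5-cliques
    g <- igraph::graph_from_adjacency_matrix(
        Matrix::bdiag(matrix(1, 5, 5), matrix(1, 5, 5)) == 1,
        mode = "undirected", diag = FALSE)
    igraph::V(g)$name <- paste0("v", 1:10)
    cm <- communityModules(g)
    expect_length(cm$modules, 2L)
    expect_gte(cm$modularity, 0)

    ## planted 2-block graph
    set.seed(11)
    n <- 20
    A <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
        p <- if ((i <= 10) == (j <= 10)) 0.9 else 0.05
        A[i, j] <- A[j, i] <- rbinom(1, 1, p)
    }
    gb <- igraph::graph_from_adjacency_matrix(A == 1, mode = "undirected",
                                              diag = FALSE)
    igraph::V(gb)$name <- paste0("x", 1:n)
    cb <- communityModules(gb)
    expect_equal(ari(cb$membership, rep(1:2, each = 10)), 1)

    expect_identical(
        communityModules(igraph::make_empty_graph(0, directed = FALSE))$modules,
        list())
})

test_that("Gaussian peak detection finds planted bumps only", {
    tg <- rep(seq(360, 1380, 30), 2) + rep(c(0, 1440), each = 35)
    day <- rep(1:2, each = 35)
    set.seed(3)
    one <- exp(-(tg - 720)^2 / (2 * 60^2)) +
        exp(-(tg - 720 - 1440)^2 / (2 * 60^2)) + rnorm(70, 0, 0.02)
    pk <- detectPeaks(one, tg, day)
    expect_identical(nrow(pk$peaks), 2L)
    expect_lt(min(abs(pk$peaks$centre - 720)), 30)
    expect_identical(sum(pk$indicator), 2L)

    flat <- rep(1, 70)
    expect_identical(nrow(detectPeaks(flat, tg, day)$peaks), 0L)

    two <- exp(-(tg - 540)^2 / (2 * 50^2)) + exp(-(tg - 1200)^2 / (2 * 50^2)) +
        rnorm(70, 0, 0.02)
    pk2 <- detectPeaks(two[day == 1], tg[day == 1], day[day == 1])
    expect_identical(nrow(pk2$peaks), 2L)
})

test_that("nutrition Jaccard matches hand cases", {
    times <- seq(0, 270, 30)
    ind <- rbind(m1 = c(1, 0, 1, 0, 0, 0, 1, 0, 1, 0),
                 m2 = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0))
    food <- FoodLog(timestamp_min = c(0, 60, 180, 240, 30),
                    nutrient_class = c(rep("carbs", 4), "fat"))
    res <- nutritionJaccard(ind, food, times)
    ## m1 vs carbs: identical indicator -> 1
    expect_equal(res$jaccard[res$module == "m1" &
                             res$nutrient_class == "carbs"], 1)
    ## m2 vs carbs: disjoint -> 0
    expect_equal(res$jaccard[res$module == "m2" &
                             res$nutrient_class == "carbs"], 0)
    ## overlap 1, union 1 for m2 vs fat
    expect_equal(res$jaccard[res$module == "m2" &
                             res$nutrient_class == "fat"], 1)
    ## overlap 2 (bins 1,3), union 4 (bins 1,3,5,10) -> 0.5
    ind2 <- rbind(m3 = c(1, 0, 1, 0, 0, 0, 0, 0, 0, 1))
    f2 <- FoodLog(timestamp_min = c(0, 60, 120), nutrient_class = "carbs")
    r2 <- nutritionJaccard(ind2, f2, times)
    expect_equal(r2$jaccard[r2$nutrient_class == "carbs"], 0.5)
    r3 <- nutritionJaccard(rbind(m4 = rep(0, 10)), f2, times)
    expect_true(all(r3$jaccard[r3$module == "m4"] >= 0))
})

test_that("consistency score rewards repeating daily patterns", {
    ## grid-level construction: 48 half-hour points per day over 4 days
    grid <- as.numeric(outer(seq(0, 1410, 30), (0:3) * 1440, "+"))
    day <- rep(1:4, each = 48)
    tod <- grid %% 1440
    set.seed(8)
    v <- rbind(daily = sin(2 * pi * (tod - 600) / 1440),
               flip = sin(2 * pi * tod / 1440) * c(1, -1)[day %% 2 + 1],
               noise = rnorm(length(grid)))
    sm <- new("SmoothedCourse", grid = grid, day = as.integer(day),
              values = v, span = setNames(rep(0.5, 3), rownames(v)),
              step = 30)
    cs <- consistencyScore(sm)
    expect_equal(unname(cs["daily"]), 1)
    expect_lte(cs["flip"], 0)
    expect_lt(abs(cs["noise"]), 0.3)

    ## null simulation: with 48 grid points per day, |score| < 0.3 is the rule
    scores <- replicate(200, {
        vn <- matrix(rnorm(length(grid)), 1)
        stats::median(apply(combn(4, 2), 2, function(dp)
            cor(vn[day == dp[1]], vn[day == dp[2]], method = "spearman")))
    })
    expect_gt(mean(abs(scores) < 0.3), 0.95)
})

test_that("rhythmicity test is powered on sinusoids and calibrated on noise", {
    tt <- simSamplingTimes(days = 7, seed = 10)
    set.seed(12)
    sig <- t(replicate(20, sin(2 * pi * tt / 1440) +
                           rnorm(length(tt), 0, 0.2)))
    rownames(sig) <- paste0("s", 1:20)
    rt <- rhythmicityTest(sig, times = tt)
    expect_true(all(rt$padj < 0.05))

    noise <- matrix(rnorm(1000 * length(tt)), 1000)
    rn <- rhythmicityTest(noise, times = tt)
    expect_gt(suppressWarnings(ks.test(rn$p, "punif"))$p.value, 0.01)

    ## molecules with too few points are skipped, not tested
    short <- matrix(rnorm(2 * 10), 2)
    rs <- rhythmicityTest(short, times = seq_len(10) * 60, min_points = 24)
    expect_true(all(is.na(rs$p)))
})
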