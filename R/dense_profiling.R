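#' @include AllClasses.R
NULL

.day_index <- function(times, gap_min = 240) {
    ## a day boundary is any sampling gap exceeding gap_min (> 4 h overnight)
    cumsum(c(1L, as.integer(diff(times) > gap_min)))
}

#' Day-wise LOESS smoothing onto a regular within-day grid
#'
#' Each molecule is fitted day by day with local quadratic regression
#' (\code{stats::loess}, tricube weights) and predicted on a regular grid
#' (default every 30 min) strictly inside each day's sampling range: the
#' overnight gap (> 4 h) defines the day boundary and is never bridged, so no
#' prediction leaks across days. The span is chosen per molecule by k-fold
#' cross-validation (contiguous time blocks) pooled over days.
#'
#' @param x an [OmicsTimeCourse-class] (one participant) or numeric matrix
#'   (molecules x samples) with \code{times}.
#' @param times sample timestamps (minutes); taken from \code{x} if omitted.
#' @param grid_step grid step in minutes (default 30).
#' @param span_grid candidate spans (default 0.3 to 0.9 by 0.1).
#' @param cv_folds folds for span selection (default 5).
#' @param gap_min gap defining a day boundary (default 240 min).
#' @param min_points_day days with fewer points are skipped with a warning.
#' @return A [SmoothedCourse-class].
#' @export
loessSmooth <- function(x, times = NULL, grid_step = 30,
                        span_grid = seq(0.3, 0.9, by = 0.1), cv_folds = 5L,
                        gap_min = 240, min_points_day = 5L) {
    if (is(x, "OmicsTimeCourse")) {
        times <- unname(timestamps(x)); m <- omicsValues(x)
    } else m <- as.matrix(x)
    stopifnot(!is.null(times), length(times) == ncol(m))
    day <- .day_index(times, gap_min)
    keep_days <- as.integer(names(which(table(day) >= min_points_day)))
    if (length(keep_days) < length(unique(day)))
        warning(length(unique(day)) - length(keep_days),
                " day(s) skipped (< ", min_points_day, " points)")
    grid <- unlist(lapply(keep_days, function(d) {
        t <- times[day == d]
        seq(ceiling(min(t) / grid_step) * grid_step,
            floor(max(t) / grid_step) * grid_step, by = grid_step)
    }))
    gday <- .day_index(grid, gap_min)

    fit_day <- function(t, y, span, newt) {
        fit <- try(suppressWarnings(
            stats::loess(y ~ t, span = span, degree = 2,
                         family = "gaussian",
                         control = stats::loess.control(surface = "direct"))),
            silent = TRUE)
        if (inherits(fit, "try-error")) return(rep(NA_real_, length(newt)))
        as.numeric(stats::predict(fit, data.frame(t = newt)))
    }
    cv_mse <- function(t, y, span) {
        fold <- cut(seq_along(t), breaks = min(cv_folds, length(t) - 2L),
                    labels = FALSE)
        se <- 0; n <- 0
        for (f in unique(fold)) {
            tr <- fold != f
            if (sum(tr) < 4L) next
            pred <- fit_day(t[tr], y[tr], span, t[!tr])
            ok <- !is.na(pred)
            se <- se + sum((pred[ok] - y[!tr][ok])^2); n <- n + sum(ok)
        }
        if (n == 0) Inf else se / n
    }
    out <- matrix(NA_real_, nrow(m), length(grid),
                  dimnames = list(rownames(m), NULL))
    spans <- setNames(numeric(nrow(m)), rownames(m))
    for (i in seq_len(nrow(m))) {
        mse <- vapply(span_grid, function(sp) {
            sum(vapply(keep_days, function(d) {
                idx <- day == d
                cv_mse(times[idx], m[i, idx], sp)
            }, numeric(1)))
        }, numeric(1))
        sp <- span_grid[which.min(mse)]
        spans[i] <- sp
        for (d in keep_days) {
            idx <- day == d
            gsel <- gday == match(d, keep_days)
            out[i, gsel] <- fit_day(times[idx], m[i, idx], sp, grid[gsel])
        }
    }
    new("SmoothedCourse", grid = as.numeric(grid), day = as.integer(gday),
        values = out, span = spans, step = grid_step)
}

#' Fuzzy c-means clustering of smoothed time courses
#'
#' Row-autoscales the gridded matrix and delegates to [fuzzyCMeans()].
#'
#' @param sm a [SmoothedCourse-class] or molecules x grid matrix.
#' @param ... passed to [fuzzyCMeans()].
#' @return See [fuzzyCMeans()].
#' @export
clusterTimecourses <- function(sm, ...) {
    m <- if (is(sm, "SmoothedCourse")) smoothedValues(sm) else as.matrix(sm)
    z <- t(scale(t(m)))
    z[is.na(z)] <- 0
    fuzzyCMeans(z, ...)
}

#' Spearman correlation network of molecules
#'
#' All molecule pairs with at least \code{min_shared} mutually observed grid
#' points are tested; edges require rho > \code{rho_min} and BH-adjusted
#' p < \code{fdr} (adjustment across all tested pairs).
#'
#' @param m molecules x grid-point matrix (e.g. [smoothedValues()]).
#' @param rho_min correlation threshold (default 0.7).
#' @param fdr BH-adjusted p threshold (default 0.05).
#' @param min_shared minimum shared points per pair (default 10).
#' @return An \pkg{igraph} undirected graph; edge attributes \code{rho},
#'   \code{padj}. Molecules with no edge remain isolated vertices.
#' @export
correlationNetwork <- function(m, rho_min = 0.7, fdr = 0.05,
                               min_shared = 10L) {
    m <- as.matrix(m)
    ids <- rownames(m) %||% paste0("m", seq_len(nrow(m)))
    pairs <- utils::combn(nrow(m), 2)
    stat <- apply(pairs, 2L, function(ij) {
        a <- m[ij[1], ]; b <- m[ij[2], ]
        cc <- stats::complete.cases(a, b)
        if (sum(cc) < min_shared) return(c(NA_real_, NA_real_))
        ct <- suppressWarnings(stats::cor.test(a[cc], b[cc],
                                               method = "spearman"))
        c(unname(ct$estimate), ct$p.value)
    })
    padj <- stats::p.adjust(stat[2, ], method = "BH")
    keep <- !is.na(stat[1, ]) & stat[1, ] > rho_min & padj < fdr
    el <- cbind(ids[pairs[1, keep]], ids[pairs[2, keep]])
    g <- igraph::graph_from_data_frame(
        data.frame(from = el[, 1], to = el[, 2],
                   rho = stat[1, keep], padj = padj[keep]),
        directed = FALSE, vertices = data.frame(name = ids))
    g
}

#' Community modules by fast greedy modularity optimization
#'
#' @param g undirected \pkg{igraph} graph.
#' @param drop_singletons drop single-molecule communities from the module
#'   list (default TRUE).
#' @return List: \code{membership} (named), \code{modules} (list of molecule
#'   id vectors), \code{modularity}.
#' @export
communityModules <- function(g, drop_singletons = TRUE) {
    if (igraph::vcount(g) == 0L)
        return(list(membership = integer(), modules = list(), modularity = NA))
    comm <- igraph::cluster_fast_greedy(igraph::simplify(g))
    memb <- igraph::membership(comm)
    mods <- split(names(memb), memb)
    if (drop_singletons)
        mods <- mods[vapply(mods, length, integer(1)) > 1L]
    list(membership = memb, modules = unname(mods),
         modularity = igraph::modularity(comm))
}

#' Gaussian peak detection in a smoothed module course
#'
#' Candidate peaks are local maxima rising above the course mean; a Gaussian
#' (amplitude, centre, width, offset) is least-squares fitted in a window
#' around each candidate (within the day) and the peak is accepted when the
#' window fit reaches R-squared >= \code{r2_min} and fitted amplitude >=
#' \code{amp_sd} standard deviations of the course.
#'
#' @param y smoothed course values on the grid.
#' @param times grid timestamps (minutes).
#' @param day optional day index per grid point (peaks never span days).
#' @param window_min half-width of the fitting window (default 90 min).
#' @param r2_min acceptance threshold on the window fit (default 0.8).
#' @param amp_sd amplitude threshold in course-sd units (default 1).
#' @return List: \code{peaks} (data.frame centre, width, amplitude, r2),
#'   \code{indicator} (binary vector over the grid; 1 at accepted centres).
#' @export
detectPeaks <- function(y, times, day = NULL, window_min = 90,
                        r2_min = 0.8, amp_sd = 1) {
    if (is.null(day)) day <- .day_index(times)
    n <- length(y)
    ind <- integer(n)
    sdy <- stats::sd(y, na.rm = TRUE)
    if (is.na(sdy) || sdy == 0)
        return(list(peaks = data.frame(), indicator = ind))
    cand <- which(vapply(seq_len(n), function(i) {
        if (is.na(y[i]) || y[i] <= mean(y, na.rm = TRUE)) return(FALSE)
        lo <- i > 1L && day[i - 1L] == day[i]
        hi <- i < n && day[i + 1L] == day[i]
        (!lo || y[i] >= y[i - 1L]) && (!hi || y[i] >= y[i + 1L]) && (lo || hi)
    }, logical(1)))
    peaks <- list()
    for (i in cand) {
        sel <- which(day == day[i] & abs(times - times[i]) <= window_min &
                     !is.na(y))
        if (length(sel) < 5L) next
        t0 <- times[sel]; y0 <- y[sel]
        fit <- try(suppressWarnings(minpack.lm::nlsLM(
            y0 ~ a * exp(-(t0 - mu)^2 / (2 * s^2)) + c0,
            start = list(a = y[i] - min(y0), mu = times[i], s = window_min / 3,
                         c0 = min(y0)),
            control = minpack.lm::nls.lm.control(maxiter = 200))),
            silent = TRUE)
        if (inherits(fit, "try-error")) next
        cf <- stats::coef(fit)
        r2 <- 1 - sum(stats::residuals(fit)^2) /
                  sum((y0 - mean(y0))^2)
        if (!is.finite(r2) || r2 < r2_min) next
        if (abs(cf["a"]) < amp_sd * sdy || cf["a"] < 0) next
        centre <- cf["mu"]
        if (centre < min(t0) || centre > max(t0)) next
        peaks[[length(peaks) + 1L]] <- data.frame(
            centre = unname(centre), width = abs(unname(cf["s"])),
            amplitude = unname(cf["a"]), r2 = r2)
        ind[which.min(abs(times - centre))] <- 1L
    }
    peaks <- if (length(peaks)) unique(do.call(rbind, peaks)) else data.frame()
    list(peaks = peaks, indicator = ind)
}

#' Jaccard association between module peaks and nutrition intake
#'
#' Food-log events are discretized onto the grid (1 in the nearest bin); the
#' Jaccard index |intersection| / |union| is computed between each module's
#' binary peak indicator and each nutrient class's event indicator. All-zero
#' pairs have Jaccard 0. Pairs above the threshold are flagged as retained.
#'
#' @param indicators module x grid binary matrix (or a single vector).
#' @param food a [FoodLog-class].
#' @param times grid timestamps (minutes).
#' @param threshold retention threshold (default 0.3, strict ">").
#' @return data.frame: module, nutrient_class, jaccard, retained.
#' @export
nutritionJaccard <- function(indicators, food, times, threshold = 0.3) {
    if (is.vector(indicators))
        indicators <- matrix(indicators, nrow = 1,
                             dimnames = list("module1", NULL))
    step <- stats::median(diff(times))
    rec <- foodRecords(food)
    classes <- unique(rec$nutrient_class)
    fmat <- matrix(0L, length(classes), length(times),
                   dimnames = list(classes, NULL))
    for (r in seq_len(nrow(rec))) {
        d <- abs(times - rec$timestamp_min[r])
        if (min(d) <= step / 2)
            fmat[rec$nutrient_class[r], which.min(d)] <- 1L
    }
    res <- expand.grid(module = rownames(indicators) %||%
                           paste0("module", seq_len(nrow(indicators))),
                       nutrient_class = classes, stringsAsFactors = FALSE)
    res$jaccard <- mapply(function(mo, cl) {
        a <- indicators[mo, ] > 0; b <- fmat[cl, ] > 0
        u <- sum(a | b)
        if (u == 0) 0 else sum(a & b) / u
    }, res$module, res$nutrient_class)
    res$retained <- res$jaccard > threshold
    res
}

#' Day-to-day consistency score of smoothed molecule courses
#'
#' For each molecule and each pair of days, values are aligned by time of day
#' and the Spearman correlation computed; the consistency score is the median
#' over all day pairs. Molecules recurring identically every day score 1.
#'
#' @param sm a [SmoothedCourse-class].
#' @param min_overlap minimum shared time-of-day points per day pair.
#' @return Named numeric vector of consistency scores.
#' @export
consistencyScore <- function(sm, min_overlap = 5L) {
    v <- smoothedValues(sm)
    tod <- sm@grid %% 1440
    days <- unique(sm@day)
    if (length(days) < 2L) stop("need at least 2 days")
    pairs <- utils::combn(days, 2)
    vapply(seq_len(nrow(v)), function(i) {
        cors <- apply(pairs, 2L, function(dp) {
            i1 <- which(sm@day == dp[1]); i2 <- which(sm@day == dp[2])
            shared <- intersect(tod[i1], tod[i2])
            if (length(shared) < min_overlap) return(NA_real_)
            a <- v[i, i1[match(shared, tod[i1])]]
            b <- v[i, i2[match(shared, tod[i2])]]
            suppressWarnings(stats::cor(a, b, method = "spearman",
                                        use = "pairwise.complete.obs"))
        })
        stats::median(cors, na.rm = TRUE)
    }, numeric(1)) |> setNames(rownames(v))
}

#' Generalized (floating-mean) Lomb-Scargle periodogram
#'
#' Power of the least-squares sinusoid fit \code{y ~ cos(wt) + sin(wt) + 1}
#' at each trial period, for irregularly sampled data. The floating mean is
#' essential here: with waking-hours-only sampling the 24-h sinusoid is far
#' from orthogonal to the constant, and the classic fixed-mean periodogram is
#' miscalibrated. Power is reported in the sample-variance normalization
#' \code{z = (n-1) R^2 / 2}, where R^2 is the variance fraction explained by
#' the sinusoid; under Gaussian noise the single-frequency null is exactly
#' \code{(R^2/2) / ((1-R^2)/(n-3)) ~ F(2, n-3)}, whatever the sampling
#' pattern.
#'
#' @param t sampling times.
#' @param y values.
#' @param periods periods at which to evaluate power (same units as t).
#' @return Numeric vector of normalized powers.
#' @export
lombScargle <- function(t, y, periods) {
    n <- length(y)
    vapply(periods, function(per) {
        w <- 2 * pi / per
        X <- cbind(1, cos(w * t), sin(w * t))
        res <- stats::lm.fit(X, y)$residuals
        r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
        (n - 1) * r2 / 2
    }, numeric(1))
}

#' Circadian rhythmicity test (Lomb-Scargle at the 24-h period)
#'
#' Computes the floating-mean Lomb-Scargle power at the target period(s) for
#' every molecule and converts the (peak) power to a p-value with the exact
#' single-frequency F(2, n-3) null (see [lombScargle()]); when several
#' periods are scanned, a Sidak correction over the scanned frequencies is
#' applied. P-values are BH-adjusted across molecules.
#' Consistency-prefiltering is the caller's job (see [consistencyScore()]);
#' molecules with fewer than \code{min_points} observations are skipped (NA).
#'
#' @param sm a [SmoothedCourse-class], or molecules x time matrix with
#'   \code{times}.
#' @param times timestamps when \code{sm} is a matrix.
#' @param periods target periods in minutes (default single 1440 = 24 h).
#' @param min_points minimum observations per molecule (default 24).
#' @param alpha significance threshold on the adjusted p.
#' @return data.frame: molecule, power, p, padj, significant.
#' @export
rhythmicityTest <- function(sm, times = NULL, periods = 1440,
                            min_points = 24L, alpha = 0.05) {
    if (is(sm, "SmoothedCourse")) {
        v <- smoothedValues(sm); times <- sm@grid
    } else v <- as.matrix(sm)
    stopifnot(length(times) == ncol(v))
    res <- t(vapply(seq_len(nrow(v)), function(i) {
        ok <- !is.na(v[i, ])
        n <- sum(ok)
        if (n < min_points) return(c(NA_real_, NA_real_))
        z <- max(lombScargle(times[ok], v[i, ok], periods))
        r2 <- min(2 * z / (n - 1), 1 - 1e-12)
        f <- (r2 / 2) / ((1 - r2) / (n - 3))
        p1 <- stats::pf(f, 2, n - 3, lower.tail = FALSE)
        p <- if (length(periods) == 1L) p1 else 1 - (1 - p1)^length(periods)
        c(z, min(max(p, 0), 1))
    }, numeric(2)))
    out <- data.frame(molecule = rownames(v) %||% seq_len(nrow(v)),
                      power = res[, 1], p = res[, 2])
    out$padj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- !is.na(out$padj) & out$padj < alpha
    out
}
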