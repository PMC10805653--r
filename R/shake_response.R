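#' @include AllClasses.R
NULL

.shake_tp <- function(x) {
    tp <- timepoints(x)
    if (all(is.na(tp))) stop("cohort has no timepoint labels")
    tp
}

#' Paired Wilcoxon screening of each timepoint against baseline
#'
#' For every analyte and every non-baseline timepoint, a paired Wilcoxon
#' signed-rank test of that timepoint against the participant-matched baseline
#' (timepoint \code{"0"}). P values are BH-adjusted across analytes within
#' each timepoint by default (\code{bh_scope = "global"} adjusts across the
#' whole family instead). Analyte/timepoint combinations with fewer than 6
#' complete pairs are degenerate and skipped with a warning.
#'
#' @param x an [OmicsTimeCourse-class] with timepoint labels; typically
#'   log2-autoscaled first.
#' @param baseline the baseline timepoint label.
#' @param alpha significance level on the adjusted p-values.
#' @param bh_scope \code{"within_timepoint"} (default) or \code{"global"}.
#' @return data.frame per analyte with raw (\code{p_<tp>}) and adjusted
#'   (\code{padj_<tp>}) p-values and \code{sig_<tp>} flags.
#' @export
wilcoxonVsBaseline <- function(x, baseline = "0", alpha = 0.05,
                               bh_scope = c("within_timepoint", "global")) {
    bh_scope <- match.arg(bh_scope)
    v <- omicsValues(x)
    tp <- .shake_tp(x)
    part <- participants(x)
    tps <- setdiff(unique(tp), baseline)
    tps <- tps[order(as.numeric(tps))]
    base_col <- function(p) which(part == p & tp == baseline)[1]
    praw <- matrix(NA_real_, nrow(v), length(tps),
                   dimnames = list(rownames(v), tps))
    n_skipped <- 0L
    for (t in tps) {
        idx <- which(tp == t)
        pb <- vapply(part[idx], base_col, numeric(1))
        ok <- !is.na(pb)
        for (i in seq_len(nrow(v))) {
            a <- v[i, idx[ok]]; b <- v[i, pb[ok]]
            cc <- stats::complete.cases(a, b)
            if (sum(cc) < 6L) { n_skipped <- n_skipped + 1L; next }
            praw[i, t] <- if (all(a[cc] == b[cc])) 1 else suppressWarnings(
                stats::wilcox.test(a[cc], b[cc], paired = TRUE)$p.value)
        }
    }
    if (n_skipped)
        warning(n_skipped, " analyte/timepoint tests skipped (< 6 pairs)")
    padj <- if (bh_scope == "within_timepoint")
        apply(praw, 2L, stats::p.adjust, method = "BH")
    else matrix(stats::p.adjust(praw, method = "BH"), nrow(praw),
                dimnames = dimnames(praw))
    out <- data.frame(analyte = rownames(v), row.names = NULL)
    for (t in tps) {
        out[[paste0("p_", t)]] <- praw[, t]
        out[[paste0("padj_", t)]] <- padj[, t]
        out[[paste0("sig_", t)]] <- !is.na(padj[, t]) & padj[, t] < alpha
    }
    out
}

## vectorized one-way ANOVA over a label vector; equality with stats::aov is
## asserted in the test suite
.anova_p <- function(v, groups) {
    groups <- as.factor(groups)
    G <- stats::model.matrix(~ groups - 1)
    ng <- colSums(G)
    k <- ncol(G); n <- ncol(v)
    gm <- (v %*% G) / matrix(ng, nrow(v), k, byrow = TRUE)
    grand <- rowMeans(v)
    ssb <- rowSums(sweep(gm, 1L, grand)^2 * matrix(ng, nrow(v), k, byrow = TRUE))
    sst <- rowSums(sweep(v, 1L, grand)^2)
    ssw <- sst - ssb
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

#' One-way ANOVA screening with a permutation-calibrated significant count
#'
#' Per analyte, a one-way ANOVA of intensity over timepoint; BH adjustment
#' across analytes; the observed number of significant analytes (adjusted
#' p < \code{alpha}) is compared against a null distribution obtained by
#' shuffling timepoint labels within each participant and re-running the whole
#' screen \code{n_perm} times. The permutation p-value is
#' \code{(1 + #(null >= observed)) / (n_perm + 1)}.
#'
#' @param x an [OmicsTimeCourse-class] with timepoint labels.
#' @param n_perm number of label permutations (default 100).
#' @param seed integer seed for the permutations.
#' @param alpha significance level on adjusted p-values.
#' @return List: \code{p}, \code{padj} (named per analyte),
#'   \code{n_significant}, \code{perm_null} (vector of null counts),
#'   \code{perm_p}.
#' @export
anovaPerm <- function(x, n_perm = 100L, seed = 1L, alpha = 0.05) {
    v <- omicsValues(x)
    tp <- .shake_tp(x)
    part <- participants(x)
    p <- .anova_p(v, tp)
    padj <- stats::p.adjust(p, method = "BH")
    obs <- sum(padj < alpha, na.rm = TRUE)
    null_counts <- .with_seed(seed + 42L, {
        vapply(seq_len(n_perm), function(b) {
            tpb <- tp
            for (pp in unique(part)) {
                idx <- which(part == pp)
                tpb[idx] <- sample(tp[idx])
            }
            pb <- stats::p.adjust(.anova_p(v, tpb), method = "BH")
            sum(pb < alpha, na.rm = TRUE)
        }, numeric(1))
    })
    list(p = setNames(p, rownames(v)), padj = setNames(padj, rownames(v)),
         n_significant = obs, perm_null = null_counts,
         perm_p = (1 + sum(null_counts >= obs)) / (n_perm + 1))
}

## Mfuzz-style fuzzifier estimate from the data dimensions:
## m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)
.mestimate <- function(N, D) {
    1 + (1418 / N + 22.05) * D^(-2) +
        (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' The fuzzifier is estimated from the data dimensions (Mfuzz-style formula,
#' see source). The cluster number is chosen by the minimum-centroid-distance
#' elbow over \code{k_range}: the first k at which the relative decrease of
#' the minimum pairwise centroid distance falls below 10\%. Clusters whose
#' centre profiles correlate above \code{merge_corr} (Pearson) are merged
#' post hoc (memberships summed); analytes whose maximum membership does not
#' exceed \code{min_membership} are dropped from the retained set.
#'
#' @param m numeric matrix of profiles (rows = analytes), log2-autoscaled.
#' @param k_range candidate cluster numbers (default 2:22; truncated with a
#'   warning if it reaches the analyte count).
#' @param merge_corr centre-correlation merge threshold.
#' @param min_membership retention threshold on the (post-merge) membership.
#' @param seed integer seed.
#' @param fuzzifier override the estimated fuzzifier.
#' @param max_iter c-means iteration cap.
#' @return List: \code{k_initial}, \code{k} (final), \code{cluster} (per
#'   analyte), \code{membership} (analyte x final cluster), \code{centers},
#'   \code{retained} (logical, membership > threshold), \code{merge_log},
#'   \code{min_centroid_dist} (per candidate k), \code{fuzzifier}.
#' @export
fuzzyCMeans <- function(m, k_range = 2:22, merge_corr = 0.8,
                        min_membership = 0.5, seed = 1L, fuzzifier = NULL,
                        max_iter = 200L) {
    m <- as.matrix(m)
    n_distinct <- nrow(unique(m))
    if (max(k_range) >= min(nrow(m), n_distinct + 1L)) {
        warning("k_range truncated to the number of distinct profiles")
        k_range <- k_range[k_range < nrow(m) & k_range <= n_distinct]
    }
    if (!length(k_range))
        stop("no valid cluster number: too few distinct profiles")
    fz <- fuzzifier %||% .mestimate(nrow(m), ncol(m))
    run <- function(k) .with_seed(seed + 7000L + k,
        e1071::cmeans(m, centers = k, m = fz, iter.max = max_iter))
    dmin <- vapply(k_range, function(k) {
        cm <- run(k)
        min(stats::dist(cm$centers))
    }, numeric(1))
    rel_dec <- c(NA, -diff(dmin) / pmax(dmin[-length(dmin)], 1e-12))
    hit <- which(!is.na(rel_dec) & rel_dec < 0.10)
    k_opt <- if (length(hit)) k_range[hit[1]] else k_range[length(k_range)]
    cm <- run(k_opt)

    ## post-hoc merge of near-identical centres
    cc <- suppressWarnings(stats::cor(t(cm$centers)))
    cc[is.na(cc)] <- 0
    g <- igraph::graph_from_adjacency_matrix(cc > merge_corr, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    merge_log <- split(seq_len(k_opt), comp)
    k_final <- length(merge_log)
    memb <- vapply(merge_log, function(cols)
        rowSums(cm$membership[, cols, drop = FALSE]), numeric(nrow(m)))
    if (is.null(dim(memb))) memb <- matrix(memb, nrow = nrow(m))
    colnames(memb) <- paste0("C", seq_len(k_final))
    centers <- t(vapply(merge_log, function(cols)
        colMeans(cm$centers[cols, , drop = FALSE]), numeric(ncol(m))))
    cl <- max.col(memb, ties.method = "first")
    list(k_initial = k_opt, k = k_final,
         cluster = setNames(cl, rownames(m)),
         membership = memb, centers = centers,
         retained = setNames(memb[cbind(seq_len(nrow(m)), cl)] > min_membership,
                             rownames(m)),
         merge_log = merge_log,
         min_centroid_dist = setNames(dmin, k_range), fuzzifier = fz)
}

#' Consensus clustering of participants by resampled k-means
#'
#' For each candidate k, participants are subsampled \code{n_resample} times
#' (fraction \code{subsample}), k-means (Euclidean) is run on each subsample,
#' and the consensus matrix records how often each pair co-clusters among the
#' resamples where both were drawn. Final assignments come from hierarchical
#' clustering of \code{1 - consensus}; k is chosen by the mean silhouette
#' width computed on the consensus similarity.
#'
#' @param m participants x features numeric matrix.
#' @param k_range candidate group counts (default 2:6).
#' @param n_resample resampling repetitions (default 1000).
#' @param subsample fraction of participants per resample.
#' @param seed integer seed.
#' @return List: \code{k}, \code{groups} (named), \code{consensus} (matrix for
#'   the chosen k), \code{silhouette} (mean width per k),
#'   \code{consensus_all} (list over k).
#' @export
consensusCluster <- function(m, k_range = 2:6, n_resample = 1000L,
                             subsample = 0.8, seed = 1L) {
    m <- as.matrix(m)
    n <- nrow(m)
    if (n < 2L * max(k_range))
        stop("need at least 2*max(k_range) participants")
    res <- .with_seed(seed + 8000L, {
        lapply(k_range, function(k) {
            co <- matrix(0, n, n); tog <- matrix(0, n, n)
            for (b in seq_len(n_resample)) {
                idx <- sort(sample(n, ceiling(subsample * n)))
                sub <- m[idx, , drop = FALSE]
                cl <- if (nrow(unique(sub)) < k) rep(1L, nrow(sub))
                      else stats::kmeans(sub, centers = k, nstart = 1L)$cluster
                same <- outer(cl, cl, "==")
                co[idx, idx] <- co[idx, idx] + same
                tog[idx, idx] <- tog[idx, idx] + 1
            }
            cons <- ifelse(tog > 0, co / tog, 0)
            diag(cons) <- 1
            dimnames(cons) <- list(rownames(m), rownames(m))
            grp <- stats::cutree(stats::hclust(stats::as.dist(1 - cons),
                                               method = "average"), k = k)
            sil <- mean(cluster::silhouette(grp, stats::as.dist(1 - cons))[, 3])
            list(consensus = cons, groups = grp, sil = sil)
        })
    })
    sil <- vapply(res, `[[`, numeric(1), "sil")
    best <- which.max(sil)
    list(k = k_range[best], groups = res[[best]]$groups,
         consensus = res[[best]]$consensus,
         silhouette = setNames(sil, k_range),
         consensus_all = setNames(lapply(res, `[[`, "consensus"), k_range))
}

#' Mean absolute change from baseline per participant group and timepoint
#'
#' @param x an [OmicsTimeCourse-class] with timepoint labels.
#' @param groups named vector (participant -> group id).
#' @param baseline baseline timepoint label.
#' @return group x timepoint matrix of mean |change from baseline|.
#' @export
responseMagnitude <- function(x, groups, baseline = "0") {
    v <- omicsValues(x)
    tp <- .shake_tp(x); part <- participants(x)
    tps <- setdiff(unique(tp), baseline)
    tps <- tps[order(as.numeric(tps))]
    gids <- sort(unique(groups))
    out <- matrix(NA_real_, length(gids), length(tps),
                  dimnames = list(as.character(gids), tps))
    for (g in gids) {
        ps <- names(groups)[groups == g]
        for (t in tps) {
            d <- unlist(lapply(ps, function(pp) {
                b <- which(part == pp & tp == baseline)[1]
                i <- which(part == pp & tp == t)[1]
                if (is.na(b) || is.na(i)) return(NULL)
                abs(v[, i] - v[, b])
            }))
            out[as.character(g), t] <- mean(d, na.rm = TRUE)
        }
    }
    out
}

#' Hypergeometric over-representation test on user-supplied sets
#'
#' Upper-tail hypergeometric p-value per annotation set (classic
#' over-representation analysis), BH-adjusted across sets. Sets are first
#' intersected with the universe; sets smaller than \code{min_set} are
#' dropped.
#'
#' @param hits character vector of significant ids (must lie in the universe).
#' @param universe character vector of all tested ids.
#' @param sets named list of character vectors.
#' @param min_set minimum (universe-intersected) set size.
#' @return data.frame: set, set size, overlap, p, BH-adjusted p.
#' @export
enrichHypergeometric <- function(hits, universe, sets, min_set = 1L) {
    if (!length(universe)) stop("empty universe")
    if (length(setdiff(hits, universe)))
        stop("hits must be a subset of the universe")
    hits <- unique(hits); universe <- unique(universe)
    sets <- lapply(sets, intersect, universe)
    sets <- sets[vapply(sets, length, integer(1)) >= min_set]
    res <- do.call(rbind, lapply(names(sets), function(nm) {
        s <- sets[[nm]]
        q <- length(intersect(hits, s))
        data.frame(set = nm, size = length(s), overlap = q,
                   p = stats::phyper(q - 1, length(s),
                                     length(universe) - length(s),
                                     length(hits), lower.tail = FALSE))
    }))
    res$padj <- stats::p.adjust(res$p, method = "BH")
    res
}
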