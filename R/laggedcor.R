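#' @include AllClasses.R
NULL

## The lagged-correlation algorithm for two asynchronous time series:
## (1) match the sparse series X into windows around each point of the dense
## series Y at a trial shift, (2) Spearman-correlate the matched vectors,
## (3) repeat over a symmetric shift grid, (4) score how Gaussian the
## correlation-vs-shift curve looks (quality). A negative best shift means
## the dense series Y leads X.

.as_series <- function(obj, times = NULL) {
    if (is(obj, "WearableStream"))
        return(list(t = obj@timestamps, v = obj@values))
    if (is.list(obj) && all(c("t", "v") %in% names(obj))) return(obj)
    stopifnot(!is.null(times), length(times) == length(obj))
    list(t = as.numeric(times), v = as.numeric(obj))
}

#' Match two asynchronous series at one shift
#'
#' For every point of the denser series \code{y} at time tj, the points of
#' \code{x} falling in the half-open window
#' \code{[tj + shift - window/2, tj + shift + window/2)} are averaged into a
#' matched value; y points with no match are dropped.
#'
#' @param x,y series: a [WearableStream-class] or \code{list(t=, v=)}.
#' @param shift trial shift Ts (minutes).
#' @param window matching window Tw (minutes), > 0.
#' @return List: \code{x}, \code{y} (equal-length matched vectors),
#'   \code{n} (number of matched pairs).
#' @export
alignAtShift <- function(x, y, shift, window) {
    stopifnot(window > 0)
    x <- .as_series(x); y <- .as_series(y)
    lo <- y$t + shift - window / 2
    hi <- y$t + shift + window / 2
    ## half-open [lo, hi): findInterval(v, t, left.open=TRUE) counts {t < v},
    ## so i1 is the first x time >= lo and i2 the last x time < hi
    i1 <- findInterval(lo, x$t, left.open = TRUE) + 1L
    i2 <- findInterval(hi, x$t, left.open = TRUE)
    xm <- vapply(seq_along(lo), function(j) {
        if (i2[j] < i1[j]) return(NA_real_)
        mean(x$v[i1[j]:i2[j]])
    }, numeric(1))
    ok <- !is.na(xm)
    ## a dense y reuses each x window many times; the count of distinct
    ## windows is the effective sample size for inference on the correlation
    n_eff <- if (any(ok)) length(unique(paste(i1[ok], i2[ok]))) else 0L
    list(x = xm[ok], y = y$v[ok], n = sum(ok), n_eff = n_eff)
}

#' Gaussian-fit quality of a correlation-vs-shift curve
#'
#' Least-squares fit of a four-parameter Gaussian (amplitude, centre, width,
#' offset) to the correlation curve over shifts; the quality score is the
#' absolute Spearman correlation between fitted and observed curves, in
#' [0, 1]. Non-convergence yields quality 0 with \code{converged = FALSE}.
#'
#' @param shifts shift grid.
#' @param cors observed correlations (NA allowed; ignored in the fit).
#' @return List: \code{quality}, \code{pcor} (fitted curve, NA where input
#'   NA), \code{converged}.
#' @export
gaussianCurveQuality <- function(shifts, cors) {
    ok <- !is.na(cors)
    if (sum(ok) < 5L)
        return(list(quality = 0, pcor = rep(NA_real_, length(shifts)),
                    converged = FALSE))
    s <- shifts[ok]; co <- cors[ok]
    i0 <- which.max(abs(co))
    st <- list(a = co[i0] - stats::median(co), mu = s[i0],
               sg = diff(range(s)) / 4, c0 = stats::median(co))
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
        co ~ a * exp(-(s - mu)^2 / (2 * sg^2)) + c0, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 500))), silent = TRUE)
    pcor <- rep(NA_real_, length(shifts))
    if (inherits(fit, "try-error"))
        return(list(quality = 0, pcor = pcor, converged = FALSE))
    cf <- stats::coef(fit)
    pall <- cf["a"] * exp(-(shifts - cf["mu"])^2 / (2 * cf["sg"]^2)) + cf["c0"]
    pcor[ok] <- pall[ok]
    q <- suppressWarnings(stats::cor(pall[ok], co, method = "spearman"))
    if (is.na(q)) q <- 0
    list(quality = min(abs(q), 1), pcor = pcor, converged = TRUE)
}

#' Lagged Spearman correlation between two asynchronous series
#'
#' Runs [alignAtShift()] over a symmetric shift grid, correlating the matched
#' vectors at each shift (Spearman); shifts with fewer than \code{min_pairs}
#' matches are invalid (NA). The reported lagged correlation is the maximum
#' absolute correlation over valid shifts, sign preserved. The Gaussian-fit
#' quality score of the whole curve (see [gaussianCurveQuality()]) guards
#' against spurious maxima. P-values use the t approximation at the
#' effective sample size (the number of distinct matched windows of the
#' sparse series): when the dense series revisits one window many times the
#' extra pairs duplicate, rather than add, information, and the nominal
#' pair count would wildly overstate significance.
#'
#' @param x the lower-frequency series (e.g. one molecule's time course).
#' @param y the higher-frequency series (e.g. a wearable stream).
#' @param x_times,y_times timestamps when x/y are plain numeric vectors.
#' @param shifts shift grid in minutes; must be symmetric about 0 (default
#'   -120 to 120 by 5).
#' @param window matching window Tw in minutes (default 30).
#' @param min_pairs minimum matched pairs per shift (default 10).
#' @return A [LagScan-class].
#' @export
laggedCorrelation <- function(x, y, x_times = NULL, y_times = NULL,
                              shifts = seq(-120, 120, by = 5), window = 30,
                              min_pairs = 10L) {
    if (abs(shifts[1] + shifts[length(shifts)]) > 1e-8)
        stop("shift grid must be symmetric about 0")
    x <- .as_series(x, x_times); y <- .as_series(y, y_times)
    n_pairs <- integer(length(shifts))
    cors <- ps <- rep(NA_real_, length(shifts))
    for (k in seq_along(shifts)) {
        al <- alignAtShift(x, y, shifts[k], window)
        n_pairs[k] <- al$n
        if (al$n < min_pairs || al$n_eff < 5L) next
        rho <- suppressWarnings(stats::cor(al$x, al$y, method = "spearman"))
        if (is.na(rho)) next
        cors[k] <- rho
        ## p from the t approximation at the effective sample size: when the
        ## matching reuses one x window for many dense y points, those pairs
        ## are copies, not observations
        tv <- rho * sqrt((al$n_eff - 2) / max(1 - rho^2, 1e-12))
        ps[k] <- 2 * stats::pt(abs(tv), al$n_eff - 2, lower.tail = FALSE)
    }
    valid <- !is.na(cors)
    if (!any(valid)) stop("insufficient overlap: no shift has enough pairs")
    best <- which(valid)[which.max(abs(cors[valid]))]
    gq <- gaussianCurveQuality(shifts, cors)
    new("LagScan", shifts = as.numeric(shifts), window = window,
        n_pairs = n_pairs, cor = cors, p = ps,
        best_shift = shifts[best], best_cor = cors[best], best_p = ps[best],
        pcor = gq$pcor, quality = if (gq$converged) gq$quality else 0,
        fit_converged = gq$converged)
}

#' @rdname accessors
#' @export
setGeneric("qualityScore", function(x) standardGeneric("qualityScore"))
#' @rdname accessors
#' @export
setMethod("qualityScore", "LagScan", function(x) x@quality)

#' Lagged-correlation network between wearable streams and molecules
#'
#' Scans every (wearable, molecule) pair with [laggedCorrelation()], adjusts
#' the best-shift p-values BH-wise across molecules within each wearable, and
#' keeps edges with adjusted p < \code{fdr} and quality >= \code{quality_min}.
#'
#' @param wearables named list of [WearableStream-class] objects.
#' @param omics an [OmicsTimeCourse-class] (molecule series at sample times).
#' @param shifts,window,min_pairs see [laggedCorrelation()].
#' @param fdr BH-adjusted p threshold (default 0.05).
#' @param quality_min Gaussian-fit quality threshold (default 0.8).
#' @return An \pkg{igraph} graph; vertices are wearables and molecules, edge
#'   attributes \code{shift}, \code{cor}, \code{padj}, \code{quality}.
#' @export
laggedCorNetwork <- function(wearables, omics, shifts = seq(-120, 120, by = 5),
                             window = 30, fdr = 0.05, quality_min = 0.8,
                             min_pairs = 10L) {
    v <- omicsValues(omics)
    tt <- unname(timestamps(omics))
    verts <- data.frame(name = c(names(wearables), rownames(v)),
                        kind = c(rep("wearable", length(wearables)),
                                 rep("molecule", nrow(v))))
    edges <- list()
    for (w in names(wearables)) {
        scans <- lapply(seq_len(nrow(v)), function(i) {
            tryCatch(laggedCorrelation(list(t = tt, v = v[i, ]),
                                       wearables[[w]], shifts = shifts,
                                       window = window, min_pairs = min_pairs),
                     error = function(e) NULL)
        })
        keep <- !vapply(scans, is.null, logical(1))
        if (!any(keep)) next
        padj <- rep(NA_real_, nrow(v))
        padj[keep] <- stats::p.adjust(
            vapply(scans[keep], function(s) s@best_p, numeric(1)),
            method = "BH")
        for (i in which(keep)) {
            s <- scans[[i]]
            if (is.na(padj[i]) || padj[i] >= fdr || s@quality < quality_min)
                next
            edges[[length(edges) + 1L]] <- data.frame(
                from = w, to = rownames(v)[i], shift = s@best_shift,
                cor = s@best_cor, padj = padj[i], quality = s@quality)
        }
    }
    ed <- if (length(edges)) do.call(rbind, edges)
         else data.frame(from = character(), to = character(),
                         shift = numeric(), cor = numeric(),
                         padj = numeric(), quality = numeric())
    igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

#' First-neighbour subnetwork of a node
#'
#' @param g an \pkg{igraph} graph.
#' @param node vertex name.
#' @return The induced subgraph on the node and its direct neighbours (edge
#'   attributes preserved).
#' @export
subnetwork <- function(g, node) {
    if (!node %in% igraph::V(g)$name) stop("node '", node, "' not in graph")
    nb <- igraph::neighbors(g, node)
    igraph::induced_subgraph(g, union(node, nb$name))
}
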