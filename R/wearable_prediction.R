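#' @include AllClasses.R
NULL

.FEATURE_NAMES <- c("mean", "median", "sd", "max", "min", "skewness",
                    "kurtosis", "range")

#' Match wearable stream segments to omics sampling times
#'
#' For each blood-sample time t, the stream points in the trailing window
#' \code{[t - window, t]} are collected (blood reflects the preceding
#' interval; points after t are never used). Empty segments are flagged.
#'
#' @param streams named list of [WearableStream-class] objects.
#' @param sample_times omics sampling times (minutes).
#' @param window window size in minutes; the canonical sweep uses
#'   5/10/20/30/40/50/60/90/120 (other values allowed with a warning).
#' @return List per sample time: named list of numeric segments (one per
#'   stream); attribute \code{"empty"} marks samples where any stream had no
#'   points.
#' @export
matchWindows <- function(streams, sample_times, window) {
    if (!window %in% c(5, 10, 20, 30, 40, 50, 60, 90, 120))
        warning("window ", window, " min is outside the canonical sweep set")
    streams <- Filter(function(s) is(s, "WearableStream"), streams)
    if (!length(streams)) stop("no WearableStream in 'streams'")
    segs <- lapply(sample_times, function(t) {
        lapply(streams, function(s) {
            s@values[s@timestamps >= t - window & s@timestamps <= t]
        })
    })
    empty <- vapply(segs, function(sl)
        any(vapply(sl, length, integer(1)) == 0L), logical(1))
    attr(segs, "empty") <- empty
    segs
}

.segment_features <- function(v) {
    if (!length(v))
        return(setNames(rep(NA_real_, 8L), .FEATURE_NAMES))
    sk <- if (length(v) < 3L || stats::sd(v) == 0) 0 else e1071::skewness(v)
    ku <- if (length(v) < 3L || stats::sd(v) == 0) 0 else e1071::kurtosis(v)
    setNames(c(mean(v), stats::median(v),
               if (length(v) > 1L) stats::sd(v) else 0,
               max(v), min(v), sk, ku, diff(range(v))), .FEATURE_NAMES)
}

#' Convert matched stream segments to the 8-statistic feature table
#'
#' Each stream segment becomes eight statistics (mean, median, standard
#' deviation, maximum, minimum, skewness, kurtosis, range); with the three
#' canonical streams this yields 24 predictors per sample. Skewness and
#' kurtosis of constant or shorter-than-3-point segments are set to 0 and the
#' rows flagged; empty segments give NA features.
#'
#' @param segments output of [matchWindows()].
#' @return Numeric matrix (samples x 8*streams) with columns
#'   \code{<stream>_<statistic>}; attribute \code{"flagged"} marks rows with
#'   degenerate or empty segments.
#' @export
engineerFeatures <- function(segments) {
    streams <- names(segments[[1L]])
    feat <- t(vapply(segments, function(sl)
        unlist(lapply(sl, .segment_features)), numeric(8L * length(streams))))
    colnames(feat) <- as.vector(outer(.FEATURE_NAMES, streams,
                                      function(f, s) paste(s, f, sep = "_")))
    flagged <- apply(feat, 1L, anyNA) |
        vapply(segments, function(sl)
            any(vapply(sl, function(v) length(v) < 3L ||
                           (length(v) > 1L && stats::sd(v) == 0) ||
                           length(v) <= 1L, logical(1))), logical(1))
    attr(feat, "flagged") <- flagged
    feat
}

#' Wearable features at omics sampling times (one call)
#'
#' @param streams named list of [WearableStream-class].
#' @param sample_times omics sampling times.
#' @param window matching window (minutes).
#' @return See [engineerFeatures()].
#' @export
wearableFeatures <- function(streams, sample_times, window) {
    engineerFeatures(matchWindows(streams, sample_times, window))
}

#' Random-forest prediction of one molecule from wearable features
#'
#' Sevenfold cross-validation by default: out-of-fold predictions are pooled
#' and \code{R2 = 1 - SSE/SST}; folds are contiguous time blocks to limit
#' temporal leakage (\code{fold_type = "random"} restores random folds).
#' Feature importances (increase in node purity) are averaged over folds. A
#' molecule is flagged predictable when R-squared exceeds \code{r2_min}.
#'
#' @param features samples x predictors matrix (rows with NA are dropped).
#' @param y molecule values per sample.
#' @param folds number of CV folds (default 7).
#' @param seed integer seed.
#' @param n_trees trees per forest (default 500).
#' @param fold_type \code{"blocked"} (default) or \code{"random"}.
#' @param r2_min predictability threshold (default 0.3).
#' @return List: \code{r2}, \code{predictable}, \code{importance} (named,
#'   averaged over folds), \code{oof} (pooled out-of-fold predictions).
#' @export
predictMolecule <- function(features, y, folds = 7L, seed = 1L,
                            n_trees = 500L,
                            fold_type = c("blocked", "random"),
                            r2_min = 0.3) {
    fold_type <- match.arg(fold_type)
    ok <- stats::complete.cases(features) & !is.na(y)
    X <- as.matrix(features)[ok, , drop = FALSE]; yy <- y[ok]
    if (stats::sd(yy) == 0) stop("constant response")
    if (nrow(X) < 3L * folds) stop("need at least 3*folds samples")
    fold <- if (fold_type == "blocked")
        cut(seq_len(nrow(X)), breaks = folds, labels = FALSE)
    else .with_seed(seed + 77L, sample(rep_len(seq_len(folds), nrow(X))))
    oof <- rep(NA_real_, nrow(X))
    imp <- numeric(ncol(X))
    .with_seed(seed + 78L, {
        for (f in seq_len(folds)) {
            tr <- fold != f
            rf <- randomForest::randomForest(X[tr, , drop = FALSE], yy[tr],
                                             ntree = n_trees)
            oof[!tr] <- stats::predict(rf, X[!tr, , drop = FALSE])
            imp <- imp + randomForest::importance(rf)[, 1]
        }
    })
    r2 <- 1 - sum((yy - oof)^2) / sum((yy - mean(yy))^2)
    list(r2 = r2, predictable = r2 > r2_min,
         importance = setNames(imp / folds, colnames(X)), oof = oof)
}

#' Sweep matching windows and report per-molecule prediction accuracy
#'
#' Runs [predictMolecule()] for every molecule and window, reporting the
#' R-squared table and, per molecule, the best window and whether any window
#' passes the predictability screen.
#'
#' @param streams named list of [WearableStream-class].
#' @param omics an [OmicsTimeCourse-class].
#' @param windows window sizes (default the canonical sweep).
#' @param folds,seed,n_trees,r2_min see [predictMolecule()].
#' @return List: \code{r2} (data.frame molecule x window, long form),
#'   \code{best} (per molecule: best window, best R2, predictable).
#' @export
windowSweep <- function(streams, omics,
                        windows = c(5, 10, 20, 30, 40, 50, 60, 90, 120),
                        folds = 7L, seed = 1L, n_trees = 500L, r2_min = 0.3) {
    v <- omicsValues(omics)
    tt <- unname(timestamps(omics))
    rows <- list()
    for (w in windows) {
        feat <- wearableFeatures(streams, tt, w)
        for (i in seq_len(nrow(v))) {
            r2 <- tryCatch(
                predictMolecule(feat, v[i, ], folds = folds, seed = seed,
                                n_trees = n_trees, r2_min = r2_min)$r2,
                error = function(e) NA_real_)
            rows[[length(rows) + 1L]] <- data.frame(
                molecule = rownames(v)[i], window = w, r2 = r2)
        }
    }
    long <- do.call(rbind, rows)
    best <- do.call(rbind, lapply(split(long, long$molecule), function(d) {
        j <- which.max(replace(d$r2, is.na(d$r2), -Inf))
        data.frame(molecule = d$molecule[1], best_window = d$window[j],
                   best_r2 = d$r2[j],
                   predictable = any(!is.na(d$r2) & d$r2 > r2_min))
    }))
    rownames(best) <- NULL
    list(r2 = long, best = best)
}
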