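#' @include AllClasses.R
NULL

## Six AUC-based metabolic response scores for the meal-challenge cohort.
## Pipeline: baseline-subtracted trapezoid AUC per molecule/participant ->
## min-max normalization per molecule across participants -> panel mean ->
## 1 - MS inversion for clearance-type panels -> Ward clustering into groups.

#' Default metabolic score panel configuration
#'
#' Six panels: carbohydrate (fructose, lactic acid, pyruvic acid; inverted),
#' amino acid (nine named amino acids; inverted), fat (all TAG-class
#' analytes; inverted), insulin secretion (C-peptide, insulin; not inverted),
#' FFA / insulin sensitivity (eight named free fatty acids; inverted) and
#' immune response (all cytokine-class analytes; not inverted). Inverted
#' panels are those where a large cumulative excursion means slow clearance,
#' so the score is reported as 1 - MS.
#'
#' Panels with an \code{analytes} vector resolve by id; panels with a
#' \code{class} entry resolve against \code{analyteClass} (fat additionally
#' by a \code{"TAG"} id prefix).
#'
#' @return Named list of panel definitions.
#' @export
defaultScoreConfig <- function() {
    list(
        carbohydrate = list(analytes = c("fructose", "lactic acid",
                                         "pyruvic acid"), invert = TRUE),
        amino_acid = list(analytes = c("alloisoleucine", "alanine",
                                       "isoleucine", "methionine", "norvaline",
                                       "phenylalanine", "tryptophan",
                                       "tyrosine", "l-phenylalanine"),
                          invert = TRUE),
        fat = list(class = "lipid", id_prefix = "TAG", invert = TRUE),
        insulin_secretion = list(analytes = c("c-peptide", "insulin"),
                                 invert = FALSE),
        ffa = list(analytes = paste("FFA", c("16:0", "16:1", "18:1", "18:2",
                                             "18:3", "22:2", "22:5", "22:6")),
                   invert = TRUE),
        immune = list(class = "cytokine", invert = FALSE))
}

#' Baseline-subtracted trapezoidal AUC of one response profile
#'
#' The profile is first shifted so its baseline (first timepoint) is zero,
#' then integrated by the trapezoid rule over the sampling times in minutes.
#' Negative AUCs (net dips below baseline) are meaningful and kept.
#'
#' @param values intensities at the timepoints.
#' @param times timepoints in minutes (default the meal-challenge design
#'   0/30/60/120/240).
#' @return The AUC (intensity x minutes).
#' @examples
#' aucBaselineSubtracted(c(0, 1, 0, 0, 0))   # 30
#' aucBaselineSubtracted(c(0, -1, -1, -1, 0)) # -195
#' @export
aucBaselineSubtracted <- function(values, times = c(0, 30, 60, 120, 240)) {
    if (anyNA(values) || length(values) != length(times))
        stop("profile must be complete at every timepoint (impute upstream)")
    y <- values - values[1]
    sum(diff(times) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Min-max normalize AUCs per molecule across participants
#'
#' \code{NA = (A - min A) / (max A - min A)} with min/max taken over
#' participants for each molecule. Zero-range molecules get 0.5 everywhere
#' and are flagged.
#'
#' @param A molecule x participant AUC matrix.
#' @return List: \code{nauc} (same shape, in [0,1]), \code{flagged}
#'   (zero-range molecule ids).
#' @export
normalizeAuc <- function(A) {
    if (ncol(A) < 2L) stop("need at least 2 participants")
    rng <- apply(A, 1L, range, na.rm = TRUE)
    span <- rng[2, ] - rng[1, ]
    flagged <- rownames(A)[span == 0]
    nauc <- (A - rng[1, ]) / ifelse(span == 0, 1, span)
    nauc[span == 0, ] <- 0.5
    list(nauc = nauc, flagged = flagged)
}

.resolve_panel <- function(panel, analytes, classes) {
    ids <- character()
    if (!is.null(panel$analytes))
        ids <- analytes[tolower(analytes) %in% tolower(panel$analytes)]
    if (!is.null(panel$class))
        ids <- union(ids, analytes[classes == panel$class &
                                   startsWith(analytes, panel$id_prefix %||% "")])
    ids
}

#' Compute the per-participant metabolic scores
#'
#' \code{MS_j} is the mean over a panel's molecules of the normalized AUCs
#' \code{NA_ij}; panels marked \code{invert} report \code{1 - MS_j} (large
#' cumulative excursion = slow clearance = low score). Participants are then
#' grouped by Ward hierarchical clustering of the score vectors (see
#' [groupParticipants()]).
#'
#' @param x an [OmicsTimeCourse-class] meal-challenge cohort with timepoint
#'   labels; values should be log2-autoscaled.
#' @param config panel configuration (default [defaultScoreConfig()]); panels
#'   that resolve no analytes are dropped with a warning, but an entirely
#'   unresolvable configuration is an error.
#' @param k number of participant groups (default 5).
#' @param baseline baseline timepoint label.
#' @return A [ScorePanel-class].
#' @export
computeScores <- function(x, config = defaultScoreConfig(), k = 5L,
                          baseline = "0") {
    v <- omicsValues(x)
    tp <- .shake_tp(x); part <- participants(x)
    pids <- unique(part)
    tps <- unique(tp)[order(as.numeric(unique(tp)))]
    times <- as.numeric(tps)
    A <- matrix(NA_real_, nrow(v), length(pids),
                dimnames = list(rownames(v), pids))
    for (j in pids) {
        cols <- vapply(tps, function(t) {
            w <- which(part == j & tp == t)
            if (length(w)) w[1] else NA_integer_
        }, integer(1))
        if (anyNA(cols)) stop("participant '", j, "' misses a timepoint")
        A[, j] <- apply(v[, cols, drop = FALSE], 1L, aucBaselineSubtracted,
                        times = times)
    }
    nz <- normalizeAuc(A)
    classes <- analyteClass(x)
    panels <- lapply(config, .resolve_panel, analytes = rownames(v),
                     classes = classes)
    empty <- vapply(panels, length, integer(1)) == 0L
    if (all(empty)) stop("no score panel resolves any analyte in the matrix")
    if (any(empty)) {
        warning("dropping unresolvable panels: ",
                paste(names(panels)[empty], collapse = ", "))
        panels <- panels[!empty]; config <- config[!empty]
    }
    scores <- vapply(names(panels), function(nm) {
        ms <- colMeans(nz$nauc[panels[[nm]], , drop = FALSE])
        if (isTRUE(config[[nm]]$invert)) 1 - ms else ms
    }, numeric(length(pids)))
    if (is.null(dim(scores)))
        scores <- matrix(scores, nrow = length(pids),
                         dimnames = list(pids, names(panels)))
    groups <- groupParticipants(scores, k = k)
    new("ScorePanel", auc = A, nauc = nz$nauc, scores = scores,
        groups = groups, flagged = nz$flagged)
}

#' Group participants by their metabolic scores
#'
#' Ward-linkage (\code{ward.D2}) hierarchical clustering on the Euclidean
#' distance between score vectors, cut at \code{k} groups.
#'
#' @param scores participant x score matrix.
#' @param k number of groups.
#' @return Named integer vector of group ids.
#' @export
groupParticipants <- function(scores, k = 5L) {
    if (k < 1L || k > nrow(scores)) stop("k must lie in 1..participants")
    if (k == 1L)
        return(setNames(rep(1L, nrow(scores)), rownames(scores)))
    hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
    stats::cutree(hc, k = k)
}

#' Flag participants with outlying baseline samples
#'
#' Baseline samples are projected onto the first two principal components of
#' the (participant x analyte) baseline matrix; a participant is flagged when
#' the robust z-score (median/MAD) on PC1 or PC2 exceeds \code{z_max}.
#'
#' @param x an [OmicsTimeCourse-class] cohort (autoscaled input recommended;
#'   the PCA re-centres, so per-analyte affine scaling does not change flags).
#' @param baseline baseline timepoint label.
#' @param z_max robust z threshold (default 3).
#' @return Character vector of flagged participant ids.
#' @export
detectBaselineOutlier <- function(x, baseline = "0", z_max = 3) {
    v <- omicsValues(x)
    tp <- .shake_tp(x); part <- participants(x)
    idx <- which(tp == baseline)
    b <- t(v[, idx, drop = FALSE])
    rownames(b) <- part[idx]
    b <- scale(b)
    b[is.na(b)] <- 0
    pc <- stats::prcomp(b, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
    rz <- apply(pc, 2L, function(z) {
        mad <- stats::mad(z)
        if (mad == 0) return(rep(0, length(z)))
        abs(z - stats::median(z)) / mad
    })
    rownames(pc)[apply(rz, 1L, max) > z_max]
}
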