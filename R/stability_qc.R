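#' @include AllClasses.R
NULL

## Storage-stability analysis: per-analyte OLS on the storage design, partial
## R^2 per term (two-fit SSE definition), and LMG relative importance
## (average sequential R^2 increment over all regressor orderings, computed
## by subset enumeration with order weights).

.design_matrix <- function(design, single_condition = "none") {
    part <- as.numeric(design$participant == sort(unique(design$participant))[2])
    X <- switch(single_condition,
        none = cbind(duration = design$duration_h,
                     temperature = design$temperature_c,
                     interaction = design$duration_h * design$temperature_c,
                     participant = part),
        duration = cbind(duration = design$duration_h, participant = part),
        temperature = cbind(temperature = design$temperature_c,
                            participant = part),
        stop("single_condition must be none, duration or temperature"))
    Xf <- cbind(`(Intercept)` = 1, X)
    qrX <- qr(Xf)
    if (qrX$rank < ncol(Xf)) {
        drop <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
        stop("rank-deficient design; collinear terms: ",
             paste(drop, collapse = ", "))
    }
    X
}

## R^2 of every regressor subset for all analytes at once (Y: analyte x n).
.subset_r2 <- function(Y, X) {
    n <- ncol(Y)
    Yt <- t(Y)
    sst <- colSums(scale(Yt, scale = FALSE)^2)
    p <- ncol(X)
    subsets <- lapply(0:(2^p - 1), function(b) which(bitwAnd(b, 2^(0:(p - 1))) > 0))
    r2 <- matrix(NA_real_, length(subsets), nrow(Y))
    for (s in seq_along(subsets)) {
        Xs <- cbind(1, X[, subsets[[s]], drop = FALSE])
        res <- stats::lm.fit(Xs, Yt)$residuals
        if (is.null(dim(res))) res <- matrix(res, ncol = nrow(Y))
        r2[s, ] <- 1 - colSums(res^2) / sst
    }
    list(r2 = r2, subsets = subsets)
}

.lmg_from_subsets <- function(r2, subsets, p) {
    ## LMG share of regressor j = sum over S not containing j of
    ## |S|! (p-|S|-1)! / p! * (R2(S+j) - R2(S))
    key <- vapply(subsets, function(s) sum(2^(s - 1)), numeric(1))
    idx_of <- match(0:(2^p - 1), key)
    shares <- matrix(0, p, ncol(r2))
    for (j in seq_len(p)) {
        for (s in seq_along(subsets)) {
            S <- subsets[[s]]
            if (j %in% S) next
            k <- length(S)
            w <- exp(lfactorial(k) + lfactorial(p - k - 1) - lfactorial(p))
            with_j <- idx_of[key[s] + 2^(j - 1) + 1]
            shares[j, ] <- shares[j, ] + w * (r2[with_j, ] - r2[s, ])
        }
    }
    shares
}

#' Per-analyte storage-effect regression
#'
#' Each analyte's level is regressed (OLS) on storage duration (h),
#' temperature (numeric, degrees C), their interaction and a participant
#' indicator. Samples with zero storage duration were never exposed to any
#' temperature and are excluded, unless a duration-only sensitivity model is
#' requested with \code{include_baseline = TRUE}. Term p-values come from the
#' coefficient t-tests; the partial R-squared of a term is
#' \code{1 - SSE(full)/SSE(without term)}; LMG shares are the
#' orderings-averaged sequential R-squared contributions and sum to the total
#' model R-squared. Significance is at nominal P = 0.05 without multiplicity
#' correction (conservative toward detecting instability).
#'
#' @param m analyte x sample numeric matrix (or [OmicsTimeCourse-class]).
#' @param design data.frame with \code{sample_id}, \code{participant},
#'   \code{duration_h}, \code{temperature_c} (rows matched to columns of
#'   \code{m} by sample id).
#' @param include_baseline keep duration-0 rows (only allowed with
#'   \code{single_condition = "duration"}).
#' @param single_condition \code{"none"} (full model) or a one-condition
#'   sensitivity model: \code{"duration"} or \code{"temperature"}.
#' @param alpha significance level for the per-term flags.
#' @return A data.frame, one row per analyte: p-values, total R-squared,
#'   partial R-squared and LMG share per term, and significance flags.
#' @export
storageRegression <- function(m, design, include_baseline = FALSE,
                              single_condition = c("none", "duration",
                                                   "temperature"),
                              alpha = 0.05) {
    single_condition <- match.arg(single_condition)
    if (is(m, "OmicsTimeCourse")) m <- omicsValues(m)
    design <- design[match(colnames(m), design$sample_id), , drop = FALSE]
    keep <- if (single_condition == "duration" && include_baseline)
        rep(TRUE, nrow(design)) else design$duration_h > 0
    design <- design[keep, , drop = FALSE]
    Y <- m[, keep, drop = FALSE]
    X <- .design_matrix(design, single_condition)
    p <- ncol(X)
    terms <- colnames(X)

    ## full-model coefficient t-tests
    Xf <- cbind(1, X)
    fit <- stats::lm.fit(Xf, t(Y))
    res <- fit$residuals
    if (is.null(dim(res))) res <- matrix(res, ncol = nrow(Y))
    dfres <- nrow(Xf) - ncol(Xf)
    sigma2 <- colSums(res^2) / dfres
    XtXinv <- chol2inv(qr.R(qr(Xf)))
    coefs <- fit$coefficients
    if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1)
    se <- sqrt(outer(diag(XtXinv), sigma2))
    tval <- coefs / se
    pval <- 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)

    sr <- .subset_r2(Y, X)
    full_idx <- length(sr$subsets)          # last subset = all regressors
    r2_total <- sr$r2[full_idx, ]
    ## partial R^2 per term: 1 - SSE(full)/SSE(full minus term)
    pr2 <- sapply(seq_len(p), function(j) {
        without <- which(vapply(sr$subsets, function(s)
            setequal(s, setdiff(seq_len(p), j)), logical(1)))
        1 - (1 - r2_total) / (1 - sr$r2[without, ])
    })
    if (is.null(dim(pr2))) pr2 <- matrix(pr2, nrow = 1)
    lmg <- t(.lmg_from_subsets(sr$r2, sr$subsets, p))

    out <- data.frame(analyte = rownames(Y), r2_total = r2_total,
                      row.names = NULL)
    for (j in seq_len(p)) {
        out[[paste0("p_", terms[j])]] <- pval[j + 1L, ]
        out[[paste0("pr2_", terms[j])]] <- pr2[, j]
        out[[paste0("lmg_", terms[j])]] <- lmg[, j]
        out[[paste0("sig_", terms[j])]] <- pval[j + 1L, ] < alpha
    }
    attr(out, "terms") <- terms
    attr(out, "alpha") <- alpha
    out
}

#' LMG relative importance of regressors
#'
#' For each regressor, the average over all orderings of its sequential
#' R-squared increment when added to the model. Shares are non-negative in
#' well-conditioned designs and always sum to the full-model R-squared.
#' Computed by exhaustive subset enumeration with the order weights
#' \eqn{|S|!(p-|S|-1)!/p!}; limited to at most 8 regressors.
#'
#' @param y response vector.
#' @param X numeric regressor matrix with column names.
#' @return Named numeric vector of LMG shares.
#' @export
lmgImportance <- function(y, X) {
    X <- as.matrix(X)
    if (ncol(X) > 8L) stop("at most 8 regressors supported")
    sr <- .subset_r2(matrix(y, nrow = 1), X)
    drop(.lmg_from_subsets(sr$r2, sr$subsets, ncol(X)))[seq_len(ncol(X))] |>
        setNames(colnames(X))
}

#' Tabulate significant storage effects against chance expectation
#'
#' @param effects output of [storageRegression()].
#' @param alpha the nominal level (the expected-by-chance proportion).
#' @return data.frame: term, n significant, proportion, expected proportion.
#' @export
significanceSummary <- function(effects, alpha = 0.05) {
    if (!nrow(effects)) stop("empty effects table")
    terms <- attr(effects, "terms")
    if (is.null(terms))
        terms <- sub("^sig_", "", grep("^sig_", names(effects), value = TRUE))
    data.frame(
        term = terms,
        n_significant = vapply(terms, function(t)
            sum(effects[[paste0("sig_", t)]]), numeric(1)),
        proportion = vapply(terms, function(t)
            mean(effects[[paste0("sig_", t)]]), numeric(1)),
        expected = alpha, row.names = NULL)
}

#' Compare two measurement platforms over shared features
#'
#' Per-feature median profiles are computed across participants on each
#' platform and compared with one overall Spearman correlation; per-feature
#' correlations across participants flag features that do not transfer
#' (rho < 0.5).
#'
#' @param mA,mB feature x participant matrices with shared feature ids.
#' @param flag_below per-feature correlation threshold (default 0.5).
#' @return List: \code{medians} (feature, medianA, medianB),
#'   \code{rho}, \code{p} (median-profile Spearman), \code{feature_cor}
#'   (per-feature rho), \code{low_correlation} (flagged feature ids).
#' @export
comparePlatforms <- function(mA, mB, flag_below = 0.5) {
    shared <- intersect(rownames(mA), rownames(mB))
    if (length(shared) < 3L) stop("need at least 3 shared features")
    mA <- mA[shared, , drop = FALSE]; mB <- mB[shared, , drop = FALSE]
    medA <- apply(mA, 1L, stats::median, na.rm = TRUE)
    medB <- apply(mB, 1L, stats::median, na.rm = TRUE)
    ct <- suppressWarnings(stats::cor.test(medA, medB, method = "spearman"))
    common_part <- intersect(colnames(mA), colnames(mB))
    fc <- if (length(common_part) >= 3L)
        vapply(shared, function(f)
            suppressWarnings(stats::cor(mA[f, common_part], mB[f, common_part],
                                        method = "spearman",
                                        use = "pairwise.complete.obs")),
            numeric(1))
    else setNames(rep(NA_real_, length(shared)), shared)
    list(medians = data.frame(feature = shared, medianA = medA, medianB = medB,
                              row.names = NULL),
         rho = unname(ct$estimate), p = ct$p.value,
         feature_cor = fc,
         low_correlation = names(fc)[!is.na(fc) & fc < flag_below])
}
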