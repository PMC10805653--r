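#' @include AllClasses.R
NULL

#' Read a wide analyte-by-sample table with sample metadata
#'
#' The matrix file is CSV or TSV (sniffed from the extension, or forced with
#' \code{sep}) whose first column holds analyte ids and remaining columns one
#' sample each. The metadata file is keyed by \code{sample_id} and must carry
#' \code{participant}; \code{timestamp_min}, \code{timepoint}, \code{assay}
#' are optional. Cells that fail numeric parsing become \code{NA} and the
#' count is reported via \code{message()}.
#'
#' @param path matrix file.
#' @param meta_path sample metadata file.
#' @param sep field separator; default inferred (".tsv"/".txt" = tab).
#' @return A validated [OmicsTimeCourse-class].
#' @export
readOmicsTable <- function(path, meta_path, sep = NULL) {
    sniff <- function(f) if (grepl("\\.(tsv|txt)$", f, ignore.case = TRUE)) "\t" else ","
    if (is.null(sep)) sep <- sniff(path)
    raw <- utils::read.table(path, sep = sep, header = TRUE,
                             check.names = FALSE, colClasses = "character")
    ids <- raw[[1L]]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicated analyte ids: ", paste(dup, collapse = ", "))
    samp <- colnames(raw)[-1L]
    dup <- unique(samp[duplicated(samp)])
    if (length(dup))
        stop("duplicated sample ids: ", paste(dup, collapse = ", "))
    vals <- suppressWarnings(
        vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
    if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
    dimnames(vals) <- list(ids, samp)
    n_bad <- sum(is.na(vals) & !is.na(as.matrix(raw[-1L])) &
                 as.matrix(raw[-1L]) != "")
    n_missing <- sum(is.na(vals))
    if (n_missing)
        message(n_missing, " missing entries after parsing (",
                n_bad, " unparseable cells)")
    meta <- utils::read.table(meta_path, sep = sniff(meta_path), header = TRUE,
                              check.names = FALSE, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(meta)) stop("metadata needs a 'sample_id' column")
    unmatched <- setdiff(samp, meta$sample_id)
    if (length(unmatched))
        stop("samples without metadata: ", paste(unmatched, collapse = ", "))
    meta <- meta[match(samp, meta$sample_id), , drop = FALSE]
    cls <- if ("analyte_class" %in% names(meta)) NULL else NULL
    OmicsTimeCourse(
        vals,
        analyte_class = "other",
        participant = meta$participant,
        timestamp_min = if ("timestamp_min" %in% names(meta))
            meta$timestamp_min else NA_real_,
        timepoint = if ("timepoint" %in% names(meta))
            as.character(meta$timepoint) else NA_character_,
        assay_batch = if ("assay" %in% names(meta)) meta$assay else NULL)
}

#' Log2 transform then autoscale each analyte
#'
#' Per analyte: \code{x -> log2(x)}, then centre to mean 0 and scale to unit
#' standard deviation across samples (missing values ignored). Zero-variance
#' analytes are set to 0 and flagged in \code{rowData(x)$zero_variance}.
#'
#' @param x an [OmicsTimeCourse-class]; all values positive or missing.
#' @return The transformed object.
#' @export
log2Autoscale <- function(x) {
    v <- omicsValues(x)
    bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop("non-positive value at analyte '", rownames(v)[bad[1, 1]],
             "', sample '", colnames(v)[bad[1, 2]], "'")
    lv <- log2(v)
    mu <- rowMeans(lv, na.rm = TRUE)
    sdv <- apply(lv, 1L, stats::sd, na.rm = TRUE)
    zero <- is.na(sdv) | sdv == 0
    out <- (lv - mu) / ifelse(zero, 1, sdv)
    out[zero, ] <- 0
    assay(x, "values") <- out
    rowData(x)$zero_variance <- zero
    metadata(x)$autoscaled <- TRUE
    x
}

#' K-nearest-neighbour imputation over analyte rows
#'
#' Each missing value of an analyte is replaced by the mean, in that sample,
#' of the \code{k} analytes nearest to it (Euclidean distance over mutually
#' observed samples, scaled to per-sample distance so differing overlap sizes
#' compare fairly). Only analytes observed in the target sample count as
#' neighbours. Ties in distance are broken by row order (deterministic).
#'
#' @param x an [OmicsTimeCourse-class].
#' @param k number of neighbours (default 10).
#' @return The imputed object; non-missing entries are untouched.
#' @export
imputeKnn <- function(x, k = 10L) {
    v <- omicsValues(x)
    if (!anyNA(v)) return(x)
    all_missing <- rownames(v)[rowSums(!is.na(v)) == 0L]
    if (length(all_missing))
        stop("analytes missing in all samples (filter first): ",
             paste(all_missing, collapse = ", "))
    out <- v
    incomplete <- which(rowSums(is.na(v)) > 0L)
    for (i in incomplete) {
        obs_i <- !is.na(v[i, ])
        ## mean squared difference over mutually observed samples
        shared <- sweep(!is.na(v), 2L, obs_i, "&")
        diff2 <- (v - matrix(v[i, ], nrow(v), ncol(v), byrow = TRUE))^2
        diff2[!shared] <- NA
        n_sh <- rowSums(shared)
        d2 <- rowSums(diff2, na.rm = TRUE) / n_sh
        d2[i] <- Inf
        d2[n_sh == 0L] <- Inf
        for (j in which(is.na(v[i, ]))) {
            cand <- d2
            cand[is.na(v[, j])] <- Inf
            ord <- order(cand)               # stable: ties broken by row order
            ord <- ord[is.finite(cand[ord])]
            if (length(ord) < k)
                stop("fewer than k=", k, " usable neighbours for analyte '",
                     rownames(v)[i], "', sample '", colnames(v)[j], "'")
            out[i, j] <- mean(v[ord[seq_len(k)], j])
        }
    }
    assay(x, "values") <- out
    x
}

#' Drop analytes by presence fraction
#'
#' Analytes observed (non-missing) in strictly more than
#' \code{min_fraction_present} of samples are retained; the removal count is
#' reported via \code{message()}.
#'
#' @param x an [OmicsTimeCourse-class].
#' @param min_fraction_present threshold in (0, 1]; strict ">" (an analyte
#'   present in exactly 50\% of samples is removed at 0.5).
#' @return The filtered object.
#' @export
filterMissingness <- function(x, min_fraction_present = 0.5) {
    stopifnot(min_fraction_present > 0, min_fraction_present <= 1)
    v <- omicsValues(x)
    frac <- rowMeans(!is.na(v))
    keep <- frac > min_fraction_present
    if (!any(keep))
        stop("no analytes pass presence > ", min_fraction_present,
             "; lower the threshold")
    message(sum(!keep), " analytes removed, ", sum(keep), " retained")
    x[keep, ]
}

#' Per-analyte coefficient of variation from log2 data
#'
#' For log-normal intensities the natural-scale CV is recovered from the
#' spread of the logs: with \eqn{\sigma} the standard deviation of an
#' analyte's log2 values, \eqn{CV = \sqrt{e^{(\sigma \ln 2)^2} - 1}}. When
#' \code{group_by_participant} is \code{TRUE} the CV is computed within each
#' participant's samples and the mean across participants is returned; groups
#' with fewer than 2 samples are excluded with a warning.
#'
#' @param x an [OmicsTimeCourse-class] holding log2 values (not autoscaled:
#'   autoscaling destroys the scale the formula needs and is rejected).
#' @param group_by_participant average per-participant CVs (default TRUE).
#' @return Named numeric vector of CVs per analyte.
#' @export
cvLogScale <- function(x, group_by_participant = TRUE) {
    if (isTRUE(metadata(x)$autoscaled))
        stop("input is autoscaled; CV on the log scale requires ",
             "log2-transformed but unscaled data")
    v <- omicsValues(x)
    cv_of_sigma <- function(s) sqrt(exp((s * log(2))^2) - 1)
    if (!group_by_participant) {
        s <- apply(v, 1L, stats::sd, na.rm = TRUE)
        return(setNames(cv_of_sigma(s), rownames(v)))
    }
    part <- participants(x)
    res <- matrix(NA_real_, nrow(v), length(unique(part)),
                  dimnames = list(rownames(v), unique(part)))
    for (p in unique(part)) {
        idx <- which(part == p)
        if (length(idx) < 2L) {
            warning("participant '", p, "' has < 2 samples; excluded from CV")
            next
        }
        s <- apply(v[, idx, drop = FALSE], 1L, stats::sd, na.rm = TRUE)
        res[, p] <- cv_of_sigma(s)
    }
    rowMeans(res, na.rm = TRUE)
}
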