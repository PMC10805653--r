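## Shared fixtures and small independent oracles used across the suite.

toy_otc <- function(values = NULL, n_analytes = 3, n_samples = 4,
                    participant = "P1") {
    if (is.null(values)) {
        values <- matrix(2^seq_len(n_analytes * n_samples),
                         n_analytes, n_samples)
    }
    dimnames(values) <- list(paste0("a", seq_len(nrow(values))),
                             paste0("s", seq_len(ncol(values))))
    OmicsTimeCourse(values, "metabolite",
                    participant = rep_len(participant, ncol(values)),
                    timestamp_min = seq(0, by = 60,
                                        length.out = ncol(values)))
}

## adjusted Rand index (independent, textbook contingency formula)
ari <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sij <- sum(comb2(tab))
    si <- sum(comb2(rowSums(tab)))
    sj <- sum(comb2(colSums(tab)))
    n2 <- comb2(sum(tab))
    exp_idx <- si * sj / n2
    (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

## brute-force BH step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
}

## mean profile per timepoint for shake cohorts (log2 scale)
shake_profiles <- function(cohort, analytes = NULL) {
    v <- log2(omicsValues(cohort))
    tp <- timepoints(cohort)
    ord <- c("0", "30", "60", "120", "240")
    if (is.null(analytes)) analytes <- rownames(v)
    t(vapply(analytes, function(a)
        tapply(v[a, ], tp, mean)[ord], numeric(5)))
}
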