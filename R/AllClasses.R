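#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

## Central data containers. OmicsTimeCourse rides on SummarizedExperiment so
## the usual assay/rowData/colData machinery (subsetting, binding) comes free;
## the class only adds the temporal-design validity rules every downstream
## stage assumes.

#' OmicsTimeCourse: an analyte x sample matrix with temporal sample metadata
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay \code{"values"}
#' holds analyte intensities (rows = analytes, columns = samples; \code{NA}
#' allowed before imputation). \code{rowData} carries \code{analyte_class}
#' (one of metabolite, lipid, protein, cytokine, hormone, other); \code{colData}
#' carries \code{participant}, \code{timestamp_min} (minutes since study start,
#' may be \code{NA} for purely categorical designs), \code{timepoint}
#' (categorical label, may be \code{NA}) and optional \code{assay_batch}.
#'
#' Validity: unique analyte and sample ids; within each participant,
#' non-missing timestamps strictly increasing in column order; no duplicated
#' (participant, timestamp) pair.
#'
#' @seealso [OmicsTimeCourse()] for the user constructor.
#' @export
setClass("OmicsTimeCourse", contains = "SummarizedExperiment")

.ANALYTE_CLASSES <- c("metabolite", "lipid", "protein", "cytokine",
                      "hormone", "other")

setValidity("OmicsTimeCourse", function(object) {
    msg <- character()
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "analyte ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    cd <- colData(object)
    need <- c("participant", "timestamp_min", "timepoint")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
    if (!"analyte_class" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain 'analyte_class'")
    else {
        bad <- setdiff(unique(rowData(object)$analyte_class), .ANALYTE_CLASSES)
        if (length(bad))
            msg <- c(msg, paste("unknown analyte_class:", paste(bad, collapse = ", ")))
    }
    if (all(need %in% colnames(cd))) {
        for (p in unique(cd$participant)) {
            ts <- cd$timestamp_min[cd$participant == p]
            ts <- ts[!is.na(ts)]
            if (length(ts) > 1L && any(diff(ts) <= 0))
                msg <- c(msg, paste0("timestamps not strictly increasing for participant '",
                                     p, "'"))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct an OmicsTimeCourse
#'
#' @param values numeric matrix, analytes x samples; dimnames required.
#' @param analyte_class character vector (length nrow) of analyte classes, or a
#'   single class recycled to all analytes.
#' @param participant,timestamp_min,timepoint per-sample metadata vectors.
#' @param assay_batch optional per-sample batch labels.
#' @return A validated \linkS4class{OmicsTimeCourse}.
#' @examples
#' m <- matrix(rlnorm(12), 3, 4,
#'             dimnames = list(paste0("a", 1:3), paste0("s", 1:4)))
#' otc <- OmicsTimeCourse(m, "metabolite",
#'                        participant = rep("P1", 4),
#'                        timestamp_min = c(0, 60, 120, 180))
#' @export
OmicsTimeCourse <- function(values, analyte_class = "other",
                            participant, timestamp_min = NA_real_,
                            timepoint = NA_character_, assay_batch = NULL) {
    if (!is.matrix(values)) values <- as.matrix(values)
    if (length(analyte_class) == 1L)
        analyte_class <- rep(analyte_class, nrow(values))
    cd <- DataFrame(participant = as.character(participant),
                    timestamp_min = as.numeric(rep_len(timestamp_min, ncol(values))),
                    timepoint = as.character(rep_len(timepoint, ncol(values))),
                    row.names = colnames(values))
    if (!is.null(assay_batch)) cd$assay_batch <- assay_batch
    se <- SummarizedExperiment(
        assays = list(values = values),
        rowData = DataFrame(analyte_class = analyte_class,
                            row.names = rownames(values)),
        colData = cd)
    new("OmicsTimeCourse", se)
}

#' WearableStream: a single wearable sensor time series
#'
#' One (timestamp, value) stream at native device frequency. Timestamps are
#' minutes since study start and must be strictly increasing; values are
#' non-negative and complete.
#'
#' @slot kind one of \code{"HR"}, \code{"steps"}, \code{"CGM"}.
#' @slot timestamps numeric, minutes, strictly increasing.
#' @slot values numeric, non-negative, no \code{NA}.
#' @export
setClass("WearableStream",
         representation(kind = "character", timestamps = "numeric",
                        values = "numeric"))

setValidity("WearableStream", function(object) {
    msg <- character()
    if (!object@kind %in% c("HR", "steps", "CGM"))
        msg <- c(msg, "kind must be one of HR, steps, CGM")
    if (length(object@timestamps) != length(object@values))
        msg <- c(msg, "timestamps and values differ in length")
    if (length(object@timestamps) > 1L && any(diff(object@timestamps) <= 0))
        msg <- c(msg, "timestamps must be strictly increasing")
    if (anyNA(object@values))
        msg <- c(msg, "values must not contain NA")
    if (length(object@values) && min(object@values) < 0)
        msg <- c(msg, "values must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @rdname WearableStream-class
#' @param kind,timestamps,values see slot descriptions.
#' @export
WearableStream <- function(kind, timestamps, values) {
    new("WearableStream", kind = kind, timestamps = as.numeric(timestamps),
        values = as.numeric(values))
}

.NUTRIENT_CLASSES <- c("amino acids", "vitamins", "fat", "electrolytes",
                       "calories", "carbs", "fibre")

#' FoodLog: timestamped nutrient-class intake records
#'
#' @slot records data.frame with columns \code{timestamp_min},
#'   \code{nutrient_class} (fixed vocabulary: amino acids, vitamins, fat,
#'   electrolytes, calories, carbs, fibre) and \code{amount}.
#' @export
setClass("FoodLog", representation(records = "data.frame"))

setValidity("FoodLog", function(object) {
    r <- object@records
    need <- c("timestamp_min", "nutrient_class", "amount")
    if (!all(need %in% names(r)))
        return(paste("records needs columns:", paste(need, collapse = ", ")))
    bad <- setdiff(unique(r$nutrient_class), .NUTRIENT_CLASSES)
    if (length(bad))
        return(paste("unknown nutrient_class:", paste(bad, collapse = ", ")))
    TRUE
})

#' @rdname FoodLog-class
#' @param timestamp_min,nutrient_class,amount record fields.
#' @export
FoodLog <- function(timestamp_min, nutrient_class, amount = 1) {
    new("FoodLog", records = data.frame(
        timestamp_min = as.numeric(timestamp_min),
        nutrient_class = as.character(nutrient_class),
        amount = as.numeric(rep_len(amount, length(timestamp_min)))))
}

#' LagScan: one lagged-correlation scan between two asynchronous series
#'
#' Produced by [laggedCorrelation()]. Holds the per-shift Spearman correlation
#' curve, the matched-pair counts, the best (maximum absolute) correlation with
#' its shift, the Gaussian-predicted curve and the Gaussian-fit quality score.
#'
#' @slot shifts numeric shift grid (minutes), symmetric about 0.
#' @slot window matching window Tw (minutes).
#' @slot n_pairs matched pairs per shift.
#' @slot cor,p per-shift Spearman rho and p (NA where pairs < min_pairs).
#' @slot best_shift,best_cor,best_p the reported lagged correlation.
#' @slot pcor Gaussian-fit predicted correlations (length of shifts).
#' @slot quality absolute Spearman correlation between pcor and cor, in [0,1].
#' @slot fit_converged logical; FALSE forces quality 0.
#' @export
setClass("LagScan",
         representation(shifts = "numeric", window = "numeric",
                        n_pairs = "integer", cor = "numeric", p = "numeric",
                        best_shift = "numeric", best_cor = "numeric",
                        best_p = "numeric", pcor = "numeric",
                        quality = "numeric", fit_converged = "logical"))

setValidity("LagScan", function(object) {
    msg <- character()
    s <- object@shifts
    if (length(s) && abs(s[1] + s[length(s)]) > 1e-8)
        msg <- c(msg, "shift grid must be symmetric about 0")
    if (!is.na(object@quality) &&
        (object@quality < 0 || object@quality > 1))
        msg <- c(msg, "quality must lie in [0, 1]")
    if (!is.na(object@best_shift) && !any(abs(s - object@best_shift) < 1e-8))
        msg <- c(msg, "best_shift must be on the shift grid")
    ok <- !is.na(object@cor)
    if (any(ok) && (max(abs(object@cor[ok])) > 1 + 1e-12))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' ScorePanel: metabolic response scores for a meal-challenge cohort
#'
#' @slot auc molecule x participant matrix of baseline-subtracted AUCs.
#' @slot nauc min-max normalized AUCs in [0, 1] (per molecule across
#'   participants).
#' @slot scores participant x score matrix of final metabolic scores in [0, 1]
#'   (inversion already applied for clearance-type panels).
#' @slot groups integer group id per participant (hierarchical, Ward).
#' @slot flagged molecules with zero AUC range (normalized to 0.5).
#' @export
setClass("ScorePanel",
         representation(auc = "matrix", nauc = "matrix", scores = "matrix",
                        groups = "integer", flagged = "character"))

setValidity("ScorePanel", function(object) {
    msg <- character()
    if (length(object@nauc) && (min(object@nauc, na.rm = TRUE) < -1e-9 ||
                                max(object@nauc, na.rm = TRUE) > 1 + 1e-9))
        msg <- c(msg, "normalized AUCs must lie in [0, 1]")
    if (length(object@scores) && (min(object@scores, na.rm = TRUE) < -1e-9 ||
                                  max(object@scores, na.rm = TRUE) > 1 + 1e-9))
        msg <- c(msg, "scores must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' SmoothedCourse: day-wise LOESS-smoothed molecule courses on a 30-min grid
#'
#' @slot grid numeric grid timestamps (minutes since study start); spacing is
#'   the grid step within a day, grid points never bridge the between-day gap.
#' @slot day integer day index per grid point.
#' @slot values molecule x grid-point matrix of fitted values.
#' @slot span named numeric, CV-chosen LOESS span per molecule.
#' @slot step grid step in minutes.
#' @export
setClass("SmoothedCourse",
         representation(grid = "numeric", day = "integer", values = "matrix",
                        span = "numeric", step = "numeric"))

setValidity("SmoothedCourse", function(object) {
    msg <- character()
    if (length(object@grid) != ncol(object@values))
        msg <- c(msg, "grid length must match value columns")
    if (length(object@grid) != length(object@day))
        msg <- c(msg, "day index length must match grid")
    d <- diff(object@grid)
    same <- diff(object@day) == 0L
    if (any(same) && any(abs(d[same] - object@step) > 1e-6))
        msg <- c(msg, "within-day grid step must equal 'step'")
    if (length(msg)) msg else TRUE
})
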