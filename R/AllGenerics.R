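#' @include AllClasses.R
NULL

#' Accessors for densomics classes
#'
#' \code{omicsValues} returns the assay matrix; \code{analyteClass},
#' \code{participants}, \code{timestamps} and \code{timepoints} return the
#' corresponding metadata vectors of an \linkS4class{OmicsTimeCourse}.
#' \code{bestShift}, \code{bestCor} and \code{qualityScore} read a
#' \linkS4class{LagScan}; \code{metabolicScores} and \code{participantGroups}
#' read a \linkS4class{ScorePanel}.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))
#' @rdname accessors
#' @export
setMethod("omicsValues", "OmicsTimeCourse", function(x) assay(x, "values"))

#' @rdname accessors
#' @export
setGeneric("analyteClass", function(x) standardGeneric("analyteClass"))
#' @rdname accessors
#' @export
setMethod("analyteClass", "OmicsTimeCourse", function(x) {
    setNames(as.character(rowData(x)$analyte_class), rownames(x))
})

#' @rdname accessors
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))
#' @rdname accessors
#' @export
setMethod("participants", "OmicsTimeCourse", function(x) {
    setNames(as.character(colData(x)$participant), colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))
#' @rdname accessors
#' @export
setMethod("timestamps", "OmicsTimeCourse", function(x) {
    setNames(colData(x)$timestamp_min, colnames(x))
})
#' @rdname accessors
#' @export
setMethod("timestamps", "WearableStream", function(x) x@timestamps)

#' @rdname accessors
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))
#' @rdname accessors
#' @export
setMethod("timepoints", "OmicsTimeCourse", function(x) {
    setNames(as.character(colData(x)$timepoint), colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("streamValues", function(x) standardGeneric("streamValues"))
#' @rdname accessors
#' @export
setMethod("streamValues", "WearableStream", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("streamKind", function(x) standardGeneric("streamKind"))
#' @rdname accessors
#' @export
setMethod("streamKind", "WearableStream", function(x) x@kind)

#' @rdname accessors
#' @export
setGeneric("foodRecords", function(x) standardGeneric("foodRecords"))
#' @rdname accessors
#' @export
setMethod("foodRecords", "FoodLog", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("bestShift", function(x) standardGeneric("bestShift"))
#' @rdname accessors
#' @export
setMethod("bestShift", "LagScan", function(x) x@best_shift)

#' @rdname accessors
#' @export
setGeneric("bestCor", function(x) standardGeneric("bestCor"))
#' @rdname accessors
#' @export
setMethod("bestCor", "LagScan", function(x) x@best_cor)

#' @rdname accessors
#' @export
setGeneric("scanCurve", function(x) standardGeneric("scanCurve"))
#' @rdname accessors
#' @export
setMethod("scanCurve", "LagScan", function(x) {
    data.frame(shift = x@shifts, n_pairs = x@n_pairs, cor = x@cor, p = x@p,
               pcor = x@pcor)
})

#' @rdname accessors
#' @export
setGeneric("metabolicScores", function(x) standardGeneric("metabolicScores"))
#' @rdname accessors
#' @export
setMethod("metabolicScores", "ScorePanel", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("participantGroups", function(x) standardGeneric("participantGroups"))
#' @rdname accessors
#' @export
setMethod("participantGroups", "ScorePanel", function(x) x@groups)

#' @rdname accessors
#' @export
setGeneric("smoothedValues", function(x) standardGeneric("smoothedValues"))
#' @rdname accessors
#' @export
setMethod("smoothedValues", "SmoothedCourse", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("smoothedGrid", function(x) standardGeneric("smoothedGrid"))
#' @rdname accessors
#' @export
setMethod("smoothedGrid", "SmoothedCourse", function(x) {
    data.frame(time = x@grid, day = x@day)
})

setMethod("show", "WearableStream", function(object) {
    cat("WearableStream <", object@kind, "> ", length(object@values),
        " points, t in [", min(object@timestamps), ", ",
        max(object@timestamps), "] min\n", sep = "")
})

setMethod("show", "FoodLog", function(object) {
    cat("FoodLog with", nrow(object@records), "records,",
        length(unique(object@records$nutrient_class)), "nutrient classes\n")
})

setMethod("show", "LagScan", function(object) {
    cat("LagScan: ", length(object@shifts), " shifts, Tw = ", object@window,
        " min\n  best shift ", object@best_shift, " min, rho = ",
        round(object@best_cor, 3), " (p = ", signif(object@best_p, 3),
        "), quality = ", round(object@quality, 3), "\n", sep = "")
})

setMethod("show", "ScorePanel", function(object) {
    cat("ScorePanel:", nrow(object@scores), "participants x",
        ncol(object@scores), "scores;",
        length(unique(object@groups)), "groups\n")
})

setMethod("show", "SmoothedCourse", function(object) {
    cat("SmoothedCourse:", nrow(object@values), "molecules on",
        ncol(object@values), "grid points (", object@step, "min step,",
        length(unique(object@day)), "days )\n")
})
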