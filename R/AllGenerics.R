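#' @rdname accessors
#' @export
setGeneric("visitRecords", function(x) standardGeneric("visitRecords"))

#' @rdname accessors
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))

#' @rdname accessors
#' @export
setGeneric("siteName", function(x) standardGeneric("siteName"))

#' @rdname accessors
#' @export
setGeneric("birdSpecies", function(x) standardGeneric("birdSpecies"))

#' @rdname accessors
#' @export
setGeneric("plantSpecies", function(x) standardGeneric("plantSpecies"))

#' @rdname accessors
#' @export
setGeneric("plantTraits", function(x) standardGeneric("plantTraits"))

#' @rdname accessors
#' @export
setGeneric("birdTraits", function(x) standardGeneric("birdTraits"))

#' @rdname accessors
#' @export
setGeneric("zValue", function(x) standardGeneric("zValue"))

#' @rdname accessors
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' Accessors for hummnet classes
#'
#' Small read-only accessors: `visitRecords` returns the records data.frame
#' of a [MonthlyVisitTable-class]; `rateMatrix`, `siteName`, `birdSpecies`
#' and `plantSpecies` unpack a [QuantitativeNetwork-class]; `plantTraits` /
#' `birdTraits` unpack a [TraitTable-class]; `zValue` and `nullValues` read
#' a [ZScoreReport-class]; `moduleLabels` returns the named list of
#' row/column module ids of a [ModulePartition-class].
#'
#' @param x the object.
#' @return See description; each accessor returns the corresponding slot
#'   content.
#' @name accessors
#' @aliases visitRecords,MonthlyVisitTable-method
NULL

#' @rdname accessors
setMethod("visitRecords", "MonthlyVisitTable", function(x) x@records)

#' @rdname accessors
setMethod("rateMatrix", "QuantitativeNetwork", function(x) x@rates)

#' @rdname accessors
setMethod("siteName", "QuantitativeNetwork", function(x) x@site)

#' @rdname accessors
setMethod("birdSpecies", "QuantitativeNetwork", function(x) rownames(x@rates))

#' @rdname accessors
setMethod("plantSpecies", "QuantitativeNetwork", function(x) colnames(x@rates))

#' @rdname accessors
setMethod("birdSpecies", "MonthlyVisitTable", function(x)
    sort(unique(x@records$bird[!is.na(x@records$bird) & x@records$visits > 0])))

#' @rdname accessors
setMethod("plantSpecies", "MonthlyVisitTable", function(x)
    sort(unique(x@records$plant)))

#' @rdname accessors
setMethod("plantTraits", "TraitTable", function(x) x@plantTraits)

#' @rdname accessors
setMethod("birdTraits", "TraitTable", function(x) x@birdTraits)

#' @rdname accessors
setMethod("zValue", "ZScoreReport", function(x) x@z)

#' @rdname accessors
setMethod("nullValues", "ZScoreReport", function(x) x@nullValues)

#' @rdname accessors
setMethod("moduleLabels", "ModulePartition", function(x)
    list(rows = x@rowLabels, cols = x@colLabels))

setMethod("show", "MonthlyVisitTable", function(object) {
    rec <- object@records
    cat("MonthlyVisitTable:", nrow(rec), "records |",
        length(unique(rec$site)), "site(s),",
        length(unique(rec$month)), "month(s) |",
        sum(rec$visits), "visits\n")
})

setMethod("show", "QuantitativeNetwork", function(object) {
    A <- object@rates
    cat(sprintf(
        "QuantitativeNetwork '%s': %d hummingbirds x %d plants, %d links, %.3g visits/h total\n",
        object@site, nrow(A), ncol(A), sum(A > 0), sum(A)))
})

setMethod("show", "ZScoreReport", function(object) {
    cat(sprintf("ZScoreReport [%s]: observed %.4g, null %.4g +/- %.4g, z = %s (n = %d, dropped %d)\n",
                object@statistic, object@observed, object@nullMean,
                object@nullSd,
                if (is.na(object@z)) "NA (degenerate null)"
                else sprintf("%.3f", object@z),
                object@nSims, object@nDropped))
})

setMethod("show", "ModulePartition", function(object) {
    cat(sprintf("ModulePartition: %d modules, Barber Q = %.4f\n",
                length(unique(c(object@rowLabels, object@colLabels))),
                object@Q))
})
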