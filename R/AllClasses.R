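#' @import methods
NULL

#' Long-format monthly visitation records
#'
#' Holds the unit of observation of a camera-transect study: for every site,
#' month and filmed plant species, how many visits each hummingbird species
#' paid and for how many hours that plant was filmed. Plants that were filmed
#' but received no visits are kept as rows with `visits = 0` and `bird = NA`;
#' they carry the sampling effort that the null models need.
#'
#' Validity enforces: a visit can only be recorded on a filmed plant
#' (`visits > 0` implies `recording_hours > 0`); recording hours are identical
#' across all records sharing (site, month, plant); no duplicated
#' (site, month, plant, bird) keys; visits are non-negative integers and
#' hours non-negative reals.
#'
#' @slot records data.frame with columns `site`, `month` (integer index from
#'   study start), `plant`, `bird` (NA for filmed-only rows), `visits`,
#'   `recording_hours`.
#' @export
setClass("MonthlyVisitTable", representation(records = "data.frame"))

.validVisitTable <- function(object) {
    rec <- object@records
    need <- c("site", "month", "plant", "bird", "visits", "recording_hours")
    miss <- setdiff(need, names(rec))
    if (length(miss))
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    msgs <- character(0)
    if (any(!is.finite(rec$visits)) || any(rec$visits < 0) ||
        any(rec$visits != round(rec$visits)))
        msgs <- c(msgs, "visits must be non-negative integers")
    if (any(!is.finite(rec$recording_hours)) || any(rec$recording_hours < 0))
        msgs <- c(msgs, "recording_hours must be non-negative and finite")
    bad <- which(rec$visits > 0 & rec$recording_hours <= 0)
    if (length(bad))
        msgs <- c(msgs, sprintf(
            "visits recorded on unfilmed plant-months (rows %s)",
            paste(utils::head(bad, 5L), collapse = ", ")))
    smp <- paste(rec$site, rec$month, rec$plant, sep = "\r")
    hrs <- tapply(rec$recording_hours, smp, function(x) diff(range(x)))
    if (any(hrs > 1e-9))
        msgs <- c(msgs, sprintf(
            "recording_hours differ within (site, month, plant): %s",
            paste(utils::head(names(hrs)[hrs > 1e-9], 3L), collapse = "; ")))
    key <- paste(smp, ifelse(is.na(rec$bird), "\r<none>", rec$bird))
    if (anyDuplicated(key))
        msgs <- c(msgs, sprintf(
            "duplicated (site, month, plant, bird) keys (e.g. row %d)",
            which(duplicated(key))[1L]))
    if (length(msgs)) msgs else TRUE
}
setValidity("MonthlyVisitTable", .validVisitTable)

#' Construct a MonthlyVisitTable
#'
#' @param records data.frame with columns `site`, `month`, `plant`, `bird`,
#'   `visits`, `recording_hours`. `bird` may be NA on zero-visit rows that
#'   only register camera effort.
#' @return A validated [MonthlyVisitTable-class] object.
#' @examples
#' rec <- data.frame(site = "s1", month = 1L, plant = "P1", bird = "H1",
#'                   visits = 6L, recording_hours = 3)
#' MonthlyVisitTable(rec)
#' @export
MonthlyVisitTable <- function(records) {
    records <- as.data.frame(records)
    for (cc in c("site", "plant", "bird"))
        records[[cc]] <- as.character(records[[cc]])
    records$month <- as.integer(records$month)
    records$visits <- as.numeric(records$visits)
    records$recording_hours <- as.numeric(records$recording_hours)
    rownames(records) <- NULL
    new("MonthlyVisitTable", records = records)
}

#' Site-level quantitative bipartite network
#'
#' A hummingbird-by-plant matrix of visitation rates (visits per hour of
#' camera recording) for one site. Rows are hummingbird species, columns are
#' plant species; every row and column has at least one positive entry
#' (species with no realized interaction are dropped at construction).
#'
#' @slot site character site identifier.
#' @slot rates numeric matrix, birds x plants, with dimnames; finite,
#'   non-negative, no empty row or column.
#' @export
setClass("QuantitativeNetwork",
         representation(site = "character", rates = "matrix"))

setValidity("QuantitativeNetwork", function(object) {
    A <- object@rates
    if (!is.numeric(A)) return("rates must be numeric")
    if (any(!is.finite(A)) || any(A < 0))
        return("rates must be finite and non-negative")
    if (is.null(rownames(A)) || is.null(colnames(A)))
        return("rates must carry species dimnames")
    if (any(rowSums(A) == 0) || any(colSums(A) == 0))
        return("empty rows/columns must be dropped before construction")
    TRUE
})

#' Per-species trait tables for both guilds
#'
#' @slot plantTraits data.frame, one row per plant species (rownames), with
#'   columns `corolla_length` (mm), `corolla_opening` (mm),
#'   `corolla_curvature` (1/mm, >= 0).
#' @slot birdTraits data.frame, one row per hummingbird species (rownames),
#'   with columns `bill_length` (mm), `body_mass` (g), `tail_length` (mm),
#'   `wing_chord` (mm), `tarsus_length` (mm).
#' @export
setClass("TraitTable",
         representation(plantTraits = "data.frame", birdTraits = "data.frame"))

setValidity("TraitTable", function(object) {
    pt <- object@plantTraits; bt <- object@birdTraits
    pneed <- c("corolla_length", "corolla_opening", "corolla_curvature")
    bneed <- c("bill_length", "body_mass", "tail_length", "wing_chord",
               "tarsus_length")
    if (length(setdiff(pneed, names(pt))))
        return("plantTraits lacks required columns")
    if (length(setdiff(bneed, names(bt))))
        return("birdTraits lacks required columns")
    if (anyDuplicated(rownames(pt)) || anyDuplicated(rownames(bt)))
        return("one entry per species identifier required")
    strict <- c(pt$corolla_length, pt$corolla_opening,
                bt$bill_length, bt$body_mass, bt$tail_length,
                bt$wing_chord, bt$tarsus_length)
    if (any(!is.finite(strict)) || any(strict <= 0))
        return("trait values must be strictly positive")
    if (any(!is.finite(pt$corolla_curvature)) || any(pt$corolla_curvature < 0))
        return("corolla_curvature must be >= 0")
    TRUE
})

#' Construct a TraitTable
#'
#' @param plantTraits,birdTraits data.frames keyed by species (rownames or a
#'   `species` column) with the trait columns documented in
#'   [TraitTable-class].
#' @return A validated [TraitTable-class] object.
#' @export
TraitTable <- function(plantTraits, birdTraits) {
    fix <- function(df) {
        df <- as.data.frame(df)
        if ("species" %in% names(df)) {
            rownames(df) <- as.character(df$species)
            df$species <- NULL
        }
        df
    }
    new("TraitTable", plantTraits = fix(plantTraits), birdTraits = fix(birdTraits))
}

#' Observed value of a statistic against its null distribution
#'
#' The z-score is `(observed - mean(nulls)) / sd(nulls)` with the sample
#' standard deviation. A degenerate null (sd = 0) yields `z = NA` (an
#' undefined flag, never +/-Inf).
#'
#' @slot statistic character label of the summarized statistic.
#' @slot observed,nullMean,nullSd numeric scalars.
#' @slot z numeric scalar, NA when the null is degenerate.
#' @slot nSims integer, number of null values the summary is based on
#'   (after dropping draws where the statistic was undefined).
#' @slot nDropped integer, number of null draws dropped as undefined.
#' @slot nullValues numeric vector of retained null values (possibly empty
#'   if not stored).
#' @export
setClass("ZScoreReport", representation(
    statistic = "character", observed = "numeric", nullMean = "numeric",
    nullSd = "numeric", z = "numeric", nSims = "integer",
    nDropped = "integer", nullValues = "numeric"))

setValidity("ZScoreReport", function(object) {
    if (length(object@z) == 1L && is.finite(object@z) &&
        is.finite(object@nullSd) && object@nullSd > 0) {
        want <- (object@observed - object@nullMean) / object@nullSd
        if (abs(object@z - want) > 1e-8 * max(1, abs(want)))
            return("z inconsistent with (observed - nullMean)/nullSd")
    }
    if (length(object@z) == 1L && !is.na(object@z) && !is.finite(object@z))
        return("z must be finite or NA, never +/-Inf")
    TRUE
})

#' Bipartite module partition with its Barber modularity
#'
#' @slot rowLabels,colLabels integer module ids (a contiguous set starting
#'   at 1) for the network's birds and plants.
#' @slot Q numeric, Barber weighted bipartite modularity of the partition.
#' @export
setClass("ModulePartition", representation(
    rowLabels = "integer", colLabels = "integer", Q = "numeric"))

setValidity("ModulePartition", function(object) {
    ids <- sort(unique(c(object@rowLabels, object@colLabels)))
    if (!identical(ids, seq_along(ids)))
        return("module ids must form a contiguous set starting at 1")
    if (object@Q <= -1 || object@Q >= 1)
        return("Q must lie in (-1, 1)")
    TRUE
})
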