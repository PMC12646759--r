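# Trait mismatch: the visitation-weighted mean absolute difference between
# hummingbird bill length and plant corolla length, per focal species, and
# its standardized effect size under the focal-species null.

# Weighted mean |bill - corolla| for one focal row or column of a rate (or
# visit-count) matrix. Weights are proportional to the entries, so any
# common positive rescaling (rates vs counts over a fixed denominator)
# leaves TM unchanged.
.tmFromVector <- function(w, billOrCorolla, partnerTraits, focal) {
    use <- w > 0
    if (!any(use)) return(NA_real_)
    if (any(is.na(partnerTraits[use])))
        stop("missing trait value for partner(s) of '", focal, "': ",
             paste(names(partnerTraits)[use & is.na(partnerTraits)],
                   collapse = ", "))
    sum(abs(billOrCorolla - partnerTraits[use]) * w[use]) / sum(w[use])
}

#' Trait mismatch of a focal hummingbird or plant
#'
#' For a hummingbird i, `TM_i = sum_j |bill_i - corolla_j| * rate_ij /
#' sum_j rate_ij`; for a plant j the symmetric form over its visitors. TM
#' is in mm; 0 indicates perfect matching between the focal species and all
#' of its realized partners, larger values increasing mismatch. TM is
#' invariant to positive rescaling of the rates.
#'
#' @param net a [QuantitativeNetwork-class].
#' @param traits a [TraitTable-class] covering the focal species and all its
#'   partners.
#' @param species focal species identifier (a row name for
#'   `traitMismatchBird`, a column name for `traitMismatchPlant`).
#' @return numeric TM in mm.
#' @examples
#' A <- matrix(c(3, 1), 1, 2, dimnames = list("H1", c("P1", "P2")))
#' tr <- TraitTable(
#'   data.frame(species = c("P1", "P2"), corolla_length = c(8, 14),
#'              corolla_opening = 5, corolla_curvature = 0),
#'   data.frame(species = "H1", bill_length = 10, body_mass = 5,
#'              tail_length = 50, wing_chord = 55, tarsus_length = 6))
#' traitMismatchBird(new("QuantitativeNetwork", site = "s", rates = A),
#'                   tr, "H1")  # (2*3 + 4*1)/4 = 2.5
#' @export
traitMismatchBird <- function(net, traits, species) {
    A <- rateMatrix(net)
    i <- match(species, rownames(A))
    if (is.na(i)) stop("bird not in network: ", species)
    bill <- birdTraits(traits)[species, "bill_length"]
    if (is.null(bill) || is.na(bill)) stop("missing bill_length for ", species)
    cor <- stats::setNames(
        plantTraits(traits)[colnames(A), "corolla_length"], colnames(A))
    .tmFromVector(A[i, ], bill, cor, species)
}

#' @rdname traitMismatchBird
#' @export
traitMismatchPlant <- function(net, traits, species) {
    A <- rateMatrix(net)
    j <- match(species, colnames(A))
    if (is.na(j)) stop("plant not in network: ", species)
    cor <- plantTraits(traits)[species, "corolla_length"]
    if (is.null(cor) || is.na(cor)) stop("missing corolla_length for ", species)
    bill <- stats::setNames(
        birdTraits(traits)[rownames(A), "bill_length"], rownames(A))
    .tmFromVector(A[, j], cor, bill, species)
}

#' Standardized effect size of trait mismatch
#'
#' Computes the focal species' observed TM and its distribution under the
#' same focal-species reshuffling used for contribution z-scores (row-wise
#' for hummingbirds, column-wise for plants). Rates in the null draws use
#' the unchanged per-plant recording-hour denominators. A negative z
#' indicates the species relies on trait matching (its realized partners
#' match its morphology more closely than availability predicts); positive
#' z indicates interaction with mismatched partners.
#'
#' @param table a [MonthlyVisitTable-class].
#' @param site site identifier.
#' @param species focal species.
#' @param guild `"bird"` or `"plant"`.
#' @param traits a [TraitTable-class] covering all filmed plants (bird
#'   focal) or all active hummingbirds (plant focal) at the site.
#' @param nSims null draws (default 1000).
#' @param seed optional integer.
#' @param keepNulls store the null TM values in the report.
#' @return A [ZScoreReport-class] with statistic `"TM"` (observed TM in mm).
#' @export
tmZScore <- function(table, site, species, guild = c("bird", "plant"),
                     traits, nSims = 1000L, seed = NULL, keepNulls = FALSE) {
    guild <- match.arg(guild)
    sd <- .siteData(table, site)
    obsBP <- apply(sd$visitsBPM, c(1L, 2L), sum)
    .withSeed(seed, {
        if (guild == "bird") {
            i <- match(species, sd$birds)
            if (is.na(i)) stop("focal bird not found at site: ", species)
            bill <- birdTraits(traits)[species, "bill_length"]
            cor <- stats::setNames(
                plantTraits(traits)[sd$plants, "corolla_length"], sd$plants)
            observed <- .tmFromVector(obsBP[i, ], bill, cor, species)
            V <- .drawFocalRowVisits(sd, species, nSims)
            nulls <- vapply(seq_len(nSims), function(s)
                .tmFromVector(V[i, , s], bill, cor, species), numeric(1))
        } else {
            j <- match(species, sd$plants)
            if (is.na(j) || sum(obsBP[, j]) == 0)
                stop("focal plant has no visits at site: ", species)
            cor <- plantTraits(traits)[species, "corolla_length"]
            bill <- stats::setNames(
                birdTraits(traits)[sd$birds, "bill_length"], sd$birds)
            observed <- .tmFromVector(obsBP[, j], cor, bill, species)
            V <- .drawFocalColVisits(sd, species, nSims)
            nulls <- vapply(seq_len(nSims), function(s)
                .tmFromVector(V[, j, s], cor, bill, species), numeric(1))
        }
        ok <- !is.na(nulls)
        .zreport("TM", observed, nulls[ok], nDropped = sum(!ok),
                 keepNulls = keepNulls)
    })
}
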