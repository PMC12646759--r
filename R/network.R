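# Site network construction, plus the internal per-site tabulation shared by
# the null-model samplers (months, filmed plants with hours, visit arrays).

# Tabulate one site into dense arrays. Returns NULL-free list:
#   months           sorted unique month indices
#   plants, birds    sorted species identifiers (birds: with >=1 visit)
#   hoursMP          months x plants matrix of recording hours
#   visitsBPM        birds x plants x months array of visit counts
#   plantHours       per-plant total recording hours across months
#   birdMonthTotals  birds x months matrix of visit totals
.siteData <- function(table, site) {
    rec <- visitRecords(table)
    rec <- rec[rec$site == site, , drop = FALSE]
    if (!nrow(rec)) stop("site not found in table: ", site)
    months <- sort(unique(rec$month))
    plants <- sort(unique(rec$plant))
    vrec <- rec[!is.na(rec$bird) & rec$visits > 0, , drop = FALSE]
    birds <- sort(unique(vrec$bird))
    mi <- match(rec$month, months); pi <- match(rec$plant, plants)
    hoursMP <- matrix(0, length(months), length(plants),
                      dimnames = list(months, plants))
    hoursMP[cbind(mi, pi)] <- rec$recording_hours
    visitsBPM <- array(0, c(length(birds), length(plants), length(months)),
                       dimnames = list(birds, plants, months))
    if (nrow(vrec))
        visitsBPM[cbind(match(vrec$bird, birds), match(vrec$plant, plants),
                        match(vrec$month, months))] <- vrec$visits
    list(site = site, months = months, plants = plants, birds = birds,
         hoursMP = hoursMP,
         visitsBPM = visitsBPM,
         plantHours = colSums(hoursMP),
         birdMonthTotals = if (length(birds))
             apply(visitsBPM, c(1L, 3L), sum)
         else matrix(0, 0L, length(months)))
}

# visits (birds x plants) + per-plant hours -> QuantitativeNetwork,
# dropping empty rows/columns. Returns NULL if nothing remains.
.ratesToNetwork <- function(site, visitsBP, plantHours) {
    keepP <- colSums(visitsBP) > 0 & plantHours > 0
    keepB <- rowSums(visitsBP) > 0
    if (!any(keepP) || !any(keepB)) return(NULL)
    V <- visitsBP[keepB, keepP, drop = FALSE]
    rates <- sweep(V, 2L, plantHours[keepP], "/")
    new("QuantitativeNetwork", site = site, rates = rates)
}

#' Build a site-level quantitative network from monthly records
#'
#' Aggregates a site's monthly visitation records into a hummingbird-by-plant
#' matrix of visitation rates. The rate for bird i on plant j is the total
#' number of visits across all months divided by the total number of hours
#' plant j was filmed at that site (per-plant denominator, which makes rates
#' comparable across plants with unequal camera effort). Species with no
#' realized interaction are dropped; rows and columns are ordered
#' lexicographically by species identifier, so the result is invariant to
#' the order of input records.
#'
#' @param table a [MonthlyVisitTable-class].
#' @param site site identifier present in the table.
#' @return A [QuantitativeNetwork-class].
#' @examples
#' tab <- MonthlyVisitTable(data.frame(
#'     site = "s1", month = c(1L, 2L), plant = "P1", bird = "H1",
#'     visits = c(2L, 2L), recording_hours = c(4, 1)))
#' rateMatrix(buildNetwork(tab, "s1"))  # 4 visits / 5 h = 0.8
#' @export
buildNetwork <- function(table, site) {
    sd <- .siteData(table, site)
    visitsBP <- if (length(sd$birds))
        apply(sd$visitsBPM, c(1L, 2L), sum)
    else matrix(0, 0L, length(sd$plants), dimnames = list(NULL, sd$plants))
    net <- .ratesToNetwork(site, visitsBP, sd$plantHours)
    if (is.null(net))
        stop("empty network: site '", site, "' has no recorded visits")
    net
}
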