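#' Read and write monthly visitation tables
#'
#' The on-disk format is delimited text (comma by default) with header
#' columns `site`, `month`, `plant`, `bird`, `visits`, `recording_hours`.
#' Rows with an empty `bird` field and zero visits register camera effort on
#' plants that were filmed but not visited. Reading validates the table and
#' fails with a message naming the offending records.
#'
#' @param path file path.
#' @param delim field delimiter, default ",".
#' @return `readVisitTable` returns a [MonthlyVisitTable-class];
#'   `writeVisitTable` invisibly returns `path`.
#' @examples
#' tab <- MonthlyVisitTable(data.frame(
#'     site = "s1", month = 1L, plant = c("P1", "P2"), bird = c("H1", NA),
#'     visits = c(4L, 0L), recording_hours = 2))
#' f <- tempfile(fileext = ".csv")
#' writeVisitTable(tab, f)
#' identical(visitRecords(readVisitTable(f)), visitRecords(tab))
#' @export
readVisitTable <- function(path, delim = ",") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = delim,
                            stringsAsFactors = FALSE, na.strings = c("NA", ""))
    need <- c("site", "month", "plant", "bird", "visits", "recording_hours")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("format error: missing column(s): ", paste(miss, collapse = ", "))
    MonthlyVisitTable(df[need])
}

#' @param table a [MonthlyVisitTable-class].
#' @rdname readVisitTable
#' @export
writeVisitTable <- function(table, path, delim = ",") {
    stopifnot(is(table, "MonthlyVisitTable"))
    utils::write.table(visitRecords(table), path, sep = delim,
                       row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}

#' Read trait tables for the two guilds
#'
#' Each file is delimited text with a `species` column plus the guild's trait
#' columns (`corolla_length`, `corolla_opening`, `corolla_curvature` for
#' plants; `bill_length`, `body_mass`, `tail_length`, `wing_chord`,
#' `tarsus_length` for hummingbirds), all in mm except body mass in g.
#'
#' @param plantPath,birdPath file paths for the plant and hummingbird tables.
#' @param delim field delimiter, default ",".
#' @return A [TraitTable-class].
#' @export
readTraitTable <- function(plantPath, birdPath, delim = ",") {
    rd <- function(p) utils::read.table(p, header = TRUE, sep = delim,
                                        stringsAsFactors = FALSE)
    TraitTable(rd(plantPath), rd(birdPath))
}

#' @param traits a [TraitTable-class].
#' @rdname readTraitTable
#' @export
writeTraitTable <- function(traits, plantPath, birdPath, delim = ",") {
    wr <- function(df, p) {
        df <- cbind(species = rownames(df), df)
        utils::write.table(df, p, sep = delim, row.names = FALSE, quote = FALSE)
    }
    wr(plantTraits(traits), plantPath)
    wr(birdTraits(traits), birdPath)
    invisible(c(plantPath, birdPath))
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that validates what downstream
#' diversity computations assume: unique tip labels and non-negative branch
#' lengths.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] tree.
#' @export
readPhylogeny <- function(path) {
    tree <- ape::read.tree(path)
    if (is.null(tree)) stop("malformed Newick file: ", path)
    validatePhylogeny(tree)
}

#' @param tree an [ape::phylo] object.
#' @rdname readPhylogeny
#' @export
validatePhylogeny <- function(tree) {
    if (!inherits(tree, "phylo")) stop("not a phylo object")
    if (anyDuplicated(tree$tip.label))
        stop("duplicate tip label(s): ",
             paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                   collapse = ", "))
    if (is.null(tree$edge.length))
        stop("tree has no branch lengths")
    if (any(tree$edge.length < 0))
        stop("negative branch lengths")
    tree
}

#' Serialize z-score reports to a tidy long-format table
#'
#' One row per report with columns `site`, `species`, `guild`, `statistic`,
#' `observed`, `null_mean`, `null_sd`, `z`, `n_sims`, `n_dropped`. `site`,
#' `species` and `guild` may be NA for community-level reports; pass them via
#' the `meta` argument.
#'
#' @param reports a list of [ZScoreReport-class] objects.
#' @param meta optional data.frame with one row per report supplying `site`,
#'   `species`, `guild`.
#' @return A data.frame; with `path` given it is also written as delimited
#'   text and the path returned invisibly.
#' @param path optional output file.
#' @param delim field delimiter, default ",".
#' @export
zScoreTable <- function(reports, meta = NULL, path = NULL, delim = ",") {
    if (is(reports, "ZScoreReport")) reports <- list(reports)
    df <- do.call(rbind, lapply(reports, function(r) data.frame(
        statistic = r@statistic, observed = r@observed, null_mean = r@nullMean,
        null_sd = r@nullSd, z = r@z, n_sims = r@nSims, n_dropped = r@nDropped,
        stringsAsFactors = FALSE)))
    if (!is.null(meta)) df <- cbind(meta, df)
    rownames(df) <- NULL
    if (!is.null(path)) {
        utils::write.table(df, path, sep = delim, row.names = FALSE,
                           quote = FALSE)
        return(invisible(df))
    }
    df
}
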