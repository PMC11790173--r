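#' @name surveyRecords
#' @title Survey records of classic and growth Turing colour patterns
#'
#' @description
#' The survey data model classifies taxa by whether they display classic
#' Turing colour patterns and/or putative-growth Turing colour patterns
#' (PGTCPs).  Each record carries a four-level label for each pattern class:
#' \code{Y} (at least one species with a clear pattern), \code{M} (maybe:
#' potential but unclear), \code{N?} (maybe no: none found, search not
#' exhaustive), \code{N} (probably no: none found, near-exhaustive search).
#' A PGTCP call (\code{pgtcp_label == "Y"}) additionally requires: at least
#' one of the four geometric categories (rosettes, intermediate_bands,
#' mixed_colors, line_and_dots); at least three motifs; and a pattern not
#' based on a pre-existing periodicity such as body segments or petals.
#'
#' Records are stored one per CSV row; \code{categories} is a
#' semicolon-joined set.
NULL

.surveyLabels <- c("Y", "M", "N?", "N")
.surveyCategories <- c("rosettes", "intermediate_bands", "mixed_colors",
                       "line_and_dots")

#' Validate a survey record
#'
#' Checks one record against the classification invariants and returns every
#' violation (violations are data, not errors).
#'
#' @param record a list or one-row data.frame with fields \code{taxon},
#'   \code{rank}, \code{classic_label}, \code{pgtcp_label},
#'   \code{categories} (character vector or ";"-joined string),
#'   \code{motif_count_at_least_3}, \code{based_on_preexisting_periodicity}.
#' @return character vector of violation messages; empty if the record is
#'   valid.
#' @export
validateRecord <- function(record) {
    record <- as.list(record)
    v <- character()
    cats <- record$categories
    if (is.null(cats)) cats <- character()
    if (length(cats) == 1L && is.character(cats))
        cats <- setdiff(strsplit(cats, ";", fixed = TRUE)[[1]], "")
    for (fld in c("classic_label", "pgtcp_label")) {
        lab <- record[[fld]]
        if (is.null(lab) || !lab %in% .surveyLabels)
            v <- c(v, sprintf("%s must be one of %s", fld,
                              paste(.surveyLabels, collapse = "/")))
    }
    bad <- setdiff(cats, .surveyCategories)
    if (length(bad))
        v <- c(v, paste0("unknown categories: ", paste(bad, collapse = ", ")))
    if (identical(record$pgtcp_label, "Y")) {
        if (length(cats) == 0L)
            v <- c(v, "criterion iv: a PGTCP record must carry at least one geometric category")
        if (!isTRUE(record$motif_count_at_least_3))
            v <- c(v, "criterion iii: a PGTCP requires at least three motifs")
        if (isTRUE(record$based_on_preexisting_periodicity))
            v <- c(v, "criterion ii: a PGTCP must not be based on a pre-existing periodicity")
    }
    v
}

#' Read and write survey record tables
#'
#' CSV storage: one record per row, header validated; \code{categories}
#' stored ";"-joined.  Reading does not validate individual records --
#' run \code{\link{validateRecord}} over rows for that.
#'
#' @param path CSV file.
#' @param records data.frame of records.
#' @return \code{readPatternRecords}: a data.frame.
#' @export
readPatternRecords <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("taxon", "rank", "classic_label", "pgtcp_label")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("record table lacks column(s): ", paste(miss, collapse = ", "))
    if (!"categories" %in% names(d)) d$categories <- ""
    if (!"motif_count_at_least_3" %in% names(d)) d$motif_count_at_least_3 <- NA
    if (!"based_on_preexisting_periodicity" %in% names(d))
        d$based_on_preexisting_periodicity <- NA
    d
}

#' @rdname readPatternRecords
#' @export
writePatternRecords <- function(records, path) {
    utils::write.csv(records, path, row.names = FALSE)
    invisible(path)
}

# survey rounding convention: integer percent unless < 5%, then one decimal
.surveyPercent <- function(k, n) {
    p <- 100 * k / n
    ifelse(p < 5, round(p, 1), round(p))
}

#' Tally survey labels
#'
#' Counts and percentages of each label per pattern class, optionally within
#' groups (e.g. per taxonomic rank).  Percentages follow the survey's
#' reporting convention: rounded to integer percent unless below 5\%, then
#' to one decimal.
#'
#' @param records data.frame of records (see \code{\link{readPatternRecords}}).
#' @param groupBy optional column name to split by (e.g. "rank").
#' @return data.frame with columns \code{group}, \code{class} ("classic" or
#'   "pgtcp"), \code{label}, \code{count}, \code{total}, \code{percent}.
#' @examples
#' r <- data.frame(taxon = paste0("t", 1:10), rank = "order",
#'                 classic_label = "N",
#'                 pgtcp_label = rep(c("Y", "N"), c(1, 9)))
#' subset(tallyLabels(r), class == "pgtcp" & label == "Y")$percent  # 10
#' @export
tallyLabels <- function(records, groupBy = NULL) {
    if (NROW(records) == 0L) stop("empty record set")
    groups <- if (is.null(groupBy)) list(all = records) else
        split(records, records[[groupBy]])
    out <- lapply(names(groups), function(gn) {
        d <- groups[[gn]]
        do.call(rbind, lapply(c(classic = "classic_label",
                                pgtcp = "pgtcp_label"), function(col) {
            cls <- if (col == "classic_label") "classic" else "pgtcp"
            data.frame(group = gn, class = cls, label = .surveyLabels,
                       count = vapply(.surveyLabels,
                                      function(l) sum(d[[col]] == l), 0L),
                       total = nrow(d),
                       percent = .surveyPercent(
                           vapply(.surveyLabels,
                                  function(l) sum(d[[col]] == l), 0L),
                           nrow(d)))
        }))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Proportion of positively labelled records
#'
#' Convenience tally: the percentage of records whose label for the given
#' class is \code{Y}, with the survey rounding convention.
#'
#' @param records data.frame of records.
#' @param class "pgtcp" or "classic".
#' @return numeric(1) percentage.
#' @examples
#' # 62 of 620 orders -> 10; 525 of 29573 species -> 1.8
#' @export
positiveProportion <- function(records, class = c("pgtcp", "classic")) {
    class <- match.arg(class)
    col <- paste0(class, "_label")
    .surveyPercent(sum(records[[col]] == "Y"), nrow(records))
}

#' Export tree-leaf colour annotations
#'
#' Produces a plain-text colour annotation mapping each taxon leaf to the
#' survey legend: yellow if a PGTCP was found in at least one species
#' (pgtcp Y; PGTCP dominates a classic find), blue if only classic Turing
#' patterns were found (classic Y), grey if none; "maybe" labels map to
#' lighter shades of the same hues.  The output is a tab-separated
#' leaf/colour table compatible with common tree-annotation dialects.
#'
#' @param records data.frame of records with unique \code{taxon} names.
#' @return character vector, one "taxon\\tcolour" line per record.
#' @export
exportTreeAnnotation <- function(records) {
    dup <- records$taxon[duplicated(records$taxon)]
    if (length(dup))
        stop("duplicate taxon names: ", paste(unique(dup), collapse = ", "))
    colour <- function(classic, pgtcp) {
        if (pgtcp == "Y") "#e6c300"          # yellow: PGTCP found
        else if (pgtcp == "M") "#f2e28a"     # pale yellow: maybe PGTCP
        else if (classic == "Y") "#1f6fc4"   # blue: classic only
        else if (classic == "M") "#9dc3e6"   # pale blue: maybe classic
        else "#bfbfbf"                       # grey: none found
    }
    vapply(seq_len(nrow(records)), function(i)
        paste(records$taxon[i],
              colour(records$classic_label[i], records$pgtcp_label[i]),
              sep = "\t"),
        character(1))
}
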