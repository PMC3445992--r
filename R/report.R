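#' Serialize a summary report
#'
#' Renders a [SummaryReport] deterministically as plain text (direction
#' and donor-phylum breakdown tables), TSV (long key/value and histogram
#' blocks) or JSON. The JSON form round-trips through
#' [summaryReportFromJSON()].
#'
#' @param report a [SummaryReport] from [summarizeScreen()].
#' @param format "text", "tsv" or "json".
#' @param path output file; when NULL the rendered text is returned.
#' @return The rendered character vector (invisibly when written to file).
#' @export
renderSummary <- function(report, format = c("text", "tsv", "json"),
                          path = NULL) {
    format <- match.arg(format)
    out <- switch(format,
        text = .renderText(report),
        tsv = .renderTsv(report),
        json = .renderJson(report))
    if (is.null(path)) return(out)
    writeLines(out, path)
    invisible(out)
}

.renderText <- function(r) {
    tt <- r@totals
    lines <- c(
        "== LGT screen summary ==",
        sprintf("genes screened      : %d (of %g trees, %g proteins)",
                tt[["n_genes"]], r@nTrees, r@nProteome),
        sprintf("LGT candidates      : %d (%.2f%% of trees, %.2f%% of proteome)",
                tt[["candidate_total"]], tt[["pct_of_trees"]],
                tt[["pct_of_proteome"]]),
        sprintf("confirmed by NJ+ML  : %d (%.2f%%)", tt[["confirmed_total"]],
                tt[["agreement_pct"]]),
        sprintf("too few taxa for ML : %d", tt[["unresolved_too_few_taxa"]]),
        sprintf("origin: bacterial %d | eukaryotic %d | archaea export %d | total %d",
                tt[["bacterial_origin_total"]], tt[["eukaryotic_origin_total"]],
                tt[["archaea_export_total"]], tt[["interdomain_total"]]),
        sprintf("NJ events           : %d (%d high confidence, %d lower support)",
                tt[["nj_event_total"]], tt[["nj_high_confidence"]],
                tt[["nj_lower_support"]]),
        sprintf("ML direction calls  : %d (%d good support)",
                tt[["ml_direction_inferred"]], tt[["ml_good_support"]]),
        "",
        "-- candidates by status --",
        sprintf("  %-28s %6d", names(r@statusCounts), r@statusCounts),
        "",
        "-- direction of transfer --")
    for (m in unique(r@directionCounts$method)) {
        sub <- r@directionCounts[r@directionCounts$method == m, ]
        lines <- c(lines, paste0("  [", m, "]"),
                   sprintf("  %-22s %6d", sub$direction, sub$n))
    }
    lines <- c(lines, "", "-- donor phylum of closest neighbor --")
    for (m in unique(r@donorCounts$method)) {
        sub <- r@donorCounts[r@donorCounts$method == m, ]
        lines <- c(lines, paste0("  [", m, "]"),
                   sprintf("  %-22s %6d", sub$donor, sub$n))
    }
    lines
}

.renderTsv <- function(r) {
    c("key\tvalue",
      sprintf("%s\t%s", names(r@totals), format(r@totals, trim = TRUE)),
      sprintf("status:%s\t%d", names(r@statusCounts), r@statusCounts),
      sprintf("companion:%s\t%d", names(r@companionCounts), r@companionCounts),
      sprintf("direction:%s:%s\t%d", r@directionCounts$method,
              r@directionCounts$direction, r@directionCounts$n),
      sprintf("donor:%s:%s\t%d", r@donorCounts$method, r@donorCounts$donor,
              r@donorCounts$n))
}

#' @rdname renderSummary
#' @export
summaryAsList <- function(report) {
    list(totals = as.list(report@totals),
         status_counts = as.list(report@statusCounts),
         companion_counts = as.list(report@companionCounts),
         direction_counts = report@directionCounts,
         donor_counts = report@donorCounts,
         tier_cross = report@tierCross,
         n_trees = report@nTrees,
         n_proteome = report@nProteome)
}

.renderJson <- function(r) {
    jsonlite::toJSON(summaryAsList(r), auto_unbox = TRUE, digits = NA,
                     pretty = TRUE)
}

#' @rdname renderSummary
#' @param json a JSON string (or file path) produced by
#'   `renderSummary(report, "json")`.
#' @return `summaryReportFromJSON`: the reconstructed [SummaryReport].
#' @export
summaryReportFromJSON <- function(json) {
    x <- jsonlite::fromJSON(json)
    emptyDF <- function(d) if (is.data.frame(d)) d else
        as.data.frame(d, stringsAsFactors = FALSE)
    new("SummaryReport",
        totals = unlist(x$totals),
        statusCounts = vapply(x$status_counts, as.integer, integer(1)),
        companionCounts = vapply(x$companion_counts, as.integer, integer(1)),
        directionCounts = emptyDF(x$direction_counts),
        donorCounts = emptyDF(x$donor_counts),
        tierCross = emptyDF(x$tier_cross),
        nTrees = x$n_trees, nProteome = x$n_proteome)
}
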