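#' Merge NJ and ML classifications for one gene
#'
#' Reconciles the verdicts of the two tree-inference methods under the
#' screen's congruence rules: a gene is `LGT_confirmed` only when both
#' methods recover an LGT topology; an LGT verdict by exactly one method is
#' `LGT_nj_only` (kept distinct but never counted as confirmed); genes
#' whose ML tree could not be built for lack of taxa are
#' `unresolved_too_few_taxa` and excluded from confirmed totals. The merged
#' direction is the shared direction when both methods resolve one, the
#' resolved direction when exactly one does, `unknown` when neither does,
#' and `"conflict"` when they disagree (such genes are flagged, excluded
#' from origin totals, and surfaced for manual review).
#'
#' The origin call is `bacterial` when the merged direction is
#' bacteria-to-archaea, or when the direction is unknown but either method
#' flags the only-archaea rescue (focal + companion were the only archaea
#' on the tree, implying a likely bacterial origin); `eukaryotic` and
#' `archaea_export` follow the merged direction; anything else is
#' `undetermined`.
#'
#' @param nj one-row data.frame as from [classifyTree()] (the NJ verdict).
#' @param ml same for the ML verdict, or NULL when the ML tree could not
#'   be built (too few taxa).
#' @return A one-row consensus data.frame.
#' @export
mergeClassification <- function(nj, ml = NULL) {
    if (!is.null(ml) && !identical(nj$gene_id, ml$gene_id))
        stop("gene_id mismatch: ", nj$gene_id, " vs ", ml$gene_id,
             call. = FALSE)
    njLGT <- nj$status != "non_LGT"
    mlAbsent <- is.null(ml) || is.na(ml$status)
    mlLGT <- !mlAbsent && ml$status != "non_LGT"

    finalStatus <-
        if (njLGT && mlAbsent) "unresolved_too_few_taxa"
        else if (njLGT && mlLGT) "LGT_confirmed"
        else if (njLGT || mlLGT) "LGT_nj_only"
        else "non_LGT"

    dirs <- c(nj = if (njLGT) nj$direction else "not_applicable",
              ml = if (mlLGT) ml$direction else
                   if (mlAbsent) NA_character_ else "not_applicable")
    resolved <- dirs[!is.na(dirs) & !dirs %in% c("unknown", "not_applicable")]
    conflict <- length(unique(resolved)) > 1L
    finalDirection <-
        if (finalStatus %in% c("non_LGT")) "not_applicable"
        else if (conflict) "conflict"
        else if (length(resolved)) unique(resolved)
        else "unknown"

    rescue <- isTRUE(nj$only_archaea_rescue) ||
        (!mlAbsent && isTRUE(ml$only_archaea_rescue))
    origin <-
        if (finalStatus != "LGT_confirmed" || conflict) "undetermined"
        else if (finalDirection == "bacteria_to_archaea") "bacterial"
        else if (finalDirection == "eukarya_to_archaea") "eukaryotic"
        else if (finalDirection == "archaea_to_bacteria") "archaea_export"
        else if (rescue) "bacterial"
        else "undetermined"

    data.frame(gene_id = nj$gene_id, final_status = finalStatus,
               final_direction = finalDirection, origin_call = origin,
               conflict = conflict, stringsAsFactors = FALSE)
}

#' Merge per-gene classification tables from two methods
#'
#' Applies [mergeClassification()] gene by gene. `ml` rows are matched to
#' `nj` rows by `gene_id`; NJ genes without an ML row are treated as
#' unresolved for too few taxa when they are NJ LGT candidates (the ML
#' method requires at least four taxa), and `non_LGT` otherwise.
#'
#' @param nj data.frame of NJ verdicts (one row per gene, as from
#'   [classifyTrees()]).
#' @param ml data.frame of ML verdicts; genes may be missing.
#' @return Wide data.frame with `nj_`/`ml_`-prefixed method columns plus
#'   final_status, final_direction, origin_call and conflict.
#' @export
mergeClassifications <- function(nj, ml) {
    if (anyDuplicated(nj$gene_id))
        stop("duplicate gene_id in NJ table", call. = FALSE)
    if (anyDuplicated(ml$gene_id))
        stop("duplicate gene_id in ML table", call. = FALSE)
    mlIdx <- match(nj$gene_id, ml$gene_id)
    res <- lapply(seq_len(nrow(nj)), function(i) {
        mlRow <- if (is.na(mlIdx[i])) NULL else ml[mlIdx[i], , drop = FALSE]
        mergeClassification(nj[i, , drop = FALSE], mlRow)
    })
    final <- do.call(rbind, res)
    keep <- c("status", "companion_present", "direction",
              "only_archaea_rescue", "only_archaea", "support", "tier",
              "donor_phylum")
    njPart <- nj[keep]
    names(njPart) <- paste0("nj_", keep)
    mlPart <- ml[mlIdx, keep, drop = FALSE]
    names(mlPart) <- paste0("ml_", keep)
    rownames(mlPart) <- NULL
    cbind(data.frame(gene_id = nj$gene_id, stringsAsFactors = FALSE),
          njPart, mlPart, final[-1L])
}

#' Summarize a merged screen
#'
#' Aggregates a merged classification table into the screen's headline
#' numbers and histograms: candidate counts by status and companion
#' composition, direction and donor-phylum histograms per method, the raw
#' bootstrap-tier cross-tabulation, and the totals (confirmed candidates,
#' origin calls, single-method event aggregations) with percentages
#' against the number of trees and the proteome size.
#'
#' Two per-method aggregations mirror how confidence groupings are usually
#' assembled from such screens: `nj_event_total` counts NJ trees with a
#' bacteria-to-archaea direction plus direction-unknown trees rescued by
#' the only-archaea rule, split into `nj_high_confidence` (high or
#' moderate tier, or rescued) and `nj_lower_support`; `ml_good_support`
#' counts ML trees with an inferred direction (or rescue) at high or
#' moderate tier.
#'
#' @param merged data.frame from [mergeClassifications()].
#' @param nTrees number of gene trees screened (percentage denominator).
#' @param nProteome number of annotated proteins (percentage denominator).
#' @return A [SummaryReport].
#' @export
summarizeScreen <- function(merged, nTrees, nProteome) {
    if (anyDuplicated(merged$gene_id))
        stop("duplicate gene_id in merged table", call. = FALSE)
    cand <- merged[merged$nj_status != "non_LGT", , drop = FALSE]
    candTotal <- nrow(cand)
    confirmed <- sum(merged$final_status == "LGT_confirmed")
    bact <- sum(merged$origin_call == "bacterial")
    euk <- sum(merged$origin_call == "eukaryotic")
    export <- sum(merged$origin_call == "archaea_export")

    njB2A <- cand$nj_direction == "bacteria_to_archaea"
    njRescued <- cand$nj_direction == "unknown" & cand$nj_only_archaea
    njEvents <- sum(njB2A) + sum(njRescued)
    njHigh <- sum(njB2A & cand$nj_tier %in% c("high", "moderate")) +
        sum(njRescued) + sum(njB2A & cand$nj_tier == "low" & cand$nj_only_archaea)
    mlDir <- !is.na(cand$ml_status) & cand$ml_status != "non_LGT" &
        (!cand$ml_direction %in% c("unknown", "not_applicable") |
         (cand$ml_direction == "unknown" & cand$ml_only_archaea))
    mlGood <- sum(mlDir & cand$ml_tier %in% c("high", "moderate"))

    totals <- c(
        n_genes = nrow(merged),
        candidate_total = candTotal,
        pct_of_trees = round(100 * candTotal / nTrees, 2),
        pct_of_proteome = round(100 * candTotal / nProteome, 2),
        confirmed_total = confirmed,
        agreement_pct = if (candTotal) round(100 * confirmed / candTotal, 2) else 0,
        unresolved_too_few_taxa = sum(merged$final_status == "unresolved_too_few_taxa"),
        bacterial_origin_total = bact,
        eukaryotic_origin_total = euk,
        archaea_export_total = export,
        interdomain_total = bact + euk + export,
        nj_event_total = njEvents,
        nj_high_confidence = njHigh,
        nj_lower_support = njEvents - njHigh,
        ml_direction_inferred = sum(mlDir),
        ml_good_support = mlGood,
        conflict_total = sum(merged$conflict))

    statusCounts <- .namedCount(merged$nj_status)
    companionCounts <- .namedCount(cand$nj_companion_present)
    dirLevels <- c("bacteria_to_archaea", "archaea_to_bacteria",
                   "eukarya_to_archaea", "unknown")
    dirDF <- rbind(
        data.frame(method = "nj", direction = dirLevels,
                   n = as.integer(table(factor(cand$nj_direction, dirLevels))),
                   stringsAsFactors = FALSE),
        data.frame(method = "ml", direction = dirLevels,
                   n = as.integer(table(factor(
                       cand$ml_direction[!is.na(cand$ml_status) &
                                         cand$ml_status != "non_LGT"],
                       dirLevels))),
                   stringsAsFactors = FALSE))
    donorDF <- rbind(
        .donorCount(cand$nj_donor_phylum, "nj"),
        .donorCount(cand$ml_donor_phylum[!is.na(cand$ml_status) &
                                         cand$ml_status != "non_LGT"], "ml"))
    tierCross <- rbind(
        .tierCross(cand$nj_direction, cand$nj_tier, cand$nj_only_archaea, "nj"),
        .tierCross(cand$ml_direction, cand$ml_tier, cand$ml_only_archaea, "ml"))

    new("SummaryReport", totals = totals, statusCounts = statusCounts,
        companionCounts = companionCounts, directionCounts = dirDF,
        donorCounts = donorDF, tierCross = tierCross,
        nTrees = nTrees, nProteome = nProteome)
}

.namedCount <- function(x) {
    tab <- table(x, useNA = "no")
    setNames(as.integer(tab), names(tab))
}

.donorCount <- function(x, method) {
    x <- x[!is.na(x)]
    tab <- table(x)
    if (!length(tab))
        return(data.frame(method = character(), donor = character(),
                          n = integer(), stringsAsFactors = FALSE))
    data.frame(method = method, donor = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
}

.tierCross <- function(direction, tier, onlyArchaea, method) {
    keep <- !is.na(direction) & direction != "not_applicable"
    if (!any(keep))
        return(data.frame(method = character(), direction = character(),
                          tier = character(), only_archaea = logical(),
                          n = integer(), stringsAsFactors = FALSE))
    tab <- as.data.frame(table(direction = direction[keep],
                               tier = tier[keep],
                               only_archaea = onlyArchaea[keep]),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, , drop = FALSE]
    data.frame(method = method, direction = tab$direction, tier = tab$tier,
               only_archaea = as.logical(tab$only_archaea),
               n = as.integer(tab$Freq), stringsAsFactors = FALSE,
               row.names = NULL)
}
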