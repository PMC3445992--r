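#' @import methods
#' @importFrom stats rnorm runif rbinom sd setNames
#' @importFrom utils read.delim head
NULL

setOldClass("phylo")

VALID_DOMAINS <- c("Bacteria", "Archaea", "Eukaryota")

#' Screen configuration
#'
#' Holds the parameters of the lateral-gene-transfer (LGT) screen: the focal
#' species whose gene trees are inspected, its companion genus (the nearest
#' archaeal relative, whose presence as sister triggers the ancient
#' pre-divergence transfer test), the bacterial-clade phylum threshold, and
#' the bootstrap tier bounds.
#'
#' @slot focalSpecies species label of the focal taxon as it appears in the
#'   taxonomy table.
#' @slot companionGenus genus whose leaves count as companions.
#' @slot companionSpecies species of the companion genus tracked individually
#'   in the `companion_present` field.
#' @slot minBacterialPhyla minimum number of distinct bacterial phyla for a
#'   clade to count as a bacterial clade (default 3).
#' @slot tierHighGt supports strictly above this are tier "high" (default 70).
#' @slot tierModerateLow,tierModerateHigh inclusive bounds of the "moderate"
#'   tier (defaults 51 and 70); anything at or below `tierModerateLow - 1`
#'   is "low", so a support of exactly 50 bins low by default.
#' @slot rooting either "midpoint" (gene trees are midpoint rooted before
#'   classification) or "asis" (trees are taken as provided).
#' @slot maxNestingLevels maximum number of ancestor levels the nesting
#'   search may ascend (default Inf).
#' @slot minDirectionLevels number of successive pure-domain enclosure
#'   levels required before a transfer direction into the focal lineage is
#'   called (default 2).
#' @slot maxExportSisterSize maximum size of a bacterial sister group for an
#'   archaea-to-bacteria export call (default 2).
#' @slot minExportGenera minimum number of distinct non-companion archaeal
#'   genera in the enclosing context for an export call (default 2).
#' @export
setClass("ScreenConfig", representation(
    focalSpecies = "character",
    companionGenus = "character",
    companionSpecies = "character",
    minBacterialPhyla = "integer",
    tierHighGt = "numeric",
    tierModerateLow = "numeric",
    tierModerateHigh = "numeric",
    rooting = "character",
    maxNestingLevels = "numeric",
    minDirectionLevels = "integer",
    maxExportSisterSize = "integer",
    minExportGenera = "integer"
))

setValidity("ScreenConfig", function(object) {
    msg <- character()
    if (length(object@focalSpecies) != 1L || !nzchar(object@focalSpecies))
        msg <- c(msg, "focalSpecies must be a single non-empty string")
    if (object@minBacterialPhyla < 1L)
        msg <- c(msg, "minBacterialPhyla must be >= 1")
    if (!(object@tierModerateLow <= object@tierModerateHigh &&
          object@tierModerateHigh <= object@tierHighGt))
        msg <- c(msg, "tier bounds must be ordered: moderateLow <= moderateHigh <= highGt")
    if (!object@rooting %in% c("midpoint", "asis"))
        msg <- c(msg, "rooting must be 'midpoint' or 'asis'")
    if (length(msg)) msg else TRUE
})

#' Construct a ScreenConfig
#'
#' Defaults describe the Methanosphaera stadtmanae screen: the focal human
#' gut methanogen with Methanobrevibacter as companion genus, a bacterial
#' clade defined as spanning at least three phyla, and bootstrap tiers
#' high (>70) / moderate (51-70) / low (<=50).
#'
#' @param focalSpecies,companionGenus,companionSpecies,minBacterialPhyla,tierHighGt,tierModerateLow,tierModerateHigh,rooting,maxNestingLevels,minDirectionLevels,maxExportSisterSize,minExportGenera see slot docs.
#' @return A `ScreenConfig` object.
#' @examples
#' cfg <- screenConfig()
#' cfg
#' @export
screenConfig <- function(focalSpecies = "Methanosphaera_stadtmanae",
                         companionGenus = "Methanobrevibacter",
                         companionSpecies = c("Methanobrevibacter_smithii",
                                              "Methanobrevibacter_ruminantium"),
                         minBacterialPhyla = 3L,
                         tierHighGt = 70, tierModerateLow = 51,
                         tierModerateHigh = 70,
                         rooting = c("midpoint", "asis"),
                         maxNestingLevels = Inf,
                         minDirectionLevels = 2L,
                         maxExportSisterSize = 2L,
                         minExportGenera = 2L) {
    new("ScreenConfig",
        focalSpecies = focalSpecies,
        companionGenus = companionGenus,
        companionSpecies = companionSpecies,
        minBacterialPhyla = as.integer(minBacterialPhyla),
        tierHighGt = tierHighGt, tierModerateLow = tierModerateLow,
        tierModerateHigh = tierModerateHigh,
        rooting = match.arg(rooting),
        maxNestingLevels = maxNestingLevels,
        minDirectionLevels = as.integer(minDirectionLevels),
        maxExportSisterSize = as.integer(maxExportSisterSize),
        minExportGenera = as.integer(minExportGenera))
}

setMethod("show", "ScreenConfig", function(object) {
    cat("ScreenConfig\n")
    cat("  focal species   :", object@focalSpecies, "\n")
    cat("  companion genus :", object@companionGenus, "\n")
    cat("  min bact. phyla :", object@minBacterialPhyla, "\n")
    cat(sprintf("  tiers           : high >%g, moderate %g-%g, low otherwise\n",
                object@tierHighGt, object@tierModerateLow, object@tierModerateHigh))
    cat("  rooting         :", object@rooting, "\n")
})

#' Gene phylogeny with leaf taxonomy
#'
#' A per-gene tree (ape `phylo`; bootstrap supports, when present, are
#' stored as internal node labels in 0-100) together with a taxonomy table
#' annotating its leaves. The taxonomy table may be empty (tree read from
#' Newick before annotation) or must cover every leaf.
#'
#' @slot geneId gene identifier.
#' @slot tree `phylo` object with >= 3 leaves.
#' @slot taxonomy data.frame with columns leaf_id, species, genus, phylum,
#'   domain; zero rows when unannotated.
#' @export
setClass("AnnotatedGeneTree", representation(
    geneId = "character",
    tree = "phylo",
    taxonomy = "data.frame"
))

setValidity("AnnotatedGeneTree", function(object) {
    msg <- character()
    phy <- object@tree
    if (length(phy$tip.label) < 3L)
        msg <- c(msg, "tree must have at least 3 leaves")
    if (anyDuplicated(phy$tip.label))
        msg <- c(msg, "duplicate leaf names in tree")
    sup <- suppressWarnings(as.numeric(phy$node.label))
    sup <- sup[!is.na(sup)]
    if (length(sup) && (any(sup < 0) || any(sup > 100)))
        msg <- c(msg, "bootstrap supports must lie in [0, 100]")
    tax <- object@taxonomy
    if (nrow(tax)) {
        need <- c("leaf_id", "species", "genus", "phylum", "domain")
        if (!all(need %in% names(tax))) {
            msg <- c(msg, paste("taxonomy must have columns:",
                                paste(need, collapse = " ")))
        } else {
            miss <- setdiff(phy$tip.label, tax$leaf_id)
            if (length(miss))
                msg <- c(msg, paste("leaves without taxonomy:",
                                    paste(head(miss, 5), collapse = ", ")))
            bad <- !tax$domain %in% VALID_DOMAINS
            if (any(bad))
                msg <- c(msg, "domain must be one of Bacteria/Archaea/Eukaryota")
            noPhy <- !nzchar(tax$phylum) & tax$domain != "Eukaryota"
            if (any(noPhy))
                msg <- c(msg, "phylum may be empty only for Eukaryota")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn AnnotatedGeneTree constructor.
#' @param geneId gene identifier.
#' @param tree an ape `phylo`.
#' @param taxonomy taxonomy data.frame (may be empty).
#' @export
annotatedGeneTree <- function(geneId, tree, taxonomy = emptyTaxonomy()) {
    new("AnnotatedGeneTree", geneId = geneId, tree = tree,
        taxonomy = as.data.frame(taxonomy, stringsAsFactors = FALSE))
}

#' @describeIn AnnotatedGeneTree an empty taxonomy table with the right columns.
#' @export
emptyTaxonomy <- function() {
    data.frame(leaf_id = character(), species = character(),
               genus = character(), phylum = character(),
               domain = character(), stringsAsFactors = FALSE)
}

setMethod("show", "AnnotatedGeneTree", function(object) {
    phy <- object@tree
    cat("AnnotatedGeneTree", object@geneId, "\n")
    cat(" ", length(phy$tip.label), "leaves,",
        if (nrow(object@taxonomy)) "annotated" else "unannotated", "\n")
    if (!is.null(phy$node.label)) {
        sup <- suppressWarnings(as.numeric(phy$node.label))
        if (any(!is.na(sup)))
            cat("  supports on", sum(!is.na(sup)), "internal nodes\n")
    }
})

#' @rdname AnnotatedGeneTree-accessors
#' @param x an AnnotatedGeneTree.
#' @export
geneId <- function(x) x@geneId

#' Accessors for AnnotatedGeneTree
#'
#' `treeOf` returns the underlying ape `phylo`; `taxonomyOf` the taxonomy
#' table; `geneId` the gene identifier.
#'
#' @param x an AnnotatedGeneTree.
#' @name AnnotatedGeneTree-accessors
#' @export
treeOf <- function(x) x@tree

#' @rdname AnnotatedGeneTree-accessors
#' @export
taxonomyOf <- function(x) x@taxonomy

#' Ancestral gene-family reconstruction
#'
#' Result of parsimony reconstruction of gene-family presence/absence on a
#' rooted species tree: a binary state for every (node, family) pair and
#' the gain/loss events implied by state changes along each branch.
#'
#' @slot tree rooted `phylo` species tree.
#' @slot nodeStates binary matrix, rows = nodes (tips then internal nodes,
#'   ape numbering; rownames are node labels), columns = families.
#' @slot events data.frame with columns node (child end of the branch),
#'   branch (label of that node), family, event ("gain"/"loss").
#' @slot mode reconstruction mode used.
#' @export
setClass("AncestralReconstruction", representation(
    tree = "phylo",
    nodeStates = "matrix",
    events = "data.frame",
    mode = "character"
))

setValidity("AncestralReconstruction", function(object) {
    msg <- character()
    if (!all(object@nodeStates %in% c(0, 1)))
        msg <- c(msg, "nodeStates must be binary")
    n <- length(object@tree$tip.label) + object@tree$Nnode
    if (nrow(object@nodeStates) != n)
        msg <- c(msg, "nodeStates must have one row per tree node")
    if (length(msg)) msg else TRUE
})

setMethod("show", "AncestralReconstruction", function(object) {
    cat("AncestralReconstruction (", object@mode, " parsimony)\n", sep = "")
    cat(" ", ncol(object@nodeStates), "families on",
        length(object@tree$tip.label), "species\n")
    cat(" ", sum(object@events$event == "gain"), "gains,",
        sum(object@events$event == "loss"), "losses\n")
})

#' Summary of a lateral-gene-transfer screen
#'
#' Aggregated counts produced by [summarizeScreen()]: headline totals,
#' per-status and per-companion candidate counts, per-method direction and
#' donor-phylum histograms, and the raw bootstrap-tier cross-tabulations
#' from which confidence groupings are assembled.
#'
#' @slot totals named numeric vector of headline quantities.
#' @slot statusCounts,companionCounts named integer vectors.
#' @slot directionCounts data.frame method x direction.
#' @slot donorCounts data.frame method x donor phylum.
#' @slot tierCross data.frame method x direction x tier x only_archaea counts.
#' @slot nTrees,nProteome denominators used for percentages.
#' @export
setClass("SummaryReport", representation(
    totals = "numeric",
    statusCounts = "integer",
    companionCounts = "integer",
    directionCounts = "data.frame",
    donorCounts = "data.frame",
    tierCross = "data.frame",
    nTrees = "numeric",
    nProteome = "numeric"
))

#' @rdname SummaryReport-class
#' @param x a SummaryReport.
#' @export
totalsOf <- function(x) x@totals

setMethod("show", "SummaryReport", function(object) {
    cat("SummaryReport over", object@nTrees, "gene trees\n")
    tt <- object@totals
    cat(sprintf("  candidates        : %d (%.2f%% of trees, %.2f%% of proteome)\n",
                tt[["candidate_total"]], tt[["pct_of_trees"]],
                tt[["pct_of_proteome"]]))
    cat(sprintf("  confirmed by both : %d (%.2f%% agreement)\n",
                tt[["confirmed_total"]], tt[["agreement_pct"]]))
    cat(sprintf("  bacterial origin  : %d; eukaryotic: %d; archaea export: %d (total %d)\n",
                tt[["bacterial_origin_total"]], tt[["eukaryotic_origin_total"]],
                tt[["archaea_export_total"]], tt[["interdomain_total"]]))
})
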