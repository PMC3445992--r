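#' Sister group of the focal leaf
#'
#' On the rooted gene tree (midpoint rooting by default, per the screen
#' configuration), returns the leaves of the sister group of the focal
#' leaf: the other side of its parent node, i.e. the focal taxon's closest
#' phylogenetic neighbors. With multiple focal copies (paralogs) each is
#' processed independently.
#'
#' @param x an annotated [AnnotatedGeneTree].
#' @param config a [ScreenConfig][screenConfig].
#' @return A character vector of leaf ids when the focal species occurs
#'   once; a named list of such vectors (one per focal leaf) otherwise.
#' @export
closestNeighborGroup <- function(x, config = screenConfig()) {
    prep <- .prepareTree(x, config)
    out <- lapply(prep$focalTips, function(tip) {
        parent <- .parentOf(prep$phy, tip)
        setdiff(.tipLabelsUnder(prep$phy, parent), prep$phy$tip.label[tip])
    })
    names(out) <- prep$phy$tip.label[prep$focalTips]
    if (length(out) == 1L) out[[1L]] else out
}

#' Bacterial-clade test
#'
#' A leaf set counts as a bacterial clade when all members are Bacteria
#' and they span at least `minBacterialPhyla` distinct phyla (default 3),
#' i.e. a sufficiently diverse sample of bacteria to indicate a genuine
#' bacterial origin rather than a stray mislabelled neighbor.
#'
#' @param taxa taxonomy data.frame rows describing the leaves.
#' @param config a [ScreenConfig][screenConfig].
#' @return TRUE or FALSE.
#' @export
isBacterialClade <- function(taxa, config = screenConfig()) {
    if (nrow(taxa) == 0L) stop("empty leaf set", call. = FALSE)
    all(taxa$domain == "Bacteria") &&
        length(unique(taxa$phylum)) >= config@minBacterialPhyla
}

#' Bootstrap support tier
#'
#' Bins a bootstrap support value into the screen's confidence tiers:
#' high (> 70), moderate (51-70) and low (otherwise, including exactly
#' 50); absent supports map to "absent". Bounds are configurable.
#'
#' @param support numeric vector of supports in \[0, 100\], NA for absent.
#' @param config a [ScreenConfig][screenConfig].
#' @return Character vector of tiers.
#' @examples
#' supportTier(c(71, 70, 51, 50, NA))
#' @export
supportTier <- function(support, config = screenConfig()) {
    bad <- !is.na(support) & (support < 0 | support > 100)
    if (any(bad))
        stop("support out of [0, 100]: ", paste(support[bad], collapse = ", "),
             call. = FALSE)
    ifelse(is.na(support), "absent",
        ifelse(support > config@tierHighGt, "high",
            ifelse(support >= config@tierModerateLow &
                   support <= config@tierModerateHigh, "moderate", "low")))
}

#' Classify a gene tree for lateral gene transfer
#'
#' Applies the sister-group decision procedure to an annotated, rooted
#' gene tree. In order: (1) a purely archaeal, non-companion sister group
#' is vertical inheritance (`non_LGT`); (2) a purely bacterial sister
#' group is `LGT_bacterial_neighbor`; (3) a sister group consisting only
#' of companion-genus leaves triggers the nesting test: the focal+companion
#' clade must sit inside a bacterial clade (all-bacterial enclosure levels
#' spanning at least `minBacterialPhyla` phyla) to become
#' `LGT_nested_methanogen_pair`, an ancient transfer predating the
#' divergence of the two genera; (4) a purely eukaryotic sister group is
#' `LGT_eukaryote_neighbor`; (5) mixed-domain sister groups are
#' conservatively `non_LGT` and flagged for manual review.
#'
#' Direction: `bacteria_to_archaea` when the focal (or focal+companion)
#' clade is surrounded by at least `minDirectionLevels` successive purely
#' bacterial enclosure levels spanning the phylum threshold, with at least
#' one other archaeon outside the enclosure to polarise the transfer;
#' `archaea_to_bacteria` when a small bacterial sister group (at most
#' `maxExportSisterSize` leaves) is nested in an otherwise archaeal
#' context spanning at least `minExportGenera` non-companion archaeal
#' genera; `eukarya_to_archaea` analogously for eukaryotic enclosures;
#' otherwise `unknown`. A single bacterial level adjacent to the root is
#' left `unknown`: without archaea beyond the enclosure the topology
#' cannot distinguish import from export.
#'
#' The `only_archaea` column records trees in which the focal species and
#' companion genus are the only archaea present; when the direction is
#' unknown this sets the `only_archaea_rescue` flag (a likely bacterial
#' origin despite the unresolvable direction). `support` is the bootstrap
#' value of the inspected branch: the edge joining the focal (or
#' focal+companion) clade to its sister.
#'
#' With multiple focal paralogs each copy is classified independently; the
#' per-gene verdict is the first LGT copy if any, and the per-leaf table is
#' attached as attribute `"perLeaf"`.
#'
#' @param x an annotated [AnnotatedGeneTree].
#' @param config a [ScreenConfig][screenConfig].
#' @return One-row data.frame with columns gene_id, status,
#'   companion_present, direction, only_archaea_rescue, only_archaea,
#'   support, tier, donor_phylum, mixed_sister, sister_composition,
#'   n_focal_copies.
#' @export
classifyTree <- function(x, config = screenConfig()) {
    prep <- .prepareTree(x, config)
    rows <- lapply(prep$focalTips, function(tip)
        .classifyFocalLeaf(prep$phy, tip, prep$tax, config))
    perLeaf <- do.call(rbind, rows)
    perLeaf$gene_id <- geneId(x)
    lgt <- which(perLeaf$status != "non_LGT")
    pick <- if (length(lgt)) lgt[1L] else 1L
    out <- perLeaf[pick, , drop = FALSE]
    out$n_focal_copies <- nrow(perLeaf)
    out <- out[, c("gene_id", "status", "companion_present", "direction",
                   "only_archaea_rescue", "only_archaea", "support", "tier",
                   "donor_phylum", "mixed_sister", "sister_composition",
                   "n_focal_copies")]
    rownames(out) <- NULL
    attr(out, "perLeaf") <- perLeaf
    out
}

#' @rdname classifyTree
#' @param trees a list of annotated AnnotatedGeneTree objects.
#' @return `classifyTrees`: a data.frame with one row per gene.
#' @export
classifyTrees <- function(trees, config = screenConfig()) {
    do.call(rbind, lapply(trees, classifyTree, config = config))
}

# ---- internals --------------------------------------------------------

.prepareTree <- function(x, config) {
    stopifnot(is(x, "AnnotatedGeneTree"))
    if (nrow(taxonomyOf(x)) == 0L)
        stop("tree is not annotated; call annotateTree() first", call. = FALSE)
    validObject(x)
    if (config@rooting == "midpoint") x <- midpointRoot(x)
    phy <- treeOf(x)
    if (!ape::is.rooted(phy))
        stop("tree must be rooted for classification", call. = FALSE)
    tax <- taxonomyOf(x)
    focal <- which(tax$species[match(phy$tip.label, tax$leaf_id)] ==
                   config@focalSpecies)
    if (!length(focal))
        stop("focal taxon not in tree: ", config@focalSpecies, call. = FALSE)
    list(phy = phy, tax = tax, focalTips = focal)
}

# Successive enclosure levels above `node`: each element is the set of
# leaf labels newly gained when stepping to the next ancestor.
.enclosureLevels <- function(phy, node, maxLevels = Inf) {
    levels <- list()
    prev <- .tipLabelsUnder(phy, node)
    p <- .parentOf(phy, node)
    while (!is.na(p) && length(levels) < maxLevels) {
        tips <- .tipLabelsUnder(phy, p)
        levels[[length(levels) + 1L]] <- setdiff(tips, prev)
        prev <- tips
        p <- .parentOf(phy, p)
    }
    levels
}

# Consecutive run of enclosure levels whose leaves are all of `domain`.
.pureEnclosure <- function(phy, tax, node, domain, config) {
    levels <- .enclosureLevels(phy, node, config@maxNestingLevels)
    run <- 0L
    leaves <- character()
    for (lv in levels) {
        lvTax <- .taxonFor(tax, lv)
        if (!all(lvTax$domain == domain)) break
        run <- run + 1L
        leaves <- c(leaves, lv)
    }
    encTax <- .taxonFor(tax, leaves)
    cladeTips <- .tipLabelsUnder(phy, node)
    outside <- setdiff(phy$tip.label, c(cladeTips, leaves))
    outTax <- .taxonFor(tax, outside)
    list(levels = run,
         leaves = leaves,
         firstLevel = if (length(levels)) levels[[1L]] else character(),
         phyla = length(unique(encTax$phylum)),
         genera = length(unique(setdiff(encTax$genus, config@companionGenus))),
         archaeaOutside = any(outTax$domain == "Archaea"))
}

.classifyFocalLeaf <- function(phy, tip, tax, config) {
    tipLabel <- phy$tip.label[tip]
    parent <- .parentOf(phy, tip)
    sister <- setdiff(.tipLabelsUnder(phy, parent), tipLabel)
    sTax <- .taxonFor(tax, sister)
    if (anyNA(sTax$domain))
        stop("unannotated leaf reached: ",
             paste(sister[is.na(sTax$domain)], collapse = ", "), call. = FALSE)
    doms <- unique(sTax$domain)
    composition <- paste(sprintf("%s:%d", names(table(sTax$domain)),
                                 as.integer(table(sTax$domain))),
                         collapse = ";")

    status <- "non_LGT"
    mixed <- FALSE
    cladeNode <- tip          # the focal(-or-pair) clade whose sister is inspected
    if (identical(doms, "Archaea")) {
        if (all(.isCompanion(sTax, config))) {
            enc <- .pureEnclosure(phy, tax, parent, "Bacteria", config)
            if (enc$levels >= 1L && enc$phyla >= config@minBacterialPhyla) {
                status <- "LGT_nested_methanogen_pair"
                cladeNode <- parent
            }
        }
    } else if (identical(doms, "Bacteria")) {
        status <- "LGT_bacterial_neighbor"
    } else if (identical(doms, "Eukaryota")) {
        status <- "LGT_eukaryote_neighbor"
    } else {
        mixed <- TRUE
    }

    direction <- if (status == "non_LGT") "not_applicable" else "unknown"
    if (status != "non_LGT") {
        bacEnc <- .pureEnclosure(phy, tax, cladeNode, "Bacteria", config)
        if (bacEnc$levels >= config@minDirectionLevels &&
            bacEnc$phyla >= config@minBacterialPhyla &&
            bacEnc$archaeaOutside) {
            direction <- "bacteria_to_archaea"
        } else if (status == "LGT_eukaryote_neighbor") {
            eukEnc <- .pureEnclosure(phy, tax, cladeNode, "Eukaryota", config)
            if (eukEnc$levels >= config@minDirectionLevels &&
                eukEnc$archaeaOutside)
                direction <- "eukarya_to_archaea"
        } else if (status == "LGT_bacterial_neighbor" &&
                   length(sister) <= config@maxExportSisterSize) {
            archEnc <- .pureEnclosure(phy, tax, parent, "Archaea", config)
            if (archEnc$levels >= 1L &&
                archEnc$genera >= config@minExportGenera)
                direction <- "archaea_to_bacteria"
        }
    }

    allTax <- .taxonFor(tax, phy$tip.label)
    archRows <- allTax[allTax$domain == "Archaea", , drop = FALSE]
    onlyArch <- nrow(archRows) > 0L &&
        all(archRows$species == config@focalSpecies |
            .isCompanion(archRows, config))
    rescue <- status != "non_LGT" && direction == "unknown" && onlyArch

    # the branch joining the focal(-or-pair) clade to its sister carries the
    # support of their common node
    supNode <- .parentOf(phy, cladeNode)
    support <- if (is.na(supNode)) NA_real_ else .nodeSupport(phy, supNode)

    neighbor <- if (cladeNode == tip) sister
                else .pureEnclosure(phy, tax, cladeNode, "Bacteria",
                                    config)$firstLevel
    nTax <- .taxonFor(tax, neighbor)
    donor <- "undetermined"
    if (status != "non_LGT" && nrow(nTax)) {
        ph <- unique(nTax$phylum)
        if (length(ph) == 1L && nzchar(ph)) donor <- ph
    }

    compSpecies <- intersect(config@companionSpecies, sTax$species)
    companion <- if (length(compSpecies) == 0L) {
        if (any(sTax$genus == config@companionGenus)) "other" else "none"
    } else if (length(compSpecies) >= 2L) "both"
    else sub(".*[_ ]", "", compSpecies)

    data.frame(gene_id = NA_character_, focal_leaf = tipLabel,
               status = status, companion_present = companion,
               direction = direction, only_archaea_rescue = rescue,
               only_archaea = onlyArch, support = support,
               tier = supportTier(support, config), donor_phylum = donor,
               mixed_sister = mixed, sister_composition = composition,
               stringsAsFactors = FALSE)
}
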