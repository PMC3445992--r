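# Internal helpers over ape phylo objects. All assume a rooted tree with
# ape node numbering: tips 1..Ntip, internal nodes Ntip+1..Ntip+Nnode.

.parentOf <- function(phy, node) {
    e <- phy$edge
    p <- e[e[, 2] == node, 1]
    if (length(p)) p else NA_integer_
}

.childrenOf <- function(phy, node) {
    e <- phy$edge
    e[e[, 1] == node, 2]
}

.rootOf <- function(phy) length(phy$tip.label) + 1L

.tipsUnder <- function(phy, node) {
    ntip <- length(phy$tip.label)
    if (node <= ntip) return(node)
    unlist(phangorn::Descendants(phy, node, type = "tips"))
}

.tipLabelsUnder <- function(phy, node) phy$tip.label[.tipsUnder(phy, node)]

# Numeric support at an internal node, NA when absent/non-numeric.
.nodeSupport <- function(phy, node) {
    ntip <- length(phy$tip.label)
    if (is.null(phy$node.label) || node <= ntip) return(NA_real_)
    lab <- phy$node.label[node - ntip]
    suppressWarnings(as.numeric(lab))
}

# TRUE if `anc` is an ancestor of (or equal to) `node`.
.isAncestor <- function(phy, node, anc, strict = FALSE) {
    if (!strict && node == anc) return(TRUE)
    p <- .parentOf(phy, node)
    while (!is.na(p)) {
        if (p == anc) return(TRUE)
        p <- .parentOf(phy, p)
    }
    FALSE
}

# Taxonomy rows for a set of leaf labels, in that order.
.taxonFor <- function(taxonomy, leaves) {
    taxonomy[match(leaves, taxonomy$leaf_id), , drop = FALSE]
}

.isCompanion <- function(taxRows, config) {
    taxRows$genus == config@companionGenus |
        taxRows$species %in% config@companionSpecies
}

# Preorder of internal+tip nodes (parents before children).
.preorderEdges <- function(phy) {
    ape::reorder.phylo(phy, "postorder")$edge[rev(seq_len(nrow(phy$edge))), ,
                                              drop = FALSE]
}
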