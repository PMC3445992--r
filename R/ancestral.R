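#' Read a presence/absence matrix
#'
#' Reads a tab-separated gene-family presence/absence matrix: first column
#' family id, remaining columns one per species, entries 0/1. Families
#' absent from every species are dropped with a warning.
#'
#' @param path TSV file path.
#' @return Binary matrix, rows = families, columns = species.
#' @export
readPresenceAbsence <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
    storage.mode(m) <- "integer"
    validatePresenceAbsence(m)
}

#' @rdname readPresenceAbsence
#' @param m a binary matrix to validate.
#' @export
validatePresenceAbsence <- function(m) {
    if (!all(m %in% c(0L, 1L)))
        stop("presence/absence entries must be 0 or 1", call. = FALSE)
    empty <- rowSums(m) == 0L
    if (any(empty)) {
        warning("dropping ", sum(empty), " all-absent family row(s)")
        m <- m[!empty, , drop = FALSE]
    }
    m
}

#' Ancestral gene-family content by parsimony
#'
#' Reconstructs presence/absence of each gene family at every node of a
#' rooted species tree and lists the gain/loss events implied along each
#' branch. Three modes:
#' \describe{
#'   \item{fitch}{unit-cost parsimony (gain and loss equally likely).}
#'   \item{dollo}{each family is gained exactly once (at the most recent
#'     common ancestor of the species carrying it) and lost freely below.}
#'   \item{weighted}{gain costs `gainPenalty` times a loss (default 2,
#'     reflecting that gain by lateral transfer is rarer than loss);
#'     solved by Sankoff dynamic programming.}
#' }
#' Cost ties at the root are resolved toward absence (families are assumed
#' gained later rather than ancestrally ubiquitous); ties during
#' backtracking prefer the parent's state. This weighted-parsimony
#' reconstruction is a deliberately simple surrogate for methods that also
#' weigh gene-family co-occurrence: it uses the phylogeny alone.
#'
#' @param m binary matrix, rows = families, columns = species (leaf labels
#'   of `tree`).
#' @param tree rooted `phylo` species tree whose tips match `colnames(m)`;
#'   alternatively supply `outgroup` to root an unrooted tree.
#' @param mode "weighted" (default), "fitch" or "dollo".
#' @param gainPenalty cost of a gain relative to a loss (weighted mode).
#' @param outgroup optional tip label used to root `tree`.
#' @return An [AncestralReconstruction].
#' @export
reconstructAncestralContent <- function(m, tree,
                                        mode = c("weighted", "fitch", "dollo"),
                                        gainPenalty = 2,
                                        outgroup = NULL) {
    mode <- match.arg(mode)
    if (!is.null(outgroup))
        tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    if (!ape::is.rooted(tree))
        stop("species tree must be rooted (or supply outgroup)", call. = FALSE)
    m <- validatePresenceAbsence(m)
    extra <- setdiff(colnames(m), tree$tip.label)
    miss <- setdiff(tree$tip.label, colnames(m))
    if (length(extra) || length(miss))
        stop("leaf/species mismatch; in matrix only: ",
             paste(extra, collapse = ", "), "; in tree only: ",
             paste(miss, collapse = ", "), call. = FALSE)

    ntip <- length(tree$tip.label)
    nnode <- tree$Nnode
    nAll <- ntip + nnode
    states <- matrix(0L, nrow = nAll, ncol = nrow(m),
                     dimnames = list(.nodeLabels(tree), rownames(m)))
    for (f in seq_len(nrow(m))) {
        leafStates <- m[f, tree$tip.label]
        states[, f] <- switch(mode,
            dollo = .dolloStates(tree, leafStates),
            fitch = .sankoffStates(tree, leafStates, gainCost = 1, lossCost = 1),
            weighted = .sankoffStates(tree, leafStates,
                                      gainCost = gainPenalty, lossCost = 1))
    }
    events <- .eventsFromStates(tree, states)
    new("AncestralReconstruction", tree = tree, nodeStates = states,
        events = events, mode = mode)
}

.nodeLabels <- function(tree) {
    ntip <- length(tree$tip.label)
    inner <- tree$node.label
    if (is.null(inner) || !all(nzchar(inner)))
        inner <- paste0("node_", seq_len(tree$Nnode) + ntip)
    c(tree$tip.label, inner)
}

# Sankoff DP over states {0,1} with asymmetric change costs.
.sankoffStates <- function(tree, leafStates, gainCost, lossCost) {
    ntip <- length(tree$tip.label)
    nAll <- ntip + tree$Nnode
    INF <- .Machine$double.xmax / 4
    cost <- matrix(INF, nrow = nAll, ncol = 2L)  # columns: state 0, state 1
    cost[seq_len(ntip), ] <- INF
    cost[cbind(seq_len(ntip), leafStates + 1L)] <- 0
    trans <- matrix(c(0, gainCost, lossCost, 0), nrow = 2L, byrow = TRUE)
    # trans[from+1, to+1]
    po <- ape::reorder.phylo(tree, "postorder")$edge
    for (i in seq_len(nrow(po))) {
        parent <- po[i, 1L]; child <- po[i, 2L]
        if (cost[parent, 1L] >= INF && cost[parent, 2L] >= INF)
            cost[parent, ] <- 0
        add <- vapply(1:2, function(s)
            min(cost[child, 1L] + trans[s, 1L],
                cost[child, 2L] + trans[s, 2L]), numeric(1))
        cost[parent, ] <- cost[parent, ] + add
    }
    states <- integer(nAll)
    root <- .rootOf(tree)
    # tie at the root resolves toward absence
    states[root] <- if (cost[root, 1L] <= cost[root, 2L]) 0L else 1L
    pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
    for (i in seq_len(nrow(pre))) {
        parent <- pre[i, 1L]; child <- pre[i, 2L]
        if (child <= ntip) { states[child] <- leafStates[child]; next }
        ps <- states[parent]
        c0 <- cost[child, 1L] + trans[ps + 1L, 1L]
        c1 <- cost[child, 2L] + trans[ps + 1L, 2L]
        states[child] <- if (c0 < c1) 0L
            else if (c1 < c0) 1L
            else ps  # tie: keep the parent's state
    }
    states
}

# Dollo: single gain at the MRCA of present leaves; a node is present iff
# it descends from (or is) that MRCA and its subtree retains the family.
.dolloStates <- function(tree, leafStates) {
    ntip <- length(tree$tip.label)
    nAll <- ntip + tree$Nnode
    present <- which(leafStates == 1L)
    states <- integer(nAll)
    if (!length(present)) return(states)
    mrca <- if (length(present) == 1L) present
            else ape::getMRCA(tree, present)
    po <- ape::reorder.phylo(tree, "postorder")$edge
    nPresent <- integer(nAll)
    nPresent[present] <- 1L
    for (i in seq_len(nrow(po)))
        nPresent[po[i, 1L]] <- nPresent[po[i, 1L]] + nPresent[po[i, 2L]]
    for (v in seq_len(nAll))
        if (nPresent[v] > 0L && .isAncestor(tree, v, mrca))
            states[v] <- 1L
    states
}

.eventsFromStates <- function(tree, states) {
    labs <- rownames(states)
    ev <- list()
    for (i in seq_len(nrow(tree$edge))) {
        parent <- tree$edge[i, 1L]; child <- tree$edge[i, 2L]
        diffs <- which(states[parent, ] != states[child, ])
        for (f in diffs) {
            ev[[length(ev) + 1L]] <- data.frame(
                node = child, branch = labs[child],
                family = colnames(states)[f],
                event = if (states[child, f] == 1L) "gain" else "loss",
                stringsAsFactors = FALSE)
        }
    }
    if (!length(ev))
        return(data.frame(node = integer(), branch = character(),
                          family = character(), event = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, ev)
    rownames(out) <- NULL
    out
}

#' Families present at a node
#'
#' @param recon an [AncestralReconstruction].
#' @param node node label (tip label or internal node label) or ape node
#'   number.
#' @return Character vector of family ids present at the node.
#' @export
familiesAt <- function(recon, node) {
    i <- .resolveNode(recon, node)
    colnames(recon@nodeStates)[recon@nodeStates[i, ] == 1L]
}

.resolveNode <- function(recon, node) {
    labs <- rownames(recon@nodeStates)
    if (is.character(node)) {
        i <- match(node, labs)
        if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
        return(i)
    }
    if (node < 1L || node > nrow(recon@nodeStates))
        stop("node number out of range: ", node, call. = FALSE)
    as.integer(node)
}

#' Gene-family differences between a node and an ancestor
#'
#' Compares the reconstructed family content of `node` with that of its
#' ancestor `ancestor` (any ancestor, not only the parent): `gained` are
#' families present at the node but absent from the ancestor, `lost` the
#' converse. Errors if the two nodes are not in an ancestor relation.
#'
#' @param recon an [AncestralReconstruction].
#' @param node,ancestor node labels or numbers; `ancestor` must be an
#'   ancestor of `node`.
#' @return list(gained = character, lost = character).
#' @export
branchDiff <- function(recon, node, ancestor) {
    a <- .resolveNode(recon, node)
    b <- .resolveNode(recon, ancestor)
    if (!.isAncestor(recon@tree, a, b, strict = TRUE))
        stop("nodes are not in an ancestor relation: ",
             rownames(recon@nodeStates)[b], " is not an ancestor of ",
             rownames(recon@nodeStates)[a], call. = FALSE)
    sa <- recon@nodeStates[a, ]
    sb <- recon@nodeStates[b, ]
    fams <- colnames(recon@nodeStates)
    list(gained = fams[sa == 1L & sb == 0L],
         lost = fams[sa == 0L & sb == 1L])
}
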