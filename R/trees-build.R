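#' Neighbor-joining tree from a distance matrix
#'
#' Builds an unrooted tree with the Saitou-Nei neighbor-joining algorithm
#' (via `ape::nj`). The matrix must be symmetric with a zero diagonal;
#' triangle-inequality violations are tolerated (NJ handles them) but
#' flagged in attribute `"triangle_violations"`. Negative branch-length
#' estimates are clamped to zero and the deficit moved to the sibling
#' branch, following the usual convention; the number of clamped branches
#' is reported in attribute `"clamped"` and via a message.
#'
#' @param dm square symmetric numeric matrix with row/col names, or a `dist`.
#' @return An unrooted `phylo` whose tips are the matrix taxa.
#' @examples
#' d <- cophenetic(ape::read.tree(text = "((A:1,B:2):1,(C:1,D:1):2);"))
#' buildNJTree(d)
#' @export
buildNJTree <- function(dm) {
    if (inherits(dm, "dist")) dm <- as.matrix(dm)
    if (!is.matrix(dm) || nrow(dm) != ncol(dm))
        stop("distance input must be a square matrix", call. = FALSE)
    if (nrow(dm) < 3L)
        stop("need at least 3 taxa", call. = FALSE)
    if (max(abs(dm - t(dm))) > 1e-8)
        stop("distance matrix is not symmetric", call. = FALSE)
    if (any(abs(diag(dm)) > 1e-12))
        stop("distance matrix must have a zero diagonal", call. = FALSE)
    if (any(dm < 0))
        stop("distances must be nonnegative", call. = FALSE)
    if (is.null(rownames(dm)))
        rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
    viol <- .countTriangleViolations(dm)
    phy <- ape::nj(as.dist(dm))
    clamped <- 0L
    neg <- which(phy$edge.length < 0)
    for (i in neg) {
        deficit <- phy$edge.length[i]
        parent <- phy$edge[i, 1L]
        sibs <- setdiff(which(phy$edge[, 1L] == parent), i)
        phy$edge.length[i] <- 0
        if (length(sibs))
            phy$edge.length[sibs[1L]] <-
                max(0, phy$edge.length[sibs[1L]] + deficit)
        clamped <- clamped + 1L
    }
    if (clamped)
        message("buildNJTree: clamped ", clamped,
                " negative branch length(s) to zero")
    attr(phy, "clamped") <- clamped
    attr(phy, "triangle_violations") <- viol
    phy
}

.countTriangleViolations <- function(dm, tol = 1e-9) {
    n <- nrow(dm)
    viol <- 0L
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
        slack <- dm[i, ] + dm[j, ] - dm[i, j]
        if (any(slack < -tol)) viol <- viol + 1L
    }
    viol
}

#' Bootstrap support by column resampling
#'
#' Resamples the columns of an alignment-like matrix with replacement,
#' rebuilds a tree from each pseudoreplicate with `builder`, and reports
#' for each internal edge of the reference tree the percentage of
#' replicate trees containing the same bipartition (via
#' `ape::boot.phylo`). Resampling is over column indices only, so results
#' are invariant to taxon (row) order under a fixed seed.
#'
#' @param x matrix whose rows are taxa (rownames required) and whose
#'   columns are resampleable characters.
#' @param builder function mapping such a matrix to a `phylo`; must be
#'   deterministic.
#' @param nReps number of bootstrap pseudoreplicates (>= 1).
#' @param seed integer seed for reproducibility.
#' @return The reference tree `builder(x)` with `node.label` set to percent
#'   support (root label empty); attribute `"support"` carries the numeric
#'   vector.
#' @export
bootstrapSupport <- function(x, builder, nReps = 1000L, seed = 1L) {
    if (nReps < 1L) stop("nReps must be >= 1", call. = FALSE)
    if (is.null(rownames(x))) stop("x must have taxon rownames", call. = FALSE)
    ref <- builder(x)
    set.seed(as.integer(seed))
    counts <- ape::boot.phylo(ref, x, builder, B = as.integer(nReps),
                              quiet = TRUE, rooted = FALSE)
    pct <- round(100 * counts / nReps)
    lab <- as.character(pct)
    lab[1L] <- ""  # root bipartition is trivial
    ref$node.label <- lab
    attr(ref, "support") <- pct
    ref
}

#' Midpoint rooting
#'
#' Roots a tree at the midpoint of its longest leaf-to-leaf path (via
#' `phangorn::midpoint`), keeping node supports attached to the correct
#' bipartitions. When all branch lengths are zero the midpoint is
#' undefined; the tree is then rooted on a centroid edge (the edge whose
#' removal best balances the leaves) with a warning.
#'
#' @param x an AnnotatedGeneTree or `phylo`.
#' @return Object of the same class as `x`, rooted.
#' @export
midpointRoot <- function(x) {
    phy <- if (is(x, "AnnotatedGeneTree")) treeOf(x) else x
    if (is.null(phy$edge.length) || all(phy$edge.length == 0)) {
        warning("all branch lengths zero; rooting on centroid edge")
        rooted <- .centroidRoot(phy)
    } else {
        hasSupport <- !is.null(phy$node.label)
        rooted <- phangorn::midpoint(phy,
            node.labels = if (hasSupport) "support" else "delete")
    }
    if (is(x, "AnnotatedGeneTree"))
        annotatedGeneTree(geneId(x), rooted, taxonomyOf(x))
    else rooted
}

.centroidRoot <- function(phy) {
    ntip <- length(phy$tip.label)
    best <- NULL
    bestImb <- Inf
    for (i in seq_len(nrow(phy$edge))) {
        child <- phy$edge[i, 2L]
        k <- length(.tipsUnder(phy, child))
        imb <- abs(ntip - 2L * k)
        if (imb < bestImb) { bestImb <- imb; best <- child }
    }
    if (best <= ntip)
        ape::root(phy, outgroup = phy$tip.label[best], resolve.root = TRUE)
    else
        ape::root(phy, node = best, resolve.root = TRUE)
}
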