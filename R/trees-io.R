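#' Read a gene tree from Newick
#'
#' Parses a Newick file (or literal string) into an [AnnotatedGeneTree].
#' Internal node labels that are numeric and within \[0, 100\] are
#' interpreted as bootstrap support of the subtending edge, following the
#' usual Newick convention. Taxonomy is attached separately with
#' [annotateTree()].
#'
#' @param path path to a Newick file, or a Newick string when `text = TRUE`.
#' @param geneId gene identifier to record; defaults to the file base name.
#' @param text if TRUE, `path` is taken as a literal Newick string.
#' @return An `AnnotatedGeneTree` with empty taxonomy.
#' @examples
#' tr <- readNewick("((A:1,B:1)90:1,C:2);", text = TRUE, geneId = "g1")
#' tr
#' @export
readNewick <- function(path, geneId = NULL, text = FALSE) {
    str <- if (text) path else paste(readLines(path, warn = FALSE), collapse = "")
    .checkBalancedNewick(str)
    phy <- tryCatch(ape::read.tree(text = str),
                    error = function(e) NULL)
    if (is.null(phy))
        stop("malformed Newick: parser failed on input", call. = FALSE)
    if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
    if (is.null(phy) || is.null(phy$tip.label))
        stop("malformed Newick: no tree parsed", call. = FALSE)
    if (length(phy$tip.label) < 3L)
        stop("tree has fewer than 3 leaves", call. = FALSE)
    dup <- phy$tip.label[duplicated(phy$tip.label)]
    if (length(dup))
        stop("duplicate leaf names: ", paste(unique(dup), collapse = ", "),
             call. = FALSE)
    if (is.null(geneId))
        geneId <- if (text) "gene" else sub("\\.[^.]*$", "", basename(path))
    annotatedGeneTree(geneId, phy)
}

# Balance check with character offset, for a friendlier parse error than
# ape's.
.checkBalancedNewick <- function(str) {
    chars <- strsplit(str, "")[[1L]]
    depth <- 0L
    for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1L
        if (chars[i] == ")") {
            depth <- depth - 1L
            if (depth < 0L)
                stop("malformed Newick: unbalanced ')' at character ", i,
                     call. = FALSE)
        }
    }
    if (depth != 0L)
        stop("malformed Newick: ", depth, " unclosed '(' at end of input",
             call. = FALSE)
    invisible(TRUE)
}

#' Write a gene tree to Newick
#'
#' Round-trips with [readNewick()]: topology, branch lengths and internal
#' node supports are preserved.
#'
#' @param x an AnnotatedGeneTree or ape `phylo`.
#' @param path output file; when NULL the Newick string is returned.
#' @return The path, or the Newick string when `path` is NULL.
#' @export
writeNewick <- function(x, path = NULL) {
    phy <- if (is(x, "AnnotatedGeneTree")) treeOf(x) else x
    str <- ape::write.tree(phy, digits = 12)
    if (is.null(path)) return(str)
    writeLines(str, path)
    invisible(path)
}

#' Read a leaf taxonomy table
#'
#' Reads a tab-separated table with header
#' `leaf_id species genus phylum domain`. Leaf ids must be unique, domain
#' must be one of Bacteria/Archaea/Eukaryota, and phylum may be empty only
#' for Eukaryota.
#'
#' @param path path to the TSV file.
#' @return A validated taxonomy data.frame.
#' @export
readTaxonomy <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    validateTaxonomy(tab)
}

#' @rdname readTaxonomy
#' @param tab a taxonomy data.frame to validate.
#' @export
validateTaxonomy <- function(tab) {
    need <- c("leaf_id", "species", "genus", "phylum", "domain")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("taxonomy table lacks columns: ", paste(miss, collapse = ", "),
             call. = FALSE)
    tab$phylum[is.na(tab$phylum)] <- ""
    dup <- tab$leaf_id[duplicated(tab$leaf_id)]
    if (length(dup))
        stop("duplicate leaf_id in taxonomy: ",
             paste(unique(dup), collapse = ", "), call. = FALSE)
    bad <- !tab$domain %in% VALID_DOMAINS
    if (any(bad))
        stop("invalid domain values: ",
             paste(unique(tab$domain[bad]), collapse = ", "), call. = FALSE)
    noPhy <- !nzchar(tab$phylum) & tab$domain != "Eukaryota"
    if (any(noPhy))
        stop("phylum may be empty only for Eukaryota (offending leaves: ",
             paste(head(tab$leaf_id[noPhy], 5), collapse = ", "), ")",
             call. = FALSE)
    tab[need]
}

#' Attach taxonomy to a gene tree
#'
#' In strict mode every leaf must be present in the taxonomy table. In
#' lenient mode leaves without taxonomy are dropped from the tree (the
#' count of dropped leaves is reported in attribute `"dropped"`), with an
#' error if fewer than 3 leaves remain.
#'
#' @param x an AnnotatedGeneTree (or phylo).
#' @param taxonomy taxonomy data.frame as from [readTaxonomy()].
#' @param mode "strict" (default) or "lenient".
#' @return An annotated `AnnotatedGeneTree`; attribute `"dropped"` holds the
#'   number of leaves removed in lenient mode.
#' @export
annotateTree <- function(x, taxonomy, mode = c("strict", "lenient")) {
    mode <- match.arg(mode)
    taxonomy <- validateTaxonomy(taxonomy)
    phy <- if (is(x, "AnnotatedGeneTree")) treeOf(x) else x
    gid <- if (is(x, "AnnotatedGeneTree")) geneId(x) else "gene"
    unknown <- setdiff(phy$tip.label, taxonomy$leaf_id)
    dropped <- 0L
    if (length(unknown)) {
        if (mode == "strict")
            stop("leaves missing from taxonomy table: ",
                 paste(unknown, collapse = ", "), call. = FALSE)
        if (length(phy$tip.label) - length(unknown) < 3L)
            stop("lenient drop would leave fewer than 3 leaves", call. = FALSE)
        phy <- ape::drop.tip(phy, unknown)
        dropped <- length(unknown)
    }
    tax <- taxonomy[taxonomy$leaf_id %in% phy$tip.label, , drop = FALSE]
    out <- annotatedGeneTree(gid, phy, tax)
    attr(out, "dropped") <- dropped
    out
}
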