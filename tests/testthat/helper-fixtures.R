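# Shared builders for the test suite. All fixtures are constructed in code.

# taxonomy row constructor
taxRow <- function(leaf, species, genus, phylum, domain) {
    data.frame(leaf_id = leaf, species = species, genus = genus,
               phylum = phylum, domain = domain, stringsAsFactors = FALSE)
}

# quick archaeal / bacterial / eukaryotic rows keyed by leaf id
bacRow <- function(leaf, phylum = "Firmicutes", genus = "Clostridium")
    taxRow(leaf, paste0(genus, "_", leaf), genus, phylum, "Bacteria")
archRow <- function(leaf, genus = "Methanosarcina")
    taxRow(leaf, paste0(genus, "_", leaf), genus, "Euryarchaeota", "Archaea")
eukRow <- function(leaf, species = "Saccharomyces_cerevisiae")
    taxRow(leaf, species, sub("_.*", "", species), "", "Eukaryota")
focalRow <- function(leaf = "Focal")
    taxRow(leaf, "Methanosphaera_stadtmanae", "Methanosphaera",
           "Euryarchaeota", "Archaea")
smithiiRow <- function(leaf = "Msmithii")
    taxRow(leaf, "Methanobrevibacter_smithii", "Methanobrevibacter",
           "Euryarchaeota", "Archaea")
ruminantiumRow <- function(leaf = "Mrum")
    taxRow(leaf, "Methanobrevibacter_ruminantium", "Methanobrevibacter",
           "Euryarchaeota", "Archaea")

# annotated tree from a newick string plus taxonomy rows
agtFrom <- function(newick, tax, geneId = "g1") {
    annotateTree(readNewick(newick, geneId = geneId, text = TRUE), tax)
}

# config that takes trees as provided (hand-built rooted examples)
cfgAsIs <- function(...) screenConfig(rooting = "asis", ...)

# unordered bipartition (split) set of a tree, as sorted strings
splitSet <- function(phy) {
    pp <- ape::prop.part(ape::unroot(phy))
    labs <- attr(pp, "labels")
    sort(vapply(pp, function(p) {
        s <- paste(sort(labs[p]), collapse = ",")
        o <- paste(sort(setdiff(labs, labs[p])), collapse = ",")
        if (s < o) paste(s, o, sep = "|") else paste(o, s, sep = "|")
    }, character(1)))
}

# brute-force minimum event cost of a binary character on a rooted tree,
# enumerating every internal labeling (the independent parsimony oracle)
bruteForceCost <- function(tree, leafStates, gainCost = 1, lossCost = 1) {
    nn <- tree$Nnode
    best <- Inf
    for (mask in 0:(2^nn - 1)) {
        st <- c(leafStates, as.integer(intToBits(mask))[seq_len(nn)])
        cost <- 0
        for (i in seq_len(nrow(tree$edge))) {
            p <- st[tree$edge[i, 1]]
            ch <- st[tree$edge[i, 2]]
            if (p == 0 && ch == 1) cost <- cost + gainCost
            if (p == 1 && ch == 0) cost <- cost + lossCost
        }
        best <- min(best, cost)
    }
    best
}

codonTable <- function() phyloLGT:::.codonTable()

# sequence using each amino acid's first codon, repeated
oneCodonPerAA <- function(repeats = 3) {
    tab <- codonTable()
    first <- tab[!duplicated(tab$aa), ]
    paste(rep(first$codon, each = repeats), collapse = "")
}

# long sequence with uniform synonymous codon usage
uniformUsageSeq <- function(nCodons = 6000, seed = 1) {
    set.seed(seed)
    tab <- codonTable()
    aaSeq <- sample(unique(tab$aa), nCodons, replace = TRUE)
    cods <- vapply(aaSeq, function(a) sample(tab$codon[tab$aa == a], 1L),
                   character(1))
    paste(cods, collapse = "")
}
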