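# Fixed taxon palette for simulated gene trees. Phyla mirror the donor
# composition typical of gut-microbiome screens.
.BACT_PALETTE <- data.frame(
    phylum = c("Firmicutes", "Bacteroidetes", "Proteobacteria",
               "Actinobacteria", "Fusobacteria", "Spirochaetes"),
    genus = c("Clostridium", "Bacteroides", "Escherichia",
              "Bifidobacterium", "Fusobacterium", "Treponema"),
    stringsAsFactors = FALSE)

.ARCH_GENERA <- c("Methanosarcina", "Methanothermobacter", "Methanococcus",
                  "Haloferax")

.EUK_SPECIES <- c("Saccharomyces_cerevisiae", "Homo_sapiens",
                  "Arabidopsis_thaliana", "Dictyostelium_discoideum")

.SCENARIOS <- c("vertical", "recent_bacterial_lgt",
                "ancient_pre_divergence_lgt", "eukaryotic_lgt",
                "archaea_export")

#' Simulate a gene tree with a planted transfer history
#'
#' Generates an annotated gene tree realising one of five outcome
#' scenarios, together with the classification the screen is expected to
#' produce on it under noise-free settings:
#' \describe{
#'   \item{vertical}{focal species sister to the companion genus inside an
#'     archaeal clade, bacteria as a distant outgroup: `non_LGT`.}
#'   \item{recent_bacterial_lgt}{focal leaf nested alone inside successive
#'     bacterial enclosures spanning the phylum threshold, other archaea
#'     outside: `LGT_bacterial_neighbor`, bacteria-to-archaea.}
#'   \item{ancient_pre_divergence_lgt}{focal + companion pair nested inside
#'     bacterial enclosures: `LGT_nested_methanogen_pair`,
#'     bacteria-to-archaea (the transfer predates the divergence of the
#'     two genera).}
#'   \item{eukaryotic_lgt}{focal leaf nested inside eukaryotic enclosures:
#'     `LGT_eukaryote_neighbor`, eukarya-to-archaea.}
#'   \item{archaea_export}{a single bacterial leaf nested inside an
#'     otherwise archaeal clade containing the focal leaf:
#'     `LGT_bacterial_neighbor`, archaea-to-bacteria.}
#' }
#' Trees carry branch lengths with a long outgroup stem, so midpoint
#' rooting recovers the intended root. The bootstrap support of the
#' planted inspected branch is drawn from a truncated normal (clamped to
#' \[0, 100\]) so tier logic is exercised; other edges get high support.
#'
#' @param scenario one of the five scenario names.
#' @param nBacteria,nBacterialPhyla,nArchaea,nEukaryotes taxon counts;
#'   scenario-specific minima are enforced.
#' @param supportMean,supportSd distribution of the planted-edge support.
#' @param seed integer seed; the output is reproducible under it.
#' @param companions which companion species flank the focal leaf in the
#'   vertical and ancient scenarios.
#' @param geneId identifier for the simulated gene.
#' @return list(tree = annotated [AnnotatedGeneTree], taxonomy =
#'   data.frame, expected = one-row data.frame with the planted status,
#'   direction, support, tier and donor phylum).
#' @export
simulateGeneTree <- function(scenario = .SCENARIOS,
                             nBacteria = 6L, nBacterialPhyla = 3L,
                             nArchaea = 4L, nEukaryotes = 0L,
                             supportMean = 85, supportSd = 10,
                             seed = 1L,
                             companions = c("both", "smithii", "ruminantium"),
                             geneId = NULL) {
    scenario <- match.arg(scenario)
    companions <- match.arg(companions)
    .checkScenario(scenario, nBacteria, nBacterialPhyla, nArchaea, nEukaryotes)
    set.seed(as.integer(seed))
    if (is.null(geneId)) geneId <- paste0("sim_", scenario, "_", seed)

    sup <- .truncSupport(supportMean, supportSd)
    tax <- .paletteTaxonomy(nBacteria, nBacterialPhyla, nArchaea, nEukaryotes,
                            companions)
    nwk <- switch(scenario,
        vertical = .nwkVertical(tax, sup),
        recent_bacterial_lgt = .nwkRecent(tax, sup),
        ancient_pre_divergence_lgt = .nwkAncient(tax, sup),
        eukaryotic_lgt = .nwkEukaryotic(tax, sup),
        archaea_export = .nwkExport(tax, sup))
    agt <- annotateTree(readNewick(nwk, geneId = geneId, text = TRUE),
                        tax$table)
    # taxa the scenario did not place in the tree are not reported
    tax$table <- taxonomyOf(agt)
    cfg <- screenConfig(minBacterialPhyla = min(3L, nBacterialPhyla))

    expected <- data.frame(
        gene_id = geneId, scenario = scenario,
        status = switch(scenario,
            vertical = "non_LGT",
            recent_bacterial_lgt = "LGT_bacterial_neighbor",
            ancient_pre_divergence_lgt = "LGT_nested_methanogen_pair",
            eukaryotic_lgt = "LGT_eukaryote_neighbor",
            archaea_export = "LGT_bacterial_neighbor"),
        direction = switch(scenario,
            vertical = "not_applicable",
            recent_bacterial_lgt = "bacteria_to_archaea",
            ancient_pre_divergence_lgt = "bacteria_to_archaea",
            eukaryotic_lgt = "eukarya_to_archaea",
            archaea_export = "archaea_to_bacteria"),
        companion_present = switch(scenario,
            vertical = companions,
            ancient_pre_divergence_lgt = companions,
            "none"),
        support = sup,
        tier = supportTier(sup, cfg),
        donor_phylum = switch(scenario,
            eukaryotic_lgt = "undetermined",
            vertical = "undetermined",
            # the ancient scenario's first (alphabetical) enclosure phylum
            ancient_pre_divergence_lgt =
                sort(.BACT_PALETTE$phylum[seq_len(nBacterialPhyla)])[1L],
            .BACT_PALETTE$phylum[1L]),
        stringsAsFactors = FALSE)
    list(tree = agt, taxonomy = tax$table, expected = expected)
}

.checkScenario <- function(scenario, nB, nP, nA, nE) {
    fail <- function(msg) stop("infeasible scenario spec: ", msg, call. = FALSE)
    if (nP > min(nB, nrow(.BACT_PALETTE)))
        fail("more bacterial phyla requested than bacteria or palette size")
    switch(scenario,
        vertical = {
            if (nA < 1L || nB < 1L) fail("vertical needs >=1 archaeon and >=1 bacterium")
        },
        recent_bacterial_lgt = ,
        ancient_pre_divergence_lgt = {
            if (nP < 3L) fail(paste(scenario, "needs >=3 bacterial phyla"))
            if (nB < 3L) fail(paste(scenario, "needs >=3 bacteria"))
            if (nA < 1L) fail(paste(scenario, "needs an archaeal outgroup"))
        },
        eukaryotic_lgt = {
            if (nE < 2L) fail("eukaryotic_lgt needs >=2 eukaryotes")
            if (nA < 1L) fail("eukaryotic_lgt needs an archaeal outgroup")
        },
        archaea_export = {
            if (nB < 2L) fail("archaea_export needs >=2 bacteria")
            if (nA < 2L) fail("archaea_export needs >=2 archaeal genera")
        })
    invisible(TRUE)
}

.truncSupport <- function(mean, sd) {
    s <- round(rnorm(1L, mean, sd))
    min(100, max(0, s))
}

.paletteTaxonomy <- function(nB, nP, nA, nE, companions) {
    bact <- data.frame(
        leaf_id = paste0("Bac_", seq_len(nB)),
        stringsAsFactors = FALSE)
    idx <- rep(seq_len(nP), length.out = nB)
    bact$genus <- .BACT_PALETTE$genus[idx]
    bact$phylum <- .BACT_PALETTE$phylum[idx]
    bact$species <- paste0(bact$genus, "_sp", seq_len(nB))
    bact$domain <- "Bacteria"

    arch <- if (nA > 0L) {
        g <- rep(.ARCH_GENERA, length.out = nA)
        data.frame(leaf_id = paste0("Arch_", seq_len(nA)),
                   species = paste0(g, "_sp", seq_len(nA)),
                   genus = g, phylum = "Euryarchaeota", domain = "Archaea",
                   stringsAsFactors = FALSE)
    } else NULL

    euk <- if (nE > 0L) {
        sp <- rep(.EUK_SPECIES, length.out = nE)
        data.frame(leaf_id = paste0("Euk_", seq_len(nE)),
                   species = sp, genus = sub("_.*", "", sp),
                   phylum = "", domain = "Eukaryota",
                   stringsAsFactors = FALSE)
    } else NULL

    focal <- data.frame(leaf_id = "Msta_1",
                        species = "Methanosphaera_stadtmanae",
                        genus = "Methanosphaera", phylum = "Euryarchaeota",
                        domain = "Archaea", stringsAsFactors = FALSE)
    compSp <- switch(companions,
        both = c("Methanobrevibacter_smithii", "Methanobrevibacter_ruminantium"),
        smithii = "Methanobrevibacter_smithii",
        ruminantium = "Methanobrevibacter_ruminantium")
    comp <- data.frame(leaf_id = paste0("Mbb_", seq_along(compSp)),
                       species = compSp, genus = "Methanobrevibacter",
                       phylum = "Euryarchaeota", domain = "Archaea",
                       stringsAsFactors = FALSE)
    cols <- c("leaf_id", "species", "genus", "phylum", "domain")
    table <- rbind(focal[cols], comp[cols],
                   if (!is.null(arch)) arch[cols],
                   bact[cols], if (!is.null(euk)) euk[cols])
    list(table = table, focal = focal, comp = comp, arch = arch,
         bact = bact, euk = euk)
}

# -- newick assembly ----------------------------------------------------

.bl <- function(lo = 0.08, hi = 0.2) sprintf("%.4f", runif(1L, lo, hi))

.leafNwk <- function(ids) paste0(ids, ":", vapply(ids, function(i) .bl(),
                                                  character(1)))

# clade over >=1 leaves as a pectinate subtree with high supports
.cladeNwk <- function(ids) {
    parts <- .leafNwk(ids)
    while (length(parts) > 1L) {
        merged <- paste0("(", parts[1L], ",", parts[2L], ")",
                         sample(90:100, 1L), ":", .bl())
        parts <- c(merged, parts[-(1:2)])
    }
    parts
}

# successively enclose `inner` by the given groups (list of id vectors)
.encloseNwk <- function(inner, groups) {
    for (g in groups)
        inner <- paste0("(", inner, ",", .cladeNwk(g), ")",
                        sample(90:100, 1L), ":", .bl())
    inner
}

.rootNwk <- function(inner, outgroupIds) {
    out <- sub(":[0-9.]+$", ":3.5", .cladeNwk(outgroupIds))
    paste0("(", inner, ",", out, ");")
}

.nwkVertical <- function(tax, sup) {
    inner <- paste0("(", .leafNwk(tax$focal$leaf_id), ",",
                    .cladeNwk(tax$comp$leaf_id), ")", sup, ":", .bl())
    inner <- .encloseNwk(inner, list(tax$arch$leaf_id))
    .rootNwk(inner, tax$bact$leaf_id)
}

.nwkRecent <- function(tax, sup) {
    # first bacterium (palette phylum 1) is the sister; remaining bacteria
    # form one enclosure level per phylum
    b <- tax$bact
    sister <- b$leaf_id[1L]
    rest <- b[-1L, , drop = FALSE]
    groups <- split(rest$leaf_id, rest$phylum)
    inner <- paste0("(", .leafNwk(tax$focal$leaf_id), ",",
                    .leafNwk(sister), ")", sup, ":", .bl())
    inner <- .encloseNwk(inner, groups)
    .rootNwk(inner, c(tax$comp$leaf_id, tax$arch$leaf_id))
}

.nwkAncient <- function(tax, sup) {
    b <- tax$bact
    groups <- split(b$leaf_id, b$phylum)
    pair <- paste0("(", .leafNwk(tax$focal$leaf_id), ",",
                   .cladeNwk(tax$comp$leaf_id), ")",
                   sample(90:100, 1L), ":", .bl())
    # the inspected branch joins the pair with its first bacterial group
    inner <- paste0("(", pair, ",", .cladeNwk(groups[[1L]]), ")",
                    sup, ":", .bl())
    inner <- .encloseNwk(inner, groups[-1L])
    .rootNwk(inner, tax$arch$leaf_id)
}

.nwkEukaryotic <- function(tax, sup) {
    e <- tax$euk$leaf_id
    inner <- paste0("(", .leafNwk(tax$focal$leaf_id), ",",
                    .leafNwk(e[1L]), ")", sup, ":", .bl())
    inner <- .encloseNwk(inner, list(e[-1L]))
    .rootNwk(inner, c(tax$comp$leaf_id, tax$arch$leaf_id, tax$bact$leaf_id))
}

.nwkExport <- function(tax, sup) {
    b <- tax$bact
    a <- tax$arch
    half <- ceiling(nrow(a) / 2)
    inner <- paste0("(", .leafNwk(tax$focal$leaf_id), ",",
                    .leafNwk(b$leaf_id[1L]), ")", sup, ":", .bl())
    inner <- .encloseNwk(inner, list(a$leaf_id[seq_len(half)],
                                     a$leaf_id[-seq_len(half)],
                                     tax$comp$leaf_id))
    .rootNwk(inner, b$leaf_id[-1L])
}

#' Simulate a batch of gene trees across scenarios
#'
#' Draws `n` scenarios (uniformly, or with the given weights), simulates
#' each with [simulateGeneTree()], and returns the trees with the planted
#' truth table — the input for classifier-recovery experiments.
#'
#' @param n number of trees.
#' @param seed master seed; per-tree seeds are derived from it.
#' @param scenarios scenario names to draw from.
#' @param weights sampling weights, recycled to `scenarios`.
#' @param ... passed to [simulateGeneTree()].
#' @return list(trees = list of AnnotatedGeneTree, expected = data.frame).
#' @export
simulateScreen <- function(n, seed = 1L, scenarios = .SCENARIOS,
                           weights = NULL, ...) {
    set.seed(as.integer(seed))
    picks <- sample(scenarios, n, replace = TRUE, prob = weights)
    subseeds <- sample.int(.Machine$integer.max %/% 2L, n)
    sims <- lapply(seq_len(n), function(i)
        simulateGeneTree(picks[i], seed = subseeds[i],
                         geneId = sprintf("sim_%04d", i), ...))
    list(trees = lapply(sims, `[[`, "tree"),
         expected = do.call(rbind, lapply(sims, `[[`, "expected")))
}

#' Per-amino-acid codon frequencies with tunable bias
#'
#' Builds a codon frequency map normalised within each amino acid. With
#' `bias = 0` all synonymous codons are equally likely; with `bias = 1`
#' only the preferred codon of each amino acid is used. The preferred
#' codon is the alphabetically first synonym unless `shuffle` is TRUE, in
#' which case it is drawn at random (use a seed for reproducibility) —
#' handy for making a "donor" usage distinct from a "host" usage.
#'
#' @param bias real in \[0, 1\].
#' @param shuffle randomly pick each amino acid's preferred codon.
#' @return Named numeric vector over the 61 sense codons.
#' @export
biasedCodonFrequencies <- function(bias = 0.7, shuffle = FALSE) {
    stopifnot(bias >= 0, bias <= 1)
    tab <- .codonTable()
    freq <- setNames(numeric(nrow(tab)), tab$codon)
    for (a in unique(tab$aa)) {
        cods <- sort(tab$codon[tab$aa == a])
        k <- length(cods)
        pref <- if (shuffle) sample(cods, 1L) else cods[1L]
        p <- rep((1 - bias) / k, k)
        names(p) <- cods
        p[pref] <- p[pref] + bias
        freq[cods] <- p
    }
    freq
}

#' Simulate coding sequences under codon amelioration
#'
#' Emulates the gradual adaptation of transferred genes to host codon
#' usage: each gene's amino-acid sequence is drawn uniformly, and each
#' codon is then drawn from the mixture
#' `alpha * host + (1 - alpha) * donor` of the two per-amino-acid codon
#' frequency maps. `alpha = 0` reproduces donor usage (a fresh transfer),
#' `alpha = 1` full host usage (a completely ameliorated gene).
#'
#' @param alpha host-frequency weight in \[0, 1\]; recycled to `nGenes`
#'   so a vector plants a per-gene amelioration gradient.
#' @param nGenes number of genes.
#' @param geneLengthCodons codons per gene.
#' @param hostFreqs,donorFreqs codon frequency maps as from
#'   [biasedCodonFrequencies()].
#' @param seed integer seed; identical seeds give identical sequences.
#' @return list(seqs = DNAStringSet, truth = data.frame(gene_id, alpha)).
#' @export
simulateCodingSequences <- function(alpha, nGenes = 50L,
                                    geneLengthCodons = 300L,
                                    hostFreqs = biasedCodonFrequencies(0.8),
                                    donorFreqs = biasedCodonFrequencies(0),
                                    seed = 1L) {
    stopifnot(all(alpha >= 0), all(alpha <= 1))
    alpha <- rep(alpha, length.out = nGenes)
    set.seed(as.integer(seed))
    tab <- .codonTable()
    aas <- unique(tab$aa)
    seqs <- vapply(seq_len(nGenes), function(i) {
        mix <- alpha[i] * hostFreqs + (1 - alpha[i]) * donorFreqs
        aaSeq <- sample(aas, geneLengthCodons, replace = TRUE)
        cods <- vapply(aaSeq, function(a) {
            cc <- tab$codon[tab$aa == a]
            p <- mix[cc]
            if (sum(p) <= 0) p <- rep(1, length(cc))
            sample(cc, 1L, prob = p)
        }, character(1))
        paste(cods, collapse = "")
    }, character(1))
    ids <- sprintf("gene_%03d", seq_len(nGenes))
    list(seqs = Biostrings::DNAStringSet(setNames(seqs, ids)),
         truth = data.frame(gene_id = ids, alpha = alpha,
                            stringsAsFactors = FALSE))
}

#' Evolve a presence/absence matrix on a species tree
#'
#' Simulates gene-family gain/loss along a rooted species tree: each
#' family starts at the root with presence probability `rootPresentProb`
#' and flips state along each branch with probability
#' `1 - exp(-rate * branch length)` (gain rate when absent, loss rate
#' when present), capped at `maxEventsPerFamily` events. No events are
#' planted on the two root-adjacent branches, so the outgroup retains the
#' root state and every planted history stays identifiable — mirroring
#' how outgroup rooting polarises real reconstructions.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param nFamilies number of families.
#' @param gainRate,lossRate per-unit-branch-length event rates; loss
#'   exceeding gain reflects the usual loss bias of gene-content
#'   evolution.
#' @param maxEventsPerFamily cap on events per family (1 gives
#'   zero-homoplasy histories that parsimony must recover exactly).
#' @param rootPresentProb probability a family is present at the root.
#' @param seed integer seed.
#' @return list(pam = families x species binary matrix, events = truth
#'   data.frame(node, branch, family, event), nodeStates = truth matrix
#'   over all nodes).
#' @export
simulatePresenceAbsence <- function(tree, nFamilies = 200L,
                                    gainRate = 0.2, lossRate = 0.4,
                                    maxEventsPerFamily = Inf,
                                    rootPresentProb = 0.5, seed = 1L) {
    stopifnot(gainRate >= 0, lossRate >= 0)
    if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
    set.seed(as.integer(seed))
    ntip <- length(tree$tip.label)
    nAll <- ntip + tree$Nnode
    labs <- .nodeLabels(tree)
    root <- .rootOf(tree)
    pre <- .preorderEdges(tree)
    rootAdjacent <- tree$edge[tree$edge[, 1L] == root, 2L]

    states <- matrix(0L, nrow = nAll, ncol = nFamilies,
                     dimnames = list(labs, sprintf("fam_%04d", seq_len(nFamilies))))
    evList <- list()
    for (f in seq_len(nFamilies)) {
        st <- integer(nAll)
        st[root] <- rbinom(1L, 1L, rootPresentProb)
        nEvents <- 0L
        for (i in seq_len(nrow(pre))) {
            parent <- pre[i, 1L]; child <- pre[i, 2L]
            st[child] <- st[parent]
            if (child %in% rootAdjacent) next
            bl <- tree$edge.length[which(tree$edge[, 1L] == parent &
                                         tree$edge[, 2L] == child)]
            rate <- if (st[parent] == 1L) lossRate else gainRate
            p <- 1 - exp(-rate * bl)
            if (nEvents < maxEventsPerFamily && runif(1L) < p) {
                st[child] <- 1L - st[parent]
                nEvents <- nEvents + 1L
                evList[[length(evList) + 1L]] <- data.frame(
                    node = child, branch = labs[child],
                    family = colnames(states)[f],
                    event = if (st[child] == 1L) "gain" else "loss",
                    stringsAsFactors = FALSE)
            }
        }
        states[, f] <- st
    }
    events <- if (length(evList)) do.call(rbind, evList)
        else data.frame(node = integer(), branch = character(),
                        family = character(), event = character(),
                        stringsAsFactors = FALSE)
    pam <- t(states[seq_len(ntip), , drop = FALSE])
    list(pam = pam, events = events, nodeStates = states)
}
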