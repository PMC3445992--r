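test_that("Newick parsing reads supports and rejects degenerate input", {
    tr <- readNewick("((A:1,B:1)90:1,C:2);", text = TRUE)
    phy <- treeOf(tr)
    expect_length(phy$tip.label, 3L)
    expect_equal(suppressWarnings(as.numeric(phy$node.label)),
                 c(NA, 90))

    expect_error(readNewick("(A:1);", text = TRUE), "fewer than 3")
    expect_error(readNewick("((A:1,A:1),B:1);", text = TRUE), "duplicate")
    expect_error(readNewick("((A:1,B:1,C:1);", text = TRUE), "unclosed")
    expect_error(readNewick("(A:1,B:1))C;", text = TRUE), "character 10")
})

test_that("Newick writing round-trips topology, lengths and supports", {
    set.seed(11)
    phy <- ape::rtree(50)
    phy$node.label <- c("", as.character(sample(0:100, phy$Nnode - 1L,
                                                replace = TRUE)))
    rt <- treeOf(readNewick(writeNewick(phy), text = TRUE))
    expect_identical(splitSet(rt), splitSet(phy))
    ord <- match(phy$tip.label, rt$tip.label)
    d1 <- cophenetic(phy)
    d2 <- cophenetic(rt)[rownames(d1), colnames(d1)]
    expect_lt(max(abs(d1 - d2)), 1e-9)
    expect_identical(sort(rt$node.label), sort(phy$node.label))
})

test_that("taxonomy annotation enforces strict and lenient contracts", {
    tax <- rbind(focalRow(), bacRow("B1"), bacRow("B2", "Bacteroidetes",
                                                  "Bacteroides"),
                 archRow("A1"))
    tr <- readNewick("((Focal:1,B1:1):1,(B2:1,A1:1):1);", text = TRUE)
    ann <- annotateTree(tr, tax)
    expect_equal(attr(ann, "dropped"), 0L)
    expect_equal(nrow(taxonomyOf(ann)), 4L)

    tr5 <- readNewick("(((Focal:1,B1:1):1,Mystery:1):1,(B2:1,A1:1):1);",
                      text = TRUE)
    expect_error(annotateTree(tr5, tax, mode = "strict"), "Mystery")
    lenient <- annotateTree(tr5, tax, mode = "lenient")
    expect_equal(attr(lenient, "dropped"), 1L)
    expect_length(treeOf(lenient)$tip.label, 4L)

    tr3 <- readNewick("((Focal:1,X:1):1,Y:1);", text = TRUE)
    expect_error(annotateTree(tr3, tax, mode = "lenient"), "fewer than 3")

    badTax <- rbind(tax, taxRow("Z", "Zoo_sp", "Zoo", "", "Bacteria"))
    expect_error(validateTaxonomy(badTax), "phylum may be empty")
})

test_that("neighbor joining solves 3 taxa in closed form and recovers additive matrices", {
    d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    phy <- buildNJTree(d)
    # three-point equations: a = (dAB + dAC - dBC) / 2, etc.
    dd <- cophenetic(phy)
    expect_equal(dd[rownames(d), colnames(d)], d, tolerance = 1e-12)
    a <- phy$edge.length[phy$edge[, 2] == which(phy$tip.label == "A")]
    expect_equal(a, (3 + 4 - 5) / 2)

    # additive matrix from a planted 6-leaf tree
    set.seed(21)
    planted <- ape::rtree(6)
    planted$edge.length <- runif(nrow(planted$edge), 0.1, 1)
    d6 <- cophenetic(planted)
    nj6 <- buildNJTree(d6)
    expect_identical(splitSet(nj6), splitSet(planted))
    expect_lt(max(abs(cophenetic(nj6)[rownames(d6), colnames(d6)] - d6)), 1e-9)

    # 5-leaf caterpillar with internal edges >= 0.1
    cat5 <- ape::read.tree(
        text = "(A:0.3,(B:0.2,(C:0.4,(D:0.3,E:0.5):0.2):0.15):0.1);")
    d5 <- cophenetic(cat5)
    nj5 <- buildNJTree(d5)
    expect_identical(splitSet(nj5), splitSet(cat5))

    dbad <- d
    dbad[1, 2] <- 10
    expect_error(buildNJTree(dbad), "not symmetric")
})

test_that("bootstrap supports behave like bipartition frequencies", {
    builder <- function(m) ape::nj(dist(m))
    x <- matrix(rep(c(0, 0, 1, 1, 2, 2.5), 40), nrow = 6, byrow = FALSE,
                dimnames = list(paste0("t", 1:6), NULL))
    # identical columns: no signal conflict, every true edge at 100%
    bt <- bootstrapSupport(x, builder, nReps = 50, seed = 1)
    expect_true(all(attr(bt, "support")[-1L] == 100))

    # a single replicate forces supports into {0, 100}
    set.seed(5)
    x2 <- matrix(rnorm(6 * 30), nrow = 6,
                 dimnames = list(paste0("t", 1:6), NULL))
    b1 <- bootstrapSupport(x2, builder, nReps = 1, seed = 3)
    expect_true(all(attr(b1, "support")[-1L] %in% c(0, 100)))

    expect_error(bootstrapSupport(x2, builder, nReps = 0), ">= 1")

    # strong planted signal: two seeds agree within the binomial envelope
    x3 <- cbind(matrix(rep(c(0, 0, 0, 5, 5, 5), 60), nrow = 6),
                matrix(rnorm(6 * 15, sd = 0.4), nrow = 6))
    rownames(x3) <- paste0("t", 1:6)
    s1 <- attr(bootstrapSupport(x3, builder, nReps = 100, seed = 1), "support")
    s2 <- attr(bootstrapSupport(x3, builder, nReps = 100, seed = 2), "support")
    # 95% envelope for a binomial proportion at n = 100 is ~ +-10 points
    expect_true(all(abs(s1[-1L] - s2[-1L]) <= 2 * 10))

    # invariance to taxon input order under canonical column resampling
    perm <- c(3, 1, 6, 2, 5, 4)
    sPerm <- attr(bootstrapSupport(x3[perm, ], builder, nReps = 100, seed = 1),
                  "support")
    expect_identical(sort(sPerm[-1L]), sort(s1[-1L]))
})

test_that("midpoint rooting bisects the longest path", {
    mp <- treeOf(midpointRoot(readNewick("((A:1,B:1):1,C:3);", text = TRUE)))
    depths <- ape::node.depth.edgelength(mp)
    expect_equal(max(depths[1:3]), 2.5)
    d0 <- cophenetic(treeOf(readNewick("((A:1,B:1):1,C:3);", text = TRUE)))
    expect_equal(cophenetic(mp)[rownames(d0), colnames(d0)], d0)

    # symmetric quartet roots on the central edge
    q <- treeOf(midpointRoot(
        readNewick("((A:1,B:1):1,(C:1,D:1):1);", text = TRUE)))
    expect_equal(unname(ape::node.depth.edgelength(q)[1:4]), rep(2, 4))

    # 20-leaf random tree: midpoint minimizes the maximum root-to-leaf depth
    set.seed(31)
    phy <- ape::rtree(20)
    mp20 <- midpointRoot(phy)
    got <- max(ape::node.depth.edgelength(mp20)[1:20])
    # exhaustive oracle: the optimum over all edge-internal root positions
    # is half the tree diameter
    expect_equal(got, max(cophenetic(phy)) / 2, tolerance = 1e-9)

    z <- ape::rtree(5)
    z$edge.length[] <- 0
    expect_warning(midpointRoot(z), "centroid")
})
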