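outTree <- function() ape::read.tree(
    text = "((((A:1,B:1):1,C:2):1,(D:1,E:1):2):1,OUT:4);")

test_that("trivial families reconstruct without events", {
    tr <- outTree()
    m <- rbind(fam_all = rep(1L, 6))
    colnames(m) <- tr$tip.label
    for (md in c("fitch", "dollo", "weighted")) {
        rec <- reconstructAncestralContent(m, tr, mode = md)
        expect_true(all(rec@nodeStates[, "fam_all"] == 1L))
        expect_identical(nrow(rec@events), 0L)
    }
})

test_that("a family in a single leaf is one Dollo gain on its terminal branch", {
    tr <- outTree()
    m <- rbind(fam_one = as.integer(tr$tip.label == "C"))
    colnames(m) <- tr$tip.label
    rec <- reconstructAncestralContent(m, tr, mode = "dollo")
    expect_identical(rec@events$event, "gain")
    expect_identical(rec@events$branch, "C")
    expect_identical(sum(rec@nodeStates[, "fam_one"]), 1L)
})

test_that("parsimony reconstruction attains the exhaustive minimum cost", {
    set.seed(71)
    for (r in 1:25) {
        nt <- sample(4:6, 1)
        tr <- ape::rtree(nt)
        ls <- rbinom(nt, 1, 0.5)
        if (sum(ls) == 0) ls[sample(nt, 1)] <- 1L
        m <- matrix(as.integer(ls), nrow = 1,
                    dimnames = list("f1", tr$tip.label))
        recF <- reconstructAncestralContent(m, tr, mode = "fitch")
        expect_identical(nrow(recF@events), as.integer(bruteForceCost(tr, ls)))
        recW <- reconstructAncestralContent(m, tr, mode = "weighted",
                                            gainPenalty = 2)
        costW <- sum(ifelse(recW@events$event == "gain", 2, 1))
        expect_identical(costW, bruteForceCost(tr, ls, gainCost = 2))
    }
})

test_that("zero-homoplasy histories are recovered event-for-event by every mode", {
    tr <- outTree()
    sim <- simulatePresenceAbsence(tr, nFamilies = 150,
                                   maxEventsPerFamily = 1, seed = 19)
    for (md in c("fitch", "dollo", "weighted")) {
        rec <- suppressWarnings(
            reconstructAncestralContent(sim$pam, tr, mode = md))
        fams <- colnames(rec@nodeStates)
        expect_true(all(rec@nodeStates == sim$nodeStates[, fams]))
        truth <- sim$events[sim$events$family %in% fams, ]
        expect_setequal(paste(rec@events$branch, rec@events$family,
                              rec@events$event),
                        paste(truth$branch, truth$family, truth$event))
        expect_identical(nrow(rec@events), nrow(truth))
    }
})

test_that("gain penalty trades gains for losses monotonically", {
    tr <- outTree()
    sim <- simulatePresenceAbsence(tr, nFamilies = 120, gainRate = 0.4,
                                   lossRate = 0.5, seed = 23)
    pam <- sim$pam
    counts <- t(vapply(c(0.5, 1, 2, 4), function(pen) {
        rec <- suppressWarnings(reconstructAncestralContent(
            pam, tr, mode = "weighted", gainPenalty = pen))
        c(gains = sum(rec@events$event == "gain"),
          losses = sum(rec@events$event == "loss"))
    }, numeric(2)))
    expect_true(all(diff(counts[, "gains"]) <= 0))
    expect_true(all(diff(counts[, "losses"]) >= 0))
})

test_that("branch diffs compare a node against an ancestor", {
    tr <- outTree()
    sim <- simulatePresenceAbsence(tr, nFamilies = 80,
                                   maxEventsPerFamily = 1, seed = 31)
    rec <- suppressWarnings(reconstructAncestralContent(sim$pam, tr,
                                                        mode = "fitch"))
    root <- length(tr$tip.label) + 1L
    rootLab <- rownames(rec@nodeStates)[root]
    d <- branchDiff(rec, "A", rootLab)
    # gained and lost are disjoint by construction
    expect_length(intersect(d$gained, d$lost), 0L)
    # identical states yield empty diffs
    same <- branchDiff(rec, "OUT", rootLab)
    expect_identical(same, list(gained = character(), lost = character()))
    # planted single gains on the terminal branch to C show up in the
    # root-to-C diff, and every gained family traces back to a gain event
    gainsOnC <- sim$events$family[sim$events$event == "gain" &
                                  sim$events$branch == "C"]
    dC <- branchDiff(rec, "C", rootLab)
    expect_true(all(gainsOnC %in% dC$gained))
    gainFams <- sim$events$family[sim$events$event == "gain"]
    expect_true(all(dC$gained %in% gainFams))
    expect_error(branchDiff(rec, "A", "B"), "ancestor")
})

test_that("input contracts are enforced", {
    tr <- outTree()
    m <- rbind(f1 = c(1L, 0L, 1L, 0L, 1L, 0L))
    colnames(m) <- c(tr$tip.label[-1], "NOT_A_LEAF")
    expect_error(reconstructAncestralContent(m, tr), "mismatch")

    m2 <- rbind(f1 = rep(1L, 6), f2 = rep(0L, 6))
    colnames(m2) <- tr$tip.label
    expect_warning(v <- validatePresenceAbsence(m2), "all-absent")
    expect_identical(rownames(v), "f1")

    # TSV round trip
    path <- tempfile(fileext = ".tsv")
    on.exit(unlink(path))
    df <- data.frame(family = c("f1", "f2"), A = c(1, 0), B = c(0, 1),
                     C = c(1, 1), D = c(0, 1), E = c(1, 0), OUT = c(1, 1))
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    m3 <- readPresenceAbsence(path)
    expect_identical(dim(m3), c(2L, 6L))
    expect_identical(unname(m3["f1", "A"]), 1L)
})
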