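test_that("closest neighbor group is the focal leaf's sister clade", {
    cfg <- cfgAsIs()
    tax <- rbind(focalRow(), bacRow("BacA"), bacRow("BacB", "Bacteroidetes",
                                                    "Bacteroides"),
                 archRow("ArchX"))
    t1 <- agtFrom("((Focal:1,BacA:1):1,ArchX:2);", tax)
    expect_setequal(closestNeighborGroup(t1, cfg), "BacA")

    t2 <- agtFrom("((Focal:1,(BacA:1,BacB:1):1):1,ArchX:2);", tax)
    expect_setequal(closestNeighborGroup(t2, cfg), c("BacA", "BacB"))

    # caterpillar with the focal leaf innermost: sister is the unique
    # adjacent leaf
    tax8 <- rbind(focalRow(), bacRow("B1"), bacRow("B2"), bacRow("B3"),
                  bacRow("B4"), bacRow("B5"), bacRow("B6"), archRow("A1"))
    cat8 <- agtFrom(
        "(A1:1,(B6:1,(B5:1,(B4:1,(B3:1,(B2:1,(Focal:1,B1:1):1):1):1):1):1):1);",
        tax8)
    expect_setequal(closestNeighborGroup(cat8, cfg), "B1")

    expect_error(closestNeighborGroup(
        agtFrom("((BacA:1,BacB:1):1,ArchX:2);", tax), cfg), "focal taxon")
})

test_that("bacterial-clade rule requires pure bacteria spanning the phylum threshold", {
    cfg <- screenConfig()
    three <- rbind(bacRow("B1", "Firmicutes"),
                   bacRow("B2", "Bacteroidetes", "Bacteroides"),
                   bacRow("B3", "Proteobacteria", "Escherichia"))
    expect_true(isBacterialClade(three, cfg))
    two <- rbind(bacRow("B1", "Firmicutes"), bacRow("B2", "Firmicutes"),
                 bacRow("B3", "Bacteroidetes", "Bacteroides"))
    expect_false(isBacterialClade(two, cfg))
    withArch <- rbind(three[1, ], archRow("A1"))
    expect_false(isBacterialClade(withArch, cfg))
    expect_error(isBacterialClade(three[0, ], cfg), "empty")
})

test_that("support tiers bin at the screen's boundaries", {
    expect_identical(supportTier(c(71, 70, 51, 50, 0, NA)),
                     c("high", "moderate", "moderate", "low", "low", "absent"))
    expect_error(supportTier(101), "out of")
    # the low/moderate boundary is configurable
    cfg50 <- screenConfig(tierModerateLow = 50)
    expect_identical(supportTier(50, cfg50), "moderate")
})

test_that("classification follows the sister-group decision procedure", {
    cfg <- cfgAsIs()

    # bacterial closest neighbor, Firmicutes donor, high support
    tax1 <- rbind(focalRow(), bacRow("BacFirm"), archRow("ArchA"),
                  bacRow("BacX", "Bacteroidetes", "Bacteroides"),
                  bacRow("BacY", "Proteobacteria", "Escherichia"))
    t1 <- agtFrom("((Focal:1,BacFirm:1)85:1,(ArchA:1,(BacX:1,BacY:1):1):1);",
                  tax1)
    c1 <- classifyTree(t1, cfg)
    expect_identical(c1$status, "LGT_bacterial_neighbor")
    expect_identical(c1$support, 85)
    expect_identical(c1$tier, "high")
    expect_identical(c1$donor_phylum, "Firmicutes")

    # focal+companion pair nested in a 3-phylum bacterial clade, with an
    # archaeal leaf outside the enclosure: ancient transfer, direction
    # unresolved (no polarity through the single bacterial level)
    tax2 <- rbind(focalRow(), smithiiRow(), bacRow("BacFirm"),
                  bacRow("BacBact", "Bacteroidetes", "Bacteroides"),
                  bacRow("BacProt", "Proteobacteria", "Escherichia"),
                  archRow("ArchOut"))
    t2 <- agtFrom(paste0("(((Focal:1,Msmithii:1)60:1,",
                         "(BacFirm:1,(BacBact:1,BacProt:1):1):1)55:1,",
                         "ArchOut:3);"), tax2)
    c2 <- classifyTree(t2, cfg)
    expect_identical(c2$status, "LGT_nested_methanogen_pair")
    expect_identical(c2$direction, "unknown")
    expect_identical(c2$support, 55)
    expect_identical(c2$tier, "moderate")
    expect_identical(c2$companion_present, "smithii")
    expect_false(c2$only_archaea_rescue)

    # archaeal sister: vertical inheritance
    tax3 <- rbind(focalRow(), archRow("ArchA"), bacRow("BacX"),
                  bacRow("BacY", "Bacteroidetes", "Bacteroides"))
    t3 <- agtFrom("((Focal:1,ArchA:1):1,(BacX:1,BacY:1):1);", tax3)
    c3 <- classifyTree(t3, cfg)
    expect_identical(c3$status, "non_LGT")
    expect_identical(c3$direction, "not_applicable")

    # mixed-domain sister: conservative non-LGT, flagged for review
    tax4 <- rbind(focalRow(), bacRow("BacA"), archRow("ArchA"),
                  archRow("ArchB", "Methanothermobacter"))
    t4 <- agtFrom("((Focal:1,(BacA:1,ArchA:1):1):1,ArchB:2);", tax4)
    c4 <- classifyTree(t4, cfg)
    expect_identical(c4$status, "non_LGT")
    expect_true(c4$mixed_sister)
    expect_match(c4$sister_composition, "Archaea:1;Bacteria:1")
})

test_that("only-archaea trees rescue an unresolved direction as likely bacterial", {
    cfg <- cfgAsIs()
    tax <- rbind(focalRow(), smithiiRow(), bacRow("B1"),
                 bacRow("B2", "Bacteroidetes", "Bacteroides"),
                 bacRow("B3", "Proteobacteria", "Escherichia"))
    tr <- agtFrom("((Focal:1,Msmithii:1)80:1,(B1:1,(B2:1,B3:1):1):1);", tax)
    cl <- classifyTree(tr, cfg)
    expect_identical(cl$status, "LGT_nested_methanogen_pair")
    expect_identical(cl$direction, "unknown")
    expect_true(cl$only_archaea)
    expect_true(cl$only_archaea_rescue)
})

test_that("classification is invariant to leaf order and re-serialization", {
    sim <- simulateGeneTree("ancient_pre_divergence_lgt", seed = 17)
    base <- classifyTree(sim$tree)
    phy <- treeOf(sim$tree)
    rot <- ape::rotateConstr(phy, rev(sort(phy$tip.label)))
    rot2 <- treeOf(readNewick(writeNewick(rot), text = TRUE))
    again <- classifyTree(annotatedGeneTree(geneId(sim$tree), rot2,
                                            taxonomyOf(sim$tree)))
    expect_identical(base, again, ignore_attr = TRUE)
})

test_that("planted scenarios are recovered and the phylum threshold is monotone", {
    sims <- simulateScreen(60, seed = 99, nEukaryotes = 3)
    got <- classifyTrees(sims$trees)
    expect_identical(got$status, sims$expected$status)
    expect_identical(got$direction, sims$expected$direction)
    expect_identical(got$tier, sims$expected$tier)

    # tightening min_bacterial_phyla can only demote LGT calls
    for (k in c(4L, 6L)) {
        stricter <- classifyTrees(sims$trees,
                                  screenConfig(minBacterialPhyla = k))
        demoted <- got$status == "non_LGT" & stricter$status != "non_LGT"
        expect_false(any(demoted))
    }
})

test_that("focal paralogs are classified per copy and aggregated", {
    cfg <- cfgAsIs()
    tax <- rbind(focalRow("Focal1"), focalRow("Focal2"), archRow("ArchA"),
                 bacRow("B1"), bacRow("B2", "Bacteroidetes", "Bacteroides"),
                 bacRow("B3", "Proteobacteria", "Escherichia"),
                 archRow("ArchB", "Methanothermobacter"))
    tax$leaf_id <- c("Focal1", "Focal2", "ArchA", "B1", "B2", "B3", "ArchB")
    # one vertical copy, one copy nested among bacteria
    tr <- agtFrom(paste0("(((Focal1:1,ArchA:1):1,ArchB:1):1,",
                         "(((Focal2:1,B1:1)77:1,B2:1):1,B3:1):1);"), tax)
    cl <- classifyTree(tr, cfg)
    expect_identical(cl$n_focal_copies, 2L)
    expect_identical(cl$status, "LGT_bacterial_neighbor")
    perLeaf <- attr(cl, "perLeaf")
    expect_identical(sort(perLeaf$status), c("LGT_bacterial_neighbor",
                                             "non_LGT"))
})
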