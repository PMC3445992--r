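test_that("relative adaptiveness applies the pseudo-count convention", {
    w <- relativeAdaptiveness(c(GGT = 10, GGC = 5, GGA = 0, GGG = 0))
    expect_equal(unname(w[c("GGT", "GGC", "GGA", "GGG")]),
                 c(1, 0.5, 0.05, 0.05))
    # uniform counts within an amino acid give w = 1 for all its codons
    w2 <- relativeAdaptiveness(c(GGT = 7, GGC = 7, GGA = 7, GGG = 7))
    expect_true(all(w2[c("GGT", "GGC", "GGA", "GGG")] == 1))
    # absent amino acids are neutral (w = 1), reported
    expect_message(relativeAdaptiveness(c(GGT = 1)), "absent")
    expect_error(relativeAdaptiveness(c(GGT = -1)), "negative")
})

test_that("CAI is the geometric mean over informative codons", {
    suppressMessages({
        w <- relativeAdaptiveness(c(GGT = 10, GGC = 5))
    })
    expect_equal(cai(c(GGT = 4), w), 1)
    expect_equal(cai(c(GGT = 1, GGC = 1), w), sqrt(0.5))
    # Met carries no information and leaves CAI unchanged
    expect_equal(cai(c(GGT = 1, GGC = 1, ATG = 5), w), sqrt(0.5))
    # duplication invariance
    expect_equal(cai(c(GGT = 2, GGC = 2), w), cai(c(GGT = 1, GGC = 1), w))
    expect_error(cai(c(ATG = 3), w), "no informative")

    # a single-gene reference whose codons are the query's own makes every
    # used codon optimal, so CAI = 1
    g <- oneCodonPerAA(4)
    ws <- suppressMessages(relativeAdaptiveness(codonUsage(
        Biostrings::DNAStringSet(c(ref = g)))))
    expect_equal(cai(g, ws), 1)
})

test_that("CAI agrees with an independent implementation", {
    set.seed(13)
    w <- relativeAdaptiveness(
        1000 * biasedCodonFrequencies(0.7, shuffle = TRUE))
    wv <- unname(w[toupper(seqinr::words())])
    for (i in 1:5) {
        g <- uniformUsageSeq(200, seed = 100 + i)
        ref <- as.numeric(seqinr::cai(seqinr::s2c(tolower(g)), w = wv,
                                      numcode = 1))
        expect_equal(cai(g, w), ref, tolerance = 1e-6)
    }
})

test_that("ENC spans its endpoints and matches the homozygosity formula", {
    # one codon per amino acid: the minimum, 20
    expect_equal(enc(oneCodonPerAA(3)), 20)

    # uniform synonymous usage approaches 61 with length
    expect_lt(abs(enc(uniformUsageSeq(6000, seed = 2)) - 61), 0.5)

    # direct evaluation of the class-average formula on biased counts:
    # each amino acid uses its first codon 70 times and spreads 30 over
    # the rest
    n <- 100
    tab <- codonTable()
    counts <- setNames(numeric(nrow(tab)), tab$codon)
    Fhat <- c()
    for (a in unique(tab$aa)) {
        cods <- tab$codon[tab$aa == a]
        k <- length(cods)
        if (k == 1) { counts[cods] <- n; next }
        cc <- c(70, rep(30 / (k - 1), k - 1))
        counts[cods] <- cc
        p <- cc / n
        Fhat[a] <- (n * sum(p^2) - 1) / (n - 1)
    }
    deg <- tab$degeneracy[match(names(Fhat), tab$aa)]
    Fbar <- tapply(Fhat, deg, mean)
    expected <- 2 + 9 / Fbar[["2"]] + 1 / Fbar[["3"]] + 5 / Fbar[["4"]] +
        3 / Fbar[["6"]]
    expect_lt(expected, 61)
    expect_equal(enc(counts), expected, tolerance = 1e-9)

    # finite-sample uniform counts overshoot 61 slightly and are clamped
    uniform <- counts
    for (a in unique(tab$aa)) {
        cods <- tab$codon[tab$aa == a]
        uniform[cods] <- n / length(cods)
    }
    expect_equal(enc(uniform), 61)

    # the worked two-fold case: p = (0.5, 0.5), n = 100 gives F = 49/99
    expect_equal((n * 0.5 - 1) / (n - 1), 49 / 99)

    # missing three-fold class (no Ile) falls back to interpolation
    noIle <- counts[tab$codon[tab$aa != "I"]]
    expect_true(is.finite(enc(noIle)))

    expect_error(enc(c(GGT = 1)), "too short")
})

test_that("ENC decreases with codon bias in expectation", {
    meanEnc <- vapply(c(0, 0.5, 0.9), function(b) {
        sims <- simulateCodingSequences(alpha = 1, nGenes = 70,
                                        geneLengthCodons = 150,
                                        hostFreqs = biasedCodonFrequencies(b),
                                        seed = 41)
        mean(codonMetrics(sims$seqs,
                          w = relativeAdaptiveness(
                              1000 * biasedCodonFrequencies(b)))$enc)
    }, numeric(1))
    expect_true(all(diff(meanEnc) < 0))
})

test_that("background z-scores and two-SD flags follow the genomic background", {
    # synthetic background around the genomic ENC scale
    set.seed(55)
    bg <- data.frame(gene_id = sprintf("b%03d", 1:200),
                     cai = rnorm(200, 0.73, 0.04),
                     enc = rnorm(200, 34.5, 3.0), stringsAsFactors = FALSE)
    probe <- data.frame(gene_id = "probe", cai = 0.73, enc = 45,
                        stringsAsFactors = FALSE)
    out <- backgroundAndFlags(rbind(bg, probe), background = bg)
    flagged <- out[out$gene_id == "probe", ]
    expect_gt(flagged$enc_z, 2)
    expect_match(flagged$flags, "high_ENC")

    # thresholds read back as mean +- 2 SD
    th <- attr(out, "background")
    expect_equal(th$enc_high, th$enc_mean + 2 * th$enc_sd)
    expect_equal(th$cai_low, th$cai_mean - 2 * th$cai_sd)

    # reference genes are excluded from the background
    spiked <- rbind(bg, data.frame(gene_id = "ribo1", cai = 0.99, enc = 20))
    outEx <- backgroundAndFlags(bg, background = spiked,
                                excludeIds = "ribo1")
    expect_equal(attr(outEx, "background")$cai_mean, mean(bg$cai))

    # degenerate zero-variance background suppresses flags with a warning
    flat <- data.frame(gene_id = sprintf("f%02d", 1:12), cai = 0.7, enc = 34)
    expect_warning(outFlat <- backgroundAndFlags(flat), "suppressed")
    expect_true(all(outFlat$cai_z == 0))
    expect_true(all(outFlat$flags == ""))

    expect_error(backgroundAndFlags(flat[1:5, ]), "at least 10")
})

test_that("CDS validation enforces frame and stop-codon rules", {
    expect_error(validateCodingSequences(c(g1 = "ATGGG")), "divisible by 3")
    expect_error(validateCodingSequences(c(g1 = "ATGTAAGGT")),
                 "internal stop")
    expect_message(validateCodingSequences(c(g1 = "ATGTAAGGT"),
                                           mode = "lenient"), "kept")
    # terminal stop is trimmed
    v <- validateCodingSequences(c(g1 = "ATGGGTTAA"))
    expect_equal(as.character(v[[1]]), "ATGGGT")
})
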