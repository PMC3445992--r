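#' @importFrom Biostrings DNAStringSet readDNAStringSet trinucleotideFrequency
#'   GENETIC_CODE width
NULL

# Degeneracy classes of the standard bacterial/archaeal code (translation
# table 11 shares the codon->amino-acid map with the standard code):
# 9 two-fold, 1 three-fold (Ile), 5 four-fold, 3 six-fold amino acids;
# Met and Trp are single-codon and contribute the "+2" of ENC.
.codonTable <- function() {
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    aa <- unname(gc)
    sense <- aa != "*"
    tab <- data.frame(codon = codons[sense], aa = aa[sense],
                      stringsAsFactors = FALSE)
    deg <- table(tab$aa)
    tab$degeneracy <- as.integer(deg[tab$aa])
    tab
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read coding sequences from FASTA
#'
#' Reads a nucleotide FASTA of coding sequences (frame 0). Each sequence
#' must have length divisible by 3 after trimming a terminal stop codon.
#' Internal stop codons are an error in strict mode and are logged (and
#' the sequence kept) in lenient mode. Codons containing N are skipped by
#' the metrics and counted in the `"n_codons_skipped"` attribute of
#' [codonUsage()].
#'
#' @param path FASTA file path.
#' @param mode "strict" or "lenient" handling of internal stops.
#' @return A `DNAStringSet` with terminal stop codons trimmed.
#' @export
readCodingSequences <- function(path, mode = c("strict", "lenient")) {
    seqs <- Biostrings::readDNAStringSet(path)
    validateCodingSequences(seqs, mode = mode)
}

#' @rdname readCodingSequences
#' @param seqs a DNAStringSet (or named character vector) of CDS.
#' @export
validateCodingSequences <- function(seqs, mode = c("strict", "lenient")) {
    mode <- match.arg(mode)
    if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stop("all coding sequences must be named", call. = FALSE)
    bad <- Biostrings::width(seqs) %% 3L != 0L
    if (any(bad))
        stop("CDS length not divisible by 3: ",
             paste(head(names(seqs)[bad], 5), collapse = ", "), call. = FALSE)
    out <- lapply(seq_along(seqs), function(i) {
        s <- as.character(seqs[[i]])
        cods <- substring(s, seq(1L, nchar(s) - 2L, by = 3L),
                          seq(3L, nchar(s), by = 3L))
        if (length(cods) && cods[length(cods)] %in% .STOP_CODONS)
            cods <- cods[-length(cods)]
        internal <- which(cods %in% .STOP_CODONS)
        if (length(internal)) {
            msg <- paste0("internal stop codon in ", names(seqs)[i],
                          " at codon ", internal[1L])
            if (mode == "strict") stop(msg, call. = FALSE)
            message(msg, " (lenient mode: kept)")
        }
        paste(cods, collapse = "")
    })
    Biostrings::DNAStringSet(setNames(unlist(out), names(seqs)))
}

#' Codon usage counts
#'
#' Counts codon occurrences (frame 0) per sequence or pooled over a set.
#'
#' @param seqs a DNAStringSet of validated CDS.
#' @param pooled if TRUE (default) return a single named count vector
#'   summed over sequences; otherwise a matrix with one row per sequence.
#' @return Named integer vector (or matrix) of counts over the 64 codons;
#'   attribute `"n_codons_skipped"` counts codons containing non-ACGT
#'   letters.
#' @export
codonUsage <- function(seqs, pooled = TRUE) {
    if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
    m <- Biostrings::trinucleotideFrequency(seqs, step = 3)
    skipped <- sum(Biostrings::width(seqs) %/% 3L) - sum(m)
    out <- if (pooled) colSums(m) else m
    attr(out, "n_codons_skipped") <- skipped
    out
}

#' Relative adaptiveness of codons
#'
#' From codon counts of a highly-expressed reference gene set, computes
#' the relative adaptiveness w of each sense codon: its count divided by
#' the count of the most-used synonymous codon for the same amino acid.
#' Zero reference counts are replaced by a 0.5 pseudo-count before
#' division (standard CAI practice), so unused codons get a small positive
#' w instead of zero. Amino acids entirely absent from the reference have
#' all their codons assigned w = 1 (neutral in the CAI product) and are
#' reported in attribute `"absent_aa"`.
#'
#' @param referenceCounts named numeric vector of codon counts (names are
#'   codons; missing codons count 0).
#' @return Named numeric vector w over the 61 sense codons, attributes
#'   `"counts"` and `"absent_aa"`.
#' @examples
#' w <- relativeAdaptiveness(c(GGT = 10, GGC = 5))
#' w[c("GGT", "GGC", "GGA", "GGG")]  # 1, 0.5, 0.05, 0.05
#' @export
relativeAdaptiveness <- function(referenceCounts) {
    tab <- .codonTable()
    counts <- setNames(numeric(nrow(tab)), tab$codon)
    given <- intersect(names(referenceCounts), tab$codon)
    counts[given] <- as.numeric(referenceCounts[given])
    if (any(counts < 0)) stop("negative reference counts", call. = FALSE)
    w <- setNames(numeric(nrow(tab)), tab$codon)
    absentAA <- character()
    for (a in unique(tab$aa)) {
        cods <- tab$codon[tab$aa == a]
        cc <- counts[cods]
        if (all(cc == 0)) {
            w[cods] <- 1
            absentAA <- c(absentAA, a)
            next
        }
        cc[cc == 0] <- 0.5
        w[cods] <- cc / max(cc)
    }
    if (length(absentAA))
        message("relativeAdaptiveness: amino acid(s) absent from reference, ",
                "w set to 1: ", paste(absentAA, collapse = ", "))
    attr(w, "counts") <- counts
    attr(w, "absent_aa") <- absentAA
    w
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness w over the codons of a
#' gene, excluding Met, Trp and stop codons (they have no synonymous
#' choice and would only dilute the index).
#'
#' @param seq a single CDS (character or DNAStringSet element) or a named
#'   codon count vector.
#' @param w relative adaptiveness from [relativeAdaptiveness()].
#' @return CAI in (0, 1].
#' @export
cai <- function(seq, w) {
    counts <- .asCodonCounts(seq)
    tab <- .codonTable()
    keep <- tab$codon[!(tab$aa %in% c("M", "W"))]
    cc <- counts[keep]
    total <- sum(cc)
    if (total == 0)
        stop("no informative codons for CAI", call. = FALSE)
    exp(sum(cc * log(w[keep])) / total)
}

#' Effective number of codons
#'
#' Wright's ENC. For each amino acid with at least two codon observations
#' the codon homozygosity is estimated as
#' F = (n * sum(p_i^2) - 1) / (n - 1); class averages over amino acids of
#' degeneracy 2, 3, 4 and 6 give
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, clamped to \[20, 61\]. Amino
#' acids observed fewer than twice, or whose F estimate is zero, are left
#' out of their class average. A missing three-fold class (Ile absent) is
#' filled by the 1/(2/F2 - 1/F4) interpolation, falling back to
#' (F2 + F4)/2 when that is undefined; any other empty class is an error.
#'
#' @param seq a single CDS or named codon count vector.
#' @return ENC in \[20, 61\].
#' @examples
#' # one codon per amino acid gives the lower bound 20
#' @export
enc <- function(seq) {
    counts <- .asCodonCounts(seq)
    tab <- .codonTable()
    Fhat <- list(`2` = numeric(), `3` = numeric(), `4` = numeric(),
                 `6` = numeric())
    for (a in unique(tab$aa)) {
        deg <- tab$degeneracy[tab$aa == a][1L]
        if (deg == 1L) next
        cc <- counts[tab$codon[tab$aa == a]]
        n <- sum(cc)
        if (n < 2) next
        p <- cc / n
        f <- (n * sum(p^2) - 1) / (n - 1)
        if (f <= 0) next
        key <- as.character(deg)
        Fhat[[key]] <- c(Fhat[[key]], f)
    }
    Fbar <- vapply(Fhat, function(v) if (length(v)) mean(v) else NA_real_,
                   numeric(1))
    if (is.na(Fbar[["3"]])) {
        denom <- 2 / Fbar[["2"]] - 1 / Fbar[["4"]]
        Fbar[["3"]] <- if (is.finite(denom) && denom > 0) 1 / denom
                       else mean(c(Fbar[["2"]], Fbar[["4"]]))
    }
    if (anyNA(Fbar))
        stop("sequence too short to estimate codon homozygosity for ",
             "degeneracy class(es): ",
             paste(names(Fbar)[is.na(Fbar)], collapse = ", "), call. = FALSE)
    val <- 2 + 9 / Fbar[["2"]] + 1 / Fbar[["3"]] + 5 / Fbar[["4"]] +
        3 / Fbar[["6"]]
    min(61, max(20, val))
}

.asCodonCounts <- function(seq) {
    if (is.numeric(seq) && !is.null(names(seq))) {
        counts <- setNames(numeric(64), names(Biostrings::GENETIC_CODE))
        counts[intersect(names(seq), names(counts))] <-
            seq[intersect(names(seq), names(counts))]
        return(counts)
    }
    if (is(seq, "DNAStringSet")) {
        if (length(seq) != 1L)
            stop("expected a single sequence", call. = FALSE)
        return(codonUsage(seq))
    }
    codonUsage(Biostrings::DNAStringSet(setNames(as.character(seq), "x")))
}

#' Per-gene codon metrics
#'
#' Computes CAI and ENC for every sequence in a CDS set.
#'
#' @param seqs a named DNAStringSet of validated CDS.
#' @param w relative adaptiveness from [relativeAdaptiveness()]; when NULL
#'   it is computed from `referenceIds` within `seqs`.
#' @param referenceIds ids of the highly-expressed reference genes (e.g.
#'   ribosomal proteins) used to derive w when `w` is NULL.
#' @return data.frame with columns gene_id, cai, enc.
#' @export
codonMetrics <- function(seqs, w = NULL, referenceIds = NULL) {
    if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(w)) {
        if (is.null(referenceIds))
            stop("provide either w or referenceIds", call. = FALSE)
        miss <- setdiff(referenceIds, names(seqs))
        if (length(miss))
            stop("reference ids not in sequence set: ",
                 paste(head(miss, 5), collapse = ", "), call. = FALSE)
        w <- relativeAdaptiveness(codonUsage(seqs[referenceIds]))
    }
    m <- codonUsage(seqs, pooled = FALSE)
    data.frame(
        gene_id = names(seqs),
        cai = vapply(seq_len(nrow(m)), function(i) cai(m[i, ], w), numeric(1)),
        enc = vapply(seq_len(nrow(m)), function(i) enc(m[i, ]), numeric(1)),
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Background statistics and amelioration outlier flags
#'
#' Computes the genomic background mean and standard deviation of CAI and
#' ENC over `metrics`, excluding the CAI reference genes (they are
#' highly expressed by construction and would bias the background), then
#' z-scores every gene against that background and flags outliers beyond
#' two standard deviations: `low_CAI`/`high_CAI`, `low_ENC`/`high_ENC`.
#' Recently transferred genes are expected to show low CAI and/or high
#' ENC; ameliorated ancient transfers resemble the background.
#'
#' @param metrics data.frame from [codonMetrics()] for the genes to flag.
#' @param background data.frame from [codonMetrics()] defining the genomic
#'   background; defaults to `metrics` itself.
#' @param excludeIds gene ids excluded from the background (the CAI
#'   reference set); the background must retain at least 10 genes.
#' @param subsetIds optional ids of a subgroup (e.g. LGT candidates) whose
#'   mean is reported next to the genomic mean.
#' @return `metrics` with added columns cai_z, enc_z, flags (comma-joined
#'   subset of the four flags); attributes `"background"` (mean/sd/
#'   thresholds) and `"subgroup_means"`.
#' @export
backgroundAndFlags <- function(metrics, background = metrics,
                               excludeIds = character(),
                               subsetIds = NULL) {
    bg <- background[!background$gene_id %in% excludeIds, , drop = FALSE]
    if (nrow(bg) < 10L)
        stop("background must contain at least 10 genes after exclusions",
             call. = FALSE)
    stats <- list(
        cai_mean = mean(bg$cai), cai_sd = sd(bg$cai),
        enc_mean = mean(bg$enc), enc_sd = sd(bg$enc))
    stats$cai_low <- stats$cai_mean - 2 * stats$cai_sd
    stats$cai_high <- stats$cai_mean + 2 * stats$cai_sd
    stats$enc_low <- stats$enc_mean - 2 * stats$enc_sd
    stats$enc_high <- stats$enc_mean + 2 * stats$enc_sd

    zeroSd <- stats$cai_sd == 0 || stats$enc_sd == 0
    if (zeroSd)
        warning("zero background standard deviation; outlier flags suppressed")
    caiZ <- if (stats$cai_sd > 0) (metrics$cai - stats$cai_mean) / stats$cai_sd
            else rep(0, nrow(metrics))
    encZ <- if (stats$enc_sd > 0) (metrics$enc - stats$enc_mean) / stats$enc_sd
            else rep(0, nrow(metrics))
    flags <- vapply(seq_len(nrow(metrics)), function(i) {
        if (zeroSd) return("")
        f <- character()
        if (caiZ[i] < -2) f <- c(f, "low_CAI")
        if (caiZ[i] > 2) f <- c(f, "high_CAI")
        if (encZ[i] < -2) f <- c(f, "low_ENC")
        if (encZ[i] > 2) f <- c(f, "high_ENC")
        paste(f, collapse = ",")
    }, character(1))
    out <- metrics
    out$cai_z <- caiZ
    out$enc_z <- encZ
    out$flags <- flags
    attr(out, "background") <- stats
    if (!is.null(subsetIds)) {
        sub <- metrics[metrics$gene_id %in% subsetIds, , drop = FALSE]
        attr(out, "subgroup_means") <- c(
            subgroup_cai = mean(sub$cai), subgroup_enc = mean(sub$enc),
            genome_cai = stats$cai_mean, genome_enc = stats$enc_mean)
    }
    out
}
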