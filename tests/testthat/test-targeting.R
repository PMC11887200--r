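test_that("soft-masked run detection matches the per-base oracle", {
    expect_equal(findSoftmaskedRuns("ACGTacgtACGT"),
                 data.frame(start = 4L, end = 8L))
    expect_equal(findSoftmaskedRuns("acgtACGTacgt"),
                 data.frame(start = c(0L, 8L), end = c(4L, 12L)))
    expect_equal(nrow(findSoftmaskedRuns("ACGT")), 0L)
    # uppercase N is a gap, lowercase n is a mask
    expect_equal(findSoftmaskedRuns("ANnNA"),
                 data.frame(start = 2L, end = 3L))

    set.seed(42)
    for (i in 1:20) {
        s <- rand_masked_seq(10000, p_lower = runif(1, 0.05, 0.6))
        expect_equal(findSoftmaskedRuns(s), oracle_runs(s))
    }
})

test_that("flank extension and merging match the per-base bitmap oracle", {
    expect_equal(expandAndMerge(data.frame(start = c(10L, 30L),
                                           end = c(20L, 40L)),
                                flank = 10L, contigLen = 100L),
                 data.frame(start = 0L, end = 50L))
    expect_equal(expandAndMerge(data.frame(start = 10L, end = 20L),
                                flank = 0L, contigLen = 100L),
                 data.frame(start = 10L, end = 20L))
    expect_equal(expandAndMerge(data.frame(start = 2L, end = 5L),
                                flank = 64L, contigLen = 40L),
                 data.frame(start = 0L, end = 40L))
    expect_error(expandAndMerge(data.frame(start = 10L, end = 200L),
                                flank = 0L, contigLen = 100L), "contig")

    set.seed(7)
    for (i in 1:25) {
        len <- sample(200:2000, 1)
        nint <- sample(1:12, 1)
        st <- sort(sample(0:(len - 2), nint))
        en <- pmin(st + sample(1:100, nint, replace = TRUE), len)
        iv <- data.frame(start = st, end = en)
        flank <- sample(0:80, 1)
        got <- expandAndMerge(iv, flank, len)
        expect_equal(got, oracle_expand_merge(iv, flank, len))
        # disjoint and sorted
        if (nrow(got) > 1)
            expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    }
})

test_that("target names round-trip, rightmost-first, for awkward contig names", {
    expect_equal(nameTarget("scaf1", 1, 150, 420), "scaf1.1.150-420")
    expect_equal(nameTarget("c", 2, 0, 7), "c.2.0-7")
    expect_equal(parseTargetName("my.contig-2.3.0-99"),
                 data.frame(contig = "my.contig-2", index = 3L,
                            start = 0L, end = 99L))
    expect_error(parseTargetName("nodots"), "nodots")
    expect_error(nameTarget("c", 0, 1, 2))
    expect_error(nameTarget("c", 1, 5, 5))

    set.seed(5)
    pieces <- c("ctg", "scaf.2", "x-1", "a.b-c", "12", "un.7-8")
    for (i in 1:100) {
        contig <- paste(sample(pieces, sample(1:3, 1), replace = TRUE),
                        collapse = sample(c(".", "-", "_"), 1))
        index <- sample(1:99, 1)
        start <- sample(0:5000, 1)
        end <- start + sample(1:5000, 1)
        parsed <- parseTargetName(nameTarget(contig, index, start, end))
        expect_equal(parsed,
                     data.frame(contig = contig, index = index,
                                start = start, end = end))
    }
})

test_that("extractTargets excises flank-extended merged soft-masked runs", {
    asm <- Biostrings::BStringSet(c(c1 = "AAAAacgtAAAA"))
    ts <- extractTargets(asm, flank = 2L)
    expect_equal(targetNames(ts), "c1.1.2-10")
    expect_equal(as.character(targetSeqs(ts)[[1]]), "AAacgtAA")

    # fully uppercase: clean empty result
    ts0 <- extractTargets(Biostrings::BStringSet(c(c1 = "ACGTACGT")))
    expect_equal(length(ts0), 0L)

    # BED overrides mask scanning and is applied with flanks
    bed <- data.frame(contig = "c1", start = 0L, end = 4L)
    tsb <- extractTargets(Biostrings::BStringSet(c(c1 = "GGttCCAAGGTT")),
                          bed = bed, flank = 0L)
    expect_equal(targetNames(tsb), "c1.1.0-4")
    expect_equal(as.character(targetSeqs(tsb)[[1]]), "GGtt")

    expect_error(extractTargets(asm,
                                bed = data.frame(contig = "nope",
                                                 start = 0L, end = 2L)),
                 "nope")
})

test_that("extracted targets are disjoint, cover the extended mask, and are excised verbatim", {
    set.seed(99)
    for (i in 1:10) {
        seqs <- stats::setNames(
            vapply(sample(500:3000, 3), rand_masked_seq, character(1),
                   p_lower = 0.08),
            paste0("ctg", 1:3))
        asm <- Biostrings::BStringSet(seqs)
        flank <- sample(c(0L, 5L, 64L), 1)
        ts <- extractTargets(asm, flank = flank)
        tc <- targetCoords(ts)
        for (ctg in names(seqs)) {
            rows <- tc[tc$contig == ctg, ]
            # per-contig disjoint, sorted, indices 1..n
            if (nrow(rows) > 1)
                expect_true(all(rows$start[-1] > rows$end[-nrow(rows)]))
            expect_equal(rows$index, seq_len(nrow(rows)))
            # coverage equals the flank-extended mask union
            expected <- oracle_expand_merge(oracle_runs(seqs[[ctg]]),
                                            flank, nchar(seqs[[ctg]]))
            expect_equal(rows[, c("start", "end")], expected,
                         ignore_attr = TRUE)
        }
        # excision fidelity, case included
        for (r in seq_len(nrow(tc)))
            expect_equal(as.character(targetSeqs(ts)[[r]]),
                         substr(seqs[[tc$contig[r]]], tc$start[r] + 1L,
                                tc$end[r]))
    }
})
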