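test_that("truth generation is deterministic and near-uniform", {
    cfg <- fixtureConfig(genomeLen = 1000, nContigs = 2L, nWindows = 0L,
                         seed = 5L)
    t1 <- makeTruth(cfg)
    t2 <- makeTruth(cfg)
    expect_identical(as.character(t1), as.character(t2))
    expect_equal(length(t1), 2L)
    expect_equal(sum(Biostrings::width(t1)), 1000)

    big <- makeTruth(fixtureConfig(genomeLen = 1e6, nContigs = 1L,
                                   nWindows = 0L, seed = 6L))
    freq <- Biostrings::letterFrequency(big, c("A", "C", "G", "T"))[1, ]
    chi <- sum((freq - 250000)^2 / 250000)
    expect_lt(chi, qchisq(0.999, df = 3))
})

test_that("zero-rate draft differs from truth only by window case", {
    cfg <- fixtureConfig(genomeLen = 20000, nContigs = 1L, nWindows = 2L,
                         windowLen = 400L, subRate = 0, indelRate = 0,
                         seed = 9L)
    truth <- makeTruth(cfg)
    d <- makeDraft(truth, cfg)
    expect_equal(unname(toupper(as.character(d$draft))),
                 unname(as.character(truth)))
    expect_equal(nrow(d$ledger), 0L)
    # windows really are lowercase in the draft
    runs <- findSoftmaskedRuns(d$draft[[1]])
    expect_equal(runs$start, d$windows$draftStart)
    expect_equal(runs$end, d$windows$draftEnd)
})

test_that("ledger replay reproduces the draft and event counts scale with rates", {
    cfg <- small_fixture_config(seed = 31L)
    truth <- makeTruth(cfg)
    d <- makeDraft(truth, cfg)
    expect_identical(as.character(applyLedger(truth, d$ledger)),
                     toupper(as.character(d$draft)))

    # expected ~ windowLen * rate per window, Poisson-ish tolerance
    n_win <- nrow(d$windows)
    exp_sub <- n_win * cfg@windowLen * cfg@subRate
    n_sub <- sum(d$ledger$type == "sub")
    expect_lt(abs(n_sub - exp_sub), 6 * sqrt(exp_sub) + 1)
    exp_ind <- n_win * cfg@windowLen * cfg@indelRate
    n_ind <- sum(d$ledger$type != "sub")
    expect_lt(abs(n_ind - exp_ind), 6 * sqrt(exp_ind) + 2)

    # events are confined to windows and sorted per contig
    for (r in seq_len(nrow(d$ledger))) {
        w <- d$windows[d$windows$contig == d$ledger$contig[r], ]
        expect_true(any(d$ledger$pos[r] >= w$start &
                        d$ledger$pos[r] < w$end))
    }
})

test_that("simulated reads hit the requested coverage and map within bounds", {
    cfg <- small_fixture_config(seed = 13L)
    fx <- simulateFixture(cfg)
    n_expected <- cfg@coverage * cfg@genomeLen / cfg@readLenMean
    expect_lt(abs(length(fx$reads) - n_expected),
              4 * sqrt(n_expected) + 5)
    expect_true(all(fx$paf$tend <= fx$paf$tlen))
    expect_true(all(fx$paf$tstart >= 0))
    # the PAF passes the strict parser round trip
    f <- withr::local_tempfile(fileext = ".paf")
    writePaf(fx$paf, f)
    expect_equal(nrow(readPaf(f)), nrow(fx$paf))
})

test_that("error-free reads are verbatim truth substrings up to strand", {
    cfg <- fixtureConfig(genomeLen = 20000, nContigs = 1L, nWindows = 1L,
                         windowLen = 300L, readErrorRate = 0,
                         coverage = 5, readLenMean = 2000L, seed = 77L)
    fx <- simulateFixture(cfg)
    tr <- as.character(fx$truth[[1]])
    for (i in seq_along(fx$reads)) {
        r <- as.character(fx$reads[[i]])
        expect_true(grepl(r, tr, fixed = TRUE) ||
                    grepl(revcomp(r), tr, fixed = TRUE))
    }
})

test_that("the evaluator is exact on the two degenerate inputs", {
    cfg <- small_fixture_config(seed = 41L)
    fx <- simulateFixture(cfg)

    perfect <- evaluatePolish(fx$truth, fx$truth, fx$ledger, fx$windows)
    expect_equal(perfect$errorsAfter, 0L)
    expect_equal(perfect$pctReductionTotal, 100)
    expect_equal(perfect$offtargetChanges, 0L)

    untouched <- evaluatePolish(fx$draft, fx$truth, fx$ledger, fx$windows)
    expect_equal(untouched$errorsAfter, nrow(fx$ledger))
    expect_equal(untouched$offtargetChanges, 0L)
})

test_that("the evaluator pinpoints an off-target modification", {
    cfg <- small_fixture_config(seed = 51L)
    fx <- simulateFixture(cfg)
    s <- as.character(fx$truth[[1]])
    # corrupt one base far from every window
    far <- 100L
    expect_true(far + 64 < min(fx$windows$start))
    substr(s, far + 1L, far + 1L) <- setdiff(BASES,
                                             substr(s, far + 1, far + 1))[1]
    mod <- Biostrings::BStringSet(stats::setNames(s, names(fx$truth)[1]))
    ev <- evaluatePolish(mod, fx$truth, fx$ledger[0, ], fx$windows)
    expect_equal(ev$offtargetChanges, 1L)
    expect_equal(ev$diffs$pos[ev$diffs$region == "offtarget"], far)
})

test_that("fixture files written to disk are consumed by the readers", {
    dir <- withr::local_tempdir()
    fx <- simulateFixture(small_fixture_config(seed = 3L), dir = dir)
    expect_equal(as.character(readFasta(fx$paths$draft)),
                 as.character(fx$draft))
    expect_equal(as.character(readReads(fx$paths$reads)),
                 as.character(fx$reads))
    expect_equal(nrow(readPaf(fx$paths$paf)), nrow(fx$paf))
})
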