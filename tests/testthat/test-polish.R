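# filters from a single error-free "read" keep the quorum gate off, which
# matches how the engine behaves at one-read coverage
filters_from <- function(seqs, kValues = c(16L, 12L))
    buildFilters(seqs, kValues = kValues, targetName = "t")

test_that("kmerSupport equals the sliding-window oracle", {
    set.seed(21)
    src <- rand_seq(200)
    fs <- filters_from(src, kValues = 12L)
    bf <- filterFor(fs, 12)
    # a verbatim substring of the inserted sequence is fully supported
    expect_equal(kmerSupport(substr(src, 41, 120), 0, fs, 12, j = 8), 1.0)
    # empty filters: zero support
    none <- buildFilters(character(), kValues = 12L)
    expect_equal(kmerSupport(src, 10, none, 12, j = 8), 0)

    # random query sequences against the oracle
    for (i in 1:20) {
        q <- rand_seq(60)
        pos <- sample(0:40, 1)
        j <- sample(1:10, 1)
        wins <- canonicalKmers(q, 12L)
        avail <- length(wins) - pos
        nwin <- min(j, avail)
        idx <- pos + seq_len(nwin)
        want <- mean(!is.na(wins[idx]) & bloomQuery(bf, ifelse(
            is.na(wins[idx]), strrep("A", 12), wins[idx])))
        expect_equal(kmerSupport(q, pos, fs, 12, j = j), want)
    }
})

test_that("tryEditAt recovers an injected substitution and deletion", {
    set.seed(33)
    truth <- rand_seq(60)
    fs <- filters_from(truth, kValues = 8L)
    params <- polishParams(kValues = 8L)

    # substitution at position 30 (0-based)
    draft <- truth
    cur <- substr(draft, 31, 31)
    substr(draft, 31, 31) <- setdiff(BASES, cur)[1]
    e <- tryEditAt(draft, 30 - 7, fs, 8, params)
    expect_equal(e$type, "sub")
    expect_equal(e$site, 30)
    expect_equal(e$to, cur)

    # deleted base: an insertion restores it
    draft2 <- paste0(substr(truth, 1, 30), substr(truth, 32, 60))
    e2 <- tryEditAt(draft2, 30 - 7, fs, 8, params)
    expect_equal(e2$type, "ins")
    expect_equal(e2$to, cur)

    # no evidence: filters built from unrelated sequence give no edit
    unrelated <- filters_from(rand_seq(60), kValues = 8L)
    expect_null(tryEditAt(draft, 30 - 7, unrelated, 8, params))
})

test_that("polishing is a fixed point on supported sequence and identity without evidence", {
    set.seed(44)
    truth <- rand_seq(400)
    fs <- filters_from(truth, kValues = c(16L, 12L))
    params <- polishParams(kValues = c(16L, 12L))

    out <- polishTarget(truth, fs, params, name = "t")
    expect_equal(out$sequence, truth)
    expect_equal(out$nSubs + out$nIns + out$nDel, 0)

    none <- buildFilters(character(), kValues = c(16L, 12L))
    out0 <- polishTarget(truth, none, params, name = "t")
    expect_equal(out0$sequence, truth)
    expect_equal(out0$nSubs + out0$nIns + out0$nDel, 0)

    # shorter than min(k): returned unchanged
    tiny <- polishTarget("ACGTACG", fs, params)
    expect_equal(tiny$sequence, "ACGTACG")
})

test_that("polishTarget reverts most injected errors against clean 30x reads", {
    set.seed(55)
    truth <- rand_seq(2000)
    # 30 error-free reads covering the target
    reads <- vapply(1:30, function(i) {
        a <- sample(1:500, 1)
        b <- sample(1500:2000, 1)
        s <- substr(truth, a, b)
        if (runif(1) < 0.5) s <- revcomp(s)
        s
    }, character(1))
    filters <- buildFilters(reads, targetName = "t")

    # 2% substitutions + 0.5% 1-bp indels inside the middle 1.8 kb
    draft_chars <- strsplit(truth, "")[[1]]
    err_at <- which(runif(2000) < 0.02 & seq_len(2000) > 100 &
                    seq_len(2000) < 1900)
    for (p in err_at)
        draft_chars[p] <- setdiff(BASES, toupper(draft_chars[p]))[
            sample(3, 1)]
    ind_at <- which(runif(2000) < 0.005 & seq_len(2000) > 100 &
                    seq_len(2000) < 1900)
    for (p in setdiff(ind_at, err_at))
        draft_chars[p] <- if (runif(1) < 0.5) "" else
            paste0(sample(BASES, 1), draft_chars[p])
    draft <- paste(draft_chars, collapse = "")
    d0 <- TargetPolish:::.banded_align(truth, draft, 64)$distance
    expect_gt(d0, 20)

    out <- polishTarget(draft, filters, polishParams(), name = "t")
    d1 <- TargetPolish:::.banded_align(truth, out$sequence, 64)$distance
    # >= 90% of injected errors reverted
    expect_lte(d1, 0.1 * d0)
})

test_that("no edit is ever logged below the acceptance threshold", {
    set.seed(66)
    fx <- simulateFixture(small_fixture_config())
    ts <- extractTargets(fx$draft)
    lifted <- liftPaf(fx$paf, buildTargetIndex(ts), quiet = TRUE)
    out <- polishAll(ts, lifted, fx$reads, editLog = TRUE)
    params <- polishParams()
    expect_true(all(out$editLog$support > params@acceptFraction))
})

test_that("polishAll outcomes are independent of target order and read-free targets pass through", {
    set.seed(88)
    fx <- simulateFixture(small_fixture_config(seed = 11L))
    ts <- extractTargets(fx$draft)
    idx <- buildTargetIndex(ts)
    lifted <- liftPaf(fx$paf, idx, quiet = TRUE)
    full <- polishAll(ts, lifted, fx$reads)

    # drop all records of target 2: that target must come back unchanged
    nm2 <- targetNames(ts)[2]
    part <- polishAll(ts, lifted[lifted$tname != nm2, ], fx$reads)
    expect_equal(as.character(part$seqs[[nm2]]),
                 as.character(targetSeqs(ts)[[nm2]]))
    expect_equal(part$stats$nSubs[part$stats$name == nm2], 0)

    # order independence: polish the targets one by one in reverse
    nms <- rev(targetNames(ts))
    for (nm in nms) {
        qn <- unique(lifted$qname[lifted$tname == nm])
        f <- buildFilters(as.character(fx$reads[qn]), targetName = nm)
        solo <- polishTarget(as.character(targetSeqs(ts)[[nm]]), f,
                             polishParams(), name = nm)
        expect_equal(solo$sequence, as.character(full$seqs[[nm]]))
    }

    expect_error(polishAll(ts, transform(lifted, tname = "ghost"),
                           fx$reads), "unknown target")
})

test_that("a second polish pass never applies more edits than the first", {
    set.seed(17)
    fx <- simulateFixture(small_fixture_config(seed = 23L))
    ts <- extractTargets(fx$draft)
    lifted <- liftPaf(fx$paf, buildTargetIndex(ts), quiet = TRUE)
    params <- polishParams()
    for (nm in targetNames(ts)) {
        qn <- unique(lifted$qname[lifted$tname == nm])
        f <- buildFilters(as.character(fx$reads[qn]), targetName = nm)
        p1 <- polishTarget(as.character(targetSeqs(ts)[[nm]]), f, params)
        p2 <- polishTarget(p1$sequence, f, params)
        expect_lte(p2$nSubs + p2$nIns + p2$nDel,
                   p1$nSubs + p1$nIns + p1$nDel)
    }
})
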