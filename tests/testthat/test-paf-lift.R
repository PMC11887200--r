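# build a TargetSet directly from coordinates over a synthetic assembly
make_target_set <- function(contig_lens, coords) {
    set.seed(1)
    seqs <- stats::setNames(vapply(contig_lens, rand_seq, character(1)),
                            names(contig_lens))
    asm <- Biostrings::BStringSet(seqs)
    bed <- coords[, c("contig", "start", "end")]
    list(asm = asm,
         ts = extractTargets(asm, bed = bed, flank = 0L))
}

test_that("target index returns exactly the overlapping targets", {
    x <- make_target_set(c(c1 = 1000L),
                         data.frame(contig = "c1",
                                    start = c(100L, 400L),
                                    end = c(200L, 500L)))
    idx <- buildTargetIndex(x$ts)
    both <- queryTargetIndex(idx, "c1", 150, 450)
    expect_equal(nrow(both), 2L)
    expect_equal(nrow(queryTargetIndex(idx, "c1", 250, 300)), 0L)
    expect_equal(nrow(queryTargetIndex(idx, "c2", 0, 1000)), 0L)
})

test_that("index queries agree with a linear scan on random targets", {
    set.seed(23)
    # 1,000 random disjoint targets over several contigs
    contigs <- paste0("ctg", 1:5)
    tgt <- do.call(rbind, lapply(contigs, function(ctg) {
        starts <- sort(sample(seq(0, 99000, by = 90), 200))
        data.frame(contig = ctg, start = starts,
                   end = starts + sample(20:80, 200, replace = TRUE))
    }))
    gr <- GenomicRanges::GRanges(tgt$contig,
                                 IRanges::IRanges(tgt$start + 1L, tgt$end))
    gr$name <- nameTarget(tgt$contig,
                          unlist(lapply(table(tgt$contig)[unique(tgt$contig)],
                                        seq_len)),
                          tgt$start, tgt$end)
    gr$index <- as.integer(sub(".*\\.([0-9]+)\\.[0-9]+-[0-9]+$", "\\1",
                               gr$name))
    seqs <- Biostrings::BStringSet(
        stats::setNames(strrep("A", GenomicRanges::width(gr)), gr$name))
    ts <- methods::new("TargetSet", granges = gr, seqs = seqs)
    idx <- buildTargetIndex(ts)
    for (i in 1:200) {
        ctg <- sample(contigs, 1)
        a <- sample(0:99900, 1)
        b <- a + sample(1:400, 1)
        got <- sort(queryTargetIndex(idx, ctg, a, b)$name)
        want <- sort(gr$name[
            as.character(GenomicRanges::seqnames(gr)) == ctg &
            GenomicRanges::start(gr) - 1L < b &
            GenomicRanges::end(gr) > a])
        expect_equal(got, want)
    }
})

test_that("liftRecord rewrites coordinates into the target frame", {
    x <- make_target_set(c(c1 = 1000L),
                         data.frame(contig = "c1", start = 150L,
                                    end = 250L))
    idx <- buildTargetIndex(x$ts)
    rec <- data.frame(qname = "r1", qlen = 300, qstart = 0, qend = 300,
                      strand = "+", tname = "c1", tlen = 1000,
                      tstart = 100, tend = 300, nmatch = 190,
                      blocklen = 200, mapq = 60, tags = "",
                      stringsAsFactors = FALSE)
    out <- liftRecord(rec, idx)
    expect_equal(nrow(out), 1L)
    expect_equal(out$tname, "c1.1.150-250")
    expect_equal(out$tstart, 0)
    expect_equal(out$tend, 100)
    expect_equal(out$tlen, 100)
    # half the block kept: counts scaled down, query clipped
    expect_equal(out$blocklen, 100)
    expect_equal(out$nmatch, 95)
    expect_true(out$qstart >= rec$qstart && out$qend <= rec$qend)

    # record entirely inside the target: nothing clipped
    rec2 <- transform(rec, tstart = 160, tend = 240, blocklen = 80,
                      nmatch = 78, qend = 80)
    out2 <- liftRecord(rec2, idx)
    expect_equal(out2$tstart, 10)
    expect_equal(out2$tend, 90)
    expect_equal(out2$nmatch, 78)
    expect_equal(out2$blocklen, 80)

    # off-target record is discarded
    rec3 <- transform(rec, tstart = 300, tend = 500)
    expect_equal(nrow(liftRecord(rec3, idx)), 0L)
})

test_that("a read spanning two targets is split into independent records", {
    x <- make_target_set(c(c1 = 1000L),
                         data.frame(contig = "c1",
                                    start = c(100L, 300L),
                                    end = c(200L, 400L)))
    idx <- buildTargetIndex(x$ts)
    rec <- data.frame(qname = "r1", qlen = 400, qstart = 0, qend = 400,
                      strand = "+", tname = "c1", tlen = 1000, tstart = 50,
                      tend = 450, nmatch = 390, blocklen = 400, mapq = 60,
                      tags = "", stringsAsFactors = FALSE)
    out <- liftPaf(rec, idx, quiet = TRUE)
    expect_equal(nrow(out), 2L)
    expect_equal(out$tname, c("c1.1.100-200", "c1.2.300-400"))
    expect_equal(out$tstart, c(0, 0))
    expect_equal(out$tend, c(100, 100))
})

test_that("liftover equals the per-base coordinate-shift oracle on random input", {
    set.seed(31)
    # random disjoint targets on one contig
    starts <- sort(sample(seq(0, 49000, by = 450), 60))
    tgt <- data.frame(contig = "c1", start = starts,
                      end = starts + sample(50:300, 60, replace = TRUE))
    x <- make_target_set(c(c1 = 50000L), tgt)
    idx <- buildTargetIndex(x$ts)
    tc <- targetCoords(x$ts)

    n <- 300
    ts_ <- sample(0:49000, n, replace = TRUE)
    te_ <- pmin(ts_ + sample(20:2000, n, replace = TRUE), 50000)
    bl <- te_ - ts_
    paf <- data.frame(qname = paste0("r", seq_len(n)), qlen = bl + 50,
                      qstart = 25, qend = bl + 25,
                      strand = sample(c("+", "-"), n, TRUE), tname = "c1",
                      tlen = 50000, tstart = ts_, tend = te_,
                      nmatch = pmax(1, bl - 10), blocklen = bl,
                      mapq = 60, tags = "", stringsAsFactors = FALSE)
    out <- liftPaf(paf, idx, quiet = TRUE)

    # oracle: per record x target, intersect and shift coordinates
    oracle <- do.call(rbind, lapply(seq_len(n), function(i) {
        hits <- tc[tc$start < paf$tend[i] & tc$end > paf$tstart[i], ]
        if (!nrow(hits)) return(NULL)
        data.frame(qname = paf$qname[i], tname = hits$name,
                   tstart = pmax(paf$tstart[i], hits$start) - hits$start,
                   tend = pmin(paf$tend[i], hits$end) - hits$start,
                   tlen = hits$end - hits$start)
    }))
    expect_equal(out[, c("qname", "tname", "tstart", "tend", "tlen")],
                 oracle, ignore_attr = TRUE)

    # invariants: coordinates in range, conservation of block length
    expect_true(all(out$tstart >= 0 & out$tstart < out$tend &
                    out$tend <= out$tlen))
    expect_true(all(out$qstart >= 0 & out$qstart < out$qend &
                    out$qend <= out$qlen))
    per_rec <- tapply(out$tend - out$tstart, out$qname, sum)
    orig <- stats::setNames(paf$tend - paf$tstart, paf$qname)
    expect_true(all(per_rec <= orig[names(per_rec)]))

    stats <- attr(out, "liftStats")
    expect_equal(unname(stats["input"]), n)
    expect_equal(unname(stats["lifted"]), nrow(out))
})

test_that("re-lifting against a whole-target index is the identity", {
    x <- make_target_set(c(c1 = 5000L),
                         data.frame(contig = "c1",
                                    start = c(500L, 2000L),
                                    end = c(900L, 2600L)))
    idx <- buildTargetIndex(x$ts)
    paf <- data.frame(qname = c("a", "b"), qlen = c(700, 500),
                      qstart = c(0, 0), qend = c(700, 500),
                      strand = c("+", "-"), tname = "c1", tlen = 5000,
                      tstart = c(400, 2100), tend = c(1100, 2500),
                      nmatch = c(650, 380), blocklen = c(700, 400),
                      mapq = 60, tags = "", stringsAsFactors = FALSE)
    lifted <- liftPaf(paf, idx, quiet = TRUE)

    # index in which each target is its own "contig" spanning itself
    gr <- GenomicRanges::GRanges(lifted$tname[!duplicated(lifted$tname)],
        IRanges::IRanges(1L, lifted$tlen[!duplicated(lifted$tname)]))
    gr$name <- lifted$tname[!duplicated(lifted$tname)]
    gr$index <- 1L
    seqs <- Biostrings::BStringSet(stats::setNames(
        strrep("A", GenomicRanges::width(gr)), gr$name))
    whole <- buildTargetIndex(
        methods::new("TargetSet", granges = gr, seqs = seqs))
    relifted <- liftPaf(lifted, whole, quiet = TRUE)
    rownames(relifted) <- NULL
    expect_equal(relifted[, c("qname", "qstart", "qend", "tstart", "tend",
                              "nmatch", "blocklen")],
                 lifted[, c("qname", "qstart", "qend", "tstart", "tend",
                            "nmatch", "blocklen")],
                 ignore_attr = TRUE)
    # names: re-lifted tname is the re-encoded whole-target name
})

test_that("all records off target are discarded and counted", {
    x <- make_target_set(c(c1 = 1000L),
                         data.frame(contig = "c1", start = 100L,
                                    end = 200L))
    idx <- buildTargetIndex(x$ts)
    paf <- data.frame(qname = c("a", "b"), qlen = 100, qstart = 0,
                      qend = 100, strand = "+", tname = "c1", tlen = 1000,
                      tstart = c(300, 500), tend = c(400, 600),
                      nmatch = 90, blocklen = 100, mapq = 60, tags = "",
                      stringsAsFactors = FALSE)
    out <- liftPaf(paf, idx, quiet = TRUE)
    expect_equal(nrow(out), 0L)
    expect_equal(unname(attr(out, "liftStats")["discarded"]), 2L)
})
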