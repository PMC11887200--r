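#' Build an interval index over target regions
#'
#' Wraps the targets in a sorted [GenomicRanges::GRanges] for O(log n)
#' overlap lookup from assembly coordinates. Construction fails if targets
#' on one contig overlap (impossible after [expandAndMerge()]).
#'
#' @param targets A [TargetSet].
#' @return A [TargetIndex].
#' @export
buildTargetIndex <- function(targets) {
    gr <- targets@granges
    if (length(gr)) {
        gr <- GenomicRanges::sort(gr)
        gr$targetLen <- GenomicRanges::width(gr)
    } else {
        gr$targetLen <- integer()
    }
    methods::new("TargetIndex", granges = gr)
}

#' Query a target index with an assembly interval
#'
#' @param index A [TargetIndex].
#' @param contig Contig name.
#' @param start,end 0-based half-open assembly coordinates.
#' @return A `data.frame` of overlapping targets (`name`, `contig`,
#'   `start`, `end`, `targetLen`), possibly empty.
#' @export
queryTargetIndex <- function(index, contig, start, end) {
    stopifnot(length(contig) == 1L, start < end)
    gr <- index@granges
    q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, gr))
    s <- S4Vectors::subjectHits(hits)
    data.frame(name = as.character(gr$name[s]),
               contig = as.character(GenomicRanges::seqnames(gr))[s],
               start = GenomicRanges::start(gr)[s] - 1L,
               end = GenomicRanges::end(gr)[s],
               targetLen = as.integer(gr$targetLen[s]),
               stringsAsFactors = FALSE)
}

#' Lift PAF records into target-region coordinates
#'
#' Rewrites read-to-assembly alignments into the coordinate system of the
#' excised target regions. Each input record yields one output record per
#' target it overlaps (a read spanning two targets is split into
#' independent records); records overlapping no target are discarded, and
#' the input/lifted/discarded counts are reported as a message and attached
#' as the `"liftStats"` attribute.
#'
#' Alignment blocks are clipped to the target interval. Because PAF blocks
#' are treated as interval evidence (no CIGAR), query coordinates are
#' clipped proportionally to the clipped target fraction (from the opposite
#' query end for `-` strand records); `nmatch` and `blocklen` are scaled by
#' the kept fraction (rounded down, floors of 0 raised to 1). `strand`,
#' `mapq` and tag columns are copied unchanged.
#'
#' @param paf A PAF `data.frame` from [readPaf()] (assembly coordinates).
#' @param index A [TargetIndex] from [buildTargetIndex()].
#' @param minOverlap Minimum clipped target overlap (bp) for keeping a
#'   lifted record (default 1, i.e. no filtering beyond "touches a
#'   target").
#' @param quiet Suppress the count message.
#' @return A PAF `data.frame` in target coordinates: `tname` is the target
#'   name and `tlen` the target length.
#' @export
liftPaf <- function(paf, index, minOverlap = 1L, quiet = FALSE) {
    stopifnot(minOverlap >= 1L)
    gr <- index@granges
    out0 <- paf[0, , drop = FALSE]
    if (nrow(paf) == 0 || length(gr) == 0) {
        if (!quiet)
            message("liftPaf: ", nrow(paf), " records in, 0 lifted, ",
                    nrow(paf), " discarded")
        attr(out0, "liftStats") <- c(input = nrow(paf), lifted = 0L,
                                     discarded = nrow(paf))
        return(out0)
    }
    .validate_paf(paf)
    q <- GenomicRanges::GRanges(paf$tname,
                                IRanges::IRanges(paf$tstart + 1L,
                                                 paf$tend))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, gr))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)

    Tst <- GenomicRanges::start(gr)[si] - 1  # 0-based target start
    Ten <- GenomicRanges::end(gr)[si]
    ts <- paf$tstart[qi]; te <- paf$tend[qi]
    ns <- pmax(ts, Tst) - Tst
    ne <- pmin(te, Ten) - Tst

    keep <- (ne - ns) >= minOverlap
    qi <- qi[keep]; si <- si[keep]
    Tst <- Tst[keep]; Ten <- Ten[keep]
    ts <- ts[keep]; te <- te[keep]; ns <- ns[keep]; ne <- ne[keep]

    span <- te - ts
    fstart <- (pmax(ts, Tst) - ts) / span
    fend <- (te - pmin(te, Ten)) / span
    fkept <- (ne - ns) / span

    qs <- paf$qstart[qi]; qe <- paf$qend[qi]; ql <- paf$qlen[qi]
    qb <- qe - qs
    minus <- paf$strand[qi] == "-"
    cut5 <- ifelse(minus, fend, fstart)   # clipped fraction at query 5' end
    cut3 <- ifelse(minus, fstart, fend)
    nqs <- qs + floor(cut5 * qb)
    nqe <- qe - floor(cut3 * qb)
    # guarantee a non-empty query interval within [0, qlen]
    fix <- nqe <= nqs
    nqe[fix] <- pmin(ql[fix], nqs[fix] + 1)
    nqs[fix] <- nqe[fix] - 1

    nm <- pmax(1, floor(paf$nmatch[qi] * fkept))
    bl <- pmax(1, floor(paf$blocklen[qi] * fkept))
    nm <- pmin(nm, bl)

    out <- data.frame(
        qname = paf$qname[qi], qlen = ql, qstart = nqs, qend = nqe,
        strand = paf$strand[qi],
        tname = as.character(gr$name)[si],
        tlen = as.numeric(gr$targetLen)[si],
        tstart = ns, tend = ne, nmatch = nm, blocklen = bl,
        mapq = paf$mapq[qi],
        tags = if (is.null(paf$tags)) "" else paf$tags[qi],
        stringsAsFactors = FALSE)
    out <- out[order(qi, Tst), , drop = FALSE]
    rownames(out) <- NULL

    discarded <- nrow(paf) - length(unique(qi))
    if (!quiet)
        message("liftPaf: ", nrow(paf), " records in, ", nrow(out),
                " lifted, ", discarded, " discarded")
    attr(out, "liftStats") <- c(input = nrow(paf), lifted = nrow(out),
                                discarded = discarded)
    out
}

#' @rdname liftPaf
#' @param rec A single-row PAF `data.frame`.
#' @return `liftRecord()`: the lifted records for one input record
#'   (zero or more rows).
#' @export
liftRecord <- function(rec, index, minOverlap = 1L) {
    stopifnot(nrow(rec) == 1L)
    out <- liftPaf(rec, index, minOverlap = minOverlap, quiet = TRUE)
    attr(out, "liftStats") <- NULL
    out
}
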