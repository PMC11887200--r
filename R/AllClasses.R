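#' Target regions of a draft assembly
#'
#' Container for the polishing targets extracted from one draft assembly:
#' merged, flank-extended intervals on the source contigs together with
#' their excised (case-preserved) sequences and coordinate-encoding names
#' of the form `"{contig}.{index}.{start}-{end}"` (0-based, half-open).
#'
#' @slot granges A [GenomicRanges::GRanges] of the target intervals on the
#'   source contigs (1-based, closed, as is native to `GRanges`), with
#'   metadata columns `name` (the coordinate-encoding target name, 0-based
#'   half-open) and `index` (ordinal of the target on its contig, from the
#'   5' end).
#' @slot seqs A [Biostrings::BStringSet] of the excised target sequences,
#'   named by target name, case preserved.
#'
#' @seealso [extractTargets()], [targetCoords()], [buildTargetIndex()]
#' @export
setClass("TargetSet", representation(granges = "GRanges",
                                     seqs = "BStringSet"))

setValidity("TargetSet", function(object) {
    gr <- object@granges
    seqs <- object@seqs
    msg <- character()
    if (length(gr) != length(seqs))
        msg <- c(msg, "granges and seqs lengths differ")
    if (length(gr)) {
        if (is.null(gr$name) || is.null(gr$index))
            return("granges must carry 'name' and 'index' metadata columns")
        if (!identical(as.character(gr$name), names(seqs)))
            msg <- c(msg, "seqs names do not match target names")
        if (anyDuplicated(gr$name))
            msg <- c(msg, "duplicate target names")
        if (any(GenomicRanges::width(gr) != Biostrings::width(seqs)))
            msg <- c(msg, "target widths do not match sequence lengths")
        hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
        if (length(hits) > length(gr))
            msg <- c(msg, "targets on one contig overlap")
        idx <- split(gr$index, as.character(GenomicRanges::seqnames(gr)))
        bad <- vapply(idx, function(i) !identical(sort(as.integer(i)),
                                                  seq_along(i)),
                      logical(1))
        if (any(bad))
            msg <- c(msg, "per-contig target indices are not 1..n")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "TargetSet", function(object) {
    cat("TargetSet with", length(object@granges), "target(s) on",
        length(unique(as.character(
            GenomicRanges::seqnames(object@granges)))),
        "contig(s)\n")
    if (length(object@granges)) {
        cat("  total target length:",
            sum(GenomicRanges::width(object@granges)), "bp\n")
        cat("  first:", object@granges$name[1], "\n")
    }
})

#' @describeIn TargetSet Number of targets.
#' @param x A `TargetSet`.
#' @export
setMethod("length", "TargetSet", function(x) length(x@granges))

#' Interval index over target regions
#'
#' Fast assembly-coordinate overlap lookup from alignment intervals to
#' target regions, used by PAF liftover. Built with [buildTargetIndex()].
#'
#' @slot granges Target intervals as a sorted [GenomicRanges::GRanges] with
#'   metadata columns `name` and `targetLen` (length of the excised target
#'   sequence).
#' @export
setClass("TargetIndex", representation(granges = "GRanges"))

setValidity("TargetIndex", function(object) {
    gr <- object@granges
    if (length(gr)) {
        if (is.null(gr$name) || is.null(gr$targetLen))
            return("granges must carry 'name' and 'targetLen'")
        hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
        if (length(hits) > length(gr))
            return("targets overlap; index requires disjoint targets")
    }
    TRUE
})

setMethod("show", "TargetIndex", function(object) {
    cat("TargetIndex over", length(object@granges), "target(s)\n")
})

#' A Bloom filter over canonical k-mers
#'
#' Probabilistic k-mer membership structure: no false negatives, tunable
#' false-positive rate. Keys are canonical (strand-neutral) k-mers packed
#' 2 bits per base, so k must lie in 2..32. The filter lives in external
#' memory and does not survive serialisation.
#'
#' @slot ptr External pointer to the native filter.
#' @slot k K-mer size (bp).
#' @slot m Number of bits.
#' @slot h Number of hash functions.
#' @seealso [bloomFilter()], [bloomInsertSeq()], [bloomQuery()]
#' @export
setClass("BloomFilter", representation(ptr = "externalptr", k = "integer",
                                       m = "numeric", h = "integer"))

setMethod("show", "BloomFilter", function(object) {
    info <- .bloom_params(object@ptr)
    cat(sprintf("BloomFilter: k=%d, m=%.0f bits, h=%d, %d insert(s)\n",
                object@k, object@m, object@h, info$n_inserted))
})

#' Per-target Bloom filters, one per k-mer size
#'
#' The read-evidence substrate for polishing one target region: one
#' [BloomFilter] per k-mer size, all populated from the same multiset of
#' reads assigned to the target.
#'
#' @slot targetName Name of the target the filters were built for.
#' @slot kValues K-mer sizes, descending.
#' @slot fpr Configured false-positive rate used for sizing.
#' @slot filters List of [BloomFilter] objects, parallel to `kValues`,
#'   populated from every read assigned to the target.
#' @slot filtersA,filtersB Per-k filters over the two deterministic halves
#'   of the read set (alternating assignment in input order). The polisher
#'   uses them as a lightweight quorum: an edit's anchor window must be
#'   present in both halves, i.e. backed by at least two reads, before it
#'   can be accepted. Empty lists disable the quorum (as does an empty
#'   half, e.g. with a single read).
#' @slot nKmers Total k-mer count of the source reads per k (the sizing
#'   capacity).
#' @seealso [buildFilters()], [polishTarget()]
#' @export
setClass("BloomFilterSet",
         representation(targetName = "character", kValues = "integer",
                        fpr = "numeric", filters = "list",
                        filtersA = "list", filtersB = "list",
                        nKmers = "numeric"))

setValidity("BloomFilterSet", function(object) {
    msg <- character()
    if (length(object@filters) != length(object@kValues))
        msg <- c(msg, "filters and kValues lengths differ")
    if (length(object@kValues) && is.unsorted(rev(object@kValues),
                                              strictly = TRUE))
        msg <- c(msg, "kValues must be strictly descending")
    if (object@fpr <= 0 || object@fpr >= 1)
        msg <- c(msg, "fpr must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BloomFilterSet", function(object) {
    cat(sprintf("BloomFilterSet for target '%s': k = %s (fpr %.3g)\n",
                object@targetName,
                paste(object@kValues, collapse = ", "), object@fpr))
})

#' Polishing parameters
#'
#' Tuning knobs of the k-mer edit engine; see [polishParams()] for the
#' meaning and defaults of each slot.
#'
#' @slot kValues K-mer sizes, strictly descending.
#' @slot verifyWindow Number of subsequent k-mer windows scored per
#'   candidate edit (0 means "use k").
#' @slot acceptFraction Minimum fraction of scored windows that must be
#'   present for an edit to be accepted, in (0, 1].
#' @slot maxIndel Maximum insertion/deletion length attempted per site (bp).
#' @slot maxSubRun Maximum length of a greedily extended substitution run
#'   (bp).
#' @slot roundsPerK Scan passes per k-mer size.
#' @slot anchorBacktrack How many bases the edit site may slide backwards
#'   at the start of an absent-window run when the implied site yields no
#'   edit.
#' @export
setClass("PolishParams",
         representation(kValues = "integer", verifyWindow = "integer",
                        acceptFraction = "numeric", maxIndel = "integer",
                        maxSubRun = "integer", roundsPerK = "integer",
                        anchorBacktrack = "integer"))

setValidity("PolishParams", function(object) {
    msg <- character()
    if (!length(object@kValues) || any(object@kValues < 2L) ||
        any(object@kValues > 32L))
        msg <- c(msg, "kValues must be in 2..32")
    if (length(object@kValues) > 1 &&
        is.unsorted(rev(object@kValues), strictly = TRUE))
        msg <- c(msg, "kValues must be strictly descending")
    if (object@verifyWindow < 0L)
        msg <- c(msg, "verifyWindow must be >= 0 (0 = use k)")
    if (object@acceptFraction <= 0 || object@acceptFraction > 1)
        msg <- c(msg, "acceptFraction must be in (0, 1]")
    if (object@maxIndel < 1L) msg <- c(msg, "maxIndel must be >= 1")
    if (object@maxSubRun < 1L) msg <- c(msg, "maxSubRun must be >= 1")
    if (object@roundsPerK < 1L) msg <- c(msg, "roundsPerK must be >= 1")
    if (object@anchorBacktrack < 0L)
        msg <- c(msg, "anchorBacktrack must be >= 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PolishParams", function(object) {
    jw <- if (object@verifyWindow == 0L) "k" else object@verifyWindow
    cat(sprintf(paste0("PolishParams: k = %s; verify window %s; accept ",
                       "fraction %.2f; max indel %d bp; %d round(s)/k\n"),
                paste(object@kValues, collapse = ", "), jw,
                object@acceptFraction, object@maxIndel, object@roundsPerK))
})

#' Synthetic fixture configuration
#'
#' Parameters of the synthetic study system: a truth genome, a draft copy
#' whose errors are confined to soft-masked windows, and long reads sampled
#' from the truth. See [fixtureConfig()].
#'
#' @slot genomeLen Total genome length (bp).
#' @slot nContigs Number of contigs.
#' @slot nWindows Number of error-injected soft-masked windows.
#' @slot windowLen Window length (bp).
#' @slot subRate Per-base substitution rate inside windows.
#' @slot indelRate Per-base indel rate inside windows (split evenly between
#'   1-bp insertions and deletions).
#' @slot readLenMean Mean simulated read length (bp).
#' @slot coverage Target read depth (fold).
#' @slot readErrorRate Per-base read error rate (3/4 substitutions, 1/8
#'   insertions, 1/8 deletions).
#' @slot seed Base random seed.
#' @export
setClass("FixtureConfig",
         representation(genomeLen = "numeric", nContigs = "integer",
                        nWindows = "integer", windowLen = "integer",
                        subRate = "numeric", indelRate = "numeric",
                        readLenMean = "integer", coverage = "numeric",
                        readErrorRate = "numeric", seed = "integer"))

setValidity("FixtureConfig", function(object) {
    msg <- character()
    rates <- c(object@subRate, object@indelRate, object@readErrorRate)
    if (any(rates < 0) || any(rates >= 1))
        msg <- c(msg, "rates must lie in [0, 1)")
    if (object@genomeLen < 1 || object@nContigs < 1L ||
        object@windowLen < 1L || object@readLenMean < 1L ||
        object@coverage <= 0)
        msg <- c(msg, "sizes and coverage must be positive")
    if (object@nWindows < 0L) msg <- c(msg, "nWindows must be >= 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "FixtureConfig", function(object) {
    cat(sprintf(paste0("FixtureConfig: %.0f bp genome in %d contig(s); %d ",
                       "window(s) x %d bp (sub %.3g, indel %.3g); reads ",
                       "%.0fx, mean %d bp, error %.3g; seed %d\n"),
                object@genomeLen, object@nContigs, object@nWindows,
                object@windowLen, object@subRate, object@indelRate,
                object@coverage, object@readLenMean, object@readErrorRate,
                object@seed))
})
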