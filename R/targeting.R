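#' Locate soft-masked runs in one sequence
#'
#' Finds maximal runs of lowercase bases (`a`, `c`, `g`, `t`, `n`).
#' Uppercase `N` is a gap character, not a mask, and does not trigger
#' targeting.
#'
#' @param seq A character scalar, [Biostrings::BString] or one-element
#'   `BStringSet`.
#' @return A `data.frame` with 0-based half-open `start`, `end` columns,
#'   one row per run, in left-to-right order.
#' @examples
#' findSoftmaskedRuns("ACGTacgtACGT")   # one run: [4, 8)
#' @export
findSoftmaskedRuns <- function(seq) {
    s <- .as_seq_scalar(seq)
    m <- gregexpr("[acgtn]+", s)[[1]]
    if (m[1] == -1L)
        return(data.frame(start = integer(), end = integer()))
    data.frame(start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + attr(m, "match.length"))
}

.as_seq_scalar <- function(seq) {
    if (is.character(seq)) {
        stopifnot(length(seq) == 1L)
        return(seq)
    }
    if (methods::is(seq, "XStringSet")) {
        stopifnot(length(seq) == 1L)
        return(as.character(seq[[1]]))
    }
    as.character(seq)
}

#' Extend intervals by a flank and merge overlaps
#'
#' Each interval is widened by `flank` bases on both sides, clamped to
#' `[0, contigLen]`; extended intervals that overlap or touch (gap 0) are
#' merged into one. Touching intervals merge so that reinsertion never has
#' to handle zero-length slices between adjacent targets.
#'
#' @param intervals A `data.frame` with 0-based half-open `start`, `end`
#'   columns, all on one contig.
#' @param flank Flank length in bp, `>= 0` (default 64).
#' @param contigLen Length of the contig the intervals lie on.
#' @return A sorted, disjoint `data.frame` of 0-based half-open intervals.
#' @export
expandAndMerge <- function(intervals, flank = 64L, contigLen) {
    stopifnot(flank >= 0, contigLen >= 1)
    if (nrow(intervals) == 0)
        return(data.frame(start = integer(), end = integer()))
    if (any(intervals$start < 0 | intervals$start >= intervals$end))
        stop("invalid interval: need 0 <= start < end")
    if (any(intervals$end > contigLen))
        stop("interval exceeds contig length ", contigLen)
    ext <- IRanges::IRanges(pmax(0L, intervals$start - as.integer(flank)) + 1L,
                            pmin(as.integer(contigLen),
                                 intervals$end + as.integer(flank)))
    red <- IRanges::reduce(ext)  # merges overlapping and book-ended runs
    data.frame(start = IRanges::start(red) - 1L, end = IRanges::end(red))
}

#' Format a coordinate-encoding target name
#'
#' Target names are `"{contig}.{index}.{start}-{end}"` with 0-based
#' half-open coordinates on the source contig. [parseTargetName()] inverts
#' the format exactly, even for contig names containing dots or dashes
#' (parsing is rightmost-first).
#'
#' @param contig Source contig name(s).
#' @param index Ordinal (`>= 1`) of the target on its contig, from the 5'
#'   end.
#' @param start,end 0-based half-open coordinates of the target on the
#'   contig.
#' @return Character vector of target names.
#' @examples
#' nameTarget("scaf1", 1, 150, 420)
#' @export
nameTarget <- function(contig, index, start, end) {
    if (any(index < 1)) stop("index must be >= 1")
    if (any(start < 0) || any(start >= end))
        stop("invalid coordinates: need 0 <= start < end")
    sprintf("%s.%d.%d-%d", contig, as.integer(index), as.integer(start),
            as.integer(end))
}

#' Parse a coordinate-encoding target name
#'
#' Inverse of [nameTarget()]. The trailing `".{index}.{start}-{end}"` is
#' matched rightmost-first, so contig names containing dots and dashes
#' round-trip unambiguously.
#'
#' @param name Character vector of target names.
#' @return A `data.frame` with columns `contig`, `index`, `start`, `end`.
#' @examples
#' parseTargetName("my.contig-2.3.0-99")
#' @export
parseTargetName <- function(name) {
    pat <- "^(.*)\\.([0-9]+)\\.([0-9]+)-([0-9]+)$"
    ok <- grepl(pat, name)
    if (any(!ok))
        stop("cannot parse target name '", name[which(!ok)[1]], "'")
    data.frame(contig = sub(pat, "\\1", name),
               index = as.integer(sub(pat, "\\2", name)),
               start = as.integer(sub(pat, "\\3", name)),
               end = as.integer(sub(pat, "\\4", name)),
               stringsAsFactors = FALSE)
}

#' Extract polishing targets from a draft assembly
#'
#' Per contig, raw intervals are taken from `bed` when supplied (the BED is
#' then authoritative and soft-mask scanning is skipped entirely),
#' otherwise from [findSoftmaskedRuns()]. Raw intervals are flank-extended
#' and merged with [expandAndMerge()], excised with case preserved, and
#' named `"{contig}.{index}.{start}-{end}"` with indices running 1..n in
#' 5' to 3' order per contig. Flanks are applied to BED targets too: the
#' polisher needs anchoring k-mer context either way.
#'
#' @param assembly Draft assembly as a named [Biostrings::BStringSet] (see
#'   [readFasta()]) or named character vector. Lowercase marks unpolished
#'   sequence.
#' @param bed Optional `data.frame` of 0-based half-open intervals
#'   (`contig`, `start`, `end`) as from [readBed()]. Intervals may overlap;
#'   they are merged like any others. Every BED contig must exist in the
#'   assembly.
#' @param flank Flank length in bp (default 64).
#' @return A [TargetSet]; empty if no target is found.
#' @examples
#' asm <- Biostrings::BStringSet(c(c1 = "AAAAacgtAAAA"))
#' extractTargets(asm, flank = 2)
#' @export
extractTargets <- function(assembly, bed = NULL, flank = 64L) {
    if (is.character(assembly))
        assembly <- Biostrings::BStringSet(assembly)
    if (is.null(names(assembly)) || anyDuplicated(names(assembly)))
        stop("assembly must have unique contig names")
    if (!is.null(bed)) {
        missing <- setdiff(unique(bed$contig), names(assembly))
        if (length(missing))
            stop("BED contig '", missing[1], "' absent from the assembly")
    }
    contigs <- names(assembly)
    lens <- stats::setNames(Biostrings::width(assembly), contigs)

    res_contig <- character()
    res_start <- integer()
    res_end <- integer()
    res_index <- integer()
    for (ctg in contigs) {
        raw <- if (!is.null(bed)) {
            bed[bed$contig == ctg, c("start", "end"), drop = FALSE]
        } else {
            findSoftmaskedRuns(assembly[[ctg]])
        }
        if (nrow(raw) == 0) next
        merged <- expandAndMerge(raw, flank = flank,
                                 contigLen = lens[[ctg]])
        res_contig <- c(res_contig, rep(ctg, nrow(merged)))
        res_start <- c(res_start, merged$start)
        res_end <- c(res_end, merged$end)
        res_index <- c(res_index, seq_len(nrow(merged)))
    }
    if (!length(res_contig)) {
        return(methods::new(
            "TargetSet",
            granges = GenomicRanges::GRanges(),
            seqs = Biostrings::BStringSet()))
    }
    nms <- nameTarget(res_contig, res_index, res_start, res_end)
    seqs <- Biostrings::BStringSet(vapply(seq_along(nms), function(i)
        substr(as.character(assembly[[res_contig[i]]]),
               res_start[i] + 1L, res_end[i]), character(1)))
    names(seqs) <- nms
    gr <- GenomicRanges::GRanges(
        seqnames = res_contig,
        ranges = IRanges::IRanges(res_start + 1L, res_end),
        name = nms, index = res_index)
    methods::new("TargetSet", granges = gr, seqs = seqs)
}

#' Target accessors
#'
#' @param x A [TargetSet].
#' @return `targetNames()`: character vector of target names;
#'   `targetSeqs()`: the excised sequences as a [Biostrings::BStringSet];
#'   `targetCoords()`: a `data.frame` with `contig`, `index` and 0-based
#'   half-open `start`, `end` plus `name`.
#' @export
targetNames <- function(x) as.character(x@granges$name)

#' @rdname targetNames
#' @export
targetSeqs <- function(x) x@seqs

#' @rdname targetNames
#' @export
targetCoords <- function(x) {
    gr <- x@granges
    data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
               index = as.integer(gr$index),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               name = as.character(gr$name),
               stringsAsFactors = FALSE)
}
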