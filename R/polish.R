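#' Construct polishing parameters
#'
#' Tuning knobs of the Bloom-filter k-mer edit engine.
#'
#' The scan works largest k first (high specificity), then smaller k
#' (sensitivity where coverage or context is thin). At every position whose
#' canonical k-mer is absent from the target's filter, candidate edits are
#' enumerated at the first base not covered by the preceding supported
#' k-mer (with the site probed a few bases either way, see
#' `anchorBacktrack`), and each candidate is scored by the fraction of the
#' next `verifyWindow` k-mer windows present in the filter. Acceptance of
#' a candidate requires all of: the anchor window (verified left context
#' plus the first edited base) present in the filter — and, when the read
#' set supports it, present in the filters of both read halves (the
#' two-read quorum, see [buildFilters()]); support at the scan anchor
#' strictly above the unedited support; and junction-anchored support —
#' windows spanning the candidate's rightmost edited base plus downstream
#' context — strictly above `acceptFraction`.
#'
#' `verifyWindow` and `acceptFraction` trade error-crowding tolerance
#' against chance acceptance: a correct edit can only be verified over
#' windows not corrupted by the *next* draft error, so small values
#' tolerate dense errors, while the anchor/quorum gates carry the burden
#' of rejecting unsupported edits (a chance acceptance needs the anchor
#' window false-positive in up to three filters at once, well below
#' `1e-4` per candidate at the default 1% filter false-positive rate).
#' The defaults (6 windows, 0.3) accept a correct edit with as little as
#' 2 of 6 clean downstream windows, i.e. with a following draft error as
#' close as ~2 bp beyond the verified junction.
#'
#' @param kValues K-mer sizes, strictly descending, each in 2..32
#'   (default `c(32, 28, 24, 20)`).
#' @param verifyWindow Number of consecutive k-mer windows scored per
#'   candidate edit; 0 means "use k" (default 6).
#' @param acceptFraction Minimum fraction of scored junction windows that
#'   must be present, in (0, 1] (default 0.3).
#' @param maxIndel Maximum insertion/deletion length attempted per site,
#'   bp (default 5).
#' @param maxSubRun Maximum length of a greedily extended substitution run
#'   in bp (default 16). Clustered substitution errors are rewritten as one
#'   run: substitutions cannot shift the reading frame, so a long run is
#'   still verified end-to-end by the junction windows.
#' @param roundsPerK Scan passes per k-mer size (default 1).
#' @param anchorBacktrack How many bases the edit site may slide backwards
#'   at the start of an absent-window run when the implied site yields no
#'   edit (default 4). Junction windows can be masked as falsely present
#'   — by Bloom false positives or by singleton k-mers from a read's own
#'   sequencing error — which pushes the first absent window past the
#'   true error site; backtracking recovers those sites.
#' @return A [PolishParams] object.
#' @export
polishParams <- function(kValues = c(32L, 28L, 24L, 20L),
                         verifyWindow = 6L, acceptFraction = 0.3,
                         maxIndel = 5L, maxSubRun = 16L, roundsPerK = 1L,
                         anchorBacktrack = 4L) {
    methods::new("PolishParams", kValues = as.integer(kValues),
                 verifyWindow = as.integer(verifyWindow),
                 acceptFraction = as.numeric(acceptFraction),
                 maxIndel = as.integer(maxIndel),
                 maxSubRun = as.integer(maxSubRun),
                 roundsPerK = as.integer(roundsPerK),
                 anchorBacktrack = as.integer(anchorBacktrack))
}

.resolve_filter <- function(filters, k) {
    if (methods::is(filters, "BloomFilterSet")) filterFor(filters, k)
    else filters
}

#' K-mer support of a position
#'
#' Fraction of the `min(j, available)` k-mer windows starting at `pos`,
#' `pos + 1`, ... that are present in the filter; windows containing
#' non-ACGT characters count as absent. This is the verification statistic
#' behind edit acceptance.
#'
#' @param seq Character scalar.
#' @param pos 0-based window start.
#' @param filters A [BloomFilterSet] or a single [BloomFilter].
#' @param k K-mer size (selects the filter when a set is given).
#' @param j Number of windows to score (default: `k`).
#' @return A fraction in `[0, 1]`.
#' @export
kmerSupport <- function(seq, pos, filters, k, j = k) {
    bf <- .resolve_filter(filters, k)
    .kmer_support(.as_seq_scalar(seq), pos, bf@ptr, as.integer(j))
}

#' Search for the best supported edit at a site
#'
#' Given a position `pos` whose k-mer is absent from the filter, enumerates
#' candidate edits at the first base not covered by the preceding
#' supported k-mer (`pos + k - 1`): the 3 substitutions, deletions of
#' 1..`maxIndel` bases, and insertions of 1..`maxIndel` bases (bases
#' beyond the first chosen greedily by k-mer support). Returns the
#' candidate whose support strictly exceeds both the unedited support and
#' `acceptFraction`, ties broken substitution > deletion > insertion, then
#' lexicographic base order.
#'
#' @inheritParams kmerSupport
#' @param params A [PolishParams].
#' @param backtrack How many bases the edit site may slide backwards when
#'   the implied site yields no edit (the scan uses this at absent-run
#'   starts, where falsely present junction windows — Bloom false
#'   positives or singleton read-error k-mers — can shift the first
#'   absent window past the true site). Default 0: edit only at
#'   `pos + k - 1`.
#' @return A list (`type`, `site`, `from`, `to`, `support`) or `NULL`
#'   when no acceptable edit exists.
#' @export
tryEditAt <- function(seq, pos, filters, k, params = polishParams(),
                      backtrack = 0L) {
    bf <- .resolve_filter(filters, k)
    j <- if (params@verifyWindow == 0L) as.integer(k)
         else params@verifyWindow
    res <- .try_edit_at(.as_seq_scalar(seq), pos, bf@ptr, j,
                        params@acceptFraction, params@maxIndel,
                        params@maxSubRun, as.integer(backtrack))
    if (!length(res)) NULL else res
}

.empty_edit_log <- function() {
    data.frame(target = character(), k = integer(), pos = numeric(),
               type = character(), from = character(), to = character(),
               support = numeric(), stringsAsFactors = FALSE)
}

#' Polish one target sequence against its Bloom filters
#'
#' Scans the sequence left to right once per k-mer size (largest first,
#' `roundsPerK` passes each). Wherever the current canonical k-mer is
#' absent from that k's filter an edit is attempted with [tryEditAt()]; an
#' accepted edit is applied and scanning resumes `k - 1` bases before the
#' edit site so the new junction k-mers are themselves verified. Edits are
#' permitted anywhere in the target, including the flanks (flank k-mers
#' are read-supported, and the per-edit log makes flank edits auditable).
#' Targets shorter than a given k skip that k; targets shorter than
#' `min(kValues)` are returned unchanged. The engine contains no
#' randomness: identical inputs give byte-identical outputs.
#'
#' @param target Target sequence (character scalar or
#'   [Biostrings::BString]); lowercase is read fine (matching is
#'   case-insensitive) but edited bases are written uppercase.
#' @param filters The target's [BloomFilterSet]; must cover every k in
#'   `params@kValues`.
#' @param params A [PolishParams].
#' @param name Target name recorded in the outcome (defaults to the
#'   filter set's target name).
#' @param editLog Keep a per-edit log (`k`, position, type, from, to,
#'   support)?
#' @return A list with `name`, `sequence` (polished), `nSubs`, `nIns`,
#'   `nDel`, `nSitesVisited` and (when `editLog`) `editLog`.
#' @export
polishTarget <- function(target, filters, params = polishParams(),
                         name = NULL, editLog = FALSE) {
    seq <- .as_seq_scalar(target)
    if (is.null(name)) name <- filters@targetName
    ptrs <- lapply(params@kValues, function(k)
        .resolve_filter(filters, k)@ptr)
    half_ptrs <- function(slot) {
        if (!methods::is(filters, "BloomFilterSet")) return(list())
        fl <- methods::slot(filters, slot)
        if (length(fl) != length(filters@kValues)) return(list())
        lapply(params@kValues, function(k) {
            i <- match(as.integer(k), filters@kValues)
            if (is.na(i)) stop("no filter for k=", k)
            fl[[i]]@ptr
        })
    }
    res <- .polish_seq(seq, ptrs, half_ptrs("filtersA"),
                       half_ptrs("filtersB"), params@kValues,
                       params@verifyWindow, params@acceptFraction,
                       params@maxIndel, params@maxSubRun,
                       params@roundsPerK, params@anchorBacktrack,
                       isTRUE(editLog))
    out <- list(name = name, sequence = res$sequence, nSubs = res$n_subs,
                nIns = res$n_ins, nDel = res$n_del,
                nSitesVisited = res$n_sites_visited)
    if (isTRUE(editLog)) {
        lg <- res$log
        out$editLog <- if (length(lg$k)) {
            data.frame(target = name, k = lg$k, pos = lg$pos,
                       type = lg$type, from = lg$from, to = lg$to,
                       support = lg$support, stringsAsFactors = FALSE)
        } else .empty_edit_log()
    }
    out
}

#' Polish every target of a TargetSet
#'
#' Groups lifted PAF records by target, gathers the full sequence of every
#' read assigned to each target, builds that target's per-k Bloom filters
#' and polishes each target independently. Targets are processed in
#' `TargetSet` order, but outcomes are independent of processing order and
#' of `threads` (the engine is deterministic and serial per target).
#' Targets with no lifted reads are returned unchanged with zero counts.
#'
#' @param targets A [TargetSet].
#' @param lifted Lifted PAF `data.frame` from [liftPaf()]; `tname` must
#'   only reference targets present in `targets`.
#' @param reads Named [Biostrings::BStringSet] (or character vector) of
#'   read sequences covering every `qname` in `lifted`.
#' @param params A [PolishParams].
#' @param bloomFpr Per-filter false-positive rate (default 0.01).
#' @param editLog Keep per-edit logs?
#' @return A list with `seqs` (named `BStringSet` of polished targets, in
#'   target order), `stats` (per-target `data.frame`: `name`, `nReads`,
#'   `nSubs`, `nIns`, `nDel`, `nSitesVisited`) and `editLog` (combined
#'   `data.frame`, empty unless requested).
#' @export
polishAll <- function(targets, lifted, reads, params = polishParams(),
                      bloomFpr = 0.01, editLog = FALSE) {
    nms <- targetNames(targets)
    if (!length(nms))
        return(list(seqs = Biostrings::BStringSet(),
                    stats = data.frame(name = character(),
                                       nReads = integer(),
                                       nSubs = numeric(), nIns = numeric(),
                                       nDel = numeric(),
                                       nSitesVisited = numeric(),
                                       stringsAsFactors = FALSE),
                    editLog = .empty_edit_log()))
    unknown <- setdiff(unique(lifted$tname), nms)
    if (length(unknown))
        stop("lifted PAF references unknown target '", unknown[1], "'")
    if (is.character(reads)) reads <- Biostrings::BStringSet(reads)
    missing_reads <- setdiff(unique(lifted$qname), names(reads))
    if (length(missing_reads))
        stop("read '", missing_reads[1],
             "' referenced by the PAF is absent from the read set")

    by_target <- split(lifted$qname, lifted$tname)
    seqs <- character(length(nms))
    stats <- vector("list", length(nms))
    logs <- vector("list", length(nms))
    tseqs <- targetSeqs(targets)
    for (i in seq_along(nms)) {
        nm <- nms[i]
        qn <- unique(by_target[[nm]])
        rs <- if (length(qn)) as.character(reads[qn]) else character()
        filters <- buildFilters(rs, kValues = params@kValues,
                                fpr = bloomFpr, targetName = nm)
        res <- polishTarget(as.character(tseqs[[i]]), filters, params,
                            name = nm, editLog = editLog)
        seqs[i] <- res$sequence
        stats[[i]] <- data.frame(name = nm, nReads = length(qn),
                                 nSubs = res$nSubs, nIns = res$nIns,
                                 nDel = res$nDel,
                                 nSitesVisited = res$nSitesVisited,
                                 stringsAsFactors = FALSE)
        logs[[i]] <- if (editLog) res$editLog else NULL
    }
    out_seqs <- Biostrings::BStringSet(seqs)
    names(out_seqs) <- nms
    list(seqs = out_seqs, stats = do.call(rbind, c(stats, list(
             make.row.names = FALSE))),
         editLog = if (editLog && length(logs))
             do.call(rbind, c(logs, list(make.row.names = FALSE)))
         else .empty_edit_log())
}
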