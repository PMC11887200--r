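#' Size a Bloom filter for a target false-positive rate
#'
#' Standard sizing: `m = ceiling(-n * ln(p) / ln(2)^2)` bits and
#' `h = max(1, round((m / n) * ln(2)))` hash functions for `n` expected
#' insertions at false-positive rate `p`.
#'
#' @param nExpected Expected number of inserted k-mers (`>= 1`).
#' @param fpr Target false-positive rate in (0, 1).
#' @return A list with elements `m` (bits) and `h` (hash functions).
#' @examples
#' sizeBloom(1000, 0.01)   # m = 9586, h = 7
#' @export
sizeBloom <- function(nExpected, fpr) {
    if (nExpected < 1) stop("nExpected must be >= 1")
    if (!is.finite(fpr) || fpr <= 0 || fpr >= 1)
        stop("fpr must be in (0, 1)")
    m <- ceiling(-nExpected * log(fpr) / log(2)^2)
    h <- max(1, round(m / nExpected * log(2)))
    list(m = m, h = as.integer(h))
}

#' Canonical k-mer of a sequence window
#'
#' The lexicographic minimum of the k-mer starting at `pos` (0-based) and
#' its reverse complement, uppercased. Returns `NA` when the window
#' contains a non-ACGT character.
#'
#' @param seq Character scalar.
#' @param pos 0-based window start, `0 <= pos <= nchar(seq) - k`.
#' @param k K-mer size (2..32).
#' @return Character scalar or `NA`.
#' @examples
#' canonicalKmer("TTTT", 0, 4)   # "AAAA"
#' @export
canonicalKmer <- function(seq, pos, k) {
    stopifnot(length(seq) == 1L, pos >= 0, pos <= nchar(seq) - k)
    .canonical_kmers(substr(seq, pos + 1L, pos + k), as.integer(k))[1]
}

#' @rdname canonicalKmer
#' @return `canonicalKmers()`: vector of the canonical k-mers of every
#'   window of `seq` (NA for invalid windows).
#' @export
canonicalKmers <- function(seq, k) {
    .canonical_kmers(.as_seq_scalar(seq), as.integer(k))
}

#' Create an empty Bloom filter
#'
#' @param nExpected Sizing capacity: expected number of insertions.
#' @param fpr Target false-positive rate at that capacity.
#' @param k K-mer size (2..32); keys are canonical k-mers.
#' @return A [BloomFilter].
#' @export
bloomFilter <- function(nExpected, fpr = 0.01, k = 32L) {
    sz <- sizeBloom(nExpected, fpr)
    methods::new("BloomFilter", ptr = .bloom_create(sz$m, sz$h,
                                                    as.integer(k)),
                 k = as.integer(k), m = sz$m, h = sz$h)
}

#' Insert and query canonical k-mers
#'
#' `bloomInsertSeq()` inserts every canonical k-mer of every sequence
#' (windows containing non-ACGT characters are skipped);
#' `bloomInsertKmers()` inserts exact k-mer strings (canonicalised first).
#' `bloomQuery()` tests membership of k-mer strings and
#' `bloomPresence()` returns per-window membership along a sequence, with
#' invalid windows reported absent. Inserted k-mers always query `TRUE`
#' (no false negatives).
#'
#' @param bf A [BloomFilter].
#' @param seqs Character vector of sequences.
#' @return `bloomInsertSeq()`/`bloomInsertKmers()`: the number of
#'   insertions, invisibly.
#' @export
bloomInsertSeq <- function(bf, seqs) {
    invisible(.bloom_insert_seqs(bf@ptr, as.character(seqs)))
}

#' @rdname bloomInsertSeq
#' @param kmers Character vector of k-mers, each of length `k`.
#' @export
bloomInsertKmers <- function(bf, kmers) {
    invisible(.bloom_insert_kmers(bf@ptr, as.character(kmers)))
}

#' @rdname bloomInsertSeq
#' @return `bloomQuery()`: logical vector, one element per k-mer.
#' @export
bloomQuery <- function(bf, kmers) {
    .bloom_query_kmers(bf@ptr, as.character(kmers))
}

#' @rdname bloomInsertSeq
#' @param seq Character scalar.
#' @return `bloomPresence()`: logical vector over the
#'   `nchar(seq) - k + 1` windows of `seq`.
#' @export
bloomPresence <- function(bf, seq) {
    .bloom_presence(bf@ptr, .as_seq_scalar(seq))
}

#' @rdname bloomInsertSeq
#' @return `bloomInfo()`: list with `m`, `h`, `k` and `n_inserted`.
#' @export
bloomInfo <- function(bf) .bloom_params(bf@ptr)

#' Build per-target Bloom filters from assigned reads
#'
#' For each k-mer size, one filter is sized from the exact total k-mer
#' count of the supplied reads (targets are small, so exact counting is
#' cheap) and populated with every canonical k-mer of every read. Reads
#' shorter than a given k simply contribute no k-mers at that size. With
#' zero reads all filters are empty and every query is `FALSE`.
#' Canonicalisation makes polishing strand-agnostic, so mapping strand is
#' never consulted here.
#'
#' @param readSeqs Character vector (or `BStringSet`) of the read
#'   sequences assigned to the target.
#' @param kValues K-mer sizes, strictly descending (default
#'   `c(32, 28, 24, 20)`).
#' @param fpr Target false-positive rate per filter (default 0.01).
#' @param targetName Name of the target the filters belong to.
#' @return A [BloomFilterSet].
#' @export
buildFilters <- function(readSeqs, kValues = c(32L, 28L, 24L, 20L),
                         fpr = 0.01, targetName = "") {
    kValues <- as.integer(kValues)
    if (!length(kValues)) stop("kValues must be non-empty")
    if (length(kValues) > 1 && is.unsorted(rev(kValues), strictly = TRUE))
        stop("kValues must be strictly descending")
    seqs <- as.character(readSeqs)
    # two deterministic read halves back the polisher's two-read quorum
    ia <- seq_along(seqs) %% 2L == 1L
    halves <- list(seqs[ia], seqs[!ia])
    filters <- vector("list", length(kValues))
    fA <- vector("list", length(kValues))
    fB <- vector("list", length(kValues))
    nk <- numeric(length(kValues))
    mk_filter <- function(ss, k) {
        n <- .count_kmers(ss, k)
        bf <- bloomFilter(max(1, n), fpr = fpr, k = k)
        if (n > 0) bloomInsertSeq(bf, ss)
        bf
    }
    for (i in seq_along(kValues)) {
        k <- kValues[i]
        nk[i] <- .count_kmers(seqs, k)
        filters[[i]] <- mk_filter(seqs, k)
        fA[[i]] <- mk_filter(halves[[1]], k)
        fB[[i]] <- mk_filter(halves[[2]], k)
    }
    methods::new("BloomFilterSet", targetName = as.character(targetName),
                 kValues = kValues, fpr = fpr, filters = filters,
                 filtersA = fA, filtersB = fB, nKmers = nk)
}

#' Extract the filter for one k-mer size
#'
#' @param filters A [BloomFilterSet].
#' @param k K-mer size; must be one of the set's `kValues`.
#' @return The [BloomFilter] for `k`.
#' @export
filterFor <- function(filters, k) {
    i <- match(as.integer(k), filters@kValues)
    if (is.na(i))
        stop("no filter for k=", k, " (available: ",
             paste(filters@kValues, collapse = ", "), ")")
    filters@filters[[i]]
}
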