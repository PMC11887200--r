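# shared helpers: tiny deterministic sequences and brute-force oracles

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                              collapse = "")

# random soft-mask over a sequence: lowercases each base independently
rand_masked_seq <- function(n, p_lower = 0.3) {
    chars <- sample(BASES, n, replace = TRUE)
    low <- runif(n) < p_lower
    chars[low] <- tolower(chars[low])
    paste(chars, collapse = "")
}

# brute-force per-base oracle for soft-masked runs
oracle_runs <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    low <- chars %in% c("a", "c", "g", "t", "n")
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep] - 1L, end = ends[keep])
}

# brute-force per-base oracle for flank extension + merging
oracle_expand_merge <- function(intervals, flank, contig_len) {
    covered <- logical(contig_len)
    for (i in seq_len(nrow(intervals))) {
        a <- max(0L, intervals$start[i] - flank)
        b <- min(contig_len, intervals$end[i] + flank)
        if (b > a) covered[(a + 1L):b] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep] - 1L, end = ends[keep])
}

revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# all canonical k-mers of a sequence by direct string manipulation
oracle_canonical <- function(seq, k) {
    n <- nchar(seq)
    if (n < k) return(character())
    vapply(seq_len(n - k + 1), function(i) {
        w <- toupper(substr(seq, i, i + k - 1))
        if (grepl("[^ACGT]", w)) return(NA_character_)
        rc <- revcomp(w)
        if (w <= rc) w else rc
    }, character(1))
}

small_fixture_config <- function(seed = 7L)
    fixtureConfig(genomeLen = 20000, nContigs = 1L, nWindows = 2L,
                  windowLen = 500L, seed = seed)
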