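#' Configure the synthetic study system
#'
#' The fixture emulates the situation the polisher is built for: a draft
#' assembly that is correct except in a handful of soft-masked windows
#' where raw, unpolished bases carry concentrated substitution and indel
#' errors, plus long reads sampled from the underlying truth genome. The
#' defaults describe the standard study conditions used throughout the
#' package tests: a 200 kb genome in 2 contigs, 10 lowercase windows of
#' 2 kb carrying 2% substitutions and 0.5% indels, and 30x reads of mean
#' length 10 kb with 1% sequencing error.
#'
#' All randomness is R's Mersenne-Twister; each generator stage seeds it
#' explicitly from `seed` (truth: `seed`; draft: `seed + 1`; reads:
#' `seed + 2`), so results are fully reproducible from the configuration
#' alone.
#'
#' @param genomeLen Total genome length in bp.
#' @param nContigs Number of contigs (lengths split evenly).
#' @param nWindows Number of soft-masked error windows (distributed over
#'   contigs round-robin).
#' @param windowLen Window length in bp.
#' @param subRate Per-base substitution rate inside windows.
#' @param indelRate Per-base indel rate inside windows (half 1-bp
#'   insertions, half 1-bp deletions).
#' @param readLenMean Mean read length in bp (lognormal, sdlog 0.25).
#' @param coverage Expected read depth.
#' @param readErrorRate Per-base read error rate (3/4 substitutions,
#'   1/8 insertions, 1/8 deletions).
#' @param seed Base seed.
#' @return A [FixtureConfig].
#' @export
fixtureConfig <- function(genomeLen = 200000, nContigs = 2L,
                          nWindows = 10L, windowLen = 2000L,
                          subRate = 0.02, indelRate = 0.005,
                          readLenMean = 10000L, coverage = 30,
                          readErrorRate = 0.01, seed = 42L) {
    methods::new("FixtureConfig", genomeLen = as.numeric(genomeLen),
                 nContigs = as.integer(nContigs),
                 nWindows = as.integer(nWindows),
                 windowLen = as.integer(windowLen),
                 subRate = as.numeric(subRate),
                 indelRate = as.numeric(indelRate),
                 readLenMean = as.integer(readLenMean),
                 coverage = as.numeric(coverage),
                 readErrorRate = as.numeric(readErrorRate),
                 seed = as.integer(seed))
}

.BASES <- c("A", "C", "G", "T")

.random_seq <- function(n) {
    paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

#' Generate the truth genome
#'
#' Uniform-random ACGT contigs, deterministic for a fixed seed.
#'
#' @param config A [FixtureConfig].
#' @return A named [Biostrings::BStringSet] (`ctg1`, `ctg2`, ...).
#' @export
makeTruth <- function(config) {
    set.seed(config@seed)
    n <- config@nContigs
    lens <- rep(floor(config@genomeLen / n), n)
    lens[n] <- config@genomeLen - sum(lens[-n])
    seqs <- vapply(lens, .random_seq, character(1))
    x <- Biostrings::BStringSet(seqs)
    names(x) <- sprintf("ctg%d", seq_len(n))
    x
}

# Inject per-base errors into a character vector of bases; returns the
# mutated pieces plus an event table (0-based offsets into the input).
# Insertion events place a base *before* the recorded position.
.inject_errors <- function(chars, subRate, insRate, delRate) {
    n <- length(chars)
    u <- runif(n)
    is_sub <- u < subRate
    is_ins <- u >= subRate & u < subRate + insRate
    is_del <- u >= subRate + insRate & u < subRate + insRate + delRate
    pieces <- chars
    ev_pos <- integer(); ev_type <- character()
    ev_ref <- character(); ev_alt <- character()
    if (any(is_sub)) {
        i <- which(is_sub)
        code <- match(toupper(chars[i]), .BASES)  # 1..4
        shift <- sample.int(3L, length(i), replace = TRUE)
        alt <- .BASES[((code - 1L + shift) %% 4L) + 1L]
        pieces[i] <- alt
        ev_pos <- c(ev_pos, i - 1L); ev_type <- c(ev_type,
                                                  rep("sub", length(i)))
        ev_ref <- c(ev_ref, toupper(chars[i])); ev_alt <- c(ev_alt, alt)
    }
    if (any(is_ins)) {
        i <- which(is_ins)
        ins <- sample(.BASES, length(i), replace = TRUE)
        pieces[i] <- paste0(ins, pieces[i])
        ev_pos <- c(ev_pos, i - 1L); ev_type <- c(ev_type,
                                                  rep("ins", length(i)))
        ev_ref <- c(ev_ref, rep("", length(i))); ev_alt <- c(ev_alt, ins)
    }
    if (any(is_del)) {
        i <- which(is_del)
        pieces[i] <- ""
        ev_pos <- c(ev_pos, i - 1L); ev_type <- c(ev_type,
                                                  rep("del", length(i)))
        ev_ref <- c(ev_ref, toupper(chars[i]))
        ev_alt <- c(ev_alt, rep("", length(i)))
    }
    o <- order(ev_pos)
    list(seq = paste(pieces, collapse = ""),
         events = data.frame(pos = ev_pos[o], type = ev_type[o],
                             ref = ev_ref[o], alt = ev_alt[o],
                             stringsAsFactors = FALSE))
}

#' Derive the error-injected, soft-masked draft
#'
#' Picks non-overlapping windows on the truth contigs, injects
#' substitutions and 1-bp indels inside them at the configured rates,
#' renders the (post-injection) windows lowercase and leaves everything
#' else uppercase and error-free. The ledger records every injected event
#' in truth coordinates (0-based; insertions sit *before* the recorded
#' position), so `applyLedger(truth, ledger)` reproduces the draft
#' exactly up to case.
#'
#' @param truth Truth genome from [makeTruth()].
#' @param config A [FixtureConfig].
#' @return A list: `draft` (BStringSet), `ledger` (`data.frame`: `contig`,
#'   `pos`, `type`, `ref`, `alt`), `windows` (`data.frame` with truth and
#'   draft coordinates of each window, 0-based half-open).
#' @export
makeDraft <- function(truth, config) {
    set.seed(config@seed + 1L)
    margin <- 300L   # keep windows away from contig ends
    gap <- 200L      # minimum spacing so flank-extended targets stay apart
    n_ctg <- length(truth)
    wl <- config@windowLen
    # round-robin allocation of windows to contigs
    alloc <- tabulate(rep(seq_len(n_ctg),
                          length.out = config@nWindows), n_ctg)
    draft <- character(n_ctg)
    ledgers <- list(); windows <- list()
    for (ci in seq_len(n_ctg)) {
        ctg <- names(truth)[ci]
        s <- as.character(truth[[ci]])
        clen <- nchar(s)
        nw <- alloc[ci]
        if (nw == 0) { draft[ci] <- s; next }
        free <- clen - 2 * margin - nw * wl - (nw - 1) * gap
        if (free < 0)
            stop("windows do not fit on contig '", ctg, "'")
        jitter <- sort(floor(runif(nw, 0, free + 1)))
        starts <- margin + (seq_len(nw) - 1L) * (wl + gap) + jitter
        ends <- starts + wl

        out_pieces <- character(2 * nw + 1)
        prev <- 0L
        ctg_events <- list()
        dstarts <- integer(nw); dends <- integer(nw)
        delta <- 0L   # cumulative draft-minus-truth length offset
        for (w in seq_len(nw)) {
            out_pieces[2 * w - 1] <- substr(s, prev + 1L, starts[w])
            chars <- strsplit(substr(s, starts[w] + 1L, ends[w]),
                              "")[[1]]
            inj <- .inject_errors(chars, config@subRate,
                                  config@indelRate / 2,
                                  config@indelRate / 2)
            out_pieces[2 * w] <- tolower(inj$seq)
            if (nrow(inj$events)) {
                inj$events$pos <- inj$events$pos + starts[w]
                inj$events$contig <- ctg
                ctg_events[[w]] <- inj$events
            }
            dstarts[w] <- starts[w] + delta
            delta <- delta + (nchar(inj$seq) - wl)
            dends[w] <- ends[w] + delta
            prev <- ends[w]
        }
        out_pieces[2 * nw + 1] <- substr(s, prev + 1L, clen)
        draft[ci] <- paste(out_pieces, collapse = "")
        ledgers[[ci]] <- do.call(rbind, ctg_events)
        windows[[ci]] <- data.frame(contig = ctg, start = starts,
                                    end = ends, draftStart = dstarts,
                                    draftEnd = dends,
                                    stringsAsFactors = FALSE)
    }
    drafts <- Biostrings::BStringSet(draft)
    names(drafts) <- names(truth)
    ledger <- do.call(rbind, ledgers)
    if (is.null(ledger))
        ledger <- data.frame(pos = integer(), type = character(),
                             ref = character(), alt = character(),
                             contig = character(), stringsAsFactors = FALSE)
    ledger <- ledger[, c("contig", "pos", "type", "ref", "alt")]
    rownames(ledger) <- NULL
    win <- do.call(rbind, windows)
    if (is.null(win))
        win <- data.frame(contig = character(), start = integer(),
                          end = integer(), draftStart = integer(),
                          draftEnd = integer(), stringsAsFactors = FALSE)
    rownames(win) <- NULL
    list(draft = drafts, ledger = ledger, windows = win)
}

#' Replay an error ledger onto the truth genome
#'
#' Applies the recorded substitutions, insertions and deletions to the
#' truth sequence. `applyLedger(truth, ledger)` equals the draft of
#' [makeDraft()] up to case — the ledger-completeness contract of the
#' generator.
#'
#' @param truth Truth genome ([Biostrings::BStringSet]).
#' @param ledger Ledger `data.frame` from [makeDraft()].
#' @return A [Biostrings::BStringSet] (uppercase).
#' @export
applyLedger <- function(truth, ledger) {
    out <- character(length(truth))
    for (ci in seq_along(truth)) {
        ctg <- names(truth)[ci]
        s <- toupper(as.character(truth[[ci]]))
        ev <- ledger[ledger$contig == ctg, , drop = FALSE]
        if (!nrow(ev)) { out[ci] <- s; next }
        pieces <- strsplit(s, "")[[1]]
        for (r in seq_len(nrow(ev))) {
            p <- ev$pos[r] + 1L
            pieces[p] <- switch(ev$type[r],
                sub = ev$alt[r],
                del = "",
                ins = paste0(ev$alt[r], pieces[p]),
                stop("unknown ledger event type '", ev$type[r], "'"))
        }
        out[ci] <- paste(pieces, collapse = "")
    }
    res <- Biostrings::BStringSet(out)
    names(res) <- names(truth)
    res
}

#' Simulate long reads and their true mappings
#'
#' Reads are sampled uniformly from the truth genome with lognormal
#' lengths around `readLenMean`, random strand, and per-base errors at
#' `readErrorRate` (3/4 substitutions, 1/8 1-bp insertions, 1/8 1-bp
#' deletions). Alongside the reads a PAF of the true read origins is
#' emitted against *draft* coordinates (truth coordinates projected
#' through the ledger's indel offsets), directly consumable by
#' [liftPaf()] without running an external mapper.
#'
#' @param truth Truth genome.
#' @param draft,ledger Draft and ledger from [makeDraft()] (needed for the
#'   coordinate projection).
#' @param config A [FixtureConfig].
#' @return A list: `reads` (uppercase [Biostrings::BStringSet]) and `paf`
#'   (`data.frame` in [readPaf()] layout).
#' @export
makeReads <- function(truth, draft, ledger, config) {
    set.seed(config@seed + 2L)
    lens <- Biostrings::width(truth)
    genome_len <- sum(lens)
    n_reads <- max(1L, round(config@coverage * genome_len /
                             config@readLenMean))
    ctg_i <- sample.int(length(truth), n_reads, replace = TRUE,
                        prob = lens / genome_len)
    rl <- round(rlnorm(n_reads, log(config@readLenMean) - 0.25^2 / 2,
                       0.25))
    rl <- pmin(pmax(rl, 200L), lens[ctg_i])
    starts <- floor(runif(n_reads, 0, lens[ctg_i] - rl + 1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)

    # per-contig truth->draft coordinate projection from the ledger
    proj <- lapply(names(truth), function(ctg) {
        ev <- ledger[ledger$contig == ctg, , drop = FALSE]
        ev <- ev[ev$type != "sub", , drop = FALSE]
        if (!nrow(ev))
            return(function(p) p)
        ev <- ev[order(ev$pos), , drop = FALSE]
        shift <- ifelse(ev$type == "ins", nchar(ev$alt), -nchar(ev$ref))
        cum <- cumsum(shift)
        # insertions sit before their position: they shift p >= pos;
        # deletions remove base pos: they shift p > pos
        at <- ev$pos + ifelse(ev$type == "ins", -0.5, 0.5)
        function(p) p + c(0, cum)[findInterval(p, at) + 1L]
    })
    names(proj) <- names(truth)
    dlens <- stats::setNames(Biostrings::width(draft), names(draft))

    seqs <- character(n_reads)
    dstart <- numeric(n_reads); dend <- numeric(n_reads)
    err <- config@readErrorRate
    for (i in seq_len(n_reads)) {
        ctg <- names(truth)[ctg_i[i]]
        sub <- substr(as.character(truth[[ctg_i[i]]]), starts[i] + 1L,
                      starts[i] + rl[i])
        if (err > 0) {
            inj <- .inject_errors(strsplit(sub, "")[[1]],
                                  err * 3 / 4, err / 8, err / 8)
            sub <- inj$seq
        }
        if (strand[i] == "-")
            sub <- as.character(
                Biostrings::reverseComplement(Biostrings::DNAString(sub)))
        seqs[i] <- sub
        p <- proj[[ctg]]
        dstart[i] <- max(0, p(starts[i]))
        dend[i] <- min(dlens[[ctg]], p(starts[i] + rl[i]))
        if (dend[i] <= dstart[i]) dend[i] <- dstart[i] + 1
    }
    reads <- Biostrings::BStringSet(seqs)
    names(reads) <- sprintf("read%05d", seq_len(n_reads))
    qlen <- nchar(seqs)
    paf <- data.frame(
        qname = names(reads), qlen = qlen, qstart = 0, qend = qlen,
        strand = strand, tname = names(truth)[ctg_i],
        tlen = as.numeric(dlens[names(truth)[ctg_i]]),
        tstart = dstart, tend = dend,
        nmatch = pmax(1, round((1 - err) * pmin(qlen, dend - dstart))),
        blocklen = pmax(qlen, dend - dstart), mapq = 60L, tags = "",
        stringsAsFactors = FALSE)
    .validate_paf(paf)
    list(reads = reads, paf = paf)
}

#' Generate the full fixture
#'
#' Runs [makeTruth()], [makeDraft()] and [makeReads()] and, optionally,
#' writes everything to a directory as plain files (`truth.fa`,
#' `draft.fa`, `reads.fq`, `reads.paf`, `ledger.tsv`, `windows.tsv`),
#' directly consumable by [runPipeline()].
#'
#' @param config A [FixtureConfig].
#' @param dir Optional output directory (created if needed).
#' @return A list: `truth`, `draft`, `ledger`, `windows`, `reads`, `paf`,
#'   `config`, plus `paths` when `dir` is given.
#' @export
simulateFixture <- function(config = fixtureConfig(), dir = NULL) {
    truth <- makeTruth(config)
    d <- makeDraft(truth, config)
    r <- makeReads(truth, d$draft, d$ledger, config)
    out <- list(truth = truth, draft = d$draft, ledger = d$ledger,
                windows = d$windows, reads = r$reads, paf = r$paf,
                config = config)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        paths <- list(truth = file.path(dir, "truth.fa"),
                      draft = file.path(dir, "draft.fa"),
                      reads = file.path(dir, "reads.fq"),
                      paf = file.path(dir, "reads.paf"),
                      ledger = file.path(dir, "ledger.tsv"),
                      windows = file.path(dir, "windows.tsv"))
        writeFasta(truth, paths$truth)
        writeFasta(d$draft, paths$draft)
        .write_fastq(r$reads, paths$reads)
        writePaf(r$paf, paths$paf)
        write.table(d$ledger, paths$ledger, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write.table(d$windows, paths$windows, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        out$paths <- paths
    }
    out
}

.write_fastq <- function(reads, path) {
    seqs <- as.character(reads)
    lines <- character(4 * length(seqs))
    lines[seq(1, by = 4, length.out = length(seqs))] <-
        paste0("@", names(reads))
    lines[seq(2, by = 4, length.out = length(seqs))] <- seqs
    lines[seq(3, by = 4, length.out = length(seqs))] <- "+"
    lines[seq(4, by = 4, length.out = length(seqs))] <-
        strrep("I", nchar(seqs))
    writeLines(lines, path)
    invisible(path)
}
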