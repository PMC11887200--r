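.FASTA_ALPHABET <- c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")

# Split FASTA headers into name (first whitespace-delimited token) and
# description (remainder); attach description as metadata.
.split_headers <- function(x, path) {
    headers <- names(x)
    if (is.null(headers) || any(!nzchar(headers)))
        stop("FASTA format error in '", path, "': record with empty header")
    nm <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    dup <- nm[duplicated(nm)]
    if (length(dup))
        stop("FASTA format error in '", path, "': duplicate record name '",
             dup[1], "'")
    names(x) <- nm
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(description = desc)
    x
}

.check_alphabet <- function(x, path) {
    bad <- setdiff(Biostrings::uniqueLetters(x), .FASTA_ALPHABET)
    if (length(bad)) {
        # locate the first offender for the error message
        pat <- paste0("[", paste(gsub("([\\^\\]\\\\-])", "\\\\\\1", bad),
                                 collapse = ""), "]")
        for (i in seq_along(x)) {
            pos <- regexpr(pat, as.character(x[[i]]))
            if (pos > 0)
                stop("FASTA format error in '", path, "': illegal character '",
                     substr(as.character(x[[i]]), pos, pos), "' in record '",
                     names(x)[i], "' at position ", pos)
        }
    }
    invisible(x)
}

#' Read a FASTA file, preserving base case
#'
#' Reads plain or gzipped FASTA (compression detected from the file
#' content, not the extension). Multi-line sequences are concatenated and
#' lower/upper case is preserved exactly, which matters because soft-masked
#' (lowercase) bases mark the polishing targets.
#'
#' @param path Path to a FASTA file, optionally gzip-compressed.
#' @return A named [Biostrings::BStringSet]; names are the first
#'   whitespace-delimited header tokens, with the remainder of each header
#'   kept in the `description` metadata column. Errors on empty files,
#'   duplicate record names, empty sequences and characters outside
#'   `ACGTNacgtn`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 a demo contig", "AAAA", "acgt"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("file not found: '", path, "'")
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0)
        stop("FASTA format error in '", path, "': no records")
    if (any(Biostrings::width(x) == 0)) {
        bad <- names(x)[Biostrings::width(x) == 0][1]
        stop("FASTA format error in '", path, "': empty sequence for '",
             bad, "'")
    }
    x <- .split_headers(x, path)
    .check_alphabet(x, path)
    x
}

#' Read long reads from FASTA or FASTQ
#'
#' Format is auto-detected from the first byte (`>` FASTA, `@` FASTQ);
#' gzip is detected from the file content. Base qualities are discarded
#' (the polisher never uses them) and sequences are folded to uppercase:
#' only the draft assembly's case carries meaning.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzipped.
#' @return A named uppercase [Biostrings::BStringSet].
#' @export
readReads <- function(path) {
    if (!file.exists(path)) stop("file not found: '", path, "'")
    con <- gzfile(path, "rb")
    first <- readChar(con, 1L, useBytes = TRUE)
    close(con)
    fmt <- if (identical(first, "@")) "fastq" else "fasta"
    x <- Biostrings::readBStringSet(path, format = fmt)
    if (length(x) == 0) stop("no reads in '", path, "'")
    x <- .split_headers(x, path)
    .check_alphabet(x, path)
    seqs <- Biostrings::BStringSet(toupper(as.character(x)))
    names(seqs) <- names(x)
    seqs
}

#' Write sequences to FASTA
#'
#' The inverse of [readFasta()]: `readFasta(writeFasta(x))` reproduces `x`
#' exactly, including base case and header descriptions.
#'
#' @param x A [Biostrings::BStringSet] (or named character vector).
#' @param path Output path.
#' @param lineWidth Sequence line width, `>= 1` (default 60).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, lineWidth = 60L) {
    if (lineWidth < 1L) stop("lineWidth must be >= 1")
    if (is.character(x)) x <- Biostrings::BStringSet(x)
    desc <- S4Vectors::mcols(x)$description
    if (!is.null(desc) && any(nzchar(desc))) {
        full <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
        names(x) <- full
    }
    Biostrings::writeXStringSet(x, path, width = as.integer(lineWidth))
    invisible(path)
}

#' Read a BED file of target intervals
#'
#' Accepts 3+ tab-separated columns; columns beyond the third are ignored.
#' Lines that are empty or begin with `#`, `track` or `browser` are
#' skipped. Coordinates are 0-based, half-open, as in the BED standard.
#'
#' @param path Path to a BED file.
#' @return A `data.frame` with columns `contig`, `start`, `end`.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("file not found: '", path, "'")
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) &
        !grepl("^(#|track\\b|browser\\b)", lines)
    lines <- lines[keep]
    lnum <- which(keep)
    if (!length(lines))
        return(data.frame(contig = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(parts)
    if (any(ncols < 3))
        stop("BED format error at line ", lnum[which(ncols < 3)[1]],
             ": fewer than 3 columns")
    contig <- vapply(parts, `[[`, character(1), 1L)
    start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1),
                                                2L)))
    end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1),
                                              3L)))
    if (anyNA(start) || anyNA(end))
        stop("BED format error at line ",
             lnum[which(is.na(start) | is.na(end))[1]],
             ": non-integer coordinate")
    if (any(start < 0))
        stop("BED format error at line ", lnum[which(start < 0)[1]],
             ": negative start")
    if (any(start >= end))
        stop("BED format error at line ", lnum[which(start >= end)[1]],
             ": start >= end")
    data.frame(contig = contig, start = start, end = end,
               stringsAsFactors = FALSE)
}

.PAF_COLS <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
               "tstart", "tend", "nmatch", "blocklen", "mapq", "tags")

# Validate the PAF coordinate/count invariants on a parsed table; `where`
# labels error messages (e.g. source line numbers).
.validate_paf <- function(paf, where = seq_len(nrow(paf))) {
    bad <- function(cond, what) {
        i <- which(cond)
        if (length(i))
            stop("PAF validation error (record ", where[i[1]], "): ", what)
    }
    bad(!(paf$strand %in% c("+", "-")), "strand must be '+' or '-'")
    bad(paf$qstart < 0 | paf$qstart >= paf$qend | paf$qend > paf$qlen,
        "query coordinates violate 0 <= start < end <= length")
    bad(paf$tstart < 0 | paf$tstart >= paf$tend | paf$tend > paf$tlen,
        "target coordinates violate 0 <= start < end <= length")
    bad(paf$nmatch < 0 | paf$blocklen < paf$nmatch,
        "block_len >= n_matches >= 0 violated")
    bad(paf$mapq < 0 | paf$mapq > 255, "mapq outside 0..255")
    invisible(paf)
}

#' Read a PAF mapping file
#'
#' Parses the 12 mandatory tab-separated PAF columns; any columns beyond
#' the twelfth are carried opaquely in a single `tags` string. Every record
#' is validated (coordinate ordering, `block_len >= n_matches >= 0`, mapq
#' range); malformed lines raise an error naming the line.
#'
#' @param path Path to a PAF file, optionally gzipped.
#' @return A `data.frame` with columns `qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, nmatch, blocklen, mapq, tags`. Coordinates
#'   are 0-based half-open as in PAF itself.
#' @export
readPaf <- function(path) {
    if (!file.exists(path)) stop("file not found: '", path, "'")
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(stats::setNames(
            data.frame(character(), numeric(), numeric(), numeric(),
                       character(), character(), numeric(), numeric(),
                       numeric(), numeric(), numeric(), integer(),
                       character(), stringsAsFactors = FALSE), .PAF_COLS))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(parts)
    if (any(ncols < 12))
        stop("PAF format error at line ", which(ncols < 12)[1],
             ": fewer than 12 columns")
    col <- function(i) vapply(parts, `[[`, character(1), i)
    num <- function(i) {
        v <- suppressWarnings(as.numeric(col(i)))
        if (anyNA(v))
            stop("PAF format error at line ", which(is.na(v))[1],
                 ": non-numeric value in column ", i)
        v
    }
    paf <- data.frame(
        qname = col(1), qlen = num(2), qstart = num(3), qend = num(4),
        strand = col(5), tname = col(6), tlen = num(7), tstart = num(8),
        tend = num(9), nmatch = num(10), blocklen = num(11),
        mapq = as.integer(num(12)),
        tags = vapply(parts, function(p)
            if (length(p) > 12) paste(p[-(1:12)], collapse = "\t") else "",
            character(1)),
        stringsAsFactors = FALSE)
    .validate_paf(paf)
}

#' Write a PAF table
#'
#' @param paf A PAF `data.frame` as returned by [readPaf()] or [liftPaf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePaf <- function(paf, path) {
    core <- paf[, .PAF_COLS[1:12], drop = FALSE]
    for (j in seq_along(core))
        if (is.numeric(core[[j]])) core[[j]] <- format(core[[j]],
                                                       scientific = FALSE,
                                                       trim = TRUE)
    lines <- do.call(paste, c(unname(as.list(core)), sep = "\t"))
    has_tags <- !is.null(paf$tags) & nzchar(paf$tags %||% "")
    lines <- ifelse(has_tags, paste(lines, paf$tags, sep = "\t"), lines)
    writeLines(lines, path)
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
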