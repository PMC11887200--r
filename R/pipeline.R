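#' Polish a draft assembly in memory
#'
#' The end-to-end targeted polishing workflow on in-memory objects:
#' extract flank-extended targets (soft-mask- or BED-driven), lift the
#' read-to-assembly PAF into target coordinates, build per-target Bloom
#' filters, polish every target and splice the results back into the
#' assembly. With zero targets the input is returned unchanged with a
#' warning — an unmasked assembly is a valid input state, not an error.
#'
#' @param assembly Draft assembly ([Biostrings::BStringSet] or named
#'   character vector); lowercase marks unpolished sequence.
#' @param reads Named read sequences ([Biostrings::BStringSet]).
#' @param paf Read-to-assembly PAF `data.frame` ([readPaf()] layout).
#' @param bed Optional target `data.frame` ([readBed()] layout); when
#'   given, soft-mask scanning is skipped.
#' @param flank Flank length in bp (default 64).
#' @param params [PolishParams] for the edit engine.
#' @param bloomFpr Bloom filter false-positive rate (default 0.01).
#' @param minOverlap Minimum lifted overlap in bp (default 1).
#' @param keepCase Keep incoming case at reinsertion instead of
#'   uppercasing polished slices.
#' @param editLog Collect the per-edit log.
#' @param threads Accepted for interface compatibility; the engine is
#'   serial per target and deterministic, so results never depend on it.
#' @param quiet Suppress per-stage messages.
#' @return A list: `assembly` (polished `BStringSet`), `targets`
#'   ([TargetSet]), `lifted` (lifted PAF), `outcomes` ([polishAll()]
#'   result) and `report` (per-stage counts).
#' @export
polishAssembly <- function(assembly, reads, paf, bed = NULL, flank = 64L,
                           params = polishParams(), bloomFpr = 0.01,
                           minOverlap = 1L, keepCase = FALSE,
                           editLog = FALSE, threads = 1L, quiet = FALSE) {
    if (is.character(assembly)) assembly <- Biostrings::BStringSet(assembly)
    say <- function(...) if (!quiet) message(...)

    targets <- extractTargets(assembly, bed = bed, flank = flank)
    say("targets: ", length(targets), " region(s), ",
        sum(Biostrings::width(targetSeqs(targets))), " bp")
    if (length(targets) == 0) {
        warning("no target regions found; assembly returned unchanged")
        return(list(assembly = assembly, targets = targets,
                    lifted = paf[0, , drop = FALSE],
                    outcomes = NULL,
                    report = list(nTargets = 0L, nReadsLifted = 0L,
                                  nRecordsLifted = 0L, nDiscarded = nrow(paf),
                                  nSubs = 0, nIns = 0, nDel = 0,
                                  changed = FALSE)))
    }
    index <- buildTargetIndex(targets)
    lifted <- liftPaf(paf, index, minOverlap = minOverlap, quiet = quiet)
    outcomes <- polishAll(targets, lifted, reads, params = params,
                          bloomFpr = bloomFpr, editLog = editLog)
    tot <- colSums(outcomes$stats[, c("nSubs", "nIns", "nDel")])
    say("polish: ", tot[["nSubs"]], " substitutions, ", tot[["nIns"]],
        " insertions, ", tot[["nDel"]], " deletions")
    polished <- reinsert(assembly, outcomes$seqs,
                         uppercase = !isTRUE(keepCase))
    stats <- attr(lifted, "liftStats")
    list(assembly = polished, targets = targets, lifted = lifted,
         outcomes = outcomes,
         report = list(nTargets = length(targets),
                       nReadsLifted = length(unique(lifted$qname)),
                       nRecordsLifted = unname(stats[["lifted"]]),
                       nDiscarded = unname(stats[["discarded"]]),
                       nSubs = unname(tot[["nSubs"]]),
                       nIns = unname(tot[["nIns"]]),
                       nDel = unname(tot[["nDel"]]),
                       changed = tot[["nSubs"]] + tot[["nIns"]] +
                           tot[["nDel"]] > 0))
}

#' Run the targeted polishing pipeline on files
#'
#' File-level driver around [polishAssembly()]: reads the draft assembly,
#' reads and PAF (and optional BED), writes the intermediate targets
#' FASTA, lifted PAF and polished-targets FASTA next to the final
#' assembly, plus a machine-readable JSON run report.
#'
#' Output files are `<outPrefix>.targets.fa`, `<outPrefix>.lifted.paf`,
#' `<outPrefix>.polished_targets.fa`, `<outPrefix>.polished.fa`,
#' `<outPrefix>.report.json` and, when `editLog = TRUE`,
#' `<outPrefix>.edits.tsv`.
#'
#' @param assemblyFile Draft assembly FASTA (soft-masking significant).
#' @param readsFile Long reads, FASTA or FASTQ, optionally gzipped.
#' @param pafFile Read-to-assembly mappings in PAF. Produce them with any
#'   long-read mapper (minimap2 defaults work; so does ntLink `pair`
#'   output with its k=88 / w=1000 defaults), or use the fixture PAF from
#'   [simulateFixture()].
#' @param outPrefix Prefix for all output files.
#' @param bedFile Optional BED of target regions.
#' @param editLog Write the per-edit TSV log.
#' @inheritParams polishAssembly
#' @return The run report (list), invisibly.
#' @export
runPipeline <- function(assemblyFile, readsFile, pafFile, outPrefix,
                        bedFile = NULL, flank = 64L,
                        params = polishParams(), bloomFpr = 0.01,
                        minOverlap = 1L, keepCase = FALSE, editLog = FALSE,
                        threads = 1L, quiet = FALSE) {
    assembly <- readFasta(assemblyFile)
    reads <- readReads(readsFile)
    paf <- readPaf(pafFile)
    bed <- if (!is.null(bedFile)) readBed(bedFile) else NULL

    res <- polishAssembly(assembly, reads, paf, bed = bed, flank = flank,
                          params = params, bloomFpr = bloomFpr,
                          minOverlap = minOverlap, keepCase = keepCase,
                          editLog = editLog, threads = threads,
                          quiet = quiet)
    dir.create(dirname(outPrefix), showWarnings = FALSE, recursive = TRUE)
    if (length(res$targets) > 0) {
        writeFasta(targetSeqs(res$targets),
                   paste0(outPrefix, ".targets.fa"))
        writePaf(res$lifted, paste0(outPrefix, ".lifted.paf"))
        writeFasta(res$outcomes$seqs,
                   paste0(outPrefix, ".polished_targets.fa"))
        if (editLog)
            write.table(res$outcomes$editLog,
                        paste0(outPrefix, ".edits.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
    }
    writeFasta(res$assembly, paste0(outPrefix, ".polished.fa"))
    jsonlite::write_json(res$report, paste0(outPrefix, ".report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(res$report)
}

#' Map reads with an external long-read mapper
#'
#' Thin wrapper that shells out to `minimap2` to produce the PAF this
#' package consumes. Only for interactive/integration use: the pipeline
#' itself never requires an external mapper (supply `pafFile` instead,
#' e.g. from ntLink or from the fixture generator).
#'
#' @param readsFile,assemblyFile Input files.
#' @param outPaf Output PAF path.
#' @param mapper Mapper executable (only `minimap2` is wrapped).
#' @param args Extra command-line arguments (default ONT preset).
#' @return `outPaf`, invisibly. Errors with an actionable message when
#'   the executable is missing or exits non-zero.
#' @export
runMapper <- function(readsFile, assemblyFile, outPaf,
                      mapper = "minimap2", args = c("-x", "map-ont")) {
    if (!identical(mapper, "minimap2"))
        stop("only minimap2 is wrapped; supply a PAF file for other ",
             "mappers")
    if (Sys.which(mapper) == "")
        stop("'", mapper, "' not found on PATH; map the reads yourself ",
             "and pass the PAF via pafFile")
    status <- system2(mapper, c(args, shQuote(assemblyFile),
                                shQuote(readsFile)),
                      stdout = outPaf, stderr = FALSE)
    if (!identical(status, 0L))
        stop(mapper, " exited with status ", status)
    .validate_paf(readPaf(outPaf))
    invisible(outPaf)
}
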