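#' Create a run configuration
#'
#' Convenience constructor for \linkS4class{RunConfig} with the workflow's
#' defaults: Ct negativity threshold 35 cycles, screen thresholds p < 0.05
#' and fold change >= 2, three candidates per direction.
#'
#' @param negativityThreshold Ct above which a well is called undetected.
#' @param referenceAssays character vector of endogenous-control assay ids.
#' @param minDetectionFraction minimum fraction of detected samples, in at
#'   least one group, for an assay to enter the screen.
#' @param pThreshold,fcThreshold screen significance and (linear) fold
#'   change thresholds.
#' @param topK candidates retained per direction.
#' @param rngSeed integer seed recorded with the configuration.
#' @return a validated \linkS4class{RunConfig}.
#' @examples
#' runConfig(referenceAssays = "RNU48")
#' @export
runConfig <- function(negativityThreshold = 35,
                      referenceAssays = character(0),
                      minDetectionFraction = 0.5,
                      pThreshold = 0.05,
                      fcThreshold = 2,
                      topK = 3L,
                      rngSeed = 1L) {
    new("RunConfig",
        negativityThreshold = as.numeric(negativityThreshold),
        referenceAssays = as.character(referenceAssays),
        minDetectionFraction = as.numeric(minDetectionFraction),
        pThreshold = as.numeric(pThreshold),
        fcThreshold = as.numeric(fcThreshold),
        topK = as.integer(topK),
        rngSeed = as.integer(rngSeed))
}

.CT_COLUMNS <- c("sample_id", "assay_id", "replicate", "ct")
.SHEET_COLUMNS <- c("sample_id", "group", "cohort")
.GROUPS <- c("benign", "malignant")
.COHORTS <- c("discovery", "validation")
.UNDETECTED <- "Undetermined"

#' Read a long-format Ct table
#'
#' Reads raw qPCR results with one row per well: `sample_id`, `assay_id`,
#' `replicate` (positive integer) and `ct`. The instrument sentinel
#' `"Undetermined"` (case-insensitive) or an empty cell marks an undetected
#' well and is returned as `NA`; any other non-numeric Ct is a parse error
#' reported with its row number. Rows must be unique on
#' (sample, assay, replicate).
#'
#' @param path path to a delimited text file with one header row.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return data.frame with columns `sample_id`, `assay_id`, `replicate`
#'   (integer) and `ct` (numeric, `NA` = undetected).
#' @seealso [writeCtTable()], [readSampleSheet()]
#' @export
readCtTable <- function(path, sep = ",") {
    if (!file.exists(path))
        stop("file not found: ", path)
    raw <- read.csv(path, sep = sep, colClasses = "character",
                    check.names = FALSE, strip.white = TRUE)
    missing <- setdiff(.CT_COLUMNS, colnames(raw))
    if (length(missing))
        stop("Ct table is missing required column(s): ",
             paste(missing, collapse = ", "))
    ct_chr <- raw$ct
    undet <- is.na(ct_chr) | ct_chr == "" |
        tolower(ct_chr) == tolower(.UNDETECTED)
    ct <- suppressWarnings(as.numeric(ct_chr))
    bad <- which(!undet & is.na(ct))
    if (length(bad))
        stop("non-numeric Ct value ", sQuote(ct_chr[bad[1]]),
             " in row ", bad[1], " (and ", length(bad) - 1L, " more)")
    ct[undet] <- NA_real_
    if (any(!is.na(ct) & (ct <= 0 | !is.finite(ct))))
        stop("Ct values must be finite and > 0")
    rep_num <- suppressWarnings(as.integer(raw$replicate))
    if (any(is.na(rep_num) | rep_num < 1L))
        stop("replicate must be a positive integer")
    out <- data.frame(sample_id = raw$sample_id,
                      assay_id = raw$assay_id,
                      replicate = rep_num,
                      ct = ct,
                      stringsAsFactors = FALSE)
    key <- paste(out$sample_id, out$assay_id, out$replicate, sep = "\r")
    if (anyDuplicated(key)) {
        d <- out[duplicated(key), , drop = FALSE][1L, ]
        stop("duplicate (sample, assay, replicate): (",
             d$sample_id, ", ", d$assay_id, ", ", d$replicate, ")")
    }
    out
}

#' Write a Ct table
#'
#' Inverse of [readCtTable()]: undetected wells (`NA`) are written as the
#' literal token `"Undetermined"`.
#'
#' @param records data.frame as returned by [readCtTable()].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
writeCtTable <- function(records, path, sep = ",") {
    stopifnot(all(.CT_COLUMNS %in% colnames(records)))
    out <- records[, .CT_COLUMNS]
    out$ct <- ifelse(is.na(out$ct), .UNDETECTED,
                     format(out$ct, trim = TRUE, scientific = FALSE))
    write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a sample sheet
#'
#' Columns `sample_id`, `group` (`benign`/`malignant`) and `cohort`
#' (`discovery`/`validation`); any other label is rejected.
#'
#' @inheritParams readCtTable
#' @return data.frame with one row per sample.
#' @export
readSampleSheet <- function(path, sep = ",") {
    if (!file.exists(path))
        stop("file not found: ", path)
    raw <- read.csv(path, sep = sep, colClasses = "character",
                    check.names = FALSE, strip.white = TRUE)
    missing <- setdiff(.SHEET_COLUMNS, colnames(raw))
    if (length(missing))
        stop("sample sheet is missing required column(s): ",
             paste(missing, collapse = ", "))
    badg <- setdiff(unique(raw$group), .GROUPS)
    if (length(badg))
        stop("unknown group label(s): ", paste(sQuote(badg), collapse = ", "),
             "; expected benign or malignant")
    badc <- setdiff(unique(raw$cohort), .COHORTS)
    if (length(badc))
        stop("unknown cohort label(s): ", paste(sQuote(badc), collapse = ", "),
             "; expected discovery or validation")
    if (anyDuplicated(raw$sample_id))
        stop("duplicate sample_id in sample sheet: ",
             raw$sample_id[duplicated(raw$sample_id)][1L])
    data.frame(sample_id = raw$sample_id, group = raw$group,
               cohort = raw$cohort, stringsAsFactors = FALSE)
}

#' Write a sample sheet
#' @param sheet data.frame as returned by [readSampleSheet()].
#' @inheritParams writeCtTable
#' @return `path`, invisibly.
#' @export
writeSampleSheet <- function(sheet, path, sep = ",") {
    stopifnot(all(.SHEET_COLUMNS %in% colnames(sheet)))
    write.table(sheet[, .SHEET_COLUMNS], path, sep = sep,
                row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Cross-validate a Ct table against its sample sheet
#'
#' Report-based consistency check run before quantification. Blocking
#' issues: samples measured but absent from the sheet (`orphan_sample`) and
#' samples lacking any measurement of a configured reference assay
#' (`missing_reference`). Non-blocking: sheet samples with no measurements
#' (`unmeasured_sample`) and (sample, assay) wells whose replicate count
#' differs from the dataset's modal count (`replicate_irregularity`).
#' The function has no side effects and is idempotent.
#'
#' @param records Ct table data.frame ([readCtTable()]).
#' @param sheet sample sheet data.frame ([readSampleSheet()]).
#' @param config a \linkS4class{RunConfig}; its `referenceAssays` drive the
#'   missing-reference check (skipped when empty).
#' @return list with `issues` (data.frame: `type`, `blocking`, `detail`) and
#'   `pass` (`TRUE` iff no blocking issue).
#' @export
validateDataset <- function(records, sheet, config = runConfig()) {
    issues <- data.frame(type = character(0), blocking = logical(0),
                         detail = character(0), stringsAsFactors = FALSE)
    add <- function(type, blocking, detail) {
        rbind(issues, data.frame(type = type, blocking = blocking,
                                 detail = detail, stringsAsFactors = FALSE))
    }
    orphans <- setdiff(unique(records$sample_id), sheet$sample_id)
    for (s in orphans)
        issues <- add("orphan_sample", TRUE,
                      paste0("sample ", s, " has Ct records but no annotation"))
    unmeasured <- setdiff(sheet$sample_id, unique(records$sample_id))
    for (s in unmeasured)
        issues <- add("unmeasured_sample", FALSE,
                      paste0("sample ", s, " is annotated but has no records"))
    refs <- config@referenceAssays
    if (length(refs)) {
        measured <- unique(records$sample_id)
        for (s in measured) {
            have <- unique(records$assay_id[records$sample_id == s])
            lacking <- setdiff(refs, have)
            if (length(lacking))
                issues <- add("missing_reference", TRUE,
                              paste0("sample ", s, " lacks reference assay(s) ",
                                     paste(lacking, collapse = ", ")))
        }
    }
    key <- paste(records$sample_id, records$assay_id, sep = "\r")
    counts <- table(key)
    if (length(counts) > 1L) {
        tab <- table(as.integer(counts))
        modal <- as.integer(names(tab)[which.max(tab)])
        odd <- names(counts)[as.integer(counts) != modal]
        for (k in odd) {
            parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
            issues <- add("replicate_irregularity", FALSE,
                          paste0("(", parts[1L], ", ", parts[2L], ") has ",
                                 counts[[k]], " replicates (modal ", modal, ")"))
        }
    }
    list(issues = issues, pass = !any(issues$blocking))
}
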