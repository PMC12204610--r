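#' @importFrom GenomicRanges GRanges reduce sort
#' @importFrom IRanges IRanges
#' @importFrom Biostrings readDNAStringSet
NULL

#' Column-name dialect for sample tables
#'
#' Sample tables arrive from heterogeneous exports, so the mapping from the
#' canonical column names to the file's header is configurable.  The default
#' dialect uses the canonical names themselves.  Canonical columns:
#' `record_id`, `wild_seq`, `edited_seq`, the eight span columns
#' (`proto_start`..`rt_end`, 0-based half-open in wild coordinates), and the
#' optional `chrom`, `gstart`, `strand`, `valid`, `unedited`, `erroneous`.
#'
#' @param ... canonical = "file column name" overrides.
#' @return named character vector mapping canonical names to file names.
#' @export
sampleTableDialect <- function(...) {
  canon <- c("record_id", "wild_seq", "edited_seq", spanCols(),
             "chrom", "gstart", "strand", "valid", "unedited", "erroneous")
  map <- stats::setNames(canon, canon)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), canon)
    if (length(bad))
      stop("unknown canonical column(s): ", paste(bad, collapse = ", "))
    map[names(over)] <- over
  }
  map
}

requiredSampleCols <- function() c("record_id", "wild_seq", "edited_seq", spanCols())

#' Build a TargetSet from a data.frame
#'
#' Validates and assembles records; optional columns absent from `df` are
#' filled with NA (anchor, observed triple) or "+" (strand).
#'
#' @param df data.frame with canonical column names (see
#'   [sampleTableDialect()]).
#' @return a [TargetSet-class]
#' @export
makeTargetSet <- function(df) {
  for (col in c("chrom", "strand")) if (is.null(df[[col]])) df[[col]] <- NA_character_
  if (is.null(df[["gstart"]])) df[["gstart"]] <- NA_integer_
  for (col in c("valid", "unedited", "erroneous"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  df$strand[is.na(df$strand)] <- "+"
  df$record_id <- as.character(df$record_id)
  df$wild_seq <- toupper(as.character(df$wild_seq))
  df$edited_seq <- toupper(as.character(df$edited_seq))
  for (col in spanCols()) df[[col]] <- as.integer(df[[col]])
  df$gstart <- as.integer(df$gstart)
  rec <- S4Vectors::DataFrame(df[, c("record_id", "wild_seq", "edited_seq",
                                     spanCols(), "chrom", "gstart", "strand",
                                     "valid", "unedited", "erroneous")])
  new("TargetSet", records = rec)
}

#' Read a delimited sample table
#'
#' Reads a CSV/TSV with header, applies the column dialect, validates every
#' row and returns the records in file order.  All malformed rows are
#' reported together, each with its file line number (header = line 1).
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (".csv" = comma, otherwise tab) unless `sep` is given.
#' @param dialect see [sampleTableDialect()].
#' @param sep optional field separator override.
#' @return a [TargetSet-class]
#' @export
readSampleTable <- function(path, dialect = sampleTableDialect(), sep = NULL) {
  if (!file.exists(path)) formatError("no such file: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  missing_cols <- setdiff(unname(dialect[requiredSampleCols()]), colnames(df))
  if (length(missing_cols))
    formatError("missing required column(s): ", paste(missing_cols, collapse = ", "))
  present <- dialect[dialect %in% colnames(df)]
  out <- df[, unname(present), drop = FALSE]
  colnames(out) <- names(present)

  line <- seq_len(nrow(out)) + 1L  # header occupies line 1
  problems <- character(0)
  note <- function(bad, what) {
    if (any(bad))
      problems <<- c(problems, sprintf("line %d (%s): %s", line[bad],
                                       as.character(out$record_id)[bad], what))
  }
  note(duplicated(out$record_id), "duplicate record_id")
  note(!isDnaString(toupper(as.character(out$wild_seq))),
       "wild_seq not a non-empty ACGT string")
  note(!isDnaString(toupper(as.character(out$edited_seq))),
       "edited_seq not a non-empty ACGT string")
  note(nchar(out$wild_seq) > 128L | nchar(out$edited_seq) > 128L,
       "sequence longer than 128 nt")
  lw <- nchar(out$wild_seq)
  for (reg in c("proto", "pam", "pbs", "rt")) {
    s <- suppressWarnings(as.integer(out[[paste0(reg, "_start")]]))
    e <- suppressWarnings(as.integer(out[[paste0(reg, "_end")]]))
    note(is.na(s) | is.na(e), paste0(reg, " span not integer"))
    ok <- !is.na(s) & !is.na(e)
    bad <- ok & !(s >= 0L & s < e & e <= lw)
    note(bad, paste0(reg, " span out of sequence bounds"))
  }
  for (col in c("valid", "unedited", "erroneous")) if (!is.null(out[[col]])) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    note(!is.na(v) & (v < 0 | v > 100), paste0(col, " outside [0, 100]"))
  }
  if (length(problems))
    validationError("invalid sample table rows:\n  ",
                    paste(problems, collapse = "\n  "))
  makeTargetSet(out)
}

#' Write a TargetSet back to a delimited file
#'
#' Inverse of [readSampleTable()] under the default dialect:
#' reading the written file reproduces the records.
#' @param x a [TargetSet-class]
#' @param path output path (".csv" = comma, otherwise tab).
#' @export
writeSampleTable <- function(x, path) {
  df <- as.data.frame(x@records)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read FASTA sequences
#'
#' @param path FASTA file (possibly multi-line records).
#' @return named character vector of uppercase sequences, file order.
#' @export
readFastaSeqs <- function(path) {
  if (!file.exists(path)) formatError("no such file: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (!length(first)) formatError("empty FASTA file: ", path)
  if (!startsWith(first[1], ">"))
    formatError("FASTA sequence before header in ", path)
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Read a BED-like interval track
#'
#' Accepts >= 3 tab-delimited columns (chrom, start, end; 0-based half-open);
#' extra columns (e.g. narrowPeak score/strand) are ignored.  The result is
#' normalized: sorted, overlapping/abutting intervals merged.  Internally
#' intervals are held as a [GenomicRanges::GRanges] (1-based closed), the
#' conversion happening here and in [writeBedTrack()].
#'
#' @param path BED file path.
#' @return a `GRanges` (the interval-set container used throughout).
#' @export
readBedTrack <- function(path) {
  if (!file.exists(path)) formatError("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep))
    return(GenomicRanges::GRanges())
  ln <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    formatError("line ", ln[which(nf < 3L)[1]], ": fewer than 3 BED columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e)
  if (any(bad))
    formatError("line ", ln[which(bad)[1]], ": non-integer coordinate")
  if (any(s >= e))
    validationError("line ", ln[which(s >= e)[1]],
                    ": interval start >= end (0-based half-open required)")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = s + 1, end = e))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Write intervals as BED
#' @param gr a `GRanges`
#' @param path output path
#' @export
writeBedTrack <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Checkpoints bundle the architecture configuration, every parameter array
#' and the initialization seed, so a run is replayable and a reloaded model
#' reproduces predictions exactly.
#'
#' @param model a [PrimeNet-class]
#' @param path checkpoint path (RDS)
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "PrimeNet"))
  saveRDS(list(kind = "primenet_checkpoint", version = 1L,
               config = model@config, params = model@params,
               seed = model@seed),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @param expectedConfig optional config; if supplied, the checkpoint must
#'   declare an identical architecture or loading fails.
#' @return `loadCheckpoint`: a [PrimeNet-class]
#' @export
loadCheckpoint <- function(path, expectedConfig = NULL) {
  if (!file.exists(path)) formatError("no such checkpoint: ", path)
  x <- readRDS(path)
  if (!identical(x$kind, "primenet_checkpoint"))
    formatError("not a PrimeNet checkpoint: ", path)
  if (!is.null(expectedConfig)) {
    arch <- function(cfg) cfg[sort(setdiff(names(cfg), character(0)))]
    if (!identical(arch(expectedConfig), arch(x$config)))
      validationError("checkpoint architecture does not match the expected ",
                      "configuration")
  }
  model <- new("PrimeNet", config = x$config, params = x$params,
               seed = as.integer(x$seed))
  tmpl <- paramTemplate(model@config)
  if (!identical(lapply(tmpl, dim2), lapply(model@params, dim2)))
    validationError("checkpoint parameter shapes do not match its declared ",
                    "configuration")
  model
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)
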