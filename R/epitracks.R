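#' @importFrom GenomicRanges seqnames start end
NULL

#' Union of epigenetic tracks from multiple labs
#'
#' Implements the concatenation strategy for multi-lab tracks: a genomic
#' position counts as accessible (or methylated) if any contributing dataset
#' marks it.  The result is normalized (sorted, merged).
#'
#' @param tracks a list of `GRanges` (or several `GRanges` via `...`).
#' @return normalized `GRanges` covering a base iff >= 1 input covers it.
#' @export
unionTracks <- function(tracks) {
  if (is(tracks, "GRanges")) tracks <- list(tracks)
  if (!length(tracks)) return(GenomicRanges::GRanges())
  gr <- do.call(c, lapply(tracks, function(g) {
    GenomicRanges::strand(g) <- "*"
    S4Vectors::mcols(g) <- NULL
    g
  }))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Per-base track readout for a genomic window
#'
#' Element `i` (1-based) of the result reports genomic base
#' `gstart + i - 1` for a "+" anchor, or `gstart + length - i` for a "-"
#' anchor, so the vector always runs along the written wild sequence
#' 5' to 3'.  Tracks are strand-agnostic; only the readout order flips.
#'
#' @param track `GRanges` for one mark.
#' @param chrom chromosome name.
#' @param gstart 0-based genomic position of wild-sequence position 0.
#' @param length window length (>= 1).
#' @param strand "+" or "-".
#' @return logical vector of the given length.
#' @export
annotateWindow <- function(track, chrom, gstart, length, strand = "+") {
  stopifnot(length >= 1)
  out <- rep(FALSE, length)
  if (!length(track) ||
      !chrom %in% unique(as.character(GenomicRanges::seqnames(track)))) {
    if (!is.na(chrom)) logMsg("chromosome '", chrom,
                              "' absent from track; window annotated all-FALSE")
    return(out)
  }
  win <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(gstart + 1, gstart + length))
  hits <- GenomicRanges::findOverlaps(win, track)
  for (j in S4Vectors::subjectHits(hits)) {
    a <- max(GenomicRanges::start(track)[j], gstart + 1)
    b <- min(GenomicRanges::end(track)[j], gstart + length)
    out[(a - gstart):(b - gstart)] <- TRUE
  }
  if (identical(strand, "-")) out <- rev(out)
  out
}

#' Per-base Y/N annotation for one record
#'
#' Builds the DNase-accessibility and methylation vectors along the wild
#' sequence.  Records without a genomic anchor get all-FALSE vectors
#' (unknown treated as inaccessible/unmethylated) with a logged note,
#' unless explicit vectors are supplied.
#'
#' @param wildLength length of the wild sequence.
#' @param chrom,gstart,strand genomic anchor (chrom may be NA).
#' @param dnase,methyl `GRanges` tracks.
#' @param dnaseVec,methylVec optional explicit logical vectors overriding
#'   the track lookup (must match `wildLength`).
#' @return list with logical elements `dnase` and `methyl`.
#' @export
buildAnnotation <- function(wildLength, chrom = NA, gstart = NA, strand = "+",
                            dnase = NULL, methyl = NULL,
                            dnaseVec = NULL, methylVec = NULL) {
  pick <- function(vec, track, what) {
    if (!is.null(vec)) {
      if (length(vec) != wildLength)
        validationError("explicit ", what, " vector has length ", length(vec),
                        ", expected ", wildLength)
      return(as.logical(vec))
    }
    if (is.na(chrom) || is.null(track)) return(rep(FALSE, wildLength))
    annotateWindow(track, chrom, gstart, wildLength, strand)
  }
  if ((is.null(dnaseVec) || is.null(methylVec)) && is.na(chrom))
    logMsg("record lacks a genomic anchor; epigenetic channels set all-FALSE")
  list(dnase = pick(dnaseVec, dnase, "dnase"),
       methyl = pick(methylVec, methyl, "methyl"))
}

# Vectorized window readout for many windows at once: one findOverlaps
# call instead of per-record GRanges construction.  Agrees per base with
# annotateWindow (property-tested).
bulkAnnotateWindows <- function(track, chrom, gstart, len, strand) {
  n <- length(chrom)
  out <- lapply(seq_len(n), function(i) rep(FALSE, len[i]))
  ok <- !is.na(chrom)
  if (!any(ok) || is.null(track) || !length(track)) return(out)
  idx <- which(ok)
  win <- GenomicRanges::GRanges(chrom[idx],
                                IRanges::IRanges(gstart[idx] + 1,
                                                 gstart[idx] + len[idx]))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(win, track))
  ts <- GenomicRanges::start(track); te <- GenomicRanges::end(track)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  for (h in seq_along(q)) {
    i <- idx[q[h]]
    a <- max(ts[s[h]], gstart[i] + 1)
    b <- min(te[s[h]], gstart[i] + len[i])
    out[[i]][(a - gstart[i]):(b - gstart[i])] <- TRUE
  }
  for (i in idx) if (identical(strand[i], "-")) out[[i]] <- rev(out[[i]])
  out
}

#' Annotations for every record of a TargetSet
#'
#' @param x a [TargetSet-class]
#' @param dnase,methyl `GRanges` tracks (may be NULL).
#' @return named list (by record_id) of annotation lists as returned by
#'   [buildAnnotation()].
#' @export
buildAnnotations <- function(x, dnase = NULL, methyl = NULL) {
  df <- x@records
  n_unanchored <- sum(is.na(df$chrom))
  if (n_unanchored)
    logMsg(n_unanchored, " record(s) lack a genomic anchor; their epigenetic ",
           "channels are all-FALSE")
  len <- nchar(df$wild_seq)
  dn <- bulkAnnotateWindows(dnase, df$chrom, df$gstart, len, df$strand)
  mt <- bulkAnnotateWindows(methyl, df$chrom, df$gstart, len, df$strand)
  out <- mapply(function(d, m) list(dnase = d, methyl = m), dn, mt,
                SIMPLIFY = FALSE)
  names(out) <- df$record_id
  out
}

#' Dump per-record annotations as a tidy TSV
#'
#' Audit export: one row per (record, position) with the two boolean marks.
#' @param annotations result of [buildAnnotations()]
#' @param path output TSV path
#' @export
writeAnnotationAudit <- function(annotations, path) {
  rows <- lapply(names(annotations), function(id) {
    a <- annotations[[id]]
    data.frame(record_id = id, position = seq_along(a$dnase) - 1L,
               dnase = a$dnase, methyl = a$methyl)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
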