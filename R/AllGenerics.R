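#' @include AllClasses.R
NULL

#' @describeIn TargetSet-class number of records
#' @param x a `TargetSet`
#' @export
setMethod("length", "TargetSet", function(x) nrow(x@records))

#' Record identifiers
#' @param x a `TargetSet` or `PseudoImageSet`
#' @return character vector of record ids
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname recordIds
#' @export
setMethod("recordIds", "TargetSet", function(x) x@records$record_id)

#' @rdname recordIds
#' @export
setMethod("recordIds", "PseudoImageSet", function(x) x@recordIds)

#' Wild / edited target sequences
#' @param x a `TargetSet`
#' @return named character vector
#' @export
setGeneric("wildSeqs", function(x) standardGeneric("wildSeqs"))
#' @rdname wildSeqs
#' @export
setMethod("wildSeqs", "TargetSet", function(x)
  stats::setNames(x@records$wild_seq, x@records$record_id))

#' @rdname wildSeqs
#' @export
setGeneric("editedSeqs", function(x) standardGeneric("editedSeqs"))
#' @rdname wildSeqs
#' @export
setMethod("editedSeqs", "TargetSet", function(x)
  stats::setNames(x@records$edited_seq, x@records$record_id))

#' Functional-region spans
#'
#' Returns the 0-based half-open spans (wild-sequence coordinates) as a
#' data.frame with one row per record.
#' @param x a `TargetSet`
#' @export
setGeneric("regionSpans", function(x) standardGeneric("regionSpans"))
#' @rdname regionSpans
#' @export
setMethod("regionSpans", "TargetSet", function(x) {
  df <- as.data.frame(x@records[, c("record_id", spanCols())])
  rownames(df) <- NULL
  df
})

#' Genomic anchors
#' @param x a `TargetSet`
#' @return data.frame with record_id, chrom, gstart (0-based), strand;
#'   chrom is NA for unanchored records.
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))
#' @rdname anchors
#' @export
setMethod("anchors", "TargetSet", function(x) {
  df <- as.data.frame(x@records[, c("record_id", "chrom", "gstart", "strand")])
  rownames(df) <- NULL
  df
})

#' Observed efficiency triples
#' @param x a `TargetSet` or `PseudoImageSet`
#' @return numeric matrix (N, 3), columns valid/unedited/erroneous, NA when
#'   unobserved
#' @export
setGeneric("observedTriples", function(x) standardGeneric("observedTriples"))
#' @rdname observedTriples
#' @export
setMethod("observedTriples", "TargetSet", function(x) {
  m <- cbind(valid = x@records$valid, unedited = x@records$unedited,
             erroneous = x@records$erroneous)
  rownames(m) <- x@records$record_id
  m
})
#' @rdname observedTriples
#' @export
setMethod("observedTriples", "PseudoImageSet", function(x) {
  m <- x@observed
  dimnames(m) <- list(x@recordIds, headNames())
  m
})

#' @export
setMethod("[", "TargetSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@records$record_id)
  new("TargetSet", records = x@records[i, , drop = FALSE])
})

#' @export
setMethod("[", "PseudoImageSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@recordIds)
  new("PseudoImageSet",
      images = x@images[, , , i, drop = FALSE],
      effLengths = x@effLengths[i, , drop = FALSE],
      recordIds = x@recordIds[i],
      observed = x@observed[i, , drop = FALSE],
      provenance = x@provenance[i])
})

#' @describeIn PseudoImageSet-class number of images
#' @param x a `PseudoImageSet`
#' @export
setMethod("length", "PseudoImageSet", function(x) dim(x@images)[4])

#' Extract the raw image array
#' @param x a `PseudoImageSet`
#' @return numeric array (L, 8, 2, N)
#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))
#' @rdname imageArray
#' @export
setMethod("imageArray", "PseudoImageSet", function(x) x@images)

setMethod("show", "TargetSet", function(object) {
  n <- length(object)
  cat(sprintf("TargetSet with %d record(s)\n", n))
  if (n) {
    anch <- sum(!is.na(object@records$chrom))
    obs <- sum(stats::complete.cases(as.data.frame(
      object@records[, c("valid", "unedited", "erroneous")])))
    cat(sprintf("  anchored: %d | with observed triple: %d\n", anch, obs))
    cat("  ids: ", paste(utils::head(object@records$record_id, 5L),
                         collapse = ", "),
        if (n > 5L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "PseudoImageSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("PseudoImageSet: %d image(s) of shape (%d x %d x %d)\n",
              d[4], d[1], d[2], d[3]))
  cat(sprintf("  observed triples: %d complete\n",
              sum(stats::complete.cases(object@observed))))
})

setMethod("show", "PrimeNet", function(object) {
  cfg <- object@config
  cat("PrimeNet model\n")
  cat(sprintf("  input: %d positions x %d channels x %d sequences\n",
              cfg$length, cfg$in_channels, cfg$n_seq))
  cat(sprintf("  MixConv kernels: %s (x%d channels each)\n",
              paste(cfg$mixconv_kernels, collapse = "/"),
              cfg$mixconv_out_channels))
  cat(sprintf("  channel attention: %s | conv attention: %s (k=%d, %s)\n",
              cfg$channel_attention_enabled, cfg$conv_attention_enabled,
              cfg$conv_attention_kernel, cfg$conv_attention_activation))
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("  parameters: %s in %d arrays (init seed %d)\n",
              format(np, big.mark = ","), length(object@params), object@seed))
})

setMethod("show", "AttributionMap", function(object) {
  cat(sprintf("AttributionMap for head '%s' (%d steps, baseline %s)\n",
              object@head, object@steps, object@baseline))
  cat(sprintf("  |score| total %.4g, max %.4g\n",
              sum(abs(object@scores)), max(abs(object@scores))))
})

#' Attribution scores as an array
#' @param x an `AttributionMap`
#' @export
setGeneric("attributionScores", function(x) standardGeneric("attributionScores"))
#' @rdname attributionScores
#' @export
setMethod("attributionScores", "AttributionMap", function(x) x@scores)
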