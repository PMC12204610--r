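#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Pseudo-image channel layout
#'
#' Fixed assignment of pseudo-image channels (0-based, as conventional for
#' this encoding): the four DNA base channels, the two epigenetic channels
#' and the two functional-region channels.  Channel 6 carries the union of
#' protospacer, PAM and primer-binding site (PBS); channel 7 carries the
#' reverse-transcriptase template (RT) region.
#'
#' @return Named list of 0-based channel indices.
#' @examples
#' channelLayout()$dnase  # 4
#' @export
channelLayout <- function() {
  list(A = 0L, G = 1L, T = 2L, C = 3L,
       dnase = 4L, methyl = 5L,
       proto_pam_pbs = 6L, rt = 7L)
}

spanCols <- function() {
  c("proto_start", "proto_end", "pam_start", "pam_end",
    "pbs_start", "pbs_end", "rt_start", "rt_end")
}

#' TargetSet: a table of pegRNA-target records
#'
#' One row per pegRNA-target pair: wild and edited target sequences
#' (uppercase ACGT, at most 128 nt), the functional-region spans in
#' 0-based half-open wild-sequence coordinates (protospacer, PAM, PBS, RT),
#' an optional genomic anchor (chrom, 0-based start of wild position 0,
#' strand) and an optional observed outcome triple in percent
#' (valid, unedited, erroneous).
#'
#' @slot records A [S4Vectors::DataFrame] with the columns documented above.
#' @export
setClass("TargetSet", representation(records = "DataFrame"))

setValidity("TargetSet", function(object) {
  df <- object@records
  need <- c("record_id", "wild_seq", "edited_seq", spanCols(),
            "chrom", "gstart", "strand", "valid", "unedited", "erroneous")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (anyDuplicated(df$record_id)) return("record_id values must be unique")
  if (!all(isDnaString(df$wild_seq)) || !all(isDnaString(df$edited_seq)))
    return("sequences must be non-empty uppercase ACGT")
  if (any(nchar(df$wild_seq) > 128L) || any(nchar(df$edited_seq) > 128L))
    return("sequences longer than 128 nt")
  lw <- nchar(df$wild_seq)
  for (reg in c("proto", "pam", "pbs", "rt")) {
    s <- df[[paste0(reg, "_start")]]; e <- df[[paste0(reg, "_end")]]
    bad <- !(s >= 0L & s < e & e <= lw)
    if (any(bad))
      return(sprintf("span '%s' out of bounds for record(s) %s", reg,
                     paste(df$record_id[bad], collapse = ", ")))
  }
  obs <- cbind(df$valid, df$unedited, df$erroneous)
  has <- !is.na(obs)
  if (any(obs[has] < 0 | obs[has] > 100))
    return("observed efficiencies must lie in [0, 100]")
  complete <- rowSums(has) == 3L
  if (any(complete)) {
    tot <- rowSums(obs[complete, , drop = FALSE])
    if (any(abs(tot - 100) > 0.5))
      return("complete observed triples must sum to 100 within 0.5")
  }
  TRUE
})

#' PseudoImageSet: encoded pegRNA-target pairs
#'
#' A batch of pseudo-images of shape (positions = 128) x (channels = 8) x
#' (sequences = 2: wild, edited), values in \{0, 1\}, left-aligned and
#' zero-padded on the right past each sequence's effective length.
#'
#' @slot images numeric array (L, 8, 2, N).
#' @slot effLengths integer matrix (N, 2): wild and edited lengths.
#' @slot recordIds character vector of length N.
#' @slot observed numeric matrix (N, 3) of observed percents (may be NA),
#'   columns valid, unedited, erroneous.
#' @slot provenance character vector of length N (e.g. cell-line tag),
#'   possibly empty strings.
#' @export
setClass("PseudoImageSet", representation(
  images = "array", effLengths = "matrix", recordIds = "character",
  observed = "matrix", provenance = "character"))

setValidity("PseudoImageSet", function(object) {
  d <- dim(object@images)
  if (length(d) != 4L || d[2] != 8L || d[3] != 2L)
    return("images must be an (L, 8, 2, N) array")
  n <- d[4]
  if (nrow(object@effLengths) != n || ncol(object@effLengths) != 2L)
    return("effLengths must be (N, 2)")
  if (length(object@recordIds) != n) return("recordIds length mismatch")
  if (nrow(object@observed) != n || ncol(object@observed) != 3L)
    return("observed must be (N, 3)")
  if (length(object@provenance) != n) return("provenance length mismatch")
  if (any(object@effLengths > d[1])) return("effective length exceeds frame")
  TRUE
})

#' PrimeNet model object
#'
#' Holds the architecture configuration (see [modelConfig()]), the flat
#' named list of parameter arrays, and the seed used at initialization so
#' the starting point is replayable from a checkpoint.
#'
#' @slot config list, see [modelConfig()].
#' @slot params named list of numeric arrays (entries `*.W` are weights,
#'   `*.b` biases).
#' @slot seed integer seed used for orthogonal initialization.
#' @export
setClass("PrimeNet", representation(config = "list", params = "list",
                                    seed = "integer"))

#' AttributionMap: per-cell importance scores for one pseudo-image
#'
#' @slot scores numeric array shaped like one pseudo-image (L, 8, 2).
#' @slot head which output the attribution explains.
#' @slot baseline textual descriptor of the integration baseline.
#' @slot steps number of path-integral steps used.
#' @export
setClass("AttributionMap", representation(
  scores = "array", head = "character", baseline = "character",
  steps = "integer"))

setValidity("AttributionMap", function(object) {
  d <- dim(object@scores)
  if (length(d) != 3L || d[2] != 8L || d[3] != 2L)
    return("scores must be (L, 8, 2)")
  if (!object@head %in% c("valid", "unedited", "erroneous"))
    return("head must be valid/unedited/erroneous")
  TRUE
})

headNames <- function() c("valid", "unedited", "erroneous")
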