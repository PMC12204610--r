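# Pseudo-image construction: 128 positions x 8 channels x 2 sequences.
# Channels (0-based): 0-3 one-hot A/G/T/C, 4 DNase accessibility,
# 5 CpG methylation, 6 protospacer+PAM+PBS, 7 RT template.

#' One-hot encode a DNA sequence
#'
#' Base-to-channel map: A, G, T, C occupy channels 0, 1, 2, 3
#' (columns 1..4 of the returned matrix).
#'
#' @param seq uppercase ACGT string.
#' @return binary matrix (nchar(seq) x 4); each row sums to 1.
#' @export
oneHotEncode <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "G", "T", "C"))
  if (anyNA(idx))
    validationError("non-ACGT character at position ",
                    which(is.na(idx))[1] - 1L, " of sequence")
  m <- matrix(0, length(chars), 4L)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Encode the epigenetic channels
#'
#' @param annot list with logical `dnase` and `methyl` of equal length.
#' @return binary matrix (L x 2): column 1 = DNase (channel 4),
#'   column 2 = methylation (channel 5).
#' @export
encodeEpigeneticChannels <- function(annot) {
  stopifnot(length(annot$dnase) == length(annot$methyl))
  cbind(as.numeric(annot$dnase), as.numeric(annot$methyl))
}

#' Encode the functional-region channels
#'
#' Column 1 (channel 6) marks the union of protospacer, PAM and PBS;
#' column 2 (channel 7) marks the RT region.  Spans are 0-based half-open.
#'
#' @param spans list with integer `proto`, `pam`, `pbs`, `rt`, each
#'   `c(start, end)`.
#' @param length sequence length.
#' @return binary matrix (length x 2).
#' @export
encodeRegionChannels <- function(spans, length) {
  mark <- function(v, sp, nm) {
    s <- sp[1]; e <- sp[2]
    if (is.na(s) || is.na(e) || s < 0 || s >= e || e > length)
      validationError("span '", nm, "' [", s, ",", e,
                      ") out of bounds for length ", length)
    v[(s + 1):e] <- 1
    v
  }
  c6 <- numeric(length)
  c6 <- mark(c6, spans$proto, "protospacer")
  c6 <- mark(c6, spans$pam, "pam")
  c6 <- mark(c6, spans$pbs, "pbs")
  c7 <- mark(numeric(length), spans$rt, "rt")
  cbind(c6, c7, deparse.level = 0)
}

# Positional correspondence between wild and edited sequence: identity on
# the longest common prefix (p positions) and suffix (s positions, clipped
# so p + s never exceeds either length); everything in between belongs to
# the edit itself.  Returns, for each edited position (1-based), the
# matching wild position or NA for inserted/replaced bases.
editCorrespondence <- function(wild, edited) {
  lw <- nchar(wild); le <- nchar(edited)
  w <- strsplit(wild, "", fixed = TRUE)[[1]]
  e <- strsplit(edited, "", fixed = TRUE)[[1]]
  nmin <- min(lw, le)
  p <- 0L
  while (p < nmin && w[p + 1L] == e[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < nmin - p && w[lw - s] == e[le - s]) s <- s + 1L
  map <- rep(NA_integer_, le)
  if (p > 0L) map[seq_len(p)] <- seq_len(p)
  if (s > 0L) map[(le - s + 1L):le] <- (lw - s + 1L):lw
  list(map = map, prefix = p, suffix = s)
}

#' Carry the wild-sequence annotation over to the edited sequence
#'
#' Epigenetic marks are locus properties measured on the unedited genome,
#' so matched positions (common prefix/suffix around the edit) copy the
#' wild annotation and inserted bases get FALSE.
#'
#' @param annot wild-sequence annotation (list `dnase`, `methyl`).
#' @param wild,edited the two sequences.
#' @return annotation list aligned to the edited sequence.
#' @export
transferAnnotationToEdit <- function(annot, wild, edited) {
  if (length(annot$dnase) != nchar(wild))
    validationError("annotation length ", length(annot$dnase),
                    " does not match wild sequence length ", nchar(wild))
  map <- editCorrespondence(wild, edited)$map
  take <- function(v) ifelse(is.na(map), FALSE, v[ifelse(is.na(map), 1L, map)])
  list(dnase = unname(take(annot$dnase)), methyl = unname(take(annot$methyl)))
}

# Map wild-coordinate spans onto the edited sequence, per-position through
# the edit correspondence; bases inserted by the edit inherit a region iff
# the region covers both flanking matched wild positions (e.g. an insertion
# inside the RT template stays RT).
mapRegionMembership <- function(inRegion, wild, edited) {
  co <- editCorrespondence(wild, edited)
  lw <- nchar(wild)
  flankL <- if (co$prefix >= 1L) inRegion[co$prefix] else FALSE
  flankR <- if (co$suffix >= 1L) inRegion[lw - co$suffix + 1L] else FALSE
  out <- logical(nchar(edited))
  matched <- !is.na(co$map)
  out[matched] <- inRegion[co$map[matched]]
  out[!matched] <- flankL && flankR
  out
}

#' Build the pseudo-image for one record
#'
#' Wild encoding sits at sequence-slice 1, edited at slice 2; each sequence
#' is left-aligned at position 1 and zero-padded on the right to the frame
#' length (128).  Channels 0-3 are the one-hot bases, channels 4-5 the
#' epigenetic marks (transferred to the edited sequence via
#' [transferAnnotationToEdit()]), channels 6-7 the functional regions
#' (wild spans mapped through the edit correspondence for the edited slice).
#'
#' @param wild,edited sequences (<= 128 nt).
#' @param spans list with `proto`, `pam`, `pbs`, `rt` spans, 0-based
#'   half-open in wild coordinates.
#' @param annot wild-sequence annotation (list `dnase`, `methyl`);
#'   defaults to all-FALSE.
#' @param frame frame length, 128.
#' @return numeric array (frame, 8, 2) with entries in \{0, 1\} and
#'   attribute `effLengths = c(wild, edited)`.
#' @export
buildPseudoImage <- function(wild, edited, spans, annot = NULL, frame = 128L) {
  lw <- nchar(wild); le <- nchar(edited)
  if (lw > frame || le > frame)
    validationError("sequence longer than the ", frame, "-position frame")
  if (is.null(annot))
    annot <- list(dnase = rep(FALSE, lw), methyl = rep(FALSE, lw))
  img <- array(0, c(frame, 8L, 2L))

  fill <- function(slice, seq, ep, reg) {
    L <- nchar(seq)
    img[1:L, 1:4, slice] <<- oneHotEncode(seq)
    img[1:L, 5:6, slice] <<- ep
    img[1:L, 7:8, slice] <<- reg
  }
  regW <- encodeRegionChannels(spans, lw)
  fill(1L, wild, encodeEpigeneticChannels(annot), regW)

  annotE <- transferAnnotationToEdit(annot, wild, edited)
  regE <- cbind(as.numeric(mapRegionMembership(regW[, 1] > 0, wild, edited)),
                as.numeric(mapRegionMembership(regW[, 2] > 0, wild, edited)))
  fill(2L, edited, encodeEpigeneticChannels(annotE), regE)

  attr(img, "effLengths") <- c(lw, le)
  img
}

spansOfRow <- function(df, i) {
  list(proto = c(df$proto_start[i], df$proto_end[i]),
       pam = c(df$pam_start[i], df$pam_end[i]),
       pbs = c(df$pbs_start[i], df$pbs_end[i]),
       rt = c(df$rt_start[i], df$rt_end[i]))
}

#' Encode a whole TargetSet into a PseudoImageSet
#'
#' Order-preserving; records that fail to encode are dropped and reported
#' (per record_id) via the `"failures"` attribute, erroring only when every
#' record fails.
#'
#' @param x a [TargetSet-class]
#' @param dnase,methyl `GRanges` tracks (optional).
#' @param annotations optional precomputed [buildAnnotations()] result.
#' @param provenance optional character tag(s) (e.g. cell line), recycled.
#' @param frame frame length, 128.
#' @return a [PseudoImageSet-class]
#' @export
buildPseudoImages <- function(x, dnase = NULL, methyl = NULL,
                              annotations = NULL, provenance = "",
                              frame = 128L) {
  df <- x@records
  n <- nrow(df)
  if (is.null(annotations)) annotations <- buildAnnotations(x, dnase, methyl)
  imgs <- array(0, c(frame, 8L, 2L, n))
  eff <- matrix(0L, n, 2L)
  ok <- logical(n)
  failures <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(
      buildPseudoImage(df$wild_seq[i], df$edited_seq[i], spansOfRow(df, i),
                       annot = annotations[[df$record_id[i]]], frame = frame),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", df$record_id[i],
                                      conditionMessage(res)))
    } else {
      imgs[, , , i] <- res
      eff[i, ] <- attr(res, "effLengths")
      ok[i] <- TRUE
    }
  }
  if (!any(ok))
    validationError("all records failed to encode:\n  ",
                    paste(failures, collapse = "\n  "))
  if (length(failures))
    logMsg(length(failures), " record(s) failed to encode and were dropped")
  obs <- cbind(df$valid, df$unedited, df$erroneous)
  out <- new("PseudoImageSet",
             images = imgs[, , , ok, drop = FALSE],
             effLengths = eff[ok, , drop = FALSE],
             recordIds = df$record_id[ok],
             observed = obs[ok, , drop = FALSE],
             provenance = rep_len(as.character(provenance), n)[ok])
  attr(out, "failures") <- failures
  out
}

# Fold an (L, 8, 2, N) image array to the (L, N, 16) layout the network
# consumes: the wild/edited axis is absorbed into the channel axis
# (channel index c + 8 * (s - 1)).
foldImages <- function(images) {
  d <- dim(images)
  aperm(array(images, c(d[1], d[2] * d[3], d[4])), c(1, 3, 2))
}

unfoldImage <- function(x) {
  # (L, 16) -> (L, 8, 2)
  array(x, c(nrow(x), 8L, 2L))
}
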