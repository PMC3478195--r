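# Stage 1: minimising Smith-Waterman local alignment over the two atom-type
# sequences with contact energies as column penalties, followed by the
# sliding-window surface filter.

#' Local aligned segments of two atom sequences
#'
#' Minimisation dynamic program over the atom-type sequences of A and B:
#' \code{H(p,q) = min(0, H(p-1,q-1) + T[type(a_p), type(b_q)],
#' H(p-1,q) + gap, H(p,q-1) + gap)}. Segments are extracted best-first (most
#' negative first, ties to the lexicographically smallest end cell); after
#' each extraction the consumed rows and columns are masked, and extraction
#' stops when the best remaining score exceeds the cap \code{x}
#' (\code{scoreCap}, 0 by default). Emitted segments are mutually
#' non-overlapping in both sequences. Atoms aligned to a space contribute
#' the gap penalty (+1 by default).
#'
#' @param A,B typed \linkS4class{ProteinStructure}s.
#' @param table an \linkS4class{AceTable}.
#' @param params a \linkS4class{ScoringParams}.
#' @return List of \linkS4class{AlignedSegment}s, best first.
#' @export
localAlignments <- function(A, B, table, params = new("ScoringParams")) {
  ta <- atomTypes(A); tb <- atomTypes(B)
  if (all(is.na(ta)) || all(is.na(tb)))
    stop("both sequences must carry ACE types (see assignAceTypes)")
  if (params@gapPenalty <= 0) stop("gap penalty must be positive")
  segs <- cpp_sw_extract(as.integer(ifelse(is.na(ta), -1L, ta)),
                         as.integer(ifelse(is.na(tb), -1L, tb)),
                         table@energies, params@gapPenalty, params@scoreCap)
  lapply(segs, function(s) {
    cm <- s$columns
    ia <- cm[, 1][cm[, 1] > 0]; ib <- cm[, 2][cm[, 2] > 0]
    new("AlignedSegment", columns = cm, score = s$score,
        spanA = as.integer(range(ia)), spanB = as.integer(range(ib)))
  })
}

#' Recompute a segment's score from its columns
#'
#' Match columns contribute the table entry for the two atom types; gap
#' columns contribute the gap penalty. Equals the stored score exactly for
#' any segment emitted by \code{\link{localAlignments}}.
#' @export
segmentScore <- function(segment, A, B, table, params = new("ScoringParams")) {
  cm <- segment@columns
  ta <- atomTypes(A); tb <- atomTypes(B)
  s <- 0
  for (r in seq_len(nrow(cm))) {
    if (cm[r, 1] > 0 && cm[r, 2] > 0)
      s <- s + table@energies[ta[cm[r, 1]] + 1L, tb[cm[r, 2]] + 1L]
    else s <- s + params@gapPenalty
  }
  s
}

#' Surface sliding-window filter of an aligned segment
#'
#' Scans the alignment columns left to right in windows of
#' \code{windowLength} columns. A window qualifies iff at least
#' \code{windowSurfaceMin} surface atoms appear among its A-side atoms AND
#' at least that many among its B-side atoms; a qualifying window's atoms
#' are emitted as a \linkS4class{FragmentPair} and its columns removed
#' before the scan continues on the remaining columns (restarting at the
#' same position); a non-qualifying window advances by one column. Gap
#' columns count toward the window length but contribute no surface atom.
#'
#' @param segment an \linkS4class{AlignedSegment}.
#' @param surfaceA,surfaceB per-atom labels of A and B
#'   (\code{"surface"}/\code{"interior"} or logical).
#' @param params a \linkS4class{ScoringParams}.
#' @return List of \linkS4class{FragmentPair}s (possibly empty; a segment
#'   shorter than one window yields none).
#' @export
windowFilter <- function(segment, surfaceA, surfaceB,
                         params = new("ScoringParams")) {
  if (is.character(surfaceA)) surfaceA <- surfaceA == "surface"
  if (is.character(surfaceB)) surfaceB <- surfaceB == "surface"
  cols <- segment@columns
  W <- params@windowLength; m <- params@windowSurfaceMin
  out <- list()
  i <- 1L
  while (i + W - 1L <= nrow(cols)) {
    win <- cols[i:(i + W - 1L), , drop = FALSE]
    aAtoms <- win[, 1][win[, 1] > 0]; bAtoms <- win[, 2][win[, 2] > 0]
    nsa <- sum(surfaceA[aAtoms]); nsb <- sum(surfaceB[bAtoms])
    if (nsa >= m && nsb >= m && length(aAtoms) >= 2L && length(bAtoms) >= 2L) {
      out[[length(out) + 1L]] <-
        new("FragmentPair", atomsA = as.integer(aAtoms),
            atomsB = as.integer(bAtoms),
            surfaceA = as.integer(nsa), surfaceB = as.integer(nsb))
      cols <- cols[-(i:(i + W - 1L)), , drop = FALSE]
    } else {
      i <- i + 1L
    }
  }
  out
}
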