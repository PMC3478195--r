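# Interface extraction and the evaluation statistics: accuracy, coverage,
# F-score, success rate, interface RMSD and fraction of native contacts.

newInterfaceSet <- function(pairs) {
  pairs <- unique(pairs[order(pairs$resA, pairs$resB), , drop = FALSE])
  rownames(pairs) <- NULL
  new("InterfaceSet", pairs = pairs,
      residuesA = unique(pairs$resA), residuesB = unique(pairs$resB))
}

#' Residue pairs of an interface set
#' @param x an \linkS4class{InterfaceSet}.
#' @export
setGeneric("interfacePairs", function(x) standardGeneric("interfacePairs"))

#' @rdname interfacePairs
#' @export
setMethod("interfacePairs", "InterfaceSet", function(x) x@pairs)

#' Per-subunit residue sets of an interface
#' @param x an \linkS4class{InterfaceSet}.
#' @param side "A" or "B".
#' @export
interfaceResidues <- function(x, side = c("A", "B")) {
  side <- match.arg(side)
  if (side == "A") x@residuesA else x@residuesB
}

#' Predicted interface residues of a pose
#'
#' A residue pair (one residue from each subunit) is on the predicted
#' interface iff some cross-subunit atom pair is within \code{cutoff}
#' (inclusive, default 4.5 Angstrom).
#'
#' @param Aposed subunit A in its posed coordinates.
#' @param B fixed subunit B.
#' @param cutoff Angstrom.
#' @return An \linkS4class{InterfaceSet}.
#' @export
predictedInterface <- function(Aposed, B, cutoff = 4.5) {
  ct <- findContacts(Aposed, B, cutoff)
  ra <- residueIds(Aposed); rb <- residueIds(B)
  newInterfaceSet(data.frame(resA = ra[ct$i], resB = rb[ct$j],
                             stringsAsFactors = FALSE))
}

#' Element-based van der Waals radii (Angstrom)
#'
#' Shipped defaults: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20;
#' anything else falls back to \code{fallback}.
#' @export
vdwRadii <- function(fallback = 1.70) {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
    DEFAULT = fallback)
}

#' Actual interface residues of a native complex
#'
#' A residue pair is on the actual interface iff some cross atom pair has
#' distance strictly less than the sum of the two van der Waals radii plus
#' \code{margin} (1 Angstrom by default).
#'
#' @param A,B the two subunits of the native complex.
#' @param radii named per-element radii; unknown elements use the
#'   \code{DEFAULT} entry (set it to NA to make unknown elements an error).
#' @param margin Angstrom.
#' @return An \linkS4class{InterfaceSet}.
#' @export
actualInterface <- function(A, B, radii = vdwRadii(), margin = 1) {
  eA <- atomTable(A)$element; eB <- atomTable(B)$element
  rA <- radii[eA]; rB <- radii[eB]
  rA[is.na(names(rA)) | is.na(rA)] <- radii[["DEFAULT"]]
  rB[is.na(names(rB)) | is.na(rB)] <- radii[["DEFAULT"]]
  if (anyNA(rA) || anyNA(rB))
    stop("unknown element without a DEFAULT fallback radius")
  cut <- max(rA) + max(rB) + margin
  ct <- findContacts(A, B, cut)
  keep <- ct$dist < rA[ct$i] + rB[ct$j] + margin   # strict: "less than"
  ra <- residueIds(A); rb <- residueIds(B)
  newInterfaceSet(data.frame(resA = ra[ct$i[keep]], resB = rb[ct$j[keep]],
                             stringsAsFactors = FALSE))
}

#' Accuracy and coverage of a predicted residue set
#'
#' Accuracy = 100 * |pred intersect actual| / |pred| (the fraction of
#' predicted interface residues that are actual ones); coverage =
#' 100 * |pred intersect actual| / |actual|. An empty prediction yields
#' accuracy 0 with \code{emptyPrediction = TRUE}; an empty actual set
#' leaves coverage NA with \code{emptyActual = TRUE}.
#'
#' @param predicted,actual character vectors of residue identifiers over
#'   the same residue universe (pooled across subunits or per subunit).
#' @return list(accuracy, coverage, correct, emptyPrediction, emptyActual).
#' @export
accuracyCoverage <- function(predicted, actual) {
  predicted <- unique(predicted); actual <- unique(actual)
  correct <- length(intersect(predicted, actual))
  list(accuracy = if (length(predicted)) 100 * correct / length(predicted) else 0,
       coverage = if (length(actual)) 100 * correct / length(actual) else NA_real_,
       correct = correct,
       emptyPrediction = length(predicted) == 0L,
       emptyActual = length(actual) == 0L)
}

#' F-score from accuracy and coverage percentages
#'
#' \code{F = 2 * Acc * Cov / (Acc + Cov)}, reported on the 0-1 scale
#' (inputs in percent); 0 when both inputs are 0.
#' @param accuracy,coverage percentages in [0, 100].
#' @export
fScore <- function(accuracy, coverage) {
  stopifnot(accuracy >= 0, coverage >= 0)
  if (accuracy + coverage == 0) return(0)
  2 * accuracy * coverage / (accuracy + coverage) / 100
}

#' Success rate of a batch of predictions
#'
#' A case is a success iff its accuracy is at least 50 percent (inclusive);
#' the rate is the percentage of successes.
#' @param accuracies numeric vector of per-case accuracy percentages
#'   (NA = undefined prediction, counted as failure).
#' @export
successRate <- function(accuracies) {
  if (!length(accuracies)) stop("no cases")
  100 * sum(!is.na(accuracies) & accuracies >= 50) / length(accuracies)
}

#' Interface RMSD of a predicted complex
#'
#' CAPRI-style convention: the C-alpha atoms of the native interface
#' residues (by default \code{actualInterface} of the native complex) are
#' superposed by least squares (Kabsch) from the predicted complex onto the
#' native complex, and the RMSD over those atoms is reported. Invariant
#' under any joint rigid motion of the predicted complex; 0 for the native
#' pose itself.
#'
#' @param predA,predB the predicted complex (A posed, B fixed).
#' @param natA,natB the native complex; residue identifiers and atom names
#'   must correspond one-to-one with the prediction.
#' @param interface optional \linkS4class{InterfaceSet} defining the
#'   interface residues (native numbering).
#' @param caName atom name of the superposition atoms.
#' @return RMSD in Angstrom.
#' @export
irmsd <- function(predA, predB, natA, natB, interface = NULL, caName = "CA") {
  if (is.null(interface)) interface <- actualInterface(natA, natB)
  pick <- function(s, keep) {
    a <- atomTable(s)
    sel <- trimws(a$name) == caName & residueIds(s) %in% keep
    cbind(paste(residueIds(s)[sel], "CA"), a$x[sel], a$y[sel], a$z[sel])
  }
  nat <- rbind(pick(natA, interface@residuesA), pick(natB, interface@residuesB))
  prd <- rbind(pick(predA, interface@residuesA), pick(predB, interface@residuesB))
  m <- match(nat[, 1], prd[, 1])
  if (anyNA(m)) stop("predicted complex lacks C-alpha atoms for some ",
                     "native interface residues")
  xyzN <- matrix(as.numeric(nat[, 2:4]), ncol = 3)
  xyzP <- matrix(as.numeric(prd[m, 2:4]), ncol = 3)
  if (nrow(xyzN) < 3) stop("need at least 3 interface C-alpha atoms")
  as.numeric(bio3d::rmsd(as.numeric(t(xyzN)), as.numeric(t(xyzP)),
                         fit = TRUE))
}

# minimum heavy-atom cross distance per residue pair
residuePairMinDist <- function(A, B, cutoff) {
  ct <- findContacts(A, B, cutoff)
  if (!nrow(ct)) return(data.frame(resA = character(), resB = character(),
                                   dist = numeric()))
  key <- paste(residueIds(A)[ct$i], residueIds(B)[ct$j], sep = "~")
  agg <- tapply(ct$dist, key, min)
  parts <- strsplit(names(agg), "~", fixed = TRUE)
  data.frame(resA = vapply(parts, `[`, "", 1), resB = vapply(parts, `[`, "", 2),
             dist = as.numeric(agg), stringsAsFactors = FALSE)
}

#' Fraction of native contacts preserved by a prediction
#'
#' Native contacts are the cross-residue pairs whose minimum heavy-atom
#' distance is strictly below \code{cutoff} in the native complex; the
#' result is the percentage of them that are also below \code{cutoff} in
#' the predicted configuration.
#'
#' @param predA,predB predicted complex.
#' @param natA,natB native complex (matching residue identifiers).
#' @param cutoff Angstrom (default 4.5).
#' @return Percentage in [0, 100].
#' @export
nativeContactFraction <- function(predA, predB, natA, natB, cutoff = 4.5) {
  natPairs <- residuePairMinDist(natA, natB, cutoff)
  natPairs <- natPairs[natPairs$dist < cutoff, , drop = FALSE]
  if (!nrow(natPairs)) stop("native complex has no contacts below the cutoff")
  prdPairs <- residuePairMinDist(predA, predB, cutoff)
  prdPairs <- prdPairs[prdPairs$dist < cutoff, , drop = FALSE]
  100 * sum(paste(natPairs$resA, natPairs$resB) %in%
              paste(prdPairs$resA, prdPairs$resB)) / nrow(natPairs)
}

#' Evaluate a predicted pose against a native complex
#'
#' Convenience wrapper producing the per-case statistics: interface size,
#' predicted size, accuracy, coverage, F-score, success, iRMSD and fraction
#' of native contacts. \code{mode = "pooled"} pools residues from both
#' subunits; \code{mode = "per-subunit"} reports each side separately.
#'
#' @param predA,predB predicted complex (A posed).
#' @param natA,natB native complex.
#' @param params a \linkS4class{ScoringParams}.
#' @param mode "pooled" or "per-subunit".
#' @return data.frame of statistics (one row pooled, two per-subunit).
#' @export
evaluatePrediction <- function(predA, predB, natA, natB,
                               params = new("ScoringParams"),
                               mode = c("pooled", "per-subunit")) {
  mode <- match.arg(mode)
  act <- actualInterface(natA, natB, margin = params@vdwMargin)
  prd <- predictedInterface(predA, predB, cutoff = params@interfaceCutoff)
  ir <- irmsd(predA, predB, natA, natB, interface = act)
  fnat <- nativeContactFraction(predA, predB, natA, natB,
                                cutoff = params@interfaceCutoff)
  onerow <- function(side, p, a) {
    ac <- accuracyCoverage(p, a)
    data.frame(side = side, interfaceSize = length(a), predictedSize = length(p),
               correct = ac$correct, accuracy = ac$accuracy,
               coverage = ac$coverage,
               fScore = fScore(ac$accuracy,
                               if (is.na(ac$coverage)) 0 else ac$coverage),
               success = !is.na(ac$accuracy) && ac$accuracy >= 50,
               irmsd = ir, nativeContacts = fnat, stringsAsFactors = FALSE)
  }
  if (mode == "pooled") {
    onerow("pooled",
           c(paste0("A:", prd@residuesA), paste0("B:", prd@residuesB)),
           c(paste0("A:", act@residuesA), paste0("B:", act@residuesB)))
  } else {
    rbind(onerow("A", prd@residuesA, act@residuesA),
          onerow("B", prd@residuesB, act@residuesB))
  }
}
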