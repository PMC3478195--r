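# Independent brute-force oracles and small fixture builders shared by the
# suite. All oracles are deliberately written as plain double/triple loops
# (or plain recursions) so they share no code path with the implementation.

# quadratic cross-pair search
bruteContacts <- function(c1, c2, cutoff) {
  out <- NULL
  for (i in seq_len(nrow(c1))) for (j in seq_len(nrow(c2))) {
    d <- sqrt(sum((c1[i, ] - c2[j, ])^2))
    if (d <= cutoff) out <- rbind(out, c(i, j, d))
  }
  if (is.null(out)) data.frame(i = integer(), j = integer(), dist = numeric())
  else data.frame(i = as.integer(out[, 1]), j = as.integer(out[, 2]),
                  dist = out[, 3])
}

# quadratic ACE sum
bruteAce <- function(c1, t1, c2, t2, E, cutoff) {
  s <- 0
  for (i in seq_len(nrow(c1))) for (j in seq_len(nrow(c2))) {
    if (is.na(t1[i]) || is.na(t2[j])) next
    if (sqrt(sum((c1[i, ] - c2[j, ])^2)) <= cutoff)
      s <- s + E[t1[i] + 1, t2[j] + 1]
  }
  s
}

# O(points x atoms) lattice labeling: 0 empty, 1 surface, 2 interior
bruteLabelGrid <- function(coords, origin, dims, spacing, radius) {
  isProtein <- function(p) {
    for (a in seq_len(nrow(coords)))
      if (sqrt(sum((p - coords[a, ])^2)) <= radius) return(TRUE)
    FALSE
  }
  point <- function(i, j, k) origin + spacing * c(i, j, k)
  lab <- array(0L, dims)
  for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1)) for (k in 0:(dims[3] - 1)) {
    if (!isProtein(point(i, j, k))) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    interior <- TRUE
    for (r in 1:6) {
      n <- nb[r, ]
      if (any(n < 0) || any(n > dims - 1) ||
          !isProtein(point(n[1], n[2], n[3]))) { interior <- FALSE; break }
    }
    lab[i + 1, j + 1, k + 1] <- if (interior) 2L else 1L
  }
  lab
}

# brute-force clash report on the shared lattice
bruteClash <- function(cA, cB, params) {
  margin <- params@proteinPointRadius + params@gridSpacing
  both <- rbind(cA, cB)
  origin <- floor(apply(both, 2, min)) - margin
  top <- ceiling(apply(both, 2, max)) + margin
  dims <- as.integer((top - origin) / params@gridSpacing) + 1L
  lA <- bruteLabelGrid(cA, origin, dims, params@gridSpacing,
                       params@proteinPointRadius)
  lB <- bruteLabelGrid(cB, origin, dims, params@gridSpacing,
                       params@proteinPointRadius)
  list(X = sum(lA == 2L & lB == 2L), XA = sum(lA == 2L), XB = sum(lB == 2L))
}

# exhaustive minimum alignment score of two full substrings (every atom of
# each interval matched or gapped), memoised plain recursion
alignScoreOracle <- function(ta, tb, E, gap) {
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {   # atoms i..len(ta), j..len(tb) remain
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    na <- length(ta) - i + 1; nb <- length(tb) - j + 1
    v <- if (na == 0 && nb == 0) 0
    else if (na == 0) nb * gap
    else if (nb == 0) na * gap
    else min(rec(i + 1, j + 1) + E[ta[i] + 1, tb[j] + 1],
             rec(i + 1, j) + gap, rec(i, j + 1) + gap)
    memo[[key]] <- v
    v
  }
  rec(1, 1)
}

# greedy best-first extraction over all interval pairs, rows/cols masked
swExtractOracle <- function(ta, tb, E, gap, x) {
  usedA <- rep(FALSE, length(ta)); usedB <- rep(FALSE, length(tb))
  out <- list()
  repeat {
    best <- NULL
    for (i in seq_along(ta)) for (j in i:length(ta)) {
      if (j < i || any(usedA[i:j])) next
      for (k in seq_along(tb)) for (l in k:length(tb)) {
        if (l < k || any(usedB[k:l])) next
        sc <- alignScoreOracle(ta[i:j], tb[k:l], E, gap)
        if (is.null(best) || sc < best$score - 1e-12)
          best <- list(score = sc, spanA = c(i, j), spanB = c(k, l))
      }
    }
    if (is.null(best) || best$score > x || best$score >= -1e-12) break
    usedA[best$spanA[1]:best$spanA[2]] <- TRUE
    usedB[best$spanB[1]:best$spanB[2]] <- TRUE
    out[[length(out) + 1]] <- best
  }
  out
}

# toy structure from bare coordinates and types (4-atom pseudo-residues)
toyFromCoords <- function(coords, types = rep(0L, nrow(coords)), chain = "A") {
  n <- nrow(coords)
  proteinStructure(data.frame(
    serial = seq_len(n), name = rep(c("N", "CA", "C", "O"), length.out = n),
    element = rep(c("N", "C", "C", "O"), length.out = n),
    resname = "GLY", resseq = rep(seq_len(ceiling(n / 4)), each = 4)[1:n],
    inscode = "", chain = chain,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    aceType = as.integer(types), stringsAsFactors = FALSE))
}

randomRotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

randomTransform <- function()
  rigidTransform(randomRotation(), stats::runif(3, -10, 10))

# minimal hand-written PDB text for parser tests
pdbLine <- function(serial, name, resname, chain, resseq, x, y, z,
                    occ = 1, alt = "", ins = "", element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resname, chain, resseq, ins, x, y, z, occ, 0, element)
}
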