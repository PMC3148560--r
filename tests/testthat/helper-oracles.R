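# Independent brute-force oracles, deliberately written as straight loops
# over the definitions so they share no code with the package internals.

# classical EHH at query SNP y: fraction of carrier pairs identical over
# every SNP between core and y (inclusive)
bruteEHH <- function(a, carriers, core, y) {
  cols <- min(core, y):max(core, y)
  m <- length(carriers)
  same <- 0L
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    vi <- a[carriers[i], cols]
    vj <- a[carriers[j], cols]
    ident <- !anyNA(c(vi, vj)) && all(vi == vj)
    if (ident) same <- same + 1L
  }
  same / choose(m, 2)
}

# weighted EHH from the definition: identity classes by haplotype string
bruteWEHH <- function(a, carriers, U, core, y) {
  cols <- min(core, y):max(core, y)
  sub <- a[carriers, cols, drop = FALSE]
  keys <- vapply(seq_len(nrow(sub)), function(r) {
    v <- sub[r, ]
    if (anyNA(v)) paste0("NA_row_", r)       # missing matches nothing
    else paste(v, collapse = "")
  }, "")
  W <- tapply(U, keys, sum)
  m <- length(carriers)
  (sum(W^2) - sum(U^2)) / (m^2 - sum(U^2))
}

# per-pair squared Hamming distance by explicit site loop
bruteHamming <- function(a) {
  n <- nrow(a); L <- ncol(a)
  v <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    h <- 0L; c <- 0L
    for (s in seq_len(L)) {
      if (is.na(a[i, s]) || is.na(a[j, s])) next
      c <- c + 1L
      if (a[i, s] != a[j, s]) h <- h + 1L
    }
    v[i, j] <- (h / c)^2 * L
  }
  v
}

# PHS by direct summation of the definition
brutePHS <- function(a, gpos) {
  n <- nrow(a); S <- ncol(a)
  tract <- function(i, j, x) {
    if (is.na(a[i, x]) || is.na(a[j, x]) || a[i, x] != a[j, x]) return(0)
    lo <- x
    while (lo > 1 && !is.na(a[i, lo - 1]) && !is.na(a[j, lo - 1]) &&
           a[i, lo - 1] == a[j, lo - 1]) lo <- lo - 1
    hi <- x
    while (hi < S && !is.na(a[i, hi + 1]) && !is.na(a[j, hi + 1]) &&
           a[i, hi + 1] == a[j, hi + 1]) hi <- hi + 1
    gpos[hi] - gpos[lo]
  }
  pairs <- utils::combn(n, 2)
  Z <- matrix(0, ncol(pairs), S)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    d <- vapply(seq_len(S), function(x) tract(i, j, x), 1)
    sdv <- stats::sd(d)
    if (is.na(sdv) || sdv == 0) next
    Z[p, ] <- (d - mean(d)) / sdv
  }
  vapply(seq_len(S), function(x) {
    car <- which(!is.na(a[, x]) & a[, x] == 1L)
    if (length(car) < 2) return(NA_real_)
    inCar <- pairs[1, ] %in% car & pairs[2, ] %in% car
    sum(Z[inCar, x]) / choose(length(car), 2) - sum(Z[, x]) / ncol(pairs)
  }, 1)
}

# straight-line reimplementation of the full classical iHS raw-score
# pipeline (pair-counting EHH + trapezoid with 0.05 truncation)
bruteIHSraw <- function(a, gpos, mafMin = 0.05, trunc = 0.05) {
  S <- ncol(a); n <- nrow(a)
  out <- rep(NA_real_, S)
  for (x in seq_len(S)) {
    if (anyNA(a[, x])) next
    f <- mean(a[, x])
    if (min(f, 1 - f) < mafMin) next
    iw <- c(A = NA_real_, D = NA_real_)
    for (al in c(0, 1)) {
      car <- which(a[, x] == al)
      if (length(car) < 2) { iw[] <- NA; break }
      tot <- 0
      for (step in c(-1, 1)) {
        prevE <- 1; prevG <- gpos[x]
        y <- x + step
        while (y >= 1 && y <= S) {
          e <- bruteEHH(a, car, x, y)
          tot <- tot + abs(gpos[y] - prevG) * (prevE + e) / 2
          if (e < trunc) break
          prevE <- e; prevG <- gpos[y]
          y <- y + step
        }
        if (y < 1 || y > S) { tot <- NA; break }  # boundary: undefined
      }
      if (is.na(tot)) { iw[] <- NA; break }
      iw[if (al == 0) "A" else "D"] <- tot
    }
    if (!anyNA(iw) && all(iw > 0)) out[x] <- log(iw["A"] / iw["D"])
  }
  out
}

constantDm <- function(n, value = 1) {
  v <- matrix(value, n, n)
  diag(v) <- 0
  new("DistanceMatrix", values = v, sitesCompared = matrix(1L, n, n))
}
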