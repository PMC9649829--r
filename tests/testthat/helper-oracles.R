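# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# epoch-walk sleep summary: walk the label vector once, counting everything
# by hand
oracle_sleep_summary <- function(labels) {
  n <- length(labels)
  onset <- NA_integer_
  tst <- 0L; waso <- 0L; latency <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == "sleep") {
      if (is.na(onset)) onset <- i
      tst <- tst + 1L
    } else {
      if (is.na(onset)) latency <- latency + 1L else waso <- waso + 1L
    }
  }
  if (is.na(onset)) {
    return(list(tst = 0, waso = 0, se = 0, latency = NA, mi = 100,
                fi = NA, sfi = NA, onset = NA))
  }
  # count sleep bouts and length-1 sleep bouts by walking transitions
  bouts <- 0L; ones <- 0L; run <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == "sleep") {
      run <- run + 1L
    } else if (run > 0L) {
      bouts <- bouts + 1L; if (run == 1L) ones <- ones + 1L; run <- 0L
    }
  }
  if (run > 0L) { bouts <- bouts + 1L; if (run == 1L) ones <- ones + 1L }
  mi <- 100 * (n - tst) / n
  fi <- 100 * ones / bouts
  list(tst = tst, waso = waso, se = 100 * tst / n, latency = latency,
       mi = mi, fi = fi, sfi = mi + fi, onset = onset)
}

# Cole-Kripke by direct per-epoch loop over the published weights
oracle_cole_kripke <- function(counts) {
  w <- c(106, 54, 58, 76, 230, 74, 67)
  n <- length(counts)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in -4:2) {
      k <- i + j
      a <- if (k >= 1 && k <= n) counts[k] else 0
      s <- s + w[j + 5] * a
    }
    out[i] <- if (0.001 * s < 1) "sleep" else "wake"
  }
  out
}

# BH step-up by direct double loop over the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) p[ord[j]] * m / j)
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

# partial correlation by explicit two-stage OLS then Pearson
oracle_partial_cor <- function(x, y, C) {
  X <- cbind(1, as.matrix(C))
  bx <- solve(t(X) %*% X, t(X) %*% x)
  by <- solve(t(X) %*% X, t(X) %*% y)
  rx <- x - X %*% bx
  ry <- y - X %*% by
  as.numeric(stats::cor(rx, ry))
}

# PLS-C by eigen-decomposition of R'R (Y side) and RR' (X side)
oracle_plsc <- function(Xr, Yr) {
  n <- nrow(Xr)
  R <- t(Xr) %*% Yr / (n - 1)
  K <- min(ncol(Xr), ncol(Yr))
  ey <- eigen(t(R) %*% R, symmetric = TRUE)
  ex <- eigen(R %*% t(R), symmetric = TRUE)
  list(R = R,
       sigma = sqrt(pmax(ey$values[seq_len(K)], 0)),
       U = ey$vectors[, seq_len(K), drop = FALSE],
       V = ex$vectors[, seq_len(K), drop = FALSE])
}

# random two-block null data, centered and scaled
make_null_blocks <- function(n, p, q) {
  list(X = scale(matrix(stats::rnorm(n * p), n)),
       Y = scale(matrix(stats::rnorm(n * q), n)))
}

# blocks with a single planted latent dimension
make_planted_blocks <- function(n, loadings_x, loadings_y, noise_x = 1,
                                noise_y = 1) {
  z <- stats::rnorm(n)
  X <- outer(z, loadings_x) + matrix(stats::rnorm(n * length(loadings_x),
                                                  0, noise_x), n)
  Y <- outer(z, loadings_y) + matrix(stats::rnorm(n * length(loadings_y),
                                                  0, noise_y), n)
  list(X = X, Y = Y, z = z)
}

cosine_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# tiny 8-h rest interval shared by actigraphy tests
test_rest <- function() {
  rest_interval(as.POSIXct("2014-06-02 23:00:00", tz = "UTC"),
                as.POSIXct("2014-06-03 07:00:00", tz = "UTC"))
}
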