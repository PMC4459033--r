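# Independent brute-force oracles and small fixtures shared by the tests.
# These deliberately use naive loops / textbook definitions so that agreement
# with the package implementations is informative.

# brute-force phase alignment index: explicit complex sums per (f, t)
plfBrute <- function(phases) {
  d <- dim(phases)
  out <- matrix(0, d[2L], d[3L])
  for (f in seq_len(d[2L])) {
    for (t in seq_len(d[3L])) {
      s <- 0i
      for (k in seq_len(d[1L])) s <- s + exp(1i * phases[k, f, t])
      out[f, t] <- Mod(s) / d[1L]
    }
  }
  out
}

# Benjamini-Hochberg step-up adjusted p-values from the textbook definition:
# adjusted_(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1
bhBrute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force 4-adjacency connected components of a logical matrix, returning
# the multiset of component sizes (sorted)
componentSizesBrute <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    stack <- list(c(i, j)); seen[i, j] <- TRUE; size <- 0L
    while (length(stack)) {
      q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        a <- q[1L] + d[1L]; b <- q[2L] + d[2L]
        if (a >= 1L && a <= nr && b >= 1L && b <= nc &&
            mask[a, b] && !seen[a, b]) {
          seen[a, b] <- TRUE
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes)
}

# small EpochSet with a caller-supplied deterministic signal plus optional
# Gaussian noise; signal(t, epoch, channelIndex) returns a series over t
makeEpochSet <- function(nEpochs = 6L, fs = 250, window = c(-0.5, 1),
                         channels = c("frontal", "RATN"),
                         signal = function(t, e, ch) numeric(length(t)),
                         noiseSD = 0, seed = 1L,
                         condition = rep(c("SE", "UE"),
                                         length.out = nEpochs)) {
  t <- seq(window[1L], window[2L], by = 1 / fs)
  dat <- array(0, dim = c(nEpochs, length(channels), length(t)))
  set.seed(seed)
  for (e in seq_len(nEpochs)) for (ch in seq_along(channels)) {
    dat[e, ch, ] <- signal(t, e, ch) + rnorm(length(t), sd = noiseSD)
  }
  new("EpochSet", participantID = "T01", channels = channels,
      samplingRate = fs, times = t, data = dat, condition = condition)
}

# exact-r construction: two length-n vectors whose sample Pearson r is
# exactly the requested value (x standardised, e orthonormal to x)
exactCorPair <- function(r, n, seed = 1L) {
  set.seed(seed)
  x <- scale(seq_len(n))[, 1L]
  e <- residuals(lm(rnorm(n) ~ x))
  e <- e / sqrt(sum(e^2)) * sqrt(sum(x^2))
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}
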