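# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit double loops, exhaustive enumeration) and
# share no code with the package internals.

# Naive density-peaks reference: literal equations with the documented
# tie-breaks (density ties broken by lower index; center ties by larger
# density then lower index).
dp_reference <- function(Y, t, K) {
  n <- nrow(Y)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sum((Y[i, ] - Y[j, ])^2)
    }
  }
  ds <- sort(D[upper.tri(D)])
  M <- n * (n - 1) / 2
  r <- floor(M * t + 0.5)
  r <- min(max(r, 1), M)
  dc <- ds[r]
  if (dc <= 0) {
    pos <- ds[ds > 0]
    dc <- if (length(pos)) pos[1] else .Machine$double.eps
  }
  rho <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) if (j != i) acc <- acc + exp(-(D[i, j] / dc)^2)
    rho[i] <- acc - 1
  }
  denser <- function(j, i) rho[j] > rho[i] || (rho[j] == rho[i] && j < i)
  delta <- numeric(n)
  n_up <- integer(n)
  for (i in seq_len(n)) {
    hs <- Filter(function(j) denser(j, i), setdiff(seq_len(n), i))
    if (!length(hs)) {
      delta[i] <- max(D[i, ])
      n_up[i] <- i
    } else {
      # candidates visited from densest down, strict < keeps the first
      hs <- hs[order(-rho[hs], hs)]
      best <- hs[1]
      for (j in hs) if (D[i, j] < D[i, best]) best <- j
      delta[i] <- D[i, best]
      n_up[i] <- best
    }
  }
  lam <- rho * delta
  centers <- order(-lam, -rho, seq_len(n))[seq_len(K)]
  L <- integer(n)
  L[centers] <- seq_len(K)
  for (i in order(-rho, seq_len(n))) {
    if (L[i] != 0L) next
    if (n_up[i] == i) {
      L[i] <- L[centers[which.min(D[i, centers])]]
    } else {
      L[i] <- L[n_up[i]]
    }
  }
  list(D = D, dc = dc, rho = rho, delta = delta, n_up = n_up, lam = lam,
       centers = centers, labels = L)
}

# Exhaustive best one-to-one label matching: max fraction of agreeing
# points over all permutations of the (<= 5) predicted label ids.
perm_match_accuracy <- function(pred, truth) {
  pids <- sort(unique(pred))
  tids <- sort(unique(truth))
  k <- max(length(pids), length(tids))
  stopifnot(k <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  targets <- c(tids, rep(NA_integer_, k - length(tids)))
  best <- 0
  for (p in perms(seq_len(k))) {
    mapped <- targets[p][match(pred, pids)]
    best <- max(best, sum(!is.na(mapped) & mapped == truth))
  }
  best / length(pred)
}

# Exhaustive one-to-one spike-time matching minimizing total |dt| among
# maximum-cardinality matchings within tolerance (tiny instances only).
brute_time_match <- function(extra, intra, tol) {
  best <- list(n = -1, cost = Inf, marked = logical(length(extra)))
  recurse <- function(i, used, pairs) {
    if (i > length(intra)) {
      n <- nrow(pairs)
      cost <- if (n > 0) sum(pairs[, 3]) else 0
      if (n > best$n || (n == best$n && cost < best$cost)) {
        m <- logical(length(extra))
        if (n > 0) m[pairs[, 2]] <- TRUE
        best <<- list(n = n, cost = cost, marked = m)
      }
      return()
    }
    recurse(i + 1, used, pairs)                    # leave intra i unmatched
    for (j in seq_along(extra)) {
      dt <- abs(extra[j] - intra[i])
      if (!used[j] && dt <= tol) {
        u <- used; u[j] <- TRUE
        recurse(i + 1, u, rbind(pairs, c(i, j, dt)))
      }
    }
  }
  recurse(1, logical(length(extra)), matrix(numeric(0), 0, 3))
  best
}

# Small well-separated Gaussian blobs with known labels.
make_blobs <- function(centers, n_each, sd = 0.05, seed = 1) {
  set.seed(seed)
  Y <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    sweep(matrix(rnorm(n_each * ncol(centers), sd = sd), n_each), 2,
          centers[k, ], `+`)
  }))
  list(Y = Y, labels = rep(seq_len(nrow(centers)), each = n_each))
}
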