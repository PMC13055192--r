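# Pure-R re-derivations of the alignment engine, used as independent
# oracles.  Everything here is written with naive loops and explicit
# formulas, independent of the package's compiled kernels.

# bounded-affine local alignment landscape: returns H, E, F ((n+1) x (m+1),
# zero/neg borders) computed cell by cell from the defining recurrences
oracle_fill <- function(w, gap_open, gap_extend, max_gap) {
  n <- nrow(w); m <- ncol(w)
  NEG <- -1e30
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      e <- NEG
      for (g in seq_len(min(max_gap, j - 1)))
        e <- max(e, H[i, j - g] - gap_open - gap_extend * (g - 1))
      E[i, j] <- e
      f <- NEG
      for (g in seq_len(min(max_gap, i - 1)))
        f <- max(f, H[i - g, j] - gap_open - gap_extend * (g - 1))
      F[i, j] <- f
      H[i, j] <- max(0, H[i - 1, j - 1] + w[i - 1, j - 1], e, f)
    }
  }
  list(H = H, E = E, F = F)
}

# deterministic move of the traceback at core cell (i, j):
# list(type, gi, gj) where type 1 = aligned pair, 2 = gap over rows,
# 3 = gap over columns, 4 = zero-contribution diagonal, 0 = stop
oracle_move <- function(fill, w, i, j, gap_open, gap_extend, max_gap) {
  eps <- 1e-12
  h <- fill$H[i + 1, j + 1]
  if (h <= 0) return(list(type = 0L))
  dg <- fill$H[i, j] + w[i, j]
  if (abs(h - dg) <= eps && w[i, j] > 0) return(list(type = 1L))
  if (abs(h - fill$F[i + 1, j + 1]) <= eps) {
    for (g in seq_len(min(max_gap, i))) {
      if (g == min(max_gap, i) ||
          abs(fill$F[i + 1, j + 1] -
              (fill$H[i + 1 - g, j + 1] - gap_open - gap_extend * (g - 1))) <= eps)
        return(list(type = 2L, g = g))
    }
  }
  if (abs(h - fill$E[i + 1, j + 1]) <= eps) {
    for (g in seq_len(min(max_gap, j))) {
      if (g == min(max_gap, j) ||
          abs(fill$E[i + 1, j + 1] -
              (fill$H[i + 1, j + 1 - g] - gap_open - gap_extend * (g - 1))) <= eps)
        return(list(type = 3L, g = g))
    }
  }
  if (abs(h - dg) <= eps) return(list(type = 4L))
  list(type = 0L)
}

oracle_smooth <- function(vals, wl) {
  h <- wl %/% 2
  n <- length(vals)
  sapply(seq_len(n), function(t) {
    lo <- max(1, t - h); hi <- min(n, t + h)
    mean(vals[lo:hi])
  })
}

# full independent trace extraction mirroring the committed algorithm:
# run-end seeds, traceback, jump-split pieces, smoothed-run segmentation
# with 3-run end anchoring, then the min_span / sigma / windowed-score
# filters, exact-duplicate removal, sub-path pruning, Chebyshev
# deduplication
oracle_local_align <- function(sim, params, self = TRUE,
                               min_span = params$min_span) {
  n <- nrow(sim); m <- ncol(sim)
  if (n < min_span || m < min_span) return(list())
  w <- sim
  if (self) {
    for (i in seq_len(n)) for (j in seq_len(m))
      if (j - i <= params$diagonal_exclusion) w[i, j] <- -4
  }
  max_gap <- max(1L, params$window_length %/% 2L)
  fl <- oracle_fill(w, params$gap_open, params$gap_extension, max_gap)
  is_pair <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    is_pair[i, j] <- oracle_move(fl, w, i, j, params$gap_open,
                                 params$gap_extension, max_gap)$type == 1L
  seeds <- NULL
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!is_pair[i, j]) next
    if (i < n && j < m && is_pair[i + 1, j + 1]) next
    seeds <- rbind(seeds, c(i, j, fl$H[i + 1, j + 1]))
  }
  if (is.null(seeds)) return(list())
  seeds <- seeds[order(-seeds[, 3], seeds[, 1], seeds[, 2]), , drop = FALSE]

  if (self) {
    offd <- sim[row(sim) != col(sim)]
  } else offd <- as.vector(sim)
  thr <- mean(offd) + params$sigma_factor * sd(offd)

  h2 <- params$window_length %/% 2L
  traces <- list()
  for (s in seq_len(nrow(seeds))) {
    i <- seeds[s, 1]; j <- seeds[s, 2]
    path <- NULL
    while (i >= 1 && j >= 1) {
      mv <- oracle_move(fl, w, i, j, params$gap_open,
                        params$gap_extension, max_gap)
      if (mv$type == 0L) break
      if (mv$type == 1L) { path <- rbind(c(i, j), path); i <- i - 1; j <- j - 1 }
      else if (mv$type == 2L) i <- i - mv$g
      else if (mv$type == 3L) j <- j - mv$g
      else { i <- i - 1; j <- j - 1 }
    }
    if (is.null(path) || nrow(path) < min_span) next
    path <- path[order(path[, 1]), , drop = FALSE]
    # jump-free pieces
    brk <- which(diff(path[, 1]) > h2 + 1 | diff(path[, 2]) > h2 + 1)
    piece_id <- cumsum(c(1, seq_len(nrow(path) - 1) %in% brk))
    for (pc in split(seq_len(nrow(path)), piece_id)) {
      if (length(pc) < min_span) next
      vals <- sim[path[pc, , drop = FALSE]]
      sm <- oracle_smooth(vals, params$window_length)
      on <- sm >= params$score_cutoff
      if (!any(on)) next
      for (run in split(which(on), cumsum(c(1, diff(which(on)) != 1)))) {
        s0 <- min(run); s1 <- max(run)
        three <- function(t) all(vals[t:(t + 2)] >= params$score_cutoff)
        while (s0 + 2 <= s1 && !three(s0)) s0 <- s0 + 1
        while (s1 - 2 >= s0 && !three(s1 - 2)) s1 <- s1 - 1
        if (s1 - s0 < 2 && (vals[s0] < params$score_cutoff ||
                            vals[s1] < params$score_cutoff)) next
        if (s1 - s0 + 1 < min_span) next
        seg <- path[pc[s0:s1], , drop = FALSE]
        segv <- sim[seg]
        if (mean(segv) < thr) next
        sc <- mean(oracle_smooth(segv, params$window_length))
        if (sc < params$score_cutoff) next
        traces[[length(traces) + 1]] <- list(pairs = seg, score = sc)
      }
    }
  }
  # exact duplicates
  sig <- sapply(traces, function(t) paste(t$pairs[, 1], t$pairs[, 2],
                                          collapse = ";"))
  traces <- traces[!duplicated(sig)]
  # maximality
  keys <- lapply(traces, function(t) paste(t$pairs[, 1], t$pairs[, 2]))
  keep <- rep(TRUE, length(traces))
  for (a in seq_along(traces)) for (b in seq_along(traces)) {
    if (a != b && keep[b] &&
        length(keys[[a]]) < length(keys[[b]]) &&
        all(keys[[a]] %in% keys[[b]])) { keep[a] <- FALSE; break }
  }
  traces <- traces[keep]
  # Chebyshev redundancy, greedy over deterministic order
  if (length(traces) > 1) {
    sc <- sapply(traces, `[[`, "score")
    np <- sapply(traces, function(t) nrow(t$pairs))
    i1 <- sapply(traces, function(t) t$pairs[1, 1])
    j1 <- sapply(traces, function(t) t$pairs[1, 2])
    traces <- traces[order(-sc, -np, i1, j1)]
    near_frac <- function(p1, p2) {
      mean(sapply(seq_len(nrow(p1)), function(k)
        any(abs(p2[, 1] - p1[k, 1]) <= 2 & abs(p2[, 2] - p1[k, 2]) <= 2)))
    }
    kept <- list()
    for (t in traces) {
      red <- FALSE
      for (k in kept)
        if (near_frac(t$pairs, k$pairs) >= 0.7 ||
            near_frac(k$pairs, t$pairs) >= 0.7) { red <- TRUE; break }
      if (!red) kept[[length(kept) + 1]] <- t
    }
    traces <- kept
  }
  traces
}

# plain Needleman-Wunsch oracle with a single linear gap penalty,
# tie preference diagonal > up > left, returning matched pairs and score
oracle_global_align <- function(sa, gap) {
  n <- nrow(sa); m <- ncol(sa)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) H[i + 1, 1] <- -gap * i
  for (j in seq_len(m)) H[1, j + 1] <- -gap * j
  for (i in seq_len(n)) for (j in seq_len(m))
    H[i + 1, j + 1] <- max(H[i, j] + sa[i, j], H[i, j + 1] - gap,
                           H[i + 1, j] - gap)
  pairs <- NULL
  i <- n; j <- m
  while (i > 0 || j > 0) {
    h <- H[i + 1, j + 1]
    if (i > 0 && j > 0 && abs(h - (H[i, j] + sa[i, j])) <= 1e-12) {
      pairs <- rbind(c(i, j), pairs); i <- i - 1; j <- j - 1
    } else if (i > 0 && abs(h - (H[i, j + 1] - gap)) <= 1e-12) {
      i <- i - 1
    } else j <- j - 1
  }
  list(pairs = pairs, score = if (is.null(pairs)) 0 else mean(sa[pairs]),
       H = H)
}

# brute-force window scan for the representative location
oracle_locate <- function(m, l) {
  L <- nrow(m)
  w <- sapply(seq_len(l), function(p) min(p, l - p + 1) - 0.5)
  best <- -Inf; best_c <- NA
  for (c in seq_len(L - l + 1)) {
    s <- 0
    for (i in seq_len(L)) for (p in seq_len(l))
      s <- s + w[p] * m[i, c + p - 1]
    if (s > best + 1e-12) { best <- s; best_c <- c }
  }
  list(start = best_c, window_score = best)
}

# explicit double-loop weighted embedding
oracle_weighted_embedding <- function(m, E, start, l) {
  D <- ncol(E)
  out <- matrix(0, l, D)
  for (r in seq_len(l)) {
    col <- start + r - 1
    for (i in seq_len(nrow(E)))
      out[r, ] <- out[r, ] + m[i, col] * E[i, ]
    if (all(m[, col] == 0)) out[r, ] <- E[col, ]
  }
  out
}

# explicit windowed trace score
oracle_windowed_score <- function(vals, wl) {
  h <- wl %/% 2
  n <- length(vals)
  sm <- numeric(n)
  for (t in seq_len(n)) {
    lo <- max(1, t - h); hi <- min(n, t + h)
    sm[t] <- sum(vals[lo:hi]) / (hi - lo + 1)
  }
  mean(sm)
}

trace_signature <- function(pairs) paste(pairs[, 1], pairs[, 2],
                                         sep = ",", collapse = ";")

expect_same_trace_set <- function(got, want) {
  sig_got <- sort(vapply(got, function(t) trace_signature(t$pairs),
                         character(1)))
  sig_want <- sort(vapply(want, function(t) trace_signature(t$pairs),
                          character(1)))
  expect_identical(sig_got, sig_want)
}

# random similarity-like symmetric matrix with optional planted bands
random_self_sim <- function(L, seed, band = NULL) {
  set.seed(seed)
  s <- matrix(rnorm(L * L, sd = 0.12), L, L)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  if (!is.null(band)) {
    for (b in band) {
      idx <- seq(b$i, length.out = b$len)
      s[cbind(idx, idx + b$off)] <- b$val
      s[cbind(idx + b$off, idx)] <- b$val
    }
  }
  pmax(pmin(s, 1), -1)
}
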