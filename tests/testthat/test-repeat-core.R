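# Transitivity, score-matrix accumulation, length candidates, window
# weights, representative localisation, weighted embedding and masking.

loose_params <- function(...) {
  alignment_params(min_span = 3L, score_cutoff = 0, sigma_factor = 0,
                   window_length = 5L, ...)
}

test_that("coordinate-sharing traces compose into the transitive trace", {
  sim <- matrix(0.6, 30, 30); diag(sim) <- 1
  t1 <- alignment_trace(cbind(3:5, 11:13), score = 0.9)
  t2 <- alignment_trace(cbind(11:13, 26:28), score = 0.9)
  out <- apply_transitivity(list(t1, t2), sim, loose_params(),
                            min_span = 3L)
  sigs <- vapply(out, function(t) trace_signature(t$pairs), character(1))
  expect_true(trace_signature(cbind(3:5, 26:28)) %in% sigs)
  comp <- out[[which(sigs == trace_signature(cbind(3:5, 26:28)))]]
  expect_equal(comp$origin, "transitive")
  # scored from the similarity matrix
  expect_equal(comp$score, windowed_trace_score(comp$pairs, sim, 5),
               tolerance = 1e-12)
})

test_that("disjoint coordinate sets compose to nothing", {
  sim <- matrix(0.6, 30, 30); diag(sim) <- 1
  t1 <- alignment_trace(cbind(3:5, 11:13), score = 0.9)
  t2 <- alignment_trace(cbind(15:17, 26:28), score = 0.9)
  out <- apply_transitivity(list(t1, t2), sim, loose_params(),
                            min_span = 3L)
  expect_length(out, 2)        # only the primaries come back
})

test_that("transitivity runs exactly one round", {
  sim <- matrix(0.6, 60, 60); diag(sim) <- 1
  # chain t1: 3..5 -> 11..13, t2: 11..13 -> 26..28, t3: 26..28 -> 41..43
  t1 <- alignment_trace(cbind(3:5, 11:13), score = 0.9)
  t2 <- alignment_trace(cbind(11:13, 26:28), score = 0.9)
  t3 <- alignment_trace(cbind(26:28, 41:43), score = 0.9)
  out <- apply_transitivity(list(t1, t2, t3), sim, loose_params(),
                            min_span = 3L)
  sigs <- vapply(out, function(t) trace_signature(t$pairs), character(1))
  expect_true(trace_signature(cbind(3:5, 26:28)) %in% sigs)   # t1 o t2
  expect_true(trace_signature(cbind(11:13, 41:43)) %in% sigs) # t2 o t3
  # (t1 o t2) o t3 = 3..5 -> 41..43 must NOT be formed in one round
  expect_false(trace_signature(cbind(3:5, 41:43)) %in% sigs)
})

test_that("composites must pass the primary filters", {
  sim <- matrix(0, 30, 30); diag(sim) <- 1
  # the composite cells carry low similarity -> windowed score < cutoff
  t1 <- alignment_trace(cbind(3:5, 11:13), score = 0.9)
  t2 <- alignment_trace(cbind(11:13, 26:28), score = 0.9)
  p <- alignment_params(min_span = 3L, score_cutoff = 0.5,
                        sigma_factor = 0, window_length = 5L)
  out <- apply_transitivity(list(t1, t2), sim, p, min_span = 3L)
  expect_length(out, 2)
  # and min_span applies to composites as well
  sim2 <- matrix(0.8, 30, 30)
  out2 <- apply_transitivity(list(t1, t2), sim2,
                             alignment_params(min_span = 5L,
                                              score_cutoff = 0,
                                              sigma_factor = 0),
                             min_span = 5L)
  expect_length(out2, 2)
})

test_that("score matrix sums trace scores over covering traces", {
  t1 <- alignment_trace(cbind(c(2, 3), c(6, 7)), score = 0.8)
  t2 <- alignment_trace(cbind(3, 7), score = 0.5)
  M <- build_score_matrix(list(t1, t2), 10)
  expect_equal(M[2, 6], 0.8)
  expect_equal(M[3, 7], 1.3)          # both traces cover (3, 7)
  expect_equal(M[6, 2], 0.8)          # mirrored
  expect_equal(M[7, 3], 1.3)
  expect_equal(sum(M != 0), 4)
  expect_equal(build_score_matrix(list(), 5), matrix(0, 5, 5))
})

test_that("score-matrix mass equals sum of score x pairs over traces", {
  g <- generate_synthetic(synthetic_repeat_spec(15, 4, dim = 32, seed = 2))
  sim <- cosine_similarity(g$embedding)
  p <- alignment_params()
  traces <- apply_transitivity(embrep:::local_align_traces(sim, p, TRUE),
                               sim, p)
  M <- build_score_matrix(traces, g$embedding$L)
  upper_mass <- sum(M[upper.tri(M)])
  expect_equal(upper_mass,
               sum(vapply(traces, function(t) t$score * t$npairs,
                          numeric(1))),
               tolerance = 1e-9)
  # candidate diagonal sums partition the mass at distances up to L/2 (a
  # unit longer than half the protein cannot repeat, so larger distances
  # are outside the candidate range by construction)
  dmax <- g$embedding$L %/% 2L
  near_mass <- sum(M[upper.tri(M) & abs(row(M) - col(M)) <= dmax])
  expect_equal(sum(candidate_lengths(M)$diagonal_sum), near_mass,
               tolerance = 1e-9)
})

test_that("candidate lengths rank distances by diagonal sums", {
  expect_equal(nrow(candidate_lengths(matrix(0, 8, 8))), 0)
  M <- matrix(0, 12, 12)
  M[3, 8] <- 1.5; M[8, 3] <- 1.5
  cl <- candidate_lengths(M)
  expect_equal(cl$d, 5L)
  expect_equal(cl$diagonal_sum, 1.5)
  g <- generate_synthetic(synthetic_repeat_spec(20, 4, dim = 48, seed = 6))
  r <- detect_repeats(g$embedding)
  sim <- cosine_similarity(g$embedding)
  expect_true(abs(candidate_lengths(r$score_matrix)$d[1] - 20) <= 2)
})

test_that("window weights form the symmetric half-offset triangle", {
  expect_equal(window_weights(4)$weights, c(0.5, 1.5, 1.5, 0.5))
  expect_equal(window_weights(5)$weights, c(0.5, 1.5, 2.5, 1.5, 0.5))
  expect_equal(window_weights(1)$weights, 0.5)
  for (l in c(2, 7, 12, 31)) {
    w <- window_weights(l)$weights
    expect_equal(w, rev(w))
    expect_true(all(w >= 0))
    expect_equal(which.max(w), ceiling(l / 2))
  }
})

test_that("representative localisation matches the brute-force scan", {
  M <- matrix(0, 30, 30)
  M[, 10:14] <- 1                        # constant column block
  rep <- locate_representative(M, 5)
  expect_equal(rep$start, 10L)
  # two identical blocks: leftmost wins
  M2 <- matrix(0, 60, 60)
  M2[, 10:14] <- 1; M2[, 40:44] <- 1
  expect_equal(locate_representative(M2, 5)$start, 10L)
  for (seed in 1:4) {
    set.seed(seed)
    Ms <- matrix(0, 25, 25)
    Ms[sample(625, 40)] <- runif(40, 0, 2)
    got <- locate_representative(Ms, 7)
    orc <- oracle_locate(Ms, 7)
    expect_equal(got$start, orc$start)
    expect_equal(got$window_score, orc$window_score, tolerance = 1e-9)
  }
  expect_error(locate_representative(matrix(0, 5, 5), 9),
               class = "embrep_param_error")
})

test_that("weighted repeat embedding equals the double-loop oracle", {
  set.seed(7)
  for (case in 1:3) {
    L <- 12; l <- 4; D <- 5
    M <- matrix(0, L, L)
    M[sample(L * L, 30)] <- runif(30, 0, 1.5)
    E <- matrix(rnorm(L * D), L, D)
    rep <- structure(list(start = 3L, length = l, window_score = 1),
                     class = "representative_repeat")
    expect_equal(weighted_repeat_embedding(M, E, rep),
                 oracle_weighted_embedding(M, E, 3L, l),
                 tolerance = 1e-12)
  }
  # single aligned row: profile row is a scaled copy of that row
  M <- matrix(0, 10, 10); M[7, 4] <- 0.6
  E <- matrix(rnorm(80), 10, 8)
  rep <- structure(list(start = 4L, length = 1L, window_score = 1),
                   class = "representative_repeat")
  er <- weighted_repeat_embedding(M, E, rep)
  expect_equal(er[1, ], 0.6 * E[7, ], tolerance = 1e-12)
  # all-zero window columns fall back to the raw slice
  rep2 <- structure(list(start = 8L, length = 2L, window_score = 0),
                    class = "representative_repeat")
  expect_equal(weighted_repeat_embedding(M, E, rep2), E[8:9, ],
               tolerance = 1e-12)
})

test_that("masking zeroes rows and columns and is idempotent", {
  set.seed(8)
  M <- matrix(runif(400), 20, 20); M <- M + t(M)
  spans <- cbind(start = c(3L, 15L), end = c(6L, 17L))
  M1 <- mask_score_matrix(M, spans)
  idx <- c(3:6, 15:17)
  expect_true(all(M1[idx, ] == 0))
  expect_true(all(M1[, idx] == 0))
  expect_equal(M1[8, 10], M[8, 10])
  expect_identical(mask_score_matrix(M1, spans), M1)
  # masking the only signal empties the candidate list
  M2 <- matrix(0, 20, 20); M2[4, 12] <- M2[12, 4] <- 1
  M3 <- mask_score_matrix(M2, cbind(4L, 4L))
  expect_equal(nrow(candidate_lengths(M3)), 0)
})

test_that("instance extraction recovers planted copies", {
  g <- generate_synthetic(synthetic_repeat_spec(20, 4, dim = 64, seed = 12))
  E <- g$embedding$values
  p <- alignment_params()
  sim <- cosine_similarity(g$embedding)
  traces <- apply_transitivity(embrep:::local_align_traces(sim, p, TRUE),
                               sim, p)
  M <- build_score_matrix(traces, nrow(E))
  rep <- locate_representative(M, 20)
  Er <- weighted_repeat_embedding(M, E, rep)
  inst <- extract_instances(Er, E, p)
  expect_gte(length(inst), 4)
  u <- g$truth$units
  hit <- vapply(seq_len(nrow(u)), function(k) {
    ov <- vapply(inst, function(i)
      max(0, min(i$end, u$end[k]) - max(i$start, u$start[k]) + 1),
      numeric(1))
    any(ov / 20 >= 0.9)
  }, logical(1))
  expect_true(all(hit))
  # accepted instances respect the pairwise overlap bound
  if (length(inst) > 1) {
    for (a in seq_along(inst)[-1]) for (b in seq_len(a - 1)) {
      ov <- max(0, min(inst[[a]]$end, inst[[b]]$end) -
                   max(inst[[a]]$start, inst[[b]]$start) + 1)
      shorter <- min(inst[[a]]$end - inst[[a]]$start,
                     inst[[b]]$end - inst[[b]]$start) + 1
      expect_lte(ov / shorter, 0.5 + 1e-9)
    }
  }
})

test_that("orthogonal representative only matches itself", {
  set.seed(13)
  E <- embrep:::normalize_rows(matrix(rnorm(60 * 64), 60, 64))
  rep_emb <- E[20:39, ]                  # the raw slice as representative
  inst <- extract_instances(rep_emb, E, alignment_params())
  expect_equal(length(inst), 1L)
  expect_lte(abs(inst[[1]]$start - 20), 1)
  expect_lte(abs(inst[[1]]$end - 39), 1)
})

test_that("A2M assembly places matches, inserts and deletions", {
  set.seed(14)
  a <- embrep:::normalize_rows(matrix(rnorm(6 * 8), 6, 8))
  seqchars <- "MKVLINGKTL"
  # gapless instance
  ga <- global_align(a, a)
  inst <- structure(list(start = 1L, end = 6L, alignment = ga, score = 1,
                         coverage = 1), class = "repeat_instance")
  msa <- assemble_msa(list(inst, inst), 6, seqchars)
  expect_equal(unname(msa), rep(toupper(substr(seqchars, 1, 6)), 2))
  # instance with one inserted residue -> one lowercase insert state
  ins <- embrep:::normalize_rows(matrix(rnorm(8), 1, 8))
  b <- rbind(a[1:3, ], ins, a[4:6, ])
  gai <- global_align(b, a)
  insti <- structure(list(start = 1L, end = 7L, alignment = gai, score = 1,
                          coverage = 1), class = "repeat_instance")
  row <- assemble_msa(list(insti), 6, seqchars)[[1]]
  expect_equal(nchar(row), 7)
  expect_equal(sum(grepl("[a-z]", strsplit(row, "")[[1]])), 1)
  # missing residue -> "-"
  d <- a[-4, ]
  gad <- global_align(d, a)
  instd <- structure(list(start = 1L, end = 5L, alignment = gad, score = 1,
                          coverage = 5 / 6), class = "repeat_instance")
  rowd <- assemble_msa(list(instd), 6, seqchars)[[1]]
  expect_equal(sum(strsplit(rowd, "")[[1]] == "-"), 1)
})

test_that("hypothesis selection ranks by metric with fundamental ties", {
  mk <- function(l, start, spans, cov = 1) {
    list(l = l,
         representative = structure(list(start = start, length = l,
                                         window_score = 1),
                                    class = "representative_repeat"),
         instances = lapply(spans, function(s)
           structure(list(start = s[1], end = s[2], alignment = NULL,
                          score = 0.9, coverage = cov),
                     class = "repeat_instance")),
         msa = character(0), metric = NA_real_)
  }
  h1 <- mk(10L, 1L, list(c(1, 10), c(11, 20), c(21, 30), c(31, 40)))
  h2 <- mk(20L, 1L, list(c(1, 20), c(21, 40)))
  # equal coverage: more instances wins
  expect_equal(select_best_length(list(h2, h1))$l, 10L)
  # clearly better coverage wins regardless of counts
  h3 <- mk(10L, 1L, list(c(1, 10), c(11, 20)))
  expect_equal(select_best_length(list(h3, h2))$l, 20L)
  # mean_coverage metric: higher per-instance coverage wins
  h4 <- mk(10L, 1L, list(c(1, 10), c(11, 20)), cov = 0.9)
  h5 <- mk(10L, 5L, list(c(1, 10), c(11, 20)), cov = 0.5)
  expect_equal(select_best_length(list(h5, h4), "mean_coverage",
                                  tolerance = 0)$instances[[1]]$coverage,
               0.9)
  # exact tie on metric and counts: smaller l, then smaller start
  h6 <- mk(10L, 3L, list(c(1, 10), c(11, 20)))
  h7 <- mk(10L, 1L, list(c(1, 10), c(11, 20)))
  expect_equal(select_best_length(list(h6, h7))$representative$start, 1L)
  expect_null(select_best_length(list()))
  # single hypothesis returns itself
  expect_equal(select_best_length(list(h2))$l, 20L)
})
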