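# Synthetic generator, providers and the embedding container.

test_that("synthetic provider obeys the shape and determinism contracts", {
  prov <- embedding_provider("synthetic", dim = 16L, seed = 7L)
  seq50 <- paste(rep("ACDEFGHIKL", 5), collapse = "")
  e1 <- embed_sequence(seq50, prov, "p1")
  expect_s3_class(e1, "residue_embedding")
  expect_equal(dim(e1), c(50L, 16L))
  e2 <- embed_sequence(seq50, prov, "p1")
  expect_identical(e1$values, e2$values)
  # different seed, different embedding
  e3 <- embed_sequence(seq50, embedding_provider("synthetic", dim = 16L,
                                                 seed = 8L))
  expect_false(identical(e1$values, e3$values))
})

test_that("embedding inputs are validated", {
  prov <- embedding_provider("synthetic", dim = 8L)
  expect_error(embed_sequence("", prov), class = "embrep_input_error")
  expect_error(embed_sequence("ACDB1", prov), class = "embrep_input_error")
  expect_error(embedding_provider("unknown_plm"), class = "embrep_config_error")
  expect_error(embedding_provider("custom"), class = "embrep_config_error")
  custom <- embedding_provider("custom",
                               fun = function(s) matrix(1, nchar(s), 4))
  expect_equal(dim(embed_sequence("ACDE", custom)), c(4L, 4L))
})

test_that("generate_synthetic plants the requested geometry", {
  spec <- synthetic_repeat_spec(20, 4, flank_left = 10, flank_right = 10,
                                within_unit_cosine = 0.9, dim = 32,
                                seed = 3)
  g <- generate_synthetic(spec)
  expect_equal(g$embedding$L, 100L)
  expect_equal(g$embedding$D, 32L)
  expect_equal(nrow(g$truth$units), 4L)
  expect_equal(g$truth$units$start, c(11L, 31L, 51L, 71L))
  expect_equal(g$truth$units$end - g$truth$units$start + 1L, rep(20L, 4))
  # rows unit-normalised
  expect_equal(unname(rowSums(g$embedding$values^2)), rep(1, 100),
               tolerance = 1e-12)
  # determinism
  g2 <- generate_synthetic(spec)
  expect_identical(g$embedding$values, g2$embedding$values)
  expect_identical(g$truth$units, g2$truth$units)
})

test_that("perfect within-unit cosine makes corresponding rows identical", {
  spec <- synthetic_repeat_spec(8, 2, flank_left = 0, flank_right = 0,
                                within_unit_cosine = 1.0, dim = 16, seed = 1)
  g <- generate_synthetic(spec)
  v <- g$embedding$values
  expect_equal(v[1:8, ], v[9:16, ], tolerance = 1e-12)
})

test_that("cross-copy cosine matches the target and exceeds background", {
  spec <- synthetic_repeat_spec(25, 5, flank_left = 30, flank_right = 30,
                                within_unit_cosine = 0.9, dim = 64, seed = 11)
  g <- generate_synthetic(spec)
  v <- g$embedding$values
  u <- g$truth$units
  # all cross-copy corresponding-position cosines
  cross <- c()
  for (a in 1:4) for (b in (a + 1):5) {
    ra <- u$start[a]:u$end[a]; rb <- u$start[b]:u$end[b]
    cross <- c(cross, rowSums(v[ra, ] * v[rb, ]))
  }
  expect_gt(mean(cross), 0.85)
  expect_lt(mean(cross), 0.95)
  # 1000 random repeat-vs-flank pairs stay below background_cosine_max on
  # average, and well below the planted signal
  set.seed(42)
  rep_idx <- sample(u$start[1]:u$end[5], 1000, replace = TRUE)
  flank_idx <- sample(c(1:30, 156:185), 1000, replace = TRUE)
  bg <- rowSums(v[rep_idx, ] * v[flank_idx, ])
  expect_lt(mean(bg), spec$background_cosine_max)
  expect_gt(mean(cross), mean(bg))
})

test_that("indels change copy lengths and keep spans consistent", {
  spec <- synthetic_repeat_spec(20, 4, indel_per_copy = 1, dim = 32,
                                seed = 5)
  g <- generate_synthetic(spec)
  u <- g$truth$units
  lens <- u$end - u$start + 1L
  expect_true(all(abs(lens - 20L) <= 1L))
  expect_true(all(diff(u$start) > 0))
  expect_equal(g$embedding$L, 20L + sum(lens))
})

test_that("infeasible geometry is rejected", {
  expect_error(synthetic_repeat_spec(20, 4, within_unit_cosine = 0.1,
                                     background_cosine_max = 0.2),
               class = "embrep_param_error")
  expect_error(synthetic_repeat_spec(3, 4), class = "embrep_param_error")
  expect_error(synthetic_repeat_spec(20, 1), class = "embrep_param_error")
})

test_that("embedding containers round-trip in both dialects", {
  e <- residue_embedding(matrix(rnorm(80), 10, 8), "round_trip")
  txt <- withr::local_tempfile(fileext = ".tsv")
  bin <- withr::local_tempfile(fileext = ".bin")
  write_embedding(e, txt)
  write_embedding(e, bin)
  et <- read_embedding(txt)
  eb <- read_embedding(bin)
  expect_identical(eb$values, e$values)        # binary is lossless
  expect_equal(et$values, e$values, tolerance = 1e-8)
  expect_equal(et$sequence_id, "round_trip")
  expect_equal(eb$sequence_id, "round_trip")
  # the two dialects agree after load
  expect_equal(et$values, eb$values, tolerance = 1e-8)
})

test_that("malformed containers raise format errors naming the location", {
  p <- withr::local_tempfile(fileext = ".tsv")
  e <- residue_embedding(matrix(rnorm(40), 10, 4), "bad")
  write_embedding(e, p)
  lines <- readLines(p)
  # header says 10 rows, payload has 9
  writeLines(lines[-5], p)
  expect_error(read_embedding(p), "header declares",
               class = "embrep_format_error")
  # corrupt one value
  writeLines(c(lines[1:4], sub("\t", "\tnot_a_number\t", lines[5]),
               lines[6:11]), p)
  expect_error(read_embedding(p), "line", class = "embrep_format_error")
  # truncated binary
  b <- withr::local_tempfile(fileext = ".bin")
  write_embedding(e, b)
  raw <- readBin(b, "raw", n = file.size(b))
  writeBin(raw[1:40], b)
  expect_error(read_embedding(b), "byte|payload",
               class = "embrep_format_error")
})

test_that("background generator is deterministic with near-zero cosines", {
  b1 <- generate_background(120, dim = 64, seed = 9)
  b2 <- generate_background(120, dim = 64, seed = 9)
  expect_identical(b1$values, b2$values)
  s <- cosine_similarity(b1)
  expect_lt(mean(abs(s[row(s) != col(s)])), 0.15)
})

test_that("two-family construction stacks regions with offset truths", {
  s1 <- synthetic_repeat_spec(12, 3, seed = 1)
  s2 <- synthetic_repeat_spec(18, 3, seed = 2)
  tf <- generate_two_family(s1, s2)
  expect_equal(tf$embedding$L, 56L + 74L)
  expect_equal(min(tf$truth2$units$start), 56L + 11L)
  expect_true(max(tf$truth1$units$end) < min(tf$truth2$units$start))
})
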