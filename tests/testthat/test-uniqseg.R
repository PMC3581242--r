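test_that("build_index records exact carrier sets", {
  fam1 <- seq_family("a", "AAAA")
  idx1 <- build_index(fam1, 3)
  expect_identical(names(idx1$carriers), "AAA")
  expect_identical(idx1$carriers[["AAA"]], "a")

  idx <- build_index(toy_family(), 3)
  expect_setequal(idx$carriers[["RCK"]], c("a", "b"))
  expect_identical(idx$carriers[["NYR"]], "a")
  expect_identical(idx$carriers[["NYQ"]], "b")

  expect_error(build_index(seq_family(c("a", "tiny"), c("AAAA", "GG")), 3),
               "tiny")
  expect_error(build_index(toy_family(), 0), "L must be")
})

test_that("every carrier really contains its pattern (brute-force check)", {
  set.seed(101)
  for (rep in 1:20) {
    fam <- random_family(sample(2:6, 1), c(8L, 40L),
                         alphabet_size = sample(c(4L, 8L, 20L), 1))
    idx <- build_index(fam, 3)
    res <- stats::setNames(fam$residues, fam$id)
    for (p in names(idx$carriers)) {
      expect_true(all(vapply(idx$carriers[[p]],
                             function(id) grepl(p, res[[id]], fixed = TRUE),
                             logical(1L))))
    }
    # and no member outside the carrier set contains the pattern
    some <- sample(names(idx$carriers), min(10L, length(idx$carriers)))
    for (p in some) {
      outside <- setdiff(fam$id, idx$carriers[[p]])
      expect_false(any(vapply(outside,
                              function(id) grepl(p, res[[id]], fixed = TRUE),
                              logical(1L))))
    }
  }
})

test_that("uniqueness_mask flags positions by carrier count", {
  idx <- build_index(toy_family(), 3)
  mask <- uniqueness_mask(idx, "a", 1)
  expect_identical(mask$flags, c(TRUE, TRUE, TRUE, TRUE,
                                 FALSE, FALSE, FALSE, FALSE))
  # m = family size: everything is unique at that level
  expect_true(all(uniqueness_mask(idx, "a", 2)$flags))
  # identical members share every pattern
  twins <- seq_family(c("t1", "t2"), c("NYRWRCKNQN", "NYRWRCKNQN"))
  expect_false(any(uniqueness_mask(build_index(twins, 3), "t1", 1)$flags))
  expect_error(uniqueness_mask(idx, "zz", 1), "not in the index")
  expect_error(uniqueness_mask(idx, "a", 0), "m must be")
})

test_that("merge_segments merges runs of consecutive flagged starts", {
  idx <- build_index(toy_family(), 3)
  segs <- merge_segments(uniqueness_mask(idx, "a", 1), idx)
  expect_identical(segs$start, 1L)
  expect_identical(segs$end, 6L)
  expect_identical(segs$segment, "NYRWRC")
  expect_identical(segs$level, 1L)

  # all-false mask gives an empty frame
  twins <- seq_family(c("t1", "t2"), c("NYRWRCKNQN", "NYRWRCKNQN"))
  idx2 <- build_index(twins, 3)
  expect_identical(nrow(merge_segments(uniqueness_mask(idx2, "t1", 1), idx2)),
                   0L)

  # runs {1} and {5} on a length-7 member: adjacent but non-overlapping
  # patterns are not merged (flags at starts 2..4 are false)
  fake_idx <- structure(list(L = 3L, carriers = list(),
                             residues = c(x = "ABCDEFG"), members = "x"),
                        class = "pp_index")
  fake_mask <- structure(list(member = "x", L = 3L, m = 1L,
                              flags = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                              counts = c(1L, 2L, 2L, 2L, 1L)),
                         class = "uniq_mask")
  segs2 <- merge_segments(fake_mask, fake_idx)
  expect_identical(segs2$start, c(1L, 5L))
  expect_identical(segs2$end, c(3L, 7L))
  expect_identical(segs2$segment, c("ABC", "EFG"))
})

test_that("disjoint-alphabet members are unique over their full length", {
  fam <- seq_family(
    c("p", "q"),
    c(paste(rep(c("A", "C", "D", "E", "G"), 10), collapse = ""),
      paste(rep(c("F", "H", "I", "K", "L"), 10), collapse = "")))
  segs <- unique_segments(fam, L = 3, m = 1)
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$start, c(1L, 1L))
  expect_identical(segs$end, c(50L, 50L))
})

test_that("unique_segments equals the brute-force oracle on random families", {
  set.seed(202)
  for (rep in 1:50) {
    fam <- random_family(sample(2:8, 1), c(8L, 60L),
                         alphabet_size = sample(c(4L, 6L, 12L, 20L), 1))
    L <- sample(2:4, 1)
    m <- sample(1:2, 1)
    got <- canon_segments(unique_segments(fam, L = L, m = m))
    want <- canon_segments(oracle_unique_segments(fam, L = L, m = m))
    expect_identical(got, want)
  }
})

test_that("segments are maximal: extending either end breaks uniqueness", {
  set.seed(303)
  fam <- random_family(5, c(20L, 50L), alphabet_size = 5)
  L <- 3L
  idx <- build_index(fam, L)
  segs <- unique_segments(fam, L = L, m = 1)
  for (r in seq_len(nrow(segs))) {
    mask <- uniqueness_mask(idx, segs$member[r], 1)
    first <- segs$start[r]; last_start <- segs$end[r] - L + 1L
    if (first > 1L) expect_false(mask$flags[first - 1L])
    if (last_start + 1L <= length(mask$flags)) {
      expect_false(mask$flags[last_start + 1L])
    }
    # starts strictly increase; adjacent segments share at most L-2 residues
    same <- segs[segs$member == segs$member[r], ]
    if (nrow(same) > 1L) {
      expect_true(all(diff(same$start) > 0))
      expect_true(all(same$start[-1L] - same$end[-nrow(same)] >= 3L - L))
    }
  }
})

test_that("flagged positions are monotone in the uniqueness level m", {
  set.seed(404)
  for (rep in 1:10) {
    fam <- random_family(5, c(15L, 40L), alphabet_size = 6)
    idx <- build_index(fam, 3)
    for (id in fam$id) {
      f1 <- uniqueness_mask(idx, id, 1)$flags
      f2 <- uniqueness_mask(idx, id, 2)$flags
      f5 <- uniqueness_mask(idx, id, 5)$flags
      expect_true(all(f2[f1]))   # every m=1 flag survives at m=2
      expect_true(all(f5[f2]))
      expect_true(all(f5))       # m = family size flags everything
    }
  }
  # containment of segments: each level-m segment inside some level-(m+1) one
  set.seed(405)
  fam <- random_family(6, c(20L, 40L), alphabet_size = 5)
  s1 <- unique_segments(fam, 3, 1)
  s2 <- unique_segments(fam, 3, 2)
  for (r in seq_len(nrow(s1))) {
    within <- s2$member == s1$member[r] & s2$start <= s1$start[r] &
      s2$end >= s1$end[r]
    expect_true(any(within))
  }
})

test_that("flagged positions grow with the pattern length L", {
  set.seed(505)
  for (rep in 1:10) {
    fam <- random_family(4, c(15L, 40L), alphabet_size = 5)
    idx3 <- build_index(fam, 3)
    idx4 <- build_index(fam, 4)
    for (id in fam$id) {
      f3 <- uniqueness_mask(idx3, id, 1)$flags
      f4 <- uniqueness_mask(idx4, id, 1)$flags
      # a unique 3-window's containing 4-window (same start) is also unique
      shared <- seq_along(f4)
      expect_true(all(f4[shared][f3[shared]]))
    }
  }
})

test_that("results do not depend on member order", {
  set.seed(606)
  fam <- random_family(6, c(15L, 40L), alphabet_size = 6)
  perm <- sample(nrow(fam))
  fam2 <- seq_family(fam$id[perm], fam$residues[perm], fam$desc[perm])
  expect_identical(canon_segments(unique_segments(fam, 3, 1)),
                   canon_segments(unique_segments(fam2, 3, 1)))
})

test_that("a two-member family is required", {
  expect_error(unique_segments(seq_family("solo", "NYRWRCKNQN")), ">= 2")
})
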