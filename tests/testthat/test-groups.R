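test_that("unique KO counts are row sums of the binary matrix", {
  pm <- toy_matrix(list(S1 = c(1, 1, 0, 1), S2 = c(0, 0, 0, 0)))
  counts <- unique_ko_counts(pm)
  expect_equal(unname(counts[["S1"]]), 3L)
  expect_equal(unname(counts[["S2"]]), 0L)
})

test_that("group presence applies the at-least-min_present rule", {
  pm <- toy_matrix(list(d1 = c(1, 0, 1), d2 = c(0, 0, 1), d3 = c(0, 0, 0),
                        p1 = c(1, 0, 0), p2 = c(0, 0, 0)))
  diplo <- species_group("diplonemids", c("d1", "d2", "d3"), 2L)
  prokin <- species_group("prokinetoplastina", c("p1", "p2"), 1L)
  gm <- group_presence(pm, list(diplo, prokin))
  # feature 1: one diplonemid only -> 0; one prokinetoplastid -> 1
  expect_equal(unname(gm["diplonemids", 1]), 0L)
  expect_equal(unname(gm["prokinetoplastina", 1]), 1L)
  # feature 3: two diplonemids -> 1
  expect_equal(unname(gm["diplonemids", 3]), 1L)

  overlapping <- species_group("x", c("d1", "p1"), 1L)
  expect_error(group_presence(pm, list(diplo, overlapping)), "overlap")
  expect_silent(group_presence(pm, list(diplo, overlapping),
                               allow_overlap = TRUE))
})

test_that("singleton groups with min_present 1 reproduce species rows", {
  pm <- toy_matrix(list(S1 = c(1, 0, 1), S2 = c(0, 1, 1)))
  gm <- group_presence(pm, list(species_group("S1", "S1", 1L),
                                species_group("S2", "S2", 1L)))
  expect_equal(unname(gm["S1", ]), unname(pm$matrix["S1", ]))
  expect_equal(unname(gm["S2", ]), unname(pm$matrix["S2", ]))
})

test_that("exclusive intersections match brute-force pattern tallies", {
  # 2 groups, patterns {10, 01, 11, 00}
  pm <- toy_matrix(list(a = c(1, 0, 1, 0), b = c(0, 1, 1, 0)))
  gm <- group_presence(pm, list(species_group("A", "a", 1L),
                                species_group("B", "b", 1L)))
  res <- exclusive_intersections(gm)
  counts <- stats::setNames(res$count, res$subset)
  expect_equal(unname(counts[c("A", "B", "A&B")]), c(1L, 1L, 1L))
  expect_equal(sum(res$count), 3L)  # the 00 feature contributes nowhere

  # 3 groups, 8 features covering all 7 nonempty patterns plus one absent
  pats <- rbind(expand.grid(0:1, 0:1, 0:1), c(0, 0, 0))
  mat <- t(as.matrix(pats))
  rownames(mat) <- c("a", "b", "c")
  colnames(mat) <- sprintf("K%05d", seq_len(ncol(mat)))
  pm3 <- presence_matrix(mat)
  gm3 <- group_presence(pm3, list(species_group("A", "a", 1L),
                                  species_group("B", "b", 1L),
                                  species_group("C", "c", 1L)))
  res3 <- exclusive_intersections(gm3)
  # independent brute force: tally per-feature patterns directly
  brute <- table(apply(mat, 2, paste, collapse = ""))
  brute <- brute[names(brute) != "000"]
  expect_equal(sum(res3$count), sum(brute))
  expect_equal(nrow(res3), length(brute))
  expect_equal(sum(res3$count), 7L)
})

test_that("exclusive subset counts conserve the present-feature total", {
  for (seed in 1:60) {
    case <- random_group_case(seed)
    gm <- group_presence(case$pm, case$groups)
    res <- exclusive_intersections(gm)
    expect_equal(sum(res$count), sum(colSums(gm) > 0L))
    feats <- attr(res, "features")
    expect_false(anyDuplicated(unlist(feats)) > 0)  # partition, not cover
  }
})

test_that("shared-loss screen requires absence in targets, presence in background", {
  rows <- list(k1 = c(0, 0, 1), k2 = c(0, 0, 0),       # target group 1
               c1 = c(0, 1, 0), c2 = c(0, 0, 0),       # target group 2
               b1 = c(1, 1, 1), b2 = c(1, 1, 0),
               b3 = c(1, 0, 0), b4 = c(0, 1, 0))       # background
  pm <- toy_matrix(rows)
  g1 <- species_group("kineto", c("k1", "k2"), 1L)
  g2 <- species_group("cili", c("c1", "c2"), 1L)
  bg <- c("b1", "b2", "b3", "b4")
  hits <- shared_loss_screen(pm, list(g1, g2), bg, min_background = 3L)
  # feature 1: absent in all targets, present in 3 background -> in
  expect_identical(hits, "K00001")
  # feature 2: present in one target species -> excluded
  # feature 3: absent in targets... no, present in k1 -> excluded
  hits2 <- shared_loss_screen(pm, list(g1, g2), bg, min_background = 4L)
  expect_length(hits2, 0L)
  expect_error(shared_loss_screen(pm, list(g1, g2), character(0)), "empty")
  expect_error(shared_loss_screen(pm, list(g1, g2), c("k1", "b1")),
               "overlap")
})

test_that("repertoire t test matches the closed-form pooled oracle", {
  a <- c(8, 9, 10, 11); b <- c(1, 2, 3, 4)
  res <- compare_versatility(a, b, method = "student")
  # independent textbook computation
  n1 <- 4; n2 <- 4
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = n1 + n2 - 2)
  expect_equal(res$t, t_oracle, tolerance = 1e-9)
  expect_equal(res$p, p_oracle, tolerance = 1e-9)
  expect_equal(res$df, 6)

  # identical degenerate samples
  res0 <- compare_versatility(c(5, 5, 5), c(5, 5, 5))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  # gross separation forces significance
  res1 <- compare_versatility(c(10, 12, 14), c(110, 112, 114))
  expect_lt(res1$p, 1e-6)

  expect_error(compare_versatility(1, c(1, 2)), "n >= 2")
})

test_that("t test is symmetric and Welch differs under unequal variances", {
  a <- c(3, 9, 14, 21, 8); b <- c(10, 11, 10, 12)
  r1 <- compare_versatility(a, b)
  r2 <- compare_versatility(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  rw <- compare_versatility(a, b, method = "welch")
  expect_false(isTRUE(all.equal(rw$df, r1$df)))
  expect_equal(rw$p, stats::t.test(a, b)$p.value)
})
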