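test_that("dice identities hold", {
  a <- labs3(0L, c(2, 4, 4)); a$data[1, 1:2, 1:2] <- 1L
  expect_equal(dice(a, a), 1)
  b <- labs3(0L, c(2, 4, 4)); b$data[2, 3:4, 3:4] <- 7L
  expect_equal(dice(a, b), 0)   # disjoint masks
  empty <- labs3(0L, c(2, 4, 4))
  expect_equal(dice(empty, empty), 1)  # both empty, by convention
  expect_error(dice(a, labs3(0L, c(2, 4, 5))), "different shapes")
})

test_that("dice matches the closed form 2*overlap/(|A|+|B|)", {
  # |Fa| = |Fb| = 100 with overlap 85 -> 0.85
  a <- labs3(0L, c(1, 10, 20)); a$data[1, , 1:10] <- 1L
  b <- labs3(0L, c(1, 10, 20))
  b$data[1, , 1:10] <- 2L
  b$data[1, 1:5, 10] <- 0L         # remove 5 shared voxels...
  b$data[1, 1:5, 11] <- 2L         # ...and move them outside A; overlap 95
  expect_equal(dice(a, b), 2 * 95 / 200)
  b$data[1, 6:10, 10] <- 0L; b$data[1, 6:10, 11] <- 2L
  b$data[1, 1:5, 9] <- 0L; b$data[1, 1:5, 12] <- 2L
  expect_equal(dice(a, b), 2 * 85 / 200)
})

test_that("dice is symmetric, bounded, and monotone in shared voxels", {
  set.seed(31)
  for (i in 1:5) {
    a <- labs3(sample(0:2, 4^3, replace = TRUE), c(4, 4, 4))
    b <- labs3(sample(0:2, 4^3, replace = TRUE), c(4, 4, 4))
    d <- dice(a, b)
    expect_equal(d, dice(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
    # adding a voxel to both masks never decreases the score
    off <- which(a$data == 0L & b$data == 0L)
    if (length(off)) {
      a2 <- a; b2 <- b
      a2$data[off[1]] <- 1L; b2$data[off[1]] <- 1L
      expect_gte(dice(a2, b2), d)
    }
  }
})

test_that("per-region dice matches regions across volumes", {
  a <- labs3(0L, c(1, 6, 6)); a$data[1, 1:3, 1:3] <- 1L; a$data[1, 5:6, 5:6] <- 2L
  b <- labs3(0L, c(1, 6, 6)); b$data[1, 1:3, 1:3] <- 9L
  tab <- dice(a, b, per_region = TRUE)
  expect_equal(tab$label_b[tab$label_a == 1L], 9L)
  expect_equal(tab$dice[tab$label_a == 1L], 1)
  expect_true(is.na(tab$label_b[tab$label_a == 2L]))
  expect_equal(tab$dice[tab$label_a == 2L], 0)
})

test_that("count_regions counts distinct positive labels", {
  expect_equal(count_regions(labs3(0L, c(2, 2, 2))), 0)
  l <- labs3(0L, c(2, 2, 2)); l$data[1, 1, 1] <- 3L; l$data[2, 2, 2] <- 7L
  expect_equal(count_regions(l), 2)
  merged <- merge_regions(l, 3L, 7L)
  expect_equal(count_regions(merged), 1)
})

test_that("the reliability gate applies both criteria", {
  # build pairs with controlled dice and counts on a 1 x 10 x 100 grid
  make_pair <- function(overlap, n_a, n_b) {
    a <- labs3(0L, c(1, 10, 200)); b <- labs3(0L, c(1, 10, 200))
    a$data[1, , 1:10] <- 1L                  # 100 voxels
    b$data[1, , (11 - round(overlap / 10)):10] <- 1L
    b$data[1, , 11:(20 - round(overlap / 10))] <- 1L
    # sprinkle extra tiny regions to set the counts
    for (j in seq_len(n_a - 1)) a$data[1, 1, 100 + 2 * j] <- j + 1L
    for (j in seq_len(n_b - 1)) b$data[1, 1, 100 + 2 * j] <- j + 1L
    list(a = a, b = b)
  }
  # dice 0.885-like pass: same counts, high overlap
  p <- make_pair(90, 39, 39)
  rep <- reliability_check(p$a, p$b)
  expect_equal(rep$count_a, 39); expect_equal(rep$count_b, 39)
  expect_gte(rep$dice, 0.85)
  expect_true(rep$passed)
  # dice below the gate fails even with equal counts
  p2 <- make_pair(80, 10, 10)
  rep2 <- reliability_check(p2$a, p2$b)
  expect_lt(rep2$dice, 0.85)
  expect_false(rep2$passed)
  # good dice but counts differing by 2 fails
  p3 <- make_pair(90, 39, 41)
  rep3 <- reliability_check(p3$a, p3$b)
  expect_gte(rep3$dice, 0.85)
  expect_false(rep3$passed)
  # counts within +/- 1 pass
  p4 <- make_pair(90, 39, 40)
  expect_true(reliability_check(p4$a, p4$b)$passed)
})

test_that("percent reduction reproduces the case-study arithmetic", {
  expect_equal(percent_reduction(554, 304), 45.1)
  expect_equal(percent_reduction(100, 100), 0.0)
  expect_equal(percent_reduction(100, 0), 100.0)
  expect_error(percent_reduction(0, 10), "positive")
  expect_error(percent_reduction(-5, 10), "positive")
})

test_that("paired t-test matches the closed form", {
  a <- c(10, 12, 14, 16); b <- c(8, 9, 11, 12)
  st <- paired_t_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_hand), df = length(d) - 1)
  ci_hand <- mean(d) + c(-1, 1) * qt(0.975, 3) * sd(d) / sqrt(4)
  expect_equal(st$t_statistic, t_hand)
  expect_equal(st$p_value, p_hand)
  expect_equal(st$ci95, ci_hand)
  expect_equal(st$mean_difference, mean(d))
  expect_equal(st$percent_reduction, round(100 * (mean(a) - mean(b)) / mean(a), 1))
  expect_true(st$ci95[1] <= st$mean_difference &&
              st$mean_difference <= st$ci95[2])
})

test_that("degenerate paired differences are handled explicitly", {
  x <- c(5, 9, 13)
  st <- paired_t_test(x, x)
  expect_true(is.nan(st$t_statistic))
  expect_equal(st$p_value, 1)
  st2 <- paired_t_test(x + 3, x)
  expect_equal(st2$mean_difference, 3)
  expect_equal(st2$ci95, c(3, 3))
  expect_equal(st2$t_statistic, Inf)
  expect_equal(st2$p_value, 0)
})

test_that("swapping groups negates t and the difference, keeps p", {
  set.seed(41)
  a <- rnorm(8, 50, 5); b <- rnorm(8, 45, 5)
  st <- paired_t_test(a, b)
  sw <- paired_t_test(b, a)
  expect_equal(sw$t_statistic, -st$t_statistic)
  expect_equal(sw$mean_difference, -st$mean_difference)
  expect_equal(sw$p_value, st$p_value)
})

test_that("paired t-test validates its input", {
  expect_error(paired_t_test(1:3, 1:4), "equal length")
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(c(1, NA), c(1, 2)), "missing")
})
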