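test_that("partition_samples halves the cases, base gets the odd one", {
  set.seed(41)
  p4 <- partition_samples(4)
  expect_length(p4$base, 2); expect_length(p4$query, 2)
  expect_setequal(c(p4$base, p4$query), 1:4)

  p5 <- partition_samples(5)
  expect_length(p5$base, 3); expect_length(p5$query, 2)
  expect_length(intersect(p5$base, p5$query), 0)

  expect_error(partition_samples(1), "at least 2")

  # dynamic redraws: each sample lands in base ~ Binomial(200, 0.5)
  counts <- integer(10)
  for (i in 1:200) counts <- counts + tabulate(partition_samples(10)$base, 10)
  expect_true(all(counts >= 60 & counts <= 140))
})

test_that("supports, multiplicities and mean accuracy obey the bookkeeping", {
  set.seed(51)
  d <- random_dataset(20, 30, classes = 2)
  for (mode in c("dynamic", "fixed")) {
    prm <- rknn_params(k = 3, r = 100, m = 5, partition_mode = mode,
                       seed = 51)
    s <- compute_supports(d, prm)
    acc <- attr(s, "acc")
    expect_length(acc, 100)
    expect_true(all(acc >= 0 & acc <= 1))
    expect_true(all(s$support >= 0 & s$support <= 1, na.rm = TRUE))
    # conservation: sum_f M(f) support(f) = m * sum acc
    lhs <- sum(s$multiplicity * s$support, na.rm = TRUE)
    expect_equal(lhs, 5 * sum(acc), tolerance = 1e-12)
    expect_identical(sum(s$multiplicity), 500L)  # r * m
    expect_equal(attr(s, "mean_acc"), mean(acc))
    # support defined exactly where multiplicity >= 1
    expect_identical(is.na(s$support), s$multiplicity == 0L)
  }
})

test_that("pre-specified subsets/partitions reproduce the loop oracle", {
  set.seed(61)
  d <- random_dataset(12, 8, classes = 3)
  subsets <- list(c(1, 4, 7), c(2, 4, 8), c(3, 5, 6))
  partitions <- replicate(3, partition_samples(12), simplify = FALSE)
  s <- compute_supports(d, rknn_params(k = 1, r = 3),
                        subsets = do.call(rbind, subsets),
                        partitions = partitions)
  ref <- bf_supports(d, subsets, partitions, k = 1)
  expect_equal(attr(s, "acc"), ref$acc)
  expect_equal(s$multiplicity, ref$multiplicity)
  expect_equal(s$support, ref$support)
})

test_that("fixed partition and fixed seed give bit-identical rankings", {
  d <- random_dataset(16, 25)
  prm <- rknn_params(k = 1, r = 50, partition_mode = "fixed", seed = 77)
  s1 <- compute_supports(d, prm)
  s2 <- compute_supports(d, prm)
  expect_identical(s1$support, s2$support)
  expect_identical(attr(s1, "acc"), attr(s2, "acc"))
})

test_that("rank_features orders by support, multiplicity, then id", {
  tab <- data.frame(feature_id = c("a", "b", "c", "d"),
                    multiplicity = c(10L, 5L, 12L, 0L),
                    support = c(0.9, 0.7, 0.9, NA))
  rk <- rank_features(tab)
  expect_equal(rk$feature_id, c("c", "a", "b", "d"))
  expect_equal(rk$rank, c(1L, 2L, 3L, NA))

  # singleton
  one <- data.frame(feature_id = "x", multiplicity = 1L, support = 0.5)
  expect_equal(rank_features(one)$rank, 1L)

  expect_error(rank_features(data.frame(feature_id = "x",
                                        multiplicity = 0L,
                                        support = NA_real_)),
               "no feature has defined support")

  # random tables vs a stable-sort oracle
  set.seed(71)
  for (i in 1:200) {
    p <- sample(3:30, 1)
    tab <- data.frame(
      feature_id = sprintf("f%02d", seq_len(p)),
      multiplicity = sample(0:5, p, replace = TRUE),
      support = sample(seq(0, 1, 0.25), p, replace = TRUE))
    tab$support[tab$multiplicity == 0] <- NA
    if (all(is.na(tab$support))) next
    rk <- rank_features(tab)
    def <- tab[!is.na(tab$support), ]
    oracle <- def[order(-def$support, -def$multiplicity,
                        seq_len(nrow(def))), "feature_id"]
    expect_identical(rk$feature_id[seq_along(oracle)], oracle)
    expect_identical(sort(rk$feature_id), sort(tab$feature_id))
  }
})

test_that("supports TSV writes NA support with blank rank", {
  d <- tiny_fixture()
  s <- compute_supports(d, rknn_params(k = 1, r = 3),
                        subsets = rbind(c(1, 2), c(3, 4), c(2, 5)),
                        partitions = list(list(base = c(1, 2, 5, 6)),
                                          list(base = c(3, 4, 7, 8)),
                                          list(base = c(1, 3, 5, 7))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_supports(s, path)
  lines <- readLines(path)
  expect_equal(lines[1], "feature_id\tmultiplicity\tsupport\trank")
  expect_equal(length(lines), 7)
  expect_match(lines[7], "^f6\t0\tNA\t$")  # undefined support last, blank rank
})
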