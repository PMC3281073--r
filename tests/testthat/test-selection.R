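test_that("geometric schedule matches its closed form", {
  # ni = floor(log(min_dim / p) / log(1 - q)), retention ceil(p (1 - q))
  sched <- geometric_schedule(100, 0.5)
  expect_length(sched, 4)                       # floor(4.64)
  expect_equal(sched, c(100L, 50L, 25L, 13L))

  for (case in list(c(5327, 0.2), c(2000, 0.2), c(100, 0.2), c(731, 0.37))) {
    p <- case[1]; q <- case[2]
    sched <- geometric_schedule(p, q)
    ni <- floor(log(4 / p) / log(1 - q))
    expect_lte(length(sched), ni)
    expect_equal(sched[1], p)
    expect_equal(sched[-1],
                 vapply(seq_len(length(sched) - 1),
                        function(i) as.integer(ceiling(sched[i] * (1 - q))),
                        integer(1)))
    expect_true(all(sched >= 4))
    expect_true(all(diff(sched) < 0))
    # early stop only when the next step would violate the floor or stall
    nxt <- ceiling(sched[length(sched)] * (1 - q))
    if (length(sched) < ni)
      expect_true(nxt < 4 || nxt >= sched[length(sched)])
  }

  # adversarial small-p/q pairs: the min_dim guard wins over the ni formula
  for (p in 5:12) {
    for (q in c(0.05, 0.1, 0.2, 0.5, 0.9)) {
      sched <- geometric_schedule(p, q)
      expect_true(all(sched >= 4))
      expect_true(all(diff(sched) < 0) || length(sched) == 1)
    }
  }
  expect_error(geometric_schedule(100, 1.5), "must lie in")
})

test_that("linear schedule runs floor((p_start - min_dim)/d) steps", {
  expect_equal(linear_schedule(10, 1), c(10L, 9L, 8L, 7L, 6L, 5L, 4L))
  expect_equal(linear_schedule(10, 4), c(10L, 6L))       # one step
  expect_equal(linear_schedule(10, 7), c(10L))           # d > p_start - 4
  expect_equal(linear_schedule(4, 1), c(4L))
  expect_equal(linear_schedule(103, 5), seq(103L, 8L, by = -5L))
})

test_that("the pre-max rule picks the iteration before the accuracy peak", {
  expect_equal(rknnfs:::pre_max_index(c(0.70, 0.80, 0.90, 0.85)), 2L)
  expect_equal(rknnfs:::pre_max_index(c(0.95, 0.80, 0.70)), 1L)  # clamp
  expect_equal(rknnfs:::pre_max_index(c(0.7, 0.9, 0.9, 0.8)), 1L) # early tie
  expect_equal(rknnfs:::argmax_first(c(0.7, 0.9, 0.9)), 2L)
})

test_that("geometric stage traces follow the schedule and nest", {
  set.seed(81)
  sim <- synthetic_dataset(n = 30, p = 40, n_informative = 5, shift = 2,
                           seed = 81)
  prm <- rknn_params(k = 3, r = 80, q = 0.5, seed = 81)
  tr <- geometric_stage(sim$dataset, prm)
  counts <- vapply(tr$iterations, function(it) it$n_features, integer(1))
  expect_equal(counts, geometric_schedule(40, 0.5))
  for (i in seq_along(tr$iterations)[-1])
    expect_true(all(tr$iterations[[i]]$feature_ids %in%
                      tr$iterations[[i - 1]]$feature_ids))
  expect_true(tr$chosen_index >= 1 &&
                tr$chosen_index <= length(tr$iterations))
})

test_that("linear stage drops d per iteration from the start set", {
  set.seed(82)
  sim <- synthetic_dataset(n = 30, p = 40, n_informative = 5, shift = 2,
                           seed = 82)
  start <- sim$dataset$feature_ids[1:10]
  tr <- linear_stage(sim$dataset, start, rknn_params(k = 3, r = 60, seed = 82))
  counts <- vapply(tr$iterations, function(it) it$n_features, integer(1))
  expect_equal(counts, 10:4)
  expect_equal(tr$iterations[[1]]$feature_ids, start)
  for (i in seq_along(tr$iterations)[-1])
    expect_true(all(tr$iterations[[i]]$feature_ids %in%
                      tr$iterations[[i - 1]]$feature_ids))
})

test_that("rknn_fs chains the stages, respects min_dim and is seed-stable", {
  set.seed(83)
  sim <- synthetic_dataset(n = 40, p = 60, n_informative = 6, shift = 2,
                           seed = 83)
  prm <- rknn_params(k = 3, r = 100, seed = 83)
  fit1 <- rknn_fs(sim$dataset, prm)
  fit2 <- rknn_fs(sim$dataset, prm)
  expect_identical(fit1$selected, fit2$selected)
  expect_identical(vapply(fit1$geometric$iterations,
                          function(it) it$mean_accuracy, numeric(1)),
                   vapply(fit2$geometric$iterations,
                          function(it) it$mean_accuracy, numeric(1)))
  expect_gte(length(fit1$selected), 4)
  # the linear stage starts from the geometric pre-max set
  start <- fit1$geometric$iterations[[fit1$geometric$chosen_index]]$feature_ids
  expect_identical(fit1$linear$iterations[[1]]$feature_ids, start)
  expect_true(all(fit1$selected %in% start))

  # p = min_dim: no elimination possible, identity selection
  dsmall <- subset_dataset(sim$dataset, features = 1:4)
  fit_small <- rknn_fs(dsmall, rknn_params(r = 20, seed = 1))
  expect_identical(fit_small$selected, dsmall$feature_ids)
  expect_null(fit_small$geometric)

  # stage1_only stops at the geometric pre-max set
  fit_s1 <- rknn_fs(sim$dataset, prm, stage1_only = TRUE)
  expect_null(fit_s1$linear)
  geo <- fit_s1$geometric
  expect_identical(fit_s1$selected,
                   geo$iterations[[geo$chosen_index]]$feature_ids)
})

test_that("trace and selection writers emit well-formed, rereadable TSV", {
  set.seed(84)
  sim <- synthetic_dataset(n = 24, p = 20, n_informative = 4, shift = 2,
                           seed = 84)
  fit <- rknn_fs(sim$dataset, rknn_params(k = 1, r = 40, q = 0.5, seed = 84))
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_trace(fit, tpath)
  tab <- read.delim(tpath)
  expect_equal(names(tab), c("stage", "iteration", "n_features",
                             "mean_accuracy", "chosen", "feature_ids"))
  expect_equal(sum(tab$chosen[tab$stage == "geometric"]), 1)
  expect_true(all(tab$n_features ==
                    lengths(strsplit(tab$feature_ids, ";"))))
  spath <- withr::local_tempfile(fileext = ".txt")
  write_selected(fit, spath)
  expect_identical(readLines(spath), fit$selected)
})
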