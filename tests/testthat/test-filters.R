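test_that("extinction LTD is detected by strict record comparison", {
  ts <- enumerate_terminals(toy_experiment())        # record 1, final 0
  expect_true(ltd_occurred(ts, "wCStoCEm"))
  ts2 <- enumerate_terminals(toy_experiment(cem_bias = -1))  # record 2, final 1
  expect_true(ltd_occurred(ts2, "wCStoCEm"))
  expect_error(ltd_occurred(ts, "wCEmtoPAG"), "record-tracked")

  # record 1, final 1 is not LTD: check on a model 1 terminal slice
  m1 <- run_experiment(experiment(1, 1))
  i <- which(abs(m1$wLAi1toLA1) == abs(m1$record.wLAi1toLA1))
  expect_true(length(i) > 0)
  expect_false(any(ltd_occurred(m1, "wLAi1toLA1")[i]))
})

test_that("filters compose by conjunction and never increase the count", {
  exp <- experiment(1, 1)
  ts <- enumerate_terminals(exp)
  expect_identical(count_configurations(ts), nrow(ts))  # empty filter identity

  chain <- list()
  last <- nrow(ts)
  for (f in experiment(1, 6)$filters) {
    chain <- c(chain, list(f))
    n <- count_configurations(ts, chain)
    expect_lte(n, last)
    last <- n
  }

  # annotation columns mark each predicate
  sub <- apply_filters(ts, list(list(name = "ltd_of", args = "wLAi1toLA1")))
  expect_true("filter.1.ltd_of" %in% names(sub))
  expect_true(all(sub$filter.1.ltd_of))
})

test_that("counts are monotone along the nested condition chains", {
  t1 <- reproduce_table(1)
  expect_true(all(diff(t1$observed[c(1, 2, 4, 5, 6)]) <= 0))
  t2 <- reproduce_table(2)
  expect_true(all(diff(t2$observed[1:4]) <= 0))
})

test_that("whole-pathway potentiation holds in the surviving row-10 set", {
  ts <- run_experiment(experiment(1, 10))
  expect_equal(nrow(ts), 6)
  circ <- attr(ts, "experiment")$circuit
  M <- abs(as.matrix(ts[, circ$connections$name]))
  r <- fearext:::cs_response_matrix(circ, M, c("LA1", "LA2", "BA1", "BA2", "ITCm"))
  # all five elements respond equally and positively to the cue
  expect_true(all(r > 0))
  expect_true(all(apply(r, 1, function(v) length(unique(v)) == 1)))
})

test_that("CS-response predicates use strict inequalities", {
  exp <- experiment(2, 1)
  ts <- enumerate_terminals(exp)
  r <- fearext:::terminal_cs_responses(ts, c("LA1", "LA2"))
  exc <- fearext:::eval_filter(ts, list(name = "any_excited", args = c("LA1", "LA2")))
  ni1 <- fearext:::eval_filter(ts, list(name = "not_inhibited_by_cs", args = "LA1"))
  expect_equal(exc, r[, 1] > 0 | r[, 2] > 0)
  # a response of exactly zero is neither excited nor inhibited
  zero <- which(r[, 1] == 0)
  expect_true(length(zero) > 0)
  expect_true(all(ni1[zero]))
  # LA2 is never inhibited by the cue in model 2
  expect_true(all(r[, 2] >= 0))
})

test_that("table reproduction reports spaces, depths and comparisons", {
  tab <- reproduce_table(1)
  expect_equal(nrow(tab), 13)
  expect_named(tab, c("model", "row", "label", "space_size", "expected",
                      "observed", "max_depth", "pass"))
  expect_equal(tab$space_size[1], 78732)
  expect_true(all(tab$observed >= 0))
  expect_s3_class(autoplot(tab), "ggplot")
})
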