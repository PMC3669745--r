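test_that("the single-weight toy circuit enumerates as computed by hand", {
  # conditioning: one LTP step (0 -> 1) makes CEm = 1 > 0; record = 1;
  # extinction: one LTD step (1 -> 0) makes CEm = 0; terminal at depth 2
  ts <- enumerate_terminals(toy_experiment())
  expect_equal(nrow(ts), 1)
  expect_equal(ts$wCStoCEm, 0)
  expect_equal(ts$record.wCStoCEm, 1)
  expect_equal(ts$depth, 2L)
  expect_equal(attr(ts, "max_depth"), 2L)

  # with bCEm = -1 conditioning needs two LTP steps (record 2), extinction one
  ts2 <- enumerate_terminals(toy_experiment(cem_bias = -1))
  expect_equal(nrow(ts2), 1)
  expect_equal(ts2$wCStoCEm, 1)
  expect_equal(ts2$record.wCStoCEm, 2)
  expect_equal(ts2$depth, 3L)
})

test_that("applicable moves and the step semantics follow the rewriting rules", {
  exp <- experiment(1, 1)
  s0 <- initial_state(exp)
  mv <- applicable_moves(s0, exp)
  expect_equal(nrow(mv), 9)            # every modifiable weight can potentiate
  expect_true(all(mv$direction == 1))

  # potentiating wCStoLA2 lets the cue activate PAG: conditioning completes
  # and both interneuron weights are recorded at magnitude 1 (signed -1)
  d <- mv$dim[mv$name == "wCStoLA2"]
  s1 <- apply_move(s0, exp, d, 1L)
  expect_equal(s1$phase, "extinguishing")
  expect_equal(unname(s1$records), c(1, 1))
  expect_named(s1$records, c("wLAi1toLA1", "wLAi2toLA2"))

  # one LTD step on wBA2toCEm shuts CEm off: extinction complete
  mv1 <- applicable_moves(s1, exp)
  expect_true(all(mv1$direction == -1))
  s2 <- apply_move(s1, exp, mv1$dim[mv1$name == "wBA2toCEm"], -1L)
  expect_equal(s2$phase, "done")
  expect_equal(nrow(applicable_moves(s2, exp)), 0)

  # a saturated weight offers no further increase
  st <- s0
  st$mags["wCStoLA2"] <- 2
  expect_false("wCStoLA2" %in% applicable_moves(st, exp)$name)

  expect_error(apply_move(s0, exp, d, -1L), "not applicable")
})

test_that("memoized enumeration equals the all-sequences oracle", {
  for (row in c(10, 11, 12)) {
    exp <- experiment(1, row)
    fast <- enumerate_terminals(exp)
    slow <- enumerate_terminals_naive(exp, depth_limit = 40, max_paths = 5e6)
    expect_equal(nrow(fast), nrow(slow), info = paste("row", row))
    expect_identical(config_keys(fast), config_keys(slow),
                     info = paste("row", row))
    # shortest-sequence depths agree as well
    expect_equal(sort(fast$depth), sort(slow$depth), info = paste("row", row))
  }
  fast <- enumerate_terminals(toy_experiment())
  slow <- enumerate_terminals_naive(toy_experiment())
  expect_identical(config_keys(fast), config_keys(slow))

  expect_equal(nrow(enumerate_terminals_naive(toy_experiment(),
                                              depth_limit = 0)), 0)
})

test_that("the terminal set is invariant to move-offering order", {
  set.seed(99)
  for (row in c(7, 10)) {
    exp <- experiment(1, row)
    ref <- config_keys(enumerate_terminals(exp))
    for (k in 1:3) {
      perm <- sample(nrow(exp$circuit$connections))
      got <- config_keys(enumerate_terminals(permute_experiment(exp, perm)))
      expect_identical(got, ref, info = paste("row", row, "perm", k))
    }
  }
})

test_that("terminal states are extinguished and phases progress monotonically", {
  for (spec in list(c(1, 1), c(2, 1))) {
    exp <- experiment(spec[1], spec[2])
    ts <- enumerate_terminals(exp)
    # every terminal has PAG off under the extinction test context
    M <- abs(as.matrix(ts[, exp$circuit$connections$name]))
    off <- !fearext:::pag_flags(exp$circuit, M, us = 0, cs = 1, il = 1)
    expect_true(all(off))
    # neither baseline has extinction dead-ends: once conditioned, the
    # all-minimum extinction configuration always silences PAG
    expect_equal(attr(ts, "n_extinction_deadends"), 0L)
  }

  # phase never reverts: a done state offers no moves, an extinguishing state
  # only extinction moves
  exp <- toy_experiment()
  s <- initial_state(exp)
  s <- apply_move(s, exp, 1L, 1L)
  expect_equal(s$phase, "extinguishing")
  s <- apply_move(s, exp, 1L, -1L)
  expect_equal(s$phase, "done")
  expect_equal(nrow(applicable_moves(s, exp)), 0)
})

test_that("atlas export writes a header and a stable data section", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ts <- enumerate_terminals(experiment(1, 10))
  write_atlas(ts, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# model: 1", lines)))
  body <- read.delim(path, comment.char = "#")
  expect_equal(nrow(body), nrow(ts))
  # byte-stable: a second write is identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(enumerate_terminals(experiment(1, 10)), path2)
  expect_identical(readLines(path2), lines)
})
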