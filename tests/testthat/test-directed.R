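test_that("the three-case error matches hand evaluation", {
  exp <- experiment(1, 1)
  p <- fearext:::ds_params(exp)
  zero <- structure(list(delta_cond = stats::setNames(rep(0, nrow(p)), p$name),
                         delta_ext = stats::setNames(rep(0, nrow(p)), p$name)),
                    class = "changeset")
  # unchanged weights: only the conditioned case fails
  expect_equal(changeset_error(zero, exp), 1)

  # the minimal integer solution: potentiate the cue input to the Fear
  # pathway, then depress its output synapse
  cs <- zero
  cs$delta_cond["wCStoLA2"] <- 1
  cs$delta_ext["wBA2toCEm"] <- -1
  expect_equal(changeset_error(cs, exp), 0)

  bad <- zero
  bad$delta_cond["wCStoLA2"] <- 3
  expect_error(changeset_error(bad, exp), "bounds")
})

test_that("random starts respect bounds, schedules and seeding", {
  for (m in 1:2) {
    exp <- experiment(m, 1)
    p <- fearext:::ds_params(exp)
    for (cs in c(FALSE, TRUE)) {
      set.seed(123)
      for (i in 1:200) {
        st <- sample_changeset(exp, constrain_signs = cs)
        fin_c <- p$init + st$delta_cond
        fin_e <- fin_c + st$delta_ext
        expect_true(all(fin_c >= 0 & fin_c <= 2))
        expect_true(all(fin_e >= 0 & fin_e <= 2))
        expect_true(all(st$delta_cond[!p$cond_free] == 0))
        expect_true(all(st$delta_ext[!p$ext_free] == 0))
        if (cs) {
          expect_true(all(st$delta_cond[p$cond_dir > 0] >= 0))
          expect_true(all(st$delta_ext[p$ext_dir < 0] <= 0))
        }
      }
    }
    # model 2's IL weights are structurally frozen during conditioning
    if (m == 2) {
      set.seed(5)
      st <- sample_changeset(exp)
      expect_equal(unname(st$delta_cond[grep("^wILto", p$name)]), rep(0, 3))
    }
  }
  set.seed(77); a <- sample_changeset(experiment(1, 1))
  set.seed(77); b <- sample_changeset(experiment(1, 1))
  expect_identical(a, b)
})

test_that("pattern search honours the accept/double, reject/halve rule", {
  exp <- experiment(1, 1)
  p <- fearext:::ds_params(exp)
  zero <- structure(list(delta_cond = stats::setNames(rep(0, nrow(p)), p$name),
                         delta_ext = stats::setNames(rep(0, nrow(p)), p$name)),
                    class = "changeset")
  sol <- zero
  sol$delta_cond["wCStoLA2"] <- 1
  sol$delta_ext["wBA2toCEm"] <- -1

  # a zero-error start is returned unchanged
  res <- pattern_search(sol, exp, keep_trace = TRUE)
  expect_equal(res$error, 0)
  expect_equal(res$changeset$delta_cond, sol$delta_cond)
  expect_equal(res$changeset$delta_ext, sol$delta_ext)
  expect_false(any(res$trace$accepted))
  # with no accepted move, Delta halves from 0.5 down through 1e-6
  expect_equal(res$iterations, sum(0.5 / 2^(0:60) >= 1e-6))

  # error is non-increasing along any trace
  set.seed(11)
  for (i in 1:10) {
    st <- sample_changeset(exp)
    r <- pattern_search(st, exp, keep_trace = TRUE)
    expect_true(all(diff(r$trace$error) <= 0))
    expect_lte(r$error, changeset_error(st, exp))
  }
})

test_that("integer terminal configurations embed as zero-error change sets", {
  # toy circuit: conditioning delta = record - initial, extinction delta =
  # final - record reproduce the search outcome exactly
  exp <- toy_experiment()
  ts <- enumerate_terminals(exp)
  cs <- structure(list(
    delta_cond = c(wCStoCEm = ts$record.wCStoCEm - 0),
    delta_ext = c(wCStoCEm = ts$wCStoCEm - ts$record.wCStoCEm)
  ), class = "changeset")
  expect_equal(changeset_error(cs, exp), 0)
})

test_that("batch summaries are seeded, consistent and tidy", {
  b1 <- batch_search(1, n = 25, seed = 9)
  b2 <- batch_search(1, n = 25, seed = 9)
  expect_identical(glance(b1), glance(b2))
  expect_equal(nrow(tidy(b1)), 25)
  expect_lte(b1$n_zero_error_with_ltd, b1$n_zero_error)
  expect_lte(b1$n_zero_error, b1$n)
  if (b1$n_zero_error > 0) {
    expect_equal(b1$ltd_percentage,
                 100 * b1$n_zero_error_with_ltd / b1$n_zero_error)
  }
  expect_s3_class(autoplot(b1), "ggplot")

  b0 <- batch_search(1, n = 0, seed = 1)
  expect_equal(b0$n_zero_error, 0)
  expect_true(is.na(b0$ltd_percentage))
})
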