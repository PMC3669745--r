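test_that("circuit validation rejects malformed specifications", {
  el <- data.frame(name = c("CS", "CEm", "PAG"), bias = c(0, 0, 0),
                   kind = c("input", "internal", "gate"))
  cn <- data.frame(source = c("CS", "CEm"), target = c("CEm", "PAG"),
                   sign = c(1, 1), initial = c(0, 1),
                   modifiable = c(TRUE, FALSE), record = c(TRUE, FALSE),
                   tie = NA_character_, cond = c("+", ""), ext = c("-", ""))

  bad <- cn; bad$target[1] <- "Nowhere"
  expect_error(circuit_spec(el, bad), "undeclared element")

  bad <- el; bad$name[2] <- "CS"
  expect_error(circuit_spec(bad, cn), "duplicate")

  bad <- cn; bad$record[2] <- TRUE
  expect_error(circuit_spec(el, bad), "modifiable")

  bad <- cn; bad$initial[1] <- 3
  expect_error(circuit_spec(el, bad), "\\[0, 2\\]")

  # cycle
  el2 <- rbind(el, data.frame(name = "X", bias = 0, kind = "internal"))
  cyc <- rbind(cn,
               data.frame(source = "CEm", target = "X", sign = 1, initial = 1,
                          modifiable = FALSE, record = FALSE, tie = NA_character_,
                          cond = "", ext = ""),
               data.frame(source = "X", target = "CEm", sign = 1, initial = 1,
                          modifiable = FALSE, record = FALSE, tie = NA_character_,
                          cond = "", ext = ""))
  expect_error(circuit_spec(el2, cyc), "cycle")

  # tie group over unequal initial magnitudes
  m2 <- model2()
  bad <- m2$connections
  bad$tie[bad$name %in% c("wCStoLAi", "wLAitoLA1")] <- "g"  # initials 0 and 1
  expect_error(circuit_spec(m2$elements, bad[, setdiff(names(bad), "name")]),
               "unequal initial magnitudes")
})

test_that("model 1 activities match the published initial conditions", {
  m1 <- model1()
  spont <- activities(m1)
  for (e in c("LA1", "LA2", "LAi1", "LAi2", "BA1", "BA2", "ITCm")) {
    expect_equal(spont[[e]], 1, info = e)
  }
  expect_equal(spont$CEm, 0)
  expect_false(spont$pag_active)

  # US alone drives the Fear pathway: LA2 = 2, BA2 = 2, CEm = 1, PAG on
  ur <- activities(m1, us = 1)
  expect_equal(ur$LA2, 2)
  expect_equal(ur$BA2, 2)
  expect_equal(ur$CEm, 1)
  expect_true(ur$pag_active)

  # the naive cue does nothing before conditioning; CEm = 0 is strictly "off"
  expect_false(pag_active(m1, cs = 1))
})

test_that("model 2 activities match the published initial conditions", {
  m2 <- model2()
  spont <- activities(m2)
  for (e in c("LAi", "LA1", "LA2", "ITCl", "ITCm")) {
    expect_equal(spont[[e]], 1, info = e)
  }
  expect_equal(spont$CEm, 0)
  expect_true(activities(m2, us = 1)$pag_active)
  expect_false(pag_active(m2, cs = 1))
})

test_that("activity evaluation is linear, integer and order-independent", {
  m1 <- model1()
  # zero weights leave every non-input element at its bias (linear mode)
  zero <- stats::setNames(rep(0, nrow(m1$connections)), m1$connections$name)
  a <- activities(m1, zero, us = 1, cs = 1, rectify = FALSE)
  bias <- stats::setNames(m1$elements$bias, m1$elements$name)
  for (e in c("LA1", "LA2", "BA1", "BA2", "ITCm", "CEm")) {
    expect_equal(a[[e]], bias[[e]], info = e)
  }

  # integer weights and biases give integer activities
  set.seed(1)
  for (i in 1:20) {
    mags <- stats::setNames(sample(0:2, nrow(m1$connections), replace = TRUE),
                            m1$connections$name)
    a <- activities(m1, mags, us = sample(0:1, 1), cs = sample(0:1, 1))
    expect_true(all(vapply(a[m1$elements$name], function(v) v == round(v),
                           logical(1))))
  }

  # permuting connection declarations changes nothing
  perm <- rev(seq_len(nrow(m1$connections)))
  cn <- m1$connections[perm, ]
  m1p <- circuit_spec(m1$elements, cn[, setdiff(names(cn), "name")])
  expect_equal(activities(m1p, us = 1)[, m1$elements$name],
               activities(m1, us = 1)[, m1$elements$name])

  expect_error(activities(m1, c(wCStoLA1 = 5)), "\\[0, 2\\]")
})

test_that("cs_response has the published structure", {
  m2 <- model2()
  # LA2 receives no inhibition: its cue response is exactly wCStoLA2
  expect_equal(cs_response(m2, "LA2")[["LA2"]], 0)
  set.seed(42)
  for (i in 1:25) {
    mags <- stats::setNames(sample(0:2, nrow(m2$connections), replace = TRUE),
                            m2$connections$name)
    r <- cs_response(m2, "LA2", mags)
    expect_equal(r[["LA2"]], mags[["wCStoLA2"]])
    expect_gte(r[["LA2"]], 0)
    # under linear semantics the IL context cancels out of the difference
    expect_equal(
      cs_response(m2, "LA1", mags, il = 0, rectify = FALSE),
      cs_response(m2, "LA1", mags, il = 1, rectify = FALSE)
    )
  }
  expect_error(cs_response(m2, "CS"), "non-input")
  expect_error(cs_response(m2, "nope"), "unknown")
})

test_that("circuit JSON round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  m2 <- model2()
  write_circuit_json(m2, path)
  back <- read_circuit_json(path)
  expect_equal(back$connections$name, m2$connections$name)
  expect_equal(back$elements$bias, m2$elements$bias)
  expect_equal(activities(back, us = 1), activities(m2, us = 1))
})
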