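test_that("component weights are the published sixteenths and sum to 1", {
  w <- cci_weights()
  expect_identical(sum(w), 1)
  expect_true(all(w > 0))
  expect_equal(w[["FPS"]], 4 / 16)
  expect_equal(w[["DTC3"]], 2 / 16)
  expect_equal(w[["MSL"]], 1 / 16)
})

test_that("score matches the index formula on canonical records", {
  cases <- list(
    list(rec = component_record(1), score = 1.0, label = "optimal"),
    list(rec = component_record(0), score = 0.0, label = "partial"),
    list(rec = component_record(0, FPS = 1), score = 0.25,
         label = "partial"),
    list(rec = component_record(0, DTC3 = 1), score = 0.125,
         label = "partial"),
    list(rec = component_record(1, FPS = 0), score = 0.75,
         label = "optimal"))
  for (cs in cases) {
    r <- compute_cci(cs$rec)
    expect_equal(r$score, cs$score)
    expect_identical(r$label, cs$label)
  }
})

test_that("dichotomisation is at 0.50, boundary inclusive", {
  expect_identical(classify_cci(0.50), "optimal")
  expect_identical(classify_cci(0.4999), "partial")
  expect_identical(classify_cci(1.0), "optimal")
  expect_identical(classify_cci(0), "partial")
  expect_error(classify_cci(1.2), "\\[0, 1\\]")
  expect_error(classify_cci(-0.1), "\\[0, 1\\]")
})

test_that("score is monotone in every component and lands on sixteenths", {
  set.seed(41)
  for (i in 1:50) {
    rec <- as.data.frame(as.list(stats::setNames(
      sample(0:1, 8, replace = TRUE), names(cci_weights()))))
    base <- compute_cci(rec)$score
    expect_equal(round(16 * base) , 16 * base, tolerance = 1e-12)
    for (cn in names(cci_weights())) {
      if (rec[[cn]] == 0) {
        up <- rec
        up[[cn]] <- 1
        expect_gt(compute_cci(up)$score, base)
      }
    }
  }
})

test_that("not-applicable handling follows the chosen policy", {
  rec <- component_record(1, ORT = NA, CPNM = NA, FPS = 0)
  # renormalise: drop ORT/CPNM (4/16), remaining weight 12/16, covered 8/16
  r <- compute_cci(rec, na_policy = "renormalise")
  expect_equal(r$score, (8 / 16) / (12 / 16))
  expect_true(r$renormalised)
  expect_equal(r$n_components, 6)
  expect_equal(compute_cci(rec, na_policy = "impute_zero")$score, 8 / 16)
  expect_equal(compute_cci(rec, na_policy = "impute_one")$score, 12 / 16)
  expect_true(is.na(compute_cci(rec, na_policy = "drop_record")$score))
  # all policies identical when everything is applicable
  full <- component_record(0, FPS = 1, MSL = 1)
  scores <- vapply(c("renormalise", "impute_zero", "impute_one",
                     "drop_record"),
                   function(p) compute_cci(full, na_policy = p)$score,
                   numeric(1))
  expect_true(all(scores == scores[1]))
})

test_that("invalid component data is rejected with record and field", {
  bad <- component_record(1, SBA = NA)
  expect_error(compute_cci(bad), "SBA.*record 1")
  bad2 <- component_record(1, MSL = 2)
  expect_error(compute_cci(bad2), "MSL")
  expect_error(compute_cci(component_record(1), na_policy = "nonsense"),
               "na_policy")
  expect_error(compute_cci(component_record(1)[, -1]), "FPS")
})

test_that("coverage_table reproduces simple and weighted shares", {
  d <- data.frame(cci_label = c("optimal", "partial"))
  t0 <- coverage_table(d)
  expect_equal(t0$pct_optimal, 50)
  expect_equal(t0$pct_partial, 50)
  des <- srs_design(d, weights = c(3, 1))
  t1 <- coverage_table(d, design = des)
  expect_equal(t1$wpct_optimal, 75)
  # empty group is reported, undefined-marked
  d2 <- data.frame(cci_label = c("optimal", "partial"),
                   g = factor(c("a", "a"), levels = c("a", "b")))
  t2 <- coverage_table(d2, by = "g")
  expect_equal(t2$n[t2$g == "b"], 0)
  expect_true(is.na(t2$pct_optimal[t2$g == "b"]))
})

test_that("coverage_table recovers the published 2012 sample split", {
  d <- data.frame(cci_label = rep(c("optimal", "partial"),
                                  c(1137, 1897)))
  t1 <- coverage_table(d, decimals = 1)
  expect_equal(t1$n, 3034)
  expect_equal(t1$pct_optimal, 37.5)
  expect_equal(t1$pct_partial, 62.5)
})

test_that("component_table uses applicable-record denominators", {
  d <- component_record(1)[rep(1, 4), ]
  d$ORT <- NA
  tab <- component_table(d)
  ort <- tab[tab$component == "ORT", ]
  expect_equal(ort$n_applicable, 0)
  expect_true(is.na(ort$pct))
  # census sample: weighted equals unweighted
  d2 <- do.call(rbind, list(component_record(1), component_record(0),
                            component_record(0, FPS = 1)))
  des <- srs_design(d2)
  tab2 <- component_table(d2, design = des, decimals = 1)
  expect_equal(tab2$wpct, tab2$pct)
  # published counts: 2238 of 3034 with qualified antenatal care -> 74%
  anc <- data.frame(component_record(0)[rep(1, 3034), ])
  anc$ANCS <- rep(c(1, 0), c(2238, 796))
  expect_equal(component_table(anc)[3, "pct"], 74)
})
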