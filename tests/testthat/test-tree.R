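walk_tree <- function(node, f) {
  f(node)
  if (!node$leaf) {
    walk_tree(node$left, f)
    walk_tree(node$right, f)
  }
}

test_that("a perfectly separating predictor yields a pure depth-1 tree", {
  d <- data.frame(x = rep(c(0, 1), each = 20),
                  y = rep(c(0, 1), each = 20))
  tr <- grow_tree(d, "y", "x")
  expect_false(tr$root$leaf)
  expect_identical(tr$root$split$var, "x")
  expect_true(tr$root$left$leaf && tr$root$right$leaf)
  expect_true(min(tr$root$left$w_class) == 0)
  expect_true(min(tr$root$right$w_class) == 0)
  pr <- predict(tr, d)
  expect_equal(pr$class, d$y)
})

test_that("a constant response gives a single leaf, not an error", {
  d <- data.frame(x = rnorm(30), y = rep(1, 30))
  tr <- grow_tree(d, "y", "x")
  expect_true(tr$root$leaf)
  expect_equal(tr$root$pred, 1L)
  expect_length(export_tree(tr, "text"), 1)
})

test_that("XOR is solved exactly at depth 2", {
  g <- expand.grid(a = c(0, 1), b = c(0, 1))
  d <- g[rep(1:4, each = 10), ]
  d$y <- as.numeric(xor(d$a == 1, d$b == 1))
  tr <- grow_tree(d, "y", c("a", "b"),
                  params = tree_params(max_depth = 2, min_node_weight = 2,
                                       min_improvement = 0))
  expect_equal(predict(tr, d)$class, d$y)
})

test_that("weighted class counts are conserved along every split", {
  set.seed(71)
  n <- 500
  d <- data.frame(num = rnorm(n),
                  cat = sample(c("p", "q", "r", "s"), n, TRUE),
                  y = rbinom(n, 1, 0.4))
  d$y[d$cat %in% c("p", "q")] <- rbinom(sum(d$cat %in% c("p", "q")), 1, 0.8)
  w <- runif(n, 0.5, 3)
  tr <- grow_tree(d, "y", c("num", "cat"), weights = w,
                  params = tree_params(max_depth = 4, min_node_weight = 20,
                                       min_improvement = 1e-4))
  walk_tree(tr$root, function(nd) {
    if (!nd$leaf) {
      expect_equal(nd$left$w + nd$right$w, nd$w, tolerance = 1e-10)
      expect_equal(nd$left$w_class + nd$right$w_class, nd$w_class,
                   tolerance = 1e-10)
      expect_gte(nd$improvement, tr$params$min_improvement)
    }
  })
  tr2 <- grow_tree(d, "y", c("num", "cat"), weights = w,
                   params = tree_params(max_depth = 4, min_node_weight = 20,
                                        min_improvement = 1e-4))
  expect_identical(export_tree(tr, "json"), export_tree(tr2, "json"))
})

test_that("prediction routes training records to their leaf majority", {
  set.seed(73)
  n <- 300
  d <- data.frame(a = rnorm(n), b = sample(c("u", "v", "w"), n, TRUE))
  d$y <- rbinom(n, 1, plogis(1.5 * d$a - 1 + (d$b == "u")))
  tr <- grow_tree(d, "y", c("a", "b"))
  pr <- predict(tr, d)
  leaves <- new.env()
  for (i in seq_len(n)) {
    key <- as.character(pr$node[i])
    leaves[[key]] <- c(leaves[[key]], pr$class[i])
  }
  for (key in ls(leaves)) expect_length(unique(leaves[[key]]), 1)
  expect_equal(nrow(predict(tr, d[0, ])), 0)
  # unknown categorical level routes to the heavier child with a warning
  dc <- data.frame(b = rep(c("u", "v"), each = 25),
                   y = rep(c(0, 1), each = 25))
  trc <- grow_tree(dc, "y", "b")
  expect_warning(pz <- predict(trc, data.frame(b = "zz")),
                 "unknown categorical")
  heavier <- if (trc$root$left$w >= trc$root$right$w) trc$root$left
             else trc$root$right
  expect_equal(pz$class, heavier$pred)
  # missing split value also routes to the heavier child, silently
  pm <- predict(trc, data.frame(b = NA_character_))
  expect_equal(pm$class, heavier$pred)
})

test_that("text and JSON exports are faithful", {
  d <- data.frame(x = rep(c(0, 1), each = 15), y = rep(c(0, 1), each = 15))
  tr <- grow_tree(d, "y", "x")
  txt <- export_tree(tr, "text")
  expect_length(txt, 3)  # root + two leaves
  js <- export_tree(tr, "json")
  tr2 <- import_tree(js)
  expect_identical(export_tree(tr2, "json"), js)
  expect_equal(predict(tr2, d)$class, predict(tr, d)$class)
})

test_that("gini split choice agrees with rpart on a clean problem", {
  skip_if_not_installed("rpart")
  set.seed(79)
  n <- 600
  d <- data.frame(strong = rnorm(n), weak = rnorm(n))
  d$y <- rbinom(n, 1, plogis(2 * d$strong + 0.2 * d$weak))
  tr <- grow_tree(d, "y", c("strong", "weak"),
                  params = tree_params(max_depth = 1))
  rp <- rpart::rpart(y ~ strong + weak, data = d, method = "class",
                     control = rpart::rpart.control(maxdepth = 1,
                                                    cp = 0, minsplit = 2))
  expect_identical(tr$root$split$var,
                   as.character(rp$frame$var[1]))
  expect_equal(tr$root$split$threshold, rp$splits[1, "index"],
               tolerance = 0.05)
})

test_that("the root split lands on the dominant drivers of optimal coverage", {
  hits <- 0
  for (seed in 1:50) {
    cfg <- sim_config(clusters_per_stratum = 4, households_per_cluster = 30,
                      seed = 4000 + seed)
    pop <- generate_population(cfg)
    s <- draw_svy_sample(pop, 3, 15, seed = 5000 + seed)
    s$optimal <- as.numeric(compute_cci(s)$label == "optimal")
    tr <- grow_tree(s, "optimal",
                    c("wealth_quintile", "anc_visits", "mother_educ",
                      "partner_educ", "radio", "tv", "working", "planned",
                      "child_sex"),
                    weights = s$weight,
                    params = tree_params(max_depth = 1))
    if (!tr$root$leaf &&
        tr$root$split$var %in% c("wealth_quintile", "anc_visits"))
      hits <- hits + 1
  }
  expect_gte(hits / 50, 0.8)
})
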