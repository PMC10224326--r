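# 2x2 rook lattice: a-b / c-d
rook2x2 <- function() list(a = c("b", "c"), b = c("a", "d"),
                           c = c("a", "d"), d = c("b", "c"))

# independent Moran evaluation used as the enumeration oracle
moran_direct <- function(x, W) {
  z <- x - mean(x)
  (length(x) / sum(W)) * sum(outer(z, z) * W) / sum(z^2)
}

test_that("weights construction enforces the adjacency contract", {
  w <- build_weights(rook2x2(), style = "B")
  expect_true(all(rowSums(w$binary) == 2))
  expect_equal(w$S0, 8)
  expect_true(all(diag(w$binary) == 0))
  ww <- build_weights(rook2x2(), style = "W")
  expect_equal(unname(rowSums(ww$w)), rep(1, 4))
  island <- c(rook2x2(), list(e = character(0)))
  expect_error(build_weights(island), "e")
  asym <- list(a = "b", b = character(0))
  expect_error(build_weights(asym), "not symmetric.*a-b")
  loop <- list(a = c("a", "b"), b = "a")
  expect_error(build_weights(loop), "self-loop")
})

test_that("the checkerboard attains I = -1 and E[I] matches the identity", {
  w <- build_weights(rook2x2(), style = "B")
  m <- global_moran(c(1, 0, 0, 1), w, n_permutations = 99, seed = 1)
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$expectation, -1 / 3)
  # mean of I over the full permutation set equals -1/(n-1)
  vals <- c(0.3, 1.2, -0.5, 0.9)
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  is <- apply(perms, 1, function(p) moran_direct(vals[p], w$binary))
  expect_equal(mean(is), -1 / 3, tolerance = 1e-12)
})

test_that("a smooth gradient on a path graph is detected as positive", {
  path <- stats::setNames(lapply(1:10, function(i)
    paste0("u", setdiff(c(i - 1, i + 1), c(0, 11)))), paste0("u", 1:10))
  w <- build_weights(path, style = "W")
  m <- global_moran(as.numeric(1:10), w, n_permutations = 999, seed = 4)
  expect_gt(m$I, 0)
  expect_lt(m$p_perm, 0.05)
})

test_that("Moran statistics are invariant to affine transforms and seeds reproduce", {
  w <- build_weights(guinea_adjacency(), style = "W")
  x <- c(0.61, 0.27, 0.56, 0.50, 0.44, 0.57, 0.53, 0.52)
  a <- global_moran(x, w, n_permutations = 499, seed = 8)
  b <- global_moran(10 * x + 3, w, n_permutations = 499, seed = 8)
  expect_equal(a$I, b$I, tolerance = 1e-12)
  expect_equal(a$p_perm, b$p_perm)
  la <- local_moran(x, w, n_permutations = 199, seed = 8)
  lb <- local_moran(10 * x + 3, w, n_permutations = 199, seed = 8)
  expect_equal(la$table$local_i, lb$table$local_i, tolerance = 1e-12)
  expect_identical(la$table$p_perm, lb$table$p_perm)
  expect_error(global_moran(rep(0.4, 8), w), "zero variance")
})

test_that("small-n Monte-Carlo permutation p approaches the exact enumeration p", {
  path6 <- stats::setNames(lapply(1:6, function(i)
    paste0("u", setdiff(c(i - 1, i + 1), c(0, 7)))), paste0("u", 1:6))
  w <- build_weights(path6, style = "W")
  x <- c(2.1, 1.7, 1.9, 0.4, 0.2, 0.6)
  iobs <- moran_direct(x, w$w)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  exact <- mean(apply(perms, 1, function(p)
    abs(moran_direct(x[p], w$w)) >= abs(iobs) - 1e-15))
  m <- global_moran(x, w, n_permutations = 19999, seed = 10)
  expect_equal(m$I, iobs, tolerance = 1e-12)
  expect_lt(abs(m$p_perm - exact), 0.02)
})

test_that("local Moran averages to the global statistic and classifies quadrants", {
  w <- build_weights(guinea_adjacency(), style = "W")
  set.seed(12)
  x <- runif(8)
  g <- global_moran(x, w, n_permutations = 99, seed = 2)
  l <- local_moran(x, w, n_permutations = 99, seed = 2)
  expect_equal(l$global_i, g$I, tolerance = 1e-10)
  z <- x - mean(x)
  lag <- drop(w$w %*% z)
  expect_identical(l$table$quadrant[z >= 0 & lag >= 0][1], "high-high")
  # hand-built neighbourhoods: unit above mean among high neighbours
  sq <- list(a = c("b", "c"), b = c("a", "d"), c = c("a", "d"),
             d = c("b", "c"))
  wsq <- build_weights(sq, style = "W")
  hi <- local_moran(c(10, 9, 8, 1), wsq, n_permutations = 99, seed = 3)
  expect_identical(hi$table$quadrant[1], "high-high")   # a high, b+c high
  lo <- local_moran(c(1, 9, 8, 10), wsq, n_permutations = 99, seed = 3)
  expect_identical(lo$table$quadrant[1], "low-high")    # a low, b+c high
})

test_that("the regional surface runs end to end on the eight-region map", {
  pop <- small_population()
  s <- draw_svy_sample(pop, 4, 20, seed = 21)
  cci <- compute_cci(s)
  s$cci_label <- cci$label
  des <- svy_design(s, "cluster_id", "stratum_id", "weight")
  w <- build_weights(guinea_adjacency(), style = "W")
  surf <- regional_cci_surface(s, des, w, class = "partial",
                               n_permutations = 199, seed = 5)
  expect_equal(nrow(surf$table), 8)
  expect_setequal(surf$table$region, guinea_regions())
  expect_true(all(surf$table$proportion >= 0 & surf$table$proportion <= 1))
  expect_true(all(surf$table$quadrant %in%
                    c("high-high", "low-low", "high-low", "low-high")))
  # all regions identical -> Moran undefined error surfaces
  s2 <- s
  s2$cci_label <- "partial"
  expect_error(regional_cci_surface(s2, des, w), "zero variance")
})

test_that("an engineered high-partial belt is labelled high-high above chance", {
  # Labé-Faranah-Mamou pushed to low coverage (high partial CCI); the same
  # procedure on a structureless configuration measures the chance level.
  w <- build_weights(guinea_adjacency(), style = "W")
  belt <- c("Labé", "Faranah", "Mamou")
  hh_rate <- function(eff, nseeds) {
    hits <- 0
    for (seed in seq_len(nseeds)) {
      cfg <- sim_config(clusters_per_stratum = 4,
                        households_per_cluster = 30,
                        wealth_region_effect = eff, seed = 1000 + seed)
      pop <- generate_population(cfg)
      s <- draw_svy_sample(pop, 3, 15, seed = 2000 + seed)
      s$cci_label <- compute_cci(s)$label
      des <- svy_design(s, "cluster_id", "stratum_id", "weight")
      surf <- regional_cci_surface(s, des, w, class = "partial",
                                   n_permutations = 99, seed = 3000 + seed,
                                   alpha = 0.10)
      tab <- surf$table
      hits <- hits + sum(tab$quadrant[tab$region %in% belt] == "high-high")
    }
    hits / (nseeds * length(belt))
  }
  eff <- stats::setNames(rep(0.6, 8), guinea_regions())
  eff[belt] <- -1.6
  engineered <- hh_rate(eff, 50)
  null_rate <- hh_rate(stats::setNames(rep(0, 8), guinea_regions()), 30)
  expect_gt(engineered, 0.5)
  expect_gt(engineered, null_rate + 0.2)
})
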