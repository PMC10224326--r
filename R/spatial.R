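#' Build a spatial weights object from an adjacency list
#'
#' @param adjacency named list: `list(region = c("neighbour", ...))`. Must be
#'   symmetric and without self-loops.
#' @param style `"W"` row-standardised (default: each unit's weights sum
#'   to 1) or `"B"` binary.
#' @param allow_islands if `FALSE` (default), a unit with no neighbours is an
#'   error.
#' @return Object of class `spatial_weights`: `units`, `binary` (0/1
#'   matrix), `w` (the styled matrix used by the Moran statistics), `style`,
#'   `S0` (sum of all weights), `islands`.
#' @export
build_weights <- function(adjacency, style = c("W", "B"),
                          allow_islands = FALSE) {
  style <- match.arg(style)
  units <- names(adjacency)
  if (is.null(units) || any(units == ""))
    stop("adjacency must be a named list", call. = FALSE)
  if (anyDuplicated(units)) stop("duplicated unit names", call. = FALSE)
  n <- length(units)
  B <- matrix(0, n, n, dimnames = list(units, units))
  for (u in units) {
    nb <- adjacency[[u]]
    if (u %in% nb) stop("self-loop at unit '", u, "'", call. = FALSE)
    unknown <- setdiff(nb, units)
    if (length(unknown))
      stop("unknown neighbour(s) of '", u, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    B[u, nb] <- 1
  }
  asym <- which(B != t(B), arr.ind = TRUE)
  if (nrow(asym)) {
    pairs <- unique(t(apply(asym, 1, sort)))
    stop("adjacency is not symmetric for pair(s): ",
         paste(apply(pairs, 1, function(i)
           paste(units[i], collapse = "-")), collapse = ", "),
         call. = FALSE)
  }
  deg <- rowSums(B)
  islands <- units[deg == 0]
  if (length(islands) && !allow_islands)
    stop("unit(s) with no neighbours: ", paste(islands, collapse = ", "),
         call. = FALSE)
  W <- B
  if (style == "W") {
    nz <- deg > 0
    W[nz, ] <- B[nz, , drop = FALSE] / deg[nz]
  }
  structure(list(units = units, binary = B, w = W, style = style,
                 S0 = sum(W), islands = islands),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("Spatial weights:", length(x$units), "units, style", x$style,
      ", S0 =", format(x$S0, digits = 6), "\n")
  invisible(x)
}

.moran_i <- function(z, W) {
  n <- length(z)
  (n / sum(W)) * drop(z %*% W %*% z) / sum(z^2)
}

#' Global Moran's I with permutation inference
#'
#' `I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' The null expectation under random relabelling is `-1/(n-1)`. The primary
#' p-value is from random permutations of the values across units
#' (`(m+1)/(M+1)` with `m` the number of permuted `|I|` at least `|I_obs|`
#' for the two-sided version); with few spatial units the normal
#' approximation is unreliable, so the analytic z/p (randomisation moments)
#' are reported as approximate.
#'
#' @param values numeric vector, one value per unit in `weights$units` order.
#' @param weights a [build_weights()] object.
#' @param n_permutations number of random relabellings.
#' @param seed RNG seed for the permutations.
#' @return Object of class `moran`: `I`, `expectation`, `z`, `p_analytic`,
#'   `p_perm` (two-sided), `p_perm_greater`, `p_perm_less`,
#'   `n_permutations`, `seed`.
#' @export
global_moran <- function(values, weights, n_permutations = 999,
                         seed = NULL) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(values)
  if (n != length(weights$units))
    stop("need one value per spatial unit", call. = FALSE)
  if (n < 3) stop("need at least 3 units", call. = FALSE)
  if (anyNA(values)) stop("missing values", call. = FALSE)
  if (stats::var(values) == 0)
    stop("Moran's I undefined for zero variance (all values equal)",
         call. = FALSE)
  W <- weights$w
  z <- values - mean(values)
  I <- .moran_i(z, W)
  EI <- -1 / (n - 1)
  # randomisation moments
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zstat <- (I - EI) / sqrt(VI)
  p_analytic <- 2 * stats::pnorm(-abs(zstat))
  perm <- .with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      zp <- sample(z)
      .moran_i(zp, W)
    }, numeric(1))
  })
  m2s <- sum(abs(perm) >= abs(I) - 1e-15)
  p_perm <- (m2s + 1) / (n_permutations + 1)
  pg <- (sum(perm >= I - 1e-15) + 1) / (n_permutations + 1)
  pl <- (sum(perm <= I + 1e-15) + 1) / (n_permutations + 1)
  structure(list(I = I, expectation = EI, variance = VI, z = zstat,
                 p_analytic = p_analytic, p_perm = p_perm,
                 p_perm_greater = pg, p_perm_less = pl,
                 n_permutations = n_permutations, seed = seed),
            class = "moran")
}

#' @export
print.moran <- function(x, ...) {
  cat("Global Moran's I\n")
  cat(sprintf("  I = %.4f (E[I] = %.4f)\n", x$I, x$expectation))
  cat(sprintf("  permutation p (two-sided, M = %d) = %.4g\n",
              x$n_permutations, x$p_perm))
  cat(sprintf("  analytic z = %.3f, p = %.4g (approximate)\n",
              x$z, x$p_analytic))
  invisible(x)
}

#' Local Moran (LISA) with quadrant classification
#'
#' Per-unit local Moran statistic `I_i = (z_i/m2) * sum_j w_ij z_j` with
#' `z_i` the mean-centred value and `m2 = sum(z^2)/n`. The quadrant is
#' determined solely by the signs of `z_i` and its spatial lag: high-high
#' and low-low mark positive local association (the unit resembles its
#' neighbourhood), high-low and low-high mark negative association. The
#' p-value per unit is from conditional permutations: unit i's value is held
#' fixed while the remaining values are shuffled across the other units.
#' Significance (at `alpha`, on the two-sided permutation p) is reported as
#' a separate flag and does not affect the quadrant.
#'
#' @inheritParams global_moran
#' @param alpha significance level for the `significant` flag.
#' @return Object of class `lisa`: data.frame `table` with per-unit
#'   `unit`, `value`, `z`, `lag`, `local_i`, `quadrant`, `p_perm`,
#'   `significant`; plus `global_i` (mean of local statistics equals the
#'   global I under row standardisation), `alpha`, `n_permutations`, `seed`.
#' @export
local_moran <- function(values, weights, n_permutations = 999, seed = NULL,
                        alpha = 0.05) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(values)
  if (n != length(weights$units))
    stop("need one value per spatial unit", call. = FALSE)
  if (anyNA(values)) stop("missing values", call. = FALSE)
  if (stats::var(values) == 0)
    stop("Moran's I undefined for zero variance (all values equal)",
         call. = FALSE)
  W <- weights$w
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  lag <- drop(W %*% z)
  Ii <- z / m2 * lag
  quadrant <- ifelse(z >= 0,
                     ifelse(lag >= 0, "high-high", "high-low"),
                     ifelse(lag >= 0, "low-high", "low-low"))
  p <- .with_seed(seed, {
    vapply(seq_len(n), function(i) {
      others <- z[-i]
      wrow <- W[i, -i]
      m <- 0
      for (b in seq_len(n_permutations)) {
        lp <- sum(wrow * sample(others)) + W[i, i] * z[i]
        if (abs(z[i] / m2 * lp) >= abs(Ii[i]) - 1e-15) m <- m + 1
      }
      (m + 1) / (n_permutations + 1)
    }, numeric(1))
  })
  tab <- data.frame(unit = weights$units, value = values, z = z, lag = lag,
                    local_i = Ii, quadrant = quadrant, p_perm = p,
                    significant = p <= alpha)
  structure(list(table = tab, global_i = mean(Ii), alpha = alpha,
                 n_permutations = n_permutations, seed = seed),
            class = "lisa")
}

#' @export
print.lisa <- function(x, ...) {
  cat("Local Moran (LISA), conditional permutation p, alpha =", x$alpha,
      "\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Region-level CCI surface with spatial autocorrelation
#'
#' Computes the design-weighted proportion of the chosen coverage class
#' (partial by default) per region, then runs global and local Moran
#' statistics on that vector over the supplied spatial weights.
#'
#' @param data records with a `region` column and CCI labels.
#' @param design a [svy_design()] on the same records.
#' @param weights a [build_weights()] whose units are the regions.
#' @param class which coverage class the surface measures (`"partial"` is
#'   the convention for mapping low coverage).
#' @param label name of the label column.
#' @inheritParams global_moran
#' @param alpha LISA significance level.
#' @return list with `table` (region, weighted proportion, SE, LISA
#'   columns), `moran` ([global_moran()] result), `lisa` ([local_moran()]
#'   result), `class`.
#' @export
regional_cci_surface <- function(data, design, weights, class = "partial",
                                 label = "cci_label",
                                 n_permutations = 999, seed = NULL,
                                 alpha = 0.05) {
  stopifnot(inherits(weights, "spatial_weights"))
  class <- match.arg(class, c("partial", "optimal"))
  if (!"region" %in% names(data)) stop("'data' needs a region column",
                                       call. = FALSE)
  regions <- weights$units
  extra <- setdiff(unique(as.character(data$region)), regions)
  if (length(extra))
    stop("region(s) not in the weights matrix: ",
         paste(extra, collapse = ", "), call. = FALSE)
  empty <- setdiff(regions, unique(as.character(data$region)))
  if (length(empty))
    stop("region(s) with no records: ", paste(empty, collapse = ", "),
         call. = FALSE)
  est <- lapply(regions, function(rg) {
    dom <- data$region == rg
    svy_prop(design, as.numeric(data[[label]] == class), domain = dom)
  })
  prop <- vapply(est, `[[`, numeric(1), "estimate")
  se <- vapply(est, `[[`, numeric(1), "se")
  mor <- global_moran(prop, weights, n_permutations = n_permutations,
                      seed = seed)
  lis <- local_moran(prop, weights, n_permutations = n_permutations,
                     seed = seed, alpha = alpha)
  tab <- cbind(data.frame(region = regions, proportion = prop, se = se),
               lis$table[c("local_i", "quadrant", "p_perm", "significant")])
  rownames(tab) <- NULL
  list(table = tab, moran = mor, lisa = lis, class = class)
}
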