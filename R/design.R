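#' Declare a complex survey design
#'
#' Describes the two-stage stratified cluster structure (stratum, primary
#' sampling unit, sampling weight) that governs all variance estimation in
#' the package. Variances are computed by Taylor linearisation with the
#' with-replacement approximation: within each stratum, the variance of a
#' weighted total is estimated from the between-PSU variability of weighted
#' PSU totals with an `n_h/(n_h - 1)` factor.
#'
#' @param data data.frame of records.
#' @param psu column name (character) or vector identifying the primary
#'   sampling unit (cluster) of each record.
#' @param strata column name or vector identifying the stratum; `NULL` means
#'   a single stratum.
#' @param weights column name or vector of positive sampling weights; `NULL`
#'   means equal weights 1.
#' @param normalise `"raw"` keeps the weights as given (inverse inclusion
#'   probabilities); `"mean1"` rescales them to mean 1. Point estimates of
#'   means/proportions and all test statistics are invariant to this choice.
#' @param single_psu what to do when a stratum contains a single PSU at
#'   variance-estimation time: `"error"` (default; silent variance
#'   underestimation is worse than a failure) or `"centre"` (centre the
#'   lonely PSU at the grand mean of all PSU totals).
#' @return An object of class `svy_design`.
#' @export
svy_design <- function(data, psu, strata = NULL, weights = NULL,
                       normalise = c("raw", "mean1"),
                       single_psu = c("error", "centre")) {
  normalise <- match.arg(normalise)
  single_psu <- match.arg(single_psu)
  grab <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1) {
      if (!x %in% names(data))
        stop(what, " column '", x, "' not found in data", call. = FALSE)
      return(data[[x]])
    }
    if (length(x) != nrow(data))
      stop(what, " must have one value per record", call. = FALSE)
    x
  }
  psu_v <- grab(psu, "psu")
  if (is.null(psu_v)) stop("'psu' is required", call. = FALSE)
  str_v <- grab(strata, "strata")
  if (is.null(str_v)) str_v <- rep(1L, nrow(data))
  w <- grab(weights, "weights")
  if (is.null(w)) w <- rep(1, nrow(data))
  if (!is.numeric(w) || anyNA(w) || any(w <= 0))
    stop("weights must be positive and non-missing", call. = FALSE)
  if (normalise == "mean1") w <- w / mean(w)
  stratum <- factor(str_v)
  # PSU ids only need to be unique within stratum; make them globally unique
  psu_f <- factor(paste(as.character(stratum), as.character(psu_v),
                        sep = "\r"))
  npsu <- tapply(psu_f, stratum, function(p) length(unique(p)))
  lonely <- names(npsu)[npsu < 2]
  if (length(lonely))
    warning("stratum with a single PSU: ",
            paste(lonely, collapse = ", "),
            " (variance not estimable with 1 PSU/stratum unless single_psu",
            " = 'centre')", call. = FALSE)
  structure(list(data = data, psu = psu_f, stratum = stratum, weight = w,
                 options = list(normalise = normalise,
                                single_psu = single_psu),
                 lonely_psu = length(lonely) > 0),
            class = "svy_design")
}

#' @export
print.svy_design <- function(x, ...) {
  cat("Two-stage stratified cluster design (with-replacement Taylor",
      "linearisation)\n")
  cat("  records:", length(x$weight),
      "| strata:", nlevels(x$stratum),
      "| PSUs:", length(unique(x$psu)), "\n")
  cat("  weights:", format(min(x$weight), digits = 4), "-",
      format(max(x$weight), digits = 4),
      sprintf("(%s)\n", x$options$normalise))
  invisible(x)
}

# subset a design to row indices (keeps all strata/PSU labels)
.design_subset <- function(design, idx) {
  d <- design
  d$data <- design$data[idx, , drop = FALSE]
  d$psu <- factor(design$psu[idx])
  d$stratum <- factor(design$stratum[idx])
  d$weight <- design$weight[idx]
  d
}

# Covariance of a vector of totals sum_i U[i, ] by the with-replacement
# between-PSU estimator. U must already include the weights.
.svy_lin_var <- function(design, U) {
  U <- as.matrix(U)
  k <- ncol(U)
  psu <- design$psu
  stratum <- design$stratum
  # PSU totals
  g <- rowsum(U, group = psu, reorder = FALSE)
  psu_str <- stratum[match(rownames(g), as.character(psu))]
  V <- matrix(0, k, k)
  grand <- colMeans(g)
  for (h in levels(droplevels(psu_str))) {
    gh <- g[psu_str == h, , drop = FALSE]
    nh <- nrow(gh)
    if (nh < 2) {
      if (design$options$single_psu == "error")
        stop("cannot estimate variance: stratum '", h,
             "' has a single PSU (set single_psu = 'centre' to proceed)",
             call. = FALSE)
      dev <- sweep(gh, 2, grand)
      V <- V + crossprod(dev)
    } else {
      dev <- sweep(gh, 2, colMeans(gh))
      V <- V + nh / (nh - 1) * crossprod(dev)
    }
  }
  V
}

#' Design-based estimate of a proportion
#'
#' Weighted (Hájek) estimate `sum(w*x)/sum(w)` of a binary indicator with
#' Taylor-linearised standard error, a logit-transformed 95% confidence
#' interval, and the design effect relative to simple random sampling of the
#' same unweighted size. `domain` restricts the estimate to a subpopulation
#' while keeping the full design structure for variance estimation.
#'
#' @param design a [svy_design()].
#' @param x binary indicator: column name or 0/1 (or logical) vector.
#' @param domain optional logical vector or column name flagging the
#'   subpopulation.
#' @return Object of class `svy_prop`: `estimate`, `se`, `ci` (length 2),
#'   `n` (unweighted records in the domain), `deff`.
#' @export
svy_prop <- function(design, x, domain = NULL) {
  if (is.character(x) && length(x) == 1) x <- design$data[[x]]
  if (is.logical(x)) x <- as.numeric(x)
  if (!is.numeric(x) || length(x) != length(design$weight))
    stop("'x' must be one binary value per design record", call. = FALSE)
  if (is.character(domain) && length(domain) == 1)
    domain <- as.logical(design$data[[domain]])
  d <- if (is.null(domain)) rep(TRUE, length(x)) else as.logical(domain)
  d[is.na(d)] <- FALSE
  if (anyNA(x[d]) || !all(x[d] %in% c(0, 1)))
    stop("'x' must be 0/1 within the domain", call. = FALSE)
  w <- design$weight
  Wd <- sum(w[d])
  if (!any(d) || Wd <= 0)
    stop("empty domain: no records (or zero total weight)", call. = FALSE)
  p <- sum(w[d] * x[d]) / Wd
  # linearised contribution of each record to the ratio estimator
  u <- ifelse(d, w * (ifelse(d, x, 0) - p), 0) / Wd
  v <- drop(.svy_lin_var(design, matrix(u, ncol = 1)))
  se <- sqrt(max(v, 0))
  n <- sum(d)
  if (p > 0 && p < 1 && se > 0) {
    l <- stats::qlogis(p)
    sl <- se / (p * (1 - p))
    ci <- stats::plogis(l + c(-1, 1) * stats::qnorm(0.975) * sl)
  } else ci <- c(p, p)
  v_srs <- if (n > 1) p * (1 - p) / (n - 1) else NA_real_
  deff <- if (!is.na(v_srs) && v_srs > 0) v / v_srs else NA_real_
  structure(list(estimate = p, se = se, ci = ci, n = n, deff = deff),
            class = "svy_prop")
}

#' @export
print.svy_prop <- function(x, ...) {
  cat(sprintf("proportion %.4f (SE %.4f), 95%% CI [%.4f, %.4f], n = %d, deff = %s\n",
              x$estimate, x$se, x$ci[1], x$ci[2], x$n,
              format(x$deff, digits = 3)))
  invisible(x)
}

#' Rao-Scott second-order corrected chi-square test
#'
#' Tests independence of two categorical variables under a complex design.
#' The Pearson statistic is computed on the design-weighted cell proportions
#' scaled to the unweighted sample size, then corrected by the Rao-Scott
#' second-order (Satterthwaite) procedure: the generalised design-effect
#' matrix is the design-based covariance of the independence contrasts
#' relative to their multinomial covariance; the statistic is divided by
#' `mean(delta) * (1 + cv^2)` of its eigenvalues, and the degrees of freedom
#' are deflated by `1 + cv^2`.
#'
#' Two p-values are reported: from the chi-square reference and (default
#' printed) from an F reference with denominator degrees of freedom equal to
#' the number of PSUs minus the number of strata. Under simple random
#' sampling (equal weights, each element its own PSU, one stratum) the
#' corrected statistic equals the classical Pearson X2 on the raw counts.
#'
#' @param design a [svy_design()].
#' @param row,col column names or vectors; each must have at least two
#'   observed levels.
#' @return Object of class `rao_scott`: `X2` (uncorrected Pearson on the
#'   weighted proportions), `statistic` (second-order corrected), `deff_mean`
#'   (first-order mean generalised design effect), `df` (Satterthwaite df),
#'   `nu` (PSUs minus strata), `p_chisq`, `p_F`, `p` (the F version),
#'   `observed` (unweighted counts), `proportions` (weighted), `singular`
#'   flag (generalised inverse used).
#' @export
rao_scott_test <- function(design, row, col) {
  getv <- function(x, what) {
    if (is.character(x) && length(x) == 1) {
      if (!x %in% names(design$data))
        stop(what, " column '", x, "' not found", call. = FALSE)
      x <- design$data[[x]]
    }
    f <- droplevels(factor(x))
    if (nlevels(f) < 2)
      stop(what, " variable is constant in the sample (needs >= 2 levels)",
           call. = FALSE)
    f
  }
  r <- getv(row, "row")
  c_ <- getv(col, "col")
  if (anyNA(r) || anyNA(c_))
    stop("missing values in test variables", call. = FALSE)
  w <- design$weight
  n <- length(w)
  R <- nlevels(r); C <- nlevels(c_)
  cell <- interaction(r, c_, lex.order = TRUE)  # r varies slowest
  M <- stats::model.matrix(~ cell - 1)
  phat <- colSums(w * M) / sum(w)               # weighted cell proportions
  P <- matrix(phat, R, C, byrow = TRUE)
  pr <- rowSums(P); pc <- colSums(P)
  E <- outer(pr, pc)
  X2 <- n * sum((P - E)^2 / E)
  # design covariance of the RC cell-proportion vector
  U <- (w / sum(w)) * sweep(M, 2, phat)
  Sig <- .svy_lin_var(design, U)
  # multinomial reference covariance with 1/(n-1) so SRS deffs are exactly 1
  V0 <- (diag(phat) - tcrossprod(phat)) / (n - 1)
  # Jacobian of the K = (R-1)(C-1) independence contrasts
  # h_rc = p_rc - p_{r+} p_{+c} for r < R, c < C
  K <- (R - 1) * (C - 1)
  H <- matrix(0, K, R * C)
  k <- 0
  for (rr in seq_len(R - 1)) for (cc in seq_len(C - 1)) {
    k <- k + 1
    for (aa in seq_len(R)) for (bb in seq_len(C)) {
      j <- (aa - 1) * C + bb
      H[k, j] <- (aa == rr) * (bb == cc) - (aa == rr) * pc[cc] -
        (bb == cc) * pr[rr]
    }
  }
  Vh <- H %*% Sig %*% t(H)
  V0h <- H %*% V0 %*% t(H)
  singular <- FALSE
  Dmat <- tryCatch(solve(V0h, Vh), error = function(e) {
    singular <<- TRUE
    MASS::ginv(V0h) %*% Vh
  })
  delta <- Re(eigen(Dmat, only.values = TRUE)$values)
  delta <- pmax(delta, 0)
  dbar <- mean(delta)
  cv2 <- if (dbar > 0) sum(delta^2) / (K * dbar^2) - 1 else 0
  cv2 <- max(cv2, 0)
  stat <- X2 / (dbar * (1 + cv2))
  df <- K / (1 + cv2)
  nu <- length(unique(design$psu)) - nlevels(droplevels(design$stratum))
  p_chisq <- stats::pchisq(stat, df, lower.tail = FALSE)
  p_F <- if (nu > 0) stats::pf(stat / df, df, nu, lower.tail = FALSE)
         else NA_real_
  obs <- table(r, c_)
  structure(list(X2 = X2, statistic = stat, deff_mean = dbar, cv2 = cv2,
                 df = df, nu = nu, p_chisq = p_chisq, p_F = p_F,
                 p = if (is.na(p_F)) p_chisq else p_F,
                 observed = obs, proportions = P, singular = singular,
                 method = "Rao-Scott second-order corrected chi-square"),
            class = "rao_scott")
}

#' @export
print.rao_scott <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  X2 = %.4f, corrected = %.4f, df = %.3f, mean deff = %.3f\n",
              x$X2, x$statistic, x$df, x$deff_mean))
  cat(sprintf("  p (F, denom df = %d) = %.4g;  p (chi-square) = %.4g\n",
              x$nu, x$p_F, x$p_chisq))
  if (x$singular)
    cat("  note: singular reference covariance, generalised inverse used\n")
  invisible(x)
}

#' Design-based rank-sum (Wilcoxon) test for two groups
#'
#' The outcome is replaced by pooled weighted mid-rank scores (ties averaged)
#' scaled to the unit interval, and a design-based Wald test that the mean
#' rank score differs between the two groups is carried out with the same
#' Taylor-linearisation machinery as [svy_prop()]. The statistic is a
#' z-score, positive when the first group (first factor level) has the
#' higher mean rank.
#'
#' @param design a [svy_design()].
#' @param group column name or vector with exactly two observed levels.
#' @param y numeric outcome, column name or vector.
#' @return Object of class `svy_ranksum`: `statistic` (z), `p`, `estimate`
#'   (difference in mean rank score), `mean_ranks` per group.
#' @export
svy_ranksum <- function(design, group, y) {
  if (is.character(group) && length(group) == 1) group <- design$data[[group]]
  if (is.character(y) && length(y) == 1) y <- design$data[[y]]
  g <- droplevels(factor(group))
  if (nlevels(g) != 2)
    stop("'group' must have exactly two observed levels", call. = FALSE)
  if (any(table(g) == 0)) stop("one group is empty", call. = FALSE)
  if (anyNA(y) || anyNA(g)) stop("missing values in 'y' or 'group'",
                                 call. = FALSE)
  w <- design$weight
  W <- sum(w)
  # weighted mid-rank (ridit) scores on the pooled sample, scaled to (0,1)
  uv <- sort(unique(y))
  wv <- vapply(uv, function(v) sum(w[y == v]), numeric(1))
  cumw <- cumsum(wv)
  ridit <- (cumw - wv / 2) / W
  r <- ridit[match(y, uv)]
  lev <- levels(g)
  m <- vapply(lev, function(l) sum(w[g == l] * r[g == l]) / sum(w[g == l]),
              numeric(1))
  est <- m[1] - m[2]
  W1 <- sum(w[g == lev[1]]); W2 <- sum(w[g == lev[2]])
  u <- w * (ifelse(g == lev[1], (r - m[1]) / W1, 0) -
              ifelse(g == lev[2], (r - m[2]) / W2, 0))
  v <- drop(.svy_lin_var(design, matrix(u, ncol = 1)))
  z <- est / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(statistic = z, p = p, estimate = est, mean_ranks = m,
                 method = "Design-based rank-sum test"),
            class = "svy_ranksum")
}

#' @export
print.svy_ranksum <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  mean rank scores: %s = %.4f, %s = %.4f\n",
              names(x$mean_ranks)[1], x$mean_ranks[1],
              names(x$mean_ranks)[2], x$mean_ranks[2]))
  cat(sprintf("  z = %.4f, p = %.4g\n", x$statistic, x$p))
  invisible(x)
}
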