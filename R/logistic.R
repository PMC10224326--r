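#' Survey-weighted logistic regression
#'
#' Fits a logistic regression by pseudo-maximum likelihood: the coefficient
#' vector maximises the weighted Bernoulli log-likelihood
#' `sum(w * (y*log(p) + (1-y)*log(1-p)))` via iteratively reweighted least
#' squares. Inference is design-based: the covariance is the sandwich
#' estimator whose meat is the with-replacement between-PSU covariance of
#' the weighted score totals within strata, so standard errors reflect the
#' clustering and stratification declared in the design.
#'
#' The reported AIC is `-2 * l_tilde + 2k` where `l_tilde` is the weighted
#' log-pseudolikelihood computed with the weights normalised to mean 1, so
#' that the AIC scales with the sample size rather than the population size
#' and is invariant to rescaling all weights by a constant.
#'
#' Rows with missing values in the response or predictors are dropped
#' (complete-case); the count is stored in `na_dropped`.
#'
#' @param formula model formula; the response must be binary (0/1, logical,
#'   or a two-level factor whose second level is modelled).
#' @param design a [svy_design()]; the model frame is taken from its data.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return Object of class `svy_logit` with components `coefficients`,
#'   `vcov` (sandwich), `loglik` (weights normalised to mean 1), `aic`, `n`,
#'   `converged`, `separation` (large-coefficient flag), `fitted`, plus the
#'   formula/terms bookkeeping used by `predict`. Methods: `print`,
#'   `summary`, `coef`, `vcov`, `predict`, `logLik`, `AIC`, `nobs`,
#'   `residuals`, `simulate`.
#' @export
svy_logit <- function(formula, design, max_iter = 25, tol = 1e-10) {
  mf <- stats::model.frame(formula, data = design$data,
                           na.action = stats::na.omit,
                           drop.unused.levels = TRUE)
  omitted <- attr(mf, "na.action")
  idx <- seq_len(nrow(design$data))
  if (!is.null(omitted)) idx <- idx[-omitted]
  dsub <- .design_subset(design, idx)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("response must be binary", call. = FALSE)
    y <- as.numeric(y == levels(y)[2])
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary", call. = FALSE)
  X <- stats::model.matrix(mt, mf)
  if (qr(X)$rank < ncol(X))
    stop("model matrix is rank-deficient after encoding", call. = FALSE)
  w <- dsub$weight
  beta <- rep(0, ncol(X))
  eps <- 1e-12
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    p <- pmin(pmax(p, eps), 1 - eps)
    Wd <- w * p * (1 - p)
    z <- eta + (y - p) / (p * (1 - p))
    beta_new <- drop(solve(crossprod(X, Wd * X), crossprod(X, Wd * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  names(beta) <- colnames(X)
  if (!converged) {
    cond <- structure(class = c("cci_fit_error", "error", "condition"),
                      list(message = paste0("svy_logit did not converge in ",
                                            max_iter, " iterations"),
                           call = sys.call(-1), beta = beta))
    stop(cond)
  }
  separation <- any(abs(beta) > 15)
  if (separation)
    warning("possible separation: |coefficient| > 15", call. = FALSE)
  eta <- drop(X %*% beta)
  p <- pmin(pmax(stats::plogis(eta), eps), 1 - eps)
  bread <- solve(crossprod(X, (w * p * (1 - p)) * X))
  scores <- (w * (y - p)) * X
  meat <- .svy_lin_var(dsub, scores)
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(names(beta), names(beta))
  wt <- w / mean(w)
  ll <- sum(wt * (y * log(p) + (1 - y) * log(1 - p)))
  k <- length(beta)
  fit <- structure(list(coefficients = beta, vcov = V, loglik = ll,
                        aic = -2 * ll + 2 * k, n = length(y), rank = k,
                        converged = converged, separation = separation,
                        fitted = stats::plogis(eta), y = y,
                        weights = w, design = dsub,
                        formula = formula, terms = mt,
                        xlevels = stats::.getXlevels(mt, mf),
                        na_dropped = length(omitted),
                        full_design = design),
                   class = "svy_logit")
  fit
}

#' @export
coef.svy_logit <- function(object, ...) object$coefficients

#' @export
vcov.svy_logit <- function(object, ...) object$vcov

#' @export
nobs.svy_logit <- function(object, ...) object$n

#' @export
logLik.svy_logit <- function(object, ...) {
  structure(object$loglik, df = object$rank, nobs = object$n,
            class = "logLik")
}

#' @export
print.svy_logit <- function(x, ...) {
  cat("Survey-weighted logistic regression (pseudo-MLE, sandwich variance)\n")
  cat("  ", deparse(x$formula), "\n")
  cat("  n =", x$n, "| AIC =", format(x$aic, digits = 6),
      if (x$na_dropped) paste("|", x$na_dropped, "rows dropped (missing)")
      else "", "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.svy_logit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- cbind(estimate = object$coefficients, se = se, z = z, p = p,
               or = exp(object$coefficients),
               or_low = exp(object$coefficients - stats::qnorm(0.975) * se),
               or_high = exp(object$coefficients + stats::qnorm(0.975) * se))
  out <- list(coefficients = tab, aic = object$aic, n = object$n,
              formula = object$formula, converged = object$converged)
  class(out) <- "summary.svy_logit"
  out
}

#' @export
print.summary.svy_logit <- function(x, ...) {
  cat("Survey-weighted logistic regression\n  ", deparse(x$formula), "\n")
  cat("  n =", x$n, "| AIC =", format(x$aic, digits = 6), "\n\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], P.values = TRUE,
               has.Pvalue = TRUE)
  invisible(x)
}

#' @export
predict.svy_logit <- function(object, newdata = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- stats::qlogis(object$fitted)
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels,
                             na.action = stats::na.pass)
    X <- stats::model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.svy_logit <- function(object, type = c("response", "pearson"),
                                ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson")
    r <- r / sqrt(object$fitted * (1 - object$fitted))
  r
}

#' @export
simulate.svy_logit <- function(object, nsim = 1, seed = NULL, ...) {
  out <- .with_seed(seed, {
    replicate(nsim, stats::rbinom(object$n, 1, object$fitted),
              simplify = FALSE)
  })
  names(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}

#' Backward stepwise model selection by AIC
#'
#' Starting from the fitted full model, repeatedly removes the single term
#' (categorical terms as whole blocks) whose removal gives the lowest AIC,
#' and stops when no removal lowers the AIC. Ties within `1e-9` are broken
#' in favour of the term appearing earliest in the model formula; the choice
#' is recorded in the trail.
#'
#' @param fit a [svy_logit()] fit of the full model.
#' @param locked character vector of term labels never considered for
#'   removal.
#' @param trace print progress.
#' @return Object of class `cci_step`: `fit` (final model), `formula`, and
#'   `trail`, a data.frame of steps `(dropped, aic)` starting with the full
#'   model (`dropped = "<full>"`).
#' @export
step_aic <- function(fit, locked = NULL, trace = FALSE) {
  stopifnot(inherits(fit, "svy_logit"))
  design <- fit$full_design
  current <- fit
  form <- fit$formula
  trail <- data.frame(dropped = "<full>", aic = fit$aic, tie = FALSE,
                      stringsAsFactors = FALSE)
  repeat {
    terms_now <- attr(stats::terms(form), "term.labels")
    droppable <- setdiff(terms_now, locked)
    if (!length(droppable)) break
    aics <- rep(NA_real_, length(droppable))
    fits <- vector("list", length(droppable))
    for (i in seq_along(droppable)) {
      f2 <- stats::update(form, paste(". ~ . -", droppable[i]))
      fits[[i]] <- tryCatch(svy_logit(f2, design),
                            error = function(e) {
                              stop("stepwise aborted while refitting without '",
                                   droppable[i], "': ", conditionMessage(e),
                                   "\n  trail so far: ",
                                   paste(trail$dropped, collapse = " -> "),
                                   call. = FALSE)
                            })
      aics[i] <- fits[[i]]$aic
    }
    best <- min(aics)
    if (best >= current$aic - 0) break
    cand <- which(aics - best <= 1e-9)
    tie <- length(cand) > 1
    pick <- cand[1]  # earliest in model-spec order
    if (trace)
      cat("drop", droppable[pick], "AIC", format(aics[pick]),
          if (tie) "(tie, earliest kept)" else "", "\n")
    current <- fits[[pick]]
    form <- current$formula
    trail <- rbind(trail, data.frame(dropped = droppable[pick],
                                     aic = aics[pick], tie = tie))
  }
  structure(list(fit = current, formula = form, trail = trail),
            class = "cci_step")
}

#' @export
print.cci_step <- function(x, ...) {
  cat("Backward stepwise AIC selection\n")
  print(x$trail)
  cat("final model: ", deparse(x$formula), "\n")
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Records are sorted by fitted probability and split into `g` groups of
#' (as nearly as possible) equal total weight; the statistic sums
#' `(O - E)^2 / (E * (1 - pbar))` over groups, where `O` and `E` are the
#' weighted observed and expected event totals and `pbar` the weighted mean
#' fitted probability, and is referred to a chi-square with `g - 2` degrees
#' of freedom.
#'
#' @param fit a converged [svy_logit()].
#' @param g number of groups (default 10); if there are fewer distinct
#'   fitted values than `g`, `g` is reduced with a warning.
#' @return Object of class `hosmer_lemeshow`: `statistic`, `df`, `p`,
#'   `groups` (data.frame with weighted size, observed, expected, mean p).
#' @export
hosmer_lemeshow <- function(fit, g = 10) {
  stopifnot(inherits(fit, "svy_logit"))
  if (g < 3) stop("'g' must be at least 3", call. = FALSE)
  p <- fit$fitted
  ndist <- length(unique(p))
  if (ndist < g) {
    warning("only ", ndist, " distinct fitted values; reducing g",
            call. = FALSE)
    g <- max(3, ndist)
  }
  o <- order(p)
  w <- fit$weights[o]
  y <- fit$y[o]
  ps <- p[o]
  W <- sum(w)
  grp <- pmin(g, ceiling(cumsum(w) / W * g - 1e-12))
  grp <- pmax(grp, 1)
  size <- tapply(w, grp, sum)
  O <- tapply(w * y, grp, sum)
  E <- tapply(w * ps, grp, sum)
  pbar <- E / size
  stat <- sum((O - E)^2 / (E * (1 - pbar)))
  df <- g - 2
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 groups = data.frame(group = as.integer(names(size)),
                                     w = as.numeric(size),
                                     observed = as.numeric(O),
                                     expected = as.numeric(E),
                                     mean_p = as.numeric(pbar))),
            class = "hosmer_lemeshow")
}

#' @export
print.hosmer_lemeshow <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow test: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Odds-ratio table in publication layout
#'
#' One row per coefficient, grouped by model term; for categorical
#' predictors the reference level is rendered as an em-dash row, as in
#' standard adjusted-odds-ratio tables.
#'
#' @param fit a [svy_logit()].
#' @param decimals decimal places for the OR and CI columns.
#' @return data.frame with character display columns `variable`, `level`,
#'   `OR`, `CI95`, `p`, and numeric columns `or`, `ci_low`, `ci_high`,
#'   `p_value` (`NA` for reference rows).
#' @export
or_table <- function(fit, decimals = 2) {
  stopifnot(inherits(fit, "svy_logit"))
  s <- summary(fit)$coefficients
  tl <- attr(fit$terms, "term.labels")
  if (any(grepl(":", tl, fixed = TRUE)))
    stop("or_table supports main-effects models only", call. = FALSE)
  fmt <- function(v) formatC(v, format = "f", digits = decimals)
  rows <- list()
  for (term in tl) {
    if (term %in% names(fit$xlevels)) {
      lev <- fit$xlevels[[term]]
      rows[[length(rows) + 1]] <- data.frame(
        variable = term, level = lev[1], OR = "—", CI95 = "—",
        p = "—", or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, stringsAsFactors = FALSE)
      for (l in lev[-1]) {
        cn <- paste0(term, l)
        if (!cn %in% rownames(s)) next
        rows[[length(rows) + 1]] <- data.frame(
          variable = term, level = l, OR = fmt(s[cn, "or"]),
          CI95 = paste0(fmt(s[cn, "or_low"]), ", ", fmt(s[cn, "or_high"])),
          p = format.pval(s[cn, "p"], digits = 2, eps = 0.001),
          or = s[cn, "or"], ci_low = s[cn, "or_low"],
          ci_high = s[cn, "or_high"], p_value = s[cn, "p"],
          stringsAsFactors = FALSE)
      }
    } else if (term %in% rownames(s)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = term, level = "", OR = fmt(s[term, "or"]),
        CI95 = paste0(fmt(s[term, "or_low"]), ", ",
                      fmt(s[term, "or_high"])),
        p = format.pval(s[term, "p"], digits = 2, eps = 0.001),
        or = s[term, "or"], ci_low = s[term, "or_low"],
        ci_high = s[term, "or_high"], p_value = s[term, "p"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
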