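#' Composite Coverage Index component weights
#'
#' The eight care-continuum interventions and their weights. The index gives
#' equal weight (1/4 each) to the four care domains: family planning,
#' maternal and newborn care, immunisation, and case management of sick
#' children; within the immunisation domain the three-dose pentavalent
#' series counts double. On the 16ths scale: FPS 4, SBA 2, ANCS 2, DTC3 2,
#' MSL 1, BCG 1, ORT 2, CPNM 2, i.e.
#' `CCI = (FPS + (SBA + ANCS)/2 + (2*DTC3 + MSL + BCG)/4 + (ORT + CPNM)/2)/4`.
#'
#' Components: FPS (family planning need satisfied), SBA (skilled birth
#' attendance), ANCS (antenatal care by a qualified provider), DTC3 (three
#' pentavalent doses), MSL (measles dose), BCG (BCG dose), ORT (oral
#' rehydration during diarrhoea; applicable only to children who had a
#' diarrhoea episode), CPNM (care seeking for cough/pneumonia symptoms;
#' applicable only to children who had a cough episode).
#'
#' @return Named numeric vector over the eight components, summing to 1.
#' @export
#' @examples
#' sum(cci_weights())  # exactly 1
cci_weights <- function() {
  c(FPS = 4, SBA = 2, ANCS = 2, DTC3 = 2, MSL = 1, BCG = 1, ORT = 2,
    CPNM = 2) / 16
}

.cci_components <- function() names(cci_weights())
.cci_always <- function() setdiff(.cci_components(), c("ORT", "CPNM"))

.check_cci_weights <- function(weights) {
  comps <- .cci_components()
  if (!all(comps %in% names(weights)) || length(weights) != length(comps))
    stop("'weights' must be named with exactly the eight CCI components: ",
         paste(comps, collapse = ", "), call. = FALSE)
  weights <- weights[comps]
  if (any(weights <= 0)) stop("all CCI weights must be > 0", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12)
    stop("CCI weights must sum to 1 (got ", format(sum(weights), digits = 15),
         ")", call. = FALSE)
  weights
}

#' Compute the Composite Coverage Index per record
#'
#' Per-record weighted average of the eight binary component indicators,
#' `score = sum(w_c * x_c)` over the applicable components, dichotomised at
#' 0.50 into partial (`< 0.50`) / optimal (`>= 0.50`) coverage.
#'
#' ORT and CPNM are conditional indicators: they are `NA` (not applicable)
#' for children without a diarrhoea, respectively cough, episode. How such
#' records are scored is governed by `na_policy`:
#' \describe{
#'   \item{renormalise}{drop the not-applicable components and rescale the
#'     remaining weights to sum to 1 (default; makes the weakest assumption
#'     and keeps the score in \[0,1\]).}
#'   \item{impute_zero}{treat not-applicable as "not covered" (0).}
#'   \item{impute_one}{treat not-applicable as "covered" (1).}
#'   \item{drop_record}{score and label are `NA` for any record with a
#'     not-applicable component.}
#' }
#'
#' @param data data.frame containing the eight component columns
#'   `FPS, SBA, ANCS, DTC3, MSL, BCG, ORT, CPNM`, coded 0/1 with `NA`
#'   allowed only for `ORT`/`CPNM` (not applicable).
#' @param weights named component weights, see [cci_weights()].
#' @param na_policy one of `"renormalise"`, `"impute_zero"`, `"impute_one"`,
#'   `"drop_record"`.
#' @return data.frame with one row per input record: `score` in \[0,1\],
#'   `label` (`"partial"`/`"optimal"`), `renormalised` (TRUE when the score
#'   used rescaled weights), `n_components` (number of components entering
#'   the score).
#' @export
#' @examples
#' d <- data.frame(FPS = 1, SBA = 0, ANCS = 0, DTC3 = 0, MSL = 0, BCG = 0,
#'                 ORT = 0, CPNM = 0)
#' compute_cci(d)$score  # 0.25: family planning carries 4/16
compute_cci <- function(data, weights = cci_weights(),
                        na_policy = c("renormalise", "impute_zero",
                                      "impute_one", "drop_record")) {
  if (is.character(na_policy) && length(na_policy) == 1 &&
      !na_policy %in% c("renormalise", "impute_zero", "impute_one",
                        "drop_record"))
    stop("unknown na_policy: '", na_policy, "'", call. = FALSE)
  na_policy <- match.arg(na_policy)
  weights <- .check_cci_weights(weights)
  comps <- .cci_components()
  missing_cols <- setdiff(comps, names(data))
  if (length(missing_cols))
    stop("missing CCI component column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- as.matrix(data[comps])
  storage.mode(x) <- "double"
  bad <- !(x %in% c(0, 1) | is.na(x))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(x)), arr.ind = TRUE)[1, ]
    stop("component '", comps[idx[2]], "' has a value outside {0, 1, NA} at ",
         "record ", idx[1], call. = FALSE)
  }
  for (cn in .cci_always()) {
    if (anyNA(x[, cn])) {
      row <- which(is.na(x[, cn]))[1]
      stop("always-applicable component '", cn, "' is missing at record ",
           row, call. = FALSE)
    }
  }
  wmat <- matrix(weights, nrow(x), length(comps), byrow = TRUE)
  obs <- !is.na(x)
  any_na <- rowSums(!obs) > 0
  if (na_policy == "impute_zero") x[!obs] <- 0
  if (na_policy == "impute_one") x[!obs] <- 1
  if (na_policy %in% c("impute_zero", "impute_one")) obs[] <- TRUE
  wsum <- rowSums(wmat * obs)
  score <- rowSums(wmat * x * obs, na.rm = TRUE) / wsum
  n_components <- rowSums(obs)
  renorm <- rep(FALSE, nrow(x))
  if (na_policy == "renormalise") renorm <- any_na
  if (na_policy == "drop_record") score[any_na] <- NA_real_
  label <- rep(NA_character_, length(score))
  ok <- !is.na(score)
  label[ok] <- classify_cci(score[ok])
  data.frame(score = score, label = label, renormalised = renorm,
             n_components = n_components)
}

#' Dichotomise a CCI score into partial/optimal coverage
#'
#' Optimal coverage if and only if the score is `>= 0.50`; the boundary value
#' 0.50 is optimal.
#'
#' @param score numeric vector in \[0,1\].
#' @return character vector, `"partial"` or `"optimal"`.
#' @export
classify_cci <- function(score) {
  if (!is.numeric(score) || anyNA(score) ||
      any(score < 0 | score > 1))
    stop("'score' must be numeric in [0, 1]", call. = FALSE)
  ifelse(score >= 0.5, "optimal", "partial")
}

.round_pct <- function(p, decimals) round(100 * p, decimals)

#' Partial/optimal coverage table
#'
#' Unweighted counts and percentages of partial and optimal coverage,
#' optionally by grouping variables and, when a [svy_design()] on the same
#' records is supplied, design-weighted percentages with linearised standard
#' errors.
#'
#' @param data data.frame containing the label column and any `by` columns.
#' @param design optional [svy_design()] built on the same rows as `data`.
#' @param by character vector of grouping column names (e.g. survey year,
#'   region), or `NULL` for a single overall row.
#' @param label name of the column holding the `"partial"`/`"optimal"` labels.
#' @param decimals decimal places for the reported percentages.
#' @return data.frame with one row per group: group columns, `n`,
#'   `n_partial`, `n_optimal`, `pct_partial`, `pct_optimal` (unweighted) and,
#'   with a design, `wpct_partial`, `wpct_optimal`, `wse_optimal`. Empty
#'   groups report `n = 0` and `NA` percentages.
#' @export
coverage_table <- function(data, design = NULL, by = NULL,
                           label = "cci_label", decimals = 1) {
  if (!label %in% names(data))
    stop("label column '", label, "' not found", call. = FALSE)
  lab <- data[[label]]
  if (!all(lab %in% c("partial", "optimal") | is.na(lab)))
    stop("labels must be 'partial' or 'optimal'", call. = FALSE)
  if (!is.null(design)) {
    if (length(design$weight) != nrow(data))
      stop("'design' must be built on the same records as 'data'",
           call. = FALSE)
  }
  groups <- if (is.null(by)) factor(rep("(all)", nrow(data)))
            else interaction(data[by], drop = FALSE, sep = " / ")
  out <- lapply(levels(groups), function(g) {
    idx <- which(groups == g & !is.na(lab))
    n <- length(idx)
    n_opt <- sum(lab[idx] == "optimal")
    n_par <- n - n_opt
    row <- data.frame(group = g, n = n, n_partial = n_par, n_optimal = n_opt,
                      pct_partial = if (n) .round_pct(n_par / n, decimals) else NA_real_,
                      pct_optimal = if (n) .round_pct(n_opt / n, decimals) else NA_real_)
    if (!is.null(design)) {
      if (n) {
        dom <- seq_len(nrow(data)) %in% idx
        p <- svy_prop(design, as.numeric(lab == "optimal" & !is.na(lab)),
                      domain = dom)
        row$wpct_optimal <- .round_pct(p$estimate, decimals)
        row$wpct_partial <- .round_pct(1 - p$estimate, decimals)
        row$wse_optimal <- 100 * p$se
      } else {
        row$wpct_optimal <- row$wpct_partial <- row$wse_optimal <- NA_real_
      }
    }
    row
  })
  res <- do.call(rbind, out)
  if (!is.null(by)) {
    parts <- do.call(rbind, strsplit(as.character(res$group), " / ",
                                     fixed = TRUE))
    colnames(parts) <- by
    res <- cbind(as.data.frame(parts), res[-1])
  } else res$group <- NULL
  rownames(res) <- NULL
  res
}

#' Per-component coverage table
#'
#' Coverage of each of the eight CCI components. For the conditional
#' components (ORT, CPNM) the denominator is the set of records where the
#' component is applicable (non-`NA`); a component applicable to no record is
#' reported with denominator 0 and `NA` coverage.
#'
#' @inheritParams coverage_table
#' @param decimals decimal places for percentages (the published tables use 0).
#' @return data.frame with one row per component: `component`,
#'   `n_applicable`, `n_covered`, `pct` (unweighted) and with a design
#'   `wpct`, `wse`.
#' @export
component_table <- function(data, design = NULL, decimals = 0) {
  comps <- .cci_components()
  missing_cols <- setdiff(comps, names(data))
  if (length(missing_cols))
    stop("missing CCI component column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.null(design) && length(design$weight) != nrow(data))
    stop("'design' must be built on the same records as 'data'",
         call. = FALSE)
  out <- lapply(comps, function(cn) {
    x <- data[[cn]]
    app <- !is.na(x)
    n <- sum(app)
    n_cov <- sum(x[app] == 1)
    row <- data.frame(component = cn, n_applicable = n, n_covered = n_cov,
                      pct = if (n) .round_pct(n_cov / n, decimals) else NA_real_)
    if (!is.null(design)) {
      if (n) {
        p <- svy_prop(design, ifelse(app, as.numeric(x == 1), 0),
                      domain = app)
        row$wpct <- .round_pct(p$estimate, decimals)
        row$wse <- 100 * p$se
      } else row$wpct <- row$wse <- NA_real_
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
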