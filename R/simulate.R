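#' Names of Guinea's eight administrative regions
#' @return character vector of length 8.
#' @export
guinea_regions <- function() {
  c("Boké", "Conakry", "Faranah", "Kankan", "Kindia", "Labé",
    "Mamou", "N'Zérékoré")
}

#' Adjacency of Guinea's administrative regions
#'
#' First-order (shared border) adjacency of the eight regions, encoded once
#' from a reference map. Conakry is a peninsula enclosed by Kindia region;
#' the graph is symmetric and connected.
#'
#' @return named list `region -> character vector of neighbours`.
#' @export
guinea_adjacency <- function() {
  rg <- guinea_regions()
  boke <- rg[1]; conakry <- rg[2]; faranah <- rg[3]; kankan <- rg[4]
  kindia <- rg[5]; labe <- rg[6]; mamou <- rg[7]; nzerekore <- rg[8]
  adj <- list(
    c(kindia, labe),                    # Boké
    c(kindia),                          # Conakry
    c(labe, mamou, kankan, nzerekore),  # Faranah
    c(faranah, nzerekore),              # Kankan
    c(boke, conakry, labe, mamou),      # Kindia
    c(boke, kindia, mamou, faranah),    # Labé
    c(kindia, labe, faranah),           # Mamou
    c(faranah, kankan)                  # N'Zérékoré
  )
  names(adj) <- rg
  adj
}

#' Default covariate model for the synthetic population
#'
#' Distributions of the sociodemographic and obstetric covariates the
#' analysis uses, chosen to resemble the published descriptive profile of a
#' West African DHS sample (mostly rural, low maternal education, radio the
#' dominant medium, about three quarters of pregnancies planned, roughly
#' half of women with four or more antenatal visits).
#'
#' @return named list of distribution parameters; see the source for the
#'   fields.
#' @export
default_covariate_model <- function() {
  list(
    educ_probs_rural = c(none = 0.82, primary = 0.11, secondary = 0.06,
                         higher = 0.01),
    educ_probs_urban = c(none = 0.55, primary = 0.16, secondary = 0.22,
                         higher = 0.07),
    partner_educ_probs_rural = c(none = 0.74, primary = 0.11,
                                 secondary = 0.11, higher = 0.04),
    partner_educ_probs_urban = c(none = 0.50, primary = 0.12,
                                 secondary = 0.23, higher = 0.15),
    media_base = c(newspaper = 0.06, radio = 0.60, tv = 0.35),
    media_wealth_slope = 0.45,
    working_prob = 0.76,
    married_prob = 0.93,
    planned_prob = 0.73,
    anc4_intercept = -0.3, anc4_wealth = 0.35, anc4_urban = 0.30,
    mother_age_probs = c("15-18" = 0.05, "19-30" = 0.58, "31-40" = 0.30,
                         "41-49" = 0.07),
    anc_first_probs = c(first = 0.40, second = 0.46, third = 0.14)
  )
}

.component_covariates <- function() {
  c("(Intercept)", "wealth_c", "educ_c", "anc4", "planned", "urban",
    "radio", "working")
}

#' Default per-component logistic coefficients (log-odds scale)
#'
#' True coefficient vectors on the covariate design
#' `(intercept, wealth_c, educ_c, anc4, planned, urban, radio, working)`,
#' where `wealth_c` is the wealth quintile centred at the middle quintile
#' and `educ_c` the maternal education level (0-3) centred at primary.
#' Intercepts target the published 2012-era marginal coverages (family
#' planning rare, BCG near-universal); a positive wealth gradient on every
#' component and a strong effect of four-plus antenatal visits on the
#' maternal-care components reproduce the structure the downstream analyses
#' are designed to detect.
#'
#' @return named list of 8 named numeric vectors, one per CCI component.
#' @export
default_component_coefficients <- function() {
  mk <- function(int, wealth, educ, anc4, planned, urban, radio, working) {
    stats::setNames(c(int, wealth, educ, anc4, planned, urban, radio,
                      working), .component_covariates())
  }
  list(
    FPS  = mk(-3.3, 0.45, 0.15, 0.50, 0.10, 0.30, 0.25, 0.15),
    SBA  = mk(-1.2, 0.55, 0.20, 0.90, 0.20, 0.60, 0.20, 0.10),
    ANCS = mk( 0.3, 0.45, 0.20, 1.00, 0.25, 0.40, 0.20, 0.10),
    DTC3 = mk(-0.3, 0.40, 0.10, 0.50, 0.10, 0.20, 0.25, 0.10),
    MSL  = mk( 0.5, 0.35, 0.10, 0.40, 0.10, 0.20, 0.20, 0.10),
    BCG  = mk( 1.6, 0.40, 0.10, 0.50, 0.10, 0.30, 0.20, 0.10),
    ORT  = mk( 0.1, 0.25, 0.10, 0.20, 0.10, 0.15, 0.25, 0.10),
    CPNM = mk( 0.7, 0.30, 0.10, 0.20, 0.10, 0.20, 0.25, 0.10)
  )
}

#' Simulation configuration for DHS-like synthetic microdata
#'
#' Defines the finite population the generator builds: two strata (urban /
#' rural) per region, `clusters_per_stratum` clusters per stratum with sizes
#' varying around `households_per_cluster`, covariates drawn from
#' `covariate_model` with a latent region + urban effect on the wealth
#' quintile (so the wealth/region confounding the analysis must handle is
#' present), and the eight CCI components drawn from logistic models with
#' the known coefficients in `component_coefficients`. ORT is generated only
#' for children with a diarrhoea episode and CPNM only for children with a
#' cough episode (`applicability_rates`).
#'
#' @param clusters_per_stratum clusters in each region-by-urbanicity stratum
#'   of the population.
#' @param households_per_cluster average woman-child records per cluster.
#' @param regions region names (default Guinea's eight).
#' @param wealth_region_effect named per-region shift of the latent wealth
#'   index; default puts Conakry high and the highland/forest regions low.
#' @param wealth_urban_effect latent wealth shift for urban strata (the
#'   confounding strength knob).
#' @param covariate_model see [default_covariate_model()].
#' @param component_coefficients see [default_component_coefficients()];
#'   exactly one named vector per CCI component.
#' @param applicability_rates named probabilities `diarrhoea`, `cough` of a
#'   recent episode (the ORT / CPNM applicability flags).
#' @param year_label survey label stored on every record.
#' @param seed integer seed; the generated population is a deterministic
#'   function of (config, seed).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(clusters_per_stratum = 24,
                       households_per_cluster = 90,
                       regions = guinea_regions(),
                       wealth_region_effect = NULL,
                       wealth_urban_effect = 1.0,
                       covariate_model = default_covariate_model(),
                       component_coefficients =
                         default_component_coefficients(),
                       applicability_rates = c(diarrhoea = 0.25,
                                               cough = 0.30),
                       year_label = "2012-like",
                       seed = 20180527) {
  bad <- function(field, why)
    stop("invalid simulation config: '", field, "' ", why, call. = FALSE)
  if (!is.numeric(clusters_per_stratum) || clusters_per_stratum < 1)
    bad("clusters_per_stratum", "must be a positive count")
  if (!is.numeric(households_per_cluster) || households_per_cluster < 1)
    bad("households_per_cluster", "must be a positive count")
  if (length(regions) < 2 || anyDuplicated(regions))
    bad("regions", "must be >= 2 distinct names")
  if (is.null(wealth_region_effect)) {
    wealth_region_effect <- stats::setNames(rep(0, length(regions)), regions)
    if (identical(sort(regions), sort(guinea_regions()))) {
      wealth_region_effect[] <- c(0.1, 1.2, -0.5, -0.1, 0.2, -0.6, -0.4,
                                  -0.3)[match(names(wealth_region_effect),
                                              guinea_regions())]
    }
  }
  if (!all(regions %in% names(wealth_region_effect)))
    bad("wealth_region_effect", "must name every region")
  comps <- .cci_components()
  if (!setequal(names(component_coefficients), comps) ||
      length(component_coefficients) != length(comps))
    bad("component_coefficients",
        "must have exactly one coefficient vector per CCI component")
  for (cn in comps) {
    b <- component_coefficients[[cn]]
    if (!setequal(names(b), .component_covariates()))
      bad("component_coefficients",
          paste0("[", cn, "] must be named over: ",
                 paste(.component_covariates(), collapse = ", ")))
  }
  if (!all(c("diarrhoea", "cough") %in% names(applicability_rates)) ||
      any(applicability_rates < 0 | applicability_rates > 1))
    bad("applicability_rates",
        "must give 'diarrhoea' and 'cough' probabilities in [0, 1]")
  cm <- covariate_model
  for (f in c("educ_probs_rural", "educ_probs_urban",
              "partner_educ_probs_rural", "partner_educ_probs_urban",
              "mother_age_probs", "anc_first_probs")) {
    if (any(cm[[f]] < 0) || abs(sum(cm[[f]]) - 1) > 1e-8)
      bad(paste0("covariate_model$", f), "must be probabilities summing to 1")
  }
  for (f in c("working_prob", "married_prob", "planned_prob")) {
    if (cm[[f]] < 0 || cm[[f]] > 1)
      bad(paste0("covariate_model$", f), "must be in [0, 1]")
  }
  structure(list(clusters_per_stratum = as.integer(clusters_per_stratum),
                 households_per_cluster = as.integer(households_per_cluster),
                 regions = regions,
                 wealth_region_effect = wealth_region_effect[regions],
                 wealth_urban_effect = wealth_urban_effect,
                 covariate_model = cm,
                 component_coefficients = component_coefficients[comps],
                 applicability_rates = applicability_rates,
                 year_label = year_label,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.wealth_levels <- function() c("Poorest", "Poorer", "Middle", "Richer",
                               "Richest")
.educ_levels <- function() c("none", "primary", "secondary", "higher")

# covariate design matrix for the component logistic models
.component_design <- function(data) {
  cbind("(Intercept)" = 1,
        wealth_c = as.numeric(data$wealth_c),
        educ_c = as.numeric(data$educ_c),
        anc4 = as.numeric(data$anc4),
        planned = as.numeric(data$planned),
        urban = as.numeric(data$urban),
        radio = as.numeric(data$radio),
        working = as.numeric(data$working))
}

#' Generate a DHS-like finite population with known truth
#'
#' Builds the full finite population described by the configuration: every
#' record carries its region, stratum (region by urban/rural), cluster id,
#' covariates, and the eight CCI components drawn Bernoulli from
#' `plogis(x %*% beta_component)`. ORT is non-missing iff the diarrhoea flag
#' is 1 and CPNM iff the cough flag is 1. The returned truth contains the
#' generating coefficients and the exhaustively evaluated population values
#' (per-component coverage, per-region optimal proportion, marginal optimal
#' proportion), so downstream estimators can be tested for parameter
#' recovery and calibration. Deterministic given (config, seed).
#'
#' @param config a [sim_config()].
#' @return Object of class `cci_population`: `data` (one row per woman-child
#'   record), `truth`, `config`.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config()", call. = FALSE)
  .with_seed(config$seed, .generate_population_impl(config))
}

.generate_population_impl <- function(config) {
  cm <- config$covariate_model
  strata <- expand.grid(region = config$regions,
                        urbanicity = c("urban", "rural"),
                        stringsAsFactors = FALSE)
  strata$stratum_id <- paste(strata$region, strata$urbanicity, sep = "_")
  mC <- config$clusters_per_stratum
  hh <- config$households_per_cluster
  cluster_rows <- list()
  for (s in seq_len(nrow(strata))) {
    sizes <- pmax(10L, round(hh * exp(stats::rnorm(mC, 0, 0.25))))
    cluster_rows[[s]] <- data.frame(
      region = strata$region[s],
      urbanicity = strata$urbanicity[s],
      stratum_id = strata$stratum_id[s],
      cluster_id = sprintf("%s_c%03d", strata$stratum_id[s], seq_len(mC)),
      size = sizes, stringsAsFactors = FALSE)
  }
  clusters <- do.call(rbind, cluster_rows)
  idx <- rep(seq_len(nrow(clusters)), clusters$size)
  n <- length(idx)
  d <- clusters[idx, c("region", "urbanicity", "stratum_id", "cluster_id")]
  rownames(d) <- NULL
  d$household_id <- stats::ave(seq_len(n), d$cluster_id,
                               FUN = seq_along)
  d$survey_year <- config$year_label
  d$urban <- as.integer(d$urbanicity == "urban")
  # wealth: latent region + urban effect, cut into population quintiles
  latent <- config$wealth_region_effect[d$region] +
    config$wealth_urban_effect * d$urban + stats::rnorm(n)
  q <- stats::quantile(latent, probs = seq(0, 1, 0.2))
  q[1] <- -Inf; q[length(q)] <- Inf
  wq <- cut(latent, breaks = q, labels = .wealth_levels(),
            include.lowest = TRUE)
  d$wealth_quintile <- as.character(wq)
  d$wealth_c <- as.integer(wq) - 3L
  samp_cat <- function(probs, cond = NULL) {
    # vectorised categorical draw; cond splits rural/urban prob vectors
    if (is.null(cond)) {
      sample(names(probs), n, replace = TRUE, prob = probs)
    } else {
      out <- character(n)
      out[!cond] <- sample(names(probs$rural), sum(!cond), replace = TRUE,
                           prob = probs$rural)
      out[cond] <- sample(names(probs$urban), sum(cond), replace = TRUE,
                          prob = probs$urban)
      out
    }
  }
  urb <- d$urban == 1
  d$mother_educ <- samp_cat(list(rural = cm$educ_probs_rural,
                                 urban = cm$educ_probs_urban), urb)
  d$educ_c <- match(d$mother_educ, .educ_levels()) - 2L
  d$partner_educ <- samp_cat(list(rural = cm$partner_educ_probs_rural,
                                  urban = cm$partner_educ_probs_urban), urb)
  for (m in names(cm$media_base)) {
    p <- stats::plogis(stats::qlogis(cm$media_base[[m]]) +
                         cm$media_wealth_slope * d$wealth_c)
    d[[m]] <- stats::rbinom(n, 1, p)
  }
  d$working <- stats::rbinom(n, 1, cm$working_prob)
  d$married <- stats::rbinom(n, 1, cm$married_prob)
  d$planned <- stats::rbinom(n, 1, cm$planned_prob)
  d$anc4 <- stats::rbinom(n, 1, stats::plogis(
    cm$anc4_intercept + cm$anc4_wealth * d$wealth_c +
      cm$anc4_urban * d$urban))
  d$anc_visits <- ifelse(d$anc4 == 1, "4+", "0-3")
  d$anc_first <- samp_cat(cm$anc_first_probs)
  d$mother_age <- samp_cat(cm$mother_age_probs)
  d$child_sex <- sample(c("female", "male"), n, replace = TRUE)
  d$child_age <- sample(1:4, n, replace = TRUE)
  d$diarrhoea <- stats::rbinom(n, 1, config$applicability_rates[["diarrhoea"]])
  d$cough <- stats::rbinom(n, 1, config$applicability_rates[["cough"]])
  X <- .component_design(d)
  for (cn in .cci_components()) {
    b <- config$component_coefficients[[cn]][colnames(X)]
    val <- stats::rbinom(n, 1, stats::plogis(drop(X %*% b)))
    if (cn == "ORT") val <- ifelse(d$diarrhoea == 1, val, NA_integer_)
    if (cn == "CPNM") val <- ifelse(d$cough == 1, val, NA_integer_)
    d[[cn]] <- val
  }
  cci <- compute_cci(d)
  comp_cov <- vapply(.cci_components(), function(cn)
    mean(d[[cn]], na.rm = TRUE), numeric(1))
  truth <- list(
    component_coefficients = config$component_coefficients,
    component_coverage = comp_cov,
    region_optimal = tapply(cci$label == "optimal", d$region, mean),
    region_partial = tapply(cci$label == "partial", d$region, mean),
    marginal_optimal = mean(cci$label == "optimal"),
    seed = config$seed)
  structure(list(data = d, truth = truth, config = config),
            class = "cci_population")
}

#' @export
print.cci_population <- function(x, ...) {
  cat("Synthetic finite population:", nrow(x$data), "records,",
      length(unique(x$data$cluster_id)), "clusters,",
      length(unique(x$data$stratum_id)), "strata\n")
  cat("  true marginal optimal-CCI proportion:",
      format(x$truth$marginal_optimal, digits = 4), "\n")
  invisible(x)
}

# systematic PPS draw of m clusters; returns selected indices and inclusion
# probabilities (certainty clusters get pi = 1)
.pps_systematic <- function(sizes, m) {
  k <- length(sizes)
  pi <- numeric(k)
  sel <- logical(k)
  remaining <- seq_len(k)
  mm <- m
  repeat {
    if (mm == 0 || !length(remaining)) break
    p <- mm * sizes[remaining] / sum(sizes[remaining])
    cert <- remaining[p >= 1]
    if (!length(cert)) break
    sel[cert] <- TRUE
    pi[cert] <- 1
    mm <- mm - length(cert)
    remaining <- setdiff(remaining, cert)
  }
  if (mm > 0 && length(remaining)) {
    ord <- sample(remaining)  # random ordering before the systematic pass
    cs <- cumsum(sizes[ord])
    tot <- cs[length(cs)]
    step <- tot / mm
    pts <- stats::runif(1, 0, step) + step * (0:(mm - 1))
    hit <- ord[findInterval(pts, cs, left.open = TRUE) + 1]
    sel[hit] <- TRUE
    pi[remaining] <- mm * sizes[remaining] / tot
  }
  list(selected = which(sel), pi = pi)
}

#' Draw a two-stage sample from a synthetic population
#'
#' First stage: within each stratum, `n_clusters` clusters are drawn by
#' systematic probability-proportional-to-size sampling on a randomly
#' ordered cluster list (clusters whose PPS probability reaches 1 are taken
#' with certainty). Second stage: within each selected cluster,
#' `n_households` records are drawn by systematic random sampling (all of
#' them if the cluster is smaller). Each record's weight is the inverse of
#' its overall inclusion probability, so requesting all clusters and all
#' households yields weights identically 1.
#'
#' @param population a [generate_population()] result.
#' @param n_clusters clusters to draw per stratum (must not exceed the
#'   available clusters).
#' @param n_households records to draw per selected cluster.
#' @param seed RNG seed for the draw.
#' @return data.frame of sampled records with columns `weight` (inverse
#'   inclusion probability), `pi1`, `pi2` appended. If any stratum
#'   contributes a single cluster the attribute `single_psu` is `TRUE` and a
#'   warning is raised (variance not estimable with 1 PSU per stratum).
#' @export
draw_svy_sample <- function(population, n_clusters, n_households,
                            seed = NULL) {
  stopifnot(inherits(population, "cci_population"))
  d <- population$data
  .with_seed(seed, {
    out <- list()
    for (s in unique(d$stratum_id)) {
      ds <- d[d$stratum_id == s, , drop = FALSE]
      ctab <- table(ds$cluster_id)
      ids <- names(ctab)
      sizes <- as.numeric(ctab)
      if (n_clusters > length(ids))
        stop("sampling error: requested ", n_clusters,
             " clusters but stratum '", s, "' has ", length(ids),
             call. = FALSE)
      if (n_clusters == length(ids)) {
        pick <- seq_along(ids)
        pi1 <- rep(1, length(ids))
      } else {
        ps <- .pps_systematic(sizes, n_clusters)
        pick <- ps$selected
        pi1 <- ps$pi
      }
      for (j in pick) {
        rows <- which(ds$cluster_id == ids[j])
        Nc <- length(rows)
        if (n_households >= Nc) {
          take <- rows
          pi2 <- 1
        } else {
          perm <- sample(rows)
          step <- Nc / n_households
          pos <- floor(stats::runif(1, 0, step) +
                         step * (0:(n_households - 1))) + 1
          take <- perm[pos]
          pi2 <- n_households / Nc
        }
        sub <- ds[take, , drop = FALSE]
        sub$pi1 <- pi1[j]
        sub$pi2 <- pi2
        sub$weight <- 1 / (pi1[j] * pi2)
        out[[length(out) + 1]] <- sub
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    single <- n_clusters == 1
    if (single)
      warning("single cluster per stratum: design variance not estimable",
              call. = FALSE)
    attr(res, "single_psu") <- single
    res
  })
}
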