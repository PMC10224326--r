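#' Write microdata to CSV
#'
#' Pinned dialect: comma separator, UTF-8, "." decimal, empty field for
#' missing / not-applicable.
#'
#' @param data microdata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate microdata CSV
#'
#' Reads a microdata file in the package dialect (comma, UTF-8, empty field
#' = missing) and validates it: mandatory columns present, positive weights,
#' components in \{0, 1, empty\}, regions in the declared set. Rows failing
#' an invariant are listed in the validation report with their row numbers;
#' they are not dropped.
#'
#' @param path CSV path.
#' @param regions optional character vector of allowed region names.
#' @return list with `data` (typed data.frame) and `report`: a list with
#'   `issues` (data.frame row/field/value/problem) and `missing_counts`
#'   (per-field count of empty cells).
#' @export
read_microdata <- function(path, regions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- tryCatch(utils::read.csv(path, na.strings = "", fileEncoding = "UTF-8",
                                stringsAsFactors = FALSE),
                error = function(e) stop("schema error: cannot parse '",
                                         path, "': ", conditionMessage(e),
                                         call. = FALSE))
  if (nrow(d) == 0 || ncol(d) == 0)
    stop("schema error: '", path, "' has no records", call. = FALSE)
  mandatory <- c("region", "stratum_id", "cluster_id", "weight",
                 .cci_components())
  miss <- setdiff(mandatory, names(d))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  issues <- list()
  note <- function(row, field, value, problem)
    issues[[length(issues) + 1]] <<- data.frame(
      row = row, field = field, value = as.character(value),
      problem = problem, stringsAsFactors = FALSE)
  bad_w <- which(is.na(d$weight) | d$weight <= 0)
  for (i in bad_w) note(i, "weight", d$weight[i], "weight must be > 0")
  if (!is.null(regions)) {
    bad_r <- which(!d$region %in% regions)
    for (i in bad_r) note(i, "region", d$region[i], "unknown region")
  }
  for (cn in .cci_components()) {
    bad_c <- which(!(d[[cn]] %in% c(0, 1) | is.na(d[[cn]])))
    for (i in bad_c) note(i, cn, d[[cn]][i], "must be 0, 1 or empty")
  }
  for (cn in .cci_always()) {
    bad_c <- which(is.na(d[[cn]]))
    for (i in bad_c) note(i, cn, NA, "always-applicable component missing")
  }
  report <- list(
    issues = if (length(issues)) do.call(rbind, issues)
             else data.frame(row = integer(0), field = character(0),
                             value = character(0), problem = character(0)),
    missing_counts = vapply(d, function(col) sum(is.na(col)), integer(1)))
  list(data = d, report = report)
}

#' Write / read a region adjacency list as JSON
#'
#' JSON object `{"region": ["neighbour", ...], ...}`.
#'
#' @param adjacency named list (see [guinea_adjacency()]).
#' @param path file path.
#' @return `write_adjacency`: `path` invisibly; `read_adjacency`: the named
#'   list.
#' @export
write_adjacency <- function(adjacency, path) {
  jsonlite::write_json(adjacency, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  adj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(adj, as.character)
}

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `microdata`/`adjacency` input paths or a `simulate` block
#' must be given. A character `config` is read from YAML or JSON first.
#'
#' @param config either a list or a path to a YAML/JSON file. Recognised
#'   fields: `microdata`, `adjacency` (paths) or `simulate` (list of
#'   [sim_config()] arguments plus `n_clusters`, `n_households`);
#'   `na_policy`; `bivariate` (covariates for the association tests);
#'   `model` (list `response`, `predictors`, `locked`); `tree`
#'   ([tree_params()] arguments); `spatial` (`style`, `n_permutations`,
#'   `alpha`, `class`); `decimals`; `seed`; `output` directory.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  has_input <- !is.null(config$microdata)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim)
    stop("config error: exactly one of 'microdata' or 'simulate' required",
         call. = FALSE)
  if (has_input && is.null(config$adjacency))
    stop("config error: 'adjacency' path required with 'microdata'",
         call. = FALSE)
  defaults <- list(na_policy = "renormalise", decimals = 1,
                   seed = 20180527,
                   bivariate = c("wealth_quintile", "mother_educ",
                                 "partner_educ", "anc_visits", "radio",
                                 "tv", "newspaper", "working", "planned"),
                   model = list(
                     response = "optimal",
                     predictors = c("wealth_quintile", "mother_educ",
                                    "partner_educ", "anc_visits",
                                    "newspaper", "radio", "tv", "working",
                                    "planned", "child_sex"),
                     locked = NULL),
                   tree = list(), spatial = list())
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  sp_def <- list(style = "W", n_permutations = 999, alpha = 0.05,
                 class = "partial")
  for (f in names(sp_def))
    if (is.null(config$spatial[[f]])) config$spatial[[f]] <- sp_def[[f]]
  if (is.null(config$output)) config$output <- tempfile("cci_run_")
  structure(config, class = "pipeline_config")
}

.write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  path
}

#' Run the full care-continuum analysis pipeline
#'
#' Chains every stage on one dataset: load (or simulate) microdata, compute
#' per-record CCI scores and partial/optimal labels, write the descriptive
#' tables (per-component coverage; partial/optimal coverage overall and by
#' region), the bivariate Rao-Scott tests, the survey-weighted logistic
#' regression with backward AIC selection, its odds-ratio table and
#' Hosmer-Lemeshow check, the regional Moran/LISA spatial analysis, and a
#' classification tree on the stepwise-selected variables. All outputs are
#' CSV/JSON files in the output directory plus a JSON manifest recording
#' seeds, options, record counts per stage and MD5 hashes of every output.
#' Reruns with the same config produce byte-identical numeric output.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return (invisibly) list with the computed objects and `files`, the
#'   written paths. On a stage failure the partial outputs are retained and
#'   the manifest records the failure point before the error is re-raised.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out_dir <- config$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("ccindex")),
                   seed = config$seed, na_policy = config$na_policy,
                   options = list(spatial = config$spatial,
                                  tree = config$tree),
                   stages = list())
  files <- character(0)
  stage <- "load"
  res <- list()
  on.exit({
    manifest$failed_stage <- stage
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  log_stage <- function(name, n_in, n_out) {
    message(sprintf("[%s] records in: %d, out: %d", name, n_in, n_out))
    manifest$stages[[name]] <<- list(n_in = n_in, n_out = n_out)
  }
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    n_clusters <- sim$n_clusters %||% 12
    n_households <- sim$n_households %||% 25
    sim$n_clusters <- sim$n_households <- NULL
    if (is.null(sim$seed)) sim$seed <- config$seed
    cfg <- do.call(sim_config, sim)
    pop <- generate_population(cfg)
    data <- draw_svy_sample(pop, n_clusters, n_households,
                            seed = cfg$seed + 1)
    adj <- guinea_adjacency()[cfg$regions]
    adj <- lapply(adj, function(nb) intersect(nb, cfg$regions))
    manifest$simulate <- list(seed = cfg$seed, sample_seed = cfg$seed + 1,
                              n_clusters = n_clusters,
                              n_households = n_households)
    res$truth <- pop$truth
    log_stage("simulate", nrow(pop$data), nrow(data))
  } else {
    md <- read_microdata(config$microdata)
    data <- md$data
    res$validation <- md$report
    adj <- read_adjacency(config$adjacency)
    log_stage("load", nrow(data), nrow(data))
  }
  stage <- "cci"
  cci <- compute_cci(data, na_policy = config$na_policy)
  data$cci_score <- cci$score
  data$cci_label <- cci$label
  data$optimal <- as.numeric(cci$label == "optimal")
  log_stage("cci", nrow(data), sum(!is.na(data$cci_label)))
  stage <- "design"
  design <- svy_design(data, psu = "cluster_id", strata = "stratum_id",
                       weights = "weight")
  stage <- "tables"
  t1 <- component_table(data, design, decimals = 0)
  files <- c(files, .write_table(t1, file.path(out_dir,
                                               "table1_components.csv")))
  t2 <- coverage_table(data, design, decimals = config$decimals)
  t2r <- coverage_table(data, design, by = "region",
                        decimals = config$decimals)
  files <- c(files, .write_table(rbind(cbind(region = "(all)", t2), t2r),
                                 file.path(out_dir, "table2_cci.csv")))
  res$component_table <- t1
  res$coverage_table <- t2
  res$coverage_by_region <- t2r
  log_stage("tables", nrow(data), nrow(t1) + nrow(t2r))
  stage <- "bivariate"
  biv <- lapply(config$bivariate, function(v) {
    rs <- rao_scott_test(design, v, "cci_label")
    data.frame(variable = v, X2 = rs$X2, corrected = rs$statistic,
               df = rs$df, p_F = rs$p_F, p_chisq = rs$p_chisq)
  })
  biv <- do.call(rbind, biv)
  files <- c(files, .write_table(biv, file.path(out_dir,
                                                "table3_bivariate.csv")))
  res$bivariate <- biv
  log_stage("bivariate", nrow(data), nrow(biv))
  stage <- "regression"
  form <- stats::reformulate(config$model$predictors,
                             response = config$model$response)
  full <- svy_logit(form, design)
  sel <- step_aic(full, locked = config$model$locked)
  files <- c(files, .write_table(sel$trail,
                                 file.path(out_dir, "stepwise_trail.csv")))
  ort <- or_table(sel$fit, decimals = 2)
  files <- c(files, .write_table(ort, file.path(out_dir, "table4_or.csv")))
  hl <- hosmer_lemeshow(sel$fit)
  jsonlite::write_json(list(statistic = hl$statistic, df = hl$df, p = hl$p),
                       file.path(out_dir, "hosmer_lemeshow.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(out_dir, "hosmer_lemeshow.json"))
  res$fit <- sel$fit
  res$stepwise <- sel
  res$or_table <- ort
  res$hosmer_lemeshow <- hl
  log_stage("regression", sel$fit$n, nrow(ort))
  stage <- "spatial"
  w <- build_weights(adj, style = config$spatial$style)
  surf <- regional_cci_surface(
    data, design, w, class = config$spatial$class,
    n_permutations = config$spatial$n_permutations,
    seed = config$seed + 2, alpha = config$spatial$alpha)
  g <- surf$moran
  files <- c(files, .write_table(
    data.frame(class = surf$class, moran_i = g$I, expectation = g$expectation,
               p_perm = g$p_perm, p_analytic = g$p_analytic,
               n_permutations = g$n_permutations),
    file.path(out_dir, "table5_moran.csv")))
  files <- c(files, .write_table(surf$table,
                                 file.path(out_dir, "lisa.csv")))
  res$spatial <- surf
  log_stage("spatial", nrow(data), nrow(surf$table))
  stage <- "tree"
  tree_vars <- attr(stats::terms(sel$formula), "term.labels")
  if (!length(tree_vars)) tree_vars <- config$model$predictors
  tp <- do.call(tree_params, config$tree)
  tree <- grow_tree(data, response = "optimal", predictors = tree_vars,
                    weights = data$weight, params = tp)
  writeLines(export_tree(tree, "text"), file.path(out_dir, "tree.txt"))
  writeLines(export_tree(tree, "json"), file.path(out_dir, "tree.json"))
  files <- c(files, file.path(out_dir, c("tree.txt", "tree.json")))
  res$tree <- tree
  log_stage("tree", nrow(data), 1L)
  stage <- "manifest"
  manifest$files <- as.list(stats::setNames(
    as.character(tools::md5sum(files)), basename(files)))
  on.exit()
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$files <- c(files, file.path(out_dir, "manifest.json"))
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
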