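# shared fixtures, built in code

# element-sampling design: each record its own PSU, one stratum, weight 1
srs_design <- function(data, weights = NULL) {
  svy_design(data, psu = seq_len(nrow(data)), weights = weights)
}

# a record with all eight components settable at once
component_record <- function(value = 1, ...) {
  d <- as.data.frame(as.list(stats::setNames(rep(value, 8),
                                             names(cci_weights()))))
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d
}

# cache expensive shared objects across test files
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small default-coefficient population used by several files
small_population <- function() {
  cached("small_pop", generate_population(
    sim_config(clusters_per_stratum = 10, households_per_cluster = 60)))
}

# clustered null data for test-statistic calibration: two categorical
# variables, independent of each other, each with cluster-level correlation
null_clustered_data <- function(n_clusters = 30, m = 12, icc_scale = 1) {
  cl <- rep(seq_len(n_clusters), each = m)
  re1 <- stats::rnorm(n_clusters, 0, icc_scale)[cl]
  re2 <- stats::rnorm(n_clusters, 0, icc_scale)[cl]
  data.frame(
    cluster = cl,
    a = ifelse(stats::runif(n_clusters * m) < stats::plogis(re1), "a1", "a0"),
    b = ifelse(stats::runif(n_clusters * m) < stats::plogis(re2), "b1", "b0"))
}
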