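#' Parameters controlling tree growth
#'
#' @param max_depth maximum depth of any split node (root has depth 0).
#' @param min_node_weight minimum total case weight a node must have to be
#'   considered for splitting, and that each child must retain.
#' @param min_improvement minimum decrease in weighted Gini impurity
#'   (normalised by the root's total weight) for a split to be accepted.
#' @return list of validated parameters.
#' @export
tree_params <- function(max_depth = 5, min_node_weight = 10,
                        min_improvement = 1e-3) {
  if (max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  if (min_node_weight <= 0) stop("min_node_weight must be > 0",
                                 call. = FALSE)
  if (min_improvement < 0) stop("min_improvement must be >= 0",
                                call. = FALSE)
  list(max_depth = max_depth, min_node_weight = min_node_weight,
       min_improvement = min_improvement)
}

.gini <- function(w1, w0) {
  W <- w1 + w0
  if (W <= 0) return(0)
  p <- w1 / W
  2 * p * (1 - p)
}

# best binary split of one predictor; returns NULL or
# list(gain (absolute weighted impurity decrease), type, threshold/left set)
.best_split_var <- function(x, y, w, min_child_w) {
  if (is.numeric(x)) {
    ux <- sort(unique(x))
    if (length(ux) < 2) return(NULL)
    cuts <- (ux[-1] + ux[-length(ux)]) / 2
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]; ws <- w[ord]
    cw1 <- cumsum(ws * ys); cw <- cumsum(ws)
    W <- sum(ws); W1 <- sum(ws * ys)
    # last index going left for each cut
    li <- findInterval(cuts, xs)
    wl <- cw[li]; wl1 <- cw1[li]
    wr <- W - wl; wr1 <- W1 - wl1
    ok <- wl >= min_child_w & wr >= min_child_w
    if (!any(ok)) return(NULL)
    imp <- wl * .gini_vec(wl1, wl - wl1) + wr * .gini_vec(wr1, wr - wr1)
    imp[!ok] <- Inf
    j <- which.min(imp)
    list(impurity = imp[j], type = "numeric", threshold = cuts[j])
  } else {
    x <- as.character(x)
    lev <- unique(x)
    if (length(lev) < 2) return(NULL)
    # order levels by class-1 rate, then scan as if ordinal
    # (exact for binary-response Gini; Breiman's shortcut)
    rate <- vapply(lev, function(l) {
      wl <- w[x == l]
      sum(wl * y[x == l]) / sum(wl)
    }, numeric(1))
    lev <- lev[order(rate, lev)]
    wlv <- vapply(lev, function(l) sum(w[x == l]), numeric(1))
    wlv1 <- vapply(lev, function(l) sum(w[x == l] * y[x == l]), numeric(1))
    cw <- cumsum(wlv); cw1 <- cumsum(wlv1)
    W <- sum(wlv); W1 <- sum(wlv1)
    k <- length(lev) - 1
    wl <- cw[1:k]; wl1 <- cw1[1:k]
    wr <- W - wl; wr1 <- W1 - wl1
    ok <- wl >= min_child_w & wr >= min_child_w
    if (!any(ok)) return(NULL)
    imp <- wl * .gini_vec(wl1, wl - wl1) + wr * .gini_vec(wr1, wr - wr1)
    imp[!ok] <- Inf
    j <- which.min(imp)
    list(impurity = imp[j], type = "categorical",
         left_levels = lev[seq_len(j)])
  }
}

.gini_vec <- function(w1, w0) {
  W <- w1 + w0
  p <- ifelse(W > 0, w1 / W, 0)
  2 * p * (1 - p)
}

.grow_node <- function(data, y, w, predictors, params, depth, root_w) {
  w1 <- sum(w * y); w0 <- sum(w) - w1
  node <- list(n = length(y), w = sum(w), w_class = c(`0` = w0, `1` = w1),
               pred = if (w1 >= w0) 1L else 0L, depth = depth)
  node_imp <- sum(w) * .gini(w1, w0)
  if (depth >= params$max_depth || sum(w) < params$min_node_weight ||
      node_imp == 0) {
    node$leaf <- TRUE
    return(node)
  }
  best <- NULL
  best_var <- NULL
  for (v in predictors) {
    s <- .best_split_var(data[[v]], y, w, params$min_node_weight / 2)
    if (is.null(s)) next
    if (is.null(best) || s$impurity < best$impurity - 1e-12) {
      best <- s
      best_var <- v
    }
  }
  if (is.null(best) ||
      (node_imp - best$impurity) / root_w < params$min_improvement) {
    node$leaf <- TRUE
    return(node)
  }
  if (best$type == "numeric") {
    left <- data[[best_var]] <= best$threshold
    node$split <- list(var = best_var, type = "numeric",
                       threshold = best$threshold)
  } else {
    xv <- as.character(data[[best_var]])
    left <- xv %in% best$left_levels
    node$split <- list(var = best_var, type = "categorical",
                       left_levels = best$left_levels,
                       seen_levels = sort(unique(xv)))
  }
  node$leaf <- FALSE
  node$improvement <- (node_imp - best$impurity) / root_w
  node$left <- .grow_node(data[left, , drop = FALSE], y[left], w[left],
                          predictors, params, depth + 1, root_w)
  node$right <- .grow_node(data[!left, , drop = FALSE], y[!left], w[!left],
                           predictors, params, depth + 1, root_w)
  node
}

#' Grow a weighted binary classification tree (CART)
#'
#' Recursive binary partitioning minimising case-weighted Gini impurity.
#' Numeric and ordinal predictors split at midpoints between observed
#' values; categorical predictors use the ordered-by-class-rate shortcut,
#' which is exact for a binary response. Growth stops on depth, node weight,
#' or when the best split's impurity decrease (normalised by the root's
#' total weight) falls below `min_improvement`. A constant response yields a
#' single-leaf tree. The survey structure enters only through the case
#' weights.
#'
#' @param data data.frame of predictors.
#' @param response binary 0/1 (or logical, or 2-level factor: second level
#'   is the event) vector, or the name of a column in `data`.
#' @param predictors character vector of predictor column names.
#' @param weights case weights (default 1).
#' @param params a [tree_params()] list.
#' @return Object of class `cci_tree` with the recursive node structure in
#'   `$root`. Methods: `print`, `predict`.
#' @export
grow_tree <- function(data, response, predictors, weights = NULL,
                      params = tree_params()) {
  if (is.character(response) && length(response) == 1) {
    y <- data[[response]]
    predictors <- setdiff(predictors, response)
  } else y <- response
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("response must be binary", call. = FALSE)
    y <- as.numeric(y == levels(y)[2])
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary", call. = FALSE)
  missing_p <- setdiff(predictors, names(data))
  if (length(missing_p))
    stop("predictor(s) not in data: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (any(w <= 0) || anyNA(w)) stop("weights must be positive",
                                    call. = FALSE)
  root <- .grow_node(data[predictors], y, w, predictors, params, 0, sum(w))
  structure(list(root = root, predictors = predictors, params = params),
            class = "cci_tree")
}

.tree_lines <- function(node, indent = "") {
  lab <- sprintf("n=%d w=%.1f p(1)=%.3f -> %d", node$n, node$w,
                 node$w_class[2] / node$w, node$pred)
  if (node$leaf) return(paste0(indent, "leaf: ", lab))
  rule <- if (node$split$type == "numeric")
    sprintf("%s <= %g", node$split$var, node$split$threshold)
  else
    sprintf("%s in {%s}", node$split$var,
            paste(node$split$left_levels, collapse = ", "))
  c(paste0(indent, "split [", rule, "]: ", lab),
    .tree_lines(node$left, paste0(indent, "  ")),
    .tree_lines(node$right, paste0(indent, "  ")))
}

#' @export
print.cci_tree <- function(x, ...) {
  cat(export_tree(x, "text"), sep = "\n")
  invisible(x)
}

#' Predict classes from a classification tree
#'
#' Deterministic routing of each record down the tree. A missing split value
#' routes to the heavier child; a categorical level never seen at a split
#' routes to the heavier child with a warning.
#'
#' @param object a [grow_tree()] result.
#' @param newdata data.frame containing all split predictors.
#' @param ... unused.
#' @return data.frame with `class` (0/1) and `node` (binary-heap node id of
#'   the leaf reached; root = 1, children 2k/2k+1). Empty input gives an
#'   empty data.frame.
#' @export
predict.cci_tree <- function(object, newdata, ...) {
  if (nrow(newdata) == 0)
    return(data.frame(class = integer(0), node = integer(0)))
  cls <- integer(nrow(newdata))
  nid <- integer(nrow(newdata))
  warn_env <- new.env()
  warn_env$unknown <- character(0)
  for (i in seq_len(nrow(newdata))) {
    node <- object$root
    id <- 1L
    repeat {
      if (node$leaf) break
      v <- newdata[[node$split$var]][i]
      heavier_left <- node$left$w >= node$right$w
      if (node$split$type == "numeric") {
        go_left <- if (is.na(v)) heavier_left else v <= node$split$threshold
      } else {
        v <- as.character(v)
        if (is.na(v)) {
          go_left <- heavier_left
        } else if (!v %in% node$split$seen_levels) {
          warn_env$unknown <- c(warn_env$unknown, v)
          go_left <- heavier_left
        } else go_left <- v %in% node$split$left_levels
      }
      node <- if (go_left) node$left else node$right
      id <- if (go_left) id * 2L else id * 2L + 1L
    }
    cls[i] <- node$pred
    nid[i] <- id
  }
  if (length(warn_env$unknown))
    warning("unknown categorical level(s) routed to heavier child: ",
            paste(unique(warn_env$unknown), collapse = ", "),
            call. = FALSE)
  data.frame(class = cls, node = nid)
}

.node_to_list <- function(node) {
  out <- list(n = node$n, w = node$w,
              w_class0 = unname(node$w_class[1]),
              w_class1 = unname(node$w_class[2]),
              pred = node$pred, depth = node$depth, leaf = node$leaf)
  if (!node$leaf) {
    out$split <- node$split
    out$improvement <- node$improvement
    out$left <- .node_to_list(node$left)
    out$right <- .node_to_list(node$right)
  }
  out
}

.node_from_list <- function(l) {
  node <- list(n = as.integer(l$n), w = as.numeric(l$w),
               w_class = c(`0` = as.numeric(l$w_class0),
                           `1` = as.numeric(l$w_class1)),
               pred = as.integer(l$pred), depth = as.integer(l$depth),
               leaf = isTRUE(l$leaf))
  if (!node$leaf) {
    sp <- l$split
    node$split <- list(var = sp$var, type = sp$type)
    if (sp$type == "numeric") {
      node$split$threshold <- as.numeric(sp$threshold)
    } else {
      node$split$left_levels <- unlist(sp$left_levels)
      node$split$seen_levels <- unlist(sp$seen_levels)
    }
    node$improvement <- as.numeric(l$improvement)
    node$left <- .node_from_list(l$left)
    node$right <- .node_from_list(l$right)
  }
  node
}

#' Export a classification tree as text or JSON
#'
#' The JSON rendering round-trips: `import_tree(export_tree(x, "json"))`
#' reproduces the tree exactly.
#'
#' @param tree a [grow_tree()] result.
#' @param format `"text"` (indented rules) or `"json"`.
#' @return character: lines of text, or a single JSON string.
#' @export
export_tree <- function(tree, format = c("text", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(tree, "cci_tree"))
  if (format == "text") return(.tree_lines(tree$root))
  as.character(jsonlite::toJSON(
    list(predictors = tree$predictors, params = tree$params,
         root = .node_to_list(tree$root)),
    auto_unbox = TRUE, digits = NA))
}

#' Import a classification tree from its JSON export
#' @param json JSON string produced by [export_tree()].
#' @return a `cci_tree`.
#' @export
import_tree <- function(json) {
  l <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(list(root = .node_from_list(l$root),
                 predictors = unlist(l$predictors),
                 params = list(max_depth = l$params$max_depth,
                               min_node_weight = l$params$min_node_weight,
                               min_improvement = l$params$min_improvement)),
            class = "cci_tree")
}
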