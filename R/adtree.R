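# Alternating decision tree (boosted): a root prediction value plus, per
# boosting iteration, one splitter node (feature <= threshold) attached
# under an existing prediction node, with real-valued prediction children.
# The classification margin of an instance is the sum of the prediction
# values along every path whose conditions it satisfies.

#' Train an alternating decision tree
#'
#' Boosting construction: instance weights start uniform; the root
#' prediction value is \eqn{\frac{1}{2}\ln(W_+/W_-)}. Each iteration
#' exhaustively searches every (prediction node, feature, threshold at
#' midpoints of observed values) triple and keeps the one minimising
#' \deqn{Z = 2\left(\sqrt{W_+(yes) W_-(yes)} + \sqrt{W_+(no) W_-(no)}\right) + W(\neg reach)}
#' New prediction values are \eqn{\frac{1}{2}\ln((W_+ + \varepsilon)/(W_- +
#' \varepsilon))} with \eqn{\varepsilon = 1/n}, and weights update
#' multiplicatively by \eqn{e^{-y \cdot value}}. Ties break on lowest
#' feature index, then lowest threshold, then earliest prediction node.
#' Deterministic.
#'
#' @param instances instance tibble with a logical `label` column and
#'   numeric feature columns (see [build_instances()]), or a numeric matrix
#'   given with `label`.
#' @param iterations number of boosting iterations (splitter nodes).
#' @param features feature columns to use; defaults to all.
#' @param label logical labels when `instances` is a matrix.
#' @return an `adtree` model: root value, splitter table, feature names,
#'   and the per-iteration Z trace.
#' @export
train_adtree <- function(instances, iterations = 10, features = NULL,
                         label = NULL) {
  if (is.matrix(instances)) {
    x <- instances
    y_log <- label
  } else {
    features <- features %||% instance_features(instances)
    x <- as.matrix(instances[, features, drop = FALSE])
    y_log <- instances$label
  }
  if (iterations < 0) abort("iterations must be non-negative")
  if (length(unique(y_log)) < 2) {
    abort("training data must contain both classes")
  }
  n <- nrow(x)
  y <- ifelse(y_log, 1, -1)
  w <- rep(1, n)
  eps <- 1 / n

  wp <- sum(w[y > 0]); wm <- sum(w[y < 0])
  root_value <- 0.5 * log(wp / wm)
  w <- w * exp(-y * root_value)

  # prediction node 1 is the root; splitter s creates nodes 2s and 2s+1
  reach <- list(rep(TRUE, n))
  splitters <- vector("list", iterations)
  z_trace <- numeric(iterations)

  for (it in seq_len(iterations)) {
    total_w <- sum(w)
    best <- NULL
    for (p in seq_along(reach)) {
      in_p <- reach[[p]]
      if (!any(in_p)) next
      w_out <- total_w - sum(w[in_p])
      for (f in seq_len(ncol(x))) {
        v <- x[in_p, f]
        ord <- order(v)
        vs <- v[ord]
        uq <- which(diff(vs) > 0)
        if (length(uq) == 0) next
        thr <- (vs[uq] + vs[uq + 1]) / 2
        win <- w[in_p][ord]
        yin <- y[in_p][ord]
        cp <- cumsum(win * (yin > 0))
        cm <- cumsum(win * (yin < 0))
        wp_yes <- cp[uq]; wm_yes <- cm[uq]
        wp_no <- cp[length(cp)] - wp_yes
        wm_no <- cm[length(cm)] - wm_yes
        z <- 2 * (sqrt(wp_yes * wm_yes) + sqrt(wp_no * wm_no)) + w_out
        k <- which(z <= min(z) + 1e-12)[1] # first minimum = lowest threshold
        tie <- !is.null(best) && abs(z[k] - best$z) <= 1e-12 &&
          (f < best$f ||
             (f == best$f && (thr[k] < best$thr - 1e-12 ||
                                (abs(thr[k] - best$thr) <= 1e-12 && p < best$p))))
        if (is.null(best) || z[k] < best$z - 1e-12 || tie) {
          best <- list(z = z[k], p = p, f = f, thr = thr[k],
                       wp_yes = wp_yes[k], wm_yes = wm_yes[k],
                       wp_no = wp_no[k], wm_no = wm_no[k])
        }
      }
    }
    if (is.null(best)) {
      # no admissible split (constant features everywhere): stop early
      splitters <- splitters[seq_len(it - 1)]
      z_trace <- z_trace[seq_len(it - 1)]
      break
    }
    a_yes <- 0.5 * log((best$wp_yes + eps) / (best$wm_yes + eps))
    a_no <- 0.5 * log((best$wp_no + eps) / (best$wm_no + eps))
    in_p <- reach[[best$p]]
    yes <- in_p & x[, best$f] <= best$thr
    no <- in_p & !yes
    w[yes] <- w[yes] * exp(-y[yes] * a_yes)
    w[no] <- w[no] * exp(-y[no] * a_no)
    reach[[2 * it]] <- yes
    reach[[2 * it + 1]] <- no
    splitters[[it]] <- tibble::tibble(
      splitter = it, parent_node = best$p,
      feature = if (is.matrix(instances)) colnames(x)[best$f] else features[best$f],
      threshold = best$thr,
      yes_value = a_yes, no_value = a_no,
      yes_node = 2L * it, no_node = 2L * it + 1L
    )
    z_trace[it] <- best$z
  }

  structure(
    list(root_value = root_value,
         splitters = purrr::list_rbind(purrr::compact(splitters)),
         feature_names = colnames(x),
         iterations = if (length(splitters) == 0) 0L else length(splitters),
         z_trace = z_trace,
         n_train = n),
    class = "adtree"
  )
}

#' Score instances with an alternating decision tree
#'
#' The margin is the sum of prediction values along all satisfied paths;
#' the predicted class is positive iff the margin is non-negative.
#'
#' @param model an `adtree`.
#' @param newdata instance tibble or numeric matrix providing every model
#'   feature.
#' @return numeric margin vector.
#' @export
adtree_score <- function(model, newdata) {
  x <- if (is.matrix(newdata)) newdata else {
    missing_f <- setdiff(model$feature_names, names(newdata))
    if (length(missing_f) > 0) {
      abort(paste("instances lack model features:",
                  paste(missing_f, collapse = ", ")))
    }
    as.matrix(newdata[, model$feature_names, drop = FALSE])
  }
  if (anyNA(x)) abort("missing feature value in instances to score")
  n <- nrow(x)
  margin <- rep(model$root_value, n)
  if (model$iterations == 0) return(margin)
  reach <- list(rep(TRUE, n))
  sp <- model$splitters
  for (i in seq_len(nrow(sp))) {
    in_p <- reach[[sp$parent_node[i]]]
    yes <- in_p & x[, sp$feature[i]] <= sp$threshold[i]
    no <- in_p & !yes
    margin[yes] <- margin[yes] + sp$yes_value[i]
    margin[no] <- margin[no] + sp$no_value[i]
    reach[[sp$yes_node[i]]] <- yes
    reach[[sp$no_node[i]]] <- no
  }
  margin
}

#' @export
predict.adtree <- function(object, newdata, type = c("margin", "class"), ...) {
  type <- match.arg(type)
  m <- adtree_score(object, newdata)
  if (type == "margin") m else m >= 0
}

#' @export
print.adtree <- function(x, ...) {
  cat(sprintf("<adtree> root %.4f, %d splitter(s) over %d feature(s)\n",
              x$root_value, x$iterations, length(x$feature_names)))
  if (x$iterations > 0) print(x$splitters[, 1:6])
  invisible(x)
}

#' @export
tidy.adtree <- function(x, ...) {
  if (x$iterations == 0) {
    return(tibble::tibble(splitter = integer(), parent_node = integer(),
                          feature = character(), threshold = numeric(),
                          yes_value = numeric(), no_value = numeric()))
  }
  x$splitters[, c("splitter", "parent_node", "feature", "threshold",
                  "yes_value", "no_value")]
}

#' @export
glance.adtree <- function(x, ...) {
  tibble::tibble(iterations = x$iterations,
                 n_features = length(x$feature_names),
                 n_features_used = length(unique(x$splitters$feature)),
                 root_value = x$root_value,
                 final_z = if (x$iterations > 0) x$z_trace[x$iterations] else NA_real_,
                 n_train = x$n_train)
}

#' Save / load an alternating decision tree as JSON text
#'
#' @param model an `adtree`.
#' @param path file path.
#' @return `load_adtree` returns the model; scores round-trip exactly.
#' @export
save_adtree <- function(model, path) {
  obj <- unclass(model)
  obj$splitters <- as.data.frame(obj$splitters)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_adtree
#' @export
load_adtree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$splitters <- tibble::as_tibble(obj$splitters)
  if (length(obj$splitters) == 0 || nrow(obj$splitters) == 0) {
    obj$splitters <- tibble::tibble(
      splitter = integer(), parent_node = integer(), feature = character(),
      threshold = numeric(), yes_value = numeric(), no_value = numeric(),
      yes_node = integer(), no_node = integer())
  }
  obj$iterations <- as.integer(obj$iterations)
  obj$root_value <- as.numeric(obj$root_value)
  obj$z_trace <- as.numeric(obj$z_trace)
  for (col in c("threshold", "yes_value", "no_value")) {
    obj$splitters[[col]] <- as.numeric(obj$splitters[[col]])
  }
  structure(obj, class = "adtree")
}

# ---- learner adapter contract ------------------------------------------
# A learner is a list(name, fit(instances, features) -> model,
# margin(model, instances) -> numeric). Lets alternative classifiers plug
# into the cross-validation, sweep and feature-selection machinery.

#' Learner adapters
#'
#' `adtree_learner()` wraps [train_adtree()]; `logistic_learner()` wraps a
#' plain logistic regression (margin = linear predictor) as an example of
#' the adapter contract; `constant_learner()` always predicts one class
#' (degenerate baseline for tests).
#'
#' @param iterations boosting iterations for the AD-Tree.
#' @return a learner adapter list with `name`, `fit` and `margin`.
#' @export
adtree_learner <- function(iterations = 10) {
  list(
    name = sprintf("adtree%d", iterations),
    fit = function(instances, features = NULL) {
      train_adtree(instances, iterations = iterations, features = features)
    },
    margin = function(model, instances) adtree_score(model, instances)
  )
}

#' @rdname adtree_learner
#' @export
logistic_learner <- function() {
  list(
    name = "logistic",
    fit = function(instances, features = NULL) {
      features <- features %||% instance_features(instances)
      df <- as.data.frame(instances[, c("label", features)])
      suppressWarnings(
        stats::glm(label ~ ., data = df, family = stats::binomial())
      )
    },
    margin = function(model, instances) {
      unname(stats::predict(model, newdata = as.data.frame(instances),
                            type = "link"))
    }
  )
}

#' @rdname adtree_learner
#' @param value fixed margin returned for every instance.
#' @export
constant_learner <- function(value = 1) {
  list(
    name = "constant",
    fit = function(instances, features = NULL) list(value = value),
    margin = function(model, instances) rep(model$value, nrow(instances))
  )
}
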