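# Classifier families for the ensemble. glmnet and mgcv back the penalized
# linear and spline members; the CART tree, bagged random forest,
# gradient-boosted trees and k-nearest-neighbour members are implemented
# here (vectorized base R) since no tree/kNN package ships in the target
# environment.

# ---- minimal CART regression trees with histogram (quantile-binned)
# ---- splits; SSE criterion, which on 0/1 labels is the gini criterion up
# ---- to a constant factor ----

N_BINS <- 32L

# Quantile-bin every covariate once per fit; nodes then score all split
# points of a variable with one O(n) rowsum pass instead of a sort.
bin_features <- function(X) {
  breaks <- lapply(seq_len(ncol(X)), function(j) {
    b <- unique(stats::quantile(X[, j], probs = seq_len(N_BINS - 1) / N_BINS,
                                names = FALSE, type = 1))
    b[is.finite(b)]
  })
  XB <- vapply(seq_len(ncol(X)), function(j)
    findInterval(X[, j], breaks[[j]]) + 1L, integer(nrow(X)))
  if (!is.matrix(XB)) XB <- matrix(XB, nrow = nrow(X))
  list(XB = XB, breaks = breaks)
}

# Best binned split of y on variable j restricted to rows idx.
best_split_binned <- function(xb, y, min_leaf) {
  nb <- max(xb)
  if (nb < 2) return(NULL)
  cnt <- tabulate(xb, nb)
  sy <- numeric(nb); sy2 <- numeric(nb)
  rs <- rowsum(cbind(y, y * y), xb)
  present <- as.integer(rownames(rs))
  sy[present] <- rs[, 1]; sy2[present] <- rs[, 2]
  cn <- cumsum(cnt); cy <- cumsum(sy); cy2 <- cumsum(sy2)
  n <- cn[nb]; tot <- cy[nb]; tot2 <- cy2[nb]
  b <- seq_len(nb - 1)
  nl <- cn[b]; nr <- n - nl
  valid <- nl >= min_leaf & nr >= min_leaf
  if (!any(valid)) return(NULL)
  sse <- rep(Inf, nb - 1)
  sse[valid] <- (cy2[b] - cy[b]^2 / nl)[valid] +
    ((tot2 - cy2[b]) - (tot - cy[b])^2 / nr)[valid]
  k <- which.min(sse)
  gain <- (tot2 - tot^2 / n) - sse[k]
  if (!is.finite(gain) || gain <= 1e-12) return(NULL)
  list(bin = k, gain = gain)
}

grow_tree <- function(XB, y, idx, depth, min_leaf, mtry, breaks) {
  n <- length(idx)
  yv <- y[idx]
  if (depth <= 0 || n < 2 * min_leaf || stats::var(yv) == 0)
    return(list(leaf = TRUE, value = mean(yv)))
  p <- ncol(XB)
  vars <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
  best <- NULL; best_v <- NULL
  for (v in vars) {
    sp <- best_split_binned(XB[idx, v], yv, min_leaf)
    if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
      best <- sp; best_v <- v
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, value = mean(yv)))
  left <- XB[idx, best_v] <= best$bin
  list(leaf = FALSE, var = best_v,
       threshold = breaks[[best_v]][best$bin],  # numeric split point
       left = grow_tree(XB, y, idx[left], depth - 1, min_leaf, mtry, breaks),
       right = grow_tree(XB, y, idx[!left], depth - 1, min_leaf, mtry, breaks))
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  recurse <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    left <- X[idx, node$var] <= node$threshold
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(tree, seq_len(nrow(X)))
  out
}

fit_forest <- function(X, y, n_trees = 30, depth = 5, min_leaf = 10,
                       subsample = 0.632) {
  mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- length(y)
  bn <- bin_features(X)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    ii <- sample.int(n, max(2 * min_leaf, round(subsample * n)))
    trees[[b]] <- grow_tree(bn$XB, y, ii, depth, min_leaf, mtry, bn$breaks)
  }
  list(trees = trees)
}

predict_forest <- function(fit, X) {
  preds <- vapply(fit$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X)))
  if (!is.matrix(preds)) preds <- matrix(preds, nrow = nrow(X))
  pmin(pmax(rowMeans(preds), 0), 1)
}

fit_boost <- function(X, y, n_iter = 50, shrinkage = 0.1, depth = 2,
                      min_leaf = 20) {
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  f <- rep(f0, length(y))
  bn <- bin_features(X)
  idx <- seq_along(y)
  trees <- vector("list", n_iter)
  for (m in seq_len(n_iter)) {
    g <- y - stats::plogis(f)            # negative gradient of log-loss
    tr <- grow_tree(bn$XB, g, idx, depth, min_leaf, ncol(X), bn$breaks)
    trees[[m]] <- tr
    f <- f + shrinkage * 4 * predict_tree(tr, X)
  }
  list(f0 = f0, shrinkage = shrinkage, trees = trees)
}

predict_boost <- function(fit, X) {
  f <- rep(fit$f0, nrow(X))
  for (tr in fit$trees) f <- f + fit$shrinkage * 4 * predict_tree(tr, X)
  stats::plogis(f)
}

# ---- kNN with z-scored features ----

fit_knn <- function(X, y, k = 10, max_prototypes = 1500) {
  # prototype subsampling keeps prediction O(n_query x 2000)
  if (length(y) > max_prototypes) {
    ii <- sample.int(length(y), max_prototypes)
    X <- X[ii, , drop = FALSE]; y <- y[ii]
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sdv, "/"), y = y,
       mu = mu, sd = sdv, k = min(k, length(y)))
}

predict_knn <- function(fit, X) {
  Xq <- sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")
  tn2 <- rowSums(fit$X^2)
  out <- numeric(nrow(Xq))
  idx <- seq_len(nrow(Xq))
  for (s in split(idx, ceiling(idx / 2000))) {
    D <- outer(rowSums(Xq[s, , drop = FALSE]^2), tn2, "+") -
      2 * Xq[s, , drop = FALSE] %*% t(fit$X)
    k <- fit$k
    tD <- t(D)  # column access is cache-friendly
    for (i in seq_along(s)) {
      v <- tD[, i]
      thr <- sort.int(v, partial = k)[k]
      out[s[i]] <- mean(fit$y[which(v <= thr)[seq_len(k)]])
    }
  }
  out
}

# ---- spline (GAM) helper: smooth terms only where the covariate has enough
# ---- distinct values ----

gam_formula <- function(variables, data) {
  terms <- vapply(variables, function(v) {
    k <- min(4L, length(unique(data[[v]])) - 1L)
    if (k >= 3) sprintf("s(%s, k = %d)", v, k) else v
  }, character(1))
  stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
}

#' Algorithm roster for the ensemble
#'
#' Five families spanning the parametric/nonparametric spread of large SDM
#' platforms: ridge-regularized logistic regression, a spline (GAM)
#' classifier, a bagged random-decision-forest, gradient-boosted trees and
#' k-nearest-neighbours. Each entry provides `fit(x, y, seed)` returning a
#' fitted object and `predict(fit, x)` returning probabilities; `x` is a
#' numeric matrix of covariates, `y` a 0/1 vector.
#'
#' @return named list of algorithm definitions.
#' @export
sdm_algorithms <- function() {
  list(
    glm_ridge = list(
      fit = function(x, y, seed) {
        set.seed(seed)
        # fixed mild ridge penalty (no tuning by design); short path aids
        # convergence
        glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = c(0.5, 0.05, 0.005))
      },
      predict = function(fit, x)
        as.vector(stats::predict(fit, newx = x, s = 0.005,
                                 type = "response"))),
    gam_spline = list(
      fit = function(x, y, seed) {
        set.seed(seed)
        d <- as.data.frame(x); d$.y <- y
        f <- gam_formula(colnames(x), d)
        if (nrow(d) > 4000)
          mgcv::bam(f, data = d, family = stats::binomial(),
                    discrete = TRUE)
        else mgcv::gam(f, data = d, family = stats::binomial())
      },
      predict = function(fit, x)
        as.vector(stats::predict(fit, newdata = as.data.frame(x),
                                 type = "response"))),
    random_forest = list(
      fit = function(x, y, seed) { set.seed(seed); fit_forest(x, y) },
      predict = predict_forest),
    boosted_trees = list(
      fit = function(x, y, seed) { set.seed(seed); fit_boost(x, y) },
      predict = predict_boost),
    knn = list(
      fit = function(x, y, seed) { set.seed(seed); fit_knn(x, y) },
      predict = predict_knn)
  )
}

#' Fit one probability-of-presence model per algorithm family
#'
#' @param train training set from [build_training_set()] (needs both labels).
#' @param variables covariate columns to use (>= 2).
#' @param algorithms roster names, subset of `names(sdm_algorithms())`.
#' @param seed integer seed; each algorithm gets a derived sub-seed.
#' @return an `arc_sdm_set`: named list of `arc_sdm_model` objects.
#' @export
fit_single_models <- function(train, variables,
                              algorithms = names(sdm_algorithms()),
                              seed = 1) {
  labs <- unique(train$label)
  if (length(labs) < 2)
    stop("training data contain a single class: ", labs)
  if (length(variables) < 2) stop("need at least 2 covariates")
  roster <- sdm_algorithms()
  bad <- setdiff(algorithms, names(roster))
  if (length(bad)) stop("unknown algorithm(s): ", paste(bad, collapse = ", "))
  x <- as.matrix(train[, variables, drop = FALSE])
  y <- as.numeric(train$label == "presence")
  models <- lapply(algorithms, function(a) {
    fit <- roster[[a]]$fit(x, y, sub_seed(seed, paste0("fit_", a)))
    structure(list(algorithm = a, fit = fit, variables = variables),
              class = "arc_sdm_model")
  })
  names(models) <- algorithms
  structure(models, class = "arc_sdm_set")
}

#' Predict presence probability from a fitted single-algorithm model
#'
#' @param object an `arc_sdm_model`.
#' @param newdata data.frame or matrix containing the model's covariates.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.arc_sdm_model <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$variables, drop = FALSE])
  p <- sdm_algorithms()[[object$algorithm]]$predict(object$fit, x)
  pmin(pmax(p, 0), 1)
}
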