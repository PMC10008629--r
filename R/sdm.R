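# Ensemble machinery: permutation importance, mean-importance variable
# selection, TSS/kappa/AUC evaluation, TSS-gated committee averaging and the
# expert range constraint.

#' Permutation importance of each covariate
#'
#' For each variable, predictions on the intact data are correlated with
#' predictions after permuting that variable; importance is
#' `1 - cor(pred, pred_permuted)` averaged over `n_perm` permutations and
#' clipped to `[0, 1]` (the convention of the large SDM platforms). Constant
#' baseline predictions give importance 0 for every variable.
#'
#' @param model an `arc_sdm_model`.
#' @param data data.frame holding the model's covariates.
#' @param n_perm permutations per variable (default 3).
#' @param seed integer seed.
#' @param max_rows rows used for the correlation (seeded subsample when the
#'   data are larger; importance is a rank statistic and stabilizes well
#'   below study-scale row counts).
#' @return data.frame `algorithm, variable, importance`.
#' @export
permutation_importance <- function(model, data, n_perm = 3, seed = 1,
                                   max_rows = 1000) {
  set.seed(sub_seed(seed, paste0("imp_", model$algorithm)))
  if (nrow(data) > max_rows)
    data <- data[sample.int(nrow(data), max_rows), , drop = FALSE]
  base <- predict(model, data)
  base_const <- stats::sd(base) == 0
  rows <- lapply(model$variables, function(v) {
    imp <- if (base_const) 0 else {
      vals <- vapply(seq_len(n_perm), function(i) {
        d <- data
        d[[v]] <- sample(d[[v]])
        p <- predict(model, d)
        if (stats::sd(p) == 0) 0 else stats::cor(base, p)
      }, numeric(1))
      mean(1 - vals)
    }
    data.frame(algorithm = model$algorithm, variable = v,
               importance = min(max(imp, 0), 1))
  })
  do.call(rbind, rows)
}

#' Select covariates whose mean importance exceeds the average contribution
#'
#' Importances are averaged across algorithms per variable; variables above
#' the across-variable mean are kept. If every variable ties, the first
#' (declared-order) argmax is kept so the selection is never empty.
#'
#' @param importance data.frame `algorithm, variable, importance` (rows from
#'   [permutation_importance()] over several algorithms).
#' @return character vector of selected variable names.
#' @export
select_variables <- function(importance) {
  if (nrow(importance) == 0) stop("empty importance table")
  mean_imp <- tapply(importance$importance, importance$variable, mean)
  mean_imp <- mean_imp[unique(importance$variable)]  # declared order
  keep <- names(mean_imp)[mean_imp > mean(mean_imp)]
  if (!length(keep)) keep <- names(mean_imp)[which.max(mean_imp)]
  keep
}

#' Confusion-matrix scores of a probabilistic prediction at one threshold
#'
#' Predictions at or above the threshold count as presence. Kappa uses the
#' usual chance-agreement correction; TSS is sensitivity + specificity - 1.
#'
#' @param pred numeric scores.
#' @param y 0/1 observed labels.
#' @param threshold binarization threshold.
#' @return list `sensitivity, specificity, TSS, kappa`.
#' @export
confusion_scores <- function(pred, y, threshold) {
  hat <- pred >= threshold
  tp <- sum(hat & y == 1); fn <- sum(!hat & y == 1)
  tn <- sum(!hat & y == 0); fp <- sum(hat & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  n <- tp + fn + tn + fp
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  list(sensitivity = sens, specificity = spec,
       TSS = sens + spec - 1, kappa = kappa)
}

#' Threshold-free AUC via the rank (Mann-Whitney) formula
#'
#' @param pred numeric scores.
#' @param y 0/1 observed labels.
#' @return AUC in `[0, 1]`; NA when a class is absent.
#' @export
auc_score <- function(pred, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(pred)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted model on a held-out test set
#'
#' Sweeps 101 evenly spaced thresholds in `[0, 1]`, picks the one maximizing
#' the True Skill Statistic (smallest threshold on ties), and reports TSS and
#' kappa at that threshold plus threshold-free AUC.
#'
#' @param model an `arc_sdm_model`.
#' @param test test set with `label` and the model's covariates.
#' @return list `algorithm, TSS, kappa, AUC, threshold, sensitivity,
#'   specificity`.
#' @export
evaluate_model <- function(model, test) {
  if (length(unique(test$label)) < 2)
    stop("test data contain a single class")
  pred <- predict(model, test)
  y <- as.numeric(test$label == "presence")
  grid <- seq(0, 1, length.out = 101)
  tss <- vapply(grid, function(th) confusion_scores(pred, y, th)$TSS, numeric(1))
  best <- grid[which.max(tss)]   # which.max -> first/smallest on ties
  sc <- confusion_scores(pred, y, best)
  list(algorithm = model$algorithm, TSS = sc$TSS, kappa = sc$kappa,
       AUC = auc_score(pred, y), threshold = best,
       sensitivity = sc$sensitivity, specificity = sc$specificity)
}

#' Committee-mean ensemble of binary member maps
#'
#' Members whose TSS passes the gate contribute their binary habitat map;
#' the committee score is the per-pixel mean of those binaries (values on
#' the lattice `0, 1/m, ..., 1`) and the ensemble binary map is
#' `score >= 0.5`.
#'
#' @param member_evals named list of evaluations (each with `$TSS`), one per
#'   member map.
#' @param member_binary_maps named list of logical/0-1 matrices on a common
#'   grid.
#' @param tss_gate minimum TSS for admission (default 0.7).
#' @return an `arc_ensemble_prediction`: `committee_score`, `binary_map`,
#'   `members`.
#' @export
committee_ensemble <- function(member_evals, member_binary_maps,
                               tss_gate = 0.7) {
  stopifnot(length(member_evals) == length(member_binary_maps))
  tss <- vapply(member_evals, function(e) e$TSS, numeric(1))
  pass <- names(member_evals)[tss >= tss_gate]
  if (!length(pass)) {
    stop("no admissible members: all TSS below gate ", tss_gate, " [",
         paste(sprintf("%s=%.3f", names(tss), tss), collapse = ", "), "]")
  }
  maps <- member_binary_maps[pass]
  score <- Reduce(`+`, lapply(maps, function(m) m * 1)) / length(maps)
  structure(list(committee_score = score, binary_map = score >= 0.5,
                 members = pass),
            class = "arc_ensemble_prediction")
}

#' Constrain an ensemble prediction to expert-allowed regions
#'
#' Zeroes the committee score and binary map outside the allowed regions
#' (the stand-in for expert range knowledge); idempotent.
#'
#' @param pred an `arc_ensemble_prediction`.
#' @param allowed_regions integer region ids.
#' @param grid the `arc_grid` the prediction lives on.
#' @return the constrained `arc_ensemble_prediction`.
#' @export
constrain_to_regions <- function(pred, allowed_regions, grid) {
  if (!length(allowed_regions)) stop("allowed_regions must be non-empty")
  bad <- setdiff(allowed_regions, unique(as.vector(grid$region_id)))
  if (length(bad)) stop("unknown region id(s): ", paste(bad, collapse = ", "))
  inside <- matrix(grid$region_id %in% allowed_regions,
                   grid$n_rows, grid$n_cols)
  pred$committee_score[!inside] <- 0
  pred$binary_map <- pred$binary_map & inside
  pred
}

# Stratified train/test indices (by label).
stratified_split <- function(labels, train_frac) {
  idx <- seq_along(labels)
  train <- unlist(lapply(split(idx, labels), function(g)
    sample(g, max(1L, round(train_frac * length(g))))))
  list(train = sort(train), test = sort(setdiff(idx, train)))
}

#' Fit the full per-species ensemble with repeated-split evaluation
#'
#' Repeats a stratified 80/20 split `n_splits` times; in each repetition all
#' algorithms are refit on the training part and scored on the holdout.
#' Per-algorithm TSS/kappa/AUC and binarization thresholds are averaged over
#' repetitions, final models are refit on all rows, and members are the
#' algorithms whose mean TSS passes the gate.
#'
#' @param train full training set (both labels).
#' @param variables covariate columns.
#' @param algorithms roster names.
#' @param tss_gate committee admission gate (default 0.7).
#' @param n_splits evaluation repetitions (default 3).
#' @param train_frac training fraction per split (default 0.8).
#' @param seed integer seed.
#' @return an `arc_ensemble_fit`: `models`, `evaluation` (data.frame),
#'   `thresholds`, `members`, `variables`.
#' @export
fit_species_ensemble <- function(train, variables,
                                 algorithms = names(sdm_algorithms()),
                                 tss_gate = 0.7, n_splits = 3,
                                 train_frac = 0.8, seed = 1) {
  evals <- list()
  for (r in seq_len(n_splits)) {
    set.seed(sub_seed(seed, paste0("split_", r)))
    sp <- stratified_split(train$label, train_frac)
    models <- fit_single_models(train[sp$train, , drop = FALSE], variables,
                                algorithms, seed = sub_seed(seed, paste0("rep", r)))
    evals[[r]] <- lapply(models, evaluate_model,
                         test = train[sp$test, , drop = FALSE])
  }
  agg <- lapply(algorithms, function(a) {
    per <- lapply(evals, `[[`, a)
    list(algorithm = a,
         TSS = mean(vapply(per, `[[`, numeric(1), "TSS")),
         kappa = mean(vapply(per, `[[`, numeric(1), "kappa")),
         AUC = mean(vapply(per, `[[`, numeric(1), "AUC")),
         threshold = mean(vapply(per, `[[`, numeric(1), "threshold")))
  })
  names(agg) <- algorithms
  eval_df <- do.call(rbind, lapply(agg, as.data.frame))
  rownames(eval_df) <- NULL
  final <- fit_single_models(train, variables, algorithms,
                             seed = sub_seed(seed, "final"))
  tssv <- vapply(agg, `[[`, numeric(1), "TSS")
  structure(list(models = final, evaluation = eval_df,
                 thresholds = vapply(agg, `[[`, numeric(1), "threshold"),
                 member_evals = agg,
                 members = algorithms[tssv >= tss_gate],
                 variables = variables, tss_gate = tss_gate),
            class = "arc_ensemble_fit")
}

#' Predict the committee-mean habitat map for one year
#'
#' Each gated member predicts probabilities on every ocean cell, binarizes
#' at its own TSS-maximizing threshold, and the committee mean of those
#' binaries is thresholded at 0.5; the result is constrained to the
#' species' allowed regions.
#'
#' @param fit an `arc_ensemble_fit`.
#' @param env an `arc_env`.
#' @param year calendar year.
#' @param allowed_regions region ids for the expert constraint (default:
#'   all regions).
#' @return an `arc_ensemble_prediction` on the stack's grid.
#' @export
predict_ensemble <- function(fit, env, year, allowed_regions = NULL) {
  grid <- env$grid
  cc <- cell_coords(grid)
  newdata <- data.frame(longitude = cc$lon, latitude = cc$lat, year = year)
  newdata <- cbind(newdata, extract_covariates(env, newdata, fit$variables))
  oc <- as.vector(ocean_mask(grid))
  maps <- list(); evals <- list()
  for (a in fit$members) {
    p <- rep(0, nrow(newdata))
    p[oc] <- predict(fit$models[[a]], newdata[oc, , drop = FALSE])
    bin <- matrix(p >= fit$thresholds[[a]], grid$n_rows, grid$n_cols)
    bin[!ocean_mask(grid)] <- FALSE
    maps[[a]] <- bin
    evals[[a]] <- fit$member_evals[[a]]
  }
  pred <- committee_ensemble(evals, maps, tss_gate = fit$tss_gate)
  if (is.null(allowed_regions))
    allowed_regions <- setdiff(unique(as.vector(grid$region_id)), 0L)
  constrain_to_regions(pred, allowed_regions, grid)
}
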