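# End-to-end experiment: screen negatives -> build similarity-profile
# features -> tune ELM hidden parameters by spherical search on the
# cross-validated AUC/AUPR fitness -> retrain the final model -> rank
# novel interactions.

#' Run the full screened-negative, spherical-search ELM experiment
#'
#' Screens high-confidence negatives, builds a class-balanced training
#' set with similarity-profile features, optimizes the ELM hidden weights
#' and biases over the box \[-1, 1\]^D (D = L(d+1)) by spherical search
#' with the k-fold cross-validated mean of (AUC + AUPR)/2 as fitness, and
#' retrains the final output weights on all balanced data at the optimum.
#' With `nfes_max = 0` the optimizer is skipped and a random parameter
#' draw (same box, same seed) is evaluated instead - the plain
#' random-hidden-layer ELM baseline.
#'
#' Cross-validation folds are fixed once from `seed`, so every fitness
#' evaluation sees the same stationary objective; the optimizer's own
#' randomness is seeded separately from the same `seed`.
#'
#' @param network a [dti_network()].
#' @param ratio negatives per positive in the balanced set.
#' @param hidden_nodes ELM hidden-node count L.
#' @param activation hidden activation name.
#' @param folds number of CV folds.
#' @param nfes_max spherical-search evaluation budget (0 disables).
#' @param pop_init,pop_min,pbest_rate,memory_size,reduction spherical
#'   search controls, see [ss_config()].
#' @param seed master seed for folds and optimizer.
#' @param out_dir optional directory; when given, writes
#'   `metrics.json`, `ss_trace.csv`, `model.json` and `config.json`.
#' @return list of class `dti_experiment`: `pairs`, `cv` (a `cv_result`
#'   at the optimum), `fitness`, `baseline_fitness` (random draw, same
#'   folds), `model` (trained `elm`), `ss` (optimizer result or NULL),
#'   `folds`, `config`.
#' @export
run_experiment <- function(network, ratio = 1, hidden_nodes = 20,
                           activation = "sigmoid", folds = 10,
                           nfes_max = 2000, pop_init = 100, pop_min = 4,
                           pbest_rate = 0.11, memory_size = 5,
                           reduction = "linear", seed = 1, out_dir = NULL) {
  stopifnot(inherits(network, "dti_network"))
  config <- list(ratio = ratio, hidden_nodes = hidden_nodes,
                 activation = activation, folds = folds,
                 nfes_max = nfes_max, pop_init = pop_init,
                 pop_min = pop_min, pbest_rate = pbest_rate,
                 memory_size = memory_size, reduction = reduction,
                 seed = seed)

  scores <- score_all(network)
  pairs <- build_balanced_training_set(network, scores, ratio)
  X <- build_feature_vectors(network, pairs)
  y <- pairs$label
  fold_id <- make_folds(nrow(X), y, k = folds, seed = seed)
  d <- ncol(X)
  D <- hidden_nodes * (d + 1L)

  fitness_of <- function(par) {
    cv_fitness(par, X, y, fold_id, hidden_nodes, activation)
  }
  baseline_par <- with_seed(seed, stats::runif(D, -1, 1))
  baseline_fitness <- fitness_of(baseline_par)

  ss <- NULL
  if (nfes_max > 0) {
    cfg <- ss_config(D, lower = -1, upper = 1, nfes_max = nfes_max,
                     pop_init = pop_init, pop_min = pop_min,
                     pbest_rate = pbest_rate, memory_size = memory_size,
                     reduction = reduction, seed = seed)
    ss <- ss_optimize(function(par) -fitness_of(par), cfg)
    best_par <- ss$par
  } else {
    best_par <- baseline_par
  }

  dec <- decode_elm_params(best_par, hidden_nodes, d)
  cv <- elm_cv(X, y, fold_id, dec$W, dec$b, activation)
  model <- elm_train(X, y, W = dec$W, b = dec$b, activation = activation)

  result <- structure(
    list(pairs = pairs, cv = cv, fitness = cv$fitness,
         baseline_fitness = baseline_fitness, model = model, ss = ss,
         folds = fold_id, config = config),
    class = "dti_experiment"
  )
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

write_experiment <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(
    list(fitness = result$fitness,
         baseline_fitness = result$baseline_fitness,
         auc = result$cv$auc, aupr = result$cv$aupr,
         per_fold = result$cv$per_fold),
    file.path(out_dir, "metrics.json"),
    digits = NA, auto_unbox = TRUE
  )
  jsonlite::write_json(result$config, file.path(out_dir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  if (!is.null(result$ss)) {
    utils::write.csv(result$ss$trace, file.path(out_dir, "ss_trace.csv"),
                     row.names = FALSE)
  }
  elm_to_json(result$model, file.path(out_dir, "model.json"))
  invisible(out_dir)
}

#' @export
print.dti_experiment <- function(x, ...) {
  cat(sprintf("dti_experiment: %d pairs (%d positive), CV AUC %.4f, AUPR %.4f, fitness %.4f\n",
              nrow(x$pairs), sum(x$pairs$label == 1), x$cv$auc, x$cv$aupr,
              x$fitness))
  invisible(x)
}

#' Rank candidate novel interactions
#'
#' Scores unlabeled pairs (no known interaction) with a trained model and
#' returns them sorted by descending score; tied scores keep row-major
#' pair order. By default every unlabeled pair is scored
#' (`n * m - n_positives` rows); `exclude` drops a set of pairs (e.g. the
#' screened training negatives) from the ranking.
#'
#' @param model a trained `elm`.
#' @param network a [dti_network()].
#' @param exclude optional data frame with columns `drug` and `target`
#'   (indices) to omit, e.g. `subset(pairs, label == 0)`.
#' @return data frame `drug_id`, `target_id`, `score`, sorted descending.
#' @export
predict_novel <- function(model, network, exclude = NULL) {
  y <- network$interactions
  n <- nrow(y)
  m <- ncol(y)
  keep <- y == 0
  if (!is.null(exclude)) {
    keep[cbind(exclude$drug, exclude$target)] <- FALSE
  }
  idx <- which(keep)
  k <- ((idx - 1L) %% n) + 1L
  j <- ((idx - 1L) %/% n) + 1L
  rowmajor <- (k - 1L) * m + j
  ord0 <- order(rowmajor)
  k <- k[ord0]; j <- j[ord0]
  pairs <- data.frame(drug = k, target = j)
  sc <- elm_predict(model, build_feature_vectors(network, pairs))
  ord <- order(-sc)
  data.frame(drug_id = network$drug_ids[k[ord]],
             target_id = network$target_ids[j[ord]],
             score = sc[ord], stringsAsFactors = FALSE)
}
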