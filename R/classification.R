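#' Verification-network configuration
#'
#' One single-hidden-layer feedforward network is trained per subject in
#' one-vs-rest fashion: output near 1 for the target subject's windows,
#' near 0 for anyone else's. The sub-band comparison experiments use 20
#' hidden nodes (a deliberately modest size so all sub-bands are compared
#' on equal footing); the verification use case uses 75.
#'
#' @param hidden_nodes hidden-layer size (>= 1, default 20).
#' @param max_epochs optimisation iteration cap (default 200).
#' @param decay L2 weight decay of the fit (default 1e-3).
#' @param train_fraction per-subject fraction of windows used for
#'   training (default 0.7).
#' @param impostor_ratio impostor training windows are downsampled
#'   (seeded) to at most this multiple of the genuine training windows
#'   (default 3), keeping the one-vs-rest classes balanced enough to
#'   train.
#' @param seed seed governing the split, the impostor downsampling and
#'   the network initialisation.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(hidden_nodes = 20, max_epochs = 200,
                              decay = 1e-3, train_fraction = 0.7,
                              impostor_ratio = 3, seed = 1) {
  if (!is.numeric(hidden_nodes) || hidden_nodes < 1) {
    stop("hidden_nodes must be >= 1")
  }
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (!is.numeric(impostor_ratio) || impostor_ratio <= 0) {
    stop("impostor_ratio must be positive")
  }
  structure(
    list(hidden_nodes = as.integer(hidden_nodes),
         max_epochs = as.integer(max_epochs), decay = decay,
         train_fraction = train_fraction, impostor_ratio = impostor_ratio,
         seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' Stratified train/test split of a feature table
#'
#' Splits per subject: each subject's rows are shuffled with the seeded
#' stream and the first `floor(train_fraction * n)` go to training, the
#' rest to testing. Disjoint by construction and reproducible.
#'
#' @param features a feature table with a `subject_id` column.
#' @param config a [classifier_config()] (supplies `train_fraction` and
#'   `seed`).
#' @return list with data.frames `train` and `test`.
#' @export
split_train_test <- function(features, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  if (!"subject_id" %in% names(features)) {
    stop("features must have a subject_id column")
  }
  counts <- table(features$subject_id)
  if (any(counts < 2)) {
    stop("every subject needs at least 2 rows to split; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  train_idx <- integer(0)
  for (sid in sort(unique(features$subject_id))) {
    rows <- which(features$subject_id == sid)
    perm <- withr::with_seed(derive_seed(config$seed, 10L, sid),
                             sample(rows))
    n_train <- max(1L, floor(config$train_fraction * length(rows)))
    train_idx <- c(train_idx, perm[seq_len(n_train)])
  }
  list(train = features[sort(train_idx), , drop = FALSE],
       test = features[setdiff(seq_len(nrow(features)), train_idx), ,
                       drop = FALSE])
}

# Logistic forward pass over nnet's weight layout (one hidden layer,
# logistic output): used both for freshly fitted and JSON-reloaded models.
nn_forward <- function(wts, n_in, n_hidden, X) {
  sig <- function(z) 1 / (1 + exp(-z))
  W1 <- matrix(wts[seq_len(n_hidden * (n_in + 1))],
               nrow = n_in + 1, ncol = n_hidden)
  w2 <- wts[n_hidden * (n_in + 1) + seq_len(n_hidden + 1)]
  H <- sig(cbind(1, X) %*% W1)
  as.numeric(sig(cbind(1, H) %*% w2))
}

#' Train one subject's verification network
#'
#' Fits a single-hidden-layer feedforward network (logistic output,
#' cross-entropy loss, quasi-Newton optimiser with weight decay) on the
#' training rows, with target 1 for `target_subject` and 0 for all other
#' subjects. Impostor rows are first downsampled (seeded) to
#' `impostor_ratio` times the genuine rows; features are z-scored with
#' parameters fitted on the (downsampled) training rows only, and those
#' parameters are stored in the model. Deterministic given the config
#' seed and the data.
#'
#' @param train training feature table (with `subject_id`).
#' @param target_subject the subject this model verifies.
#' @param config a [classifier_config()].
#' @return an object of class `subject_model`.
#' @export
train_subject_model <- function(train, target_subject,
                                config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  if (!target_subject %in% train$subject_id) {
    stop("target subject absent from training data")
  }
  if (all(train$subject_id == target_subject)) {
    stop("training data contains a single class (no impostor subjects)")
  }
  fcols <- feature_columns(train)
  gen <- which(train$subject_id == target_subject)
  imp <- which(train$subject_id != target_subject)
  n_imp <- min(length(imp),
               ceiling(config$impostor_ratio * length(gen)))
  imp <- withr::with_seed(
    derive_seed(config$seed, 20L, target_subject),
    sort(sample(imp, n_imp))
  )
  rows <- c(gen, imp)
  X <- as.matrix(train[rows, fcols, drop = FALSE])
  y <- as.numeric(train$subject_id[rows] == target_subject)
  centre <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, centre), 2, scale, "/")

  fit <- withr::with_seed(
    derive_seed(config$seed, 21L, target_subject),
    nnet::nnet(Xs, y, size = config$hidden_nodes, entropy = TRUE,
               decay = config$decay, maxit = config$max_epochs,
               MaxNWts = (length(fcols) + 2) * config$hidden_nodes + 1,
               trace = FALSE)
  )
  structure(
    list(subject_id = target_subject, wts = fit$wts,
         n_in = length(fcols), n_hidden = config$hidden_nodes,
         feature_names = fcols, centre = centre, scale = scale,
         seed = config$seed, converged = fit$convergence == 0,
         final_loss = fit$value),
    class = "subject_model"
  )
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf(
    "<subject_model> subject %s: %d-%d-1 network, %d features, seed %d\n",
    format(x$subject_id), x$n_in, x$n_hidden, x$n_in, x$seed))
  invisible(x)
}

#' Score feature rows with a subject model
#'
#' Applies the model's stored standardisation and forward pass; outputs
#' are sigmoid-bounded verification scores in \[0, 1\] (1 = looks like the
#' target subject).
#'
#' @param model a [train_subject_model()] result (fresh or re-loaded via
#'   [load_model()]).
#' @param features a feature table containing the model's feature
#'   columns, or a numeric matrix with matching number of columns.
#' @return numeric vector of scores, one per row.
#' @export
score <- function(model, features) {
  stopifnot(inherits(model, "subject_model"))
  if (is.data.frame(features)) {
    missing <- setdiff(model$feature_names, names(features))
    if (length(missing) > 0) {
      stop("features lack model columns: ", paste(missing, collapse = ", "))
    }
    X <- as.matrix(features[, model$feature_names, drop = FALSE])
  } else {
    X <- as.matrix(features)
    if (ncol(X) != model$n_in) {
      stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                   model$n_in, ncol(X)))
    }
  }
  Xs <- sweep(sweep(X, 2, model$centre), 2, model$scale, "/")
  nn_forward(model$wts, model$n_in, model$n_hidden, Xs)
}

#' Collect genuine and impostor scores for every subject
#'
#' For each model, its target subject's test rows are scored as genuine
#' attempts and every other subject's test rows as impostor attempts.
#'
#' @param models list of `subject_model` (any order).
#' @param test test feature table (with `subject_id`).
#' @return named list (by target subject) of `score_set` objects, each
#'   with numeric `genuine` and `impostor` elements.
#' @export
collect_scores <- function(models, test) {
  if (nrow(test) == 0) stop("test set is empty")
  out <- list()
  for (m in models) {
    gen_rows <- test$subject_id == m$subject_id
    if (!any(gen_rows)) {
      stop("no test rows for target subject ", m$subject_id)
    }
    out[[as.character(m$subject_id)]] <- structure(
      list(genuine = score(m, test[gen_rows, , drop = FALSE]),
           impostor = score(m, test[!gen_rows, , drop = FALSE])),
      class = "score_set"
    )
  }
  out
}

#' Save / load a subject model as JSON
#'
#' The JSON records the architecture, weights, standardisation parameters
#' and seed; [load_model()] restores a model whose [score()] output is
#' identical to the original's.
#'
#' @param model a `subject_model`.
#' @param path JSON file path.
#' @return `path` (save) or the restored `subject_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "subject_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$centre <- stats::setNames(as.numeric(obj$centre), obj$feature_names)
  obj$scale <- stats::setNames(as.numeric(obj$scale), obj$feature_names)
  structure(obj, class = "subject_model")
}
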