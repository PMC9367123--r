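## L2-regularised logistic scoring model (DEWS).
##
## Fitting is ridge logistic regression (glmnet, alpha = 0) on the
## normalised 38-feature matrix. The regularisation strength is chosen
## by ten-fold cross-validation that is grouped by admission episode
## (all rows of an episode share a fold — no within-patient leakage)
## and stratified on the episode-level outcome (any positive row). The
## selected model is refit on the full training data.

#' Train a DEWS logistic model
#'
#' @param features feature data frame from [build_features()] (with
#'   `episode_id`), or a numeric matrix plus `episode` ids.
#' @param labels integer 0/1 outcome labels, one per row.
#' @param episode episode id per row; defaults to
#'   `features$episode_id`.
#' @param folds number of cross-validation folds (default 10). Reduced
#'   with a warning when there are fewer positive episodes than folds.
#' @param reg_grid inverse regularisation strengths C to search
#'   (default 7 log-spaced values 1e-3 to 1e3); the ridge penalty
#'   passed to the optimiser is `1 / (n C)`.
#' @param seed RNG seed for fold assignment.
#' @param outcome outcome name stored on the model.
#' @param feature_names manifest subset to use (default the full
#'   38-feature manifest present in `features`).
#' @param thresh optimiser convergence tolerance.
#' @return a `dews_model`: coefficients (named), intercept,
#'   `reg_strength` (chosen C), `lambda`, normalizer, manifest version,
#'   outcome, per-fold AUROC at the chosen strength (`cv_summary`) and
#'   the full CV grid (`cv_grid`).
#' @export
train_dews <- function(features, labels, episode = NULL, folds = 10L,
                       reg_grid = 10^seq(-3, 3, length.out = 7),
                       seed = 1L, outcome = "d_icu",
                       feature_names = NULL, thresh = 1e-8) {
  if (is.null(episode)) {
    if (!is.data.frame(features) || is.null(features$episode_id)) {
      stop("supply 'episode' ids or a feature data frame with episode_id",
           call. = FALSE)
    }
    episode <- features$episode_id
  }
  if (is.null(feature_names)) {
    manifest <- feature_manifest()
    feature_names <- if (is.data.frame(features)) {
      intersect(manifest, names(features))
    } else {
      intersect(manifest, colnames(features))
    }
    if (length(feature_names) == 0L) {
      feature_names <- colnames(feature_matrix(features))
    }
  }
  X_raw <- feature_matrix(features)[, feature_names, drop = FALSE]
  y <- as.integer(labels)
  n <- nrow(X_raw)
  stopifnot(length(y) == n, length(episode) == n)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }

  normalizer <- fit_normalizer_matrix(X_raw)
  X <- apply_normalizer_matrix(normalizer, X_raw)

  fold_id <- make_grouped_folds(episode, y, folds, seed)
  folds_used <- max(fold_id)

  lambda <- sort(1 / (n * reg_grid), decreasing = TRUE)
  C_of_lambda <- 1 / (n * lambda)

  cv_auc <- matrix(NA_real_, nrow = folds_used, ncol = length(lambda))
  for (f in seq_len(folds_used)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE,
                          thresh = thresh, maxit = 1e6)
    pred <- predict(fit, X[!tr, , drop = FALSE], type = "response",
                    s = lambda)
    for (j in seq_along(lambda)) {
      cv_auc[f, j] <- auroc(pred[, j], y[!tr])
    }
  }
  mean_auc <- colMeans(cv_auc, na.rm = TRUE)
  # tie-break toward the stronger penalty (larger lambda = first index)
  best <- which.max(mean_auc)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE,
                        thresh = thresh, maxit = 1e6)
  beta <- as.numeric(predict(fit, type = "coefficients",
                             s = lambda[best]))
  structure(list(
    coefficients = setNames(beta[-1], feature_names),
    intercept = beta[1],
    reg_strength = C_of_lambda[best],
    lambda = lambda[best],
    normalizer = normalizer,
    manifest_version = attr(feature_manifest(), "version"),
    features = feature_names,
    outcome = outcome,
    folds = folds_used,
    seed = seed,
    cv_summary = cv_auc[, best],
    cv_grid = data.frame(C = C_of_lambda, lambda = lambda,
                         mean_auroc = mean_auc)),
    class = "dews_model")
}

# normalizer on a plain matrix (no manifest reordering)
fit_normalizer_matrix <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  const <- !is.finite(sdev) | sdev == 0
  sdev[const] <- 1
  structure(list(mean = mu, sd = sdev,
                 constant = colnames(X)[const], features = colnames(X)),
            class = "dews_normalizer")
}

apply_normalizer_matrix <- function(normalizer, X) {
  sweep(sweep(X[, normalizer$features, drop = FALSE], 2,
              normalizer$mean, "-"), 2, normalizer$sd, "/")
}

#' Episode-grouped, outcome-stratified fold assignment
#'
#' Every row of an episode lands in the same fold; episodes are
#' stratified by episode-level outcome (any positive row) so each fold
#' receives a balanced share of positive episodes.
#'
#' @param episode episode id per row.
#' @param y 0/1 label per row.
#' @param folds requested number of folds; reduced with a warning when
#'   fewer positive episodes exist.
#' @param seed RNG seed.
#' @return integer fold id per row.
#' @export
make_grouped_folds <- function(episode, y, folds = 10L, seed = 1L) {
  ep_pos <- tapply(y, episode, function(v) as.integer(any(v == 1L)))
  ids <- names(ep_pos)
  n_pos <- sum(ep_pos == 1L)
  if (n_pos < folds) {
    folds <- max(2L, n_pos)
    warning("fewer positive episodes than folds; reduced to ", folds,
            call. = FALSE)
  }
  set.seed(seed)
  fold_of <- integer(length(ids))
  names(fold_of) <- ids
  for (cls in c(1L, 0L)) {
    grp <- ids[ep_pos == cls]
    grp <- sample(grp)
    fold_of[grp] <- rep_len(seq_len(folds), length(grp))
  }
  unname(fold_of[as.character(episode)])
}

#' Score observations with a trained DEWS model
#'
#' @param model a `dews_model`.
#' @param features feature data frame or matrix containing the model's
#'   feature columns.
#' @return numeric vector of probabilities in (0, 1):
#'   `plogis(intercept + coefficients . normalized features)`.
#' @export
dews_score <- function(model, features) {
  stopifnot(inherits(model, "dews_model"))
  X_raw <- feature_matrix(features)
  missing <- setdiff(model$features, colnames(X_raw))
  if (length(missing) > 0L) {
    stop("feature manifest mismatch; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- apply_normalizer_matrix(model$normalizer,
                               X_raw[, model$features, drop = FALSE])
  as.numeric(plogis(model$intercept + X %*% model$coefficients))
}

#' @export
print.dews_model <- function(x, ...) {
  cat(sprintf("<dews_model> outcome=%s, %d features, C=%.4g\n",
              x$outcome, length(x$coefficients), x$reg_strength))
  cat(sprintf("  CV AUROC (chosen C): %.3f (mean of %d folds)\n",
              mean(x$cv_summary, na.rm = TRUE), x$folds))
  invisible(x)
}

#' Persist / restore a model as JSON
#'
#' @param model a `dews_model`.
#' @param path output path.
#' @return `read_model` returns the restored `dews_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "dews_model"))
  obj <- model
  class(obj) <- NULL
  obj$normalizer <- unclass(obj$normalizer)
  # named atomic vectors serialise as bare arrays; keep names via lists
  obj$coefficients <- as.list(obj$coefficients)
  obj$normalizer$mean <- as.list(obj$normalizer$mean)
  obj$normalizer$sd <- as.list(obj$normalizer$sd)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- setNames(as.numeric(obj$coefficients),
                               names(obj$coefficients))
  obj$normalizer <- structure(list(
    mean = setNames(as.numeric(obj$normalizer$mean),
                    names(obj$normalizer$mean)),
    sd = setNames(as.numeric(obj$normalizer$sd),
                  names(obj$normalizer$sd)),
    constant = as.character(obj$normalizer$constant %||% character()),
    features = as.character(obj$normalizer$features)),
    class = "dews_normalizer")
  structure(obj, class = "dews_model")
}
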