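MODEL_SCHEMA_VERSION <- 1L

#' Fit a correspondence classifier
#'
#' Trains the calibrated binary classifier that maps a pair-feature vector
#' to the probability that the two fragments belong to the same individual.
#' Stage `"step1"` (detection pairs) uses a linear-kernel support vector
#' machine with Platt-scaled probability output; stage `"step2"` (tracklet
#' pairs) uses a random forest whose probability is the vote fraction.
#' Class imbalance is handled by inverse-frequency class weights rather
#' than subsampling, so the sample-generation rules remain untouched.
#'
#' @param samples A labeled sample table from [generate_step1_samples()] or
#'   [generate_step2_samples()]: the stage's feature columns plus a logical
#'   `label`.
#' @param stage `"step1"` or `"step2"`.
#' @param hyperparams Named list overriding defaults (`cost` for step 1;
#'   `ntree`, `mtry`, `nodesize` for step 2).
#' @param grid Optional named list of hyperparameter vectors; when given, a
#'   seeded 75/25 split selects the combination with the best held-out ROC
#'   AUC before refitting on all samples.
#' @param max_samples Cap on the number of training rows; larger inputs are
#'   uniformly subsampled with the given seed (the class ratio is left to
#'   the weighting).
#' @param seed Integer seed controlling subsampling and fitting.
#' @return A `correspondence_model` object.
#' @export
fit_correspondence_model <- function(samples,
                                     stage = c("step1", "step2"),
                                     hyperparams = list(),
                                     grid = NULL,
                                     max_samples = 50000L,
                                     seed = 1L) {
  stage <- match.arg(stage)
  feats <- if (stage == "step1") step1_feature_names() else step2_feature_names()
  missing_cols <- setdiff(c(feats, "label"), names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Samples lack required column(s) for stage ", stage, ": ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  y <- samples$label
  if (length(unique(y)) < 2) {
    abort("Training requires at least one positive and one negative sample.")
  }
  x <- as.data.frame(samples[, feats])
  if (any(!is.finite(as.matrix(x)))) abort("Non-finite feature values in samples.")

  set.seed(seed)
  if (nrow(x) > max_samples) {
    keep <- sample.int(nrow(x), max_samples)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
    if (length(unique(y)) < 2) {
      abort("Subsampling removed one class; increase max_samples.")
    }
  }

  defaults <- if (stage == "step1") {
    list(cost = 1)
  } else {
    list(ntree = 200L, mtry = 2L, nodesize = 5L)
  }
  hp <- modifyList(defaults, hyperparams)

  if (!is.null(grid)) {
    hp <- modifyList(hp, select_hyperparams(x, y, stage, hp, grid, seed))
  }

  set.seed(seed)
  predictor <- fit_stage(x, y, stage, hp)

  structure(
    list(
      stage = stage,
      predictor = predictor,
      feature_names = feats,
      schema_version = MODEL_SCHEMA_VERSION,
      metadata = list(
        n_samples = length(y),
        n_positive = sum(y),
        n_negative = sum(!y),
        seed = seed,
        hyperparams = hp,
        config_hash = rlang::hash(list(stage, feats, MODEL_SCHEMA_VERSION))
      )
    ),
    class = "correspondence_model"
  )
}

fit_stage <- function(x, y, stage, hp) {
  yf <- factor(y, levels = c(FALSE, TRUE))
  wts <- length(y) / (2 * table(yf))
  if (stage == "step1") {
    e1071::svm(
      x = x, y = yf, kernel = "linear", cost = hp$cost,
      class.weights = wts, probability = TRUE, scale = TRUE
    )
  } else {
    randomForest::randomForest(
      x = x, y = yf,
      ntree = hp$ntree, mtry = hp$mtry, nodesize = hp$nodesize,
      classwt = as.numeric(wts), importance = TRUE
    )
  }
}

select_hyperparams <- function(x, y, stage, hp, grid, seed) {
  set.seed(seed)
  holdout <- sample.int(length(y)) <= length(y) * 0.25
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  scores <- vapply(seq_len(nrow(combos)), function(i) {
    set.seed(seed)
    fit <- fit_stage(
      x[!holdout, , drop = FALSE], y[!holdout], stage,
      modifyList(hp, as.list(combos[i, , drop = FALSE]))
    )
    p <- stage_probability(fit, x[holdout, , drop = FALSE])
    rank_auc(p, y[holdout])
  }, numeric(1))
  as.list(combos[which.max(scores), , drop = FALSE])
}

stage_probability <- function(predictor, x) {
  if (inherits(predictor, "svm")) {
    pr <- predict(predictor, newdata = x, probability = TRUE)
    unname(attr(pr, "probabilities")[, "TRUE"])
  } else {
    unname(predict(predictor, newdata = x, type = "prob")[, "TRUE"])
  }
}

# Mann-Whitney ROC AUC from scores and logical labels.
rank_auc <- function(scores, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Correspondence probability for feature vectors
#'
#' @param model A [fit_correspondence_model()] result.
#' @param features A data frame containing the model stage's feature
#'   columns (extra columns are ignored).
#' @return Numeric vector of probabilities in \[0, 1\], one per row;
#'   deterministic for a fixed fitted model.
#' @export
predict_probability <- function(model, features) {
  stopifnot(inherits(model, "correspondence_model"))
  missing_cols <- setdiff(model$feature_names, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Feature columns do not match model stage `", model$stage, "`; missing: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(features) == 0) {
    return(numeric(0))
  }
  x <- as.data.frame(features[, model$feature_names])
  stage_probability(model$predictor, x)
}

#' @export
print.correspondence_model <- function(x, ...) {
  m <- x$metadata
  cat(sprintf(
    "<correspondence_model: %s> %s; %d samples (%d pos / %d neg), seed %d\n",
    x$stage,
    if (x$stage == "step1") "linear SVM + Platt scaling" else "random forest",
    m$n_samples, m$n_positive, m$n_negative, m$seed
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correspondence model
#'
#' For the step-1 linear SVM, returns the hyperplane weight of each feature
#' (on the internally scaled feature space) plus the intercept; for the
#' step-2 random forest, the permutation importance of each feature.
#'
#' @param x A `correspondence_model`.
#' @param ... Unused.
#' @return A tibble with one row per feature.
#' @method tidy correspondence_model
#' @export
tidy.correspondence_model <- function(x, ...) {
  if (x$stage == "step1") {
    w <- drop(t(x$predictor$coefs) %*% x$predictor$SV)
    tibble(
      term = c(x$feature_names, "(intercept)"),
      estimate = c(w, -x$predictor$rho)
    )
  } else {
    imp <- randomForest::importance(x$predictor, type = 1)
    tibble(term = rownames(imp), estimate = as.numeric(imp))
  }
}

#' Glance at a correspondence model
#'
#' @param x A `correspondence_model`.
#' @param ... Unused.
#' @return A one-row tibble with the stage, sample counts, positive
#'   fraction, and the fit's own training summary (number of support
#'   vectors or out-of-bag error).
#' @method glance correspondence_model
#' @export
glance.correspondence_model <- function(x, ...) {
  m <- x$metadata
  tibble(
    stage = x$stage,
    n_samples = m$n_samples,
    positive_fraction = m$n_positive / m$n_samples,
    fit_summary = if (x$stage == "step1") {
      x$predictor$tot.nSV
    } else {
      x$predictor$err.rate[x$predictor$ntree, "OOB"]
    },
    seed = m$seed
  )
}

#' Persist and restore fitted correspondence models
#'
#' Models are stored as a versioned bundle (predictor, feature schema,
#' metadata). Loading a bundle whose feature schema does not match the
#' installed package fails loudly rather than silently producing garbage
#' probabilities.
#'
#' @param model A `correspondence_model`.
#' @param path File path for the bundle.
#' @return `save_correspondence_model()` returns `path` invisibly;
#'   `load_correspondence_model()` returns the model.
#' @export
save_correspondence_model <- function(model, path) {
  stopifnot(inherits(model, "correspondence_model"))
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname save_correspondence_model
#' @export
load_correspondence_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "correspondence_model")) {
    abort("File is not a correspondence model bundle.")
  }
  if (!identical(model$schema_version, MODEL_SCHEMA_VERSION)) {
    abort(sprintf(
      "Model bundle schema version %s does not match the installed package (%s).",
      format(model$schema_version), format(MODEL_SCHEMA_VERSION)
    ))
  }
  expected <- if (model$stage == "step1") step1_feature_names() else step2_feature_names()
  if (!identical(model$feature_names, expected)) {
    abort("Model bundle feature schema does not match this package version.")
  }
  model
}
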