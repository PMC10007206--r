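# Per-participant sleep-stage classification across jitter levels:
# cross-validated SVM (Gaussian kernel, one-vs-one multiclass) and kNN
# errors, non-parametric Bayes-error bounds from the kNN error, feature
# sensitivity slopes, ensemble error curves, and confusion-matrix pooling.

#' Evaluation configuration
#'
#' @param classifier `"svm"` (Gaussian-kernel one-vs-one, via libsvm) or
#'   `"knn"`.
#' @param k_folds cross-validation folds (>= 2).
#' @param knn_k neighbour count for the kNN classifier / Bayes bound input.
#' @param feature_subset `"all"` or one of the six feature names.
#' @param scheme labeling scheme the evaluation runs under.
#' @param block_cv use contiguous temporal blocks as folds instead of
#'   stratified random folds (guards against autocorrelation leakage).
#' @param seed integer seed for fold assignment and tie-breaking.
#' @return object of class `eval_config`.
#' @export
eval_config <- function(classifier = c("svm", "knn"), k_folds = 10L,
                        knn_k = 10L, feature_subset = "all",
                        scheme = c("micro", "macro"), block_cv = FALSE,
                        seed = 1L) {
  classifier <- match.arg(classifier)
  scheme <- match.arg(scheme)
  if (k_folds < 2) stop("k_folds must be >= 2")
  if (!identical(feature_subset, "all") &&
      !feature_subset %in% HRV_FEATURES)
    stop("feature_subset must be 'all' or one of ",
         paste(HRV_FEATURES, collapse = ","))
  structure(list(classifier = classifier, k_folds = as.integer(k_folds),
                 knn_k = as.integer(knn_k), feature_subset = feature_subset,
                 scheme = scheme, block_cv = block_cv,
                 seed = as.integer(seed)),
            class = "eval_config")
}

# Stratified (or temporal-block) fold assignment.
assign_folds <- function(y, k, block = FALSE, seed = 1L) {
  n <- length(y)
  if (block) return(as.integer(cut(seq_len(n), k, labels = FALSE)))
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated classification error for one participant at one level
#'
#' Stratified k-fold cross-validation of the configured classifier on the
#' participant's per-epoch features against the cleaned stage labels.
#' Features are z-scored with training-fold statistics inside each fold.
#' The SVM backend is libsvm's Gaussian-kernel machine with its native
#' one-vs-one multiclass voting and default kernel scale/cost; kNN uses
#' majority vote over `knn_k` neighbours.
#'
#' If some class has fewer members than folds the error is still computed
#' (such classes are spread over as many folds as they have members) but the
#' result carries `attr(, "flagged") = TRUE` so downstream summaries can
#' report it rather than silently dropping the cell.
#'
#' @param features feature tibble for one participant/level (rows =
#'   epochs), with the columns in `HRV_FEATURES` and a `valid` flag.
#' @param labels [hypnogram()] aligned to the feature rows, or a character
#'   vector of per-epoch labels.
#' @param cfg an [eval_config()].
#' @param keep_rows optional logical mask of rows to use (e.g. the
#'   across-level common-valid mask); defaults to `features$valid`.
#' @return error percentage in `[0, 100]`, with attributes `flagged`
#'   (logical) and `confusion` (table, true x predicted).
#' @export
cv_error <- function(features, labels, cfg, keep_rows = NULL) {
  labs <- if (inherits(labels, "hypnogram")) labels$labels else
    as.character(labels)
  if (length(labs) != nrow(features))
    stop("labels and feature rows are misaligned")
  if (is.null(keep_rows)) keep_rows <- features$valid
  cols <- if (identical(cfg$feature_subset, "all")) HRV_FEATURES else
    cfg$feature_subset
  x <- as.matrix(features[keep_rows, cols, drop = FALSE])
  y <- factor(labs[keep_rows])
  if (nrow(x) < cfg$k_folds) stop("too few valid epochs for k-fold CV")
  if (nlevels(droplevels(y)) < 2)
    stop("need at least 2 classes present to classify")
  y <- droplevels(y)
  flagged <- any(table(y) < cfg$k_folds)
  folds <- assign_folds(y, cfg$k_folds, cfg$block_cv, cfg$seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(cfg$k_folds)) {
    tr <- folds != f
    if (!any(tr) || !any(!tr)) next
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sg[!is.finite(sg) | sg < 1e-12] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    xte <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    ytr <- droplevels(y[tr])
    p <- if (cfg$classifier == "svm") {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", scale = FALSE)
      stats::predict(fit, xte)
    } else {
      with_seed(split_seed(cfg$seed, f),
                class::knn(xtr, xte, ytr,
                           k = min(cfg$knn_k, length(ytr))))
    }
    pred[!tr] <- as.character(p)
  }
  err <- 100 * mean(as.character(pred) != as.character(y), na.rm = TRUE)
  # confusion over the scheme's full alphabet so matrices pool across
  # participants; a class a night never shows (or the classifier never
  # predicts) becomes an all-zero column for the exclusion rule
  alpha <- if (cfg$scheme == "micro") STAGES_MICRO else STAGES_MACRO
  if (!all(levels(y) %in% alpha)) alpha <- levels(y)
  conf <- table(true = factor(as.character(y), alpha),
                predicted = factor(as.character(pred), alpha))
  structure(err, flagged = flagged, confusion = conf)
}

#' Non-parametric Bayes-error bounds from a kNN error
#'
#' For an L-class problem with kNN error `e_knn` (fraction), the Bayes error
#' is bracketed by
#' `((L-1)/L) * (1 - sqrt(1 - (L/(L-1)) * e_knn)) <= E_bayes <= e_knn`.
#'
#' @param e_knn kNN classifier error as a fraction in `[0, (L-1)/L]`
#'   (vectorized).
#' @param L number of classes (>= 2).
#' @return tibble with columns `lower`, `upper` (fractions).
#' @export
bayes_bounds <- function(e_knn, L) {
  if (L < 2) stop("L must be >= 2")
  if (any(e_knn < 0)) stop("e_knn must be non-negative")
  chance <- (L - 1) / L
  if (any(e_knn > chance + 1e-12))
    stop("e_knn exceeds (L-1)/L = ", round(chance, 4),
         "; bound formula undefined (negative radicand)")
  rad <- pmax(1 - e_knn / chance, 0)
  tibble::tibble(lower = chance * (1 - sqrt(rad)), upper = e_knn)
}

#' Sensitivity slope of classification error to HBI MAE
#'
#' Ordinary-least-squares slope of error (%) on MAE (seconds): percentage
#' points of additional staging error per second of heartbeat-interval MAE.
#'
#' @param mae_s HBI MAE values in seconds (the independent variable).
#' @param error_pct classification errors (%) at those severities.
#' @return slope in %/s, with attribute `intercept`.
#' @export
sensitivity_slope <- function(mae_s, error_pct) {
  ok <- is.finite(mae_s) & is.finite(error_pct)
  if (sum(ok) < 3) stop("need at least 3 points for a slope")
  if (stats::sd(mae_s[ok]) < 1e-12) stop("degenerate MAE spread")
  fit <- stats::lm(error_pct[ok] ~ mae_s[ok])
  structure(unname(stats::coef(fit)[2]),
            intercept = unname(stats::coef(fit)[1]))
}

#' Ensemble summary of per-participant error curves
#'
#' @param curves tibble with columns `participant_id`, `level`, `mae_ms`,
#'   `error_pct` (one point per participant per level, all participants on
#'   the same level grid).
#' @return tibble per level: pooled `mae_ms` (mean across participants),
#'   `mean`, `sd`, and `lo`/`hi` = mean -/+ 1.96 SD of the error (%).
#' @export
ensemble_curve <- function(curves) {
  lv <- sort(unique(curves$level))
  out <- lapply(lv, function(l) {
    d <- curves[curves$level == l, ]
    e <- d$error_pct
    m <- mean(e, na.rm = TRUE)
    s <- stats::sd(e)
    if (!is.finite(s)) s <- 0
    tibble::tibble(level = l, mae_ms = mean(d$mae_ms, na.rm = TRUE),
                   mean = m, sd = s,
                   lo = m - 1.96 * s, hi = m + 1.96 * s)
  })
  do.call(rbind, out)
}

#' Pool per-participant confusion matrices
#'
#' Participants whose matrix has an all-zero predicted-class column (a class
#' the classifier never predicted) are excluded before summation, and the
#' exclusion count is reported.
#'
#' @param confusions list of confusion matrices (identical dimnames,
#'   true x predicted).
#' @return pooled matrix with attributes `n_excluded` and `n_used`.
#' @export
aggregate_confusion <- function(confusions) {
  if (length(confusions) == 0) stop("no confusion matrices supplied")
  dn <- dimnames(confusions[[1]])
  ok <- vapply(confusions, function(m) {
    if (!identical(dimnames(m), dn)) stop("inconsistent class order")
    all(colSums(m) > 0)
  }, logical(1))
  if (!any(ok)) stop("every participant has an empty detection column")
  pooled <- Reduce(`+`, confusions[ok])
  structure(pooled, n_excluded = sum(!ok), n_used = sum(ok))
}

#' Evaluate a cohort across jitter levels
#'
#' For every participant and requested ladder level: recompute (or look up)
#' the feature matrix, clean the night's labels under the scheme, apply the
#' common-valid epoch mask (epochs valid at every evaluated level, so sample
#' size is constant across levels), and run cross-validated SVM and kNN.
#' Bayes lower bounds derive from the kNN error.
#'
#' @param stacks named list (by participant) of feature tibbles as returned
#'   by [feature_stack()], covering `levels`.
#' @param hyps named list of raw [hypnogram()]s (same names).
#' @param ladder the [build_ladder()] result (for per-level MAEs).
#' @param levels integer vector of levels evaluated (0 = baseline).
#' @param scheme `"micro"` or `"macro"`.
#' @param feature_subset `"all"` or a single feature name.
#' @param k_folds,knn_k,seed passed to [eval_config()].
#' @param min_epochs short-run threshold for label cleaning.
#' @return tibble: `participant_id, level, mae_ms, scheme, feature_subset,
#'   error_pct, eknn_pct, bayes_lower_pct, flagged`, with per-participant
#'   level-0 confusion matrices in `attr(, "confusions")`.
#' @export
evaluate_cohort <- function(stacks, hyps, ladder, levels, scheme = "micro",
                            feature_subset = "all", k_folds = 10L,
                            knn_k = 10L, seed = 1L, min_epochs = 4L) {
  ids <- names(stacks)
  cfg_svm <- eval_config("svm", k_folds, knn_k, feature_subset, scheme,
                         seed = seed)
  cfg_knn <- eval_config("knn", k_folds, knn_k, feature_subset, scheme,
                         seed = seed)
  confusions <- list()
  rows <- list()
  for (pi in seq_along(ids)) {
    id <- ids[pi]
    st <- stacks[[id]]
    labs <- clean_hypnogram(hyps[[id]], scheme, min_epochs)
    L <- length(unique(labs$labels))
    # epochs valid at every evaluated level -> constant sample size
    vt <- tapply(st$valid, st$epoch_index, all)
    common <- as.logical(vt[as.character(sort(unique(st$epoch_index)))])
    for (lev in levels) {
      fl <- st[st$level == lev, ]
      fl <- fl[order(fl$epoch_index), ]
      es <- cv_error(fl, labs, cfg_svm, keep_rows = common)
      ek <- cv_error(fl, labs, cfg_knn, keep_rows = common)
      bl <- bayes_bounds(min(as.numeric(ek) / 100, (L - 1) / L), L)$lower
      if (lev == 0 && identical(feature_subset, "all"))
        confusions[[id]] <- attr(es, "confusion")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = id, level = lev,
        mae_ms = if (lev == 0) 0 else ladder$mae_ms[lev, pi],
        scheme = scheme, feature_subset = feature_subset,
        error_pct = as.numeric(es), eknn_pct = as.numeric(ek),
        bayes_lower_pct = 100 * bl,
        flagged = isTRUE(attr(es, "flagged")))
    }
  }
  structure(do.call(rbind, rows), confusions = confusions)
}
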