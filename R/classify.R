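#' Per-column z-score normalization learned from training rows
#'
#' Centers and scales every column using training statistics only; test rows
#' are transformed with the same model.  Zero-variance columns are centered
#' but left unscaled, with a warning.
#'
#' @param x numeric training matrix (rows = trials).
#' @return an object of class `normalizer` with `center` and `scale`.
#' @export
fit_normalizer <- function(x) {
  if (nrow(x) < 2L) stop("fit_normalizer() needs at least 2 training rows")
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  zero <- scale == 0 | !is.finite(scale)
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s): centered only")
    scale[zero] <- 1
  }
  structure(list(center = center, scale = scale), class = "normalizer")
}

#' @rdname fit_normalizer
#' @param model a `normalizer`.
#' @param rows matrix to transform (same columns as the training matrix).
#' @export
apply_normalizer <- function(model, rows) {
  stopifnot(inherits(model, "normalizer"))
  if (ncol(rows) != length(model$center))
    stop("column count does not match the normalizer")
  sweep(sweep(rows, 2L, model$center, "-"), 2L, model$scale, "/")
}

#' RBF-kernel support vector machine
#'
#' Thin wrapper over `e1071::svm` (libsvm) with the radial basis kernel.
#' `gamma` defaults to `1 / (n_features * var(x))` (the "scale" heuristic);
#' input is expected to be normalized already, so internal scaling is off.
#'
#' @param x numeric matrix of normalized training rows.
#' @param labels 0/1 vector.
#' @param C soft-margin cost (default 1).
#' @param gamma RBF kernel width; `NULL` for the scale heuristic.
#' @return a fitted `e1071::svm` object; predict with [predict_svm_rbf()].
#' @export
train_svm_rbf <- function(x, labels, C = 1, gamma = NULL) {
  if (length(unique(labels)) < 2L)
    stop("degenerate classes: training set has a single class")
  if (is.null(gamma)) {
    v <- stats::var(as.vector(x))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  e1071::svm(x, factor(labels, levels = c(0L, 1L)), kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE)
}

#' @rdname train_svm_rbf
#' @param model a fitted SVM.
#' @param rows matrix of rows to classify.
#' @return integer 0/1 predictions.
#' @export
predict_svm_rbf <- function(model, rows) {
  as.integer(as.character(predict(model, rows)))
}

# Deterministic grouped k-fold assignment: groups (subjects) sorted and
# dealt round-robin, so repeated fits are reproducible without RNG.
grouped_folds <- function(groups, k) {
  u <- sort(unique(as.character(groups)))
  k <- max(1L, min(k, length(u)))
  fold_of <- setNames(rep_len(seq_len(k), length(u)), u)
  unname(fold_of[as.character(groups)])
}

# Grouped-CV accuracy of an RBF SVM on the given columns; the SBS inner
# evaluator.  Single-class inner training folds fall back to majority vote.
svm_cv_accuracy <- function(values, labels, groups, k = 5, C = 1,
                            gamma = NULL) {
  fold <- grouped_folds(groups, k)
  correct <- 0L; total <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    ytr <- labels[tr]
    if (length(unique(ytr)) < 2L) {
      maj <- as.integer(names(which.max(table(ytr))))
      pred <- rep(maj, sum(te))
    } else {
      m <- train_svm_rbf(values[tr, , drop = FALSE], ytr, C = C, gamma = gamma)
      pred <- predict_svm_rbf(m, values[te, , drop = FALSE])
    }
    correct <- correct + sum(pred == labels[te])
    total <- total + sum(te)
  }
  correct / total
}

#' Fit the ST-SBSSVM model
#'
#' The full training procedure on labelled feature rows: (1) per-column
#' z-score normalization; (2) the significance-test filter, retaining
#' columns whose positive and negative halves differ at level `alpha`
#' (t-test or KS test by majority normality vote, see
#' [significance_filter()]); (3) SVM-wrapped sequential backward selection
#' over the retained columns, scored by grouped cross-validation on the
#' training subjects; (4) a final RBF SVM on the best subset.
#'
#' @param x numeric matrix (trials x features) or a [feature_matrix].
#' @param labels 0/1 vector (taken from `x` when it is a `feature_matrix`).
#' @param subjects per-row subject identifiers used for grouped inner CV;
#'   `NULL` treats every row as its own group.
#' @param alpha significance level of the filter stage (default 0.05).
#' @param test `"auto"`, `"t_test"` or `"ks_test"`.
#' @param skip_st skip the filter stage (the plain SBS-SVM variant, also
#'   used when the filter has already been applied globally).
#' @param C,gamma SVM hyperparameters, see [train_svm_rbf()].
#' @param inner_folds grouped CV folds for the SBS evaluator (default 5).
#' @param var_equal pooled-variance t-test in the filter (default `TRUE`).
#' @return an object of class `st_sbssvm` with `print`, `summary`,
#'   `predict` and `plot` methods.
#' @examples
#' fm <- generate_feature_table(n_subjects = 4, n_trials = 8, n_features = 12,
#'                              n_informative = 3, delta = 2.5, seed = 1)
#' fit <- st_sbssvm(fm)
#' fit$features
#' predict(fit, fm$values[1:3, , drop = FALSE])
#' @export
st_sbssvm <- function(x, labels = NULL, subjects = NULL, alpha = 0.05,
                      test = "auto", skip_st = FALSE, C = 1, gamma = NULL,
                      inner_folds = 5, var_equal = TRUE) {
  cl <- match.call()
  if (inherits(x, "feature_matrix")) {
    labels <- x$labels; subjects <- subjects %||% x$subject_id
    x <- x$values
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  labels <- as.integer(labels)
  if (is.null(subjects)) subjects <- seq_len(nrow(x))
  norm <- suppressWarnings(fit_normalizer(x))
  xn <- apply_normalizer(norm, x)
  selection <- NULL
  if (!skip_st) {
    selection <- significance_filter(xn, labels, alpha = alpha, test = test,
                                     var_equal = var_equal)
    xs <- selection$filtered
  } else {
    xs <- xn
  }
  evaluator <- function(v, y)
    svm_cv_accuracy(v, y, groups = subjects, k = inner_folds,
                    C = C, gamma = gamma)
  trace <- if (ncol(xs) >= 2L) sbs(xs, labels, evaluator) else NULL
  features <- if (is.null(trace)) colnames(xs) else trace$best_subset
  svm_fit <- train_svm_rbf(xs[, features, drop = FALSE], labels,
                           C = C, gamma = gamma)
  structure(
    list(call = cl, normalizer = norm, selection = selection, trace = trace,
         features = features, svm = svm_fit,
         all_columns = colnames(x), labels = labels,
         settings = list(alpha = alpha, skip_st = skip_st, C = C,
                         gamma = gamma, inner_folds = inner_folds)),
    class = "st_sbssvm")
}

#' @export
print.st_sbssvm <- function(x, ...) {
  cat("ST-SBSSVM model\n")
  cat("Call: "); print(x$call)
  if (!is.null(x$selection))
    cat(sprintf("Filter stage (%s): %d of %d columns retained\n",
                x$selection$test_used, x$selection$retained_count,
                length(x$all_columns)))
  else
    cat("Filter stage: skipped\n")
  if (!is.null(x$trace))
    cat(sprintf("SBS stage: best subset of %d features (CV accuracy %.3f)\n",
                length(x$features), x$trace$best_accuracy))
  cat("Selected features:", paste(utils::head(x$features, 8L), collapse = ", "),
      if (length(x$features) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.st_sbssvm <- function(object, ...) {
  print(object)
  if (!is.null(object$selection)) {
    tab <- object$selection$table
    cat("\nTop filter-stage columns by p-value:\n")
    print(utils::head(tab[order(tab$p_value), ], 10L), row.names = FALSE)
  }
  if (!is.null(object$trace)) {
    cat("\nSBS accuracy by subset size:\n")
    print(data.frame(size = object$trace$subset_sizes,
                     accuracy = round(object$trace$subset_accuracy, 4)),
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
predict.st_sbssvm <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$all_columns))
    stop("newdata must have the training columns (",
         length(object$all_columns), ")")
  colnames(newdata) <- object$all_columns
  xn <- apply_normalizer(object$normalizer, newdata)
  predict_svm_rbf(object$svm, xn[, object$features, drop = FALSE])
}

#' @export
plot.st_sbssvm <- function(x, ...) {
  if (is.null(x$trace)) stop("no SBS trace to plot")
  plot(x$trace, ...)
}

#' Baseline and reference classification pipelines
#'
#' Builds a fit/predict pipeline over the high-dimensional feature rows:
#' `"svm"` (RBF SVM on all columns), `"pca_svm"` (PCA retaining 95%
#' variance, then SVM), `"knn"` (k-nearest neighbours, k = 5), `"pca_knn"`,
#' `"rf"` (random forest, 100 trees), `"sbs_svm"` (SBS wrapper without the
#' filter stage), and `"st_sbssvm"` (the full method).  Every pipeline fits
#' its normalization -- and any selection -- on training rows only.
#'
#' @param method one of the names above.
#' @param options list of settings: `knn_k`, `rf_trees`, `pca_var`, `C`,
#'   `gamma`, `alpha`, `test`, `inner_folds`, `skip_st`.
#' @return a list with elements `name`, `options`, `fit(x, y, subjects)` and
#'   `predict(model, x)`.
#' @export
make_pipeline <- function(method = c("st_sbssvm", "svm", "pca_svm", "knn",
                                     "pca_knn", "rf", "sbs_svm"),
                          options = list()) {
  method <- match.arg(method)
  opt <- utils::modifyList(
    list(knn_k = 5, rf_trees = 100, pca_var = 0.95, C = 1, gamma = NULL,
         alpha = 0.05, test = "auto", inner_folds = 5, skip_st = FALSE),
    options)
  norm_fit <- function(x) {
    nm <- suppressWarnings(fit_normalizer(x))
    list(norm = nm, xn = apply_normalizer(nm, x))
  }
  pca_fit <- function(xn) {
    pc <- stats::prcomp(xn, center = FALSE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- which(cum >= opt$pca_var)[1L]
    list(rotation = pc$rotation[, seq_len(k), drop = FALSE], k = k)
  }
  fns <- switch(method,
    svm = list(
      fit = function(x, y, subjects) {
        nf <- norm_fit(x)
        list(norm = nf$norm, svm = train_svm_rbf(nf$xn, y, opt$C, opt$gamma))
      },
      predict = function(m, x)
        predict_svm_rbf(m$svm, apply_normalizer(m$norm, x))),
    pca_svm = list(
      fit = function(x, y, subjects) {
        nf <- norm_fit(x); pc <- pca_fit(nf$xn)
        list(norm = nf$norm, pca = pc,
             svm = train_svm_rbf(nf$xn %*% pc$rotation, y, opt$C, opt$gamma))
      },
      predict = function(m, x)
        predict_svm_rbf(m$svm, apply_normalizer(m$norm, x) %*% m$pca$rotation)),
    knn = list(
      fit = function(x, y, subjects) {
        nf <- norm_fit(x)
        list(norm = nf$norm, train = nf$xn, y = y)
      },
      predict = function(m, x)
        as.integer(as.character(class::knn(m$train, apply_normalizer(m$norm, x),
                                           factor(m$y, levels = c(0L, 1L)),
                                           k = opt$knn_k)))),
    pca_knn = list(
      fit = function(x, y, subjects) {
        nf <- norm_fit(x); pc <- pca_fit(nf$xn)
        list(norm = nf$norm, pca = pc, train = nf$xn %*% pc$rotation, y = y)
      },
      predict = function(m, x)
        as.integer(as.character(class::knn(
          m$train, apply_normalizer(m$norm, x) %*% m$pca$rotation,
          factor(m$y, levels = c(0L, 1L)), k = opt$knn_k)))),
    rf = list(
      fit = function(x, y, subjects) {
        nf <- norm_fit(x)
        list(norm = nf$norm,
             rf = randomForest::randomForest(nf$xn,
                                             factor(y, levels = c(0L, 1L)),
                                             ntree = opt$rf_trees))
      },
      predict = function(m, x)
        as.integer(as.character(predict(m$rf, apply_normalizer(m$norm, x))))),
    sbs_svm = list(
      fit = function(x, y, subjects)
        st_sbssvm(x, y, subjects, skip_st = TRUE, C = opt$C,
                  gamma = opt$gamma, inner_folds = opt$inner_folds),
      predict = function(m, x) predict(m, x)),
    st_sbssvm = list(
      fit = function(x, y, subjects)
        st_sbssvm(x, y, subjects, alpha = opt$alpha, test = opt$test,
                  skip_st = opt$skip_st, C = opt$C, gamma = opt$gamma,
                  inner_folds = opt$inner_folds),
      predict = function(m, x) predict(m, x)))
  list(name = method, options = opt, fit = fns$fit, predict = fns$predict)
}

#' Leave-one-subject-out evaluation
#'
#' One fold per distinct subject: the held-out subject's trials form the
#' test set and every stage of the pipeline -- normalization, filtering,
#' SBS, classifier fitting -- is fitted on the remaining subjects only.
#' Fold accuracy is the fraction of the held-out subject's trials labelled
#' correctly; the reported accuracy is the unweighted mean over folds.
#' With `paper_faithful = TRUE` the significance filter is instead applied
#' once to the full matrix before the folds (the global-filter variant;
#' this lets the test subject influence the screening and is kept only for
#' faithful reproduction).
#'
#' @param fm a [feature_matrix].
#' @param pipeline a pipeline from [make_pipeline()] (or its method name).
#' @param paper_faithful apply the filter stage globally before LOSO.
#' @param keep_models keep each fold's fitted model in the result.
#' @param keep_predictions keep each fold's predicted labels.
#' @param verbose print per-fold progress to stderr.
#' @return an object of class `evaluation_result`: `folds` data frame
#'   (subject, n_test, accuracy, seconds), `mean_accuracy`, per-fold
#'   `selected` feature lists where the pipeline selects, `elapsed_s`.
#' @export
loso_evaluate <- function(fm, pipeline = "st_sbssvm", paper_faithful = FALSE,
                          keep_models = FALSE, keep_predictions = FALSE,
                          verbose = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.character(pipeline)) pipeline <- make_pipeline(pipeline)
  values <- fm$values
  if (paper_faithful) {
    sel <- significance_filter(values, fm$labels)
    values <- sel$filtered
    if (pipeline$name %in% c("st_sbssvm"))
      pipeline <- make_pipeline(pipeline$name,
                                utils::modifyList(pipeline$options,
                                                  list(skip_st = TRUE)))
  }
  subj <- as.character(fm$subject_id)
  us <- unique(subj)
  if (length(us) < 2L) stop("LOSO needs at least 2 distinct subjects")
  t0 <- proc.time()[["elapsed"]]
  rows <- list(); selected <- list(); models <- list(); predictions <- list()
  for (s in us) {
    te <- subj == s; tr <- !te
    if (!any(te)) { warning("subject ", s, " has no trials; fold skipped"); next }
    if (length(unique(fm$labels[tr])) < 2L) {
      warning("training set for subject ", s, " is single-class; fold skipped")
      next
    }
    f0 <- proc.time()[["elapsed"]]
    model <- pipeline$fit(values[tr, , drop = FALSE], fm$labels[tr], subj[tr])
    pred <- pipeline$predict(model, values[te, , drop = FALSE])
    secs <- proc.time()[["elapsed"]] - f0
    acc <- mean(pred == fm$labels[te])
    rows[[s]] <- data.frame(subject = s, n_test = sum(te), accuracy = acc,
                            seconds = secs, stringsAsFactors = FALSE)
    if (!is.null(model$features)) selected[[s]] <- model$features
    if (keep_models) models[[s]] <- model
    if (keep_predictions) predictions[[s]] <- pred
    if (verbose)
      message(sprintf("fold %s: accuracy %.3f (%.1fs)", s, acc, secs))
  }
  if (!length(rows)) stop("no evaluable folds")
  folds <- do.call(rbind, rows)
  rownames(folds) <- NULL
  structure(
    list(method = pipeline$name, folds = folds,
         mean_accuracy = mean(folds$accuracy),
         selected = if (length(selected)) selected else NULL,
         models = if (keep_models) models else NULL,
         predictions = if (keep_predictions) predictions else NULL,
         paper_faithful = paper_faithful,
         elapsed_s = proc.time()[["elapsed"]] - t0),
    class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(paste0("evaluation_result (%s): mean LOSO accuracy %.3f over ",
                     "%d subject folds (%.1f s)\n"),
              x$method, x$mean_accuracy, nrow(x$folds), x$elapsed_s))
  invisible(x)
}

#' Compare classification methods against the ST-SBSSVM reference
#'
#' Either evaluates each method under the same leave-one-subject-out folds
#' as the reference and tabulates the reference-minus-method accuracy
#' differences in percentage points, or aggregates externally supplied
#' per-method accuracies/differences into the same report.
#'
#' @param fm a [feature_matrix] (ignored when `accuracies` or `differences`
#'   are supplied).
#' @param methods character vector of baseline method names.
#' @param reference the reference method (default `"st_sbssvm"`).
#' @param accuracies optional named vector of mean accuracies (fractions in
#'   `[0, 1]` or percentages) including the reference.
#' @param differences optional named vector of reference-minus-method
#'   differences, already in percentage points.
#' @param options pipeline options passed to [make_pipeline()].
#' @param paper_faithful see [loso_evaluate()].
#' @param verbose per-fold progress.
#' @return an object of class `comparison_report`: `table` (method,
#'   accuracy, difference_pp), `average_difference_pp`, `reference`,
#'   `reference_accuracy`.
#' @export
compare_methods <- function(fm = NULL,
                            methods = c("svm", "pca_svm", "sbs_svm", "knn",
                                        "pca_knn", "rf"),
                            reference = "st_sbssvm", accuracies = NULL,
                            differences = NULL, options = list(),
                            paper_faithful = FALSE, verbose = FALSE) {
  if (!is.null(differences)) {
    tab <- data.frame(method = names(differences), accuracy = NA_real_,
                      difference_pp = as.numeric(differences),
                      stringsAsFactors = FALSE)
    ref_acc <- NA_real_
    evals <- NULL
  } else if (!is.null(accuracies)) {
    if (!reference %in% names(accuracies))
      stop("`accuracies` must include the reference method '", reference, "'")
    pct <- if (max(accuracies) <= 1) 100 else 1   # accept fractions or %
    ref_acc <- accuracies[[reference]] * pct
    rest <- accuracies[setdiff(names(accuracies), reference)]
    tab <- data.frame(method = names(rest), accuracy = as.numeric(rest) * pct,
                      difference_pp = ref_acc - as.numeric(rest) * pct,
                      stringsAsFactors = FALSE)
    evals <- NULL
  } else {
    stopifnot(inherits(fm, "feature_matrix"))
    run <- function(m) loso_evaluate(fm, make_pipeline(m, options),
                                     paper_faithful = paper_faithful,
                                     verbose = verbose)
    ref_eval <- run(reference)
    evals <- c(setNames(list(ref_eval), reference),
               setNames(lapply(methods, run), methods))
    ref_acc <- ref_eval$mean_accuracy * 100
    accs <- vapply(evals[methods], function(e) e$mean_accuracy * 100,
                   numeric(1))
    tab <- data.frame(method = methods, accuracy = accs,
                      difference_pp = ref_acc - accs,
                      stringsAsFactors = FALSE)
  }
  structure(
    list(table = tab, reference = reference, reference_accuracy = ref_acc,
         average_difference_pp = mean(tab$difference_pp),
         evaluations = evals),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report (reference: %s", x$reference))
  if (is.finite(x$reference_accuracy))
    cat(sprintf(", accuracy %.1f%%", x$reference_accuracy))
  cat(")\n")
  tab <- x$table
  tab$difference_pp <- sprintf("%+.2f", tab$difference_pp)
  print(tab, row.names = FALSE)
  cat(sprintf("Average difference from %s: %+.1f percentage points\n",
              x$reference, x$average_difference_pp))
  invisible(x)
}

#' @rdname compare_methods
#' @param report a `comparison_report`.
#' @param path JSON file path; a CSV of the per-method table uses the same
#'   stem.
#' @export
save_comparison_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  jsonlite::write_json(
    list(reference = report$reference,
         reference_accuracy = report$reference_accuracy,
         average_difference_pp = report$average_difference_pp,
         table = report$table),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(report$table, paste0(sub("\\.json$", "", path), ".csv"),
                   row.names = FALSE)
  invisible(path)
}
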