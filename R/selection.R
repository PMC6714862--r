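#' Split feature rows by class label
#'
#' Divides the trial rows into the positive-label and negative-label parts,
#' so that every column yields a positive sample and a negative sample.
#'
#' @param values numeric matrix (trials x features).
#' @param labels 0/1 vector, one per row.
#' @return list with matrices `pos` and `neg`.
#' @export
split_by_label <- function(values, labels) {
  if (nrow(values) != length(labels)) stop("labels must match the row count")
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("degenerate classes: both labels must be present")
  list(pos = values[labels == 1L, , drop = FALSE],
       neg = values[labels == 0L, , drop = FALSE])
}

#' Choose the two-sample test by a majority normality vote
#'
#' Each column is split into its positive and negative halves and each half
#' is tested for normality (Shapiro-Wilk, deterministically thinned to at
#' most 500 values).  If more than half of all column-halves are compatible
#' with normality (p > `alpha_norm`), the Student's t-test is used for every
#' column; otherwise (including an exact tie) the two-sample
#' Kolmogorov-Smirnov test is used.  One choice applies to all columns.
#'
#' @param values numeric matrix (trials x features).
#' @param labels 0/1 vector, one per row.
#' @param alpha_norm significance level of the normality test (default 0.05).
#' @param max_n per-half subsample ceiling for Shapiro-Wilk (default 500).
#' @return `"t_test"` or `"ks_test"`.
#' @export
normality_decision <- function(values, labels, alpha_norm = 0.05, max_n = 500) {
  halves <- split_by_label(values, labels)
  if (nrow(halves$pos) < 3L || nrow(halves$neg) < 3L)
    stop("need at least 3 rows per class for the normality test")
  thin <- function(v) {
    if (length(v) > max_n) v[round(seq(1L, length(v), length.out = max_n))]
    else v
  }
  pass <- vapply(seq_len(ncol(values)), function(j) {
    vapply(list(halves$pos[, j], halves$neg[, j]), function(v) {
      v <- thin(v)
      if (pop_var(v) == 0) return(FALSE)   # constant half: not normal
      stats::shapiro.test(v)$p.value > alpha_norm
    }, logical(1))
  }, logical(2))
  if (mean(pass) > 0.5) "t_test" else "ks_test"
}

#' Significance-test (ST) feature screening
#'
#' The filter stage: every column's positive and negative halves are compared
#' with a two-sample test -- Student's t (pooled variance by default) when
#' the majority of column-halves look normal, the Kolmogorov-Smirnov test
#' otherwise (see [normality_decision()]).  Columns with `p < alpha`
#' (significance flag `h = 1`) are retained in their original order.
#'
#' @param values numeric matrix (trials x features) or a [feature_matrix].
#' @param labels 0/1 vector (ignored when `values` is a `feature_matrix`).
#' @param alpha retention significance level (default 0.05).
#' @param test `"auto"` (normality vote), `"t_test"` or `"ks_test"`.
#' @param var_equal pooled-variance t-test (default `TRUE`); `FALSE` gives
#'   the Welch variant.
#' @param p_adjust multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"none"`: the stage is a screening step).
#' @return an object of class `selection_result`: per-column `table`
#'   (name, statistic, p_value, h), `test_used`, `retained_mask`,
#'   `retained_count`, and `filtered` (the retained columns).
#' @export
significance_filter <- function(values, labels = NULL, alpha = 0.05,
                                test = c("auto", "t_test", "ks_test"),
                                var_equal = TRUE, p_adjust = "none") {
  test <- match.arg(test)
  if (inherits(values, "feature_matrix")) {
    labels <- values$labels
    values <- values$values
  }
  halves <- split_by_label(values, labels)
  if (nrow(halves$pos) < 3L || nrow(halves$neg) < 3L)
    stop("need at least 3 rows per class")
  if (test == "auto") test <- normality_decision(values, labels)
  res <- vapply(seq_len(ncol(values)), function(j) {
    p <- halves$pos[, j]; q <- halves$neg[, j]
    if (test == "t_test") {
      if (pop_var(c(p, q)) == 0) return(c(0, 1))   # constant column
      ht <- stats::t.test(p, q, var.equal = var_equal)
      c(unname(ht$statistic), ht$p.value)
    } else {
      ht <- suppressWarnings(stats::ks.test(p, q))  # ties warn, exact p off
      c(unname(ht$statistic), ht$p.value)
    }
  }, numeric(2))
  pvals <- stats::p.adjust(res[2L, ], method = p_adjust)
  h <- as.integer(pvals < alpha)
  if (!any(h == 1L))
    stop("empty selection: no column significant at alpha = ", alpha)
  cn <- colnames(values) %||% sprintf("V%d", seq_len(ncol(values)))
  structure(
    list(table = data.frame(name = cn, statistic = res[1L, ],
                            p_value = pvals, h = h,
                            stringsAsFactors = FALSE),
         test_used = test, alpha = alpha,
         retained_mask = h == 1L, retained_count = sum(h),
         filtered = values[, h == 1L, drop = FALSE]),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %s at alpha = %g, retained %d of %d columns\n",
              x$test_used, x$alpha, x$retained_count, nrow(x$table)))
  invisible(x)
}

#' Serialize a selection result
#'
#' Per-column records plus the retained mask go to JSON; the filtered matrix
#' goes to a CSV alongside.
#'
#' @param sel a `selection_result`.
#' @param path JSON file path; the CSV uses the same stem.
#' @export
save_selection_result <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  jsonlite::write_json(
    list(test_used = sel$test_used, alpha = sel$alpha,
         retained_count = sel$retained_count, columns = sel$table),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(sel$filtered,
                   paste0(sub("\\.json$", "", path), "_filtered.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Sequential backward selection (SBS)
#'
#' Greedy wrapper stage: starting from all columns, repeatedly evaluates the
#' removal of each remaining column and drops the one whose removal gives the
#' highest evaluator accuracy, down to a single remaining feature.  Every
#' visited subset's accuracy is recorded; the best subset is the accuracy
#' argmax.  Ties are broken deterministically: among equally good removals
#' the column with the largest current index is dropped, and among equally
#' accurate subset sizes the larger subset wins (retaining more information).
#'
#' @param values numeric matrix (trials x features) with column names.
#' @param labels 0/1 vector, one per row (passed to the evaluator).
#' @param evaluator `function(values, labels)` returning an accuracy in
#'   `[0, 1]` for the given column subset.
#' @return an object of class `sbs_trace`: `elimination_order` (column names
#'   in removal order), `subset_sizes` (p, p-1, ..., 1), `subset_accuracy`,
#'   `best_subset` (column names), `best_accuracy`, `n_evaluations`.
#' @export
sbs <- function(values, labels, evaluator) {
  p <- ncol(values)
  if (p < 2L) stop("sbs() needs at least 2 columns")
  cn <- colnames(values) %||% sprintf("V%d", seq_len(p))
  colnames(values) <- cn
  current <- seq_len(p)
  n_eval <- 0L
  eval_subset <- function(cols) {
    acc <- evaluator(values[, cols, drop = FALSE], labels)
    if (!is.finite(acc) || acc < 0 || acc > 1)
      stop("evaluator returned an invalid accuracy for subset {",
           paste(cn[cols], collapse = ", "), "}")
    n_eval <<- n_eval + 1L
    acc
  }
  sizes <- integer(p); accs <- numeric(p)
  subsets <- vector("list", p)
  elim <- character(p - 1L)
  sizes[1L] <- p
  accs[1L] <- eval_subset(current)
  subsets[[1L]] <- current
  step <- 1L
  while (length(current) > 1L) {
    cand_acc <- vapply(seq_along(current),
                       function(k) eval_subset(current[-k]), numeric(1))
    # ties: drop the largest current index => last position among the best
    best <- max(which(cand_acc == max(cand_acc)))
    elim[step] <- cn[current[best]]
    current <- current[-best]
    step <- step + 1L
    sizes[step] <- length(current)
    accs[step] <- cand_acc[best]
    subsets[[step]] <- current
  }
  # ties on accuracy: prefer the larger subset (earlier in the trace)
  best_i <- which.max(accs)
  structure(
    list(elimination_order = elim, subset_sizes = sizes,
         subset_accuracy = accs,
         best_subset = cn[subsets[[best_i]]],
         best_accuracy = accs[best_i],
         n_evaluations = n_eval),
    class = "sbs_trace")
}

#' @export
print.sbs_trace <- function(x, ...) {
  cat(sprintf(paste0("sbs_trace: %d -> 1 features in %d evaluations; ",
                     "best subset has %d features (accuracy %.3f)\n"),
              x$subset_sizes[1L], x$n_evaluations,
              length(x$best_subset), x$best_accuracy))
  invisible(x)
}

#' @export
plot.sbs_trace <- function(x, ...) {
  plot(x$subset_sizes, x$subset_accuracy, type = "b", pch = 19,
       xlab = "subset size", ylab = "evaluation accuracy",
       main = "Sequential backward selection", ...)
  graphics::abline(v = length(x$best_subset), lty = 2, col = "grey40")
  invisible(x)
}

#' @rdname save_selection_result
#' @param trace an `sbs_trace`.
#' @export
save_sbs_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sbs_trace"))
  jsonlite::write_json(unclass(trace), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
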