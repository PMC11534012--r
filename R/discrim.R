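# Nonparametric k-nearest-neighbour discriminant analysis of optical
# clusters on water-quality variables, with leave-one-out error rates and
# forward stepwise variable selection.

scale_features <- function(x, center = FALSE) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  list(x = sweep(x, 2, sds, `/`), sd = sds)
}

class_priors <- function(y, priors = c("uniform", "proportional")) {
  priors <- match.arg(priors)
  lv <- levels(y)
  if (priors == "uniform") {
    stats::setNames(rep(1 / length(lv), length(lv)), lv)
  } else {
    stats::setNames(as.numeric(table(y)) / length(y), lv)
  }
}

#' k-nearest-neighbour class posterior
#'
#' Posterior probabilities for a query point: among the `k` nearest
#' training points by Euclidean distance on unit-variance-standardized
#' features, class counts are weighted by the priors and normalized.
#' Distance ties at the k-th neighbour include every tied point.
#'
#' @param train_x numeric feature matrix (rows = training points).
#' @param train_y class labels (coerced to factor).
#' @param query numeric vector (one point) on the original feature scale.
#' @param k neighbourhood size (`1 <= k <= n_train`).
#' @param priors `"uniform"` or `"proportional"`.
#' @param standardize scale features to unit variance before distances.
#' @return Named posterior vector summing to 1.
#' @export
knn_posterior <- function(train_x, train_y, query, k = 4,
                          priors = "uniform", standardize = TRUE) {
  train_x <- as.matrix(train_x)
  n <- nrow(train_x)
  if (n == 0) stop("empty training set")
  if (k > n) stop("k exceeds the training size")
  y <- factor(train_y)
  if (standardize) {
    sc <- scale_features(train_x)
    train_x <- sc$x
    query <- as.numeric(query) / sc$sd
  }
  d <- sqrt(rowSums(sweep(train_x, 2, as.numeric(query))^2))
  pr <- class_priors(y, priors)
  posterior_from_dist(d, y, k, pr)
}

# Shared posterior rule: k nearest with ties included, prior-weighted
# class counts.
posterior_from_dist <- function(d, y, k, pr) {
  dk <- sort(d, partial = k)[k]
  nb <- which(d <= dk + 1e-12)
  counts <- table(y[nb])
  w <- pr[names(counts)] * as.numeric(counts)
  if (sum(w) == 0) w <- rep(1, length(w))
  stats::setNames(as.numeric(w / sum(w)), names(counts))
}

#' Leave-one-out error rates of the kNN discriminant rule
#'
#' Classifies every point from all others (self excluded) with the
#' `k`-nearest-neighbour rule, breaking posterior ties toward the
#' lower-indexed class (flagged). Per-class error is the misclassified
#' fraction within the class; the overall rate is the prior-weighted
#' combination of per-class rates.
#'
#' @param x feature matrix.
#' @param y class labels (>= 2 classes; every class needs more than `k`
#'   members).
#' @param variables columns of `x` to use (default all).
#' @param k neighbourhood size.
#' @param priors `"uniform"` or `"proportional"`.
#' @param standardize scale features to unit variance before distances.
#' @return Object of class `error_report`: `per_class`, `overall`,
#'   `variables`, `n`, `n_ties`, `predicted`.
#' @export
loo_error_rates <- function(x, y, variables = NULL, k = 4,
                            priors = "uniform", standardize = TRUE) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("at least two classes are required")
  if (any(table(y) <= k)) stop("every class needs more than k members")
  if (!is.null(variables)) x <- x[, variables, drop = FALSE]
  if (anyNA(x)) stop("missing feature values")
  if (standardize) x <- scale_features(x)$x
  n <- nrow(x)
  pr <- class_priors(y, priors)

  # full pairwise distances; n stays modest (thousands), so this is the
  # simple exact route
  dmat <- as.matrix(stats::dist(x))
  pred <- character(n); ties <- logical(n)
  lv <- levels(y)
  for (i in seq_len(n)) {
    d <- dmat[i, -i]
    post <- posterior_from_dist(d, y[-i], k, pr)
    full <- stats::setNames(numeric(nlevels(y)), lv)
    full[names(post)] <- post
    best <- which(full == max(full))
    if (length(best) > 1) ties[i] <- TRUE
    pred[i] <- lv[min(best)]
  }
  per_class <- vapply(lv, function(cl) {
    mean(pred[y == cl] != cl)
  }, numeric(1))
  overall <- sum(pr[lv] * per_class) / sum(pr[lv])
  structure(list(per_class = per_class, overall = overall,
                 variables = colnames(x), n = n, n_ties = sum(ties),
                 predicted = factor(pred, levels = lv)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<kNN LOO error: overall %.4f on n=%d [%s]>\n",
              x$overall, x$n, paste(x$variables, collapse = ", ")))
  print(round(x$per_class, 4))
  invisible(x)
}

#' Forward stepwise variable selection for the kNN discriminant rule
#'
#' At each step, adds the candidate variable whose inclusion minimizes
#' the overall leave-one-out error, and records the full error matrix
#' (every candidate at every step, per-class and total) for reporting.
#'
#' @param x feature matrix of candidate variables.
#' @param y class labels.
#' @param k neighbourhood size.
#' @param max_vars maximum number of variables to select.
#' @param priors,standardize passed to [loo_error_rates()].
#' @return List: `order` (variables in selection order), `path`
#'   (data.frame of the chosen model per step), `error_matrix`
#'   (every evaluated candidate: step, variable set, per-class errors,
#'   total).
#' @export
stepwise_select <- function(x, y, k = 4, max_vars = ncol(x),
                            priors = "uniform", standardize = TRUE) {
  x <- as.matrix(x)
  candidates <- colnames(x)
  if (length(candidates) < 1) stop("at least one candidate variable")
  chosen <- character(0)
  rows <- list(); path <- list()
  lv <- levels(factor(y))
  for (step in seq_len(min(max_vars, length(candidates)))) {
    remaining <- setdiff(candidates, chosen)
    errs <- stats::setNames(numeric(length(remaining)), remaining)
    for (v in remaining) {
      rep_ <- loo_error_rates(x, y, variables = c(chosen, v), k = k,
                              priors = priors, standardize = standardize)
      errs[v] <- rep_$overall
      rows[[length(rows) + 1L]] <- data.frame(
        step = step, base = paste(chosen, collapse = " + "),
        candidate = v,
        t(stats::setNames(rep_$per_class, paste0("cluster_", lv))),
        total = rep_$overall, stringsAsFactors = FALSE)
    }
    pick <- names(errs)[which.min(errs)]
    chosen <- c(chosen, pick)
    path[[step]] <- data.frame(step = step,
                               variables = paste(chosen, collapse = " + "),
                               total_error = unname(min(errs)),
                               stringsAsFactors = FALSE)
  }
  list(order = chosen, path = do.call(rbind, path),
       error_matrix = do.call(rbind, rows))
}
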