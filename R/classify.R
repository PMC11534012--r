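# Trophic-state classification and fuzzy optical water typing.

#' Trophic-state class from chlorophyll
#'
#' Classifies chlorophyll (ug/L) into the four productivity classes of the
#' estuarine trophic-state index: Low (0, 5], Medium (5, 20],
#' High (20, 60], Hypereutrophic (60, Inf). The half-open bounds mean a
#' value exactly on a bound belongs to the lower class (5 -> Low,
#' 20 -> Medium, 60 -> High).
#'
#' @param chl numeric vector, ug/L (> 0).
#' @param bounds increasing class bounds, default `c(5, 20, 60)`.
#' @return Factor with levels Low, Medium, High, Hypereutrophic.
#' @export
bricker_class <- function(chl, bounds = c(5, 20, 60)) {
  if (any(!is.finite(chl)) || any(chl <= 0)) {
    stop("chlorophyll must be finite and positive")
  }
  cut(chl, breaks = c(0, bounds, Inf),
      labels = c("Low", "Medium", "High", "Hypereutrophic"),
      right = TRUE)
}

#' Trophic-state class frequencies
#'
#' Counts and percentage shares per trophic class. Accepts either raw
#' chlorophyll values or precomputed per-class counts (named or in class
#' order Low, Medium, High, Hypereutrophic).
#'
#' @param chl chlorophyll values (ug/L), ignored when `counts` is given.
#' @param counts optional numeric vector of per-class counts.
#' @param bounds class bounds passed to [bricker_class()].
#' @return data.frame with `class`, `count`, `percent` (summing to 100),
#'   plus a `total` attribute.
#' @export
tsi_frequencies <- function(chl = NULL, counts = NULL,
                            bounds = c(5, 20, 60)) {
  labels <- c("Low", "Medium", "High", "Hypereutrophic")
  if (is.null(counts)) {
    if (is.null(chl) || length(chl) == 0) stop("no chlorophyll values")
    counts <- as.integer(table(bricker_class(chl, bounds)))
  } else {
    if (!is.null(names(counts))) counts <- counts[labels]
    counts <- as.numeric(counts)
    if (length(counts) != 4) stop("counts must have four classes")
  }
  total <- sum(counts)
  out <- data.frame(class = factor(labels, levels = labels),
                    count = counts,
                    percent = 100 * counts / total)
  attr(out, "total") <- total
  out
}

#' Fuzzy c-means clustering
#'
#' Alternating-update fuzzy c-means on row profiles: memberships
#' `u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))` and centres
#' `v_j = sum_i u_ij^m x_i / sum_i u_ij^m`, iterated until the largest
#' centre shift falls below `tol`. A profile coincident with a centre
#' receives crisp membership there. The objective
#' `J = sum_ij u_ij^m d_ij^2` is recorded each iteration and is
#' non-increasing. `k = 1` returns the coordinate-wise mean with unit
#' memberships.
#'
#' @param x numeric matrix, one row per profile.
#' @param k number of clusters (`1 <= k < n`).
#' @param m fuzzifier (> 1).
#' @param tol convergence tolerance on the max centre shift.
#' @param max_iter iteration cap.
#' @param seed optional RNG seed for the random initial centres.
#' @param init optional k x p matrix of initial centres.
#' @return Object of class `fuzzy_cmeans`: `k`, `centers`, `membership`,
#'   `m`, `objective`, `objective_path`, `iterations`, `converged`,
#'   `cluster` (hard assignment).
#' @export
fuzzy_cmeans <- function(x, k, m = 2, tol = 1e-6, max_iter = 500,
                         seed = NULL, init = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("profiles must be finite")
  n <- nrow(x); p <- ncol(x)
  if (k < 1) stop("k must be at least 1")
  if (k > 1 && k >= n) stop("k must be smaller than the number of profiles")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  if (k == 1) {
    v <- matrix(colMeans(x), 1, p, dimnames = list(NULL, colnames(x)))
    d2 <- rowSums((x - matrix(v, n, p, byrow = TRUE))^2)
    res <- list(k = 1L, centers = v, membership = matrix(1, n, 1), m = m,
                objective = sum(d2), objective_path = sum(d2),
                iterations = 0L, converged = TRUE, cluster = rep(1L, n))
    class(res) <- "fuzzy_cmeans"
    return(res)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- if (!is.null(init)) as.matrix(init) else {
    x[sample(n, k), , drop = FALSE]
  }

  sq_dist <- function(x, v) {
    # n x k matrix of squared Euclidean distances
    outer(rowSums(x^2), rep(1, nrow(v))) +
      outer(rep(1, nrow(x)), rowSums(v^2)) - 2 * x %*% t(v)
  }
  memberships <- function(d2) {
    d2 <- pmax(d2, 0)
    u <- matrix(0, n, k)
    zero <- d2 < 1e-300
    any_zero <- rowSums(zero) > 0
    w <- d2[!any_zero, , drop = FALSE]^(-1 / (m - 1))
    u[!any_zero, ] <- w / rowSums(w)
    if (any(any_zero)) {
      z <- zero[any_zero, , drop = FALSE]
      u[any_zero, ] <- z / rowSums(z)
    }
    u
  }

  path <- numeric(0)
  it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    d2 <- sq_dist(x, v)
    u <- memberships(d2)
    um <- u^m
    v_new <- (t(um) %*% x) / colSums(um)
    path <- c(path, sum(um * d2))
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  d2 <- sq_dist(x, v)
  u <- memberships(d2)
  colnames(v) <- colnames(x)
  res <- list(k = as.integer(k), centers = v, membership = u, m = m,
              objective = sum(u^m * d2), objective_path = path,
              iterations = it, converged = converged,
              cluster = max.col(u, ties.method = "first"))
  class(res) <- "fuzzy_cmeans"
  res
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat(sprintf("<fuzzy c-means: k=%d, m=%g, J=%.6g, %d iterations%s>\n",
              x$k, x$m, x$objective, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Cluster validity indices
#'
#' Eight standard indices for choosing the cluster count, each expected to
#' attain its extremum at the optimum: partition coefficient `pc` (max),
#' partition entropy `pe` (min), modified partition coefficient `mpc`
#' (max), Xie-Beni `xie_beni` (min), Fukuyama-Sugeno `fukuyama_sugeno`
#' (min), partition density `pd` (max), average partition density `apd`
#' (max), and a compactness/separation index `si` (min; mean fuzzy
#' within-cluster scatter over the squared distance to the nearest other
#' centre). The density indices use diagonal fuzzy covariances with a
#' small ridge for numerical stability.
#'
#' @param result a [fuzzy_cmeans()] fit with `k >= 2`.
#' @param x the profile matrix the fit was computed on.
#' @return Named numeric vector of the eight indices.
#' @export
validity_indices <- function(result, x) {
  x <- as.matrix(x)
  u <- result$membership; v <- result$centers
  k <- result$k; m <- result$m; n <- nrow(x)
  if (k < 2) stop("validity indices require k >= 2 (inter-centre distances)")
  um <- u^m
  d2 <- outer(rowSums(x^2), rep(1, k)) +
    outer(rep(1, n), rowSums(v^2)) - 2 * x %*% t(v)
  d2 <- pmax(d2, 0)

  pc <- sum(u^2) / n
  pe <- -sum(ifelse(u > 0, u * log(u), 0)) / n
  mpc <- 1 - k / (k - 1) * (1 - pc)

  cen_d2 <- as.matrix(stats::dist(v))^2
  diag(cen_d2) <- Inf
  min_sep <- min(cen_d2)
  xie_beni <- sum(um * d2) / (n * min_sep)

  vbar <- colMeans(x)
  fs <- sum(um * d2) - sum(colSums(um) *
                             rowSums((v - matrix(vbar, k, ncol(x),
                                                 byrow = TRUE))^2))

  # Gath-Geva style densities with diagonal fuzzy covariance
  ridge <- 1e-12
  s_j <- numeric(k); vol_j <- numeric(k)
  for (j in seq_len(k)) {
    dev <- sweep(x, 2, v[j, ])
    var_j <- colSums(um[, j] * dev^2) / sum(um[, j]) + ridge
    vol_j[j] <- sqrt(prod(var_j))
    maha <- rowSums(sweep(dev^2, 2, var_j, `/`))
    s_j[j] <- sum(u[maha < ncol(x), j])   # central members
  }
  pd <- sum(s_j) / sum(vol_j)
  apd <- mean(s_j / vol_j)

  within <- colSums(um * d2) / colSums(um)
  nearest <- apply(cen_d2, 1, min)
  si <- mean(within / nearest)

  c(pc = pc, pe = pe, mpc = mpc, xie_beni = xie_beni,
    fukuyama_sugeno = fs, pd = pd, apd = apd, si = si)
}

# Direction in which each index improves.
index_directions <- function() {
  c(pc = "max", pe = "min", mpc = "max", xie_beni = "min",
    fukuyama_sugeno = "min", pd = "max", apd = "max", si = "min")
}

#' Select the cluster count by validity-index consensus
#'
#' Fits fuzzy c-means for every candidate `k` with several random
#' initialisations (best objective kept), evaluates the validity indices,
#' and reports each criterion's preferred `k` plus a consensus `k*` (the
#' majority vote of the named criteria, ties resolved toward the smaller
#' `k`). The full index table is returned for audit.
#'
#' @param x profile matrix.
#' @param k_range candidate cluster counts (within `[2, n - 1]`).
#' @param criteria index names that vote on the consensus.
#' @param m fuzzifier.
#' @param nstart random initialisations per k.
#' @param seed root seed; initialisation s for cluster count k uses
#'   `seed + 97 * k + s`.
#' @return List: `k_star`, `preferred` (named vector of each criterion's
#'   k), `index_table` (data.frame k x indices), `fits` (best fit per k).
#' @export
select_k <- function(x, k_range = 2:8,
                     criteria = c("fukuyama_sugeno", "apd", "si"),
                     m = 2, nstart = 10, seed = 1) {
  x <- as.matrix(x)
  if (length(k_range) == 0) stop("empty k_range")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > nrow(x) - 1) {
    stop("k_range must lie within [2, n - 1]")
  }
  fits <- list(); rows <- list()
  for (k in k_range) {
    best <- NULL
    for (s in seq_len(nstart)) {
      f <- fuzzy_cmeans(x, k, m = m, seed = seed + 97L * k + s)
      if (is.null(best) || f$objective < best$objective) best <- f
    }
    fits[[as.character(k)]] <- best
    rows[[as.character(k)]] <- c(k = k, validity_indices(best, x))
  }
  index_table <- as.data.frame(do.call(rbind, rows))
  rownames(index_table) <- NULL

  dirs <- index_directions()
  preferred <- vapply(names(dirs), function(ix) {
    v <- index_table[[ix]]
    kk <- index_table$k
    if (dirs[[ix]] == "max") kk[which.max(v)] else kk[which.min(v)]
  }, numeric(1))

  votes <- preferred[criteria]
  tab <- table(votes)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  k_star <- min(winners)
  list(k_star = as.integer(k_star), preferred = preferred,
       index_table = index_table, fits = fits)
}
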