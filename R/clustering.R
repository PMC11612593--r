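# Day clustering: k-means on z-scored 24-hour multivariate profiles.
# Clusters define the "cluster" temporal granularity; clustering is per
# participant because downstream pattern detection is per participant.

#' Build per-day multivariate profile features
#'
#' One feature vector per fully covered (qualifying) day: the 24 hourly IOB
#' means, then 24 COB, then 24 IG, each variable z-scored using that
#' participant's mean and SD over all qualifying-day hourly values. A
#' zero-variance variable is set to zeros with a warning.
#'
#' @param grid an `hourly_grid`.
#' @return A `day_features` list: `features` (days x 72 matrix), `dates`,
#'   `participant_id`. Empty when no day qualifies.
#' @export
day_features <- function(grid) {
  qd <- qualifying_days(grid)
  pid <- attr(grid, "participant_id")
  if (length(qd) == 0) {
    return(structure(list(features = matrix(numeric(), 0, 72), dates = qd,
      participant_id = pid), class = "day_features"))
  }
  q <- qualifying_hours(grid)
  day <- as.Date(q$hour, tz = "UTC")
  hod <- as.integer(format(q$hour, "%H", tz = "UTC"))
  feat <- matrix(NA_real_, length(qd), 72,
    dimnames = list(as.character(qd), NULL))
  for (vi in seq_along(aid_variables())) {
    v <- aid_variables()[vi]
    x <- q[[v]]
    mu <- mean(x); sdv <- stats::sd(x)
    if (sdv == 0 || !is.finite(sdv)) {
      warning(sprintf("variable %s has zero variance; features set to 0", v))
      z <- rep(0, length(x))
    } else {
      z <- (x - mu) / sdv
    }
    feat[cbind(match(day, qd), (vi - 1) * 24 + hod + 1)] <- z
  }
  structure(list(features = feat, dates = qd, participant_id = pid),
    class = "day_features")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (sum(d2) > 0) {
      centers[j + 1] <- sample.int(n, 1, prob = d2 / sum(d2))
    } else { # all remaining points coincide with a center
      centers[j + 1] <- sample(setdiff(seq_len(n), centers[seq_len(j)]), 1)
    }
    nd <- rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Cluster days by their diurnal profiles
#'
#' Lloyd's k-means from k-means++ initialization, keeping the best of
#' `restarts` restarts by total within-cluster squared distance (inertia).
#' Deterministic given `seed`.
#'
#' @param features a `day_features` object or a numeric matrix (days x
#'   features).
#' @param k number of clusters (`2 <= k <=` number of days).
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts (default 10).
#' @return A `cluster_assignment` list: `k`, `labels` (1..k per day),
#'   `dates`, `centroids` (k x 72), `inertia`, `silhouette`, `seed`.
#' @export
fit_kmeans <- function(features, k, seed = 1L, restarts = 10L) {
  dates <- NULL; pid <- NULL
  if (inherits(features, "day_features")) {
    dates <- features$dates; pid <- features$participant_id
    features <- features$features
  }
  n <- nrow(features)
  if (k > n) stop("k cannot exceed the number of days", call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(features, k)
      fit <- suppressWarnings(stats::kmeans(features, centers = init,
        iter.max = 100, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  sil <- if (k < n) mean_silhouette(features, best$cluster) else NA_real_
  structure(list(k = k, labels = as.integer(best$cluster), dates = dates,
    participant_id = pid, centroids = best$centers,
    inertia = best$tot.withinss, silhouette = sil, seed = seed),
    class = "cluster_assignment")
}

#' Mean silhouette width of a clustering
#'
#' Standard silhouette on Euclidean distances: for each point,
#' `(b - a) / max(a, b)` with `a` the mean distance to its own cluster and
#' `b` the smallest mean distance to another cluster. Singleton clusters
#' score 0.
#'
#' @param x numeric matrix (observations x features).
#' @param labels integer cluster labels.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
mean_silhouette <- function(x, labels) {
  n <- nrow(x)
  dm <- as.matrix(stats::dist(x))
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) { s[i] <- 0; next }
    a <- sum(dm[i, own]) / n_own
    b <- min(vapply(setdiff(ks, labels[i]), function(kk) {
      mean(dm[i, labels == kk])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose k by silhouette
#'
#' Fits [fit_kmeans()] for each k in `k_range` (truncated, with a message,
#' to at most `nrow - 1`) and returns the k with the largest mean
#' silhouette; ties break toward the smaller k.
#'
#' @param features a `day_features` object or numeric matrix.
#' @param k_range candidate k values (default 2:8).
#' @param seed integer seed.
#' @param restarts restarts per fit.
#' @return The selected k.
#' @export
choose_k <- function(features, k_range = 2:8, seed = 1L, restarts = 10L) {
  mat <- if (inherits(features, "day_features")) features$features else features
  if (length(k_range) == 0) stop("k_range is empty", call. = FALSE)
  k_max <- nrow(mat) - 1
  if (any(k_range > k_max)) {
    message(sprintf("k_range truncated to <= %d (days - 1)", k_max))
    k_range <- k_range[k_range <= k_max]
    if (length(k_range) == 0) stop("no feasible k in k_range", call. = FALSE)
  }
  sils <- vapply(k_range, function(k) {
    fit_kmeans(features, k, seed = seed, restarts = restarts)$silhouette
  }, numeric(1))
  k_range[which.max(sils)]
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment> k = %d over %d days; inertia %.2f, silhouette %.3f\n",
    x$k, length(x$labels), x$inertia, x$silhouette))
  print(table(cluster = x$labels))
  invisible(x)
}
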