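# Matrix-profile motif and discord discovery on hourly series.
#
# The self-join matrix profile records, for each length-m window, the
# z-normalized Euclidean distance to its nearest non-trivial match (trivial
# matches inside an exclusion zone around the window itself are ignored).
# Minima of the profile are motifs (recurring shapes), maxima are discords
# (anomalies). Computed by direct evaluation of all window pairs — exact at
# desk scale; fast approximate backends are out of scope.

#' Self-join matrix profile of an hourly series
#'
#' Windows are z-normalized with the population standard deviation; windows
#' whose SD falls below `eps` are floored at `eps` and counted in
#' `n_flat_windows`. The exclusion zone half-width defaults to
#' `ceiling(m / 2)`: matches with `|i - j| <= exclusion` are ignored.
#'
#' @param x numeric series without missing values (use
#'   [longest_covered_stretch()] to extract one from a grid).
#' @param m window length in hours (series must have length >= 2 m).
#' @param exclusion exclusion-zone half-width.
#' @param eps floor for the window standard deviation.
#' @return A `matrix_profile` list: `m`, `profile`, `profile_index` (1-based
#'   position of the nearest neighbor), `exclusion`, `n`, `n_flat_windows`.
#' @export
matrix_profile <- function(x, m, exclusion = ceiling(m / 2), eps = 1e-8) {
  n <- length(x)
  if (anyNA(x)) stop("series must not contain missing values", call. = FALSE)
  if (n < 2 * m) stop("series must be at least twice the window length",
    call. = FALSE)
  nw <- n - m + 1
  # rolling mean / population sd via cumulative sums
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  mu <- (cs[(m + 1):(n + 1)] - cs[1:nw]) / m
  sig2 <- (cs2[(m + 1):(n + 1)] - cs2[1:nw]) / m - mu^2
  sig <- sqrt(pmax(sig2, 0))
  flat <- sig < eps
  sig[flat] <- eps
  # z-normalized windows; distance via the Gram matrix:
  # d(i,j)^2 = 2m - 2 * z_i . z_j  for unit-variance, zero-mean windows
  W <- matrix(x[outer(seq_len(nw) - 1, seq_len(m), `+`)], nw, m)
  Z <- (W - mu) / sig
  G <- tcrossprod(Z)
  D2 <- 2 * m - 2 * G
  band <- abs(outer(seq_len(nw), seq_len(nw), `-`)) <= exclusion
  D2[band] <- Inf
  profile_index <- max.col(-D2, ties.method = "first")
  profile <- sqrt(pmax(D2[cbind(seq_len(nw), profile_index)], 0))
  structure(list(m = m, profile = profile, profile_index = profile_index,
    exclusion = exclusion, n = n, n_flat_windows = sum(flat)),
    class = "matrix_profile")
}

#' Longest contiguous fully covered stretch of a variable
#'
#' Missing hours are not imputed (imputation fabricates motifs); the matrix
#' profile is computed on the longest run of consecutive hours in which the
#' variable is covered.
#'
#' @param grid an `hourly_grid`.
#' @param variable `"iob"`, `"cob"` or `"ig"`.
#' @return A numeric vector of hourly values (possibly short or empty).
#' @export
longest_covered_stretch <- function(grid, variable) {
  variable <- match.arg(variable, aid_variables())
  cov <- grid[[paste0(variable, "_covered")]]
  if (length(cov) == 0 || !any(cov)) return(numeric())
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- (ends[best] - r$lengths[best] + 1):ends[best]
  grid[[variable]][idx]
}

#' Top motif of a matrix profile
#'
#' The position pair with minimal profile distance; ties break toward the
#' smaller index.
#'
#' @param mp a `matrix_profile`.
#' @return List with `positions` (sorted pair) and `distance`.
#' @export
top_motif <- function(mp) {
  i <- which.min(mp$profile)
  list(positions = sort(c(i, mp$profile_index[i])), distance = mp$profile[i])
}

#' Top discord of a matrix profile
#'
#' The position with maximal profile distance; ties break toward the smaller
#' index.
#'
#' @param mp a `matrix_profile`.
#' @return List with `position` and `distance`.
#' @export
top_discord <- function(mp) {
  i <- which.max(mp$profile)
  list(position = i, distance = mp$profile[i])
}

#' @export
print.matrix_profile <- function(x, ...) {
  mot <- top_motif(x); dis <- top_discord(x)
  cat(sprintf("<matrix_profile> n = %d, m = %d, exclusion = %d\n",
    x$n, x$m, x$exclusion))
  cat(sprintf("  top motif at (%d, %d), distance %.4f\n",
    mot$positions[1], mot$positions[2], mot$distance))
  cat(sprintf("  top discord at %d, distance %.4f\n", dis$position,
    dis$distance))
  if (x$n_flat_windows > 0) {
    cat(sprintf("  note: %d near-constant windows (sd floored)\n",
      x$n_flat_windows))
  }
  invisible(x)
}

#' @export
plot.matrix_profile <- function(x, ...) {
  graphics::plot(x$profile, type = "l", xlab = "window start (hour)",
    ylab = "z-normalized distance to nearest match",
    main = sprintf("Matrix profile (m = %d h)", x$m), ...)
  mot <- top_motif(x); dis <- top_discord(x)
  graphics::abline(v = mot$positions, col = "forestgreen", lty = 2)
  graphics::abline(v = dis$position, col = "firebrick", lty = 3)
  invisible(x)
}
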