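#' Algebraic (Kasa) least-squares circle fit
#'
#' Fits a circle to labelled pupil-edge points by solving the linear system
#' of the algebraic distance formulation. At pupil-tracking noise levels the
#' difference from a geometric fit is below reporting precision.
#'
#' @param x,y point coordinates (at least 3 finite points)
#' @return list with `cx`, `cy`, `r`
#' @export
fit_circle <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("circle fit needs at least 3 points", call. = FALSE)
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- stats::lm.fit(A, b)$coefficients
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  list(cx = unname(sol[1]), cy = unname(sol[2]), r = sqrt(max(r2, 0)))
}

#' Hampel outlier filter
#'
#' Sliding-window median filter: a sample further than `n_sigma` scaled
#' median absolute deviations from its local median (window of `k`
#' neighbours on each side) is replaced by that median. Missing values are
#' ignored within windows and propagated in the output.
#'
#' @param x numeric series (may contain NA)
#' @param k neighbours on each side (default 10)
#' @param n_sigma outlier threshold in robust SD units (default 1.0)
#' @return filtered series, same length
#' @export
hampel_filter <- function(x, k = 10L, n_sigma = 1.0) {
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    w <- x[max(1L, i - k):min(n, i + k)]
    w <- w[!is.na(w)]
    med <- stats::median(w)
    sigma <- 1.4826 * stats::median(abs(w - med))
    if (abs(x[i] - med) > n_sigma * sigma) out[i] <- med
  }
  out
}

#' Pupil area from labelled edge points
#'
#' Fits a circle per frame to the visible pupil-edge points (up to eight;
#' frames with fewer than 3 visible points give a missing value), converts
#' the radius to an area (`pi * r^2`), and smooths the area series with a
#' Hampel filter (10 neighbours, 1.0 SD).
#'
#' @param px,py frames x points matrices of edge coordinates (NA = point
#'   not visible)
#' @param k,n_sigma Hampel filter parameters
#' @return numeric pupil-area series with NA for unfittable frames
#' @export
pupil_area <- function(px, py, k = 10L, n_sigma = 1.0) {
  stopifnot(all(dim(px) == dim(py)))
  area <- rep(NA_real_, nrow(px))
  for (i in seq_len(nrow(px))) {
    ok <- is.finite(px[i, ]) & is.finite(py[i, ])
    if (sum(ok) >= 3) {
      fit <- fit_circle(px[i, ok], py[i, ok])
      area[i] <- pi * fit$r^2
    }
  }
  hampel_filter(area, k = k, n_sigma = n_sigma)
}
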