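# Random-matrix-theory selection of the correlation threshold. The nearest-
# neighbor spacing distribution (NNSD) of the unfolded eigenvalues of a
# thresholded correlation matrix transitions from the Wigner-Dyson (GOE)
# surmise — the signature of a noise-dominated, system-wide correlated matrix
# — to the Poisson law exp(-s) as genuinely modular structure is isolated.
# The chosen threshold is the earliest grid point from which the NNSD stays
# closer to Poisson than to GOE.

# collapse near-degenerate eigenvalues, unfold by a smoothing-spline fit of
# the cumulative spectral function, return unit-mean spacings (or NULL when
# too few survive)
unfolded_spacings <- function(ev, unfolding_df = 10, degeneracy_tol = 1e-10,
                              min_spacings = 30) {
  ev <- sort(ev)
  keep <- c(TRUE, diff(ev) >= degeneracy_tol)
  ev <- ev[keep]
  n <- length(ev)
  if (n < min_spacings + 1) return(NULL)
  df_use <- min(unfolding_df, n - 4)
  if (df_use < 2) return(NULL)
  fit <- stats::smooth.spline(ev, seq_len(n), df = df_use)
  zeta <- stats::predict(fit, ev)$y
  s <- diff(zeta)
  s <- s[s > 0]
  if (length(s) < min_spacings) return(NULL)
  s / mean(s)
}

# KS distance of a sample to a theoretical CDF
ks_distance <- function(s, cdf) {
  s <- sort(s)
  n <- length(s)
  f <- cdf(s)
  max(pmax(abs(f - (seq_len(n) - 1) / n), abs(f - seq_len(n) / n)))
}

nnsd_distances <- function(s) {
  c(poisson = ks_distance(s, function(x) 1 - exp(-x)),
    goe = ks_distance(s, function(x) 1 - exp(-pi * x^2 / 4)))
}

#' Random-matrix-theory correlation threshold
#'
#' For each candidate threshold `t` in `grid`, off-diagonal entries with
#' `|r| < t` are zeroed, the eigenvalue spectrum is computed, near-degenerate
#' eigenvalues are collapsed, the spectrum is unfolded by a smoothing-spline
#' fit of the cumulative spectral function (`unfolding_df` degrees of
#' freedom), and the Kolmogorov-Smirnov distances of the unit-mean
#' nearest-neighbor spacings to the Poisson law \eqn{e^{-s}} and the GOE
#' (Wigner-Dyson) surmise \eqn{(\pi s/2) e^{-\pi s^2/4}} are recorded.
#' The selected threshold is the smallest `t` at which the Poisson distance
#' drops below the GOE distance and stays below for at least `persistence`
#' consecutive usable grid points (or through the end of the usable grid when
#' fewer remain); a one-point dip does not count as the transition, and noisy
#' flips in the sparse tail of the grid do not veto an established
#' transition.
#'
#' Grid points with fewer than `min_spacings` usable spacings are skipped
#' with a warning; if no persistent transition exists the function errors
#' (widen the grid or relax the upstream filters).
#'
#' @param x Symmetric correlation matrix with unit diagonal, or a clr tibble
#'   (correlations are then computed across samples).
#' @param grid Candidate thresholds (default 0.10 to 0.98 in steps of 0.01).
#' @param unfolding_df Degrees of freedom of the unfolding spline (default 10).
#' @param degeneracy_tol Eigenvalue-collapse tolerance.
#' @param min_spacings Minimum usable spacings per grid point (default 30).
#' @param persistence Number of consecutive Poisson-closer usable grid points
#'   required to call the transition (default 5).
#' @return A `micronet_rmt` object: `threshold` and a per-t diagnostic
#'   `trace` tibble (`threshold`, `n_spacings`, `ks_poisson`, `ks_goe`,
#'   `closer`).
#' @export
rmt_threshold <- function(x, grid = seq(0.10, 0.98, by = 0.01),
                          unfolding_df = 10, degeneracy_tol = 1e-10,
                          min_spacings = 30, persistence = 5) {
  r <- if (is.data.frame(x)) cor(wide_matrix(x)) else as.matrix(x)
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-8) {
    abort("`x` must be (or yield) a symmetric correlation matrix.")
  }
  trace <- purrr::map_dfr(grid, function(t) {
    a <- r
    a[abs(a) < t] <- 0
    diag(a) <- diag(r)
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    s <- unfolded_spacings(ev, unfolding_df, degeneracy_tol, min_spacings)
    if (is.null(s)) {
      return(tibble(threshold = t, n_spacings = NA_integer_,
                    ks_poisson = NA_real_, ks_goe = NA_real_))
    }
    d <- nnsd_distances(s)
    tibble(threshold = t, n_spacings = length(s),
           ks_poisson = d[["poisson"]], ks_goe = d[["goe"]])
  })
  usable <- !is.na(trace$ks_poisson)
  if (!any(usable)) {
    abort("No grid point yields enough spacings; the matrix is too small or too sparse.")
  }
  n_skipped <- sum(!usable)
  if (n_skipped > 0) {
    warn(sprintf("%d grid point(s) skipped (fewer than %d usable spacings).",
                 n_skipped, min_spacings))
  }
  trace$closer <- ifelse(is.na(trace$ks_poisson), NA_character_,
                         ifelse(trace$ks_poisson < trace$ks_goe, "Poisson", "GOE"))
  poisson_closer <- trace$closer[usable] == "Poisson"
  ## earliest usable t opening a run of `persistence` Poisson-closer points
  thr <- NA_real_
  for (i in seq_along(poisson_closer)) {
    j <- i:min(i + persistence - 1, length(poisson_closer))
    if (all(poisson_closer[j])) {
      thr <- trace$threshold[usable][i]
      break
    }
  }
  if (is.na(thr)) {
    abort("No persistent GOE-to-Poisson transition found; adjust the grid or upstream filters.")
  }
  structure(list(threshold = thr, trace = trace,
                 unfolding_df = unfolding_df, grid = grid),
            class = "micronet_rmt")
}

#' @export
print.micronet_rmt <- function(x, ...) {
  cat(sprintf("RMT threshold: tau = %.2f (%d usable grid points)\n",
              x$threshold, sum(!is.na(x$trace$ks_poisson))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.micronet_rmt <- function(x, ...) x$trace

#' @exportS3Method generics::glance
glance.micronet_rmt <- function(x, ...) {
  tibble(threshold = x$threshold,
         n_usable = sum(!is.na(x$trace$ks_poisson)),
         unfolding_df = x$unfolding_df)
}
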