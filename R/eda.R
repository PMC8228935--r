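# Essential dynamics: backbone covariance PCA after removal of rigid-body
# motion, cosine-content diagnostics of the principal projections, and
# two-dimensional free-energy landscapes over selected components.
#
# Internal coordinates are Angstrom; eigenvalues are reported in nm^2 and
# projections in nm to match the conventional trajectory-analysis units.

#' Principal component analysis of backbone fluctuations
#'
#' Frames are superposed onto the ensemble mean structure over the
#' backbone selection (eliminating rotation and translation), the
#' covariance matrix of the 3M-dimensional backbone coordinate vector is
#' formed, and its eigendecomposition gives the collective modes.
#' Projections are centred scores of each frame on each mode.
#'
#' @param ensemble An `ensemble` with at least 2 frames.
#' @param selection Atom indices defining the analysed coordinates
#'   (default: backbone N, CA, C, O).
#' @return A `pca_ed` object: list with `eigenvalues` (nm^2, descending),
#'   `eigenvectors` (orthonormal columns), `projections` (frames x modes,
#'   nm), `trace` (nm^2) and `times` (ps).
#' @export
backbone_pca <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (n_frames(ensemble) < 2) stop("PCA needs at least 2 frames")
  if (is.null(selection)) selection <- backbone_indices(ensemble$topology)
  if (length(selection) < 3) stop("selection too small for superposition")
  ft <- fit_frames(ensemble, selection)
  nf <- length(ft$frames)
  X <- t(vapply(ft$frames, function(fr)
    as.vector(t(fr[selection, , drop = FALSE])), numeric(3 * length(selection))))
  X <- sweep(X, 2, colMeans(X))
  C <- crossprod(X) / nf              # population covariance, A^2
  ev <- eigen(C, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  proj <- X %*% ev$vectors
  out <- list(eigenvalues = vals / 100,           # A^2 -> nm^2
              eigenvectors = ev$vectors,
              projections = proj / 10,            # A -> nm
              trace = sum(diag(C)) / 100,
              times = ensemble$times)
  class(out) <- "pca_ed"
  out
}

#' @export
print.pca_ed <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat("backbone PCA: trace", format(x$trace, digits = 6), "nm^2;",
      "leading eigenvalues (nm^2):",
      paste(format(x$eigenvalues[seq_len(k)], digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.pca_ed <- function(object, n_modes = 20, ...) {
  k <- min(n_modes, length(object$eigenvalues))
  ev <- object$eigenvalues[seq_len(k)]
  data.frame(mode = seq_len(k), eigenvalue_nm2 = ev,
             cumulative_variance = cumsum(ev) / sum(object$eigenvalues))
}

#' @export
plot.pca_ed <- function(x, modes = c(1, 2), ...) {
  graphics::plot(x$projections[, modes[1]], x$projections[, modes[2]],
                 xlab = paste0("PC", modes[1], " (nm)"),
                 ylab = paste0("PC", modes[2], " (nm)"),
                 pch = 16, cex = 0.5, ...)
  invisible(x)
}

#' Cosine content of a principal-component projection
#'
#' Measures the overlap of a projection `p(t)` with a half-period cosine:
#' `c_i = (2/T) * (integral cos(i*pi*t/T) p(t) dt)^2 / integral p(t)^2 dt`,
#' discretised by the trapezoid rule on the frame time grid. Values near 1
#' indicate random-diffusion-like, unconverged sampling; modes with
#' cosine content at or below 0.2 are conventionally accepted for
#' free-energy landscapes.
#'
#' @param projection Numeric per-frame scores of one mode (or a `pca_ed`
#'   object, in which case `mode_index` selects the column).
#' @param mode_index Cosine half-period count `i` (and the projection
#'   column when a `pca_ed` is supplied). Default 1.
#' @param times Frame times; default: equally spaced on \[0, T\].
#' @return Cosine content in \[0, 1\].
#' @export
cosine_content <- function(projection, mode_index = 1, times = NULL) {
  if (inherits(projection, "pca_ed")) {
    if (is.null(times)) times <- projection$times
    projection <- projection$projections[, mode_index]
  }
  n <- length(projection)
  if (n < 4) stop("cosine content needs at least 4 frames")
  if (is.null(times)) times <- seq_len(n) - 1
  if (stats::var(projection) == 0 && all(projection == 0))
    stop("zero-variance projection")
  tt <- times - times[1]
  Tn <- tt[n]
  cosv <- cos(mode_index * pi * tt / Tn)
  trap <- function(y) sum(diff(tt) * (y[-1] + y[-n]) / 2)
  num <- (2 / Tn) * trap(cosv * projection)^2
  den <- trap(projection^2)
  if (den == 0) stop("zero-variance projection")
  min(1, num / den)
}

#' Two-dimensional free-energy landscape from two projections
#'
#' Bins the joint sample of two collective coordinates on an
#' `n_bins x n_bins` grid and converts occupation probabilities to free
#' energies `dG = -ln(P / P_max)` in units of kT, so the most populated
#' bin sits at 0 and empty bins are infinite. Local minima are bins not
#' exceeded by any 8-neighbour.
#'
#' @param pc1,pc2 Equal-length numeric score vectors.
#' @param n_bins Grid resolution per axis (default 32, >= 2).
#' @param temperature Temperature in Kelvin (default 300). Only used to
#'   annotate the energy scale in physical units; the grid itself is in kT.
#' @return A `fel` object: list with `free_energy` (matrix, kT; `Inf` for
#'   empty bins), `counts`, `x_edges`, `y_edges`, `minima` (data.frame of
#'   bin indices and centres) and `temperature`.
#' @export
free_energy_landscape <- function(pc1, pc2, n_bins = 32, temperature = 300) {
  if (length(pc1) != length(pc2)) stop("score vectors differ in length")
  if (n_bins < 2) stop("n_bins must be at least 2")
  rx <- range(pc1); ry <- range(pc2)
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  rx <- pad(rx); ry <- pad(ry)
  xe <- seq(rx[1], rx[2], length.out = n_bins + 1)
  ye <- seq(ry[1], ry[2], length.out = n_bins + 1)
  ix <- pmin(findInterval(pc1, xe, rightmost.closed = TRUE), n_bins)
  iy <- pmin(findInterval(pc2, ye, rightmost.closed = TRUE), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  g <- matrix(Inf, n_bins, n_bins)
  nz <- counts > 0
  g[nz] <- -log(counts[nz] / max(counts))
  # local minima over the 8-neighbourhood, finite bins only
  minima <- list()
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    if (!nz[i, j]) next
    ii <- max(1, i - 1):min(n_bins, i + 1)
    jj <- max(1, j - 1):min(n_bins, j + 1)
    if (g[i, j] <= min(g[ii, jj]))
      minima[[length(minima) + 1]] <-
        data.frame(bin_x = i, bin_y = j,
                   x = (xe[i] + xe[i + 1]) / 2, y = (ye[j] + ye[j + 1]) / 2,
                   free_energy = g[i, j])
  }
  out <- list(free_energy = g, counts = counts, x_edges = xe, y_edges = ye,
              minima = if (length(minima)) do.call(rbind, minima)
                       else data.frame(bin_x = integer(), bin_y = integer(),
                                       x = numeric(), y = numeric(),
                                       free_energy = numeric()),
              temperature = temperature)
  class(out) <- "fel"
  out
}

#' @export
print.fel <- function(x, ...) {
  cat("free-energy landscape:", nrow(x$free_energy), "x", ncol(x$free_energy),
      "bins,", sum(is.finite(x$free_energy)), "occupied,",
      nrow(x$minima), "local minima\n")
  invisible(x)
}

#' @export
plot.fel <- function(x, ...) {
  g <- x$free_energy
  g[!is.finite(g)] <- NA
  graphics::image(x = (x$x_edges[-1] + x$x_edges[-length(x$x_edges)]) / 2,
                  y = (x$y_edges[-1] + x$y_edges[-length(x$y_edges)]) / 2,
                  z = g, xlab = "PC1", ylab = "PC2", ...)
  invisible(x)
}

#' Select the principal components admitted to the landscape
#'
#' Applies the sampling-convergence filter: the two lowest-index modes
#' whose cosine content does not exceed `threshold`.
#'
#' @param pca A `pca_ed` object.
#' @param threshold Cosine-content cutoff (default 0.2).
#' @param n_check Number of leading modes to test (default 20).
#' @return Integer vector of the selected mode indices (length 2, or fewer
#'   when not enough modes pass).
#' @export
fel_modes <- function(pca, threshold = 0.2, n_check = 20) {
  stopifnot(inherits(pca, "pca_ed"))
  n_check <- min(n_check, ncol(pca$projections))
  ok <- integer(0)
  for (i in seq_len(n_check)) {
    p <- pca$projections[, i]
    if (stats::var(p) == 0) next
    if (cosine_content(p, i, pca$times) <= threshold) ok <- c(ok, i)
    if (length(ok) == 2) break
  }
  ok
}
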