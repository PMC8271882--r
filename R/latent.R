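# PCA latent basis: the low-dimensional second view y_n in R^Q paired with
# each V-dimensional pose in the joint-distribution representation.

#' Fit a PCA latent basis
#'
#' Computes the top-q principal components of the pooled pose frames: the
#' orthonormal eigenvectors of the sample covariance of the centered data,
#' ordered by decreasing explained variance. A deterministic sign convention
#' (each component's largest-magnitude coefficient is positive) removes the
#' eigenvector sign ambiguity so that refitting identical data yields an
#' identical basis.
#'
#' @param frames n x V numeric matrix of pooled pose frames, n >= 2.
#' @param q number of components, 1 <= q <= min(n - 1, V).
#' @return object of class `latent_basis`: `mean` (V), `components` (q x V,
#'   orthonormal rows), `explained_variance_ratio` (q fractions of the total
#'   variance, non-increasing).
#' @export
fit_latent_basis <- function(frames, q) {
  frames <- as_sample_matrix(frames, "frames")
  n <- nrow(frames); V <- ncol(frames)
  if (n < 2L) stop_validation("need at least 2 frames to fit a latent basis")
  if (q < 1L || q > min(n - 1L, V))
    stop_validation(sprintf("q = %d out of range [1, %d]", q, min(n - 1L, V)))
  mu <- colMeans(frames)
  Xc <- sweep(frames, 2L, mu)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (n - 1)                    # covariance eigenvalues
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < q)
    stop_validation(sprintf("input has rank %d < q = %d components requested", rank, q))
  comp <- t(sv$v[, seq_len(q), drop = FALSE])
  for (k in seq_len(q)) {
    j <- which.max(abs(comp[k, ]))
    if (comp[k, j] < 0) comp[k, ] <- -comp[k, ]
  }
  ratio <- ev[seq_len(q)] / sum(ev)
  structure(list(mean = mu, components = comp,
                 explained_variance_ratio = ratio),
            class = "latent_basis")
}

#' @export
print.latent_basis <- function(x, ...) {
  cat(sprintf("<latent_basis> Q = %d, V = %d, variance preserved = %.1f%%\n",
              nrow(x$components), ncol(x$components),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project frames onto a latent basis
#'
#' Centers the frames with the basis mean and projects onto the component
#' rows: `(frames - mean) %*% t(components)`. Orthonormal projection can only
#' contract pairwise distances, so latent-space distances never exceed the
#' corresponding ambient distances.
#'
#' @param frames m x V numeric matrix.
#' @param basis a fitted [fit_latent_basis()] object.
#' @return m x Q matrix of latent coordinates.
#' @export
project_latent <- function(frames, basis) {
  frames <- as_sample_matrix(frames, "frames")
  if (ncol(frames) != length(basis$mean))
    stop_dim(sprintf("frames have dimension %d but basis expects %d",
                     ncol(frames), length(basis$mean)))
  sweep(frames, 2L, basis$mean) %*% t(basis$components)
}

#' Fraction of variance preserved by a latent basis
#'
#' @param basis a fitted [fit_latent_basis()] object.
#' @return scalar in \[0, 1\]: the sum of the explained-variance ratios.
#' @export
variance_preserved <- function(basis) {
  sum(basis$explained_variance_ratio)
}

#' Serialize / restore a latent basis
#'
#' Writes the basis (mean, components, explained-variance ratios) as JSON for
#' reproducibility; `read_latent_basis()` restores it.
#'
#' @param basis a `latent_basis`.
#' @param path JSON file path.
#' @export
write_latent_basis <- function(basis, path) {
  jsonlite::write_json(list(mean = basis$mean,
                            components = basis$components,
                            explained_variance_ratio = basis$explained_variance_ratio),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_latent_basis
#' @export
read_latent_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(obj$mean),
                 components = as.matrix(obj$components),
                 explained_variance_ratio = as.numeric(obj$explained_variance_ratio)),
            class = "latent_basis")
}
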