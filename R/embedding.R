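# Sample-based estimators of RKHS distances between marginal distributions
# (MMD) and joint distributions (EHECCO, the tensor-space distance between
# cross-covariance operator embeddings).

NEG_CLAMP <- -1e-9

#' Weighted two-view sample set
#'
#' The object the EHECCO metric compares: a set of N paired samples
#' \eqn{\{x_n \in R^V, y_n \in R^Q\}} drawn from a joint distribution over a
#' primary space (e.g. flattened normalized 3D joint coordinates) and a latent
#' space (e.g. PCA coordinates), together with a probability vector
#' \eqn{\alpha} holding the joint probability mass of each pair. In the motion
#' capture pipeline one such set — codebook poses plus their latent
#' projections under the uniform empirical measure — represents one record.
#'
#' @param primary N x V numeric matrix of primary-space samples.
#' @param latent N x Q numeric matrix of latent-space samples, same N.
#' @param weights probability vector of length N; entries in \[0, 1\] summing
#'   to 1 within 1e-9. Default: uniform 1/N.
#' @return an object of class `weighted_sample_set` with elements `primary`,
#'   `latent`, `weights`.
#' @examples
#' weighted_sample_set(matrix(rnorm(15), 5), matrix(rnorm(10), 5))
#' @export
weighted_sample_set <- function(primary, latent, weights = NULL) {
  primary <- as_sample_matrix(primary, "primary")
  latent <- as_sample_matrix(latent, "latent")
  if (nrow(primary) != nrow(latent))
    stop_dim(sprintf("primary has %d samples but latent has %d",
                     nrow(primary), nrow(latent)))
  n <- nrow(primary)
  if (is.null(weights)) weights <- rep(1 / n, n)
  weights <- as.numeric(weights)
  if (length(weights) != n)
    stop_validation(sprintf("weights has length %d, expected %d", length(weights), n))
  if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1))
    stop_validation("weights must lie in [0, 1]")
  if (abs(sum(weights) - 1) > 1e-9)
    stop_validation(sprintf("weights must sum to 1 (got %.12f)", sum(weights)))
  structure(list(primary = primary, latent = latent, weights = weights),
            class = "weighted_sample_set")
}

#' @export
print.weighted_sample_set <- function(x, ...) {
  cat(sprintf("<weighted_sample_set> N = %d, V = %d, Q = %d\n",
              nrow(x$primary), ncol(x$primary), ncol(x$latent)))
  invisible(x)
}

check_wss <- function(x, arg = "P") {
  if (!inherits(x, "weighted_sample_set"))
    stop_validation(sprintf("'%s' must be a weighted_sample_set", arg))
  x
}

check_wss_pair <- function(P, R) {
  check_wss(P, "P"); check_wss(R, "R")
  if (ncol(P$primary) != ncol(R$primary))
    stop_dim(sprintf("primary-space dimension mismatch: %d vs %d",
                     ncol(P$primary), ncol(R$primary)))
  if (ncol(P$latent) != ncol(R$latent))
    stop_dim(sprintf("latent-space dimension mismatch: %d vs %d",
                     ncol(P$latent), ncol(R$latent)))
  invisible(NULL)
}

clamp_sq <- function(value) {
  if (value < NEG_CLAMP)
    stop(errorCondition(
      sprintf("squared distance estimator returned %.3e < %.0e; kernel matrices are not PSD",
              value, NEG_CLAMP),
      class = c("ehecco_internal_error", "ehecco_error")))
  max(value, 0)
}

#' Squared maximum mean discrepancy between two sample sets
#'
#' Empirical estimator of the squared RKHS distance between the mean
#' embeddings of two marginal distributions:
#' \deqn{\hat d^2 = \frac{1}{N^2}\mathbf{1}^\top K_{x,x}\mathbf{1}
#'   + \frac{1}{M^2}\mathbf{1}^\top K_{z,z}\mathbf{1}
#'   - \frac{2}{NM}\mathbf{1}^\top K_{x,z}\mathbf{1},}
#' with Gaussian kernel matrices evaluated at an effective bandwidth
#' controlled by `convention`: the estimator is conventionally written with
#' kernel \eqn{\kappa_{2\sigma}}, which the default reads as doubling the
#' bandwidth (denominator \eqn{8\sigma^2}); `"variance"` doubles the variance
#' (denominator \eqn{4\sigma^2}); `"plain"` uses \eqn{\sigma} as given. The
#' result is clamped at zero from below.
#'
#' @param X N x d matrix of samples from the first distribution.
#' @param Z M x d matrix of samples from the second distribution.
#' @param sigma positive bandwidth (before the convention scaling).
#' @param convention kernel bandwidth-doubling convention, see Details.
#' @return non-negative scalar squared distance.
#' @examples
#' mmd_squared(matrix(0), matrix(1), sigma = 1) # 2 * (1 - exp(-1/8))
#' @export
mmd_squared <- function(X, Z, sigma, convention = c("bandwidth", "variance", "plain")) {
  X <- as_sample_matrix(X, "X")
  Z <- as_sample_matrix(Z, "Z")
  if (ncol(X) != ncol(Z))
    stop_dim(sprintf("dimension mismatch: X has %d columns, Z has %d", ncol(X), ncol(Z)))
  b <- effective_sigma(check_sigma(sigma), match.arg(convention))
  kxx <- mean(gaussian_kernel_matrix(X, X, b))
  kzz <- mean(gaussian_kernel_matrix(Z, Z, b))
  kxz <- mean(gaussian_kernel_matrix(X, Z, b))
  clamp_sq(kxx + kzz - 2 * kxz)
}

#' Squared EHECCO distance between two joint distributions
#'
#' Estimator of the squared tensor-RKHS distance between the cross-covariance
#' operator embeddings of two joint distributions, each represented by a
#' [weighted_sample_set()]. With \eqn{K^\varphi} the Gaussian kernel matrix on
#' primary samples (bandwidth `sigma_phi`), \eqn{K^\phi} the Gaussian kernel
#' matrix on latent samples (bandwidth `sigma_psi`), \eqn{\circ} the Hadamard
#' (elementwise) product and \eqn{\alpha} the probability vectors:
#' \deqn{\hat d_J^2 = \alpha_{x,y}^\top (K^\varphi_{x,x} \circ K^\phi_{y,y}) \alpha_{x,y}
#'  + \alpha_{z,l}^\top (K^\varphi_{z,z} \circ K^\phi_{l,l}) \alpha_{z,l}
#'  - 2\, \alpha_{x,y}^\top (K^\varphi_{x,z} \circ K^\phi_{y,l}) \alpha_{z,l}.}
#'
#' The Hadamard product realizes the tensor-product kernel
#' \eqn{\kappa_\varphi \cdot \kappa_\phi}, so the estimator compares joint —
#' not merely marginal — structure: two sets whose marginals agree but whose
#' cross-space coupling differs are separated. Negative floating-point
#' round-off is clamped to zero; a value below -1e-9 raises an
#' internal-consistency error since positive semi-definite kernels make the
#' quantity analytically non-negative.
#'
#' @param P,R [weighted_sample_set()] objects with matching primary dimension
#'   V and latent dimension Q (sample counts N, M may differ).
#' @param sigma_phi positive bandwidth of the primary-space kernel.
#' @param sigma_psi positive bandwidth of the latent-space kernel.
#' @return non-negative scalar squared distance.
#' @seealso [ehecco_squared_oracle()] for the brute-force reference,
#'   [pairwise_distance_matrix()] for whole-dataset use.
#' @export
ehecco_squared <- function(P, R, sigma_phi, sigma_psi) {
  check_wss_pair(P, R)
  sigma_phi <- check_sigma(sigma_phi, "sigma_phi")
  sigma_psi <- check_sigma(sigma_psi, "sigma_psi")
  term <- function(A, B, wa, wb) {
    Kp <- gaussian_kernel_matrix(A$primary, B$primary, sigma_phi)
    Kl <- gaussian_kernel_matrix(A$latent, B$latent, sigma_psi)
    drop(crossprod(wa, (Kp * Kl) %*% wb))
  }
  clamp_sq(term(P, P, P$weights, P$weights) +
           term(R, R, R$weights, R$weights) -
           2 * term(P, R, P$weights, R$weights))
}

#' Brute-force EHECCO reference estimator
#'
#' Computes exactly the same quantity as [ehecco_squared()] by explicit nested
#' summation \eqn{\sum_i \sum_j \alpha_i \alpha_j\,
#' \kappa_\varphi(\cdot,\cdot)\,\kappa_\phi(\cdot,\cdot)}, one scalar kernel
#' evaluation at a time and with no matrix algebra. It exists as an
#' independent testing oracle for the vectorized estimator and is only
#' intended for small sample counts (N, M up to ~100).
#'
#' @inheritParams ehecco_squared
#' @return non-negative scalar squared distance.
#' @export
ehecco_squared_oracle <- function(P, R, sigma_phi, sigma_psi) {
  check_wss_pair(P, R)
  sigma_phi <- check_sigma(sigma_phi, "sigma_phi")
  sigma_psi <- check_sigma(sigma_psi, "sigma_psi")
  kgauss <- function(a, b, s) exp(-sum((a - b)^2) / (2 * s^2))
  dsum <- function(A, B, wa, wb) {
    acc <- 0
    for (i in seq_len(nrow(A$primary))) {
      for (j in seq_len(nrow(B$primary))) {
        acc <- acc + wa[i] * wb[j] *
          kgauss(A$primary[i, ], B$primary[j, ], sigma_phi) *
          kgauss(A$latent[i, ], B$latent[j, ], sigma_psi)
      }
    }
    acc
  }
  clamp_sq(dsum(P, P, P$weights, P$weights) +
           dsum(R, R, R$weights, R$weights) -
           2 * dsum(P, R, P$weights, R$weights))
}

# Self term alpha' (Kxx o Kyy) alpha of one representation, for one or many
# bandwidth pairs. Returns a length(sp) x length(sl) matrix.
rep_self_terms <- function(rep, sigmas_phi, sigmas_psi) {
  sdp <- squared_distance_matrix(rep$primary, rep$primary)
  sdl <- squared_distance_matrix(rep$latent, rep$latent)
  w <- rep$weights
  out <- matrix(NA_real_, length(sigmas_phi), length(sigmas_psi))
  for (a in seq_along(sigmas_phi)) {
    Ep <- exp(-sdp / (2 * sigmas_phi[a]^2))
    for (b in seq_along(sigmas_psi)) {
      El <- exp(-sdl / (2 * sigmas_psi[b]^2))
      out[a, b] <- drop(crossprod(w, (Ep * El) %*% w))
    }
  }
  out
}

# Cross terms alpha_i' (K o K) alpha_j for all bandwidth pairs at once,
# reusing one squared-distance evaluation per space.
rep_cross_terms <- function(ri, rj, sigmas_phi, sigmas_psi) {
  sdp <- squared_distance_matrix(ri$primary, rj$primary)
  sdl <- squared_distance_matrix(ri$latent, rj$latent)
  out <- matrix(NA_real_, length(sigmas_phi), length(sigmas_psi))
  Eps <- lapply(sigmas_phi, function(s) exp(-sdp / (2 * s^2)))
  Els <- lapply(sigmas_psi, function(s) exp(-sdl / (2 * s^2)))
  for (a in seq_along(sigmas_phi))
    for (b in seq_along(sigmas_psi))
      out[a, b] <- drop(crossprod(ri$weights, (Eps[[a]] * Els[[b]]) %*% rj$weights))
  out
}

#' Pairwise EHECCO dissimilarity matrix
#'
#' Computes the symmetric \eqn{\Lambda \times \Lambda} matrix of pairwise
#' EHECCO distances between record representations. By default entries are
#' the distance \eqn{d_J = \sqrt{\max(\hat d_J^2, 0)}} rather than the squared
#' estimator: downstream t-SNE embedding and dissimilarity-space features
#' behave better with a distance-like quantity. Only the upper triangle is
#' computed, then mirrored; the diagonal is exactly zero.
#'
#' @param reps list of [weighted_sample_set()] objects, length >= 2.
#' @param sigma_phi,sigma_psi positive kernel bandwidths for the primary and
#'   latent spaces.
#' @param squared if `TRUE` return squared distances instead of distances.
#' @return symmetric numeric matrix with zero diagonal; row/column names taken
#'   from the names of `reps` when present.
#' @export
pairwise_distance_matrix <- function(reps, sigma_phi, sigma_psi, squared = FALSE) {
  if (!is.list(reps) || length(reps) < 2L)
    stop_validation("'reps' must be a list of at least 2 weighted_sample_set objects")
  for (i in seq_along(reps)) {
    if (!inherits(reps[[i]], "weighted_sample_set"))
      stop_validation(sprintf("reps[[%d]] is not a weighted_sample_set", i))
    if (i > 1L) {
      ok <- tryCatch({ check_wss_pair(reps[[1L]], reps[[i]]); TRUE },
                     ehecco_dim_error = function(e) e)
      if (!isTRUE(ok))
        stop_dim(sprintf("reps[[%d]] is incompatible with reps[[1]]: %s",
                         i, conditionMessage(ok)))
    }
  }
  grid <- ehecco_distance_grid(reps, sigma_phi, sigma_psi, squared = squared)
  D <- grid[[1L]][[1L]]
  dimnames(D) <- list(names(reps), names(reps))
  D
}

# All-pairs distance matrices for every (sigma_phi, sigma_psi) combination,
# sharing the squared-distance computation across bandwidths. Returns a
# nested list D[[a]][[b]]. Backbone of the pipeline's bandwidth grid search.
ehecco_distance_grid <- function(reps, sigmas_phi, sigmas_psi, squared = FALSE) {
  L <- length(reps)
  na <- length(sigmas_phi); nb <- length(sigmas_psi)
  for (s in sigmas_phi) check_sigma(s, "sigma_phi")
  for (s in sigmas_psi) check_sigma(s, "sigma_psi")
  selfs <- lapply(reps, rep_self_terms, sigmas_phi, sigmas_psi)
  D <- lapply(seq_len(na), function(a)
    lapply(seq_len(nb), function(b) matrix(0, L, L)))
  if (L >= 2L) {
    for (i in seq_len(L - 1L)) {
      for (j in seq.int(i + 1L, L)) {
        cr <- rep_cross_terms(reps[[i]], reps[[j]], sigmas_phi, sigmas_psi)
        for (a in seq_len(na)) {
          for (b in seq_len(nb)) {
            v <- clamp_sq(selfs[[i]][a, b] + selfs[[j]][a, b] - 2 * cr[a, b])
            if (!squared) v <- sqrt(v)
            D[[a]][[b]][i, j] <- v
            D[[a]][[b]][j, i] <- v
          }
        }
      }
    }
  }
  D
}

# Rectangular EHECCO distance block between two representation lists
# (e.g. test records vs training records), at a single bandwidth pair.
cross_distance_matrix <- function(reps_a, reps_b, sigma_phi, sigma_psi,
                                  squared = FALSE) {
  sa <- vapply(reps_a, function(r) rep_self_terms(r, sigma_phi, sigma_psi)[1, 1],
               numeric(1))
  sb <- vapply(reps_b, function(r) rep_self_terms(r, sigma_phi, sigma_psi)[1, 1],
               numeric(1))
  D <- matrix(NA_real_, length(reps_a), length(reps_b))
  for (i in seq_along(reps_a)) {
    for (j in seq_along(reps_b)) {
      cr <- rep_cross_terms(reps_a[[i]], reps_b[[j]], sigma_phi, sigma_psi)[1, 1]
      v <- clamp_sq(sa[i] + sb[j] - 2 * cr)
      D[i, j] <- if (squared) v else sqrt(v)
    }
  }
  D
}

#' Read or write a dissimilarity matrix
#'
#' `write_distance_matrix()` serializes a square dissimilarity matrix either
#' as delimited text (CSV with a header row of record identifiers) or as a
#' compact binary array (little-endian doubles preceded by the integer order;
#' exact float round-trip). `read_distance_matrix()` reverses either form,
#' dispatching on the file extension (`.bin` for binary, text otherwise).
#'
#' @param D square numeric matrix.
#' @param path file path; use extension `.bin` for the binary form.
#' @return `read_distance_matrix()` returns the matrix with any stored
#'   identifiers as row/column names.
#' @export
write_distance_matrix <- function(D, path) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop_validation("'D' must be square")
  if (grepl("\\.bin$", path)) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.integer(nrow(D)), con, size = 4L, endian = "little")
    writeBin(as.vector(D), con, size = 8L, endian = "little")
  } else {
    ids <- rownames(D)
    if (is.null(ids)) ids <- paste0("record_", seq_len(nrow(D)))
    utils::write.table(matrix(ids, 1L), path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    utils::write.table(format(D, digits = 17, scientific = TRUE, trim = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE, append = TRUE)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  if (grepl("\\.bin$", path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    D <- matrix(readBin(con, "double", n * n, size = 8L, endian = "little"), n, n)
  } else {
    ids <- as.character(utils::read.csv(path, header = FALSE, nrows = 1L,
                                        colClasses = "character")[1L, ])
    D <- as.matrix(utils::read.csv(path, header = FALSE, skip = 1L))
    dimnames(D) <- list(ids, ids)
  }
  D
}
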