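# Pose codebooks: spectral clustering of a record's frames and selection of
# one representative (medoid) pose per cluster.

#' Spectral clustering of pose frames
#'
#' Partitions the T frames of a record into `n_clusters` groups with the
#' standard normalized spectral clustering algorithm: a Gaussian (radial basis
#' function) affinity with bandwidth set by the median heuristic on the
#' frames, the symmetric normalized Laplacian embedding formed from the top
#' `n_clusters` eigenvectors, row normalization, and a seeded k-means
#' partition of the embedded rows. Every cluster is non-empty.
#'
#' @param frames T x V numeric matrix of (flattened, normalized) poses.
#' @param n_clusters number of clusters, 1 <= n_clusters <= T.
#' @param seed integer seed controlling the k-means initialization.
#' @return integer vector of T cluster labels in 1..n_clusters.
#' @export
spectral_cluster <- function(frames, n_clusters, seed = 1L) {
  frames <- as_sample_matrix(frames, "frames")
  T_ <- nrow(frames)
  if (n_clusters < 1L) stop_validation("n_clusters must be >= 1")
  if (T_ < n_clusters)
    stop_validation(sprintf("cannot form %d clusters from %d frames", n_clusters, T_))
  if (n_clusters == 1L) return(rep(1L, T_))
  if (n_clusters == T_) return(seq_len(T_))

  sigma <- suppressWarnings(
    if (T_ >= 2L) median_heuristic_bandwidth(frames) else 1.0)
  A <- gaussian_kernel_matrix(frames, frames, sigma)
  diag(A) <- 0
  d <- pmax(rowSums(A), .Machine$double.eps)
  Dm <- 1 / sqrt(d)
  L <- A * tcrossprod(Dm)                 # D^{-1/2} A D^{-1/2}
  eig <- eigen(L, symmetric = TRUE)
  U <- eig$vectors[, seq_len(n_clusters), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  U <- U / pmax(norms, .Machine$double.eps)
  labels <- with_seed(seed, {
    km <- stats::kmeans(U, centers = n_clusters, nstart = 10L, iter.max = 100L)
    km$cluster
  })
  as.integer(labels)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Build a pose codebook for one record
#'
#' Gathers the most representative poses of a record: frames are
#' spectral-clustered into `n_clusters` groups and each group contributes its
#' medoid — the member frame minimizing the summed within-cluster Euclidean
#' distance, ties broken by lowest frame index. Representatives are therefore
#' actual recorded poses, never synthetic averages. If the record is shorter
#' than `n_clusters` all frames are kept and the cluster count is reduced
#' with a warning.
#'
#' @inheritParams spectral_cluster
#' @return object of class `codebook`: `indices` (frame indices into the
#'   source record, one per cluster, in increasing order), `poses`
#'   (n_clusters x V matrix of the selected rows), `n_clusters`.
#' @export
build_codebook <- function(frames, n_clusters, seed = 1L) {
  frames <- as_sample_matrix(frames, "frames")
  T_ <- nrow(frames)
  if (T_ < n_clusters) {
    warning(sprintf("record has %d frames < n_clusters = %d; using all frames",
                    T_, n_clusters))
    n_clusters <- T_
  }
  labels <- spectral_cluster(frames, n_clusters, seed)
  idx <- integer(n_clusters)
  for (k in seq_len(n_clusters)) {
    members <- which(labels == k)
    if (length(members) == 1L) {
      idx[k] <- members
    } else {
      dd <- as.matrix(stats::dist(frames[members, , drop = FALSE]))
      sums <- rowSums(dd)
      idx[k] <- members[which.min(sums)]  # which.min takes the first = lowest index on ties
    }
  }
  idx <- sort(idx)
  structure(list(indices = idx, poses = frames[idx, , drop = FALSE],
                 n_clusters = n_clusters),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> %d poses of dimension %d (frames %d..%d)\n",
              x$n_clusters, ncol(x$poses), min(x$indices), max(x$indices)))
  invisible(x)
}

#' Export a codebook as CSV
#'
#' One row per selected pose: the source frame index followed by the pose
#' vector.
#'
#' @param codebook a [build_codebook()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_codebook_csv <- function(codebook, path) {
  df <- data.frame(frame = codebook$indices, codebook$poses, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
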