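# End-to-end motion-capture classification: per-record representation,
# EHECCO dissimilarity matrix, dissimilarity-space SVM with nested grid
# search, stratified 10-fold cross-validation, t-SNE visualization, and
# covariate correlation analysis.

SVM_COST_GRID <- c(1, 10, 100, 1000, 10000)
SVM_GAMMA_GRID <- c(0.01, 0.1, 1, 100, 1000)

#' Build the two-view representation of one record
#'
#' Turns a (normalized) pose sequence into the [weighted_sample_set()] the
#' EHECCO metric compares: the primary samples X are the record's codebook
#' poses (spectral-clustering medoids of the flattened frames), the latent
#' samples Y are their projections under the supplied latent basis, and the
#' weights are the uniform empirical measure 1/Nc over the codebook poses.
#'
#' @param poses a `pose_sequence`, normally already passed through
#'   [hip_normalize()].
#' @param basis a fitted [fit_latent_basis()].
#' @param n_clusters codebook size Nc (reduced with a warning for records
#'   shorter than Nc).
#' @param seed integer seed for the codebook clustering.
#' @return a `weighted_sample_set` with N = Nc samples.
#' @export
represent_record <- function(poses, basis, n_clusters = 50L, seed = 1L) {
  frames <- flatten_poses(poses)
  cb <- build_codebook(frames, n_clusters, seed)
  X <- cb$poses
  weighted_sample_set(X, project_latent(X, basis))
}

# Normalize any supported record form to a T x V flattened frame matrix:
# pose_sequence, hierarchy/motion pair, or an already-flattened matrix.
record_frames <- function(record, root_joint = NULL) {
  if (is.matrix(record)) return(record)
  if (inherits(record, "pose_sequence"))
    return(flatten_poses(hip_normalize(record, root_joint)))
  if (is.list(record) && !is.null(record$hierarchy) && !is.null(record$motion))
    return(flatten_poses(hip_normalize(
      forward_kinematics(record$hierarchy, record$motion), root_joint)))
  stop_validation("unsupported record type; expected pose_sequence, hierarchy/motion pair, or matrix")
}

# Stratified fold assignment (1..folds), deterministic given the seed.
make_stratified_folds <- function(labels, folds, seed) {
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Select EHECCO bandwidths and SVM hyperparameters by grid search
#'
#' Exhaustive search over the 5 x 5 bandwidth pairs (each space's base
#' bandwidth expanded by [bandwidth_grid()]) crossed with the SVM penalty
#' grid \{1, 10, 100, 1000, 10000\} and precision (RBF gamma) grid
#' \{0.01, 0.1, 1, 100, 1000\} — 625 candidate tuples — scored by internal
#' stratified cross-validation accuracy on the training records only. Ties
#' are broken by the smallest grid indices, in the order sigma_phi,
#' sigma_psi, cost, gamma.
#'
#' @param reps list of training [weighted_sample_set()] representations.
#' @param labels training class labels, >= 2 classes.
#' @param sigma0_phi,sigma0_psi base (median-heuristic) bandwidths of the
#'   primary and latent space.
#' @param cost_grid,gamma_grid SVM hyperparameter grids.
#' @param inner_folds internal stratified CV folds used for scoring.
#' @param seed integer seed for the internal folds.
#' @return list with `sigma_phi`, `sigma_psi`, `cost`, `gamma`, the achieved
#'   internal `accuracy`, and the chosen grid indices.
#' @export
select_hyperparameters <- function(reps, labels, sigma0_phi, sigma0_psi,
                                   cost_grid = SVM_COST_GRID,
                                   gamma_grid = SVM_GAMMA_GRID,
                                   inner_folds = 3L, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop_validation("hyperparameter selection needs at least 2 classes")
  sphis <- bandwidth_grid(sigma0_phi)
  spsis <- bandwidth_grid(sigma0_psi)
  grid <- ehecco_distance_grid(reps, sphis, spsis)
  counts <- table(labels)
  folds <- min(inner_folds, min(counts))
  if (folds < 2L) folds <- 2L
  fold_id <- make_stratified_folds(labels, folds, seed)
  best <- list(acc = -Inf)
  for (a in seq_along(sphis)) {
    for (b in seq_along(spsis)) {
      D <- grid[[a]][[b]]
      for (ci in seq_along(cost_grid)) {
        for (gi in seq_along(gamma_grid)) {
          correct <- 0L
          for (f in seq_len(folds)) {
            tr <- which(fold_id != f); te <- which(fold_id == f)
            if (length(te) == 0L || length(unique(labels[tr])) < 2L) next
            clf <- train_classifier(D[tr, tr, drop = FALSE], labels[tr],
                                    cost = cost_grid[ci], gamma = gamma_grid[gi])
            pred <- predict_classifier(clf, D[te, tr, drop = FALSE])
            correct <- correct + sum(pred == labels[te])
          }
          acc <- correct / length(labels)
          if (acc > best$acc) {
            best <- list(acc = acc, a = a, b = b, ci = ci, gi = gi)
          }
        }
      }
    }
  }
  list(sigma_phi = sphis[best$a], sigma_psi = spsis[best$b],
       cost = cost_grid[best$ci], gamma = gamma_grid[best$gi],
       accuracy = best$acc,
       indices = c(sigma_phi = best$a, sigma_psi = best$b,
                   cost = best$ci, gamma = best$gi))
}

#' Train an SVM on a dissimilarity matrix
#'
#' Trains a support vector machine in the dissimilarity space: record i's
#' feature vector is row i of the training distance matrix, i.e. its EHECCO
#' distances to all training records, and an RBF kernel is applied on top of
#' those features (multi-class handled one-vs-one). An alternative
#' `"precomputed"` mode instead converts distances directly into the kernel
#' exp(-gamma D^2); it requires the kernlab package.
#'
#' @param D_train square symmetric training distance matrix, zero diagonal.
#' @param labels training class labels aligned with `D_train` rows.
#' @param cost SVM penalty parameter C.
#' @param gamma RBF precision parameter.
#' @param mode `"features"` (RBF on dissimilarity features, the default) or
#'   `"precomputed"` (distance-derived kernel).
#' @return classifier object of class `dissimilarity_svm`; predict with
#'   [predict_classifier()].
#' @export
train_classifier <- function(D_train, labels, cost, gamma,
                             mode = c("features", "precomputed")) {
  mode <- match.arg(mode)
  D_train <- as.matrix(D_train)
  labels <- as.character(labels)
  if (nrow(D_train) != ncol(D_train) || nrow(D_train) != length(labels))
    stop_dim(sprintf("D_train is %d x %d with %d labels",
                     nrow(D_train), ncol(D_train), length(labels)))
  if (length(unique(labels)) < 2L)
    stop_validation("training labels contain a single class")
  y <- factor(labels)
  if (mode == "features") {
    model <- e1071::svm(x = D_train, y = y, kernel = "radial", cost = cost,
                        gamma = gamma, scale = FALSE)
  } else {
    if (!requireNamespace("kernlab", quietly = TRUE))
      stop_validation("mode = 'precomputed' requires the kernlab package")
    K <- exp(-gamma * D_train^2)
    model <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, C = cost,
                           kernel = "matrix")
  }
  structure(list(model = model, mode = mode, cost = cost, gamma = gamma,
                 n_train = nrow(D_train), classes = levels(y)),
            class = "dissimilarity_svm")
}

#' Predict classes from distances to the training records
#'
#' @param classifier a [train_classifier()] result.
#' @param D_block m x n_train matrix: each row holds one record's distances
#'   to the training records, in training order.
#' @return character vector of m predicted class labels.
#' @export
predict_classifier <- function(classifier, D_block) {
  if (is.null(dim(D_block))) D_block <- matrix(D_block, nrow = 1L)
  if (ncol(D_block) != classifier$n_train)
    stop_dim(sprintf("feature length %d != number of training records %d",
                     ncol(D_block), classifier$n_train))
  if (classifier$mode == "features") {
    as.character(stats::predict(classifier$model, D_block))
  } else {
    K <- exp(-classifier$gamma * D_block^2)
    sv <- kernlab::SVindex(classifier$model)
    as.character(kernlab::predict(
      classifier$model,
      kernlab::as.kernelMatrix(K[, sv, drop = FALSE])))
  }
}

#' Cross-validated end-to-end evaluation
#'
#' Runs the full pipeline under stratified k-fold cross-validation with
#' strict train/test separation in every fold: forward kinematics, hip
#' normalization, and per-record codebooks are computed once (they involve no
#' cross-record information), then per fold the latent basis, both
#' median-heuristic base bandwidths, and all hyperparameters are fitted on
#' the training records only before the rectangular test-vs-train EHECCO
#' block is evaluated. Accuracy is trace(confusion)/N, the multi-class
#' generalization of (Tp + Tn)/N.
#'
#' @param records list of records (`pose_sequence`, hierarchy/motion pairs,
#'   or pre-flattened T x V matrices), or a `synthetic_mocap_dataset`.
#' @param labels class labels (taken from the dataset when `records` is a
#'   `synthetic_mocap_dataset`).
#' @param n_clusters codebook size Nc per record.
#' @param q latent dimension Q.
#' @param folds number of cross-validation folds (reduced with a warning when
#'   a class has fewer members).
#' @param seed master seed fixing codebooks, folds, internal grids and SVM
#'   training; two runs with the same seed are identical.
#' @param inner_folds internal folds of the per-fold grid search.
#' @param cost_grid,gamma_grid SVM grids passed to
#'   [select_hyperparameters()].
#' @param verbose print per-fold progress.
#' @return object of class `evaluation_report`: `fold_accuracies`,
#'   `mean_accuracy`, `confusion` (rows = true class), per-fold
#'   `chosen_hyperparameters`, and the per-record `predictions`.
#' @export
cross_validate <- function(records, labels = NULL, n_clusters = 50L, q = 3L,
                           folds = 10L, seed = 1L, inner_folds = 3L,
                           cost_grid = SVM_COST_GRID,
                           gamma_grid = SVM_GAMMA_GRID, verbose = FALSE) {
  if (inherits(records, "synthetic_mocap_dataset")) {
    if (is.null(labels)) labels <- records$labels
    records <- records$records
  }
  labels <- as.character(labels)
  L <- length(records)
  if (L != length(labels)) stop_dim("records and labels lengths differ")
  K <- length(unique(labels))
  if (K < 2L) stop_validation("classification needs at least 2 classes")
  min_count <- min(table(labels))
  if (min_count < folds) {
    warning(sprintf("smallest class has %d records; reducing folds from %d to %d",
                    min_count, folds, max(2L, min_count)))
    folds <- max(2L, min_count)
  }

  frames <- lapply(records, record_frames)
  codebooks <- lapply(seq_len(L), function(i)
    build_codebook(frames[[i]], n_clusters, seed = derive_seed(seed, i))$poses)

  fold_id <- make_stratified_folds(labels, folds, derive_seed(seed, 777001L))
  classes <- sort(unique(labels))
  confusion <- matrix(0L, K, K, dimnames = list(true = classes, predicted = classes))
  fold_acc <- numeric(folds)
  chosen <- vector("list", folds)
  predictions <- character(L)

  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    Xpool <- do.call(rbind, codebooks[tr])
    basis <- fit_latent_basis(Xpool, q)
    sigma0_phi <- median_heuristic_bandwidth(Xpool)
    reps <- lapply(codebooks, function(X)
      weighted_sample_set(X, project_latent(X, basis)))
    Ypool <- do.call(rbind, lapply(reps[tr], `[[`, "latent"))
    sigma0_psi <- median_heuristic_bandwidth(Ypool)

    hp <- select_hyperparameters(reps[tr], labels[tr], sigma0_phi, sigma0_psi,
                                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                                 inner_folds = inner_folds,
                                 seed = derive_seed(seed, 888000L + f))
    D_train <- pairwise_distance_matrix(reps[tr], hp$sigma_phi, hp$sigma_psi)
    clf <- train_classifier(D_train, labels[tr], cost = hp$cost, gamma = hp$gamma)
    D_test <- cross_distance_matrix(reps[te], reps[tr], hp$sigma_phi, hp$sigma_psi)
    pred <- predict_classifier(clf, D_test)
    predictions[te] <- pred
    fold_acc[f] <- mean(pred == labels[te])
    for (i in seq_along(te))
      confusion[labels[te[i]], pred[i]] <- confusion[labels[te[i]], pred[i]] + 1L
    chosen[[f]] <- data.frame(fold = f, sigma_phi = hp$sigma_phi,
                              sigma_psi = hp$sigma_psi, cost = hp$cost,
                              gamma = hp$gamma, inner_accuracy = hp$accuracy)
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.3f (sigma_phi %.3g, sigma_psi %.3g, C %g, gamma %g)",
                      f, folds, fold_acc[f], hp$sigma_phi, hp$sigma_psi,
                      hp$cost, hp$gamma))
  }
  structure(list(fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 confusion = confusion,
                 chosen_hyperparameters = do.call(rbind, chosen),
                 predictions = predictions,
                 folds = folds, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d-fold CV mean accuracy: %.3f\n",
              x$folds, x$mean_accuracy))
  cat("fold accuracies:", paste(sprintf("%.2f", x$fold_accuracies), collapse = " "), "\n")
  cat("confusion matrix (rows = true class):\n")
  print(x$confusion)
  invisible(x)
}

#' t-SNE embedding of a dissimilarity matrix
#'
#' Embeds the records in `dims` dimensions with t-distributed stochastic
#' neighbor embedding run in precomputed-distance mode (exact, theta = 0),
#' seeded for reproducibility.
#'
#' @param D square symmetric dissimilarity matrix.
#' @param dims output dimension (1, 2 or 3).
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity; must be < number of records, and is
#'   reduced with a warning when larger than (n - 1)/3 (the algorithm's
#'   admissible maximum).
#' @return n x dims coordinate matrix.
#' @export
tsne_embed <- function(D, dims = 2L, seed = 1L, perplexity = 5) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D)) stop_validation("'D' must be square")
  if (perplexity >= n)
    stop_validation(sprintf("perplexity (%g) must be smaller than the number of records (%d)",
                            perplexity, n))
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    warning(sprintf("perplexity %g too large for %d records; using %d",
                    perplexity, n, max_perp))
    perplexity <- max_perp
  }
  out <- with_seed(seed,
    Rtsne::Rtsne(D, dims = dims, perplexity = perplexity, is_distance = TRUE,
                 theta = 0.0, pca = FALSE, check_duplicates = FALSE,
                 max_iter = 1000L))
  out$Y
}

#' Correlate the embedded metric with subject covariates
#'
#' Projects the dissimilarity matrix to one dimension with t-SNE, averages
#' the projection per subject, and reports the absolute Pearson correlation
#' |r| between that per-subject mean and each numeric covariate column —
#' the linear-dependence view of how subject measurements relate to where
#' the metric places their movement records. When `labels` are supplied the
#' analysis is additionally emitted per class. The full absolute correlation
#' matrix (projection plus covariate-vs-covariate) accompanies the table.
#'
#' @param D square dissimilarity matrix over records.
#' @param subject_ids subject identifier per record.
#' @param covariates data.frame with a `subject` column and numeric
#'   measurement columns; constant columns yield `NA` with a warning.
#' @param labels optional class label per record for the per-class variant.
#' @param seed,perplexity passed to [tsne_embed()].
#' @return list: `correlations` (named |r| vector), `subject_projection`
#'   (data.frame of per-subject mean 1-D coordinates), `full_matrix`
#'   (absolute correlation matrix), and `per_class` (list of per-class |r|
#'   vectors) when `labels` are given.
#' @export
covariate_correlation <- function(D, subject_ids, covariates, labels = NULL,
                                  seed = 1L, perplexity = 5) {
  subject_ids <- as.character(subject_ids)
  if (nrow(as.matrix(D)) != length(subject_ids))
    stop_dim("subject_ids length must match D")
  if (!"subject" %in% names(covariates))
    stop_validation("covariates must contain a 'subject' column")
  missing_subj <- setdiff(unique(subject_ids), as.character(covariates$subject))
  if (length(missing_subj) > 0L)
    stop_validation(sprintf("no covariates for subject(s): %s",
                            paste(missing_subj, collapse = ", ")))
  proj <- drop(tsne_embed(D, dims = 1L, seed = seed, perplexity = perplexity))

  num_cols <- names(covariates)[vapply(covariates, is.numeric, logical(1))]
  corr_against <- function(idx) {
    subj_mean <- tapply(proj[idx], subject_ids[idx], mean)
    cv <- covariates[match(names(subj_mean), as.character(covariates$subject)), ,
                     drop = FALSE]
    r <- vapply(num_cols, function(col) {
      x <- cv[[col]]
      if (stats::sd(x) == 0 || stats::sd(subj_mean) == 0) {
        warning(sprintf("covariate '%s' (or the projection) is constant; correlation undefined", col))
        return(NA_real_)
      }
      abs(stats::cor(subj_mean, x))
    }, numeric(1))
    list(r = r, subj_mean = subj_mean, cv = cv)
  }

  pooled <- corr_against(seq_along(subject_ids))
  varying <- num_cols[vapply(pooled$cv[num_cols], function(x) stats::sd(x) > 0,
                             logical(1))]
  full <- abs(stats::cor(cbind(projection = pooled$subj_mean,
                               pooled$cv[varying])))
  out <- list(correlations = pooled$r,
              subject_projection = data.frame(subject = names(pooled$subj_mean),
                                              mean_projection = as.numeric(pooled$subj_mean)),
              full_matrix = full)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    out$per_class <- lapply(split(seq_along(labels), labels),
                            function(idx) corr_against(idx)$r)
  }
  out
}
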