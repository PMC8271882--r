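# Internal validation helpers and classed error conditions.

stop_validation <- function(msg, class = "ehecco_validation_error") {
  stop(errorCondition(msg, class = c(class, "ehecco_error")))
}

stop_dim <- function(msg) {
  stop(errorCondition(msg, class = c("ehecco_dim_error", "ehecco_error")))
}

as_sample_matrix <- function(x, arg = "x") {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L) stop_validation(sprintf("'%s' must contain at least one sample", arg))
  if (!all(is.finite(x))) stop_validation(sprintf("'%s' contains non-finite values", arg))
  x
}

check_sigma <- function(sigma, arg = "sigma") {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop_validation(sprintf("'%s' must be a single positive finite number (got %s)",
                            arg, paste(format(sigma), collapse = ", ")))
  as.numeric(sigma)
}

# Squared Euclidean cross-distance matrix via the stable expansion
# ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b, with negative round-off clamped to 0.
squared_distance_matrix <- function(A, B) {
  sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sq[sq < 0] <- 0
  sq
}

# Deterministic per-record seed derived from a master seed; kept within the
# 32-bit signed integer range R requires.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}
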