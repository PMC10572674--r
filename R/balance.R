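#' SMOTE oversampling to the majority-class count
#'
#' Synthetic Minority Oversampling: every class is grown to the size of the
#' largest class by interpolating between a randomly chosen class member `x`
#' and one of its `k` nearest same-class neighbours `x_nn` (Euclidean
#' distance): `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`. Original rows
#' are preserved unchanged and synthetic rows are appended. The effective
#' neighbourhood is `min(k, class size - 1)`.
#'
#' @param X Numeric matrix `N x D`.
#' @param y Integer class labels of length `N` (any coding; classes with a
#'   single member cannot be oversampled and raise an error).
#' @param k Number of nearest neighbours considered (default 5, the
#'   original algorithm's choice).
#' @param seed Integer seed; the output is fully determined by
#'   `(X, y, k, seed)`.
#' @return List with the balanced `X`, `y`, and `synthetic`, a logical
#'   vector marking appended rows.
#' @examples
#' X <- matrix(rnorm(40), ncol = 2)
#' y <- rep(c(0L, 1L), c(15, 5))
#' b <- smote_balance(X, y, seed = 1)
#' table(b$y) # both classes at 15
#' @export
smote_balance <- function(X, y, k = 5L, seed = 1L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y)) {
    stop_dermtex("X and y must have matching lengths", "dermtex_shape_error")
  }
  if (k < 1) stop_dermtex("k must be >= 1", "dermtex_config_error")
  y <- as.integer(y)
  counts <- table(y)
  target <- max(counts)
  new_X <- list(X)
  new_y <- list(y)
  for (cl in as.integer(names(counts))) {
    n_cl <- counts[[as.character(cl)]]
    need <- target - n_cl
    if (need == 0) next
    if (n_cl < 2) {
      stop_dermtex(sprintf("class %d has a single member and cannot be oversampled", cl),
                   "dermtex_balance_error")
    }
    Xc <- X[y == cl, , drop = FALSE]
    k_eff <- min(k, n_cl - 1)
    D <- as.matrix(stats::dist(Xc))
    diag(D) <- Inf
    # k_eff nearest same-class neighbours of each row
    ord <- apply(D, 1, function(d) order(d)[seq_len(k_eff)])
    nn <- if (k_eff == 1) matrix(ord, ncol = 1) else t(ord)
    set.seed(mix_seed(seed, cl))
    base <- sample.int(n_cl, need, replace = TRUE)
    pick <- sample.int(k_eff, need, replace = TRUE)
    u <- stats::runif(need)
    x0 <- Xc[base, , drop = FALSE]
    x1 <- Xc[nn[cbind(base, pick)], , drop = FALSE]
    new_X[[length(new_X) + 1]] <- x0 + u * (x1 - x0)
    new_y[[length(new_y) + 1]] <- rep(cl, need)
  }
  Xb <- do.call(rbind, new_X)
  yb <- unlist(new_y, use.names = FALSE)
  list(X = Xb, y = yb,
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(Xb) - nrow(X))))
}
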