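#' Configuration for the sparse PLS-DA selector
#'
#' @param n_components Latent components (selection uses component 1).
#' @param keep_x Features retained (nonzero loadings) per component.
#' @param max_nipals_iter Maximum alternating iterations per component.
#' @param tolerance Convergence tolerance on the loading update.
#' @param scale Unit-variance scale the feature columns before fitting
#'   (standard PLS-DA practice; selection is then not dominated by
#'   high-variance metabolites).
#' @param seed RNG seed (kept for interface symmetry; the fit itself is
#'   deterministic).
#' @return A validated `spls_config` list.
#' @export
spls_config <- function(n_components = 1L, keep_x = 50L,
                        max_nipals_iter = 500L, tolerance = 1e-9,
                        scale = TRUE, seed = 1L) {
  config <- list(n_components = as.integer(n_components),
                 keep_x = as.integer(keep_x),
                 max_nipals_iter = as.integer(max_nipals_iter),
                 tolerance = tolerance, scale = isTRUE(scale),
                 seed = as.integer(seed))
  if (config$n_components < 1L) stop("n_components must be >= 1")
  if (config$keep_x < 1L) stop("keep_x must be >= 1")
  if (config$tolerance <= 0) stop("tolerance must be > 0")
  structure(config, class = "spls_config")
}

#' Sparse PLS discriminant analysis as a feature selector
#'
#' One-hot codes the two-class response, centers X and Y, and extracts
#' sparse latent directions by alternating (NIPALS-style) updates of the
#' X-loading against the X-Y cross-covariance, soft-thresholded so that
#' exactly `keep_x` loadings per component are nonzero; X and Y are deflated
#' between components.  The sign convention fixes the largest-|loading|
#' feature of each component to a positive loading, making signs
#' deterministic.  The selected set is the nonzero-loading features of
#' component 1, each carrying a signed loading (beta).
#'
#' @param x Numeric samples x features matrix (typically residuals); no NA.
#' @param y Two-level factor.
#' @param config An [spls_config()].
#' @return An `spls_result`: `loadings` (named, component 1, unit norm,
#'   zeros for unselected), `selected` (nonzero-loading ids),
#'   `loading_matrix` (features x components), `converged` flags.
#' @export
spls_da_select <- function(x, y, config = spls_config()) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("feature matrix must not contain NA")
  y <- factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly 2 classes")
  stopifnot(inherits(config, "spls_config"))
  if (config$keep_x > ncol(x))
    stop("keep_x (", config$keep_x, ") exceeds the number of features (",
         ncol(x), ")")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))

  sds <- apply(x, 2L, sd)
  X <- scale(x, center = TRUE,
             scale = if (config$scale) ifelse(sds > 0, sds, 1) else FALSE)
  Y <- stats::model.matrix(~ y - 1)
  Y <- scale(Y, center = TRUE, scale = FALSE)

  soft_keep <- function(w, keep) {
    if (keep < length(w)) {
      cut <- sort(abs(w), decreasing = TRUE)[keep + 1L]
      w <- sign(w) * pmax(abs(w) - cut, 0)
    }
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w / nrm else w
  }

  p <- ncol(X)
  W <- matrix(0, p, config$n_components,
              dimnames = list(colnames(x), NULL))
  converged <- logical(config$n_components)
  for (h in seq_len(config$n_components)) {
    M <- crossprod(X, Y) # p x 2 cross-covariance
    w <- soft_keep(drop(M[, 1L]), config$keep_x)
    for (it in seq_len(config$max_nipals_iter)) {
      t_score <- drop(X %*% w)
      q <- drop(crossprod(Y, t_score))
      q <- q / sqrt(sum(q^2))
      u <- drop(Y %*% q)
      w_new <- soft_keep(drop(crossprod(X, u)), config$keep_x)
      if (sqrt(sum((w_new - w)^2)) < config$tolerance) {
        w <- w_new
        converged[h] <- TRUE
        break
      }
      w <- w_new
    }
    if (!converged[h])
      warning("sPLS-DA component ", h, " did not converge in ",
              config$max_nipals_iter, " iterations; using last iterate")
    # deterministic sign: largest-|loading| feature positive
    top <- which.max(abs(w))
    if (length(top) && w[top] < 0) w <- -w
    W[, h] <- w
    t_score <- drop(X %*% w)
    if (sum(t_score^2) > 0) {
      pload <- drop(crossprod(X, t_score)) / sum(t_score^2)
      X <- X - tcrossprod(t_score, pload)
      cq <- drop(crossprod(Y, t_score)) / sum(t_score^2)
      Y <- Y - tcrossprod(t_score, cq)
    }
  }
  loadings <- setNames(W[, 1L], colnames(x))
  structure(list(loadings = loadings,
                 selected = sort(names(loadings)[loadings != 0]),
                 loading_matrix = W, converged = converged,
                 config = config),
            class = "spls_result")
}

#' Sign-stable consensus over sPLS-DA runs
#'
#' A feature enters the consensus only if it carries a nonzero loading in
#' every run *and* the loading sign is identical across all runs — the
#' confirmation rule used when sPLS-DA replaces the shadow-feature selector.
#'
#' @param results List of `spls_result` objects aligned on the same feature
#'   ids.
#' @return Sorted character vector of consensus feature ids.
#' @export
sign_stable_consensus <- function(results) {
  if (!length(results)) stop("empty results list")
  ids <- names(results[[1L]]$loadings)
  for (r in results)
    if (!identical(names(r$loadings), ids))
      stop("results are not aligned on the same feature ids")
  signs <- vapply(results, function(r) sign(r$loadings), numeric(length(ids)))
  signs <- matrix(signs, nrow = length(ids), dimnames = list(ids, NULL))
  stable <- apply(signs, 1L, function(s) all(s != 0) && all(s == s[1L]))
  sort(ids[stable])
}

#' @export
print.spls_result <- function(x, ...) {
  cat(sprintf("sPLS-DA result: %d selected features (keep_x = %d, %d component(s))\n",
              length(x$selected), x$config$keep_x, x$config$n_components))
  invisible(x)
}
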