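#' Configuration for the shadow-feature random-forest selector
#'
#' Defaults follow the study settings: up to 1,000 iterations, confirmation /
#' rejection significance 0.01, Bonferroni correction over the currently
#' undecided features, and inverse-class-frequency ("balanced") class
#' weighting inside the forest to protect the 2:1 group imbalance.
#'
#' @param max_iter Maximum selector iterations.
#' @param alpha Significance level of the binomial hit test.
#' @param n_trees Trees per forest; `"auto"` uses
#'   `max(100, 2 * n_features)` capped at 500.
#' @param correction Multiple-testing correction over undecided features:
#'   `"bonferroni"` (classical) or `"none"`.
#' @param seed RNG seed for shadow permutations and forest fits.
#' @return A validated `boruta_config` list.
#' @export
boruta_config <- function(max_iter = 1000L, alpha = 0.01, n_trees = 300L,
                          correction = c("bonferroni", "none"), seed = 1L) {
  correction <- match.arg(correction)
  if (!identical(n_trees, "auto")) {
    n_trees <- as.integer(n_trees)
    if (n_trees < 10L) stop("n_trees must be >= 10")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(max_iter = max_iter, alpha = alpha, n_trees = n_trees,
                 correction = correction, seed = as.integer(seed)),
            class = "boruta_config")
}

#' All-relevant feature selection against shadow features
#'
#' Each iteration permutes every currently undecided feature column to create
#' "shadow" features, fits a random-forest classifier (impurity importance,
#' inverse-class-frequency class weights) on the real features that are not
#' yet rejected plus the shadows, and scores a *hit* for every undecided
#' feature whose importance strictly exceeds the maximum shadow importance.
#' After each iteration a two-sided binomial test (success probability 0.5)
#' on each undecided feature's hit count, corrected over the undecided pool,
#' confirms features in the upper tail and rejects those in the lower tail;
#' decided features leave the pool.  The run stops when the pool is empty or
#' `max_iter` is reached; remaining features are *tentative*.
#'
#' Zero-variance features are rejected up front with a warning.
#'
#' @param x Numeric samples x features matrix (typically residuals); no NA.
#' @param y Two-level factor of group labels.
#' @param config A [boruta_config()].
#' @return A `boruta_result`: `status` (named factor with levels confirmed /
#'   tentative / rejected), `hit_counts`, `n_iterations_run`,
#'   `decision_iteration` (NA for tentative), and the config.
#' @export
boruta_run <- function(x, y, config = boruta_config()) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("feature matrix must not contain NA")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(y) != 2L)
    stop("y must have exactly 2 classes, found ", nlevels(y))
  if (any(table(y) < 2L)) stop("each class needs at least 2 samples")
  stopifnot(inherits(config, "boruta_config"))

  p <- ncol(x)
  features <- colnames(x)
  status <- setNames(rep("undecided", p), features)
  hits <- setNames(integer(p), features)
  n_participated <- setNames(integer(p), features)
  decided_at <- setNames(rep(NA_integer_, p), features)

  zero_var <- apply(x, 2L, var) == 0
  if (any(zero_var)) {
    warning("rejecting ", sum(zero_var), " zero-variance feature(s)")
    status[zero_var] <- "rejected"
    decided_at[zero_var] <- 0L
  }

  class_weights <- as.numeric(length(y) / (2 * table(y)))
  n_trees <- if (identical(config$n_trees, "auto"))
    min(500L, max(100L, 2L * p)) else config$n_trees

  iter <- 0L
  while (iter < config$max_iter && any(status == "undecided")) {
    iter <- iter + 1L
    undecided <- names(status)[status == "undecided"]
    keep_real <- names(status)[status != "rejected"]
    # per-(iteration, feature) RNG streams: shadow permutations do not depend
    # on column order or on max_iter, so runs with the same seed agree on
    # their common iterations
    shadows <- vapply(undecided, function(f) {
      set.seed(derive_seeds(config$seed, sprintf("it%d:%s", iter, f)))
      sample(x[, f])
    }, numeric(nrow(x)))
    colnames(shadows) <- paste0(".shadow.", undecided)
    design <- cbind(x[, keep_real, drop = FALSE], shadows)
    fit <- ranger::ranger(x = design, y = y, num.trees = n_trees,
                          importance = "impurity",
                          class.weights = class_weights,
                          num.threads = 1L,
                          seed = derive_seeds(config$seed,
                                              sprintf("forest:it%d", iter)))
    imp <- fit$variable.importance
    shadow_max <- max(imp[colnames(shadows)])
    hit <- imp[undecided] > shadow_max
    hits[undecided] <- hits[undecided] + hit
    n_participated[undecided] <- n_participated[undecided] + 1L

    n <- n_participated[undecided]
    h <- hits[undecided]
    upper <- pbinom(h - 1L, n, 0.5, lower.tail = FALSE)
    lower <- pbinom(h, n, 0.5)
    p_two <- pmin(1, 2 * pmin(upper, lower))
    if (config$correction == "bonferroni")
      p_two <- pmin(1, p_two * length(undecided))
    confirm <- p_two < config$alpha & h > n / 2
    reject <- p_two < config$alpha & h < n / 2
    status[undecided[confirm]] <- "confirmed"
    status[undecided[reject]] <- "rejected"
    decided_at[undecided[confirm | reject]] <- iter
  }
  status[status == "undecided"] <- "tentative"
  structure(list(
    status = factor(status, levels = c("confirmed", "tentative", "rejected")),
    hit_counts = hits,
    n_participated = n_participated,
    n_iterations_run = iter,
    decision_iteration = decided_at,
    config = config), class = "boruta_result")
}

#' Confirmed features of a selector result
#' @param result A `boruta_result` (or `spls_result`).
#' @return Character vector of confirmed/selected feature ids.
#' @export
confirmed_features <- function(result) {
  if (inherits(result, "boruta_result"))
    return(names(result$status)[result$status == "confirmed"])
  if (inherits(result, "spls_result"))
    return(result$selected)
  stop("unsupported selector result of class ", class(result)[1L])
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$status)
  cat(sprintf("boruta result: %d confirmed, %d tentative, %d rejected (%d iterations)\n",
              tab[["confirmed"]], tab[["tentative"]], tab[["rejected"]],
              x$n_iterations_run))
  invisible(x)
}
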