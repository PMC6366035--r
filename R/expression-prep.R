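#' Construct an expression matrix with sample metadata
#'
#' Container for log2-scale feature x sample expression values with per-sample
#' condition/time annotation and an optional feature-to-gene map.
#'
#' @param values Numeric feature x sample matrix (log2 scale), finite.
#' @param condition Character vector per sample, e.g. `"control"` /
#'   `"irradiated"`.
#' @param time_h Non-negative numeric vector per sample (hours).
#' @param gene_map Optional named character vector mapping feature id to
#'   gene id.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition, time_h = rep(0, ncol(values)),
                              gene_map = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop_invalid("expression values must carry feature ids as rownames")
  }
  if (anyDuplicated(rownames(values))) stop_invalid("feature ids must be unique")
  if (!all(is.finite(values))) stop_invalid("expression values must be finite")
  if (length(condition) != ncol(values) || length(time_h) != ncol(values)) {
    stop_invalid("condition and time_h must annotate every sample column")
  }
  if (!is.null(gene_map)) {
    missing <- setdiff(rownames(values), names(gene_map))
    if (length(missing)) {
      stop_invalid("gene_map missing %d feature id(s)", length(missing))
    }
  }
  structure(list(values = values,
                 samples = data.frame(sample_id = colnames(values) %||%
                                        paste0("s", seq_len(ncol(values))),
                                      condition = as.character(condition),
                                      time_h = as.numeric(time_h),
                                      stringsAsFactors = FALSE),
                 gene_map = gene_map),
            class = "expression_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

# ---- Gaussian mixture noise filter --------------------------------------

# One block of EM iterations for a 1-D Gaussian mixture; vectorized E-step.
# Stops early when the absolute log-likelihood improvement drops below tol.
em_iterate <- function(x, w, mu, sdv, n_iter, tol) {
  n <- length(x)
  k <- length(mu)
  ll <- -Inf
  for (it in seq_len(n_iter)) {
    # dens[i, j] = w_j * Normal(x_i; mu_j, sd_j), computed in one sweep
    z <- outer(x, mu, `-`) / rep(sdv, each = n)
    dens <- exp(-0.5 * z * z) *
      rep(w / (sdv * sqrt(2 * pi)), each = n)
    rowtot <- .rowSums(dens, n, k)
    rowtot[rowtot < 1e-300] <- 1e-300
    ll_new <- sum(log(rowtot))
    resp <- dens / rowtot
    nk <- .colSums(resp, n, k)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- .colSums(resp * x, n, k) / nk
    sdv <- sqrt(.colSums(resp * x * x, n, k) / nk - mu^2)
    sdv[!is.finite(sdv) | sdv < 1e-4] <- 1e-4
    if (is.finite(ll) && abs(ll_new - ll) < tol) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  list(weights = w, means = mu, sds = sdv, loglik = ll)
}

# Multi-start EM for a 1-D Gaussian mixture with k components, using the
# classic short-run strategy: every start runs a small number of burn-in
# iterations, the best by likelihood is then run to convergence (absolute
# log-likelihood tolerance tol, at most max_iter iterations).
fit_gmm_1d <- function(x, k, n_starts = 100L, tol = 1e-2, max_iter = 5000L,
                       seed = NULL, short_iters = 10L) {
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      # random init: means at random data quantiles, shared moderate sd
      mu <- stats::quantile(x, sort(stats::runif(k)), names = FALSE)
      sdv <- rep(stats::sd(x) / k + 1e-3, k)
      w <- rep(1 / k, k)
      cand <- em_iterate(x, w, mu, sdv, min(short_iters, max_iter), tol)
      if (is.null(best) || cand$loglik > best$loglik) best <- cand
    }
    best <- em_iterate(x, best$weights, best$means, best$sds, max_iter, tol)
  })
  best$k <- k
  best
}

gmm_bic <- function(fit, n) {
  p <- 3 * fit$k - 1
  -2 * fit$loglik + p * log(n)
}

#' Fit a Gaussian-mixture noise model to expression summaries
#'
#' Models the distribution of per-feature log2 expression summaries as a
#' Gaussian mixture, selects the number of components by BIC, and derives a
#' noise threshold below which features are considered unexpressed. Two
#' removal rules are available:
#' \describe{
#'   \item{`top_three`}{order components by mean and keep the top
#'     `min(3, k - 1)` (the high/medium/low expression classes); the
#'     component(s) below are noise. With a single component nothing is
#'     removed.}
#'   \item{`kmeans`}{cluster the component means into a keep and a remove
#'     group with 2-means; the lower-mean group is noise.}
#' }
#' In both rules the threshold is the log2 level at which the posterior
#' probability of belonging to the kept components reaches 0.5, located
#' between the removed and kept component means.
#'
#' @param expr_summary Numeric vector of per-feature summaries (log2); for a
#'   matrix use the per-feature mean across samples (see
#'   [summarize_features()]).
#' @param k_min,k_max Range of component counts tried (defaults 2 to 8).
#' @param n_starts Random EM starts per component count (default 100).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-2).
#' @param max_iter Maximum EM iterations per start (default 5000).
#' @param rule Removal rule, `"top_three"` (default) or `"kmeans"`.
#' @param seed Integer seed for the random starts.
#' @return Object of class `noise_filter` with elements `weights`, `means`,
#'   `sds`, `n_components`, `threshold`, `kept_ids`, `removed_ids`, `rule`,
#'   `bic` (per tried k), `loglik`.
#' @export
fit_noise_model <- function(expr_summary, k_min = 2L, k_max = 8L,
                            n_starts = 100L, tol = 1e-2, max_iter = 5000L,
                            rule = c("top_three", "kmeans"), seed = 1L) {
  rule <- match.arg(rule)
  x <- as.numeric(expr_summary)
  ids <- names(expr_summary) %||% as.character(seq_along(x))
  if (k_min < 1L || k_max < k_min) stop_invalid("need 1 <= k_min <= k_max")
  if (length(x) < 3L * k_max) {
    stop_invalid("too few features (%d) for up to %d components", length(x), k_max)
  }
  ks <- k_min:k_max
  fits <- lapply(seq_along(ks), function(i) {
    fit_gmm_1d(x, ks[i], n_starts, tol, max_iter, seed = seed + i)
  })
  bic <- vapply(fits, gmm_bic, numeric(1L), n = length(x))
  fit <- fits[[which.min(bic)]]
  ord <- order(fit$means)
  w <- fit$weights[ord]; mu <- fit$means[ord]; sdv <- fit$sds[ord]
  k <- fit$k
  n_keep <- if (rule == "top_three") {
    if (k == 1L) k else min(3L, k - 1L)
  } else if (k == 1L) {
    k
  } else {
    # exact 1-D 2-means on the sorted component means: enumerate the k - 1
    # split points and keep the high-mean cluster
    wss <- vapply(seq_len(k - 1L), function(s) {
      sum((mu[1:s] - mean(mu[1:s]))^2) + sum((mu[(s + 1):k] - mean(mu[(s + 1):k]))^2)
    }, numeric(1L))
    k - which.min(wss)
  }
  keep_idx <- seq.int(k - n_keep + 1L, k)
  threshold <- if (n_keep == k) {
    min(x) - 1e-9  # nothing removed
  } else {
    posterior_boundary(w, mu, sdv, keep_idx)
  }
  kept <- x >= threshold
  structure(list(weights = w, means = mu, sds = sdv, n_components = k,
                 threshold = threshold, kept_ids = ids[kept],
                 removed_ids = ids[!kept], rule = rule,
                 bic = stats::setNames(bic, ks), loglik = fit$loglik,
                 summary_values = stats::setNames(x, ids)),
            class = "noise_filter")
}

# x where posterior P(kept | x) = 0.5, searched between the highest removed
# mean and the lowest kept mean.
posterior_boundary <- function(w, mu, sdv, keep_idx) {
  drop_idx <- setdiff(seq_along(mu), keep_idx)
  f <- function(x) {
    d <- w * stats::dnorm(x, mu, sdv)
    sum(d[keep_idx]) / sum(d) - 0.5
  }
  lo <- max(mu[drop_idx])
  hi <- min(mu[keep_idx])
  if (f(lo) > 0) return(lo)
  if (f(hi) < 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' @export
print.noise_filter <- function(x, ...) {
  cat(sprintf("Gaussian-mixture noise filter (%s rule): %d components\n",
              x$rule, x$n_components))
  cat(sprintf("  threshold = %.4f (log2); kept %d, removed %d features\n",
              x$threshold, length(x$kept_ids), length(x$removed_ids)))
  invisible(x)
}

#' Per-feature expression summary for noise filtering
#'
#' @param expr An `expression_matrix`.
#' @return Named vector of per-feature mean log2 expression across samples.
#' @export
summarize_features <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  rowMeans(expr$values)
}

#' Apply a fitted noise filter to an expression matrix
#'
#' Restricts the matrix to the features the filter kept, preserving order.
#'
#' @param expr An `expression_matrix`.
#' @param result A `noise_filter` fitted on the same feature set (or a
#'   single numeric threshold to apply to the per-feature mean summary).
#' @return Filtered `expression_matrix`; warns if everything is removed.
#' @export
apply_noise_filter <- function(expr, result) {
  stopifnot(inherits(expr, "expression_matrix"))
  ids <- rownames(expr$values)
  if (is.numeric(result) && length(result) == 1L) {
    kept <- ids[summarize_features(expr) >= result]
  } else {
    stopifnot(inherits(result, "noise_filter"))
    if (!setequal(c(result$kept_ids, result$removed_ids), ids)) {
      stop_invalid("noise filter was fitted on a different feature set")
    }
    kept <- intersect(ids, result$kept_ids)
  }
  if (!length(kept)) {
    warning("noise filter removed every feature", call. = FALSE)
  }
  out <- expr
  out$values <- expr$values[ids %in% kept, , drop = FALSE]
  out
}

#' Collapse duplicate features mapping to the same gene
#'
#' Retains, for every gene, the single feature with the highest mean
#' expression across samples; ties break to the lexicographically smallest
#' feature id.
#'
#' @param expr An `expression_matrix` with a `gene_map`.
#' @return `expression_matrix` with one feature per gene.
#' @export
collapse_duplicates <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(expr$gene_map)) {
    stop_invalid("collapse_duplicates needs a feature-to-gene map")
  }
  ids <- rownames(expr$values)
  genes <- expr$gene_map[ids]
  means <- rowMeans(expr$values)
  ord <- order(genes, -means, ids)  # per gene: highest mean first, then id
  keep <- ord[!duplicated(genes[ord])]
  out <- expr
  out$values <- expr$values[sort(keep), , drop = FALSE]
  out$gene_map <- expr$gene_map
  out
}

#' Compute experimental log2 fold changes
#'
#' `fc_j = mean(post samples) - mean(pre samples)` per feature, on the log2
#' scale — the observed fold change of feature j between the pre-treatment
#' (e.g. non-irradiated control) and post-treatment samples.
#'
#' @param expr An `expression_matrix`.
#' @param pre,post Sample selectors: logical or integer column index, or a
#'   one-argument function of the sample metadata data frame returning one.
#' @return Named numeric vector of fold changes per feature.
#' @export
#' @examples
#' m <- matrix(c(5, 6), 1, 2, dimnames = list("g1", c("a", "b")))
#' x <- expression_matrix(m, condition = c("control", "irradiated"))
#' compute_fold_change(x, pre = function(s) s$condition == "control",
#'                     post = function(s) s$condition == "irradiated")
compute_fold_change <- function(expr, pre, post) {
  stopifnot(inherits(expr, "expression_matrix"))
  resolve <- function(sel) {
    if (is.function(sel)) sel <- sel(expr$samples)
    if (is.logical(sel)) sel <- which(sel)
    sel
  }
  pre_i <- resolve(pre)
  post_i <- resolve(post)
  if (!length(pre_i) || !length(post_i)) {
    stop_invalid("pre and post selectors must each match at least one sample")
  }
  fc <- rowMeans(expr$values[, post_i, drop = FALSE]) -
    rowMeans(expr$values[, pre_i, drop = FALSE])
  fc
}
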