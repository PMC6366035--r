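#' Rank miRNAs by single-predictor explanatory power
#'
#' Fits, for every miRNA separately, the one-predictor model
#' `fc ~ dk_i * (c'_.i * miRNA_i) + b0` by least squares and records the
#' Spearman correlation between its prediction and the observed fold
#' changes, together with the refitted `dk_i`. miRNAs are ranked by
#' descending correlation (ties broken by id). Because the slope is
#' re-estimated per miRNA, the correlation is non-negative for any
#' non-degenerate column even when `dk_i` is negative — least squares flips
#' the prediction to match the data.
#'
#' A miRNA whose design column is all zero has no predictive direction; its
#' correlation is recorded as `NA` and it is ranked last.
#'
#' @param C_prime,mirna_expr,fc_observed Model inputs (see [mirimpact()]).
#' @return Object of class `mirna_ranking`: a data frame with columns
#'   `rank`, `mirna_id`, `rho_single`, `dk_single`.
#' @export
rank_mirnas <- function(C_prime, mirna_expr, fc_observed) {
  design <- build_design(C_prime, mirna_expr)
  fc <- align_fc(fc_observed, design$transcript_ids)
  res <- lapply(seq_along(design$mirna_ids), function(i) {
    a <- design$A[, i]
    if (all(a == 0)) {
      return(data.frame(mirna_id = design$mirna_ids[i],
                        rho_single = NA_real_, dk_single = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sol <- min_norm_lsq(cbind(a, 1), fc)
    pred <- a * sol$coef[1L] + sol$coef[2L]
    rho <- suppressWarnings(spearman(pred, fc))
    data.frame(mirna_id = design$mirna_ids[i], rho_single = rho,
               dk_single = sol$coef[1L], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  ord <- order(-tab$rho_single, tab$mirna_id, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  class(tab) <- c("mirna_ranking", "data.frame")
  tab
}

#' @export
print.mirna_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("miRNA ranking by single-predictor Spearman rho (%d miRNAs)\n",
              nrow(x)))
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat(sprintf("  ... %d more\n", nrow(x) - n))
  invisible(x)
}

#' Cumulative-inclusion correlation curve
#'
#' Adds miRNAs to the model one at a time — in decreasing rank order
#' (`forward`) or increasing (`reverse`) — refitting the coefficient
#' subvector and intercept at every step, and records the Spearman
#' correlation between prediction and observation at each model size. The
#' last point of either curve equals the full-model training correlation.
#' On real data the forward curve typically plateaus once the few dozen
#' influential miRNAs are in.
#'
#' @param C_prime,mirna_expr,fc_observed Model inputs.
#' @param ranking A `mirna_ranking` covering the miRNAs of `C_prime`
#'   (computed with [rank_mirnas()] if omitted).
#' @param order `"forward"` (best first) or `"reverse"` (worst first).
#' @return Object of class `cumulative_curve`: data frame with columns
#'   `n_included`, `mirna_added`, `rho`; attribute `order`.
#' @export
cumulative_curve <- function(C_prime, mirna_expr, fc_observed,
                             ranking = NULL, order = c("forward", "reverse")) {
  order <- match.arg(order)
  design <- build_design(C_prime, mirna_expr)
  fc <- align_fc(fc_observed, design$transcript_ids)
  if (is.null(ranking)) {
    ranking <- rank_mirnas(design$C_prime, design$mirna_expr, fc)
  }
  if (!setequal(ranking$mirna_id, design$mirna_ids)) {
    stop_invalid("ranking must cover exactly the miRNAs of C_prime")
  }
  ids <- ranking$mirna_id
  if (order == "reverse") ids <- rev(ids)
  rho <- numeric(length(ids))
  for (n in seq_along(ids)) {
    use <- design$mirna_ids %in% ids[seq_len(n)]
    Xn <- cbind(design$A[, use, drop = FALSE], 1)
    sol <- min_norm_lsq(Xn, fc)
    pred <- drop(Xn %*% sol$coef)
    rho[n] <- suppressWarnings(spearman(pred, fc))
  }
  out <- data.frame(n_included = seq_along(ids), mirna_added = ids, rho = rho,
                    stringsAsFactors = FALSE)
  attr(out, "order") <- order
  class(out) <- c("cumulative_curve", "data.frame")
  out
}

#' Smallest model size within tolerance of the curve maximum
#'
#' Reports the smallest number of included miRNAs whose correlation is
#' within `tol` of the maximum over the whole curve.
#'
#' @param curve A `cumulative_curve`.
#' @param tol Tolerance on the correlation (default 0.01).
#' @return Integer model size.
#' @export
plateau_size <- function(curve, tol = 0.01) {
  stopifnot(inherits(curve, "cumulative_curve"))
  rho <- curve$rho
  best <- max(rho, na.rm = TRUE)
  min(which(rho >= best - tol))
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("Cumulative-inclusion curve (%s order), %d steps\n",
              attr(x, "order"), nrow(x)))
  cat(sprintf("  final rho = %.3f; within 0.01 of maximum from n = %d\n",
              x$rho[nrow(x)], plateau_size(x)))
  invisible(x)
}

#' @export
plot.cumulative_curve <- function(x, ...) {
  plot(x$n_included, x$rho, type = "l",
       xlab = "number of miRNAs included",
       ylab = "Spearman rho (prediction vs observation)", ...)
  graphics::abline(v = plateau_size(x), lty = 2, col = "grey50")
  invisible(x)
}
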