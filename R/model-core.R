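#' Assemble the model design matrix A = C' diag(miRNA)
#'
#' Entry `A_ji = c'_ji * miRNA_i`: the impact of miRNA i on mRNA j is
#' proportional to its weighted binding-site count on that transcript and to
#' its log2 abundance. miRNAs present in C' but missing from the expression
#' vector are dropped with a warning; the intersection keeps the column
#' order of C'.
#'
#' @param C_prime Transcripts x miRNAs weighted count matrix (named dims).
#' @param mirna_expr Named (or positionally aligned) log2 miRNA abundances.
#' @return List of class `model_design`: `A`, `mirna_expr`,
#'   `transcript_ids`, `mirna_ids`, `C_prime`.
#' @export
build_design <- function(C_prime, mirna_expr) {
  C_prime <- as.matrix(C_prime)
  if (is.null(names(mirna_expr))) {
    if (length(mirna_expr) != ncol(C_prime)) {
      stop_invalid("unnamed mirna_expr must have length ncol(C_prime)")
    }
    names(mirna_expr) <- colnames(C_prime) %||% paste0("mir_", seq_along(mirna_expr))
    if (is.null(colnames(C_prime))) colnames(C_prime) <- names(mirna_expr)
  }
  common <- intersect(colnames(C_prime), names(mirna_expr))
  if (!length(common)) {
    stop_invalid("no miRNA shared between C_prime columns and mirna_expr")
  }
  dropped <- setdiff(colnames(C_prime), common)
  if (length(dropped)) {
    warning(sprintf("dropping %d miRNA(s) absent from the expression vector",
                    length(dropped)), call. = FALSE)
  }
  keep <- colnames(C_prime)[colnames(C_prime) %in% common]
  Cp <- C_prime[, keep, drop = FALSE]
  ex <- as.numeric(mirna_expr[keep])
  A <- sweep(Cp, 2L, ex, `*`)
  structure(list(A = A, mirna_expr = stats::setNames(ex, keep),
                 transcript_ids = rownames(Cp) %||%
                   paste0("mrna_", seq_len(nrow(Cp))),
                 mirna_ids = keep, C_prime = Cp),
            class = "model_design")
}

# Minimum-norm least squares via SVD: returns coefficients for the system
# X b ~ y, dropping singular values below rel_tol * max(sv).
min_norm_lsq <- function(X, y, rel_tol = 1e-10) {
  sv <- svd(X)
  d <- sv$d
  pos <- d > rel_tol * max(d, 0)
  rank <- sum(pos)
  dinv <- ifelse(pos, 1 / d, 0)
  coefs <- sv$v %*% (dinv * crossprod(sv$u, y))
  list(coef = drop(coefs), rank = rank)
}

#' Estimate perturbation coefficients by least squares
#'
#' Solves `fc ~ A dk + b0` for the per-miRNA perturbation coefficients `dk`
#' and the shared intercept `b0`, minimizing the residual sum of squares.
#' The intercept is estimated jointly by augmenting the design with a
#' constant column. Rank-deficient designs (collinear target profiles)
#' return the minimum-norm solution; fitted values are unaffected by the
#' choice and the effective rank is reported.
#'
#' @param design A `model_design` from [build_design()].
#' @param fc_observed Observed log2 fold changes, aligned with
#'   `design$transcript_ids` (names checked when present).
#' @return Object of class `mirimpact_fit`: `dk` (named), `b0`, `fitted`,
#'   `residuals`, `rho_train` (Spearman of fitted vs observed), `rank`,
#'   `design`, `fc_observed`.
#' @export
fit_least_squares <- function(design, fc_observed) {
  stopifnot(inherits(design, "model_design"))
  fc <- align_fc(fc_observed, design$transcript_ids)
  A <- design$A
  if (nrow(A) < 2L) stop_invalid("need at least 2 transcripts to fit")
  if (!all(is.finite(A)) || !all(is.finite(fc))) {
    stop_invalid("non-finite values in design or fold changes")
  }
  X <- cbind(A, `(b0)` = 1)
  sol <- min_norm_lsq(X, fc)
  dk <- sol$coef[seq_len(ncol(A))]
  names(dk) <- design$mirna_ids
  b0 <- sol$coef[ncol(A) + 1L]
  fitted <- drop(A %*% dk) + b0
  structure(list(dk = dk, b0 = b0, fitted = stats::setNames(fitted, design$transcript_ids),
                 residuals = stats::setNames(fc - fitted, design$transcript_ids),
                 rho_train = spearman(fitted, fc), rank = sol$rank,
                 design = design, fc_observed = fc),
            class = "mirimpact_fit")
}

align_fc <- function(fc, transcript_ids) {
  fc <- if (is.list(fc) && !is.null(fc$fc)) stats::setNames(fc$fc, fc$transcript_ids) else fc
  if (!is.null(names(fc))) {
    missing <- setdiff(transcript_ids, names(fc))
    if (length(missing)) {
      stop_invalid("fold changes missing for %d transcript(s)", length(missing))
    }
    fc <- fc[transcript_ids]
  } else if (length(fc) != length(transcript_ids)) {
    stop_invalid("fold-change vector length %d does not match %d transcripts",
                 length(fc), length(transcript_ids))
  }
  as.numeric(fc)
}

#' Predict fold changes from a fitted model
#'
#' `prediction = A[, subset] dk[subset] + b0`. With `subset` omitted, all
#' miRNAs contribute. Restricting to a subset reuses the already-estimated
#' coefficients (no refit).
#'
#' @param model A `mirimpact_fit`.
#' @param design Optional `model_design` to predict for (defaults to the
#'   training design).
#' @param subset Optional character vector of miRNA ids to include.
#' @return Named numeric vector of predicted log2 fold changes.
#' @export
predict_fold_change <- function(model, design = model$design, subset = NULL) {
  stopifnot(inherits(model, "mirimpact_fit"), inherits(design, "model_design"))
  ids <- design$mirna_ids
  if (is.null(subset)) subset <- ids
  unknown <- setdiff(subset, ids)
  if (length(unknown)) {
    stop_invalid("unknown miRNA id(s) in subset: %s",
                 paste(utils::head(unknown, 3L), collapse = ", "))
  }
  use <- ids %in% subset
  dk <- model$dk[ids[use]]
  pred <- drop(design$A[, use, drop = FALSE] %*% dk) + model$b0
  stats::setNames(pred, design$transcript_ids)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). Returns `NA` with a warning when either vector is constant, where
#' rank correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_invalid("spearman needs two vectors of equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Spearman correlation undefined for a constant vector",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Split-sample validation of the model
#'
#' Repeatedly partitions the transcripts into a training and a validation
#' set, estimates `(dk, b0)` on the training rows, predicts the validation
#' rows with the trained coefficients, and records the Spearman correlation
#' on both sides.
#'
#' @param C_prime Weighted target matrix.
#' @param mirna_expr log2 miRNA abundances.
#' @param fc_observed Observed fold changes.
#' @param split_fraction Fraction of transcripts in the training set
#'   (default 0.5).
#' @param n_splits Number of random splits (default 10000; histograms
#'   stabilize long before that — 1000 is usually plenty).
#' @param seed Integer seed.
#' @return Object of class `split_validation`: vectors `rho_train`,
#'   `rho_valid`, plus `split_fraction`, `n_splits`, `seed`.
#' @export
split_validate <- function(C_prime, mirna_expr, fc_observed,
                           split_fraction = 0.5, n_splits = 10000L,
                           seed = 1L) {
  design <- build_design(C_prime, mirna_expr)
  fc <- align_fc(fc_observed, design$transcript_ids)
  n <- nrow(design$A)
  n_train <- round(split_fraction * n)
  if (n_train < 2L || n - n_train < 2L) {
    stop_invalid("split leaves too few transcripts on one side")
  }
  with_seed(seed, {
    rho_tr <- numeric(n_splits)
    rho_va <- numeric(n_splits)
    for (s in seq_len(n_splits)) {
      tr <- sample(n, n_train)
      d_tr <- subset_design(design, tr)
      fit <- fit_least_squares(d_tr, fc[tr])
      d_va <- subset_design(design, -tr)
      pred_va <- predict_fold_change(fit, d_va)
      rho_tr[s] <- fit$rho_train
      rho_va[s] <- spearman(pred_va, fc[-tr])
    }
    structure(list(rho_train = rho_tr, rho_valid = rho_va,
                   split_fraction = split_fraction, n_splits = n_splits,
                   seed = seed),
              class = "split_validation")
  })
}

subset_design <- function(design, rows) {
  out <- design
  out$A <- design$A[rows, , drop = FALSE]
  out$C_prime <- design$C_prime[rows, , drop = FALSE]
  out$transcript_ids <- design$transcript_ids[rows]
  out
}

#' @export
print.split_validation <- function(x, ...) {
  cat(sprintf("Split validation: %d splits, training fraction %.2f\n",
              x$n_splits, x$split_fraction))
  cat(sprintf("  mean rho (train) = %.3f, mean rho (validation) = %.3f\n",
              mean(x$rho_train), mean(x$rho_valid)))
  invisible(x)
}

#' Matrix-randomization null controls
#'
#' Quantifies how much of the model's correlation depends on the real
#' interaction structure, using three randomization schemes:
#' \describe{
#'   \item{`uniform`}{replace C' by i.i.d. Uniform(0,1) entries, fit and
#'     predict with it;}
#'   \item{`permute`}{globally shuffle the entries of C', fit and predict
#'     with the shuffled matrix;}
#'   \item{`permute_after_fit`}{estimate `(dk, b0)` on the original C',
#'     then predict with a freshly shuffled C' each repetition.}
#' }
#' Each repetition records the Spearman correlation between the (null)
#' prediction and the observed fold changes.
#'
#' @param C_prime,mirna_expr,fc_observed Model inputs.
#' @param scheme Randomization scheme.
#' @param n_reps Number of repetitions (default 1000).
#' @param seed Integer seed.
#' @return Object of class `randomization_result` with `rho` (length
#'   `n_reps`), `scheme`, `n_reps`, `seed`.
#' @export
randomization_control <- function(C_prime, mirna_expr, fc_observed,
                                  scheme = c("uniform", "permute",
                                             "permute_after_fit"),
                                  n_reps = 1000L, seed = 1L) {
  scheme <- match.arg(scheme)
  C_prime <- as.matrix(C_prime)
  design0 <- build_design(C_prime, mirna_expr)
  fc <- align_fc(fc_observed, design0$transcript_ids)
  base_fit <- if (scheme == "permute_after_fit") {
    fit_least_squares(design0, fc)
  } else NULL
  with_seed(seed, {
    rho <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      Cr <- randomize_matrix(design0$C_prime,
                             if (scheme == "uniform") "uniform" else "permute")
      d_r <- build_design(Cr, design0$mirna_expr)
      pred <- if (scheme == "permute_after_fit") {
        predict_fold_change(base_fit, d_r)
      } else {
        fit_least_squares(d_r, fc)$fitted
      }
      rho[r] <- spearman(pred, fc)
    }
    structure(list(rho = rho, scheme = scheme, n_reps = n_reps, seed = seed),
              class = "randomization_result")
  })
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("Randomization control (%s): %d repetitions\n", x$scheme, x$n_reps))
  if (x$n_reps > 0) {
    cat(sprintf("  mean rho = %.4f (sd %.4f)\n", mean(x$rho), stats::sd(x$rho)))
  }
  invisible(x)
}
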