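#' Generate per-algorithm synthetic binding-site count tables
#'
#' Emulates the sparse, small-integer character of miRNA target-prediction
#' output. For each of the four algorithm layers, a (miRNA, transcript) pair
#' carries a site with probability `sparsity`; occupied pairs draw a count
#' from 1 + Poisson(`count_mean`) so that occupied always means at least one
#' site (a zero-inflated Poisson).
#'
#' @param n_mrna,n_mirna Positive integers: numbers of transcripts and miRNAs.
#' @param sparsity Probability in (0, 1] that a pair carries any site in a
#'   given layer.
#' @param count_mean Non-negative mean of the Poisson part; 0 makes every
#'   occupied pair carry exactly one site.
#' @param algorithms Algorithm layer names; defaults to the four standard
#'   predictors.
#' @param seed Integer seed; identical arguments give identical tables.
#' @return Data frame with columns `mirna_id`, `transcript_id`, `algorithm`,
#'   `count` containing only the nonzero records.
#' @export
generate_target_counts <- function(n_mrna, n_mirna, sparsity = 0.05,
                                   count_mean = 0.3,
                                   algorithms = names(algorithm_weights()),
                                   seed = NULL) {
  if (n_mrna < 1 || n_mirna < 1) {
    stop_invalid("n_mrna and n_mirna must be positive")
  }
  if (sparsity <= 0 || sparsity > 1) stop_invalid("sparsity must be in (0, 1]")
  if (count_mean < 0) stop_invalid("count_mean must be non-negative")
  transcript_ids <- sprintf("mrna_%04d", seq_len(n_mrna))
  mirna_ids <- sprintf("mir_%03d", seq_len(n_mirna))
  with_seed(seed, {
    out <- lapply(algorithms, function(alg) {
      occupied <- which(stats::runif(n_mrna * n_mirna) < sparsity)
      if (!length(occupied)) return(NULL)
      ri <- ((occupied - 1L) %% n_mrna) + 1L
      ci <- ((occupied - 1L) %/% n_mrna) + 1L
      data.frame(mirna_id = mirna_ids[ci],
                 transcript_id = transcript_ids[ri],
                 algorithm = alg,
                 count = 1L + stats::rpois(length(occupied), count_mean),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) {
      out <- data.frame(mirna_id = character(), transcript_id = character(),
                        algorithm = character(), count = integer(),
                        stringsAsFactors = FALSE)
    }
    attr(out, "transcript_ids") <- transcript_ids
    attr(out, "mirna_ids") <- mirna_ids
    out
  })
}

#' Generate fold changes from the linear perturbation model
#'
#' Generative use of the model itself: `fc = C' diag(mirna_expr) true_dk +
#' true_b0 + eps` with `eps ~ Normal(0, noise_sd^2)` i.i.d. With
#' `noise_sd = 0` the output equals the deterministic prediction exactly.
#'
#' @param C_prime Transcripts x miRNAs weighted count matrix.
#' @param mirna_expr log2 miRNA abundances, length `ncol(C_prime)`.
#' @param true_dk True perturbation coefficients, length `ncol(C_prime)`.
#' @param true_b0 True shared intercept (log2 FC units).
#' @param noise_sd Standard deviation of additive Gaussian noise (log2 FC).
#' @param seed Integer seed.
#' @return Numeric fold-change vector of length `nrow(C_prime)`, named by
#'   transcript if `C_prime` has rownames.
#' @export
generate_fold_changes <- function(C_prime, mirna_expr, true_dk, true_b0 = 0.1,
                                  noise_sd = 0, seed = NULL) {
  C_prime <- as.matrix(C_prime)
  if (length(mirna_expr) != ncol(C_prime) || length(true_dk) != ncol(C_prime)) {
    stop_invalid("mirna_expr and true_dk must have length ncol(C_prime) = %d",
                 ncol(C_prime))
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  fc <- drop(C_prime %*% (as.numeric(mirna_expr) * as.numeric(true_dk))) + true_b0
  if (noise_sd > 0) {
    fc <- with_seed(seed, fc + stats::rnorm(length(fc), 0, noise_sd))
  }
  names(fc) <- rownames(C_prime)
  fc
}

#' Generate UTR sequences with planted seed-complement sites
#'
#' Builds random UTRs hosting an exact, known number of seed-complement
#' sites per miRNA at non-overlapping positions, over a uniform A/C/G/T
#' background. Sequences are re-drawn whenever chance background matches (or
#' matches straddling planted sites) would distort the count, so a seed-scan
#' of the output returns exactly `insert_counts`.
#'
#' @param utr_len Length of every generated UTR (nt).
#' @param mirna_seqs Named character vector of mature miRNA sequences.
#' @param insert_counts Integer matrix (UTRs x miRNAs, miRNA columns named
#'   as `mirna_seqs`) of how many sites of each miRNA to plant in each UTR.
#' @param seed_span Seed position range, see [scan_seed_matches()].
#' @param seed Integer seed.
#' @param max_tries Redraw budget per UTR before giving up.
#' @return Named character vector of UTR sequences (DNA alphabet), one per
#'   row of `insert_counts`.
#' @export
generate_planted_sequences <- function(utr_len, mirna_seqs, insert_counts,
                                       seed_span = c(2L, 8L), seed = NULL,
                                       max_tries = 200L) {
  insert_counts <- as.matrix(insert_counts)
  if (is.null(colnames(insert_counts))) colnames(insert_counts) <- names(mirna_seqs)
  if (!setequal(colnames(insert_counts), names(mirna_seqs))) {
    stop_invalid("insert_counts columns must match names(mirna_seqs)")
  }
  insert_counts <- insert_counts[, names(mirna_seqs), drop = FALSE]
  sites <- vapply(mirna_seqs, function(m) {
    mm <- as_dna(m, "mature miRNA")
    reverse_complement(substr(mm, seed_span[1L], seed_span[2L]))
  }, character(1L))
  site_len <- nchar(sites[1L])
  per_utr_sites <- rowSums(insert_counts)
  if (any(per_utr_sites * site_len > utr_len)) {
    stop_invalid("requested insertions exceed UTR capacity (utr_len = %d)", utr_len)
  }
  with_seed(seed, {
    out <- vapply(seq_len(nrow(insert_counts)), function(u) {
      wanted <- insert_counts[u, ]
      for (try in seq_len(max_tries)) {
        s <- plant_one_utr(utr_len, sites, wanted, site_len)
        if (is.null(s)) next
        got <- vapply(seq_along(mirna_seqs), function(i) {
          scan_seed_matches(s, mirna_seqs[[i]], seed_span)
        }, integer(1L))
        if (all(got == wanted)) return(s)
      }
      stop_invalid("could not realize exact planted counts for UTR %d in %d tries",
                   u, max_tries)
    }, character(1L))
    names(out) <- if (!is.null(rownames(insert_counts))) rownames(insert_counts) else
      sprintf("utr_%03d", seq_len(nrow(insert_counts)))
    out
  })
}

# One attempt: random background, then plant all requested sites at
# non-overlapping slots. Returns NULL if a non-overlapping placement was not
# found in this attempt.
plant_one_utr <- function(utr_len, sites, wanted, site_len) {
  bg <- sample(c("A", "C", "G", "T"), utr_len, replace = TRUE)
  n_sites <- sum(wanted)
  if (n_sites > 0L) {
    # choose non-overlapping start positions by rejection
    starts <- integer(0)
    for (k in seq_len(200L)) {
      cand <- sort(sample(utr_len - site_len + 1L, n_sites))
      if (n_sites == 1L || all(diff(cand) >= site_len)) {
        starts <- cand
        break
      }
    }
    if (!length(starts)) return(NULL)
    starts <- sample(starts)  # random assignment of sites to slots
    which_site <- rep(seq_along(wanted), wanted)
    for (k in seq_len(n_sites)) {
      chars <- strsplit(sites[which_site[k]], "", fixed = TRUE)[[1L]]
      bg[starts[k]:(starts[k] + site_len - 1L)] <- chars
    }
  }
  paste(bg, collapse = "")
}

#' Draw per-feature expression levels from a two-component Gaussian mixture
#'
#' Fixture generator for the expression noise filter: i.i.d. log2-scale
#' expression summaries from a mixture of a low (noise) and a high (signal)
#' component, or any 2-component mixture.
#'
#' @param n_features Number of draws.
#' @param weights Mixture weights (length 2, summing to 1).
#' @param means,sds Component means and standard deviations (length 2,
#'   `sds > 0`), log2 units.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_features`; attribute `component`
#'   records the true component (1 or 2) of each draw.
#' @export
generate_mixture_expression <- function(n_features, weights = c(0.5, 0.5),
                                        means = c(2, 8), sds = c(1, 1),
                                        seed = NULL) {
  if (abs(sum(weights) - 1) > 1e-9) stop_invalid("mixture weights must sum to 1")
  if (any(sds <= 0)) stop_invalid("component sds must be positive")
  stopifnot(length(weights) == 2L, length(means) == 2L, length(sds) == 2L)
  with_seed(seed, {
    comp <- 1L + (stats::runif(n_features) >= weights[1L])
    x <- stats::rnorm(n_features, means[comp], sds[comp])
    attr(x, "component") <- comp
    x
  })
}

#' Simulate a complete irradiation-response dataset with known truth
#'
#' One-call generator for the full model pipeline: sparse per-algorithm
#' binding-site counts combined into C' with the default weights, log2 miRNA
#' abundances ~ Uniform(2, 12) (the typical microarray dynamic range above
#' the noise floor), a sparse true coefficient vector with `n_active`
#' nonzero entries drawn Normal(0, `dk_sd`^2), a shared intercept, and
#' observed fold changes from the model plus Gaussian noise.
#'
#' Instead of a fixed `noise_sd`, a target coefficient of determination
#' `target_r2` may be given; the noise SD is then set to
#' `sd(signal) * sqrt((1 - R2) / R2)` so the noiseless signal explains about
#' `target_r2` of the fold-change variance.
#'
#' @param n_mrna,n_mirna Numbers of transcripts and miRNAs.
#' @param n_active Number of miRNAs with nonzero true coefficient.
#' @param dk_sd SD of the nonzero true coefficients (default 0.01, the
#'   magnitude scale of estimated per-miRNA coefficients on real arrays).
#' @param b0 True shared intercept; default 0.1 (order of magnitude 1e-1).
#' @param noise_sd Gaussian noise SD on fold changes; ignored when
#'   `target_r2` is given.
#' @param target_r2 Optional target fraction of fold-change variance
#'   explained by the noiseless signal.
#' @param sparsity,count_mean Passed to [generate_target_counts()].
#' @param seed Integer seed controlling every random draw.
#' @return List of class `mirimpact_sim`: `C_prime`, `counts` (long table),
#'   `mirna_expr`, `true_dk`, `true_b0`, `noise_sd`, `fc_observed`,
#'   `fc_noiseless`, `active_set`, `seed`.
#' @export
simulate_dataset <- function(n_mrna = 3000, n_mirna = 150, n_active = 30,
                             dk_sd = 0.01, b0 = 0.1, noise_sd = 0,
                             target_r2 = NULL, sparsity = 0.05,
                             count_mean = 0.3, seed = 1L) {
  if (n_active > n_mirna) stop_invalid("n_active cannot exceed n_mirna")
  counts <- generate_target_counts(n_mrna, n_mirna, sparsity, count_mean,
                                   seed = seed)
  C_prime <- build_weighted_matrix(counts,
                                   transcript_ids = attr(counts, "transcript_ids"),
                                   mirna_ids = attr(counts, "mirna_ids"))
  with_seed(seed + 1L, {
    mirna_expr <- stats::runif(n_mirna, 2, 12)
    names(mirna_expr) <- colnames(C_prime)
    active <- sort(sample(n_mirna, n_active))
    true_dk <- numeric(n_mirna)
    true_dk[active] <- stats::rnorm(n_active, 0, dk_sd)
    names(true_dk) <- colnames(C_prime)
    fc0 <- generate_fold_changes(C_prime, mirna_expr, true_dk, b0, 0)
    if (!is.null(target_r2)) {
      stopifnot(target_r2 > 0, target_r2 < 1)
      noise_sd <- stats::sd(fc0 - b0) * sqrt((1 - target_r2) / target_r2)
    }
    fc <- fc0
    if (noise_sd > 0) fc <- fc0 + stats::rnorm(n_mrna, 0, noise_sd)
    structure(list(C_prime = C_prime, counts = counts,
                   mirna_expr = mirna_expr, true_dk = true_dk, true_b0 = b0,
                   noise_sd = noise_sd, fc_observed = fc, fc_noiseless = fc0,
                   active_set = colnames(C_prime)[active], seed = seed),
              class = "mirimpact_sim")
  })
}

#' @export
print.mirimpact_sim <- function(x, ...) {
  cat(sprintf("Synthetic miRNA-mRNA dataset: %d transcripts x %d miRNAs\n",
              nrow(x$C_prime), ncol(x$C_prime)))
  cat(sprintf("  active miRNAs: %d; true b0 = %.3g; noise SD = %.4g\n",
              length(x$active_set), x$true_b0, x$noise_sd))
  invisible(x)
}
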