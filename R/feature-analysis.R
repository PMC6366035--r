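# Parse a dot-bracket string into the pairing vector: pair[i] = j if
# position i pairs with j, NA if unpaired. Errors on unbalanced brackets.
parse_dot_bracket <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1L]]
  if (any(!chars %in% c("(", ")", "."))) {
    stop_invalid("dot-bracket string may contain only '(', ')' and '.'")
  }
  pair <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop_invalid("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair[i] <- j
      pair[j] <- i
    }
  }
  if (length(stack)) stop_invalid("unbalanced dot-bracket: unmatched '('")
  pair
}

# Lengths of maximal runs of TRUE in a logical vector.
run_lengths <- function(flag) {
  r <- rle(flag)
  r$lengths[r$values]
}

# Helix (complementary fragment) lengths: maximal runs of stacked base
# pairs, walking the 5' side of each pair in sequence order. A run
# continues while position i+1 pairs with pair(i) - 1.
helix_lengths <- function(pair) {
  five <- which(!is.na(pair) & seq_along(pair) < pair)
  if (!length(five)) return(integer(0))
  lens <- integer(0)
  cur <- 1L
  for (t in seq_along(five)[-1L]) {
    i_prev <- five[t - 1L]; i <- five[t]
    if (i == i_prev + 1L && pair[i] == pair[i_prev] - 1L) {
      cur <- cur + 1L
    } else {
      lens <- c(lens, cur)
      cur <- 1L
    }
  }
  c(lens, cur)
}

#' Compute structural features of miRNAs
#'
#' Per-miRNA features relevant to RISC loading and target binding, derived
#' from the mature sequence, the pre-miRNA sequence, its secondary structure
#' in dot-bracket notation, the weighted target matrix, and expression:
#' mature/pre-miRNA length and GC content, seed GC content, hairpin length
#' (first to last paired base on the 5' arm, inclusive), number of G:C (or
#' C:G) base pairs, number of unpaired fragments within the mature-miRNA
#' span of the duplex, mean length of complementary fragments (maximal
#' helices — runs of stacked base pairs),
#' number of targeted transcripts (`c'_ji > 0`), and log2 expression.
#'
#' The hairpin/fragment definitions are explicit conventions of this
#' package (recorded here and in the vignette) since no single community
#' standard exists.
#'
#' @param matures Named character vector of mature miRNA sequences.
#' @param premirnas Optional named character vector of pre-miRNA sequences
#'   (names matching `matures`).
#' @param structures Optional named character vector of dot-bracket strings,
#'   one per pre-miRNA, same length as the pre-miRNA sequence.
#' @param targets Optional weighted target matrix (columns = miRNA ids).
#' @param expr Optional named log2 expression vector.
#' @param seed_span Seed position range (default positions 2-8).
#' @return Data frame of class `mirna_features`, one row per miRNA.
#' @export
compute_mirna_features <- function(matures, premirnas = NULL,
                                   structures = NULL, targets = NULL,
                                   expr = NULL, seed_span = c(2L, 8L)) {
  matures <- as_named_chars(matures, "mir")
  ids <- names(matures)
  out <- data.frame(mirna_id = ids, stringsAsFactors = FALSE)
  out$mature_length <- nchar(matures)
  out$gc_mature <- vapply(matures, gc_percent, numeric(1L))
  out$gc_seed <- vapply(matures, function(m) {
    gc_percent(substr(as_dna(m), seed_span[1L], min(seed_span[2L], nchar(m))))
  }, numeric(1L))
  if (!is.null(premirnas)) {
    pre <- vapply(premirnas[ids], as_dna, character(1L))
    out$premirna_length <- nchar(pre)
    out$gc_premirna <- vapply(pre, gc_percent, numeric(1L))
  }
  if (!is.null(structures)) {
    if (is.null(premirnas)) {
      stop_invalid("structures require the pre-miRNA sequences")
    }
    feats <- lapply(ids, function(id) {
      st <- structures[[id]]
      sq <- as_dna(premirnas[[id]])
      if (nchar(st) != nchar(sq)) {
        stop_invalid("structure and pre-miRNA length differ for %s", id)
      }
      structure_features(sq, st, matures[[id]])
    })
    feats <- do.call(rbind, feats)
    out <- cbind(out, feats)
  }
  if (!is.null(targets)) {
    tm <- as.matrix(targets)
    out$n_targeted_transcripts <- vapply(ids, function(id) {
      if (id %in% colnames(tm)) sum(tm[, id] > 0) else NA_integer_
    }, numeric(1L))
  }
  if (!is.null(expr)) {
    out$expression <- as.numeric(expr[ids])
  }
  rownames(out) <- NULL
  class(out) <- c("mirna_features", "data.frame")
  out
}

# Features from one pre-miRNA dot-bracket structure.
structure_features <- function(premirna_seq, structure, mature_seq) {
  pair <- parse_dot_bracket(structure)
  paired <- !is.na(pair)
  chars <- strsplit(premirna_seq, "", fixed = TRUE)[[1L]]
  # G:C pairs: count each pair once (i < partner)
  idx <- which(paired & seq_along(pair) < pair)
  n_gc <- sum(vapply(idx, function(i) {
    all(sort(c(chars[i], chars[pair[i]])) == c("C", "G"))
  }, logical(1L)))
  # 5' arm = opening-bracket positions
  open_pos <- which(strsplit(structure, "", fixed = TRUE)[[1L]] == "(")
  hairpin_len <- if (length(open_pos)) {
    max(open_pos) - min(open_pos) + 1L
  } else 0L
  # mature span within the precursor (first exact match; NA features if absent)
  mat <- as_dna(mature_seq)
  pos <- regexpr(mat, premirna_seq, fixed = TRUE)
  if (pos > 0L) {
    span <- pos:(pos + nchar(mat) - 1L)
    n_unpaired_frag <- length(run_lengths(!paired[span]))
  } else {
    n_unpaired_frag <- NA_integer_
  }
  comp_runs <- helix_lengths(pair)
  data.frame(hairpin_length = hairpin_len,
             n_gc_pairs = n_gc,
             n_unpaired_fragments = n_unpaired_frag,
             n_complementary_fragments = length(comp_runs),
             mean_complementary_fragment_length =
               if (length(comp_runs)) mean(comp_runs) else 0,
             stringsAsFactors = FALSE)
}

#' Split miRNAs by the sign of their perturbation coefficient
#'
#' Positive `dk` means irradiation weakened the miRNA's repression (its
#' targets rise); negative means strengthened repression.
#'
#' @param model A `mirimpact_fit` (or a named numeric `dk` vector).
#' @return List with character vectors `positive`, `negative`, `zero`.
#' @export
split_by_dk_sign <- function(model) {
  dk <- if (inherits(model, "mirimpact_fit")) model$dk else model
  stopifnot(!is.null(names(dk)))
  list(positive = names(dk)[dk > 0],
       negative = names(dk)[dk < 0],
       zero = names(dk)[dk == 0])
}

# ---- Mann-Whitney U ------------------------------------------------------

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of whether two samples originate from the same
#' population. The U statistic counts pairs (a, b) with a > b, ties
#' counting one half. For group sizes both <= `exact_max` the p-value is
#' computed by exhaustive enumeration of all group assignments (exact even
#' under ties); larger groups use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest per-group size for exact enumeration (default 8).
#' @return List with `U` (statistic for sample `a`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8L) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop_invalid("both groups must be non-empty")
  U <- u_statistic(a, b)
  if (n1 <= exact_max && n2 <= exact_max) {
    # enumerate all assignments of the pooled values into groups
    pooled <- c(a, b)
    combs <- utils::combn(n1 + n2, n1)
    u_all <- apply(combs, 2L, function(ix) u_statistic(pooled[ix], pooled[-ix]))
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
    list(U = U, p_value = p, method = "exact enumeration")
  } else {
    n <- n1 + n2
    r <- rank(c(a, b))
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    mu <- n1 * n2 / 2
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    list(U = U, p_value = p, method = "normal approximation")
  }
}

u_statistic <- function(a, b) {
  sum(vapply(a, function(x) sum(x > b) + 0.5 * sum(x == b), numeric(1L)))
}

#' Compare feature distributions between two miRNA (or mRNA) groups
#'
#' Runs, for every numeric feature column, a two-sided Mann-Whitney U test
#' (default) or Welch two-sample t-test between the two groups, reporting
#' group means, the p-value and a significance flag.
#'
#' @param features Data frame with an id column (first column or
#'   `mirna_id`) and numeric feature columns.
#' @param group_a,group_b Character vectors of ids defining the groups.
#' @param test `"mann_whitney_u"` (default) or `"two_sample_t"`.
#' @param alpha Significance level for the flag (default 0.05).
#' @return Data frame of class `group_comparison` with one row per feature:
#'   `feature`, `mean_a`, `mean_b`, `p_value`, `significant`.
#' @export
compare_groups <- function(features, group_a, group_b,
                           test = c("mann_whitney_u", "two_sample_t"),
                           alpha = 0.05) {
  test <- match.arg(test)
  id_col <- if ("mirna_id" %in% names(features)) "mirna_id" else names(features)[1L]
  ids <- features[[id_col]]
  if (!length(group_a) || !length(group_b)) {
    stop_invalid("both groups must be non-empty")
  }
  num_cols <- names(features)[vapply(features, is.numeric, logical(1L))]
  rows <- lapply(num_cols, function(fn) {
    va <- features[[fn]][ids %in% group_a]
    vb <- features[[fn]][ids %in% group_b]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (length(va) < 2L || length(vb) < 2L) {
      return(data.frame(feature = fn, mean_a = mean(va), mean_b = mean(vb),
                        p_value = NA_real_, significant = NA,
                        stringsAsFactors = FALSE))
    }
    p <- if (test == "mann_whitney_u") {
      mann_whitney_u(va, vb)$p_value
    } else {
      stats::t.test(va, vb)$p.value
    }
    data.frame(feature = fn, mean_a = mean(va), mean_b = mean(vb),
               p_value = p, significant = is.finite(p) && p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "test") <- test
  attr(out, "alpha") <- alpha
  class(out) <- c("group_comparison", "data.frame")
  out
}

# ---- mRNA fit-quality classification ------------------------------------

#' Classify transcripts by model fit quality
#'
#' Splits transcripts into a good-fit and a poor-fit group by the absolute
#' difference between predicted and observed log2 fold change. A transcript
#' with `|observed - predicted| <= cutoff` is a good fit (the boundary
#' counts as good).
#'
#' @param fc_observed,fc_predicted Aligned numeric vectors.
#' @param cutoff Positive error cutoff in log2 FC units (default 0.5).
#' @return List of class `fit_classification`: `good_ids`, `poor_ids`,
#'   `abs_error` (named), `cutoff`.
#' @export
classify_mrna_fit <- function(fc_observed, fc_predicted, cutoff = 0.5) {
  if (length(fc_observed) != length(fc_predicted)) {
    stop_invalid("observed and predicted vectors must have equal length")
  }
  if (cutoff <= 0) stop_invalid("cutoff must be positive")
  ids <- names(fc_observed) %||% as.character(seq_along(fc_observed))
  err <- stats::setNames(abs(as.numeric(fc_observed) - as.numeric(fc_predicted)),
                         ids)
  structure(list(good_ids = ids[err <= cutoff], poor_ids = ids[err > cutoff],
                 abs_error = err, cutoff = cutoff),
            class = "fit_classification")
}

#' @export
print.fit_classification <- function(x, ...) {
  cat(sprintf("Fit classification at |error| cutoff %.2f: %d good, %d poor\n",
              x$cutoff, length(x$good_ids), length(x$poor_ids)))
  invisible(x)
}

#' Sweep the fit-quality cutoff and compare annotations per cutoff
#'
#' Re-classifies transcripts at every cutoff in `cutoffs` and compares each
#' numeric annotation column between the good- and poor-fit groups
#' (two-sample t-test by default, matching how transcript structural
#' features are usually compared). Larger cutoffs give (weakly) larger
#' good-fit groups, so the trajectories show how group separation evolves
#' with classification stringency.
#'
#' @param fc_observed,fc_predicted Aligned fold-change vectors (named by
#'   transcript).
#' @param annotations Data frame with transcript ids in the first column
#'   (or `transcript_id`) and numeric annotation columns (3'-UTR length,
#'   ARE counts, promoter-element counts, turnover time, ...).
#' @param cutoffs Strictly increasing positive grid (default `seq(0.1, 1,
#'   by = 0.1)`).
#' @param test Passed to [compare_groups()].
#' @return Data frame with columns `cutoff`, `n_good`, `n_poor`, `feature`,
#'   `mean_good`, `mean_poor`, `p_value`.
#' @export
sweep_fit_cutoff <- function(fc_observed, fc_predicted, annotations,
                             cutoffs = seq(0.1, 1, by = 0.1),
                             test = c("two_sample_t", "mann_whitney_u")) {
  test <- match.arg(test)
  if (any(cutoffs <= 0)) stop_invalid("all cutoffs must be positive")
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop_invalid("cutoffs must be strictly increasing")
  }
  id_col <- if ("transcript_id" %in% names(annotations)) "transcript_id" else
    names(annotations)[1L]
  out <- lapply(cutoffs, function(ct) {
    cl <- classify_mrna_fit(fc_observed, fc_predicted, ct)
    cmp <- compare_groups(
      stats::setNames(annotations, sub(paste0("^", id_col, "$"), "mirna_id",
                                       names(annotations))),
      cl$good_ids, cl$poor_ids, test = test)
    data.frame(cutoff = ct, n_good = length(cl$good_ids),
               n_poor = length(cl$poor_ids), feature = cmp$feature,
               mean_good = cmp$mean_a, mean_poor = cmp$mean_b,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
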