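#' Default target-prediction algorithm weights
#'
#' Weights used to combine per-algorithm binding-site counts into the
#' weighted target matrix C'. The defaults reflect how many prediction
#' features (text scan, binding energy, conservation, RNA folding) each
#' algorithm considers: miRanda, TargetScan and RNAhybrid each weigh 0.3,
#' the plain text-scan stage (NucleoSeq-style) 0.1.
#'
#' @return Named numeric vector of non-negative weights.
#' @export
#' @examples
#' algorithm_weights()
algorithm_weights <- function() {
  c(miranda = 0.3, targetscan = 0.3, rnahybrid = 0.3, nucleoseq = 0.1)
}

#' Count seed matches of a miRNA in a 3'-UTR sequence
#'
#' Scans a UTR for occurrences of the reverse complement (DNA alphabet) of
#' the miRNA seed region. Occurrences are counted non-overlapping, greedily
#' left to right: once a site is counted, scanning resumes after its last
#' base. Two sites cannot physically be bound at overlapping positions,
#' hence the non-overlapping convention.
#'
#' @param utr_sequence UTR nucleotide string (A/C/G/T/U, case-insensitive).
#' @param mature_mirna Mature miRNA nucleotide string.
#' @param seed_span Integer vector of length 2: first and last mature-miRNA
#'   position (1-based, inclusive) of the seed. Default `c(2, 8)`, the
#'   conventional 7-mer seed.
#' @return Non-negative integer count of seed-complement sites.
#' @export
#' @examples
#' scan_seed_matches("TCAACATCAGTCTGATAAGCTAAA", "UAGCUUAUCAGACUGAUGUUGA")
scan_seed_matches <- function(utr_sequence, mature_mirna, seed_span = c(2L, 8L)) {
  utr <- as_dna(utr_sequence, "UTR sequence")
  mat <- as_dna(mature_mirna, "mature miRNA sequence")
  stopifnot(length(seed_span) == 2L)
  seed_span <- as.integer(seed_span)
  if (seed_span[1L] < 1L || seed_span[2L] > nchar(mat) ||
      seed_span[1L] > seed_span[2L]) {
    stop_invalid("seed_span [%d, %d] outside mature miRNA of length %d",
                 seed_span[1L], seed_span[2L], nchar(mat))
  }
  seed <- substr(mat, seed_span[1L], seed_span[2L])
  site <- reverse_complement(seed)
  count_nonoverlapping(utr, site)
}

# Greedy left-to-right non-overlapping count of fixed pattern in subject.
count_nonoverlapping <- function(subject, pattern) {
  if (nchar(subject) < nchar(pattern) || nchar(pattern) == 0L) return(0L)
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(0L)
  # gregexpr with fixed = TRUE already advances past each match, which is
  # exactly the greedy non-overlapping convention.
  length(hits)
}

#' Count AU-rich element (ARE) motifs in a UTR
#'
#' Counts positions matching the destabilizing ARE consensus `TTATTTAWW`
#' (W = A or T). Because the consensus is degenerate, matches are counted
#' with overlap allowed, unlike seed sites.
#'
#' @param utr_sequence UTR nucleotide string (A/C/G/T/U).
#' @return Non-negative integer count of (possibly overlapping) matches.
#' @export
#' @examples
#' count_are_motifs("TTATTTAAA")  # 1
count_are_motifs <- function(utr_sequence) {
  utr <- as_dna(utr_sequence, "UTR sequence")
  hits <- gregexpr("(?=TTATTTA[AT][AT])", utr, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(0L)
  length(hits)
}

#' Build the weighted target-count matrix C'
#'
#' Combines per-algorithm binding-site counts into the transcripts x miRNAs
#' matrix C' with entries `c'_ji = sum_k w_k * c^k_ji`. Pairs absent from a
#' table contribute count 0 for that algorithm.
#'
#' @param tables Data frame (or list of data frames that are row-bound) with
#'   columns `mirna_id`, `transcript_id`, `algorithm`, `count`.
#' @param weights Named non-negative weights per algorithm; defaults to
#'   [algorithm_weights()]. Every algorithm appearing in `tables` must have
#'   a weight.
#' @param transcript_ids,mirna_ids Row/column identifier order for the
#'   matrix. Defaults to the sorted identifiers present in `tables`.
#' @return A `weighted_target_matrix`: a numeric matrix with `dimnames`
#'   (transcripts x miRNAs) and attribute `weights`.
#' @export
build_weighted_matrix <- function(tables, weights = algorithm_weights(),
                                  transcript_ids = NULL, mirna_ids = NULL) {
  if (is.list(tables) && !is.data.frame(tables)) {
    tables <- do.call(rbind, tables)
  }
  req <- c("mirna_id", "transcript_id", "algorithm", "count")
  if (!all(req %in% names(tables))) {
    stop_invalid("count table must have columns %s", paste(req, collapse = ", "))
  }
  if (any(weights < 0) || !any(weights > 0)) {
    stop_invalid("algorithm weights must be non-negative with at least one > 0")
  }
  if (any(tables$count < 0) || any(tables$count != round(tables$count))) {
    stop_invalid("binding-site counts must be non-negative integers")
  }
  unknown <- setdiff(unique(tables$algorithm), names(weights))
  if (length(unknown)) {
    stop_invalid("no weight configured for algorithm(s): %s",
                 paste(unknown, collapse = ", "))
  }
  key <- paste(tables$transcript_id, tables$mirna_id, tables$algorithm, sep = "\r")
  if (anyDuplicated(key)) {
    stop_invalid("duplicate (transcript, miRNA, algorithm) records in count table")
  }
  if (is.null(transcript_ids)) transcript_ids <- sort(unique(tables$transcript_id))
  if (is.null(mirna_ids)) mirna_ids <- sort(unique(tables$mirna_id))
  if (anyDuplicated(transcript_ids) || anyDuplicated(mirna_ids)) {
    stop_invalid("transcript_ids and mirna_ids must be unique")
  }
  m <- matrix(0, nrow = length(transcript_ids), ncol = length(mirna_ids),
              dimnames = list(transcript_ids, mirna_ids))
  keep <- tables$transcript_id %in% transcript_ids & tables$mirna_id %in% mirna_ids
  tb <- tables[keep, , drop = FALSE]
  if (nrow(tb)) {
    ri <- match(tb$transcript_id, transcript_ids)
    ci <- match(tb$mirna_id, mirna_ids)
    contrib <- tb$count * weights[tb$algorithm]
    # accumulate over algorithms hitting the same cell, via linear indices
    lin <- (ci - 1L) * nrow(m) + ri
    agg <- rowsum(contrib, group = lin)
    m[as.integer(rownames(agg))] <- agg[, 1L]
  }
  structure(m, weights = weights, class = c("weighted_target_matrix", "matrix", "array"))
}

#' Randomize a weighted target matrix for null-model controls
#'
#' Produces control versions of C' used to check that model performance
#' depends on the real interaction structure:
#' \describe{
#'   \item{`uniform`}{same shape, entries drawn i.i.d. Uniform(0, 1);}
#'   \item{`permute`}{all entries of C' globally shuffled (entry multiset
#'     preserved), used for both fitting and prediction;}
#'   \item{`permute_after_fit`}{same shuffle; the distinction from
#'     `permute` is downstream — parameters are estimated on the original
#'     matrix and only prediction uses the shuffled one (see
#'     [randomization_control()]).}
#' }
#'
#' @param C_prime Weighted target matrix (transcripts x miRNAs).
#' @param scheme One of `"uniform"`, `"permute"`, `"permute_after_fit"`.
#' @param seed Integer seed for reproducibility.
#' @return Matrix of the same shape and dimnames.
#' @export
randomize_matrix <- function(C_prime, scheme = c("uniform", "permute",
                                                 "permute_after_fit"),
                             seed = NULL) {
  scheme <- match.arg(scheme)
  C_prime <- as.matrix(C_prime)
  with_seed(seed, {
    out <- if (scheme == "uniform") {
      matrix(stats::runif(length(C_prime)), nrow = nrow(C_prime))
    } else {
      matrix(sample(as.numeric(C_prime)), nrow = nrow(C_prime))
    }
    dimnames(out) <- dimnames(C_prime)
    out
  })
}

#' Scan a set of UTRs against a set of miRNAs
#'
#' Applies [scan_seed_matches()] to every (UTR, miRNA) pair, producing a
#' long-format count table suitable for [build_weighted_matrix()] (the
#' in-repo text-scan stage, algorithm name `"nucleoseq"`).
#'
#' @param utrs Named character vector of UTR sequences (or
#'   `Biostrings::DNAStringSet`).
#' @param matures Named character vector of mature miRNA sequences.
#' @param seed_span Seed position range, see [scan_seed_matches()].
#' @param algorithm Algorithm label recorded in the output table.
#' @return Data frame with columns `mirna_id`, `transcript_id`,
#'   `algorithm`, `count` (zero-count pairs included).
#' @export
scan_utr_set <- function(utrs, matures, seed_span = c(2L, 8L),
                         algorithm = "nucleoseq") {
  utrs <- as_named_chars(utrs, "utr")
  matures <- as_named_chars(matures, "mirna")
  grid <- expand.grid(transcript_id = names(utrs), mirna_id = names(matures),
                      stringsAsFactors = FALSE)
  grid$algorithm <- algorithm
  grid$count <- mapply(function(tid, mid) {
    scan_seed_matches(utrs[[tid]], matures[[mid]], seed_span)
  }, grid$transcript_id, grid$mirna_id, USE.NAMES = FALSE)
  grid[, c("mirna_id", "transcript_id", "algorithm", "count")]
}

as_named_chars <- function(x, prefix) {
  if (methods::is(x, "XStringSet")) {
    x <- as.character(x)
  }
  x <- vapply(x, as.character, character(1L))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- paste0(prefix, "_", seq_along(x))
  }
  x
}
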