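# Readers and writers for the plain-text formats the pipeline exchanges:
# tab-separated count tables, expression matrices with a condition/time
# header, FASTA, Vienna dot-bracket files, and JSON sidecars.

#' Read / write a binding-site count table
#'
#' Tab-separated with header `mirna_id  transcript_id  algorithm  count`.
#'
#' @param path File path.
#' @return `read_count_table`: data frame with those four columns.
#' @export
read_count_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("mirna_id", "transcript_id", "algorithm", "count")
  if (!all(req %in% names(tb))) {
    stop_invalid("count table %s lacks required columns", path)
  }
  tb$count <- as.integer(tb$count)
  tb[, req]
}

#' @rdname read_count_table
#' @param tables Count-table data frame.
#' @export
write_count_table <- function(tables, path) {
  utils::write.table(tables[, c("mirna_id", "transcript_id", "algorithm", "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix
#'
#' Tab-separated feature x sample table with two metadata rows above the
#' data: the first row holds sample conditions, the second time points
#' (hours); the header row carries sample ids.
#'
#' @param path File path.
#' @param gene_map Optional feature-to-gene named character vector attached
#'   to the result.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, gene_map = NULL) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  condition <- as.character(unlist(body[1L, ]))
  time_h <- as.numeric(unlist(body[2L, ]))
  vals <- as.matrix(body[-(1:2), , drop = FALSE])
  mode(vals) <- "numeric"
  rownames(vals) <- ids[-(1:2)]
  expression_matrix(vals, condition, time_h, gene_map)
}

#' @rdname read_expression_matrix
#' @param expr An `expression_matrix`.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  hdr <- rbind(condition = expr$samples$condition,
               time_h = expr$samples$time_h)
  colnames(hdr) <- colnames(expr$values)
  out <- rbind(as.data.frame(hdr, stringsAsFactors = FALSE),
               as.data.frame(expr$values))
  out <- cbind(feature_id = rownames(out), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readBStringSet` returning a plain named
#' character vector in the DNA alphabet (U converted to T).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- vapply(as.character(x), as_dna, character(1L))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta_sequences <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(vapply(seqs, as_dna, character(1L)))
  names(x) <- names(seqs) %||% paste0("seq_", seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a Vienna-style dot-bracket structure file
#'
#' Records of three lines: `>id`, sequence, structure (extra fields after
#' whitespace on the structure line, such as a free energy, are dropped).
#'
#' @param path File path.
#' @return List with named character vectors `sequences` and `structures`.
#' @export
read_dot_bracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads) || any(diff(heads) < 3L) ||
      max(heads) + 2L > length(lines)) {
    stop_invalid("malformed dot-bracket file %s", path)
  }
  ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[heads]))
  seqs <- lines[heads + 1L]
  structs <- sub("\\s.*$", "", lines[heads + 2L])
  list(sequences = stats::setNames(seqs, ids),
       structures = stats::setNames(structs, ids))
}

#' Write the weighted target matrix as a sparse triplet table
#'
#' Tab-separated `transcript_id  mirna_id  weight`, nonzero entries only,
#' with an optional JSON sidecar recording the algorithm weights.
#'
#' @param C_prime Weighted target matrix.
#' @param path Output path.
#' @param sidecar Optional path for a JSON metadata file.
#' @export
write_weighted_matrix <- function(C_prime, path, sidecar = NULL) {
  m <- as.matrix(C_prime)
  nz <- which(m != 0, arr.ind = TRUE)
  tb <- data.frame(transcript_id = rownames(m)[nz[, 1L]],
                   mirna_id = colnames(m)[nz[, 2L]],
                   weight = m[nz], stringsAsFactors = FALSE)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sidecar)) {
    jsonlite::write_json(list(weights = as.list(attr(C_prime, "weights")),
                              n_transcripts = nrow(m), n_mirnas = ncol(m)),
                         sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a sparse triplet table back into a dense weighted matrix
#'
#' @param path Triplet table path (`transcript_id  mirna_id  weight`).
#' @param transcript_ids,mirna_ids Optional full identifier lists (rows or
#'   columns that are entirely zero are only recoverable when given).
#' @return Numeric matrix with dimnames.
#' @export
read_weighted_matrix <- function(path, transcript_ids = NULL, mirna_ids = NULL) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(transcript_ids)) transcript_ids <- sort(unique(tb$transcript_id))
  if (is.null(mirna_ids)) mirna_ids <- sort(unique(tb$mirna_id))
  m <- matrix(0, length(transcript_ids), length(mirna_ids),
              dimnames = list(transcript_ids, mirna_ids))
  m[cbind(match(tb$transcript_id, transcript_ids),
          match(tb$mirna_id, mirna_ids))] <- tb$weight
  m
}

#' Write a fitted model as JSON
#'
#' @param fit A `mirimpact_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "mirimpact_fit"))
  jsonlite::write_json(list(dk = as.list(fit$dk), b0 = fit$b0,
                            rho_train = fit$rho_train, rank = fit$rank),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Writes the long count table, the miRNA expression vector, the observed
#' fold changes, and a JSON sidecar with the ground-truth parameters.
#'
#' @param sim A `mirimpact_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mirimpact_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "target_counts.tsv"))
  utils::write.table(data.frame(mirna_id = names(sim$mirna_expr),
                                log2_expression = sim$mirna_expr),
                     file.path(dir, "mirna_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(transcript_id = names(sim$fc_observed),
                                log2_fc = sim$fc_observed),
                     file.path(dir, "fold_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(true_dk = as.list(sim$true_dk),
                            true_b0 = sim$true_b0, noise_sd = sim$noise_sd,
                            active_set = sim$active_set, seed = sim$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
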