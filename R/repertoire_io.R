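# Reading and writing clonotype tables.
#
# The canonical in-memory representation of a repertoire is a tibble with
# columns clone_id, v_alpha, j_alpha, cdr3_alpha, v_beta, j_beta,
# cdr3_beta, epitope, clone_count. Missing chains/labels are NA. Epitope
# labels partition the specific records; background records carry NA.
# Coincidence statistics are computed over distinct clones (one row each);
# clone_count is metadata unless count-weighting is requested explicitly.

REPERTOIRE_COLS <- c("clone_id", "v_alpha", "j_alpha", "cdr3_alpha",
                     "v_beta", "j_beta", "cdr3_beta", "epitope",
                     "clone_count")

# Strip the IMGT allele suffix ("*01") from a gene call, keeping the
# gene-level designation.
strip_allele <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  sub("\\*.*$", "", x)
}

is_canonical_cdr3 <- function(x) {
  !is.na(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

new_repertoire <- function(df, provenance = list()) {
  out <- as_tibble(df[, REPERTOIRE_COLS])
  attr(out, "provenance") <- provenance
  out
}

#' Provenance of a repertoire table
#'
#' Returns the source-file and filter log attached by the readers: input
#' row count, rows dropped for non-canonical CDR3s, rows retained.
#'
#' @param x a repertoire tibble returned by [read_airr()] or
#'   [read_paired_tsv()].
#' @return a list with elements such as `source`, `n_input`, `n_dropped`,
#'   `n_retained`.
#' @export
provenance <- function(x) attr(x, "provenance")

#' Read an AIRR Rearrangement TSV for one chain
#'
#' Reads a tab-separated file following the AIRR Rearrangement standard
#' (columns `junction_aa`, `v_call`, `j_call`, optionally
#' `duplicate_count`, `sequence_id`, `epitope`) and returns a repertoire
#' tibble with the named chain populated. Gene calls are normalized by
#' stripping the allele suffix (`"TRBV19*01"` becomes `"TRBV19"`). Rows
#' whose `junction_aa` is empty or contains characters outside the 20
#' canonical amino acid letters are dropped; the drop count is recorded in
#' [provenance()].
#'
#' @param path path to the TSV file.
#' @param chain which chain locus the file describes, `"beta"` or
#'   `"alpha"`.
#' @return a repertoire tibble (one row per clone).
#' @export
read_airr <- function(path, chain = c("beta", "alpha")) {
  chain <- match.arg(chain)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character",
                   na.strings = c("NA", ""))
  required <- c("junction_aa", "v_call", "j_call")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("missing mandatory AIRR column(s): ", paste(miss, collapse = ", "))
  }
  n_input <- nrow(df)
  keep <- is_canonical_cdr3(df$junction_aa)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  count <- if ("duplicate_count" %in% names(df)) {
    suppressWarnings(as.integer(df$duplicate_count))
  } else rep(NA_integer_, n)
  count[is.na(count) | count < 1] <- 1L
  clone_id <- if ("sequence_id" %in% names(df) && n > 0) {
    as.character(df$sequence_id)
  } else if (n > 0) sprintf("row%06d", seq_len(n)) else character(0)
  epitope <- if ("epitope" %in% names(df)) as.character(df$epitope)
             else rep(NA_character_, n)
  na <- rep(NA_character_, n)
  out <- tibble(
    clone_id = clone_id,
    v_alpha = if (chain == "alpha") strip_allele(df$v_call) else na,
    j_alpha = if (chain == "alpha") strip_allele(df$j_call) else na,
    cdr3_alpha = if (chain == "alpha") df$junction_aa else na,
    v_beta = if (chain == "beta") strip_allele(df$v_call) else na,
    j_beta = if (chain == "beta") strip_allele(df$j_call) else na,
    cdr3_beta = if (chain == "beta") df$junction_aa else na,
    epitope = epitope,
    clone_count = count
  )
  new_repertoire(out, list(source = path, format = "airr", chain = chain,
                           n_input = n_input, n_dropped = n_dropped,
                           n_retained = n))
}

#' Read a paired-chain clonotype TSV
#'
#' Reads the paired-chain dialect with columns `cdr3_alpha`, `v_alpha`,
#' `j_alpha`, `cdr3_beta`, `v_beta`, `j_beta` and optionally `epitope`,
#' `clone_count`, `clone_id`. A missing `clone_count` defaults to 1; an
#' empty `epitope` marks a background record. Rows whose non-missing CDR3
#' strings contain non-canonical letters are dropped (counted in
#' [provenance()]); rows missing both chains are dropped as well. Rows
#' sharing a `clone_id` are merged, summing their counts.
#'
#' @param path path to the TSV file.
#' @return a repertoire tibble (one row per distinct clone).
#' @export
read_paired_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character",
                   na.strings = c("NA", ""))
  required <- c("cdr3_alpha", "v_alpha", "j_alpha",
                "cdr3_beta", "v_beta", "j_beta")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  n_input <- nrow(df)
  ok_a <- is.na(df$cdr3_alpha) | is_canonical_cdr3(df$cdr3_alpha)
  ok_b <- is.na(df$cdr3_beta) | is_canonical_cdr3(df$cdr3_beta)
  has_chain <- !(is.na(df$cdr3_alpha) & is.na(df$cdr3_beta))
  keep <- ok_a & ok_b & has_chain
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  count <- if ("clone_count" %in% names(df)) {
    suppressWarnings(as.integer(df$clone_count))
  } else rep(NA_integer_, n)
  count[is.na(count) | count < 1] <- 1L
  clone_id <- if ("clone_id" %in% names(df) && n > 0) {
    as.character(df$clone_id)
  } else if (n > 0) sprintf("row%06d", seq_len(n)) else character(0)
  epitope <- if ("epitope" %in% names(df)) as.character(df$epitope)
             else rep(NA_character_, n)
  out <- tibble(
    clone_id = clone_id,
    v_alpha = strip_allele(df$v_alpha),
    j_alpha = strip_allele(df$j_alpha),
    cdr3_alpha = as.character(df$cdr3_alpha),
    v_beta = strip_allele(df$v_beta),
    j_beta = strip_allele(df$j_beta),
    cdr3_beta = as.character(df$cdr3_beta),
    epitope = epitope,
    clone_count = count
  )
  # merge rows with identical clone_id, summing counts
  if (n > 0 && anyDuplicated(out$clone_id)) {
    first <- !duplicated(out$clone_id)
    sums <- tapply(out$clone_count, out$clone_id, sum)
    merged <- out[first, , drop = FALSE]
    merged$clone_count <- as.integer(sums[merged$clone_id])
    out <- merged
  }
  new_repertoire(out, list(source = path, format = "paired_tsv",
                           n_input = n_input, n_dropped = n_dropped,
                           n_retained = nrow(out)))
}

#' Write a paired-chain clonotype TSV
#'
#' Inverse of [read_paired_tsv()]: writes the repertoire columns as a
#' tab-separated file readable by that function.
#'
#' @param table a repertoire tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_paired_tsv <- function(table, path) {
  write.table(table[, REPERTOIRE_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

SCORE_COLS <- c("feature", "conditioning", "scope", "bits",
                "ci_low", "ci_high", "n_specific", "n_background", "units")

#' Write information scores to TSV or JSON
#'
#' @param scores a data frame of information scores (rows from
#'   [relevancy()] and friends, combined with `rbind`), or a list of such
#'   rows, or an empty list/data frame (written as a header-only file).
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- if (length(scores) == 0) NULL else do.call(rbind, scores)
  }
  if (is.null(scores) || nrow(scores) == 0) {
    scores <- as_tibble(setNames(
      lapply(SCORE_COLS, function(x) character(0)), SCORE_COLS))
  } else {
    scores <- as.data.frame(scores)
    if (!"units" %in% names(scores)) scores$units <- "bits"
    scores <- scores[, intersect(SCORE_COLS, names(scores)), drop = FALSE]
  }
  if (format == "tsv") {
    write.table(scores, path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(scores, path, dataframe = "rows", na = "null",
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
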