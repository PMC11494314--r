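# Features: discrete random variables over TCR records.
#
# A feature maps each clonotype to a hashable categorical value (here a
# canonical character string) or NA when the required fields are missing.
# Records with missing values are excluded per feature from coincidence
# counting, not deleted from the table, so single-chain features use all
# available records. A product feature's values coincide iff all component
# values coincide; products are encoded by joining component values with a
# non-printing separator.

#' Construct a feature specification
#'
#' Parses the feature mini-language into a feature object usable by
#' [extract_feature()]. Recognized tokens:
#' \describe{
#'   \item{`va`, `ja`, `vb`, `jb`}{gene segment choice at a locus}
#'   \item{`cdr3a`, `cdr3b`}{CDR3 amino acid string of a chain}
#'   \item{`alpha`, `beta`}{a whole chain, defined as the product of its
#'     V gene, J gene and CDR3}
#'   \item{`tcr`}{the paired-chain receptor, product of both chains}
#'   \item{`lena`, `lenb`}{CDR3 length}
#'   \item{`chargea`, `chargeb`}{CDR3 net charge, see [net_charge()]}
#'   \item{`bowa`, `bowb`, `bowab`}{bag-of-words representation of the
#'     CDR3(s): the unordered multiset of amino acids}
#'   \item{`aa:X:cdr3a` / `aa:X:cdr3b`}{count of amino acid `X` in a CDR3}
#'   \item{`remap:<file>:cdr3a` / `remap:<file>:cdr3b`}{CDR3 remapped
#'     through the reduced alphabet stored in `<file>` (two-column TSV,
#'     see [read_alphabet()])}
#' }
#' Tokens joined with `+` form a product feature, e.g. `"vb+cdr3b"`. For
#' programmatic remapping with an in-memory [alphabet_map()], use
#' [remap_feature()].
#'
#' @param spec a mini-language string, or an existing feature object
#'   (returned unchanged).
#' @param h_weight histidine weight used by charge features (default 0).
#' @return an object of class `tcr_feature`.
#' @export
tcr_feature <- function(spec, h_weight = 0) {
  if (inherits(spec, "tcr_feature")) return(spec)
  stopifnot(is.character(spec), length(spec) == 1)
  toks <- strsplit(spec, "+", fixed = TRUE)[[1]]
  leaves <- list()
  for (tok in toks) leaves <- c(leaves, leaves_for_token(tok, h_weight))
  structure(list(name = spec, leaves = leaves), class = "tcr_feature")
}

#' @export
print.tcr_feature <- function(x, ...) {
  cat("<tcr_feature> ", x$name, " (", length(x$leaves), " leaf",
      if (length(x$leaves) != 1) "s", ")\n", sep = "")
  invisible(x)
}

chain_cdr3_col <- function(tok) {
  switch(tok,
    cdr3a = "cdr3_alpha", cdr3b = "cdr3_beta",
    stop("expected 'cdr3a' or 'cdr3b', got '", tok, "'"))
}

leaves_for_token <- function(tok, h_weight = 0) {
  if (grepl("^aa:", tok)) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("malformed aa token: '", tok, "'")
    aa <- toupper(parts[2])
    if (!aa %in% AA_LETTERS) stop("unknown amino acid: '", parts[2], "'")
    return(list(list(kind = "aa", col = chain_cdr3_col(parts[3]), aa = aa)))
  }
  if (grepl("^remap:", tok)) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("malformed remap token: '", tok, "'")
    map <- read_alphabet(parts[2])
    return(list(list(kind = "remap", col = chain_cdr3_col(parts[3]),
                     map = map)))
  }
  gene <- function(col) list(kind = "gene", col = col)
  cdr3 <- function(col) list(kind = "cdr3", col = col)
  switch(tok,
    va = list(gene("v_alpha")), ja = list(gene("j_alpha")),
    vb = list(gene("v_beta")),  jb = list(gene("j_beta")),
    cdr3a = list(cdr3("cdr3_alpha")), cdr3b = list(cdr3("cdr3_beta")),
    lena = list(list(kind = "length", col = "cdr3_alpha")),
    lenb = list(list(kind = "length", col = "cdr3_beta")),
    chargea = list(list(kind = "charge", col = "cdr3_alpha",
                        h_weight = h_weight)),
    chargeb = list(list(kind = "charge", col = "cdr3_beta",
                        h_weight = h_weight)),
    bowa = list(list(kind = "bow", col = "cdr3_alpha")),
    bowb = list(list(kind = "bow", col = "cdr3_beta")),
    bowab = list(list(kind = "bow", col = "cdr3_alpha"),
                 list(kind = "bow", col = "cdr3_beta")),
    alpha = list(gene("v_alpha"), gene("j_alpha"), cdr3("cdr3_alpha")),
    beta = list(gene("v_beta"), gene("j_beta"), cdr3("cdr3_beta")),
    tcr = list(gene("v_alpha"), gene("j_alpha"), cdr3("cdr3_alpha"),
               gene("v_beta"), gene("j_beta"), cdr3("cdr3_beta")),
    stop("unknown feature token: '", tok, "'")
  )
}

#' Feature remapped through a reduced alphabet
#'
#' Builds a feature whose value is a chain's CDR3 translated through a
#' reduced amino acid alphabet (the `R(CDR3)` representation).
#'
#' @param alphabet an [alphabet_map()].
#' @param chain `"beta"`, `"alpha"` or `"both"` (product of both chains).
#' @return a `tcr_feature`.
#' @export
remap_feature <- function(alphabet, chain = c("beta", "alpha", "both")) {
  chain <- match.arg(chain)
  leaf <- function(col) list(kind = "remap", col = col, map = alphabet)
  leaves <- switch(chain,
    beta = list(leaf("cdr3_beta")),
    alpha = list(leaf("cdr3_alpha")),
    both = list(leaf("cdr3_alpha"), leaf("cdr3_beta")))
  structure(list(name = paste0("remap(", attr(alphabet, "label") %||% "",
                               "):", chain),
                 leaves = leaves), class = "tcr_feature")
}

leaf_values <- function(tab, leaf) {
  s <- as.character(tab[[leaf$col]])
  switch(leaf$kind,
    gene = s,
    cdr3 = s,
    length = ifelse(is.na(s), NA_character_, as.character(nchar(s))),
    charge = as.character(net_charge(s, h_weight = leaf$h_weight %||% 0)),
    bow = bow_key(s),
    aa = as.character(aa_content(s, leaf$aa)),
    remap = remap(s, leaf$map),
    stop("unknown feature kind: '", leaf$kind, "'")
  )
}

#' Extract a feature column from a repertoire table
#'
#' Maps every record to its (canonical, hashable) feature value. The value
#' is `NA` when any field the feature needs is missing for that record; a
#' product feature is missing if any component is. Extraction is
#' deterministic and pure.
#'
#' @param table a repertoire tibble.
#' @param feature a mini-language string or `tcr_feature`.
#' @return a character vector, one value (or `NA`) per record.
#' @export
extract_feature <- function(table, feature) {
  f <- tcr_feature(feature)
  vals <- lapply(f$leaves, leaf_values, tab = table)
  if (length(vals) == 1) return(vals[[1]])
  out <- do.call(paste, c(vals, sep = FEATURE_SEP))
  out[Reduce(`|`, lapply(vals, is.na))] <- NA_character_
  out
}

#' CDR3 net charge
#'
#' Net charge of an amino acid string: (number of K, R) minus (number of
#' D, E). Histidine contributes `h_weight` (default 0; set 1 or a
#' fractional weight to count it as positively charged, in which case
#' values are binned to one decimal before being used as feature values).
#'
#' @param cdr3 character vector of amino acid strings.
#' @param h_weight charge assigned to histidine.
#' @return numeric vector (integer-valued when `h_weight` is integer).
#' @export
net_charge <- function(cdr3, h_weight = 0) {
  cdr3 <- as.character(cdr3)
  n_of <- function(pattern) nchar(cdr3) - nchar(gsub(pattern, "", cdr3))
  val <- n_of("[KR]") - n_of("[DE]") + h_weight * n_of("H")
  if (h_weight %% 1 != 0) val <- round(val, 1)
  val
}

#' Count of one amino acid in a CDR3
#'
#' @param cdr3 character vector of amino acid strings.
#' @param aa a single one-letter amino acid code.
#' @return integer vector of multiplicities.
#' @export
aa_content <- function(cdr3, aa) {
  stopifnot(is.character(aa), length(aa) == 1, nchar(aa) == 1)
  cdr3 <- as.character(cdr3)
  as.integer(nchar(cdr3) - nchar(gsub(aa, "", cdr3, fixed = TRUE)))
}

#' Bag-of-words representation of CDR3 sequences
#'
#' The unordered multiset of amino acids in each string, as a matrix of
#' counts with one column per canonical amino acid. Two sequences coincide
#' in the bag-of-words feature iff their count vectors are equal (all
#' positional information discarded).
#'
#' @param cdr3 character vector of amino acid strings.
#' @return an integer matrix, `length(cdr3)` rows by 20 columns.
#' @export
bag_of_words <- function(cdr3) {
  cdr3 <- as.character(cdr3)
  m <- vapply(AA_LETTERS, function(a) aa_content(cdr3, a),
              integer(length(cdr3)))
  if (length(cdr3) == 1) m <- matrix(m, nrow = 1,
                                     dimnames = list(NULL, AA_LETTERS))
  m
}

# Canonical hash of the bag-of-words value: the sorted letter string.
# Equal sorted strings <=> equal count vectors.
bow_key <- function(cdr3) {
  vapply(strsplit(as.character(cdr3), "", fixed = TRUE),
         function(l) if (length(l) == 1 && is.na(l[1])) NA_character_
                     else paste(sort(l), collapse = ""),
         character(1))
}
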