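# Reduced amino acid alphabets: surjective maps from the 20 canonical
# amino acids onto k group symbols. Remapping a CDR3 through such a map
# compresses it; the relevancy retained by the remapped feature measures
# how much specificity information survives the compression. Group
# symbols are canonical: each group is labelled by its lexicographically
# first member, so two maps inducing the same partition compare equal.

#' Construct a reduced amino acid alphabet
#'
#' @param mapping a character vector mapping each of the 20 canonical
#'   amino acids (names) to a group symbol (values). All 20 letters must
#'   be mapped. Group symbols are canonicalized to the lexicographically
#'   first amino acid of each group.
#' @param label optional provenance string.
#' @return an `alphabet_map`: a named character vector with attributes
#'   `k` (number of groups) and `label`.
#' @export
alphabet_map <- function(mapping, label = NULL) {
  if (is.null(names(mapping)) || !setequal(names(mapping), AA_LETTERS)) {
    stop("mapping must name all 20 canonical amino acids")
  }
  mapping <- mapping[AA_LETTERS]
  groups <- split(names(mapping), unname(mapping))
  sym <- vapply(groups, function(g) sort(g)[1], character(1))
  canon <- setNames(sym[match(unname(mapping), names(groups))],
                    names(mapping))
  structure(canon, class = "alphabet_map", k = length(groups),
            label = label %||% paste0("k", length(groups)))
}

#' @export
print.alphabet_map <- function(x, ...) {
  cat("<alphabet_map> ", attr(x, "label"), " (k = ", attr(x, "k"),
      ")\n", sep = "")
  for (g in sort(unique(unname(x)))) {
    cat("  ", g, ": ", paste(sort(names(x)[x == g]), collapse = ""),
        "\n", sep = "")
  }
  invisible(x)
}

#' Identity (20-letter) alphabet
#' @return an [alphabet_map()] mapping each amino acid to itself.
#' @export
identity_alphabet <- function() {
  alphabet_map(setNames(AA_LETTERS, AA_LETTERS), label = "identity")
}

#' Read / write an alphabet file
#'
#' Alphabet files are two-column TSVs with columns `amino_acid` and
#' `group`.
#'
#' @param path file path.
#' @return [read_alphabet()] returns an [alphabet_map()];
#'   [write_alphabet()] returns `path` invisibly.
#' @export
read_alphabet <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("amino_acid", "group") %in% names(df))) {
    stop("alphabet file needs columns 'amino_acid' and 'group'")
  }
  alphabet_map(setNames(df$group, df$amino_acid), label = basename(path))
}

#' @rdname read_alphabet
#' @param alphabet an [alphabet_map()].
#' @export
write_alphabet <- function(alphabet, path) {
  write.table(data.frame(amino_acid = names(alphabet),
                         group = unname(alphabet)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remap sequences through a reduced alphabet
#'
#' Translates every amino acid of each string to its group symbol. String
#' length is preserved; composing two remaps equals remapping by the
#' composed map.
#'
#' @param seq character vector of amino acid strings (`NA` propagates).
#' @param alphabet an [alphabet_map()].
#' @return character vector over group symbols.
#' @export
remap <- function(seq, alphabet) {
  chartr(paste(names(alphabet), collapse = ""),
         paste(unname(alphabet), collapse = ""),
         as.character(seq))
}

#' Built-in amino acid property scales
#'
#' One-dimensional biophysical property scales shipped with the package
#' (configuration data, not hard-coded): Grantham (1974) polarity,
#' Eisenberg & McLachlan (1986) solvation free energy, Fauchere et
#' al. (1988) normalized van der Waals volume, Levitt (1976) side-chain
#' radius of gyration, Chothia (1976) accessible surface area in a
#' tripeptide.
#'
#' @return a data frame with column `amino_acid` and one numeric column
#'   per scale.
#' @export
aa_property_scales <- function() {
  read.delim(system.file("extdata", "aa_property_scales.tsv",
                         package = "tcrinfo"),
             sep = "\t", stringsAsFactors = FALSE)
}

#' Alphabet from hierarchical clustering of a property scale
#'
#' Agglomerative (complete-linkage) clustering of the amino acids by a
#' one-dimensional property value, cut at k groups. Complete linkage on a
#' 1-D scale yields contiguous value intervals, i.e. a grouping "by
#' property".
#'
#' @param scale a named numeric vector of per-amino-acid values (all 20
#'   letters), or the name of a built-in scale from
#'   [aa_property_scales()].
#' @param k number of groups (1..20).
#' @return an [alphabet_map()].
#' @export
property_cluster_alphabet <- function(scale, k) {
  stopifnot(k >= 1, k <= 20)
  if (is.character(scale) && length(scale) == 1) {
    tab <- aa_property_scales()
    if (!scale %in% names(tab)) {
      stop("unknown built-in scale '", scale, "'; available: ",
           paste(setdiff(names(tab), "amino_acid"), collapse = ", "))
    }
    scale <- setNames(tab[[scale]], tab$amino_acid)
  }
  if (is.null(names(scale)) || !setequal(names(scale), AA_LETTERS)) {
    stop("scale must name all 20 canonical amino acids")
  }
  scale <- scale[AA_LETTERS]
  grp <- if (k == 20) seq_len(20) else {
    cutree(hclust(dist(scale), method = "complete"), k = k)
  }
  alphabet_map(setNames(as.character(grp), AA_LETTERS),
               label = paste0("property:k", k))
}

# Relevancy (bits) of remapped CDR3 feature(s); -Inf when undefined.
remap_bits <- function(part, spec_seqs, eps, bg_seqs, weights,
                       warn = TRUE) {
  from <- paste(AA_LETTERS, collapse = "")
  to <- paste(part[AA_LETTERS], collapse = "")
  tr <- function(sl) {
    mapped <- lapply(sl, chartr, old = from, new = to)
    if (length(mapped) == 1) mapped[[1]]
    else do.call(paste, c(mapped, sep = FEATURE_SEP))
  }
  pcs <- pc_conditional(tr(spec_seqs), eps, weights = weights)$p_hat
  pcb <- pc_pairs(tr(bg_seqs))$p_hat
  if (is.na(pcs) || is.na(pcb) || pcs <= 0 || pcb <= 0) {
    if (warn) warning("relevancy undefined for a candidate alphabet ",
                      "(zero coincidences); scored as -Inf")
    return(-Inf)
  }
  log2(pcs / pcb)
}

feature_base_cols <- function(feature_base) {
  switch(feature_base,
    cdr3b = "cdr3_beta", cdr3a = "cdr3_alpha",
    both = c("cdr3_alpha", "cdr3_beta"),
    stop("feature_base must be 'cdr3a', 'cdr3b' or 'both'"))
}

extract_base_seqs <- function(tab, cols) {
  sl <- lapply(cols, function(cl) as.character(tab[[cl]]))
  keep <- !Reduce(`|`, lapply(sl, is.na))
  list(seqs = lapply(sl, `[`, keep), keep = keep)
}

#' Greedy search for an information-optimal reduced alphabet
#'
#' Agglomerative greedy search: starting from 20 singleton groups,
#' repeatedly merge the pair of groups whose merge maximizes the
#' relevancy of the remapped CDR3 feature(s), until k groups remain. Ties
#' are broken lexicographically by group symbol. At k = 20 the retained
#' information equals the unreduced CDR3 relevancy; at k = 1 only the
#' sequence length survives.
#'
#' @param specific repertoire tibble of epitope-labeled clones.
#' @param background repertoire tibble of background clones.
#' @param k target number of groups.
#' @param feature_base which CDR3(s) the alphabet is scored on:
#'   `"cdr3b"`, `"cdr3a"`, or `"both"` (product feature).
#' @param weights epitope weighting for the rho2 average.
#' @return a list with elements `alphabet` (the final [alphabet_map()]),
#'   `bits` (its retained relevancy) and `trace` (tibble of the retained
#'   bits after each merge, columns `k`, `bits`).
#' @export
greedy_optimal_alphabet <- function(specific, background, k = 2,
                                    feature_base = "cdr3b",
                                    weights = "uniform") {
  stopifnot(k >= 1, k <= 20)
  cols <- feature_base_cols(feature_base)
  sp <- extract_base_seqs(specific, cols)
  eps <- as.character(specific$epitope)[sp$keep]
  bg <- extract_base_seqs(background, cols)
  part <- setNames(AA_LETTERS, AA_LETTERS)
  score <- function(p) remap_bits(p, sp$seqs, eps, bg$seqs, weights)
  bits <- score(part)
  trace_k <- 20L
  trace_bits <- bits
  while (length(unique(part)) > k) {
    gs <- sort(unique(unname(part)))
    best_bits <- -Inf
    best_part <- NULL
    for (i in seq_len(length(gs) - 1)) {
      for (j in (i + 1):length(gs)) {
        cand <- part
        cand[cand == gs[j]] <- gs[i]
        s <- score(cand)
        if (s > best_bits) {  # ties keep the first (lexicographic) pair
          best_bits <- s
          best_part <- cand
        }
      }
    }
    part <- best_part
    bits <- best_bits
    trace_k <- c(trace_k, length(unique(part)))
    trace_bits <- c(trace_bits, bits)
  }
  list(alphabet = alphabet_map(part, label = paste0("greedy:k", k)),
       bits = bits,
       trace = tibble(k = trace_k, bits = trace_bits))
}

#' Score a set of alphabets by retained relevancy
#'
#' Evaluates the relevancy retained by each alphabet's remapped CDR3
#' feature and flags Pareto-optimal alphabets: those not dominated by any
#' alphabet with no more groups and no less information (one strictly
#' better).
#'
#' @inheritParams greedy_optimal_alphabet
#' @param alphabets a (optionally named) list of [alphabet_map()]s.
#' @return a tibble with columns `label`, `k`, `bits`, `pareto`.
#' @export
alphabet_scoreboard <- function(specific, background, alphabets,
                                feature_base = "cdr3b",
                                weights = "uniform") {
  if (length(alphabets) == 0) {
    return(tibble(label = character(0), k = integer(0),
                  bits = numeric(0), pareto = logical(0)))
  }
  cols <- feature_base_cols(feature_base)
  sp <- extract_base_seqs(specific, cols)
  eps <- as.character(specific$epitope)[sp$keep]
  bg <- extract_base_seqs(background, cols)
  labs <- names(alphabets) %||%
    vapply(alphabets, function(a) attr(a, "label") %||% "", character(1))
  k <- vapply(alphabets, function(a) attr(a, "k"), numeric(1))
  bits <- vapply(alphabets, function(a)
    remap_bits(a, sp$seqs, eps, bg$seqs, weights), numeric(1))
  dominated <- vapply(seq_along(alphabets), function(i) {
    any(k <= k[i] & bits >= bits[i] & (k < k[i] | bits > bits[i]))
  }, logical(1))
  tibble(label = labs, k = as.integer(k), bits = bits,
         pareto = !dominated)
}
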