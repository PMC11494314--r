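# Programmatic fixtures: toy repertoire tables and planted-structure
# generators shared across test files.

# minimal repertoire tibble; any column can be overridden
toy_repertoire <- function(n, cdr3_beta = NULL, cdr3_alpha = NULL,
                           v_beta = NULL, j_beta = NULL, v_alpha = NULL,
                           j_alpha = NULL, epitope = NULL,
                           clone_count = NULL) {
  fill <- function(x, default) if (is.null(x)) rep(default, n) else x
  tibble::tibble(
    clone_id = sprintf("c%04d", seq_len(n)),
    v_alpha = fill(v_alpha, NA_character_),
    j_alpha = fill(j_alpha, NA_character_),
    cdr3_alpha = fill(cdr3_alpha, NA_character_),
    v_beta = fill(v_beta, NA_character_),
    j_beta = fill(j_beta, NA_character_),
    cdr3_beta = fill(cdr3_beta, NA_character_),
    epitope = fill(epitope, NA_character_),
    clone_count = fill(clone_count, 1L)
  )
}

rand_seqs <- function(n, len, letters = AA20) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Data with a planted binary partition of the amino acids: specificity
# depends only on the image of the CDR3 under the planted 2-letter map.
# Background CDR3s are i.i.d. uniform over all 20 letters; specific
# CDR3s follow a fixed group pattern (uniform within the pattern's group
# at each position), so the planted partition is the unique maximally
# informative 2-letter alphabet.
planted_partition_data <- function(n_spec = 800, n_bg = 3200,
                                   seed = 71,
                                   pattern = c("A", "B", "B", "A")) {
  group_a <- AA20[1:10]
  group_b <- AA20[11:20]
  set.seed(seed)
  bg <- rand_seqs(n_bg, length(pattern))
  sp <- vapply(seq_len(n_spec), function(i) {
    paste(vapply(pattern, function(g) {
      sample(if (g == "A") group_a else group_b, 1)
    }, character(1)), collapse = "")
  }, character(1))
  list(
    specific = toy_repertoire(n_spec, cdr3_beta = sp, epitope = "e1"),
    background = toy_repertoire(n_bg, cdr3_beta = bg),
    partition = setNames(c(rep("A", 10), rep("B", 10)), AA20)
  )
}

# uniform background over all strings of `len` letters from `alphabet`;
# specific uniform over the subset whose first letter is alphabet[1].
# The letter-swap symmetry of the space makes the fuzzy-match
# cross-coincidence term equal the background near-coincidence
# probability exactly at every distance.
binary_string_space <- function(len = 4, alphabet = c("A", "G")) {
  grid <- expand.grid(rep(list(alphabet), len), stringsAsFactors = FALSE)
  strings <- apply(grid, 1, paste, collapse = "")
  list(strings = strings,
       spec = strings[substr(strings, 1, 1) == alphabet[1]])
}
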