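# Fixture builders shared across test files; everything is generated in
# code at test time.

toy_counts <- function() {
  matrix(c(3, 7, 2,
           5, 5, 9,
           8, 1, 30), nrow = 3,
         dimnames = list(c("g1", "g2", "g3"), c("L1", "L2", "L3")))
}

toy_dataset <- function(totals = NULL) mdeq_data(toy_counts(), totals)

# dataset with two libraries of given (N, T) for a single gene "g"
pair_dataset <- function(n1, t1, n2, t2) {
  mdeq_data(matrix(c(n1, n2), 1, 2, dimnames = list("g", c("A", "B"))),
            totals = c(A = t1, B = t2))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

count_tsv_lines <- function(m, totals = NULL) {
  header <- paste(c("id", colnames(m)), collapse = "\t")
  rows <- apply(cbind(rownames(m), m), 1, paste, collapse = "\t")
  if (!is.null(totals))
    rows <- c(paste(c("TOTAL", totals), collapse = "\t"), rows)
  c(header, rows)
}

# random crisp annotation over a named probability vector
random_annotation <- function(universe, n_terms, term_size, seed = 1) {
  set.seed(seed)
  sets <- lapply(seq_len(n_terms), function(i)
    sample(universe, term_size))
  names(sets) <- sprintf("T%03d", seq_len(n_terms))
  annotation_set(sets)
}

# Mann-Whitney pair-counting AUC oracle: ties get half credit
auc_pair_oracle <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
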