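# Question language: chained strict inequalities over library, group and
# pool operands, combined with AND/OR (AND binds tighter), parentheses for
# grouping. "A < B < C" desugars to AND(A<B, B<C). "A,B" is a replicate
# group (beta mixture); "A+B" is a pool (counts and totals summed before the
# posterior is formed).

# ---- tokenizer ----

tokenize_question <- function(text) {
  n <- nchar(text)
  toks <- list()
  i <- 1
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1; next }
    if (ch %in% c("<", ">", "(", ")", ",", "+")) {
      toks[[length(toks) + 1]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z0-9_.:-]+", substr(text, i, n)))
    if (length(m) == 0)
      stop("question parse error at position ", i,
           ": unexpected character '", ch, "'", call. = FALSE)
    type <- if (toupper(m) %in% c("AND", "OR")) toupper(m) else "id"
    toks[[length(toks) + 1]] <- list(type = type, value = m, pos = i)
    i <- i + nchar(m)
  }
  toks
}

# ---- recursive-descent parser ----

# parser state: token list + cursor, passed in an environment
new_parser <- function(toks, text) {
  e <- new.env(parent = emptyenv())
  e$toks <- toks; e$i <- 1L; e$text <- text
  e
}
peek <- function(p) if (p$i <= length(p$toks)) p$toks[[p$i]] else NULL
advance <- function(p) { t <- peek(p); p$i <- p$i + 1L; t }
parse_fail <- function(p, msg) {
  t <- peek(p)
  where <- if (is.null(t)) "end of question" else
    paste0("token ", p$i, " ('", t$value, "', position ", t$pos, ")")
  stop("question parse error at ", where, ": ", msg, call. = FALSE)
}

parse_operand <- function(p) {
  t <- peek(p)
  if (is.null(t) || t$type != "id")
    parse_fail(p, "expected a library id")
  ids <- advance(p)$value
  sep <- NULL
  repeat {
    t <- peek(p)
    if (is.null(t) || !(t$type %in% c(",", "+"))) break
    if (is.null(sep)) sep <- t$type
    else if (sep != t$type)
      parse_fail(p, "cannot mix ',' (group) and '+' (pool) in one operand")
    advance(p)
    t <- peek(p)
    if (is.null(t) || t$type != "id")
      parse_fail(p, paste0("expected a library id after '", sep, "'"))
    ids <- c(ids, advance(p)$value)
  }
  type <- if (is.null(sep)) "lib" else if (sep == ",") "group" else "pool"
  list(node = "operand", type = type, ids = ids)
}

parse_clause <- function(p) {
  left <- parse_operand(p)
  cmps <- list()
  repeat {
    t <- peek(p)
    if (is.null(t) || !(t$type %in% c("<", ">"))) break
    op <- advance(p)$type
    right <- parse_operand(p)
    cmps[[length(cmps) + 1]] <- list(node = "cmp", op = op,
                                     left = left, right = right)
    left <- right
  }
  if (length(cmps) == 0)
    parse_fail(p, "expected '<' or '>' (a clause is a comparison chain)")
  if (length(cmps) == 1) cmps[[1]]
  else list(node = "and", args = cmps)
}

parse_primary <- function(p) {
  t <- peek(p)
  if (!is.null(t) && t$type == "(") {
    advance(p)
    node <- parse_or(p)
    t <- peek(p)
    if (is.null(t) || t$type != ")") parse_fail(p, "expected ')'")
    advance(p)
    return(node)
  }
  parse_clause(p)
}

parse_and <- function(p) {
  args <- list(parse_primary(p))
  while (!is.null(t <- peek(p)) && t$type == "AND") {
    advance(p)
    args[[length(args) + 1]] <- parse_primary(p)
  }
  if (length(args) == 1) args[[1]] else list(node = "and", args = args)
}

parse_or <- function(p) {
  args <- list(parse_and(p))
  while (!is.null(t <- peek(p)) && t$type == "OR") {
    advance(p)
    args[[length(args) + 1]] <- parse_and(p)
  }
  if (length(args) == 1) args[[1]] else list(node = "or", args = args)
}

#' Parse a multi-condition expression question
#'
#' Grammar: a question is clauses joined by \code{AND}/\code{OR} (AND binds
#' tighter; parentheses group). A clause is a chain of strict comparisons
#' \code{operand (< | >) operand ...}; chains desugar to conjunctions
#' (\code{A < B < C} is \code{A < B AND B < C}). An operand is a single
#' library id, a comma-list (replicate group, modeled as an equal-weight
#' beta mixture) or a '+'-list (pool: counts and totals summed first).
#'
#' @param text question string, e.g. \code{"A < B < C"} or
#'   \code{"L1,L2 > L3,L4"}.
#' @param data optional \code{mdeq_data}; when given, every operand id must
#'   name a library of the dataset.
#' @return an object of class \code{"mdeq_question"}: the AST, with the
#'   original text as attribute \code{"text"}.
#' @examples
#' q <- parse_question("A < B < C")
#' format(q)
#' @export
parse_question <- function(text, data = NULL) {
  toks <- tokenize_question(text)
  if (length(toks) == 0) stop("empty question", call. = FALSE)
  p <- new_parser(toks, text)
  ast <- parse_or(p)
  if (!is.null(peek(p))) parse_fail(p, "unexpected trailing input")
  if (!is.null(data)) {
    unknown <- setdiff(question_libraries(ast), libraries(data))
    if (length(unknown))
      stop("question references unknown librar",
           if (length(unknown) > 1) "ies: " else "y: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(ast, class = "mdeq_question", text = text)
}

# all library ids referenced anywhere in the AST
question_libraries <- function(ast) {
  if (ast$node == "operand") return(ast$ids)
  if (ast$node == "cmp")
    return(unique(c(ast$left$ids, ast$right$ids)))
  unique(unlist(lapply(ast$args, question_libraries)))
}

# canonical operand key: same libraries => same posterior draws within one
# simulation iteration (shared-draw semantics)
operand_key <- function(op) {
  paste0(op$type, ":", paste(sort(op$ids), collapse = "|"))
}

# unique operands of the question, keyed canonically
question_operands <- function(ast) {
  collect <- function(a) {
    if (a$node == "cmp") return(list(a$left, a$right))
    if (a$node %in% c("and", "or"))
      return(do.call(c, lapply(a$args, collect)))
    list(a)
  }
  ops <- collect(ast)
  keys <- vapply(ops, operand_key, "")
  ops[!duplicated(keys)][order(unique(keys))]
}

#' @export
format.mdeq_question <- function(x, ...) {
  fmt <- function(a) {
    switch(a$node,
      operand = paste(a$ids, collapse = if (a$type == "pool") "+" else ","),
      cmp = paste(fmt(a$left), a$op, fmt(a$right)),
      and = paste(vapply(a$args, fmt, ""), collapse = " AND "),
      or = paste0("(", paste(vapply(a$args, fmt, ""), collapse = " OR "), ")"))
  }
  fmt(x)
}

#' @export
print.mdeq_question <- function(x, ...) {
  cat("Question:", attr(x, "text"), "\n")
  cat("Parsed:  ", format(x), "\n")
  invisible(x)
}

#' Pool libraries into one beta posterior
#'
#' Pooling sums a gene's counts and the library totals across the listed
#' libraries before the uniform-prior update, giving
#' Beta(sum N + 1, sum T - sum N + 1). Pooling two equal libraries roughly
#' halves the posterior variance relative to one of them.
#'
#' @param data an \code{mdeq_data} object.
#' @param gene gene id.
#' @param lib_ids character vector of >= 1 library ids.
#' @return a \code{\link{beta_posterior}}.
#' @export
pool_libraries <- function(data, gene, lib_ids) {
  if (length(lib_ids) < 1) stop("need at least one library", call. = FALSE)
  stopifnot(all(lib_ids %in% libraries(data)))
  N <- sum(data$counts[gene, lib_ids])
  T_total <- sum(data$totals[lib_ids])
  beta_posterior(N, T_total)
}

# posterior model for one operand and one gene
operand_model <- function(op, data, gene) {
  N <- data$counts[gene, op$ids]
  T_total <- data$totals[op$ids]
  switch(op$type,
    lib = beta_posterior(N, T_total),
    group = group_model(N, T_total, group_id = operand_key(op)),
    pool = beta_posterior(sum(N), sum(T_total)))
}

#' Evaluate a question on abundance draws
#'
#' All atomic comparisons are evaluated jointly on one set of draws: each
#' operand has exactly one abundance value per simulation iteration, shared
#' across every comparison it appears in (so \code{A < B AND B < C} uses a
#' single B draw, making it identical to \code{A < B < C}). Comparisons are
#' strict; ties between continuous draws have measure zero.
#'
#' @param ast a parsed question.
#' @param draws named list mapping operand keys (see the internal canonical
#'   key \code{type:ids}) to numeric draw vectors of common length.
#' @return logical vector, one entry per simulation iteration.
#' @export
evaluate_question <- function(ast, draws) {
  ev <- function(a) {
    switch(a$node,
      cmp = {
        l <- draws[[operand_key(a$left)]]
        r <- draws[[operand_key(a$right)]]
        if (is.null(l) || is.null(r))
          stop("missing draws for operand in comparison", call. = FALSE)
        if (a$op == "<") l < r else l > r
      },
      and = Reduce(`&`, lapply(a$args, ev)),
      or = Reduce(`|`, lapply(a$args, ev)),
      stop("cannot evaluate node of type ", a$node, call. = FALSE))
  }
  ev(ast)
}

#' Monte-Carlo question probability for one gene
#'
#' Draws \code{n_sims} joint posterior samples of every operand's abundance
#' and reports the fraction of iterations in which the question evaluates
#' true: p_hat = S_t / S_n, where S_t counts the iterations returning true
#' and S_n is the total number of iterations. Deterministic for a fixed
#' seed; the draw stream depends only on (seed, gene), never on which other
#' genes are scored, and operands are drawn in canonical order, so a
#' question and its operator-flipped complement consume identical draws.
#'
#' @param gene gene id.
#' @param question an \code{mdeq_question} or question string.
#' @param data an \code{mdeq_data} object.
#' @param n_sims number of Monte-Carlo iterations (default 10000).
#' @param seed integer seed.
#' @return list of class \code{"mdeq_gene_prob"}: gene_id, p_hat, s_true,
#'   n_sims, mc_se (binomial standard error), seed, all_zero (TRUE when the
#'   gene has zero counts in every referenced library).
#' @export
estimate_probability <- function(gene, question, data, n_sims = 10000,
                                 seed = 1) {
  if (is.character(question)) question <- parse_question(question, data)
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  if (!gene %in% gene_universe(data))
    stop("gene '", gene, "' not in dataset", call. = FALSE)
  ops <- question_operands(question)
  set.seed(gene_seed(seed, gene))
  draws <- list()
  for (op in ops)
    draws[[operand_key(op)]] <-
      sample_abundance(operand_model(op, data, gene), n_sims)
  s_true <- sum(evaluate_question(question, draws))
  p <- s_true / n_sims
  structure(list(
    gene_id = gene, p_hat = p, s_true = s_true, n_sims = n_sims,
    mc_se = sqrt(p * (1 - p) / n_sims), seed = seed,
    all_zero = all(data$counts[gene, question_libraries(question)] == 0)),
    class = "mdeq_gene_prob")
}

#' @export
print.mdeq_gene_prob <- function(x, ...) {
  cat(sprintf("%s: P(question) = %.4f (S_t = %d of S_n = %d, MC se %.4f)\n",
              x$gene_id, x$p_hat, x$s_true, x$n_sims, x$mc_se))
  invisible(x)
}

#' Exact ordering probability for two independent beta posteriors
#'
#' Quadrature of P(X > Y) = integral f_X(x) F_Y(x) dx for X ~ Beta(a1, b1),
#' Y ~ Beta(a2, b2). Used as an independent check on the Monte-Carlo
#' estimator for single-library operands.
#'
#' @param x,y \code{beta_posterior} objects (scalar shapes).
#' @return P(X > Y) to quadrature accuracy.
#' @export
prob_greater_beta <- function(x, y) {
  stats::integrate(function(t) stats::dbeta(t, x$a, x$b) *
                     stats::pbeta(t, y$a, y$b),
                   0, 1, rel.tol = 1e-10)$value
}
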