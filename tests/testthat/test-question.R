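test_that("comparison chains desugar to conjunctions of adjacent pairs", {
  q <- parse_question("A < B < C")
  expect_s3_class(q, "mdeq_question")
  expect_equal(q$node, "and")
  expect_length(q$args, 2)
  expect_equal(q$args[[1]]$left$ids, "A")
  expect_equal(q$args[[1]]$right$ids, "B")
  expect_equal(q$args[[2]]$left$ids, "B")
  expect_equal(q$args[[2]]$right$ids, "C")
  expect_equal(format(q), "A < B AND B < C")
})

test_that("comma-lists parse as replicate groups, '+'-lists as pools", {
  q <- parse_question("GSM383859,GSM383860 > GSM383869,GSM383870")
  expect_equal(q$node, "cmp")
  expect_equal(q$left$type, "group")
  expect_equal(q$left$ids, c("GSM383859", "GSM383860"))
  expect_equal(q$right$ids, c("GSM383869", "GSM383870"))
  p <- parse_question("A+B > C")
  expect_equal(p$left$type, "pool")
  expect_equal(p$left$ids, c("A", "B"))
  expect_error(parse_question("A,B+C > D"), "cannot mix")
})

test_that("AND binds tighter than OR and parentheses regroup", {
  q <- parse_question("A > B OR A > C AND B > C")
  expect_equal(q$node, "or")
  expect_equal(q$args[[2]]$node, "and")
  r <- parse_question("(A > B OR A > C) AND B > C")
  expect_equal(r$node, "and")
  expect_equal(r$args[[1]]$node, "or")
})

test_that("malformed questions fail with positioned parse errors", {
  expect_error(parse_question("A < < B"), "token 3")
  expect_error(parse_question("A <"), "end of question")
  expect_error(parse_question("A"), "clause")
  expect_error(parse_question(""), "empty question")
  expect_error(parse_question("A < B)"), "trailing")
  expect_error(parse_question("A ? B"), "unexpected character")
  d <- toy_dataset()
  expect_error(parse_question("L1 < LX", d), "unknown library: LX")
})

test_that("questions evaluate by strict comparison with standard logic", {
  q <- parse_question("A < B AND B < C")
  key <- function(id) paste0("lib:", id)
  draws <- setNames(list(0.1, 0.2, 0.3), vapply(c("A", "B", "C"), key, ""))
  expect_true(evaluate_question(q, draws))
  draws2 <- setNames(list(0.1, 0.5, 0.3), names(draws))
  expect_false(evaluate_question(q, draws2))
  q2 <- parse_question("A > B OR A > C")
  draws3 <- setNames(list(0.4, 0.5, 0.3), names(draws))
  expect_true(evaluate_question(q2, draws3))
  expect_error(evaluate_question(q, draws[1:2]), "missing draws")
  # vectorized over iterations
  dv <- setNames(list(c(0.1, 0.9), c(0.2, 0.2), c(0.3, 0.1)), names(draws))
  expect_equal(evaluate_question(q, dv), c(TRUE, FALSE))
})

test_that("identical libraries give probability one half by symmetry", {
  d <- pair_dataset(10, 100, 10, 100)
  e <- estimate_probability("g", "A > B", d, n_sims = 10000, seed = 1)
  expect_lt(abs(e$p_hat - 0.5), 4 * sqrt(0.25 / 10000))
  expect_equal(e$p_hat, e$s_true / e$n_sims)
})

test_that("a question and its flipped complement sum to one exactly", {
  d <- pair_dataset(20, 100, 5, 100)
  for (seed in c(1, 9, 101)) {
    a <- estimate_probability("g", "A > B", d, n_sims = 3000, seed = seed)
    b <- estimate_probability("g", "A < B", d, n_sims = 3000, seed = seed)
    expect_identical(a$s_true + b$s_true, 3000L)
  }
})

test_that("chained and explicit conjunction forms are bit-identical", {
  m <- matrix(c(1, 40, 5, 45, 20, 50), 2, 3,
              dimnames = list(c("g1", "g2"), c("A", "B", "C")))
  d <- mdeq_data(m, totals = c(A = 1000, B = 1000, C = 1000))
  f1 <- mdeq("A < B < C", d, n_sims = 4000, seed = 5)
  f2 <- mdeq("A < B AND B < C", d, n_sims = 4000, seed = 5)
  expect_identical(f1$results$s_true, f2$results$s_true)
})

test_that("Monte-Carlo estimates match the quadrature oracle", {
  set.seed(20)
  for (i in 1:6) {
    n1 <- sample(0:30, 1); n2 <- sample(0:30, 1)
    t1 <- sample(50:200, 1); t2 <- sample(50:200, 1)
    d <- pair_dataset(n1, t1, n2, t2)
    q <- prob_greater_beta(beta_posterior(n1, t1), beta_posterior(n2, t2))
    e <- estimate_probability("g", "A > B", d, n_sims = 10000, seed = i)
    se <- sqrt(max(q * (1 - q), 1e-6) / 10000)
    expect_lt(abs(e$p_hat - q), 3 * se + 1e-4)
  }
})

test_that("the ordering probability is monotone in the count", {
  t1 <- 100
  quads <- vapply(c(5, 10, 15, 20), function(n)
    prob_greater_beta(beta_posterior(n, t1), beta_posterior(10, t1)), 0)
  expect_true(all(diff(quads) > 0))
})

test_that("group and pool operands drive the estimator end to end", {
  m <- matrix(c(2, 3, 4, 30, 35, 1), 1, 6,
              dimnames = list("g", c("A1", "A2", "A3", "B1", "B2", "C")))
  d <- mdeq_data(m, totals = setNames(rep(500, 6), colnames(m)))
  e <- estimate_probability("g", "A1,A2,A3 < B1,B2", d,
                            n_sims = 4000, seed = 2)
  expect_gt(e$p_hat, 0.9)
  ep <- estimate_probability("g", "A1+A2+A3 < B1+B2", d,
                             n_sims = 4000, seed = 2)
  expect_gt(ep$p_hat, 0.99)
  # an all-zero gene is still scored, with the flag raised
  m0 <- matrix(c(0, 0), 1, 2, dimnames = list("z", c("A", "B")))
  d0 <- mdeq_data(m0, totals = c(A = 100, B = 100))
  e0 <- estimate_probability("z", "A > B", d0, n_sims = 2000, seed = 1)
  expect_true(e0$all_zero)
  expect_lt(abs(e0$p_hat - 0.5), 4 * sqrt(0.25 / 2000))
})

test_that("estimates are deterministic and independent of the gene subset", {
  m <- matrix(c(1, 40, 5, 45, 20, 50), 2, 3,
              dimnames = list(c("g1", "g2"), c("A", "B", "C")))
  d <- mdeq_data(m, totals = c(A = 1000, B = 1000, C = 1000))
  f1 <- mdeq("A < B < C", d, n_sims = 2000, seed = 3)
  f2 <- mdeq("A < B < C", d, n_sims = 2000, seed = 3)
  expect_identical(f1$results, f2$results)
  solo <- mdeq("A < B < C", d, n_sims = 2000, seed = 3, genes = "g2")
  expect_equal(solo$results$s_true,
               f1$results$s_true[f1$results$gene_id == "g2"])
})

test_that("ranking filters by cutoff and breaks ties by gene id", {
  df <- data.frame(gene_id = c("g2", "g1", "g3", "g4"),
                   p_hat = c(0.6, 0.9, 0.8, 0.8))
  expect_equal(rank_genes(df, 0.70)$gene_id, c("g1", "g3", "g4"))
  expect_equal(rank_genes(df, 70)$gene_id, c("g1", "g3", "g4"))  # percent
  expect_equal(rank_genes(df, 0)$gene_id, c("g1", "g3", "g4", "g2"))
  expect_equal(rank_genes(df, 80)$gene_id, rank_genes(df, 0.8)$gene_id)
  expect_error(rank_genes(df, 101), "cutoff")
  expect_error(rank_genes(df, -0.1), "cutoff")
})
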