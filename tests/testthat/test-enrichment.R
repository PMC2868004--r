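test_that("the fuzzy table generalizes the crisp 2x2 table", {
  p <- c(1, 1, 0, 0, 1, 0)
  w <- c(1, 0, 1, 0, 1, 1)
  tbl <- fuzzy_table(p, w)
  expect_equal(sum(tbl), length(p))
  expect_equal(unname(tbl),
               c(sum(p & w), sum(p & !w), sum(!p & w), sum(!p & !w)))
  # fuzzy cells stay non-negative and still sum to the universe size
  set.seed(1)
  pf <- runif(50); wf <- runif(50)
  tf <- fuzzy_table(pf, wf)
  expect_true(all(tf >= 0))
  expect_equal(sum(tf), 50)
})

test_that("Yule's Q matches hand arithmetic and is antisymmetric", {
  expect_equal(yules_q(c(10, 0, 0, 10)), 1)
  expect_equal(yules_q(c(5, 5, 5, 5)), 0)
  expect_equal(yules_q(c(8, 2, 3, 7)), 50 / 62)
  expect_equal(yules_q(c(0, 3, 0, 0)), 0)  # both products vanish
  set.seed(2)
  for (i in 1:10) {
    tbl <- runif(4, 0, 20)
    # swapping the columns (annotated <-> unannotated) negates Q
    expect_equal(yules_q(tbl[c(2, 1, 4, 3)]), -yules_q(tbl))
  }
  # crisp probabilities and weights reduce exactly to the classic table
  p <- rep(c(1, 0), times = c(12, 28))
  w <- rep(c(1, 0, 1, 0), times = c(9, 3, 6, 22))
  expect_equal(yules_q(fuzzy_table(p, w)),
               (9 * 22 - 3 * 6) / (9 * 22 + 3 * 6))
})

test_that("a term holding exactly the certain genes attains the p floor", {
  p <- setNames(rep(0, 80), sprintf("g%02d", 1:80))
  p[1:8] <- 1
  ann <- annotation_set(list(HIT = names(p)[1:8], MISS = names(p)[41:48]))
  res <- enrich_all(p, ann, n_perm = 1000, seed = 4)
  hit <- res[res$term_id == "HIT", ]
  expect_equal(hit$q, 1)
  expect_equal(hit$p_value, 1 / 1001)
  expect_equal(hit$sum_p_in_term, 8)
  expect_equal(res$term_id[1], "HIT")  # significance ordering
})

test_that("constant gene probabilities make every term non-significant", {
  p <- setNames(rep(0.4, 60), sprintf("g%02d", 1:60))
  ann <- random_annotation(names(p), n_terms = 4, term_size = 10, seed = 3)
  res <- enrich_all(p, ann, n_perm = 200, seed = 1)
  expect_true(all(res$p_value == 1))
})

test_that("single-term p-values agree with the all-terms run", {
  set.seed(9)
  p <- setNames(runif(100), sprintf("g%03d", 1:100))
  ann <- random_annotation(names(p), n_terms = 6, term_size = 12, seed = 5)
  all_res <- enrich_all(p, ann, n_perm = 300, seed = 11)
  one <- permutation_pvalue("T003", p, ann, n_perm = 300, seed = 11)
  expect_equal(one$p_value,
               all_res$p_value[all_res$term_id == "T003"])
  expect_equal(one$q, all_res$q[all_res$term_id == "T003"])
})

test_that("permutation p-values are calibrated under independence", {
  set.seed(31)
  p <- setNames(runif(250), sprintf("g%03d", 1:250))
  ann <- random_annotation(names(p), n_terms = 200, term_size = 15,
                           seed = 32)
  res <- enrich_all(p, ann, n_perm = 400, seed = 33)
  frac <- mean(res$p_value <= 0.05)
  bounds <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("observed association is invariant to gene relabeling", {
  set.seed(12)
  p <- setNames(runif(60), sprintf("g%02d", 1:60))
  ann <- random_annotation(names(p), n_terms = 3, term_size = 10, seed = 6)
  base <- enrich_all(p, ann, n_perm = 300, seed = 2)
  # rename genes consistently in probabilities and annotation
  new_names <- sprintf("h%02d", 1:60)
  p3 <- setNames(unname(p), new_names)
  ann3 <- annotation_set(lapply(ann$sets, function(w)
    setNames(unname(w), new_names[match(names(w), names(p))])))
  res3 <- enrich_all(p3, ann3, n_perm = 300, seed = 2)
  expect_equal(res3$q, base$q)
  expect_equal(res3$p_value, base$p_value)
})

test_that("orderings, thresholds and degenerate annotations behave", {
  p <- setNames(c(rep(1, 10), rep(0, 40)), sprintf("g%02d", 1:50))
  ann <- annotation_set(list(
    BIG = names(p)[11:40], GOOD = names(p)[1:10], TINY = names(p)[45:47]))
  res_n <- enrich_all(p, ann, n_perm = 200, seed = 1, ordering = "n_genes")
  expect_equal(res_n$term_id, c("BIG", "GOOD", "TINY"))
  res_a <- enrich_all(p, ann, n_perm = 200, seed = 1,
                      ordering = "association")
  expect_equal(res_a$term_id[1], "GOOD")
  res_t <- enrich_all(p, ann, n_perm = 200, seed = 1, threshold = 0.05)
  expect_equal(res_t$term_id, "GOOD")
  # same rows regardless of ordering
  expect_setequal(res_n$p_value, res_a$p_value)
  # empty annotation and no-overlap terms
  expect_equal(nrow(enrich_all(p, annotation_set(list()), n_perm = 200)), 0)
  expect_warning(
    out <- enrich_all(p, annotation_set(list(NOPE = c(zz = 1))),
                      n_perm = 200),
    "no annotated gene")
  expect_equal(nrow(out), 0)
  expect_error(enrich_all(p, ann, n_perm = 10), "n_perm")
})

test_that("functional screening counts genes above the cutoff per term", {
  p <- c(g1 = 0.9, g2 = 0.5, g3 = 0.95, g4 = 0.1)
  ann <- annotation_set(list(T1 = c("g1", "g2"), T2 = c("g3", "g4"),
                             T3 = c("g2", "g4")))
  scr <- functional_screen(p, ann, cutoff = 0.7)
  expect_equal(scr$n_above_cutoff[scr$term_id == "T1"], 1L)
  expect_equal(scr$n_above_cutoff[scr$term_id == "T3"], 0L)  # still listed
  expect_equal(scr$term_id[scr$n_above_cutoff == 0], "T3")
  scr0 <- functional_screen(p, ann, cutoff = 0)
  expect_equal(scr0$n_above_cutoff, scr0$n_genes)
  # percent cutoffs accepted
  expect_equal(functional_screen(p, ann, cutoff = 70), scr)
})
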