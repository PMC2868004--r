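# Synthetic tag-count libraries with planted monotone expression profiles,
# plus a ROC harness for sensitivity/specificity studies. Counts follow the
# same urn model the estimator assumes: N ~ Binomial(T, pi) per gene and
# library, pi being the latent mRNA abundance.

#' Simulation configuration
#'
#' Defaults describe a modest SAGE-scale study: 200 genes, 3 ordered
#' conditions, one library per condition, 1e5 sequenced tags per library,
#' 10% of genes carrying a planted monotone profile with a 4-fold abundance
#' step per condition, baseline abundances log-uniform over [1e-6, 1e-3].
#'
#' @param n_genes number of genes.
#' @param n_conditions number of ordered biological conditions.
#' @param libs_per_condition replicate libraries per condition (the mixture
#'   size m of each condition group).
#' @param total_tags sequenced tags per library.
#' @param fraction_tp fraction of genes with a planted profile, in (0, 1).
#' @param effect_size multiplicative abundance step per condition for
#'   planted genes; 1 means no signal anywhere.
#' @param pi_log10_range range of log10 baseline abundance (log-uniform).
#' @param seed integer seed.
#' @return list of class \code{"mdeq_sim_config"}.
#' @export
sim_config <- function(n_genes = 200, n_conditions = 3,
                       libs_per_condition = 1, total_tags = 1e5,
                       fraction_tp = 0.1, effect_size = 4,
                       pi_log10_range = c(-6, -3), seed = 1) {
  stopifnot(n_genes >= 2, n_conditions >= 2, libs_per_condition >= 1,
            total_tags >= 1, fraction_tp > 0, fraction_tp < 1,
            effect_size > 0, length(pi_log10_range) == 2)
  structure(list(n_genes = n_genes, n_conditions = n_conditions,
                 libs_per_condition = libs_per_condition,
                 total_tags = total_tags, fraction_tp = fraction_tp,
                 effect_size = effect_size,
                 pi_log10_range = pi_log10_range, seed = seed),
            class = "mdeq_sim_config")
}

#' Simulate a labeled expression dataset
#'
#' Baseline abundances are drawn log-uniformly per gene; planted
#' (true-positive) genes have their abundance multiplied by
#' effect_size^(k-1) in condition k, a monotone increasing profile, while
#' the remaining genes share one abundance across conditions. Counts are
#' drawn Binomial(total_tags, pi) per gene and library. Should the planted
#' effects push a library's total abundance above 1, abundances in that
#' library are renormalized (with a warning). Libraries are named
#' \code{C<k>.<j>} for condition k, replicate j.
#'
#' @param config an \code{\link{sim_config}}.
#' @return list of class \code{"mdeq_sim"}: \code{data} (an
#'   \code{mdeq_data}), \code{truth} (named logical per gene),
#'   \code{conditions} (named character: library -> condition),
#'   \code{pi} (gene x condition abundance matrix), \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "mdeq_sim_config"))
  set.seed(config$seed)
  g <- config$n_genes; k <- config$n_conditions
  genes <- sprintf("g%04d", seq_len(g))
  pi0 <- 10^stats::runif(g, config$pi_log10_range[1],
                         config$pi_log10_range[2])
  n_tp <- max(1, round(config$fraction_tp * g))
  tp <- sort(sample.int(g, n_tp))
  # labels mark the designated genes even when effect_size = 1, in which
  # case they carry no actual effect (null labels, AUC ~ 0.5 by design)
  truth <- stats::setNames(seq_len(g) %in% tp, genes)
  pi <- matrix(pi0, g, k, dimnames = list(genes, paste0("C", seq_len(k))))
  for (cond in seq_len(k))
    pi[tp, cond] <- pi0[tp] * config$effect_size^(cond - 1)
  over <- colSums(pi) > 1
  if (any(over)) {
    warning("renormalizing abundances in condition(s) ",
            paste(colnames(pi)[over], collapse = ", "),
            " to stay on the simplex", call. = FALSE)
    pi[, over] <- sweep(pi[, over, drop = FALSE], 2,
                        colSums(pi[, over, drop = FALSE]), "/")
  }
  m <- config$libs_per_condition
  lib_ids <- as.vector(t(outer(seq_len(k), seq_len(m),
                               function(a, b) sprintf("C%d.%d", a, b))))
  counts <- matrix(0, g, k * m, dimnames = list(genes, lib_ids))
  conditions <- character(0)
  for (cond in seq_len(k)) for (rep_j in seq_len(m)) {
    lib <- sprintf("C%d.%d", cond, rep_j)
    counts[, lib] <- stats::rbinom(g, config$total_tags, pi[, cond])
    conditions[lib] <- paste0("C", cond)
  }
  structure(list(data = mdeq_data(counts,
                                  totals = stats::setNames(
                                    rep(config$total_tags, k * m),
                                    lib_ids)),
                 truth = truth, conditions = conditions, pi = pi,
                 config = config),
            class = "mdeq_sim")
}

#' @export
print.mdeq_sim <- function(x, ...) {
  cat("Simulated labeled dataset:", x$config$n_genes, "genes,",
      x$config$n_conditions, "conditions x",
      x$config$libs_per_condition, "libraries,",
      sum(x$truth), "planted monotone profiles\n")
  invisible(x)
}

#' Monotone ordering question over a simulation's condition groups
#'
#' Builds the question "all condition groups strictly increasing" (or
#' decreasing) with each condition's replicate libraries as a comma-group
#' operand, e.g. \code{"C1.1,C1.2 < C2.1,C2.2 < C3.1,C3.2"}.
#'
#' @param sim an \code{mdeq_sim}.
#' @param direction \code{"increasing"} or \code{"decreasing"}.
#' @return question string.
#' @export
condition_question <- function(sim, direction = c("increasing",
                                                  "decreasing")) {
  direction <- match.arg(direction)
  conds <- unique(sim$conditions)
  operands <- vapply(conds, function(cc)
    paste(names(sim$conditions)[sim$conditions == cc], collapse = ","), "")
  paste(operands, collapse = if (direction == "increasing") " < " else " > ")
}

#' Score a simulated dataset with the question estimator
#'
#' @param sim an \code{mdeq_sim}.
#' @param n_sims Monte-Carlo iterations per gene (default 2000 for study
#'   throughput).
#' @param seed integer seed for the estimator (independent of the
#'   simulation seed).
#' @param question question string; default is the monotone increasing
#'   question over the condition groups.
#' @return an \code{\link{mdeq}} fit.
#' @export
score_dataset <- function(sim, n_sims = 2000, seed = 1, question = NULL) {
  question <- question %||% condition_question(sim)
  mdeq(question, sim$data, n_sims = n_sims, seed = seed)
}

#' Empirical ROC curve and AUC
#'
#' Threshold-sweep ROC with tied scores grouped, area by the trapezoidal
#' rule (equal to the Mann-Whitney pair-counting statistic with half credit
#' for tied pairs).
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param truth logical (or 0/1) vector aligned with \code{scores}.
#' @return list of class \code{"mdeq_roc"}: \code{points} (data.frame
#'   threshold, fpr, tpr), \code{auc}, \code{n_pos}, \code{n_neg}.
#' @examples
#' roc_curve(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))$auc
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & truth), 0)
  fp <- vapply(thr, function(t) sum(scores >= t & !truth), 0)
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "mdeq_roc")
}

#' @export
print.mdeq_roc <- function(x, ...) {
  cat(sprintf("ROC: %d positives vs %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
plot.mdeq_roc <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "false positive rate",
       ylab = "true positive rate",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Leave-one-out jackknife standard error of the AUC
#'
#' @inheritParams roc_curve
#' @return standard error estimate.
#' @export
auc_jackknife_se <- function(scores, truth) {
  truth <- as.logical(truth)
  n <- length(scores)
  loo <- vapply(seq_len(n), function(i) {
    t2 <- truth[-i]
    if (!any(t2) || all(t2)) return(NA_real_)
    roc_curve(scores[-i], t2)$auc
  }, 0)
  loo <- loo[!is.na(loo)]
  k <- length(loo)
  sqrt((k - 1) / k * sum((loo - mean(loo))^2))
}

#' Naive pairwise baseline score
#'
#' A transparent stand-in for classical paired analyses: for each adjacent
#' pair of conditions (replicates pooled), a one-sided two-proportion
#' z-test in the question's direction; the gene's score is the minimum over
#' pairs of (1 - p-value), i.e. the weakest link of the chain.
#'
#' @param sim an \code{mdeq_sim}.
#' @param direction as in \code{\link{condition_question}}.
#' @return named numeric score vector per gene.
#' @export
naive_pairwise_score <- function(sim, direction = c("increasing",
                                                    "decreasing")) {
  direction <- match.arg(direction)
  conds <- unique(sim$conditions)
  pooled_n <- sapply(conds, function(cc) {
    libs <- names(sim$conditions)[sim$conditions == cc]
    rowSums(sim$data$counts[, libs, drop = FALSE])
  })
  pooled_t <- sapply(conds, function(cc)
    sum(sim$data$totals[names(sim$conditions)[sim$conditions == cc]]))
  score <- rep(1, nrow(pooled_n))
  for (j in seq_len(length(conds) - 1)) {
    n1 <- pooled_n[, j]; n2 <- pooled_n[, j + 1]
    t1 <- pooled_t[j]; t2 <- pooled_t[j + 1]
    p1 <- n1 / t1; p2 <- n2 / t2
    pbar <- (n1 + n2) / (t1 + t2)
    se <- sqrt(pbar * (1 - pbar) * (1 / t1 + 1 / t2))
    z <- ifelse(se > 0, (p2 - p1) / se, 0)
    if (direction == "decreasing") z <- -z
    pval <- stats::pnorm(z, lower.tail = FALSE) # H1: step in direction
    score <- pmin(score, 1 - pval)
  }
  stats::setNames(score, rownames(pooled_n))
}

#' Compare detection methods on one labeled dataset
#'
#' Runs each method on the same simulated data and reports its ROC AUC with
#' a leave-one-gene-out jackknife standard error.
#'
#' @param sim an \code{mdeq_sim}.
#' @param methods subset of \code{c("mdeq", "naive_pairwise")}.
#' @param n_sims Monte-Carlo iterations for the question estimator.
#' @param seed estimator seed.
#' @return data.frame: method, auc, jackknife_se.
#' @export
compare_methods <- function(sim, methods = c("mdeq", "naive_pairwise"),
                            n_sims = 2000, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- lapply(methods, function(mth) {
    scores <- switch(mth,
      mdeq = coef(score_dataset(sim, n_sims = n_sims, seed = seed)),
      naive_pairwise = naive_pairwise_score(sim))
    scores <- scores[names(sim$truth)]
    data.frame(method = mth, auc = roc_curve(scores, sim$truth)$auc,
               jackknife_se = auc_jackknife_se(scores, sim$truth),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
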