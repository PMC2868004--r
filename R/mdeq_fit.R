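#' Fit question probabilities across a dataset
#'
#' The central estimator: for every gene, the posterior probability that the
#' ordering question holds, estimated by joint Monte Carlo over the
#' per-operand abundance posteriors (beta for single libraries and pools,
#' equal-weight beta mixture for replicate groups).
#'
#' @param question question string or parsed \code{mdeq_question}
#'   (see \code{\link{parse_question}}).
#' @param data an \code{\link{mdeq_data}} dataset.
#' @param n_sims Monte-Carlo iterations per gene (default 10000; the
#'   binomial standard error of any p_hat is at most sqrt(0.25/n_sims)).
#' @param seed integer seed; results are reproducible and per-gene draw
#'   streams are independent of the gene subset scored.
#' @param genes optional subset of gene ids to score (default all).
#' @return an object of class \code{"mdeq_fit"}: list with \code{results}
#'   (data.frame gene_id, p_hat, s_true, n_sims, mc_se, all_zero),
#'   \code{question}, \code{n_sims}, \code{seed}, \code{call}.
#' @examples
#' m <- matrix(c(1, 40, 5, 45, 20, 50), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("A", "B", "C")))
#' d <- mdeq_data(m, totals = c(A = 1000, B = 1000, C = 1000))
#' fit <- mdeq("A < B < C", d, n_sims = 2000, seed = 1)
#' fit
#' coef(fit)
#' @seealso \code{\link{rank_genes}}, \code{\link{enrich_all}}
#' @export
mdeq <- function(question, data, n_sims = 10000, seed = 1, genes = NULL) {
  cl <- match.call()
  if (is.character(question)) question <- parse_question(question, data)
  if (!inherits(data, "mdeq_data"))
    stop("data must be an mdeq_data object", call. = FALSE)
  genes <- genes %||% gene_universe(data)
  stopifnot(all(genes %in% gene_universe(data)))
  rows <- lapply(genes, function(g)
    estimate_probability(g, question, data, n_sims = n_sims, seed = seed))
  results <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    p_hat = vapply(rows, `[[`, 0, "p_hat"),
    s_true = vapply(rows, `[[`, 0, "s_true"),
    n_sims = n_sims,
    mc_se = vapply(rows, `[[`, 0, "mc_se"),
    all_zero = vapply(rows, `[[`, NA, "all_zero"),
    stringsAsFactors = FALSE)
  structure(list(results = results, question = question,
                 n_sims = n_sims, seed = seed, call = cl),
            class = "mdeq_fit")
}

#' @export
print.mdeq_fit <- function(x, ...) {
  cat("Multi-condition expression question fit\n")
  cat("  question:", attr(x$question, "text"), "\n")
  cat("  genes:", nrow(x$results),
      " n_sims:", x$n_sims, " seed:", x$seed, "\n")
  top <- utils::head(x$results[order(-x$results$p_hat,
                                     x$results$gene_id), ], 5)
  cat("  top genes by P(question):\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-12s %.4f\n", top$gene_id[i], top$p_hat[i]))
  invisible(x)
}

#' @export
summary.mdeq_fit <- function(object, cutoffs = c(0.5, 0.7, 0.8, 0.9,
                                                 0.95), ...) {
  p <- object$results$p_hat
  out <- list(
    question = attr(object$question, "text"),
    n_genes = length(p),
    n_sims = object$n_sims,
    seed = object$seed,
    quantiles = stats::quantile(p, c(0, 0.25, 0.5, 0.75, 1)),
    above = vapply(cutoffs, function(k) sum(p >= k), 0L))
  names(out$above) <- paste0(">=", cutoffs)
  class(out) <- "summary.mdeq_fit"
  out
}

#' @export
print.summary.mdeq_fit <- function(x, ...) {
  cat("Question:", x$question, "\n")
  cat(x$n_genes, "genes scored with", x$n_sims,
      "Monte-Carlo iterations (seed", paste0(x$seed, ")\n"))
  cat("P(question) quantiles:\n")
  print(round(x$quantiles, 4))
  cat("Genes at or above cutoff:\n")
  print(x$above)
  invisible(x)
}

#' @export
coef.mdeq_fit <- function(object, ...) {
  stats::setNames(object$results$p_hat, object$results$gene_id)
}

#' @export
as.data.frame.mdeq_fit <- function(x, ...) x$results

#' @export
plot.mdeq_fit <- function(x, cutoff = NULL, ...) {
  p <- sort(coef(x), decreasing = TRUE)
  plot(seq_along(p), p, type = "s", xlab = "gene rank",
       ylab = "P(question true)", ylim = c(0, 1),
       main = attr(x$question, "text"), ...)
  if (!is.null(cutoff))
    graphics::abline(h = normalize_cutoff(cutoff), lty = 2)
  invisible(x)
}

#' Rank genes passing a probability cutoff
#'
#' Genes whose question probability reaches the cutoff, sorted by
#' probability (descending), ties broken by gene id (ascending). The cutoff
#' may be a fraction (0.8) or a percent (80); values above 1 are read as
#' percents.
#'
#' @param x an \code{mdeq_fit} or its \code{results} data.frame.
#' @param cutoff probability cutoff in [0, 1] or (1, 100].
#' @return data.frame of the passing genes in rank order.
#' @examples
#' df <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                  p_hat = c(0.9, 0.6, 0.8))
#' rank_genes(df, 70)    # percent form of 0.7
#' @export
rank_genes <- function(x, cutoff = 0.7) {
  cutoff <- normalize_cutoff(cutoff)
  df <- if (inherits(x, "mdeq_fit")) x$results else as.data.frame(x)
  keep <- df[df$p_hat >= cutoff, , drop = FALSE]
  keep[order(-keep$p_hat, keep$gene_id), , drop = FALSE]
}
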