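# Randomization-null enrichment of functional terms against the
# probability-weighted gene list. Both the gene list (question
# probabilities p_g) and the annotation (membership weights w_g) may be
# fuzzy; crisp 0/1 values recover the classical 2x2 contingency analysis.

#' Fuzzy contingency table for one term
#'
#' Generalizes the 2x2 gene-list-by-term table to probabilistic memberships:
#' n11 = sum p_g w_g, n10 = sum p_g (1 - w_g), n01 = sum (1 - p_g) w_g,
#' n00 = sum (1 - p_g)(1 - w_g), summed over the gene universe. The four
#' cells always add up to the number of genes.
#'
#' @param p numeric vector of question probabilities over the universe.
#' @param w numeric vector of term membership weights in [0, 1], aligned
#'   with \code{p}.
#' @return named numeric vector c(n11, n10, n01, n00).
#' @export
fuzzy_table <- function(p, w) {
  stopifnot(length(p) == length(w), all(p >= 0 & p <= 1),
            all(w >= 0 & w <= 1))
  n11 <- sum(p * w)
  c(n11 = n11, n10 = sum(p) - n11, n01 = sum(w) - n11,
    n00 = length(p) - sum(p) - sum(w) + n11)
}

#' Yule's Q association measure
#'
#' Q = (n11 n00 - n10 n01) / (n11 n00 + n10 n01), in [-1, 1]; 0 is
#' independence, 1 perfect association of the gene list with the term. When
#' both cross-products vanish the table carries no association information
#' and Q is defined as 0.
#'
#' @param tbl table as returned by \code{\link{fuzzy_table}} (or any numeric
#'   vector n11, n10, n01, n00).
#' @return Q.
#' @examples
#' yules_q(c(10, 0, 0, 10)) # 1: perfect association
#' yules_q(c(5, 5, 5, 5))   # 0: independence
#' @export
yules_q <- function(tbl) {
  conc <- tbl[1] * tbl[4]
  disc <- tbl[2] * tbl[3]
  if (conc + disc == 0) return(0)
  unname((conc - disc) / (conc + disc))
}

# weight matrix (universe genes x terms) from an annotation, dropping genes
# outside the universe; terms with no annotated gene in the universe are
# dropped with a warning
annotation_matrix <- function(annotation, universe) {
  W <- matrix(0, length(universe), length(annotation$sets),
              dimnames = list(universe, names(annotation$sets)))
  for (term in names(annotation$sets)) {
    w <- annotation$sets[[term]]
    keep <- names(w) %in% universe
    if (any(keep)) W[names(w)[keep], term] <- w[keep]
  }
  empty <- colSums(W > 0) == 0
  if (any(empty)) {
    warning("skipping ", sum(empty),
            " term(s) with no annotated gene in the universe: ",
            paste(utils::head(colnames(W)[empty], 5), collapse = ", "),
            call. = FALSE)
    W <- W[, !empty, drop = FALSE]
  }
  W
}

# shared core: observed Q and permutation p-values for all terms at once.
# Only n11 varies under permutation of p over genes (the margins are fixed),
# so one crossprod per permutation set suffices.
enrich_core <- function(p, W, n_perm, seed) {
  G <- length(p)
  sp <- sum(p)
  sw <- colSums(W)
  q_of_n11 <- function(n11) {
    conc <- n11 * (G - sp - sw + n11)
    disc <- (sp - n11) * (sw - n11)
    q <- (conc - disc) / (conc + disc)
    q[conc + disc == 0] <- 0
    q
  }
  n11_obs <- drop(crossprod(W, p))
  q_obs <- q_of_n11(n11_obs)
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) p[sample.int(G)], numeric(G))
  n11_null <- crossprod(W, P)                    # terms x n_perm
  q_null <- apply(n11_null, 2, q_of_n11)
  if (is.null(dim(q_null))) q_null <- matrix(q_null, nrow = ncol(W))
  exceed <- rowSums(q_null >= q_obs - 1e-12)
  pval <- (1 + exceed) / (n_perm + 1)
  data.frame(term_id = colnames(W), q = q_obs, p_value = pval,
             n_genes = colSums(W > 0), sum_p_in_term = n11_obs,
             row.names = NULL, stringsAsFactors = FALSE)
}

# coerce fit / named vector to a named probability vector
gene_probabilities <- function(x) {
  if (inherits(x, "mdeq_fit")) return(coef(x))
  if (is.data.frame(x))
    return(stats::setNames(x$p_hat, x$gene_id))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected an mdeq_fit, a results data.frame, or a named numeric",
       call. = FALSE)
}

#' Permutation p-value for one term
#'
#' The null distribution of Yule's Q is built by permuting the gene-to-
#' probability assignment over the whole gene universe, which preserves the
#' annotation structure and the multiset of probabilities. The p-value uses
#' the add-one correction p = (1 + #\{Q_null >= Q_obs\}) / (n_perm + 1), so
#' it is never smaller than 1/(n_perm + 1).
#'
#' @param term term id present in \code{annotation}.
#' @param probs an \code{mdeq_fit} or named numeric vector of gene
#'   probabilities (the universe).
#' @param annotation an \code{mdeq_annotation}.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @return one-row data.frame: term_id, q, p_value, n_genes,
#'   sum_p_in_term.
#' @export
permutation_pvalue <- function(term, probs, annotation, n_perm = 1000,
                               seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  p <- gene_probabilities(probs)
  if (!term %in% names(annotation$sets))
    stop("unknown term '", term, "'", call. = FALSE)
  W <- annotation_matrix(annotation_set(annotation$sets[term]), names(p))
  if (ncol(W) == 0) return(invisible(NULL))
  enrich_core(p, W, n_perm, seed)
}

#' Enrichment of all terms with permutation significance
#'
#' Computes Yule's Q on the fuzzy contingency table of every term against
#' the probability-weighted gene list and derives per-term p-values from a
#' shared randomization null (the gene-to-probability assignment is
#' permuted; one permutation set serves all terms). Benjamini-Hochberg
#' adjusted p-values are reported alongside; filtering, when requested,
#' uses the raw p-value.
#'
#' @param probs an \code{mdeq_fit} or named numeric vector of question
#'   probabilities; its names define the gene universe.
#' @param annotation an \code{mdeq_annotation}.
#' @param n_perm permutations for the null (default 1000).
#' @param seed integer seed.
#' @param threshold optional raw p-value filter.
#' @param ordering \code{"significance"} (p ascending), \code{"association"}
#'   (Q descending) or \code{"n_genes"} (annotated-gene count descending).
#' @return data.frame: term_id, q, p_value, bh_adjusted, n_genes,
#'   sum_p_in_term; ordered as requested, ties broken by term_id.
#' @export
enrich_all <- function(probs, annotation, n_perm = 1000, seed = 1,
                       threshold = NULL,
                       ordering = c("significance", "association",
                                    "n_genes")) {
  ordering <- match.arg(ordering)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  p <- gene_probabilities(probs)
  if (length(annotation$sets) == 0)
    return(data.frame(term_id = character(), q = numeric(),
                      p_value = numeric(), bh_adjusted = numeric(),
                      n_genes = integer(), sum_p_in_term = numeric()))
  W <- annotation_matrix(annotation, names(p))
  if (ncol(W) == 0)
    return(data.frame(term_id = character(), q = numeric(),
                      p_value = numeric(), bh_adjusted = numeric(),
                      n_genes = integer(), sum_p_in_term = numeric()))
  res <- enrich_core(p, W, n_perm, seed)
  res$bh_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[, c("term_id", "q", "p_value", "bh_adjusted", "n_genes",
                 "sum_p_in_term")]
  if (!is.null(threshold))
    res <- res[res$p_value <= threshold, , drop = FALSE]
  ord <- switch(ordering,
    significance = order(res$p_value, -abs(res$q), res$term_id),
    association = order(-res$q, res$term_id),
    n_genes = order(-res$n_genes, res$term_id))
  res[ord, , drop = FALSE]
}

#' Functional screening: genes above cutoff per term
#'
#' For each term, the number of member genes whose question probability
#' reaches the cutoff; terms are listed by that count (descending, ties by
#' term id). Membership is crisp here: any gene with positive annotation
#' weight counts.
#'
#' @inheritParams enrich_all
#' @param cutoff probability cutoff, fraction or percent
#'   (see \code{\link{rank_genes}}).
#' @return data.frame: term_id, n_above_cutoff, n_genes.
#' @export
functional_screen <- function(probs, annotation, cutoff = 0.7) {
  cutoff <- normalize_cutoff(cutoff)
  p <- gene_probabilities(probs)
  W <- annotation_matrix(annotation, names(p))
  hit <- p >= cutoff
  out <- data.frame(
    term_id = colnames(W),
    n_above_cutoff = as.integer(colSums(W > 0 & hit)),
    n_genes = as.integer(colSums(W > 0)),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$n_above_cutoff, out$term_id), , drop = FALSE]
}
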