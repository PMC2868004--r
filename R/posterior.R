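#' Beta posterior for a tag abundance
#'
#' Under the urn model, observing N tags for a gene out of T sequenced tags
#' is Binomial(T, pi) in the latent mRNA abundance pi. With a uniform prior
#' the posterior is Beta(a, b) with a = N + 1, b = T - N + 1. N = T = 0
#' returns the uniform prior itself.
#'
#' @param N tag count(s) for the gene, 0 <= N <= T.
#' @param T_total total sequenced tags in the library (same length as N or
#'   scalar).
#' @return an object of class \code{"beta_posterior"} with numeric fields
#'   \code{a} and \code{b} (vectorized).
#' @examples
#' beta_posterior(3, 10)        # Beta(4, 8)
#' mean(beta_posterior(0, 100)) # 1/102
#' @export
beta_posterior <- function(N, T_total) {
  if (any(N < 0) || any(T_total < 0) || any(N > T_total))
    stop("need 0 <= N <= T", call. = FALSE)
  structure(list(a = N + 1, b = T_total - N + 1), class = "beta_posterior")
}

#' @export
mean.beta_posterior <- function(x, ...) x$a / (x$a + x$b)

#' Posterior variance
#' @param x a \code{beta_posterior}.
#' @return ab / ((a+b)^2 (a+b+1)), vectorized.
#' @export
variance <- function(x) UseMethod("variance")

#' @export
variance.beta_posterior <- function(x) {
  s <- x$a + x$b
  x$a * x$b / (s^2 * (s + 1))
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%s, %s) posterior\n",
              paste(format(x$a), collapse = ","),
              paste(format(x$b), collapse = ",")))
  invisible(x)
}

#' Equal-weight beta mixture for a group of replicate libraries
#'
#' Replicate libraries of one biological condition are encoded as a mixture
#' of their per-library beta posteriors with equal weights 1/m, m being the
#' number of libraries in the group. With m = 1 the model is exactly the
#' single beta posterior.
#'
#' @param N vector of per-library tag counts for the gene.
#' @param T_total vector of per-library totals (recycled if scalar).
#' @param group_id optional label.
#' @return an object of class \code{"mdeq_group"} with fields \code{a},
#'   \code{b} (length-m shape vectors), \code{m} and \code{group_id}.
#' @examples
#' g <- group_model(c(2, 10), c(12, 12)) # two replicate libraries
#' mixture_density(g, 0.5)
#' @export
group_model <- function(N, T_total, group_id = "group") {
  T_total <- rep_len(T_total, length(N))
  bp <- beta_posterior(N, T_total)
  structure(list(a = bp$a, b = bp$b, m = length(N), group_id = group_id),
            class = "mdeq_group")
}

#' @export
print.mdeq_group <- function(x, ...) {
  cat(sprintf("Group '%s': equal-weight mixture of %d beta component(s)\n",
              x$group_id, x$m))
  for (i in seq_len(x$m))
    cat(sprintf("  Beta(%g, %g)\n", x$a[i], x$b[i]))
  invisible(x)
}

#' Mixture density of a group model
#'
#' @param model an \code{mdeq_group} (or \code{beta_posterior}, treated as
#'   m = 1).
#' @param pi abundance value(s) in (0, 1).
#' @return density (1/m) * sum_i BetaPDF(pi; a_i, b_i), vectorized over
#'   \code{pi}.
#' @export
mixture_density <- function(model, pi) {
  if (inherits(model, "beta_posterior"))
    model <- structure(list(a = model$a, b = model$b, m = length(model$a)),
                       class = "mdeq_group")
  if (any(pi <= 0) || any(pi >= 1))
    stop("pi must lie strictly inside (0, 1)", call. = FALSE)
  out <- numeric(length(pi))
  for (i in seq_len(model$m))
    out <- out + stats::dbeta(pi, model$a[i], model$b[i])
  out / model$m
}

#' Draw posterior abundance samples
#'
#' For a single-library model (m = 1) draws come straight from the beta
#' posterior; for a true mixture (m > 1) each draw first picks a component
#' uniformly at random and then draws from that component's beta. The switch
#' is automatic.
#'
#' @param model an \code{mdeq_group} or \code{beta_posterior}.
#' @param n_draws number of samples (>= 1).
#' @param rng_seed optional seed; when supplied the draw is reproducible.
#' @return numeric vector of length \code{n_draws} in (0, 1).
#' @export
sample_abundance <- function(model, n_draws, rng_seed = NULL) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (inherits(model, "beta_posterior"))
    model <- structure(list(a = model$a, b = model$b, m = length(model$a)),
                       class = "mdeq_group")
  draw_mixture(model$a, model$b, n_draws)
}

# component-indicator sampling; m == 1 short-circuits to plain rbeta
draw_mixture <- function(a, b, n) {
  m <- length(a)
  if (m == 1L) return(stats::rbeta(n, a, b))
  idx <- sample.int(m, n, replace = TRUE)
  stats::rbeta(n, a[idx], b[idx])
}
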