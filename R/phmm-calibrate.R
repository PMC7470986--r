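# Maximum-likelihood Gumbel fit (location mu, rate lambda) for a vector of
# maxima-like scores.  Solved via the standard profile equation in the
# scale parameter beta = 1/lambda.
fit_gumbel <- function(x) {
  if (stats::sd(x) == 0) {
    stop("calibration error: degenerate score distribution (all scores equal)",
         call. = FALSE)
  }
  xbar <- mean(x)
  g <- function(beta) {
    w <- exp(-(x - max(x)) / beta)
    beta - xbar + sum(x * w) / sum(w)
  }
  lo <- stats::sd(x) / 50
  hi <- stats::sd(x) * 50
  beta <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  shift <- max(x)
  mu <- shift - beta * log(mean(exp(-(x - shift) / beta)))
  c(mu = mu, lambda = 1 / beta)
}

#' Calibrate a model's E-value parameters
#'
#' Scores `n_random` background-sampled sequences with the local Viterbi
#' scorer and fits a Gumbel distribution to the score maxima by maximum
#' likelihood.  The fitted location/rate pair is stored on the model and
#' used by [evalue_from_bits()]: `E(s) = n_db * exp(-lambda * (s - mu))`.
#'
#' @param hmm A [profile_hmm].
#' @param n_random Number of null sequences (>= 100).
#' @param length_dist Either a fixed integer length, an integer vector to
#'   sample lengths from, or a function `n -> lengths`.  Default: the
#'   model length.
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @return The model with `gumbel_mu` and `gumbel_lambda` set.
#' @export
calibrate_evalue <- function(hmm, n_random = 200, length_dist = NULL, seed = 1) {
  stopifnot(n_random >= 100)
  scores <- with_seed(seed, {
    lens <- sample_lengths(length_dist, n_random, hmm$M)
    vapply(lens, function(L) {
      s <- paste(sample(AA20, L, replace = TRUE, prob = hmm$background),
                 collapse = "")
      viterbi_raw(hmm, s)$score
    }, numeric(1))
  })
  fit <- fit_gumbel(scores)
  hmm$gumbel_mu <- unname(fit["mu"])
  hmm$gumbel_lambda <- unname(fit["lambda"])
  hmm
}

sample_lengths <- function(length_dist, n, default_len) {
  if (is.null(length_dist)) return(rep(default_len, n))
  if (is.function(length_dist)) return(as.integer(length_dist(n)))
  if (length(length_dist) == 1) return(rep(as.integer(length_dist), n))
  sample(as.integer(length_dist), n, replace = TRUE)
}

#' E-value of a bit score under a calibrated model
#'
#' @param hmm A calibrated [profile_hmm].
#' @param bits Bit score(s).
#' @param n_db Effective database size the expectation is scaled to.
#' @return E-value(s), strictly decreasing in `bits`.
#' @export
evalue_from_bits <- function(hmm, bits, n_db = 1) {
  if (is.na(hmm$gumbel_mu)) stop("model '", hmm$name, "' is not calibrated")
  n_db * exp(-hmm$gumbel_lambda * (bits - hmm$gumbel_mu))
}
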