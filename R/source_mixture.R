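#' Source attribution by multinomial mixture (EM)
#'
#' Attributes a post-intervention sample's reads to three sources: the donor
#' profile, the recipient's own pre-intervention (D0) profile, and an
#' "unknown" uniform source absorbing taxa explained by neither. The model is
#' a multinomial whose category probabilities are the convex mixture
#' `p = lambda_d * donor + lambda_p * pre + lambda_u * uniform`; the weights
#' are the maximum-likelihood estimates obtained by EM. This is a
#' deterministic counterpart to Gibbs-sampled Bayesian source tracking,
#' answering the same question (the donor-attributable proportion) with an
#' exactly testable estimator.
#'
#' Source profiles are smoothed before normalisation: `pseudo` mass is added
#' to every taxon so that taxa unobserved in a source keep nonzero
#' probability and the likelihood stays finite.
#'
#' @param post Count vector of the post-intervention sample.
#' @param donor,pre Abundance (or count) vectors of the two candidate sources,
#'   over the same taxon universe as `post`.
#' @param pseudo Per-taxon smoothing mass added to the normalised source
#'   profiles (default 1e-6).
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default 1e-10).
#' @param max_iter Iteration cap; exceeding it without converging is an error
#'   carrying the likelihood trace.
#' @return A one-row `fmt_sourcemix` tibble: `lambda_donor`, `lambda_pre`,
#'   `lambda_unknown`, `log_likelihood`, `n_iter`, `converged`.
#' @examples
#' donor <- c(10, 10, 0, 0)
#' pre <- c(0, 0, 10, 10)
#' post <- c(30, 30, 20, 20)  # 60:40 donor:pre
#' estimate_source_mixture(post, donor, pre)
#' @export
estimate_source_mixture <- function(post, donor, pre, pseudo = 1e-6,
                                    tol = 1e-10, max_iter = 10000) {
  if (length(post) != length(donor) || length(post) != length(pre)) {
    abort("`post`, `donor` and `pre` must cover the same taxon universe.")
  }
  assert_count_vector(post, "post")
  assert_count_vector(donor, "donor")
  assert_count_vector(pre, "pre")
  k <- length(post)

  smooth <- function(x) {
    p <- x / sum(x)
    (p + pseudo) / (1 + k * pseudo)
  }
  q <- cbind(donor = smooth(donor), pre = smooth(pre), unknown = rep(1 / k, k))
  lambda <- c(donor = 1, pre = 1, unknown = 1) / 3
  n <- post
  n_total <- sum(n)
  loglik <- function(l) sum(n * log(q %*% l))
  ll <- loglik(lambda)
  trace <- ll

  for (it in seq_len(max_iter)) {
    mix <- as.vector(q %*% lambda)                  # per-taxon mixture prob
    resp <- sweep(q, 2, lambda, "*") / mix          # responsibilities (taxa x 3)
    lambda <- colSums(n * resp) / n_total
    ll_new <- loglik(lambda)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) <= tol * abs(ll)) {
      return(new_sourcemix(lambda, ll_new, it, TRUE))
    }
    ll <- ll_new
  }
  rlang::abort(
    sprintf("EM did not converge within %d iterations.", max_iter),
    class = "fmtengraft_em_nonconvergence",
    trace = trace
  )
}

new_sourcemix <- function(lambda, ll, n_iter, converged) {
  out <- tibble(
    lambda_donor = unname(lambda["donor"]),
    lambda_pre = unname(lambda["pre"]),
    lambda_unknown = unname(lambda["unknown"]),
    log_likelihood = ll,
    n_iter = n_iter,
    converged = converged
  )
  class(out) <- c("fmt_sourcemix", class(out))
  out
}

#' Source-mixture attribution across a cohort
#'
#' Runs [estimate_source_mixture()] for every recipient post-intervention
#' sample in the table, against the subject's assigned donor (FMT) or the
#' mean donor profile (sham) and the subject's D0 baseline.
#'
#' @param table A feature table (typically rarefied).
#' @param metadata Sample metadata.
#' @param timepoints Post timepoints to attribute (default all scheduled).
#' @param pseudo,tol,max_iter Passed to [estimate_source_mixture()].
#' @return Tibble with one row per subject-timepoint: the lambda triplet and
#'   log-likelihood.
#' @export
source_mixture_table <- function(table, metadata, timepoints = POST_TIMEPOINTS,
                                 pseudo = 1e-6, tol = 1e-10, max_iter = 10000) {
  table <- as_ftbl_checked(table)
  md <- sample_metadata(metadata)
  m <- ft_matrix(table)
  md <- filter(md, .data$sample_id %in% rownames(m))
  donors <- filter(md, .data$role == "donor")
  recips <- filter(md, .data$role == "recipient", .data$timepoint %in% timepoints)

  purrr::pmap(select(recips, "subject_id", "arm", "timepoint", "sample_id"),
              function(subject_id, arm, timepoint, sample_id) {
    base_id <- md$sample_id[md$subject_id == subject_id & md$timepoint == "D0"]
    if (length(base_id) != 1) return(NULL)
    donor_ids <- if (arm == "FMT") {
      did <- unique(md$donor_id[md$subject_id == subject_id & md$role == "recipient"])
      did <- did[!is.na(did) & did != ""]
      donors$sample_id[donors$subject_id %in% did]
    } else {
      donors$sample_id
    }
    if (length(donor_ids) == 0) return(NULL)
    donor_prof <- colMeans(sweep(m[donor_ids, , drop = FALSE], 1,
                                 rowSums(m[donor_ids, , drop = FALSE]), "/"))
    fit <- estimate_source_mixture(m[sample_id, ], donor_prof, m[base_id, ],
                                   pseudo = pseudo, tol = tol, max_iter = max_iter)
    bind_cols(tibble(subject_id = subject_id, arm = arm, timepoint = timepoint),
              as_tibble(fit))
  }) |>
    bind_rows()
}
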