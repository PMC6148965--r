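#' Negative-binomial log-likelihood
#'
#' Joint log-likelihood of a vector of counts under a negative-binomial
#' distribution parameterized by its mean `mu` and dispersion `phi`, with
#' `variance = mu + phi * mu^2`. At `phi = 0` the Poisson log-likelihood (the
#' continuous limit) is returned.
#'
#' @param y Vector of non-negative integer counts.
#' @param mu Positive mean.
#' @param phi Non-negative dispersion.
#' @return A single numeric log-likelihood value.
#' @examples
#' nb_loglik(c(2, 5, 1), mu = 2.5, phi = 0.3)
#' nb_loglik(0, mu = 1, phi = 0)  # Poisson: log(exp(-1)) = -1
#' @export
nb_loglik <- function(y, mu, phi) {
  check_count_vector(y)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("`mu` must be a single positive number", call. = FALSE)
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi < 0)
    stop("`phi` must be a single non-negative number", call. = FALSE)
  cpp_nb_loglik(as.numeric(y), mu, phi)
}

check_count_vector <- function(y) {
  if (!is.numeric(y) || length(y) == 0L || anyNA(y))
    stop("`y` must be a non-empty numeric vector without missing values",
         call. = FALSE)
  if (any(y < 0))
    stop("`y` contains negative values", call. = FALSE)
  if (any(abs(y - round(y)) > 1e-8))
    stop("`y` must be integer-valued; round normalized counts first",
         call. = FALSE)
  invisible(y)
}

#' Per-gene negative-binomial maximum likelihood fit
#'
#' Fits NB(mu, phi) to a single gene's counts by profile likelihood: for any
#' fixed dispersion the likelihood is maximized at the sample mean, so the fit
#' reduces to a deterministic one-dimensional golden-section search over
#' `phi` on `[0, phi_max]`. The sampling variance of the dispersion estimate
#' (`tau2_hat`) is the inverse observed Fisher information of the profile
#' log-likelihood, computed by central finite differences (one-sided at the
#' `phi = 0` boundary) and floored at 1e-6; when the profile carries no
#' curvature information on the dispersion, `tau2_hat` is `Inf`, which makes
#' the downstream posterior mean collapse to the prior mean.
#'
#' @param y Vector of non-negative integer counts, length at least 2, with at
#'   least one positive entry.
#' @param context One of `"pooled"`, `"group1"`, `"group2"`; bookkeeping only.
#' @param phi_max Upper bound of the dispersion search interval.
#' @return An object of class `nb_fit`: a list with elements `mu_hat`,
#'   `phi_hat`, `loglik`, `tau2_hat`, `context`, `n_obs`, `boundary`.
#' @examples
#' nb_mle(c(3, 9, 1, 12))
#' @export
nb_mle <- function(y, context = c("pooled", "group1", "group2"),
                   phi_max = 50) {
  context <- match.arg(context)
  check_count_vector(y)
  if (length(y) < 2L)
    stop("need at least 2 observations to fit an NB model", call. = FALSE)
  if (all(y == 0))
    stop("all-zero counts: the NB mean lies on the boundary", call. = FALSE)
  f <- cpp_nb_fit(as.numeric(y), phi_max)
  structure(
    list(mu_hat = unname(f["mu"]), phi_hat = unname(f["phi"]),
         loglik = unname(f["loglik"]), tau2_hat = unname(f["tau2"]),
         context = context, n_obs = length(y),
         boundary = unname(f["boundary"]) == 1),
    class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("NB fit (%s, n = %d): mu = %.4g, phi = %.4g, loglik = %.4g, tau2 = %.3g%s\n",
              x$context, x$n_obs, x$mu_hat, x$phi_hat, x$loglik, x$tau2_hat,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Likelihood ratio test of simultaneous mean and dispersion change
#'
#' Tests, for one gene, the null hypothesis that the two groups share a common
#' NB mean and dispersion against group-specific (mu, phi). The statistic is
#' `lr = 2 * (loglik_group1 + loglik_group2 - loglik_pooled)`, clipped at 0,
#' and is referred to a chi-square distribution with 2 degrees of freedom
#' (`p = exp(-lr / 2)`), an approximation that is accurate for large groups.
#'
#' @param y1,y2 Integer count vectors for the normal and disease group.
#' @return An object of class `lrt_pair` with elements `lr`, `p_chi2`, `fits`
#'   (the pooled and per-group `nb_fit` objects), and `reason` (`NA` on
#'   success; on a fit failure `lr` and `p_chi2` are `NA` and `reason` says
#'   which context failed).
#' @examples
#' lrt_statistic(c(5, 6, 5, 4), c(1, 25, 2, 30))
#' @export
lrt_statistic <- function(y1, y2) {
  fits <- list(pooled = NULL, group1 = NULL, group2 = NULL)
  reason <- NA_character_
  lr <- p <- NA_real_
  f <- function(y, ctx) tryCatch(nb_mle(y, ctx), error = function(e) e)
  fits$pooled <- f(c(y1, y2), "pooled")
  fits$group1 <- f(y1, "group1")
  fits$group2 <- f(y2, "group2")
  bad <- vapply(fits, inherits, logical(1), what = "condition")
  if (any(bad)) {
    reason <- paste0("fit failed in context ", paste(names(fits)[bad], collapse = ", "),
                     ": ", conditionMessage(fits[[which(bad)[1]]]))
  } else {
    lr <- max(0, 2 * (fits$group1$loglik + fits$group2$loglik - fits$pooled$loglik))
    p <- exp(-lr / 2)
  }
  structure(list(lr = lr, p_chi2 = p, fits = fits, reason = reason),
            class = "lrt_pair")
}

#' Likelihood ratio statistic with shrunken dispersions plugged in
#'
#' Recomputes the two-group likelihood ratio with the three dispersions fixed
#' at supplied (empirical-Bayes shrunken) values; only the means are
#' maximized, and since the NB score in the mean vanishes at the sample mean
#' for any fixed dispersion, each mean is the corresponding sample mean. The
#' plug-in dispersions break the nesting of the two models, so the statistic
#' may be negative; it is returned unclipped and its null distribution is
#' estimated by permutation (see [build_null()]).
#'
#' @param y1,y2 Integer count vectors for the two groups.
#' @param phiB_pooled,phiB_1,phiB_2 Shrunken dispersions for the pooled,
#'   group-1 and group-2 contexts; all must be non-negative.
#' @return A single numeric statistic (possibly negative), or `NA` if any
#'   context has an all-zero count vector.
#' @export
lrt_statistic_eb <- function(y1, y2, phiB_pooled, phiB_1, phiB_2) {
  check_count_vector(y1); check_count_vector(y2)
  phis <- c(phiB_pooled, phiB_1, phiB_2)
  if (anyNA(phis) || any(phis < 0))
    stop("shrunken dispersions must be non-negative", call. = FALSE)
  m1 <- mean(y1); m2 <- mean(y2); mp <- mean(c(y1, y2))
  if (m1 <= 0 || m2 <= 0 || mp <= 0) return(NA_real_)
  ll1 <- cpp_nb_loglik(as.numeric(y1), m1, phiB_1)
  ll2 <- cpp_nb_loglik(as.numeric(y2), m2, phiB_2)
  llp <- cpp_nb_loglik(as.numeric(c(y1, y2)), mp, phiB_pooled)
  2 * (ll1 + ll2 - llp)
}

# Row-wise fits for a genes x samples matrix; returns a data.frame with one
# row per gene and NA rows where the fit is impossible (all-zero counts).
fit_context <- function(m, phi_max = 50) {
  f <- cpp_fit_nb_rows(m, phi_max)
  data.frame(mu = f[, "mu"], phi = f[, "phi"], loglik = f[, "loglik"],
             tau2 = f[, "tau2"], ok = !is.na(f[, "mu"]))
}

#' Mean-only negative-binomial likelihood ratio baseline
#'
#' A comparator that tests only the group-mean difference, assuming a common
#' dispersion across groups (the assumption made by mean-shift DE methods).
#' The alternative fits separate group means with one shared dispersion
#' (profiled); the null is the pooled single-(mu, phi) fit. The statistic is
#' referred to chi-square with 1 degree of freedom.
#'
#' @param counts Genes x samples matrix of integer counts.
#' @param group Integer vector (1 = normal, 2 = disease) per sample.
#' @return Data frame with per-gene `lr`, `p`, and `ok` flag.
#' @export
meanonly_test <- function(counts, group) {
  stopifnot(ncol(counts) == length(group), all(group %in% c(1L, 2L)))
  m <- round(as.matrix(counts))
  alt <- cpp_fit_common_phi_rows(m, which(group == 1L), which(group == 2L))
  nul <- cpp_fit_nb_rows(m)
  lr <- pmax(0, 2 * (alt[, "loglik"] - nul[, "loglik"]))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  data.frame(lr = lr, p = p, ok = !is.na(lr), row.names = rownames(counts))
}
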