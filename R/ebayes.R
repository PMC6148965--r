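#' Estimate the genome-wide dispersion hyperprior for one pooling context
#'
#' Per-gene dispersion MLEs are modeled as normal around the gene's true
#' dispersion with known sampling variance, and the true dispersions as
#' normal around a genome-wide mean: `phi_hat_g | phi_g ~ N(phi_g, tau2_g)`,
#' `phi_g ~ N(phi0, tau20)`. The hyperprior is estimated by a robust method
#' of moments: `phi0 = mean(phi_hat)` and `tau20 = max(0, var(phi_hat) -
#' median(tau2))`, using every gene with a successful fit. The median (not
#' the mean) of the per-gene sampling variances is used because with few
#' replicates the Fisher-information variances are heavy-tailed — a handful
#' of nearly-flat profile likelihoods would otherwise dominate the average,
#' driving `tau20` to the zero boundary for some group labelings and not
#' others, which destabilizes the permutation null.
#'
#' @param phi_hats Per-gene dispersion estimates (NA allowed for failed fits).
#' @param tau2s Per-gene sampling variances of the dispersion estimates.
#' @param context One of `"pooled"`, `"group1"`, `"group2"`.
#' @return Object of class `hyperprior`: list with `context`, `phi0`,
#'   `tau20`, `n_genes_used`.
#' @export
estimate_hyperprior <- function(phi_hats, tau2s,
                                context = c("pooled", "group1", "group2")) {
  context <- match.arg(context)
  if (length(phi_hats) != length(tau2s))
    stop("phi_hats and tau2s must have equal length", call. = FALSE)
  # genes with an infinite sampling variance (flat profile) still carry a
  # point estimate and enter the first moment; only finite tau2s can enter
  # the noise-correction term
  ok <- !is.na(phi_hats) & is.finite(phi_hats) & !is.na(tau2s) & tau2s > 0
  if (sum(ok) < 10L)
    stop("fewer than 10 usable genes; hyperprior would be unreliable",
         call. = FALSE)
  ph <- phi_hats[ok]
  t2 <- tau2s[ok & is.finite(tau2s)]
  noise <- if (length(t2)) stats::median(t2) else 0
  structure(
    list(context = context,
         phi0 = max(0, mean(ph)),
         tau20 = max(0, stats::var(ph) - noise),
         n_genes_used = sum(ok)),
    class = "hyperprior")
}

#' @export
print.hyperprior <- function(x, ...) {
  cat(sprintf("hyperprior (%s): phi0 = %.4g, tau20 = %.4g, from %d genes\n",
              x$context, x$phi0, x$tau20, x$n_genes_used))
  invisible(x)
}

#' Posterior-mean dispersion shrinkage
#'
#' Shrinks each gene's dispersion MLE toward the genome-wide prior mean by
#' the normal-normal posterior mean,
#' `(phi_hat/tau2_g + phi0/tau20) / (1/tau2_g + 1/tau20)`,
#' i.e. a precision-weighted average of the gene's estimate and the prior
#' mean. The result is floored at 0 (the normal prior admits negative
#' values; the NB model requires a non-negative dispersion). When
#' `tau20 = 0` the prior is infinitely informative and `phi0` is returned.
#'
#' @param phi_hat_g Per-gene dispersion estimate(s); vectorized.
#' @param tau2_g Sampling variance(s), all > 0; recycled against `phi_hat_g`.
#' @param hp A `hyperprior` object from [estimate_hyperprior()].
#' @return Shrunken dispersion(s), same length as `phi_hat_g`; `NA` inputs
#'   propagate.
#' @export
shrink_dispersion <- function(phi_hat_g, tau2_g, hp) {
  stopifnot(inherits(hp, "hyperprior"))
  if (any(tau2_g <= 0, na.rm = TRUE))
    stop("tau2_g must be positive", call. = FALSE)
  if (hp$tau20 == 0) {
    out <- rep(hp$phi0, length(phi_hat_g))
    out[is.na(phi_hat_g) | is.na(tau2_g)] <- NA_real_
    return(out)
  }
  num <- phi_hat_g / tau2_g + hp$phi0 / hp$tau20
  den <- 1 / tau2_g + 1 / hp$tau20
  pmax(0, num / den)
}
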