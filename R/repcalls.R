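#' Negative-binomial prediction interval
#'
#' Equal-tailed interval for a single new observation from NB(mu, phi),
#' computed by pmf summation: `lo` is the largest integer with
#' `P(Y < lo) <= alpha/2` and `hi` the smallest integer with
#' `P(Y > hi) <= alpha/2`. At `phi = 0` the Poisson pmf is used.
#'
#' @param mu Positive mean.
#' @param phi Non-negative dispersion.
#' @param alpha Two-sided error level in (0, 1).
#' @return Integer vector `c(lo, hi)`.
#' @export
nb_interval <- function(mu, phi, alpha = 0.05) {
  if (!(mu > 0)) stop("`mu` must be positive", call. = FALSE)
  if (phi < 0) stop("`phi` must be non-negative", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  a2 <- alpha / 2
  upper <- ceiling(mu + 10 * sqrt(mu + phi * mu^2) + 50)
  repeat {
    k <- 0:upper
    pmf <- if (phi < 1e-12) stats::dpois(k, mu)
           else stats::dnbinom(k, size = 1 / phi, mu = mu)
    Fk <- cumsum(pmf)
    if (1 - Fk[length(Fk)] <= a2 || upper > 1e8) break
    upper <- upper * 2
  }
  eps <- 1e-12
  # P(Y < lo) = F(lo - 1); F(-1) = 0
  Fprev <- c(0, Fk)             # Fprev[lo + 1] = F(lo - 1), lo = 0..upper
  lo <- max(which(Fprev <= a2 + eps)) - 1L
  hi_idx <- which(Fk >= 1 - a2 - eps)
  hi <- if (length(hi_idx)) hi_idx[1L] - 1L else upper
  c(lo = as.integer(lo), hi = as.integer(hi))
}

#' Classify disease replicates of declared DE genes
#'
#' For each declared DE gene, builds the NB prediction interval of the
#' normal group from its estimated mean and shrunken dispersion, and compares
#' each disease replicate's (rounded) normalized count to it. The per-test
#' level is Bonferroni-adjusted across the family of comparisons — by
#' default the `n2` disease replicates within a gene — so the family-wise
#' error rate is controlled at `fwer`.
#'
#' @param de_genes Character vector of DE gene IDs.
#' @param fits_g1 Data frame with columns `gene_id`, `mu`, `phiB`: the
#'   normal-group mean and shrunken dispersion per gene.
#' @param disease_obs Matrix of normalized disease-group counts, rownames =
#'   gene IDs, one column per disease replicate.
#' @param fwer Family-wise error level (default 0.05).
#' @param global_family If `TRUE`, Bonferroni divides across all
#'   `genes x replicates` comparisons instead of within-gene.
#' @return Object of class `replicate_calls`: list with `calls` (character
#'   matrix, values `aberrant_high` / `aberrant_low` / `normal`), `lo`,
#'   `hi`, `observed`, `alpha_family`, `per_test_alpha`.
#' @export
classify_replicates <- function(de_genes, fits_g1, disease_obs, fwer = 0.05,
                                global_family = FALSE) {
  de_genes <- as.character(de_genes)
  missing <- setdiff(de_genes, fits_g1$gene_id)
  if (length(missing))
    stop("missing normal-group fit for DE gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  missing_obs <- setdiff(de_genes, rownames(disease_obs))
  if (length(missing_obs))
    stop("missing disease observations for DE gene(s): ",
         paste(missing_obs, collapse = ", "), call. = FALSE)
  n2 <- ncol(disease_obs)
  n_tests <- if (global_family) length(de_genes) * n2 else n2
  alpha <- fwer / n_tests
  reps <- colnames(disease_obs)
  if (is.null(reps)) reps <- paste0("disease", seq_len(n2))
  calls <- matrix("normal", length(de_genes), n2,
                  dimnames = list(de_genes, reps))
  lo <- hi <- stats::setNames(integer(length(de_genes)), de_genes)
  obs <- round(disease_obs[de_genes, , drop = FALSE])
  idx <- match(de_genes, fits_g1$gene_id)
  for (i in seq_along(de_genes)) {
    iv <- nb_interval(fits_g1$mu[idx[i]], fits_g1$phiB[idx[i]], alpha)
    lo[i] <- iv["lo"]; hi[i] <- iv["hi"]
    calls[i, obs[i, ] > iv["hi"]] <- "aberrant_high"
    calls[i, obs[i, ] < iv["lo"]] <- "aberrant_low"
  }
  structure(list(calls = calls, lo = lo, hi = hi, observed = obs,
                 alpha_family = fwer, per_test_alpha = alpha),
            class = "replicate_calls")
}

#' @export
print.replicate_calls <- function(x, ...) {
  cat(sprintf("replicate calls: %d DE genes x %d disease replicates (FWER %.3g, per-test alpha %.4g)\n",
              nrow(x$calls), ncol(x$calls), x$alpha_family, x$per_test_alpha))
  ab <- rowSums(x$calls != "normal")
  cat(sprintf("  genes with >= 1 aberrant replicate: %d\n", sum(ab > 0)))
  invisible(x)
}

#' Unique and shared DE genes across disease replicates
#'
#' Counts, for every non-empty subset of disease replicates, the DE genes
#' whose aberrant-replicate set is exactly that subset (the cells of a Venn
#' diagram), plus per-replicate totals and the all-replicates intersection.
#'
#' @param calls A `replicate_calls` object.
#' @return List with `subset_counts` (named integer vector; names are
#'   `+`-joined replicate IDs), `per_replicate` totals, `n_all_replicates`,
#'   `n_zero_aberrant`, `n_genes`.
#' @export
share_summary <- function(calls) {
  stopifnot(inherits(calls, "replicate_calls"))
  ab <- calls$calls != "normal"
  reps <- colnames(calls$calls)
  key <- apply(ab, 1, function(r) paste(reps[r], collapse = "+"))
  nonzero <- key[key != ""]
  subset_counts <- if (length(nonzero)) {
    tb <- table(nonzero)
    stats::setNames(as.integer(tb), names(tb))
  } else integer(0)
  list(subset_counts = subset_counts,
       per_replicate = colSums(ab),
       n_all_replicates = sum(rowSums(ab) == ncol(ab)),
       n_zero_aberrant = sum(rowSums(ab) == 0),
       n_genes = nrow(ab))
}
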