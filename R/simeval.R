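# NB draws with elementwise (mu, phi); phi = 0 cells are Poisson.
rnb <- function(n, mu, phi) {
  mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  out <- numeric(n)
  pois <- phi < 1e-12
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois),
                                               size = 1 / phi[!pois],
                                               mu = mu[!pois])
  out
}

#' Build a pool of per-gene (mu, phi) parameters
#'
#' The simulation draws each gene's normal-group NB parameters from a pool.
#' An empirical pool is a table of per-gene estimates from real data (e.g.
#' fitted normal-group means and dispersions); the synthetic default is a
#' documented stand-in with `log10(mu) ~ N(2, 0.5^2)` truncated to
#' `mu >= 1` and `phi ~ Gamma(shape 2, mean 0.15)`, spanning the low-count
#' to highly-expressed range typical of bulk RNA-seq.
#'
#' @param source Either the string `"synthetic"` or a data frame with
#'   columns `gene_id`, `mu`, `phi`.
#' @param n_pool Number of synthetic pairs to draw (ignored for empirical).
#' @param seed Seed for the synthetic draw.
#' @return Object of class `param_pool`: data frame with columns `mu`,
#'   `phi`; attribute `provenance` is `"empirical-file"` or `"synthetic"`.
#' @export
build_parameter_pool <- function(source = "synthetic", n_pool = 5000,
                                 seed = NULL) {
  if (is.data.frame(source)) {
    if (!all(c("mu", "phi") %in% names(source)))
      stop("empirical pool needs columns mu and phi", call. = FALSE)
    if (any(source$mu <= 0) || anyNA(source$mu))
      stop("empirical pool contains mu <= 0", call. = FALSE)
    if (any(source$phi < 0) || anyNA(source$phi))
      stop("empirical pool contains phi < 0", call. = FALSE)
    pool <- data.frame(mu = source$mu, phi = source$phi)
    attr(pool, "provenance") <- "empirical-file"
  } else if (identical(source, "synthetic")) {
    pool <- with_local_seed(seed, {
      lmu <- stats::rnorm(n_pool, mean = 2, sd = 0.5)
      while (any(bad <- lmu < 0))  # truncate to mu >= 1
        lmu[bad] <- stats::rnorm(sum(bad), mean = 2, sd = 0.5)
      data.frame(mu = 10^lmu,
                 phi = stats::rgamma(n_pool, shape = 2, scale = 0.15 / 2))
    })
    attr(pool, "provenance") <- "synthetic"
  } else stop("source must be 'synthetic' or an empirical data frame",
              call. = FALSE)
  class(pool) <- c("param_pool", "data.frame")
  pool
}

scenario_of_study <- c("1" = 1L, "2" = 2L, "3" = 3L)

#' Simulate one study dataset with ground truth
#'
#' Generates a two-group count matrix under one of four study designs.
#' Normal-group counts are NB with gene parameters sampled (with
#' replacement) from the pool; equally-expressed (EE) disease genes follow
#' the same law. DE genes follow one of three scenarios:
#' * Scenario 1 — dispersion shift in every disease replicate:
#'   `phi2 = phi1 + X_phi * delta_phi`, `delta_phi ~ Beta(2, 2)`,
#'   `X_phi = 0.4`.
#' * Scenario 2 — the same dispersion shift, but only in the last `k`
#'   replicates, `k ~ U\{1, 2, 3, 4\}`.
#' * Scenario 3 — joint shift: `phi2 = phi1 + 0.3 * delta_phi` and
#'   `mu2 = mu1 + 2 * delta_mu * sigma1`, `delta_mu ~ Beta(2, 4)`,
#'   `sigma1 = sqrt(mu1 + phi1 * mu1^2)` (the NB standard deviation).
#'
#' Studies 1-3 use a 4:1 EE:DE split (4000/1000 at 5000 genes) with the
#' matching scenario; study 4 mixes 79% EE with the three scenarios in
#' equal 7% shares (3950/350/350/350 at 5000 genes). Library sizes are equal
#' by construction, so the counts are treated as already normalized.
#'
#' @param study Study id in 1..4.
#' @param n_genes Total genes.
#' @param n_per_group Replicates per group.
#' @param pool A `param_pool` from [build_parameter_pool()].
#' @param seed Seed for all draws.
#' @return List with `counts` (a normalized [desyn_counts]), `truth` (data
#'   frame: `gene_id`, `is_de`, `scenario`, `mu1`, `phi1`, `delta_phi`,
#'   `delta_mu`, `k`), and per-replicate disease parameter matrices `mu2`,
#'   `phi2`.
#' @export
simulate_study <- function(study, n_genes = 5000, n_per_group = 4, pool,
                           seed = NULL) {
  if (!study %in% 1:4) stop("study must be 1, 2, 3, or 4", call. = FALSE)
  stopifnot(inherits(pool, "param_pool"), n_per_group >= 2)
  with_local_seed(seed, {
    if (study == 4) {
      n_each <- round(n_genes * 0.07)
      scen <- c(rep(0L, n_genes - 3 * n_each),
                rep(1L, n_each), rep(2L, n_each), rep(3L, n_each))
    } else {
      n_de <- round(n_genes * 0.2)
      scen <- c(rep(0L, n_genes - n_de),
                rep(scenario_of_study[[as.character(study)]], n_de))
    }
    G <- n_genes; n2 <- n_per_group
    pick <- sample.int(nrow(pool), G, replace = TRUE)
    mu1 <- pool$mu[pick]; phi1 <- pool$phi[pick]
    X_phi <- ifelse(scen == 3L, 0.3, 0.4)
    delta_phi <- ifelse(scen > 0L, stats::rbeta(G, 2, 2), NA_real_)
    delta_mu <- ifelse(scen == 3L, stats::rbeta(G, 2, 4), NA_real_)
    kmax <- min(4L, n2)
    k <- ifelse(scen == 2L, sample.int(kmax, G, replace = TRUE), NA_integer_)
    mu2 <- matrix(mu1, G, n2)
    phi2 <- matrix(phi1, G, n2)
    s1 <- scen == 1L
    phi2[s1, ] <- phi1[s1] + X_phi[s1] * delta_phi[s1]
    s2 <- which(scen == 2L)
    for (g in s2) {
      cols <- (n2 - k[g] + 1L):n2   # the last k replicates
      phi2[g, cols] <- phi1[g] + X_phi[g] * delta_phi[g]
    }
    s3 <- scen == 3L
    sigma1 <- sqrt(mu1 + phi1 * mu1^2)
    phi2[s3, ] <- phi1[s3] + X_phi[s3] * delta_phi[s3]
    mu2[s3, ] <- mu1[s3] + 2 * delta_mu[s3] * sigma1[s3]
    y1 <- matrix(rnb(G * n_per_group, rep(mu1, n_per_group),
                     rep(phi1, n_per_group)), G, n_per_group)
    y2 <- matrix(rnb(G * n2, as.vector(mu2), as.vector(phi2)), G, n2)
    counts <- cbind(y1, y2)
    rownames(counts) <- sprintf("gene%05d", seq_len(G))
    colnames(counts) <- c(paste0("normal", seq_len(n_per_group)),
                          paste0("disease", seq_len(n2)))
    cm <- desyn_counts(counts, rep(c(1L, 2L), c(n_per_group, n2)),
                       normalized = TRUE)
    truth <- data.frame(gene_id = rownames(counts), is_de = scen > 0L,
                        scenario = scen, mu1 = mu1, phi1 = phi1,
                        delta_phi = delta_phi, delta_mu = delta_mu, k = k)
    rownames(mu2) <- rownames(phi2) <- rownames(counts)
    list(counts = cm, truth = truth, mu2 = mu2, phi2 = phi2)
  })
}

#' Simulate a fully-null (all-EE) dataset
#'
#' Both groups are drawn from the same per-gene NB law with parameters
#' sampled from the pool; used for null-calibration checks.
#'
#' @inheritParams simulate_study
#' @return Same structure as [simulate_study()]; every gene is EE.
#' @export
simulate_null <- function(n_genes = 1000, n_per_group = 4, pool,
                          seed = NULL) {
  stopifnot(inherits(pool, "param_pool"))
  with_local_seed(seed, {
    G <- n_genes; n <- 2L * n_per_group
    pick <- sample.int(nrow(pool), G, replace = TRUE)
    mu1 <- pool$mu[pick]; phi1 <- pool$phi[pick]
    counts <- matrix(rnb(G * n, rep(mu1, n), rep(phi1, n)), G, n)
    rownames(counts) <- sprintf("gene%05d", seq_len(G))
    colnames(counts) <- c(paste0("normal", seq_len(n_per_group)),
                          paste0("disease", seq_len(n_per_group)))
    cm <- desyn_counts(counts, rep(c(1L, 2L), each = n_per_group),
                       normalized = TRUE)
    truth <- data.frame(gene_id = rownames(counts), is_de = FALSE,
                        scenario = 0L, mu1 = mu1, phi1 = phi1,
                        delta_phi = NA_real_, delta_mu = NA_real_,
                        k = NA_integer_)
    list(counts = cm, truth = truth,
         mu2 = matrix(mu1, G, n_per_group),
         phi2 = matrix(phi1, G, n_per_group))
  })
}

#' Evaluate a gene ranking against simulation truth
#'
#' Computes, for each nominal FDR level, the declared set (score <= level),
#' the true positive rate and the realized false discovery proportion
#' (defined as 0 when nothing is declared), plus the full ROC curve obtained
#' by sweeping the score threshold (ties grouped, trapezoidal area).
#' `NA` scores are treated as least significant: never declared and ranked
#' last.
#'
#' @param scores Per-gene q-values or p-values; lower = more significant.
#' @param is_de Logical ground-truth DE flags, aligned with `scores`.
#' @param fdr_grid Nominal FDR levels to evaluate.
#' @return Object of class `desyn_eval`: list with `by_level` (data frame:
#'   `level`, `n_declared`, `tp`, `tpr`, `actual_fdr`), `roc` (data frame
#'   `fpr`, `tpr`), `auc`.
#' @export
evaluate <- function(scores, is_de, fdr_grid = c(0.01, 0.05, 0.1)) {
  if (length(scores) != length(is_de))
    stop("scores and truth have different lengths", call. = FALSE)
  is_de <- as.logical(is_de)
  s <- ifelse(is.na(scores), Inf, scores)
  nD <- sum(is_de); nE <- sum(!is_de)
  by_level <- do.call(rbind, lapply(fdr_grid, function(lv) {
    decl <- s <= lv
    tp <- sum(decl & is_de)
    fp <- sum(decl & !is_de)
    data.frame(level = lv, n_declared = sum(decl), tp = tp,
               tpr = if (nD > 0) tp / nD else NA_real_,
               actual_fdr = if (sum(decl) > 0) fp / sum(decl) else 0)
  }))
  o <- order(s)
  ss <- s[o]; d <- is_de[o]
  last <- which(!duplicated(ss, fromLast = TRUE))  # last index per tie group
  tpr <- c(0, cumsum(d)[last] / max(nD, 1))
  fpr <- c(0, cumsum(!d)[last] / max(nE, 1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(by_level = by_level,
                 roc = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "desyn_eval")
}

#' @export
print.desyn_eval <- function(x, ...) {
  cat("evaluation (AUC =", round(x$auc, 4), ")\n")
  print(x$by_level, row.names = FALSE)
  invisible(x)
}

#' Repeat a simulation study and summarize a caller's performance
#'
#' Runs `n_reps` independent repetitions of a study, applies a caller to
#' each simulated matrix, and summarizes true positives, total positives and
#' realized FDR at the nominal level plus AUC, as means and standard
#' deviations across repetitions. Per-repetition seeds are
#' `base_seed + repetition index`.
#'
#' @param study Study id in 1..4.
#' @param n_per_group Replicates per group.
#' @param n_reps Number of repetitions.
#' @param pool A `param_pool`.
#' @param caller `function(cm, seed)` returning per-gene scores (q-values)
#'   aligned with the simulated genes; `NA` = not testable.
#' @param base_seed Base seed.
#' @param n_genes Genes per repetition.
#' @param fdr Nominal FDR level for the declared set.
#' @return List with `per_rep` (data frame: `rep`, `tp`, `n_declared`,
#'   `actual_fdr`, `tpr`, `auc`) and `summary` (means and SDs).
#' @export
run_study_replicates <- function(study, n_per_group = 4, n_reps = 50, pool,
                                 caller, base_seed = 1, n_genes = 5000,
                                 fdr = 0.05) {
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    seed_i <- base_seed + i
    sim <- simulate_study(study, n_genes, n_per_group, pool, seed = seed_i)
    q <- tryCatch(caller(sim$counts, seed_i), error = function(e)
      stop("caller failed on repetition ", i, ": ", conditionMessage(e),
           call. = FALSE))
    ev <- evaluate(q, sim$truth$is_de, fdr_grid = fdr)
    rows[[i]] <- data.frame(rep = i, tp = ev$by_level$tp,
                            n_declared = ev$by_level$n_declared,
                            actual_fdr = ev$by_level$actual_fdr,
                            tpr = ev$by_level$tpr, auc = ev$auc)
  }
  per_rep <- do.call(rbind, rows)
  num <- per_rep[, c("tp", "n_declared", "actual_fdr", "tpr", "auc")]
  list(per_rep = per_rep,
       summary = data.frame(stat = names(num),
                            mean = vapply(num, mean, numeric(1)),
                            sd = vapply(num, stats::sd, numeric(1)),
                            row.names = NULL))
}

#' Caller wrapping the full mean-and-dispersion test
#'
#' Adapter with the `function(cm, seed)` signature expected by
#' [run_study_replicates()]: runs the core pipeline (no filtering or TMM;
#' simulated counts are already normalized with equal library sizes) and
#' returns per-gene q-values.
#' @param cm A normalized [desyn_counts].
#' @param seed Seed for permutation subsampling.
#' @param ... Passed to [desyn_core()].
#' @return Per-gene q-values (`NA` for untestable genes).
#' @export
desyn_caller <- function(cm, seed, ...) {
  desyn_core(cm, seed = seed, ...)$results$q_value
}

#' Caller wrapping the mean-only NB LRT baseline
#'
#' @inheritParams desyn_caller
#' @return Per-gene q-values from Storey's method applied to the mean-only
#'   chi-square p-values.
#' @export
meanonly_caller <- function(cm, seed, ...) {
  res <- meanonly_test(cm$counts, cm$group)
  storey_qvalues(res$p)
}
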