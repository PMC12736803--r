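# Negative-binomial threshold-Wald differential expression with
# empirical-Bayes false-sign-rate shrinkage, and the cross-experiment
# consensus selection built on top of it.

#' Median-of-ratios size factors
#'
#' Per gene, the geometric mean over samples is the reference; each sample's
#' factor is the median over genes (with positive reference) of
#' count/reference. If no gene is positive in all samples, the geometric
#' mean is computed over positive counts only for genes positive in at least
#' half the samples.
#'
#' @param counts gene x sample non-negative integer matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  logc <- log(counts)
  logc[!is.finite(logc)] <- NA
  all_pos <- rowSums(is.na(logc)) == 0
  if (any(all_pos)) {
    ref <- rowMeans(logc[all_pos, , drop = FALSE])
    lr <- logc[all_pos, , drop = FALSE] - ref
  } else {
    half_pos <- rowSums(!is.na(logc)) >= ncol(counts) / 2
    if (!any(half_pos))
      sg_stop("no gene sufficiently expressed to normalize",
              "solgrn_normalization_error")
    ref <- rowMeans(logc[half_pos, , drop = FALSE], na.rm = TRUE)
    lr <- logc[half_pos, , drop = FALSE] - ref
  }
  sf <- exp(apply(lr, 2, median, na.rm = TRUE))
  setNames(sf, colnames(counts))
}

# Per-gene method-of-moments NB dispersion on normalized counts, shrunk
# 50:50 (log scale) toward a log-linear mean-dispersion trend. Cells are
# experiment x condition groups so condition means are not absorbed into
# the variance.
estimate_dispersion <- function(norm_counts, cells) {
  cells <- droplevels(as.factor(cells))
  mu <- rowMeans(norm_counts)
  n <- ncol(norm_counts)
  n_cells <- nlevels(cells)
  ss <- matrix(0, nrow(norm_counts), 1)
  for (lv in levels(cells)) {
    cols <- which(cells == lv)
    if (length(cols) < 2) next
    sub <- norm_counts[, cols, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  dfree <- max(1, n - n_cells)
  s2 <- as.vector(ss) / dfree
  raw <- pmax((s2 - mu) / pmax(mu, 1e-8)^2, 1e-8)
  use <- mu >= 1
  if (sum(use) >= 10) {
    fit <- lm(log(raw[use]) ~ log(mu[use]))
    trend <- exp(coef(fit)[1] + coef(fit)[2] * log(pmax(mu, 1e-8)))
  } else {
    trend <- rep(exp(mean(log(raw))), length(raw))
  }
  alpha <- exp(0.5 * log(raw) + 0.5 * log(pmax(trend, 1e-8)))
  pmin(pmax(alpha, 1e-8), 10)
}

# IRLS fit of a log-link NB GLM with fixed dispersion alpha and offset.
# Returns coefficient vector and covariance of the estimates.
nb_irls <- function(y, X, offset, alpha, maxit = 25, tol = 1e-8) {
  beta <- qr.coef(qr(X), log((y + 0.5)) - offset)
  beta[is.na(beta)] <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- eta - offset + (y - mu) / mu
    fit <- lm.wfit(X, z, w)
    newb <- fit$coefficients
    newb[is.na(newb)] <- 0
    if (max(abs(newb - beta)) < tol) { beta <- newb; break }
    beta <- newb
  }
  eta <- drop(X %*% beta) + offset
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  list(beta = beta, cov = cov)
}

#' Negative-binomial Wald contrast with a fold-change threshold
#'
#' Fits a per-gene NB log-link GLM (intercept, experiment indicators when
#' more than one experiment is present, stress indicator) with median-of-
#' ratios offsets and method-of-moments dispersions shrunk toward a
#' mean-dispersion trend. Tests the composite null |LFC| <= `lfc_threshold`
#' with a Wald statistic evaluated at the nearer boundary
#' (p = 2 x min over boundaries of the one-sided tail, capped at 1).
#'
#' Genes with mean normalized count below `min_mean` are excluded before
#' testing (independent filtering); all-zero genes are flagged untestable
#' with p = 1 and LFC = 0.
#'
#' @param counts gene x sample integer matrix.
#' @param samples data frame with `sample_id`, `experiment_id`, `condition`
#'   (`control`/`stress`), rows matching `counts` columns.
#' @param lfc_threshold log2 threshold of the composite null (default 0.32).
#' @param min_mean independent-filtering cutoff on mean normalized count.
#' @return data frame of class `contrast_result`: gene, base_mean, lfc, se,
#'   wald_p, status (`ok`, `low_count`, `all_zero`).
#' @export
nb_wald_contrast <- function(counts, samples, lfc_threshold = 0.32,
                             min_mean = 1) {
  stopifnot(nrow(samples) == ncol(counts))
  if (lfc_threshold < 0)
    sg_stop("lfc_threshold must be >= 0", "solgrn_config_error")
  cond <- factor(samples$condition, levels = c("control", "stress"))
  if (nlevels(droplevels(cond)) < 2)
    sg_stop("both conditions required", "solgrn_design_error")
  exper <- factor(samples$experiment_id)
  multi <- nlevels(exper) > 1
  X <- if (multi)
    stats::model.matrix(~ exper + cond) else stats::model.matrix(~ cond)
  if (qr(X)$rank < ncol(X))
    sg_stop("design matrix is not full rank (confounded design)",
            "solgrn_design_error")
  sf <- size_factors(counts)
  offset <- log(sf)
  q <- sweep(counts, 2, sf, `/`)
  base_mean <- rowMeans(q)
  alpha <- estimate_dispersion(q, interaction(exper, cond))

  ln2 <- log(2)
  n <- nrow(counts)
  out <- data.frame(gene = rownames(counts), base_mean = base_mean,
                    lfc = NA_real_, se = NA_real_, wald_p = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  sidx <- ncol(X)   # stress coefficient is last
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) {
      out$lfc[i] <- 0; out$se[i] <- NA; out$wald_p[i] <- 1
      out$status[i] <- "all_zero"
      next
    }
    if (base_mean[i] < min_mean) {
      out$status[i] <- "low_count"
      next
    }
    fit <- nb_irls(y, X, offset, alpha[i])
    if (is.null(fit$cov)) { out$status[i] <- "all_zero"; out$wald_p[i] <- 1; next }
    b <- fit$beta[sidx] / ln2
    se <- sqrt(fit$cov[sidx, sidx]) / ln2
    # composite null |beta| <= threshold, evaluated at the nearer boundary
    p_up <- pnorm((b - lfc_threshold) / se, lower.tail = FALSE)
    p_dn <- pnorm((b + lfc_threshold) / se, lower.tail = TRUE)
    out$lfc[i] <- b; out$se[i] <- se
    out$wald_p[i] <- min(1, 2 * min(p_up, p_dn))
  }
  attr(out, "lfc_threshold") <- lfc_threshold
  class(out) <- c("contrast_result", class(out))
  out
}

#' Empirical-Bayes shrinkage and false-sign-rate s-values
#'
#' Normal-normal shrinkage: the prior N(0, tau^2) has tau^2 estimated by
#' method of moments from the raw effects and their standard errors
#' (tau^2 = max(0, var(lfc) - mean(se^2))). `shrunk_lfc` is the posterior
#' mean; the s-value is the posterior probability that the true effect's
#' sign differs from the sign of the posterior mean.
#'
#' @param result a [nb_wald_contrast()] result.
#' @return the same data frame with `shrunk_lfc` and `s_value` columns;
#'   attribute `tau2` records the prior variance. If tau^2 = 0 all shrunken
#'   effects are 0 with s-value 0.5 and attribute `degenerate` is TRUE.
#' @export
shrink_and_svalue <- function(result) {
  ok <- result$status == "ok" & is.finite(result$lfc) & is.finite(result$se)
  result$shrunk_lfc <- NA_real_
  result$s_value <- NA_real_
  # moment estimation of the prior variance uses informative genes only:
  # near-divergent fits (one arm all zero) have huge se that carry no
  # information but would dominate mean(se^2)
  est <- ok & result$se <= 10
  if (sum(est) < 2) est <- ok
  tau2 <- max(0, var(result$lfc[est]) - mean(result$se[est]^2))
  attr(result, "tau2") <- tau2
  attr(result, "degenerate") <- tau2 == 0
  if (tau2 == 0) {
    result$shrunk_lfc[ok] <- 0
    result$s_value[ok] <- 0.5
    return(result)
  }
  se2 <- result$se[ok]^2
  shrink <- tau2 / (tau2 + se2)
  post_mean <- shrink * result$lfc[ok]
  post_sd <- sqrt(tau2 * se2 / (tau2 + se2))
  # P(true sign != sign(posterior mean)); 0.5 exactly at zero
  s <- pnorm(0, mean = abs(post_mean), sd = post_sd)
  result$shrunk_lfc[ok] <- post_mean
  result$s_value[ok] <- s
  result
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff its s-value is strictly below `s_cut` and
#' |shrunk LFC| >= `lfc_cut`; direction is the sign of the shrunken effect.
#'
#' @param result a [shrink_and_svalue()] result.
#' @param s_cut s-value cutoff (strict; default 0.005).
#' @param lfc_cut absolute shrunken-LFC cutoff (inclusive; default 0.32).
#' @return data frame gene, direction (`up`/`down`), shrunk_lfc, s_value.
#' @export
call_degs <- function(result, s_cut = 0.005, lfc_cut = 0.32) {
  sel <- !is.na(result$s_value) & result$s_value < s_cut &
    !is.na(result$shrunk_lfc) & abs(result$shrunk_lfc) >= lfc_cut
  data.frame(gene = result$gene[sel],
             direction = ifelse(result$shrunk_lfc[sel] > 0, "up", "down"),
             shrunk_lfc = result$shrunk_lfc[sel],
             s_value = result$s_value[sel],
             stringsAsFactors = FALSE)
}

#' Occurrence-group consensus over per-comparison DEG calls
#'
#' Counts, per gene, the number of pairwise comparisons in which it was
#' called a DEG. Direction is the consensus sign when all calls agree and
#' `discordant` otherwise. A gene is retained iff its occurrence reaches
#' `min_occurrence` and its direction is not discordant.
#'
#' @param per_comparison_degs list of [call_degs()] outputs (one per
#'   comparison).
#' @param min_occurrence occurrence cutoff (<= number of comparisons).
#' @return data frame gene, occurrence, direction, retained.
#' @export
occurrence_rank <- function(per_comparison_degs, min_occurrence) {
  if (length(per_comparison_degs) < 1)
    sg_stop("need at least one comparison", "solgrn_input_error")
  if (min_occurrence > length(per_comparison_degs))
    sg_stop("min_occurrence exceeds the number of comparisons",
            "solgrn_input_error")
  all <- do.call(rbind, per_comparison_degs)
  if (is.null(all) || nrow(all) == 0)
    return(data.frame(gene = character(0), occurrence = integer(0),
                      direction = character(0), retained = logical(0),
                      stringsAsFactors = FALSE))
  tab <- table(all$gene)
  genes <- names(tab)
  dirs <- vapply(genes, function(g) {
    d <- unique(all$direction[all$gene == g])
    if (length(d) == 1) d else "discordant"
  }, "")
  out <- data.frame(gene = genes, occurrence = as.integer(tab),
                    direction = unname(dirs), stringsAsFactors = FALSE)
  out$retained <- out$occurrence >= min_occurrence &
    out$direction != "discordant"
  out[order(out$gene), ]
}

#' Select the top genes per direction from the consensus/combined intersection
#'
#' Candidate pool: genes retained by the occurrence consensus that are also
#' DEGs of the combined (batch-adjusted) model in the same direction.
#' Ordering key: occurrence descending, |combined shrunken LFC| descending,
#' gene id ascending (so ranks are a total order). The top `k_per_direction`
#' per direction are returned; when a direction's pool is smaller than k,
#' the entire pool is returned.
#'
#' @param consensus [occurrence_rank()] output.
#' @param combined_degs [call_degs()] output of the combined model.
#' @param k_per_direction selection cap per direction (default 500).
#' @return data frame gene, direction, occurrence, combined_lfc, rank,
#'   selected (all TRUE).
#' @export
select_top <- function(consensus, combined_degs, k_per_direction = 500) {
  pool <- merge(consensus[consensus$retained, ],
                combined_degs, by = "gene")
  pool <- pool[pool$direction.x == pool$direction.y, ]
  if (nrow(pool) == 0)
    return(data.frame(gene = character(0), direction = character(0),
                      occurrence = integer(0), combined_lfc = numeric(0),
                      rank = integer(0), selected = logical(0),
                      stringsAsFactors = FALSE))
  pool <- data.frame(gene = pool$gene, direction = pool$direction.x,
                     occurrence = pool$occurrence,
                     combined_lfc = pool$shrunk_lfc,
                     stringsAsFactors = FALSE)
  out <- NULL
  for (dir in c("up", "down")) {
    sub <- pool[pool$direction == dir, ]
    if (nrow(sub) == 0) next
    ord <- order(-sub$occurrence, -abs(sub$combined_lfc), sub$gene)
    sub <- sub[ord, ]
    k <- min(k_per_direction, nrow(sub))
    sub <- sub[seq_len(k), ]
    sub$rank <- seq_len(k)
    out <- rbind(out, sub)
  }
  out$selected <- TRUE
  rownames(out) <- NULL
  out
}

#' Run the full two-strategy consensus selection
#'
#' Strategy 1: one stress-vs-control contrast per experiment, DEGs called
#' per comparison, occurrence consensus. Strategy 2: one combined model over
#' all experiments with the experiment factor in the design. The final set
#' is the intersection, ranked by occurrence group then |LFC|.
#'
#' @param counts gene x sample integer matrix.
#' @param samples sample sheet (sample_id, experiment_id, condition).
#' @param min_occurrence occurrence cutoff; default majority of experiments.
#' @param k_per_direction top-set size per direction.
#' @param s_cut,lfc_cut DEG-calling cutoffs.
#' @return list with `per_experiment` (contrast results), `combined`
#'   (contrast result), `combined_degs`, `consensus`, `selection`.
#' @export
consensus_select <- function(counts, samples,
                             min_occurrence = NULL, k_per_direction = 500,
                             s_cut = 0.005, lfc_cut = 0.32) {
  exps <- unique(samples$experiment_id)
  if (is.null(min_occurrence))
    min_occurrence <- ceiling(length(exps) * 5 / 6)
  per_exp <- lapply(exps, function(e) {
    sel <- samples$experiment_id == e
    shrink_and_svalue(
      nb_wald_contrast(counts[, sel, drop = FALSE], samples[sel, ],
                       lfc_threshold = lfc_cut))
  })
  names(per_exp) <- exps
  per_exp_degs <- lapply(per_exp, call_degs, s_cut = s_cut, lfc_cut = lfc_cut)
  combined <- shrink_and_svalue(
    nb_wald_contrast(counts, samples, lfc_threshold = lfc_cut))
  combined_degs <- call_degs(combined, s_cut = s_cut, lfc_cut = lfc_cut)
  consensus <- occurrence_rank(per_exp_degs, min_occurrence)
  selection <- select_top(consensus, combined_degs, k_per_direction)
  list(per_experiment = per_exp, per_experiment_degs = per_exp_degs,
       combined = combined, combined_degs = combined_degs,
       consensus = consensus, selection = selection)
}
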