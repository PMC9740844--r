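#' Log10 transform and Pareto-scale a metabolite panel
#'
#' Per metabolite: `y = log10(x)`, then mean-centering and division by the
#' square root of the standard deviation (Pareto scaling, the usual
#' compromise between no scaling and unit-variance scaling for metabolomics
#' panels spanning several orders of magnitude). Metabolites with zero
#' variance are passed through centered-only, with a warning.
#'
#' @param panel A [metabolite_panel()] (strictly positive concentrations),
#'   or a positive metabolite-by-sample matrix.
#' @return Numeric matrix, samples in rows, metabolites in columns (the
#'   orientation consumed by [fit_plsda()]). Attribute `"groups"` carries
#'   the panel's group factor when a panel was given.
#' @export
#' @examples
#' m <- matrix(c(1, 10, 100), nrow = 1,
#'             dimnames = list("X", c("s1", "s2", "s3")))
#' preprocess(metabolite_panel(m, c("A", "A", "B")))  # -1, 0, 1
preprocess <- function(panel) {
  if (inherits(panel, "metabolite_panel")) {
    mat <- panel$concentrations
    groups <- panel$groups
  } else {
    mat <- panel
    groups <- NULL
    bad <- which(!is.finite(mat) | mat <= 0, arr.ind = TRUE)
    if (length(bad))
      stop_ctx("non-positive concentration for metabolite '",
               rownames(mat)[bad[1, 1]] %||% bad[1, 1], "', sample '",
               colnames(mat)[bad[1, 2]] %||% bad[1, 2], "'",
               class = "validation_error")
  }
  y <- log10(t(mat))                       # samples x metabolites
  mu <- colMeans(y)
  s <- apply(y, 2, stats::sd)
  if (any(s == 0))
    warning("constant metabolite(s) passed through centered-only: ",
            paste(colnames(y)[s == 0], collapse = ", "))
  out <- sweep(y, 2, mu)
  div <- ifelse(s > 0, sqrt(s), 1)
  out <- sweep(out, 2, div, "/")
  attr(out, "groups") <- groups
  out
}

#' Fit a two-group PLS-DA model (NIPALS PLS1)
#'
#' Partial least squares discriminant analysis against a +/-1 group-coded
#' response by the NIPALS algorithm with per-component deflation: for each
#' component, the weight vector is `w = X'y / ||X'y||`, scores `t = Xw`,
#' X-loadings `p = X't/(t't)`, Y-loading `q = y't/(t't)`, then `X` and `y`
#' are deflated by the rank-one fits. Columns of `X` and `y` are centered
#' internally (a no-op after [preprocess()]). The explained Y-variance of
#' component a is `q_a^2 t_a't_a / y0'y0`.
#'
#' @param X Samples-by-variables numeric matrix, e.g. from [preprocess()].
#' @param groups Two-level factor/character of length `nrow(X)`; defaults
#'   to `attr(X, "groups")`. The first level is coded +1.
#' @param n_components Number of latent components (default 2); reduced
#'   with a warning if the data rank is lower.
#' @param tol Score-norm threshold below which the residual is considered
#'   rank-deficient.
#' @return Object of class `"plsda_fit"`: `scores` (samples x components),
#'   `weights` (unit-norm columns), `x_loadings`, `y_loadings`,
#'   `explained_y_variance` (fractions), `coefficients` (regression vector
#'   for prediction), `vip` (see [vip_scores()]), plus the group coding.
#' @export
#' @examples
#' sim <- simulate_metabolite_panel(metabo_sim_config(
#'   planted_effects = c(Orn = 1), seed = 4))
#' fit <- fit_plsda(preprocess(sim$panel))
#' fit
fit_plsda <- function(X, groups = attr(X, "groups"), n_components = 2,
                      tol = 1e-10) {
  X <- as.matrix(X)
  if (is.null(groups))
    stop_ctx("groups must be supplied (or attached to X by preprocess)",
             class = "input_error")
  groups <- if (is.factor(groups)) droplevels(groups) else
    factor(groups, levels = unique(groups))
  if (nlevels(groups) != 2)
    stop_ctx("PLS-DA here is a two-group method; got ", nlevels(groups),
             " groups", class = "input_error")
  if (min(tabulate(groups)) < 2)
    stop_ctx("need at least 2 samples per group", class = "input_error")
  n_components <- assert_count(n_components, "n_components")

  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  y0 <- ifelse(groups == levels(groups)[1], 1, -1)
  y_center <- mean(y0)
  y <- y0 - y_center
  ssy0 <- sum(y^2)
  p <- ncol(Xc)

  W <- P <- matrix(0, p, 0)
  Tt <- matrix(0, nrow(Xc), 0)
  q <- ssy <- numeric(0)
  Xd <- Xc; yd <- y
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    wn <- sqrt(sum(w^2))
    if (wn < tol) {
      warning(sprintf(
        "rank deficiency: reducing n_components from %d to %d",
        n_components, a - 1L))
      break
    }
    w <- w / wn
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    if (tt < tol) {
      warning(sprintf(
        "rank deficiency: reducing n_components from %d to %d",
        n_components, a - 1L))
      break
    }
    p_ <- drop(crossprod(Xd, t_)) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - q_ * t_
    W <- cbind(W, w); P <- cbind(P, p_); Tt <- cbind(Tt, t_)
    q <- c(q, q_); ssy <- c(ssy, q_^2 * tt)
  }
  a <- length(q)
  if (a == 0)
    stop_ctx("no PLS component could be extracted (X'y is null)",
             class = "rank_error")
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("comp", seq_len(a)))
  dimnames(Tt) <- list(rownames(X), paste0("comp", seq_len(a)))
  ## regression vector B = W (P'W)^-1 q for predicting the coded response
  B <- W %*% solve(crossprod(P, W), q)
  fit <- structure(list(
    n_components = a, scores = Tt, weights = W, x_loadings = P,
    y_loadings = q, explained_y_variance = ssy / ssy0, ssy = ssy,
    coefficients = drop(B), x_center = x_center, y_center = y_center,
    groups = groups, group_levels = levels(groups)), class = "plsda_fit")
  fit$vip <- vip_scores(fit)
  fit
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat(sprintf("PLS-DA fit (%s vs %s): %d component(s)\n",
              x$group_levels[1], x$group_levels[2], x$n_components))
  cat("explained Y-variance per component:",
      paste0(sprintf("%.1f%%", 100 * x$explained_y_variance),
             collapse = ", "), "\n")
  top <- sort(x$vip, decreasing = TRUE)
  cat("top VIP:", paste(sprintf("%s (%.2f)", names(top)[1:min(5, length(top))],
                                top[1:min(5, length(top))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.plsda_fit <- function(object, ...) {
  list(n_components = object$n_components,
       explained_y_variance = object$explained_y_variance,
       n_discriminant_vip_1.5 = sum(object$vip > 1.5))
}

#' @export
coef.plsda_fit <- function(object, ...) object$coefficients

#' Predict group membership from a PLS-DA fit
#' @param object A [fit_plsda()] model.
#' @param newdata Samples-by-variables matrix on the same variables (and
#'   the same preprocessing) as the training data.
#' @param ... Unused.
#' @return Data frame with the predicted coded response (`y_hat`) and the
#'   predicted group label (sign of `y_hat`).
#' @export
predict.plsda_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  yh <- drop(sweep(newdata, 2, object$x_center) %*% object$coefficients) +
    object$y_center
  data.frame(sample = rownames(newdata) %||% seq_len(nrow(newdata)),
             y_hat = yh,
             group = object$group_levels[ifelse(yh >= 0, 1L, 2L)])
}

#' Score plot of a PLS-DA fit
#' @param x A [fit_plsda()] model.
#' @param components Which two components to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.plsda_fit <- function(x, components = c(1, 2), ...) {
  a <- min(components[2], x$n_components)
  s <- x$scores[, c(components[1], a), drop = FALSE]
  if (ncol(s) == 1) s <- cbind(s, jitter(rep(0, nrow(s))))
  graphics::plot(s, col = as.integer(x$groups), pch = 19,
                 xlab = sprintf("Component %d (%.1f%%)", components[1],
                                100 * x$explained_y_variance[components[1]]),
                 ylab = sprintf("Component %d (%.1f%%)", a,
                                100 * x$explained_y_variance[a]), ...)
  graphics::legend("topright", legend = x$group_levels, col = 1:2, pch = 19)
  invisible(x)
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt( p * sum_a( w_ja^2 * SSY_a ) / sum_a SSY_a )` with `p` the
#' number of variables, `w` the unit-norm PLS weights and `SSY_a` the
#' Y-variance explained by component a — the weighted sum of squares of the
#' PLS loadings, weighting each dimension by the variation it explains.
#' By construction the mean of VIP^2 over variables is exactly 1.
#'
#' @param model A [fit_plsda()] model.
#' @return Named numeric vector of VIP scores (>= 0), one per variable.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_fit"))
  ssy <- model$ssy
  if (sum(ssy) <= 0)
    stop_ctx("VIP undefined: the model explains no Y-variance",
             class = "undefined_vip_error")
  p <- nrow(model$weights)
  vip2 <- p * drop(model$weights^2 %*% ssy) / sum(ssy)
  sqrt(vip2)
}

#' Variables discriminating the groups by VIP
#'
#' @param model A [fit_plsda()] model.
#' @param cutoff Strict VIP cutoff (default 1.5; 1.0 is the other
#'   conventional choice).
#' @return Data frame (metabolite_id, vip) with `vip > cutoff`, sorted
#'   descending.
#' @export
discriminant_features <- function(model, cutoff = 1.5) {
  vip <- if (inherits(model, "plsda_fit")) model$vip else model
  keep <- vip > cutoff
  out <- data.frame(metabolite_id = names(vip)[keep], vip = unname(vip[keep]))
  out <- out[order(-out$vip), , drop = FALSE]
  rownames(out) <- NULL
  out
}

mann_whitney <- function(x, y) {
  ## exact when both groups are small and untied; otherwise the normal
  ## approximation with continuity and tie correction
  exact <- min(length(x), length(y)) <= 8 &&
    !anyDuplicated(c(x, y))
  stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                     correct = TRUE)$p.value
}

#' Normality-gated univariate testing of a metabolite panel
#'
#' Per metabolite: the D'Agostino-Pearson omnibus test is applied to the
#' raw concentrations of each group; if both groups are consistent with
#' normality (p > `alpha_normality`) the groups are compared by an unpaired
#' Welch t-test, otherwise by a two-sided Mann-Whitney test (exact for
#' small untied samples, normal approximation with continuity and tie
#' correction otherwise). Groups smaller than 8 cannot support the omnibus
#' normality test and fall back to Mann-Whitney with a warning.
#'
#' @param panel A [metabolite_panel()]; the first group level is group A
#'   (fold changes are A over B).
#' @param alpha_normality Normality-gate level (default 0.05).
#' @param alpha Significance level for the direction call (default 0.05).
#' @return Data frame with one row per metabolite: means and standard
#'   errors per group, normality p-values, `test_used`
#'   (welch_t/mann_whitney), `p_value`, `log2_fold_change` and `direction`
#'   (increased/decreased/ns, at `p <= alpha`).
#' @export
univariate_panel <- function(panel, alpha_normality = 0.05, alpha = 0.05) {
  stopifnot(inherits(panel, "metabolite_panel"))
  ga <- levels(panel$groups)[1]
  a_idx <- panel$groups == ga
  na <- sum(a_idx); nb <- sum(!a_idx)
  if (min(na, nb) < 3)
    stop_ctx("insufficient data: univariate testing needs >= 3 samples ",
             "per group", class = "insufficient_data_error")
  can_norm <- min(na, nb) >= 8
  if (!can_norm)
    warning("groups too small for the normality test; ",
            "using Mann-Whitney throughout")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  rows <- lapply(panel$metabolite_ids, function(mid) {
    xa <- panel$concentrations[mid, a_idx]
    xb <- panel$concentrations[mid, !a_idx]
    if (can_norm) {
      pna <- tryCatch(dagostino_pearson(xa)$p.value,
                      muscleomics_error = function(e) NA_real_)
      pnb <- tryCatch(dagostino_pearson(xb)$p.value,
                      muscleomics_error = function(e) NA_real_)
    } else pna <- pnb <- NA_real_
    use_welch <- isTRUE(pna > alpha_normality) &&
      isTRUE(pnb > alpha_normality)
    p <- if (use_welch)
      stats::t.test(xa, xb, var.equal = FALSE)$p.value
    else mann_whitney(xa, xb)
    l2fc <- log2(mean(xa) / mean(xb))
    data.frame(metabolite_id = mid,
               mean_a = mean(xa), sem_a = sem(xa),
               mean_b = mean(xb), sem_b = sem(xb),
               normality_p_a = pna, normality_p_b = pnb,
               test_used = if (use_welch) "welch_t" else "mann_whitney",
               p_value = p, log2_fold_change = l2fc,
               direction = if (p <= alpha && l2fc > 0) "increased"
               else if (p <= alpha && l2fc < 0) "decreased" else "ns")
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- levels(panel$groups)
  out
}

#' Volcano classification of univariate results
#'
#' Classifies each metabolite from its fold change and significance:
#' `increased` iff `log2_fold_change > fc_threshold_log2` and
#' `p_value <= p_threshold`; `decreased` symmetrically. Emits the plotting
#' coordinates (log2 fold change, -log10 p).
#'
#' @param univariate Result of [univariate_panel()], or a
#'   [metabolite_panel()] (tested with defaults first).
#' @param fc_threshold_log2 Absolute log2-fold-change threshold
#'   (default 0: significance-only gating).
#' @param p_threshold Significance threshold (default 0.05).
#' @return Data frame of class `"volcano"`: metabolite_id,
#'   log2_fold_change, neg_log10_p, class.
#' @export
volcano <- function(univariate, fc_threshold_log2 = 0, p_threshold = 0.05) {
  if (inherits(univariate, "metabolite_panel"))
    univariate <- univariate_panel(univariate)
  cls <- with(univariate, ifelse(
    p_value <= p_threshold & log2_fold_change > fc_threshold_log2,
    "increased",
    ifelse(p_value <= p_threshold & log2_fold_change < -fc_threshold_log2,
           "decreased", "ns")))
  structure(data.frame(metabolite_id = univariate$metabolite_id,
                       log2_fold_change = univariate$log2_fold_change,
                       neg_log10_p = -log10(univariate$p_value),
                       class = factor(cls, c("increased", "decreased", "ns"))),
            class = c("volcano", "data.frame"),
            thresholds = c(fc = fc_threshold_log2, p = p_threshold))
}

#' @export
plot.volcano <- function(x, ...) {
  cols <- c(increased = "forestgreen", decreased = "firebrick", ns = "grey30")
  graphics::plot(x$log2_fold_change, x$neg_log10_p,
                 col = cols[as.character(x$class)], pch = 19,
                 xlab = "log2 fold change", ylab = "-log10 p", ...)
  thr <- attr(x, "thresholds")
  graphics::abline(h = -log10(thr["p"]), lty = 2)
  if (thr["fc"] > 0) graphics::abline(v = c(-1, 1) * thr["fc"], lty = 3)
  invisible(x)
}

#' Euclidean hierarchical clustering for the panel heatmap
#'
#' Ranks metabolites by univariate p-value, keeps the `top_k` most
#' significant, and clusters both metabolites and samples by agglomerative
#' hierarchical clustering on Euclidean distances over the preprocessed
#' (log10 + Pareto) matrix. Returns the reordered matrix and serialisable
#' dendrogram descriptions (merge table, heights, leaf order).
#'
#' @param panel A [metabolite_panel()] with >= 2 metabolites.
#' @param top_k Number of top-ranked metabolites kept (default 40); capped
#'   at the panel size with a warning.
#' @param linkage Agglomeration method (default `"ward.D2"`, Ward linkage
#'   on Euclidean distances; `"single"`, `"complete"`, `"average"` also
#'   supported).
#' @return List of class `"heatmap_clustering"`: `matrix` (preprocessed,
#'   rows/cols in dendrogram order), `rows` and `cols` (each with `merge`,
#'   `height`, `order`, `labels`), `ranking` (the univariate table used).
#' @export
cluster_heatmap <- function(panel, top_k = 40,
                            linkage = c("ward.D2", "single", "complete",
                                        "average")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(panel, "metabolite_panel"))
  if (nrow(panel$concentrations) < 2)
    stop_ctx("clustering needs at least 2 metabolites",
             class = "input_error")
  univ <- univariate_panel(panel)
  if (top_k > nrow(univ)) {
    warning("top_k exceeds the number of metabolites; using all")
    top_k <- nrow(univ)
  }
  keep <- univ$metabolite_id[order(univ$p_value)][seq_len(top_k)]
  pre <- preprocess(panel)                 # samples x metabolites
  sub <- t(pre[, keep, drop = FALSE])      # metabolites x samples
  dend <- function(mat) {
    hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = linkage)
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = rownames(mat))
  }
  rows <- dend(sub)
  cols <- dend(t(sub))
  structure(list(matrix = sub[rows$order, cols$order, drop = FALSE],
                 rows = rows, cols = cols,
                 ranking = univ[order(univ$p_value), , drop = FALSE],
                 linkage = linkage),
            class = "heatmap_clustering")
}

#' @export
print.heatmap_clustering <- function(x, ...) {
  cat(sprintf(
    "heatmap clustering (%s linkage, Euclidean): %d metabolites x %d samples\n",
    x$linkage, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
plot.heatmap_clustering <- function(x, ...) {
  stats::heatmap(x$matrix, Rowv = NA, Colv = NA, scale = "none", ...)
  invisible(x)
}
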