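panel_from_matrix <- function(mat, groups) {
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("M%02d", seq_len(nrow(mat)))
  metabolite_panel(mat, groups)
}

test_that("preprocessing applies log10 then Pareto scaling per metabolite", {
  m <- matrix(c(1, 10, 100, 2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_warning(pre <- preprocess(panel_from_matrix(m, c("A", "A", "B"))),
                 "constant")
  # {1,10,100} -> log10 {0,1,2} -> centered {-1,0,1}; sd 1 so divisor 1
  expect_equal(unname(pre[, "a"]), c(-1, 0, 1))
  expect_equal(unname(pre[, "b"]), c(0, 0, 0))  # constant: centered-only

  set.seed(19)
  rnd <- matrix(rlnorm(60, sdlog = 1), nrow = 6)
  pre2 <- preprocess(panel_from_matrix(rnd, rep(c("A", "B"), each = 5)))
  # Pareto identity: scaled variance equals the pre-scaling sd
  logsd <- apply(log10(t(rnd)), 2, sd)
  expect_equal(unname(apply(pre2, 2, var)), unname(logsd),
               tolerance = 1e-12)

  bad <- rnd; bad[2, 3] <- 0
  expect_error(metabolite_panel(bad, rep(c("A", "B"), each = 5)),
               class = "validation_error")
})

test_that("PLS-DA separates constructed groups and matches the closed form", {
  # groups differ cleanly along one variable: component-1 scores separate
  set.seed(23)
  X <- cbind(sep = c(rnorm(5, 3, 0.1), rnorm(5, -3, 0.1)),
             matrix(rnorm(40, sd = 0.3), 10))
  g <- rep(c("A", "B"), each = 5)
  fit <- fit_plsda(X, g, n_components = 2)
  s1 <- fit$scores[, 1]
  expect_true(max(s1[g == "B"]) < min(s1[g == "A"]) ||
                max(s1[g == "A"]) < min(s1[g == "B"]))

  # component-1 weights are proportional to X'y for centered data
  Xc <- scale(X, scale = FALSE)
  y <- ifelse(g == "A", 1, -1)
  w_ref <- drop(crossprod(Xc, y - mean(y)))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(unname(fit$weights[, 1]), unname(w_ref), tolerance = 1e-12)
})

test_that("a response aligned with one column yields a unit weight vector", {
  set.seed(29)
  y0 <- rep(c(1, -1), 4)                  # centered +/-1 coding
  g <- ifelse(y0 > 0, "A", "B")
  noise <- matrix(rnorm(8 * 3), 8)
  noise <- sweep(noise, 2, colMeans(noise))
  # strip the response direction out of the noise columns
  noise <- noise - y0 %*% t(crossprod(noise, y0)) / sum(y0^2)
  X <- cbind(noise[, 1], y0 / sqrt(sum(y0^2)), noise[, 2:3])
  fit <- fit_plsda(X, g, n_components = 1)
  w <- fit$weights[, 1]
  # closed form w = X'y / ||X'y|| concentrates on the aligned column
  expect_equal(abs(w[2]), 1, tolerance = 1e-10)
  expect_equal(unname(abs(w[-2])), rep(0, 3), tolerance = 1e-10)
})

test_that("PLS-DA on a planted panel separates the group centroids", {
  sim <- simulate_metabolite_panel(metabo_sim_config(
    planted_effects = c(Orn = 1, C16 = -1), seed = 37))
  fit <- fit_plsda(preprocess(sim$panel))
  cent <- tapply(fit$scores[, 1], fit$groups, mean)
  pooled_sd <- sd(fit$scores[, 1])
  expect_gt(abs(diff(cent)) / pooled_sd, 1)  # clear centroid separation
  expect_true(all(abs(colSums(fit$weights^2) - 1) < 1e-12))  # unit norms
})

test_that("rank-deficient designs reduce the component count with a warning", {
  X <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 4, 6, 8, 10, 12))
  g <- rep(c("A", "B"), 3)
  expect_warning(fit <- fit_plsda(X, g, n_components = 4),
                 "rank deficiency")
  expect_lt(fit$n_components, 4)
})

test_that("VIP scores obey the formula and its normalisation identity", {
  # one component, weights (0.6, 0.8): VIP = sqrt(2 * w^2) exactly
  hand <- structure(list(weights = matrix(c(0.6, 0.8), 2,
                                          dimnames = list(c("x", "y"), NULL)),
                         ssy = 1), class = "plsda_fit")
  expect_equal(unname(vip_scores(hand)),
               c(0.848528137423857, 1.1313708498984762), tolerance = 1e-12)

  # a single variable is forced to VIP = 1 by the normalisation
  one <- structure(list(weights = matrix(1, 1, 1,
                                         dimnames = list("z", NULL)),
                        ssy = 0.4), class = "plsda_fit")
  expect_equal(unname(vip_scores(one)), 1)

  # mean VIP^2 = 1 on fitted models
  set.seed(41)
  for (i in 1:5) {
    X <- matrix(rnorm(12 * 8), 12)
    fit <- fit_plsda(X, rep(c("A", "B"), each = 6), n_components = 2)
    expect_equal(mean(fit$vip^2), 1, tolerance = 1e-10)
  }
  zero <- structure(list(weights = matrix(1, 1, 1), ssy = 0),
                    class = "plsda_fit")
  expect_error(vip_scores(zero), class = "undefined_vip_error")
})

test_that("discriminant feature selection is strict and sorted", {
  p <- 4
  flat <- structure(list(weights = matrix(1 / sqrt(p), p, 1,
                                          dimnames = list(letters[1:p], NULL)),
                         ssy = 1), class = "plsda_fit")
  flat$vip <- vip_scores(flat)            # all exactly 1
  expect_equal(nrow(discriminant_features(flat, cutoff = 1.5)), 0)
  expect_equal(nrow(discriminant_features(flat, cutoff = 1)), 0)  # strict >
  all_of_them <- discriminant_features(flat, cutoff = 0)
  expect_equal(nrow(all_of_them), p)
  sim <- simulate_metabolite_panel(metabo_sim_config(
    planted_effects = c(Orn = 1, Cit = -1, C16 = -1), seed = 43))
  fit <- fit_plsda(preprocess(sim$panel))
  disc <- discriminant_features(fit, cutoff = 1.5)
  expect_true(all(c("Orn", "Cit", "C16") %in% disc$metabolite_id))
  expect_true(all(diff(disc$vip) <= 0))
})

test_that("univariate testing gates on normality and matches test oracles", {
  # identical values in both groups: exact Mann-Whitney, p = 1, ns
  m <- matrix(rep(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 2), nrow = 1,
              dimnames = list("flat", NULL))
  pan <- metabolite_panel(m, rep(c("A", "B"), each = 9))
  u <- univariate_panel(pan)
  expect_equal(u$p_value, 1)
  expect_equal(u$direction, "ns")

  # {1,2,3} vs {4,5,6}: exhaustively enumerated two-sided p = 0.1
  m2 <- matrix(1:6, nrow = 1, dimnames = list("x", NULL))
  pan2 <- metabolite_panel(m2, rep(c("A", "B"), each = 3))
  expect_warning(u2 <- univariate_panel(pan2), "too small")
  expect_equal(u2$p_value, 0.1)
  expect_equal(u2$p_value, mw_exact_oracle(1:3, 4:6))
  expect_equal(u2$test_used, "mann_whitney")
})

test_that("small-group direction calls respect the significance gate", {
  m2 <- matrix(1:6, nrow = 1, dimnames = list("x", NULL))
  pan2 <- metabolite_panel(m2, rep(c("A", "B"), each = 3))
  suppressWarnings(u2 <- univariate_panel(pan2))
  expect_equal(u2$direction, "ns")
  suppressWarnings(u3 <- univariate_panel(pan2, alpha = 0.1))
  expect_equal(u3$direction, "decreased")
})

test_that("Welch branch reproduces the closed-form statistic", {
  set.seed(47)
  conc <- rbind(matrix(abs(rnorm(36, 10, 1)) + 1, nrow = 2))
  rownames(conc) <- c("m1", "m2")
  pan <- metabolite_panel(conc, rep(c("A", "B"), each = 9))
  u <- univariate_panel(pan)
  for (i in seq_len(nrow(u))) {
    xa <- conc[i, 1:9]; xb <- conc[i, 10:18]
    if (u$test_used[i] == "welch_t")
      expect_equal(u$p_value[i], welch_oracle(xa, xb), tolerance = 1e-12)
    expect_equal(u$mean_a[i], mean(xa))
    expect_equal(u$sem_a[i], sd(xa) / 3)    # SEM with n = 9
    expect_equal(u$log2_fold_change[i], log2(mean(xa) / mean(xb)))
  }
  expect_true(any(u$test_used == "welch_t"))

  # skewed data fails the normality gate and falls back to Mann-Whitney
  set.seed(53)
  skew <- rbind(exp(rnorm(18, 0, 2)) + 0.01)
  rownames(skew) <- "s"
  us <- univariate_panel(metabolite_panel(skew, rep(c("A", "B"), each = 9)))
  expect_equal(us$test_used, "mann_whitney")
})

test_that("Mann-Whitney wrapper equals exhaustive enumeration when exact", {
  set.seed(59)
  for (i in 1:10) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1)
    vals <- sample(1:100, na + nb)        # untied
    x <- vals[seq_len(na)]; y <- vals[-seq_len(na)]
    expect_equal(muscleomics:::mann_whitney(x, y), mw_exact_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("volcano classification mirrors thresholds and group relabeling", {
  univ <- data.frame(metabolite_id = c("a", "b", "c", "d"),
                     p_value = c(0.01, 0.2, 0.04, 1),
                     log2_fold_change = c(1.2, 2.0, -0.8, 0.0))
  v <- volcano(univ)
  expect_equal(as.character(v$class), c("increased", "ns", "decreased", "ns"))
  expect_equal(v$neg_log10_p, -log10(univ$p_value))
  # all p = 1 -> everything ns
  allns <- volcano(transform(univ, p_value = 1))
  expect_true(all(allns$class == "ns"))
  # fold-change threshold gates symmetric classes
  v2 <- volcano(univ, fc_threshold_log2 = 1)
  expect_equal(as.character(v2$class), c("increased", "ns", "ns", "ns"))
  # sign flip of the fold changes swaps the sets exactly
  flip <- volcano(transform(univ, log2_fold_change = -log2_fold_change))
  expect_equal(as.character(flip$class),
               c("decreased", "ns", "increased", "ns"))
})

test_that("group relabeling swaps volcano classes end to end", {
  sim <- simulate_metabolite_panel(metabo_sim_config(
    planted_effects = c(Orn = 1, C16 = -1), seed = 61))
  pan <- sim$panel
  swapped <- metabolite_panel(
    pan$concentrations,
    factor(pan$groups, levels = rev(levels(pan$groups))))
  v1 <- volcano(univariate_panel(pan))
  v2 <- volcano(univariate_panel(swapped))
  expect_equal(v1$metabolite_id[v1$class == "increased"],
               v2$metabolite_id[v2$class == "decreased"])
  expect_equal(v1$metabolite_id[v1$class == "decreased"],
               v2$metabolite_id[v2$class == "increased"])
})

test_that("heatmap clustering follows hand-checkable linkage behaviour", {
  set.seed(67)
  conc <- matrix(rlnorm(5 * 8, log(10), 0.5), nrow = 5,
                 dimnames = list(paste0("m", 1:5), NULL))
  conc[2, ] <- conc[1, ]                  # two identical metabolites
  pan <- metabolite_panel(conc, rep(c("A", "B"), each = 4))
  hm <- cluster_heatmap(pan, top_k = 5, linkage = "single")
  expect_equal(hm$rows$height[1], 0, tolerance = 1e-12)
  first_pair <- sort(-hm$rows$merge[1, ])
  expect_setequal(hm$rows$labels[first_pair], c("m1", "m2"))

  # merge heights match a naive agglomerative oracle
  pre <- preprocess(pan)
  sub <- t(pre[, hm$rows$labels, drop = FALSE])
  expect_equal(hm$rows$height, naive_linkage_heights(sub, "single"),
               tolerance = 1e-12)
  hm_c <- cluster_heatmap(pan, top_k = 5, linkage = "complete")
  expect_equal(hm_c$rows$height,
               naive_linkage_heights(sub, "complete"), tolerance = 1e-12)

  # permuting metabolite input order leaves merge heights unchanged
  perm <- sample(5)
  pan_p <- metabolite_panel(conc[perm, ], rep(c("A", "B"), each = 4))
  hm_p <- cluster_heatmap(pan_p, top_k = 5, linkage = "single")
  expect_equal(sort(hm_p$rows$height), sort(hm$rows$height),
               tolerance = 1e-12)

  expect_warning(cluster_heatmap(pan, top_k = 50), "top_k")
  tiny <- metabolite_panel(conc[1, , drop = FALSE],
                           rep(c("A", "B"), each = 4))
  expect_error(cluster_heatmap(tiny), class = "input_error")
})

test_that("heatmap ranking keeps the most significant metabolites", {
  sim <- simulate_metabolite_panel(metabo_sim_config(
    planted_effects = c(Orn = 2, C16 = -2), cv_noise = 0.1, seed = 71))
  hm <- cluster_heatmap(sim$panel, top_k = 10)
  expect_true(all(c("Orn", "C16") %in% rownames(hm$matrix)))
  expect_equal(nrow(hm$matrix), 10)
})
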