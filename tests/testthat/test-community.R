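test_that("hellinger transform matches hand computation and is equivariant", {
  h <- hellinger(matrix(c(1, 1, 2), 1))
  expect_equal(drop(h), c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(round(drop(h), 5), c(0.5, 0.5, 0.70711), ignore_attr = TRUE)
  # single-OTU sample is scale invariant
  for (n in c(1, 7, 1000)) {
    expect_equal(drop(hellinger(matrix(c(n, 0, 0), 1))), c(1, 0, 0),
                 ignore_attr = TRUE)
  }
  # permuting OTU columns permutes output identically; rows have unit norm
  set.seed(1)
  x <- matrix(rpois(60, 5), 6, 10)
  perm <- sample(10)
  expect_equal(hellinger(x)[, perm], hellinger(x[, perm]),
               ignore_attr = TRUE)
  expect_equal(rowSums(hellinger(x)^2), rep(1, 6), ignore_attr = TRUE)
  xz <- x; xz[2, ] <- 0; rownames(xz) <- paste0("s", 1:6)
  expect_error(hellinger(xz), "s2")
})

test_that("bray-curtis matches its formula on identity, disjoint, and mixed rows", {
  expect_equal(as.vector(bray_curtis(rbind(c(1, 2, 3), c(1, 2, 3)))), 0)
  expect_equal(as.vector(bray_curtis(rbind(c(1, 1, 0), c(0, 0, 1)))), 1)
  # brute-force formula evaluation oracle
  x <- c(0.5, 0.5, 0); y <- c(0, 0.5, 0.5)
  expect_equal(as.vector(bray_curtis(rbind(x, y))),
               sum(abs(x - y)) / sum(x + y))
  expect_equal(as.vector(bray_curtis(rbind(x, y))), 0.5)
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 1))), "all-zero")
  # bounded by 1 on hellinger rows
  set.seed(2)
  d <- bray_curtis(hellinger(matrix(rpois(80, 3), 8, 10) + 1))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("dissimilarity to control averages cross pairs per replicate", {
  dm <- matrix(0.3, 4, 4); diag(dm) <- 0
  ids <- c("a1", "a2", "c1", "c2")
  dimnames(dm) <- list(ids, ids)
  meta <- tibble::tibble(sample_id = ids, soil = "A",
                         amendment = c("OM", "OM", "soil", "soil"),
                         day = 26, replicate = c(1, 2, 1, 2))
  cell <- dissimilarity_to_control(dm, meta)
  expect_equal(cell$mean, 0.3)
  expect_equal(cell$se, 0)
  # one amended replicate at distances (0.2, 0.4) -> its value is 0.3
  dm2 <- dm
  dm2["a1", c("c1", "c2")] <- c(0.2, 0.4)
  dm2[c("c1", "c2"), "a1"] <- c(0.2, 0.4)
  cell2 <- dissimilarity_to_control(dm2, meta)
  expect_equal(cell2$mean, 0.3)  # mean of (0.3, 0.3)
  # empty cells warn and are omitted, not zero
  meta3 <- dplyr::mutate(meta, amendment = c("OM", "OM", "OM", "OM"))
  expect_warning(out <- dissimilarity_to_control(dm, meta3), "omitted")
  expect_equal(nrow(out), 0)
})

test_that("permanova reproduces the enumerated exact p on the 4-sample toy", {
  dm <- matrix(1, 4, 4) - diag(4)
  dm[1, 2] <- dm[2, 1] <- 0
  dm[3, 4] <- dm[4, 3] <- 0
  g <- data.frame(grp = c("x", "x", "y", "y"))
  res <- permanova(dm, g, ~ grp, exact = TRUE)
  expect_equal(res$p[1], 1 / 3)
  expect_equal(attr(res, "n_permutations"), 24)
  # sampled permutation p converges to the enumerated value
  res2 <- permanova(dm, g, ~ grp, n_perm = 9999, seed = 1)
  expect_lt(abs(res2$p[1] - 1 / 3), 0.02)
})

test_that("permanova agrees with an independent implementation (vegan adonis2)", {
  set.seed(42)
  x <- matrix(rexp(20 * 8), 20, 8)
  rownames(x) <- paste0("s", 1:20)
  meta <- data.frame(soil = rep(c("a", "b"), 10),
                     day = rep(c(1, 10, 26, 10, 1), 4))
  d <- bray_curtis(hellinger(x))
  mine <- permanova(d, meta, ~ soil * day, n_perm = 99, seed = 3)
  ref <- vegan::adonis2(d ~ soil * day, data = meta, by = "terms",
                        permutations = 99)
  expect_equal(mine$SS, ref$SumOfSqs, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(mine$F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(mine$df, ref$Df, ignore_attr = TRUE)
  expect_equal(mine$R2[1:3], ref$R2[1:3], tolerance = 1e-10)
  expect_equal(sum(mine$R2[1:4]), 1)
})

test_that("duplicating all samples increases pseudo-F at fixed R2", {
  set.seed(5)
  x <- matrix(rexp(6 * 5), 6, 5)
  g <- data.frame(grp = rep(c("a", "b"), each = 3))
  d1 <- as.matrix(bray_curtis(x))
  r1 <- permanova(d1, g, ~ grp, n_perm = 99)
  idx <- rep(1:6, 2)
  d2 <- d1[idx, idx]
  rownames(d2) <- colnames(d2) <- paste0("s", 1:12)
  r2 <- permanova(d2, g[idx, , drop = FALSE], ~ grp, n_perm = 99)
  expect_gt(r2$F[1], r1$F[1])
  expect_equal(r2$R2[1], r1$R2[1], tolerance = 1e-10)
})

test_that("permanova rejects degenerate designs", {
  dm <- as.matrix(dist(1:4)); rownames(dm) <- colnames(dm) <- paste0("s", 1:4)
  expect_error(permanova(dm, data.frame(g = rep("a", 4)), ~ g), "single level")
  expect_error(permanova(dm, data.frame(g = c("a", "b", "c", "d")), ~ g),
               "not enough samples")
  expect_error(permanova(dm, data.frame(g = c("a", "a", "b", "b")), ~ g,
                         n_perm = 10), "n_perm")
})

test_that("beta-binomial fit with vanishing dispersion matches binomial GLM", {
  set.seed(7)
  n <- 16
  size <- rep(30000, n)
  amended <- rep(c(0, 1), each = 8)
  day <- rep(c(0, 1), 8)
  y <- rbinom(n, size, plogis(-7 + 1.5 * amended + 0.3 * day))
  X <- cbind(1, amended, day)
  fit <- fit_beta_binomial(y, size, X, fixed_phi = 1e-9)
  ref <- glm(cbind(y, size - y) ~ amended + day, family = binomial)
  expect_lt(max(abs(fit$beta - coef(ref))), 1e-3)
  expect_lt(abs(fit$logLik - as.numeric(logLik(ref))), 1e-3)
})

test_that("beta-binomial null z-scores are well behaved", {
  set.seed(8)
  n <- 16
  size <- rep(10000, n)
  amended <- rep(c(0, 1), each = 8)
  X <- cbind(1, amended)
  Z <- cbind(1, amended)
  z <- replicate(300, {
    p <- plogis(rnorm(1, -7, 1))
    y <- rbinom(n, size, rbeta(n, p * 999, (1 - p) * 999))
    f <- fit_beta_binomial(y, size, X, Z)
    if (f$converged) f$wald_z[2] else NA
  })
  z <- z[!is.na(z)]
  expect_gt(length(z), 250)
  expect_gt(mean(abs(z) < 4), 0.98)
  expect_lt(abs(median(z)), 0.3)
})

test_that("responder q-values are monotone BH adjustments above raw p", {
  comm <- responder_fixture(seed = 3, n_otus = 300, n_responders = 10,
                            read_depth = 10000)
  res <- detect_responders(comm$table, amendment = "OM")
  ok <- res$converged & is.finite(res$wald_p)
  expect_true(all(res$q[ok] >= res$wald_p[ok]))
  o <- order(res$wald_p[ok])
  expect_true(all(diff(res$q[ok][o]) >= -1e-12))
  expect_equal(res$q[ok],
               p.adjust(res$wald_p[ok], method = "BH"))
  # responders satisfy the prevalence filter by construction
  expect_true(all(res$mean_ra >= 1e-4))
})

test_that("planted responders are found and calls are column-order invariant", {
  comm <- responder_fixture(seed = 4, n_otus = 300, n_responders = 10,
                            lfc = 4, read_depth = 10000)
  res <- detect_responders(comm$table, amendment = "OM")
  called <- res$otu[res$positive_responder]
  expect_gt(length(intersect(called, comm$truth$otu)), 4)
  expect_lt(length(setdiff(called, comm$truth$otu)), 3)
  # permute OTU columns
  perm <- sample(ncol(comm$table$counts))
  tab2 <- amplicon_table(comm$table$counts[, perm], comm$table$metadata)
  res2 <- detect_responders(tab2, amendment = "OM")
  expect_setequal(res2$otu[res2$positive_responder], called)
})

test_that("responder detection validates its inputs", {
  comm <- responder_fixture(seed = 5, n_otus = 50, n_responders = 2,
                            read_depth = 2000)
  expect_error(detect_responders(comm$table, amendment = "biochar"), "OM")
  meta_no_ctrl <- comm$table$metadata
  tab <- comm$table
  keep <- tab$metadata$amendment != "soil"
  tab2 <- amplicon_table(tab$counts[keep, ], tab$metadata[keep, ])
  expect_error(detect_responders(tab2, amendment = "OM"), "control")
})

test_that("response regression recovers an exact line and ignores duplication", {
  x <- c(-2, -1, 0, 1.5, 3, 4)
  y <- -1.7 + 1.3 * x
  # summary.lm warns about the perfect fit; the coefficients are the point
  fit <- suppressWarnings(amendment_response_regression(y, x))
  expect_equal(fit$slope, 1.3)
  expect_equal(fit$intercept, -1.7)
  expect_equal(fit$r2_adj, 1)
  fit2 <- suppressWarnings(amendment_response_regression(c(y, y), c(x, x)))
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$intercept, fit$intercept)
  expect_error(amendment_response_regression(1:2, 1:2), "at least 3")
  # independent x and y: slope near zero, p roughly uniform
  set.seed(11)
  ps <- replicate(200, {
    amendment_response_regression(rnorm(20), rnorm(20))$p
  })
  expect_gt(mean(ps < 0.05), 0.0)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("perfectly monotone cells give spearman rho of 1", {
  est <- tibble::tibble(
    soil = paste0("S", 1:5), amendment = "PyOM", time_h = 624,
    percent = c(0, 5, 20, 60, 130), percent_ci_low = NA_real_,
    percent_ci_high = NA_real_, significant = TRUE)
  shift <- tibble::tibble(
    soil = paste0("S", 1:5), amendment = "PyOM", day = 26, n = 4,
    mean = c(0.1, 0.15, 0.2, 0.3, 0.4), se = 0.01,
    ci_low = 0, ci_high = 1)
  l <- link_priming_dissimilarity(est, shift, n_perm = 99, seed = 1)
  expect_equal(l$rho, 1)
  expect_lt(l$p, 0.05)
  expect_warning(
    l2 <- link_priming_dissimilarity(est[1:2, ], shift[1:2, ]),
    "fewer than 3")
  expect_true(is.na(l2$rho))
})
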