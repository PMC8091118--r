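#' OTU count table with sample metadata
#'
#' Light container pairing a samples x OTUs integer count matrix with the
#' sample metadata the downstream analyses need.
#'
#' @param counts Matrix, samples in rows (rownames = sample ids), OTUs in
#'   columns, non-negative integers, positive row sums.
#' @param metadata Data frame with columns `sample_id`, `soil`,
#'   `amendment`, `day`, `replicate`; one row per sample.
#' @param marker Marker gene label, `"16S"` or `"ITS2"`.
#' @return An `amplicon_table` list with elements `counts`, `metadata`,
#'   `marker`.
#' @export
amplicon_table <- function(counts, metadata, marker = "16S") {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop("samples with zero total counts: ",
         paste(rownames(counts)[rs == 0], collapse = ", "))
  }
  req <- c("sample_id", "soil", "amendment", "day", "replicate")
  if (!all(req %in% names(metadata))) {
    stop("metadata needs columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample ids")
  if (is.null(rownames(counts))) {
    stop("`counts` must have sample ids as rownames")
  }
  missing <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing) > 0L) {
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  }
  metadata <- tibble::as_tibble(metadata)
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  if (anyNA(metadata$soil) || anyNA(metadata$amendment) ||
      anyNA(metadata$day) || anyNA(metadata$replicate)) {
    stop("metadata is incomplete for some samples")
  }
  if (!marker %in% c("16S", "ITS2")) stop("marker must be 16S or ITS2")
  structure(list(counts = counts, metadata = metadata, marker = marker),
            class = "amplicon_table")
}

#' @export
print.amplicon_table <- function(x, ...) {
  cat("<amplicon_table> ", nrow(x$counts), " samples x ", ncol(x$counts),
      " OTUs (", x$marker, ")\n", sep = "")
  invisible(x)
}

#' Hellinger transform of a count matrix
#'
#' Square root of relative abundances: `h_ij = sqrt(count_ij /
#' rowsum_i)`. Each transformed row has unit squared norm.
#'
#' @param counts Samples x OTUs matrix of non-negative values with
#'   positive row sums.
#' @return Transformed matrix of the same shape.
#' @export
hellinger <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    bad <- if (is.null(rownames(counts))) which(rs == 0) else
      rownames(counts)[rs == 0]
    stop("zero row sum for sample(s): ", paste(bad, collapse = ", "))
  }
  vegan::decostand(counts, method = "hellinger")
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` over all row pairs.
#' Applied to Hellinger-transformed abundances this is the community
#' dissimilarity used throughout the pipeline.
#'
#' @param x Samples x variables matrix with non-negative entries and no
#'   all-zero rows.
#' @return A `dist` object.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis requires non-negative values")
  if (any(rowSums(x) == 0)) {
    stop("all-zero row(s); Bray-Curtis is undefined for empty profiles")
  }
  vegan::vegdist(x, method = "bray")
}

#' Mean dissimilarity of amended replicates to unamended controls
#'
#' For every (soil, amendment, day) cell: each amended replicate's value
#' is its mean dissimilarity to all control replicates of the same soil
#' and day (all cross pairs); the cell's mean and SE are taken across
#' amended replicates. Empty cells are dropped with a warning rather
#' than reported as zero.
#'
#' @param d A `dist` or square matrix over samples (e.g.
#'   [bray_curtis()] of [hellinger()] counts).
#' @param metadata Sample metadata as in [amplicon_table()], ordered or
#'   keyed by `sample_id` matching the labels of `d`.
#' @param conf_z CI quantile (default 1.96). CI bounds are clipped to
#'   [0, 1] for reporting.
#' @return Tibble: soil, amendment, day, n, mean, se, ci_low, ci_high.
#' @export
dissimilarity_to_control <- function(d, metadata, conf_z = 1.96) {
  dm <- as.matrix(d)
  ids <- rownames(dm)
  if (is.null(ids) || !all(ids %in% metadata$sample_id)) {
    stop("distance labels must match metadata sample ids")
  }
  meta <- metadata[match(ids, metadata$sample_id), ]
  cells <- dplyr::distinct(meta[meta$amendment != "soil",
                                c("soil", "amendment", "day")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    am <- which(meta$soil == cl$soil & meta$amendment == cl$amendment &
                  meta$day == cl$day)
    ct <- which(meta$soil == cl$soil & meta$amendment == "soil" &
                  meta$day == cl$day)
    if (length(am) == 0L || length(ct) == 0L) {
      warning("no amended or control samples for (", cl$soil, ", ",
              cl$amendment, ", day ", cl$day, "); cell omitted")
      next
    }
    reps <- rowMeans(dm[am, ct, drop = FALSE])
    m <- mean(reps)
    se <- if (length(reps) >= 2) stats::sd(reps) / sqrt(length(reps)) else
      NA_real_
    out[[i]] <- tibble::tibble(
      soil = cl$soil, amendment = cl$amendment, day = cl$day,
      n = length(reps), mean = m, se = se,
      ci_low = max(0, m - conf_z * se), ci_high = min(1, m + conf_z * se))
  }
  dplyr::bind_rows(out)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a distance matrix among model
#' terms using the Gower-centered inner-product formulation
#' (`G = C (-D^2 / 2) C` with `C` the centering matrix): sequential
#' (Type I) sums of squares `SS_j = tr(P_j G)` from the incremental
#' projectors of the nested model matrices, pseudo-F per term, and
#' permutation p-values under free permutation of sample rows:
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`. With
#' `exact = TRUE` all `n!` row permutations are enumerated and
#' `p = #\{F_perm >= F_obs\} / n!` (the identity counts in the
#' numerator), which the sampled formula converges to.
#'
#' @param d A `dist` or square symmetric dissimilarity matrix.
#' @param data Data frame of sample covariates, rows aligned with `d`.
#' @param formula Right-hand-side formula of terms, e.g.
#'   `~ soil * day + amendment`; terms are fitted in order.
#' @param n_perm Number of permutations (>= 99) when `exact = FALSE`.
#' @param seed Optional integer seed for the permutations.
#' @param exact Enumerate all permutations (requires n <= 8).
#' @return Tibble: term, df, SS, R2, F, p, plus Residual and Total rows;
#'   attributes `n_permutations` and `seed`.
#' @export
permanova <- function(d, data, formula, n_perm = 999, seed = NULL,
                      exact = FALSE) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (!isTRUE(all.equal(dm, t(dm)))) stop("distance matrix must be symmetric")
  if (!exact && n_perm < 99) stop("`n_perm` must be >= 99")
  trms <- stats::terms(formula, data = data)
  labels <- attr(trms, "term.labels")
  if (length(labels) == 0L) stop("formula has no terms")
  for (v in all.vars(formula)) {
    if (is.character(data[[v]]) || is.logical(data[[v]])) {
      data[[v]] <- factor(data[[v]])
    }
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2L) {
      stop("term variable \"", v, "\" has a single level")
    }
  }
  G <- gower_center(dm)
  ss_total <- sum(diag(G))
  # incremental projectors of the nested sequence of model matrices
  projs <- list()
  H_prev <- matrix(1 / n, n, n)  # intercept
  rank_prev <- 1L
  dfs <- integer(length(labels))
  for (j in seq_along(labels)) {
    f_j <- stats::reformulate(labels[seq_len(j)])
    X <- stats::model.matrix(f_j, data = data)
    q <- qr(X)
    H <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    projs[[j]] <- H - H_prev
    dfs[j] <- q$rank - rank_prev
    H_prev <- H
    rank_prev <- q$rank
  }
  if (any(dfs == 0L)) stop("aliased model term (zero incremental rank)")
  df_res <- n - rank_prev
  if (df_res <= 0L) stop("not enough samples for the model terms")
  P_res <- diag(n) - H_prev
  stat <- function(Gp) {
    ss <- vapply(projs, function(P) sum(P * Gp), 0)
    ss_res <- sum(diag(Gp)) - sum(H_prev * Gp)
    (ss / dfs) / (ss_res / df_res)
  }
  F_obs <- stat(G)
  ss_obs <- vapply(projs, function(P) sum(P * G), 0)
  ss_res <- ss_total - sum(ss_obs)
  if (exact) {
    if (n > 8L) stop("`exact = TRUE` supported only for n <= 8")
    perms <- all_permutations(n)
    Fp <- vapply(perms, function(p) stat(G[p, p]), numeric(length(labels)))
    Fp <- matrix(Fp, nrow = length(labels))
    count <- rowSums(Fp >= F_obs - 1e-12)
    p <- count / length(perms)
    n_used <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- numeric(length(labels))
    for (b in seq_len(n_perm)) {
      p_idx <- sample.int(n)
      count <- count + (stat(G[p_idx, p_idx]) >= F_obs - 1e-12)
    }
    p <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }
  out <- tibble::tibble(
    term = c(labels, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(ss_obs, ss_res, ss_total),
    R2 = c(ss_obs, ss_res, ss_total) / ss_total,
    F = c(F_obs, NA, NA),
    p = c(p, NA, NA))
  attr(out, "n_permutations") <- n_used
  attr(out, "seed") <- seed
  out
}

gower_center <- function(dm) {
  A <- -0.5 * dm^2
  n <- nrow(A)
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

# all n! permutations, built by inserting n into each (n-1)-permutation
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Beta-binomial regression with modeled dispersion (single taxon)
#'
#' Maximum-likelihood fit of `y ~ BetaBinomial(size, mu, phi)` with
#' `logit(mu) = X beta` and `logit(phi) = Z gamma`, by bounded
#' quasi-Newton (L-BFGS-B) from a moment-based start. The Wald test for
#' a mean-model coefficient compares `beta / se` to a t distribution
#' with `n - p` degrees of freedom (`p` = total parameters), the
#' small-sample convention of beta-binomial differential-abundance
#' tools. With `phi -> 0` the model reduces to binomial logistic
#' regression.
#'
#' @param y Successes (counts of the taxon), integer vector.
#' @param size Trials (library sizes), `size >= y >= 0`.
#' @param X Mean model matrix (include the intercept column).
#' @param Z Dispersion model matrix (include the intercept column).
#' @param fixed_phi Optional fixed dispersion value; when supplied the
#'   dispersion submodel is dropped and only `beta` is estimated (with
#'   `fixed_phi` near zero the fit reduces to binomial logistic
#'   regression).
#' @return List: `beta`, `gamma`, `vcov` (of `c(beta, gamma)`), `se_beta`,
#'   `wald_z`, `wald_p` (per mean coefficient), `logLik`, `converged`.
#' @export
fit_beta_binomial <- function(y, size, X, Z = matrix(1, length(y), 1),
                              fixed_phi = NULL) {
  stopifnot(length(y) == length(size), nrow(X) == length(y),
            nrow(Z) == length(y))
  if (any(y < 0) || any(y > size)) stop("need 0 <= y <= size")
  kx <- ncol(X); kz <- if (is.null(fixed_phi)) ncol(Z) else 0L
  nll <- function(par) {
    mu <- stats::plogis(drop(X %*% par[seq_len(kx)]))
    phi <- if (kz == 0L) rep(fixed_phi, length(y)) else
      stats::plogis(drop(Z %*% par[kx + seq_len(kz)]))
    a <- mu * (1 - phi) / phi
    b <- (1 - mu) * (1 - phi) / phi
    ll <- lchoose(size, y) + lbeta(y + a, size - y + b) - lbeta(a, b)
    if (!all(is.finite(ll))) return(1e10)
    -sum(ll)
  }
  # moment-based start: smoothed group-free logit + Pearson overdispersion
  p_hat <- (sum(y) + 0.5) / (sum(size) + 1)
  beta0 <- numeric(kx)
  beta0[1] <- stats::qlogis(p_hat)
  # crude slope starts from smoothed per-level proportions of binary columns
  for (j in seq_len(kx)[-1]) {
    xj <- X[, j]
    if (all(xj %in% c(0, 1)) && any(xj == 1) && any(xj == 0)) {
      p1 <- (sum(y[xj == 1]) + 0.5) / (sum(size[xj == 1]) + 1)
      p0 <- (sum(y[xj == 0]) + 0.5) / (sum(size[xj == 0]) + 1)
      beta0[j] <- stats::qlogis(p1) - stats::qlogis(p0)
    }
  }
  gamma0 <- numeric(kz)
  if (kz > 0L) {
    mu0 <- stats::plogis(drop(X %*% beta0))
    chi2 <- sum((y - size * mu0)^2 / pmax(size * mu0 * (1 - mu0), 1e-8))
    disp <- max(chi2 / max(length(y) - kx, 1), 1)
    phi0 <- min(max((disp - 1) / max(mean(size) - 1, 1), 1e-5), 0.5)
    gamma0[1] <- stats::qlogis(phi0)
  }
  par0 <- c(beta0, gamma0)
  lower <- c(rep(-30, kx), rep(-15, kz))
  upper <- c(rep(30, kx), rep(8, kz))
  fit <- try(stats::optim(par0, nll, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error") || fit$convergence != 0) {
    return(list(beta = rep(NA_real_, kx), gamma = rep(NA_real_, kz),
                vcov = NULL, se_beta = rep(NA_real_, kx),
                wald_z = rep(NA_real_, kx), wald_p = rep(NA_real_, kx),
                logLik = NA_real_, converged = FALSE))
  }
  H <- try(stats::optimHess(fit$par, nll), silent = TRUE)
  vc <- if (inherits(H, "try-error")) NULL else
    tryCatch(solve(H), error = function(e) NULL)
  ok <- !is.null(vc) && all(is.finite(diag(vc)[seq_len(kx)])) &&
    all(diag(vc)[seq_len(kx)] > 0)
  se <- if (ok) sqrt(diag(vc)[seq_len(kx)]) else rep(NA_real_, kx)
  z <- fit$par[seq_len(kx)] / se
  # small-sample Wald reference: t with df = n - #parameters
  df <- length(y) - kx - kz
  p <- if (df > 0) 2 * stats::pt(-abs(z), df) else 2 * stats::pnorm(-abs(z))
  list(beta = fit$par[seq_len(kx)], gamma = fit$par[kx + seq_len(kz)],
       vcov = vc, se_beta = se, wald_z = z, wald_df = df,
       wald_p = p, logLik = -fit$value, converged = ok)
}

#' Detect amendment-responder OTUs
#'
#' Within one soil, restricted to the two later harvests (days 10 and
#' 26), each OTU passing the prevalence filter (mean relative abundance
#' across all of that soil's samples on those days >= `min_prevalence`,
#' default 0.01%) is fitted with [fit_beta_binomial()]: mean model
#' `~ amendment + day`, dispersion model `~ amendment` (differential
#' variance between amended and control). The log2 fold change is
#' defined on fitted mean relative abundances, averaged at equal weight
#' over the two days. Wald p-values are BH-adjusted within the (soil,
#' amendment) family; responders satisfy `q < q_max` and `|log2fc| >=
#' lfc_min` (positive responders: `log2fc >= +lfc_min`, inclusive).
#' Non-converged OTUs are excluded from responder calls and counted in
#' attribute `n_nonconverged`.
#'
#' @param table An [amplicon_table()].
#' @param soil Soil to analyze (default: the only soil in the table).
#' @param amendment `"OM"` or `"PyOM"`.
#' @param days Harvest days analyzed jointly (default `c(10, 26)`).
#' @param min_prevalence Mean relative abundance threshold (default
#'   `1e-4`, i.e. 0.01%).
#' @param q_max BH-adjusted significance threshold (default 0.05).
#' @param lfc_min Absolute log2 fold change threshold (default 2).
#' @return Tibble: otu, soil, amendment, mean_ra, log2fc, wald_p, q,
#'   responder, positive_responder, converged; attributes `n_tested`,
#'   `n_nonconverged`.
#' @export
detect_responders <- function(table, soil = NULL, amendment,
                              days = c(10, 26), min_prevalence = 1e-4,
                              q_max = 0.05, lfc_min = 2) {
  stopifnot(inherits(table, "amplicon_table"))
  meta <- table$metadata
  if (is.null(soil)) {
    soils <- unique(meta$soil)
    if (length(soils) != 1L) stop("specify `soil`: table has several")
    soil <- soils
  }
  if (!amendment %in% c("OM", "PyOM")) stop("amendment must be OM or PyOM")
  in_soil <- meta$soil == soil & meta$day %in% days
  if (!any(in_soil)) stop("no samples for soil \"", soil, "\" on those days")
  # prevalence on all treatments of the soil, the tested days
  ra_all <- table$counts[in_soil, , drop = FALSE] /
    rowSums(table$counts[in_soil, , drop = FALSE])
  mean_ra <- colMeans(ra_all)
  sel <- in_soil & meta$amendment %in% c("soil", amendment)
  msel <- meta[sel, ]
  if (!any(msel$amendment == "soil")) stop("no control samples")
  if (min(table(msel$amendment)) < 2L) {
    stop("fewer than 2 replicates per group")
  }
  counts <- table$counts[sel, , drop = FALSE]
  size <- rowSums(counts)
  keep <- which(mean_ra >= min_prevalence)
  if (length(keep) == 0L) stop("no OTUs pass the prevalence filter")
  amended <- as.numeric(msel$amendment == amendment)
  day26 <- as.numeric(msel$day == max(days))
  X <- cbind(1, amended = amended, day = day26)
  Z <- cbind(1, amended = amended)
  res <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    j <- keep[i]
    fit <- fit_beta_binomial(counts[, j], size, X, Z)
    if (fit$converged) {
      lp_days <- c(0, 1)  # equal-weight day average
      mu_am <- mean(stats::plogis(fit$beta[1] + fit$beta[2] +
                                    fit$beta[3] * lp_days))
      mu_ct <- mean(stats::plogis(fit$beta[1] + fit$beta[3] * lp_days))
      lfc <- log2(mu_am / mu_ct)
    } else {
      lfc <- NA_real_
    }
    res[[i]] <- tibble::tibble(
      otu = colnames(counts)[j], soil = soil, amendment = amendment,
      mean_ra = mean_ra[j], log2fc = lfc, wald_p = fit$wald_p[2],
      converged = fit$converged)
  }
  out <- dplyr::bind_rows(res)
  out$q <- NA_real_
  conv <- out$converged & is.finite(out$wald_p)
  out$q[conv] <- stats::p.adjust(out$wald_p[conv], method = "BH")
  out$responder <- conv & out$q < q_max & abs(out$log2fc) >= lfc_min
  out$positive_responder <- out$responder & out$log2fc >= lfc_min
  attr(out, "n_tested") <- sum(conv)
  attr(out, "n_nonconverged") <- sum(!out$converged)
  out
}

#' Pair OM and PyOM responses per OTU
#'
#' Joins two [detect_responders()] tables (same soil, the two
#' amendments) on OTU id, keeping OTUs significant (`q < q_max`) for at
#' least one amendment.
#'
#' @param res_om,res_pyom [detect_responders()] outputs for OM and PyOM.
#' @param q_max Significance threshold for inclusion.
#' @return Tibble: otu, soil, lfc_om, lfc_pyom, mean_ra.
#' @export
pair_amendment_responses <- function(res_om, res_pyom, q_max = 0.05) {
  j <- dplyr::inner_join(
    res_om[, c("otu", "soil", "log2fc", "q", "mean_ra")],
    res_pyom[, c("otu", "soil", "log2fc", "q")],
    by = c("otu", "soil"), suffix = c("_om", "_pyom"))
  j <- j[!is.na(j$q_om) & !is.na(j$q_pyom) &
           (j$q_om < q_max | j$q_pyom < q_max), ]
  tibble::tibble(otu = j$otu, soil = j$soil, lfc_om = j$log2fc_om,
                 lfc_pyom = j$log2fc_pyom, mean_ra = j$mean_ra)
}

#' Regress OM responses on PyOM responses
#'
#' Ordinary least squares of the per-OTU response (log2 fold change) to
#' OM on the response to PyOM, summarizing whether taxa that respond to
#' one amendment respond similarly to the other.
#'
#' @param responses_om,responses_pyom Paired numeric vectors (>= 3
#'   points), e.g. from [pair_amendment_responses()].
#' @return List: intercept, slope, r2_adj, p (slope Wald p), n, fit (the
#'   `lm` object).
#' @export
amendment_response_regression <- function(responses_om, responses_pyom) {
  stopifnot(length(responses_om) == length(responses_pyom))
  ok <- is.finite(responses_om) & is.finite(responses_pyom)
  if (sum(ok) < 3L) stop("need at least 3 paired responses")
  fit <- stats::lm(om ~ pyom,
                   data = data.frame(om = responses_om[ok],
                                     pyom = responses_pyom[ok]))
  sm <- summary(fit)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r2_adj = sm$adj.r.squared,
       p = unname(sm$coefficients["pyom", "Pr(>|t|)"]),
       n = sum(ok), fit = fit)
}

#' Link priming magnitude to community shift magnitude
#'
#' Joins, per (soil, amendment), the estimated percent net change in
#' nSOC-derived emissions at `day` with the mean Bray-Curtis
#' dissimilarity to control at `day`, and reports the Spearman rank
#' correlation across cells with a permutation p-value (average ranks
#' for ties; two-sided on |rho|).
#'
#' @param priming_est Output of [priming_estimates()].
#' @param shift Output of [dissimilarity_to_control()].
#' @param day Evaluation day (default 26, the final harvest).
#' @param n_perm Permutations for the p-value.
#' @param seed Optional seed.
#' @return List: `table` (soil, amendment, percent, dissimilarity, and
#'   their CIs), `rho`, `p`, `n`. With fewer than 3 cells `rho` and `p`
#'   are `NA` and only the table is informative.
#' @export
link_priming_dissimilarity <- function(priming_est, shift, day = 26,
                                       n_perm = 999, seed = NULL) {
  pct <- percent_change_at(priming_est, day)
  sh <- shift[shift$day == day, ]
  tab <- dplyr::inner_join(
    pct[, c("soil", "amendment", "percent")],
    sh[, c("soil", "amendment", "mean", "se", "ci_low", "ci_high")],
    by = c("soil", "amendment"))
  names(tab)[names(tab) == "mean"] <- "dissimilarity"
  ci <- priming_est[, c("soil", "amendment", "time_h", "percent_ci_low",
                        "percent_ci_high")]
  tab <- dplyr::left_join(
    tab, dplyr::inner_join(pct[, c("soil", "amendment", "time_h_used")],
                           ci, by = c("soil", "amendment",
                                      time_h_used = "time_h")),
    by = c("soil", "amendment"))
  if (nrow(tab) < 3L) {
    warning("fewer than 3 (soil, amendment) cells; correlation omitted")
    return(list(table = tab, rho = NA_real_, p = NA_real_, n = nrow(tab)))
  }
  rho <- stats::cor(tab$percent, tab$dissimilarity, method = "spearman")
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    r <- stats::cor(tab$percent, sample(tab$dissimilarity),
                    method = "spearman")
    if (abs(r) >= abs(rho) - 1e-12) count <- count + 1L
  }
  list(table = tab, rho = rho, p = (1 + count) / (1 + n_perm),
       n = nrow(tab))
}
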