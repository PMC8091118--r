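#' Specify a first-order carbon pool
#'
#' A carbon pool mineralizes by first-order kinetics: its instantaneous
#' CO2-C flux at time `t` (days since wet-up) is `c0 * k * exp(-k * t)`,
#' expressed per gram of the material the pool belongs to (soil for native
#' soil organic carbon pools, amendment for amendment pools).
#'
#' @param name Pool label, e.g. `"fast"` or `"slow"`.
#' @param c0 Initial mineralizable carbon mass (ug C per g material), >= 0.
#' @param k First-order rate constant (day^-1), >= 0.
#' @param delta13c Isotopic signature of respired CO2-C from this pool
#'   (permil vs VPDB), finite.
#' @return A `pool_spec` list.
#' @export
pool_spec <- function(name, c0, k, delta13c) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(c0) || c0 < 0) stop("pool `c0` must be finite and >= 0")
  if (!is.finite(k) || k < 0) stop("pool `k` must be finite and >= 0")
  if (!is.finite(delta13c)) stop("pool `delta13c` must be finite")
  structure(list(name = name, c0 = c0, k = k, delta13c = delta13c),
            class = "pool_spec")
}

#' Specify an early-peaking priming response
#'
#' Priming multiplies the mineralization flux of the native-soil pools in
#' amended jars by `1 + amplitude * exp(-t / tau)`: the stimulation is
#' strongest immediately after amendment and decays with time constant
#' `tau`, matching the common observation that amendment effects on native
#' SOC mineralization are largest early in an incubation.
#'
#' @param amplitude Dimensionless multiplier excess at `t = 0`; must be
#'   >= -1 so the multiplier stays non-negative. Negative values encode
#'   negative priming.
#' @param tau Decay time of the stimulation (days), > 0.
#' @return A `priming_spec` list.
#' @export
priming_spec <- function(amplitude = 0, tau = 5) {
  if (!is.finite(amplitude) || amplitude < -1) {
    stop("priming `amplitude` must be finite and >= -1")
  }
  if (!is.finite(tau) || tau <= 0) stop("priming `tau` must be > 0")
  structure(list(amplitude = amplitude, tau = tau), class = "priming_spec")
}

#' Specify a soil scenario
#'
#' All native pools of a soil share the soil's delta13C signature (the
#' mixing model uses a single soil end-member), so `delta13c` overrides
#' any value carried by the supplied pools.
#'
#' @param name Soil label.
#' @param pools List of [pool_spec()] native-SOC pools (c0 in ug C per g
#'   soil).
#' @param delta13c Soil end-member signature (permil vs VPDB).
#' @return A `soil_spec` list.
#' @export
soil_spec <- function(name, pools, delta13c = -27) {
  stopifnot(is.character(name), length(name) == 1L, length(pools) >= 1L)
  pools <- lapply(pools, function(p) {
    stopifnot(inherits(p, "pool_spec"))
    p$delta13c <- delta13c
    p
  })
  structure(list(name = name, pools = pools, delta13c = delta13c),
            class = "soil_spec")
}

#' Two-pool (fast/slow) soil scenario
#'
#' Convenience constructor reproducing the early-peaking flux curves of
#' real incubations without over-parameterizing: a small fast pool and a
#' large slow pool.
#'
#' The default rates leave both pools only partially consumed by day 26,
#' so that strong early-peaking priming multipliers remain compatible
#' with per-pool mass balance (cumulative CO2-C never exceeding `c0`).
#'
#' @inheritParams soil_spec
#' @param c0_fast,k_fast Fast pool size (ug C / g soil) and rate (day^-1).
#' @param c0_slow,k_slow Slow pool size and rate.
#' @return A `soil_spec`.
#' @export
two_pool_soil <- function(name, c0_fast = 150, k_fast = 0.02,
                          c0_slow = 2600, k_slow = 0.0015,
                          delta13c = -27) {
  soil_spec(name,
            pools = list(pool_spec("fast", c0_fast, k_fast, delta13c),
                         pool_spec("slow", c0_slow, k_slow, delta13c)),
            delta13c = delta13c)
}

#' Specify an amendment
#'
#' @param name Amendment label, one of `"OM"` or `"PyOM"` (the reserved
#'   label `"soil"` denotes the unamended control).
#' @param pools List of [pool_spec()] amendment pools, `c0` in ug C per g
#'   *amendment*; effective pool size per g soil is `c0 * rate`.
#' @param rate Addition rate as mass fraction of soil (g amendment / g
#'   soil), >= 0.
#' @param priming Either a single [priming_spec()] applied to every soil,
#'   or a named list of `priming_spec` keyed by soil name.
#' @param delta13c Amendment end-member signature (permil vs VPDB);
#'   overrides pool values (one bulk end-member per amendment).
#' @return An `amendment_spec` list.
#' @export
amendment_spec <- function(name, pools, rate, priming = priming_spec(0, 5),
                           delta13c = 500) {
  if (!name %in% c("OM", "PyOM")) {
    stop("amendment `name` must be \"OM\" or \"PyOM\"")
  }
  if (!is.finite(rate) || rate < 0) stop("amendment `rate` must be >= 0")
  pools <- lapply(pools, function(p) {
    stopifnot(inherits(p, "pool_spec"))
    p$delta13c <- delta13c
    p
  })
  ok <- inherits(priming, "priming_spec") ||
    (is.list(priming) && all(vapply(priming, inherits, TRUE, "priming_spec")))
  if (!ok) stop("`priming` must be a priming_spec or a named list of them")
  structure(list(name = name, pools = pools, rate = rate,
                 priming = priming, delta13c = delta13c),
            class = "amendment_spec")
}

#' Default OM (ground plant biomass) amendment, 3% by mass
#' @inheritParams amendment_spec
#' @return An `amendment_spec`.
#' @export
om_amendment <- function(priming = priming_spec(0, 5), rate = 0.03,
                         delta13c = 500) {
  amendment_spec("OM",
                 pools = list(pool_spec("fast", 4e4, 0.06, delta13c),
                              pool_spec("slow", 3.8e5, 0.002, delta13c)),
                 rate = rate, priming = priming, delta13c = delta13c)
}

#' Default PyOM (pyrolyzed biomass) amendment, 0.99% by mass
#' @inheritParams amendment_spec
#' @return An `amendment_spec`.
#' @export
pyom_amendment <- function(priming = priming_spec(0, 5), rate = 0.0099,
                           delta13c = 500) {
  amendment_spec("PyOM",
                 pools = list(pool_spec("fast", 1.2e4, 0.03, delta13c),
                              pool_spec("slow", 6e5, 2e-4, delta13c)),
                 rate = rate, priming = priming, delta13c = delta13c)
}

resolve_priming <- function(amend, soil_name) {
  p <- amend$priming
  if (inherits(p, "priming_spec")) return(p)
  if (!soil_name %in% names(p)) {
    stop("no priming_spec for soil \"", soil_name, "\" in amendment \"",
         amend$name, "\"")
  }
  p[[soil_name]]
}

#' Design a synthetic incubation experiment
#'
#' Encodes the experimental layout: one jar per soil x treatment x
#' replicate x harvest day, wet up at `t = 0`, with gas measurements every
#' `sampling_interval_days` until the jar's harvest. Unamended control
#' jars for every soil are always included (the downstream end-member
#' estimation requires them).
#'
#' @param soils List of [soil_spec()] scenarios.
#' @param amendments List of [amendment_spec()]s.
#' @param n_reps Replicate jars per (soil, treatment, harvest day), >= 1.
#' @param duration_days Incubation length (days), > 0.
#' @param sampling_interval_days Gas measurement interval (days), in
#'   (0, duration_days].
#' @param harvest_days Destructive-sampling days; each jar is assigned one
#'   and measured until then.
#' @param sd_delta Gaussian measurement noise on delta13C (permil).
#' @param cv_flux Multiplicative flux noise: measured flux =
#'   latent x max(0, 1 + N(0, cv_flux)).
#' @param control Logical; include unamended control jars. Must be `TRUE`
#'   for a simulable design.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return An `incubation_design` list.
#' @export
incubation_design <- function(soils, amendments, n_reps = 4,
                              duration_days = 26,
                              sampling_interval_days = 1,
                              harvest_days = c(1, 10, 26),
                              sd_delta = 2, cv_flux = 0.05,
                              control = TRUE, seed = 1) {
  stopifnot(length(soils) >= 1L,
            all(vapply(soils, inherits, TRUE, "soil_spec")),
            all(vapply(amendments, inherits, TRUE, "amendment_spec")))
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  if (!is.finite(duration_days) || duration_days <= 0) {
    stop("`duration_days` must be > 0")
  }
  if (sampling_interval_days <= 0 || sampling_interval_days > duration_days) {
    stop("`sampling_interval_days` must lie in (0, duration_days]")
  }
  if (length(harvest_days) < 1L || any(harvest_days <= 0) ||
      any(harvest_days > duration_days)) {
    stop("`harvest_days` must lie in (0, duration_days]")
  }
  if (sd_delta < 0 || cv_flux < 0) stop("noise parameters must be >= 0")
  nm <- vapply(soils, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate soil names")
  # reject designs whose primed cumulative nSOC-C would exceed the pool size
  for (s in soils) {
    for (a in amendments) {
      pr <- resolve_priming(a, s$name)
      for (p in s$pools) {
        if (cumulative_pool_c(p, pr, duration_days) > p$c0 + 1e-9) {
          stop("design violates mass balance: primed cumulative CO2-C of ",
               "pool \"", p$name, "\" in soil \"", s$name,
               "\" exceeds its c0")
        }
      }
    }
  }
  structure(list(soils = soils, amendments = amendments, n_reps = n_reps,
                 duration_days = duration_days,
                 sampling_interval_days = sampling_interval_days,
                 harvest_days = sort(unique(harvest_days)),
                 sd_delta = sd_delta, cv_flux = cv_flux,
                 control = control, seed = seed),
            class = "incubation_design")
}

# closed-form cumulative CO2-C (ug / g material) of one pool under the
# flux multiplier 1 + a * exp(-t / tau), integrated from 0 to t_day
cumulative_pool_c <- function(pool, priming = NULL, t_day) {
  base <- pool$c0 * (1 - exp(-pool$k * t_day))
  if (is.null(priming) || priming$amplitude == 0) return(base)
  r <- pool$k + 1 / priming$tau
  base + priming$amplitude * pool$c0 * pool$k * (1 - exp(-r * t_day)) / r
}

# latent flux (ug C / g material / h) of a pool set at t_day
latent_flux <- function(pools, t_day, multiplier = 1) {
  out <- numeric(length(t_day))
  for (p in pools) out <- out + p$c0 * p$k * exp(-p$k * t_day) / 24
  out * multiplier
}

#' Priming amplitude that yields a target cumulative increase
#'
#' Solves, in closed form, for the priming amplitude `a` such that the
#' cumulative nSOC-derived CO2-C of the soil's pools at `day`, under the
#' multiplier `1 + a * exp(-t/tau)`, exceeds the unprimed cumulative by
#' `percent` percent. The relation is linear in `a`.
#'
#' @param soil A [soil_spec()].
#' @param percent Target percent increase at `day`.
#' @param tau Priming decay time (days).
#' @param day Evaluation day.
#' @return A [priming_spec()] with the solved amplitude.
#' @export
amplitude_for_percent <- function(soil, percent, tau = 5, day = 26) {
  base <- sum(vapply(soil$pools, cumulative_pool_c, 0, t_day = day))
  extra <- 0
  for (p in soil$pools) {
    r <- p$k + 1 / tau
    extra <- extra + p$c0 * p$k * (1 - exp(-r * day)) / r
  }
  priming_spec(amplitude = (percent / 100) * base / extra, tau = tau)
}

#' Simulate a soil incubation gas time series
#'
#' Generates, per jar, one gas measurement per sampling interval until its
#' harvest day. The latent total flux is the sum over pools of
#' `c0 * k * exp(-k t)` (per hour), with the native-soil pools multiplied
#' by `1 + a * exp(-t/tau)` in amended jars; the latent delta13C is the
#' flux-weighted mean of the pool signatures. Measured delta adds Gaussian
#' noise (`sd_delta`); measured flux multiplies by `max(0, 1 + N(0,
#' cv_flux))`. Fixed `design$seed` gives identical output.
#'
#' @param design An [incubation_design()].
#' @return A list of class `incubation_sim` with elements
#'   `measurements` (tibble: jar_id, time_h, flux, delta),
#'   `jars` (tibble: jar_id, soil, amendment, replicate, soil_mass_g,
#'   harvest_day), and `truth` (latent per-jar trajectories, closed-form
#'   cumulative nSOC-derived CO2-C, and true priming percent per soil x
#'   amendment x harvest day).
#' @export
simulate_incubation <- function(design) {
  stopifnot(inherits(design, "incubation_design"))
  if (!isTRUE(design$control)) {
    stop("design lacks unamended control jars for its soils; ",
         "end-member estimation downstream would be impossible")
  }
  set.seed(design$seed)
  treatments <- c("soil", vapply(design$amendments, `[[`, "", "name"))
  amend_by_name <- stats::setNames(design$amendments,
                                   vapply(design$amendments, `[[`, "", "name"))
  jars <- list(); meas <- list(); latent <- list()
  for (s in design$soils) {
    for (trt in treatments) {
      for (h in design$harvest_days) {
        for (rep in seq_len(design$n_reps)) {
          jar_id <- sprintf("%s_%s_d%02d_r%d", s$name, trt, h, rep)
          jars[[jar_id]] <- tibble::tibble(
            jar_id = jar_id, soil = s$name, amendment = trt,
            replicate = rep, soil_mass_g = 5, harvest_day = h)
          dt <- design$sampling_interval_days
          t_day <- seq(dt, h, by = dt)
          if (trt == "soil") {
            pr <- NULL
            mult <- 1
            fa <- numeric(length(t_day))
            da <- NA_real_
          } else {
            am <- amend_by_name[[trt]]
            pr <- resolve_priming(am, s$name)
            mult <- 1 + pr$amplitude * exp(-t_day / pr$tau)
            fa <- latent_flux(am$pools, t_day) * am$rate
            da <- am$delta13c
          }
          fs <- latent_flux(s$pools, t_day, mult)
          tot <- fs + fa
          # single-source mixtures carry the source delta exactly
          dl <- ifelse(fa > 0 & tot > 0,
                       (fs * s$delta13c + fa * ifelse(is.na(da), 0, da)) / tot,
                       s$delta13c)
          cum_true <- vapply(t_day, function(td) {
            sum(vapply(s$pools, cumulative_pool_c, 0, priming = pr,
                       t_day = td))
          }, 0)
          d_meas <- dl + stats::rnorm(length(t_day), 0, design$sd_delta)
          f_meas <- tot * pmax(0, 1 + stats::rnorm(length(t_day), 0,
                                                   design$cv_flux))
          meas[[jar_id]] <- tibble::tibble(
            jar_id = jar_id, time_h = t_day * 24,
            flux = f_meas, delta = d_meas)
          latent[[jar_id]] <- tibble::tibble(
            jar_id = jar_id, time_h = t_day * 24,
            flux_soil_latent = fs, flux_amendment_latent = fa,
            delta_latent = dl, cum_soil_true = cum_true)
        }
      }
    }
  }
  priming_truth <- list()
  for (s in design$soils) {
    cum_ctrl <- function(d) sum(vapply(s$pools, cumulative_pool_c, 0,
                                       t_day = d))
    for (am in design$amendments) {
      pr <- resolve_priming(am, s$name)
      for (h in design$harvest_days) {
        cc <- cum_ctrl(h)
        ca <- sum(vapply(s$pools, cumulative_pool_c, 0, priming = pr,
                         t_day = h))
        priming_truth[[length(priming_truth) + 1L]] <- tibble::tibble(
          soil = s$name, amendment = am$name, day = h,
          delta_abs_true = ca - cc,
          percent_true = if (cc > 0) 100 * (ca - cc) / cc else NA_real_)
      }
    }
  }
  structure(list(
    measurements = dplyr::bind_rows(meas),
    jars = dplyr::bind_rows(jars),
    truth = list(latent = dplyr::bind_rows(latent),
                 priming = dplyr::bind_rows(priming_truth),
                 design = design)),
    class = "incubation_sim")
}

#' Specify a synthetic OTU community generator
#'
#' Baseline OTU relative abundances are drawn log-normally per soil; each
#' OTU has a "home" soil and occurs in any other soil with probability
#' `otu_soil_overlap`, so distinct soils share few taxa when overlap is
#' small. In amended samples, planted responder OTUs have their expected
#' abundance multiplied by `2 ^ (log2fc * g)`, where
#' `g = min(1, kappa * priming_percent / 100)` couples the compositional
#' shift to the priming magnitude of that soil x amendment. Counts are
#' Dirichlet-multinomial: Dirichlet(theta * p) then multinomial at
#' `read_depth`.
#'
#' @param n_otus Number of OTUs.
#' @param base_logmean_sd SD of the log-normal baseline abundance draw.
#' @param n_responders Number of planted responders (present in all
#'   soils), <= n_otus.
#' @param responder_log2fc_range Range from which true log2 fold changes
#'   are drawn uniformly.
#' @param kappa Coupling of compositional shift to priming percent; >= 0.
#' @param read_depth Library size per sample, > 0.
#' @param theta Dirichlet concentration scaling; larger = closer to
#'   multinomial. The implied per-OTU beta-binomial overdispersion is
#'   about `1 / (1 + theta)`.
#' @param day_effect_sd SD of per-OTU log-scale offsets for days 10 and
#'   26 (shared across treatments; emulates community drift over the
#'   incubation).
#' @param otu_soil_overlap Probability an OTU also occurs in each
#'   non-home soil.
#' @param seed Integer RNG seed.
#' @return A `community_sim_spec` list.
#' @export
community_sim_spec <- function(n_otus = 2000, base_logmean_sd = 1.5,
                               n_responders = 40,
                               responder_log2fc_range = c(2, 4),
                               kappa = 1, read_depth = 30000, theta = 1000,
                               day_effect_sd = 0.25, otu_soil_overlap = 0.3,
                               seed = 1) {
  if (n_responders > n_otus) stop("`n_responders` must be <= `n_otus`")
  if (read_depth <= 0) stop("`read_depth` must be > 0")
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (theta <= 0) stop("`theta` must be > 0")
  structure(list(n_otus = n_otus, base_logmean_sd = base_logmean_sd,
                 n_responders = n_responders,
                 responder_log2fc_range = responder_log2fc_range,
                 kappa = kappa, read_depth = read_depth, theta = theta,
                 day_effect_sd = day_effect_sd,
                 otu_soil_overlap = otu_soil_overlap, seed = seed),
            class = "community_sim_spec")
}

#' Simulate OTU count tables coupled to priming magnitude
#'
#' @param spec A [community_sim_spec()].
#' @param priming Tibble with columns `soil`, `amendment`, `percent`: the
#'   true priming percent of each amended treatment (controls need no
#'   row).
#' @param sample_design Tibble with columns `soil`, `amendment`, `day`,
#'   `replicate`, one row per sample to draw.
#' @return A list with `table` (an [amplicon_table()]) and `truth`
#'   (tibble of planted responder OTU ids with, per soil, the true log2
#'   fold change and expected control relative abundance).
#' @export
simulate_community <- function(spec, priming, sample_design) {
  stopifnot(inherits(spec, "community_sim_spec"))
  req <- c("soil", "amendment", "day", "replicate")
  if (!all(req %in% names(sample_design))) {
    stop("`sample_design` needs columns ", paste(req, collapse = ", "))
  }
  set.seed(spec$seed)
  soils <- unique(sample_design$soil)
  n_soil <- length(soils)
  otus <- sprintf("otu_%04d", seq_len(spec$n_otus))
  home <- sample(n_soil, spec$n_otus, replace = TRUE)
  present <- matrix(stats::runif(spec$n_otus * n_soil) <
                      spec$otu_soil_overlap,
                    nrow = spec$n_otus, ncol = n_soil)
  present[cbind(seq_len(spec$n_otus), home)] <- TRUE
  base <- matrix(stats::rnorm(spec$n_otus * n_soil, 0,
                              spec$base_logmean_sd),
                 nrow = spec$n_otus, ncol = n_soil)
  days <- sort(unique(sample_design$day))
  day_off <- matrix(0, nrow = spec$n_otus, ncol = length(days),
                    dimnames = list(NULL, as.character(days)))
  if (length(days) > 1L && spec$day_effect_sd > 0) {
    for (j in seq_along(days)[-1]) {
      day_off[, j] <- stats::rnorm(spec$n_otus, 0, spec$day_effect_sd)
    }
  }
  resp_idx <- sample(spec$n_otus, spec$n_responders)
  present[resp_idx, ] <- TRUE  # responders detectable in every soil
  lfc <- stats::runif(spec$n_responders, spec$responder_log2fc_range[1],
                      spec$responder_log2fc_range[2])
  g_of <- function(soil, amendment) {
    if (amendment == "soil") return(0)
    row <- priming[priming$soil == soil & priming$amendment == amendment, ]
    if (nrow(row) == 0L) {
      stop("no priming percent for (", soil, ", ", amendment, ")")
    }
    min(1, spec$kappa * row$percent[1] / 100)
  }
  sd <- sample_design
  sd$sample_id <- sprintf("%s_%s_d%02d_r%d", sd$soil, sd$amendment,
                          sd$day, sd$replicate)
  if (anyDuplicated(sd$sample_id)) stop("duplicate sample design rows")
  counts <- matrix(0L, nrow = nrow(sd), ncol = spec$n_otus,
                   dimnames = list(sd$sample_id, otus))
  for (i in seq_len(nrow(sd))) {
    si <- match(sd$soil[i], soils)
    w <- exp(base[, si] + day_off[, as.character(sd$day[i])]) *
      present[, si]
    g <- g_of(sd$soil[i], sd$amendment[i])
    if (g > 0) w[resp_idx] <- w[resp_idx] * 2^(lfc * g)
    p <- w / sum(w)
    alpha <- spec$theta * p
    x <- numeric(spec$n_otus)
    pos <- alpha > 0
    x[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
    if (sum(x) == 0) stop("degenerate community draw (all-zero weights)")
    counts[i, ] <- as.integer(stats::rmultinom(1, spec$read_depth,
                                               x / sum(x)))
  }
  # ground truth: expected control relative abundance per soil (mean over
  # the days sampled in that soil) for the planted responders
  truth <- list()
  for (si in seq_along(soils)) {
    ds <- sort(unique(sd$day[sd$soil == soils[si]]))
    pbar <- rowMeans(vapply(ds, function(dy) {
      w <- exp(base[, si] + day_off[, as.character(dy)]) * present[, si]
      w / sum(w)
    }, numeric(spec$n_otus)))
    truth[[si]] <- tibble::tibble(otu = otus[resp_idx], soil = soils[si],
                                  log2fc_true = lfc,
                                  baseline_ra = pbar[resp_idx])
  }
  list(table = amplicon_table(counts,
                              sd[, c("sample_id", req)]),
       truth = dplyr::bind_rows(truth))
}

#' Write a complete synthetic fixture set to disk
#'
#' Simulates an incubation (and, when `spec` is given, matched OTU
#' tables), then writes the flux CSV, jar metadata TSV, OTU count TSV,
#' sample metadata TSV, and a ground-truth JSON keyed by jar and OTU.
#' Outputs round-trip through [read_flux_csv()], [read_jar_metadata()] and
#' [read_otu_table()]. On failure no partial files are left behind.
#'
#' @param outdir Writable directory (created if absent).
#' @param design An [incubation_design()].
#' @param spec Optional [community_sim_spec()].
#' @return Named character vector of file paths, invisibly a list with
#'   the simulated objects attached as attribute `"objects"`.
#' @export
write_fixture_set <- function(outdir, design, spec = NULL) {
  stopifnot(inherits(design, "incubation_design"))
  if (length(design$soils) == 0L || length(design$amendments) == 0L) {
    stop("empty design: need at least one soil and one amendment")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop("fixture write failed in \"", outdir, "\": ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    sim <- simulate_incubation(design)
    paths <- c(flux = file.path(outdir, "flux.csv"),
               jars = file.path(outdir, "jars.tsv"),
               truth = file.path(outdir, "truth.json"))
    write_flux_csv(sim$measurements, sim$jars, paths[["flux"]])
    written <- c(written, paths[["flux"]])
    write_jar_metadata(sim$jars, paths[["jars"]])
    written <- c(written, paths[["jars"]])
    truth <- list(priming = sim$truth$priming,
                  jar_cumulative = dplyr::slice_tail(
                    dplyr::group_by(sim$truth$latent, .data$jar_id), n = 1)[
                      , c("jar_id", "time_h", "cum_soil_true")])
    comm <- NULL
    if (!is.null(spec)) {
      last_day <- max(design$harvest_days)
      pr <- dplyr::filter(sim$truth$priming, .data$day == last_day)
      pr <- dplyr::select(pr, "soil", "amendment", percent = "percent_true")
      sdn <- dplyr::distinct(sim$jars[, c("soil", "amendment",
                                          "harvest_day", "replicate")])
      names(sdn)[3] <- "day"
      comm <- simulate_community(spec, pr, sdn)
      paths <- c(paths, otu = file.path(outdir, "otu_counts.tsv"),
                 samples = file.path(outdir, "sample_metadata.tsv"))
      write_otu_table(comm$table, paths[["otu"]], paths[["samples"]])
      written <- c(written, paths[["otu"]], paths[["samples"]])
      truth$responders <- comm$truth
    }
    jsonlite::write_json(truth, paths[["truth"]], dataframe = "rows",
                         digits = NA, auto_unbox = TRUE)
    written <- c(written, paths[["truth"]])
    attr(paths, "objects") <- list(sim = sim, community = comm)
    invisible(paths)
  }, error = on_fail)
}
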