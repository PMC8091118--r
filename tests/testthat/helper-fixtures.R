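# shared fixtures, all generated in code

# one-pool soil, optionally primed OM treatment, noise configurable
single_pool_design <- function(k = 0.01, priming = priming_spec(0),
                               sd_delta = 0, cv_flux = 0, n_reps = 1,
                               harvest_days = 26, seed = 1) {
  s <- soil_spec("A", list(pool_spec("only", 100, k, -27)))
  incubation_design(list(s), list(om_amendment(priming = priming)),
                    n_reps = n_reps, harvest_days = harvest_days,
                    sd_delta = sd_delta, cv_flux = cv_flux, seed = seed)
}

# the +X% recovery scenario: 2-pool soil, n = 4, delta sd 2, flux cv 5%
recovery_design <- function(percent, seed) {
  s <- two_pool_soil("A")
  pr <- if (percent > 0) amplitude_for_percent(s, percent) else
    priming_spec(0)
  incubation_design(list(s), list(om_amendment(priming = pr)),
                    n_reps = 4, harvest_days = 26, seed = seed)
}

# run partition -> cumulate -> summarize -> priming for a simulation
priming_from_sim <- function(sim, deltas = c(OM = 500, PyOM = 500)) {
  em <- estimate_end_members(sim$measurements, sim$jars, deltas)
  cum <- cumulate(partition_measurements(sim$measurements, sim$jars, em))
  priming_estimates(summarize_treatment(cum))
}

# 5-soil linkage scenario with true priming percents `pcts`
linkage_run <- function(seed, kappa, pcts = c(0, 5, 20, 60, 130)) {
  soils <- lapply(seq_along(pcts), function(i) {
    two_pool_soil(paste0("S", i))
  })
  prim <- lapply(seq_along(pcts), function(i) {
    if (pcts[i] > 0) amplitude_for_percent(soils[[i]], pcts[i]) else
      priming_spec(0)
  })
  names(prim) <- vapply(soils, `[[`, "", "name")
  d <- incubation_design(soils, list(pyom_amendment(priming = prim)),
                         n_reps = 4, harvest_days = 26, seed = seed)
  sim <- simulate_incubation(d)
  est <- priming_from_sim(sim, c(PyOM = 500))
  spec <- community_sim_spec(n_otus = 500, n_responders = 30,
                             read_depth = 20000, kappa = kappa,
                             seed = seed + 50000L)
  truth_pr <- sim$truth$priming[sim$truth$priming$day == 26,
                                c("soil", "amendment", "percent_true")]
  names(truth_pr)[3] <- "percent"
  sdn <- unique(sim$jars[, c("soil", "amendment", "harvest_day",
                             "replicate")])
  names(sdn)[3] <- "day"
  comm <- simulate_community(spec, truth_pr, sdn)
  dd <- bray_curtis(hellinger(comm$table$counts))
  shift <- dissimilarity_to_control(dd, comm$table$metadata)
  link_priming_dissimilarity(est, shift, n_perm = 99, seed = seed)
}

# planted-responder community fixture at the stated scale
responder_fixture <- function(seed, n_otus = 2000, n_responders = 40,
                              lfc = 3, read_depth = 30000) {
  spec <- community_sim_spec(n_otus = n_otus, n_responders = n_responders,
                             responder_log2fc_range = c(lfc, lfc),
                             kappa = 1, read_depth = read_depth,
                             theta = 1000, seed = seed)
  priming <- tibble::tibble(soil = "A", amendment = "OM", percent = 100)
  sdn <- expand.grid(soil = "A", amendment = c("soil", "OM"),
                     day = c(10, 26), replicate = 1:4,
                     stringsAsFactors = FALSE)
  simulate_community(spec, priming, sdn)
}
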