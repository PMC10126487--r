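test_that("growth closure handles chains, free-growers and seedless cycles", {
  # requirement-free species always grow
  free <- community_model(
    tibble::tibble(id = "a", required = list(character()), secreted = list("z")),
    medium = character())
  expect_equal(growth_closure(free)$growing, "a")

  # two-step chain: a unlocks b
  res <- growth_closure(chain_model())
  expect_setequal(res$growing, c("a", "b"))
  expect_setequal(res$available, c("m0", "m1"))

  # mutual dependency with no entry point: neither grows
  deadlock <- community_model(
    tibble::tibble(id = c("a", "b"),
                   required = list("x", "y"),
                   secreted = list("y", "x")),
    medium = character())
  expect_length(growth_closure(deadlock)$growing, 0)

  expect_error(growth_closure(chain_model(), members = "nope"), "unknown")
})

test_that("growth closure is monotone in members and medium", {
  withr::with_seed(31, {
    for (k in 1:8) {
      mod <- simulate_exchange_community(
        n_species = 6, crossfeed_density = stats::runif(1),
        loop_count = sample(0:1, 1), seed = sample(1e4, 1))
      ids <- mod$species$id
      sub <- sample(ids, 3)
      small <- growth_closure(mod, members = sub)$growing
      big <- growth_closure(mod, members = c(sub, sample(setdiff(ids, sub), 2)))$growing
      expect_true(all(small %in% big))
      poor <- growth_closure(mod, medium = mod$medium[1])$growing
      rich <- growth_closure(mod)$growing
      expect_true(all(poor %in% rich))
    }
  })
})

test_that("coupling scores hit the independence and essentiality bounds", {
  # recipient living off the medium is independent of every donor
  indep <- community_model(
    tibble::tibble(id = c("r", "d1", "d2"),
                   required = list("e", "e", "e"),
                   secreted = list(character(), "m", character())),
    medium = "e")
  expect_equal(species_coupling_score(indep, "r", "d1", mode = "exhaustive"), 0)
  expect_equal(species_coupling_score(indep, "r", "d2", mode = "exhaustive"), 0)

  # unique producer of a required non-medium metabolite is essential
  expect_equal(
    species_coupling_score(essential_donor_model(), "r", "d", mode = "exhaustive"),
    1)
  expect_error(species_coupling_score(chain_model(), "a", "a"), "differ")
})

test_that("exhaustive coupling scores match brute-force subset enumeration", {
  mods <- list(
    redundant_donor_model(),
    simulate_exchange_community(n_species = 5, crossfeed_density = 0.7, seed = 8),
    simulate_exchange_community(n_species = 6, loop_count = 1, seed = 12)
  )
  for (mod in mods) {
    sp <- as_set_description(mod)
    ids <- mod$species$id
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    for (pr in pairs) {
      expect_equal(
        species_coupling_score(mod, pr[1], pr[2], mode = "exhaustive"),
        oracle_scs(sp, mod$medium, pr[1], pr[2]))
      expect_equal(
        species_coupling_score(mod, pr[2], pr[1], mode = "exhaustive"),
        oracle_scs(sp, mod$medium, pr[2], pr[1]))
    }
  }
})

test_that("redundant donors split the dependency as the subset fraction", {
  mod <- redundant_donor_model()
  s <- species_coupling_score(mod, "r", "d1", mode = "exhaustive")
  expect_equal(s, oracle_scs(as_set_description(mod), mod$medium, "r", "d1"))
  expect_true(s > 0 && s < 1)
  expect_equal(species_coupling_score(mod, "r", "d2", mode = "exhaustive"), s)
})

test_that("Monte-Carlo coupling scores estimate the exhaustive value", {
  mod <- simulate_exchange_community(n_species = 6, crossfeed_density = 0.6,
                                     loop_count = 1, seed = 2)
  exact <- species_coupling_score(mod, "sp_04", "sp_01", mode = "exhaustive")
  # unbiasedness: mean over seeds within 3 standard errors
  ests <- vapply(1:20, function(s) {
    species_coupling_score(mod, "sp_04", "sp_01", mode = "montecarlo",
                           n_samples = 200, seed = s)
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - exact), 3 * max(se, 1e-6))
  # convergence: a large sample lands close
  big <- species_coupling_score(mod, "sp_04", "sp_01", mode = "montecarlo",
                                n_samples = 1e4, seed = 1)
  expect_lt(abs(big - exact), 0.02)
})

test_that("all coupling scores lie in [0, 1] with a zero diagonal convention", {
  mod <- simulate_exchange_community(n_species = 6, crossfeed_density = 0.8,
                                     loop_count = 1, seed = 6)
  run <- coupling_run(mod, mode = "exhaustive")
  expect_true(all(run$scs$scs >= 0 & run$scs$scs <= 1))
  expect_false(any(run$scs$donor == run$scs$recipient))
})

test_that("transfer attribution applies the secretion/requirement rule", {
  # no cross-fed requirement -> empty table
  indep <- community_model(
    tibble::tibble(id = c("a", "b"), required = list("e", "e"),
                   secreted = list("m", character())),
    medium = "e")
  expect_equal(nrow(transfer_attribution(indep)), 0)

  # chain: exactly one record, donor a -> recipient b carrying m1
  tr <- transfer_attribution(chain_model())
  expect_equal(tr, tibble::tibble(donor = "a", recipient = "b",
                                  metabolite = "m1"))

  # medium metabolites are never attributed, non-growing species never donate
  mod <- simulate_exchange_community(n_species = 7, crossfeed_density = 0.7,
                                     loop_count = 1, seed = 9)
  tr2 <- transfer_attribution(mod)
  expect_false(any(tr2$metabolite %in% mod$medium))
  growing <- growth_closure(mod)$growing
  expect_true(all(c(tr2$donor, tr2$recipient) %in% growing))
})

test_that("standardized transfer frequencies sum to one", {
  mod <- simulate_exchange_community(n_species = 7, crossfeed_density = 0.8,
                                     seed = 3)
  freq <- transfer_frequency(transfer_attribution(mod), standardize = TRUE)
  expect_equal(sum(freq$frequency), 1)
})

test_that("MIP worked examples and bounds", {
  # no secretions: exchange changes nothing
  inert <- community_model(
    tibble::tibble(id = c("a", "b"), required = list("e", c("e", "f")),
                   secreted = list(character(), character())),
    medium = c("e", "f"))
  expect_equal(as.numeric(metabolic_interaction_potential(inert)), 0)

  # chain: union {m0, m1}, minimal medium {m0} -> MIP 1
  mip <- metabolic_interaction_potential(chain_model())
  expect_equal(as.numeric(mip), 1)
  expect_equal(attr(mip, "minimal_medium"), "m0")
  expect_equal(attr(mip, "status"), "exact")

  # fully cross-fed community has something to gain from exchange
  mod <- simulate_exchange_community(n_species = 5, crossfeed_density = 1,
                                     medium_size = 2, seed = 4)
  mip2 <- metabolic_interaction_potential(mod)
  expect_gte(as.numeric(mip2), 1)
  expect_lte(as.numeric(mip2), length(unique(unlist(mod$species$required))))
})

test_that("MIP exact search agrees with greedy when forced beyond its limit", {
  mod <- simulate_exchange_community(n_species = 5, crossfeed_density = 0.6,
                                     seed = 13)
  exact <- metabolic_interaction_potential(mod)
  greedy <- metabolic_interaction_potential(mod, exact_limit = 0)
  expect_equal(attr(greedy, "status"), "greedy_lower_bound")
  expect_lte(as.numeric(greedy), as.numeric(exact))
})

test_that("MRO worked examples, variants and invariances", {
  make <- function(req) community_model(
    tibble::tibble(id = names(req), required = unname(req),
                   secreted = replicate(length(req), character())),
    medium = character())

  same <- make(list(a = c("x", "y"), b = c("x", "y"), c = c("x", "y")))
  expect_equal(as.numeric(metabolic_resource_overlap(same)), 1)

  disjoint <- make(list(a = "x", b = "y", c = "z"))
  expect_equal(as.numeric(metabolic_resource_overlap(disjoint)), 0)

  mixed <- make(list(a = c("x", "y"), b = c("y", "z"), c = "w"))
  expect_equal(as.numeric(metabolic_resource_overlap(mixed)), 1 / 6)
  expect_equal(as.numeric(metabolic_resource_overlap(mixed, "union")),
               mean(c(1 / 3, 0, 0)))

  # invariant to metabolite relabeling and species order
  relabeled <- make(list(c = "W", b = c("Y", "Z"), a = c("X", "Y")))
  expect_equal(as.numeric(metabolic_resource_overlap(relabeled)), 1 / 6)

  expect_error(metabolic_resource_overlap(make(list(a = "x"))), "two species")
})

test_that("replicate runs keep seeded bookkeeping and exhaustive determinism", {
  mod <- simulate_exchange_community(n_species = 6, crossfeed_density = 0.7,
                                     loop_count = 1, seed = 1)
  runs <- replicate_runs(mod, n_runs = 10, base_seed = 100, mode = "exhaustive")
  expect_length(runs$runs, 10)
  expect_equal(runs$seeds, 100:109)
  expect_equal(anyDuplicated(runs$seeds), 0L)
  # exhaustive: every run identical, SD exactly zero
  expect_true(all(runs$summary$scs_sd == 0))
  expect_identical(runs$runs[[1]]$scs, runs$runs[[10]]$scs)
  g <- glance(runs)
  expect_equal(g$n_runs, 10)
  expect_equal(g$mip_sd, 0)
})

test_that("Monte-Carlo replicate summaries converge toward exhaustive scores", {
  mod <- simulate_exchange_community(n_species = 6, crossfeed_density = 0.6,
                                     loop_count = 1, seed = 2)
  exact <- replicate_runs(mod, n_runs = 1, mode = "exhaustive")$summary
  mc <- replicate_runs(mod, n_runs = 5, base_seed = 7, mode = "montecarlo",
                       n_samples = 1000)$summary
  joined <- dplyr::inner_join(exact, mc, by = c("donor", "recipient"),
                              suffix = c("_ex", "_mc"))
  expect_lt(max(abs(joined$scs_mean_ex - joined$scs_mean_mc)), 0.08)
  expect_true(any(mc$scs_sd > 0))
})
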