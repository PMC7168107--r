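test_that("fault injection draws faultable components only, deterministically", {
  chain <- toy_chain()
  set.seed(1)
  draws <- replicate(50, inject_faults(chain, 1))
  expect_false("D1" %in% draws)
  expect_setequal(unique(draws), c("R1", "N1", "M1"))
  expect_setequal(inject_faults(chain, 3), c("R1", "N1", "M1"))
  expect_error(inject_faults(chain, 4), class = "physdx_config_error")
  f1 <- physdx:::with_seed(9, inject_faults(chain, 2))
  f2 <- physdx:::with_seed(9, inject_faults(chain, 2))
  expect_identical(f1, f2)
})

test_that("shared affecting components are detected via closure overlap", {
  dia <- toy_diamond()
  expect_true(has_shared_affecting_component(dia, c("N1", "N2")))  # share R1
  expect_false(has_shared_affecting_component(dia, "N1"))
  forest <- anatomy_model(
    data.frame(id = c("R1", "R2", "N1", "N2"),
               kind = c("nerve_root", "nerve_root", "nerve", "nerve")),
    data.frame(source = c("R1", "R2"), target = c("N1", "N2")))
  expect_false(has_shared_affecting_component(forest, c("N1", "N2")))
  # one fault affecting the other counts as shared
  chain <- toy_chain()
  expect_true(has_shared_affecting_component(chain, c("R1", "M1")))
})

test_that("symptom labeling covers exactly the affected closure in relaxed mode", {
  chain <- toy_chain()
  set.seed(2)
  labels <- label_symptoms(chain, "N1", fail_prob = 1)
  expect_identical(names(labels)[!labels], c("N1", "M1", "D1"))
  expect_true(labels["R1"])
  # fault on a sink: everything else passes
  labels <- label_symptoms(chain, "M1", fail_prob = 1)
  expect_identical(names(labels)[!labels], "M1")
})

test_that("every fault gets at least one explaining symptom", {
  chain <- toy_chain()
  for (seed in 1:40) {
    set.seed(seed)
    labels <- label_symptoms(chain, "N1", fail_prob = 0.5)
    falses <- names(labels)[!labels]
    expect_true(all(falses %in% c("N1", "M1", "D1")))
    expect_gte(length(falses), 1)
  }
})

test_that("observation selection respects the cardinality bound", {
  labels <- setNames(rep(FALSE, 6), paste0("C", 1:6))
  set.seed(3)
  for (i in 1:30) {
    obs <- select_observations(labels, 4)
    expect_true(length(obs) >= 1 && length(obs) <= 4)
    expect_true(all(!obs))
  }
  one <- select_observations(labels, 1)
  expect_length(one, 1)
  expect_error(select_observations(setNames(TRUE, "C1"), 1),
               class = "physdx_contract_error")
})

test_that("scenarios satisfy their structural invariants", {
  m <- generate_synthetic_model(seed = 4)
  for (seed in 1:25) {
    k <- sample(1:5, 1)
    sc <- generate_scenario(m, k, fail_prob = 0.5, seed = 200 + seed)
    expect_false(any(sc$faults %in% m$dermatomes))
    affected <- unique(c(sc$faults,
                         unlist(m$descendants[sc$faults], use.names = FALSE)))
    falses <- names(sc$labels)[!sc$labels]
    expect_true(all(falses %in% affected))
    for (f in sc$faults) {
      expect_true(any(!sc$labels[c(f, m$descendants[[f]])]),
                  label = paste("fault", f, "explained, seed", seed))
    }
    expect_true(length(sc$initial_obs) >= 1 && length(sc$initial_obs) <= sc$k)
    expect_true(all(names(sc$initial_obs) %in% falses))
    # post-resampling faults are pairwise ancestor-disjoint
    expect_false(has_shared_affecting_component(m, sc$faults))
  }
  sc1 <- generate_scenario(m, 3, seed = 77)
  sc2 <- generate_scenario(m, 3, seed = 77)
  expect_identical(sc1$faults, sc2$faults)
  expect_identical(sc1$labels, sc2$labels)
  expect_identical(unclass(sc1$initial_obs), unclass(sc2$initial_obs))
})

test_that("relaxed mode labels exactly the fault closure as failing", {
  m <- generate_synthetic_model(seed = 5)
  for (seed in 1:10) {
    sc <- generate_scenario(m, 2, fail_prob = 1, seed = 300 + seed)
    affected <- sort(unique(c(sc$faults,
                              unlist(m$descendants[sc$faults], use.names = FALSE))))
    expect_identical(sort(names(sc$labels)[!sc$labels]), affected)
  }
})

test_that("initial observations always admit a diagnosis covering a fault", {
  m <- generate_synthetic_model(seed = 6)
  for (seed in 1:15) {
    sc <- generate_scenario(m, sample(1:4, 1), seed = 400 + seed)
    d <- diagnose(m, sc$initial_obs)
    expect_gte(length(d$diagnoses), 1)
    for (o in names(sc$initial_obs)) {
      closure <- c(o, ancestors(m, o))
      expect_true(any(closure %in% sc$faults))
    }
  }
})

test_that("batches match their configured composition", {
  m <- generate_synthetic_model(seed = 8)
  cfg <- sim_config(instances_per_cardinality = 5, multi_fault_range = c(2, 4),
                    fail_prob = 1, seed = 31)
  b <- generate_batch(m, cfg)
  nf <- length(faultable_components(m))
  expect_identical(b$manifest$n_pre_discard, nf + 5L * 3L)
  expect_identical(b$manifest$n_kept, length(b$scenarios))
  expect_identical(b$manifest$n_kept, nf + 5L * 3L)  # resample mode refills
  ks <- vapply(b$scenarios, `[[`, numeric(1), "k")
  expect_identical(sum(ks == 1), nf)
  expect_true(all(table(ks[ks > 1]) == 5))
  # singles cover every faultable component exactly once
  singles <- unlist(lapply(b$scenarios[ks == 1], `[[`, "faults"))
  expect_setequal(singles, faultable_components(m))

  b2 <- generate_batch(m, cfg)
  expect_identical(vapply(b$scenarios, function(s) paste(s$faults, collapse = ","),
                          character(1)),
                   vapply(b2$scenarios, function(s) paste(s$faults, collapse = ","),
                          character(1)))

  # discard mode: every diamond k=2 draw is entangled and dropped
  dia <- toy_diamond()
  bd <- generate_batch(dia, sim_config(instances_per_cardinality = 10,
                                       multi_fault_range = c(3, 3),
                                       singles_exhaustive = FALSE,
                                       discard_mode = "discard", seed = 1))
  expect_identical(bd$manifest$n_kept, 0L)
  expect_identical(bd$manifest$n_discarded, 10L)
})

test_that("scenario oracles answer from the label map consistently", {
  m <- generate_synthetic_model(seed = 9)
  sc <- generate_scenario(m, 2, fail_prob = 1, seed = 55)
  oracle <- oracle_from_scenario(sc)
  falses <- names(sc$labels)[!sc$labels]
  trues <- names(sc$labels)[sc$labels]
  expect_false(oracle(falses[1]))
  expect_true(oracle(trues[1]))
  expect_identical(oracle(falses[1]), oracle(falses[1]))
})

test_that("scenario JSONL round-trips", {
  m <- generate_synthetic_model(seed = 12)
  b <- generate_batch(m, sim_config(instances_per_cardinality = 2,
                                    multi_fault_range = c(2, 3), seed = 13))
  path <- withr::local_tempfile(fileext = ".jsonl")
  mpath <- withr::local_tempfile(fileext = ".json")
  write_scenarios(b, path, mpath)
  back <- read_scenarios(path)
  expect_length(back, length(b$scenarios))
  i <- length(back)
  expect_identical(back[[i]]$faults, b$scenarios[[i]]$faults)
  expect_identical(back[[i]]$labels, b$scenarios[[i]]$labels)
  expect_identical(unclass(back[[i]]$initial_obs),
                   unclass(b$scenarios[[i]]$initial_obs))
  manifest <- jsonlite::fromJSON(mpath)
  expect_identical(manifest$n_kept, length(back))
})
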