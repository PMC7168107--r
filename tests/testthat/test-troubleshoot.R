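test_that("entropy matches closed forms", {
  m <- toy_chain()
  Deq <- physdx:::new_diagnosis_set(list("M1", "N1", "R1"), m,
                                    observation_set(), prior = 0.1)
  expect_equal(diagnosis_entropy(Deq), log2(3))
  D1 <- physdx:::new_diagnosis_set(list("M1"), m, observation_set(), prior = 0.1)
  expect_equal(diagnosis_entropy(D1), 0)
  # (0.5, 0.25, 0.25) -> 1.5 bits: sizes (1, 2, 2) at prior 0.5
  Dh <- physdx:::new_diagnosis_set(list("M1", c("N1", "M1"), c("R1", "M1")), m,
                                   observation_set(), prior = 0.5)
  expect_equal(sort(Dh$prob), c(0.25, 0.25, 0.5))
  expect_equal(diagnosis_entropy(Dh), 1.5, tolerance = 1e-9)
})

test_that("candidate probes are the union of diagnosis members", {
  frag <- fragment_model()
  d <- diagnose(frag, observation_set("DC6", FALSE))
  expect_setequal(candidate_probes(d), c("C6", "Radial"))
  expect_setequal(candidate_probes(d, already_tested = "C6"), "Radial")
  d0 <- diagnose(frag, observation_set())
  expect_length(candidate_probes(d0), 0)
})

test_that("answers update the diagnosis set per the weak fault model", {
  frag <- fragment_model()
  d <- diagnose(frag, observation_set("DC6", FALSE))
  # a failed Median test (closure {Median, C6}) leaves only {C6}
  d2 <- update_on_answer(d, "Median", FALSE)
  expect_identical(canon_sets(d2$diagnoses), "C6")
  expect_equal(d2$prob, 1)
  # a pass changes nothing
  d3 <- update_on_answer(d, "Deltoid", TRUE)
  expect_identical(d3$diagnoses, d$diagnoses)
  expect_equal(d3$prob, d$prob)
  # failing R1 on the chain keeps only the diagnoses implicating R1
  chain <- toy_chain()
  dm <- diagnose(chain, observation_set("M1", FALSE))
  dm <- update_on_answer(dm, "R1", FALSE)
  expect_identical(canon_sets(dm$diagnoses), "R1")
})

test_that("inconsistent answers raise the dedicated condition", {
  m <- toy_diamond()
  d <- diagnose(m, observation_set("N1", FALSE))   # {N1} or {R1}
  d <- update_on_answer(d, "N1", FALSE)
  expect_identical(canon_sets(d$diagnoses), c("N1", "R1"))
  # craft a singleton set {N1}, then fail a probe with disjoint closure
  dn <- physdx:::new_diagnosis_set(list("N1"), m, observation_set(), 0.1)
  expect_error(update_on_answer(dn, "N2", FALSE),
               class = "physdx_inconsistent_answer")
})

test_that("expected information gain matches the hand-computed fragment case", {
  frag <- fragment_model()
  d <- diagnose(frag, observation_set("DC6", FALSE))
  expect_equal(expected_information_gain(d, "Median"), 0.5, tolerance = 1e-9)
})

test_that("gain is zero for all-hitting and never-hitting probes", {
  frag <- fragment_model()
  d <- diagnose(frag, observation_set("DC6", FALSE))
  # closure(Radial) = {Radial, C6} intersects both candidates
  expect_equal(expected_information_gain(d, "Radial"), 0)
  # a probe intersecting no diagnosis: Brachialis closure = {Brachialis,
  # Median, C6} intersects {C6}; craft instead on the chain
  chain <- toy_chain()
  dm <- physdx:::new_diagnosis_set(list("M1"), chain, observation_set(), 0.1)
  expect_equal(expected_information_gain(dm, "M1"), 0)
  dmn <- physdx:::new_diagnosis_set(list("N1", "M1"), chain, observation_set(), 0.1)
  expect_gte(expected_information_gain(dmn, "N1"), 0)
})

test_that("probing isolates the injected fault in the fragment scenario", {
  frag <- fragment_model()
  sc <- generate_scenario(frag, 1, fail_prob = 1, seed = 7, faults = "C6")
  expect_false(any(sc$labels))   # C6 affects every component
  d0 <- diagnose(frag, sc$initial_obs)
  s <- run_probing(d0, oracle_from_scenario(sc), "info_gain", seed = 3)
  expect_identical(canon_sets(s$final$diagnoses), "C6")
  expect_equal(s$final$prob, 1)
})

test_that("probing sessions are deterministic and monotone", {
  m <- generate_synthetic_model(seed = 10)
  for (seed in 1:20) {
    sc <- generate_scenario(m, sample(1:4, 1), fail_prob = 0.5, seed = 100 + seed)
    d0 <- diagnose(m, sc$initial_obs)
    s1 <- run_probing(d0, oracle_from_scenario(sc), "info_gain", seed = seed)
    s2 <- run_probing(d0, oracle_from_scenario(sc), "info_gain", seed = seed)
    expect_identical(s1$log, s2$log)
    sizes <- c(length(d0$diagnoses), s1$log$set_size_after)
    expect_true(all(diff(sizes) <= 0))
    expect_true(all(s1$log$expected_gain >= 0))
    # termination within |union of diagnosis members| probes
    expect_lte(nrow(s1$log), length(candidate_probes(d0)))
  }
})

test_that("singleton initial sets terminate with no probes", {
  chain <- toy_chain()
  d <- physdx:::new_diagnosis_set(list("R1"), chain, observation_set(), 0.1)
  s <- run_probing(d, function(x) TRUE, "info_gain", seed = 1)
  expect_identical(nrow(s$log), 0L)
  expect_identical(s$final$diagnoses, d$diagnoses)
})

test_that("random policy explores but reaches a sound final set", {
  m <- generate_synthetic_model(seed = 11)
  sc <- generate_scenario(m, 3, fail_prob = 1, seed = 21)
  d0 <- diagnose(m, sc$initial_obs)
  s <- run_probing(d0, oracle_from_scenario(sc), "random", seed = 5)
  expect_true(all(diff(c(length(d0$diagnoses), s$log$set_size_after)) <= 0))
  # the injected faults stay diagnosable throughout
  expect_true(any(vapply(s$final$diagnoses,
                         function(d) all(d %in% sc$faults), logical(1))) ||
                length(s$final$diagnoses) >= 1)
})
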