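test_that("single-step decoding is the emission-column argmax", {
  spec <- default_spec_t()
  for (c in 0:3)
    expect_identical(viterbi_decode(c, spec), c)
  # and equals the shortcut on a single observation
  for (e in 0:3)
    expect_identical(viterbi_decode(e, spec), shortcut_constant(e, spec, 1))
})

test_that("viterbi matches brute-force path enumeration on random models", {
  set.seed(101)
  n_checked <- 0L
  for (rep in 1:60) {
    n <- sample(2:4, 1)
    len <- sample(2:6, 1)
    zf <- sample(c(0, 0, 0.3), 1)
    spec <- random_spec(n, zero_frac = zf)
    obs <- sample(0:(n - 1), len, replace = TRUE)
    oracle <- brute_viterbi(obs, spec)
    if (!oracle$feasible) {
      expect_error(viterbi_decode(obs, spec), "no feasible path")
      next
    }
    got <- viterbi_decode(obs, spec)
    expect_equal(path_score(got, obs, spec), oracle$score, tolerance = 1e-9)
    if (oracle$n_near_max == 1L)
      expect_identical(got, oracle$path)
    # feasibility: never traverse a forbidden transition
    if (length(got) > 1)
      expect_true(all(spec$transition[cbind(got[-length(got)] + 1,
                                            got[-1] + 1)] > 0))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 30)
})

test_that("ties in the backtrack resolve to the lowest class index", {
  # two classes, fully symmetric model: every path has equal probability
  spec <- hmm_spec(matrix(0.5, 2, 2), matrix(0.5, 2, 2), c(0.5, 0.5))
  expect_identical(viterbi_decode(c(0L, 1L, 0L), spec), c(0L, 0L, 0L))
  expect_identical(shortcut_constant(1L, spec, 4), rep(0L, 4))
})

test_that("an all-blocked time step raises a no-feasible-path error", {
  trans <- rbind(c(1, 0), c(0, 1))
  emis <- rbind(c(1, 0), c(0, 1)) # class i only ever observed as i
  spec <- hmm_spec(trans, emis, c(1, 0)) # must start in class 0
  expect_error(viterbi_decode(c(0L, 1L), spec), "time step 1")
  expect_error(viterbi_decode(1L, spec), "time step 0")
  # the same observations are feasible when the start allows class 1
  spec2 <- hmm_spec(trans, emis, c(0.5, 0.5))
  expect_identical(viterbi_decode(c(1L, 1L), spec2), c(1L, 1L))
})

test_that("uniform transitions reduce decoding to per-step emission argmax", {
  # the mechanism behind the naive model changing nothing: with all
  # transitions equal and identity column argmax, decode(seq) == seq
  spec <- hmm_spec(build_transition_naive(4), default_emission(4))
  set.seed(5)
  for (i in 1:25) {
    obs <- sample(0:3, sample(1:12, 1), replace = TRUE)
    expect_identical(viterbi_decode(obs, spec), as.integer(obs))
  }
})

test_that("decoding is deterministic", {
  set.seed(33)
  spec <- random_spec(4)
  obs <- sample(0:3, 40, replace = TRUE)
  expect_identical(viterbi_decode(obs, spec), viterbi_decode(obs, spec))
})

test_that("the constant-observation shortcut agrees with Viterbi for the default model", {
  spec <- default_spec_t()
  audit <- audit_shortcut(spec, lengths = 1:6)
  expect_identical(nrow(audit), 0L)
  for (e in 0:3)
    expect_identical(shortcut_constant(e, spec, 21), rep(e, 21L))
})

test_that("shortcut audit reports disagreements when they exist", {
  # an emission whose column argmax fights a transition matrix that forbids
  # staying in that class makes the shortcut approximation visible
  trans <- rbind(c(0.05, 0.95), c(0.95, 0.05)) # strongly alternating
  emis <- rbind(c(0.6, 0.4), c(0.4, 0.6))
  spec <- hmm_spec(trans, emis)
  expect_warning(audit <- audit_shortcut(spec, lengths = 1:6), "disagrees")
  expect_gt(nrow(audit), 0)
})

test_that("behavioural scenarios decode as the physics requires", {
  spec <- default_spec_t()
  # isolated contrary observations after conversion are overridden
  fwd <- scenario_behaviour("forward", noise_steps = c(11, 16))
  dec <- viterbi_decode(fwd, spec)
  expect_identical(dec[c(12, 17)], c(3L, 3L))
  # without noise the decode is the clean monotone transition
  clean <- scenario_behaviour("forward")
  expect_identical(viterbi_decode(clean, spec), clean)
  # a single trailing contrary observation does not flip the final state
  rev1 <- scenario_behaviour("reverse", noise_steps = 20)
  expect_identical(tail(viterbi_decode(rev1, spec), 1), 3L)
  # but a sustained contrary run eventually does
  flipped <- FALSE
  for (k in 2:4) {
    revk <- scenario_behaviour("reverse", noise_steps = (21 - k):20)
    if (tail(viterbi_decode(revk, spec), 1) == 2L) { flipped <- TRUE; break }
  }
  expect_true(flipped)
})
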