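test_that("the basis-pursuit objective reduces to its analytic values", {
  # zero codes: 1/2 ||s||^2
  s <- c(1, 2, -1, 0.5)
  dict <- step_dictionary(matrix(c(1, 0), 2, 1))
  z <- matrix(0, 4, 1)
  expect_equal(cdl_objective(list(s), dict, list(z), lam = 3),
               0.5 * sum(s^2))

  # hand computation: s=(1,0,0), atom d=(1), code x=(1,0,0), lambda=5 -> 5
  d1 <- step_dictionary(matrix(1, 1, 1))
  x <- matrix(c(1, 0, 0), 3, 1)
  expect_equal(cdl_objective(list(c(1, 0, 0)), d1, list(x), lam = 5), 5)

  # perfect reconstruction at lambda = 0
  atom <- planted_atom()
  da <- step_dictionary(matrix(atom, ncol = 1))
  spikes <- rep(0, 300); spikes[c(40, 180)] <- c(2, -1)
  srec <- Re(stats::fft(stats::fft(spikes) *
                          stats::fft(c(atom, rep(0, 230))),
                        inverse = TRUE)) / 300
  expect_equal(cdl_objective(list(srec), da, list(matrix(spikes, ncol = 1)),
                             lam = 0), 0, tolerance = 1e-12)

  expect_error(cdl_objective(list(srec), da, list(matrix(0, 10, 1)), 1),
               "mismatch")
})

test_that("dictionary learning recovers a planted atom", {
  sigs <- planted_signals(n_signals = 20L, seed = 42L)
  fit <- learn_dictionary(sigs, m = 1, atom_sec = 0.7, lam = 0.2,
                          iters = 150, seed = 7)
  # unit norm
  expect_equal(sqrt(sum(fit$dictionary$atoms[, 1]^2)), 1, tolerance = 1e-6)
  # normalised cross-correlation against the planted atom, over circular
  # shifts and sign
  ncc <- atom_ncc(planted_atom(), fit$dictionary$atoms[, 1])
  expect_gte(ncc, 0.90)
  # objective descent against the zero-code random initialisation
  obj_final <- cdl_objective(sigs, fit$dictionary, fit$codes, 0.2)
  obj_init <- sum(vapply(sigs, function(s) 0.5 * sum(s^2), 0))
  expect_lt(obj_final, obj_init)
})

test_that("an overwhelming sparsity weight drives all codes to zero", {
  sigs <- planted_signals(n_signals = 4L, T_len = 400L, seed = 9L)
  fit <- learn_dictionary(sigs, m = 2, atom_sec = 0.7, lam = 1e6,
                          iters = 30, seed = 2)
  expect_true(all(vapply(fit$codes, function(x) max(abs(x)), 0) == 0))
  obj <- cdl_objective(sigs, fit$dictionary, fit$codes, 1e6)
  expect_equal(obj, sum(vapply(sigs, function(s) 0.5 * sum(s^2), 0)),
               tolerance = 1e-10)
})

test_that("learning is deterministic given the seed and validates input", {
  sigs <- planted_signals(n_signals = 3L, T_len = 300L, seed = 5L)
  f1 <- learn_dictionary(sigs, m = 2, lam = 0.5, iters = 20, seed = 11)
  f2 <- learn_dictionary(sigs, m = 2, lam = 0.5, iters = 20, seed = 11)
  expect_identical(f1$dictionary$atoms, f2$dictionary$atoms)
  expect_error(learn_dictionary(list(rnorm(50)), m = 1, atom_sec = 0.7),
               "longer")
})

test_that("cross-validation selects the planted number of atoms", {
  u <- seq(0, 1, length.out = 70)
  a1 <- exp(-((u - 0.3) / 0.08)^2); a1 <- a1 / sqrt(sum(a1^2))
  a2 <- sin(2 * pi * 4 * u) * exp(-((u - 0.6) / 0.15)^2)
  a2 <- a2 / sqrt(sum(a2^2))
  sigs <- withr::with_seed(5, lapply(1:12, function(i) {
    n <- 1000; s <- 0
    for (a in list(a1, a2)) {
      spikes <- stats::rbinom(n, 1, 0.008) * 2 *
        sample(c(-1, 1), n, replace = TRUE)
      s <- s + Re(stats::fft(stats::fft(spikes) *
                               stats::fft(c(a, rep(0, n - 70))),
                             inverse = TRUE)) / n
    }
    s + stats::rnorm(n, sd = 0.005)
  }))
  m <- select_num_atoms(sigs, candidate_ms = 1:4, folds = 3, lam = 0.2,
                        iters = 100, seed = 3)
  expect_equal(m, 2L)
  # singleton candidate set and determinism
  expect_equal(select_num_atoms(sigs[1:4], candidate_ms = 3, folds = 2,
                                lam = 0.2, iters = 10, seed = 1), 3L)
  expect_error(select_num_atoms(sigs[1:2], candidate_ms = 1, folds = 3),
               "fewer signals")
})

test_that("embedding is the identity under a one-sample impulse atom", {
  dct <- step_dictionary(matrix(1, 1, 1))
  s <- withr::with_seed(2, rnorm(200))
  expect_equal(embed_signal(s, dct)$channels[1, ], s)
})

test_that("embedding centres the atom on an input impulse", {
  atom <- planted_atom()
  dct <- step_dictionary(matrix(atom, ncol = 1))
  s <- rep(0, 300); p <- 150
  s[p + 1] <- 1                      # impulse at 0-based position p
  e <- embed_signal(s, dct)$channels[1, ]
  c0 <- 70 %/% 2 + 1                 # atom element placed at p
  expect_equal(e[p + 1], atom[c0])
  expect_equal(which(abs(e) > 1e-8)[1], p + 1 - (c0 - 1))
})

test_that("embedding is linear and shift-equivariant away from borders", {
  atom <- planted_atom()
  dct <- step_dictionary(matrix(cbind(atom, rev(atom)), ncol = 2))
  withr::with_seed(4, {
    a <- rnorm(400); b <- rnorm(400)
    ea <- embed_signal(a, dct)$channels
    eb <- embed_signal(b, dct)$channels
    eab <- embed_signal(a + b, dct)$channels
    expect_equal(eab, ea + eb, tolerance = 1e-10)
    # shift by k samples shifts the embedding by k, away from borders
    k <- 30L
    a_shift <- c(rep(0, k), a[1:(400 - k)])
    es <- embed_signal(a_shift, dct)$channels
    inner <- 100:300
    expect_equal(es[, inner + k], ea[, inner], tolerance = 1e-10)
  })
  expect_error(embed_signal(rnorm(50), dct), "shorter")
})
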