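test_that("corpus generation is a pure function of spec and seed", {
  spec <- zebra_finch_spec(n_songs = 4, n_nonsong = 4, seed = 7)
  a <- generate_corpus(spec)
  b <- generate_corpus(spec)
  expect_identical(a$songs, b$songs)
  expect_identical(a$nonsong, b$nonsong)
  expect_identical(a$canonical_times, b$canonical_times)
})

test_that("zero jitter and no noise yield bit-identical songs", {
  spec <- zebra_finch_spec(n_songs = 5, n_nonsong = 2, seed = 3,
                           onset_jitter_sd_ms = 0, amplitude_jitter_sd = 0,
                           noise_snr_db = Inf)
  corpus <- generate_corpus(spec)
  for (i in 2:5) expect_identical(corpus$songs[[i]], corpus$songs[[1]])
  expect_true(all(corpus$canonical_times == corpus$canonical_times[1, 1]))
})

test_that("realized onset jitter converges to the requested SD", {
  spec <- zebra_finch_spec(n_songs = 1000, n_nonsong = 1, seed = 42)
  corpus <- generate_corpus(spec)
  offsets <- corpus$canonical_times[, 1] - spec$targets[1]
  expect_equal(offsets, corpus$onset_shift_ms)
  # within 10% of the requested 2 ms at n = 1000
  expect_lt(abs(sd(offsets) - 2) / 2, 0.10)
})

test_that("clips are equal length and non-song clips carry construction flags", {
  corpus <- generate_corpus(zebra_finch_spec(n_songs = 6, n_nonsong = 6,
                                             seed = 1))
  lens <- vapply(c(corpus$songs, corpus$nonsong), length, integer(1))
  expect_true(all(lens == lens[1]))
  expect_true(all(corpus$nonsong_kinds %in%
                    c("silence", "cage_noise", "noise_burst", "call")))
  expect_equal(nrow(corpus$canonical_times), 6)
})

test_that("syllables above Nyquist are rejected with a clear message", {
  bad <- list(syllable_spec("harmonic_stack", duration_ms = 50, f0 = 4000,
                            n_harmonics = 10))
  expect_error(corpus_spec(bad, targets = 50, sample_rate = 44100),
               "Nyquist")
})

test_that("delta corpus places the canonical target exactly 5 ms after the impulse", {
  corpus <- generate_delta_corpus(n_songs = 12, seed = 1)
  for (i in 1:12) {
    k <- which.max(abs(corpus$songs[[i]]))
    expect_identical(k, corpus$impulse_sample[i])
    expect_equal(corpus$canonical_times[i, 1] - k / corpus$rate * 1000, 5)
  }
})

test_that("delta impulse phase sweeps uniformly over one frame hop", {
  corpus <- generate_delta_corpus(n_songs = 200, seed = 1)
  phases <- (corpus$impulse_sample - corpus$impulse_sample[1]) %% 66
  counts <- table(phases)
  expect_equal(length(counts), 66)          # every residue visited
  expect_lte(max(counts) - min(counts), 2)  # near-uniform coverage
})

test_that("a corpus round-trips losslessly through write_corpus/read_corpus", {
  corpus <- generate_corpus(zebra_finch_spec(n_songs = 3, n_nonsong = 3,
                                             seed = 9))
  dir <- withr::local_tempdir()
  man <- write_corpus(corpus, dir)
  expect_equal(nrow(man), 6)
  back <- read_corpus(dir)
  expect_identical(back$songs, corpus$songs)
  expect_identical(back$nonsong, corpus$nonsong)
  expect_equal(back$rate, corpus$rate)
  expect_identical(back$id, corpus$id)
  # annotation times serialized well below 1 microsecond of error
  expect_lt(max(abs(back$canonical_times - corpus$canonical_times)), 1e-6)
})
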