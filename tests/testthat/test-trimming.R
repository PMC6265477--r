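# a U6-like 111-mer: positions 1-106 paired (telestem and upstream),
# 107-111 unpaired
u6_like_111 <- function() {
  seqs <- paste(c(rep("G", 50), rep("C", 46), rep("U", 10), rep("U", 5)),
                collapse = "")
  paired <- c(rep(TRUE, 106), rep(FALSE, 5))
  rna_state(seqs, paired = paired)
}

test_that("telestem pairing gates trimming at 107 nucleotides", {
  st <- u6_like_111()
  expect_equal(st$length, 111)
  res <- trimming_extent(st)
  expect_equal(res$final_length, 107)
  expect_equal(res$stop_reason, "paired_n_minus_1")
  expect_equal(length(res$removed), 4)
})

test_that("a 2'-deoxy at n-1 blocks processing; at n-2 allows exactly one cut", {
  n <- 8
  # deoxy at n-1
  st1 <- rna_state(strsplit("UAUUUUUU", "")[[1]], deoxy = n - 1)
  r1 <- trimming_extent(st1)
  expect_equal(r1$final_length, n)
  expect_equal(length(r1$removed), 0)
  expect_equal(r1$stop_reason, "deoxy_n_minus_1")
  # deoxy at n-2: one cut, then the deoxy residue is the new n-1
  st2 <- rna_state(strsplit("UAUUUUUU", "")[[1]], deoxy = n - 2)
  r2 <- trimming_extent(st2)
  expect_equal(r2$final_length, n - 1)
  expect_equal(length(r2$removed), 1)
  expect_equal(r2$stop_reason, "deoxy_n_minus_1")
  # the measured substrate names encode the single-cleavage design (dU at n-2)
  st3 <- rna_state("UAUUUdUUA")
  expect_equal(trimming_extent(st3)$final_length, st3$length - 1)
})

test_that("trimming is idempotent and respects the length floor", {
  st <- u6_like_111()
  res <- trimming_extent(st)
  # re-running on the trimmed state removes nothing
  st2 <- rna_state(st$sequence[1:res$final_length],
                   paired = st$paired[1:res$final_length],
                   deoxy = st$deoxy[1:res$final_length])
  res2 <- trimming_extent(st2)
  expect_equal(res2$final_length, res$final_length)
  expect_equal(length(res2$removed), 0)
  # unpaired RNA degrades to the floor
  free <- rna_state("AAAAAAAA")
  expect_equal(trimming_extent(free)$final_length, 1)
  expect_equal(trimming_extent(free)$stop_reason, "min_length")
  expect_equal(trimming_extent(free, min_length = 4)$final_length, 4)
})

test_that("single-step decay matches the exponential law in both modes", {
  st <- rna_state("UAUUUdUUA") # exactly one allowed cut, terminal UA
  L <- as.character(st$length)
  k <- default_rate_map()[["UA"]]
  tg <- c(0.01, 0.05, 0.1)
  det <- simulate_distributive_trimming(st, t_grid = tg,
                                        mode = "deterministic")
  expect_equal(det$length_distribution[L, ], exp(-k * tg),
               tolerance = 1e-9, ignore_attr = TRUE)
  sto <- simulate_distributive_trimming(st, t_grid = tg,
                                        mode = "stochastic", seed = 4,
                                        n_replicates = 20000)
  expect_equal(sto$length_distribution[L, ],
               det$length_distribution[L, ], tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("length distributions are proper and the pairing gate freezes them", {
  st <- u6_like_111()
  sim <- simulate_distributive_trimming(st, t_grid = c(0.1, 1, 25),
                                        mode = "deterministic")
  expect_true(all(abs(colSums(sim$length_distribution) - 1) < 1e-9))
  # long-time limit: everything at the gated final length
  expect_gt(sim$length_distribution["107", 3], 0.999)
  # fully paired RNA: point mass at the initial length for all t
  frozen <- rna_state("GGGGCCCC", paired = rep(TRUE, 8))
  fs <- simulate_distributive_trimming(frozen, t_grid = c(0.5, 5),
                                       mode = "deterministic")
  expect_true(all(fs$length_distribution["8", ] == 1))
})

test_that("deterministic and Gillespie distributions agree on a 5-step chain", {
  # pairing through position 5 leaves exactly 5 allowed cuts (11 -> 6)
  st <- rna_state("GGGGGUAUAUA", paired = c(rep(TRUE, 5), rep(FALSE, 6)))
  det <- simulate_distributive_trimming(st, t_grid = c(0.05, 0.2),
                                        mode = "deterministic")
  sto <- simulate_distributive_trimming(st, t_grid = c(0.05, 0.2),
                                        mode = "stochastic", seed = 9,
                                        n_replicates = 10000)
  expect_equal(dim(det$length_distribution), dim(sto$length_distribution))
  for (k in 1:2) {
    tv <- 0.5 * sum(abs(det$length_distribution[, k] -
                        sto$length_distribution[, k]))
    expect_lt(tv, 0.02)
  }
})

test_that("the UA-terminated species is consumed faster than UU-terminated", {
  ua <- rna_state("UUUUUUUA")
  uu <- rna_state("UUUUUUUU")
  t_early <- 0.01
  d_ua <- simulate_distributive_trimming(ua, t_grid = t_early,
                                         mode = "deterministic")
  d_uu <- simulate_distributive_trimming(uu, t_grid = t_early,
                                         mode = "deterministic")
  expect_lt(d_ua$length_distribution["8", 1], d_uu$length_distribution["8", 1])
})

test_that("rate map gaps are reported by dinucleotide", {
  st <- rna_state("UUUA")
  expect_error(simulate_distributive_trimming(st, rate_map = c(UU = 1)),
               "UA")
})

test_that("rna_state parses dot-bracket pairing and d-prefixed sequences", {
  st <- rna_state("ACGU", paired = "((..")
  expect_identical(st$paired, c(TRUE, TRUE, FALSE, FALSE))
  st2 <- rna_state("UAUUUdUUU")
  expect_equal(st2$length, 8)
  expect_identical(which(st2$deoxy), 6L)
  expect_error(rna_state("ACGU", paired = "(((.."), "length")
})
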