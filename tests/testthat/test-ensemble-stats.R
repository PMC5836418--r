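test_that("pair_entropy matches the binary entropy function", {
  expect_equal(pair_entropy(0.5), 1)
  expect_equal(pair_entropy(0), 0)
  expect_equal(pair_entropy(1), 0)
  expect_equal(pair_entropy(0.25), 0.811278124459133, tolerance = 1e-12)
  expect_equal(pair_entropy(0.25), pair_entropy(0.75))
  expect_error(pair_entropy(1.2), "\\[0, 1\\]")
  expect_error(pair_entropy(-0.1), "\\[0, 1\\]")
})

test_that("conditional entropy handles perfect, independent and exclusive cases", {
  # identical indicators at p = 0.5: knowing one determines the other
  expect_equal(conditional_entropy(matrix(c(0.5, 0, 0, 0.5), 2)), 0)
  # independent with p_x = 0.5
  joint <- outer(c(0.5, 0.5), c(0.4, 0.6))
  expect_equal(conditional_entropy(joint), 1)
  # mutually exclusive and exhaustive (p_x = 0.4, p_y = 0.6)
  joint <- matrix(c(0, 0.6, 0.4, 0), 2, byrow = TRUE)
  expect_equal(conditional_entropy(joint), 0)
  expect_error(conditional_entropy(matrix(c(0.5, 0.2, 0.2, 0.2), 2)), "sum to 1")
  expect_error(conditional_entropy(matrix(c(-0.1, 0.5, 0.3, 0.3), 2)),
               "nonnegative")
})

test_that("build_ensemble assembles candidates, indicators, and marginals", {
  seq <- "GGAAACC"
  s1 <- rna_structure(seq, c(1, 7, 2, 6))
  s2 <- rna_structure(seq, c(1, 7))
  ens <- build_ensemble(list(s1, s2))
  expect_equal(unname(ens$candidates), rbind(c(1L, 7L), c(2L, 6L)))
  st <- pair_stats(ens)
  expect_equal(st$p, c(1, 0.5))
  expect_equal(st$count, c(2L, 1L))
  # identical samples: zero entropy everywhere
  ens10 <- build_ensemble(rep(list(s1), 10))
  expect_true(all(pair_stats(ens10)$H == 0))
  expect_error(build_ensemble(list(s1)), "at least 2")
  s3 <- rna_structure("GGAAACCC", c(1, 8))
  expect_error(build_ensemble(list(s1, s3)), "one sequence")
})

test_that("sampled marginals converge to exact toy marginals", {
  ex <- exact_ensemble(bistable_seq())
  ens <- build_ensemble(sample_structures(ex, 1000, seed = 31))
  st <- pair_stats(ens)
  for (r in seq_len(nrow(st))) {
    p <- exact_marginal(ex, c(st$i[r], st$j[r]))
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(st$p[r] - p), max(3 * se, 0.01))
  }
})

test_that("mutual information is symmetric, bounded, and exact on identities", {
  ens <- bistable_ensemble()
  a <- c(1, 12); b <- c(5, 18)
  # I(X;X) = H(X)
  expect_equal(mutual_information(ens, a, a), 1)
  # complementary halves: mutually exclusive and exhaustive at p = 0.5
  expect_equal(mutual_information(ens, a, b), 1)
  expect_equal(mutual_information(ens, a, b), mutual_information(ens, b, a))
  expect_error(mutual_information(ens, c(1, 18), a), "not among")
})

test_that("empirically independent columns give zero MI", {
  # pair a varies in the first half, pair b varies in the second half of an
  # interleaved design, making the two columns exactly independent
  seq <- strrep("A", 20)
  mk <- function(a, b) {
    pairs <- NULL
    if (a) pairs <- rbind(pairs, c(1, 10))
    if (b) pairs <- rbind(pairs, c(2, 9))
    rna_structure(seq, pairs)
  }
  ens <- build_ensemble(list(mk(0, 0), mk(0, 1), mk(1, 0), mk(1, 1)))
  expect_equal(mutual_information(ens, c(1, 10), c(2, 9)), 0)
})

test_that("information identities hold on random sampled ensembles", {
  set.seed(47)
  for (rep in 1:25) {
    seq <- random_seq(sample(10:14, 1))
    ex <- exact_ensemble(seq)
    if (nrow(ex$candidates) < 2) next
    ens <- build_ensemble(sample_structures(ex, 80, seed = rep))
    m <- nrow(ens$candidates)
    if (m < 2) next
    st <- pair_stats(ens)
    for (t in 1:3) {
      ab <- sample(m, 2)
      a <- as.integer(ens$candidates[ab[1], ])
      b <- as.integer(ens$candidates[ab[2], ])
      mi <- mutual_information(ens, a, b)
      expect_lt(abs(mi - mutual_information(ens, b, a)), 1e-12)
      expect_gte(mi, 0)
      expect_lte(mi, min(st$H[ab]) + 1e-9)
      # chain rule: H[a] = I(a;b) + H[a|b], from the empirical joint
      xa <- ens$indicator[, ab[1]]; xb <- ens$indicator[, ab[2]]
      w <- ens$weights
      joint <- matrix(c(sum(w[xa == 0 & xb == 0]), sum(w[xa == 0 & xb == 1]),
                        sum(w[xa == 1 & xb == 0]), sum(w[xa == 1 & xb == 1])),
                      2, byrow = TRUE)
      expect_equal(st$H[ab[1]], mi + conditional_entropy(joint),
                   tolerance = 1e-9)
    }
  }
})

test_that("filter_candidates reproduces the 10/990-of-1000 rule", {
  # pair a = {1,10} in k_a of 1000 samples, pair b = {2,9} (nested inside a,
  # compatible) in k_b; samples containing a also contain b when both counts
  # demand it
  seq <- strrep("A", 30)
  mk <- function(k_a, k_b, n = 1000) {
    stopifnot(k_a <= k_b || k_b == 0)
    out <- vector("list", n)
    for (t in seq_len(n)) {
      pairs <- NULL
      if (t <= k_a) pairs <- rbind(pairs, c(1, 10))
      if (t <= k_b) pairs <- rbind(pairs, c(2, 9))
      out[[t]] <- rna_structure(seq, pairs)
    }
    build_ensemble(out)
  }
  ens <- mk(9, 500)
  keep <- filter_candidates(ens)
  expect_equal(unname(ens$candidates[keep, , drop = FALSE]),
               rbind(c(2L, 9L)))        # 9/1000 excluded, 500/1000 kept
  ens <- mk(10, 991)
  keep <- filter_candidates(ens)
  expect_equal(unname(ens$candidates[keep, , drop = FALSE]),
               rbind(c(1L, 10L)))       # 10/1000 kept, 991/1000 excluded
  ens <- mk(0, 990)
  expect_length(filter_candidates(ens), 1)  # 990/1000 kept
  expect_error(filter_candidates(ens, 0.9, 0.1), "low_frac")
})

test_that("closed-form conflicting-pair MI matches spot values and domain", {
  expect_equal(mi_conflicting_closed_form(0.5, 0.5), 1)
  expect_equal(mi_conflicting_closed_form(0.3, 0), 0)
  expect_equal(mi_conflicting_closed_form(0, 0.7), 0)
  expect_lt(mi_conflicting_closed_form(0.3, 0.2),
            mi_conflicting_closed_form(0.3, 0.4))
  expect_error(mi_conflicting_closed_form(0.6, 0.5), "> 1")
})

test_that("closed form is monotone in p_kl with the stated derivative", {
  for (p_ij in c(0.05, 0.2, 0.5, 0.8)) {
    q <- seq(0, 1 - p_ij - 1e-6, length.out = 200)
    v <- mi_conflicting_closed_form(p_ij, q)
    expect_true(all(diff(v) >= -1e-12))
    # central difference vs the closed-form derivative
    # d I / d p_kl = log2((1 - p_kl) / (1 - p_ij - p_kl))
    h <- 1e-6
    mid <- q[50]
    num <- (mi_conflicting_closed_form(p_ij, mid + h) -
            mi_conflicting_closed_form(p_ij, mid - h)) / (2 * h)
    analytic <- (log(1 - mid) - log(1 - p_ij - mid)) / log(2)
    expect_equal(num, analytic, tolerance = 1e-5)
  }
})

test_that("ensemble entropy sums per-pair entropies", {
  ens <- bistable_ensemble()
  st <- pair_stats(ens)
  expect_equal(ensemble_entropy(st), 8)  # 8 candidates at p = 0.5
  expect_equal(ensemble_entropy(st, 1:2), 2)
  st0 <- pair_stats(build_ensemble(rep(list(bistable_left()), 5)))
  expect_equal(ensemble_entropy(st0), 0)
})

test_that("mi_table reports the focal pair's row sums and TSV export works", {
  ens <- bistable_ensemble()
  tab <- mi_table(ens, c(1, 12))
  expect_equal(nrow(tab), 8)
  expect_equal(attr(tab, "mi_sum"), 8)  # H + 7 perfectly coupled pairs
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats_tsv(tab, path)
  back <- read.delim(path)
  expect_equal(back$mi, tab$mi)
})
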