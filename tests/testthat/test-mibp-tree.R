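test_that("find_mibp picks the pair with maximal summed MI", {
  # A = {2,10} in half the samples, its conflicting pair B = {5,14} in the
  # complementary half, C = {16,20} in all samples: MIBP is A with
  # mi_sum = H(A) + I(A;B) = 2 bits (C is filtered as constant)
  seq <- strrep("A", 20)
  with_A <- rna_structure(seq, c(2, 10, 16, 20))
  with_B <- rna_structure(seq, c(5, 14, 16, 20))
  ens <- build_ensemble(c(rep(list(with_A), 10), rep(list(with_B), 10)))
  got <- find_mibp(ens)
  expect_equal(got$pair, c(2L, 10L))
  expect_equal(got$mi_sum, 2)
  # excluding the self-term drops exactly H(A) = 1 bit
  got2 <- find_mibp(ens, include_self = FALSE)
  expect_equal(got2$mi_sum, 1)
  # all-constant ensemble: every candidate filtered, no MIBP
  ens0 <- build_ensemble(rep(list(with_A), 10))
  expect_null(find_mibp(ens0))
})

test_that("find_mibp agrees with brute-force search on exact toy ensembles", {
  set.seed(101)
  tried <- 0
  for (rep in 1:12) {
    seq <- random_seq(sample(12:16, 1))
    ex <- exact_ensemble(seq)
    we <- exact_weighted_ensemble(ex)
    keep <- filter_candidates(we)
    if (length(keep) < 2) next
    tried <- tried + 1
    got <- find_mibp(we)
    # brute force: per-candidate sums via exact_mi over the toy joints
    sums <- vapply(keep, function(k) {
      focal <- as.integer(we$candidates[k, ])
      sum(vapply(keep, function(t) {
        other <- as.integer(we$candidates[t, ])
        if (all(other == focal)) {
          pair_entropy(exact_marginal(ex, focal))
        } else {
          exact_mi(ex, focal, other)
        }
      }, numeric(1)))
    }, numeric(1))
    best <- keep[which(sums >= max(sums) - 1e-9)[1]]
    expect_equal(got$index, best)
    expect_equal(got$mi_sum, max(sums), tolerance = 1e-9)
  }
  expect_gte(tried, 5)
})

test_that("exact-mode and large-sample MIBPs coincide", {
  ex <- exact_ensemble(bistable_seq())
  exact_pick <- find_mibp(exact_weighted_ensemble(ex))
  sampled <- build_ensemble(sample_structures(ex, 10000, seed = 9))
  sampled_pick <- find_mibp(sampled)
  expect_equal(sampled_pick$pair, exact_pick$pair)
})

test_that("split_cluster partitions members with conditioned marginals", {
  seq <- strrep("A", 20)
  with_p <- rna_structure(seq, c(2, 10))
  without <- rna_structure(seq, c(5, 14))
  ens <- build_ensemble(c(rep(list(with_p), 4), rep(list(without), 6)))
  halves <- split_cluster(ens, 1:10, c(2, 10))
  expect_length(halves$present, 4)
  expect_length(halves$absent, 6)
  expect_setequal(c(halves$present, halves$absent), 1:10)
  st_p <- pair_stats(ens, halves$present)
  st_a <- pair_stats(ens, halves$absent)
  expect_equal(st_p$p[st_p$i == 2 & st_p$j == 10], 1)
  expect_equal(st_a$p[st_a$i == 2 & st_a$j == 10], 0)
  expect_error(split_cluster(ens, halves$present, c(2, 10)), "degenerate")
})

test_that("build_tree splits the two-conformation ensemble exactly once", {
  ens <- bistable_ensemble(10)
  tree <- build_tree(ens, cutoff_bits = 2, min_node_samples = 2)
  leaves <- tree_leaves(tree)
  expect_length(leaves, 2)
  expect_equal(vapply(leaves, `[[`, numeric(1), "probability"), c(0.5, 0.5))
  expect_equal(conditional_entropy_of_tree(tree), 0)
  # the split separates the conformations: each leaf is pure
  left_members <- 1:10   # construction order in bistable_ensemble
  expect_true(setequal(leaves[[1]]$members, left_members) ||
              setequal(leaves[[2]]$members, left_members))
  # root MIBP in one helix, first conflicting pair in the other
  root <- tree$root
  left_keys <- c("1-12", "2-11", "3-10", "4-9")
  right_keys <- c("5-18", "6-17", "7-16", "8-15")
  mibp_key <- paste(root$mibp[1], root$mibp[2], sep = "-")
  confl_key <- paste(root$conflicting$i[1], root$conflicting$j[1], sep = "-")
  expect_true((mibp_key %in% left_keys && confl_key %in% right_keys) ||
              (mibp_key %in% right_keys && confl_key %in% left_keys))
})

test_that("zero-entropy ensembles give a single-leaf tree", {
  ens <- build_ensemble(rep(list(bistable_left()), 12))
  tree <- build_tree(ens)
  expect_length(tree_leaves(tree), 1)
  st <- pair_stats(ens)
  expect_equal(conditional_entropy_of_tree(tree), ensemble_entropy(st))
})

test_that("leaves partition samples and probabilities sum to one", {
  set.seed(77)
  for (rep in 1:6) {
    seq <- random_seq(sample(14:18, 1))
    ex <- exact_ensemble(seq)
    if (nrow(ex$candidates) < 2) next
    ens <- build_ensemble(sample_structures(ex, 400, seed = rep))
    tree <- build_tree(ens, cutoff_bits = 1, min_node_samples = 10)
    leaves <- tree_leaves(tree)
    members <- sort(unlist(lapply(leaves, `[[`, "members")))
    expect_identical(members, seq_along(ens$structures))
    expect_lt(abs(sum(vapply(leaves, `[[`, numeric(1), "probability")) - 1),
              1e-12)
    # constraints along each path are on distinct pairs and satisfiable
    for (leaf in leaves) {
      cons <- leaf$constraints
      expect_false(any(duplicated(paste(cons$i, cons$j))))
      expect_gt(length(leaf$members), 0)
    }
  }
})

test_that("splitting never increases conditional tree entropy on exact ensembles", {
  for (seq in c(bistable_seq(), "GGCGAAAACGCCAAAGGGC")) {
    we <- exact_weighted_ensemble(exact_ensemble(seq))
    st <- pair_stats(we)
    h_root <- ensemble_entropy(st)
    tree <- build_tree(we, cutoff_bits = 0.5, min_node_samples = 2)
    expect_lte(conditional_entropy_of_tree(tree), h_root + 1e-9)
  }
})

test_that("tree construction is invariant to sample order", {
  ex <- exact_ensemble(bistable_seq())
  smp <- sample_structures(ex, 300, seed = 12)
  t1 <- build_tree(build_ensemble(smp))
  set.seed(5)
  t2 <- build_tree(build_ensemble(smp[sample(300)]))
  same_shape <- function(a, b) {
    if (is.null(a$children) != is.null(b$children)) return(FALSE)
    if (!is.null(a$mibp) && !identical(a$mibp, b$mibp)) return(FALSE)
    if (abs(a$probability - b$probability) > 1e-12) return(FALSE)
    if (is.null(a$children)) return(TRUE)
    same_shape(a$children$present, b$children$present) &&
      same_shape(a$children$absent, b$children$absent)
  }
  expect_true(same_shape(t1$root, t2$root))
})

test_that("greedy conflicting pairs are mutually conflicting and truncated at 5", {
  ens <- bistable_ensemble()
  confl <- find_conflicting_pairs(ens, c(1, 12))
  expect_equal(nrow(confl), 1)          # right-helix pairs are mutually nested
  expect_equal(c(confl$i[1], confl$j[1]), c(5, 18))
  # no conflicting candidate at all
  seq <- strrep("A", 20)
  ens2 <- build_ensemble(c(rep(list(rna_structure(seq, c(1, 10))), 5),
                           rep(list(rna_structure(seq, c(12, 20))), 5)))
  expect_equal(nrow(find_conflicting_pairs(ens2, c(1, 10))), 0)
  # 7 mutually conflicting candidates -> truncated at 5
  seq3 <- strrep("A", 40)
  share <- lapply(0:7, function(k) rna_structure(seq3, c(10 + k, 25 + k)))
  ens3 <- build_ensemble(share)
  confl3 <- find_conflicting_pairs(ens3, c(10, 25))
  expect_equal(nrow(confl3), 5)
  for (a in seq_len(4)) for (b in seq(a + 1, 5)) {
    expect_true(conflicts(c(confl3$i[a], confl3$j[a]),
                          c(confl3$i[b], confl3$j[b])))
  }
})

test_that("greedy order follows marginal probability with positional ties", {
  # B conflicts with the mibp at p = 0.8; D conflicts with the mibp and with
  # B at p = 0.6 -> greedy returns B then D
  seq <- strrep("A", 30)
  mibp <- c(10, 20)
  B <- c(15, 25)  # crosses {10,20}
  D <- c(5, 16)   # crosses {10,20} and {15,25}
  mk <- function(has_b, has_d) {
    pairs <- NULL
    if (has_b) pairs <- rbind(pairs, B)
    if (has_d && !has_b) pairs <- rbind(pairs, D)
    rna_structure(seq, rbind(pairs, c(1, 28)))
  }
  samples <- c(rep(list(mk(TRUE, FALSE)), 8),
               rep(list(mk(FALSE, TRUE)), 2))
  # add the mibp-containing samples so it is a candidate
  samples <- c(samples, rep(list(rna_structure(seq, rbind(mibp, c(1, 28)))), 2))
  ens <- build_ensemble(samples)
  confl <- find_conflicting_pairs(ens, mibp)
  expect_equal(unname(as.matrix(confl[, 1:2])),
               rbind(c(15L, 25L), c(5L, 16L)))
  expect_true(all(diff(confl$p) <= 0))
})

test_that("the most probable conflicting pair maximizes MI with the MIBP (exact)", {
  for (seq in c(bistable_seq(), "GGGGAAACCCCAAAGGGGAAACCCC")) {
    ex <- exact_ensemble(seq)
    we <- exact_weighted_ensemble(ex)
    best <- find_mibp(we)
    if (is.null(best)) next
    confl <- find_conflicting_pairs(we, best$pair)
    if (nrow(confl) == 0) next
    # among all conflicting candidates, the chosen first pair has maximal
    # pairwise MI with the MIBP (Claim-1 monotonicity consequence)
    cand <- we$candidates
    mask <- vapply(seq_len(nrow(cand)), function(r) {
      p <- as.integer(cand[r, ])
      !all(p == best$pair) && oracle_conflict(best$pair, p)
    }, logical(1))
    mis <- vapply(which(mask), function(r) {
      exact_mi(ex, best$pair, as.integer(cand[r, ]))
    }, numeric(1))
    chosen_mi <- exact_mi(ex, best$pair, c(confl$i[1], confl$j[1]))
    expect_gte(chosen_mi, max(mis) - 1e-9)
  }
})

test_that("locate_structure finds the leaf whose constraints a structure satisfies", {
  ens <- bistable_ensemble()
  tree <- build_tree(ens, min_node_samples = 2)
  loc_left <- locate_structure(tree, bistable_left())
  loc_right <- locate_structure(tree, bistable_right())
  expect_false(loc_left$id == loc_right$id)
  expect_equal(loc_left$probability, 0.5)
  # each sampled member structure lands in the leaf holding its index
  leaves <- tree_leaves(tree)
  for (leaf in leaves) {
    for (m in leaf$members[1]) {
      loc <- locate_structure(tree, ens$structures[[m]])
      expect_equal(loc$id, leaf$id)
    }
  }
  expect_error(locate_structure(tree, rna_structure("GAAAC", c(1, 5))),
               "differs")
})
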