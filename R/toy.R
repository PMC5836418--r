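#' Toy additive pair-energy model
#'
#' A deliberately simple energy model for short sequences: the energy of a
#' structure is the sum of per-pair-type energies, with no stacking or loop
#' terms. Under it the full Boltzmann distribution of a short sequence can be
#' enumerated exactly, which makes it the package's synthetic-data generator
#' and brute-force oracle. It is not a folding model: real ensembles come
#' from an external thermodynamic sampler via [read_structures()].
#'
#' @param gc,au,gu energies of G-C, A-U and G-U pairs (arbitrary units;
#'   defaults -3, -2, -1: more negative = more stable).
#' @param kT temperature factor (> 0, default 1).
#' @param min_loop minimum unpaired bases in a hairpin (default 3).
#' @param max_len enumeration length cap (default 30; the structure space
#'   grows exponentially).
#' @return Object of class `toy_energy_model`.
#' @export
toy_energy_model <- function(gc = -3, au = -2, gu = -1, kT = 1,
                             min_loop = 3, max_len = 30) {
  stopifnot(is.finite(gc), is.finite(au), is.finite(gu), kT > 0,
            min_loop >= 1, max_len >= 1)
  structure(list(gc = gc, au = au, gu = gu, kT = kT,
                 min_loop = min_loop, max_len = max_len),
            class = "toy_energy_model")
}

pair_energy <- function(model, a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  switch(key, "CG" = model$gc, "AU" = model$au, "GU" = model$gu,
         stop("not an allowed pair: ", a, "-", b))
}

#' Enumerate all valid structures of a short sequence
#'
#' Complete, duplicate-free list of every pseudoknot-free structure
#' (including the empty one) with allowed pairings and the model's minimum
#' hairpin loop, in a deterministic order (lexicographic by sorted pair
#' list).
#'
#' @param seq an [rna_sequence()] or string, length at most `model$max_len`.
#' @param model a [toy_energy_model()].
#' @return List of `rna_structure` objects.
#' @examples
#' length(enumerate_structures("GGGAAACCC"))  # 20
#' @export
enumerate_structures <- function(seq, model = toy_energy_model()) {
  seq <- rna_sequence(seq)
  n <- length(seq)
  if (n > model$max_len) {
    stop(sprintf(paste0("sequence length %d exceeds the enumeration cap %d; ",
                        "use sample_structures on a shorter sequence or an ",
                        "external sampler"), n, model$max_len))
  }
  bases <- seq$bases
  memo <- new.env(parent = emptyenv())
  # All pair sets over interval [i, j] as a list of pair matrices.
  enum <- function(i, j) {
    if (i >= j) return(list(as_pair_matrix(NULL)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum(i + 1, j)              # i unpaired
    for (k in seq(i + model$min_loop + 1, length.out = max(0, j - i - model$min_loop))) {
      if (!can_pair(bases[i], bases[k])) next
      inner <- enum(i + 1, k - 1)
      outer_part <- enum(k + 1, j)
      for (a in inner) for (b in outer_part) {
        out[[length(out) + 1]] <- as_pair_matrix(rbind(c(i, k), a, b))
      }
    }
    memo[[key]] <- out
    out
  }
  sets <- enum(1, n)
  key_of <- function(p) paste(pair_keys(p), collapse = ";")
  sets <- sets[order(vapply(sets, key_of, character(1)))]
  lapply(sets, function(p) rna_structure(seq, p))
}

#' Exact Boltzmann ensemble of a short sequence
#'
#' Enumerates every structure, scores it with the additive toy model and
#' normalizes `P(x) = exp(-E(x)/kT) / Z` exactly (via log-sum-exp). Exact
#' marginals, joints and mutual informations are then direct finite sums —
#' the oracle that the sample-based statistics are tested against.
#'
#' @param seq an [rna_sequence()] or string.
#' @param model a [toy_energy_model()].
#' @return Object of class `toy_ensemble_exact`: `seq`, `model`,
#'   `structures`, `energies`, `probs` (summing to 1) and `candidates`
#'   (pairs appearing in at least one structure).
#' @export
exact_ensemble <- function(seq, model = toy_energy_model()) {
  seq <- rna_sequence(seq)
  structures <- enumerate_structures(seq, model)
  energies <- vapply(structures, function(s) {
    if (nrow(s$pairs) == 0) return(0)
    sum(vapply(seq_len(nrow(s$pairs)), function(r) {
      pair_energy(model, seq$bases[s$pairs[r, 1]], seq$bases[s$pairs[r, 2]])
    }, numeric(1)))
  }, numeric(1))
  loga <- -energies / model$kT
  loga <- loga - max(loga)
  probs <- exp(loga) / sum(exp(loga))
  cand <- as_pair_matrix(unique(do.call(
    rbind, lapply(structures, function(s) s$pairs))))
  structure(list(seq = seq, model = model, structures = structures,
                 energies = energies, probs = probs, candidates = cand),
            class = "toy_ensemble_exact")
}

#' @export
print.toy_ensemble_exact <- function(x, ...) {
  cat(sprintf("<toy_ensemble_exact> %s: %d structures, %d candidate pairs\n",
              x$seq$name, length(x$structures), nrow(x$candidates)))
  invisible(x)
}

#' Exact marginal probability of a pair in a toy ensemble
#'
#' @param exact a [exact_ensemble()] object.
#' @param pair basepair `c(i, j)`.
#' @return `P(X_ij = 1)` by direct summation over structures.
#' @export
exact_marginal <- function(exact, pair) {
  key <- paste(pair[1], pair[2], sep = "-")
  has <- vapply(exact$structures, function(s) key %in% pair_keys(s$pairs),
                logical(1))
  sum(exact$probs[has])
}

#' Exact 2x2 joint distribution of two pairs in a toy ensemble
#'
#' @param exact a [exact_ensemble()] object.
#' @param a,b basepairs `c(i, j)`.
#' @return 2x2 matrix, `joint[x+1, y+1] = P(X_a = x, X_b = y)`.
#' @export
exact_joint <- function(exact, a, b) {
  ka <- paste(a[1], a[2], sep = "-")
  kb <- paste(b[1], b[2], sep = "-")
  joint <- matrix(0, 2, 2)
  for (s in seq_along(exact$structures)) {
    keys <- pair_keys(exact$structures[[s]]$pairs)
    joint[(ka %in% keys) + 1, (kb %in% keys) + 1] <-
      joint[(ka %in% keys) + 1, (kb %in% keys) + 1] + exact$probs[s]
  }
  joint
}

#' Exact mutual information of two pairs in a toy ensemble
#'
#' Computed directly from the exact joint:
#' `I = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )`.
#'
#' @inheritParams exact_joint
#' @return Mutual information in bits.
#' @export
exact_mi <- function(exact, a, b) {
  joint <- exact_joint(exact, a, b)
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (x in 1:2) for (y in 1:2) {
    if (joint[x, y] > 0) {
      mi <- mi + joint[x, y] * log2(joint[x, y] / (px[x] * py[y]))
    }
  }
  if (mi < 1e-12) 0 else mi
}

#' Exact ensemble as a weighted sample set
#'
#' Feeds the enumerated structures into [build_ensemble()] with their exact
#' Boltzmann probabilities as weights: one "sample" per distinct structure.
#' Every downstream statistic (marginal, entropy, MI, MIBP, tree) then takes
#' its exact value with no Monte-Carlo error.
#'
#' @param exact a [exact_ensemble()] object.
#' @return An `rna_ensemble` in exact-weights mode.
#' @export
exact_weighted_ensemble <- function(exact) {
  build_ensemble(exact$structures, weights = exact$probs)
}

#' Seeded i.i.d. samples from a toy ensemble
#'
#' Inverse-CDF draws from the exact enumerated distribution; reproducible
#' for a fixed seed and independent of (and restoring) the caller's RNG
#' state.
#'
#' @param exact a [exact_ensemble()] object.
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @return List of `n` `rna_structure` objects.
#' @export
sample_structures <- function(exact, n, seed = 1) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  idx <- sample.int(length(exact$structures), n, replace = TRUE,
                    prob = exact$probs)
  exact$structures[idx]
}

#' Write a simulated sample file plus an exact-statistics sidecar
#'
#' Emits a standard multi-structure dot-bracket file (consumable by
#' [read_structures()], exactly like external sampler output) and a TSV
#' sidecar of exact per-pair marginals and entropies for oracle comparisons.
#'
#' @param exact a [exact_ensemble()] object.
#' @param n number of samples.
#' @param seed integer seed.
#' @param path output dot-bracket path; the sidecar is `path` +
#'   `".exact.tsv"`.
#' @return List with `samples` and `sidecar` paths, invisibly.
#' @export
write_toy_samples <- function(exact, n, seed, path) {
  samples <- sample_structures(exact, n, seed)
  write_dotbracket_file(samples, path)
  side <- paste0(path, ".exact.tsv")
  p <- vapply(seq_len(nrow(exact$candidates)),
              function(r) exact_marginal(exact, exact$candidates[r, ]),
              numeric(1))
  utils::write.table(
    data.frame(i = exact$candidates[, 1], j = exact$candidates[, 2],
               p = p, H = pair_entropy(p)),
    side, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(samples = path, sidecar = side))
}
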