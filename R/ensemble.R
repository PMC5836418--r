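# x * log2(x) with the 0 log 0 = 0 convention, vectorized.
xlog2x <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

#' Entropy of a basepair indicator
#'
#' Binary entropy `H = -p log2 p - (1 - p) log2(1 - p)` in bits, with the
#' `0 log 0 = 0` convention so it is continuous (and zero) at `p = 0` and
#' `p = 1`, and maximal (1 bit) at `p = 0.5`.
#'
#' @param p probability (vectorized), each in `[0, 1]`.
#' @return Entropy in bits, in `[0, 1]`.
#' @examples
#' pair_entropy(c(0, 0.25, 0.5, 1))
#' @export
pair_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  -xlog2x(p) - xlog2x(1 - p)
}

#' Conditional entropy from a 2x2 joint distribution
#'
#' For binary indicators X (rows: X=0, X=1) and Y (columns: Y=0, Y=1),
#' returns `H[X | Y] = P(Y=0) H[X | Y=0] + P(Y=1) H[X | Y=1]` in bits.
#' Conditioning outcomes with zero probability contribute nothing.
#'
#' @param joint 2x2 numeric matrix, nonnegative, summing to 1;
#'   `joint[x+1, y+1] = P(X = x, Y = y)`.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(joint) {
  joint <- as.matrix(joint)
  if (!all(dim(joint) == c(2, 2))) stop("joint must be a 2x2 matrix")
  if (any(joint < -1e-12)) stop("joint probabilities must be nonnegative")
  if (abs(sum(joint) - 1) > 1e-9) stop("joint probabilities must sum to 1")
  joint <- pmax(joint, 0)
  h <- 0
  for (y in 1:2) {
    py <- sum(joint[, y])
    if (py > 0) h <- h + py * pair_entropy(joint[2, y] / py)
  }
  h
}

#' Build a sample ensemble from structures
#'
#' Converts a list of sampled structures over one sequence into a binary
#' sample-by-candidate-pair indicator matrix with per-sample weights.
#' Candidates are the distinct basepairs observed in at least one sample,
#' ordered by `(i, j)`. Weights default to uniform `1/n` (plain Boltzmann
#' samples); passing the exact structure probabilities of an enumerated
#' ensemble as weights turns every downstream statistic into its exact value.
#'
#' @param structures list of >= 2 `rna_structure` objects over one sequence.
#' @param weights optional nonnegative per-structure weights (normalized to
#'   sum to 1); default uniform.
#' @return Object of class `rna_ensemble`: `seq`, `structures`, `candidates`
#'   (m-by-2 integer matrix), `indicator` (n-by-m 0/1 matrix), `weights`.
#' @export
build_ensemble <- function(structures, weights = NULL) {
  if (!is.list(structures) || length(structures) < 2) {
    stop("need at least 2 sampled structures")
  }
  seqs <- vapply(structures, function(s) s$seq$residues, character(1))
  if (length(unique(seqs)) != 1) {
    stop("all sampled structures must share one sequence; found ",
         length(unique(seqs)), " distinct sequences")
  }
  seq <- structures[[1]]$seq
  n <- length(structures)
  if (is.null(weights)) {
    weights <- rep(1 / n, n)
  } else {
    if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
      stop("weights must be nonnegative, one per structure, with positive sum")
    }
    weights <- weights / sum(weights)
  }
  all_keys <- unlist(lapply(structures, function(s) pair_keys(s$pairs)))
  cand <- as_pair_matrix(unique(do.call(
    rbind, lapply(structures, function(s) s$pairs))))
  ck <- pair_keys(cand)
  ind <- matrix(0L, nrow = n, ncol = nrow(cand))
  for (r in seq_len(n)) {
    ind[r, match(pair_keys(structures[[r]]$pairs), ck)] <- 1L
  }
  colnames(ind) <- ck
  structure(
    list(seq = seq, structures = structures, candidates = cand,
         indicator = ind, weights = weights),
    class = "rna_ensemble"
  )
}

#' @export
print.rna_ensemble <- function(x, ...) {
  cat(sprintf("<rna_ensemble> %s: %d samples, %d candidate pairs\n",
              x$seq$name, length(x$structures), nrow(x$candidates)))
  invisible(x)
}

# Member-restricted, renormalized weights.
member_weights <- function(ens, members = NULL) {
  w <- ens$weights
  if (!is.null(members)) {
    w <- numeric(length(ens$weights))
    w[members] <- ens$weights[members]
  }
  if (sum(w) <= 0) stop("member set carries no probability mass")
  w / sum(w)
}

#' Per-candidate marginals and entropies
#'
#' @param ens an `rna_ensemble`.
#' @param members optional sample indices defining a cluster; statistics are
#'   then conditional on membership (weights renormalized over members).
#' @return `data.frame` with one row per candidate pair: `i`, `j`, `count`
#'   (unweighted member sample count containing the pair), `p` (weighted
#'   marginal), `H` (entropy in bits).
#' @export
pair_stats <- function(ens, members = NULL) {
  w <- member_weights(ens, members)
  sub <- if (is.null(members)) seq_along(ens$structures) else members
  p <- as.numeric(crossprod(ens$indicator, w))
  cnt <- as.integer(colSums(ens$indicator[sub, , drop = FALSE]))
  data.frame(i = ens$candidates[, 1], j = ens$candidates[, 2],
             count = cnt, p = p, H = pair_entropy(pmin(pmax(p, 0), 1)))
}

#' Mutual information between two candidate basepairs
#'
#' `I(X_a; X_b) = H[X_a] - H[X_a | X_b]`, estimated from the weighted
#' empirical 2x2 joint of the two indicator columns. Symmetric; values below
#' `1e-12` (floating noise) are clamped to zero.
#'
#' @param ens an `rna_ensemble`.
#' @param a,b basepairs `c(i, j)`; both must be ensemble candidates.
#' @param members optional cluster sample indices (see [pair_stats()]).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(ens, a, b, members = NULL) {
  ia <- match(paste(a[1], a[2], sep = "-"), pair_keys(ens$candidates))
  ib <- match(paste(b[1], b[2], sep = "-"), pair_keys(ens$candidates))
  if (is.na(ia) || is.na(ib)) stop("pair not among ensemble candidates")
  w <- member_weights(ens, members)
  xa <- ens$indicator[, ia]
  xb <- ens$indicator[, ib]
  p11 <- sum(w[xa == 1 & xb == 1])
  pa <- sum(w[xa == 1])
  pb <- sum(w[xb == 1])
  # symmetric plug-in form of H[X_a] - H[X_a | X_b]
  joint <- c(1 - pa - pb + p11, pb - p11, pa - p11, p11)
  marg <- c((1 - pa) * (1 - pb), (1 - pa) * pb, pa * (1 - pb), pa * pb)
  mi <- 0
  for (k in 1:4) {
    if (joint[k] > 0 && marg[k] > 0) {
      mi <- mi + joint[k] * log2(joint[k] / marg[k])
    }
  }
  if (mi < 1e-12) 0 else mi
}

# Full pairwise MI matrix (and entropy vector) over a candidate subset.
# Weighted plug-in joints; diagonal = H. Clamps values < 1e-12 to 0.
mi_matrix <- function(ens, cand_idx = NULL, members = NULL) {
  if (is.null(cand_idx)) cand_idx <- seq_len(nrow(ens$candidates))
  w <- member_weights(ens, members)
  X <- ens$indicator[, cand_idx, drop = FALSE]
  p <- as.numeric(crossprod(X, w))
  p <- pmin(pmax(p, 0), 1)
  P11 <- crossprod(X, X * w)                   # P(a=1, b=1)
  P10 <- outer(p, rep(1, length(p))) - P11     # P(a=1, b=0)
  P01 <- t(P10)                                # P(a=0, b=1)
  P00 <- 1 - P11 - P10 - P01
  H <- pair_entropy(p)
  # I = sum_{xy} p_xy log2( p_xy / (p_x p_y) ), term-wise with 0 log 0 = 0
  term <- function(Pxy, px, py) {
    denom <- outer(px, py)
    out <- matrix(0, nrow(Pxy), ncol(Pxy))
    pos <- Pxy > 0 & denom > 0
    out[pos] <- Pxy[pos] * log2(Pxy[pos] / denom[pos])
    out
  }
  MI <- term(pmax(P11, 0), p, p) + term(pmax(P10, 0), p, 1 - p) +
        term(pmax(P01, 0), 1 - p, p) + term(pmax(P00, 0), 1 - p, 1 - p)
  MI[MI < 1e-12] <- 0
  diag(MI) <- H
  list(mi = MI, H = H, p = p, cand_idx = cand_idx)
}

#' Filter candidate pairs by sample frequency
#'
#' Pairs observed in nearly none or nearly all samples have near-zero entropy
#' and contribute negligibly to mutual information; dropping them before the
#' MIBP search saves time without changing the answer. The default fractions
#' 0.01 and 0.99 generalize the absolute counts 10 and 990 out of 1000
#' samples to any ensemble size.
#'
#' @param ens an `rna_ensemble`.
#' @param low_frac,high_frac inclusive frequency bounds in `[0, 1]`.
#' @param members optional cluster sample indices.
#' @return Integer indices into `ens$candidates` of the retained pairs.
#' @export
filter_candidates <- function(ens, low_frac = 0.01, high_frac = 0.99,
                              members = NULL) {
  if (!(low_frac >= 0 && low_frac < high_frac && high_frac <= 1)) {
    stop("need 0 <= low_frac < high_frac <= 1")
  }
  w <- member_weights(ens, members)
  f <- as.numeric(crossprod(ens$indicator, w))
  eps <- 1e-12
  which(f >= low_frac - eps & f <= high_frac + eps)
}

#' Closed-form mutual information of two conflicting basepairs
#'
#' Conflicting pairs can never be present together, so their joint presence
#' probability is zero and the mutual information reduces to
#' `I = (1-p-q) log2(1-p-q) - (1-p) log2(1-p) - (1-q) log2(1-q)`.
#' For fixed `p > 0` this is strictly increasing in `q`: the most probable
#' pair conflicting with a given basepair is also the one sharing the most
#' mutual information with it.
#'
#' @param p_ij,p_kl marginal probabilities of the two conflicting pairs;
#'   must satisfy `p_ij + p_kl <= 1`.
#' @return Mutual information in bits.
#' @examples
#' mi_conflicting_closed_form(0.5, 0.5)  # 1 bit: complementary indicators
#' @export
mi_conflicting_closed_form <- function(p_ij, p_kl) {
  if (any(p_ij < 0) || any(p_kl < 0)) stop("probabilities must be nonnegative")
  if (any(p_ij + p_kl > 1 + 1e-12)) {
    stop("p_ij + p_kl > 1: impossible for conflicting (mutually exclusive) pairs")
  }
  r <- pmin(pmax(1 - p_ij - p_kl, 0), 1)
  mi <- xlog2x(r) - xlog2x(1 - p_ij) - xlog2x(1 - p_kl)
  mi[mi < 1e-12 & mi > -1e-9] <- 0
  mi
}

#' Total (ensemble) entropy of a set of candidate pairs
#'
#' The sum of per-pair entropies `H[X_ij]`; over the full candidate set this
#' is the ensemble entropy reported for a sequence.
#'
#' @param stats a `data.frame` from [pair_stats()] (needs column `H`).
#' @param subset optional row indices to sum over (default all).
#' @return Entropy in bits.
#' @export
ensemble_entropy <- function(stats, subset = NULL) {
  h <- stats$H
  if (!is.null(subset)) h <- h[subset]
  sum(h)
}

#' Mutual information of a focal pair with every candidate
#'
#' @param ens an `rna_ensemble`.
#' @param focal a candidate basepair `c(i, j)`.
#' @param members optional cluster sample indices.
#' @return `data.frame` (`i`, `j`, `mi`) with one row per candidate plus an
#'   attribute `mi_sum` holding the total, including the focal self-term.
#' @export
mi_table <- function(ens, focal, members = NULL) {
  idx <- match(paste(focal[1], focal[2], sep = "-"), pair_keys(ens$candidates))
  if (is.na(idx)) stop("focal pair not among ensemble candidates")
  m <- mi_matrix(ens, members = members)
  out <- data.frame(i = ens$candidates[, 1], j = ens$candidates[, 2],
                    mi = m$mi[, idx])
  attr(out, "mi_sum") <- sum(m$mi[, idx])
  out
}

#' Export per-pair statistics to TSV
#'
#' @param stats data.frame from [pair_stats()] or [mi_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
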