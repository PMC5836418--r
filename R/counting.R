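# Minimal exact nonnegative big-integer arithmetic for structure counts.
# Representation: double vector of base-1e4 digits, little-endian, no leading
# zero limb (zero = the single limb 0). Schoolbook add/multiply stay exact in
# doubles: every intermediate is far below 2^53 for the sizes reached here.

BIG_BASE <- 1e4

big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x))
  if (x == 0) return(0)
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% BIG_BASE)
    x <- x %/% BIG_BASE
  }
  d
}

big_trim <- function(a) {
  n <- length(a)
  while (n > 1 && a[n] == 0) n <- n - 1
  a[seq_len(n)]
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  s <- numeric(n)
  s[seq_along(a)] <- a
  s[seq_along(b)] <- s[seq_along(b)] + b
  carry <- 0
  for (k in seq_len(n)) {
    s[k] <- s[k] + carry
    carry <- s[k] %/% BIG_BASE
    s[k] <- s[k] %% BIG_BASE
  }
  while (carry > 0) {
    s <- c(s, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  big_trim(s)
}

big_mul <- function(a, b) {
  if ((length(a) == 1 && a[1] == 0) || (length(b) == 1 && b[1] == 0)) return(0)
  res <- numeric(length(a) + length(b))
  for (k in seq_along(a)) {
    if (a[k] == 0) next
    seg <- seq_along(b) + k - 1
    res[seg] <- res[seg] + a[k] * b
    # normalize eagerly so partial sums stay < 2^53
    carry <- 0
    for (t in seq(k, length(res))) {
      res[t] <- res[t] + carry
      carry <- res[t] %/% BIG_BASE
      res[t] <- res[t] %% BIG_BASE
    }
    stopifnot(carry == 0)
  }
  big_trim(res)
}

big_to_string <- function(a) {
  a <- big_trim(a)
  parts <- sprintf("%04d", rev(a))
  parts[1] <- sub("^0+(?=.)", "", parts[1], perl = TRUE)
  paste(parts, collapse = "")
}

big_log10 <- function(a) {
  a <- big_trim(a)
  if (length(a) == 1 && a[1] == 0) return(-Inf)
  top <- 0
  k <- length(a)
  used <- 0
  val <- 0
  while (k >= 1 && used < 4) {   # leading ~16 decimal digits suffice
    val <- val * BIG_BASE + a[k]
    k <- k - 1
    used <- used + 1
  }
  log10(val) + 4 * k
}

#' Constraint set for structure counting
#'
#' @param forced_pairs pairs that every counted structure must contain
#'   (matrix/data.frame of `(i, j)` rows or flat vector); mutually
#'   non-conflicting.
#' @param forbidden_pairs pairs that no counted structure may contain.
#' @param forced_unpaired positions that must stay unpaired.
#' @return Object of class `constraint_set`.
#' @export
constraint_set <- function(forced_pairs = NULL, forbidden_pairs = NULL,
                           forced_unpaired = integer(0)) {
  fp <- as_pair_matrix(forced_pairs)
  fb <- as_pair_matrix(forbidden_pairs)
  fu <- sort(unique(as.integer(forced_unpaired)))
  if (nrow(fp) >= 2) {
    for (a in seq_len(nrow(fp) - 1)) {
      cl <- conflicts_with(fp[a, ], fp[seq(a + 1, nrow(fp)), , drop = FALSE])
      if (any(cl)) {
        stop(sprintf("forced pairs conflict: {%d,%d} vs {%d,%d}",
                     fp[a, 1], fp[a, 2],
                     fp[a + which(cl)[1], 1], fp[a + which(cl)[1], 2]))
      }
    }
  }
  clash <- intersect(pair_keys(fp), pair_keys(fb))
  if (length(clash) > 0) {
    stop("pair(s) both forced and forbidden: ", paste(clash, collapse = ", "))
  }
  if (any(c(fp) %in% fu)) {
    stop("a forced pair touches a forced-unpaired position")
  }
  structure(list(forced_pairs = fp, forbidden_pairs = fb,
                 forced_unpaired = fu),
            class = "constraint_set")
}

#' Count secondary structures under constraints
#'
#' Exact count of distinct basepair sets over the sequence that are valid
#' (no triples, no pseudoknots, allowed pairings only, at least `min_loop`
#' unpaired bases in every hairpin) and satisfy the constraints. Computed by
#' the interval recursion
#' `N(i,j) = N(i+1,j) + sum_k [i pairs k] N(i+1,k-1) N(k+1,j)`
#' with constraint masking, in exact big-integer arithmetic, so counts of
#' astronomical size carry no rounding. Counts are of basepair sets only;
#' tools that enumerate coaxial stacking states of the same pair set
#' separately report larger numbers.
#'
#' @param seq an [rna_sequence()] or string.
#' @param constraints a [constraint_set()] (default: none).
#' @param min_loop minimum unpaired bases enclosed by a pair (default 3, the
#'   field-standard hairpin loop; pairs require `j - i > min_loop`).
#' @return Object of class `structure_count`: `count` (exact decimal string),
#'   `log10_count`, and `count_num` (numeric; `Inf` if above 2^53).
#' @examples
#' count_structures("GGGAAACCC")$count  # "20"
#' @export
count_structures <- function(seq, constraints = NULL, min_loop = 3) {
  seq <- rna_sequence(seq)
  if (is.null(constraints)) constraints <- constraint_set()
  stopifnot(inherits(constraints, "constraint_set"))
  n <- length(seq)
  bases <- seq$bases
  forced_partner <- integer(n)
  fp <- constraints$forced_pairs
  for (r in seq_len(nrow(fp))) {
    if (fp[r, 2] > n) stop("forced pair out of range")
    forced_partner[fp[r, 1]] <- fp[r, 2]
    forced_partner[fp[r, 2]] <- fp[r, 1]
  }
  forbidden <- pair_keys(constraints$forbidden_pairs)
  unp <- constraints$forced_unpaired
  admissible <- function(i, k) {
    if (k - i <= min_loop) return(FALSE)
    if (!can_pair(bases[i], bases[k])) return(FALSE)
    if (i %in% unp || k %in% unp) return(FALSE)
    if (paste(i, k, sep = "-") %in% forbidden) return(FALSE)
    if (forced_partner[i] != 0 && forced_partner[i] != k) return(FALSE)
    if (forced_partner[k] != 0 && forced_partner[k] != i) return(FALSE)
    TRUE
  }
  # N[[i]][[j]] over 1 <= i <= j <= n; empty interval handled inline.
  N <- vector("list", n)
  for (i in seq_len(n)) N[[i]] <- vector("list", n)
  get_N <- function(i, j) if (i > j) 1 else N[[i]][[j]]
  one <- 1
  for (len in seq_len(n)) {
    for (i in seq_len(n - len + 1)) {
      j <- i + len - 1
      total <- if (forced_partner[i] == 0) get_N(i + 1, j) else 0
      for (k in seq(i, j)) {
        if (k <= i) next
        if (admissible(i, k)) {
          total <- big_add(total, big_mul(get_N(i + 1, k - 1), get_N(k + 1, j)))
        }
      }
      N[[i]][[j]] <- total
    }
  }
  big <- get_N(1, n)
  l10 <- big_log10(big)
  structure(list(count = big_to_string(big), log10_count = l10,
                 count_num = if (l10 < 15.9) as.numeric(big_to_string(big)) else Inf),
            class = "structure_count")
}

#' @export
print.structure_count <- function(x, ...) {
  cat(sprintf("<structure_count> %s (log10 = %.4f)\n", x$count, x$log10_count))
  invisible(x)
}

#' Derive entropy constraints from ensemble statistics
#'
#' Basepairs whose marginal entropy is below `threshold_bits` are effectively
#' decided: those with probability near 1 are constrained present and those
#' with probability near 0 constrained absent (at the default 0.002 bits the
#' split point `p = 0.5` is unambiguous — qualifying pairs have
#' `p < ~1.2e-4` or `p > ~1 - 1.2e-4`). The candidate universe is every
#' allowed pairing of the sequence at the minimum separation, so pairs never
#' observed in any sample (probability 0) are constrained absent.
#'
#' @param stats `data.frame` from [pair_stats()] over the observed
#'   candidates; unlisted universe pairs are taken to have `p = 0`.
#' @param seq the [rna_sequence()].
#' @param threshold_bits entropy threshold (default 0.002 bits).
#' @param min_loop minimum hairpin loop defining the pair universe.
#' @return A [constraint_set()] with the decided pairs.
#' @export
entropy_constraints <- function(stats, seq, threshold_bits = 0.002,
                                min_loop = 3) {
  seq <- rna_sequence(seq)
  n <- length(seq)
  uni <- candidate_universe(seq, min_loop)
  p <- numeric(nrow(uni))
  if (nrow(stats) > 0) {
    m <- match(pair_keys(uni), paste(stats$i, stats$j, sep = "-"))
    p[!is.na(m)] <- stats$p[m[!is.na(m)]]
  }
  H <- pair_entropy(pmin(pmax(p, 0), 1))
  low <- H < threshold_bits
  forced <- uni[low & p > 0.5, , drop = FALSE]
  forbidden <- uni[low & p <= 0.5, , drop = FALSE]
  constraint_set(forced_pairs = forced, forbidden_pairs = forbidden)
}

# All allowed (can_pair, min-separation) pairs of a sequence.
candidate_universe <- function(seq, min_loop = 3) {
  seq <- rna_sequence(seq)
  n <- length(seq)
  out <- NULL
  for (i in seq_len(max(0, n - min_loop - 1))) {
    for (j in seq(i + min_loop + 1, n)) {
      if (can_pair(seq$bases[i], seq$bases[j])) out <- rbind(out, c(i, j))
    }
  }
  as_pair_matrix(out)
}

#' Probability mass retained under a constraint set
#'
#' The weight fraction of ensemble samples that satisfy every constraint:
#' contain all forced pairs, none of the forbidden pairs, and leave all
#' forced-unpaired positions unpaired.
#'
#' @param ens an `rna_ensemble`.
#' @param constraints a [constraint_set()].
#' @return Fraction in `[0, 1]`.
#' @export
retained_mass <- function(ens, constraints) {
  stopifnot(inherits(constraints, "constraint_set"))
  fk <- pair_keys(constraints$forced_pairs)
  bk <- pair_keys(constraints$forbidden_pairs)
  unp <- constraints$forced_unpaired
  ok <- vapply(ens$structures, function(s) {
    keys <- pair_keys(s$pairs)
    all(fk %in% keys) && !any(bk %in% keys) &&
      !any(unp %in% c(s$pairs))
  }, logical(1))
  sum(ens$weights[ok])
}

#' Export structure counts to TSV
#'
#' @param rows `data.frame` with columns such as `label`, `count`,
#'   `log10_count`, `retained_mass`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
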