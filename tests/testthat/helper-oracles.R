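# Independent brute-force oracles, deliberately written against different
# algorithms than the package code paths they check.

# All admissible pairs of a sequence string (A/C/G/U), j - i > min_loop.
oracle_pairs <- function(seq, min_loop = 3) {
  b <- strsplit(seq, "")[[1]]
  ok <- function(x, y) paste(sort(c(x, y)), collapse = "") %in% c("AU", "CG", "GU")
  out <- NULL
  n <- length(b)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i > min_loop && ok(b[i], b[j])) out <- rbind(out, c(i, j))
  }
  out
}

oracle_conflict <- function(p, q) {
  shared <- length(intersect(p, q)) > 0
  cross <- (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
           (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
  shared || cross
}

# Count valid structures by subset search over the admissible pair list:
# grow compatible subsets pair by pair (each pair only combined with
# later pairs), counting every compatible subset including the empty one.
oracle_count <- function(seq, min_loop = 3) {
  pairs <- oracle_pairs(seq, min_loop)
  if (is.null(pairs)) return(1L)
  m <- nrow(pairs)
  compat <- matrix(TRUE, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a != b) compat[a, b] <- !oracle_conflict(pairs[a, ], pairs[b, ])
  }
  grow <- function(allowed) {
    total <- 1L  # the current subset itself
    for (k in allowed) {
      total <- total + grow(allowed[allowed > k & compat[k, allowed]])
    }
    total
  }
  grow(seq_len(m))
}

# Same subset search, returning each structure as a sorted pair key string.
oracle_enumerate_keys <- function(seq, min_loop = 3) {
  pairs <- oracle_pairs(seq, min_loop)
  out <- character(0)
  emit <- function(sel) {
    if (length(sel) == 0) return("")
    p <- pairs[sel, , drop = FALSE]
    p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
    paste(paste(p[, 1], p[, 2], sep = "-"), collapse = ";")
  }
  grow <- function(sel, allowed) {
    out[[length(out) + 1]] <<- emit(sel)
    for (k in allowed) {
      ok <- allowed[allowed > k]
      ok <- ok[vapply(ok, function(x) !oracle_conflict(pairs[k, ], pairs[x, ]),
                      logical(1))]
      grow(c(sel, k), ok)
    }
  }
  if (is.null(pairs)) return("")
  grow(integer(0), seq_len(nrow(pairs)))
  sort(out)
}

# Random A/C/G/U sequence of length n (uses the ambient RNG).
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Bistable test sequence: a left G-C hairpin (pairs (1,12)...(4,9)) competes
# with a right A-U hairpin (pairs (5,18)...(8,15)); every left-helix pair
# crosses every right-helix pair.
bistable_seq <- function() "GGGGAAAACCCCAAUUUU"
bistable_left <- function() rna_structure(bistable_seq(),
                                          c(1, 12, 2, 11, 3, 10, 4, 9))
bistable_right <- function() rna_structure(bistable_seq(),
                                           c(5, 18, 6, 17, 7, 16, 8, 15))

# Two-conformation constructed ensemble: n_each copies of each hairpin.
bistable_ensemble <- function(n_each = 10) {
  build_ensemble(c(rep(list(bistable_left()), n_each),
                   rep(list(bistable_right()), n_each)))
}
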