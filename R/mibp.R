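#' Find the most informative basepair (MIBP)
#'
#' The MIBP of an ensemble (or of a cluster of its samples) is the candidate
#' basepair maximizing the summed mutual information with all candidate
#' pairs. The sum runs over frequency-filtered candidates and, by default,
#' includes the focal pair itself, contributing the constant self-term
#' `H[X_kl]` (set `include_self = FALSE` to drop it; the argmax rarely
#' changes since the self-term is bounded by 1 bit). Ties are broken by
#' smallest `i`, then smallest `j`.
#'
#' @param ens an `rna_ensemble`.
#' @param members optional sample indices restricting to a cluster.
#' @param low_frac,high_frac frequency filter passed to [filter_candidates()].
#' @param include_self include `I(X;X) = H[X]` in each candidate's sum.
#' @return `NULL` when no candidate survives filtering, else a list with
#'   `pair` (`c(i, j)`), `mi_sum` (bits) and `index` (into `ens$candidates`).
#' @export
find_mibp <- function(ens, members = NULL, low_frac = 0.01, high_frac = 0.99,
                      include_self = TRUE) {
  keep <- filter_candidates(ens, low_frac, high_frac, members)
  if (length(keep) == 0) return(NULL)
  m <- mi_matrix(ens, cand_idx = keep, members = members)
  sums <- colSums(m$mi)
  if (!include_self) sums <- sums - diag(m$mi)
  best <- which(sums >= max(sums) - 1e-9)[1]  # candidates sorted by (i, j)
  idx <- keep[best]
  list(pair = as.integer(ens$candidates[idx, ]), mi_sum = sums[best],
       index = idx)
}

#' Split a cluster on the presence of a basepair
#'
#' @param ens an `rna_ensemble`.
#' @param members sample indices of the cluster to split.
#' @param pair the basepair `c(i, j)` to condition on; must have frequency
#'   strictly between 0 and 1 among members.
#' @return List with `present` and `absent` member index vectors (a
#'   partition of `members`).
#' @export
split_cluster <- function(ens, members, pair) {
  idx <- match(paste(pair[1], pair[2], sep = "-"), pair_keys(ens$candidates))
  if (is.na(idx)) stop("split pair not among ensemble candidates")
  x <- ens$indicator[members, idx]
  present <- members[x == 1]
  absent <- members[x == 0]
  if (length(present) == 0 || length(absent) == 0) {
    stop(sprintf("degenerate split on pair {%d,%d}: one side is empty",
                 pair[1], pair[2]))
  }
  list(present = present, absent = absent)
}

#' Greedy conflicting basepairs of a cluster MIBP
#'
#' Starting from the MIBP, repeatedly picks the candidate with the highest
#' cluster-conditional marginal probability that conflicts with the MIBP and
#' with every previously chosen pair, stopping after `max_n` pairs or when no
#' candidate with positive marginal remains. The returned pairs are pairwise
#' mutually conflicting; when present they explain why the cluster splits
#' into divergent conformations.
#'
#' @param ens an `rna_ensemble`.
#' @param mibp the focal basepair `c(i, j)`.
#' @param members optional cluster sample indices.
#' @param max_n maximum number of conflicting pairs (default 5).
#' @return `data.frame` (`i`, `j`, `p`) in greedy order; zero rows when the
#'   MIBP has no conflicting candidate.
#' @export
find_conflicting_pairs <- function(ens, mibp, members = NULL, max_n = 5) {
  st <- pair_stats(ens, members)
  chosen <- matrix(integer(0), ncol = 2)
  probs <- numeric(0)
  eligible <- st$p > 1e-12 & conflicts_with(mibp, as.matrix(st[, c("i", "j")]))
  while (sum(eligible) > 0 && nrow(chosen) < max_n) {
    cand <- which(eligible)
    best <- cand[order(-st$p[cand], st$i[cand], st$j[cand])[1]]
    pick <- c(st$i[best], st$j[best])
    chosen <- rbind(chosen, pick)
    probs <- c(probs, st$p[best])
    eligible <- eligible &
      conflicts_with(pick, as.matrix(st[, c("i", "j")]))
  }
  out <- data.frame(i = as.integer(chosen[, 1]), j = as.integer(chosen[, 2]),
                    p = probs)
  rownames(out) <- NULL
  out
}

new_cluster_node <- function(ens, members, constraints) {
  st <- pair_stats(ens, members)
  list(
    constraints = constraints,          # data.frame i, j, state
    members = members,
    probability = sum(ens$weights[members]),
    marginals = st,
    cond_entropy = ensemble_entropy(st),
    mibp = NULL, mi_sum = NA_real_,
    conflicting = data.frame(i = integer(0), j = integer(0), p = numeric(0)),
    children = NULL
  )
}

#' Build the binary MIBP cluster tree
#'
#' Greedy recursion: at each node find the cluster-conditional MIBP and split
#' the node's samples by its presence, so each branch conditions on the
#' presence or absence of one MIBP. A node becomes a leaf when the product of
#' its probability mass (relative to the root) and the MIBP's summed mutual
#' information falls below `cutoff_bits`, when no candidate survives
#' frequency filtering, or when it holds fewer than `min_node_samples`
#' members (sample-based mutual information on a handful of structures is
#' noise). The leaves form an exhaustive partition of the samples.
#'
#' @param ens an `rna_ensemble`.
#' @param cutoff_bits stopping threshold on `probability x mi_sum`
#'   (default 2 bits; a node splits when the product is `>= cutoff_bits`).
#' @param min_node_samples minimum member count for a node to be considered
#'   for splitting (default 10).
#' @param low_frac,high_frac candidate frequency filter.
#' @param max_conflicts conflicting pairs recorded per split node.
#' @param include_self see [find_mibp()].
#' @return Object of class `mibp_tree`: `root` (nested node list), `ens`,
#'   `config`; nodes carry constraints, probability, conditional marginals,
#'   conditional entropy, MIBP, MI sum and conflicting pairs.
#' @export
build_tree <- function(ens, cutoff_bits = 2, min_node_samples = 10,
                       low_frac = 0.01, high_frac = 0.99, max_conflicts = 5,
                       include_self = TRUE) {
  grow <- function(members, constraints) {
    node <- new_cluster_node(ens, members, constraints)
    best <- find_mibp(ens, members, low_frac, high_frac, include_self)
    if (!is.null(best)) {
      node$mibp <- best$pair
      node$mi_sum <- best$mi_sum
      node$conflicting <- find_conflicting_pairs(ens, best$pair, members,
                                                 max_conflicts)
    }
    can_split <- !is.null(best) &&
      length(members) >= min_node_samples &&
      node$probability * best$mi_sum >= cutoff_bits
    if (can_split) {
      halves <- split_cluster(ens, members, best$pair)
      cons_p <- rbind(constraints,
                      data.frame(i = best$pair[1], j = best$pair[2],
                                 state = "present"))
      cons_a <- rbind(constraints,
                      data.frame(i = best$pair[1], j = best$pair[2],
                                 state = "absent"))
      node$children <- list(present = grow(halves$present, cons_p),
                            absent = grow(halves$absent, cons_a))
    }
    node
  }
  root <- grow(seq_along(ens$structures),
               data.frame(i = integer(0), j = integer(0),
                          state = character(0)))
  root <- assign_node_ids(root, 1L)$node
  structure(
    list(root = root, ens = ens,
         config = list(cutoff_bits = cutoff_bits,
                       min_node_samples = min_node_samples,
                       low_frac = low_frac, high_frac = high_frac,
                       max_conflicts = max_conflicts,
                       include_self = include_self)),
    class = "mibp_tree"
  )
}

# Preorder ids: root 1, then present subtree, then absent subtree.
assign_node_ids <- function(node, next_id) {
  node$id <- next_id
  next_id <- next_id + 1L
  if (!is.null(node$children)) {
    res <- assign_node_ids(node$children$present, next_id)
    node$children$present <- res$node
    res2 <- assign_node_ids(node$children$absent, res$next_id)
    node$children$absent <- res2$node
    next_id <- res2$next_id
  }
  list(node = node, next_id = next_id)
}

#' @export
print.mibp_tree <- function(x, ...) {
  lv <- tree_leaves(x)
  cat(sprintf("<mibp_tree> %d leaves (cutoff %.3g bits)\n",
              length(lv), x$config$cutoff_bits))
  show <- function(node, depth) {
    lab <- if (is.null(node$children)) "leaf" else
      sprintf("split {%d,%d}", node$mibp[1], node$mibp[2])
    cat(sprintf("%s#%d p=%.4f H=%.3f %s\n",
                strrep("  ", depth), node$id, node$probability,
                node$cond_entropy, lab))
    if (!is.null(node$children)) {
      show(node$children$present, depth + 1)
      show(node$children$absent, depth + 1)
    }
  }
  show(x$root, 0)
  invisible(x)
}

#' Leaves of a cluster tree, left to right
#'
#' @param tree an `mibp_tree`.
#' @return List of leaf nodes (present child before absent child).
#' @export
tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (is.null(node$children)) {
      out[[length(out) + 1]] <<- node
    } else {
      walk(node$children$present)
      walk(node$children$absent)
    }
  }
  walk(tree$root)
  out
}

#' Conditional entropy of a cluster tree
#'
#' The leaf-probability-weighted sum of within-leaf ensemble entropies: the
#' basepair uncertainty that remains after learning which cluster a
#' structure falls in. For a single-leaf tree it equals the root ensemble
#' entropy; on exact ensembles it never exceeds it.
#'
#' @param tree an `mibp_tree`.
#' @return Entropy in bits.
#' @export
conditional_entropy_of_tree <- function(tree) {
  sum(vapply(tree_leaves(tree),
             function(l) l$probability * l$cond_entropy, numeric(1)))
}

#' Locate the leaf cluster containing a structure
#'
#' Walks the tree from the root, taking the present child when the structure
#' contains that node's MIBP and the absent child otherwise. Every structure
#' over the sequence satisfies exactly one leaf's constraint list.
#'
#' @param tree an `mibp_tree`.
#' @param s an `rna_structure` over the same sequence.
#' @return List with `id` (leaf node id), `probability` (leaf mass) and
#'   `constraints` (the leaf's constraint data.frame).
#' @export
locate_structure <- function(tree, s) {
  if (s$seq$residues != tree$ens$seq$residues) {
    stop("structure sequence differs from the ensemble sequence")
  }
  keys <- pair_keys(s$pairs)
  node <- tree$root
  while (!is.null(node$children)) {
    has <- paste(node$mibp[1], node$mibp[2], sep = "-") %in% keys
    node <- if (has) node$children$present else node$children$absent
  }
  list(id = node$id, probability = node$probability,
       constraints = node$constraints)
}

# Plain-list tree representation consumed by the JSON report and renderer.
tree_as_list <- function(tree) {
  conv <- function(node) {
    list(
      id = node$id,
      constraints = lapply(seq_len(nrow(node$constraints)), function(r) {
        list(i = node$constraints$i[r], j = node$constraints$j[r],
             state = node$constraints$state[r])
      }),
      probability = node$probability,
      n_members = length(node$members),
      conditional_entropy = node$cond_entropy,
      mibp = if (is.null(node$mibp)) NULL else
        list(i = node$mibp[1], j = node$mibp[2], mi_sum = node$mi_sum),
      conflicting_pairs = lapply(seq_len(nrow(node$conflicting)), function(r) {
        list(i = node$conflicting$i[r], j = node$conflicting$j[r],
             p = node$conflicting$p[r])
      }),
      marginals = lapply(seq_len(nrow(node$marginals)), function(r) {
        list(i = node$marginals$i[r], j = node$marginals$j[r],
             p = node$marginals$p[r])
      }),
      children = if (is.null(node$children)) NULL else
        list(present = conv(node$children$present),
             absent = conv(node$children$absent))
    )
  }
  list(sequence = list(name = tree$ens$seq$name,
                       residues = tree$ens$seq$residues),
       n_samples = length(tree$ens$structures),
       config = tree$config,
       root = conv(tree$root))
}
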