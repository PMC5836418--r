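log_stage <- function(verbose, ...) {
  if (verbose) message(sprintf("[rnamibp] %s", sprintf(...)))
}

#' End-to-end ensemble analysis
#'
#' Runs the full workflow on a sampled ensemble: read the samples (and
#' optionally a FASTA sequence to check them against), build the indicator
#' ensemble, grow the MIBP cluster tree, derive entropy constraints, count
#' the structure space before and after constraining, and render the
#' HTML/SVG/JSON report. Deterministic: rerunning with identical inputs and
#' options reproduces every output byte for byte.
#'
#' @param samples path to a multi-structure dot-bracket or concatenated CT
#'   file (or a list of `rna_structure` objects).
#' @param out_dir report output directory.
#' @param sequence optional FASTA path, string or [rna_sequence()]; when
#'   given it must match the samples' sequence.
#' @param reference optional native/reference structure as a dot-bracket
#'   string or `rna_structure`; its leaf cluster and that cluster's
#'   probability are reported.
#' @param format sample file format (`"auto"`, `"dotbracket"`, `"ct"`).
#' @param cutoff_bits tree stopping threshold (default 2 bits).
#' @param entropy_threshold entropy-constraint threshold (default 0.002
#'   bits).
#' @param low_frac,high_frac candidate frequency filter (defaults 0.01 /
#'   0.99).
#' @param max_conflicts conflicting pairs per node (default 5).
#' @param min_node_samples minimum members for a split (default 10).
#' @param min_loop minimum hairpin loop for counting/constraints (default
#'   3).
#' @param plot_floor chord plotting floor (default 0.01).
#' @param count whether to run the structure-space counts (default TRUE;
#'   the DP is cubic in sequence length).
#' @param verbose log stages to stderr.
#' @return Invisibly, a list with `tree`, `stats`, `constraints`, `counts`,
#'   `retained`, `reference_leaf` and the written `paths`.
#' @export
mibp_analyze <- function(samples, out_dir, sequence = NULL, reference = NULL,
                         format = "auto", cutoff_bits = 2,
                         entropy_threshold = 0.002, low_frac = 0.01,
                         high_frac = 0.99, max_conflicts = 5,
                         min_node_samples = 10, min_loop = 3,
                         plot_floor = 0.01, count = TRUE, verbose = TRUE) {
  structures <- if (is.list(samples) && inherits(samples[[1]], "rna_structure"))
    samples else read_structures(samples, format)
  seq <- structures[[1]]$seq
  if (!is.null(sequence)) {
    given <- if (inherits(sequence, "rna_sequence")) sequence
      else if (is.character(sequence) && file.exists(sequence))
        read_fasta_sequence(sequence)
      else rna_sequence(sequence)
    if (given$residues != seq$residues) {
      stop(sprintf(paste0("sequence mismatch: supplied sequence (%d nt) ",
                          "differs from the samples' sequence (%d nt)"),
                   length(given), length(seq)))
    }
    seq <- given
    structures <- lapply(structures, function(s) { s$seq <- seq; s })
  }
  log_stage(verbose, "read %d sampled structures over %d nt (%s)",
            length(structures), length(seq), seq$name)

  ens <- build_ensemble(structures)
  stats <- pair_stats(ens)
  ens_H <- ensemble_entropy(stats)
  log_stage(verbose, "%d candidate pairs, ensemble entropy %.3f bits",
            nrow(ens$candidates), ens_H)

  tree <- build_tree(ens, cutoff_bits = cutoff_bits,
                     min_node_samples = min_node_samples,
                     low_frac = low_frac, high_frac = high_frac,
                     max_conflicts = max_conflicts)
  cond_H <- conditional_entropy_of_tree(tree)
  n_leaves <- length(tree_leaves(tree))
  log_stage(verbose, "tree: %d clusters, conditional entropy %.3f bits",
            n_leaves, cond_H)

  cs <- entropy_constraints(stats, seq, threshold_bits = entropy_threshold,
                            min_loop = min_loop)
  kept <- retained_mass(ens, cs)
  log_stage(verbose,
            "entropy constraints: %d forced, %d forbidden, %.4f mass retained",
            nrow(cs$forced_pairs), nrow(cs$forbidden_pairs), kept)

  counts <- NULL
  if (count) {
    c0 <- count_structures(seq, min_loop = min_loop)
    c1 <- count_structures(seq, cs, min_loop = min_loop)
    counts <- data.frame(
      label = c("unconstrained", "entropy_constrained"),
      count = c(c0$count, c1$count),
      log10_count = c(c0$log10_count, c1$log10_count),
      retained_mass = c(1, kept))
    log_stage(verbose, "structure space: 10^%.2f -> 10^%.2f",
              c0$log10_count, c1$log10_count)
  }

  ref_leaf <- NULL
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "rna_structure")) reference
      else rna_structure(seq, parse_dotbracket_line(reference, length(seq)))
    loc <- locate_structure(tree, ref)
    ref_leaf <- list(id = loc$id, probability = loc$probability)
    log_stage(verbose, "reference structure falls in cluster %d (p = %.4f)",
              loc$id, loc$probability)
  }

  extra <- list(
    analysis = list(
      ensemble_entropy = ens_H,
      conditional_entropy = cond_H,
      n_clusters = n_leaves,
      entropy_threshold = entropy_threshold,
      n_forced = nrow(cs$forced_pairs),
      n_forbidden = nrow(cs$forbidden_pairs),
      retained_mass = kept,
      counts = if (is.null(counts)) NULL else list(
        unconstrained = counts$count[1],
        unconstrained_log10 = counts$log10_count[1],
        constrained = counts$count[2],
        constrained_log10 = counts$log10_count[2]),
      reference_leaf = ref_leaf,
      min_loop = min_loop))
  paths <- render_report(tree, out_dir, floor = plot_floor, extra = extra)
  if (!is.null(counts)) {
    write_counts_tsv(counts, file.path(out_dir, "counts.tsv"))
  }
  write_stats_tsv(stats, file.path(out_dir, "pair_stats.tsv"))
  log_stage(verbose, "report written to %s", out_dir)
  invisible(list(tree = tree, stats = stats, constraints = cs,
                 counts = counts, retained = kept, reference_leaf = ref_leaf,
                 paths = paths))
}

#' Simulate a sampled ensemble from the toy model
#'
#' Enumerates the exact toy Boltzmann ensemble of a short sequence and writes
#' `n` seeded samples as a standard dot-bracket file plus an exact-statistics
#' sidecar (see [write_toy_samples()]).
#'
#' @param sequence string or [rna_sequence()], within the enumeration cap.
#' @param n number of samples.
#' @param seed integer seed.
#' @param path output dot-bracket path.
#' @param model a [toy_energy_model()].
#' @return List with `samples` and `sidecar` paths, invisibly.
#' @export
mibp_simulate <- function(sequence, n, seed, path,
                          model = toy_energy_model()) {
  if (n < 1) stop("n must be at least 1")
  exact <- exact_ensemble(rna_sequence(sequence), model)
  write_toy_samples(exact, n, seed, path)
}

#' Count the structure space of a sequence, optionally constrained
#'
#' @param sequence string, FASTA path or [rna_sequence()].
#' @param forced,forbidden pairs for a [constraint_set()] (matrix or flat
#'   `c(i1, j1, ...)` vector).
#' @param unpaired positions forced unpaired.
#' @param min_loop minimum hairpin loop (default 3).
#' @param samples optional sample file or structure list; adds the retained
#'   probability mass under the constraints.
#' @return `data.frame` with unconstrained and constrained rows: `label`,
#'   `count` (exact decimal string), `log10_count`, `retained_mass`.
#' @export
mibp_count <- function(sequence, forced = NULL, forbidden = NULL,
                       unpaired = integer(0), min_loop = 3, samples = NULL) {
  seq <- if (is.character(sequence) && length(sequence) == 1 &&
             file.exists(sequence)) read_fasta_sequence(sequence)
    else rna_sequence(sequence)
  cs <- constraint_set(forced, forbidden, unpaired)
  unconstrained <- count_structures(seq, min_loop = min_loop)
  constrained <- count_structures(seq, cs, min_loop = min_loop)
  kept <- NA_real_
  if (!is.null(samples)) {
    structures <- if (is.list(samples)) samples else read_structures(samples)
    ens <- build_ensemble(structures)
    kept <- retained_mass(ens, cs)
  }
  data.frame(
    label = c("unconstrained", "constrained"),
    count = c(unconstrained$count, constrained$count),
    log10_count = c(unconstrained$log10_count, constrained$log10_count),
    retained_mass = c(1, kept))
}
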