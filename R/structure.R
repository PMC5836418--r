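#' Secondary structure object
#'
#' A secondary structure is a set of basepairs over a sequence, subject to the
#' standard pseudoknot-free model: every position belongs to at most one pair
#' (no triples), no two pairs cross (no pseudoknots), paired bases are
#' non-adjacent (`j - i >= 2`).
#'
#' @param seq an [rna_sequence()] (or string coercible to one).
#' @param pairs basepairs as an n-by-2 matrix/data.frame of `(i, j)` rows or a
#'   flat vector `c(i1, j1, i2, j2, ...)`; may be empty.
#' @param validate if `TRUE` (default) reject structures violating the model.
#' @return An object of class `rna_structure` with elements `seq` and `pairs`
#'   (integer matrix with columns `i`, `j`, sorted by `i`).
#' @examples
#' s <- rna_structure("GGAAACC", c(1, 7, 2, 6))
#' write_dotbracket(s)
#' @export
rna_structure <- function(seq, pairs = NULL, validate = TRUE) {
  seq <- rna_sequence(seq)
  pairs <- as_pair_matrix(pairs)
  s <- structure(list(seq = seq, pairs = pairs), class = "rna_structure")
  if (validate) {
    v <- validate_structure(s)
    if (length(v) > 0) stop("invalid structure: ", paste(v, collapse = "; "))
  }
  s
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> %s: %d pairs over %d nt\n",
              x$seq$name, nrow(x$pairs), length(x$seq)))
  cat(x$seq$residues, "\n")
  cat(write_dotbracket(x), "\n")
  invisible(x)
}

#' Validate a secondary structure
#'
#' Checks the pseudoknot-free model rules and returns violations as data
#' rather than raising: an empty character vector means the structure is
#' valid. Rules checked: positions in `[1, n]`, `j - i >= 2`, no position in
#' more than one pair (triple), no crossing pairs (pseudoknot).
#'
#' @param s an `rna_structure` (possibly built with `validate = FALSE`).
#' @return Character vector of human-readable violation messages, one per
#'   offending pair or pair-of-pairs; empty when valid.
#' @export
validate_structure <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  n <- length(s$seq)
  p <- s$pairs
  out <- character(0)
  if (nrow(p) == 0) return(out)
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1]; j <- p[r, 2]
    if (i < 1 || j > n) {
      out <- c(out, sprintf("pair {%d,%d} out of range [1,%d]", i, j, n))
    }
    if (j - i < 2) {
      out <- c(out, sprintf("pair {%d,%d} joins adjacent bases (j-i must be >= 2)", i, j))
    }
  }
  pos <- c(p[, 1], p[, 2])
  dup <- unique(pos[duplicated(pos)])
  for (d in dup) {
    out <- c(out, sprintf("triple: position %d appears in more than one pair", d))
  }
  if (nrow(p) >= 2) {
    for (a in seq_len(nrow(p) - 1)) {
      for (b in seq(a + 1, nrow(p))) {
        i <- p[a, 1]; j <- p[a, 2]; k <- p[b, 1]; l <- p[b, 2]
        if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) {
          out <- c(out, sprintf("pseudoknot: pairs {%d,%d} and {%d,%d} cross", i, j, k, l))
        }
      }
    }
  }
  out
}

#' Write a structure in dot-bracket notation
#'
#' @param s an `rna_structure`.
#' @return Single string of `.`, `(` and `)`; the exact inverse of the
#'   dot-bracket reader, so round trips are the identity.
#' @export
write_dotbracket <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  chars <- rep(".", length(s$seq))
  if (nrow(s$pairs) > 0) {
    chars[s$pairs[, 1]] <- "("
    chars[s$pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

# Parse one dot-bracket line into a pair matrix; `line_no` is for error text.
parse_dotbracket_line <- function(line, n, line_no = NA) {
  where <- if (is.na(line_no)) "" else sprintf(" (line %s)", line_no)
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  if (any(chars %in% c("[", "]", "{", "}", "<", ">"))) {
    stop("pseudoknots unsupported: extra bracket layers found", where)
  }
  bad <- setdiff(unique(chars), c(".", "(", ")"))
  if (length(bad) > 0) {
    stop("invalid dot-bracket character(s) ", paste(bad, collapse = ""), where)
  }
  stack <- integer(0)
  pairs <- NULL
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch == "(") {
      stack <- c(stack, pos)
    } else if (ch == ")") {
      if (length(stack) == 0) stop("unbalanced brackets: unmatched ')'", where)
      pairs <- rbind(pairs, c(stack[length(stack)], pos))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) stop("unbalanced brackets: unmatched '('", where)
  if (length(chars) != n) {
    stop(sprintf("structure length %d does not match sequence length %d%s",
                 length(chars), n, where))
  }
  as_pair_matrix(pairs)
}

#' Read sampled secondary structures from a file
#'
#' Adapter for external stochastic samplers. Two formats are supported:
#'
#' * `dotbracket`: an optional FASTA header line, one sequence line, then one
#'   dot-bracket string per line (only `.`, `(`, `)`; extra bracket layers are
#'   rejected because pseudoknots are out of model).
#' * `ct`: one or more concatenated connect-format records over the same
#'   sequence, each a header line whose first field is the length followed by
#'   one whitespace-delimited row per position
#'   `(index, base, prev, next, pair, natural index)`; header energy
#'   annotations are ignored.
#'
#' @param source path to a file, or a character vector of lines.
#' @param format `"auto"` (default; CT is detected from the header/first
#'   record shape), `"dotbracket"` or `"ct"`.
#' @return List of `rna_structure` objects, in input order, all sharing one
#'   identical sequence.
#' @export
read_structures <- function(source, format = c("auto", "dotbracket", "ct")) {
  format <- match.arg(format)
  lines <- if (length(source) == 1 && file.exists(source)) readLines(source) else source
  lines <- lines[!grepl("^[[:space:]]*$", lines)]
  if (length(lines) == 0) stop("no content in structure input")
  if (format == "auto") {
    first <- lines[if (startsWith(lines[1], ">")) 2 else 1]
    tok <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
    looks_ct <- !startsWith(lines[1], ">") &&
      !grepl("^[.()ACGUTacgut]+$", trimws(first)) &&
      grepl("^[0-9]+$", tok[1])
    format <- if (looks_ct) "ct" else "dotbracket"
  }
  if (format == "ct") read_ct_lines(lines) else read_dotbracket_lines(lines)
}

read_dotbracket_lines <- function(lines) {
  idx <- 1
  name <- "seq"
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    idx <- 2
  }
  if (idx > length(lines)) stop("missing sequence line in dot-bracket input")
  seq <- rna_sequence(trimws(lines[idx]), name = name)
  n <- length(seq)
  struct_lines <- lines[seq(idx + 1, length.out = max(0, length(lines) - idx))]
  if (length(struct_lines) == 0) stop("no structure lines in dot-bracket input")
  out <- vector("list", length(struct_lines))
  for (k in seq_along(struct_lines)) {
    pairs <- parse_dotbracket_line(trimws(struct_lines[k]), n, line_no = idx + k)
    out[[k]] <- rna_structure(seq, pairs)
  }
  out
}

read_ct_lines <- function(lines) {
  out <- list()
  seq <- NULL
  k <- 1
  while (k <= length(lines)) {
    tok <- strsplit(trimws(lines[k]), "[[:space:]]+")[[1]]
    if (!grepl("^[0-9]+$", tok[1])) {
      stop("malformed CT header at line ", k, ": expected a length count")
    }
    n <- as.integer(tok[1])
    if (k + n > length(lines)) stop("truncated CT record starting at line ", k)
    rows <- lines[(k + 1):(k + n)]
    bases <- character(n)
    partner <- integer(n)
    for (r in seq_len(n)) {
      f <- strsplit(trimws(rows[r]), "[[:space:]]+")[[1]]
      if (length(f) < 5) stop("malformed CT row at line ", k + r)
      bases[as.integer(f[1])] <- f[2]
      partner[as.integer(f[1])] <- as.integer(f[5])
    }
    this_seq <- rna_sequence(paste(bases, collapse = ""),
                             name = paste(tok[-1], collapse = " "))
    if (is.null(seq)) {
      seq <- this_seq
    } else if (seq$residues != this_seq$residues) {
      stop("CT records carry different sequences (record starting line ", k, ")")
    }
    sel <- which(partner > seq_len(n) & partner > 0)
    pairs <- cbind(sel, partner[sel])
    out[[length(out) + 1]] <- rna_structure(seq, as_pair_matrix(pairs))
    k <- k + n + 1
  }
  if (length(out) == 0) stop("no CT records found")
  out
}

#' Write structures as a multi-structure dot-bracket file
#'
#' Writes a FASTA-style header, the sequence line, then one dot-bracket line
#' per structure — the same layout [read_structures()] consumes.
#'
#' @param structures list of `rna_structure` over a common sequence.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dotbracket_file <- function(structures, path) {
  stopifnot(length(structures) >= 1)
  seq <- structures[[1]]$seq
  lines <- c(paste0(">", seq$name), seq$residues,
             vapply(structures, write_dotbracket, character(1)))
  writeLines(lines, path)
  invisible(path)
}
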