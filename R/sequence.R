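#' RNA sequence object
#'
#' Light wrapper around a nucleotide string. Input is uppercased and DNA-style
#' `T` is normalized to `U`; any character outside `A`, `C`, `G`, `U` after
#' normalization is an error. Positions are 1-based throughout the package.
#'
#' @param residues single string (or character vector of single letters) over
#'   A/C/G/U; T and lowercase accepted on input.
#' @param name free-text label for the sequence.
#' @return An object of class `rna_sequence` with elements `name`, `residues`
#'   (normalized string) and `bases` (character vector of single letters).
#' @examples
#' rna_sequence("gaaac")
#' rna_sequence("GATTACA", name = "dna-style input")
#' @export
rna_sequence <- function(residues, name = "seq") {
  if (inherits(residues, "rna_sequence")) return(residues)
  if (!is.character(residues) || length(residues) < 1) {
    stop("`residues` must be a character string")
  }
  s <- paste(residues, collapse = "")
  s <- toupper(gsub("[[:space:]]", "", s))
  s <- gsub("T", "U", s, fixed = TRUE)
  if (nchar(s) < 1) stop("sequence must contain at least one base")
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(bases), c("A", "C", "G", "U"))
  if (length(bad) > 0) {
    stop("invalid nucleotide character(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(name = as.character(name)[1], residues = s, bases = bases),
    class = "rna_sequence"
  )
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)\n", x$name, nchar(x$residues)))
  cat(x$residues, "\n")
  invisible(x)
}

#' @export
length.rna_sequence <- function(x) nchar(x$residues)

#' Read the first sequence from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return An [rna_sequence()] built from the first record.
#' @export
read_fasta_sequence <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) < 1) stop("no sequences in FASTA file: ", path)
  rna_sequence(as.character(recs[[1]]), name = names(recs)[1])
}

#' Can two bases form an allowed pair?
#'
#' Only Watson-Crick (A-U, G-C) and wobble (G-U) pairings are allowed;
#' the relation is symmetric in its arguments.
#'
#' @param a,b single base letters in A/C/G/U (vectorized, recycled).
#' @return Logical vector.
#' @examples
#' can_pair("A", "U")  # TRUE
#' can_pair("G", "U")  # TRUE  (wobble)
#' can_pair("A", "G")  # FALSE
#' @export
can_pair <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  ok <- c("A", "C", "G", "U")
  bad <- setdiff(unique(c(a, b)), ok)
  if (length(bad) > 0) {
    stop("non-nucleotide letter(s): ", paste(bad, collapse = ", "))
  }
  key <- ifelse(a < b, paste0(a, b), paste0(b, a))
  key %in% c("AU", "CG", "GU")
}

#' Do two basepairs conflict?
#'
#' Pairs `{i,j}` and `{k,l}` conflict when they cannot coexist in one
#' pseudoknot-free structure: they share an endpoint, or they cross
#' (`i < k < j < l` or `k < i < l < j`).
#'
#' @param p,q basepairs as length-2 integer vectors `c(i, j)` with `i < j`.
#' @return `TRUE` if the pairs conflict.
#' @examples
#' conflicts(c(2, 9), c(4, 7))   # FALSE: nested
#' conflicts(c(2, 6), c(4, 9))   # TRUE: crossing
#' conflicts(c(2, 6), c(6, 10))  # TRUE: shared endpoint
#' @export
conflicts <- function(p, q) {
  p <- as.integer(p); q <- as.integer(q)
  stopifnot(length(p) == 2, length(q) == 2, p[1] < p[2], q[1] < q[2])
  shared <- any(p %in% q)
  cross <- (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
           (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
  shared || cross
}

# Vectorized conflict test of one pair against the rows of a pair matrix.
# An identical pair is not its own conflict (the relation is over distinct
# pairs), so equal rows come back FALSE.
conflicts_with <- function(pair, pairs) {
  if (nrow(pairs) == 0) return(logical(0))
  i <- pair[1]; j <- pair[2]
  k <- pairs[, 1]; l <- pairs[, 2]
  shared <- (i == k) | (i == l) | (j == k) | (j == l)
  cross <- (i < k & k < j & j < l) | (k < i & i < l & l < j)
  (shared | cross) & !(i == k & j == l)
}

# Canonical empty / sorted pair matrix with columns i, j.
as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0) ||
      length(pairs) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  if (!is.matrix(pairs)) pairs <- matrix(as.integer(pairs), ncol = 2, byrow = TRUE)
  storage.mode(pairs) <- "integer"
  swap <- pairs[, 1] > pairs[, 2]
  if (any(swap)) pairs[swap, ] <- pairs[swap, 2:1]
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

# "i-j" keys for pair matrices; used for set operations on pairs.
pair_keys <- function(pairs) {
  if (nrow(pairs) == 0) return(character(0))
  paste(pairs[, 1], pairs[, 2], sep = "-")
}
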