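AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch dynamic programming under a simple match/mismatch
#' score with a linear gap penalty, with a deterministic tie-break
#' (diagonal preferred over up over left). Percent identity is computed
#' over all alignment columns, gap columns included (full-length
#' identity) — tools that divide by the shorter sequence or by aligned
#' columns only will report higher values.
#'
#' @param a,b Protein sequences (1-letter, no gaps).
#' @param match Score for identical residues (default 1).
#' @param mismatch Score for differing residues (default -1).
#' @param gap Per-column gap penalty (default -2, linear).
#' @return An `alignment_result`: `aligned_a`, `aligned_b`, `score`,
#'   `n_columns`, `matches`, `identity_percent`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  bad <- setdiff(unique(c(av, bv)), AA_ALPHABET)
  if (length(bad))
    stop("illegal residue character(s): ", paste(bad, collapse = ","))
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)  # 1 diag, 2 up, 3 left
  S[, 1L] <- gap * 0:n; P[-1L, 1L] <- 2L
  S[1L, ] <- gap * 0:m; P[1L, -1L] <- 3L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + if (av[i] == bv[j]) match else mismatch
      u <- S[i, j + 1L] + gap
      l <- S[i + 1L, j] + gap
      best <- max(d, u, l)
      S[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }
  i <- n + 1L; j <- m + 1L
  ra <- character(0); rb <- character(0)
  while (i > 1L || j > 1L) {
    p <- P[i, j]
    if (p == 1L) {
      ra <- c(av[i - 1L], ra); rb <- c(bv[j - 1L], rb)
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      ra <- c(av[i - 1L], ra); rb <- c("-", rb)
      i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j - 1L], rb)
      j <- j - 1L
    }
  }
  matches <- sum(ra == rb & ra != "-")
  ncol_aln <- length(ra)
  structure(list(aligned_a = paste(ra, collapse = ""),
                 aligned_b = paste(rb, collapse = ""),
                 score = S[n + 1L, m + 1L],
                 n_columns = ncol_aln, matches = matches,
                 identity_percent = 100 * matches / ncol_aln),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %g; identity %.1f%% (%d/%d columns)\n",
              x$score, x$identity_percent, x$matches, x$n_columns))
  invisible(x)
}

#' Pairwise identity matrix for a set of protein sequences
#'
#' @param seqs Named character vector of ungapped protein sequences.
#' @param ... Scoring parameters passed to [global_align()].
#' @return Symmetric numeric matrix of full-length percent identities.
#' @export
identity_matrix <- function(seqs, ...) {
  n <- length(seqs)
  out <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n >= 2L)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      id <- global_align(seqs[[i]], seqs[[j]], ...)$identity_percent
      out[i, j] <- out[j, i] <- id
    }
  out
}

#' Residue content and invariance of one alignment column
#'
#' @param msa Character vector of equal-length gapped sequences.
#' @param column 1-based column index.
#' @return List with `residues` (table of non-gap residues at the column)
#'   and `is_invariant` (TRUE iff a single residue type across all
#'   non-gap rows; an all-gap column is not invariant).
#' @export
column_conserved <- function(msa, column) {
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L)
    stop("alignment rows must have equal length")
  if (column < 1L || column > widths[1])
    stop("column ", column, " out of range (1..", widths[1], ")")
  res <- substr(msa, column, column)
  res <- res[!res %in% c("-", ".")]
  list(residues = table(res),
       is_invariant = length(unique(res)) == 1L && length(res) > 0L)
}

#' Presence/absence synteny check for a packaged gene-order table
#'
#' Reads a species-by-gene synteny table (columns `species`, `lineage`,
#' `upstream`, `gene_present`, `downstream`) and verifies the declarative
#' expectation that the gene is flanked by the stated neighbours and
#' present in every non-rodent row while absent in rodent rows.
#'
#' @param path TSV path; defaults to the packaged synthetic CPAMD8 table.
#' @param upstream,downstream Expected flanking genes.
#' @return The table with a logical `as_expected` column.
#' @export
synteny_check <- function(path = system.file("extdata",
                                             "synteny_cpamd8_synthetic.tsv",
                                             package = "varcascade",
                                             mustWork = TRUE),
                          upstream = "HAUS8", downstream = "SIN3B") {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  rodent <- tb$lineage == "rodent"
  tb$as_expected <- ifelse(rodent, !tb$gene_present,
                           tb$gene_present & tb$upstream == upstream &
                             tb$downstream == downstream)
  tb
}
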