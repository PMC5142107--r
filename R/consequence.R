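AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Ter")

aa3 <- function(x) unname(AA_THREE[x])

#' Translate a coding sequence up to its first stop codon
#'
#' Standard nuclear genetic code; any incomplete trailing codon is ignored.
#'
#' @param x Nucleotide string.
#' @return List with `residues` (1-letter amino acids before the first
#'   stop), `terminated` (was a stop reached), `stop_index` (codon index of
#'   the stop, NA if none) and `n_codons` (complete codons in `x`).
#' @export
translate_cds <- function(x) {
  x <- toupper(x)
  n3 <- nchar(x) - nchar(x) %% 3L
  if (n3 == 0L)
    return(list(residues = character(0), terminated = FALSE,
                stop_index = NA_integer_, n_codons = 0L))
  aa <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n3)),
                          no.init.codon = TRUE)), "")[[1]]
  stop_at <- which(aa == "*")[1]
  if (is.na(stop_at)) {
    list(residues = aa, terminated = FALSE, stop_index = NA_integer_,
         n_codons = n3 %/% 3L)
  } else {
    list(residues = if (stop_at > 1L) aa[seq_len(stop_at - 1L)] else character(0),
         terminated = TRUE, stop_index = as.integer(stop_at),
         n_codons = n3 %/% 3L)
  }
}

#' Protein-level consequence of a mutant transcript
#'
#' Translates reference and mutant cDNA (stopping at the first stop codon)
#' and classifies the difference. If the cDNA length change is a multiple
#' of 3 and the mutant carries no premature stop, the change is in-frame:
#' the altered block is located by maximal common prefix then maximal
#' common suffix, which places deletion/insertion boundaries at their
#' 3'-most (HGVS-normalized) position. Otherwise the change is a
#' frameshift, written `p.(Ref)(pos)(New)fs*N` with the first altered
#' residue counted as position 1 and N the stop position in the new frame.
#' A mutant that never reaches a stop codon is reported as `fs*?` and
#' flagged.
#'
#' @param ref_transcript A `transcript_model` with coding sequence, or the
#'   reference CDS as a character string.
#' @param mutant_cdna Mutant cDNA string.
#' @return An object of class `protein_consequence`: list with `category`
#'   (inframe_deletion, inframe_insertion, inframe_delins, frameshift,
#'   missense, synonymous, no_change), `hgvs_p`, `first_residue`,
#'   `n_residues_changed` (deleted/inserted residue count for in-frame
#'   changes, 0 for frameshifts), `stop_offset` (the N of fs*N, 0
#'   otherwise) and `flagged` (TRUE when the mutant lacks a stop codon).
#' @export
consequence <- function(ref_transcript, mutant_cdna) {
  ref_cds <- if (inherits(ref_transcript, "transcript_model")) {
    if (is.null(ref_transcript$cds)) stop("transcript has no coding sequence")
    ref_transcript$cds
  } else {
    toupper(ref_transcript)
  }
  mutant_cdna <- toupper(mutant_cdna)
  rp <- translate_cds(ref_cds)
  mp <- translate_cds(mutant_cdna)
  ra <- rp$residues
  ma <- mp$residues
  lr <- length(ra); lm <- length(ma)
  len_change <- nchar(mutant_cdna) - nchar(ref_cds)

  out <- function(category, hgvs_p, first_residue = NA_integer_,
                  n_changed = 0L, stop_offset = 0L, flagged = FALSE) {
    structure(list(category = category, hgvs_p = hgvs_p,
                   first_residue = as.integer(first_residue),
                   n_residues_changed = as.integer(n_changed),
                   stop_offset = as.integer(stop_offset), flagged = flagged),
              class = "protein_consequence")
  }

  if (identical(ra, ma) && rp$terminated && mp$terminated) {
    if (identical(ref_cds, mutant_cdna))
      return(out("no_change", "p.(=)"))
    return(out("synonymous", "p.(=)"))
  }

  premature <- mp$terminated && mp$stop_index < mp$n_codons
  inframe <- (len_change %% 3L == 0L) && mp$terminated && !premature

  if (inframe) {
    # maximal common prefix, then maximal common suffix of the remainder:
    # yields the 3'-most (HGVS) placement of the altered block
    maxp <- min(lr, lm)
    p <- 0L
    while (p < maxp && ra[p + 1L] == ma[p + 1L]) p <- p + 1L
    maxs <- min(lr, lm) - p
    s <- 0L
    while (s < maxs && ra[lr - s] == ma[lm - s]) s <- s + 1L
    del <- if (p + 1L <= lr - s) ra[(p + 1L):(lr - s)] else character(0)
    ins <- if (p + 1L <= lm - s) ma[(p + 1L):(lm - s)] else character(0)
    if (!length(del) && !length(ins))
      return(out("synonymous", "p.(=)"))
    if (!length(ins)) {
      a <- p + 1L; b <- lr - s
      hg <- if (a == b) sprintf("p.%s%ddel", aa3(ra[a]), a)
            else sprintf("p.%s%d_%s%ddel", aa3(ra[a]), a, aa3(ra[b]), b)
      return(out("inframe_deletion", hg, a, length(del)))
    }
    if (!length(del)) {
      if (p == 0L)  # insertion before the initiator: no flanking residue pair
        return(out("inframe_insertion", sprintf("p.?ins%d", length(ins)),
                   1L, length(ins)))
      hg <- sprintf("p.%s%d_%s%dins%d", aa3(ra[p]), p, aa3(ra[p + 1L]), p + 1L,
                    length(ins))
      return(out("inframe_insertion", hg, p, length(ins)))
    }
    if (length(del) == 1L && length(ins) == 1L) {
      a <- p + 1L
      return(out("missense", sprintf("p.%s%d%s", aa3(ra[a]), a, aa3(ins)), a, 1L))
    }
    a <- p + 1L; b <- lr - s
    hg <- if (a == b)
      sprintf("p.%s%ddelins%s", aa3(ra[a]), a, paste(aa3(ins), collapse = ""))
    else
      sprintf("p.%s%d_%s%ddelins%s", aa3(ra[a]), a, aa3(ra[b]), b,
              paste(aa3(ins), collapse = ""))
    return(out("inframe_delins", hg, a, length(ins)))
  }

  # frameshift / premature stop path
  maxp <- min(lr, lm)
  i <- 1L
  while (i <= maxp && ra[i] == ma[i]) i <- i + 1L
  if (i <= maxp || (i <= lr && i <= lm)) {
    # first altered residue exists in both translations
    newr <- ma[i]
    if (mp$terminated) {
      n <- lm - i + 2L
      return(out("frameshift", sprintf("p.%s%d%sfs*%d", aa3(ra[i]), i, aa3(newr), n),
                 i, 0L, n))
    }
    return(out("frameshift", sprintf("p.%s%d%sfs*?", aa3(ra[i]), i, aa3(newr)),
               i, 0L, NA_integer_, flagged = TRUE))
  }
  if (i > lm && i <= lr) {
    if (!mp$terminated)  # truncated message with no stop reached
      return(out("frameshift", sprintf("p.%s%dfs*?", aa3(ra[i]), i), i, 0L,
                 NA_integer_, flagged = TRUE))
    # mutant translation stops where the reference continues: immediate stop
    return(out("frameshift", sprintf("p.%s%d*", aa3(ra[i]), i), i, 0L, 1L))
  }
  # reference exhausted: stop codon lost / C-terminal extension
  ext <- if (mp$terminated) as.character(lm - lr + 1L) else "?"
  out("frameshift", sprintf("p.Ter%dext*%s", lr + 1L, ext), lr + 1L, 0L,
      if (mp$terminated) lm - lr + 1L else NA_integer_,
      flagged = !mp$terminated)
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat("Protein consequence:", x$hgvs_p, "(", x$category, ")\n")
  if (x$category %in% c("inframe_deletion", "inframe_insertion", "inframe_delins"))
    cat("  residues changed:", x$n_residues_changed, "\n")
  if (!is.na(x$stop_offset) && x$stop_offset > 0L && x$category == "frameshift")
    cat("  new frame terminates at fs*", x$stop_offset, "\n", sep = "")
  if (isTRUE(x$flagged)) cat("  flagged: mutant lacks a stop codon\n")
  invisible(x)
}

#' 3'-normalize an HGVS p. deletion description
#'
#' Shifts a `p.X{a}_Y{b}del` (or `p.X{a}del`) description to its 3'-most
#' equivalent position given the reference protein sequence, per the HGVS
#' normalization rule. Descriptions that are not deletions, or that are
#' already 3'-most, are returned unchanged, so the operation is idempotent.
#'
#' @param hgvs_p An HGVS p. string.
#' @param ref_protein Reference protein as a 1-letter string or character
#'   vector.
#' @return The normalized HGVS p. string.
#' @export
normalize_hgvs_p <- function(hgvs_p, ref_protein) {
  if (length(ref_protein) == 1L && nchar(ref_protein[1]) > 1L)
    ref_protein <- strsplit(ref_protein, "")[[1]]
  m <- regmatches(hgvs_p,
    regexec("^p\\.([A-Za-z]{3})(\\d+)(?:_([A-Za-z]{3})(\\d+))?del$", hgvs_p))[[1]]
  if (!length(m)) return(hgvs_p)
  a <- as.integer(m[3])
  b <- if (nzchar(m[5])) as.integer(m[5]) else a
  n <- length(ref_protein)
  while (b + 1L <= n && ref_protein[a] == ref_protein[b + 1L]) {
    a <- a + 1L; b <- b + 1L
  }
  if (a == b) sprintf("p.%s%ddel", aa3(ref_protein[a]), a)
  else sprintf("p.%s%d_%s%ddel", aa3(ref_protein[a]), a, aa3(ref_protein[b]), b)
}
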