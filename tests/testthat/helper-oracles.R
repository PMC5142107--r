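# Independent oracles, kept deliberately naive and separate from the
# package implementation.

CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

naive_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  aa <- character(0)
  terminated <- FALSE
  for (i in seq_len(n)) {
    codon <- substr(seq, 3L * i - 2L, 3L * i)
    r <- CODON_TABLE[[codon]]
    if (r == "*") { terminated <- TRUE; break }
    aa <- c(aa, r)
  }
  list(aa = aa, terminated = terminated, n_codons = n)
}

# brute-force classification of a mutant against a reference CDS: pure
# deletions/insertions are located by enumerating every placement of the
# removed/inserted residue block and taking the 3'-most one
naive_consequence <- function(ref_cds, mut_cdna) {
  rp <- naive_translate(ref_cds); mp <- naive_translate(mut_cdna)
  ra <- rp$aa; ma <- mp$aa
  lr <- length(ra); lm <- length(ma)
  len_change <- nchar(mut_cdna) - nchar(ref_cds)
  # a stop at codon k is premature iff k < number of complete codons
  stop_codon <- if (mp$terminated) length(ma) + 1L else NA_integer_
  premature <- mp$terminated && stop_codon < mp$n_codons

  if (identical(ra, ma) && rp$terminated && mp$terminated) {
    cat_ <- if (identical(toupper(ref_cds), toupper(mut_cdna))) "no_change" else "synonymous"
    return(list(category = cat_, first_residue = NA_integer_,
                n_residues_changed = 0L, stop_offset = 0L))
  }
  if (len_change %% 3L == 0L && mp$terminated && !premature) {
    if (lr > lm) {
      d <- lr - lm
      starts <- which(vapply(seq_len(lr - d + 1L), function(a)
        identical(c(if (a > 1L) ra[1:(a - 1L)], if (a + d <= lr) ra[(a + d):lr]), ma),
        logical(1)))
      if (length(starts)) {
        a <- max(starts)
        return(list(category = "inframe_deletion", first_residue = a,
                    n_residues_changed = d, stop_offset = 0L))
      }
    } else if (lm > lr) {
      d <- lm - lr
      starts <- which(vapply(seq_len(lm - d + 1L), function(a)
        identical(c(if (a > 1L) ma[1:(a - 1L)], if (a + d <= lm) ma[(a + d):lm]), ra),
        logical(1)))
      if (length(starts)) {
        a <- max(starts)
        return(list(category = "inframe_insertion", first_residue = a - 1L,
                    n_residues_changed = d, stop_offset = 0L))
      }
    } else {
      diffs <- which(ra != ma)
      if (length(diffs) == 1L)
        return(list(category = "missense", first_residue = diffs,
                    n_residues_changed = 1L, stop_offset = 0L))
    }
    # delins: trim common prefix then suffix
    p <- 0L
    while (p < min(lr, lm) && ra[p + 1L] == ma[p + 1L]) p <- p + 1L
    s <- 0L
    while (s < min(lr, lm) - p && ra[lr - s] == ma[lm - s]) s <- s + 1L
    return(list(category = "inframe_delins", first_residue = p + 1L,
                n_residues_changed = lm - s - p, stop_offset = 0L))
  }
  # frameshift
  i <- 1L
  while (i <= min(lr, lm) && ra[i] == ma[i]) i <- i + 1L
  if (i <= min(lr, lm)) {
    n <- if (mp$terminated) lm - i + 2L else NA_integer_
    return(list(category = "frameshift", first_residue = i,
                n_residues_changed = 0L, stop_offset = n))
  }
  if (i > lm && i <= lr) {
    n <- if (mp$terminated) 1L else NA_integer_
    return(list(category = "frameshift", first_residue = i,
                n_residues_changed = 0L, stop_offset = n))
  }
  list(category = "frameshift", first_residue = lr + 1L,
       n_residues_changed = 0L,
       stop_offset = if (mp$terminated) lm - lr + 1L else NA_integer_)
}

# random toy transcript with a handful of exons and stored introns; the
# reference CDS is built from non-stop codons so the reference protein is
# always full length
random_toy_transcript <- function(n_exons = sample(3:6, 1)) {
  lens <- sample(6:30, n_exons, replace = TRUE)
  total <- sum(lens)
  pad <- (3L - total %% 3L) %% 3L
  lens[n_exons] <- lens[n_exons] + pad
  total <- sum(lens)
  bases <- c("A", "C", "G", "T")
  nonstop <- names(CODON_TABLE)[CODON_TABLE != "*"]
  cds <- paste0("ATG",
                paste(sample(nonstop, total / 3L - 2L, replace = TRUE),
                      collapse = ""),
                "TAA")
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  introns <- lapply(seq_len(n_exons - 1L), function(i)
    paste0("GT", paste(sample(bases, sample(5:40, 1), replace = TRUE), collapse = ""), "AG"))
  names(introns) <- as.character(seq_len(n_exons - 1L))
  transcript_model("TOY", data.frame(index = seq_len(n_exons),
                                     c_start = starts, c_end = ends),
                   cds = cds, introns = introns)
}

random_splice_event <- function(tx) {
  n_ex <- nrow(tx$exons)
  kind <- sample(c("exon_skip", "multi_exon_skip", "intron_retention",
                   "cryptic_donor", "cryptic_acceptor"), 1)
  if (kind == "exon_skip")
    return(splice_event("exon_skip", exons = sample(n_ex, 1)))
  if (kind == "multi_exon_skip") {
    a <- sample(n_ex - 1L, 1)
    return(splice_event("multi_exon_skip", exons = a:(a + 1L)))
  }
  i <- sample(n_ex - 1L, 1)
  len <- nchar(tx$introns[[as.character(i)]])
  if (kind == "intron_retention")
    return(splice_event("intron_retention", intron = i))
  if (kind == "cryptic_donor")
    return(splice_event("cryptic_donor", intron = i, offset = sample(len, 1)))
  splice_event("cryptic_acceptor", intron = i, offset = -sample(len, 1))
}

# exhaustive global alignment score by recursive enumeration
enumerate_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) +
                    if (substr(a, i, i) == substr(b, j, j)) match else mismatch)
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# allele-level brute force for trio segregation -----------------------------

# genotype -> set of possible ordered allele pairs (1 = alt)
gt_alleles <- function(g) {
  switch(g,
         hom_ref = list(c(0L, 0L)),
         het = list(c(0L, 1L), c(1L, 0L)),
         hom_alt = list(c(1L, 1L)))
}

# brute force: proband hom_alt; enumerate parental allele pairs and
# transmissions; consistent iff some transmission yields the proband
# genotype and no unaffected member is hom_alt
oracle_homozygous_trio <- function(father, mother, unaffected_sib = NULL) {
  # complete penetrance: no unaffected individual (parent or sib) may be
  # homozygous for the causal allele
  if (father == "hom_alt" || mother == "hom_alt") return(FALSE)
  if (!is.null(unaffected_sib) && unaffected_sib == "hom_alt") return(FALSE)
  for (fa in gt_alleles(father)) for (mo in gt_alleles(mother))
    for (i in 1:2) for (j in 1:2)
      if (fa[i] == 1L && mo[j] == 1L) return(TRUE)
  FALSE
}

# brute force for compound heterozygosity in a fully genotyped trio:
# enumerate the two trans assignments of the alleles to parental origins
oracle_compound_het_trio <- function(fA, fB, mA, mB) {
  carries <- function(g) g %in% c("het", "hom_alt")
  # unaffected parent carrying both alleles excludes the model
  if (carries(fA) && carries(fB)) return(FALSE)
  if (carries(mA) && carries(mB)) return(FALSE)
  (carries(fA) && carries(mB)) || (carries(fB) && carries(mA))
}
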