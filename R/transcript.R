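#' Transcript model in cDNA coordinates
#'
#' A transcript is described by an ordered exon table in 1-based cDNA (c.)
#' coordinates, where c.1 is the first base of the start codon, plus an
#' optional coding sequence and optional intron sequences. Exons must tile
#' the coding sequence contiguously: exon k+1 starts one base after exon k
#' ends, and exon 1 starts at c.1. Intron k is the intron between exon k and
#' exon k+1.
#'
#' @param gene Gene symbol.
#' @param exons Data frame with columns `index`, `c_start`, `c_end`
#'   (1-based inclusive cDNA coordinates).
#' @param cds Coding sequence (single character string, A/C/G/T). When
#'   supplied it must span exactly the exon table (`nchar(cds)` equals the
#'   last `c_end`), be a multiple of 3 long, and end in a stop codon.
#' @param introns Optional named list mapping intron index (as character)
#'   to intron nucleotide sequence. Only introns needed for retention or
#'   cryptic-site simulation have to be present.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene, exons, cds = NULL, introns = NULL) {
  stopifnot(is.character(gene), length(gene) == 1L)
  exons <- as.data.frame(exons)
  stopifnot(all(c("index", "c_start", "c_end") %in% names(exons)))
  exons <- exons[order(exons$index), c("index", "c_start", "c_end")]
  for (col in names(exons)) exons[[col]] <- as.integer(exons[[col]])
  rownames(exons) <- NULL
  if (nrow(exons) == 0L) stop("transcript needs at least one exon")
  if (exons$c_start[1] != 1L)
    stop("first exon must start at c.1")
  if (any(exons$c_end < exons$c_start))
    stop("exon with c_end < c_start")
  if (nrow(exons) > 1L) {
    gaps <- exons$c_start[-1L] - exons$c_end[-nrow(exons)]
    if (any(gaps != 1L))
      stop("exon intervals must be contiguous in cDNA coordinates")
  }
  if (!identical(exons$index, seq_len(nrow(exons))))
    stop("exon indices must be 1..n in order")
  if (!is.null(cds)) {
    cds <- toupper(cds)
    if (grepl("[^ACGT]", cds)) stop("coding sequence contains non-ACGT characters")
    if (nchar(cds) != exons$c_end[nrow(exons)])
      stop("coding sequence length does not match the exon table")
    if (nchar(cds) %% 3L != 0L)
      stop("coding sequence length must be a multiple of 3")
    last_codon <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (!last_codon %in% c("TAA", "TAG", "TGA"))
      stop("coding sequence must end in a stop codon")
  }
  if (!is.null(introns)) {
    introns <- as.list(introns)
    if (is.null(names(introns)) || any(names(introns) == ""))
      stop("introns must be a named list keyed by intron index")
    bad <- !names(introns) %in% as.character(exons$index[-nrow(exons)])
    if (any(bad)) stop("intron index out of range: ", names(introns)[bad][1])
    introns <- lapply(introns, toupper)
  }
  structure(list(gene = gene, exons = exons, cds = cds, introns = introns),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript model for", x$gene, "\n")
  cat("  exons:", nrow(x$exons), " cDNA length:", x$exons$c_end[nrow(x$exons)], "nt\n")
  if (!is.null(x$cds))
    cat("  CDS present (", nchar(x$cds) / 3L - 1L, "codons + stop )\n")
  if (!is.null(x$introns))
    cat("  intron sequences:", paste(names(x$introns), collapse = ", "), "\n")
  invisible(x)
}

#' Residue index of a coding position
#'
#' Codon i spans cDNA positions c.(3i-2)..c.(3i), so the residue affected by
#' an exonic position is `ceiling(position / 3)`.
#'
#' @param c_position 1-based cDNA position within the CDS.
#' @param transcript Optional `transcript_model`; when given, the position is
#'   checked against the CDS length.
#' @return Integer residue index.
#' @export
codon_of <- function(c_position, transcript = NULL) {
  if (!is.numeric(c_position) || any(c_position != floor(c_position)))
    stop("c_position must be an integer cDNA position (intronic offsets have no codon)")
  if (any(c_position < 1L))
    stop("c_position must be >= 1")
  if (!is.null(transcript)) {
    len <- transcript$exons$c_end[nrow(transcript$exons)]
    if (any(c_position > len))
      stop("c_position beyond CDS length (", len, ")")
  }
  as.integer(ceiling(c_position / 3))
}

#' Parse an HGVS c. description
#'
#' Supports the subset of HGVS coding-DNA nomenclature used for small
#' variants: substitutions (`c.76A>C`, `c.700+1G>T`), insertions
#' (`c.2352_2353insC`) and deletions (`c.76_78del`, `c.76delA`). Intronic
#' positions use the `c.N+k` (donor side) / `c.N-k` (acceptor side) offset
#' convention.
#'
#' @param x A single HGVS c. string.
#' @return A list with `type` ("sub", "ins" or "del"), `pos`, `offset`,
#'   `pos2`, `offset2`, `ref`, `alt`, `inserted`, `deleted` (unused slots NA).
#' @export
parse_hgvs_c <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("–|−", "-", x)  # tolerate en-dash / minus glyphs
  res <- list(type = NA_character_, pos = NA_integer_, offset = 0L,
              pos2 = NA_integer_, offset2 = 0L,
              ref = NA_character_, alt = NA_character_,
              inserted = NA_character_, deleted = NA_character_)
  m <- regmatches(s, regexec("^c\\.(\\d+)([+-]\\d+)?([ACGT])>([ACGT])$", s))[[1]]
  if (length(m)) {
    res$type <- "sub"
    res$pos <- as.integer(m[2])
    res$offset <- if (nzchar(m[3])) as.integer(m[3]) else 0L
    res$ref <- m[4]; res$alt <- m[5]
    return(res)
  }
  m <- regmatches(s, regexec("^c\\.(\\d+)_(\\d+)ins([ACGT]+)$", s))[[1]]
  if (length(m)) {
    res$type <- "ins"
    res$pos <- as.integer(m[2]); res$pos2 <- as.integer(m[3])
    res$inserted <- m[4]
    if (res$pos2 != res$pos + 1L)
      stop("insertion positions must be adjacent in ", x)
    return(res)
  }
  m <- regmatches(s, regexec("^c\\.(\\d+)(?:_(\\d+))?del([ACGT]*)$", s))[[1]]
  if (length(m)) {
    res$type <- "del"
    res$pos <- as.integer(m[2])
    res$pos2 <- if (nzchar(m[3])) as.integer(m[3]) else res$pos
    res$deleted <- if (nzchar(m[4])) m[4] else NA_character_
    if (res$pos2 < res$pos) stop("deletion end before start in ", x)
    return(res)
  }
  stop("cannot parse HGVS c. description: '", x,
       "' (failed at '", sub("^c\\.", "", s), "')")
}

#' Identify the splice site disrupted by an intronic variant
#'
#' `c.N+1` / `c.N+2` hit the donor (GT) of the intron following the exon
#' that ends at c.N; `c.N-1` / `c.N-2` hit the acceptor (AG) of the intron
#' preceding the exon that starts at c.N. Larger offsets are resolved the
#' same way (sign decides the side) but only positions at an annotated exon
#' boundary are accepted.
#'
#' @param cdna_change HGVS c. string with an intronic offset.
#' @param transcript A `transcript_model`.
#' @return List with `kind` ("donor" or "acceptor") and `intron_index`
#'   (intron k lies between exon k and exon k+1).
#' @export
site_of_variant <- function(cdna_change, transcript) {
  p <- parse_hgvs_c(cdna_change)
  if (p$offset == 0L)
    stop("'", cdna_change, "' is exonic; splice-site resolution needs a c.N+k or c.N-k position")
  ex <- transcript$exons
  if (p$offset > 0L) {
    i <- ex$index[ex$c_end == p$pos]
    if (length(i) != 1L)
      stop("no exon ends at c.", p$pos, " in ", transcript$gene)
    if (i == nrow(ex)) stop("last exon has no downstream intron")
    list(kind = "donor", intron_index = as.integer(i))
  } else {
    i <- ex$index[ex$c_start == p$pos]
    if (length(i) != 1L)
      stop("no exon starts at c.", p$pos, " in ", transcript$gene)
    if (i == 1L) stop("first exon has no upstream intron")
    list(kind = "acceptor", intron_index = as.integer(i) - 1L)
  }
}

#' Apply a small exonic variant to a transcript's coding sequence
#'
#' Substitutions are checked against the stated reference base;
#' `c.A_BinsX` inserts X between adjacent positions A and B; deletions
#' remove the stated range (and are checked when the deleted bases are
#' spelled out).
#'
#' @param transcript A `transcript_model` with a coding sequence.
#' @param cdna_change HGVS c. string (exonic, no intron offsets).
#' @return The mutant cDNA as a character string.
#' @export
apply_small_variant <- function(transcript, cdna_change) {
  if (is.null(transcript$cds))
    stop("transcript has no coding sequence")
  cds <- transcript$cds
  p <- parse_hgvs_c(cdna_change)
  if (p$offset != 0L || p$offset2 != 0L)
    stop("'", cdna_change, "' is intronic; use splice-event simulation instead")
  n <- nchar(cds)
  if (p$pos > n || (!is.na(p$pos2) && p$pos2 > n + 1L))
    stop("position beyond CDS length in ", cdna_change)
  if (p$type == "sub") {
    have <- substr(cds, p$pos, p$pos)
    if (have != p$ref)
      stop("reference mismatch at c.", p$pos, ": transcript has ", have,
           ", variant states ", p$ref)
    paste0(substr(cds, 1L, p$pos - 1L), p$alt, substr(cds, p$pos + 1L, n))
  } else if (p$type == "ins") {
    paste0(substr(cds, 1L, p$pos), p$inserted, substr(cds, p$pos2, n))
  } else { # del
    if (!is.na(p$deleted)) {
      have <- substr(cds, p$pos, p$pos2)
      if (have != p$deleted)
        stop("reference mismatch for deletion at c.", p$pos, ": transcript has ",
             have, ", variant states ", p$deleted)
    }
    paste0(substr(cds, 1L, p$pos - 1L), substr(cds, p$pos2 + 1L, n))
  }
}

#' Apply an intronic single-base substitution to a stored intron sequence
#'
#' Used to model splice-site point mutations (e.g. a +1 G>T donor change)
#' before simulating aberrant splicing: the retained intronic segment of a
#' cryptic-site or retention event must carry the mutation.
#'
#' @param transcript A `transcript_model` carrying the relevant intron.
#' @param cdna_change HGVS c. string with intron offset (e.g. "c.700+1G>T").
#' @return A `transcript_model` with the intron base substituted.
#' @export
apply_intronic_variant <- function(transcript, cdna_change) {
  p <- parse_hgvs_c(cdna_change)
  if (p$type != "sub" || p$offset == 0L)
    stop("expected an intronic substitution, got '", cdna_change, "'")
  site <- site_of_variant(cdna_change, transcript)
  key <- as.character(site$intron_index)
  if (is.null(transcript$introns[[key]]))
    stop("no sequence stored for intron ", key, " of ", transcript$gene)
  intron <- transcript$introns[[key]]
  ipos <- if (p$offset > 0L) p$offset else nchar(intron) + p$offset + 1L
  if (ipos < 1L || ipos > nchar(intron))
    stop("offset ", p$offset, " outside intron ", key)
  have <- substr(intron, ipos, ipos)
  if (have != p$ref)
    stop("reference mismatch in intron ", key, " at offset ", p$offset,
         ": intron has ", have, ", variant states ", p$ref)
  substr(intron, ipos, ipos) <- p$alt
  transcript$introns[[key]] <- intron
  transcript
}

#' Packaged synthetic transcript fixture for the CPAMD8 worked examples
#'
#' Loads a synthetic reconstruction of the CPAMD8-1a coding transcript
#' (42 exons, 1932 residues). Exon boundaries relevant to the published
#' splice-site mutations are anchored to their printed HGVS coordinates
#' (exon 7 ends at c.700, exon 29 = c.3928..c.4002, exon 33 = c.4393..c.4548,
#' exon 34 = c.4549..c.4611); the base-level sequence is synthetic, built
#' so that every documented variant and aberrant splicing event reproduces
#' its published protein-level consequence. Intron 7 (160 nt, with the
#' cryptic donor at +142) and intron 33 (78 nt, stop-free in the retained
#' frame) are included.
#'
#' @return A `transcript_model`.
#' @export
cpamd8_transcript <- function() {
  path <- system.file("extdata", "cpamd8_1a_synthetic.json",
                      package = "varcascade", mustWork = TRUE)
  read_transcript_json(path)
}

#' Read a transcript model from JSON
#'
#' The JSON layout mirrors `transcript_model`: fields `gene`, `exons`
#' (array of objects with `index`, `c_start`, `c_end`), optional `cds`
#' string and optional `introns` object keyed by intron index.
#'
#' @param path Path to a JSON file.
#' @return A `transcript_model`.
#' @export
read_transcript_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  introns <- if (!is.null(x$introns)) as.list(x$introns) else NULL
  transcript_model(gene = x$gene, exons = as.data.frame(x$exons),
                   cds = x$cds, introns = introns)
}

#' Write a transcript model to JSON
#' @param transcript A `transcript_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_json <- function(transcript, path) {
  x <- list(gene = transcript$gene, exons = transcript$exons)
  if (!is.null(transcript$cds)) x$cds <- transcript$cds
  if (!is.null(transcript$introns)) x$introns <- transcript$introns
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
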