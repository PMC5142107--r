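GT_CODES <- c("hom_ref", "het", "hom_alt", "hemi", "missing")
FREQ_SOURCES <- c("thousand_genomes", "evs", "exac", "internal")
# panel sizes used when a source has no entry for a variant (absence = 0 count)
DEFAULT_AN <- c(thousand_genomes = 5008L, evs = 12000L, exac = 120000L,
                internal = 1980L)

freq_cols <- function() {
  as.vector(t(outer(FREQ_SOURCES, c("ac", "an", "hom"),
                    function(s, f) paste0(f, "_", s))))
}

#' A population frequency record for one variant in one database
#'
#' @param source One of "thousand_genomes", "evs", "exac", "internal".
#' @param alt_allele_count Non-negative alternate allele count.
#' @param total_alleles Positive total genotyped alleles.
#' @param homozygote_count Non-negative count of homozygous carriers.
#' @return A `frequency_record`.
#' @export
frequency_record <- function(source, alt_allele_count, total_alleles,
                             homozygote_count = 0L) {
  source <- match.arg(source, FREQ_SOURCES)
  ac <- as.integer(alt_allele_count)
  an <- as.integer(total_alleles)
  hom <- as.integer(homozygote_count)
  if (ac < 0L) stop("alt_allele_count must be non-negative")
  if (an <= 0L) stop("total_alleles must be positive")
  if (ac > an) stop("alt_allele_count exceeds total_alleles")
  if (2L * hom > ac) stop("2 * homozygote_count exceeds alt_allele_count")
  structure(list(source = source, alt_allele_count = ac, total_alleles = an,
                 homozygote_count = hom), class = "frequency_record")
}

#' A set of annotated variants with per-sample genotypes
#'
#' The container used throughout the filtering cascade: a variant table
#' (one row per biallelic chrom/pos/ref/alt) and a genotype matrix coded
#' as "hom_ref", "het", "hom_alt", "hemi" or "missing".
#'
#' @param variants Data frame with at least `chrom`, `pos`, `ref`, `alt`;
#'   annotation columns (`gene`, `cdna_change`, `consequence_class`,
#'   `sift`, `polyphen`, `phylop`) and per-source frequency count columns
#'   (`ac_<source>`, `an_<source>`, `hom_<source>`) are filled with
#'   defaults when absent (absence from a source means a zero count).
#' @param genotypes Character matrix, rows matching `variants`, one column
#'   per sample.
#' @return A `variant_set`.
#' @export
variant_set <- function(variants, genotypes) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ")
  for (col in c("gene", "cdna_change"))
    if (is.null(variants[[col]])) variants[[col]] <- NA_character_
  if (is.null(variants$consequence_class))
    variants$consequence_class <- "other"
  for (col in c("sift", "polyphen", "phylop"))
    if (is.null(variants[[col]])) variants[[col]] <- NA_real_
  for (s in FREQ_SOURCES) {
    ac <- paste0("ac_", s); an <- paste0("an_", s); hom <- paste0("hom_", s)
    if (is.null(variants[[ac]])) variants[[ac]] <- 0L
    if (is.null(variants[[an]])) variants[[an]] <- DEFAULT_AN[[s]]
    if (is.null(variants[[hom]])) variants[[hom]] <- 0L
    if (any(variants[[ac]] > variants[[an]]))
      stop("alt allele count exceeds total alleles for source ", s)
    if (any(2L * variants[[hom]] > variants[[ac]]))
      stop("homozygote count inconsistent with allele count for source ", s)
  }
  variants$key <- variant_key(variants)
  if (anyDuplicated(variants$key))
    stop("duplicate variant keys: ", variants$key[duplicated(variants$key)][1])
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != nrow(variants))
    stop("genotype matrix rows must match the variant table")
  if (!all(genotypes %in% GT_CODES))
    stop("invalid genotype code: ",
         paste(setdiff(unique(as.vector(genotypes)), GT_CODES), collapse = ","))
  hemi_rows <- which(apply(genotypes == "hemi", 1L, any))
  bad <- hemi_rows[!variants$chrom[hemi_rows] %in% c("X", "chrX", "Y", "chrY")]
  if (length(bad))
    stop("hemizygous genotype on autosome at ", variants$key[bad[1]])
  rownames(genotypes) <- variants$key
  structure(list(variants = variants, genotypes = genotypes),
            class = "variant_set")
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants x",
      ncol(x$genotypes), "samples\n")
  invisible(x)
}

n_variants <- function(vs) nrow(vs$variants)

subset_variants <- function(vs, idx) {
  variants <- vs$variants[idx, , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(variants = variants,
                 genotypes = vs$genotypes[idx, , drop = FALSE]),
            class = "variant_set")
}

#' Minimal-representation normalization of an indel
#'
#' Trims shared trailing bases, then shared leading bases (keeping at least
#' one base on each allele and advancing the position), so that equivalent
#' VCF paddings of the same indel key identically against an annotation
#' table.
#'
#' @param pos 1-based position.
#' @param ref,alt Allele strings.
#' @return List with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

parse_gt_string <- function(gt, alt_index) {
  # GT subfield only; "|" treated as unphased
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return("missing")
  cnt <- sum(alleles == as.character(alt_index))
  if (length(alleles) == 1L) {
    if (cnt == 1L) "hemi" else "hom_ref"
  } else {
    c("hom_ref", "het", "hom_alt")[cnt + 1L]
  }
}

#' Read a multi-sample VCF into a variant set
#'
#' Parses the GT subfield for every sample, decomposes multi-allelic sites
#' into one record per alternate allele, normalizes indel representation,
#' and attaches annotations (gene, consequence class, per-source frequency
#' counts, in-silico scores) from a tab-separated table keyed by
#' chrom/pos/ref/alt. Variants missing from the annotation table trigger a
#' warning and are kept unannotated, with zero frequency counts.
#'
#' @param path VCF file (plain or gzipped).
#' @param annotation_table Optional path to the annotation TSV (columns
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `cdna_change`,
#'   `consequence_class`, `ac_*`/`an_*`/`hom_*` per source, `sift`,
#'   `polyphen`, `phylop`).
#' @return A `variant_set`.
#' @export
read_vcf <- function(path, annotation_table = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no genotype (GT) columns")
  samples <- colnames(gt)[-1L]
  fmt <- gt[, 1L]
  gt_idx <- vapply(strsplit(fmt, ":"), function(f) {
    i <- which(f == "GT")
    if (!length(i)) stop("VCF record without GT in FORMAT")
    i[1]
  }, integer(1))
  gt_str <- gt[, -1L, drop = FALSE]
  rows <- list(); geno <- list(); k <- 0L
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    cells <- vapply(gt_str[r, ], function(cell) {
      if (is.na(cell)) return(NA_character_)
      strsplit(cell, ":")[[1]][gt_idx[r]]
    }, character(1))
    for (a in seq_along(alts)) {
      norm <- normalize_variant(as.integer(fix[r, "POS"]), fix[r, "REF"], alts[a])
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = fix[r, "CHROM"], pos = norm$pos,
                              ref = norm$ref, alt = norm$alt,
                              stringsAsFactors = FALSE)
      geno[[k]] <- vapply(cells, parse_gt_string, character(1), alt_index = a)
    }
  }
  variants <- do.call(rbind, rows)
  genotypes <- do.call(rbind, geno)
  colnames(genotypes) <- samples
  if (!is.null(annotation_table)) {
    ann <- read_annotations(annotation_table)
    key <- variant_key(variants)
    m <- match(key, ann$key)
    if (anyNA(m))
      warning(sum(is.na(m)), " variant(s) missing from the annotation table; ",
              "kept unannotated (e.g. ", key[is.na(m)][1], ")")
    for (col in setdiff(names(ann), c("chrom", "pos", "ref", "alt", "key"))) {
      variants[[col]] <- ann[[col]][m]
      if (grepl("^(ac|hom)_", col)) variants[[col]][is.na(m)] <- 0L
      if (grepl("^an_", col))
        variants[[col]][is.na(m)] <- DEFAULT_AN[[sub("^an_", "", col)]]
    }
  }
  variant_set(variants, genotypes)
}

#' Read a variant annotation table
#' @param path TSV path.
#' @return Data frame with a `key` column added.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(ann)))
  norm <- Map(normalize_variant, ann$pos, ann$ref, ann$alt)
  ann$pos <- vapply(norm, `[[`, integer(1), "pos")
  ann$ref <- vapply(norm, `[[`, character(1), "ref")
  ann$alt <- vapply(norm, `[[`, character(1), "alt")
  ann$key <- variant_key(ann)
  ann
}

gt_to_vcf_string <- function(code) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", hemi = "1",
    missing = "./.")[code]
}

#' Write a variant set as a minimal VCF 4.2 file
#'
#' Biallelic records, GT-only FORMAT. Output order is the row order of the
#' variant table, so writing is deterministic.
#'
#' @param vs A `variant_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  v <- vs$variants
  gts <- apply(vs$genotypes, 2L, gt_to_vcf_string)
  if (is.null(dim(gts))) gts <- matrix(gts, nrow = 1L)
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=varcascade",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(vs$genotypes)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the annotation table for a variant set
#' @param vs A `variant_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(vs, path) {
  cols <- c("chrom", "pos", "ref", "alt", "gene", "cdna_change",
            "consequence_class", freq_cols(), "sift", "polyphen", "phylop")
  df <- vs$variants[, cols]
  for (col in c("sift", "polyphen", "phylop"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", sprintf("%.4f", df[[col]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 6-column PED pedigree file
#'
#' Whitespace-delimited: family, individual, father, mother, sex (1 male /
#' 2 female / other unknown), phenotype (2 affected / 1 unaffected / other
#' unknown). "0" marks a founder. A parent id that does not exist as an
#' individual row in the same family is replaced by the founder marker and
#' recorded in the `founder_substitutions` attribute. Cyclic parentage is
#' a hard error.
#'
#' @param path PED file path.
#' @return Data frame of class `pedigree` with columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id`, `sex`, `affected`.
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    ped <- data.frame(family_id = character(0), individual_id = character(0),
                      father_id = character(0), mother_id = character(0),
                      sex = character(0), affected = logical(0),
                      stringsAsFactors = FALSE)
    class(ped) <- c("pedigree", "data.frame")
    return(ped)
  }
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 6L)) stop("PED rows must have 6 columns")
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  ped <- data.frame(family_id = m[, 1], individual_id = m[, 2],
                    father_id = m[, 3], mother_id = m[, 4],
                    sex = c("male", "female")[match(m[, 5], c("1", "2"))],
                    affected = c(FALSE, TRUE)[match(m[, 6], c("1", "2"))],
                    stringsAsFactors = FALSE)
  ped$sex[is.na(ped$sex)] <- "unknown"
  subs <- character(0)
  for (r in seq_len(nrow(ped))) {
    fam_ids <- ped$individual_id[ped$family_id == ped$family_id[r]]
    for (col in c("father_id", "mother_id")) {
      p <- ped[[col]][r]
      if (p != "0" && !p %in% fam_ids) {
        subs <- c(subs, sprintf("%s/%s: %s -> founder", ped$family_id[r],
                                ped$individual_id[r], p))
        ped[[col]][r] <- "0"
      }
    }
  }
  check_pedigree_cycles(ped)
  class(ped) <- c("pedigree", "data.frame")
  attr(ped, "founder_substitutions") <- subs
  ped
}

check_pedigree_cycles <- function(ped) {
  for (fam in unique(ped$family_id)) {
    sub <- ped[ped$family_id == fam, ]
    parents <- function(id) {
      r <- sub[sub$individual_id == id, ]
      setdiff(c(r$father_id, r$mother_id), "0")
    }
    for (id in sub$individual_id) {
      stack <- parents(id)
      seen <- character(0)
      while (length(stack)) {
        cur <- stack[1]; stack <- stack[-1]
        if (cur == id)
          stop("cyclic parentage involving ", id, " in family ", fam)
        if (cur %in% seen) next
        seen <- c(seen, cur)
        stack <- c(stack, parents(cur))
      }
    }
  }
  invisible(TRUE)
}

#' Write a pedigree as a 6-column PED file
#' @param ped A `pedigree` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  sex <- match(ped$sex, c("male", "female"))
  sex[is.na(sex)] <- 0L
  phe <- ifelse(is.na(ped$affected), 0L, ifelse(ped$affected, 2L, 1L))
  writeLines(paste(ped$family_id, ped$individual_id, ped$father_id,
                   ped$mother_id, sex, phe, sep = "\t"), path)
  invisible(path)
}

#' Write the candidate report and filter trace
#'
#' The report is a TSV with one row per qualifying variant per family; the
#' trace is a JSON file with one entry per cascade step (label, input and
#' retained counts).
#'
#' @param candidates Data frame of candidate rows (as in
#'   `cascade_result$candidates`); may have zero rows.
#' @param trace A `filter_trace`.
#' @param path Output TSV path for the report.
#' @param trace_path Output path for the JSON trace (default: `path` with a
#'   `.trace.json` suffix).
#' @return `path`, invisibly.
#' @export
write_report <- function(candidates, trace, path,
                         trace_path = paste0(path, ".trace.json")) {
  cols <- c("family", "gene", "model", "key", "cdna_change", "zygosity")
  df <- as.data.frame(candidates, stringsAsFactors = FALSE)
  for (col in setdiff(cols, names(df))) df[[col]] <- character(0)
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  steps <- lapply(seq_len(nrow(trace$steps)), function(i)
    list(step = trace$steps$step[i], label = trace$steps$label[i],
         n_input = trace$steps$n_input[i],
         n_retained = trace$steps$n_retained[i]))
  jsonlite::write_json(list(steps = steps), trace_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
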