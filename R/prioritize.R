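#' Start an empty filter trace
#'
#' A filter trace records, for each cascade step, the step label, input
#' count, retained count and retained variant keys; retained sets are
#' always subsets of their inputs.
#'
#' @return A `filter_trace`.
#' @export
new_trace <- function() {
  structure(list(steps = data.frame(step = integer(0), label = character(0),
                                    n_input = integer(0), n_retained = integer(0),
                                    stringsAsFactors = FALSE),
                 retained = list()),
            class = "filter_trace")
}

add_trace_step <- function(trace, label, input_keys, retained_keys) {
  if (!all(retained_keys %in% input_keys))
    stop("trace step '", label, "' retains keys not present in its input")
  i <- nrow(trace$steps) + 1L
  trace$steps[i, ] <- list(i, label, length(input_keys), length(retained_keys))
  trace$retained[[i]] <- retained_keys
  trace
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("Filter trace:\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

# continued-fraction rationalization so threshold comparisons are exact
# integer arithmetic (e.g. 0.005 -> 1/200, and 21/11520 vs 1/200 is decided
# by 21*200 <=> 11520)
rationalize <- function(x, max_denominator = 1e6) {
  stopifnot(x >= 0)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_denominator) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < .Machine$double.eps * max(1, x)) break
    if (r == a) break
    r <- 1 / (r - a)
  }
  c(num = p1, den = q1)
}

#' Allele frequency of a population frequency record
#'
#' @param rec A `frequency_record`, or an alt allele count (with `an`).
#' @param an Total alleles when `rec` is given as a count.
#' @return The allele frequency as a numeric fraction.
#' @export
allele_frequency <- function(rec, an = NULL) {
  if (inherits(rec, "frequency_record")) {
    ac <- rec$alt_allele_count; an <- rec$total_alleles
  } else {
    ac <- rec
    if (is.null(an)) stop("total allele count required")
  }
  if (any(an <= 0)) stop("total_alleles must be positive")
  ac / an
}

max_allele_frequency <- function(vs) {
  v <- vs$variants
  af <- rep(0, nrow(v))
  for (s in FREQ_SOURCES)
    af <- pmax(af, v[[paste0("ac_", s)]] / v[[paste0("an_", s)]])
  af
}

#' Step 1: retain rare variants
#'
#' A variant is retained iff its allele frequency is at or below the
#' threshold in every population source (equivalently, the maximum
#' frequency across sources is <= threshold; a variant common in any one
#' database is filtered). The boundary is inclusive: MAF equal to the
#' threshold is kept. Absence from a source counts as frequency zero.
#' Comparisons are exact rational arithmetic on the stored counts.
#'
#' @param vs A `variant_set`.
#' @param threshold Minor allele frequency threshold (default 0.005).
#' @param trace Optional `filter_trace` to append to.
#' @return List with `variants` (the retained `variant_set`) and `trace`.
#' @export
filter_rare <- function(vs, threshold = 0.005, trace = new_trace()) {
  v <- vs$variants
  frac <- rationalize(threshold)
  keep <- rep(TRUE, nrow(v))
  for (s in FREQ_SOURCES) {
    ac <- v[[paste0("ac_", s)]]; an <- v[[paste0("an_", s)]]
    keep <- keep & (ac * frac["den"] <= frac["num"] * an)
  }
  out <- subset_variants(vs, keep)
  trace <- add_trace_step(trace, sprintf("rare_filter_maf_%g", threshold),
                          v$key, out$variants$key)
  list(variants = out, trace = trace)
}

#' Flag variants with population homozygotes
#'
#' Under a recessive model, a causal variant is not expected to occur in
#' the homozygous state in population databases. This screen annotates
#' (never removes) variants whose homozygote count is positive in any
#' source.
#'
#' @param vs A `variant_set`.
#' @return `vs` with a logical `pop_homozygote` column added; the flagged
#'   subset is in the `flagged` attribute (variant keys).
#' @export
homozygote_screen <- function(vs) {
  v <- vs$variants
  flag <- rep(FALSE, nrow(v))
  for (s in FREQ_SOURCES)
    flag <- flag | (v[[paste0("hom_", s)]] > 0L)
  vs$variants$pop_homozygote <- flag
  attr(vs, "flagged") <- v$key[flag]
  vs
}

#' Partition a proband's variants by zygosity
#'
#' @param vs A `variant_set`.
#' @param proband Sample id present in the genotype matrix.
#' @return List of key vectors: `hom_alt`, `het`, `hemi` — a disjoint
#'   partition of the variants at which the proband is non-reference.
#' @export
partition_zygosity <- function(vs, proband) {
  if (!proband %in% colnames(vs$genotypes))
    stop("proband ", proband, " not in the genotype matrix")
  g <- vs$genotypes[, proband]
  keys <- vs$variants$key
  list(hom_alt = keys[g == "hom_alt"],
       het = keys[g == "het"],
       hemi = keys[g == "hemi"])
}

#' Default list of genes previously associated with anterior segment dysgenesis
#' @return Character vector of gene symbols.
#' @export
asd_known_genes <- function() {
  path <- system.file("extdata", "asd_known_genes.txt", package = "varcascade",
                      mustWork = TRUE)
  read_gene_list(path)
}

#' Read a one-symbol-per-line gene list
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Cross-reference retained variants with known disease genes
#'
#' @param vs A `variant_set` (typically the rare-filtered set).
#' @param known_genes Character vector of gene symbols.
#' @return A `variant_set` restricted to variants in known genes (possibly
#'   empty).
#' @export
known_gene_crossref <- function(vs, known_genes) {
  subset_variants(vs, !is.na(vs$variants$gene) &
                    vs$variants$gene %in% known_genes)
}

is_x_chrom <- function(chrom) chrom %in% c("X", "chrX", "x")

#' Step 2: X-linked candidate screen for a male proband
#'
#' Returns rare hemizygous X-chromosome variants carried by the proband,
#' with their pathogenicity annotations, for manual review. Applied to a
#' female proband it returns an empty set with a warning.
#'
#' @param vs Rare-filtered `variant_set`.
#' @param proband Sample id.
#' @param pedigree A `pedigree` (for the proband's sex).
#' @return A `variant_set` of candidates.
#' @export
xlinked_step <- function(vs, proband, pedigree) {
  sex <- pedigree$sex[pedigree$individual_id == proband]
  if (!length(sex)) stop("proband ", proband, " not in pedigree")
  if (sex != "male") {
    warning("X-linked hemizygous screen is only meaningful for a male proband")
    return(subset_variants(vs, rep(FALSE, n_variants(vs))))
  }
  g <- vs$genotypes[, proband]
  subset_variants(vs, is_x_chrom(vs$variants$chrom) & g %in% c("hemi", "hom_alt"))
}

#' Step 3: autosomal recessive candidate genes for one family
#'
#' Reports genes compatible with a recessive model in the proband: genes
#' with at least one homozygous-alternate rare variant (model
#' "homozygous") and genes with at least two distinct rare heterozygous
#' variants (model "potential_compound_het"). The X chromosome is
#' excluded (it is handled by the hemizygous screen).
#'
#' @param vs Rare-filtered `variant_set`.
#' @param proband Sample id.
#' @param family Family label for the report.
#' @return A `candidate_report`: data frame with columns `family`, `gene`,
#'   `model`, `n_variants` and a `keys` list-column.
#' @export
recessive_step <- function(vs, proband, family = proband) {
  parts <- partition_zygosity(vs, proband)
  v <- vs$variants
  auto <- !is_x_chrom(v$chrom)
  gene_of <- function(keys) v$gene[match(keys, v$key)]
  hom_keys <- parts$hom_alt[auto[match(parts$hom_alt, v$key)]]
  het_keys <- parts$het[auto[match(parts$het, v$key)]]
  hom_keys <- hom_keys[!is.na(gene_of(hom_keys))]
  het_keys <- het_keys[!is.na(gene_of(het_keys))]
  rows <- list()
  for (g in unique(gene_of(hom_keys))) {
    k <- hom_keys[gene_of(hom_keys) == g]
    rows[[length(rows) + 1L]] <-
      data.frame(family = family, gene = g, model = "homozygous",
                 n_variants = length(k), stringsAsFactors = FALSE)
    rows[[length(rows)]]$keys <- list(k)
  }
  het_by_gene <- split(het_keys, gene_of(het_keys))
  for (g in names(het_by_gene)) {
    k <- unique(het_by_gene[[g]])
    if (length(k) >= 2L) {
      rows[[length(rows) + 1L]] <-
        data.frame(family = family, gene = g, model = "potential_compound_het",
                   n_variants = length(k), stringsAsFactors = FALSE)
      rows[[length(rows)]]$keys <- list(k)
    }
  }
  rep_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), gene = character(0), model = character(0),
               n_variants = integer(0), keys = I(list()), stringsAsFactors = FALSE)
  class(rep_df) <- c("candidate_report", "data.frame")
  rep_df
}

#' Step 4: genes shared by all family reports
#'
#' @param reports List of per-family `candidate_report`s.
#' @return Character vector of genes that qualify (under any recessive
#'   model) in every family. A single-family input is returned as-is with
#'   a warning.
#' @export
intersect_step <- function(reports) {
  gene_sets <- lapply(reports, function(r) unique(r$gene))
  if (length(gene_sets) < 2L) {
    warning("intersection over a single family returns its gene set unchanged")
    return(gene_sets[[1]])
  }
  Reduce(intersect, gene_sets)
}

#' Singleton-heterozygote fallback when no gene is shared by all families
#'
#' When the full intersection is empty (or the shared genes are all
#' demoted as implausible), genes qualifying in all but one family are
#' re-ranked, and for the family that lacks a qualifying configuration the
#' gene's rare singleton heterozygous variants are listed. This
#' formalizes the manual re-analysis of rare heterozygous variants that
#' recovers a second allele hidden by, for example, missing exome
#' coverage.
#'
#' @param reports List of per-family `candidate_report`s (named by family).
#' @param rare_vs Rare-filtered `variant_set`.
#' @param probands Named character vector family -> proband sample id.
#' @return Data frame: `gene`, `missing_family`, `n_singleton_hets`,
#'   `singleton_keys` (list-column), ranked by singleton support.
#' @export
singleton_het_fallback <- function(reports, rare_vs, probands) {
  fams <- names(reports)
  rows <- list()
  for (miss in fams) {
    others <- setdiff(fams, miss)
    shared <- Reduce(intersect, lapply(reports[others], function(r) unique(r$gene)))
    if (!length(shared)) next
    parts <- partition_zygosity(rare_vs, probands[[miss]])
    v <- rare_vs$variants
    het_genes <- v$gene[match(parts$het, v$key)]
    for (g in shared) {
      k <- parts$het[!is.na(het_genes) & het_genes == g]
      rows[[length(rows) + 1L]] <- {
        df <- data.frame(gene = g, missing_family = miss,
                         n_singleton_hets = length(k), stringsAsFactors = FALSE)
        df$singleton_keys <- list(k)
        df
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), missing_family = character(0),
               n_singleton_hets = integer(0), singleton_keys = I(list()),
               stringsAsFactors = FALSE)
  out[order(-out$n_singleton_hets), , drop = FALSE]
}

#' Rank candidate variants by in-silico pathogenicity support
#'
#' Predictions are supporting evidence, never a hard filter: each variant
#' gets a support score counting, where available, SIFT < 0.05 (damaging),
#' PolyPhen-2 >= 0.85 (probably damaging) and PhyloP > 0.95 (conserved).
#' Protein-truncating and splice-site classes score full support.
#'
#' @param vs A `variant_set`.
#' @param sift_damaging,polyphen_damaging,phylop_conserved Thresholds.
#' @return `vs` with an `insilico_support` column (0-3).
#' @export
insilico_rank <- function(vs, sift_damaging = 0.05, polyphen_damaging = 0.85,
                          phylop_conserved = 0.95) {
  v <- vs$variants
  score <- ifelse(!is.na(v$sift) & v$sift < sift_damaging, 1L, 0L) +
    ifelse(!is.na(v$polyphen) & v$polyphen >= polyphen_damaging, 1L, 0L) +
    ifelse(!is.na(v$phylop) & v$phylop > phylop_conserved, 1L, 0L)
  lof <- v$consequence_class %in% c("frameshift", "splice_site")
  score[lof] <- 3L
  vs$variants$insilico_support <- score
  vs
}

#' Coding exons of a candidate gene without exome coverage
#'
#' Projects the transcript's exons into genomic space (via the layout
#' stored in the mask) and reports every coding exon with zero overlap
#' against the sample's covered intervals — the exons that need targeted
#' (e.g. Sanger) follow-up.
#'
#' @param gene Gene symbol.
#' @param transcript The gene's `transcript_model`.
#' @param mask A `coverage_mask` (see [mask_coverage()]).
#' @param sample Sample id.
#' @return Integer vector of uncovered coding exon indices.
#' @export
coverage_gap_report <- function(gene, transcript, mask, sample) {
  if (is.null(transcript)) stop("no transcript model available for ", gene)
  if (!identical(mask$gene, gene))
    stop("coverage mask is for ", mask$gene, ", not ", gene)
  cov <- mask$covered[[sample]]
  if (is.null(cov)) cov <- data.frame(start = numeric(0), end = numeric(0))
  ex <- exon_genomic_intervals(transcript, mask$layout)
  uncovered <- integer(0)
  for (i in seq_len(nrow(ex))) {
    # genomic intervals are 0-based half-open
    overlaps <- any(cov$start < ex$end[i] & cov$end > ex$start[i])
    if (!overlaps) uncovered <- c(uncovered, ex$index[i])
  }
  uncovered
}

# project cDNA exons to 0-based half-open genomic intervals under the
# fixed-intron synthetic layout
exon_genomic_intervals <- function(transcript, layout) {
  ex <- transcript$exons
  start <- layout$gene_start + (ex$c_start - 1L) + (ex$index - 1L) * layout$intron_len
  data.frame(index = ex$index, start = start,
             end = start + (ex$c_end - ex$c_start + 1L))
}
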