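#' Run the full four-step variant prioritization cascade
#'
#' Step 1 retains rare variants (MAF at or below `maf_threshold` in every
#' population source), segregates them by proband zygosity and
#' cross-references known disease genes. Step 2 screens rare hemizygous
#' X-chromosome variants in male probands. Step 3 selects autosomal
#' recessive candidate genes per family (homozygous, or at least two
#' distinct heterozygous variants). Step 4 intersects candidate genes
#' across families. If the intersection is empty, genes qualifying in all
#' but one family are re-ranked by that family's rare singleton
#' heterozygous variants (the re-analysis that recovers an allele hidden
#' by a coverage gap); supplying a targeted-sequencing `rescue` table
#' merges recovered genotypes before step 3 instead.
#'
#' @param vs A `variant_set` for the whole cohort.
#' @param pedigree A `pedigree`; the proband of each family is its first
#'   affected member.
#' @param known_genes Known disease-gene symbols (default the packaged
#'   anterior-segment-dysgenesis list).
#' @param maf_threshold Rare-variant threshold (default 0.005, inclusive).
#' @param rescue Optional data frame (`key`, `sample`, `genotype`) of
#'   genotypes recovered by targeted sequencing.
#' @param transcript,coverage Optional transcript model and coverage masks
#'   (named by sample) for coverage-gap reporting on candidate genes.
#' @return A `cascade_result`: list with `trace` (4-step `filter_trace`),
#'   `rare` (the rare `variant_set`), `known_gene_hits`, `xlinked`,
#'   `reports` (per family), `shared_genes`, `fallback`, `candidates`
#'   (flat per-variant data frame), `coverage_gaps`, `probands`.
#' @export
run_cascade <- function(vs, pedigree, known_genes = asd_known_genes(),
                        maf_threshold = 0.005, rescue = NULL,
                        transcript = NULL, coverage = NULL) {
  fams <- unique(pedigree$family_id)
  probands <- stats::setNames(vapply(fams, function(f) {
    m <- pedigree[pedigree$family_id == f, ]
    p <- m$individual_id[which(m$affected)]
    if (!length(p)) stop("family ", f, " has no affected member")
    p[1]
  }, character(1)), fams)

  # step 1: rare filter + zygosity segregation + known-gene cross-reference
  st1 <- filter_rare(vs, threshold = maf_threshold)
  rare <- homozygote_screen(st1$variants)
  trace <- st1$trace
  known_hits <- known_gene_crossref(rare, known_genes)

  # step 2: X-linked hemizygous screen (male probands)
  xlinked <- list()
  x_keys <- character(0)
  for (f in fams) {
    sex <- pedigree$sex[pedigree$individual_id == probands[[f]]]
    if (identical(sex, "male")) {
      xlinked[[f]] <- xlinked_step(rare, probands[[f]], pedigree)
      x_keys <- union(x_keys, xlinked[[f]]$variants$key)
    }
  }
  trace <- add_trace_step(trace, "xlinked_hemizygous", rare$variants$key, x_keys)

  # targeted-sequencing rescue merges before the recessive step
  if (!is.null(rescue) && nrow(rescue)) rare <- apply_rescue(rare, rescue)

  # step 3: per-family autosomal recessive candidates
  reports <- lapply(fams, function(f) recessive_step(rare, probands[[f]], f))
  names(reports) <- fams
  step3_keys <- unique(unlist(lapply(reports, function(r) unlist(r$keys))))
  trace <- add_trace_step(trace, "recessive_candidates", rare$variants$key,
                          step3_keys)

  # step 4: genes shared by all families
  shared <- if (length(fams) >= 2L) intersect_step(reports) else
    unique(reports[[1]]$gene)
  fallback <- NULL
  if (!length(shared) && length(fams) >= 2L)
    fallback <- singleton_het_fallback(reports, rare, probands)
  shared_keys <- unlist(lapply(reports, function(r)
    unlist(r$keys[r$gene %in% shared])))
  if (!is.null(fallback) && nrow(fallback))
    shared_keys <- c(shared_keys, unlist(fallback$singleton_keys))
  trace <- add_trace_step(trace, "cross_family_intersection", step3_keys,
                          unique(intersect(shared_keys, step3_keys)))

  candidate_genes <- if (length(shared)) shared else
    unique(fallback$gene[fallback$n_singleton_hets > 0])

  # flat candidate table for reporting
  cand_rows <- list()
  v <- rare$variants
  for (f in fams) {
    r <- reports[[f]]
    for (i in which(r$gene %in% candidate_genes)) {
      keys <- r$keys[[i]]
      m <- match(keys, v$key)
      cand_rows[[length(cand_rows) + 1L]] <-
        data.frame(family = f, gene = r$gene[i], model = r$model[i],
                   key = keys, cdna_change = v$cdna_change[m],
                   zygosity = rare$genotypes[keys, probands[[f]]],
                   stringsAsFactors = FALSE)
    }
  }
  if (!is.null(fallback)) {
    for (i in which(fallback$n_singleton_hets > 0)) {
      keys <- fallback$singleton_keys[[i]]
      m <- match(keys, v$key)
      cand_rows[[length(cand_rows) + 1L]] <-
        data.frame(family = fallback$missing_family[i], gene = fallback$gene[i],
                   model = "singleton_het", key = keys,
                   cdna_change = v$cdna_change[m],
                   zygosity = rare$genotypes[keys,
                                             probands[[fallback$missing_family[i]]]],
                   stringsAsFactors = FALSE)
    }
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(family = character(0), gene = character(0), model = character(0),
               key = character(0), cdna_change = character(0),
               zygosity = character(0), stringsAsFactors = FALSE)

  # coverage-gap follow-up for candidate genes
  gaps <- list()
  if (!is.null(transcript) && !is.null(coverage)) {
    for (sample in names(coverage)) {
      mask <- coverage[[sample]]
      if (mask$gene %in% candidate_genes)
        gaps[[sample]] <- coverage_gap_report(mask$gene, transcript, mask, sample)
    }
  }

  structure(list(trace = trace, rare = rare, known_gene_hits = known_hits,
                 xlinked = xlinked, reports = reports, shared_genes = shared,
                 fallback = fallback, candidates = candidates,
                 coverage_gaps = gaps, probands = probands),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Variant prioritization cascade\n")
  print(x$trace$steps, row.names = FALSE)
  if (nrow(x$known_gene_hits$variants))
    cat("rare variants in known disease genes:",
        nrow(x$known_gene_hits$variants), "\n")
  else cat("no rare variants in known disease genes\n")
  for (f in names(x$xlinked))
    cat("X-linked hemizygous candidates (", f, "): ",
        nrow(x$xlinked[[f]]$variants), "\n", sep = "")
  if (length(x$shared_genes)) {
    cat("gene(s) shared by all families:",
        paste(x$shared_genes, collapse = ", "), "\n")
  } else if (!is.null(x$fallback) && nrow(x$fallback)) {
    cat("no gene shared by all families; singleton-het fallback:\n")
    print(x$fallback[, c("gene", "missing_family", "n_singleton_hets")],
          row.names = FALSE)
  } else {
    cat("no candidate gene identified\n")
  }
  if (nrow(x$candidates)) {
    cat("candidate variants:\n")
    print(x$candidates, row.names = FALSE)
  }
  for (sample in names(x$coverage_gaps))
    cat("uncovered coding exons in ", sample, ": ",
        paste(x$coverage_gaps[[sample]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
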