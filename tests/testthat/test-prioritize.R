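# small in-memory cohort shared across the filtering tests
small_cohort <- generate_cohort(
  scenarios = paper_scenarios(),
  background = background_model(n_variants_per_proband = 600),
  seed = 20)
small_vs <- as_variant_set(small_cohort)

test_that("allele frequencies are exact count ratios", {
  expect_equal(allele_frequency(frequency_record("evs", 21, 11520)),
               21 / 11520)
  expect_identical(allele_frequency(frequency_record("internal", 0, 1980)), 0)
  expect_equal(allele_frequency(frequency_record("exac", 1, 120688)),
               8.28584e-06, tolerance = 1e-4)
  expect_error(allele_frequency(1, 0), "positive")
})

test_that("rare filter keeps MAF <= threshold under the max-over-sources rule", {
  mk <- function(ac, an) {
    v <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G", gene = "X1")
    for (s in varcascade:::FREQ_SOURCES) {
      v[[paste0("ac_", s)]] <- 0L
      v[[paste0("an_", s)]] <- varcascade:::DEFAULT_AN[[s]]
      v[[paste0("hom_", s)]] <- 0L
    }
    v$ac_internal <- ac; v$an_internal <- an
    variant_set(v, matrix("het", 1, 1, dimnames = list(NULL, "S")))
  }
  # absent from all sources -> retained
  expect_identical(nrow(filter_rare(mk(0L, 1980L))$variants$variants), 1L)
  # exactly at the boundary -> retained (inclusive threshold)
  expect_identical(nrow(filter_rare(mk(1L, 200L))$variants$variants), 1L)
  # just above in a single source -> removed, even if zero elsewhere
  expect_identical(nrow(filter_rare(mk(2L, 200L))$variants$variants), 0L)
})

test_that("rare filter agrees with brute-force per-source checks", {
  set.seed(33)
  n <- 1000L
  v <- data.frame(chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
                  gene = "G1")
  for (s in varcascade:::FREQ_SOURCES) {
    an <- varcascade:::DEFAULT_AN[[s]]
    v[[paste0("ac_", s)]] <- rbinom(n, an, runif(n, 0, 0.02))
    v[[paste0("an_", s)]] <- an
    v[[paste0("hom_", s)]] <- 0L
  }
  vs <- variant_set(v, matrix("het", n, 1, dimnames = list(NULL, "S")))
  got <- filter_rare(vs, 0.005)$variants$variants$key
  want <- vs$variants$key[
    vapply(seq_len(n), function(i) {
      all(vapply(varcascade:::FREQ_SOURCES, function(s)
        v[[paste0("ac_", s)]][i] / v[[paste0("an_", s)]][i] <= 0.005,
        logical(1)))
    }, logical(1))]
  expect_identical(got, want)
})

test_that("raising the MAF threshold never shrinks the retained set", {
  vs <- small_vs
  thresholds <- c(0.001, 0.005, 0.01, 0.05, 0.2)
  kept <- lapply(thresholds, function(t)
    filter_rare(vs, t)$variants$variants$key)
  for (i in seq_len(length(kept) - 1L))
    expect_true(all(kept[[i]] %in% kept[[i + 1L]]))
})

test_that("every step's retained set is a subset of its input", {
  res <- run_cascade(small_vs, small_cohort$pedigree,
                     rescue = rescue_table(small_cohort))
  tr <- res$trace
  expect_identical(nrow(tr$steps), 4L)
  for (i in seq_len(nrow(tr$steps))) {
    expect_lte(tr$steps$n_retained[i], tr$steps$n_input[i])
    expect_identical(tr$steps$n_retained[i], length(tr$retained[[i]]))
  }
})

test_that("homozygote screen annotates but never removes", {
  rare <- filter_rare(small_vs)$variants
  screened <- homozygote_screen(rare)
  expect_identical(screened$variants$key, rare$variants$key)
  pl <- planted_variants(small_cohort)
  expect_false(any(screened$variants$pop_homozygote[
    screened$variants$key %in% pl$key]))
  # a positive homozygote count in any source flags the variant
  v <- screened$variants[1, ]
  v$ac_exac <- 10L; v$hom_exac <- 3L
  one <- variant_set(v[setdiff(names(v), "key")],
                     matrix("het", 1, 1, dimnames = list(NULL, "S")))
  expect_true(homozygote_screen(one)$variants$pop_homozygote)
})

test_that("zygosity partition is disjoint and covers non-reference genotypes", {
  parts <- partition_zygosity(small_vs, "F1_II1")
  allk <- c(parts$hom_alt, parts$het, parts$hemi)
  expect_identical(anyDuplicated(allk), 0L)
  g <- small_vs$genotypes[, "F1_II1"]
  expect_identical(sort(allk),
                   sort(small_vs$variants$key[g %in% c("het", "hom_alt", "hemi")]))
  expect_error(partition_zygosity(small_vs, "NOBODY"), "not in the genotype")
})

test_that("known-gene cross-reference finds nothing rare in a study-analogue cohort", {
  rare <- filter_rare(small_vs)$variants
  hits <- known_gene_crossref(rare, asd_known_genes())
  expect_identical(nrow(hits$variants), 0L)
  # a planted rare PAX6 variant is found
  v <- rare$variants[1, ]
  v$gene <- "PAX6"
  v$pos <- v$pos + 1L
  withpax <- variant_set(rbind(rare$variants[, setdiff(names(v), "key")],
                               v[setdiff(names(v), "key")]),
                         rbind(rare$genotypes, rare$genotypes[1, , drop = FALSE]))
  hits <- known_gene_crossref(withpax, asd_known_genes())
  expect_identical(nrow(hits$variants), 1L)
  expect_true(all(hits$variants$key %in% withpax$variants$key))
})

test_that("X-linked screen returns the single planted hemizygous candidate", {
  rare <- filter_rare(small_vs)$variants
  x <- xlinked_step(rare, "F2_II1", small_cohort$pedigree)
  expect_identical(nrow(x$variants), 1L)
  expect_identical(x$variants$gene, "ARMCX4")
  expect_true(all(varcascade:::is_x_chrom(x$variants$chrom)))
  # female proband: empty with a warning
  expect_warning(xf <- xlinked_step(rare, "F1_II1", small_cohort$pedigree),
                 "male")
  expect_identical(nrow(xf$variants), 0L)
})

test_that("recessive step matches a brute-force per-gene scan", {
  rare <- apply_rescue(filter_rare(small_vs)$variants,
                       rescue_table(small_cohort))
  for (fam in c("F1", "F2", "F3")) {
    pro <- paste0(fam, "_II1")
    if (!pro %in% colnames(rare$genotypes)) pro <- paste0(fam, "_II2")
    rep_df <- recessive_step(rare, pro, fam)
    # brute force: group all autosomal non-ref variants of the proband by gene
    v <- rare$variants
    g <- rare$genotypes[, pro]
    auto <- !varcascade:::is_x_chrom(v$chrom) & !is.na(v$gene)
    want_hom <- sort(unique(v$gene[auto & g == "hom_alt"]))
    het_tab <- table(v$gene[auto & g == "het"])
    want_ch <- sort(names(het_tab)[het_tab >= 2L])
    expect_identical(sort(rep_df$gene[rep_df$model == "homozygous"]), want_hom)
    expect_identical(sort(rep_df$gene[rep_df$model == "potential_compound_het"]),
                     want_ch)
    # a single het variant never qualifies
    expect_true(all(rep_df$n_variants[rep_df$model == "potential_compound_het"] >= 2L))
  }
})

test_that("family 1 qualifies under the homozygous model for the causal gene", {
  rare <- filter_rare(small_vs)$variants
  rep1 <- recessive_step(rare, "F1_II1", "F1")
  expect_true(any(rep1$gene == "CPAMD8" & rep1$model == "homozygous"))
})

test_that("intersection keeps only genes qualifying in every family", {
  mk_report <- function(fam, genes, model = "potential_compound_het") {
    df <- data.frame(family = fam, gene = genes, model = model,
                     n_variants = 2L, stringsAsFactors = FALSE)
    df$keys <- replicate(length(genes), c("k1", "k2"), simplify = FALSE)
    class(df) <- c("candidate_report", "data.frame")
    df
  }
  reports <- list(F1 = mk_report("F1", c("A", "B")),
                  F2 = mk_report("F2", c("B", "C")),
                  F3 = mk_report("F3", c("B", "D")))
  expect_identical(intersect_step(reports), "B")
  # decoy qualifying in 2/3 families is excluded
  reports$F3 <- mk_report("F3", "D")
  expect_identical(intersect_step(reports), character(0))
  expect_warning(intersect_step(reports["F1"]), "single family")
})

test_that("coverage-gap report equals the generator's mask and rescues merge", {
  mask <- small_cohort$coverage[["F3_II2"]]
  gaps <- coverage_gap_report("CPAMD8", small_cohort$transcript, mask, "F3_II2")
  expect_identical(gaps, mask$masked_exons)
  expect_identical(length(gaps), 6L)
  expect_true(7L %in% gaps)
  # full coverage: empty report
  ex <- varcascade:::exon_genomic_intervals(small_cohort$transcript, mask$layout)
  full <- mask
  full$covered[["F3_II2"]] <- ex[, c("start", "end")]
  expect_identical(
    coverage_gap_report("CPAMD8", small_cohort$transcript, full, "F3_II2"),
    integer(0))
  expect_error(coverage_gap_report("OTHER", small_cohort$transcript, mask,
                                   "F3_II2"), "mask is for")
})

test_that("in-silico support ranks but never filters", {
  rare <- filter_rare(small_vs)$variants
  ranked <- insilico_rank(rare)
  expect_identical(nrow(ranked$variants), nrow(rare$variants))
  pl <- planted_variants(small_cohort)
  missense_key <- pl$key[pl$cdna_change == "c.4351T>C"]
  expect_identical(
    ranked$variants$insilico_support[ranked$variants$key == missense_key], 3L)
})
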