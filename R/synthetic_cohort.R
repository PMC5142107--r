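#' Background model for synthetic exome variant tables
#'
#' Describes the non-causal variant load of each proband: roughly 25,000
#' exonic variants per exome, of which a small fraction is rare. Allele
#' frequencies follow a two-mode spectrum: a common mode, uniform on
#' `common_af_range`, and a rare mode, exponential with mean `rare_af_mean`
#' truncated at the rare threshold. Population database counts are drawn
#' binomially per source at the true frequency, with panel sizes echoing
#' the four real panels (1000 Genomes 5,008; EVS 12,000; ExAC 120,000;
#' internal 1,980 alleles).
#'
#' @param n_variants_per_proband Exonic variants per proband (default 25000).
#' @param fraction_rare Fraction of each proband's variants in the rare
#'   mode (default 0.006, giving on the order of 115-150 rare
#'   heterozygous variants per exome).
#' @param rare_af_mean Mean of the exponential rare-mode frequency.
#' @param common_af_range Range of the uniform common mode.
#' @param n_genes Size of the autosomal background gene pool.
#' @return A `background_model` list.
#' @export
background_model <- function(n_variants_per_proband = 25000L,
                             fraction_rare = 0.006,
                             rare_af_mean = 0.001,
                             common_af_range = c(0.01, 0.5),
                             n_genes = 2000L) {
  stopifnot(n_variants_per_proband >= 0L, fraction_rare >= 0, fraction_rare <= 1,
            rare_af_mean > 0, length(common_af_range) == 2L)
  structure(list(n_variants_per_proband = as.integer(n_variants_per_proband),
                 fraction_rare = fraction_rare, rare_af_mean = rare_af_mean,
                 common_af_range = common_af_range, n_genes = as.integer(n_genes)),
            class = "background_model")
}

#' Describe a family scenario with planted causal variants
#'
#' @param scenario_id Family label (must match a pedigree family id).
#' @param inheritance One of "homozygous_consanguineous",
#'   "compound_het_full_trio", "compound_het_partial_genotyping".
#' @param causal_gene Gene symbol carrying the causal variants.
#' @param causal_variants List of variant descriptions, each a list with
#'   `cdna_change`, `consequence_class`, `genotypes` (named character
#'   vector of planted non-reference genotypes) and optionally
#'   `frequencies` (named list source -> c(ac, an, hom)) and score fields.
#' @param coverage_gap_exons Optional exon indices without exome coverage
#'   in the proband (applied after generation).
#' @return A `cohort_scenario`.
#' @export
cohort_scenario <- function(scenario_id, inheritance, causal_gene = "CPAMD8",
                            causal_variants, coverage_gap_exons = NULL) {
  inheritance <- match.arg(inheritance,
    c("homozygous_consanguineous", "compound_het_full_trio",
      "compound_het_partial_genotyping"))
  n <- length(causal_variants)
  if (inheritance == "homozygous_consanguineous" && n != 1L)
    stop("homozygous scenario plants exactly 1 causal variant")
  if (inheritance != "homozygous_consanguineous" && n != 2L)
    stop("compound-het scenarios plant exactly 2 causal variants")
  structure(list(scenario_id = scenario_id, inheritance = inheritance,
                 causal_gene = causal_gene, causal_variants = causal_variants,
                 coverage_gap_exons = coverage_gap_exons),
            class = "cohort_scenario")
}

# genotype configurations of the three study families, with population
# counts matching the published database entries for the five variants
#' The three family scenarios emulating the study cohort
#'
#' Family 1: consanguineous trio, homozygous missense (c.4351T>C) with
#' heterozygous carrier parents. Family 2: trio compound heterozygous for
#' a frameshift (c.2352_2353insC, paternal) and a splice-acceptor variant
#' (c.4549-1G>A, maternal). Family 3: two affected siblings compound
#' heterozygous for two splice-donor variants (c.700+1G>T, maternal;
#' c.4002+1G>A, presumed paternal — the father is unavailable), an
#' unaffected granddaughter carrying c.700+1G>T only, and by default a
#' six-exon exome coverage gap over the region of c.700+1G>T in the
#' proband.
#'
#' @param coverage_gap Apply the family-3 six-exon coverage gap (default
#'   TRUE).
#' @return List of three `cohort_scenario` objects.
#' @export
paper_scenarios <- function(coverage_gap = TRUE) {
  fr <- function(tg, evs_ac, evs_an, exac_ac, exac_an)
    list(thousand_genomes = c(tg, 5008L, 0L), evs = c(evs_ac, evs_an, 0L),
         exac = c(exac_ac, exac_an, 0L), internal = c(0L, 1980L, 0L))
  v1 <- list(cdna_change = "c.4351T>C", consequence_class = "missense",
             genotypes = c(F1_II1 = "hom_alt", F1_I1 = "het", F1_I2 = "het"),
             frequencies = fr(0L, 0L, 12378L, 0L, 116178L),
             sift = 0.01, polyphen = 0.948, phylop = 0.98)
  v2a <- list(cdna_change = "c.2352_2353insC", consequence_class = "frameshift",
              genotypes = c(F2_II1 = "het", F2_I1 = "het"),
              frequencies = fr(0L, 21L, 11520L, 47L, 115670L))
  v2b <- list(cdna_change = "c.4549-1G>A", consequence_class = "splice_site",
              genotypes = c(F2_II1 = "het", F2_I2 = "het"),
              frequencies = fr(0L, 1L, 12356L, 1L, 120688L))
  v3a <- list(cdna_change = "c.700+1G>T", consequence_class = "splice_site",
              genotypes = c(F3_II2 = "het", F3_II3 = "het", F3_I2 = "het",
                            F3_III1 = "het"),
              frequencies = fr(0L, 0L, 12140L, 0L, 120212L))
  v3b <- list(cdna_change = "c.4002+1G>A", consequence_class = "splice_site",
              genotypes = c(F3_II2 = "het", F3_II3 = "het"),
              frequencies = fr(0L, 0L, 12350L, 0L, 120350L))
  list(cohort_scenario("F1", "homozygous_consanguineous",
                       causal_variants = list(v1)),
       cohort_scenario("F2", "compound_het_full_trio",
                       causal_variants = list(v2a, v2b)),
       cohort_scenario("F3", "compound_het_partial_genotyping",
                       causal_variants = list(v3a, v3b),
                       coverage_gap_exons = if (coverage_gap) 4:9 else NULL))
}

#' Pedigree of the three synthetic study families
#'
#' Family 3 includes the unavailable father (F3_I1, retained in the
#' pedigree but never genotyped), a married-in spouse (F3_SP) and the
#' unaffected granddaughter F3_III1.
#'
#' @return A `pedigree` data frame.
#' @export
cohort_pedigree <- function() {
  ped <- data.frame(
    family_id = c("F1", "F1", "F1", "F2", "F2", "F2",
                  "F3", "F3", "F3", "F3", "F3", "F3"),
    individual_id = c("F1_I1", "F1_I2", "F1_II1", "F2_I1", "F2_I2", "F2_II1",
                      "F3_I1", "F3_I2", "F3_II2", "F3_II3", "F3_SP", "F3_III1"),
    father_id = c("0", "0", "F1_I1", "0", "0", "F2_I1",
                  "0", "0", "F3_I1", "F3_I1", "0", "F3_II2"),
    mother_id = c("0", "0", "F1_I2", "0", "0", "F2_I2",
                  "0", "0", "F3_I2", "F3_I2", "0", "F3_SP"),
    sex = c("male", "female", "female", "male", "female", "male",
            "male", "female", "male", "female", "female", "female"),
    affected = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE,
                 FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# samples whose DNA is unavailable: genotypes always missing
UNAVAILABLE_SAMPLES <- "F3_I1"

#' Genomic layout of the synthetic causal gene
#' @return List with `chrom`, `gene_start` and the fixed `intron_len` used
#'   to project cDNA coordinates into the synthetic genome.
#' @export
cpamd8_layout <- function() list(chrom = "19", gene_start = 1000000L,
                                 intron_len = 100L)

#' Project a cDNA position (with optional intron offset) to the synthetic genome
#' @param transcript A `transcript_model`.
#' @param layout A layout list (see [cpamd8_layout()]).
#' @param pos cDNA position.
#' @param offset Intronic offset (0 for exonic).
#' @return 1-based genomic position.
#' @export
cdna_to_genomic <- function(transcript, layout, pos, offset = 0L) {
  ex <- transcript$exons
  i <- max(which(ex$c_start <= pos))
  # consistent with the 0-based half-open exon intervals of the layout:
  # c.1 sits at 1-based genomic position gene_start + 1
  g <- layout$gene_start + pos + (i - 1L) * layout$intron_len
  g + offset
}

plant_af <- 1e-4  # nominal population frequency of planted causal alleles

#' Generate a synthetic multi-family exome cohort
#'
#' Builds a multi-sample variant table with planted causal configurations
#' for each scenario, a two-mode frequency background, and deliberate
#' decoys: common variants in the causal gene, a decoy gene with rare
#' heterozygous variants in only two of the three families, and (for the
#' family-2 analogue) a single benign hemizygous X candidate. Rare
#' background variants are confined to autosomal non-disease-associated
#' genes, so that the known-gene cross-reference and the hemizygous X
#' screen behave as in the study. Generation is fully deterministic given
#' `seed`.
#'
#' @param scenarios List of `cohort_scenario`s (default [paper_scenarios()]).
#' @param background A `background_model`.
#' @param seed Integer seed; every random draw depends on it.
#' @param transcript Transcript model of the causal gene.
#' @return A `synthetic_cohort`: list with `variants`, `genotypes`,
#'   `pedigree`, `transcript`, `layout`, `coverage` (masks by sample),
#'   `rescue` (genotypes removed by coverage masking), `scenarios`, `seed`.
#' @export
generate_cohort <- function(scenarios = paper_scenarios(),
                            background = background_model(),
                            seed = 1L,
                            transcript = cpamd8_transcript()) {
  set.seed(as.integer(seed))
  ped <- cohort_pedigree()
  layout <- cpamd8_layout()
  fams <- vapply(scenarios, `[[`, character(1), "scenario_id")
  if (any(!fams %in% ped$family_id))
    stop("scenario family not in pedigree: ", setdiff(fams, ped$family_id)[1])
  samples <- ped$individual_id

  # -- scenario validation: never plant hom_alt in an unaffected sample ----
  for (sc in scenarios)
    for (v in sc$causal_variants) {
      hom <- names(v$genotypes)[v$genotypes == "hom_alt"]
      bad <- hom[!ped$affected[match(hom, ped$individual_id)]]
      if (length(bad))
        stop("scenario ", sc$scenario_id, " plants hom_alt in unaffected sample ",
             bad[1])
    }

  # -- gene pool -----------------------------------------------------------
  n_bg <- background$n_genes
  bg_genes <- sprintf("G%04d", seq_len(n_bg))
  bg_chrom <- rep(as.character(1:22), length.out = n_bg)
  idx_in_chrom <- stats::ave(seq_len(n_bg), bg_chrom, FUN = seq_along)
  bg_start <- 1e7 + (idx_in_chrom - 1L) * 50000L
  x_genes <- sprintf("XG%02d", 1:40)
  known <- asd_known_genes()
  gene_table <- rbind(
    data.frame(gene = bg_genes, chrom = bg_chrom, window = bg_start,
               stringsAsFactors = FALSE),
    data.frame(gene = x_genes, chrom = "X", window = 1e7 + (0:39) * 50000L,
               stringsAsFactors = FALSE),
    data.frame(gene = known, chrom = "11", window = 9e6 + seq_along(known) * 50000L,
               stringsAsFactors = FALSE))

  rows <- list()   # per-block variant data.frames
  gmat <- list()   # matching genotype matrices (all samples)

  blank_geno <- function(n) {
    m <- matrix("hom_ref", n, length(samples), dimnames = list(NULL, samples))
    m[, UNAVAILABLE_SAMPLES] <- "missing"
    m
  }
  code3 <- c("hom_ref", "het", "hom_alt")

  # -- background per family ----------------------------------------------
  n_per <- background$n_variants_per_proband
  n_rare <- round(n_per * background$fraction_rare)
  n_common <- n_per - n_rare
  rare_pool <- bg_genes
  common_pool <- c(bg_genes, x_genes, known)

  for (sc in scenarios) {
    fam <- sc$scenario_id
    members <- ped[ped$family_id == fam, ]
    proband <- members$individual_id[members$affected][1]
    father <- members$father_id[members$individual_id == proband]
    mother <- members$mother_id[members$individual_id == proband]
    n <- n_rare + n_common
    if (n == 0L) next
    af <- c(pmin(stats::rexp(n_rare, rate = 1 / background$rare_af_mean), 0.005),
            stats::runif(n_common, background$common_af_range[1],
                         background$common_af_range[2]))
    af <- pmax(af, 1e-6)
    gene <- c(sample(rare_pool, n_rare, replace = TRUE),
              sample(common_pool, n_common, replace = TRUE))
    gi <- match(gene, gene_table$gene)
    chrom <- gene_table$chrom[gi]
    is_x <- chrom == "X"
    ref_i <- sample.int(4L, n, replace = TRUE)
    alt_i <- (ref_i - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
    bases <- c("A", "C", "G", "T")
    df <- data.frame(chrom = chrom, pos = 0L, ref = bases[ref_i],
                     alt = bases[alt_i], gene = gene,
                     cdna_change = NA_character_,
                     consequence_class = sample(
                       c("missense", "synonymous", "other", "frameshift",
                         "splice_site"), n, replace = TRUE,
                       prob = c(0.5, 0.3, 0.15, 0.03, 0.02)),
                     stringsAsFactors = FALSE)
    for (s in FREQ_SOURCES) {
      an <- DEFAULT_AN[[s]]
      ac <- stats::rbinom(n, an, af)
      hom <- pmin(stats::rbinom(n, an %/% 2L, af^2), ac %/% 2L)
      df[[paste0("ac_", s)]] <- ac
      df[[paste0("an_", s)]] <- an
      df[[paste0("hom_", s)]] <- hom
    }
    miss <- df$consequence_class == "missense"
    df$sift <- ifelse(miss, round(stats::runif(n), 3), NA_real_)
    df$polyphen <- ifelse(miss, round(stats::runif(n), 3), NA_real_)
    df$phylop <- ifelse(miss, round(stats::runif(n), 3), NA_real_)

    geno <- blank_geno(n)
    avail <- setdiff(members$individual_id, UNAVAILABLE_SAMPLES)
    male <- stats::setNames(members$sex == "male", members$individual_id)

    # autosomal: Mendelian trio (plus extended family-3 members)
    is_hom <- stats::runif(n) < af / (2 - af)
    donor_is_father <- stats::runif(n) < 0.5
    fa1 <- is_hom | (!is_hom & donor_is_father)       # transmitted to proband
    mo1 <- is_hom | (!is_hom & !donor_is_father)
    fa2 <- stats::runif(n) < af
    mo2 <- stats::runif(n) < af
    geno[, proband] <- code3[1L + is_hom * 2L + (!is_hom) * 1L]
    if (father %in% avail) geno[, father] <- code3[1L + fa1 + fa2]
    if (mother %in% avail) geno[, mother] <- code3[1L + mo1 + mo2]
    if (fam == "F3") {
      pick <- function(a, b) ifelse(stats::runif(n) < 0.5, a, b)
      sib <- pick(fa1, fa2) + pick(mo1, mo2)
      geno[, "F3_II3"] <- code3[1L + sib]
      sp1 <- stats::runif(n) < af; sp2 <- stats::runif(n) < af
      geno[, "F3_SP"] <- code3[1L + sp1 + sp2]
      pro_a2 <- is_hom                                # proband's second allele
      g3 <- pick(rep(TRUE, n), pro_a2) + pick(sp1, sp2)
      geno[, "F3_III1"] <- code3[1L + g3]
    }
    # X chromosome: independent Hardy-Weinberg draws, hemizygous males;
    # the proband carries by construction
    if (any(is_x)) {
      xi <- which(is_x)
      for (id in avail) {
        if (id == proband) {
          geno[xi, id] <- if (male[[id]]) "hemi" else
            code3[1L + 1L + (stats::runif(length(xi)) < af[xi] / (2 - af[xi]))]
        } else if (male[[id]]) {
          geno[xi, id] <- ifelse(stats::runif(length(xi)) < af[xi], "hemi", "hom_ref")
        } else {
          cnt <- (stats::runif(length(xi)) < af[xi]) + (stats::runif(length(xi)) < af[xi])
          geno[xi, id] <- code3[1L + cnt]
        }
      }
    }
    rows[[length(rows) + 1L]] <- df
    gmat[[length(gmat) + 1L]] <- geno
  }

  # -- planted causal variants --------------------------------------------
  plant_freq_cols <- function(df, frequencies) {
    for (s in FREQ_SOURCES) {
      cnt <- frequencies[[s]]
      if (is.null(cnt)) cnt <- c(0L, DEFAULT_AN[[s]], 0L)
      df[[paste0("ac_", s)]] <- cnt[1]
      df[[paste0("an_", s)]] <- cnt[2]
      df[[paste0("hom_", s)]] <- cnt[3]
    }
    df
  }
  cds <- transcript$cds
  for (sc in scenarios) {
    for (v in sc$causal_variants) {
      p <- parse_hgvs_c(v$cdna_change)
      gpos <- cdna_to_genomic(transcript, layout, p$pos, p$offset)
      if (p$type == "sub") {
        ref <- p$ref; alt <- p$alt
      } else if (p$type == "ins") {
        ref <- substr(cds, p$pos, p$pos)
        alt <- paste0(ref, p$inserted)
      } else {
        ref <- substr(cds, p$pos, p$pos2)
        alt <- substr(cds, p$pos, p$pos)
        gpos <- gpos  # deletion anchored at first deleted base
      }
      df <- data.frame(chrom = layout$chrom, pos = gpos, ref = ref, alt = alt,
                       gene = sc$causal_gene, cdna_change = v$cdna_change,
                       consequence_class = v$consequence_class,
                       stringsAsFactors = FALSE)
      df <- plant_freq_cols(df, v$frequencies)
      df$sift <- if (is.null(v$sift)) NA_real_ else v$sift
      df$polyphen <- if (is.null(v$polyphen)) NA_real_ else v$polyphen
      df$phylop <- if (is.null(v$phylop)) NA_real_ else v$phylop
      df$planted <- TRUE
      geno <- blank_geno(1L)
      geno[1L, names(v$genotypes)] <- unname(v$genotypes)
      rows[[length(rows) + 1L]] <- df
      gmat[[length(gmat) + 1L]] <- geno
    }
  }

  # -- decoys --------------------------------------------------------------
  decoy_rows <- function(chrom, pos, gene, class, carriers, rare = TRUE) {
    n <- length(pos)
    df <- data.frame(chrom = chrom, pos = pos,
                     ref = rep("A", n), alt = rep("G", n), gene = gene,
                     cdna_change = NA_character_, consequence_class = class,
                     stringsAsFactors = FALSE)
    af0 <- if (rare) plant_af else 0.2
    for (s in FREQ_SOURCES) {
      an <- DEFAULT_AN[[s]]
      df[[paste0("ac_", s)]] <- if (rare)
        pmin(stats::rbinom(n, an, af0), floor(0.005 * an)) else
        stats::rbinom(n, an, af0)
      df[[paste0("an_", s)]] <- an
      df[[paste0("hom_", s)]] <- if (rare) 0L else
        pmin(stats::rbinom(n, an %/% 2L, af0^2), df[[paste0("ac_", s)]] %/% 2L)
    }
    df$sift <- NA_real_; df$polyphen <- NA_real_; df$phylop <- NA_real_
    geno <- blank_geno(n)
    for (i in seq_len(n))
      geno[i, names(carriers[[i]])] <- unname(carriers[[i]])
    list(df = df, geno = geno)
  }
  fam_probands <- stats::setNames(
    vapply(fams, function(f) {
      m <- ped[ped$family_id == f, ]; m$individual_id[m$affected][1]
    }, character(1)), fams)
  if (n_rare > 0L && length(fams) >= 2L) {
    # a decoy gene compound-het in only the first two families
    two <- fams[1:2]
    d <- decoy_rows("13", 9000000L + c(10L, 17L, 24L, 31L), "DCY2OF3",
                    "missense",
                    list(stats::setNames("het", fam_probands[[two[1]]]),
                         stats::setNames("het", fam_probands[[two[1]]]),
                         stats::setNames("het", fam_probands[[two[2]]]),
                         stats::setNames("het", fam_probands[[two[2]]])),
                    rare = TRUE)
    rows[[length(rows) + 1L]] <- d$df; gmat[[length(gmat) + 1L]] <- d$geno
    # a single benign rare hemizygous X candidate in the male proband of F2
    if ("F2" %in% fams) {
      d <- decoy_rows("X", 5001000L, "ARMCX4", "missense",
                      list(c(F2_II1 = "hemi", F2_I2 = "het")), rare = TRUE)
      d$df$cdna_change <- "c.979A>G"
      d$df$sift <- 0.62; d$df$polyphen <- 0.05; d$df$phylop <- 0.20
      rows[[length(rows) + 1L]] <- d$df; gmat[[length(gmat) + 1L]] <- d$geno
    }
  }
  # common variants in the causal gene (filtered at step 1)
  for (k in seq_along(fams)) {
    cpos <- c(150L, 250L) + k
    gpos <- vapply(cpos, function(p) cdna_to_genomic(transcript, layout, p),
                   numeric(1))
    carriers <- rep(list(stats::setNames("het", fam_probands[[fams[k]]])), 2L)
    d <- decoy_rows(layout$chrom, gpos, "CPAMD8", "synonymous", carriers,
                    rare = FALSE)
    d$df$ref <- vapply(cpos, function(p) substr(cds, p, p), character(1))
    d$df$alt <- ifelse(d$df$ref == "A", "G", "A")
    rows[[length(rows) + 1L]] <- d$df; gmat[[length(gmat) + 1L]] <- d$geno
  }

  variants <- do.call(rbind, lapply(rows, function(df) {
    if (is.null(df$planted)) df$planted <- FALSE
    df
  }))
  genotypes <- do.call(rbind, gmat)

  # unique deterministic positions for background rows (within gene windows)
  bg_idx <- which(variants$pos == 0L)
  win <- gene_table$window[match(variants$gene[bg_idx], gene_table$gene)]
  off <- stats::ave(seq_along(bg_idx), variants$gene[bg_idx], FUN = seq_along)
  variants$pos[bg_idx] <- win + off * 7L

  ord <- order(match(variants$chrom, c(as.character(1:22), "X")), variants$pos,
               variants$alt)
  variants <- variants[ord, , drop = FALSE]
  genotypes <- genotypes[ord, , drop = FALSE]
  rownames(variants) <- NULL
  variants$key <- variant_key(variants)
  rownames(genotypes) <- variants$key

  cohort <- structure(list(variants = variants, genotypes = genotypes,
                           pedigree = ped, transcript = transcript,
                           layout = layout, coverage = list(), rescue = NULL,
                           scenarios = scenarios, background = background,
                           seed = as.integer(seed)),
                      class = "synthetic_cohort")
  for (sc in scenarios)
    if (!is.null(sc$coverage_gap_exons))
      cohort <- mask_coverage(cohort, sc$causal_gene, sc$coverage_gap_exons,
                              fam_probands[[sc$scenario_id]])
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort (seed ", x$seed, "): ", nrow(x$variants),
      " variants x ", ncol(x$genotypes), " samples, ",
      length(x$scenarios), " families\n", sep = "")
  np <- sum(x$variants$planted)
  cat("  planted causal records:", np, "\n")
  if (length(x$coverage))
    cat("  coverage masks:", paste(names(x$coverage), collapse = ", "), "\n")
  invisible(x)
}

#' Planted causal records of a synthetic cohort
#' @param cohort A `synthetic_cohort`.
#' @return The planted subset of the variant table.
#' @export
planted_variants <- function(cohort) {
  cohort$variants[cohort$variants$planted, , drop = FALSE]
}

#' Convert a synthetic cohort to a variant set
#' @param cohort A `synthetic_cohort`.
#' @return A `variant_set`.
#' @export
as_variant_set <- function(cohort) {
  cols <- setdiff(names(cohort$variants), c("planted", "key"))
  variant_set(cohort$variants[, cols], cohort$genotypes)
}

#' Remove exome coverage for selected exons of a gene in one sample
#'
#' Emulates a capture/coverage gap: genotypes of the sample at variants
#' falling within the masked exons (padded by 8 nt to include the splice
#' sites) become missing, and a `coverage_mask` recording the sample's
#' remaining covered exon intervals is attached to the cohort. The removed
#' genotypes are stored in `cohort$rescue` so a targeted-sequencing rescue
#' can later restore them.
#'
#' @param cohort A `synthetic_cohort`.
#' @param gene Gene symbol (masking a gene with no planted causal variant
#'   is allowed, with a warning).
#' @param exon_indices Exon indices to mask; an empty vector is a no-op.
#' @param sample Sample id.
#' @return The modified cohort.
#' @export
mask_coverage <- function(cohort, gene, exon_indices, sample) {
  if (!length(exon_indices)) return(cohort)
  tx <- cohort$transcript
  if (!identical(gene, tx$gene))
    stop("no transcript model for gene ", gene)
  causal_genes <- vapply(cohort$scenarios, `[[`, character(1), "causal_gene")
  if (!gene %in% causal_genes)
    warning("masking coverage in non-causal gene ", gene)
  if (any(!exon_indices %in% tx$exons$index))
    stop("exon index out of range for ", gene)
  ex <- exon_genomic_intervals(tx, cohort$layout)
  pad <- 8L
  masked <- ex[ex$index %in% exon_indices, , drop = FALSE]
  in_masked <- cohort$variants$gene %in% gene &
    Reduce(`|`, lapply(seq_len(nrow(masked)), function(i)
      cohort$variants$pos > masked$start[i] - pad &
        cohort$variants$pos <= masked$end[i] + pad))
  hit <- which(in_masked & cohort$genotypes[, sample] != "missing")
  if (length(hit)) {
    removed <- data.frame(key = cohort$variants$key[hit], sample = sample,
                          genotype = cohort$genotypes[hit, sample],
                          stringsAsFactors = FALSE)
    cohort$rescue <- rbind(cohort$rescue, removed)
    cohort$genotypes[hit, sample] <- "missing"
  }
  covered <- ex[!ex$index %in% exon_indices, , drop = FALSE]
  mask <- structure(list(gene = gene, layout = cohort$layout,
                         masked_exons = sort(as.integer(exon_indices)),
                         covered = stats::setNames(
                           list(covered[, c("start", "end")]), sample)),
                    class = "coverage_mask")
  cohort$coverage[[sample]] <- mask
  cohort
}

#' Targeted-sequencing rescue table for masked genotypes
#'
#' @param cohort A masked `synthetic_cohort`.
#' @return Data frame (`key`, `sample`, `genotype`) of genotypes removed by
#'   coverage masking, or an empty frame.
#' @export
rescue_table <- function(cohort) {
  if (is.null(cohort$rescue))
    return(data.frame(key = character(0), sample = character(0),
                      genotype = character(0), stringsAsFactors = FALSE))
  cohort$rescue
}

#' Merge rescued genotypes into a variant set
#' @param vs A `variant_set`.
#' @param rescue Data frame as returned by [rescue_table()].
#' @return The updated `variant_set`.
#' @export
apply_rescue <- function(vs, rescue) {
  for (i in seq_len(nrow(rescue))) {
    k <- rescue$key[i]
    if (k %in% rownames(vs$genotypes))
      vs$genotypes[k, rescue$sample[i]] <- rescue$genotype[i]
  }
  vs
}

#' Write a synthetic cohort to disk (VCF + PED + annotations + BED)
#'
#' Deterministic: the same cohort always produces byte-identical files.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named list of paths (`vcf`, `ped`, `annotations`, `bed` when
#'   masks exist).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- as_variant_set(cohort)
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                ped = file.path(dir, "cohort.ped"),
                annotations = file.path(dir, "annotations.tsv"))
  write_vcf(vs, paths$vcf)
  write_ped(cohort$pedigree, paths$ped)
  write_annotations(vs, paths$annotations)
  if (length(cohort$coverage)) {
    paths$bed <- file.path(dir, "coverage.bed")
    lines <- character(0)
    for (sample in names(cohort$coverage)) {
      mask <- cohort$coverage[[sample]]
      cov <- mask$covered[[sample]]
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%s", mask$layout$chrom,
                                cov$start, cov$end, sample, mask$gene))
    }
    writeLines(lines, paths$bed)
  }
  paths
}
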