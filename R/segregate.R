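carries_alt <- function(g) g %in% c("het", "hom_alt", "hemi")
genotyped <- function(g) !is.na(g) & g != "missing"

new_verdict <- function(model, consistent, phase, evidence) {
  structure(list(model = model, consistent = consistent, phase = phase,
                 evidence = evidence), class = "segregation_verdict")
}

#' @export
print.segregation_verdict <- function(x, ...) {
  cat(sprintf("Segregation verdict (%s): %s, phase %s\n", x$model,
              if (x$consistent) "consistent" else "inconsistent", x$phase))
  for (e in x$evidence) cat(" -", e, "\n")
  invisible(x)
}

family_members <- function(pedigree, family_id) {
  pedigree[pedigree$family_id == family_id, , drop = FALSE]
}

gt_of <- function(vs, key, individual) {
  if (!key %in% rownames(vs$genotypes)) stop("unknown variant key ", key)
  if (!individual %in% colnames(vs$genotypes)) return("missing")
  vs$genotypes[key, individual]
}

#' Test a homozygous variant for recessive segregation
#'
#' Consistent iff every genotyped parent of the proband is a heterozygous
#' carrier and no genotyped unaffected family member is homozygous for the
#' alternate allele. Ungenotyped individuals never render a verdict
#' inconsistent; they are noted as unobserved.
#'
#' @param vs A `variant_set`.
#' @param pedigree A `pedigree`.
#' @param family_id Family label.
#' @param key Variant key (chrom:pos:ref:alt).
#' @param proband Proband sample id; must be homozygous-alternate.
#' @return A `segregation_verdict` with model "homozygous".
#' @export
check_homozygous <- function(vs, pedigree, family_id, key, proband) {
  fam <- family_members(pedigree, family_id)
  pg <- gt_of(vs, key, proband)
  if (pg != "hom_alt")
    stop("proband ", proband, " is not homozygous-alternate at ", key)
  prow <- fam[fam$individual_id == proband, ]
  evidence <- sprintf("%s: hom_alt (proband)", proband)
  consistent <- TRUE
  for (parent in setdiff(c(prow$father_id, prow$mother_id), "0")) {
    g <- gt_of(vs, key, parent)
    if (!genotyped(g)) {
      evidence <- c(evidence, sprintf("%s: unobserved", parent))
      next
    }
    evidence <- c(evidence, sprintf("%s: %s", parent, g))
    if (!carries_alt(g)) consistent <- FALSE   # obligate carrier missing the allele
  }
  others <- setdiff(fam$individual_id, proband)
  for (id in others) {
    aff <- fam$affected[fam$individual_id == id]
    g <- gt_of(vs, key, id)
    if (!genotyped(g)) next
    if (isFALSE(aff) && g == "hom_alt") {
      consistent <- FALSE
      evidence <- c(evidence, sprintf("%s: hom_alt but unaffected", id))
    }
  }
  new_verdict("homozygous", consistent, "unphased", evidence)
}

#' Test two heterozygous variants for compound-heterozygous segregation
#'
#' The proband must be heterozygous for both variants of the same gene.
#' The configuration is consistent with recessive inheritance iff no
#' genotyped unaffected individual carries both alleles, every genotyped
#' affected sibling carries both, and (when both parents are genotyped)
#' each allele is attributable to a parent. Phase is "confirmed_trans"
#' when both parents are genotyped and each carries exactly one of the two
#' alleles; "inferred_trans" when exactly one parent is genotyped and
#' carries exactly one allele (the other allele is imputed to the missing
#' parent); "unphased" otherwise. Unaffected carriers of a single allele
#' are always permitted.
#'
#' @param vs A `variant_set`.
#' @param pedigree A `pedigree`.
#' @param family_id Family label.
#' @param keyA,keyB Distinct variant keys.
#' @param proband Proband sample id.
#' @return A `segregation_verdict` with model "compound_het".
#' @export
check_compound_het <- function(vs, pedigree, family_id, keyA, keyB, proband) {
  if (identical(keyA, keyB))
    stop("compound heterozygosity needs two distinct variants")
  fam <- family_members(pedigree, family_id)
  gA <- gt_of(vs, keyA, proband); gB <- gt_of(vs, keyB, proband)
  if (gA != "het" || gB != "het")
    stop("proband ", proband, " must be heterozygous for both variants")
  prow <- fam[fam$individual_id == proband, ]
  evidence <- sprintf("%s: het/het (proband)", proband)
  consistent <- TRUE

  member_gt <- function(id) c(A = gt_of(vs, keyA, id), B = gt_of(vs, keyB, id))
  n_carried <- function(g) sum(carries_alt(g))

  # unaffected members must not carry both; genotyped affected sibs must carry both
  for (id in setdiff(fam$individual_id, proband)) {
    g <- member_gt(id)
    if (!any(genotyped(g))) next
    aff <- fam$affected[fam$individual_id == id]
    evidence <- c(evidence, sprintf("%s: %s/%s", id, g["A"], g["B"]))
    if (isFALSE(aff) && all(genotyped(g)) && n_carried(g) == 2L) {
      consistent <- FALSE
      evidence <- c(evidence, sprintf("%s: unaffected yet carries both alleles", id))
    }
    if (isTRUE(aff) && all(genotyped(g)) && n_carried(g) < 2L) {
      consistent <- FALSE
      evidence <- c(evidence, sprintf("%s: affected but carries only %d allele(s)",
                                      id, n_carried(g)))
    }
  }

  parents <- c(prow$father_id, prow$mother_id)
  parents <- parents[parents != "0"]
  pgt <- lapply(parents, member_gt)
  observed <- vapply(pgt, function(g) all(genotyped(g)), logical(1))
  if (length(parents) == 2L && all(observed)) {
    # both alleles must be transmissible from the parents
    for (al in c("A", "B")) {
      if (!any(vapply(pgt, function(g) carries_alt(g[al]), logical(1)))) {
        consistent <- FALSE
        evidence <- c(evidence,
                      sprintf("allele %s carried by neither genotyped parent", al))
      }
    }
  }
  phase <- "unphased"
  obs_n_carried <- vapply(pgt[observed], n_carried, integer(1))
  if (length(parents) == 2L && all(observed)) {
    carried <- lapply(pgt, function(g) names(g)[carries_alt(g)])
    if (all(obs_n_carried == 1L) &&
        setequal(unlist(carried), c("A", "B")))
      phase <- "confirmed_trans"
  } else if (sum(observed) == 1L) {
    if (obs_n_carried == 1L) phase <- "inferred_trans"
  }
  if (!consistent) phase <- "unphased"
  new_verdict("compound_het", consistent, phase, evidence)
}

#' Segregation verdicts for every candidate gene model in every family
#'
#' Runs the appropriate segregation test for each row of a candidate gene
#' report. Genes failing segregation in any family are demoted (flagged),
#' never deleted.
#'
#' @param reports List of per-family `candidate_report`s (named by family).
#' @param vs A `variant_set` containing the candidate variants.
#' @param pedigree A `pedigree`.
#' @param probands Named character vector family -> proband id.
#' @return Data frame with one row per (family, gene, model): `consistent`,
#'   `phase`, `demoted`, plus a `verdict` list-column.
#' @export
classify_inheritance <- function(reports, vs, pedigree, probands) {
  rows <- list()
  for (fam in names(reports)) {
    rep_df <- reports[[fam]]
    for (i in seq_len(nrow(rep_df))) {
      keys <- rep_df$keys[[i]]
      verdict <- if (rep_df$model[i] == "homozygous") {
        vds <- lapply(keys, function(k)
          check_homozygous(vs, pedigree, fam, k, probands[[fam]]))
        vds[[which.max(vapply(vds, `[[`, logical(1), "consistent"))]]
      } else {
        pairs <- utils::combn(keys, 2L, simplify = FALSE)
        vds <- lapply(pairs, function(p)
          check_compound_het(vs, pedigree, fam, p[1], p[2], probands[[fam]]))
        ok <- vapply(vds, `[[`, logical(1), "consistent")
        vds[[if (any(ok)) which(ok)[1] else 1L]]
      }
      rows[[length(rows) + 1L]] <- {
        df <- data.frame(family = fam, gene = rep_df$gene[i],
                         model = rep_df$model[i],
                         consistent = verdict$consistent,
                         phase = verdict$phase, stringsAsFactors = FALSE)
        df$verdict <- list(verdict)
        df
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), gene = character(0), model = character(0),
               consistent = logical(0), phase = character(0),
               verdict = I(list()), stringsAsFactors = FALSE)
  bad_genes <- unique(out$gene[!out$consistent])
  out$demoted <- out$gene %in% bad_genes
  out
}
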