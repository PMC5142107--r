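tx <- cpamd8_transcript()

test_that("codon arithmetic maps coding positions to residues", {
  expect_identical(codon_of(4351), 1451L)
  expect_identical(codon_of(3), 1L)
  expect_identical(codon_of(2353), 785L)
  expect_identical(codon_of(1), 1L)
  expect_error(codon_of(0), "must be >= 1")
  expect_error(codon_of(6000, tx), "beyond CDS length")
  expect_error(codon_of(4351.5), "integer")
})

test_that("HGVS c. parsing handles the supported variant classes", {
  p <- parse_hgvs_c("c.4351T>C")
  expect_identical(p[c("type", "pos", "ref", "alt")],
                   list(type = "sub", pos = 4351L, ref = "T", alt = "C"))
  p <- parse_hgvs_c("c.700+1G>T")
  expect_identical(p$offset, 1L)
  p <- parse_hgvs_c("c.4549-1G>A")
  expect_identical(p$offset, -1L)
  p <- parse_hgvs_c("c.2352_2353insC")
  expect_identical(p[c("type", "pos", "pos2", "inserted")],
                   list(type = "ins", pos = 2352L, pos2 = 2353L, inserted = "C"))
  expect_identical(parse_hgvs_c("c.10_12del")$pos2, 12L)
  expect_error(parse_hgvs_c("c.10_13insA"), "adjacent")
  expect_error(parse_hgvs_c("g.12345A>T"), "cannot parse")
  expect_error(parse_hgvs_c("c.100A>"), "cannot parse")
})

test_that("splice sites are resolved from intronic HGVS positions", {
  s <- site_of_variant("c.700+1G>T", tx)
  expect_identical(s, list(kind = "donor", intron_index = 7L))
  s <- site_of_variant("c.4549-1G>A", tx)
  expect_identical(s, list(kind = "acceptor", intron_index = 33L))
  s <- site_of_variant("c.4002+1G>A", tx)
  expect_identical(s, list(kind = "donor", intron_index = 29L))
  expect_error(site_of_variant("c.4351T>C", tx), "exonic")
  expect_error(site_of_variant("c.701+1G>T", tx), "no exon ends")
})

test_that("splice events change the cDNA length by the affected base count", {
  len0 <- nchar(tx$cds)
  skip34 <- apply_event(tx, splice_event("exon_skip", exons = 34))
  expect_identical(nchar(skip34), len0 - 63L)
  ret33 <- apply_event(tx, splice_event("intron_retention", intron = 33))
  expect_identical(nchar(ret33), len0 + 78L)
  tx7 <- apply_intronic_variant(tx, "c.700+1G>T")
  cr <- apply_event(tx7, splice_event("cryptic_donor", intron = 7, offset = 142))
  expect_identical(nchar(cr), len0 + 142L)
  expect_error(apply_event(tx7, splice_event("cryptic_donor", intron = 7,
                                             offset = 9999)),
               "exceeds intron")
  # length invariant over random events on toy transcripts
  set.seed(11)
  for (i in 1:50) {
    toy <- random_toy_transcript()
    ev <- random_splice_event(toy)
    mut <- apply_event(toy, ev)
    expected <- switch(ev$kind,
      exon_skip = ,
      multi_exon_skip = -sum(with(toy$exons, (c_end - c_start + 1L)[index %in% ev$exons])),
      intron_retention = nchar(toy$introns[[as.character(ev$intron)]]),
      cryptic_donor = ev$offset,
      cryptic_acceptor = -ev$offset)
    expect_identical(nchar(mut) - nchar(toy$cds), as.integer(expected))
  }
})

test_that("published splice outcomes give the published protein consequences", {
  cc <- consequence(tx, apply_event(tx, splice_event("exon_skip", exons = 34)))
  expect_identical(cc$hgvs_p, "p.Ile1517_Gln1537del")
  expect_identical(cc$category, "inframe_deletion")
  expect_identical(cc$n_residues_changed, 21L)

  cc <- consequence(tx, apply_event(tx, splice_event("intron_retention", intron = 33)))
  expect_identical(cc$hgvs_p, "p.Ala1516_Ile1517ins26")
  expect_identical(cc$n_residues_changed, 26L)

  cc <- consequence(tx, apply_event(tx, splice_event("multi_exon_skip", exons = 33:34)))
  expect_identical(cc$hgvs_p, "p.Asp1465_Gln1537del")
  expect_identical(cc$n_residues_changed, 73L)

  cc <- consequence(tx, apply_event(tx, splice_event("exon_skip", exons = 29)))
  expect_identical(cc$hgvs_p, "p.Gly1310_Glu1334del")
  expect_identical(cc$n_residues_changed, 25L)

  tx7 <- apply_intronic_variant(tx, "c.700+1G>T")
  cc <- consequence(tx7, apply_event(tx7, splice_event("cryptic_donor",
                                                       intron = 7, offset = 142)))
  expect_identical(cc$hgvs_p, "p.Gly234Valfs*30")
  expect_identical(cc$stop_offset, 30L)
  cc <- consequence(tx, apply_event(tx, splice_event("exon_skip", exons = 7)))
  expect_identical(cc$hgvs_p, "p.Asp216Alafs*5")
  cc <- consequence(tx, apply_event(tx, splice_event("multi_exon_skip", exons = 6:7)))
  expect_identical(cc$hgvs_p, "p.Leu210Alafs*5")
})

test_that("small exonic variants give the published protein consequences", {
  cc <- consequence(tx, apply_small_variant(tx, "c.4351T>C"))
  expect_identical(cc$hgvs_p, "p.Ser1451Pro")
  expect_identical(cc$category, "missense")
  expect_identical(cc$first_residue, 1451L)

  cc <- consequence(tx, apply_small_variant(tx, "c.2352_2353insC"))
  expect_identical(cc$hgvs_p, "p.Arg785Glnfs*23")
  expect_identical(cc$first_residue, 785L)
  expect_identical(cc$stop_offset, 23L)

  expect_error(apply_small_variant(tx, "c.4351A>C"), "reference mismatch")
  # deleting a base and re-inserting it restores the sequence
  del <- apply_small_variant(tx, "c.100del")
  toy <- transcript_model("T", data.frame(index = 1, c_start = 1,
                                          c_end = nchar(del)))
  toy$cds <- del
  back <- apply_small_variant(toy, sprintf("c.99_100ins%s",
                                           substr(tx$cds, 100, 100)))
  expect_identical(back, tx$cds)
})

test_that("a synthetic codon-aligned exon skip removes exactly its residues", {
  # toy gene: exon 2 encodes Met-Lys-Leu
  cds <- paste0("ATGGCA", "ATGAAACTG", "GCCTAA")
  toy <- transcript_model("TOY", data.frame(index = 1:3,
                                            c_start = c(1, 7, 16),
                                            c_end = c(6, 15, 21)), cds = cds)
  cc <- consequence(toy, apply_event(toy, splice_event("exon_skip", exons = 2)))
  expect_identical(cc$category, "inframe_deletion")
  expect_identical(cc$n_residues_changed, 3L)
  expect_identical(cc$hgvs_p, "p.Met3_Leu5del")
})

test_that("consequence matches the naive translate-and-diff oracle on random events", {
  set.seed(101)
  for (i in 1:200) {
    toy <- random_toy_transcript()
    ev <- random_splice_event(toy)
    mut <- apply_event(toy, ev)
    got <- consequence(toy, mut)
    want <- naive_consequence(toy$cds, mut)
    expect_identical(got$category, want$category,
                     info = sprintf("trial %d: %s", i, format(ev)[1]))
    expect_identical(got$first_residue, want$first_residue)
    expect_identical(got$n_residues_changed, want$n_residues_changed)
    expect_identical(got$stop_offset, want$stop_offset)
  }
})

test_that("in-frame category occurs iff length change is 0 mod 3 with no premature stop",
{
  # exhaustive over all single-exon skips of a 30-nt ten-codon toy CDS
  cds <- paste0("ATG", "AAA", "CCC", "GGG", "TTT", "ACA", "CAC", "AGA", "GCT", "TAA")
  for (split1 in seq(2, 26, by = 3)) {
    exons <- data.frame(index = 1:3,
                        c_start = c(1, split1 + 1, split1 + 3),
                        c_end = c(split1, split1 + 2, 30))
    toy <- transcript_model("TOY", exons, cds = cds)
    for (ex in 1:2) {
      mut <- apply_event(toy, splice_event("exon_skip", exons = ex))
      cc <- consequence(toy, mut)
      n_removed <- with(toy$exons, c_end[ex] - c_start[ex] + 1L)
      mp <- translate_cds(mut)
      premature <- mp$terminated && mp$stop_index < mp$n_codons
      inframe_expected <- n_removed %% 3L == 0L && mp$terminated && !premature
      expect_identical(cc$category %in% c("inframe_deletion", "inframe_insertion",
                                          "inframe_delins", "synonymous"),
                       inframe_expected)
    }
  }
})

test_that("candidate event enumeration covers the observed aberrant products", {
  # lost acceptor of intron 33: exon-34 skip, intron-33 retention, 33-34 skip
  s <- site_of_variant("c.4549-1G>A", tx)
  evs <- enumerate_candidate_events(s, tx)
  kinds <- vapply(evs, function(e)
    paste0(e$kind, ":", paste(c(e$exons, e$intron), collapse = "-")), character(1))
  expect_true("exon_skip:34" %in% kinds)
  expect_true("intron_retention:33" %in% kinds)
  expect_true(any(grepl("multi_exon_skip:33-34", kinds)))

  # lost donor of intron 7 with the mutant intron sequence: cryptic +142
  tx7 <- apply_intronic_variant(tx, "c.700+1G>T")
  s <- site_of_variant("c.700+1G>T", tx7)
  evs <- enumerate_candidate_events(s, tx7)
  crypt <- Filter(function(e) e$kind == "cryptic_donor", evs)
  expect_true(142L %in% vapply(crypt, `[[`, integer(1), "offset"))
  kinds <- vapply(evs, `[[`, character(1), "kind")
  expect_true("exon_skip" %in% kinds && "multi_exon_skip" %in% kinds)

  # no intron sequence: cryptic candidates omitted, structural ones present
  s <- site_of_variant("c.4002+1G>A", tx)
  evs <- enumerate_candidate_events(s, tx)
  kinds <- vapply(evs, `[[`, character(1), "kind")
  expect_false(any(grepl("cryptic", kinds)))
  expect_true(all(c("exon_skip", "intron_retention", "multi_exon_skip") %in% kinds))
})

test_that("splice_outcomes reports the published products of c.700+1G>T", {
  out <- splice_outcomes(tx, "c.700+1G>T")
  expect_true(all(c("p.Asp216Alafs*5", "p.Leu210Alafs*5", "p.Gly234Valfs*30")
                  %in% out$hgvs_p))
})

test_that("3'-normalization of HGVS p. deletions is idempotent", {
  ref <- "MAAABCDE"
  expect_identical(normalize_hgvs_p("p.Ala2del", ref), "p.Ala4del")
  expect_identical(normalize_hgvs_p(normalize_hgvs_p("p.Ala2del", ref), ref),
                   normalize_hgvs_p("p.Ala2del", ref))
  set.seed(5)
  for (i in 1:50) {
    aa <- paste(sample(c("A", "G", "S"), 12, replace = TRUE), collapse = "")
    a <- sample(10, 1); b <- min(a + sample(0:2, 1), 12)
    aavec <- strsplit(aa, "")[[1]]
    h <- if (a == b) sprintf("p.%s%ddel", varcascade:::aa3(aavec[a]), a)
         else sprintf("p.%s%d_%s%ddel", varcascade:::aa3(aavec[a]), a,
                      varcascade:::aa3(aavec[b]), b)
    once <- normalize_hgvs_p(h, aa)
    expect_identical(normalize_hgvs_p(once, aa), once)
  }
})
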