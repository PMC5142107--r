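# trio pedigree and two-variant fixtures shared by the segregation and
# acceptance suites

trio_ped <- function(sib = FALSE, sib_affected = FALSE) {
  ids <- c("FA", "MO", "PRO", if (sib) "SIB")
  ped <- data.frame(
    family_id = "F",
    individual_id = ids,
    father_id = c("0", "0", "FA", if (sib) "FA"),
    mother_id = c("0", "0", "MO", if (sib) "MO"),
    sex = c("male", "female", "female", if (sib) "male"),
    affected = c(FALSE, FALSE, TRUE, if (sib) sib_affected),
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

two_variant_set <- function(genos) {
  # genos: named list sample -> c(gtA, gtB)
  v <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G",
                  gene = "GENE", stringsAsFactors = FALSE)
  g <- do.call(cbind, lapply(genos, function(x) x))
  variant_set(v, g)
}
keyA <- "1:100:A:G"; keyB <- "1:200:A:G"
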