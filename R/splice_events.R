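#' Describe an aberrant splicing event
#'
#' @param kind One of "exon_skip", "multi_exon_skip", "intron_retention",
#'   "cryptic_donor", "cryptic_acceptor".
#' @param exons Integer vector of exon indices (skip events).
#' @param intron Intron index (retention and cryptic events).
#' @param offset Signed offset in nucleotides for cryptic sites: +k for a
#'   donor (the first k intronic bases stay in the message), -k for an
#'   acceptor (the last k intronic bases stay).
#' @return An object of class `splice_event`.
#' @export
splice_event <- function(kind, exons = NULL, intron = NULL, offset = NULL) {
  kind <- match.arg(kind, c("exon_skip", "multi_exon_skip", "intron_retention",
                            "cryptic_donor", "cryptic_acceptor"))
  if (kind %in% c("exon_skip", "multi_exon_skip")) {
    if (is.null(exons) || !length(exons)) stop("skip event needs exon indices")
    exons <- sort(unique(as.integer(exons)))
    if (kind == "exon_skip" && length(exons) != 1L)
      stop("exon_skip takes a single exon; use multi_exon_skip")
    if (kind == "multi_exon_skip" && length(exons) < 2L)
      stop("multi_exon_skip needs at least two exons")
  } else {
    if (is.null(intron)) stop(kind, " needs an intron index")
    intron <- as.integer(intron)
  }
  if (kind == "cryptic_donor") {
    if (is.null(offset) || offset <= 0L)
      stop("cryptic_donor offset must be positive (+k retains the first k intronic bases)")
  }
  if (kind == "cryptic_acceptor") {
    if (is.null(offset) || offset >= 0L)
      stop("cryptic_acceptor offset must be negative (-k retains the last k intronic bases)")
  }
  structure(list(kind = kind, exons = exons, intron = intron,
                 offset = if (is.null(offset)) NA_integer_ else as.integer(offset)),
            class = "splice_event")
}

#' @export
print.splice_event <- function(x, ...) {
  desc <- switch(x$kind,
    exon_skip = paste("skip exon", x$exons),
    multi_exon_skip = paste("skip exons", paste(range(x$exons), collapse = "-")),
    intron_retention = paste("retain intron", x$intron),
    cryptic_donor = paste0("cryptic donor in intron ", x$intron, " at +", x$offset),
    cryptic_acceptor = paste0("cryptic acceptor in intron ", x$intron, " at ", x$offset))
  cat("Splice event:", desc, "\n")
  invisible(x)
}

#' Apply an aberrant splicing event to a transcript
#'
#' Exon skips remove the skipped exons' bases from the cDNA; intron
#' retention inserts the full intron between its flanking exons; a cryptic
#' donor at +k retains the first k bases of the intron; a cryptic acceptor
#' at -k retains the last k bases. The length change always equals the
#' event's affected base count.
#'
#' @param transcript A `transcript_model` with a coding sequence (and, for
#'   retention/cryptic events, the relevant intron sequence).
#' @param event A `splice_event`.
#' @return The mutant cDNA as a character string.
#' @export
apply_event <- function(transcript, event) {
  stopifnot(inherits(event, "splice_event"))
  if (is.null(transcript$cds)) stop("transcript has no coding sequence")
  cds <- transcript$cds
  ex <- transcript$exons
  n <- nchar(cds)
  get_intron <- function(i) {
    seqc <- transcript$introns[[as.character(i)]]
    if (is.null(seqc))
      stop("no sequence stored for intron ", i, " of ", transcript$gene)
    seqc
  }
  switch(event$kind,
    exon_skip = ,
    multi_exon_skip = {
      if (any(!event$exons %in% ex$index))
        stop("exon index out of range: ", paste(setdiff(event$exons, ex$index), collapse = ","))
      keep <- rep(TRUE, n)
      for (i in event$exons) {
        row <- ex[ex$index == i, ]
        keep[row$c_start:row$c_end] <- FALSE
      }
      paste(strsplit(cds, "")[[1]][keep], collapse = "")
    },
    intron_retention = {
      i <- event$intron
      if (!i %in% ex$index[-nrow(ex)]) stop("intron index out of range: ", i)
      intron <- get_intron(i)
      cut <- ex$c_end[ex$index == i]
      paste0(substr(cds, 1L, cut), intron, substr(cds, cut + 1L, n))
    },
    cryptic_donor = {
      i <- event$intron
      intron <- get_intron(i)
      if (event$offset > nchar(intron))
        stop("cryptic donor offset +", event$offset, " exceeds intron ", i,
             " length (", nchar(intron), ")")
      cut <- ex$c_end[ex$index == i]
      paste0(substr(cds, 1L, cut), substr(intron, 1L, event$offset),
             substr(cds, cut + 1L, n))
    },
    cryptic_acceptor = {
      i <- event$intron
      intron <- get_intron(i)
      k <- -event$offset
      if (k > nchar(intron))
        stop("cryptic acceptor offset ", event$offset, " exceeds intron ", i,
             " length (", nchar(intron), ")")
      cut <- ex$c_end[ex$index == i]
      paste0(substr(cds, 1L, cut),
             substr(intron, nchar(intron) - k + 1L, nchar(intron)),
             substr(cds, cut + 1L, n))
    })
}

#' Enumerate plausible aberrant outcomes of a disrupted splice site
#'
#' When a canonical donor or acceptor is destroyed, the common in-vivo
#' outcomes are skipping of the adjacent exon, skipping of the adjacent
#' exon together with its neighbour, retention of the intron, and use of a
#' nearby cryptic site. The candidate list always contains the first three;
#' cryptic candidates (bare GT dinucleotides downstream of a lost donor,
#' bare AG dinucleotides upstream of a lost acceptor) are added when the
#' intron sequence is available. No splice-strength scoring is attempted.
#'
#' @param site A list as returned by [site_of_variant()].
#' @param transcript A `transcript_model`.
#' @param window Search window (nt) into the intron for cryptic sites.
#' @return A list of `splice_event` objects, single-exon skip first, then
#'   intron retention, then the double skip, then cryptic sites by distance.
#' @export
enumerate_candidate_events <- function(site, transcript, window = 500L) {
  ex <- transcript$exons
  i <- site$intron_index
  events <- list()
  if (site$kind == "donor") {
    events[[length(events) + 1L]] <- splice_event("exon_skip", exons = i)
    events[[length(events) + 1L]] <- splice_event("intron_retention", intron = i)
    if (i >= 2L)
      events[[length(events) + 1L]] <- splice_event("multi_exon_skip", exons = c(i - 1L, i))
  } else {
    events[[length(events) + 1L]] <- splice_event("exon_skip", exons = i + 1L)
    events[[length(events) + 1L]] <- splice_event("intron_retention", intron = i)
    if (i + 2L <= nrow(ex))
      events[[length(events) + 1L]] <- splice_event("multi_exon_skip", exons = c(i, i + 1L))
  }
  intron <- transcript$introns[[as.character(i)]]
  if (!is.null(intron)) {
    len <- nchar(intron)
    if (site$kind == "donor") {
      # a GT starting at intron position k+1 acts as a donor retaining +1..+k
      hits <- gregexpr("(?=GT)", intron, perl = TRUE)[[1]]
      hits <- hits[hits > 1L & hits - 1L <= min(window, len - 2L)]
      for (h in hits)
        events[[length(events) + 1L]] <-
          splice_event("cryptic_donor", intron = i, offset = h - 1L)
    } else {
      # an AG ending at intron position len-k acts as an acceptor retaining the last k bases
      hits <- gregexpr("(?=AG)", intron, perl = TRUE)[[1]]
      hits <- hits[hits > 0L]
      offs <- -(len - (hits + 1L))          # retained suffix length
      sel <- offs < 0L & -offs <= min(window, len - 2L)
      for (o in sort(offs[sel], decreasing = TRUE))
        events[[length(events) + 1L]] <-
          splice_event("cryptic_acceptor", intron = i, offset = o)
    }
  }
  events
}

#' Simulate all candidate outcomes of a splice-site point mutation
#'
#' Convenience wrapper: resolves the disrupted site from the HGVS string,
#' applies the intronic base change to the stored intron (so cryptic-site
#' and retention products carry the mutation), enumerates candidate events
#' and, where sequence allows, computes the protein consequence of each.
#'
#' @param transcript A `transcript_model` with coding sequence.
#' @param cdna_change Intronic HGVS substitution, e.g. "c.4549-1G>A".
#' @param window Cryptic-site search window in nt.
#' @return Data frame with one row per candidate event: `event`, a
#'   description; `category`, `hgvs_p`, `n_residues_changed`, `stop_offset`
#'   from [consequence()] (NA where the needed intron sequence is absent).
#' @export
splice_outcomes <- function(transcript, cdna_change, window = 500L) {
  site <- site_of_variant(cdna_change, transcript)
  tx <- transcript
  key <- as.character(site$intron_index)
  if (!is.null(tx$introns[[key]]))
    tx <- apply_intronic_variant(tx, cdna_change)
  events <- enumerate_candidate_events(site, tx, window = window)
  rows <- lapply(events, function(ev) {
    desc <- switch(ev$kind,
      exon_skip = sprintf("skip exon %d", ev$exons),
      multi_exon_skip = sprintf("skip exons %d-%d", min(ev$exons), max(ev$exons)),
      intron_retention = sprintf("retain intron %d", ev$intron),
      cryptic_donor = sprintf("cryptic donor +%d", ev$offset),
      cryptic_acceptor = sprintf("cryptic acceptor %d", ev$offset))
    cons <- tryCatch(consequence(tx, apply_event(tx, ev)), error = function(e) NULL)
    data.frame(event = desc,
               category = if (is.null(cons)) NA_character_ else cons$category,
               hgvs_p = if (is.null(cons)) NA_character_ else cons$hgvs_p,
               n_residues_changed = if (is.null(cons)) NA_integer_ else cons$n_residues_changed,
               stop_offset = if (is.null(cons)) NA_integer_ else cons$stop_offset,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
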