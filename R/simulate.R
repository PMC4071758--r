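#' Specification for one synthetic gene model
#'
#' Default shape parameters mimic compact multi-exon plant genes of the
#' SPO11 kind: exons of tens to a couple of hundred nt, U2-type introns well
#' above the ~20 nt credibility floor, moderate GC, and UTRs of realistic
#' plant length. Generation is a pure function of the spec: the same spec
#' (including `seed`) yields byte-identical sequences.
#'
#' @param seed integer seed driving all randomness for this gene.
#' @param n_exons number of exons (>= 1).
#' @param exon_len,intron_len length-2 integer ranges (nt) sampled uniformly.
#' @param gc_fraction GC content of UTR/intron sequence.
#' @param utr5_len,utr3_len UTR lengths (nt) on the spliced transcript.
#' @param utr_introns_3 number of introns to place fully inside the 3'UTR.
#' @param stop_free_introns intron indices (over all gaps) whose retention
#'   must not introduce an in-frame stop before the canonical one; these
#'   introns are also forced to a length divisible by 3 so retention
#'   preserves frame (the PTC-free intron-retention case).
#' @param gene_id,species,seqname,strand identifiers; minus-strand specs are
#'   written reverse-complemented on disk and re-oriented at load.
#' @return a `gene_spec` list.
#' @export
gene_spec <- function(seed, n_exons = 11L, exon_len = c(60L, 180L),
                      intron_len = c(60L, 150L), gc_fraction = 0.45,
                      utr5_len = 120L, utr3_len = 200L, utr_introns_3 = 0L,
                      stop_free_introns = integer(),
                      gene_id = sprintf("g%03d", seed %% 1000L),
                      species = "synthetic", seqname = paste0("chr_", gene_id),
                      strand = "+") {
  if (n_exons < 1L) abort("n_exons must be >= 1", class = "splicefate_spec")
  if (exon_len[1] > exon_len[2] || intron_len[1] > intron_len[2]) {
    abort("empty length range", class = "splicefate_spec")
  }
  structure(
    list(
      seed = as.integer(seed), n_exons = as.integer(n_exons),
      exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
      gc_fraction = gc_fraction, utr5_len = as.integer(utr5_len),
      utr3_len = as.integer(utr3_len), utr_introns_3 = as.integer(utr_introns_3),
      stop_free_introns = as.integer(stop_free_introns),
      gene_id = gene_id, species = species, seqname = seqname, strand = strand
    ),
    class = "gene_spec"
  )
}

sample_stop_free_codons <- function(n) {
  if (n <= 0L) return("")
  codons <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  paste(sample(codons, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic gene model from a spec
#'
#' Builds a spliced transcript (5'UTR + ATG + stop-free codons + one terminal
#' stop + 3'UTR), cuts it into `n_exons` exons, and interleaves GT..AG
#' introns. The canonical CDS has no internal in-frame stop by construction.
#' Introns listed in `stop_free_introns` are resampled (bounded retries)
#' until their retention leaves the reading up to the canonical stop
#' stop-free, verified with the naive translation oracle.
#'
#' @param spec a [gene_spec()].
#' @return a validated [gene_model()].
#' @export
gen_gene_model <- function(spec) {
  withr::with_seed(spec$seed, gen_gene_model_impl(spec))
}

sample_range <- function(range, n) {
  vals <- seq(range[1], range[2])
  vals[sample.int(length(vals), n, replace = TRUE)]
}

gen_gene_model_impl <- function(spec) {
  n <- spec$n_exons
  exon_lens <- sample_range(spec$exon_len, n)

  # reserve short 3'-terminal exons when 3'UTR introns are requested
  u3 <- spec$utr_introns_3
  if (u3 > 0L) {
    if (n < u3 + 1L) abort("too few exons for requested 3'UTR introns", class = "splicefate_spec")
    piece <- max(10L, spec$utr3_len %/% (u3 + 2L))
    exon_lens[(n - u3 + 1L):n] <- piece
    if (u3 * piece + 30L > spec$utr3_len) {
      abort("utr3_len too small for requested 3'UTR introns", class = "splicefate_spec")
    }
    # the exon just upstream of the reserved tail must host the stop codon,
    # so the junction before it stays inside the CDS
    need <- spec$utr3_len - u3 * piece + 10L
    exon_lens[n - u3] <- max(exon_lens[n - u3], need)
  }

  spliced_len <- sum(exon_lens)
  cds_len <- spliced_len - spec$utr5_len - spec$utr3_len
  fix <- cds_len %% 3L
  if (fix != 0L) {
    exon_lens[if (u3 > 0L) 1L else n] <- exon_lens[if (u3 > 0L) 1L else n] + (3L - fix)
    spliced_len <- sum(exon_lens)
    cds_len <- cds_len + (3L - fix)
  }
  if (cds_len < 6L) {
    abort("exon lengths cannot accommodate start and stop codons",
      class = "splicefate_spec"
    )
  }

  utr5 <- random_dna(spec$utr5_len, spec$gc_fraction)
  cds <- paste0(
    "ATG", sample_stop_free_codons((cds_len - 6L) %/% 3L),
    sample(STOP_CODONS, 1L)
  )
  utr3 <- random_dna(spec$utr3_len, spec$gc_fraction)
  transcript <- paste0(utr5, cds, utr3)
  stopifnot(nchar(transcript) == spliced_len)

  bounds <- c(0L, cumsum(exon_lens))
  exon_seqs <- substring(transcript, bounds[-length(bounds)] + 1L, bounds[-1L])
  gen_intron <- function(len) {
    paste0("GT", random_dna(len - 4L, spec$gc_fraction), "AG")
  }
  intron_lens <- if (n > 1L) sample_range(spec$intron_len, n - 1L) else integer()
  intron_lens[spec$stop_free_introns] <-
    intron_lens[spec$stop_free_introns] %/% 3L * 3L
  if (any(intron_lens < max(4L, 20L))) intron_lens <- pmax(intron_lens, 20L)
  intron_seqs <- vapply(intron_lens, gen_intron, character(1))

  cds_start <- spec$utr5_len
  cds_span <- c(cds_start, cds_start + cds_len)

  # resample stop-free introns until retention keeps the frame clean
  for (i in spec$stop_free_introns) {
    if (i < 1L || i > n - 1L) abort("stop_free_introns index out of range", class = "splicefate_spec")
    ok <- FALSE
    for (try in 1:1000) {
      retained <- paste0(
        paste(exon_seqs[1:i], collapse = ""), intron_seqs[i],
        paste(exon_seqs[(i + 1L):n], collapse = "")
      )
      var_cds <- substring(retained, cds_start + 1L)
      tr <- oracle_scan_protein(var_cds)
      if (tr$stop_found && tr$length_aa == (cds_len + intron_lens[i]) %/% 3L - 1L) {
        ok <- TRUE
        break
      }
      intron_seqs[i] <- gen_intron(intron_lens[i])
    }
    if (!ok) {
      abort(sprintf("could not build stop-free intron %d", i), class = "splicefate_spec")
    }
  }

  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- exon_seqs
  if (n > 1L) pieces[seq(2L, 2L * n - 2L, by = 2L)] <- intron_seqs
  genome <- paste(pieces, collapse = "")

  starts <- integer(n)
  pos <- 0L
  exons <- vector("list", n)
  for (k in seq_len(n)) {
    exons[[k]] <- tibble::tibble(start = pos, end = pos + exon_lens[k])
    pos <- pos + exon_lens[k] + if (k < n) intron_lens[k] else 0L
  }

  gene_model(
    gene_id = spec$gene_id, genome = genome, exons = dplyr::bind_rows(exons),
    cds_span = cds_span, species = spec$species, strand = spec$strand,
    seqname = spec$seqname
  )
}

## ---- naive oracles (kept deliberately simple and separate) ----------------

#' Naive codon-walk translation oracle
#'
#' Character-by-character scan against a hard-coded stop set; used to write
#' expected outcomes into synthetic manifests so that tests of the main
#' translation/ORF path are not self-confirming.
#'
#' @param cds nucleotide string starting at the start codon.
#' @return list with `length_aa` and `stop_found`.
#' @export
oracle_scan_protein <- function(cds) {
  n <- nchar(cds)
  i <- 1L
  aa <- 0L
  while (i + 2L <= n) {
    codon <- substr(cds, i, i + 2L)
    if (codon == "TAA" || codon == "TAG" || codon == "TGA") {
      return(list(length_aa = aa, stop_found = TRUE))
    }
    aa <- aa + 1L
    i <- i + 3L
  }
  list(length_aa = aa, stop_found = FALSE)
}

#' Naive variant-protein oracle from a chain
#'
#' Pastes the chain sequence directly and scans from the canonical start
#' position found by plain coordinate arithmetic.
#'
#' @param model a [gene_model()].
#' @param chain variant exon chain tibble.
#' @return list with `length_aa`, `stop_found`, `start_present`.
#' @export
oracle_variant_protein <- function(model, chain) {
  g_start <- spliced_to_local(model$exons, model$cds_span[1])
  seqs <- substring(model$genome, chain$start + 1L, chain$end)
  full <- paste(seqs, collapse = "")
  # locate start by walking the chain
  offset <- 0L
  start_at <- NA_integer_
  for (k in seq_len(nrow(chain))) {
    if (chain$start[k] <= g_start && g_start < chain$end[k]) {
      start_at <- offset + (g_start - chain$start[k])
      break
    }
    offset <- offset + (chain$end[k] - chain$start[k])
  }
  if (is.na(start_at)) {
    return(list(
      length_aa = 0L, stop_found = FALSE, start_present = FALSE,
      stop_local = NA_integer_
    ))
  }
  res <- oracle_scan_protein(substring(full, start_at + 1L))
  stop_local <- NA_integer_
  if (res$stop_found) {
    # walk the chain to the locus coordinate of the stop codon's first base
    target <- start_at + 3L * res$length_aa
    off <- 0L
    for (k in seq_len(nrow(chain))) {
      w <- chain$end[k] - chain$start[k]
      if (target < off + w) {
        stop_local <- chain$start[k] + (target - off)
        break
      }
      off <- off + w
    }
  }
  c(res, list(start_present = TRUE, stop_local = stop_local))
}

#' Naive PTC oracle: is the variant's first stop the canonical stop codon?
#' @param model a [gene_model()].
#' @param chain variant exon chain.
#' @return logical: `TRUE` when the variant has a premature (or no) stop.
#' @export
oracle_variant_ptc <- function(model, chain) {
  o <- oracle_variant_protein(model, chain)
  if (!o$start_present || !o$stop_found) return(TRUE)
  canon_stop <- oracle_variant_protein(model, model$exons)$stop_local
  o$stop_local != canon_stop
}

#' Naive three-frame uORF scanner oracle
#' @param utr5 5'UTR string.
#' @return integer uORF count (terminating within the UTR).
#' @export
oracle_uorf_count <- function(utr5) {
  n <- nchar(utr5)
  count <- 0L
  if (n < 6L) return(count)
  for (i in seq_len(n - 2L)) {
    if (substr(utr5, i, i + 2L) == "ATG") {
      j <- i + 3L
      while (j + 2L <= n) {
        cod <- substr(utr5, j, j + 2L)
        if (cod == "TAA" || cod == "TAG" || cod == "TGA") {
          count <- count + 1L
          break
        }
        j <- j + 3L
      }
    }
  }
  count
}

## ---- event application ----------------------------------------------------

event_junctions <- function(type, anchor, n_exons) {
  # which canonical junctions (donor D_i / acceptor A_i of intron i) an event
  # consumes; used to reject conflicting specs
  switch(type,
    IR = c(sprintf("D%d", anchor), sprintf("A%d", anchor)),
    Alt5SS = sprintf("D%d", anchor),
    Alt3SS = sprintf("A%d", anchor),
    ES = c(
      if (anchor > 1L) sprintf("A%d", anchor - 1L),
      if (anchor < n_exons) sprintf("D%d", anchor)
    )
  )
}

#' Realize a set of splice events as a variant exon chain
#'
#' Builds, from the canonical model, the chain realizing exactly the
#' requested events, with ground-truth labels attached so classification can
#' be checked against construction. Events that would consume the same
#' canonical splice junction (e.g. `IR` of intron 3 together with `Alt5SS` on
#' intron 3) are rejected as conflicting. AltSS deltas must leave at least
#' 1 nt of exon (negative delta) or a residual gap of at least the model's
#' minimum intron length (positive delta).
#'
#' @param model a [gene_model()].
#' @param event_specs tibble (or data.frame) with `type`, `anchor`, `delta`
#'   (delta is ignored for `IR`/`ES`, required for AltSS). Empty spec gives
#'   the canonical chain.
#' @param form_id,tissues,provenance metadata attached to the output row.
#' @return one-row forms tibble: `form_id`, `gene_id`, `chain`, `tissues`,
#'   `provenance`, `truth` (list-column of the normalized expected events).
#' @export
apply_events <- function(model, event_specs = NULL, form_id = "form",
                         tissues = character(), provenance = "synthetic") {
  ex <- model$exons
  n <- nrow(ex)
  gaps <- intron_gap_table(model)
  ev <- if (is.null(event_specs) || nrow(event_specs) == 0L) {
    tibble::tibble(type = character(), anchor = integer(), delta = integer())
  } else {
    tibble::as_tibble(event_specs)
  }
  if (!"delta" %in% names(ev)) ev$delta <- NA_integer_

  used <- character()
  for (i in seq_len(nrow(ev))) {
    j <- event_junctions(ev$type[i], ev$anchor[i], n)
    if (any(j %in% used)) {
      abort("conflicting events on the same splice junction", class = "splicefate_spec")
    }
    used <- c(used, j)
  }

  start_shift <- rep(0L, n) # applied to exon starts (Alt3SS on upstream intron)
  end_shift <- rep(0L, n) # applied to exon ends (Alt5SS on downstream intron)
  drop_exon <- rep(FALSE, n)
  merge_gap <- rep(FALSE, max(n - 1L, 0L))
  truth <- list()

  for (i in seq_len(nrow(ev))) {
    type <- ev$type[i]
    a <- as.integer(ev$anchor[i])
    d <- as.integer(ev$delta[i])
    if (type == "IR") {
      if (a < 1L || a > n - 1L) abort("IR anchor out of range", class = "splicefate_spec")
      merge_gap[a] <- TRUE
      truth[[length(truth) + 1L]] <- tibble::tibble(
        type = "IR", anchor = a, delta_nt = gaps$length[a]
      )
    } else if (type == "ES") {
      if (a < 2L || a > n - 1L) {
        abort("ES anchor must be an internal exon", class = "splicefate_spec")
      }
      drop_exon[a] <- TRUE
      truth[[length(truth) + 1L]] <- tibble::tibble(
        type = "ES", anchor = a, delta_nt = -(ex$end[a] - ex$start[a])
      )
    } else if (type == "Alt5SS") {
      if (a < 1L || a > n - 1L || is.na(d) || d == 0L) {
        abort("Alt5SS needs an intron anchor and nonzero delta", class = "splicefate_spec")
      }
      if (d > 0L && gaps$length[a] - d < model$min_intron) {
        abort("Alt5SS delta leaves too short a residual intron", class = "splicefate_spec")
      }
      if (d < 0L && ex$end[a] - ex$start[a] + d < 1L) {
        abort("Alt5SS delta consumes the whole exon", class = "splicefate_spec")
      }
      end_shift[a] <- d
      truth[[length(truth) + 1L]] <- tibble::tibble(
        type = "Alt5SS", anchor = a, delta_nt = d
      )
    } else if (type == "Alt3SS") {
      if (a < 1L || a > n - 1L || is.na(d) || d == 0L) {
        abort("Alt3SS needs an intron anchor and nonzero delta", class = "splicefate_spec")
      }
      if (d > 0L && gaps$length[a] - d < model$min_intron) {
        abort("Alt3SS delta leaves too short a residual intron", class = "splicefate_spec")
      }
      if (d < 0L && ex$end[a + 1L] - ex$start[a + 1L] + d < 1L) {
        abort("Alt3SS delta consumes the whole exon", class = "splicefate_spec")
      }
      start_shift[a + 1L] <- -d
      truth[[length(truth) + 1L]] <- tibble::tibble(
        type = "Alt3SS", anchor = a, delta_nt = d
      )
    } else {
      abort(sprintf("unknown event type '%s'", type), class = "splicefate_spec")
    }
  }

  segs <- list()
  open_start <- NA_integer_
  for (k in seq_len(n)) {
    if (drop_exon[k]) next
    s <- ex$start[k] + start_shift[k]
    e <- ex$end[k] + end_shift[k]
    if (is.na(open_start)) open_start <- s
    if (k < n && merge_gap[k] && !drop_exon[k + 1L]) {
      next # keep segment open through the retained intron
    }
    # close segment: from open_start to this exon's (possibly shifted) end,
    # but if we merged through, start was set when opened
    segs[[length(segs) + 1L]] <- tibble::tibble(start = open_start, end = e)
    open_start <- NA_integer_
  }
  chain <- dplyr::bind_rows(segs)

  truth_tbl <- if (length(truth) == 0L) empty_events() else {
    sort_events(dplyr::bind_rows(truth))
  }
  tibble::tibble(
    form_id = form_id, gene_id = model$gene_id, chain = list(chain),
    tissues = list(tissues), provenance = provenance, truth = list(truth_tbl)
  )
}
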