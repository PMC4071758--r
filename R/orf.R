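#' Translate a coding sequence to its first in-frame stop
#'
#' Standard genetic code; translation halts at the first in-frame stop codon
#' and the returned protein excludes it. Codons containing ambiguity codes
#' (N, etc.) translate to `X` and never count as stop codons. A sequence not
#' starting with `ATG` is translated anyway but flagged with a warning.
#'
#' @param cds nucleotide string, length >= 3.
#' @return list with `protein` (character), `length_aa` (integer, excludes
#'   the stop), `stop_found` (logical).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) abort("CDS shorter than one codon", class = "splicefate_input")
  if (substring(cds, 1L, 3L) != "ATG") {
    warn("CDS does not start with ATG; translating anyway")
  }
  n_codon <- nchar(cds) %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X" # ambiguity codes: never a stop
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0L) {
    prot <- paste(aa[seq_len(stop_at[1] - 1L)], collapse = "")
    list(protein = prot, length_aa = stop_at[1] - 1L, stop_found = TRUE)
  } else {
    list(protein = paste(aa, collapse = ""), length_aa = n_codon, stop_found = FALSE)
  }
}

canonical_protein_length <- function(model) {
  (model$cds_span[2] - model$cds_span[1]) %/% 3L - 1L
}

#' ORF analysis of one splice variant
#'
#' Builds the variant CDS from the canonical start codon, translates to the
#' first in-frame stop, and asks whether that stop is the canonical one: a
#' premature termination codon (PTC) is called iff the first stop does not
#' start at the genomic position of the canonical stop codon (same coordinate
#' implies the same reading frame at that point, since codon boundaries
#' coincide). Under this positional definition a frame-preserving event that
#' lengthens or shortens the protein without introducing a new stop is still
#' PTC-free and is called putatively functional.
#'
#' The exon-junction heuristic used for NMD in many systems (stop more than
#' 50 nt upstream of the last exon junction) is available as a secondary
#' flag via `junction_rule = TRUE`; it never affects `ptc` itself.
#'
#' @param model a [gene_model()].
#' @param chain variant exon chain tibble.
#' @param junction_rule also report the 50-nt exon-junction flag
#'   (`ejc_rule`); default off.
#' @return one-row tibble: `protein_length_aa`, `ptc`, `stop_class`
#'   (`canonical` / `premature` / `none_found`), `delta_aa`,
#'   `functional_call`, `start_lost`, `stop_spliced_pos` (0-based position of
#'   the stop codon in the variant transcript, `NA` if none), and optionally
#'   `ejc_rule`.
#' @export
analyze_orf <- function(model, chain, junction_rule = FALSE) {
  canon_len <- canonical_protein_length(model)
  out <- tibble::tibble(
    protein_length_aa = 0L, ptc = TRUE, stop_class = "none_found",
    delta_aa = -canon_len, functional_call = FALSE, start_lost = TRUE,
    stop_spliced_pos = NA_integer_
  )
  cds <- extract_spliced_cds(model, chain)
  if (isTRUE(attr(cds, "start_lost"))) {
    if (junction_rule) out$ejc_rule <- NA
    return(out)
  }
  tr <- suppressWarnings(translate_cds(cds))
  out$start_lost <- FALSE
  out$protein_length_aa <- tr$length_aa
  out$delta_aa <- tr$length_aa - canon_len

  g_start <- spliced_to_local(model$exons, model$cds_span[1])
  c0 <- local_to_spliced(chain, g_start) # variant spliced pos of start
  if (!tr$stop_found) {
    out$stop_class <- "none_found"
    out$ptc <- TRUE
    out$functional_call <- FALSE
  } else {
    stop_var_spliced <- c0 + 3L * tr$length_aa
    stop_var_local <- spliced_to_local(chain, stop_var_spliced)
    canon_stop_local <- spliced_to_local(model$exons, model$cds_span[2] - 3L)
    canonical_stop <- identical(stop_var_local, canon_stop_local)
    out$stop_class <- if (canonical_stop) "canonical" else "premature"
    out$ptc <- !canonical_stop
    out$functional_call <- canonical_stop
    out$stop_spliced_pos <- stop_var_spliced
  }
  if (junction_rule) {
    out$ejc_rule <- if (is.na(out$stop_spliced_pos)) {
      NA
    } else {
      junctions <- exon_spliced_offsets(chain)
      last_junction <- if (nrow(chain) > 1L) junctions[nrow(chain)] else NA_integer_
      !is.na(last_junction) && (last_junction - (out$stop_spliced_pos + 3L)) > 50L
    }
  }
  out
}

#' ORF analysis across a forms tibble
#'
#' @param forms classified forms tibble (needs `chain`; keeps `form_id` etc.).
#' @param model a [gene_model()].
#' @param junction_rule see [analyze_orf()].
#' @return tibble with one ORF report row per form, prefixed by `gene_id`,
#'   `form_id` (and `form_name` when present).
#' @export
analyze_orfs <- function(forms, model, junction_rule = FALSE) {
  reps <- purrr::map(forms$chain, ~ analyze_orf(model, .x, junction_rule))
  id_cols <- intersect(c("gene_id", "form_id", "form_name", "form_ascii"), names(forms))
  dplyr::bind_cols(forms[, id_cols, drop = FALSE], dplyr::bind_rows(reps))
}

#' Detect upstream ORFs in a 5'UTR
#'
#' Every `ATG` in the 5'UTR that opens a reading frame terminated by a stop
#' codon while still inside the UTR counts as one uORF. ATGs whose frame runs
#' into the main CDS without meeting a UTR stop are counted separately as
#' overlapping uORFs and excluded from `uorf_count`.
#'
#' @param utr5 5'UTR nucleotide string (possibly empty).
#' @return one-row tibble: `uorf_count`, `overlapping_count`, and `spans`
#'   (list-column tibble of `start`, `end`, 0-based half-open within the UTR,
#'   stop codon included).
#' @export
detect_uorfs <- function(utr5) {
  utr5 <- toupper(utr5 %||% "")
  n <- nchar(utr5)
  empty <- tibble::tibble(
    uorf_count = 0L, overlapping_count = 0L,
    spans = list(tibble::tibble(start = integer(), end = integer()))
  )
  if (n < 3L) return(empty)
  starts <- gregexpr("ATG", utr5, fixed = TRUE)[[1]]
  if (starts[1] == -1L) return(empty)
  spans <- list()
  n_over <- 0L
  for (s in starts) { # s is 1-based
    found <- FALSE
    j <- s + 3L
    while (j + 2L <= n) {
      if (substring(utr5, j, j + 2L) %in% STOP_CODONS) {
        spans[[length(spans) + 1L]] <- tibble::tibble(start = s - 1L, end = j + 2L)
        found <- TRUE
        break
      }
      j <- j + 3L
    }
    if (!found) n_over <- n_over + 1L
  }
  tibble::tibble(
    uorf_count = length(spans), overlapping_count = n_over,
    spans = list(dplyr::bind_rows(c(spans, list(empty$spans[[1]]))))
  )
}

#' Annotate NMD-candidate features of one splice variant
#'
#' Computes, from the gene model and the variant's ORF report, the features
#' commonly associated with nonsense-mediated decay in plants: uORFs in the
#' variant 5'UTR, a long 3'UTR (variant stop to transcript end, default
#' threshold 350 nt), and a splice junction (canonical intron) fully
#' downstream of the variant stop codon. The report flags candidate features
#' only; it never claims actual NMD targeting.
#'
#' @param model a [gene_model()].
#' @param chain variant exon chain.
#' @param orf one-row ORF report from [analyze_orf()] for the same chain.
#' @param long_3utr_threshold nt above which a 3'UTR is flagged long.
#' @return one-row tibble: `uorf_count`, `utr3_len`, `long_3utr`,
#'   `intron_in_3utr`.
#' @export
annotate_nmd_features <- function(model, chain, orf,
                                  long_3utr_threshold = 350L) {
  var_len <- sum(interval_widths(chain))
  if (is.na(orf$stop_spliced_pos)) {
    utr3_len <- 0L
    introns_downstream <- 0L
    uorf_count <- NA_integer_
  } else {
    utr3_len <- var_len - (orf$stop_spliced_pos + 3L)
    # canonical introns still spliced in the variant, fully 3' of the stop
    stop_local_end <- spliced_to_local(chain, orf$stop_spliced_pos) + 3L
    gaps <- intron_gap_table(model)
    spliced_out <- purrr::map_lgl(seq_len(nrow(gaps)), function(i) {
      !chain_covers(chain, gaps$start[i]) && !chain_covers(chain, gaps$end[i] - 1L)
    })
    introns_downstream <- sum(spliced_out & gaps$start >= stop_local_end)
    g_start <- spliced_to_local(model$exons, model$cds_span[1])
    c0 <- local_to_spliced(chain, g_start)
    var_utr5 <- substring(chain_seq(model$genome, chain), 1L, c0)
    uorf_count <- detect_uorfs(var_utr5)$uorf_count
  }
  tibble::tibble(
    uorf_count = uorf_count,
    utr3_len = as.integer(utr3_len),
    long_3utr = utr3_len > long_3utr_threshold,
    intron_in_3utr = introns_downstream > 0L,
    introns_in_3utr = as.integer(introns_downstream)
  )
}

#' NMD-candidate features across a forms tibble
#'
#' @param forms forms tibble with `chain`.
#' @param model a [gene_model()].
#' @param orfs ORF table from [analyze_orfs()] (same row order).
#' @param long_3utr_threshold see [annotate_nmd_features()].
#' @return tibble of per-form NMD feature rows with id columns.
#' @export
annotate_nmd <- function(forms, model, orfs, long_3utr_threshold = 350L) {
  stopifnot(nrow(forms) == nrow(orfs))
  reps <- purrr::map(seq_len(nrow(forms)), function(i) {
    annotate_nmd_features(model, forms$chain[[i]], orfs[i, ], long_3utr_threshold)
  })
  id_cols <- intersect(c("gene_id", "form_id", "form_name", "form_ascii"), names(forms))
  dplyr::bind_cols(forms[, id_cols, drop = FALSE], dplyr::bind_rows(reps))
}
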