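#' Gene model objects
#'
#' A `gene_model` holds the canonical exon/intron architecture of one gene in
#' transcript orientation: the locus sequence (reverse-complemented at load
#' time for minus-strand genes), the ordered exon intervals, and the CDS span
#' in spliced-transcript coordinates. All downstream operations (splice-form
#' classification, ORF analysis, intron projection) consume this object, so
#' strand and coordinate-base conversions are confined to this file.
#'
#' Internal coordinates are 0-based half-open on the oriented locus; GFF3 disk
#' coordinates (1-based inclusive, native strand) are converted only in
#' [load_gene_model()] and [write_gene_model()].
#'
#' @param gene_id gene identifier.
#' @param genome oriented locus nucleotide sequence (character scalar).
#' @param exons tibble with `start`, `end` (0-based half-open, ascending,
#'   transcript 5'->3').
#' @param cds_span length-2 integer, CDS start/end in spliced coordinates
#'   (0-based half-open).
#' @param species species label used to match species-tree leaves.
#' @param strand original strand on disk, `"+"` or `"-"`.
#' @param seqname sequence (chromosome/scaffold) name on disk.
#' @param min_intron minimum credible intron length in nt; shorter inter-exon
#'   gaps fail validation as likely annotation artifacts.
#' @return a validated `gene_model` object.
#' @export
gene_model <- function(gene_id, genome, exons, cds_span, species = NA_character_,
                       strand = "+", seqname = gene_id, min_intron = 20L) {
  exons <- tibble::as_tibble(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  m <- structure(
    list(
      gene_id = gene_id,
      species = species,
      strand = strand,
      seqname = seqname,
      genome = genome,
      exons = exons,
      cds_span = as.integer(cds_span),
      min_intron = as.integer(min_intron)
    ),
    class = "gene_model"
  )
  validate_gene_model(m)
}

validate_gene_model <- function(m) {
  validate_intervals(m$exons, paste0("gene ", m$gene_id, ": exons"))
  if (nrow(m$exons) > 1L) {
    gaps <- m$exons$start[-1L] - m$exons$end[-nrow(m$exons)]
    if (any(gaps < m$min_intron)) {
      abort(sprintf(
        "gene %s: intron of %d nt below minimum intron length (%d nt)",
        m$gene_id, min(gaps), m$min_intron
      ), class = "splicefate_validation")
    }
  }
  if (max(m$exons$end) > nchar(m$genome)) {
    abort(sprintf("gene %s: exon beyond sequence end", m$gene_id),
      class = "splicefate_validation"
    )
  }
  cds_len <- m$cds_span[2] - m$cds_span[1]
  if (cds_len %% 3L != 0L || cds_len < 6L) {
    abort(sprintf(
      "gene %s: CDS length %d is not a multiple of 3 (or < 6 nt)",
      m$gene_id, cds_len
    ), class = "splicefate_validation")
  }
  if (m$cds_span[1] < 0L || m$cds_span[2] > spliced_length(m)) {
    abort(sprintf("gene %s: CDS span outside spliced transcript", m$gene_id),
      class = "splicefate_validation"
    )
  }
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model %s [%s]> %d exons / %d introns, spliced %d nt, CDS %d nt (%s strand)\n",
    x$gene_id, x$species, nrow(x$exons), nrow(x$exons) - 1L,
    spliced_length(x), x$cds_span[2] - x$cds_span[1], x$strand
  ))
  invisible(x)
}

spliced_length <- function(m) sum(interval_widths(m$exons))

exon_spliced_offsets <- function(exons) {
  c(0L, cumsum(exons$end - exons$start))
}

#' Map spliced-transcript coordinates to oriented-locus coordinates
#'
#' @param exons exon/chain interval tibble (0-based half-open).
#' @param spos spliced positions (0-based).
#' @return integer locus positions (0-based).
#' @keywords internal
spliced_to_local <- function(exons, spos) {
  off <- exon_spliced_offsets(exons)
  vapply(spos, function(s) {
    k <- findInterval(s, off)
    if (k < 1L || k > nrow(exons) || s >= off[k + 1L]) {
      abort(sprintf("spliced position %d outside transcript", s))
    }
    exons$start[k] + (s - off[k])
  }, integer(1))
}

# locus position -> spliced coordinate within a chain; NA when not covered
local_to_spliced <- function(exons, gpos) {
  off <- exon_spliced_offsets(exons)
  vapply(gpos, function(g) {
    k <- which(exons$start <= g & g < exons$end)
    if (length(k) == 0L) return(NA_integer_)
    off[k] + (g - exons$start[k])
  }, integer(1))
}

chain_covers <- function(chain, gpos) {
  any(chain$start <= gpos & gpos < chain$end)
}

# concatenated sequence of chain segments in transcript orientation
chain_seq <- function(genome, chain) {
  paste(substring(genome, chain$start + 1L, chain$end), collapse = "")
}

canonical_chain <- function(m) m$exons

# spliced range [s, e) -> per-exon locus intervals
spliced_range_to_local <- function(exons, s, e) {
  off <- exon_spliced_offsets(exons)
  out <- list()
  for (k in seq_len(nrow(exons))) {
    a <- max(s, off[k])
    b <- min(e, off[k + 1L])
    if (a < b) {
      out[[length(out) + 1L]] <- tibble::tibble(
        start = exons$start[k] + (a - off[k]),
        end = exons$start[k] + (b - off[k])
      )
    }
  }
  dplyr::bind_rows(out)
}

# every inter-exon gap, annotated with the transcript region of its junction
intron_gap_table <- function(m) {
  ex <- m$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(tibble::tibble(
      gap_index = integer(), start = integer(), end = integer(),
      length = integer(), junction_spliced = integer(), region = character()
    ))
  }
  junction <- exon_spliced_offsets(ex)[2:n]
  tibble::tibble(
    gap_index = seq_len(n - 1L),
    start = ex$end[-n],
    end = ex$start[-1L],
    length = ex$start[-1L] - ex$end[-n],
    junction_spliced = junction,
    region = dplyr::case_when(
      junction <= m$cds_span[1] ~ "utr5",
      junction >= m$cds_span[2] ~ "utr3",
      TRUE ~ "cds"
    )
  )
}

#' Derive intron records from a gene model
#'
#' Returns one record per inter-exon gap whose junction falls inside the CDS,
#' with the coding offset (nt of coding sequence 5' of the intron) and the
#' intron phase (`cds_offset mod 3`). Introns fully inside the UTRs are not
#' listed here; their counts are available via [utr_intron_counts()].
#'
#' @param model a [gene_model()].
#' @return tibble with `intron_index` (1-based ordinal over CDS introns),
#'   `gap_index` (ordinal over all inter-exon gaps), locus `start`/`end`,
#'   `length`, `cds_offset`, `phase`.
#' @export
derive_introns <- function(model) {
  gaps <- intron_gap_table(model)
  cds <- gaps[gaps$region == "cds", , drop = FALSE]
  tibble::tibble(
    gene_id = model$gene_id,
    intron_index = seq_len(nrow(cds)),
    gap_index = cds$gap_index,
    start = cds$start,
    end = cds$end,
    length = cds$length,
    cds_offset = cds$junction_spliced - model$cds_span[1],
    phase = (cds$junction_spliced - model$cds_span[1]) %% 3L
  )
}

#' Count introns lying fully inside the UTRs
#'
#' @param model a [gene_model()].
#' @return named integer vector with elements `utr5` and `utr3`.
#' @export
utr_intron_counts <- function(model) {
  gaps <- intron_gap_table(model)
  c(
    utr5 = sum(gaps$region == "utr5"),
    utr3 = sum(gaps$region == "utr3")
  )
}

#' UTR lengths of the canonical transcript
#' @param model a [gene_model()].
#' @return named integer vector with `utr5` and `utr3` lengths in nt.
#' @export
utr_lengths <- function(model) {
  c(
    utr5 = model$cds_span[1],
    utr3 = spliced_length(model) - model$cds_span[2]
  )
}

#' Extract the (variant) coding sequence implied by an exon chain
#'
#' Concatenates the chain segments in transcript orientation and slices from
#' the locus position of the canonical start codon. When the chain does not
#' contain that position (the start codon was lost by the variant), the full
#' spliced sequence is returned and the `start_lost` attribute is `TRUE`.
#'
#' @param model a [gene_model()].
#' @param chain exon-chain tibble (`start`, `end`, 0-based half-open); default
#'   the canonical chain.
#' @return character scalar with attribute `start_lost` (logical).
#' @export
extract_spliced_cds <- function(model, chain = NULL) {
  chain <- chain %||% canonical_chain(model)
  validate_intervals(chain, "chain")
  if (max(chain$end) > nchar(model$genome) || min(chain$start) < 0L) {
    abort("chain interval outside sequence bounds", class = "splicefate_range")
  }
  g_start <- spliced_to_local(model$exons, model$cds_span[1])
  full <- chain_seq(model$genome, chain)
  if (!chain_covers(chain, g_start)) {
    return(structure(full, start_lost = TRUE))
  }
  c0 <- local_to_spliced(chain, g_start)
  structure(substring(full, c0 + 1L), start_lost = FALSE)
}

## ---- GFF3 / FASTA input ---------------------------------------------------

read_fasta_seq <- function(fasta_path, seqname = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  if (is.null(seqname)) {
    return(ss)
  }
  if (!seqname %in% names(ss)) {
    abort(sprintf("sequence '%s' not found in %s", seqname, fasta_path),
      class = "splicefate_not_found"
    )
  }
  as.character(ss[[seqname]])
}

# disk (1-based inclusive, native strand) -> local oriented 0-based half-open
disk_to_local <- function(start1, end1, strand, seqlen) {
  if (strand == "-") {
    tibble::tibble(start = seqlen - end1, end = seqlen - start1 + 1L)
  } else {
    tibble::tibble(start = start1 - 1L, end = end1)
  }
}

local_to_disk <- function(iv, strand, seqlen) {
  if (strand == "-") {
    tibble::tibble(start = seqlen - iv$end + 1L, end = seqlen - iv$start)
  } else {
    tibble::tibble(start = iv$start + 1L, end = iv$end)
  }
}

gff_children <- function(gr, parent_id, type) {
  mc <- S4Vectors::mcols(gr)
  keep <- mc$type %in% type &
    vapply(mc$Parent, function(p) parent_id %in% p, logical(1))
  gr[keep]
}

#' Load a gene model from GFF3 + FASTA
#'
#' Reads gene/mRNA/exon/CDS features for one gene, picks the canonical mRNA
#' (longest CDS; ties broken by lexicographic mRNA id), reverse-complements
#' minus-strand genes, and returns a validated transcript-oriented
#' [gene_model()]. Fails closed: a missing gene id, a CDS not divisible by 3,
#' or overlapping exons each raise a classed error naming the gene.
#'
#' @param gff3_path path to a GFF3 annotation.
#' @param fasta_path path to the genomic FASTA holding the parent sequence.
#' @param gene_id the gene to load.
#' @param species optional species label; when absent, a `species` attribute
#'   on the gene feature is used if present.
#' @param min_intron minimum intron length accepted (nt).
#' @return a [gene_model()].
#' @export
load_gene_model <- function(gff3_path, fasta_path, gene_id,
                            species = NULL, min_intron = 20L) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  gi <- which(mc$type == "gene" & !is.na(mc$ID) & mc$ID == gene_id)
  if (length(gi) == 0L) {
    abort(sprintf("gene '%s' not found in %s", gene_id, gff3_path),
      class = "splicefate_not_found"
    )
  }
  gene <- gr[gi[1]]
  strand <- as.character(BiocGenerics::strand(gene))
  if (!strand %in% c("+", "-")) strand <- "+"
  seqname <- as.character(GenomicRanges::seqnames(gene))
  if (is.null(species)) {
    species <- if ("species" %in% names(mc)) mc$species[gi[1]] else NA_character_
    species <- species %||% NA_character_
  }

  mrnas <- gff_children(gr, gene_id, c("mRNA", "transcript"))
  if (length(mrnas) == 0L) {
    abort(sprintf("gene '%s': no mRNA features", gene_id),
      class = "splicefate_validation"
    )
  }
  mrna_ids <- S4Vectors::mcols(mrnas)$ID
  cds_len_of <- vapply(mrna_ids, function(id) {
    sum(BiocGenerics::width(gff_children(gr, id, "CDS")))
  }, numeric(1))
  ord <- order(-cds_len_of, mrna_ids)
  canon_id <- mrna_ids[ord[1]]

  exon_gr <- gff_children(gr, canon_id, "exon")
  cds_gr <- gff_children(gr, canon_id, "CDS")
  if (length(exon_gr) == 0L || length(cds_gr) == 0L) {
    abort(sprintf("gene '%s': canonical mRNA lacks exon or CDS features", gene_id),
      class = "splicefate_validation"
    )
  }

  chrom <- read_fasta_seq(fasta_path, seqname)
  seqlen <- nchar(chrom)
  genome <- if (strand == "-") revcomp(chrom) else chrom

  to_local <- function(g) {
    iv <- disk_to_local(BiocGenerics::start(g), BiocGenerics::end(g), strand, seqlen)
    iv[order(iv$start), , drop = FALSE]
  }
  exons <- to_local(exon_gr)
  cds_iv <- to_local(cds_gr)

  validate_intervals(exons, paste0("gene ", gene_id, ": exons"))
  cds_len <- sum(interval_widths(cds_iv))
  sp_first <- local_to_spliced(exons, min(cds_iv$start))
  sp_last <- local_to_spliced(exons, max(cds_iv$end) - 1L)
  if (is.na(sp_first) || is.na(sp_last) || sp_last - sp_first + 1L != cds_len) {
    abort(sprintf("gene '%s': CDS features are not contiguous within exons", gene_id),
      class = "splicefate_validation"
    )
  }

  gene_model(
    gene_id = gene_id, genome = genome, exons = exons,
    cds_span = c(sp_first, sp_first + cds_len),
    species = species, strand = strand, seqname = seqname,
    min_intron = min_intron
  )
}

## ---- GFF3 / FASTA output --------------------------------------------------

#' Write a gene model (and optional splice forms) to GFF3 + FASTA
#'
#' Emits gene/mRNA/exon/CDS features in disk coordinates (1-based inclusive,
#' native strand) so that [load_gene_model()] round-trips the model exactly.
#'
#' @param model a [gene_model()].
#' @param gff3_path,fasta_path output paths.
#' @param forms optional forms tibble (see [load_forms()]); each form is
#'   written as an additional mRNA with its exon chain and `tissue` /
#'   `provenance` attributes.
#' @return invisibly, the GFF3 path.
#' @export
write_gene_model <- function(model, gff3_path, fasta_path = NULL, forms = NULL) {
  seqlen <- nchar(model$genome)
  chrom <- if (model$strand == "-") revcomp(model$genome) else model$genome

  rows <- list()
  add <- function(iv, type, id, parent, extra = list()) {
    d <- local_to_disk(iv, model$strand, seqlen)
    n <- nrow(d)
    df <- tibble::tibble(
      seqnames = model$seqname, start = d$start, end = d$end,
      strand = model$strand, type = type,
      ID = if (is.null(id)) NA_character_ else id,
      Parent = if (is.null(parent)) NA_character_ else parent
    )
    for (nm in names(extra)) df[[nm]] <- extra[[nm]]
    rows[[length(rows) + 1L]] <<- df
  }

  span <- tibble::tibble(start = min(model$exons$start), end = max(model$exons$end))
  add(span, "gene", model$gene_id, NULL,
    extra = list(species = model$species %||% NA_character_)
  )
  mrna_id <- paste0(model$gene_id, ".t1")
  add(span, "mRNA", mrna_id, model$gene_id)
  add(model$exons, "exon", NA_character_, mrna_id)
  cds_iv <- spliced_range_to_local(model$exons, model$cds_span[1], model$cds_span[2])
  prior <- c(0L, cumsum(interval_widths(cds_iv)))[seq_len(nrow(cds_iv))]
  add(cds_iv, "CDS", NA_character_, mrna_id,
    extra = list(phase = (3L - prior %% 3L) %% 3L)
  )

  if (!is.null(forms)) {
    for (i in seq_len(nrow(forms))) {
      fid <- forms$form_id[i]
      ch <- forms$chain[[i]]
      fspan <- tibble::tibble(start = min(ch$start), end = max(ch$end))
      add(fspan, "mRNA", fid, model$gene_id, extra = list(
        tissue = paste(forms$tissues[[i]], collapse = ","),
        provenance = forms$provenance[i] %||% "observed"
      ))
      add(ch, "exon", NA_character_, fid)
    }
  }

  df <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  par <- as.list(df$Parent)
  par[is.na(df$Parent)] <- list(character(0))
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(par)
  for (nm in setdiff(names(df), c("seqnames", "start", "end", "strand", "type", "ID", "Parent"))) {
    S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  }
  rtracklayer::export(gr, gff3_path, format = "gff3")
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(chrom)
    names(ss) <- model$seqname
    Biostrings::writeXStringSet(ss, fasta_path, width = 80L)
  }
  invisible(gff3_path)
}

#' Load observed/synthetic splice forms from a GFF3 of exon chains
#'
#' Each form is one mRNA feature (with exon children) whose `Parent` is the
#' model's gene id. Optional `tissue` (comma-separated subset of
#' `generative`, `vegetative`) and `provenance` attributes are carried along.
#' Coordinates are converted to the model's transcript orientation.
#'
#' @param gff3_path path to the forms GFF3.
#' @param model the canonical [gene_model()] the chains refer to.
#' @return tibble with `form_id`, `gene_id`, `chain` (list of interval
#'   tibbles), `tissues` (list of character), `provenance`.
#' @export
load_forms <- function(gff3_path, model) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  mrnas <- gff_children(gr, model$gene_id, c("mRNA", "transcript"))
  mc <- S4Vectors::mcols(mrnas)
  seqlen <- nchar(model$genome)
  out <- purrr::map(seq_along(mrnas), function(i) {
    fid <- mc$ID[i]
    ex <- gff_children(gr, fid, "exon")
    iv <- disk_to_local(BiocGenerics::start(ex), BiocGenerics::end(ex),
      model$strand, seqlen
    )
    iv <- iv[order(iv$start), , drop = FALSE]
    tis <- if ("tissue" %in% names(mc)) mc$tissue[i] else NA_character_
    tis <- if (is.na(tis) || tis == "") character() else strsplit(tis, ",")[[1]]
    tibble::tibble(
      form_id = fid, gene_id = model$gene_id,
      chain = list(iv), tissues = list(tis),
      provenance = if ("provenance" %in% names(mc)) {
        mc$provenance[i] %||% "observed"
      } else {
        "observed"
      }
    )
  })
  dplyr::bind_rows(out)
}

#' Map a spliced cDNA sequence onto the gene locus by exact anchoring
#'
#' Reconstructs the exon chain of a spliced transcript by exact substring
#' matching: the next `anchor`-mer of unmapped cDNA must occur verbatim
#' downstream on the locus (nearest occurrence wins). Any mismatch, ambiguity
#' at the first anchor, or unmappable junction rejects the sequence — there is
#' deliberately no fuzzy alignment, as input structures are assumed
#' sequence-verified.
#'
#' @param model a [gene_model()].
#' @param cdna spliced transcript sequence (character scalar, transcript
#'   orientation).
#' @param anchor anchor length in nt (default 20).
#' @return chain tibble (`start`, `end`).
#' @export
map_spliced_cdna <- function(model, cdna, anchor = 20L) {
  g <- model$genome
  n <- nchar(cdna)
  if (n < anchor) abort("cDNA shorter than anchor length", class = "splicefate_map")
  first <- substring(cdna, 1L, anchor)
  hits <- gregexpr(first, g, fixed = TRUE)[[1]]
  if (hits[1] == -1L) abort("cDNA start anchor not found on locus", class = "splicefate_map")
  if (length(hits) > 1L) {
    abort("cDNA start anchor is ambiguous on locus", class = "splicefate_map")
  }
  gpos <- hits[1] - 1L # 0-based
  cpos <- 0L
  segs <- list()
  while (cpos < n) {
    # extend exact match
    m <- 0L
    while (cpos + m < n && gpos + m < nchar(g) &&
      substring(cdna, cpos + m + 1L, cpos + m + 1L) ==
        substring(g, gpos + m + 1L, gpos + m + 1L)) {
      m <- m + 1L
    }
    if (m == 0L) abort("cDNA does not match locus at junction", class = "splicefate_map")
    segs[[length(segs) + 1L]] <- tibble::tibble(start = gpos, end = gpos + m)
    cpos <- cpos + m
    if (cpos >= n) break
    nxt <- substring(cdna, cpos + 1L, min(cpos + anchor, n))
    if (nchar(nxt) < anchor) {
      abort("trailing cDNA too short to anchor a junction", class = "splicefate_map")
    }
    rest <- substring(g, gpos + m + 2L) # require a gap of >= 1 nt
    hit <- regexpr(nxt, rest, fixed = TRUE)
    if (hit == -1L) abort("cDNA junction anchor not found downstream", class = "splicefate_map")
    gpos <- (gpos + m + 1L) + (hit - 1L)
  }
  dplyr::bind_rows(segs)
}

## ---- report writers -------------------------------------------------------

#' Write the forms table and intron-position matrix as TSV reports
#'
#' @param forms_table classified + named forms joined with ORF results (as
#'   produced by the pipeline); must contain `form_name`, `events_string`,
#'   `ptc`, `protein_length_aa`, `tissues`, `functional_call`.
#' @param out_dir output directory (created if needed).
#' @param matrix optional [map_to_alignment()] result written as a wide
#'   gene-by-class TSV with decimal-phase notations (`-` for absent).
#' @param orf_table optional full ORF/NMD table written alongside.
#' @return invisibly, the paths written.
#' @export
write_reports <- function(forms_table, out_dir, matrix = NULL, orf_table = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(orf_table) &&
    length(setdiff(orf_table$form_id, forms_table$form_id)) > 0L) {
    abort("orf_table contains form ids absent from forms_table",
      class = "splicefate_consistency"
    )
  }
  ft <- forms_table
  ft$tissues <- vapply(ft$tissues, function(t) paste(sort(t), collapse = ","), character(1))
  keep <- intersect(
    c(
      "gene_id", "form_id", "form_name", "form_ascii", "events_string",
      "n_events", "ptc", "protein_length_aa", "delta_aa", "tissues",
      "functional_call"
    ),
    names(ft)
  )
  p <- file.path(out_dir, "forms.tsv")
  readr::write_tsv(ft[, keep], p)
  paths <- c(paths, p)
  if (!is.null(orf_table)) {
    p <- file.path(out_dir, "orf_nmd.tsv")
    readr::write_tsv(
      orf_table[, setdiff(names(orf_table), c("chain", "spans"))], p
    )
    paths <- c(paths, p)
  }
  if (!is.null(matrix)) {
    p <- file.path(out_dir, "intron_matrix.tsv")
    readr::write_tsv(intron_matrix_wide(matrix), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
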