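test_that("generated SPO11-like architectures load with the expected intron counts", {
  # 15-exon SPO11-1-like and 11-exon SPO11-2-like shapes, plus the trivial
  # single-exon case
  for (case in list(c(15L, 14L), c(11L, 10L), c(1L, 0L))) {
    m <- gen_gene_model(gene_spec(seed = 7L, n_exons = case[1], utr5_len = 30L, utr3_len = 30L))
    expect_equal(nrow(m$exons), case[1])
    gaps <- nrow(m$exons) - 1L
    expect_equal(gaps, case[2])
    expect_equal(nrow(derive_introns(m)), case[2]) # UTRs shorter than exon 1/n
  }
})

test_that("intron records carry coding offsets and phases", {
  m54 <- manual_model(exon_cds = c(54L, 120L, 93L))
  ir <- derive_introns(m54)
  expect_equal(ir$cds_offset[1], 54L)
  expect_equal(ir$phase[1], 0L)

  m52 <- manual_model(exon_cds = c(52L, 122L, 93L))
  ir2 <- derive_introns(m52)
  expect_equal(ir2$cds_offset[1], 52L)
  expect_equal(ir2$phase[1], 1L)

  expect_true(all(diff(ir$cds_offset) > 0))
  expect_equal(ir$phase, ir$cds_offset %% 3L)
})

test_that("coding-exon contributions sum to the CDS and intron count matches", {
  for (seed in 1:5) {
    m <- gen_gene_model(gene_spec(seed, n_exons = 9L, utr5_len = 25L, utr3_len = 25L))
    cds <- extract_spliced_cds(m)
    expect_false(attr(cds, "start_lost"))
    expect_equal(nchar(cds) - utr_lengths(m)[["utr3"]], m$cds_span[2] - m$cds_span[1])
    # start in first exon, stop in last: CDS introns = exon count - 1
    expect_equal(nrow(derive_introns(m)), nrow(m$exons) - 1L)
  }
})

test_that("extract_spliced_cds reflects retained introns and skipped exons", {
  m <- manual_model(exon_cds = c(54L, 90L, 120L, 93L), intron_len = 72L)
  canon_len <- nchar(extract_spliced_cds(m)) - 9L # minus 3'UTR
  expect_equal(canon_len %% 3L, 0L)

  ir_form <- apply_events(m, event_tbl("IR", 2, NA))
  expect_equal(
    nchar(extract_spliced_cds(m, ir_form$chain[[1]])),
    canon_len + 9L + 72L
  )
  es_form <- apply_events(m, event_tbl("ES", 3, NA))
  expect_equal(
    nchar(extract_spliced_cds(m, es_form$chain[[1]])),
    canon_len + 9L - 120L
  )
  # start codon's exon absent: full sequence plus flag
  no_start <- m$exons[-1L, ]
  cds <- extract_spliced_cds(m, no_start)
  expect_true(attr(cds, "start_lost"))
  expect_equal(nchar(cds), sum(no_start$end - no_start$start))
})

test_that("GFF3+FASTA round trip preserves the model structurally", {
  for (strand in c("+", "-")) {
    m <- gen_gene_model(gene_spec(seed = 11L, n_exons = 8L, strand = strand))
    td <- withr::local_tempdir()
    write_gene_model(m, file.path(td, "g.gff3"), file.path(td, "g.fasta"))
    m2 <- load_gene_model(file.path(td, "g.gff3"), file.path(td, "g.fasta"), m$gene_id)
    expect_identical(m2$exons, m$exons)
    expect_identical(m2$cds_span, m$cds_span)
    expect_identical(m2$genome, m$genome)
    expect_identical(m2$strand, strand)
  }
})

test_that("a minus-strand gene and its plus-strand twin give identical intron records", {
  base <- list(seed = 23L, n_exons = 10L, utr5_len = 40L, utr3_len = 40L)
  m_plus <- gen_gene_model(do.call(gene_spec, c(base, strand = "+")))
  m_minus <- gen_gene_model(do.call(gene_spec, c(base, strand = "-")))
  td <- withr::local_tempdir()
  write_gene_model(m_minus, file.path(td, "m.gff3"), file.path(td, "m.fasta"))
  reloaded <- load_gene_model(file.path(td, "m.gff3"), file.path(td, "m.fasta"), m_minus$gene_id)
  expect_identical(
    derive_introns(reloaded)[, c("intron_index", "length", "cds_offset", "phase")],
    derive_introns(m_plus)[, c("intron_index", "length", "cds_offset", "phase")]
  )
})

test_that("the loader fails closed on bad inputs", {
  m <- gen_gene_model(gene_spec(seed = 3L, n_exons = 5L))
  td <- withr::local_tempdir()
  write_gene_model(m, file.path(td, "g.gff3"), file.path(td, "g.fasta"))
  expect_error(
    load_gene_model(file.path(td, "g.gff3"), file.path(td, "g.fasta"), "no_such_gene"),
    class = "splicefate_not_found"
  )
  # CDS not a multiple of 3
  expect_error(
    gene_model("bad", strrep("A", 100), tibble::tibble(start = 0L, end = 100L),
      cds_span = c(10L, 32L)
    ),
    class = "splicefate_validation"
  )
  # overlapping exons
  expect_error(
    gene_model("bad2", strrep("A", 200),
      tibble::tibble(start = c(0L, 40L), end = c(50L, 100L)),
      cds_span = c(0L, 90L)
    ),
    regexp = "overlap"
  )
  # intron below the minimum length
  expect_error(
    gene_model("bad3", strrep("A", 200),
      tibble::tibble(start = c(0L, 55L), end = c(50L, 100L)),
      cds_span = c(0L, 90L)
    ),
    class = "splicefate_validation"
  )
})

test_that("3'UTR introns are counted separately, not as CDS introns", {
  m <- gen_gene_model(gene_spec(
    seed = 31L, n_exons = 9L, utr3_len = 220L, utr_introns_3 = 2L
  ))
  expect_equal(unname(utr_intron_counts(m)["utr3"]), 2L)
  expect_equal(nrow(derive_introns(m)) + 2L, nrow(m$exons) - 1L - unname(utr_intron_counts(m)["utr5"]))
})

test_that("spliced cDNA maps back to its exon chain by exact anchoring", {
  m <- gen_gene_model(gene_spec(seed = 17L, n_exons = 7L))
  for (ev in list(NULL, event_tbl("IR", 3, NA), event_tbl("ES", 4, NA))) {
    f <- apply_events(m, ev)
    cdna <- chain <- f$chain[[1]]
    seqs <- paste(substring(m$genome, chain$start + 1L, chain$end), collapse = "")
    mapped <- map_spliced_cdna(m, seqs)
    expect_identical(as.data.frame(mapped), as.data.frame(chain))
  }
  expect_error(map_spliced_cdna(m, strrep("A", 50)), class = "splicefate_map")
})

test_that("report writer emits the forms table and a stable intron matrix", {
  m <- manual_model(exon_cds = rep(45L, 9L), gene_id = "gene_a")
  forms <- dplyr::bind_rows(
    apply_events(m, NULL, form_id = "f0", tissues = "generative"),
    apply_events(m, event_tbl("IR", 8, NA), form_id = "f1", tissues = "vegetative")
  )
  named <- assign_form_names(classify_forms(forms, m))
  orf <- analyze_orfs(named, m)
  tbl <- dplyr::left_join(named, orf[, c("form_id", "ptc", "protein_length_aa", "delta_aa", "functional_call")], by = "form_id")
  td <- withr::local_tempdir()

  fixture <- gen_conservation_fixture(seed = 5L, n_species = 2L, n_conserved = 3L, n_extra = 0L)
  # two identical genes -> identical matrix rows
  proj <- fixture$projections
  mx <- map_to_alignment(proj, fixture$msa)
  paths <- write_reports(tbl, td, matrix = mx)
  forms_tsv <- readr::read_tsv(file.path(td, "forms.tsv"), show_col_types = FALSE)
  expect_equal(nrow(forms_tsv), 2L)
  expect_true(any(grepl("IR:intron8", forms_tsv$events_string)))
  expect_equal(forms_tsv$events_string[forms_tsv$form_name == "α"], NA_character_)

  # consistency error on id mismatch
  bad_orf <- orf
  bad_orf$form_id <- paste0(bad_orf$form_id, "_x")
  expect_error(write_reports(tbl, td, orf_table = bad_orf), class = "splicefate_consistency")

  # bit-stable on rewrite
  before <- tools::md5sum(paths)
  write_reports(tbl, td, matrix = mx)
  expect_identical(unname(tools::md5sum(paths)), unname(before))
})
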