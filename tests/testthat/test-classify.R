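test_that("the canonical chain classifies as event-free and fully explained", {
  m <- manual_model()
  d <- diff_chains(m, m$exons)
  expect_true(all(d$status %in% c("spliced", "present")))
  expect_equal(nrow(classify_form(m, m$exons)), 0L)
})

test_that("single events are recovered with anchor and signed delta", {
  m <- manual_model(exon_cds = c(54L, 120L, 90L, 96L, 63L), intron_len = 40L)

  ir <- apply_events(m, event_tbl("IR", 3, NA))
  expect_equal(
    classify_form(m, ir$chain[[1]]),
    tibble::tibble(type = "IR", anchor = 3L, delta_nt = 40L)
  )
  d <- diff_chains(m, ir$chain[[1]])
  expect_equal(d$status[d$feature == "intron" & d$index == 3L], "retained")

  es <- apply_events(m, event_tbl("ES", 2, NA))
  expect_equal(
    classify_form(m, es$chain[[1]]),
    tibble::tibble(type = "ES", anchor = 2L, delta_nt = -120L)
  )
  expect_equal(
    diff_chains(m, es$chain[[1]]) %>%
      dplyr::filter(.data$feature == "exon", .data$index == 2L) %>%
      dplyr::pull("status"),
    "absent"
  )

  # acceptor of intron 4 shifted 12 nt into exon 5
  a3 <- apply_events(m, event_tbl("Alt3SS", 4, -12))
  expect_equal(
    classify_form(m, a3$chain[[1]]),
    tibble::tibble(type = "Alt3SS", anchor = 4L, delta_nt = -12L)
  )
  # donor of intron 2 extended 15 nt into the intron
  a5 <- apply_events(m, event_tbl("Alt5SS", 2, 15))
  expect_equal(
    classify_form(m, a5$chain[[1]]),
    tibble::tibble(type = "Alt5SS", anchor = 2L, delta_nt = 15L)
  )
})

test_that("a skipped exon with a shortened neighbour is one combination form", {
  m <- manual_model(exon_cds = c(54L, 120L, 90L, 96L, 63L))
  f <- apply_events(m, event_tbl("ES", 3, NA, "Alt3SS", 3, -9))
  ev <- classify_form(m, f$chain[[1]])
  expect_equal(ev$type, c("ES", "Alt3SS"))
  expect_equal(ev$anchor, c(3L, 3L))
  expect_equal(ev$delta_nt, c(-90L, -9L))
})

test_that("partial intron inclusion on both sides yields two AltSS events", {
  m <- manual_model(exon_cds = c(54L, 120L, 93L), intron_len = 60L)
  # hand-built chain: exon 1 extended 10 nt into intron 1, exon 2 extended
  # 8 nt upstream into intron 1, central 42 nt still spliced
  ch <- m$exons
  ch$end[1] <- ch$end[1] + 10L
  ch$start[2] <- ch$start[2] - 8L
  ev <- classify_form(m, ch)
  expect_equal(ev$type, c("Alt5SS", "Alt3SS"))
  expect_equal(ev$delta_nt, c(10L, 8L))
  expect_equal(ev$anchor, c(1L, 1L))
})

test_that("chains outside the taxonomy are rejected with classed errors", {
  m <- manual_model(exon_cds = c(54L, 120L, 93L), intron_len = 60L)
  # cryptic exon in the middle of intron 1
  gaps <- derive_introns(m)
  cryptic <- dplyr::bind_rows(
    m$exons[1, ],
    tibble::tibble(start = gaps$start[1] + 10L, end = gaps$start[1] + 30L),
    m$exons[-1, ]
  )
  expect_error(classify_form(m, cryptic), class = "splicefate_taxonomy")
  # interior deletion within an exon
  inner <- dplyr::bind_rows(
    tibble::tibble(start = m$exons$start[1], end = m$exons$start[1] + 20L),
    tibble::tibble(start = m$exons$start[1] + 30L, end = m$exons$end[1]),
    m$exons[-1, ]
  )
  expect_error(classify_form(m, inner), class = "splicefate_taxonomy")
  # overlapping chain segments
  overlapping <- dplyr::bind_rows(
    tibble::tibble(start = 0L, end = 50L),
    tibble::tibble(start = 40L, end = 80L)
  )
  expect_error(diff_chains(m, overlapping), regexp = "overlap")
})

test_that("event recovery round-trips over the full synthetic grid", {
  ds <- gen_dataset(seed = 42L, n_genes = 4L, n_exons = 9L)
  # classify against the right model per gene
  ok <- purrr::map_lgl(seq_len(nrow(ds$forms)), function(i) {
    model <- ds$models[[ds$forms$gene_id[i]]]
    identical(
      classify_form(model, ds$forms$chain[[i]]),
      ds$forms$truth[[i]]
    )
  })
  expect_true(all(ok))
})

test_that("spliced length is conserved through event deltas", {
  ds <- gen_dataset(seed = 9L, n_genes = 3L, n_exons = 8L)
  for (i in seq_len(nrow(ds$forms))) {
    model <- ds$models[[ds$forms$gene_id[i]]]
    ev <- classify_form(model, ds$forms$chain[[i]])
    expect_equal(
      sum(ds$forms$chain[[i]]$end - ds$forms$chain[[i]]$start),
      sum(model$exons$end - model$exons$start) + sum(ev$delta_nt)
    )
  }
})

test_that("Greek naming is canonical-first, anchor-sorted, and order-invariant", {
  m <- manual_model(exon_cds = c(54L, 120L, 90L, 96L, 63L))
  forms <- dplyr::bind_rows(
    apply_events(m, event_tbl("IR", 3, NA), form_id = "x1", tissues = "generative"),
    apply_events(m, NULL, form_id = "x0", tissues = "generative"),
    apply_events(m, event_tbl("IR", 1, NA), form_id = "x2", tissues = "vegetative")
  )
  named <- assign_form_names(classify_forms(forms, m))
  expect_equal(named$form_ascii, c("alpha", "beta", "gamma"))
  expect_equal(named$form_name[1], "α")
  expect_equal(named$events_string[named$form_ascii == "beta"], "IR:intron1")
  expect_equal(named$events_string[named$form_ascii == "gamma"], "IR:intron3")

  # permuting input rows never changes the letters
  perm <- assign_form_names(classify_forms(forms[c(3, 1, 2), ], m))
  expect_identical(
    named[, c("form_ascii", "events_string")],
    perm[, c("form_ascii", "events_string")]
  )
})

test_that("duplicate forms merge and union their tissues", {
  m <- manual_model()
  forms <- dplyr::bind_rows(
    apply_events(m, NULL, form_id = "c"),
    apply_events(m, event_tbl("IR", 2, NA), form_id = "a", tissues = "generative"),
    apply_events(m, event_tbl("IR", 2, NA), form_id = "b", tissues = "vegetative")
  )
  named <- assign_form_names(classify_forms(forms, m))
  expect_equal(nrow(named), 2L)
  beta <- named[named$form_ascii == "beta", ]
  expect_equal(beta$tissues[[1]], c("generative", "vegetative"))
  expect_equal(beta$merged_from, 2L)
})

test_that("naming requires a canonical form", {
  m <- manual_model()
  only_var <- apply_events(m, event_tbl("IR", 1, NA), form_id = "v")
  expect_error(
    assign_form_names(classify_forms(only_var, m)),
    class = "splicefate_validation"
  )
})

test_that("tallies report per-event and per-form views", {
  m <- manual_model(exon_cds = rep(48L, 10L), intron_len = 40L)
  forms <- dplyr::bind_rows(
    apply_events(m, NULL, form_id = "f0"),
    apply_events(m, event_tbl("IR", 2, NA), form_id = "f1"),
    apply_events(m, event_tbl("IR", 5, NA, "Alt3SS", 8, -6), form_id = "f2"),
    apply_events(m, event_tbl("ES", 4, NA), form_id = "f3")
  )
  t <- tally_events(assign_form_names(classify_forms(forms, m)))
  expect_equal(t$total_forms, 3L)
  expect_equal(t$ir_only_forms, 1L)
  expect_equal(t$combination_forms, 1L)
  expect_equal(t$ir_events, 2L)
  expect_equal(t$ir_forms, 2L)
  expect_equal(t$alt3_events, 1L)
  expect_equal(t$es_events, 1L)
  # alpha only -> zero
  t0 <- tally_events(assign_form_names(classify_forms(forms[1, ], m)))
  expect_equal(t0$total_forms, 0L)
})

test_that("tissue comparison partitions the non-canonical forms exhaustively", {
  m <- manual_model(exon_cds = rep(48L, 10L), intron_len = 40L)
  forms <- dplyr::bind_rows(
    apply_events(m, NULL, form_id = "f0", tissues = c("generative", "vegetative")),
    apply_events(m, event_tbl("IR", 1, NA), form_id = "f1", tissues = "generative"),
    apply_events(m, event_tbl("IR", 3, NA), form_id = "f2", tissues = "vegetative"),
    apply_events(m, event_tbl("IR", 5, NA), form_id = "f3", tissues = c("generative", "vegetative"))
  )
  named <- assign_form_names(classify_forms(forms, m))
  cmp <- compare_tissues(named)
  expect_equal(sum(cmp$membership == "both"), 1L)
  expect_equal(sort(table(cmp$membership) %>% as.integer()), c(1L, 1L, 1L))
  expect_equal(nrow(cmp), sum(named$n_events > 0L))

  # randomized synthetic sets: partition sizes always sum to the set size
  for (seed in 1:5) {
    withr::with_seed(seed, {
      tiss <- sample(list("generative", "vegetative", c("generative", "vegetative")),
        6L,
        replace = TRUE
      )
    })
    fs <- dplyr::bind_rows(c(
      list(apply_events(m, NULL, form_id = "a0")),
      purrr::map(1:6, ~ apply_events(m, event_tbl("IR", .x, NA),
        form_id = paste0("v", .x), tissues = tiss[[.x]]
      ))
    ))
    cmp2 <- compare_tissues(assign_form_names(classify_forms(fs, m)))
    expect_equal(nrow(cmp2), 6L)
  }

  # empty tissue tag excluded with a warning
  forms_empty <- dplyr::bind_rows(
    forms,
    apply_events(m, event_tbl("IR", 7, NA), form_id = "f4")
  )
  expect_warning(
    cmp3 <- compare_tissues(assign_form_names(classify_forms(forms_empty, m))),
    regexp = "tissue"
  )
  expect_equal(nrow(cmp3), 3L)
})
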