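#' Reported SPO11 splice-form compositions
#'
#' The per-gene alternative-splicing form inventories reported for the SPO11
#' genes of five plant species, encoded as event compositions suitable for
#' [apply_events()]: Arabidopsis thaliana SPO11-1 (eight forms, five of them
#' pure intron retentions, one alt 5'ss, one alt 3'ss, one alt 3'ss combined
#' with IR), A. thaliana SPO11-2 (six forms), Carica papaya SPO11-1 (eleven
#' mutually distinct forms spanning IR, ES, both AltSS types and their
#' combinations), Brassica rapa SPO11-1 (five), and one form each for
#' Physcomitrella patens SPO11-1 (retention of intron 8) and SPO11-2
#' (skipping of exon 2). Where the original report names only the event
#' vocabulary, anchors and splice-site shifts are representative choices on
#' the corresponding 15-exon (SPO11-1-like) or 11-exon (SPO11-2-like)
#' architecture.
#'
#' @return named list; each element has `n_exons` and `forms`, a named list
#'   of event tibbles (`type`, `anchor`, `delta`).
#' @export
spo11_form_compositions <- function() {
  ev <- function(...) {
    v <- list(...)
    idx <- seq(1L, length(v), by = 3L)
    tibble::tibble(
      type = vapply(idx, function(i) as.character(v[[i]]), character(1)),
      anchor = vapply(idx, function(i) as.integer(v[[i + 1L]]), integer(1)),
      delta = vapply(idx, function(i) as.integer(v[[i + 2L]]), integer(1))
    )
  }
  list(
    AthSPO11_1 = list(n_exons = 15L, forms = list(
      beta = ev("IR", 2, NA),
      gamma = ev("IR", 4, NA),
      delta = ev("IR", 6, NA),
      epsilon = ev("IR", 9, NA),
      zeta = ev("IR", 12, NA),
      eta = ev("Alt3SS", 10, -9),
      theta = ev("Alt5SS", 7, 15),
      iota = ev("Alt3SS", 13, -6, "IR", 3, NA)
    )),
    AthSPO11_2 = list(n_exons = 11L, forms = list(
      beta = ev("IR", 1, NA),
      gamma = ev("IR", 5, NA),
      delta = ev("IR", 8, NA),
      epsilon = ev("Alt5SS", 3, -9),
      zeta = ev("Alt5SS", 6, 12, "IR", 9, NA),
      eta = ev("ES", 4, NA, "Alt3SS", 4, -9)
    )),
    CpaSPO11_1 = list(n_exons = 15L, forms = list(
      beta = ev("IR", 3, NA),
      gamma = ev("ES", 5, NA),
      delta = ev("Alt5SS", 2, 15),
      epsilon = ev("Alt3SS", 6, -9),
      zeta = ev("IR", 1, NA, "IR", 7, NA),
      eta = ev("IR", 4, NA, "ES", 9, NA),
      theta = ev("IR", 10, NA, "Alt5SS", 5, -6),
      iota = ev("IR", 12, NA, "Alt3SS", 2, -6),
      kappa = ev("ES", 3, NA, "Alt3SS", 3, -9),
      lambda = ev("Alt5SS", 11, 12, "Alt3SS", 13, -6),
      mu = ev("ES", 7, NA, "Alt5SS", 9, 15)
    )),
    BraSPO11_1 = list(n_exons = 15L, forms = list(
      beta = ev("IR", 2, NA),
      gamma = ev("IR", 7, NA),
      delta = ev("Alt3SS", 5, -9),
      epsilon = ev("Alt3SS", 9, 12),
      zeta = ev("ES", 4, NA, "IR", 10, NA)
    )),
    PpaSPO11_1 = list(n_exons = 15L, forms = list(
      beta = ev("IR", 8, NA)
    )),
    PpaSPO11_2 = list(n_exons = 11L, forms = list(
      beta = ev("ES", 2, NA)
    ))
  )
}

#' Realize a reported composition on a synthetic gene and tally it
#'
#' Builds a synthetic gene of the composition's exon count, applies every
#' form as a variant chain, classifies, names, and tallies — the desk-scale
#' reconstruction of a reported per-gene form inventory.
#'
#' @param composition one element of [spo11_form_compositions()].
#' @param seed seed for the synthetic gene backbone.
#' @param gene_id identifier for the synthetic gene.
#' @return list with `model`, `named` (named forms tibble), `tally`.
#' @export
realize_composition <- function(composition, seed, gene_id = "synth") {
  model <- gen_gene_model(gene_spec(
    seed = seed, n_exons = composition$n_exons, gene_id = gene_id,
    utr5_len = 40L, utr3_len = 60L
  ))
  forms <- dplyr::bind_rows(c(
    list(apply_events(model, NULL, form_id = paste0(gene_id, ".canonical"))),
    purrr::imap(composition$forms, function(ev, nm) {
      apply_events(model, ev, form_id = paste0(gene_id, ".", nm))
    })
  ))
  forms$truth <- NULL
  named <- assign_form_names(classify_forms(forms, model))
  list(model = model, named = named, tally = tally_events(named))
}
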