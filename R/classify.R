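#' Splice-event taxonomy
#'
#' A variant exon chain is compared with the canonical chain as two coverage
#' sets on the oriented locus. Every maximal interval present in exactly one
#' of the two must be explainable by the event taxonomy:
#'
#' * a chain-only interval equal to a full canonical intron is intron
#'   retention (`IR`, positive delta);
#' * a chain-only interval flush with an intron's 5' (donor) end is an
#'   alternative 5' splice site (`Alt5SS`, positive delta), flush with its 3'
#'   (acceptor) end an alternative 3' splice site (`Alt3SS`, positive delta);
#'   both at once on one intron are two AltSS events;
#' * a canonical-only interval equal to a full exon is exon skipping (`ES`,
#'   negative delta);
#' * a canonical-only interval flush with an exon's 3' edge is an `Alt5SS`
#'   (negative delta) on the downstream intron; flush with its 5' edge an
#'   `Alt3SS` (negative delta) on the upstream intron.
#'
#' Anything else (a cryptic exon inside an intron, an interior deletion, a
#' segment outside the gene span, a truncated terminal exon edge with no
#' flanking intron) is outside the taxonomy and raises a classed error.
#'
#' `delta_nt` is always the signed change to the mature transcript length, so
#' canonical spliced length + sum(delta_nt) equals the variant spliced length.
#'
#' @name splice-events
NULL

EVENT_TYPES <- c("IR", "ES", "Alt5SS", "Alt3SS")

event_type_code <- function(type) match(type, EVENT_TYPES)

empty_events <- function() {
  tibble::tibble(
    type = character(), anchor = integer(), delta_nt = integer()
  )
}

sort_events <- function(ev) {
  ev[order(ev$anchor, event_type_code(ev$type), ev$delta_nt), , drop = FALSE]
}

#' Compact string encoding of an event list
#'
#' `IR:intron8`, `ES:exon2`, `Alt5SS:intron3(+14)`, `Alt3SS:intron5(-12)`;
#' multiple events joined by `;`. Empty list encodes as `""` (the canonical
#' form).
#'
#' @param events event tibble from [classify_form()].
#' @return character scalar.
#' @export
events_string <- function(events) {
  if (nrow(events) == 0L) return("")
  ev <- sort_events(events)
  paste(vapply(seq_len(nrow(ev)), function(i) {
    t <- ev$type[i]
    if (t == "IR") {
      sprintf("IR:intron%d", ev$anchor[i])
    } else if (t == "ES") {
      sprintf("ES:exon%d", ev$anchor[i])
    } else {
      sprintf("%s:intron%d(%+d)", t, ev$anchor[i], ev$delta_nt[i])
    }
  }, character(1)), collapse = ";")
}

validate_chain <- function(model, chain) {
  validate_intervals(chain, "chain")
  span_lo <- min(model$exons$start)
  span_hi <- max(model$exons$end)
  if (min(chain$start) < span_lo || max(chain$end) > span_hi) {
    abort("chain segment outside the gene span (novel segment)",
      class = "splicefate_taxonomy"
    )
  }
  invisible(chain)
}

#' Primitive differences between a chain and the canonical model
#'
#' Reports, per canonical intron, whether it is spliced, retained, or has a
#' shifted donor/acceptor, and per canonical exon whether it is present,
#' absent, or truncated/extended at an edge. This is the exhaustive substrate
#' that [classify_form()] maps to events: every chain nucleotide is explained
#' or an error is raised.
#'
#' @param model a [gene_model()].
#' @param chain exon-chain tibble.
#' @return tibble with `feature` (`"intron"`/`"exon"`), `index`, `status`,
#'   `delta_nt`.
#' @export
diff_chains <- function(model, chain) {
  validate_chain(model, chain)
  ex <- model$exons
  n_ex <- nrow(ex)
  gaps <- intron_gap_table(model)

  plus <- interval_setdiff(chain, ex) # in chain, not canonical
  minus <- interval_setdiff(ex, chain) # canonical, not in chain

  res <- list()
  note <- function(feature, index, status, delta) {
    res[[length(res) + 1L]] <<- tibble::tibble(
      feature = feature, index = as.integer(index),
      status = status, delta_nt = as.integer(delta)
    )
  }

  # chain-only pieces must sit inside a single intron, flush with an end
  for (i in seq_len(nrow(plus))) {
    p <- plus[i, ]
    k <- which(gaps$start <= p$start & p$end <= gaps$end)
    if (length(k) != 1L) {
      abort("variant segment not contained in a canonical intron (novel segment)",
        class = "splicefate_taxonomy"
      )
    }
    g <- gaps[k, ]
    w <- p$end - p$start
    if (p$start == g$start && p$end == g$end) {
      note("intron", g$gap_index, "retained", w)
    } else if (p$start == g$start) {
      note("intron", g$gap_index, "donor_shifted", w)
    } else if (p$end == g$end) {
      note("intron", g$gap_index, "acceptor_shifted", w)
    } else {
      abort("included intron sequence not flush with a splice site (cryptic exon)",
        class = "splicefate_taxonomy"
      )
    }
  }

  # canonical-only pieces must be a full exon or flush with one exon edge
  for (i in seq_len(nrow(minus))) {
    p <- minus[i, ]
    k <- which(ex$start <= p$start & p$end <= ex$end)
    stopifnot(length(k) == 1L)
    w <- p$end - p$start
    if (p$start == ex$start[k] && p$end == ex$end[k]) {
      note("exon", k, "absent", -w)
    } else if (p$end == ex$end[k]) {
      if (k == n_ex) {
        abort("terminal exon truncated at the transcript end (outside taxonomy)",
          class = "splicefate_taxonomy"
        )
      }
      note("exon", k, "truncated_3p", -w)
    } else if (p$start == ex$start[k]) {
      if (k == 1L) {
        abort("first exon truncated at the transcript start (outside taxonomy)",
          class = "splicefate_taxonomy"
        )
      }
      note("exon", k, "truncated_5p", -w)
    } else {
      abort("interior exon deletion (outside taxonomy)",
        class = "splicefate_taxonomy"
      )
    }
  }

  diffs <- dplyr::bind_rows(
    c(res, list(tibble::tibble(
      feature = character(), index = integer(),
      status = character(), delta_nt = integer()
    )))
  )

  # fill in the unchanged features for an exhaustive report
  intron_status <- rep("spliced", nrow(gaps))
  exon_status <- rep("present", n_ex)
  base <- dplyr::bind_rows(
    tibble::tibble(
      feature = "intron", index = gaps$gap_index,
      status = intron_status, delta_nt = 0L
    ),
    tibble::tibble(
      feature = "exon", index = seq_len(n_ex),
      status = exon_status, delta_nt = 0L
    )
  )
  changed <- paste(diffs$feature, diffs$index)
  base <- base[!(paste(base$feature, base$index) %in% changed), , drop = FALSE]
  out <- dplyr::bind_rows(diffs, base)
  out[order(match(out$feature, c("intron", "exon")), out$index), , drop = FALSE]
}

#' Classify a variant exon chain into splice events
#'
#' Maps the primitive differences from [diff_chains()] onto the event
#' taxonomy (see [splice-events]) and returns the events sorted by anchor,
#' then type (`IR`, `ES`, `Alt5SS`, `Alt3SS`). Anchors are intron indices for
#' `IR`/`Alt5SS`/`Alt3SS` (the intron whose donor/acceptor moved) and exon
#' indices for `ES`, both counted over the whole transcript.
#'
#' @param model a [gene_model()].
#' @param chain exon-chain tibble.
#' @return event tibble with `type`, `anchor`, `delta_nt`.
#' @export
classify_form <- function(model, chain) {
  diffs <- diff_chains(model, chain)
  ev <- list()
  push <- function(type, anchor, delta) {
    ev[[length(ev) + 1L]] <<- tibble::tibble(
      type = type, anchor = as.integer(anchor), delta_nt = as.integer(delta)
    )
  }
  for (i in seq_len(nrow(diffs))) {
    d <- diffs[i, ]
    if (d$status %in% c("spliced", "present")) next
    if (d$feature == "intron") {
      if (d$status == "retained") push("IR", d$index, d$delta_nt)
      if (d$status == "donor_shifted") push("Alt5SS", d$index, d$delta_nt)
      if (d$status == "acceptor_shifted") push("Alt3SS", d$index, d$delta_nt)
    } else {
      if (d$status == "absent") push("ES", d$index, d$delta_nt)
      # an exon shortened at an edge is an AltSS on the flanking intron
      if (d$status == "truncated_3p") push("Alt5SS", d$index, d$delta_nt)
      if (d$status == "truncated_5p") push("Alt3SS", d$index - 1L, d$delta_nt)
    }
  }
  events <- if (length(ev) == 0L) empty_events() else sort_events(dplyr::bind_rows(ev))
  # length bookkeeping must always balance
  stopifnot(
    spliced_length(model) + sum(events$delta_nt) == sum(interval_widths(chain))
  )
  events
}

#' Classify every form in a forms tibble
#'
#' @param forms forms tibble ([load_forms()] or [apply_events()] output).
#' @param model a [gene_model()].
#' @return `forms` with added `events` (list-column), `n_events`,
#'   `events_string`.
#' @export
classify_forms <- function(forms, model) {
  forms$events <- purrr::map(forms$chain, ~ classify_form(model, .x))
  forms$n_events <- purrr::map_int(forms$events, nrow)
  forms$events_string <- purrr::map_chr(forms$events, events_string)
  forms
}

#' Assign Greek form names to classified forms of one gene
#'
#' The canonical (event-free) form is `alpha`; the remaining forms are sorted
#' structurally — by first event anchor, then event type, then delta, then the
#' full event signature — and named `beta`, `gamma`, ... in Greek alphabet
#' order. Naming is a pure function of the event lists: permuting the input
#' rows never changes the letters. Forms with identical event lists are
#' merged, with their tissue sets unioned.
#'
#' @param forms classified forms tibble (from [classify_forms()]); must
#'   contain exactly one canonical form.
#' @return tibble with one row per distinct form: `form_name` (Greek glyph),
#'   `form_ascii`, plus the merged columns of `forms`.
#' @export
assign_form_names <- function(forms) {
  stopifnot(all(c("events", "events_string") %in% names(forms)))
  if (sum(forms$n_events == 0L) == 0L) {
    abort("no canonical (event-free) form present", class = "splicefate_validation")
  }
  merged <- forms %>%
    dplyr::group_by(.data$gene_id, .data$events_string) %>%
    dplyr::summarise(
      form_id = .data$form_id[1],
      chain = list(.data$chain[[1]]),
      events = list(.data$events[[1]]),
      n_events = .data$n_events[1],
      tissues = list(sort(unique(unlist(.data$tissues)))),
      provenance = paste(sort(unique(.data$provenance)), collapse = "+"),
      merged_from = dplyr::n(),
      .groups = "drop"
    )

  key <- purrr::map(merged$events, function(ev) {
    if (nrow(ev) == 0L) {
      c(-1, -1, 0)
    } else {
      c(ev$anchor[1], event_type_code(ev$type[1]), ev$delta_nt[1])
    }
  })
  ord <- order(
    purrr::map_dbl(key, 1), purrr::map_dbl(key, 2), purrr::map_dbl(key, 3),
    merged$events_string
  )
  merged <- merged[ord, , drop = FALSE]
  labs <- purrr::map(seq_len(nrow(merged)), greek_label)
  merged$form_name <- purrr::map_chr(labs, "glyph")
  merged$form_ascii <- purrr::map_chr(labs, "ascii")
  merged %>%
    dplyr::select(
      "gene_id", "form_name", "form_ascii", "form_id", "events_string",
      "n_events", "events", "chain", "tissues", "provenance", "merged_from"
    )
}

#' Tally splice events for one gene's named forms
#'
#' Because a combination form carries several events, the tally reports both
#' views: `*_events` counts every constituent event, `*_forms` counts forms
#' containing at least one event of that type. `total_forms` is the number of
#' non-canonical forms; `ir_only_forms` the number whose events are all `IR`.
#'
#' @param named_forms output of [assign_form_names()].
#' @return one-row tibble of counts.
#' @export
tally_events <- function(named_forms) {
  nc <- named_forms[named_forms$n_events > 0L, , drop = FALSE]
  all_ev <- dplyr::bind_rows(c(nc$events, list(empty_events())))
  per_event <- vapply(EVENT_TYPES, function(t) sum(all_ev$type == t), integer(1))
  per_form <- vapply(EVENT_TYPES, function(t) {
    sum(purrr::map_lgl(nc$events, ~ t %in% .x$type))
  }, integer(1))
  tibble::tibble(
    gene_id = if (nrow(named_forms) > 0L) named_forms$gene_id[1] else NA_character_,
    total_forms = nrow(nc),
    ir_only_forms = sum(purrr::map_lgl(nc$events, ~ nrow(.x) > 0L && all(.x$type == "IR"))),
    combination_forms = sum(nc$n_events > 1L),
    ir_events = per_event[["IR"]],
    es_events = per_event[["ES"]],
    alt5_events = per_event[["Alt5SS"]],
    alt3_events = per_event[["Alt3SS"]],
    ir_forms = per_form[["IR"]],
    es_forms = per_form[["ES"]],
    alt5_forms = per_form[["Alt5SS"]],
    alt3_forms = per_form[["Alt3SS"]]
  )
}

#' Partition non-canonical forms by tissue of observation
#'
#' @param named_forms output of [assign_form_names()]; tissue sets must be
#'   subsets of `{generative, vegetative}`. Forms with an empty tissue set are
#'   excluded with a warning.
#' @return tibble with `form_name`, `membership` in
#'   `both` / `generative_only` / `vegetative_only`.
#' @export
compare_tissues <- function(named_forms) {
  nc <- named_forms[named_forms$n_events > 0L, , drop = FALSE]
  empty <- purrr::map_lgl(nc$tissues, ~ length(.x) == 0L)
  if (any(empty)) {
    warn(sprintf(
      "%d form(s) without a tissue tag excluded from the tissue comparison",
      sum(empty)
    ))
    nc <- nc[!empty, , drop = FALSE]
  }
  membership <- purrr::map_chr(nc$tissues, function(t) {
    g <- "generative" %in% t
    v <- "vegetative" %in% t
    if (g && v) "both" else if (g) "generative_only" else "vegetative_only"
  })
  tibble::tibble(
    gene_id = nc$gene_id, form_name = nc$form_name, form_ascii = nc$form_ascii,
    membership = membership
  )
}
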