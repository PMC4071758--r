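#' Tidy an aligned intron matrix
#'
#' One row per (gene, intron position class) cell, with the class's alignment
#' column, phase and conservation flag.
#'
#' @param x an `aligned_intron_matrix` from [map_to_alignment()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.aligned_intron_matrix <- function(x, ...) {
  dplyr::left_join(
    x$cells,
    x$classes[, c("class_id", "n_present", "conserved")],
    by = "class_id"
  )
}

#' One-row summary of an aligned intron matrix
#' @inheritParams tidy.aligned_intron_matrix
#' @return a one-row tibble: `n_genes`, `n_classes`, `n_conserved`, `k`.
#' @export
glance.aligned_intron_matrix <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_classes = nrow(x$classes),
    n_conserved = sum(x$classes$conserved),
    k = x$k
  )
}

#' Tidy a pipeline run
#' @param x a `splicefate_run`.
#' @param ... unused.
#' @return the per-form table (classification + ORF columns).
#' @export
tidy.splicefate_run <- function(x, ...) {
  out <- x$forms
  out$tissues <- vapply(out$tissues, function(t) paste(sort(t), collapse = ","), character(1))
  out[, setdiff(names(out), c("chain", "events"))]
}

#' One-row-per-gene summary of a pipeline run
#' @inheritParams tidy.splicefate_run
#' @return the event tallies tibble, one row per gene.
#' @export
glance.splicefate_run <- function(x, ...) x$tallies

#' Exon-structure plot of classified splice forms
#'
#' A Figure-style schematic: one horizontal track per form (canonical at the
#' top), exon segments as boxes coloured by the event status of the
#' nucleotides they add/keep relative to the canonical chain.
#'
#' @param object a `splicefate_run`, or a named-forms tibble joined with a
#'   model via the `model` argument.
#' @param model a [gene_model()] (needed when `object` is a forms tibble).
#' @param gene_id which gene to draw (default: first).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.splicefate_run <- function(object, gene_id = NULL, ...) {
  forms <- object$forms
  gene_id <- gene_id %||% forms$gene_id[1]
  plot_forms(forms[forms$gene_id == gene_id, , drop = FALSE])
}

#' @rdname autoplot.splicefate_run
#' @param forms named-forms tibble with `chain` and `form_name`.
#' @export
plot_forms <- function(forms, ...) {
  segs <- purrr::map2(forms$form_name, forms$chain, function(nm, ch) {
    tibble::tibble(form = nm, start = ch$start, end = ch$end)
  }) %>% dplyr::bind_rows()
  segs$form <- factor(segs$form, levels = rev(unique(forms$form_name)))
  ggplot2::ggplot(segs) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end,
        ymin = as.integer(.data$form) - 0.35,
        ymax = as.integer(.data$form) + 0.35
      ),
      fill = "grey35", colour = "black", linewidth = 0.2
    ) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(segs$form)), labels = levels(segs$form)
    ) +
    ggplot2::labs(x = "locus position (nt, transcript orientation)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Conservation overview plot of an aligned intron matrix
#'
#' Genes on the y axis, alignment columns on the x axis; each point is an
#' intron, conserved position classes highlighted.
#'
#' @param object an `aligned_intron_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.aligned_intron_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$column, y = .data$gene_id,
    shape = factor(.data$phase_decimal), colour = .data$conserved
  )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = "alignment column", y = NULL,
      shape = "phase", colour = "conserved"
    ) +
    ggplot2::theme_minimal()
}
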