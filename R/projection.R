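#' Project an intron position into decimal-phase protein coordinates
#'
#' An intron with `cds_offset` coding nucleotides 5' of it interrupts codon
#' `ceil(cds_offset / 3)`. Phase 1 (after the first codon nucleotide) is
#' written `.3`, phase 2 `.6`, and phase 0 (between codons n and n+1) `.0`
#' anchored on codon n — e.g. offsets 52, 53, 54 project to 18.3, 18.6 and
#' 18.0. Pure and vectorized over offsets.
#'
#' @param cds_offset positive integer vector of coding-nt offsets.
#' @return tibble: `cds_offset`, `residue`, `phase`, `phase_decimal`,
#'   `notation`.
#' @export
project_intron <- function(cds_offset) {
  if (any(cds_offset < 1L)) {
    abort("cds_offset must be >= 1", class = "splicefate_input")
  }
  residue <- as.integer(ceiling(cds_offset / 3))
  phase <- as.integer(cds_offset %% 3L)
  digit <- c(0L, 3L, 6L)[phase + 1L]
  tibble::tibble(
    cds_offset = as.integer(cds_offset),
    residue = residue,
    phase = phase,
    phase_decimal = digit / 10,
    notation = sprintf("%d.%d", residue, digit)
  )
}

#' Parse decimal-phase notation back to residue and phase
#' @param notation character vector like `"18.3"`.
#' @return tibble with `residue`, `phase`, `phase_decimal`.
#' @export
parse_notation <- function(notation) {
  parts <- stringr::str_split(notation, "\\.", simplify = TRUE)
  digit <- as.integer(parts[, 2])
  tibble::tibble(
    residue = as.integer(parts[, 1]),
    phase = match(digit, c(0L, 3L, 6L)) - 1L,
    phase_decimal = digit / 10
  )
}

#' Project all CDS introns of a gene model
#'
#' @param model a [gene_model()].
#' @return tibble: one projection row per CDS intron, in intron order, with
#'   `gene_id`, `intron_index`, `cds_offset`, `residue`, `phase`,
#'   `phase_decimal`, `notation`.
#' @export
project_gene <- function(model) {
  ir <- derive_introns(model)
  if (nrow(ir) == 0L) {
    return(tibble::tibble(
      gene_id = character(), intron_index = integer(), cds_offset = integer(),
      residue = integer(), phase = integer(), phase_decimal = double(),
      notation = character()
    ))
  }
  dplyr::bind_cols(
    tibble::tibble(gene_id = ir$gene_id, intron_index = ir$intron_index),
    project_intron(ir$cds_offset)
  )
}

read_alignment <- function(msa) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa)) {
    ss <- Biostrings::readAAStringSet(msa)
    msa <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  if (is.null(names(msa)) || any(names(msa) == "")) {
    abort("alignment rows must be named by gene id", class = "splicefate_input")
  }
  if (length(unique(nchar(msa))) != 1L) {
    abort("alignment rows differ in length", class = "splicefate_input")
  }
  toupper(msa)
}

# residue index (1-based, ungapped) -> alignment column (1-based)
residue_to_column <- function(row, residue) {
  chars <- strsplit(row, "")[[1]]
  cols <- which(chars != "-")
  if (max(residue) > length(cols)) {
    abort("projected residue beyond the ungapped alignment row",
      class = "splicefate_consistency"
    )
  }
  cols[residue]
}

#' Map per-gene intron projections through a protein alignment
#'
#' Converts each projected residue to its alignment column by counting
#' non-gap characters in that gene's row, then groups projections into intron
#' position classes keyed by the exact `(column, phase)` pair. A class is
#' conserved when at least `k` genes have an entry in it (default: all genes
#' in the alignment — strict identity across species). A phase-0 projection
#' (between codons n and n+1) is keyed on the column of residue n.
#'
#' @param projections tibble of projections (rows from [project_gene()],
#'   possibly several genes).
#' @param msa named character vector of aligned protein rows (or a path to an
#'   aligned FASTA); names are gene ids.
#' @param k minimum number of genes per conserved class; `NULL` means all.
#' @param proteins optional named character vector of unaligned canonical
#'   proteins; when given, each gene's ungapped alignment row is checked
#'   against it.
#' @return an `aligned_intron_matrix` object: list with `cells` (tibble
#'   `gene_id`, `intron_index`, `column`, `phase_decimal`, `class_id`,
#'   `notation`), `classes` (tibble `class_id`, `column`, `phase_decimal`,
#'   `n_present`, `conserved`), `genes`, `k`.
#' @export
map_to_alignment <- function(projections, msa, k = NULL, proteins = NULL) {
  msa <- read_alignment(msa)
  genes <- names(msa)
  missing <- setdiff(unique(projections$gene_id), genes)
  if (length(missing) > 0L) {
    abort(sprintf(
      "gene(s) %s have projections but no alignment row",
      paste(missing, collapse = ", ")
    ), class = "splicefate_consistency")
  }
  if (!is.null(proteins)) {
    for (g in intersect(names(proteins), genes)) {
      ungapped <- gsub("-", "", msa[[g]], fixed = TRUE)
      if (!identical(ungapped, toupper(proteins[[g]]))) {
        abort(sprintf("alignment row of gene %s does not match its protein", g),
          class = "splicefate_consistency"
        )
      }
    }
  }
  k <- k %||% length(genes)

  cells <- projections %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::group_modify(function(d, key) {
      d$column <- residue_to_column(msa[[key$gene_id]], d$residue)
      d
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(class_id = sprintf("c%04d.%d", .data$column, round(10 * .data$phase_decimal))) %>%
    dplyr::select(
      "gene_id", "intron_index", "residue", "column", "phase_decimal",
      "class_id", "notation"
    )

  classes <- cells %>%
    dplyr::group_by(.data$class_id, .data$column, .data$phase_decimal) %>%
    dplyr::summarise(n_present = dplyr::n_distinct(.data$gene_id), .groups = "drop") %>%
    dplyr::mutate(conserved = .data$n_present >= k) %>%
    dplyr::arrange(.data$column, .data$phase_decimal)

  structure(
    list(cells = cells, classes = classes, genes = genes, k = k),
    class = "aligned_intron_matrix"
  )
}

#' @export
print.aligned_intron_matrix <- function(x, ...) {
  cat(sprintf(
    "<aligned_intron_matrix> %d genes, %d intron position classes (%d conserved at k=%d)\n",
    length(x$genes), nrow(x$classes), sum(x$classes$conserved), x$k
  ))
  invisible(x)
}

#' Wide gene-by-class view of an aligned intron matrix
#'
#' @param x an `aligned_intron_matrix`.
#' @param absent fill string for absent cells.
#' @return tibble: one row per gene, one column per class (ordered by
#'   alignment column and phase) holding the decimal-phase notation.
#' @export
intron_matrix_wide <- function(x, absent = "-") {
  wide <- tidyr::pivot_wider(
    x$cells[, c("gene_id", "class_id", "notation")],
    names_from = "class_id", values_from = "notation", values_fill = absent
  )
  # all genes (even intron-less ones) and deterministic class order
  out <- tibble::tibble(gene_id = x$genes) %>%
    dplyr::left_join(wide, by = "gene_id")
  cls <- x$classes$class_id
  for (cl in cls) if (!cl %in% names(out)) out[[cl]] <- absent
  out <- out[, c("gene_id", cls)]
  out[is.na(out)] <- absent
  out
}

#' Presence/absence profiles of intron position classes
#'
#' @param x an `aligned_intron_matrix`.
#' @param species optional named character mapping gene_id -> species (tree
#'   leaf names); default uses gene ids as leaves.
#' @return tibble `class_id` x `leaf` with logical `present`.
#' @export
class_profiles <- function(x, species = NULL) {
  leaves <- if (is.null(species)) {
    stats::setNames(x$genes, x$genes)
  } else {
    species
  }
  grid <- tidyr::expand_grid(
    class_id = x$classes$class_id,
    gene_id = x$genes
  )
  grid$leaf <- unname(leaves[grid$gene_id])
  present_key <- paste(x$cells$class_id, x$cells$gene_id)
  grid$present <- paste(grid$class_id, grid$gene_id) %in% present_key
  grid
}

#' Infer intron losses on a species tree by Dollo parsimony
#'
#' Under Dollo parsimony an intron position class is gained exactly once and
#' can only be lost thereafter. Loss events are the maximal all-absent clades
#' below the gain: the minimum set of branches explaining every absence
#' without allowing regain. By default the gain is placed at the tree root —
#' the intron classes interrogated for loss are those treated as ancestral
#' for the clade under study, so an absence shared by two sister taxa whose
#' outgroup retains the intron is explained by one loss on their common
#' branch, and an absence confined to a single species by one terminal loss.
#' With `gain = "mrca"` the gain moves to the most recent common ancestor of
#' the present leaves (the strictly loss-minimal placement), under which
#' leaves outside that span never had the intron and contribute no loss.
#'
#' @param presence named logical vector (names = tree leaf labels) for one
#'   intron position class.
#' @param tree a rooted `phylo` tree (or path to a Newick file).
#' @param gain `"root"` (default: ancestral presence) or `"mrca"`.
#' @return tibble of loss events: `branch` (label: the leaf name for a
#'   terminal loss, the sorted clade leaves joined by `|` otherwise),
#'   `n_leaves` below the branch.
#' @export
infer_intron_losses <- function(presence, tree, gain = c("root", "mrca")) {
  gain <- match.arg(gain)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  leaves <- tree$tip.label
  if (!all(names(presence) %in% leaves)) {
    abort("presence profile references leaves not in the tree",
      class = "splicefate_consistency"
    )
  }
  pres <- stats::setNames(rep(FALSE, length(leaves)), leaves)
  pres[names(presence)] <- presence
  present_leaves <- names(pres)[pres]
  none <- tibble::tibble(branch = character(), n_leaves = integer())
  if (length(present_leaves) == 0L) return(none)
  n_tip <- length(leaves)
  root <- if (gain == "mrca") {
    if (length(present_leaves) == 1L) {
      return(none) # gained on that terminal branch, nothing below to lose
    }
    ape::getMRCA(tree, present_leaves)
  } else {
    setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  }
  kids <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  tips_below <- function(node) {
    if (node <= n_tip) return(leaves[node])
    unlist(lapply(kids(node), tips_below))
  }

  losses <- list()
  walk <- function(node) {
    below <- tips_below(node)
    if (!any(pres[below])) {
      losses[[length(losses) + 1L]] <<- tibble::tibble(
        branch = paste(sort(below), collapse = "|"),
        n_leaves = length(below)
      )
      return(invisible())
    }
    if (node > n_tip) for (child in kids(node)) walk(child)
  }
  for (child in kids(root)) walk(child)
  out <- dplyr::bind_rows(c(losses, list(none)))
  dplyr::arrange(out, .data$branch)
}

#' Intron losses for every class of an aligned intron matrix
#'
#' @param x an `aligned_intron_matrix`.
#' @param tree rooted `phylo` or Newick path.
#' @param species optional gene_id -> species map (see [class_profiles()]).
#' @param gain gain placement, see [infer_intron_losses()].
#' @return tibble: `class_id`, `branch`, `n_leaves`, one row per loss event.
#' @export
infer_losses_matrix <- function(x, tree, species = NULL, gain = c("root", "mrca")) {
  gain <- match.arg(gain)
  prof <- class_profiles(x, species)
  out <- prof %>%
    dplyr::group_by(.data$class_id) %>%
    dplyr::group_modify(function(d, key) {
      p <- tapply(d$present, d$leaf, any)
      infer_intron_losses(stats::setNames(as.logical(p), names(p)), tree, gain = gain)
    }) %>%
    dplyr::ungroup()
  out
}
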