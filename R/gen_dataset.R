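#' Generate a planted-conservation alignment fixture
#'
#' Emulates the cross-species comparison substrate: `n_species` pseudo-species
#' proteins that are identical in length over a shared core but carry
#' species-specific insertion blocks (which become gap columns for everyone
#' else), plus per-gene intron projections with `n_conserved` intron position
#' classes planted at identical (alignment column, phase) coordinates in
#' every species and `n_extra` species-specific classes each.
#'
#' @param seed integer seed.
#' @param n_species number of pseudo-species rows.
#' @param n_conserved number of planted conserved classes.
#' @param n_extra species-specific extra introns per species.
#' @param core_len length of the shared core (residues).
#' @param ins_len length of each species-specific insertion block.
#' @return list with `msa` (named character), `projections` (tibble),
#'   `species` (gene_id -> species map), `truth` (list: `n_conserved`,
#'   `conserved_columns`).
#' @export
gen_conservation_fixture <- function(seed, n_species = 4L, n_conserved = 6L,
                                     n_extra = 1L, core_len = 240L,
                                     ins_len = 8L) {
  withr::with_seed(seed, {
    aas <- setdiff(strsplit(rawToChar(as.raw(65:90)), "")[[1]], c("B", "J", "O", "U", "X", "Z"))
    genes <- sprintf("sp%02d_gene", seq_len(n_species))

    # species s gets one insertion block after core position ins_at[s]
    ins_at <- sort(sample(seq(20L, core_len - 20L), n_species))
    # planted conserved classes at core residues away from insertion points
    avail <- setdiff(seq(5L, core_len - 5L), unlist(lapply(ins_at, function(p) (p - 2L):(p + 2L))))
    cons_core <- sort(sample(avail, n_conserved))
    cons_phase <- sample(0:2, n_conserved, replace = TRUE)
    # species-specific extras at distinct core residues nobody else uses
    extra_pool <- setdiff(avail, cons_core)
    extra_core <- matrix(sample(extra_pool, n_species * n_extra), nrow = n_species)

    rows <- character(n_species)
    projections <- list()
    for (s in seq_len(n_species)) {
      core <- sample(aas, core_len, replace = TRUE)
      # alignment row: core with every species' insertion point expanded;
      # own block holds residues, other blocks hold gaps
      row_chars <- character()
      own_before <- integer(core_len) # own inserted residues before core pos
      ins_count <- 0L
      for (p in seq_len(core_len)) {
        row_chars <- c(row_chars, core[p])
        hit <- which(ins_at == p)
        if (length(hit) == 1L) {
          block <- if (hit == s) sample(aas, ins_len, replace = TRUE) else rep("-", ins_len)
          row_chars <- c(row_chars, block)
          if (hit == s) ins_count <- ins_count + ins_len
        }
        if (p < core_len) own_before[p + 1L] <- ins_count
      }
      rows[s] <- paste(row_chars, collapse = "")

      res_of_core <- function(p) p + own_before[p]
      cds_off <- function(res, phase) if (phase == 0L) 3L * res else 3L * (res - 1L) + phase
      offs <- vapply(seq_len(n_conserved), function(i) {
        cds_off(res_of_core(cons_core[i]), cons_phase[i])
      }, integer(1))
      extra_offs <- vapply(seq_len(n_extra), function(j) {
        # species-specific phase pattern keeps extras out of any shared class
        cds_off(res_of_core(extra_core[s, j]), (s + j) %% 3L)
      }, integer(1))
      all_offs <- sort(c(offs, extra_offs))
      pr <- project_intron(all_offs)
      projections[[s]] <- dplyr::bind_cols(
        tibble::tibble(gene_id = genes[s], intron_index = seq_along(all_offs)),
        pr
      )
    }
    names(rows) <- genes
    list(
      msa = rows,
      projections = dplyr::bind_rows(projections),
      species = stats::setNames(sub("_gene$", "", genes), genes),
      truth = list(n_conserved = n_conserved, conserved_core = cons_core,
                   conserved_phase = cons_phase)
    )
  })
}

#' Generate a labelled splice-variant dataset
#'
#' The test substrate standing in for an RT-PCR clone collection: a grid of
#' seeded gene models, each with its canonical form plus variants realizing
#' single events and (optionally) pairwise combinations, with ground-truth
#' event labels and expected protein outcomes computed by the naive oracles
#' of this module (never by the modules under test). Tissue labels come from
#' the grid, alternating deterministically.
#'
#' @param seed integer seed.
#' @param n_genes number of gene models.
#' @param n_exons exons per gene.
#' @param types event types to plant (subset of `IR`, `ES`, `Alt5SS`,
#'   `Alt3SS`).
#' @param pairwise also plant pairwise combinations of the types.
#' @param out_dir optional directory; when given, writes per-gene GFF3+FASTA
#'   (model + forms) and a `manifest.tsv`.
#' @param ... further arguments passed to [gene_spec()].
#' @return list with `models` (named list of gene models), `forms` (tibble
#'   over all genes incl. canonical forms), `manifest` (tibble with expected
#'   outcomes).
#' @export
gen_dataset <- function(seed, n_genes = 5L, n_exons = 9L,
                        types = c("IR", "ES", "Alt5SS", "Alt3SS"),
                        pairwise = TRUE, out_dir = NULL, ...) {
  models <- list()
  all_forms <- list()
  manifest <- list()
  tissue_cycle <- list("generative", "vegetative", c("generative", "vegetative"))

  for (g in seq_len(n_genes)) {
    spec <- gene_spec(seed = seed * 1000L + g, n_exons = n_exons,
                      gene_id = sprintf("synth%02d", g), ...)
    model <- gen_gene_model(spec)
    models[[model$gene_id]] <- model
    n_introns <- n_exons - 1L

    specs <- list()
    mid <- max(2L, n_introns %/% 2L)
    single_spec <- function(type, anchor) {
      delta <- switch(type,
        IR = NA_integer_, ES = NA_integer_,
        Alt5SS = if (anchor %% 2L == 0L) -9L else 15L,
        Alt3SS = if (anchor %% 2L == 0L) 12L else -6L
      )
      tibble::tibble(type = type, anchor = anchor, delta = delta)
    }
    anchors <- function(type, k) {
      # spread anchors over the gene, exons for ES (internal), introns else
      lo <- if (type == "ES") 2L else 1L
      hi <- if (type == "ES") n_exons - 1L else n_introns
      unique(pmin(pmax(round(seq(lo, hi, length.out = k)), lo), hi))
    }
    for (t in types) specs[[t]] <- single_spec(t, anchors(t, 3L)[2L])
    if (pairwise && length(types) > 1L) {
      combs <- utils::combn(types, 2L, simplify = FALSE)
      for (cb in combs) {
        a <- anchors(cb[1], 3L)[1L]
        b <- anchors(cb[2], 3L)[3L]
        if (cb[1] == "ES") a <- max(a, 2L)
        specs[[paste(cb, collapse = "+")]] <- dplyr::bind_rows(
          single_spec(cb[1], a), single_spec(cb[2], b)
        )
      }
    }

    forms <- list(apply_events(model, NULL,
      form_id = paste0(model$gene_id, ".alpha"),
      tissues = c("generative", "vegetative")
    ))
    fi <- 0L
    for (nm in names(specs)) {
      fi <- fi + 1L
      forms[[length(forms) + 1L]] <- apply_events(
        model, specs[[nm]],
        form_id = sprintf("%s.v%02d", model$gene_id, fi),
        tissues = tissue_cycle[[(fi - 1L) %% 3L + 1L]]
      )
    }
    forms <- dplyr::bind_rows(forms)
    all_forms[[g]] <- forms

    orc <- purrr::map(forms$chain, ~ oracle_variant_protein(model, .x))
    manifest[[g]] <- tibble::tibble(
      gene_id = model$gene_id,
      form_id = forms$form_id,
      truth_events = purrr::map_chr(forms$truth, events_string),
      expected_protein_aa = purrr::map_int(orc, ~ as.integer(.x$length_aa)),
      expected_stop_found = purrr::map_lgl(orc, "stop_found"),
      expected_ptc = purrr::map_lgl(forms$chain, ~ oracle_variant_ptc(model, .x)),
      tissues = purrr::map_chr(forms$tissues, ~ paste(sort(.x), collapse = ","))
    )
  }

  forms <- dplyr::bind_rows(all_forms)
  manifest <- dplyr::bind_rows(manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(models)) {
      m <- models[[id]]
      f <- forms[forms$gene_id == id, , drop = FALSE]
      write_gene_model(m,
        gff3_path = file.path(out_dir, paste0(id, ".gff3")),
        fasta_path = file.path(out_dir, paste0(id, ".fasta")),
        forms = f
      )
    }
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  }
  list(models = models, forms = forms, manifest = manifest)
}

#' Write a simple species tree
#'
#' @param species character vector of leaf names (>= 2).
#' @param path optional Newick output path.
#' @return the `phylo` tree (a rooted ladder over the given order).
#' @export
gen_species_tree <- function(species, path = NULL) {
  n <- length(species)
  stopifnot(n >= 2L)
  nwk <- species[1]
  for (i in 2:n) nwk <- sprintf("(%s,%s)", nwk, species[i])
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  if (!is.null(path)) ape::write.tree(tree, file = path)
  tree
}
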