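#' Read and validate a pipeline run configuration
#'
#' YAML with blocks `paths` (`gff3`, `fasta`, `forms`, optional `msa`,
#' `tree`), `genes` (gene ids; default: every gene feature in the GFF3),
#' `thresholds` (`long_3utr`, `min_intron`, `k_conserved`), `seed`, and
#' `out_dir`. All referenced paths must exist at run start.
#'
#' @param config path to a YAML file or an equivalent named list.
#' @return validated config list (with an added `config_path` when read from
#'   disk).
#' @export
read_run_config <- function(config) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) {
      abort(sprintf("config file '%s' not found", config), class = "splicefate_config")
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$paths) || is.null(config$paths$gff3) || is.null(config$paths$fasta)) {
    abort("config is missing paths$gff3 / paths$fasta", class = "splicefate_config")
  }
  for (field in c("gff3", "fasta", "forms", "msa", "tree")) {
    p <- config$paths[[field]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("config paths$%s: file '%s' does not exist", field, p),
        class = "splicefate_config"
      )
    }
  }
  if (isTRUE(config$stages$conserve %||% !is.null(config$paths$msa)) &&
    is.null(config$paths$msa)) {
    abort("conserve stage requested but config paths$msa is missing",
      class = "splicefate_config"
    )
  }
  th <- config$thresholds %||% list()
  config$thresholds <- list(
    long_3utr = as.integer(th$long_3utr %||% 350L),
    min_intron = as.integer(th$min_intron %||% 20L),
    k_conserved = if (is.null(th$k_conserved)) NULL else as.integer(th$k_conserved)
  )
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% "splicefate_out"
  config$config_path <- cfg_path
  config
}

gff3_gene_ids <- function(gff3_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  as.character(stats::na.omit(mc$ID[mc$type == "gene"]))
}

#' Run the splicing-fate pipeline end to end
#'
#' classify -> ORF/PTC -> NMD features -> intron projection -> (optionally)
#' conservation mapping and Dollo loss inference, writing deterministic TSV
#' reports plus a run log. Rerunning on identical inputs produces
#' byte-identical TSVs (no timestamps in any table). If a gene's forms file
#' contains no event-free chain, the canonical form is added from the
#' annotation.
#'
#' @param config see [read_run_config()].
#' @return (invisibly) a `splicefate_run` list with `forms`, `orf`, `nmd`,
#'   `tallies`, `tissue_comparison`, `projections`, `matrix`, `losses`,
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  gene_ids <- cfg$genes %||% gff3_gene_ids(cfg$paths$gff3)
  if (length(gene_ids) == 0L) {
    abort("no genes found in the annotation", class = "splicefate_validation")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = "splicefate_stage", parent = e
      )
    })
  }

  all_named <- list()
  all_orf <- list()
  all_nmd <- list()
  all_tally <- list()
  all_proj <- list()
  species_map <- character()

  for (gid in gene_ids) {
    model <- stage(paste0("load:", gid), load_gene_model(
      cfg$paths$gff3, cfg$paths$fasta, gid,
      min_intron = cfg$thresholds$min_intron
    ))
    species_map[gid] <- model$species %||% gid

    forms <- if (!is.null(cfg$paths$forms)) {
      stage(paste0("forms:", gid), load_forms(cfg$paths$forms, model))
    } else {
      tibble::tibble(
        form_id = character(), gene_id = character(), chain = list(),
        tissues = list(), provenance = character()
      )
    }
    forms <- stage(paste0("classify:", gid), classify_forms(forms, model))
    if (!any(forms$n_events == 0L)) {
      canon <- apply_events(model, NULL,
        form_id = paste0(gid, ".canonical"),
        provenance = "annotation"
      )
      canon$truth <- NULL
      forms <- dplyr::bind_rows(classify_forms(canon, model), forms)
    }
    named <- stage(paste0("name:", gid), assign_form_names(forms))
    orf <- stage(paste0("orf:", gid), analyze_orfs(named, model))
    nmd <- stage(paste0("nmd:", gid), annotate_nmd(
      named, model, orf,
      long_3utr_threshold = cfg$thresholds$long_3utr
    ))
    all_named[[gid]] <- named
    all_orf[[gid]] <- orf
    all_nmd[[gid]] <- nmd
    all_tally[[gid]] <- tally_events(named)
    all_proj[[gid]] <- stage(paste0("project:", gid), project_gene(model))
  }

  named <- dplyr::bind_rows(all_named)
  orf <- dplyr::bind_rows(all_orf)
  nmd <- dplyr::bind_rows(all_nmd)
  tallies <- dplyr::bind_rows(all_tally)
  projections <- dplyr::bind_rows(all_proj)
  tissue_cmp <- suppressWarnings(dplyr::bind_rows(purrr::map(all_named, compare_tissues)))

  matrix <- NULL
  losses <- NULL
  if (!is.null(cfg$paths$msa)) {
    matrix <- stage("conserve", map_to_alignment(
      projections, cfg$paths$msa,
      k = cfg$thresholds$k_conserved
    ))
    if (!is.null(cfg$paths$tree)) {
      losses <- stage("losses", infer_losses_matrix(
        matrix, cfg$paths$tree,
        species = species_map
      ))
    }
  }

  forms_table <- named %>%
    dplyr::left_join(
      orf[, c("gene_id", "form_id", "ptc", "protein_length_aa", "delta_aa", "functional_call")],
      by = c("gene_id", "form_id")
    )
  paths <- write_reports(forms_table, out_dir,
    matrix = matrix,
    orf_table = dplyr::left_join(orf, nmd[, setdiff(names(nmd), c("form_name", "form_ascii"))],
      by = c("gene_id", "form_id")
    )
  )
  p <- file.path(out_dir, "tallies.tsv")
  readr::write_tsv(tallies, p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "projections.tsv")
  readr::write_tsv(projections, p)
  paths <- c(paths, p)
  if (nrow(tissue_cmp) > 0L) {
    p <- file.path(out_dir, "tissue_comparison.tsv")
    readr::write_tsv(tissue_cmp, p)
    paths <- c(paths, p)
  }
  if (!is.null(losses)) {
    p <- file.path(out_dir, "losses.tsv")
    readr::write_tsv(losses, p)
    paths <- c(paths, p)
  }

  log_lines <- c(
    sprintf("splicefate %s", as.character(utils::packageVersion("splicefate"))),
    sprintf("genes: %s", paste(gene_ids, collapse = ", ")),
    sprintf("seed: %d", cfg$seed),
    sprintf(
      "thresholds: long_3utr=%d min_intron=%d k_conserved=%s",
      cfg$thresholds$long_3utr, cfg$thresholds$min_intron,
      cfg$thresholds$k_conserved %||% "all"
    ),
    if (!is.null(cfg$config_path)) {
      sprintf("config md5: %s", unname(tools::md5sum(cfg$config_path)))
    }
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  if (!is.null(cfg$config_path)) {
    file.copy(cfg$config_path, file.path(out_dir, "config.yaml"), overwrite = TRUE)
  }

  structure(
    list(
      forms = forms_table, orf = orf, nmd = nmd, tallies = tallies,
      tissue_comparison = tissue_cmp, projections = projections,
      matrix = matrix, losses = losses, paths = paths, config = cfg
    ),
    class = "splicefate_run"
  )
}

#' @export
print.splicefate_run <- function(x, ...) {
  cat(sprintf(
    "<splicefate_run> %d gene(s), %d form(s); reports in %s\n",
    dplyr::n_distinct(x$forms$gene_id), nrow(x$forms), x$config$out_dir
  ))
  invisible(x)
}
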