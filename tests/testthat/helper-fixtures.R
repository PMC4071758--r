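# Hand-built gene models with fully predictable sequences.
#
# Coding sequence is ATG + "GCT" repeats + TAA: the GCT period has no stop
# codon in any frame, so removing or inserting any multiple of 3 nt keeps the
# reading stop-free. UTRs are C runs; introns are GT + body + AG with a
# C-only body by default (stop-free in every frame) or a "TAATAA..." body to
# plant in-frame stops.
#
# exon_cds: coding nt contributed by each exon (first includes ATG, last
# includes the TAA stop); sum must be a multiple of 3.
manual_model <- function(exon_cds = c(54L, 120L, 90L, 63L),
                         utr5 = 6L, utr3 = 9L,
                         intron_len = 30L, intron_body = "C",
                         gene_id = "toy", species = "toyspecies") {
  stopifnot(sum(exon_cds) %% 3L == 0L, exon_cds[1] >= 3L)
  n <- length(exon_cds)
  cds <- paste0("ATG", strrep("GCT", (sum(exon_cds) - 6L) %/% 3L), "TAA")
  transcript <- paste0(strrep("C", utr5), cds, strrep("C", utr3))
  exon_lens <- exon_cds
  exon_lens[1] <- exon_lens[1] + utr5
  exon_lens[n] <- exon_lens[n] + utr3
  bounds <- c(0L, cumsum(exon_lens))
  exon_seqs <- substring(transcript, bounds[-(n + 1L)] + 1L, bounds[-1L])
  if (length(intron_len) == 1L) intron_len <- rep(intron_len, n - 1L)
  intron_seq <- function(len) {
    body <- strrep(intron_body, ceiling((len - 4L) / nchar(intron_body)))
    paste0("GT", substring(body, 1L, len - 4L), "AG")
  }
  introns <- vapply(intron_len, intron_seq, character(1))
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, by = 2L, length.out = n)] <- exon_seqs
  if (n > 1L) pieces[seq(2L, by = 2L, length.out = n - 1L)] <- introns
  genome <- paste(pieces, collapse = "")
  exons <- list()
  pos <- 0L
  for (k in seq_len(n)) {
    exons[[k]] <- tibble::tibble(start = pos, end = pos + exon_lens[k])
    pos <- pos + exon_lens[k] + if (k < n) intron_len[k] else 0L
  }
  gene_model(
    gene_id = gene_id, genome = genome, exons = dplyr::bind_rows(exons),
    cds_span = c(utr5, utr5 + sum(exon_cds)), species = species
  )
}

# stop-free synthetic CDS of an exact length (for the CDS -> protein relation)
manual_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 6L)
  paste0("ATG", strrep("GCT", (len - 6L) %/% 3L), "TAA")
}

event_tbl <- function(...) {
  # event_tbl("IR", 3, NA, "Alt3SS", 5, -12)
  v <- list(...)
  stopifnot(length(v) %% 3L == 0L)
  idx <- seq(1L, length(v), by = 3L)
  tibble::tibble(
    type = vapply(idx, function(i) as.character(v[[i]]), character(1)),
    anchor = vapply(idx, function(i) as.integer(v[[i + 1L]]), integer(1)),
    delta = vapply(idx, function(i) as.integer(v[[i + 2L]]), integer(1))
  )
}

# independent decimal-phase projection by naive codon walking
oracle_project <- function(cds_offset) {
  residue <- 0L
  consumed <- 0L
  while (consumed < cds_offset) {
    residue <- residue + 1L
    consumed <- consumed + 3L
  }
  within_codon <- cds_offset - (residue - 1L) * 3L # 1, 2, or 3
  if (within_codon == 3L) {
    sprintf("%d.0", residue)
  } else {
    sprintf("%d.%d", residue, c(3L, 6L)[within_codon])
  }
}

# exhaustive Dollo oracle for a root gain: the minimum number of branches
# whose clades cover every absent leaf, no present leaf, each leaf once —
# brute force over all subsets of branches (small trees only)
oracle_dollo_min_losses <- function(presence, tree) {
  leaves <- tree$tip.label
  pres <- stats::setNames(rep(FALSE, length(leaves)), leaves)
  pres[names(presence)] <- presence
  present <- names(pres)[pres]
  absent <- setdiff(leaves, present)
  if (length(present) == 0L || length(absent) == 0L) return(0L)
  n_tip <- length(leaves)
  kids <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  tips_below <- function(node) {
    if (node <= n_tip) return(leaves[node])
    unlist(lapply(kids(node), tips_below))
  }
  cand <- tree$edge[, 2] # every branch (child node identifies it)
  for (k in seq_along(cand)) {
    for (sub in utils::combn(cand, k, simplify = FALSE)) {
      covered <- unlist(lapply(sub, tips_below))
      if (setequal(covered, absent) && !any(covered %in% present) &&
        length(covered) == length(unique(covered))) {
        return(k)
      }
    }
  }
  stop("no covering subset found") # unreachable on a binary tree
}

# small helper: write model (+forms) and a pipeline config into a temp dir
write_pipeline_inputs <- function(model, forms, dir,
                                  msa = NULL, tree = NULL, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff3 <- file.path(dir, "genes.gff3")
  fasta <- file.path(dir, "genome.fasta")
  write_gene_model(model, gff3, fasta, forms = forms)
  cfg <- list(
    paths = list(gff3 = gff3, fasta = fasta, forms = gff3),
    out_dir = file.path(dir, "out"),
    seed = 1L
  )
  if (!is.null(msa)) {
    msa_path <- file.path(dir, "alignment.faa")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(msa), msa_path)
    cfg$paths$msa <- msa_path
  }
  if (!is.null(tree)) {
    tree_path <- file.path(dir, "species.nwk")
    ape::write.tree(tree, tree_path)
    cfg$paths$tree <- tree_path
  }
  cfg <- utils::modifyList(cfg, extra)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
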