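test_that("decimal-phase projection follows the codon.phase convention", {
  p <- project_intron(c(52L, 53L, 54L))
  expect_equal(p$notation, c("18.3", "18.6", "18.0"))
  expect_equal(p$residue, c(18L, 18L, 18L))
  expect_equal(p$phase_decimal, c(0.3, 0.6, 0.0))
  expect_error(project_intron(0L), class = "splicefate_input")
  expect_error(project_intron(-3L), class = "splicefate_input")
})

test_that("projection is pure and notation parses back losslessly", {
  offs <- 1:300
  p <- project_intron(offs)
  back <- parse_notation(p$notation)
  expect_equal(back$residue, p$residue)
  expect_equal(back$phase, p$phase)
  # naive codon-walk oracle agreement
  expect_equal(p$notation, vapply(offs, oracle_project, character(1)))
})

test_that("gene projection covers every CDS intron in order", {
  m <- gen_gene_model(gene_spec(seed = 7L, n_exons = 15L, utr5_len = 30L, utr3_len = 30L))
  pr <- project_gene(m)
  expect_equal(nrow(pr), 14L)
  expect_equal(pr$intron_index, 1:14)
  expect_equal(pr$phase, derive_introns(m)$phase)

  # exon coding contributions all multiples of 3 -> every phase 0
  m0 <- manual_model(exon_cds = c(54L, 90L, 120L, 63L))
  expect_true(all(project_gene(m0)$phase_decimal == 0))

  # seeded random models agree with the naive walk
  for (seed in 1:5) {
    mm <- gen_gene_model(gene_spec(seed, n_exons = 8L))
    pp <- project_gene(mm)
    expect_equal(pp$notation, vapply(pp$cds_offset, oracle_project, character(1)))
  }
})

test_that("identical genes give fully conserved classes", {
  pr <- dplyr::bind_rows(
    project_intron(c(10L, 25L, 41L)) %>% dplyr::mutate(gene_id = "g1", intron_index = 1:3),
    project_intron(c(10L, 25L, 41L)) %>% dplyr::mutate(gene_id = "g2", intron_index = 1:3)
  )
  prot <- strrep("A", 20)
  mx <- map_to_alignment(pr, c(g1 = prot, g2 = prot))
  expect_equal(nrow(mx$classes), 3L)
  expect_true(all(mx$classes$conserved))
  expect_equal(glance(mx)$n_conserved, 3L)
})

test_that("planted conservation is recovered exactly and is gap-invariant", {
  fx <- gen_conservation_fixture(seed = 3L, n_species = 4L, n_conserved = 6L, n_extra = 1L)
  mx <- map_to_alignment(fx$projections, fx$msa)
  expect_equal(sum(mx$classes$conserved), 6L)
  # extras are species-specific singleton classes
  expect_equal(sum(mx$classes$n_present == 1L), 4L)

  # inserting an all-gap column never changes conserved-class membership
  msa_gapped <- vapply(fx$msa, function(row) {
    paste0(substring(row, 1, 10), "-", substring(row, 11))
  }, character(1))
  mx2 <- map_to_alignment(fx$projections, msa_gapped)
  expect_equal(sum(mx2$classes$conserved), 6L)
  cons_genes <- function(m) {
    m$cells %>%
      dplyr::left_join(m$classes[, c("class_id", "conserved")], by = "class_id") %>%
      dplyr::filter(.data$conserved) %>%
      dplyr::arrange(.data$gene_id, .data$intron_index) %>%
      dplyr::pull(.data$notation)
  }
  expect_identical(cons_genes(mx2), cons_genes(mx))
})

test_that("raising the conservation quorum k never adds classes", {
  fx <- gen_conservation_fixture(seed = 11L, n_species = 5L, n_conserved = 4L, n_extra = 2L)
  counts <- vapply(1:5, function(k) {
    sum(map_to_alignment(fx$projections, fx$msa, k = k)$classes$conserved)
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("alignment consistency is enforced", {
  pr <- project_intron(100L) %>% dplyr::mutate(gene_id = "g1", intron_index = 1L)
  expect_error(
    map_to_alignment(pr, c(g1 = strrep("A", 20))),
    class = "splicefate_consistency"
  )
  expect_error(
    map_to_alignment(pr %>% dplyr::mutate(gene_id = "gX"), c(g1 = strrep("A", 40))),
    class = "splicefate_consistency"
  )
  expect_error(
    map_to_alignment(pr, c(g1 = strrep("A", 40)), proteins = c(g1 = strrep("C", 40))),
    class = "splicefate_consistency"
  )
})

test_that("Dollo loss inference handles the canonical phylogenetic patterns", {
  # two sister taxa lost an ancestral intron; the outgroup kept it:
  # exactly one loss on their common internal branch
  tree <- ape::read.tree(text = "((Osa,Ogl),Obr);")
  losses <- infer_intron_losses(c(Osa = FALSE, Ogl = FALSE, Obr = TRUE), tree)
  expect_equal(nrow(losses), 1L)
  expect_equal(losses$branch, "Ogl|Osa")
  expect_equal(losses$n_leaves, 2L)

  # under the loss-minimal gain placement the same profile needs no loss
  expect_equal(nrow(infer_intron_losses(
    c(Osa = FALSE, Ogl = FALSE, Obr = TRUE), tree,
    gain = "mrca"
  )), 0L)

  tree4 <- ape::read.tree(text = "(((Osa,Ogl),Obr),Out);")
  losses4 <- infer_intron_losses(
    c(Osa = FALSE, Ogl = FALSE, Obr = TRUE, Out = TRUE), tree4
  )
  expect_equal(nrow(losses4), 1L)
  expect_equal(losses4$branch, "Ogl|Osa")

  # absence in a single leaf: one terminal loss
  tree5 <- ape::read.tree(text = "((((Ugi,Ath),Bra),Osa),Ppa);")
  pres <- c(Ugi = FALSE, Ath = TRUE, Bra = TRUE, Osa = TRUE, Ppa = TRUE)
  l5 <- infer_intron_losses(pres, tree5)
  expect_equal(nrow(l5), 1L)
  expect_equal(l5$branch, "Ugi")

  # present everywhere: no losses
  expect_equal(nrow(infer_intron_losses(
    c(Ugi = TRUE, Ath = TRUE, Bra = TRUE, Osa = TRUE, Ppa = TRUE), tree5
  )), 0L)

  # empty profile: no events
  expect_equal(nrow(infer_intron_losses(
    c(Ugi = FALSE, Ath = FALSE, Bra = FALSE, Osa = FALSE, Ppa = FALSE), tree5
  )), 0L)
})

test_that("Dollo loss counts equal the exhaustive minimum on small trees", {
  trees <- list(
    ape::read.tree(text = "((a,b),(c,d));"),
    ape::read.tree(text = "(((a,b),c),(d,e));"),
    ape::read.tree(text = "((((a,b),c),d),(e,f));")
  )
  withr::with_seed(123L, {
    for (tree in trees) {
      leaves <- tree$tip.label
      for (rep in 1:20) {
        pres <- stats::setNames(sample(c(TRUE, FALSE), length(leaves), replace = TRUE), leaves)
        ours <- nrow(infer_intron_losses(pres, tree))
        expect_equal(ours, oracle_dollo_min_losses(pres, tree))
      }
    }
  })
})

test_that("matrix-wide loss inference maps genes to species-tree leaves", {
  fx <- gen_conservation_fixture(seed = 8L, n_species = 3L, n_conserved = 2L, n_extra = 1L)
  mx <- map_to_alignment(fx$projections, fx$msa, k = 3L)
  tree <- gen_species_tree(unname(fx$species))
  losses <- infer_losses_matrix(mx, tree, species = fx$species)
  # classes present in every species never show a loss
  cons_ids <- mx$classes$class_id[mx$classes$conserved]
  expect_equal(sum(losses$class_id %in% cons_ids), 0L)
  # under the loss-minimal placement the species-specific extras (single-leaf
  # gains) contribute no losses at all
  expect_equal(nrow(infer_losses_matrix(mx, tree, species = fx$species, gain = "mrca")), 0L)

  # knock one conserved class out of two of three species: the absences are
  # explained by loss branches
  cons <- cons_ids[1]
  victim <- mx$cells$class_id == cons & mx$cells$gene_id %in% names(fx$species)[1:2]
  pruned <- fx$projections[!(paste(fx$projections$gene_id, fx$projections$notation) %in%
    paste(mx$cells$gene_id, mx$cells$notation)[victim]), ]
  mx2 <- map_to_alignment(pruned, fx$msa, k = 3L)
  l2 <- infer_losses_matrix(mx2, tree, species = fx$species)
  expect_gte(sum(l2$class_id == cons), 1L)
})
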