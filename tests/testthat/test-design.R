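test_that("mutant tip projection extends the CA->CB direction to 5.5 A", {
  m <- hs_structure(
    residues = data.frame(chain = "A", resno = 1L, aa = "S",
                          modeled = TRUE),
    atoms = data.frame(chain = "A", resno = 1L, elety = c("CA", "CB"),
                       x = c(0, 1), y = 0, z = 0))
  expect_equal(unname(project_mutant_tip(m, "A", 1)), c(5.5, 0, 0))

  degen <- m
  degen$atoms$x <- c(0, 0)
  expect_error(project_mutant_tip(degen, "A", 1), "coincide")

  ## glycine: CB synthesised from ideal backbone geometry
  gly <- hs_structure(
    residues = data.frame(chain = "A", resno = 1L, aa = "G",
                          modeled = TRUE),
    atoms = data.frame(chain = "A", resno = 1L,
                       elety = c("N", "CA", "C"),
                       x = c(-1.2, 0, 1.2), y = c(-0.4, 0, -0.4), z = 0))
  tip <- project_mutant_tip(gly, "A", 1)
  expect_equal(sqrt(sum(tip^2)), 5.5, tolerance = 1e-6)

  noca <- gly
  noca$atoms <- noca$atoms[noca$atoms$elety != "CA", ]
  expect_error(project_mutant_tip(noca, "A", 1), "no CA")
})

test_that("planted introductions are recovered and constraints enforced", {
  fx <- generate_fixture(seed = 42)
  surf <- surface_profile(fx$model)
  pr <- propose_introductions(fx$model, surf)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$mutation[1], fx$truth$expected_mutation)
  expect_equal(pr$n_anchors[1], 2)
  expect_equal(pr$kind[1], "introduce")

  ## masked candidate: no proposal, audit records the mask
  fm <- generate_fixture(seed = 42, masked = TRUE)
  sm <- surface_profile(fm$model)
  pm <- propose_introductions(fm$model, sm,
                              design_constraints(masks = fm$truth$mask))
  expect_equal(nrow(pm), 0)
  audit <- attr(pm, "audit")
  expect_true("masked" %in%
                audit$reason[audit$position == fm$truth$candidate$resno])

  ## hydrophobic candidate: excluded by the no-charged-into-hydrophobic rule
  fh <- generate_fixture(seed = 42, candidate_aa = "L")
  sh <- surface_profile(fh$model)
  expect_equal(nrow(propose_introductions(fh$model, sh)), 0)

  ## proline sites are allowed but flagged
  fp <- generate_fixture(seed = 42, candidate_aa = "P")
  sp <- surface_profile(fp$model)
  pp <- propose_introductions(fp$model, sp)
  expect_equal(nrow(pp), 1)
  expect_match(pp$flags[1], "proline_site")
})

test_that("proposals never land on masked, hydrophobic or buried residues", {
  for (seed in c(3, 14, 27, 58, 71)) {
    fx <- generate_fixture(seed = seed, candidate_distances = c(NA, NA))
    surf <- surface_profile(fx$model)
    mask <- mask_ranges("A", 1, 4, "edge")
    pr <- propose_introductions(fx$model, surf,
                                design_constraints(masks = mask))
    if (nrow(pr)) {
      expect_false(any(in_mask(mask, pr$chain, pr$position)))
      expect_false(any(pr$from_aa %in% c("I", "V", "L", "F", "M", "W")))
      key <- paste(pr$chain, pr$position)
      expect_true(all(surf$exposed[match(key, paste(surf$chain,
                                                    surf$resno))]))
    }
  }
})

test_that("ranking is monotone in anchors with position tie-breaks", {
  p <- data.frame(
    chain = "A", position = c(176L, 75L, 20L),
    from_aa = "S", to_aa = "K",
    mutation = c("S176K", "S75K", "S20K"), kind = "introduce",
    n_anchors = c(1L, 1L, 2L), anchor_detail = "",
    affected_sites = "", score = c(1.1, 1.1, 2.2), flags = "",
    stringsAsFactors = FALSE)
  r <- rank_proposals(p)
  expect_equal(r$mutation, c("S20K", "S75K", "S176K"))
  expect_equal(nrow(rank_proposals(p[0, ])), 0)
})

test_that("removal modes reproduce the canonical benchmark sets", {
  fx <- fixture_cluster_motif_removal(seed = 8)
  m <- fx$model
  surf <- surface_profile(m)
  cl <- find_spatial_clusters(m, surf, use_long = FALSE)
  expect_length(cl$clusters, 1)
  expect_equal(sort(cl$clusters[[1]]$members$resno),
               fx$truth$cluster_members)
  hits <- scan_model_motifs(m, patterns = motif_patterns("BXXXBB",
                                                         "BXXXBB"))
  expect_equal(hits$start, fx$truth$motif$start)

  per <- propose_removals(m, clusters = cl, mode = "per_site",
                          exclude = fx$truth$exclude)
  expect_equal(per$mutation, fx$truth$expected_per_site_cluster)

  mini <- propose_removals(m, motifs = hits, mode = "minimal_set",
                           exclude = fx$truth$exclude)
  expect_equal(mini$mutation, fx$truth$expected_minimal_motif)

  expect_error(propose_removals(m, mode = "per_site"), "no targeted sites")
})

test_that("minimal_set removals are self-verifying and respect masks", {
  fx <- fixture_cluster_motif_removal(seed = 5)
  m <- fx$model
  surf <- surface_profile(m)
  cl <- find_spatial_clusters(m, surf, use_long = FALSE)
  hits <- scan_model_motifs(m, patterns = motif_patterns("BXXXBB",
                                                         "BXXXBB"))
  mini <- propose_removals(m, motifs = hits, clusters = cl,
                           mode = "minimal_set",
                           exclude = fx$truth$exclude)
  expect_equal(mini$mutation, fx$truth$expected_full_removal)
  v <- verify_design(m, mini, motifs = hits, clusters = cl)
  expect_true(v$ok)
  ## re-scan of the mutant finds neither the motif nor the cluster
  mut <- apply_proposals(m, mini)
  expect_equal(nrow(scan_model_motifs(
    mut, patterns = motif_patterns("BXXXBB", "BXXXBB"))), 0)
  msurf <- surface_profile(mut)
  expect_length(find_spatial_clusters(mut, msurf,
                                      use_long = FALSE)$clusters, 0)

  ## a site whose members are all masked is unresolvable
  mask <- mask_ranges("A", 239, 245, "tail")
  blocked <- propose_removals(
    m, motifs = hits, constraints = design_constraints(masks = mask),
    mode = "per_site")
  expect_equal(nrow(blocked), 0)
  expect_length(attr(blocked, "unresolvable"), 1)
})

test_that("applying then reverting proposals restores the sequence", {
  fx <- fixture_cluster_motif_removal(seed = 2)
  m <- fx$model
  before <- model_sequence(m)["A"]
  muts <- c("K42Q", "K43Q", "K243Q", "R244Q")
  rn <- m$residues$resno[m$residues$chain == "A"]
  mutated <- apply_mutations(before, muts, resno = rn)
  inverse <- vapply(muts, function(x) {
    p <- parse_mutation(x)
    format_mutation(p$to_aa, p$position, p$from_aa)
  }, character(1))
  expect_equal(apply_mutations(mutated, inverse, resno = rn),
               unname(before))
  expect_error(apply_mutations(mutated, muts, resno = rn), "[Ss]tale")
})

test_that("charge deltas cross-check structural proposals", {
  fx <- generate_fixture(seed = 13)
  surf <- surface_profile(fx$model)
  pr <- propose_introductions(fx$model, surf)
  expect_equal(mutation_charge_delta(pr$mutation), nrow(pr),
               tolerance = 0.01)
  fr <- fixture_cluster_motif_removal(seed = 1)
  sr <- surface_profile(fr$model)
  clr <- find_spatial_clusters(fr$model, sr, use_long = FALSE)
  hits <- scan_model_motifs(fr$model, patterns = motif_patterns("BXXXBB",
                                                                "BXXXBB"))
  rem <- propose_removals(fr$model, motifs = hits, clusters = clr,
                          mode = "minimal_set", exclude = 239)
  expect_equal(mutation_charge_delta(rem$mutation), -nrow(rem),
               tolerance = 0.01)
})

test_that("verification fails for His-only anchors with histidine disabled", {
  ## two His anchors 6 A apart and a Ser completing them
  tips <- rbind(c(0, 0, 0), c(6, 0, 0))
  cloud <- site_cloud(tips, aa = "H")
  m <- cloud$model
  m$residues <- rbind(m$residues,
                      data.frame(chain = "A", resno = 3L, aa = "S",
                                 modeled = TRUE))
  ## CA placed so the projected tip lands ~6 A from both His tips
  m$atoms <- rbind(m$atoms, data.frame(
    chain = "A", resno = 3L, elety = c("CA", "CB"),
    x = 3, y = c(10.7, 9.7), z = 0))
  surf <- rbind(cloud$surface,
                data.frame(chain = "A", resno = 3L, aa = "S",
                           modeled = TRUE, exposed = TRUE,
                           rel_sasa = 1))
  pr <- propose_introductions(m, surf, design_constraints())
  expect_equal(pr$position, 3)
  nohis <- design_constraints(use_histidine = FALSE)
  expect_equal(nrow(propose_introductions(m, surf, nohis)), 0)
  v <- verify_design(m, pr, nohis, n_points = 120)
  expect_false(v$ok)
})

test_that("constraint validation rejects inconsistent targets", {
  expect_error(design_constraints(introduce_to_aa = "S"), "basic")
  expect_error(design_constraints(removal_to_aa = "K"), "non-basic")
  expect_error(design_constraints(removal_to_aa = "E"), "non-basic")
  expect_error(design_constraints(removal_to_aa = "L"), "hydrophobic")
})
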