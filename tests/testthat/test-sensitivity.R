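test_that("and_to_or weakens the gate and and_to_itt makes mixed inputs unknown", {
  m <- parse_model("c1: C = A · B")
  a_only <- c(A = 1, B = 0)
  # AND: C off with a single input
  expect_equal(compute_lss(m, lih_scenario(inputs = a_only))$values[["C"]], 0L)
  m_or <- apply_edits(m, lih_edit("and_to_or", "c1"))
  expect_length(m_or$hyperarcs, 2L)
  expect_equal(compute_lss(m_or, lih_scenario(inputs = a_only))$values[["C"]], 1L)
  m_itt <- apply_edits(m, lih_edit("and_to_itt", "c1"))
  expect_length(m_itt$itt_gates, 1L)
  expect_true(is.na(compute_lss(m_itt,
                                lih_scenario(inputs = a_only))$values[["C"]]))
  # unanimous corners still determined after ITT conversion
  expect_equal(compute_lss(m_itt,
                           lih_scenario(inputs = c(A = 1, B = 1)))$values[["C"]], 1L)
  m_rm <- apply_edits(m, lih_edit("remove_reaction", "c1"))
  expect_true(is.na(compute_lss(m_rm,
                                lih_scenario(inputs = a_only))$values[["C"]]))
})

test_that("edit preconditions reject scale-2 arcs, single literals and shared targets", {
  m <- fixture("crosstalk_v3")
  expect_error(apply_edits(m, lih_edit("remove_reaction", "mapk_pi3k")),
               "time-scale-2")
  expect_error(apply_edits(m, lih_edit("and_to_or", "jak_il6")), ">= 2")
  # dna target has a single arc, so ITT conversion is allowed there
  m2 <- apply_edits(m, lih_edit("and_to_itt", "dna"))
  expect_length(m2$itt_gates, 1L)
  # but not on a target with other incoming arcs
  expect_error(apply_edits(m, lih_edit("and_to_itt", "mapk_ins_tnfa")),
               "other incoming")
  expect_error(apply_edits(m, lih_edit("remove_reaction", "nope")),
               "no hyperarc")
})

test_that("and_to_or only ever adds determined activations (weakening)", {
  for (seed in 1:15) {
    m <- random_boolean_model(5L + (seed %% 4L), 4L + (seed %% 8L),
                              seed = seed + 40L)
    elig <- lihnet:::eligible_arcs(m, "and_to_or")
    if (length(elig) == 0L) next
    edited <- apply_edits(m, lih_edit("and_to_or", elig[1]))
    clamps <- random_clamps(m, seed = seed + 41L)
    st0 <- compute_lss(m, lih_scenario(perturbations = clamps))
    st1 <- compute_lss(edited, lih_scenario(perturbations = clamps))
    on0 <- names(st0$values)[!is.na(st0$values) & st0$values >= 1L]
    on1 <- names(st1$values)[!is.na(st1$values) & st1$values >= 1L]
    expect_true(all(on0 %in% on1),
                label = sprintf("seed %d: activations preserved", seed))
  }
})

test_that("relative agreement is 100% for the unedited model and pools have C(m,k) size", {
  v3 <- fixture("crosstalk_v3")
  obs <- fixture("fig4_observations")
  ref <- lihnet:::score_correct(v3, obs, "initial")
  expect_equal(ref, 11L)
  scan <- sensitivity_scan(v3, obs, n_edits = 1, kinds = "remove_reaction")
  m_elig <- length(lihnet:::eligible_arcs(v3, "remove_reaction"))
  expect_equal(nrow(scan$variants), choose(m_elig, 1))
  scan2 <- sensitivity_scan(v3, obs, n_edits = 2, kinds = "remove_reaction")
  expect_equal(nrow(scan2$variants), choose(m_elig, 2))
  expect_true(all(scan$variants$relative <= 100 + 1e-9))
})

test_that("removing the IL6->JAK arc breaks exactly the JAK-dependent scenarios", {
  v3 <- fixture("crosstalk_v3")
  obs <- fixture("fig4_observations")
  edited <- apply_edits(v3, lih_edit("remove_reaction", "jak_il6"))
  cmp <- compare_observations(edited, obs)
  # hand-evaluated oracle: JAK loses its only arc and becomes undetermined,
  # so every scenario whose output is not forced by another route (TGFb on,
  # or a determined mitogen arc into MAPK/PI3K) goes indeterminate; that is
  # the three IL6-positive scenarios plus Insulin-only and TNFa-only
  lost <- sort(cmp$details$label[cmp$details$status == "indeterminate"])
  expect_equal(lost, c("IL6", "IL6+Insulin", "IL6+TNFa", "Insulin", "TNFa"))
  expect_equal(sum(cmp$details$status == "mismatch"), 0L)
  scan <- sensitivity_scan(v3, obs, n_edits = 1, kinds = "remove_reaction")
  rel <- scan$variants$relative[scan$variants$edits == "jak_il6"]
  expect_equal(rel, 100 * 6 / 11)
})

test_that("sampled scans are reproducible run-to-run", {
  v3 <- fixture("crosstalk_v3")
  obs <- fixture("fig4_observations")
  a <- sensitivity_scan(v3, obs, n_edits = 2, kinds = "remove_reaction",
                        mode = "sampled", sample_n = 5, seed = 11)
  b <- sensitivity_scan(v3, obs, n_edits = 2, kinds = "remove_reaction",
                        mode = "sampled", sample_n = 5, seed = 11)
  expect_identical(a$variants, b$variants)
  expect_equal(nrow(a$variants), 5L)
})

test_that("variant enumeration over redundant arcs finds 3 of 4 and one version class", {
  # C = A OR B observed active under A=1, B=1: either arc (or both) suffices
  m <- parse_model("ca: C = A\ncb: C = B")
  obs <- list(lih_observation(lih_scenario(inputs = c(A = 1, B = 1)),
                              c(C = 1), label = "both"))
  space <- list(lih_edit("remove_reaction", "ca"),
                lih_edit("remove_reaction", "cb"))
  ev <- enumerate_variants(m, space, obs)
  expect_equal(nrow(ev$variants), 4L)
  expect_equal(ev$n_explaining, 3L)
  expect_equal(ev$n_classes, 1L)
  # full-truth-table grouping distinguishes C=A, C=B and C=A+B
  ev2 <- enumerate_variants(m, space, obs, group_by = "full_io")
  expect_equal(ev2$n_explaining, 3L)
  expect_equal(ev2$n_classes, 3L)
  # empty edit space: base model only
  ev3 <- enumerate_variants(m, list(), obs)
  expect_equal(nrow(ev3$variants), 1L)
  expect_equal(ev3$n_explaining, 1L)
})

test_that("identical truth tables land in one version class", {
  # removing either redundant copy of the same arc leaves behavior unchanged
  m <- parse_model("c1: C = A\nc2: C = A\ncb: C = B")
  obs <- list(lih_observation(lih_scenario(inputs = c(A = 1, B = 0)),
                              c(C = 1), label = "a"),
              lih_observation(lih_scenario(inputs = c(A = 0, B = 1)),
                              c(C = 1), label = "b"))
  space <- list(lih_edit("remove_reaction", "c1"),
                lih_edit("remove_reaction", "c2"))
  ev <- enumerate_variants(m, space, obs, group_by = "full_io")
  # keeping either copy (or both) leaves C = A + B: three explaining
  # variants with identical truth tables in a single class
  expect_equal(ev$n_explaining, 3L)
  expect_equal(ev$n_classes, 1L)
})

test_that("observation deduplication keeps the last occurrence of a label", {
  o1 <- lih_observation(lih_scenario(inputs = c(A = 1)), c(C = 0), "EGF")
  o2 <- lih_observation(lih_scenario(inputs = c(A = 1)), c(C = 1), "EGF")
  o3 <- lih_observation(lih_scenario(inputs = c(A = 0)), c(C = 0), "ctrl")
  dd <- dedup_observations(list(o1, o3, o2))
  expect_length(dd, 2L)
  kept <- dd[[which(vapply(dd, `[[`, "", "label") == "EGF")]]
  expect_equal(unname(kept$expected), 1L)
})

test_that("scan preconditions are enforced and reports serialize", {
  v3 <- fixture("crosstalk_v3")
  obs <- fixture("fig4_observations")
  expect_error(sensitivity_scan(v3, list(), n_edits = 1), "empty")
  expect_error(sensitivity_scan(v3, obs, n_edits = 5), "1, 2 or 3")
  p <- withr::local_tempfile(fileext = ".tsv")
  scan <- sensitivity_scan(v3, obs, n_edits = 1, kinds = "remove_reaction")
  write_sensitivity_tsv(scan, p)
  expect_equal(nrow(utils::read.delim(p)), nrow(scan$variants))
})
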