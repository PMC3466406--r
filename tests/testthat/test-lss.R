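ligands0 <- c(EGF = 0, HGF = 0, IL6 = 0, Insulin = 0, TNFa = 0, TGFb = 0)

test_that("cross-talk closes pathway activation at full time scales", {
  m <- fixture("crosstalk_original")
  # JAK active alone: both pathways reachable, DNA synthesis on
  st <- compute_lss(m, lih_scenario(inputs = ligands0,
                                    perturbations = c(JAK = 1)))
  expect_equal(st$values[["DNA_synthesis"]], 1L)
  expect_equal(st$values[["MAPK"]], 1L)
  expect_equal(st$values[["PI3K"]], 1L)
  # PI3K module off blocks DNA synthesis even with JAK on
  st2 <- compute_lss(m, lih_scenario(inputs = ligands0,
                                     perturbations = c(JAK = 1, PI3K = 0)))
  expect_equal(st2$values[["DNA_synthesis"]], 0L)
})

test_that("time scales open the negative feedback loop of the MAPK toy", {
  toy <- fixture("mapk_toy")
  full <- compute_lss(toy, lih_scenario(inputs = c(Stimulus = 1),
                                        time_scale_mode = "full"))
  expect_setequal(names(full$values)[is.na(full$values)],
                  c("Raf", "MEK", "ERK", "FBdummy"))
  expect_equal(full$values[["Ras"]], 1L)
  init <- compute_lss(toy, lih_scenario(inputs = c(Stimulus = 1),
                                        time_scale_mode = "initial"))
  expect_equal(init$determined_fraction, 1)
  expect_equal(init$values[["ERK"]], 1L)
  expect_equal(init$values[["FBdummy"]], 0L) # default with scale-2 arc removed
})

test_that("OR across arcs resolves to the maximum satisfied level", {
  m <- parse_model("C = A ; 2C = B ; 3C = D")
  st <- compute_lss(m, lih_scenario(inputs = c(A = 1, B = 1, D = 0)))
  expect_equal(st$values[["C"]], 2L)
  # a higher-level arc that is still open leaves the species undetermined
  st2 <- compute_lss(m, lih_scenario(inputs = c(A = 1, B = 1)))
  expect_true(is.na(st2$values[["C"]]))
  # all arcs false -> 0
  st3 <- compute_lss(m, lih_scenario(inputs = c(A = 0, B = 0, D = 0)))
  expect_equal(st3$values[["C"]], 0L)
})

test_that("ITT gates determine only the unanimous corners", {
  m <- parse_model("species:\nA1 1 normal -\nA2 1 normal -\nB 1 normal -\nrules:\nB ?= A1 · A2")
  on <- compute_lss(m, lih_scenario(inputs = c(A1 = 1, A2 = 1)))
  expect_equal(on$values[["B"]], 1L)
  off <- compute_lss(m, lih_scenario(inputs = c(A1 = 0, A2 = 0)))
  expect_equal(off$values[["B"]], 0L)
  mixed <- compute_lss(m, lih_scenario(inputs = c(A1 = 1, A2 = 0)))
  expect_true(is.na(mixed$values[["B"]]))
})

test_that("multivalued thresholds follow >=-semantics and negation is <", {
  m <- parse_model("3C = !A · 2B")
  expect_equal(compute_lss(m, lih_scenario(inputs = c(A = 0, B = 2)))$values[["C"]], 3L)
  expect_equal(compute_lss(m, lih_scenario(inputs = c(A = 1, B = 2)))$values[["C"]], 0L)
  expect_equal(compute_lss(m, lih_scenario(inputs = c(A = 0, B = 1)))$values[["C"]], 0L)
})

test_that("frozen species keep their value unless perturbed", {
  chain <- parse_model("B = A ; C = B", format = "boolean")
  sc <- lih_scenario(inputs = c(A = 1), frozen = c(B = 0))
  st <- compute_lss(chain, sc)
  expect_equal(st$values[["B"]], 0L)
  expect_equal(st$values[["C"]], 0L)
  # clamp conflicts with propagation are diagnosed, clamp wins
  expect_equal(st$conflicts$species, "B")
  st2 <- compute_lss(chain, scenario_perturb(sc, c(B = 1)))
  expect_equal(st2$values[["B"]], 1L)
  expect_equal(st2$values[["C"]], 1L)
})

test_that("species with no arcs fall back to clamp, then default, then undetermined", {
  m <- parse_model("species:\nA 1 normal 1\nB 1 normal -\nC 1 normal -\nrules:\nC = A")
  st <- compute_lss(m, lih_scenario())
  expect_equal(st$values[["A"]], 1L) # default
  expect_true(is.na(st$values[["B"]])) # no default
  expect_equal(st$values[["C"]], 1L)
  st2 <- compute_lss(m, lih_scenario(inputs = c(A = 0)))
  expect_equal(st2$values[["A"]], 0L) # clamp beats default
  expect_equal(st2$values[["C"]], 0L)
})

test_that("determined values agree with every synchronous fixed point (oracle)", {
  for (seed in 1:60) {
    n <- 4L + (seed %% 9L)
    m <- random_boolean_model(n, n_hyperarcs = 3L + (seed %% 13L), seed = seed)
    clamps <- random_clamps(m, seed = seed + 1000L)
    st <- compute_lss(m, lih_scenario(perturbations = clamps))
    fps <- oracle_fixed_points(m, clamps)
    det <- names(st$values)[!is.na(st$values)]
    for (s in det) {
      expect_true(all(fps[, s] == st$values[[s]]),
                  label = sprintf("seed %d species %s consistent", seed, s))
    }
  }
})

test_that("adding determined values as clamps is idempotent, clamping more is monotone", {
  for (seed in 1:25) {
    m <- random_boolean_model(4L + (seed %% 6L), 3L + (seed %% 10L), seed = seed)
    clamps <- random_clamps(m, seed = seed + 2000L)
    st <- compute_lss(m, lih_scenario(perturbations = clamps))
    det <- st$values[!is.na(st$values)]
    st2 <- compute_lss(m, lih_scenario(perturbations = det))
    expect_identical(st2$values, st$values)
    # monotonicity: determining one undetermined species never flips others
    und <- names(st$values)[is.na(st$values)]
    if (length(und) > 0L) {
      extra <- stats::setNames(1L, und[1])
      st3 <- compute_lss(m, lih_scenario(perturbations = c(clamps, extra)))
      for (s in names(det)) {
        if (!is.na(st3$values[[s]])) {
          expect_equal(st3$values[[s]], unname(det[[s]]),
                       label = sprintf("seed %d species %s stable", seed, s))
        }
      }
    }
  }
})

test_that("scenario validation rejects bad clamps", {
  m <- fixture("mapk_toy")
  expect_error(compute_lss(m, lih_scenario(inputs = c(Nothing = 1))),
               "unknown species")
  expect_error(compute_lss(m, lih_scenario(inputs = c(Stimulus = 2))),
               "out of range")
  expect_error(lih_scenario(inputs = c(A = 1), frozen = c(A = 0)),
               "at most one")
})

test_that("indeterminacy causes are classified and inherited", {
  # ITT with one undefined input: target blames both the gate and the input
  m <- parse_model("species:\nA1 1 normal -\nA2 1 normal -\nB 1 normal -\nrules:\nB ?= A1 · A2")
  sc <- lih_scenario(inputs = c(A1 = 1))
  st <- compute_lss(m, sc)
  rep <- explain_indeterminacy(m, sc, st)
  expect_setequal(rep$cause[rep$species == "A2"], "undefined-input")
  expect_setequal(rep$cause[rep$species == "B"], c("ITT", "undefined-input"))
  # feedback loop attribution in the MAPK toy at full scales
  toy <- fixture("mapk_toy")
  sc2 <- lih_scenario(inputs = c(Stimulus = 1), time_scale_mode = "full")
  st2 <- compute_lss(toy, sc2)
  rep2 <- explain_indeterminacy(toy, sc2, st2)
  expect_setequal(unique(rep2$species), c("Raf", "MEK", "ERK", "FBdummy"))
  expect_true(all(rep2$cause == "feedback-loop"))
  # fully determined state: empty report
  sc3 <- lih_scenario(inputs = c(Stimulus = 1), time_scale_mode = "initial")
  expect_equal(nrow(explain_indeterminacy(toy, sc3, compute_lss(toy, sc3))), 0L)
})

test_that("states and scenarios round-trip through their file formats", {
  toy <- fixture("mapk_toy")
  st <- compute_lss(toy, lih_scenario(inputs = c(Stimulus = 1),
                                      time_scale_mode = "full"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_state_tsv(st, p)
  back <- utils::read.delim(p)
  expect_equal(back$species, names(st$values))
  expect_equal(back$value, unname(st$values))
  ps <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Stimulus\t1\tinput", "Raf\t0\tperturb", "MEK\t1\tfrozen"), ps)
  sc <- read_scenario(ps)
  expect_equal(sc$inputs, c(Stimulus = 1L))
  expect_equal(sc$perturbations, c(Raf = 0L))
  expect_equal(sc$frozen, c(MEK = 1L))
})
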