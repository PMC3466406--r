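mis_keys <- function(mis) {
  sort(vapply(mis, function(m) lihnet:::format_clamps(m$clamps), ""))
}

test_that("chain model: upstream and direct activation are both size-1 sets", {
  chain <- parse_model("B = A ; C = B", format = "boolean")
  ctx <- lih_scenario(inputs = c(A = 0))
  mis <- compute_mis(chain, ctx, lih_goal("C", "=", 1), max_size = 1)
  expect_equal(mis_keys(mis), c("A=1", "B=1"))
  # freezing upstream species at their unstimulated values removes A=1
  frozen <- lih_scenario(frozen = c(A = 0, B = 0))
  mis2 <- compute_mis(chain, frozen, lih_goal("C", "=", 1), max_size = 1)
  expect_equal(mis_keys(mis2), "B=1")
  # the direct-mediator wrapper reproduces the constrained result
  med <- mis_direct_mediators(chain, ctx, lih_goal("C", "=", 1),
                              module_species = c("A", "B"), max_size = 1)
  expect_equal(mis_keys(med), "B=1")
  expect_equal(mis_direct_mediators(chain, ctx, lih_goal("C", "=", 1),
                                    module_species = character(0)), list())
})

test_that("pathway-module constraint finds the unique size-2 coactivation set", {
  m <- fixture("crosstalk_original")
  ctx <- lih_scenario(inputs = c(EGF = 0, HGF = 0, IL6 = 0, Insulin = 0,
                                 TNFa = 0, TGFb = 0),
                      time_scale_mode = "initial")
  med <- mis_direct_mediators(m, ctx, lih_goal("DNA_synthesis", "=", 1),
                              module_species = c("MAPK", "PI3K"))
  expect_length(med, 1L)
  expect_equal(med[[1]]$clamps, c(MAPK = 1L, PI3K = 1L))
  # exhaustive cross-check: no single module clamp suffices
  for (sp in c("MAPK", "PI3K")) {
    for (v in 0:1) {
      frozen_ctx <- lih_scenario(
        inputs = ctx$inputs,
        frozen = stats::setNames(c(0L, 0L), c("MAPK", "PI3K"))[
          setdiff(c("MAPK", "PI3K"), sp)],
        time_scale_mode = "initial")
      st <- compute_lss(m, scenario_perturb(frozen_ctx,
                                            stats::setNames(v, sp)))
      expect_false(identical(st$values[["DNA_synthesis"]], 1L))
    }
  }
})

test_that("a context already satisfying the goal yields the empty set", {
  chain <- parse_model("B = A ; C = B", format = "boolean")
  ctx <- lih_scenario(inputs = c(A = 1))
  mis <- compute_mis(chain, ctx, lih_goal("C", "=", 1), max_size = 2)
  expect_length(mis, 1L)
  expect_equal(mis[[1]]$size, 0L)
})

test_that("returned sets are irreducible: dropping any clamp breaks the goal", {
  for (seed in 1:12) {
    m <- random_boolean_model(4L + (seed %% 5L), 3L + (seed %% 9L),
                              seed = seed + 300L)
    goal_sp <- vapply(m$species, `[[`, "", "name")[1]
    goal <- lih_goal(goal_sp, "=", 1L)
    ctx <- lih_scenario()
    mis <- compute_mis(m, ctx, goal, max_size = 2)
    for (set in mis) {
      if (set$size < 2L) next
      for (drop in names(set$clamps)) {
        st <- compute_lss(m, scenario_perturb(ctx, set$clamps[
          setdiff(names(set$clamps), drop)]))
        expect_false(lihnet:::goal_satisfied(goal, st),
                     label = sprintf("seed %d: subset of %s fails", seed,
                                     lihnet:::format_clamps(set$clamps)))
      }
    }
  }
})

test_that("enumeration equals brute force with superset filtering (oracle)", {
  for (seed in 1:30) {
    m <- random_boolean_model(4L + (seed %% 7L), 3L + (seed %% 10L),
                              seed = seed + 700L)
    nm <- vapply(m$species, `[[`, "", "name")
    goal <- lih_goal(nm[1], "=", 1L)
    ctx <- lih_scenario()
    candidates <- sort(setdiff(nm, nm[1]))
    got <- mis_keys(compute_mis(m, ctx, goal, max_size = 2))
    want <- oracle_mis(m, ctx, goal, max_size = 2, candidates = candidates,
                       levels_for = function(s) 0:1)
    # when the empty context already satisfies the goal the engine reports
    # the empty set; the oracle enumerates nonempty supports only
    if (length(got) == 1L && got == "") {
      expect_true(lihnet:::goal_satisfied(goal, compute_lss(m, ctx)))
    } else {
      expect_equal(got, want, label = sprintf("model seed %d", seed + 700L))
    }
  }
})

test_that("multivalued candidates clamp to extremes by default, all levels on request", {
  m <- parse_model("species:\nA 3 normal -\nB 1 normal -\nrules:\nB = 2A")
  ctx <- lih_scenario()
  mis <- compute_mis(m, ctx, lih_goal("B", "=", 1), max_size = 1)
  expect_equal(mis_keys(mis), "A=3")
  mis_all <- compute_mis(m, ctx, lih_goal("B", "=", 1), max_size = 1,
                         candidate_levels = "all")
  expect_equal(mis_keys(mis_all), c("A=2", "A=3"))
})

test_that("an undetermined goal species never satisfies the goal", {
  # mutual positive loop: B undetermined without intervention
  m <- parse_model("B = A ; A = B", format = "boolean")
  ctx <- lih_scenario()
  expect_true(is.na(compute_lss(m, ctx)$values[["B"]]))
  mis <- compute_mis(m, ctx, lih_goal("B", "=", 1), max_size = 1)
  expect_equal(mis_keys(mis), "A=1")
})

test_that("guards and argument validation fire", {
  m <- random_boolean_model(10, 12, seed = 5)
  ctx <- lih_scenario()
  goal <- lih_goal("S01", "=", 1L)
  expect_error(compute_mis(m, ctx, goal, max_size = 3, max_space = 10),
               "max_space")
  expect_error(compute_mis(m, ctx, goal, max_size = 0), "max_size")
  expect_error(compute_mis(m, ctx, lih_goal("nope"), max_size = 1),
               "unknown species")
  expect_error(mis_direct_mediators(m, ctx, goal, "nope"), "not in model")
})

test_that("overlap annotation reproduces the mutation contingency counts", {
  fx <- fixture("table2_contingency")
  full <- annotate_mis_overlap(fx$mis_species, fx$mutated, fx$universe)
  expect_equal(unname(as.vector(t(unclass(full)))), c(6L, 6L, 2L, 6L))
  red <- annotate_mis_overlap(fx$mis_species, fx$mutated, fx$universe,
                              excluded = fx$excluded)
  expect_equal(unname(as.vector(t(unclass(red)))), c(6L, 1L, 2L, 5L))
  # empty mutated set: first row empty
  none <- annotate_mis_overlap(c("a"), character(0), c("a", "b"))
  expect_equal(unname(none["mutated", ]), c(0L, 0L))
  expect_equal(unname(none["not_mutated", ]), c(1L, 1L))
  # excluding an MIS member warns
  expect_warning(annotate_mis_overlap(c("a"), c("a", "b"), c("a", "b", "c"),
                                      excluded = "a"), "MIS members")
  expect_error(annotate_mis_overlap("z", "a", c("a", "b")), "subsets")
})

test_that("MIS reports serialize to TSV", {
  chain <- parse_model("B = A ; C = B", format = "boolean")
  goal <- lih_goal("C", "=", 1)
  mis <- compute_mis(chain, lih_scenario(inputs = c(A = 0)), goal,
                     max_size = 1)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_mis_tsv(mis, goal, p)
  df <- utils::read.delim(p)
  expect_equal(nrow(df), 2L)
  expect_true(all(df$goal == "C=1"))
})
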