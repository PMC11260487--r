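lib <- example_block_library()
rules <- default_taxonomy(lib)

occ_with <- function(overrides) {
  v <- setNames(rep(1, nrow(lib)), lib$name)
  v[names(overrides)] <- overrides
  v
}

test_that("state labels render and round-trip", {
  expect_identical(state_label(3L, "D"), "3D")
  s <- parse_state_label("3D")
  expect_identical(s$ptc_stage, 3L)
  expect_identical(s$h68_stage, "D")
  expect_error(parse_state_label("5X"))
})

test_that("state assignment follows the two-axis rules", {
  # everything folded -> latest state on both axes
  expect_identical(as.character(assign_state(occ_with(c()), rules)), "4D")

  # only core folded -> earliest state
  early <- setNames(rep(0, nrow(lib)), lib$name)
  early[lib$name[lib$category == "core"]] <- 1
  expect_identical(as.character(assign_state(early, rules)), "1A")

  # folded H73/H90-93, flexible H89, docked H68/69 -> 3D
  v <- occ_with(c(H73 = 0.9, H89 = 0.2, H90 = 0.9, H91 = 0.9, H92 = 0.9,
                  H93 = 0.9, H68 = 0.9, H69 = 0.9, H71 = 0.9))
  v[lib$name[lib$category == "CP"]] <- 0.9
  expect_identical(as.character(assign_state(v, rules)), "3D")

  # H73 lagging keeps the class in stage 2 even with H90-93 folded
  v2 <- occ_with(c(H73 = 0.3, H89 = 0.2))
  expect_identical(attr(assign_state(v2, rules), "ptc_stage"), 2L)

  # letter bins partition [0,1] into quartiles
  for (pair in list(c(0.1, "A"), c(0.3, "B"), c(0.6, "C"), c(0.9, "D"))) {
    v3 <- occ_with(setNames(rep(as.numeric(pair[1]), 3),
                            c("H68", "H69", "H71")))
    expect_identical(attr(assign_state(v3, rules), "h68_stage"), pair[2])
  }

  # missing category blocks raise a rule error naming the block
  expect_error(assign_state(occ_with(c())[-match("H73", lib$name)], rules),
               class = "ribostates_rule_error")
})

test_that("raising any category occupancy never lowers a stage", {
  set.seed(21)
  for (rep in 1:20) {
    v <- setNames(runif(nrow(lib)), lib$name)
    s0 <- assign_state(v, rules)
    bump <- sample(names(rules$block_categories), 1)
    v2 <- v
    v2[bump] <- min(1, v[bump] + runif(1, 0, 1 - v[bump]))
    s1 <- assign_state(v2, rules)
    expect_gte(attr(s1, "ptc_stage"), attr(s0, "ptc_stage"))
    expect_gte(match(attr(s1, "h68_stage"), LETTERS),
               match(attr(s0, "h68_stage"), LETTERS))
  }
})

test_that("state fractions are particle-weighted and sum to one", {
  mk_classes <- function(volumes, classes) structure(list(
    classes = tibble::tibble(volume = volumes, class = classes),
    n_classes = length(unique(classes)), tree = NULL,
    linkage = "ward.D2", metric = "euclidean", gap_ratio = NA_real_),
    class = "class_assignment")

  one <- mk_classes("v1", 1L)
  st <- tibble::tibble(class = 1L, state = "2C")
  sf <- state_fractions(one, st, c(v1 = 50), dataset = "x", rules = rules)
  expect_equal(sf$fraction, 1)

  two <- mk_classes(c("v1", "v2"), c(1L, 2L))
  st2 <- tibble::tibble(class = 1:2, state = c("2C", "3D"))
  sf2 <- state_fractions(two, st2, c(v1 = 25, v2 = 75), rules = rules)
  expect_equal(sf2$fraction[sf2$state == "2C"], 0.25)
  expect_equal(sf2$fraction[sf2$state == "3D"], 0.75)
  expect_equal(sum(sf2$fraction), 1, tolerance = 1e-9)

  # volumes of the same class pool their particles
  pooled <- mk_classes(c("v1", "v2", "v3"), c(1L, 1L, 2L))
  sf3 <- state_fractions(pooled, st2, c(v1 = 10, v2 = 30, v3 = 60),
                         rules = rules)
  expect_equal(sf3$fraction[sf3$state == "2C"], 0.4)

  expect_error(state_fractions(two, st2, c(v1 = 25)),
               class = "ribostates_consistency_error")
})

test_that("distribution comparisons conserve probability", {
  mk_summary <- function(states, fracs, n = 1000) {
    structure(tibble::tibble(
      state = states, ptc_stage = as.integer(substr(states, 1, 1)),
      h68_stage = substr(states, 2, 2),
      particles = fracs * n, fraction = fracs),
      class = c("state_summary", class(tibble::tibble())),
      dataset = "s", taxonomy = rules)
  }
  a <- mk_summary(c("2C", "3D"), c(0.56, 0.44))
  b <- mk_summary(c("2C", "3D", "4D"), c(0.27, 0.52, 0.21))
  cmp <- compare_state_distributions(a, b)
  expect_equal(cmp$delta[cmp$state == "2C"], -0.29)
  expect_equal(sum(cmp$delta), 0, tolerance = 1e-9)
  expect_equal(cmp$fraction_a[cmp$state == "4D"], 0)

  same <- compare_state_distributions(a, a)
  expect_true(all(same$delta == 0))

  other_rules <- default_taxonomy(lib, theta = 0.6)
  b2 <- mk_summary(c("2C", "3D"), c(0.5, 0.5))
  attr(b2, "taxonomy") <- other_rules
  expect_error(compare_state_distributions(a, b2),
               class = "ribostates_comparison_error")
})

test_that("ptc stage marginals aggregate letters", {
  mk <- function(states, fracs) structure(tibble::tibble(
    state = states, ptc_stage = as.integer(substr(states, 1, 1)),
    h68_stage = substr(states, 2, 2), particles = fracs * 100,
    fraction = fracs),
    class = c("state_summary", class(tibble::tibble())),
    dataset = "s", taxonomy = rules)
  m <- ptc_stage_marginal(mk(c("2A", "2C", "3D"), c(0.3, 0.26, 0.44)))
  expect_equal(m$fraction[m$ptc_stage == 2], 0.56)
  expect_equal(sum(m$fraction), 1)
})
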