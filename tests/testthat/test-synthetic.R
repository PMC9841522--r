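# Generator contracts: determinism, planted-truth recovery, label sampling.

test_that("gen_molecules meets violation quotas exactly and repeats", {
  spec <- deck_spec(n_compounds = 100, seed = 21,
                    violation_quotas = c(aromatic_rings = 7, hbd = 3,
                                         `alert:aldehyde` = 2))
  g1 <- gen_molecules(spec)
  expect_equal(nrow(g1$deck), 100)
  expect_equal(sum(g1$truth$role == "violator"), 12)

  v <- stage1_filter(g1$deck)
  # filter recovers exactly the planted labels
  expect_equal(sort(v$compound_id[!v$passed]),
               sort(g1$truth$id[g1$truth$role == "violator"]))
  # per-rule recovery: each planted violator fails with its planted rule
  # (property reasons carry the threshold, e.g. "aromatic_rings>4")
  for (i in which(g1$truth$role == "violator")) {
    rs <- v$reasons[[which(v$compound_id == g1$truth$id[i])]]
    expect_true(any(startsWith(rs, g1$truth$violated_rule[i])))
  }

  # byte-identical regeneration from the same spec
  g2 <- gen_molecules(spec)
  expect_identical(as.data.frame(g1$deck), as.data.frame(g2$deck))
  expect_identical(g1$truth, g2$truth)

  # all-zero quotas -> everything passes
  g0 <- gen_molecules(deck_spec(n_compounds = 40, seed = 3))
  expect_true(all(stage1_filter(g0$deck)$passed))
})

test_that("infeasible quota combinations raise generation errors", {
  expect_error(deck_spec(n_compounds = 5,
                         violation_quotas = c(hbd = 4), stage2_quota = 3),
               "infeasible")
  expect_error(deck_spec(violation_quotas = c(bogus = 1)), "quota names")
})

test_that("gen_labels hits the requested rate in expectation", {
  expect_true(all(!gen_labels(500, 0, seed = 1)$active))
  expect_true(all(gen_labels(500, 1, seed = 1)$active))
  # 200 seeds x n = 960 at p = 0.005: mean within 3 binomial SEs
  p <- 0.005; n <- 960; reps <- 200
  rates <- vapply(seq_len(reps), function(s)
    mean(gen_labels(n, p, seed = s)$active), numeric(1))
  se <- sqrt(p * (1 - p) / (n * reps))
  expect_lt(abs(mean(rates) - p), 3 * se)
})

test_that("ranked-list generator plants exact overlap structure", {
  ids <- sprintf("x%04d", 1:800)
  gl <- gen_ranked_lists(ids, top_n = 200, pool_size = 411, seed = 5,
                         filler_ids = sprintf("f%03d", 1:50))
  expect_equal(length(gl$lists), 3)
  # each engine has exactly top_n planted members ahead of fillers
  for (rl in gl$lists) {
    expect_gte(nrow(rl), 200)
    expect_true(all(grepl("^x", top_n(rl, 200)$id)))
  }
  p <- pool_ranked_lists(gl$lists, 200)
  expect_equal(nrow(p), 411)
  # direction handling: third engine is lower-better yet contributes
  expect_equal(attr(gl$lists[[3]], "direction"), "lower")
  expect_true(any(p$engines == "glide_sp" | grepl("glide_sp", p$engines)))
  # infeasible unions rejected
  expect_error(gen_ranked_lists(ids, 200, 100, seed = 1), "pool_size")
  expect_error(gen_ranked_lists(ids[1:100], 200, 650, seed = 1),
               "pool_size|member ids")
})

test_that("pose generator output is reproducible for a fixed seed", {
  deck <- pharm_test_deck(6)
  model <- example_pharmacophore()
  plan <- setNames(rep(2L, 6), deck$id)
  p1 <- gen_poses(deck, model, plan, seed = 31)
  p2 <- gen_poses(deck, model, plan, seed = 31)
  expect_identical(lapply(p1, `[[`, "coords"), lapply(p2, `[[`, "coords"))
  p3 <- gen_poses(deck, model, plan, seed = 32)
  expect_false(identical(lapply(p1, `[[`, "coords"),
                         lapply(p3, `[[`, "coords")))
})

test_that("overlapping model spheres are rejected by the pose generator", {
  bad <- pharmacophore_model(
    data.frame(kind = c("acceptor_site", "acceptor_site"),
               x = c(0, 1), y = 0, z = 0, radius = 1.4),
    min_required = 1)
  deck <- pharm_test_deck(1)
  expect_error(gen_poses(deck, bad, setNames(1L, deck$id)), "overlap")
})
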