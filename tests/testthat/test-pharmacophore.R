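# Atom typing, feature matching, exclusion vetoes, best-pose logic and
# rigid-motion invariance.

simple_model <- function(min_required = 1, exclusions = NULL) {
  pharmacophore_model(
    features = data.frame(kind = c("acceptor_site", "donor_site"),
                          x = c(0, 10), y = 0, z = 0, radius = 1.4),
    min_required = min_required, exclusions = exclusions)
}

test_that("atom typing follows the donor/acceptor rules", {
  deck <- compound_deck(c("methanol", "benzene", "cpd1"),
                        c("CO", "c1ccccc1",
                          "O=S(=O)(C)c1ccc(Nc2ncnc3sccc23)cc1"))
  sdf <- deck_sdf(deck)
  mk <- function(i) {
    obj <- sdf[[i]]
    n <- nrow(ChemmineR::atomblock(obj))
    pose(deck$id[i], sub("_.*", "", rownames(ChemmineR::atomblock(obj))),
         matrix(0, n, 3), sdf = obj)
  }
  # hydroxyl O (one implicit H, lone pairs): both donor and acceptor
  expect_equal(type_ligand_atoms(mk(1)), c("neither", "both"))
  # benzene carbons: all neither
  expect_true(all(type_ligand_atoms(mk(2)) == "neither"))
  # sulfone oxygens acceptors; anilino NH donor; ring N acceptors
  p3 <- mk(3)
  typ <- type_ligand_atoms(p3)
  ox <- typ[p3$elements == "O"]
  expect_true(all(ox %in% c("acceptor")))
  nn <- typ[p3$elements == "N"]
  expect_true(any(nn %in% c("donor", "both")))   # anilino N-H donates
  expect_true(sum(nn == "acceptor") >= 2)  # pyrimidine nitrogens
  expect_true(all(typ[p3$elements == "C"] == "neither"))
})

test_that("feature matching honours radii, min_required and exclusions", {
  deck <- compound_deck("w", "CO")   # methanol: O is donor+acceptor
  obj <- deck_sdf(deck)[[1]]
  # carbon parked far away; hydroxyl O probes the first (acceptor) sphere
  at <- function(x) pose("w", c("C", "O"),
                         rbind(c(50, 50, 50), c(x, 0, 0)), sdf = obj)
  m <- match_pose(at(0), simple_model(1))
  expect_true(m$passed)
  expect_equal(m$matched_features, 1L)

  # exactly at the boundary counts as inside
  expect_true(match_pose(at(1.4), simple_model(1))$passed)
  expect_false(match_pose(at(1.4 + 1e-9), simple_model(1))$passed)

  # 1 of 2 matched with min_required 2 fails
  expect_false(match_pose(at(0), simple_model(2))$passed)

  # matching but inside an exclusion sphere fails with the hit recorded
  excl <- data.frame(x = 1.0, y = 0, z = 0, radius = 1.4)
  mex <- match_pose(at(0), simple_model(1, exclusions = excl))
  expect_false(mex$passed)
  expect_equal(nrow(mex$exclusion_hits), 1)
  expect_equal(mex$exclusion_hits$sphere, 1L)
})

test_that("screen_poses passes a compound when any pose passes", {
  deck <- compound_deck("w", "CO")
  obj <- deck_sdf(deck)[[1]]
  good <- pose("w", c("C", "O"), rbind(c(50, 50, 50), c(0, 0, 0)),
               sdf = obj)
  bad <- pose("w", c("C", "O"), rbind(c(50, 50, 50), c(60, 60, 60)),
              sdf = obj)
  scr <- screen_poses(list(bad, good), simple_model(1))
  expect_equal(scr$pass_ids, "w")
  expect_equal(scr$results$best, c(FALSE, TRUE))

  scr2 <- screen_poses(list(bad, bad), simple_model(1))
  expect_equal(length(scr2$pass_ids), 0)
  expect_equal(nrow(scr2$results), 2)   # failing poses still reported
})

test_that("planted match plans are recovered exactly over 200 poses", {
  n <- 200
  deck <- pharm_test_deck(n)
  model <- example_pharmacophore()
  plan <- setNames(rep(0:3, length.out = n), deck$id)
  excl_viol <- deck$id[seq(5, n, by = 20)]   # planted exclusion hits
  poses <- gen_poses(deck, model, plan, exclusion_violators = excl_viol,
                     seed = 99)
  scr <- screen_poses(poses, model)
  want_pass <- plan >= model$min_required & !(names(plan) %in% excl_viol)
  expect_setequal(scr$pass_ids, names(plan)[want_pass])
  # matched feature counts equal the plan where no exclusion was planted
  ok <- !(scr$results$compound_id %in% excl_viol)
  expect_equal(scr$results$n_matched[ok],
               unname(plan[scr$results$compound_id[ok]]))
})

test_that("matching is invariant under 20 joint rigid motions", {
  n <- 12
  deck <- pharm_test_deck(n)
  model <- example_pharmacophore()
  plan <- setNames(rep(0:3, length.out = n), deck$id)
  poses <- gen_poses(deck, model, plan, seed = 7)
  base <- screen_poses(poses, model)
  set.seed(123)
  for (rep in 1:20) {
    rot <- random_rotation()
    tr <- rnorm(3, sd = 20)
    poses_t <- lapply(poses, function(p) {
      pose(p$compound_id, p$elements,
           transform_points(p$coords, rot, tr), p$scores, p$sdf)
    })
    model_t <- transform_model(model, rot, tr)
    got <- screen_poses(poses_t, model_t)
    expect_equal(got$pass_ids, base$pass_ids)
    expect_equal(got$results$n_matched, base$results$n_matched)
    expect_equal(got$results$match_distance, base$results$match_distance,
                 tolerance = 1e-9)
  }
})

test_that("pharmacophore JSON schema round-trips", {
  model <- example_pharmacophore()
  tf <- tempfile(fileext = ".json")
  write_pharmacophore(model, tf)
  back <- read_pharmacophore(tf)
  expect_equal(back$min_required, model$min_required)
  expect_equal(back$features$x, model$features$x)
  expect_equal(nrow(back$exclusions), nrow(model$exclusions))
})

test_that("degenerate inputs raise typed errors", {
  expect_error(pharmacophore_model(
    data.frame(kind = "acceptor_site", x = 0, y = 0, z = 0, radius = 0),
    1), "radius")
  expect_error(pharmacophore_model(
    data.frame(kind = "acceptor_site", x = 0, y = 0, z = 0), 2),
    "min_required")
  p <- pose("w", "O", matrix(0, 1, 3), sdf = NULL)
  expect_error(type_ligand_atoms(p), "connectivity")
})
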