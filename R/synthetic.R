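# Synthetic deck, pose, ranked-list and label generators with planted ground
# truth, so every triage stage is testable without a commercial library or
# docking engines. All generators are pure functions of (spec, seed): a named
# random stream is derived per sub-generator from the single integer seed.
#
# Clean molecules come from a fragment grammar (heteroaryl cores, N-linkers,
# ring decorations, sulfone/sulfonamide-style caps echoing kinase-inhibitor
# chemotypes), which guarantees chemical validity and lets property
# violations be planted by construction instead of rejection sampling.

# ---- fragment grammar -------------------------------------------------------

.grammar <- list(
  # %s is the exocyclic substituent position (ring digits 1-2 reserved)
  cores = c(
    "c1cc2c(%s)ncnc2s1",     # thieno[2,3-d]pyrimidin-4-yl
    "Cn1ccc2c(%s)ncnc21",    # 7-methyl-pyrrolo[2,3-d]pyrimidin-4-yl
    "c1ccc2c(%s)ncnc2c1",    # quinazolin-4-yl
    "c1ccc2c(%s)ncnc2n1",    # pyrido[2,3-d]pyrimidin-4-yl
    "c1cc2c(%s)ncnc2o1",     # furo[2,3-d]pyrimidin-4-yl
    "c1ccc(%s)nc1",          # pyridin-2-yl
    "c1nc(%s)ccn1",          # pyrimidin-4-yl
    "Cn1ncc2c(%s)ncnc21"),   # 1-methyl-pyrazolo[3,4-d]pyrimidin-4-yl
  linkers = c("N", "NC"),    # anilino or N-benzyl
  # ring decoration ortho to the cap ("" = unsubstituted)
  decorations = c("", "C", "F", "OC"),
  caps = c(
    "S(C)(=O)=O", "S(=O)(=O)N(C)C", "S(=O)(=O)N4CCCC4", "C(N)=O",
    "C(=O)N(C)C", "C#N", "OC", "C(=O)NC", "F", "OCC", "C(C)=O",
    "N4CCOCC4", "C(=O)N4CCCC4", "S(C)=O", "C(=O)OC"))

#' SMILES of the synthetic fragment grammar
#'
#' Enumerates core x linker x decoration x cap combinations
#' (8 x 2 x 4 x 15 = 960 distinct clean structures) in a fixed order.
#'
#' @param n how many structures (recycled cyclically beyond 960)
#' @param offset 0-based starting index into the enumeration
#' @return character vector of SMILES
#' @export
grammar_smiles <- function(n, offset = 0) {
  g <- .grammar
  combos <- expand.grid(cap = seq_along(g$caps),
                        deco = seq_along(g$decorations),
                        linker = seq_along(g$linkers),
                        core = seq_along(g$cores))
  total <- nrow(combos)
  ix <- ((offset + seq_len(n) - 1L) %% total) + 1L
  vapply(ix, function(i) {
    row <- combos[i, ]
    deco <- g$decorations[row$deco]
    phenyl <- if (nzchar(deco))
      sprintf("c3ccc(%s)c(%s)c3", g$caps[row$cap], deco)
    else sprintf("c3ccc(%s)cc3", g$caps[row$cap])
    sprintf(g$cores[row$core], paste0(g$linkers[row$linker], phenyl))
  }, character(1))
}

# one planted violator per stage-1 rule; each fires exactly its own rule
.violators <- c(
  aromatic_rings  = "c1ccc(-c2ccc(-c3ccc(-c4ccc(-c5ncccn5)nc4)nc3)nc2)nc1",
  rotatable_bonds = "COCCOCCOCCOCCOCCOC",
  hbd             = "NCC(O)C(O)C(O)CO",
  clogp           = "CCCCCCCCCCCCC",
  tpsa            = "O=[N+]([O-])c1cc([N+](=O)[O-])cc([N+](=O)[O-])c1")
# alert-firing molecules for planted substructure failures
.alert_violators <- c(
  aldehyde    = "O=Cc1ccccc1",
  acyl_halide = "CC(=O)Cl",
  michael_acceptor = "C=CC(=O)c1ccccc1")

#' Deck generation specification
#'
#' Captures everything [gen_molecules()] needs: the deck size, the seed, and
#' the planted counts of stage-1 violations per rule.
#'
#' @param n_compounds total deck size
#' @param seed integer master seed
#' @param violation_quotas named integer vector; names are property rule ids
#'   (`aromatic_rings`, `rotatable_bonds`, `hbd`, `clogp`, `tpsa`) or alert
#'   ids (`alert:aldehyde`, `alert:acyl_halide`, `alert:michael_acceptor`)
#' @param hit_rate Bernoulli activity rate for [gen_labels()]
#' @param top_n per-engine prefix size for [gen_ranked_lists()]
#' @param pool_size target union size for [gen_ranked_lists()]
#' @param stage2_quota planted count of (logd > 5 and psa > 100) compounds
#' @return object of class `deck_spec`
#' @export
deck_spec <- function(n_compounds = 400, seed = 17,
                      violation_quotas = integer(0), hit_rate = 0.005,
                      top_n = 100, pool_size = NULL, stage2_quota = 0) {
  quotas <- violation_quotas
  known <- c(names(.violators), paste0("alert:", names(.alert_violators)))
  if (length(quotas)) {
    if (is.null(names(quotas)) || !all(names(quotas) %in% known))
      stop("violation quota names must be among: ",
           paste(known, collapse = ", "))
    if (any(quotas < 0)) stop("negative violation quota")
  }
  if (sum(quotas) + stage2_quota > n_compounds)
    stop("infeasible quotas: exceed n_compounds")
  structure(list(n_compounds = as.integer(n_compounds),
                 seed = as.integer(seed),
                 violation_quotas = quotas,
                 hit_rate = hit_rate,
                 top_n = as.integer(top_n),
                 pool_size = pool_size,
                 stage2_quota = as.integer(stage2_quota)),
            class = "deck_spec")
}

#' Generate a synthetic deck with planted stage-1 violations
#'
#' Clean compounds are drawn from the fragment grammar; each requested
#' violation quota is met by planting molecules that fire exactly that rule
#' (verified in the package tests by running the filter on its own output).
#' Row order is shuffled deterministically from the seed.
#'
#' @param spec a [deck_spec()]
#' @return list with `deck` (a `compound_deck`) and `truth` (data.frame
#'   `id`, `role` = clean/violator, `violated_rule` = rule id or NA)
#' @export
gen_molecules <- function(spec) {
  stopifnot(inherits(spec, "deck_spec"))
  quotas <- spec$violation_quotas
  n_viol <- sum(quotas)
  n_clean <- spec$n_compounds - n_viol

  viol_smiles <- character(0)
  viol_rule <- character(0)
  for (rule in names(quotas)) {
    if (quotas[[rule]] == 0) next
    smi <- if (startsWith(rule, "alert:"))
      .alert_violators[[sub("^alert:", "", rule)]] else .violators[[rule]]
    viol_smiles <- c(viol_smiles, rep(smi, quotas[[rule]]))
    viol_rule <- c(viol_rule, rep(rule, quotas[[rule]]))
  }
  smiles <- c(grammar_smiles(n_clean), viol_smiles)
  role <- c(rep("clean", n_clean), rep("violator", length(viol_smiles)))
  rule <- c(rep(NA_character_, n_clean), viol_rule)

  perm <- with_stream(spec$seed, "gen_molecules",
                      sample.int(spec$n_compounds))
  ids <- sprintf("CMP%05d", seq_len(spec$n_compounds))
  deck <- compound_deck(ids, smiles[perm], source = "synthetic")
  truth <- data.frame(id = ids, role = role[perm],
                      violated_rule = rule[perm])
  list(deck = deck, truth = truth)
}

#' Generate binary activity labels at a fixed hit rate
#'
#' @param ids compound ids (or an integer count)
#' @param hit_rate Bernoulli success probability in \[0, 1\]
#' @param seed integer seed
#' @return data.frame `id`, `active` (logical)
#' @export
gen_labels <- function(ids, hit_rate, seed = 17) {
  stopifnot(hit_rate >= 0, hit_rate <= 1)
  if (is.numeric(ids) && length(ids) == 1) ids <- sprintf("CMP%05d", seq_len(ids))
  act <- with_stream(seed, "gen_labels",
                     stats::rbinom(length(ids), 1, hit_rate) == 1)
  data.frame(id = as.character(ids), active = act)
}

# ---- ranked lists with controlled overlap -----------------------------------

#' Generate engine ranked lists with a controlled top-N union
#'
#' Builds three ranked lists whose top-`top_n` prefixes union to exactly
#' `pool_size` members: with `N = top_n` and `P = pool_size`, `a` members are
#' shared by all three engines, `b` by exactly two and `c` by exactly one,
#' where `3a + 2b + c = 3N` and `a + b + c = P` (a generation error is
#' raised when no non-negative solution exists or the deck is too small).
#' One engine is lower-better to exercise direction handling. Compounds in
#' `filler_ids` are appended below each cutoff.
#'
#' @param member_ids candidate ids for the pooled union (length >= pool_size)
#' @param top_n per-engine prefix size
#' @param pool_size exact union size to plant
#' @param seed integer seed
#' @param filler_ids optional ids ranked below the top-N in every engine
#' @param engines three engine names
#' @return list with `lists` (three `ranked_list`s), `truth` (data.frame
#'   `id`, `n_engines`) for the planted union
#' @export
gen_ranked_lists <- function(member_ids, top_n, pool_size, seed = 17,
                             filler_ids = character(0),
                             engines = c("chemscore", "asp", "glide_sp")) {
  N <- as.integer(top_n); P <- as.integer(pool_size)
  stopifnot(length(engines) == 3)
  if (P < N || P > 3 * N)
    stop("pool_size must lie in [top_n, 3 top_n]")
  if (length(member_ids) < P)
    stop("need at least pool_size member ids, got ", length(member_ids))
  rem <- 3L * N - P        # = 2a + b
  a <- rem %/% 2L
  b <- rem - 2L * a        # 0 or 1
  cc <- P - a - b
  if (a > P || cc < 0) stop("infeasible overlap plan for these sizes")

  members <- with_stream(seed, "gen_ranked_lists_members",
                         sample(member_ids, P))
  cls <- rep(c(3L, 2L, 1L), c(a, b, cc))
  # balanced engine assignment: pairs and singles rotate over engines
  pair_sets <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  engine_of <- vector("list", P)
  pair_i <- 0L; single_i <- 0L
  single_load <- integer(3)
  pair_load <- integer(3)
  for (i in seq_len(P)) {
    if (cls[i] == 3L) {
      engine_of[[i]] <- 1:3
    } else if (cls[i] == 2L) {
      ps <- pair_sets[[(pair_i %% 3L) + 1L]]
      pair_i <- pair_i + 1L
      engine_of[[i]] <- ps
      pair_load[ps] <- pair_load[ps] + 1L
    }
  }
  # singles fill each engine to exactly N
  need <- N - a - pair_load
  if (any(need < 0) || sum(need) != cc)
    stop("infeasible overlap plan: engine quotas do not balance")
  singles <- which(cls == 1L)
  eng_for_single <- rep.int(1:3, need)
  for (j in seq_along(singles)) engine_of[[singles[j]]] <- eng_for_single[j]

  # intended global order: the sampled member order itself
  lists <- lapply(1:3, function(e) {
    mem <- members[vapply(engine_of, function(z) e %in% z, logical(1))]
    kf <- min(length(filler_ids), 2L * N)
    fill <- if (kf > 0) filler_ids[seq_len(kf)] else character(0)
    ids <- c(mem, fill)
    # strictly monotone scores in intended order; engine 3 is lower-better
    sc <- seq_along(ids)
    if (e < 3) ranked_list(engines[e], ids, 1e4 - sc, "higher")
    else ranked_list(engines[e], ids, sc * 0.25, "lower")
  })
  truth <- data.frame(id = members,
                      n_engines = vapply(engine_of, length, integer(1)))
  list(lists = lists, truth = truth)
}

# ---- poses with planted pharmacophore matches -------------------------------

#' Example 4-feature pharmacophore model
#'
#' Two acceptor and two donor projection spheres (radius 1.4 A, 2-of-4
#' required) with two exclusion spheres. Centers are synthetic and chosen
#' to be well separated (>= 3 radii), mimicking the geometry class of an
#' ATP/AMP-site model; they are not protein-derived coordinates.
#'
#' @return a `pharmacophore_model`
#' @export
example_pharmacophore <- function() {
  pharmacophore_model(
    features = data.frame(
      kind = c("acceptor_site", "acceptor_site", "donor_site", "donor_site"),
      x = c(0, 7, 0, 7), y = c(0, 0, 7, 7), z = c(0, 0, 0, 0),
      radius = 1.4),
    min_required = 2L,
    exclusions = data.frame(x = c(3.5, -5), y = c(3.5, -5), z = c(4, 0),
                            radius = 1.4))
}

#' Generate docked-style poses with planted pharmacophore match counts
#'
#' For each compound, `plan[id]` polar atoms of the complementary type are
#' placed inside distinct feature spheres at distance `radius * u`,
#' `u ~ U(0, 0.9)`, from the center; every other atom is placed on a remote
#' lattice at least two radii away from every sphere. Compounds listed in
#' `exclusion_violators` additionally get one atom planted inside the first
#' exclusion sphere, so they fail regardless of matches.
#'
#' @param deck a `compound_deck`
#' @param model a `pharmacophore_model`
#' @param plan named integer vector id -> number of features to match
#'   (0 to number of features); ids absent from `plan` get 0
#' @param exclusion_violators character ids planted to hit an exclusion
#' @param seed integer seed
#' @return list of `pose` objects, one per deck compound (deck order)
#' @export
gen_poses <- function(deck, model, plan = integer(0),
                      exclusion_violators = character(0), seed = 17) {
  stopifnot(inherits(deck, "compound_deck"),
            inherits(model, "pharmacophore_model"))
  ft <- model$features
  centers <- rbind(as.matrix(ft[, c("x", "y", "z")]),
                   as.matrix(model$exclusions[, c("x", "y", "z")]))
  radii <- c(ft$radius, model$exclusions$radius)
  if (nrow(centers) > 1) {
    cd <- as.matrix(stats::dist(centers))
    diag(cd) <- Inf
    need <- outer(radii, radii, `+`)
    if (any(cd < need))
      stop("model spheres overlap; planted placement would be ambiguous")
  }
  if (length(exclusion_violators) && nrow(model$exclusions) == 0)
    stop("cannot plant exclusion violations: model has no exclusion spheres")
  # remote lattice base: far outside every sphere
  base <- apply(centers, 2, max) + 60
  sdf <- deck_sdf(deck)
  with_stream(seed, "gen_poses", {
    lapply(seq_len(nrow(deck)), function(i) {
      obj <- sdf[[i]]
      el <- sdf_elements(obj)
      n <- length(el)
      p0 <- pose(deck$id[i], el, matrix(0, n, 3), sdf = obj)
      typ <- type_ligand_atoms(p0)
      want <- plan[deck$id[i]]
      want <- if (!length(want) || is.na(want)) 0L else as.integer(want)
      if (want > nrow(ft))
        stop("plan for ", deck$id[i], " exceeds feature count")
      coords <- matrix(0, n, 3)
      # remote lattice, 2.5 A spacing, guaranteed outside all spheres
      coords[, 1] <- base[1] + 2.5 * seq_len(n)
      coords[, 2] <- base[2]
      coords[, 3] <- base[3]
      used <- logical(n)
      placed <- 0L
      for (f in seq_len(nrow(ft))) {
        if (placed >= want) break
        compat <- which(!used &
                          (typ == feature_complement[[ft$kind[f]]] |
                             typ == "both"))
        if (!length(compat))
          stop("compound ", deck$id[i], " lacks a free ",
               feature_complement[[ft$kind[f]]],
               " atom for feature ", f, " (infeasible plan)")
        a <- compat[1]
        u <- stats::runif(1, 0, 0.9)
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        coords[a, ] <- c(ft$x[f], ft$y[f], ft$z[f]) + ft$radius[f] * u * dir
        used[a] <- TRUE
        placed <- placed + 1L
      }
      if (placed < want)
        stop("compound ", deck$id[i], ": only ", placed, " of ", want,
             " features plantable")
      if (deck$id[i] %in% exclusion_violators) {
        free <- which(!used)
        if (!length(free)) stop("no free atom for exclusion plant on ",
                                deck$id[i])
        ex <- model$exclusions[1, ]
        u <- stats::runif(1, 0, 0.9)
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        coords[free[1], ] <- c(ex$x, ex$y, ex$z) + ex$radius * u * dir
      }
      pose(deck$id[i], el, coords, sdf = obj)
    })
  })
}
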