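# A complete planted triage scenario mirroring the published funnel
# arithmetic: three top-1000 lists pooling to 2057 unique compounds, a
# stage-2 property cut leaving 1743, K-medoids into 960 clusters and a
# purchase set of 960 after trimming 21 over-quota additions from the
# top 50.
#
# The stage-2 survivors are laid out as 960 structure families (shared
# SMILES within a family, so within-family fingerprint distance is 0 and
# between-family distance is positive): 21 pairs whose both members sit in
# the consensus top 50 (the worse member is then not its cluster's best and
# must be force-added), 762 pairs whose worse member ranks below the top 50,
# and 177 singletons. That makes the 960-cluster PAM partition the provable
# cost-0 optimum and the trim count exactly reproducible.

#' Generate the planted funnel scenario
#'
#' All sub-generators derive their streams from `seed`; identical seeds give
#' identical scenarios. Stage-2 descriptors (`logd`, `psa`) are planted
#' columns in `truth`, mirroring a workflow where the pool's logD/PSA come
#' from an external calculator.
#'
#' @param seed integer master seed
#' @param top_n per-engine prefix size (default 1000)
#' @param pool_size planted consensus-pool size (default 2057)
#' @param n_survivors planted stage-2 survivor count (default 1743)
#' @param n_clusters K for the diversity clustering (default 960)
#' @param target purchase-set size (default 960)
#' @param top_m force-included top block (default 50)
#' @param planted_nonbest how many top-`top_m` compounds are planted as
#'   non-representatives of their cluster (default 21, so `target +
#'   planted_nonbest` pre-trim)
#' @param n_fillers extra clean compounds ranked below every cutoff
#' @param stage1_quotas named planted stage-1 violation counts (see
#'   [deck_spec()]); these compounds never reach the docking lists
#' @return object of class `funnel_scenario`: list with `deck`, `lists`,
#'   `model`, `pharm_plan`, `truth` (per-compound roles, planted logd/psa,
#'   family, activity label), `params`
#' @export
gen_funnel_scenario <- function(seed = 17, top_n = 1000, pool_size = 2057,
                                n_survivors = 1743, n_clusters = 960,
                                target = 960, top_m = 50,
                                planted_nonbest = 21, n_fillers = 150,
                                stage1_quotas = c(aromatic_rings = 4,
                                                  rotatable_bonds = 4,
                                                  hbd = 4, clogp = 4,
                                                  tpsa = 4,
                                                  `alert:aldehyde` = 4)) {
  stage2_quota <- pool_size - n_survivors
  stopifnot(stage2_quota >= 0, planted_nonbest <= top_m %/% 2,
            n_survivors >= top_m)
  n_pairs_total <- n_survivors - n_clusters
  n_pairs_rest <- n_pairs_total - planted_nonbest
  if (n_pairs_rest < 0 || n_clusters > n_survivors)
    stop("infeasible family plan: need n_clusters <= n_survivors <= 2*n_clusters")
  n_viol <- sum(stage1_quotas)
  n_total <- pool_size + n_fillers + n_viol

  pool_ids <- sprintf("POOL%04d", seq_len(pool_size))
  fill_ids <- sprintf("FILL%04d", seq_len(n_fillers))
  viol_ids <- sprintf("VIOL%04d", seq_len(n_viol))

  gl <- gen_ranked_lists(pool_ids, top_n, pool_size, seed = seed,
                         filler_ids = fill_ids)
  pool <- pool_ranked_lists(gl$lists, top_n)
  ranked <- global_rank(pool)

  victims <- with_stream(seed, "stage2_victims",
                         sort(sample(pool_ids, stage2_quota)))
  survivors <- ranked[!ranked %in% victims]
  stopifnot(length(survivors) == n_survivors)

  # family layout over survivor ranks (1 = best)
  family <- integer(n_survivors)
  fam <- 0L
  single_head <- top_m - 2L * planted_nonbest     # best-block singletons
  for (i in seq_len(single_head)) { fam <- fam + 1L; family[i] <- fam }
  i <- single_head + 1L
  while (i < single_head + 2L * planted_nonbest) {  # pairs inside top block
    fam <- fam + 1L; family[i] <- fam; family[i + 1L] <- fam; i <- i + 2L
  }
  while (fam < single_head + planted_nonbest + n_pairs_rest && i < n_survivors) {
    fam <- fam + 1L; family[i] <- fam; family[i + 1L] <- fam; i <- i + 2L
  }
  while (i <= n_survivors) { fam <- fam + 1L; family[i] <- fam; i <- i + 1L }
  stopifnot(fam == n_clusters, all(family > 0))

  # structures: survivors get their family's grammar structure, everything
  # else cycles through the grammar; violators get their planted molecules
  smiles_of <- character(n_total)
  names(smiles_of) <- c(pool_ids, fill_ids, viol_ids)
  fam_smiles <- grammar_smiles(n_clusters)
  smiles_of[survivors] <- fam_smiles[family]
  rest <- setdiff(c(pool_ids, fill_ids), survivors)
  smiles_of[rest] <- grammar_smiles(length(rest), offset = 0)
  vsm <- character(0)
  vrule <- character(0)
  for (rule in names(stage1_quotas)) {
    if (stage1_quotas[[rule]] == 0) next
    smi <- if (startsWith(rule, "alert:"))
      .alert_violators[[sub("^alert:", "", rule)]] else .violators[[rule]]
    vsm <- c(vsm, rep(smi, stage1_quotas[[rule]]))
    vrule <- c(vrule, rep(rule, stage1_quotas[[rule]]))
  }
  smiles_of[viol_ids] <- vsm

  deck <- compound_deck(names(smiles_of), unname(smiles_of),
                        source = "synthetic_funnel")

  # planted stage-2 descriptors
  all_ids <- names(smiles_of)
  logd <- with_stream(seed, "logd", stats::runif(n_total, 0.5, 4.5))
  psa <- with_stream(seed, "psa", stats::runif(n_total, 20, 95))
  names(logd) <- names(psa) <- all_ids
  logd[victims] <- with_stream(seed, "logd_victims",
                               stats::runif(length(victims), 5.5, 7.5))
  psa[victims] <- with_stream(seed, "psa_victims",
                              stats::runif(length(victims), 105, 145))

  labels <- gen_labels(all_ids, hit_rate = 0.005, seed = seed)

  truth <- data.frame(
    id = all_ids,
    role = c(rep("pool", pool_size), rep("filler", n_fillers),
             rep("violator", n_viol)),
    violated_rule = c(rep(NA_character_, pool_size + n_fillers), vrule),
    stage2_victim = all_ids %in% victims,
    survivor_rank = match(all_ids, survivors),
    family = family[match(all_ids, survivors)],
    logd = unname(logd),
    psa = unname(psa),
    active = labels$active)

  pharm_plan <- stats::setNames(
    rep(2L, pool_size + n_fillers), c(pool_ids, fill_ids))

  structure(list(
    deck = deck, lists = gl$lists, model = example_pharmacophore(),
    pharm_plan = pharm_plan, truth = truth,
    params = list(seed = seed, top_n = top_n, pool_size = pool_size,
                  n_survivors = n_survivors, n_clusters = n_clusters,
                  target = target, top_m = top_m,
                  planted_nonbest = planted_nonbest)),
    class = "funnel_scenario")
}

#' @export
print.funnel_scenario <- function(x, ...) {
  p <- x$params
  cat("<funnel_scenario> deck ", nrow(x$deck), " -> pool ", p$pool_size,
      " -> stage2 ", p$n_survivors, " -> k ", p$n_clusters, " -> select ",
      p$target, " (trim ", p$planted_nonbest, ")\n", sep = "")
  invisible(x)
}

#' Run the consensus/stage-2/diversity tail of the funnel on a scenario
#'
#' Executes pool -> stage-2 -> fingerprint -> K-medoids -> purchase-set
#' selection with the package operations and returns all intermediate
#' objects, so tests and reports can compare against the planted truth.
#'
#' @param scenario a `funnel_scenario`
#' @param radius,nbits fingerprint parameters (defaults 4 / 2048)
#' @return list with `pool`, `stage2`, `survivor_deck`, `clustering`,
#'   `selection`, `counts` (named funnel counts)
#' @export
run_funnel <- function(scenario, radius = 4, nbits = 2048) {
  stopifnot(inherits(scenario, "funnel_scenario"))
  p <- scenario$params
  pool <- pool_ranked_lists(scenario$lists, p$top_n)
  desc <- data.frame(id = pool$id,
                     logd = scenario$truth$logd[match(pool$id,
                                                      scenario$truth$id)],
                     psa = scenario$truth$psa[match(pool$id,
                                                    scenario$truth$id)])
  s2 <- stage2_filter(desc)
  survivor_ids <- global_rank(pool)
  survivor_ids <- survivor_ids[survivor_ids %in%
                                 s2$compound_id[s2$passed]]
  sdeck <- deck_subset(scenario$deck, survivor_ids)
  fps <- fingerprint_deck(sdeck, radius = radius, nbits = nbits)
  d <- tanimoto_distance_matrix(fps)
  cl <- kmedoids(d, p$n_clusters, seed = p$seed)
  sel <- select_purchase_set(cl, survivor_ids, target = p$target,
                             top_m = p$top_m)
  list(pool = pool, stage2 = s2, survivor_deck = sdeck, clustering = cl,
       selection = sel,
       counts = c(pool = nrow(pool), survivors = length(survivor_ids),
                  clusters = cl$k, chosen = length(sel$chosen),
                  trimmed = length(sel$trimmed)))
}
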