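# Filter descriptors and the two-stage library triage.
#
# Stage 1 removes substructure alerts (PAINS-like and reactive motifs) and
# property outliers: >4 aromatic rings, >10 rotatable bonds, >3 H-bond
# donors, clogP > 5, TPSA > 125 A^2 (all strict inequalities: a compound at
# the threshold passes). Stage 2, applied to the consensus pool, removes
# compounds with logD > 5 AND PSA > 100 by default (OR semantics available).

# symmetric SMARTS: every rotatable bond matches twice (once per direction)
.rotor_smarts <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"
# amide C-N single bonds, counted once per bond (one carbonyl O per C)
.amide_rotor_smarts <- "[NX3;!D1]-&!@[CX3;!D1]=[OX1]"

# crude ionization penalties for the built-in logD surrogate
.basic_n_smarts <- "[NX3;!$([NX3]~[!#6;!#1]);!$([NX3]C=[O,S,N]);!$([NX3]a);!X4]"
.acid_smarts <- "[CX3](=O)[OX2H1]"

smarts_count <- function(sdf, smarts) {
  out <- tryCatch(
    ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = FALSE),
    error = function(e) stop("SMARTS failed to compile or match: '",
                             smarts, "': ", conditionMessage(e)))
  as.integer(out)
}

#' Built-in logD(7.4) surrogate
#'
#' A deliberately simple estimator for testing only: OpenBabel logP minus a
#' fixed ionization penalty per basic aliphatic amine (-2.0) and per
#' carboxylic acid (-1.5), approximating the partition loss of species mostly
#' ionized at pH 7.4. It does not reproduce any vendor logD predictor;
#' callers with measured or vendor-computed values should supply them via the
#' `logd` argument of [compute_descriptors()].
#'
#' @param sdf ChemmineR `SDFset`
#' @param logp numeric vector of logP values for the same molecules
#' @return numeric vector of logD estimates
#' @export
estimate_logd <- function(sdf, logp) {
  nb <- smarts_count(sdf, .basic_n_smarts)
  na_ <- smarts_count(sdf, .acid_smarts)
  logp - 2.0 * nb - 1.5 * na_
}

#' Compute the triage filter descriptors for a deck
#'
#' Aromatic rings are SSSR rings of the sanitized structure (fused systems
#' count per smallest ring). Rotatable bonds are non-ring single bonds
#' between non-terminal heavy atoms, with amide C-N rotors excluded by
#' default. clogP, TPSA and H-bond donor counts come from OpenBabel.
#' `psa` equals `tpsa` unless supplied; `logd` defaults to the built-in
#' surrogate of [estimate_logd()] unless supplied.
#'
#' @param deck a `compound_deck`
#' @param logd,psa optional caller-supplied numeric columns (recycled or per
#'   compound) overriding the built-in values
#' @param include_amide_rotors logical; count amide C-N bonds as rotatable
#' @return data.frame with columns `id`, `aromatic_rings`, `rotatable_bonds`,
#'   `hbd`, `clogp`, `tpsa`, `logd`, `psa`, `heavy_atoms`
#' @export
compute_descriptors <- function(deck, logd = NULL, psa = NULL,
                                include_amide_rotors = FALSE) {
  stopifnot(inherits(deck, "compound_deck"))
  sdf <- deck_sdf(deck)
  props <- attr(deck, "obprops") %||% ChemmineR::propOB(sdf)
  ring <- ChemmineR::rings(sdf, type = "count", arom = TRUE, inner = TRUE)
  if (is.null(dim(ring)))   # single-molecule decks yield a bare vector
    ring <- matrix(ring, 1, dimnames = list(NULL, names(ring)))
  rot_all <- smarts_count(sdf, .rotor_smarts) %/% 2L
  rot <- if (include_amide_rotors) rot_all else
    pmax(0L, rot_all - smarts_count(sdf, .amide_rotor_smarts))
  heavy <- vapply(seq_len(nrow(deck)), function(i) {
    sum(sdf_elements(sdf[[i]]) != "H")
  }, integer(1))
  clogp <- as.numeric(props[, "logP"])
  tpsa <- as.numeric(props[, "TPSA"])
  data.frame(
    id = deck$id,
    aromatic_rings = as.integer(ring[, "AROMATIC"]),
    rotatable_bonds = as.integer(rot),
    hbd = as.integer(props[, "HBD"]),
    clogp = clogp,
    tpsa = tpsa,
    logd = if (is.null(logd)) estimate_logd(sdf, clogp) else
      rep_len(logd, nrow(deck)),
    psa = if (is.null(psa)) tpsa else rep_len(psa, nrow(deck)),
    heavy_atoms = heavy,
    row.names = NULL)
}

#' Default stage-1 property thresholds
#'
#' A compound fails when it exceeds a threshold strictly (e.g. 5 aromatic
#' rings fails `aromatic_rings > 4`; exactly 4 passes).
#' @return named list of upper bounds
#' @export
stage1_thresholds <- function() {
  list(aromatic_rings = 4, rotatable_bonds = 10, hbd = 3,
       clogp = 5, tpsa = 125)
}

#' Curated default substructure alert set
#'
#' A small built-in selection of PAINS-like and reactive-group SMARTS
#' (quinones, catechols, rhodanine-like enones, Michael acceptors, acyl and
#' sulfonyl halides, aldehydes, epoxides/aziridines, isocyanates, azo/nitroso
#' groups, anhydrides, alkyl halides at activated positions). It is a
#' pragmatic screening default, not a reproduction of any published list;
#' full external lists load via [read_alert_set()].
#'
#' @return an `alert_set`: data.frame with columns `label`, `smarts`
#' @export
default_alert_set <- function() {
  pat <- c(
    quinone            = "O=C1C=CC(=O)C=C1",
    catechol           = "c1cc([OX2H1])c([OX2H1])cc1",
    rhodanine_like     = "C1(=O)SC(=S)N1",
    michael_acceptor   = "[CX3]=[CX3]-[CX3]=[OX1]",
    acyl_halide        = "[CX3](=O)[F,Cl,Br,I]",
    sulfonyl_halide    = "[SX4](=O)(=O)[F,Cl,Br,I]",
    aldehyde           = "[CX3H1](=O)[#6]",
    epoxide_aziridine  = "[OX2r3,NX3r3]1[#6r3][#6r3]1",
    isocyanate         = "[NX2]=[CX2]=[OX1]",
    azo                = "[#6]-[NX2]=[NX2]-[#6]",
    nitroso            = "[#6]-[NX2]=[OX1]",
    anhydride          = "[CX3](=O)[OX2][CX3](=O)",
    alpha_halo_ketone  = "[CX3](=O)[CX4][F,Cl,Br,I]")
  alert_set("builtin", names(pat), unname(pat))
}

#' Construct an alert set, validating that every SMARTS compiles
#'
#' @param name set name
#' @param labels,smarts parallel character vectors
#' @return an `alert_set` data.frame (`label`, `smarts`) with attribute `name`
#' @export
alert_set <- function(name, labels, smarts) {
  stopifnot(length(labels) == length(smarts), !anyDuplicated(labels))
  probe <- ChemmineR::smiles2sdf(c(probe = "CC(=O)Nc1ccc(O)cc1"))
  for (i in seq_along(smarts)) smarts_count(probe, smarts[i])  # compile check
  structure(data.frame(label = labels, smarts = smarts,
                       stringsAsFactors = FALSE),
            name = name, class = c("alert_set", "data.frame"))
}

#' Load an alert set from a two-column CSV (label, smarts)
#' @param path CSV file with header columns `label` and `smarts`
#' @param name set name (default: file name)
#' @return an `alert_set`
#' @export
read_alert_set <- function(path, name = basename(path)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "smarts") %in% names(tab)))
    stop("alert file needs 'label' and 'smarts' columns: ", path)
  alert_set(name, tab$label, tab$smarts)
}

filter_verdicts <- function(ids, reasons) {
  data.frame(compound_id = ids,
             passed = lengths(reasons) == 0,
             reasons = I(reasons),
             row.names = NULL)
}

#' Stage-1 library filter: substructure alerts plus property rules
#'
#' Every deck member receives exactly one verdict listing all rules that
#' fired (`alert:<label>` or `<descriptor>><threshold>`); the pass set is the
#' deck minus any compound with at least one reason. Compounds whose
#' descriptors could not be computed fail with reason `descriptor_error`.
#'
#' @param deck a `compound_deck`
#' @param descriptors optional precomputed [compute_descriptors()] table
#' @param alerts list of `alert_set`s (default: the built-in set)
#' @param thresholds named list as [stage1_thresholds()]
#' @return data.frame of verdicts: `compound_id`, `passed`, `reasons`
#'   (list column)
#' @export
stage1_filter <- function(deck, descriptors = NULL,
                          alerts = list(default_alert_set()),
                          thresholds = stage1_thresholds()) {
  stopifnot(inherits(deck, "compound_deck"))
  if (inherits(alerts, "alert_set")) alerts <- list(alerts)
  desc <- descriptors %||% compute_descriptors(deck)
  desc <- desc[match(deck$id, desc$id), , drop = FALSE]
  sdf <- deck_sdf(deck)

  reasons <- rep(list(character(0)), nrow(deck))
  for (aset in alerts) {
    for (i in seq_len(nrow(aset))) {
      hit <- smarts_count(sdf, aset$smarts[i]) > 0
      lab <- paste0("alert:", aset$label[i])
      reasons[hit] <- lapply(reasons[hit], c, lab)
    }
  }
  for (rule in names(thresholds)) {
    if (!rule %in% names(desc)) stop("unknown threshold rule: ", rule)
    v <- desc[[rule]]
    bad <- !is.na(v) & v > thresholds[[rule]]
    lab <- paste0(rule, ">", thresholds[[rule]])
    reasons[bad] <- lapply(reasons[bad], c, lab)
    err <- is.na(v)
    reasons[err] <- lapply(reasons[err], function(r)
      unique(c(r, "descriptor_error")))
  }
  filter_verdicts(deck$id, reasons)
}

#' Stage-2 pool filter on logD and polar surface area
#'
#' Default removes a compound when `logd > 5` AND `psa > 100` (both bounds
#' exceeded), the literal reading of the removal rule; `combine = "or"`
#' removes when either is exceeded.
#'
#' @param descriptors data.frame with columns `id`, `logd`, `psa` (e.g. from
#'   [compute_descriptors()], possibly with caller-supplied columns)
#' @param thresholds named list, upper bounds for `logd` and `psa`
#' @param combine `"and"` (default) or `"or"`
#' @return data.frame of verdicts: `compound_id`, `passed` (kept), `reasons`
#' @export
stage2_filter <- function(descriptors,
                          thresholds = list(logd = 5, psa = 100),
                          combine = c("and", "or")) {
  combine <- match.arg(combine)
  stopifnot(all(c("id", "logd", "psa") %in% names(descriptors)))
  ld <- descriptors$logd
  ps <- descriptors$psa
  miss <- is.na(ld) | is.na(ps)
  over_ld <- !miss & ld > thresholds$logd
  over_ps <- !miss & ps > thresholds$psa
  removed <- if (combine == "and") over_ld & over_ps else over_ld | over_ps
  reasons <- rep(list(character(0)), nrow(descriptors))
  lab <- sprintf("logd>%s%s%spsa>%s", thresholds$logd,
                 if (combine == "and") "&" else "|",
                 "", thresholds$psa)
  reasons[removed] <- list(lab)
  reasons[miss] <- list("missing_descriptor")
  filter_verdicts(descriptors$id, reasons)
}

#' Apply a verdict table to a deck
#' @param deck a `compound_deck`
#' @param verdicts data.frame from [stage1_filter()] / [stage2_filter()]
#' @return the sub-deck of passing compounds
#' @export
apply_verdicts <- function(deck, verdicts) {
  deck_subset(deck, verdicts$compound_id[verdicts$passed])
}
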