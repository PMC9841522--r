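# 3D pharmacophore model and pose filtering.
#
# A model is a set of typed projection spheres (acceptor_site spheres mark
# where a ligand H-bond acceptor heavy atom should sit opposite a protein
# donor, donor_site spheres the converse), an m-of-n match requirement, and
# exclusion spheres that veto a pose when any ligand heavy atom enters them.
# Poses are evaluated as docked: no re-fitting, one shared coordinate frame.
# Distance exactly equal to a sphere radius counts as inside (<=).

#' Construct a pharmacophore model
#'
#' @param features data.frame with columns `kind` (`"acceptor_site"` or
#'   `"donor_site"`), `x`, `y`, `z` (Angstrom) and optionally `radius`
#'   (default 1.4)
#' @param min_required minimum number of matched features for a pass
#' @param exclusions data.frame with `x`, `y`, `z` and optional `radius`
#'   (default 1.4); may be empty or NULL
#' @return object of class `pharmacophore_model`
#' @export
pharmacophore_model <- function(features, min_required,
                                exclusions = NULL) {
  features <- as.data.frame(features)
  stopifnot(all(c("kind", "x", "y", "z") %in% names(features)))
  if (!"radius" %in% names(features)) features$radius <- 1.4
  if (!all(features$kind %in% c("acceptor_site", "donor_site")))
    stop("feature kind must be acceptor_site or donor_site")
  if (any(features$radius <= 0)) stop("feature radius must be > 0")
  if (is.null(exclusions))
    exclusions <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                             radius = numeric(0))
  exclusions <- as.data.frame(exclusions)
  if (nrow(exclusions) && !"radius" %in% names(exclusions))
    exclusions$radius <- 1.4
  if (nrow(exclusions) && any(exclusions$radius <= 0))
    stop("exclusion radius must be > 0")
  min_required <- as.integer(min_required)
  if (min_required < 0 || min_required > nrow(features))
    stop("min_required must lie in [0, number of features]")
  structure(list(features = features, min_required = min_required,
                 exclusions = exclusions),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat("<pharmacophore_model> ", nrow(x$features), " features (",
      x$min_required, " required), ", nrow(x$exclusions),
      " exclusion spheres\n", sep = "")
  invisible(x)
}

#' Write / read a pharmacophore model as JSON
#'
#' Schema (version 1): `{version, min_required, features: [{kind, x, y, z,
#' radius}], exclusions: [{x, y, z, radius}]}`.
#'
#' @param model a `pharmacophore_model`
#' @param path JSON file path
#' @return `path` invisibly (write); a `pharmacophore_model` (read)
#' @export
write_pharmacophore <- function(model, path) {
  stopifnot(inherits(model, "pharmacophore_model"))
  jsonlite::write_json(
    list(version = 1L, min_required = model$min_required,
         features = model$features, exclusions = model$exclusions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pharmacophore
#' @export
read_pharmacophore <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported pharmacophore schema version: ", obj$version)
  excl <- obj$exclusions
  if (is.null(excl) || (is.data.frame(excl) && !nrow(excl))) excl <- NULL
  pharmacophore_model(obj$features, obj$min_required, excl)
}

# ---- ligand atom typing -----------------------------------------------------

# standard valences used to infer implicit hydrogens from a kekulized molblock
.std_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                  Br = 1, I = 1, B = 3, Si = 4, Se = 2)

#' Type ligand atoms as H-bond donors / acceptors
#'
#' Rule-based typing from the pose's connectivity (the `sdf` slot filled by
#' [read_pose_sdf()] or the synthetic generator): an atom is an *acceptor* if
#' it is N or O, not positively charged, and not an amide/sulfonamide
#' nitrogen (N single-bonded to C=O or S=O); it is a *donor* if it is N or O
#' bearing at least one hydrogen (explicit neighbour or implied by standard
#' valence minus bond-order sum). Atoms can be both (hydroxyl O), either, or
#' `neither`.
#'
#' @param p a `pose` whose `sdf` slot carries matching connectivity
#' @return character vector over atoms: `"acceptor"`, `"donor"`, `"both"`,
#'   or `"neither"`
#' @export
type_ligand_atoms <- function(p) {
  stopifnot(inherits(p, "pose"))
  if (is.null(p$sdf))
    stop("pose ", p$compound_id, " carries no connectivity; cannot type atoms")
  elements <- sdf_elements(p$sdf)
  if (length(elements) != length(p$elements) ||
      !all(elements == p$elements))
    stop("atom mismatch between pose and structure for ", p$compound_id)
  bb <- ChemmineR::bondblock(p$sdf)
  if (is.null(dim(bb)) || ncol(bb) < 3) bb <- matrix(numeric(0), 0, 3)
  ab <- ChemmineR::atomblock(p$sdf)
  n <- length(elements)
  deg_order <- numeric(n)   # sum of bond orders
  nbrs <- vector("list", n)
  border <- vector("list", n)
  if (nrow(bb)) for (b in seq_len(nrow(bb))) {
    i <- bb[b, 1]; j <- bb[b, 2]; o <- bb[b, 3]
    oo <- if (o == 4) 1.5 else o   # aromatic molfile order, if present
    deg_order[i] <- deg_order[i] + oo
    deg_order[j] <- deg_order[j] + oo
    nbrs[[i]] <- c(nbrs[[i]], j); border[[i]] <- c(border[[i]], o)
    nbrs[[j]] <- c(nbrs[[j]], i); border[[j]] <- c(border[[j]], o)
  }
  # legacy per-atom charge code lives in molfile field 2 after the element
  # (ChemmineR column C6): 1..3 -> +3..+1, 5..7 -> -1..-3
  chg <- integer(n)
  if ("C6" %in% colnames(ab)) {
    code <- ab[, "C6"]
    chg[code %in% 1:3] <- 4L - as.integer(code[code %in% 1:3])   # +3..+1
    chg[code %in% 5:7] <- 4L - as.integer(code[code %in% 5:7])   # -1..-3
  }
  h_explicit <- vapply(seq_len(n), function(i)
    sum(elements[nbrs[[i]]] == "H"), integer(1))
  h_implicit <- vapply(seq_len(n), function(i) {
    v <- .std_valence[elements[i]]
    if (is.na(v)) return(0L)
    # pyridinium-style N+ gains a bonding site; anionic atoms lose protons
    if (elements[i] == "N") v <- v + max(0L, chg[i])
    as.integer(max(0, round(v + min(0, chg[i]) - deg_order[i])))
  }, integer(1))
  has_h <- (h_explicit + h_implicit) > 0
  # amide / sulfonamide nitrogen: N single-bonded to a C or S that carries =O
  amide_n <- vapply(seq_len(n), function(i) {
    if (elements[i] != "N") return(FALSE)
    for (k in seq_along(nbrs[[i]])) {
      j <- nbrs[[i]][k]
      if (border[[i]][k] == 1 && elements[j] %in% c("C", "S")) {
        jo <- nbrs[[j]]; jb <- border[[j]]
        if (any(elements[jo] == "O" & jb == 2)) return(TRUE)
      }
    }
    FALSE
  }, logical(1))

  polar <- elements %in% c("N", "O")
  acceptor <- polar & chg <= 0 & !(elements == "N" & amide_n)
  donor <- polar & has_h
  out <- rep("neither", n)
  out[acceptor & !donor] <- "acceptor"
  out[donor & !acceptor] <- "donor"
  out[acceptor & donor] <- "both"
  out
}

# ---- matching ---------------------------------------------------------------

feature_complement <- c(acceptor_site = "acceptor", donor_site = "donor")

#' Match one pose against a pharmacophore model
#'
#' Feature i is matched iff some ligand heavy atom of the complementary type
#' lies within (<=) the feature sphere; any heavy atom inside an exclusion
#' sphere is recorded as an exclusion hit and vetoes the pose. A pose passes
#' iff it matches at least `min_required` features and has no exclusion hit.
#'
#' @param p a `pose`
#' @param model a `pharmacophore_model`
#' @param typing optional atom typing (from [type_ligand_atoms()]); computed
#'   from the pose connectivity when omitted
#' @return object of class `match_result`: list with `compound_id`,
#'   `matched_features` (integer indices), `exclusion_hits` (data.frame
#'   `atom`, `sphere`), `n_matched`, `match_distance` (summed atom-to-center
#'   distance over matched features, best atom per feature), `passed`
#' @export
match_pose <- function(p, model, typing = NULL) {
  stopifnot(inherits(p, "pose"), inherits(model, "pharmacophore_model"))
  if (!length(p$elements)) stop("empty pose for ", p$compound_id)
  typing <- typing %||% type_ligand_atoms(p)
  heavy <- p$elements != "H"
  xyz <- p$coords[heavy, , drop = FALSE]
  typ <- typing[heavy]

  matched <- integer(0)
  sumdist <- 0
  ft <- model$features
  for (i in seq_len(nrow(ft))) {
    want <- feature_complement[[ft$kind[i]]]
    cand <- typ == want | typ == "both"
    if (!any(cand)) next
    d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) -
                         c(ft$x[i], ft$y[i], ft$z[i]))^2))
    if (min(d) <= ft$radius[i]) {
      matched <- c(matched, i)
      sumdist <- sumdist + min(d)
    }
  }
  ex <- model$exclusions
  hits <- data.frame(atom = integer(0), sphere = integer(0))
  heavy_idx <- which(heavy)
  for (s in seq_len(nrow(ex))) {
    d <- sqrt(colSums((t(xyz) - c(ex$x[s], ex$y[s], ex$z[s]))^2))
    inside <- which(d <= ex$radius[s])
    if (length(inside))
      hits <- rbind(hits, data.frame(atom = heavy_idx[inside],
                                     sphere = rep(s, length(inside))))
  }
  structure(list(compound_id = p$compound_id,
                 matched_features = matched,
                 exclusion_hits = hits,
                 n_matched = length(matched),
                 match_distance = sumdist,
                 passed = length(matched) >= model$min_required &&
                   nrow(hits) == 0),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", x$compound_id, ": ", x$n_matched, " features [",
      paste(x$matched_features, collapse = ","), "], ",
      nrow(x$exclusion_hits), " exclusion hits -> ",
      if (x$passed) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' Screen a pose set against a pharmacophore model
#'
#' A compound passes if any of its poses passes. The reported best pose per
#' compound is the one with the most matched features, ties broken by the
#' smallest summed atom-to-center distance over matched features, then by
#' first pose index.
#'
#' @param poses list of `pose` objects (several poses per compound allowed)
#' @param model a `pharmacophore_model`
#' @param typings optional list of atom typings parallel to `poses`
#' @return list with `pass_ids` (character), `results` (data.frame: one row
#'   per pose with `compound_id`, `pose_index`, `n_matched`,
#'   `match_distance`, `exclusion_hits`, `passed`, `best`), and
#'   `matches` (list of `match_result`)
#' @export
screen_poses <- function(poses, model, typings = NULL) {
  stopifnot(length(poses) >= 1)
  matches <- lapply(seq_along(poses), function(i)
    match_pose(poses[[i]], model, typing = typings[[i]] %||% NULL))
  res <- data.frame(
    compound_id = vapply(matches, `[[`, character(1), "compound_id"),
    pose_index = seq_along(matches),
    n_matched = vapply(matches, `[[`, integer(1), "n_matched"),
    match_distance = vapply(matches, `[[`, numeric(1), "match_distance"),
    exclusion_hits = vapply(matches, function(m) nrow(m$exclusion_hits),
                            integer(1)),
    passed = vapply(matches, `[[`, logical(1), "passed"))
  res$best <- FALSE
  for (idv in unique(res$compound_id)) {
    ix <- which(res$compound_id == idv)
    o <- ix[order(-res$n_matched[ix], res$match_distance[ix], ix)]
    res$best[o[1]] <- TRUE
  }
  pass_ids <- unique(res$compound_id[res$passed])
  list(pass_ids = pass_ids, results = res, matches = matches)
}

#' Apply one rigid motion (rotation + translation) to 3D points
#'
#' Utility used to state and test the rigid-motion invariance of matching:
#' transforming pose coordinates and all model centers jointly leaves every
#' match result unchanged.
#'
#' @param xyz n x 3 matrix
#' @param rotation 3 x 3 rotation matrix
#' @param translation length-3 numeric
#' @return transformed n x 3 matrix
#' @export
transform_points <- function(xyz, rotation, translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)))
  sweep(as.matrix(xyz) %*% t(rotation), 2, -translation)
}

#' Apply a rigid motion to a whole pharmacophore model
#' @param model a `pharmacophore_model`
#' @inheritParams transform_points
#' @return transformed `pharmacophore_model`
#' @export
transform_model <- function(model, rotation, translation = c(0, 0, 0)) {
  f <- model$features
  f[, c("x", "y", "z")] <- transform_points(f[, c("x", "y", "z")],
                                            rotation, translation)
  e <- model$exclusions
  if (nrow(e))
    e[, c("x", "y", "z")] <- transform_points(e[, c("x", "y", "z")],
                                              rotation, translation)
  pharmacophore_model(f, model$min_required, if (nrow(e)) e else NULL)
}
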