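# Fingerprinting, Tanimoto distances, K-medoids clustering and the final
# purchase-set assembly (cluster representatives + global top-M + trim).

#' Circular (Morgan-type) fingerprints for a deck
#'
#' Hashed circular substructure fingerprints computed with OpenBabel's ECFP
#' implementation (`ECFP{2*radius}`: radius counts bond shells, so the
#' default radius 4 maps to ECFP8). OpenBabel hashes into 4096 bits; when
#' `nbits` is smaller the vector is folded (OR of halves) to the requested
#' width. Structures with equal canonical SMILES give identical vectors.
#'
#' @param deck a `compound_deck`
#' @param radius circular radius in bonds, 0-5 (default 4)
#' @param nbits fingerprint width after folding: 4096, 2048 (default), 1024..
#' @param chunk internal batch size for the OpenBabel call
#' @return object of class `fp_set`: list with `ids`, `bits` (list of sorted
#'   0-based bit indices per compound), `radius`, `nbits`
#' @export
fingerprint_deck <- function(deck, radius = 4, nbits = 2048, chunk = 100) {
  stopifnot(inherits(deck, "compound_deck"), radius %in% 0:5,
            nbits >= 16, 4096 %% nbits == 0)
  sdf <- deck_sdf(deck)
  type <- paste0("ECFP", 2 * radius)
  n <- nrow(deck)
  # fingerprintOB degrades superlinearly with batch size; chunk the call
  mats <- lapply(seq(1, n, by = chunk), function(start) {
    ix <- seq(start, min(start + chunk - 1, n))
    ChemmineR::fingerprintOB(sdf[ix], type)@fpma
  })
  m <- do.call(rbind, mats)
  fold <- ncol(m) / nbits
  bits <- lapply(seq_len(n), function(i) {
    on <- which(m[i, ] != 0) - 1L
    sort(unique(on %% nbits))
  })
  structure(list(ids = deck$id, bits = bits,
                 radius = as.integer(radius), nbits = as.integer(nbits)),
            class = "fp_set")
}

#' @export
print.fp_set <- function(x, ...) {
  cat("<fp_set> ", length(x$ids), " fingerprints, radius ", x$radius,
      " (ECFP", 2 * x$radius, "), ", x$nbits, " bits\n", sep = "")
  invisible(x)
}

#' Tanimoto similarity of two sparse fingerprints
#'
#' |intersection| / |union| of set bits. Two empty fingerprints are defined
#' as identical (similarity 1).
#'
#' @param a,b integer vectors of set-bit indices (same bit space)
#' @param nbits_a,nbits_b widths, checked for equality when supplied
#' @return similarity in \[0, 1\]
#' @export
tanimoto <- function(a, b, nbits_a = NULL, nbits_b = NULL) {
  if (!is.null(nbits_a) && !is.null(nbits_b) && nbits_a != nbits_b)
    stop("fingerprint widths differ: ", nbits_a, " vs ", nbits_b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Pairwise Tanimoto distance matrix (1 - similarity)
#'
#' @param fps an `fp_set`
#' @return symmetric n x n matrix with zero diagonal, dimnames = ids
#' @export
tanimoto_distance_matrix <- function(fps) {
  stopifnot(inherits(fps, "fp_set"))
  n <- length(fps$ids)
  m <- matrix(0L, n, fps$nbits)
  for (i in seq_len(n)) m[i, fps$bits[[i]] + 1L] <- 1L
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, `+`) - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  d <- 1 - sim
  diag(d) <- 0
  dimnames(d) <- list(fps$ids, fps$ids)
  d
}

#' K-medoids (PAM) clustering of a distance matrix
#'
#' Deterministic PAM: greedy BUILD initialization followed by best-swap
#' iterations until no strictly improving swap exists. The seed only
#' controls tie-breaking order (BUILD and swap candidates); for a fixed seed
#' and input order the result is fully reproducible. The returned cost trace
#' (cost after BUILD and after each accepted swap) is non-increasing.
#'
#' @param distances symmetric numeric matrix, zero diagonal; dimnames used
#'   as point ids when present
#' @param k number of clusters, 1 <= k <= n
#' @param seed integer tie-breaking seed
#' @return object of class `kmedoids_clustering`: list with `k`, `medoids`
#'   (ids), `medoid_index`, `assignment` (named id -> medoid id), `cost`,
#'   `cost_trace` (after BUILD then after each swap), `cluster_sizes`
#' @export
kmedoids <- function(distances, k, seed = 1) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (ncol(d) != n) stop("distance matrix must be square")
  if (k > n) stop("k (", k, ") exceeds number of points (", n, ")")
  if (k < 1) stop("k must be >= 1")
  if (any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0) || any(d < 0))
    stop("distances must be symmetric, non-negative, zero on the diagonal")
  ids <- rownames(d) %||% as.character(seq_len(n))
  tie_order <- with_stream(seed, "kmedoids", sample.int(n))
  fit <- .pam_cpp(d, as.integer(k), as.integer(tie_order))
  assignment <- stats::setNames(ids[fit$assignment], ids)
  structure(list(
    k = as.integer(k),
    medoids = ids[fit$medoids],
    medoid_index = fit$medoids,
    assignment = assignment,
    cost = fit$cost,
    cost_trace = c(fit$build_costs[length(fit$build_costs)], fit$swap_costs),
    cluster_sizes = table(factor(assignment, levels = ids[fit$medoids])),
    seed = seed), class = "kmedoids_clustering")
}

#' @export
print.kmedoids_clustering <- function(x, ...) {
  cat("<kmedoids_clustering> k = ", x$k, ", cost = ",
      format(x$cost, digits = 6), ", ", length(x$cost_trace) - 1,
      " accepted swaps\n", sep = "")
  invisible(x)
}

#' Assemble the purchase set from a clustering and a global ranking
#'
#' Three steps mirroring the triage workflow: (1) take the best-ranked
#' member of every cluster; (2) add every compound of the global top
#' `top_m` not already selected (reason `topM_added`); (3) while the
#' selection exceeds `target`, trim the worst-ranked selected compounds
#' (recorded worst-first). With k clusters and a top-`top_m` of which j are
#' not cluster representatives, the pre-trim size is k + j.
#'
#' @param clustering a `kmedoids_clustering`
#' @param ranking character vector of compound ids, best first, totally
#'   ordering all clustered compounds
#' @param target final set size
#' @param top_m size of the top-ranked block force-included before trimming
#' @return object of class `selection_report`: list with `chosen` (ids in
#'   rank order), `reason` (named: `cluster_best` / `topM_added`), `trimmed`
#'   (worst first), `pre_trim_size`
#' @export
select_purchase_set <- function(clustering, ranking, target, top_m = 50) {
  stopifnot(inherits(clustering, "kmedoids_clustering"))
  members <- names(clustering$assignment)
  if (!all(members %in% ranking))
    stop("ranking does not cover all clustered compounds")
  ranking <- ranking[ranking %in% members]
  if (target > clustering$k + top_m)
    stop("infeasible target ", target, ": exceeds clusters (", clustering$k,
         ") + top_m (", top_m, ")")
  if (target > length(members))
    stop("infeasible target ", target, ": only ", length(members),
         " compounds")
  pos <- stats::setNames(seq_along(ranking), ranking)

  cl <- clustering$assignment
  best_of_cluster <- vapply(split(names(cl), cl), function(ids_in)
    ids_in[which.min(pos[ids_in])], character(1))
  reason <- stats::setNames(rep("cluster_best", length(best_of_cluster)),
                            best_of_cluster)
  top_block <- ranking[seq_len(min(top_m, length(ranking)))]
  added <- setdiff(top_block, best_of_cluster)
  reason[added] <- "topM_added"

  chosen <- names(reason)[order(pos[names(reason)])]
  pre_trim <- length(chosen)
  trimmed <- character(0)
  if (pre_trim > target) {
    n_trim <- pre_trim - target
    trimmed <- rev(chosen)[seq_len(n_trim)]   # worst-ranked first
    chosen <- chosen[seq_len(target)]
  }
  reason <- reason[chosen]
  structure(list(chosen = chosen, reason = reason, trimmed = trimmed,
                 pre_trim_size = pre_trim),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> ", length(x$chosen), " chosen (",
      sum(x$reason == "cluster_best"), " cluster representatives, ",
      sum(x$reason == "topM_added"), " top-M additions), ",
      length(x$trimmed), " trimmed\n", sep = "")
  invisible(x)
}

#' Selection report as a data.frame (for CSV reports)
#' @param x a `selection_report`
#' @param ... unused
#' @return data.frame `compound_id`, `reason` plus trimmed rows flagged
#' @export
as.data.frame.selection_report <- function(x, ...) {
  rbind(
    data.frame(compound_id = x$chosen, reason = unname(x$reason),
               trimmed = FALSE),
    if (length(x$trimmed))
      data.frame(compound_id = x$trimmed, reason = "trimmed", trimmed = TRUE))
}
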