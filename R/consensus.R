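# Consensus pooling of ranked docking outputs.
#
# Each scoring function contributes its top-N compounds; the pool is the
# union, with provenance. Because raw score magnitudes of different engines
# are not comparable, the global order over the pool is positional:
# key = (best positional rank across engines, mean positional rank over the
# engines where the compound appears, compound id). Lower is better; the key
# yields a deterministic total order.

#' Construct a ranked engine output
#'
#' Entries are sorted by score according to `direction`, ties broken by
#' compound id ascending, so positional ranks are deterministic.
#'
#' @param engine engine name (non-empty string)
#' @param ids character compound ids, unique within the list
#' @param scores numeric scores, parallel to `ids`
#' @param direction `"higher"` (better) or `"lower"` (better)
#' @return object of class `ranked_list`: data.frame `id`, `score`, `rank`
#'   with attributes `engine`, `direction`
#' @export
ranked_list <- function(engine, ids, scores,
                        direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(nzchar(engine), length(ids) == length(scores))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate compound ids in ranked list '", engine, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  o <- order(if (direction == "higher") -scores else scores, ids,
             method = "radix")
  out <- data.frame(id = ids[o], score = scores[o], rank = seq_along(o))
  structure(out, engine = engine, direction = direction,
            class = c("ranked_list", "data.frame"))
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("<ranked_list> ", attr(x, "engine"), " (", attr(x, "direction"),
      "-better), ", nrow(x), " entries\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Read a ranked list from CSV (columns engine, id, score)
#' @param path CSV path
#' @param direction score direction for this engine
#' @return a `ranked_list`
#' @export
read_ranked_list <- function(path, direction = c("higher", "lower")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("engine", "id", "score")
  if (!all(need %in% names(tab)))
    stop("ranked-list CSV needs columns ", paste(need, collapse = ", "))
  eng <- unique(tab$engine)
  if (length(eng) != 1) stop("one engine per ranked-list file, got: ",
                             paste(eng, collapse = ", "))
  ranked_list(eng, tab$id, tab$score, direction = match.arg(direction))
}

#' Top-n prefix of a ranked list
#'
#' Returns the first `min(n, length)` entries of the deterministic order
#' (score by direction, ties by id ascending — the lexicographically smaller
#' id survives a tie at the cut).
#'
#' @param rl a `ranked_list`
#' @param n non-negative integer
#' @return a `ranked_list` prefix
#' @export
top_n <- function(rl, n) {
  stopifnot(inherits(rl, "ranked_list"), n >= 0)
  k <- min(as.integer(n), nrow(rl))
  out <- as.data.frame(rl)[seq_len(k), , drop = FALSE]
  structure(out, engine = attr(rl, "engine"),
            direction = attr(rl, "direction"),
            class = c("ranked_list", "data.frame"))
}

#' Pool the top-n prefixes of several ranked lists
#'
#' Members are the union of per-engine top-n sets; provenance records which
#' engines contributed each member; the global order uses the
#' best-then-mean positional rank key (see [global_rank()]). Positional
#' ranks are taken within each full input list, not within the prefix.
#'
#' @param lists list of `ranked_list` objects (distinct engine names)
#' @param n per-engine prefix size
#' @return object of class `consensus_pool`: data.frame with `id`, `engines`
#'   (`;`-joined provenance), `n_engines`, `best_rank`, `mean_rank`,
#'   `rank` (global, 1 = best), ordered by `rank`
#' @export
pool_ranked_lists <- function(lists, n) {
  stopifnot(length(lists) >= 1,
            all(vapply(lists, inherits, logical(1), "ranked_list")))
  engines <- vapply(lists, attr, character(1), "engine")
  if (anyDuplicated(engines))
    stop("duplicate engine names: ", paste(engines, collapse = ", "))
  prefixes <- lapply(lists, top_n, n = n)
  members <- sort(unique(unlist(lapply(prefixes, `[[`, "id"))))
  if (!length(members)) stop("empty pool (n = 0 or empty lists)")
  # positional rank of each member within each complete list
  rank_mat <- matrix(NA_real_, length(members), length(lists),
                     dimnames = list(members, engines))
  contrib <- matrix(FALSE, length(members), length(lists),
                    dimnames = list(members, engines))
  for (j in seq_along(lists)) {
    rl <- lists[[j]]
    m <- match(members, rl$id)
    rank_mat[, j] <- rl$rank[m]
    contrib[, j] <- members %in% prefixes[[j]]$id
  }
  best <- apply(rank_mat, 1, min, na.rm = TRUE)
  meanr <- rowMeans(rank_mat, na.rm = TRUE)
  o <- order(best, meanr, members, method = "radix")
  out <- data.frame(
    id = members,
    engines = apply(contrib, 1, function(z) paste(engines[z], collapse = ";")),
    n_engines = rowSums(contrib),
    best_rank = best,
    mean_rank = meanr,
    row.names = NULL)[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, n = as.integer(n), engines = engines,
            class = c("consensus_pool", "data.frame"))
}

#' @export
print.consensus_pool <- function(x, ...) {
  cat("<consensus_pool> ", nrow(x), " unique members from ",
      length(attr(x, "engines")), " engines (top-", attr(x, "n"),
      " each)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Global ranking of pool members
#'
#' The ordering rule is the package's documented choice (the source workflow
#' does not define one): members sort by best positional rank across
#' engines, then mean positional rank over engines where the compound
#' appears, then compound id. Returns ids, best first.
#'
#' @param pool a `consensus_pool`
#' @return character vector of member ids in rank order
#' @export
global_rank <- function(pool) {
  stopifnot(inherits(pool, "consensus_pool"))
  pool$id[order(pool$rank)]
}
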