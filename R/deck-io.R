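# Deck and pose I/O: SMILES/CSV compound tables, SDF pose files, CSV reports.
# Structure handling is delegated to ChemmineR/ChemmineOB (OpenBabel); all
# readers are total: broken records are skipped with a diagnostic, never fatal.

# Convert SMILES to an SDFset, tolerating invalid entries. OpenBabel aborts a
# whole batch on one bad string, so failing chunks are bisected down to the
# offending molecules. Returns list(sdf = SDFset or NULL, failed = int indices).
smiles_to_sdf_safe <- function(smiles, chunk = 200) {
  stopifnot(!is.null(names(smiles)))
  n <- length(smiles)
  ok <- list()
  failed <- integer(0)
  convert <- function(ix) {
    res <- try(suppressWarnings(ChemmineR::smiles2sdf(smiles[ix])),
               silent = TRUE)
    if (!inherits(res, "try-error") && length(res) == length(ix)) {
      ok[[length(ok) + 1L]] <<- res
    } else if (length(ix) == 1L) {
      failed <<- c(failed, ix)
    } else {
      half <- length(ix) %/% 2L
      convert(ix[seq_len(half)])
      convert(ix[(half + 1L):length(ix)])
    }
  }
  for (start in seq(1L, n, by = chunk))
    convert(seq(start, min(start + chunk - 1L, n)))
  sdf <- if (length(ok)) {
    # concatenating SDFsets via c() is version-fragile; rebuild from SDF lists
    parts <- lapply(ok, ChemmineR::SDFset2SDF)
    all <- unlist(parts, recursive = FALSE)
    ChemmineR::SDFset(all, ID = unlist(lapply(ok, ChemmineR::cid)))
  } else NULL
  list(sdf = sdf, failed = sort(failed))
}

#' Build a compound deck from identifiers and SMILES
#'
#' Every structure is parsed with OpenBabel; rows whose SMILES fail to parse
#' are skipped (recorded in the `skipped` attribute), and canonical SMILES are
#' stored so duplicate detection can be structure-based.
#'
#' @param ids character vector of unique compound identifiers
#' @param smiles character vector of SMILES, same length
#' @param source optional free-text provenance tag recycled over rows
#' @return a `compound_deck`: data.frame with columns `id`, `smiles`,
#'   `cansmi`, `source`; attributes `sdf` (ChemmineR `SDFset`, one entry per
#'   kept row) and `skipped` (data.frame of dropped rows with reasons)
#' @export
compound_deck <- function(ids, smiles, source = "") {
  stopifnot(length(ids) == length(smiles), !anyNA(ids))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(smiles) <- ids
  conv <- smiles_to_sdf_safe(smiles)
  keep <- setdiff(seq_along(ids), conv$failed)
  if (!length(keep)) stop("no valid structures in deck")
  skipped <- data.frame(row = conv$failed, id = ids[conv$failed],
                        smiles = unname(smiles[conv$failed]),
                        reason = rep("invalid_smiles", length(conv$failed)))
  sdf <- conv$sdf
  obprops <- tryCatch(ChemmineR::propOB(sdf), error = function(e) NULL)
  cansmi <- if (!is.null(obprops)) as.character(obprops[, "cansmi"]) else
    rep(NA_character_, length(keep))
  deck <- data.frame(id = ids[keep], smiles = unname(smiles[keep]),
                     cansmi = unname(cansmi),
                     source = rep_len(as.character(source), length(ids))[keep],
                     stringsAsFactors = FALSE)
  structure(deck, sdf = sdf, skipped = skipped, obprops = obprops,
            class = c("compound_deck", "data.frame"))
}

#' @export
print.compound_deck <- function(x, ...) {
  cat("<compound_deck> ", nrow(x), " compounds (",
      nrow(attr(x, "skipped")), " rows skipped at ingest)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' SDFset backing a deck
#' @param deck a `compound_deck`
#' @return ChemmineR `SDFset`, in deck row order
#' @export
deck_sdf <- function(deck) {
  stopifnot(inherits(deck, "compound_deck"))
  attr(deck, "sdf")
}

#' Subset a deck by compound id
#' @param deck a `compound_deck`
#' @param ids character ids to keep (order respected)
#' @return a `compound_deck`
#' @export
deck_subset <- function(deck, ids) {
  stopifnot(inherits(deck, "compound_deck"))
  ix <- match(ids, deck$id)
  if (anyNA(ix)) stop("ids absent from deck: ",
                      paste(ids[is.na(ix)], collapse = ", "))
  out <- as.data.frame(deck)[ix, , drop = FALSE]
  rownames(out) <- NULL
  op <- attr(deck, "obprops")
  structure(out, sdf = attr(deck, "sdf")[ix],
            skipped = attr(deck, "skipped")[0, ],
            obprops = if (!is.null(op)) op[ix, , drop = FALSE] else NULL,
            class = c("compound_deck", "data.frame"))
}

#' Read a compound deck from a delimited SMILES table
#'
#' @param path CSV (or TSV, by extension or `sep`) file with a header row
#' @param id_column,smiles_column column names holding id and SMILES
#' @param sep field separator; default inferred from the file extension
#' @param source provenance tag stored on records (default: the file name)
#' @return a `compound_deck` (see [compound_deck()]); skipped rows, including
#'   rows with invalid SMILES, are in `attr(, "skipped")`
#' @export
read_smiles_table <- function(path, id_column = "id",
                              smiles_column = "smiles", sep = NULL,
                              source = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- sep %||% if (grepl("\\.tsv$|\\.tab$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  miss <- setdiff(c(id_column, smiles_column), names(tab))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  compound_deck(tab[[id_column]], tab[[smiles_column]], source = source)
}

# ---- poses ------------------------------------------------------------------

#' Construct a pose object
#'
#' @param compound_id compound identifier
#' @param elements character vector of element symbols, one per atom
#' @param coords numeric n x 3 matrix of Cartesian coordinates in Angstrom
#' @param scores named numeric vector of per-engine docking scores
#' @param sdf optional ChemmineR `SDF` carrying the connectivity of the same
#'   atoms in the same order (needed for donor/acceptor typing)
#' @return object of class `pose`
#' @export
pose <- function(compound_id, elements, coords, scores = numeric(0),
                 sdf = NULL) {
  coords <- as.matrix(coords)
  stopifnot(length(elements) >= 1, nrow(coords) == length(elements),
            ncol(coords) == 3, all(is.finite(coords)))
  if (length(scores) && (is.null(names(scores)) || any(!nzchar(names(scores)))))
    stop("engine scores must be named")
  structure(list(compound_id = as.character(compound_id),
                 elements = as.character(elements),
                 coords = coords, scores = scores, sdf = sdf),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat("<pose> ", x$compound_id, ": ", length(x$elements), " atoms",
      if (length(x$scores))
        paste0("; scores [", paste(names(x$scores), collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

sdf_elements <- function(sdfobj) {
  sub("_.*$", "", rownames(ChemmineR::atomblock(sdfobj)))
}

#' Read docked poses from an SDF file
#'
#' One `pose` per SDF record. Per-engine docking scores are pulled from SDF
#' data fields named in `score_tags`; a record missing a tag yields a pose
#' without that engine plus a warning. Records whose molblock fails to parse
#' are skipped with a diagnostic.
#'
#' @param path SDF (V2000) file with 3D coordinates
#' @param score_tags named character vector, engine name -> SDF property name
#' @return list with `poses` (list of `pose`) and `skipped`
#'   (data.frame of unreadable records)
#' @export
read_pose_sdf <- function(path, score_tags = character(0)) {
  if (!file.exists(path)) stop("no such file: ", path)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  ok <- ChemmineR::validSDF(sdfset)
  skipped <- data.frame(record = which(!ok),
                        reason = rep("unreadable_molblock", sum(!ok)))
  if (any(!ok)) {
    warning(sum(!ok), " SDF record(s) skipped as unreadable")
    sdfset <- sdfset[ok]
  }
  poses <- lapply(seq_along(ChemmineR::cid(sdfset)), function(i) {
    obj <- sdfset[[i]]
    ab <- ChemmineR::atomblock(obj)
    db <- ChemmineR::datablock(obj)
    scores <- numeric(0)
    for (eng in names(score_tags)) {
      tag <- score_tags[[eng]]
      if (tag %in% names(db)) {
        scores[eng] <- as.numeric(db[[tag]])
      } else {
        warning("pose ", ChemmineR::sdfid(obj), ": missing score tag '",
                tag, "' for engine '", eng, "'")
      }
    }
    pose(ChemmineR::sdfid(obj), sdf_elements(obj), ab[, 1:3, drop = FALSE],
         scores, sdf = obj)
  })
  list(poses = poses, skipped = skipped)
}

# molblock text for one pose (V2000); bonds taken from pose$sdf when present
pose_molblock <- function(p) {
  n <- length(p$elements)
  bonds <- if (!is.null(p$sdf)) ChemmineR::bondblock(p$sdf) else
    matrix(numeric(0), 0, 3)
  header <- c(p$compound_id, "  screentriage", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      n, nrow(bonds)))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   p$coords[, 1], p$coords[, 2], p$coords[, 3], p$elements)
  bl <- if (nrow(bonds)) sprintf("%3d%3d%3d  0  0  0  0",
                                 bonds[, 1], bonds[, 2], bonds[, 3]) else
    character(0)
  c(header, atoms, bl, "M  END")
}

#' Write poses to an SDF file
#'
#' Coordinates are written at 4 decimals; engine scores become SDF data
#' fields (`> <tag>`), so [read_pose_sdf()] round-trips.
#'
#' @param poses list of `pose` objects
#' @param path output file
#' @param score_tags named character vector engine -> SDF property name;
#'   default uses the engine names themselves
#' @return `path`, invisibly
#' @export
write_pose_sdf <- function(poses, path, score_tags = NULL) {
  stopifnot(all(vapply(poses, inherits, logical(1), "pose")))
  lines <- unlist(lapply(poses, function(p) {
    tags <- score_tags %||% stats::setNames(names(p$scores), names(p$scores))
    dat <- unlist(lapply(names(p$scores), function(eng) {
      tag <- if (eng %in% names(tags)) tags[[eng]] else eng
      c(paste0(">  <", tag, ">"), format(p$scores[[eng]], digits = 10), "")
    }))
    c(pose_molblock(p), dat, "$$$$")
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a CSV report with deterministic row order
#'
#' Rows are ordered by the first column (typically the compound id); list
#' columns (e.g. filter reasons) are flattened to `;`-joined strings.
#'
#' @param rows data.frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_report <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  rows <- as.data.frame(rows)
  for (j in seq_along(rows))
    if (is.list(rows[[j]])) rows[[j]] <- collapse_reasons(rows[[j]])
  if (nrow(rows) > 1)
    rows <- rows[order(rows[[1]], method = "radix"), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a CSV report
#' @param path CSV written by [write_report()]
#' @return data.frame
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
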