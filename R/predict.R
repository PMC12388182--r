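# HOSE-code nearest-environment shift prediction. Reference assignments are
# indexed under their extended HOSE code at every depth 1..max_spheres; a
# query walks from the deepest sphere down until it finds stored examples
# and averages their shifts. Shallow matches and thin evidence raise a
# reliability warning.

# round half away from zero, the convention used for printed shift errors
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Printed shift-prediction error
#'
#' The error column of a prediction report: the absolute difference between
#' observed and predicted shift, rounded half-up to two decimals (the
#' precision at which both nuclei are reported).
#'
#' @param observed observed shift (ppm).
#' @param predicted predicted shift (ppm).
#' @return absolute error in ppm, two decimals.
#' @examples
#' shift_error(69.58, 69.36)  # 0.22
#' @export
shift_error <- function(observed, predicted) round_half_up(abs(observed - predicted), 2L)

#' Build a HOSE-code shift index
#'
#' Indexes reference shift assignments under the extended HOSE code of the
#' assigned atom at every depth from 1 to `max_spheres`, per nucleus. For
#' 1H records the assigned atom index is the carbon carrying the
#' hydrogen(s); the proton shift is indexed under the carbon's code, so
#' protons are looked up through their carbon environment.
#'
#' @param mols named list of `zmol` (names are molecule ids; unnamed lists
#'   get ids "1", "2", ...).
#' @param assignments data frame with columns `mol_id`, `atom`, `nucleus`
#'   (e.g. "13C", "1H") and `shift` (ppm). When NULL, each molecule's
#'   `Assignments` SDF property is parsed instead (lines
#'   `atom<TAB>nucleus<TAB>shift`).
#' @param max_spheres indexing depth (default 4).
#' @return object of class `shift_index`.
#' @seealso [predict_shift()], [predict_molecule()], [read_assignments()]
#' @export
build_shift_index <- function(mols, assignments = NULL, max_spheres = 4L) {
  if (inherits(mols, "zmol")) mols <- list(mols)
  ids <- names(mols)
  if (is.null(ids)) ids <- as.character(seq_along(mols))
  names(mols) <- ids
  if (is.null(assignments)) {
    assignments <- do.call(rbind, lapply(ids, function(id) {
      prop <- mols[[id]]$properties[["Assignments"]]
      if (is.null(prop)) return(NULL)
      tab <- utils::read.delim(text = prop, header = FALSE,
                        col.names = c("atom", "nucleus", "shift"))
      data.frame(mol_id = id, tab)
    }))
    if (is.null(assignments))
      assignments <- data.frame(mol_id = character(), atom = integer(),
                                nucleus = character(), shift = numeric())
  }
  stopifnot(all(c("mol_id", "atom", "nucleus", "shift") %in% names(assignments)))
  if (any(!is.finite(assignments$shift)))
    stop("all reference shifts must be finite", call. = FALSE)

  idx <- new.env(parent = emptyenv())
  n_rec <- 0L
  code_cache <- list()
  for (r in seq_len(nrow(assignments))) {
    rec <- assignments[r, ]
    id <- as.character(rec$mol_id)
    m <- mols[[id]]
    if (is.null(m))
      stop(sprintf("assignment record %d references unknown molecule '%s'", r, id),
           call. = FALSE)
    if (is.na(rec$atom) || rec$atom < 1L || rec$atom > n_atoms(m))
      stop(sprintf("assignment record %d (molecule '%s') references nonexistent atom %s",
                   r, id, rec$atom), call. = FALSE)
    ckey <- paste(id, rec$atom)
    if (is.null(code_cache[[ckey]])) {
      code_cache[[ckey]] <- generate_hose(m, rec$atom, max_spheres)
    }
    code <- code_cache[[ckey]]
    for (s in seq_len(max_spheres)) {
      key <- paste0(rec$nucleus, "|", s, "|",
                    .normalize_code_text(hose_truncate(code, s)$text))
      slot <- if (exists(key, envir = idx, inherits = FALSE))
        get(key, envir = idx, inherits = FALSE) else list(shifts = numeric(), mol = character())
      slot$shifts <- c(slot$shifts, rec$shift)
      slot$mol <- c(slot$mol, id)
      assign(key, slot, envir = idx)
    }
    n_rec <- n_rec + 1L
  }
  structure(
    list(map = idx, max_spheres = as.integer(max_spheres), n_records = n_rec,
         nuclei = unique(as.character(assignments$nucleus))),
    class = "shift_index"
  )
}

#' @export
print.shift_index <- function(x, ...) {
  cat(sprintf("<shift index: %d records, nuclei %s, %d spheres, %d keys>\n",
              x$n_records, paste(x$nuclei, collapse = "/"), x$max_spheres,
              length(ls(x$map))))
  invisible(x)
}

.index_lookup <- function(idx, nucleus, depth, text) {
  key <- paste0(nucleus, "|", depth, "|", .normalize_code_text(text))
  if (exists(key, envir = idx$map, inherits = FALSE))
    get(key, envir = idx$map, inherits = FALSE)
  else list(shifts = numeric(), mol = character())
}

.new_prediction <- function(value, spheres_used, n_examples, spread, observed) {
  warn <- spheres_used < zob_option("warn_spheres") ||
    n_examples < zob_option("min_examples")
  err <- if (!is.null(observed) && !is.na(observed) && !is.na(value))
    shift_error(observed, round_half_up(value, 2L)) else NA_real_
  structure(
    list(value = value, spheres_used = as.integer(spheres_used),
         n_examples = as.integer(n_examples), spread = spread,
         warning = warn, observed = if (is.null(observed)) NA_real_ else observed,
         error_vs_observed = err),
    class = "shift_prediction"
  )
}

#' @export
print.shift_prediction <- function(x, ...) {
  if (is.na(x$value)) {
    cat("<no prediction: no matching environment in the index>\n")
  } else {
    cat(sprintf("<predicted %.2f ppm from %d example(s) at %d sphere(s)%s>\n",
                x$value, x$n_examples, x$spheres_used,
                if (x$warning) ", low reliability" else ""))
  }
  invisible(x)
}

#' Predict one atom's shift by HOSE-code lookup with sphere fallback
#'
#' Generates the query atom's extended HOSE code and looks it up at depth
#' `max_spheres`, falling back one sphere at a time until at least one
#' reference example matches. The prediction is the arithmetic mean (or
#' median, see `zob_options(aggregate=)`) of the matched shifts. A
#' reliability warning is set when the matched depth is below
#' `warn_spheres` (default 3) or fewer than `min_examples` (default 2)
#' references contributed. Records from molecules listed in `exclude` are
#' ignored, which implements leave-out prediction of a compound that is
#' itself in the index.
#'
#' @param idx a `shift_index`.
#' @param m query `zmol`.
#' @param atom query atom index.
#' @param nucleus nucleus label, must be present in the index.
#' @param observed optional observed shift (ppm); adds the printed error.
#' @param exclude character vector of molecule ids to ignore.
#' @return a `shift_prediction`: `value`, `spheres_used`, `n_examples`,
#'   `spread` (sd of matched shifts), `warning`, `error_vs_observed`.
#' @export
predict_shift <- function(idx, m, atom, nucleus, observed = NULL, exclude = NULL) {
  stopifnot(inherits(idx, "shift_index"))
  if (!nucleus %in% idx$nuclei)
    stop(sprintf("nucleus '%s' is not indexed", nucleus), call. = FALSE)
  code <- generate_hose(m, atom, idx$max_spheres)
  .predict_from_code(idx, code, nucleus, observed, exclude)
}

.predict_from_code <- function(idx, code, nucleus, observed = NULL, exclude = NULL) {
  agg <- zob_option("aggregate")
  for (s in rev(seq_len(idx$max_spheres))) {
    slot <- .index_lookup(idx, nucleus, s, hose_truncate(code, s)$text)
    keep <- !(slot$mol %in% exclude)
    shifts <- slot$shifts[keep]
    if (length(shifts) >= 1L) {
      value <- if (identical(agg, "median")) stats::median(shifts) else mean(shifts)
      spread <- if (length(shifts) > 1L) stats::sd(shifts) else 0
      return(.new_prediction(value, s, length(shifts), spread, observed))
    }
  }
  .new_prediction(NA_real_, 0L, 0L, NA_real_, observed)
}

#' Predict shifts for a whole molecule, grouped by equivalent atoms
#'
#' Predicts every atom of the requested nuclei: for `13C` all carbons, for
#' `1H` the hydrogens attached to those carbons, predicted through their
#' carbon's HOSE code under the `1H` nucleus. Symmetry-equivalent atoms --
#' atoms with identical full-depth codes -- are grouped into one report row
#' listing the member indices. When observed shifts are supplied, each row
#' carries the printed error against the (rounded) prediction.
#'
#' @param idx a `shift_index`.
#' @param m query `zmol`.
#' @param nuclei character vector, subset of c("13C", "1H").
#' @param observed optional data frame (`atom`, `nucleus`, `shift`) of
#'   measured values; a group's observed value is the mean over its members
#'   with recorded shifts.
#' @param exclude molecule ids to ignore in the index (leave-out).
#' @return data frame with columns `atom_group`, `nucleus`, `observed`,
#'   `predicted`, `error`, `spheres`, `n`, `warning`.
#' @export
predict_molecule <- function(idx, m, nuclei = c("13C", "1H"), observed = NULL,
                             exclude = NULL) {
  stopifnot(inherits(idx, "shift_index"))
  mh <- add_implicit_hydrogens(m)
  mn <- normalize_for_hose(mh)
  carbons <- which(mn$atoms$element == "C")
  codes <- lapply(carbons, function(at) generate_hose(mn, at, idx$max_spheres,
                                                      normalize = FALSE))
  texts <- vapply(codes, function(cd) cd$text, character(1))
  groups <- split(seq_along(carbons), factor(texts, levels = unique(texts)))

  obs_for <- function(members, nucleus) {
    if (is.null(observed)) return(NA_real_)
    sel <- observed$atom %in% carbons[members] & observed$nucleus == nucleus
    if (!any(sel)) return(NA_real_)
    mean(observed$shift[sel])
  }

  rows <- list()
  for (g in groups) {
    members <- carbons[g]
    label <- paste(members, collapse = ", ")
    code <- codes[[g[1]]]
    for (nuc in nuclei) {
      if (nuc == "1H" && all(mh$atoms$hcount[members] == 0L)) next
      if (!nuc %in% idx$nuclei && idx$n_records > 0L) next
      obs <- obs_for(g, nuc)
      pr <- .predict_from_code(idx, code, nuc, observed = obs, exclude = exclude)
      rows[[length(rows) + 1L]] <- data.frame(
        atom_group = label, nucleus = nuc, observed = obs,
        predicted = round_half_up(pr$value, 2L), error = pr$error_vs_observed,
        spheres = pr$spheres_used, n = pr$n_examples, warning = pr$warning
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(atom_group = character(), nucleus = character(),
                      observed = numeric(), predicted = numeric(),
                      error = numeric(), spheres = integer(), n = integer(),
                      warning = logical()))
  }
  do.call(rbind, rows)
}

#' Read a shift assignment table
#'
#' Reads a TSV with columns `mol_id`, `atom`, `nucleus`, `shift`.
#'
#' @param path file path.
#' @return data frame suitable for [build_shift_index()].
#' @export
read_assignments <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mol_id", "atom", "nucleus", "shift") %in% names(tab)))
  tab
}

#' Write a prediction report
#'
#' @param report data frame from [predict_molecule()].
#' @param path output path; format chosen by extension (`.json` via
#'   jsonlite if available, otherwise TSV).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path) && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
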