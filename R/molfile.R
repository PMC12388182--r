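# Extended V2000 molfile / SDF I/O. Two extensions over plain V2000:
#  * bond-order 0 is legal in the bond block (zero bond);
#  * per-atom explicit hydrogen counts as property lines
#    "M  <tag>  1 <atom> <count>" (tag configurable, default ZHC).
# Bond type 4 maps to order 1 + aromatic flag; query type 8 ("any bond") is
# accepted on input and converted to a zero bond with a notice.

.parse_error <- function(lineno, msg) {
  stop(sprintf("molfile parse error at line %d: %s", lineno, msg), call. = FALSE)
}

.fixed_int <- function(line, from, to, lineno, what) {
  s <- trimws(substr(line, from, to))
  v <- suppressWarnings(as.integer(s))
  if (is.na(v)) .parse_error(lineno, paste("cannot read", what))
  v
}

#' Parse an extended V2000 molfile
#'
#' Reads a single molfile block. Zero-order bonds (bond type 0) are
#' preserved; bond type 4 becomes order 1 with the aromatic flag; query
#' bond type 8 ("any bond") is converted to a zero bond with a notice,
#' matching the drawing-tool workaround for editors that cannot enter zero
#' bonds directly. Formal charges are read from `M  CHG` lines, isotopes
#' from `M  ISO`, and explicit hydrogen counts from the configured property
#' tag (default `M  ZHC`). Wedge marks (stereo 1/6) are kept on covalent
#' bonds; a wedge on a zero bond is dropped with a warning since zero-order
#' wedge bonds do not exist.
#'
#' @param text molfile content: a single string or a character vector of
#'   lines.
#' @return a `zmol`.
#' @seealso [write_molfile()], [read_sdf()]
#' @export
parse_molfile <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  if (length(lines) < 4L) .parse_error(length(lines), "truncated header")
  title <- trimws(lines[1])
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(trimws(substr(counts, 1, 3))))
  nbonds <- suppressWarnings(as.integer(trimws(substr(counts, 4, 6))))
  if (is.na(natoms) || is.na(nbonds) || natoms < 0L || nbonds < 0L)
    .parse_error(4L, "malformed counts line")

  atoms <- data.frame(
    element = character(natoms), charge = integer(natoms),
    isotope = NA_integer_, hcount = NA_integer_,
    x = numeric(natoms), y = numeric(natoms), z = numeric(natoms)
  )
  for (i in seq_len(natoms)) {
    ln <- 4L + i
    if (ln > length(lines)) .parse_error(ln, "missing atom line")
    line <- lines[ln]
    xyz <- suppressWarnings(as.numeric(c(
      trimws(substr(line, 1, 10)), trimws(substr(line, 11, 20)),
      trimws(substr(line, 21, 30))
    )))
    if (anyNA(xyz)) .parse_error(ln, "cannot read coordinates")
    el <- trimws(substr(line, 32, 34))
    if (!nzchar(el) || !grepl("^[A-Z][a-z]?$", el))
      .parse_error(ln, paste0("invalid element symbol '", el, "'"))
    atoms$x[i] <- xyz[1]; atoms$y[i] <- xyz[2]; atoms$z[i] <- xyz[3]
    atoms$element[i] <- el
  }

  bonds <- data.frame(
    a1 = integer(nbonds), a2 = integer(nbonds), order = integer(nbonds),
    aromatic = logical(nbonds), stereo = rep("none", nbonds)
  )
  for (i in seq_len(nbonds)) {
    ln <- 4L + natoms + i
    if (ln > length(lines)) .parse_error(ln, "missing bond line")
    line <- lines[ln]
    a1 <- .fixed_int(line, 1, 3, ln, "bond atom 1")
    a2 <- .fixed_int(line, 4, 6, ln, "bond atom 2")
    type <- .fixed_int(line, 7, 9, ln, "bond type")
    st <- trimws(substr(line, 10, 12))
    st <- if (nzchar(st)) suppressWarnings(as.integer(st)) else 0L
    if (a1 < 1L || a1 > natoms || a2 < 1L || a2 > natoms)
      .parse_error(ln, "bond references a nonexistent atom")
    if (a1 == a2) .parse_error(ln, "bond endpoints must differ")
    if (type == 8L) {
      message(sprintf("line %d: 'any bond' query type 8 read as zero bond", ln))
      type <- 0L
    }
    if (!type %in% c(0:4)) .parse_error(ln, paste("unsupported bond type", type))
    bonds$a1[i] <- a1; bonds$a2[i] <- a2
    if (type == 4L) {
      bonds$order[i] <- 1L
      bonds$aromatic[i] <- TRUE
    } else bonds$order[i] <- type
    stereo <- if (isTRUE(st == 1L)) "wedge_up" else if (isTRUE(st == 6L)) "wedge_down" else "none"
    if (stereo != "none" && bonds$order[i] == 0L) {
      warning(sprintf("line %d: wedge mark on zero-order bond dropped", ln),
              call. = FALSE)
      stereo <- "none"
    }
    bonds$stereo[i] <- stereo
  }

  tag <- zob_option("hcount_tag")
  prop_from <- 4L + natoms + nbonds + 1L
  for (ln in seq(prop_from, length.out = max(0L, length(lines) - prop_from + 1L))) {
    line <- lines[ln]
    if (startsWith(line, "M  END")) break
    if (!startsWith(line, "M  ")) next
    key <- substr(line, 4, 6)
    fields <- as.integer(strsplit(trimws(substr(line, 7, nchar(line))), "\\s+")[[1]])
    if (key %in% c("CHG", "ISO") || key == substr(tag, 1, 3)) {
      if (anyNA(fields) || length(fields) < 1L || length(fields) != 1L + 2L * fields[1])
        .parse_error(ln, paste("malformed property line", key))
      for (k in seq_len(fields[1])) {
        idx <- fields[2L * k]
        val <- fields[2L * k + 1L]
        if (idx < 1L || idx > natoms)
          .parse_error(ln, "property references a nonexistent atom")
        if (key == "CHG") atoms$charge[idx] <- val
        else if (key == "ISO") atoms$isotope[idx] <- val
        else {
          if (val < 0L) .parse_error(ln, "negative hydrogen count")
          atoms$hcount[idx] <- val
        }
      }
    }
  }

  molecule(atoms, bonds, title = title)
}

#' Write an extended V2000 molfile
#'
#' Inverse of [parse_molfile()]. Zero bonds are written with a literal 0 in
#' the bond-type column; aromatic-flagged single bonds are written as type
#' 4; every atom with an explicit hydrogen count gets one property line
#' `M  <tag>  1 <atom> <count>`. Output is deterministic: two calls on the
#' same molecule produce byte-identical text.
#'
#' @param m a `zmol`.
#' @return a single string containing the molfile block (no trailing
#'   `$$$$`).
#' @export
write_molfile <- function(m) {
  validate_molecule(m)
  a <- m$atoms
  b <- m$bonds
  out <- c(
    m$title,
    "  zobmol  2D",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b))
  )
  for (i in seq_len(nrow(a))) {
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          a$x[i], a$y[i], a$z[i], a$element[i]))
  }
  for (i in seq_len(nrow(b))) {
    type <- if (b$aromatic[i] && b$order[i] == 1L) 4L else b$order[i]
    st <- switch(b$stereo[i], wedge_up = 1L, wedge_down = 6L, 0L)
    out <- c(out, sprintf("%3d%3d%3d%3d", b$a1[i], b$a2[i], type, st))
  }
  chg <- which(a$charge != 0L)
  for (i in chg) out <- c(out, sprintf("M  CHG  1 %3d %3d", i, a$charge[i]))
  iso <- which(!is.na(a$isotope))
  for (i in iso) out <- c(out, sprintf("M  ISO  1 %3d %3d", i, a$isotope[i]))
  tag <- zob_option("hcount_tag")
  hc <- which(!is.na(a$hcount))
  for (i in hc) out <- c(out, sprintf("M  %s  1 %3d %3d", tag, i, a$hcount[i]))
  out <- c(out, "M  END")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read a multi-record SDF
#'
#' Splits on `$$$$` record separators, parses each molfile block with
#' [parse_molfile()] and attaches SDF data items (`> <name>` blocks)
#' verbatim to each molecule's `properties`.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional SDF content given directly (overrides `path`).
#' @return list of `zmol`.
#' @export
read_sdf <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  } else readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0L, utils::head(lines == "$$$$", -1L))))
  mols <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (!any(nzchar(trimws(rec)))) next
    endi <- which(startsWith(rec, "M  END"))
    if (length(endi) == 0L) .parse_error(1L, "record without M  END")
    m <- parse_molfile(rec[seq_len(endi[1])])
    rest <- rec[-seq_len(endi[1])]
    props <- list()
    i <- 1L
    while (i <= length(rest)) {
      if (startsWith(rest[i], ">")) {
        nm <- sub("^>\\s*<([^>]*)>.*$", "\\1", rest[i])
        j <- i + 1L
        vals <- character()
        while (j <= length(rest) && nzchar(trimws(rest[j]))) {
          vals <- c(vals, rest[j])
          j <- j + 1L
        }
        props[[nm]] <- paste(vals, collapse = "\n")
        i <- j + 1L
      } else i <- i + 1L
    }
    m$properties <- props
    mols[[length(mols) + 1L]] <- m
  }
  mols
}

#' Write a multi-record SDF
#'
#' @param mols list of `zmol`.
#' @param path optional output file; when NULL the SDF text is returned.
#' @return the SDF text (invisibly when written to `path`).
#' @export
write_sdf <- function(mols, path = NULL) {
  blocks <- vapply(mols, function(m) {
    txt <- write_molfile(m)
    for (nm in names(m$properties)) {
      txt <- paste0(txt, sprintf(">  <%s>\n%s\n\n", nm, m$properties[[nm]]))
    }
    paste0(txt, "$$$$\n")
  }, character(1))
  out <- paste(blocks, collapse = "")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", out), path)
    return(invisible(out))
  }
  out
}
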