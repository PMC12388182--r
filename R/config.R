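# Package-level configuration: metal list, valence table, hydrogen-count
# property tag, prediction thresholds. Kept in an environment so the CLI and
# tests can override without touching global options().

.zob <- new.env(parent = emptyenv())

.zob_defaults <- function() {
  list(
    # metals whose presence (together with >=1 zero bond) makes a compound
    # organometallic; deduplicated, user-extensible
    metals = c("Hf", "Co", "Zr", "W", "Ni", "Pt", "Os", "Ti", "Rh", "Fe"),
    # single lowest common valence per element; higher valence states need
    # explicit hydrogen counts
    valences = c(C = 4L, N = 3L, P = 3L, O = 2L, S = 2L),
    # molfile property tag for explicit hydrogen counts ("M  <tag> ...")
    hcount_tag = "ZHC",
    # traverse through metal atoms when expanding HOSE spheres
    hose_through_metals = TRUE,
    # prediction reliability: warn if matched depth < warn_spheres or the
    # number of reference examples < min_examples
    warn_spheres = 3L,
    min_examples = 2L,
    # aggregation of matched reference shifts: "mean" or "median"
    aggregate = "mean"
  )
}

.zob_reset <- function() {
  defaults <- .zob_defaults()
  for (nm in names(defaults)) assign(nm, defaults[[nm]], envir = .zob)
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) .zob_reset()

#' Get or set zobmol configuration
#'
#' `zob_option(name)` returns one setting; `zob_options(...)` sets named
#' settings and invisibly returns the previous values, so callers can
#' restore them. Settings: `metals` (character vector), `valences` (named
#' integer vector), `hcount_tag` (property tag used in molfiles),
#' `hose_through_metals` (logical), `warn_spheres`, `min_examples`
#' (integers), `aggregate` ("mean" or "median").
#'
#' @param name setting name.
#' @param ... named settings to change.
#' @return `zob_option`: the setting's value. `zob_options`: previous values
#'   of the changed settings, invisibly.
#' @examples
#' zob_option("metals")
#' old <- zob_options(warn_spheres = 2L)
#' zob_options(warn_spheres = old$warn_spheres)
#' @export
zob_option <- function(name) {
  if (!exists(name, envir = .zob, inherits = FALSE))
    stop("unknown zobmol option: ", name, call. = FALSE)
  get(name, envir = .zob, inherits = FALSE)
}

#' @rdname zob_option
#' @export
zob_options <- function(...) {
  new <- list(...)
  if (length(new) == 0L) {
    return(mget(names(.zob_defaults()), envir = .zob))
  }
  if (is.null(names(new)) || any(names(new) == ""))
    stop("all arguments must be named", call. = FALSE)
  old <- list()
  for (nm in names(new)) {
    old[[nm]] <- zob_option(nm)
    assign(nm, new[[nm]], envir = .zob)
  }
  invisible(old)
}

#' Load configuration from a key/value file
#'
#' Reads a plain-text config file with one `key: value` pair per line
#' (`#` starts a comment). List values are comma-separated; the valence
#' table uses `element=valence` entries, e.g.
#' `valences: C=4, N=3, P=3, O=2, S=2`.
#'
#' @param path path to the config file.
#' @return previous values of the changed settings, invisibly.
#' @export
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  new <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln, call. = FALSE)
    key <- m[2]
    val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    new[[key]] <- switch(key,
      metals = parts,
      valences = {
        kv <- strsplit(parts, "=", fixed = TRUE)
        v <- vapply(kv, function(p) as.integer(trimws(p[2])), integer(1))
        names(v) <- vapply(kv, function(p) trimws(p[1]), character(1))
        v
      },
      hcount_tag = val,
      aggregate = val,
      hose_through_metals = toupper(val) %in% c("TRUE", "YES", "1"),
      warn_spheres = as.integer(val),
      min_examples = as.integer(val),
      stop("unknown config key: ", key, call. = FALSE)
    )
  }
  do.call(zob_options, new)
}
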