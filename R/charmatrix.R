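# Discrete morphological character matrices: taxa x characters with
# missing (?), inapplicable/gap (-) and polymorphic ({01}) cells, a
# per-character ordered (morphocline) flag and a per-taxon active flag.
# NEXUS (DATA/CHARACTERS block) and TNT (xread) dialects are supported.

#' Construct a character matrix
#'
#' @param cells Character matrix, taxa in rows, characters in columns. Cells
#'   are single state symbols (`"0"`..`"9"`), `"?"` (missing), `"-"`
#'   (gap/inapplicable, treated as missing for counting), or polymorphic
#'   sets written `"{01}"` or `"(01)"`.
#' @param taxa Taxon labels; default `rownames(cells)`.
#' @param ordered Logical vector (recycled) flagging ordered characters.
#' @param active Logical vector (recycled) flagging active taxa.
#' @param char_labels Optional character labels; default `"char<i>"`.
#' @param symbols State symbol list; default the digits appearing in `cells`.
#' @return Object of class `character_matrix` with components `taxa`,
#'   `active`, `cells` (normalized: polymorphic cells as `"{..}"` with sorted
#'   states), `ordered`, `char_labels`, `symbols`.
#' @export
character_matrix <- function(cells, taxa = rownames(cells), ordered = FALSE,
                             active = TRUE, char_labels = NULL,
                             symbols = NULL) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  if (is.null(taxa)) stop("taxa labels required")
  stopifnot(length(taxa) == nrow(cells))
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  norm <- normalize_cells(cells)
  if (is.null(symbols)) {
    symbols <- sort(setdiff(unique(unlist(strsplit(norm, ""))),
                            c("?", "-", "{", "}")))
    if (!length(symbols)) symbols <- "0"
  }
  check_cells(norm, symbols)
  ordered <- rep_len(as.logical(ordered), ncol(cells))
  active <- rep_len(as.logical(active), nrow(cells))
  if (is.null(char_labels)) char_labels <- paste0("char", seq_len(ncol(cells)))
  stopifnot(length(char_labels) == ncol(cells))
  dimnames(norm) <- list(taxa, char_labels)
  structure(list(taxa = as.character(taxa), active = active, cells = norm,
                 ordered = ordered, char_labels = as.character(char_labels),
                 symbols = symbols),
            class = "character_matrix")
}

normalize_cells <- function(cells) {
  poly <- grepl("^[({].+[})]$", cells)
  cells[poly] <- vapply(cells[poly], function(x) {
    states <- sort(unique(strsplit(gsub("[(){}]", "", x), "")[[1L]]))
    paste0("{", paste(states, collapse = ""), "}")
  }, character(1))
  cells
}

check_cells <- function(cells, symbols) {
  states <- gsub("[{}]", "", cells)
  ok <- cells %in% c("?", "-") |
    vapply(strsplit(states, ""), function(s) all(s %in% symbols), logical(1))
  if (!all(ok)) {
    stop("cell value(s) outside symbol list: ",
         paste(unique(cells[!ok]), collapse = ", "))
  }
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Character matrix: ", length(x$taxa), " taxa (", sum(x$active),
      " active) x ", ncol(x$cells), " characters (", sum(x$ordered),
      " ordered)\n", sep = "")
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$cells)

# integer state values of one cell; NULL for missing/gap
cell_states <- function(cell) {
  if (cell %in% c("?", "-")) return(NULL)
  as.integer(strsplit(gsub("[{}]", "", cell), "")[[1L]])
}

#' Read a character matrix
#'
#' NEXUS: a single non-interleaved `DATA`/`CHARACTERS` block; `SYMBOLS`,
#' `MISSING`, `GAP` honored; polymorphisms as `(..)` or `{..}`; an optional
#' `ASSUMPTIONS` block `TYPESET` with an `ord:` list (numbers and `a-b`
#' ranges) sets ordered flags. TNT: `xread`, optionally followed by a
#' `ccode + <0-based indices>;` line for ordered characters; polymorphisms
#' as `[..]`.
#'
#' @param path File path.
#' @param format `"nexus"` or `"tnt"`; default guessed from the extension.
#' @return A [character_matrix()].
#' @export
read_matrix <- function(path, format = c("nexus", "tnt")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(format) > 1L) {
    format <- if (grepl("\\.(tnt|ss)$", path, ignore.case = TRUE)) "tnt"
              else "nexus"
  }
  format <- match.arg(format, c("nexus", "tnt"))
  lines <- readLines(path, warn = FALSE)
  if (format == "nexus") parse_nexus(lines) else parse_tnt(lines)
}

split_tokens_keep_sets <- function(x) {
  # splits a sequence string into cells, keeping (..)/{..}/[..] together
  out <- character()
  i <- 1L
  chars <- strsplit(x, "")[[1L]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "{", "[")) {
      close <- c("(" = ")", "{" = "}", "[" = "]")[ch]
      j <- i
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      if (j > length(chars)) stop("unbalanced state set in matrix row")
      out <- c(out, paste0("{", paste(chars[(i + 1L):(j - 1L)], collapse = ""),
                           "}"))
      i <- j + 1L
    } else if (grepl("\\s", ch)) {
      i <- i + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

parse_index_list <- function(txt) {
  toks <- strsplit(trimws(txt), "[ ,]+")[[1L]]
  toks <- toks[nzchar(toks)]
  out <- integer()
  for (tk in toks) {
    if (grepl("^\\d+-\\d+$", tk)) {
      ab <- as.integer(strsplit(tk, "-")[[1L]])
      out <- c(out, seq(ab[1L], ab[2L]))
    } else if (grepl("^\\d+$", tk)) {
      out <- c(out, as.integer(tk))
    } else stop("cannot parse character index: ", tk)
  }
  out
}

parse_nexus <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip comments
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) {
    stop("not a NEXUS file (missing #NEXUS header)")
  }
  dim_m <- regmatches(txt, regexec(
    "DIMENSIONS[^;]*NTAX\\s*=\\s*(\\d+)[^;]*NCHAR\\s*=\\s*(\\d+)", txt,
    ignore.case = TRUE))[[1L]]
  if (length(dim_m) < 3L) stop("malformed NEXUS: DIMENSIONS not found")
  ntax <- as.integer(dim_m[2L]); nchar_ <- as.integer(dim_m[3L])
  missing_ch <- "?"; gap_ch <- "-"
  fmt <- regmatches(txt, regexec("FORMAT([^;]*);", txt, ignore.case = TRUE))[[1L]]
  symbols <- NULL
  if (length(fmt) >= 2L) {
    sym_m <- regmatches(fmt[2L], regexec("SYMBOLS\\s*=\\s*\"([^\"]*)\"",
                                         fmt[2L], ignore.case = TRUE))[[1L]]
    if (length(sym_m) >= 2L) {
      symbols <- strsplit(gsub("\\s", "", sym_m[2L]), "")[[1L]]
    }
    mis_m <- regmatches(fmt[2L], regexec("MISSING\\s*=\\s*(\\S)", fmt[2L],
                                         ignore.case = TRUE))[[1L]]
    if (length(mis_m) >= 2L) missing_ch <- mis_m[2L]
    gap_m <- regmatches(fmt[2L], regexec("GAP\\s*=\\s*(\\S)", fmt[2L],
                                         ignore.case = TRUE))[[1L]]
    if (length(gap_m) >= 2L) gap_ch <- gap_m[2L]
  }
  mat_m <- regmatches(txt, regexec("MATRIX\\s*\n(.*?);", txt,
                                   ignore.case = TRUE))[[1L]]
  if (length(mat_m) < 2L) stop("malformed NEXUS: MATRIX block not found")
  rows <- strsplit(mat_m[2L], "\n")[[1L]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  taxa <- character(); cells <- list()
  for (r in rows) {
    m <- regmatches(r, regexec("^('[^']+'|\\S+)\\s+(.*)$", r))[[1L]]
    if (length(m) < 3L) stop("malformed NEXUS matrix row: ", r)
    taxa <- c(taxa, gsub("^'|'$", "", m[2L]))
    states <- split_tokens_keep_sets(m[3L])
    states[states == missing_ch] <- "?"
    states[states == gap_ch] <- "-"
    cells[[length(cells) + 1L]] <- states
  }
  lens <- lengths(cells)
  if (any(lens != nchar_)) {
    stop("ragged NEXUS matrix: expected ", nchar_, " characters, got ",
         paste(unique(lens[lens != nchar_]), collapse = ","))
  }
  if (length(taxa) != ntax) {
    stop("NEXUS matrix has ", length(taxa), " rows, DIMENSIONS says ", ntax)
  }
  cm <- do.call(rbind, cells)
  rownames(cm) <- taxa
  ordered <- rep(FALSE, nchar_)
  ts_m <- regmatches(txt, regexec("TYPESET[^;]*=\\s*([^;]*);", txt,
                                  ignore.case = TRUE))[[1L]]
  if (length(ts_m) >= 2L) {
    parts <- strsplit(ts_m[2L], ",")[[1L]]
    for (p in parts) {
      kv <- strsplit(p, ":")[[1L]]
      if (length(kv) == 2L && grepl("^\\s*ord\\s*$", kv[1L], ignore.case = TRUE)) {
        idx <- parse_index_list(kv[2L])
        if (any(idx < 1L | idx > nchar_)) stop("TYPESET index out of range")
        ordered[idx] <- TRUE
      }
    }
  }
  character_matrix(cm, taxa = taxa, ordered = ordered, symbols = symbols)
}

parse_tnt <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("'[^']*'", "", txt)  # strip quoted comment
  m <- regmatches(txt, regexec("xread\\s*(\\d+)\\s+(\\d+)\\s*\n(.*?);", txt,
                               ignore.case = TRUE))[[1L]]
  if (length(m) < 4L) stop("malformed TNT file: xread block not found")
  nchar_ <- as.integer(m[2L]); ntax <- as.integer(m[3L])
  rows <- trimws(strsplit(m[4L], "\n")[[1L]])
  rows <- rows[nzchar(rows)]
  taxa <- character(); cells <- list()
  for (r in rows) {
    mm <- regmatches(r, regexec("^(\\S+)\\s+(.*)$", r))[[1L]]
    if (length(mm) < 3L) stop("malformed TNT matrix row: ", r)
    taxa <- c(taxa, mm[2L])
    cells[[length(cells) + 1L]] <- split_tokens_keep_sets(mm[3L])
  }
  lens <- lengths(cells)
  if (any(lens != nchar_)) {
    stop("ragged TNT matrix: expected ", nchar_, " characters per row")
  }
  if (length(taxa) != ntax) {
    stop("TNT matrix has ", length(taxa), " rows, header says ", ntax)
  }
  cm <- do.call(rbind, cells)
  rownames(cm) <- taxa
  ordered <- rep(FALSE, nchar_)
  cc <- regmatches(txt, regexec("ccode\\s*\\+\\s*([-0-9 ]+);", txt,
                                ignore.case = TRUE))[[1L]]
  if (length(cc) >= 2L) {
    idx <- parse_index_list(cc[2L]) + 1L  # TNT indices are 0-based
    if (any(idx < 1L | idx > nchar_)) stop("ccode index out of range")
    ordered[idx] <- TRUE
  }
  character_matrix(cm, taxa = taxa, ordered = ordered)
}

#' Write a character matrix
#'
#' The NEXUS writer emits a DATA block (SYMBOLS, MISSING=?, GAP=-) plus an
#' ASSUMPTIONS/TYPESET block when any character is ordered; the TNT writer
#' emits `xread` plus a `ccode +` line. `read_matrix(write_matrix(m))`
#' reproduces `m` up to whitespace. Inactive taxa are written like any
#' other row (deactivation is an analysis setting, not a file feature).
#'
#' @param matrix A [character_matrix()].
#' @param path Output path.
#' @param format `"nexus"` or `"tnt"`.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(matrix, path, format = c("nexus", "tnt")) {
  stopifnot(inherits(matrix, "character_matrix"))
  format <- match.arg(format)
  rows <- apply(matrix$cells, 1L, function(r) {
    if (format == "tnt") r <- gsub("\\{", "[", gsub("\\}", "]", r))
    paste(r, collapse = "")
  })
  labels <- gsub("\\s", "_", matrix$taxa)
  if (format == "nexus") {
    out <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(matrix$taxa),
                     ncol(matrix$cells)),
             sprintf("FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;",
                     paste(matrix$symbols, collapse = " ")),
             "MATRIX", paste(labels, rows), ";", "END;")
    if (any(matrix$ordered)) {
      out <- c(out, "BEGIN ASSUMPTIONS;",
               sprintf("TYPESET * default = ord: %s;",
                       paste(which(matrix$ordered), collapse = " ")),
               "END;")
    }
  } else {
    out <- c("xread", "'exported character matrix'",
             sprintf("%d %d", ncol(matrix$cells), length(matrix$taxa)),
             paste(labels, rows), ";")
    if (any(matrix$ordered)) {
      out <- c(out, sprintf("ccode + %s;",
                            paste(which(matrix$ordered) - 1L, collapse = " ")))
    }
    out <- c(out, "proc /;")
  }
  writeLines(out, path)
  invisible(path)
}

#' The seven additional cranial characters
#'
#' Definitions and codings of the seven characters added to the base matrix,
#' at their positions in the final 263-character numbering (32, 33, 62, 64,
#' 87, 88, 92). They are scored only for the four study taxa; every other
#' taxon is coded missing on insertion. Inapplicable codings are `"-"`.
#'
#' @return List of definitions, each with `index`, `label`, `bone`,
#'   `description`, `ordered` and `scores` (named by study taxon).
#' @export
new_characters_table3 <- function() {
  sc <- function(dl, ei, dc, cs) {
    c(Desmatochelys_lowii = dl, Eretmochelys_imbricata = ei,
      Dermochelys_coriacea = dc, Chelydra_serpentina = cs)
  }
  list(
    list(index = 32L, label = "postorbital_ventral_recess",
         bone = "postorbital",
         description = "recess on the ventral side of the dorsal part of the postorbital: 0 absent, 1 present",
         ordered = FALSE, scores = sc("1", "0", "0", "1")),
    list(index = 33L, label = "orbit_posterior_notch_position",
         bone = "postorbital",
         description = "position of notch in the posterior orbit margin: 0 at the top, 1 at mid level",
         ordered = FALSE, scores = sc("1", "0", "0", "1")),
    list(index = 62L, label = "epipterygoid_trigeminal_participation",
         bone = "epipterygoid",
         description = "participation of the epipterygoid to the foramen nervi trigemini: 0 absent, 1 present",
         ordered = FALSE, scores = sc("0", "-", "-", "1")),
    list(index = 64L, label = "prootic_parietal_suture_extent",
         bone = "prootic",
         description = "extent of the prootic-parietal suture: 0 very short or absent, 1 long",
         ordered = FALSE, scores = sc("1", "0", "0", "1")),
    list(index = 87L, label = "prootic_dorsomedial_process",
         bone = "prootic",
         description = "dorsomedial process of the prootic in medial view: 0 absent, 1 present",
         ordered = FALSE, scores = sc("-", "0", "0", "1")),
    list(index = 88L, label = "opisthotic_stapediotemporal_participation",
         bone = "opisthotic",
         description = "participation of the opisthotic in the foramen stapedio-temporale: 0 absent, 1 present",
         ordered = FALSE, scores = sc("1", "0", "1", "0")),
    list(index = 92L, label = "quadrate_processus_epipterygoideus",
         bone = "quadrate",
         description = "processus epipterygoideus of the quadrate: 0 absent, 1 present",
         ordered = FALSE, scores = sc("0", "1", "1", "1"))
  )
}

#' Insert new characters into a matrix
#'
#' Character definitions give their positions in the FINAL numbering; columns
#' already in the matrix shift right accordingly, which realizes the dual
#' numbering of the expanded matrix (e.g. old character 74 becomes 78 after
#' the four insertions at 32, 33, 62 and 64). Taxa named in a definition's
#' `scores` get that coding; all other taxa are coded `"?"`.
#'
#' @param matrix A [character_matrix()].
#' @param defs List of definitions as in [new_characters_table3()].
#' @return List with `matrix` (the expanded [character_matrix()]) and
#'   `index_map` (integer vector: `index_map[i]` is the new index of old
#'   character `i`). Re-inserting a definition whose label is already present
#'   is an error.
#' @export
insert_characters <- function(matrix, defs = new_characters_table3()) {
  stopifnot(inherits(matrix, "character_matrix"))
  idx <- vapply(defs, function(d) as.integer(d$index), integer(1))
  labs <- vapply(defs, function(d) as.character(d$label), character(1))
  if (anyDuplicated(idx)) stop("duplicate insertion indices")
  dup <- intersect(labs, matrix$char_labels)
  if (length(dup)) {
    stop("character(s) already inserted: ", paste(dup, collapse = ", "))
  }
  n_old <- ncol(matrix$cells)
  n_new <- n_old + length(defs)
  if (any(idx < 1L | idx > n_new)) stop("insertion index out of range")
  is_insert <- seq_len(n_new) %in% idx
  index_map <- which(!is_insert)        # index_map[old] = new position
  cells <- matrix("?", nrow(matrix$cells), n_new)
  cells[, index_map] <- matrix$cells
  ordered <- logical(n_new)
  ordered[index_map] <- matrix$ordered
  char_labels <- character(n_new)
  char_labels[index_map] <- matrix$char_labels
  for (d in defs) {
    hit <- match(names(d$scores), matrix$taxa)
    cells[hit[!is.na(hit)], d$index] <- unname(d$scores)[!is.na(hit)]
    ordered[d$index] <- isTRUE(d$ordered)
    char_labels[d$index] <- d$label
  }
  out <- character_matrix(cells, taxa = matrix$taxa, ordered = ordered,
                          active = matrix$active, char_labels = char_labels,
                          symbols = union(matrix$symbols,
                                          sort(setdiff(unique(unlist(strsplit(
                                            gsub("[{}]", "", cells), ""))),
                                            c("?", "-")))))
  list(matrix = out, index_map = index_map)
}

#' Built-in recoding patch for Desmatochelys lowii
#'
#' The ten cell updates for *Desmatochelys lowii* motivated by the CT
#' reinterpretation of KUVP 1200, with character indices in the final
#' (263-character) numbering. `"?"` means the cell becomes missing.
#'
#' @return Data frame with columns `taxon`, `index`, `old`, `new`, `note`.
#' @export
dlowii_recoding_patch <- function() {
  data.frame(
    taxon = "Desmatochelys_lowii",
    index = c(8L, 18L, 21L, 78L, 84L, 90L, 96L, 105L, 107L, 109L),
    old = c("0", "1", "1", "1", "1", "0", "0", "0", "1", "0"),
    new = c("?", "0", "0", "0", "0", "1", "1", "2", "?", "?"),
    note = c("prefrontal scutes not observable",
             "pineal foramen is post-burial damage",
             "jugal separated from quadrate by quadratojugal",
             "no median pterygoid ridge",
             "basioccipital tubercles present in MNA V4516",
             "rostrum basisphenoidale rod-like",
             "dorsum sellae high",
             "foramen nervi hypoglossi covered by basioccipital",
             "foramen posterius canalis carotici interni not visible",
             "fenestra perilymphatica not identifiable"),
    stringsAsFactors = FALSE)
}

#' Apply a recoding patch
#'
#' Every entry's current cell must equal its expected old state; otherwise
#' nothing is changed and an error reports the mismatches (this guards
#' against double application and against patching a matrix whose columns
#' were renumbered differently).
#'
#' @param matrix A [character_matrix()].
#' @param patch Data frame as returned by [dlowii_recoding_patch()].
#' @return The patched matrix, with an `audit` attribute logging each change.
#' @export
apply_recoding_patch <- function(matrix, patch = dlowii_recoding_patch()) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (any(patch$index < 1L | patch$index > ncol(matrix$cells))) {
    stop("patch index out of matrix bounds")
  }
  rows <- match(patch$taxon, matrix$taxa)
  if (anyNA(rows)) {
    stop("patch taxon not in matrix: ",
         paste(unique(patch$taxon[is.na(rows)]), collapse = ", "))
  }
  current <- matrix$cells[cbind(rows, patch$index)]
  bad <- current != normalize_cells(patch$old)
  if (any(bad)) {
    stop("expected-state mismatch, patch not applied: ",
         paste(sprintf("%s char %d is '%s', expected '%s'",
                       patch$taxon[bad], patch$index[bad], current[bad],
                       patch$old[bad]), collapse = "; "))
  }
  matrix$cells[cbind(rows, patch$index)] <- normalize_cells(patch$new)
  new_states <- setdiff(unique(unlist(strsplit(gsub("[{}]", "", patch$new),
                                               ""))), c("?", "-"))
  matrix$symbols <- sort(union(matrix$symbols, new_states))
  attr(matrix, "audit") <-
    data.frame(taxon = patch$taxon, index = patch$index,
               from = patch$old, to = patch$new, stringsAsFactors = FALSE)
  matrix
}

#' Built-in list of ordered (morphocline) characters
#'
#' The 37 characters of the final 263-character numbering that form
#' morphoclines and are run ordered.
#'
#' @return Integer vector of length 37.
#' @export
ordered_characters <- function() {
  c(7L, 17L, 22L, 44L, 49L, 52L, 55L, 57L, 59L, 66L, 70L, 71L, 76L, 79L,
    89L, 101L, 106L, 118L, 122L, 128L, 135L, 138L, 144L, 148L, 171L, 174L,
    189L, 191L, 211L, 223L, 225L, 229L, 244L, 256L, 257L, 258L, 262L)
}

#' Flag characters as ordered
#'
#' @param matrix A [character_matrix()].
#' @param indices 1-based character indices to run ordered; default the
#'   built-in 37-entry morphocline list.
#' @return The matrix with the ordered flags set.
#' @export
set_ordered <- function(matrix, indices = ordered_characters()) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (any(indices < 1L | indices > ncol(matrix$cells))) {
    stop("ordered-character index out of range")
  }
  matrix$ordered[indices] <- TRUE
  matrix
}

#' Deactivate taxa
#'
#' Deactivated taxa are kept in the matrix (and written to file) but are
#' excluded from tree length and search.
#'
#' @param matrix A [character_matrix()].
#' @param labels Taxon labels to deactivate.
#' @return The matrix with the active flags cleared.
#' @export
deactivate_taxa <- function(matrix, labels) {
  stopifnot(inherits(matrix, "character_matrix"))
  hit <- match(labels, matrix$taxa)
  if (anyNA(hit)) {
    stop("unknown taxon label(s): ",
         paste(labels[is.na(hit)], collapse = ", "))
  }
  matrix$active[hit] <- FALSE
  matrix
}

#' Active-taxon view of a matrix
#'
#' @param matrix A [character_matrix()].
#' @return A [character_matrix()] restricted to active taxa.
#' @export
active_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  keep <- matrix$active
  character_matrix(matrix$cells[keep, , drop = FALSE],
                   taxa = matrix$taxa[keep], ordered = matrix$ordered,
                   char_labels = matrix$char_labels, symbols = matrix$symbols)
}
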