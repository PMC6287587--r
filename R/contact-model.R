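# Coding scheme for sutural contacts between skull bones.
#
# A contact between two bones is coded by one or more anterior-to-posterior
# segments, each carrying a spatial relation and an ordinal suture depth:
#   spatial: p  parallel            (self-symmetric)
#            o  overlapping      /  u  underlying   (directional complements)
#            c  clasping         /  cb clasped-by   (directional complements)
#            t  vertically transverse (self-symmetric)
#   depth:   s  smooth < if faintly < im moderately < is strongly
#            interfingering; "?" when the suture type cannot be determined
#            (e.g. in poorly preserved fossil material).

#' Spatial relation codes
#'
#' The six spatial relation codes a suture cross-section can take. `o`/`u`
#' and `c`/`cb` describe the same geometry seen from either bone, so they are
#' swapped when a contact is re-expressed from the other bone's point of view
#' (see [spatial_complement()]); `p` and `t` are self-symmetric.
#'
#' @return Character vector of the six codes.
#' @export
#' @examples
#' spatial_relations()
spatial_relations <- function() c("p", "o", "u", "c", "cb", "t")

#' Directional complement of a spatial relation
#'
#' @param code Character vector of spatial relation codes.
#' @return The codes as seen from the other bone: `o` and `u` swap, `c` and
#'   `cb` swap, `p` and `t` are unchanged.
#' @export
#' @examples
#' spatial_complement(c("o", "p", "cb"))
spatial_complement <- function(code) {
  stopifnot(all(code %in% spatial_relations()))
  map <- c(p = "p", o = "u", u = "o", c = "cb", cb = "c", t = "t")
  unname(map[code])
}

#' Suture depth codes and their ordinal levels
#'
#' @return Named integer vector mapping the four depth codes to levels
#'   0 (smooth) through 3 (strongly interfingering). The unknown code `"?"`
#'   is not part of the scale and has no level.
#' @export
depth_levels <- function() c(s = 0L, "if" = 1L, im = 2L, is = 3L)

#' Ordinal level of a depth code
#'
#' @param depth Character vector of depth codes (`s`, `if`, `im`, `is`, `?`).
#' @return Integer vector of levels 0..3; `NA` for the unknown code `"?"`,
#'   which participates in no numeric comparison.
#' @export
#' @examples
#' depth_level(c("s", "is", "?"))
depth_level <- function(depth) {
  ok <- depth %in% c(names(depth_levels()), "?")
  if (!all(ok)) {
    stop("invalid depth code(s): ", paste(unique(depth[!ok]), collapse = ", "))
  }
  out <- depth_levels()[depth]
  unname(out)
}

#' Controlled vocabulary of skull bone names
#'
#' The bones a contact table may refer to. The nasal and the columella are
#' part of the vocabulary but are typically excluded from similarity
#' calculations via the policy's `excluded_bones` (the nasal occurs in only
#' one of the four study taxa).
#'
#' @return Character vector of bone names.
#' @export
bone_vocabulary <- function() {
  c("prefrontal", "frontal", "parietal", "postorbital", "jugal",
    "quadratojugal", "squamosal", "premaxilla", "maxilla", "vomer",
    "palatine", "pterygoid", "epipterygoid", "basisphenoid", "parasphenoid",
    "prootic", "opisthotic", "quadrate", "basioccipital", "exoccipital",
    "supraoccipital", "nasal", "columella")
}

contact_statuses <- function() c("present", "absent", "unknown")

new_segments <- function(spatial = character(), depth = character()) {
  data.frame(spatial = as.character(spatial), depth = as.character(depth),
             stringsAsFactors = FALSE)
}

check_segments <- function(segments) {
  if (!is.data.frame(segments) || !all(c("spatial", "depth") %in% names(segments))) {
    stop("segments must be a data frame with columns 'spatial' and 'depth'")
  }
  bad_sp <- setdiff(unique(segments$spatial), spatial_relations())
  if (length(bad_sp)) {
    stop("invalid spatial code(s): ", paste(bad_sp, collapse = ", "))
  }
  bad_d <- setdiff(unique(segments$depth), c(names(depth_levels()), "?"))
  if (length(bad_d)) {
    stop("invalid depth code(s): ", paste(bad_d, collapse = ", "))
  }
  invisible(segments)
}

#' Canonicalize a bone contact
#'
#' Expresses a contact on the canonical (alphabetically ordered) bone pair.
#' Relations are stored as "`bone_a` acts on `bone_b`", so if the input names
#' arrive in the reversed order every directional code in `segments` is
#' replaced by its complement (`o` by `u`, `c` by `cb`, and vice versa).
#' Canonicalization is idempotent.
#'
#' @param bone_x,bone_y Bone names (distinct, both in `vocabulary`).
#' @param segments Data frame with columns `spatial` and `depth`, the
#'   anterior-to-posterior segments of the contact as seen from `bone_x`.
#'   Must be empty unless `status` is `"present"`.
#' @param status One of `"present"`, `"absent"`, `"unknown"`.
#' @param vocabulary Character vector of admissible bone names.
#' @return A `contact_record`: list with `bone_a` (< `bone_b`), `bone_b`,
#'   `status` and `segments`.
#' @export
#' @examples
#' canonicalize_contact("prefrontal", "frontal",
#'                      data.frame(spatial = "o", depth = "im"))
canonicalize_contact <- function(bone_x, bone_y, segments = new_segments(),
                                 status = "present",
                                 vocabulary = bone_vocabulary()) {
  stopifnot(length(bone_x) == 1L, length(bone_y) == 1L)
  unknown <- setdiff(c(bone_x, bone_y), vocabulary)
  if (length(unknown)) {
    stop("bone name(s) not in vocabulary: ", paste(unknown, collapse = ", "))
  }
  if (bone_x == bone_y) stop("a bone cannot contact itself: ", bone_x)
  status <- match.arg(status, contact_statuses())
  check_segments(segments)
  if (status != "present" && nrow(segments) > 0L) {
    stop("segments must be empty when status is '", status, "'")
  }
  if (status == "present" && nrow(segments) == 0L) {
    stop("a present contact needs at least one segment")
  }
  if (bone_x > bone_y) {
    segments$spatial <- spatial_complement(segments$spatial)
    tmp <- bone_x; bone_x <- bone_y; bone_y <- tmp
  }
  structure(list(bone_a = bone_x, bone_b = bone_y, status = status,
                 segments = segments),
            class = "contact_record")
}

long_columns <- function() {
  c("taxon", "bone_a", "bone_b", "status", "segment_index", "spatial", "depth")
}

canonicalize_rows <- function(data) {
  flip <- data$bone_a > data$bone_b
  if (any(flip)) {
    sp <- data$spatial[flip]
    sp[!is.na(sp)] <- spatial_complement(sp[!is.na(sp)])
    data$spatial[flip] <- sp
    tmp <- data$bone_a[flip]
    data$bone_a[flip] <- data$bone_b[flip]
    data$bone_b[flip] <- tmp
  }
  data[order(data$taxon, data$bone_a, data$bone_b, data$segment_index), ,
       drop = FALSE]
}

#' Construct a contact table
#'
#' The central container of the phenetic analysis: one record per taxon and
#' canonical bone pair, each record either an explicit absence, an explicit
#' unknown, or a present contact with its ordered segments.
#'
#' @param data Data frame in the long one-row-per-segment layout with columns
#'   `taxon`, `bone_a`, `bone_b`, `status`, `segment_index`, `spatial`,
#'   `depth`. Non-present rows leave the last three columns `NA`.
#' @param taxa Optional character vector declaring the taxa covered; defaults
#'   to the taxa appearing in `data`. Declared taxa without records are kept
#'   and flagged by [validate_contact_table()].
#' @param vocabulary Admissible bone names.
#' @return An object of class `contact_table`.
#' @export
contact_table <- function(data, taxa = NULL, vocabulary = bone_vocabulary()) {
  miss <- setdiff(long_columns(), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  data <- data[long_columns()]
  for (col in c("taxon", "bone_a", "bone_b", "status", "spatial", "depth")) {
    data[[col]] <- as.character(data[[col]])
    data[[col]][!is.na(data[[col]]) & data[[col]] == ""] <- NA_character_
  }
  data$segment_index <- suppressWarnings(as.integer(data$segment_index))

  bad_status <- setdiff(unique(data$status), contact_statuses())
  if (length(bad_status)) {
    stop("invalid status value(s): ", paste(bad_status, collapse = ", "))
  }
  if (any(data$bone_a == data$bone_b)) {
    stop("self-contacts are not representable (bone_a == bone_b)")
  }
  pres <- data$status == "present"
  if (any(pres & (is.na(data$spatial) | is.na(data$depth) | is.na(data$segment_index)))) {
    stop("present rows need segment_index, spatial and depth")
  }
  if (any(!pres & (!is.na(data$spatial) | !is.na(data$depth) | !is.na(data$segment_index)))) {
    stop("absent/unknown rows must leave segment fields empty")
  }
  check_segments(new_segments(data$spatial[pres], data$depth[pres]))

  data <- canonicalize_rows(data)
  key <- paste(data$taxon, data$bone_a, data$bone_b, data$segment_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- data[duplicated(key), c("taxon", "bone_a", "bone_b"), drop = FALSE]
    stop("duplicate rows for (taxon, bone pair, segment): ",
         paste(unique(paste(dup$taxon, dup$bone_a, dup$bone_b, sep = "/")),
               collapse = "; "))
  }
  pair_key <- paste(data$taxon, data$bone_a, data$bone_b, sep = "\r")
  n_status <- tapply(data$status, pair_key, function(s) length(unique(s)))
  if (any(n_status > 1L)) {
    stop("conflicting statuses for the same (taxon, bone pair)")
  }
  # within a present record the segment indices must be 1..k
  for (k in unique(pair_key[pres])) {
    idx <- sort(data$segment_index[pair_key == k])
    if (!identical(idx, seq_along(idx))) {
      stop("segment_index must run 1..k within a contact: ", gsub("\r", "/", k))
    }
  }
  taxa <- sort(unique(c(taxa, data$taxon)))
  rownames(data) <- NULL
  structure(list(data = data, taxa = taxa, bone_vocabulary = vocabulary),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  n_rec <- length(unique(paste(x$data$taxon, x$data$bone_a, x$data$bone_b)))
  cat("Bone contact table: ", length(x$taxa), " taxa, ", n_rec,
      " contact records\n", sep = "")
  cat("Taxa: ", paste(x$taxa, collapse = ", "), "\n", sep = "")
  tab <- table(x$data$status[!duplicated(paste(x$data$taxon, x$data$bone_a,
                                               x$data$bone_b))])
  cat("Record statuses: ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Retrieve one contact record
#'
#' @param table A `contact_table`.
#' @param taxon Taxon label.
#' @param bone_x,bone_y Bone pair (any order).
#' @return A `contact_record`, or `NULL` if the pair is not scored for the
#'   taxon.
#' @export
get_contact <- function(table, taxon, bone_x, bone_y) {
  stopifnot(inherits(table, "contact_table"))
  a <- min(bone_x, bone_y); b <- max(bone_x, bone_y)
  rows <- table$data[table$data$taxon == taxon & table$data$bone_a == a &
                       table$data$bone_b == b, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  segs <- new_segments(rows$spatial[!is.na(rows$spatial)],
                       rows$depth[!is.na(rows$depth)])
  structure(list(bone_a = a, bone_b = b, status = rows$status[1L],
                 segments = segs),
            class = "contact_record")
}

#' Bone pairs scored for a taxon
#'
#' @param table A `contact_table`.
#' @param taxon Taxon label.
#' @return Data frame with columns `bone_a`, `bone_b`, `status`, one row per
#'   scored pair.
#' @export
scored_pairs <- function(table, taxon) {
  stopifnot(inherits(table, "contact_table"))
  d <- table$data[table$data$taxon == taxon, , drop = FALSE]
  d <- d[!duplicated(paste(d$bone_a, d$bone_b)), c("bone_a", "bone_b", "status")]
  rownames(d) <- NULL
  d
}

#' Read a contact table from the long tab-separated format
#'
#' One row per segment; columns `taxon`, `bone_a`, `bone_b`,
#' `status` (present/absent/unknown), `segment_index` (1-based, blank for
#' non-present rows), `spatial` (p/o/u/c/cb/t) and `depth` (s/if/im/is/?).
#' Records are canonicalized on read, so a file may list either bone first.
#'
#' @param path File path.
#' @param dialect Only `"long_tsv"` is defined.
#' @param vocabulary Admissible bone names.
#' @return A [contact_table()].
#' @export
read_contact_table <- function(path, dialect = "long_tsv",
                               vocabulary = bone_vocabulary()) {
  dialect <- match.arg(dialect, "long_tsv")
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           na.strings = NULL, fileEncoding = "UTF-8",
                           check.names = FALSE)
  miss <- setdiff(long_columns(), names(raw))
  if (length(miss)) {
    stop("malformed contact file (missing column(s) ",
         paste(miss, collapse = ", "), "): ", path)
  }
  tab <- tryCatch(contact_table(raw, vocabulary = vocabulary),
                  error = function(e) {
                    stop("parse error in ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  issues <- validate_contact_table(tab)
  bad <- issues[issues$issue == "out_of_vocabulary", , drop = FALSE]
  if (nrow(bad)) {
    stop("parse error in ", path, ": bone name(s) not in vocabulary: ",
         paste(unique(bad$detail), collapse = ", "))
  }
  tab
}

#' Write a contact table in the long tab-separated format
#'
#' Writing then re-reading reproduces the table exactly (records are stored
#' canonically); unknown depths are serialized as `"?"`.
#'
#' @param table A `contact_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_contact_table <- function(table, path) {
  stopifnot(inherits(table, "contact_table"))
  out <- table$data
  out$segment_index <- ifelse(is.na(out$segment_index), "",
                              as.character(out$segment_index))
  for (col in c("spatial", "depth")) out[[col]][is.na(out[[col]])] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a contact table
#'
#' Reports structural issues without failing: bones outside the vocabulary,
#' present records with no segments, and declared taxa that carry no records.
#' An empty result means the table is valid.
#'
#' @param table A `contact_table`.
#' @return Data frame with columns `issue`, `taxon`, `detail` (zero rows when
#'   valid).
#' @export
validate_contact_table <- function(table) {
  stopifnot(inherits(table, "contact_table"))
  issues <- list()
  d <- table$data
  oov <- setdiff(unique(c(d$bone_a, d$bone_b)), table$bone_vocabulary)
  for (b in oov) {
    hit <- d$bone_a == b | d$bone_b == b
    issues[[length(issues) + 1L]] <-
      data.frame(issue = "out_of_vocabulary",
                 taxon = unique(d$taxon[hit])[1L], detail = b)
  }
  pair_key <- paste(d$taxon, d$bone_a, d$bone_b, sep = "\r")
  for (k in unique(pair_key)) {
    rows <- d[pair_key == k, , drop = FALSE]
    if (rows$status[1L] == "present" && all(is.na(rows$spatial))) {
      issues[[length(issues) + 1L]] <-
        data.frame(issue = "present_without_segments", taxon = rows$taxon[1L],
                   detail = paste(rows$bone_a[1L], rows$bone_b[1L], sep = "-"))
    }
  }
  empty <- setdiff(table$taxa, unique(d$taxon))
  for (t in empty) {
    issues[[length(issues) + 1L]] <-
      data.frame(issue = "taxon_without_records", taxon = t, detail = "")
  }
  if (!length(issues)) {
    return(data.frame(issue = character(), taxon = character(),
                      detail = character()))
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
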