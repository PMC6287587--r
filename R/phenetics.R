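# Percentage similarity between taxa based on their bone contacts.
#
# Two contacts on the same bone pair are compared segment by segment: any
# difference in spatial relation makes them dissimilar, while suture depth
# only makes them dissimilar when the two depths differ by at least
# `depth_threshold` ordinal categories (default 2: a faintly interfingering
# clasping suture is similar to a moderately interfingering one, but not to
# a strongly interfingering one).

#' Similarity policy
#'
#' Bundles every free choice of the contact-similarity statistic. The
#' defaults follow the coding scheme's published rules where stated and a
#' documented convention where not (see the methods vignette).
#'
#' @param depth_threshold Minimum ordinal category difference at which suture
#'   depth alone makes two segments dissimilar. Default 2.
#' @param unknown_depth How to treat a segment pair in which at least one
#'   depth is unknown (`"?"`): `"treat_as_similar"` scores it on the spatial
#'   relation alone; `"exclude_pair"` drops the whole bone pair from the
#'   comparison.
#' @param both_absent Whether a bone pair absent in both taxa is dropped from
#'   the denominator (`"exclude"`, default) or counted as a shared similarity
#'   (`"count_similar"`).
#' @param multi_segment `"sequence_exact"` compares multi-segment contacts
#'   position by position in anterior-to-posterior order; `"multiset"`
#'   ignores the order and asks for a perfect matching of similar segments.
#' @param excluded_bones Bones whose contacts are removed before comparison
#'   (default the nasal, which occurs in only one study taxon).
#' @param rounding Percentage rounding rule; only
#'   `"nearest_integer_percent"` (half away from zero) is defined.
#' @return An object of class `similarity_policy`.
#' @export
similarity_policy <- function(depth_threshold = 2L,
                              unknown_depth = c("treat_as_similar",
                                                "exclude_pair"),
                              both_absent = c("exclude", "count_similar"),
                              multi_segment = c("sequence_exact", "multiset"),
                              excluded_bones = "nasal",
                              rounding = "nearest_integer_percent") {
  depth_threshold <- as.integer(depth_threshold)
  stopifnot(length(depth_threshold) == 1L, depth_threshold >= 1L)
  structure(list(depth_threshold = depth_threshold,
                 unknown_depth = match.arg(unknown_depth),
                 both_absent = match.arg(both_absent),
                 multi_segment = match.arg(multi_segment),
                 excluded_bones = as.character(excluded_bones),
                 rounding = match.arg(rounding, "nearest_integer_percent")),
            class = "similarity_policy")
}

round_half_up <- function(x) floor(x + 0.5)

#' Are two contact segments similar?
#'
#' `FALSE` as soon as the spatial relations differ. With equal spatial
#' relations, `FALSE` when both depths are known and differ by at least
#' `policy$depth_threshold` categories; otherwise `TRUE`. An unknown depth is
#' resolved by `policy$unknown_depth`: `"treat_as_similar"` gives `TRUE`,
#' `"exclude_pair"` gives `NA` (the caller drops the bone pair).
#'
#' @param a,b Lists (or one-row data frames) with elements `spatial` and
#'   `depth`.
#' @param policy A [similarity_policy()].
#' @return `TRUE`, `FALSE`, or `NA` (only under `unknown_depth =
#'   "exclude_pair"`).
#' @export
#' @examples
#' pol <- similarity_policy()
#' segments_similar(list(spatial = "c", depth = "if"),
#'                  list(spatial = "c", depth = "im"), pol)  # TRUE
#' segments_similar(list(spatial = "c", depth = "if"),
#'                  list(spatial = "c", depth = "is"), pol)  # FALSE
segments_similar <- function(a, b, policy = similarity_policy()) {
  if (a$spatial != b$spatial) return(FALSE)
  la <- depth_level(a$depth); lb <- depth_level(b$depth)
  if (is.na(la) || is.na(lb)) {
    return(if (policy$unknown_depth == "treat_as_similar") TRUE else NA)
  }
  abs(la - lb) < policy$depth_threshold
}

all_segments_similar <- function(sa, sb, policy) {
  # positional comparison; NA propagates as NA (pair excluded)
  res <- vapply(seq_len(nrow(sa)), function(i) {
    segments_similar(list(spatial = sa$spatial[i], depth = sa$depth[i]),
                     list(spatial = sb$spatial[i], depth = sb$depth[i]),
                     policy)
  }, logical(1))
  if (any(is.na(res))) return(NA)
  all(res)
}

multiset_segments_similar <- function(sa, sb, policy) {
  n <- nrow(sa)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  saw_na <- FALSE
  for (p in perms(seq_len(n))) {
    res <- all_segments_similar(sa, sb[p, , drop = FALSE], policy)
    if (is.na(res)) { saw_na <- TRUE; next }
    if (res) return(TRUE)
  }
  if (saw_na) NA else FALSE
}

#' Compare two whole contacts on the same bone pair
#'
#' @param a,b `contact_record`s for the same canonical bone pair.
#' @param policy A [similarity_policy()].
#' @return `"similar"`, `"dissimilar"`, or `"not_comparable"`. Present versus
#'   absent is dissimilar; either status unknown is not comparable; both
#'   absent follows `policy$both_absent`; both present are compared segment
#'   by segment under `policy$multi_segment` (differing segment counts are
#'   dissimilar under `"sequence_exact"`).
#' @export
contacts_similar <- function(a, b, policy = similarity_policy()) {
  if (a$bone_a != b$bone_a || a$bone_b != b$bone_b) {
    stop("records refer to different bone pairs: ",
         paste(a$bone_a, a$bone_b, sep = "-"), " vs ",
         paste(b$bone_a, b$bone_b, sep = "-"))
  }
  if (a$status == "unknown" || b$status == "unknown") return("not_comparable")
  if (a$status == "absent" && b$status == "absent") {
    return(if (policy$both_absent == "count_similar") "similar"
           else "not_comparable")
  }
  if (a$status != b$status) return("dissimilar")
  sa <- a$segments; sb <- b$segments
  if (nrow(sa) != nrow(sb)) return("dissimilar")
  res <- if (policy$multi_segment == "sequence_exact") {
    all_segments_similar(sa, sb, policy)
  } else {
    multiset_segments_similar(sa, sb, policy)
  }
  if (is.na(res)) "not_comparable" else if (res) "similar" else "dissimilar"
}

compare_taxa <- function(table, taxon_a, taxon_b, policy) {
  pa <- scored_pairs(table, taxon_a)
  pb <- scored_pairs(table, taxon_b)
  ka <- paste(pa$bone_a, pa$bone_b, sep = "\r")
  kb <- paste(pb$bone_a, pb$bone_b, sep = "\r")
  shared <- intersect(ka, kb)
  n_sim <- 0L; n_cmp <- 0L
  for (k in shared) {
    bones <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    if (any(bones %in% policy$excluded_bones)) next
    ra <- get_contact(table, taxon_a, bones[1L], bones[2L])
    rb <- get_contact(table, taxon_b, bones[1L], bones[2L])
    verdict <- contacts_similar(ra, rb, policy)
    if (verdict == "not_comparable") next
    n_cmp <- n_cmp + 1L
    if (verdict == "similar") n_sim <- n_sim + 1L
  }
  list(n_compared = n_cmp, n_similar = n_sim)
}

#' Percentage similarity between two taxa
#'
#' The percentage of comparable bone contacts that are similar between two
#' taxa: bone pairs scored in both taxa enter the denominator, minus pairs
#' touching an excluded bone and pairs that are not comparable (unknown
#' status, both-absent under the default policy, or excluded because of an
#' unknown depth under `unknown_depth = "exclude_pair"`). Symmetric in its
#' taxon arguments.
#'
#' @param table A [contact_table()].
#' @param taxon_a,taxon_b Taxon labels present in `table`.
#' @param policy A [similarity_policy()].
#' @return List with `percent` (integer, rounded half away from zero),
#'   `n_compared` and `n_similar`.
#' @export
pairwise_similarity <- function(table, taxon_a, taxon_b,
                                policy = similarity_policy()) {
  stopifnot(inherits(table, "contact_table"))
  for (t in c(taxon_a, taxon_b)) {
    if (!t %in% table$taxa) stop("taxon not in table: ", t)
  }
  cmp <- compare_taxa(table, taxon_a, taxon_b, policy)
  if (cmp$n_compared == 0L) {
    stop("no comparable bone pairs between ", taxon_a, " and ", taxon_b)
  }
  list(percent = round_half_up(100 * cmp$n_similar / cmp$n_compared),
       n_compared = cmp$n_compared, n_similar = cmp$n_similar)
}

#' Taxon-by-taxon similarity matrix
#'
#' Fills every off-diagonal cell with [pairwise_similarity()]; the diagonal
#' is undefined and printed as "-". Pairs with no comparable contacts are
#' flagged in `$degenerate` and left `NA`, never silently zero.
#'
#' @param table A [contact_table()] with at least two taxa.
#' @param policy A [similarity_policy()].
#' @return Object of class `similarity_matrix`: list with `taxa`, `percent`
#'   (symmetric matrix), `n_compared`, `n_similar`, `degenerate` (character
#'   vector of flagged pairs) and the `policy` used.
#' @export
similarity_matrix <- function(table, policy = similarity_policy()) {
  stopifnot(inherits(table, "contact_table"))
  taxa <- table$taxa
  if (length(taxa) < 2L) stop("need at least two taxa")
  k <- length(taxa)
  percent <- matrix(NA_real_, k, k, dimnames = list(taxa, taxa))
  n_cmp <- matrix(NA_integer_, k, k, dimnames = list(taxa, taxa))
  n_sim <- matrix(NA_integer_, k, k, dimnames = list(taxa, taxa))
  degenerate <- character()
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      cmp <- compare_taxa(table, taxa[i], taxa[j], policy)
      if (cmp$n_compared == 0L) {
        degenerate <- c(degenerate, paste(taxa[i], taxa[j], sep = " / "))
        next
      }
      pct <- round_half_up(100 * cmp$n_similar / cmp$n_compared)
      percent[i, j] <- percent[j, i] <- pct
      n_cmp[i, j] <- n_cmp[j, i] <- cmp$n_compared
      n_sim[i, j] <- n_sim[j, i] <- cmp$n_similar
    }
  }
  structure(list(taxa = taxa, percent = percent, n_compared = n_cmp,
                 n_similar = n_sim, degenerate = degenerate, policy = policy),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Bone-contact similarity matrix (", length(x$taxa), " taxa)\n", sep = "")
  disp <- matrix("-", nrow(x$percent), ncol(x$percent),
                 dimnames = dimnames(x$percent))
  off <- !is.na(x$percent)
  disp[off] <- paste0(x$percent[off], "%")
  print(as.data.frame(disp), ...)
  if (length(x$degenerate)) {
    cat("No comparable contacts for: ",
        paste(x$degenerate, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a similarity matrix (and its counts) to TSV
#'
#' @param x A `similarity_matrix`.
#' @param path Output path for the percentage matrix; the per-pair counts
#'   `n_similar/n_compared` go to `<path>` with a `.counts.tsv` suffix added.
#' @return Invisibly, `path`.
#' @export
write_similarity_matrix <- function(x, path) {
  stopifnot(inherits(x, "similarity_matrix"))
  disp <- matrix("-", nrow(x$percent), ncol(x$percent),
                 dimnames = dimnames(x$percent))
  off <- !is.na(x$percent)
  disp[off] <- as.character(x$percent[off])
  utils::write.table(cbind(taxon = rownames(disp), as.data.frame(disp)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- matrix("-", nrow(x$percent), ncol(x$percent),
                   dimnames = dimnames(x$percent))
  counts[off] <- paste0(x$n_similar[off], "/", x$n_compared[off])
  utils::write.table(cbind(taxon = rownames(counts), as.data.frame(counts)),
                     paste0(path, ".counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rank the other taxa by similarity to a focal taxon
#'
#' @param matrix A `similarity_matrix`.
#' @param focal Focal taxon label.
#' @return Data frame with columns `taxon` and `percent`, sorted by
#'   descending similarity, ties broken alphabetically.
#' @export
rank_report <- function(matrix, focal) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  if (!focal %in% matrix$taxa) stop("unknown focal taxon: ", focal)
  others <- setdiff(matrix$taxa, focal)
  pct <- matrix$percent[focal, others]
  out <- data.frame(taxon = others, percent = as.numeric(pct))
  out <- out[order(-out$percent, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
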