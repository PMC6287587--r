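# Independent oracles and small fixture builders shared across tests.
# The oracles re-derive the statistics from first principles, on purpose
# with different code paths than the package implementation.

# ---- contact-table builders ----------------------------------------------

segment_row <- function(taxon, a, b, i, sp, d) {
  data.frame(taxon = taxon, bone_a = a, bone_b = b, status = "present",
             segment_index = i, spatial = sp, depth = d)
}

status_row <- function(taxon, a, b, status) {
  data.frame(taxon = taxon, bone_a = a, bone_b = b, status = status,
             segment_index = NA_integer_, spatial = NA_character_,
             depth = NA_character_)
}

# a random two-taxon contact table over n_pairs bone pairs
random_contact_rows <- function(n_pairs, taxa = c("tA", "tB"),
                                p_absent = 0.2, p_unknown = 0.1,
                                p_unknown_depth = 0.15, p_two_seg = 0.3) {
  vocab <- setdiff(bone_vocabulary(), "columella")
  pairs <- t(utils::combn(sort(vocab), 2L))
  pick <- pairs[sample.int(nrow(pairs), n_pairs), , drop = FALSE]
  rows <- list()
  for (t in taxa) {
    for (i in seq_len(n_pairs)) {
      u <- runif(1)
      if (u < p_absent) {
        rows[[length(rows) + 1L]] <- status_row(t, pick[i, 1], pick[i, 2],
                                                "absent")
      } else if (u < p_absent + p_unknown) {
        rows[[length(rows) + 1L]] <- status_row(t, pick[i, 1], pick[i, 2],
                                                "unknown")
      } else {
        k <- if (runif(1) < p_two_seg) 2L else 1L
        depths <- ifelse(runif(k) < p_unknown_depth, "?",
                         sample(c("s", "if", "im", "is"), k, replace = TRUE))
        rows[[length(rows) + 1L]] <-
          segment_row(t, pick[i, 1], pick[i, 2], seq_len(k),
                      sample(spatial_relations(), k, replace = TRUE), depths)
      }
    }
  }
  do.call(rbind, rows)
}

# ---- phenetic similarity oracle ------------------------------------------

# straight re-derivation of (n_compared, n_similar) from the raw long rows,
# independent of the contact_table accessors
oracle_similarity <- function(rows, taxon_a, taxon_b, policy) {
  seg_ok <- function(sp1, d1, sp2, d2) {
    if (sp1 != sp2) return(FALSE)
    l1 <- switch(d1, s = 0, "if" = 1, im = 2, is = 3, NA)
    l2 <- switch(d2, s = 0, "if" = 1, im = 2, is = 3, NA)
    if (is.na(l1) || is.na(l2)) {
      return(if (policy$unknown_depth == "treat_as_similar") TRUE else NA)
    }
    abs(l1 - l2) < policy$depth_threshold
  }
  canon <- function(df) {
    flip <- df$bone_a > df$bone_b
    comp <- c(p = "p", o = "u", u = "o", c = "cb", cb = "c", t = "t")
    df$spatial[flip & !is.na(df$spatial)] <-
      comp[df$spatial[flip & !is.na(df$spatial)]]
    ba <- pmin(df$bone_a, df$bone_b); bb <- pmax(df$bone_a, df$bone_b)
    df$bone_a <- ba; df$bone_b <- bb
    df
  }
  rows <- canon(rows)
  key <- function(df) paste(df$bone_a, df$bone_b)
  ra <- rows[rows$taxon == taxon_a, ]
  rb <- rows[rows$taxon == taxon_b, ]
  shared <- intersect(unique(key(ra)), unique(key(rb)))
  n_cmp <- 0L; n_sim <- 0L
  for (k in shared) {
    pa <- ra[key(ra) == k, ]
    pb <- rb[key(rb) == k, ]
    if (pa$bone_a[1] %in% policy$excluded_bones ||
        pa$bone_b[1] %in% policy$excluded_bones) next
    sa <- pa$status[1]; sb <- pb$status[1]
    if (sa == "unknown" || sb == "unknown") next
    if (sa == "absent" && sb == "absent") {
      if (policy$both_absent == "count_similar") {
        n_cmp <- n_cmp + 1L; n_sim <- n_sim + 1L
      }
      next
    }
    if (sa != sb) { n_cmp <- n_cmp + 1L; next }
    pa <- pa[order(pa$segment_index), ]
    pb <- pb[order(pb$segment_index), ]
    if (nrow(pa) != nrow(pb)) { n_cmp <- n_cmp + 1L; next }
    if (policy$multi_segment == "sequence_exact") {
      verdicts <- mapply(seg_ok, pa$spatial, pa$depth, pb$spatial, pb$depth)
      if (any(is.na(verdicts))) next
      n_cmp <- n_cmp + 1L
      if (all(verdicts)) n_sim <- n_sim + 1L
    } else {
      n <- nrow(pa)
      perm_list <- combinat_perms(n)
      results <- vapply(perm_list, function(p) {
        v <- mapply(seg_ok, pa$spatial, pa$depth, pb$spatial[p], pb$depth[p])
        if (any(is.na(v))) NA else all(v)
      }, logical(1))
      if (any(results %in% TRUE)) { n_cmp <- n_cmp + 1L; n_sim <- n_sim + 1L }
      else if (all(is.na(results))) next
      else n_cmp <- n_cmp + 1L
    }
  }
  list(n_compared = n_cmp, n_similar = n_sim,
       percent = if (n_cmp > 0) floor(100 * n_sim / n_cmp + 0.5) else NA)
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# ---- parsimony oracle -----------------------------------------------------

# exact minimum steps by enumerating every assignment of states to internal
# nodes (leaves resolve their allowed sets freely)
oracle_char_length <- function(tree, column, ordered = FALSE) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  internals <- sort(unique(tree$edge[, 1][tree$edge[, 1] > ntip]))
  leaf_sets <- lapply(tree$tip.label, function(l) {
    cell <- column[[l]]
    if (cell %in% c("?", "-")) 0:9
    else as.integer(strsplit(gsub("[{}]", "", cell), "")[[1]])
  })
  states <- 0:max(unlist(leaf_sets[vapply(leaf_sets, length, 1L) < 10]), 1)
  grids <- do.call(expand.grid, rep(list(states), length(internals)))
  cost_fn <- if (ordered) function(i, j) abs(i - j) else
    function(i, j) as.integer(i != j)
  best <- Inf
  for (g in seq_len(nrow(grids))) {
    assign_int <- as.integer(grids[g, ])
    names(assign_int) <- internals
    total <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      ps <- assign_int[as.character(p)]
      if (ch > ntip) {
        total <- total + cost_fn(ps, assign_int[as.character(ch)])
      } else {
        total <- total + min(vapply(leaf_sets[[ch]], cost_fn, numeric(1),
                                    i = ps))
      }
    }
    best <- min(best, total)
  }
  as.integer(best)
}

# splits of a phylo tree as canonical "a|b|c" keys (test-side re-derivation)
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character()
  for (cl in pp) {
    side <- sort(labs[cl]); other <- sort(setdiff(labs, side))
    if (length(side) < 2 || length(other) < 2) next
    a <- paste(side, collapse = "|"); b <- paste(other, collapse = "|")
    keys <- c(keys, if (a < b) a else b)
  }
  unique(keys)
}

random_column <- function(tips, n_states = 3, p_missing = 0.1, p_poly = 0.1) {
  cells <- vapply(tips, function(t) {
    u <- runif(1)
    if (u < p_missing) return("?")
    if (u < p_missing + p_poly) {
      st <- sort(sample(0:(n_states - 1), 2))
      return(paste0("{", paste(st, collapse = ""), "}"))
    }
    as.character(sample(0:(n_states - 1), 1))
  }, character(1))
  names(cells) <- tips
  cells
}
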