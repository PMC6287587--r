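# Maximum-parsimony machinery: tree length under Fitch (unordered) and
# linear / ordered (Sankoff with |i-j| costs) characters, consistency and
# retention indices, exhaustive (branch-and-bound) and random-addition +
# TBR heuristic search with backbone constraints, strict consensus.
#
# Trees cross the API as ape "phylo" objects; internally an unrooted binary
# tree is a plain edge matrix over node ids 1..N (tips, in the order of the
# active taxa) and N+1.. (internal), which keeps tree surgery cheap.

INF <- .Machine$integer.max %/% 4L

ut_new <- function(edges, labels) {
  list(N = length(labels), edges = edges, labels = labels)
}

ut_tips <- function(ut) sort(intersect(unique(as.vector(ut$edges)),
                                       seq_len(ut$N)))

ut_from_phylo <- function(phy, labels = NULL) {
  stopifnot(inherits(phy, "phylo"))
  phy <- ape::unroot(phy)
  if (is.null(labels)) labels <- sort(phy$tip.label)
  perm <- match(phy$tip.label, labels)
  if (anyNA(perm)) stop("tree contains tips not in the taxon set")
  N <- length(labels)
  edges <- phy$edge
  # remap: tip i -> perm[i]; internal ids shift to follow N
  remap <- function(v) ifelse(v <= length(phy$tip.label), perm[v],
                              v - length(phy$tip.label) + N)
  edges <- cbind(remap(edges[, 1L]), remap(edges[, 2L]))
  ut_new(edges, labels)
}

ut_children_order <- function(ut, root) {
  # parent pointers, postorder node list and per-node children (at most 2
  # once rooted at a tip) via an iterative DFS from `root`
  e1 <- ut$edges[, 1L]; e2 <- ut$edges[, 2L]
  maxid <- max(e1, e2)
  deg <- integer(maxid)
  nb <- matrix(0L, 3L, maxid)
  for (i in seq_along(e1)) {
    a <- e1[i]; b <- e2[i]
    deg[a] <- deg[a] + 1L; nb[deg[a], a] <- b
    deg[b] <- deg[b] + 1L; nb[deg[b], b] <- a
  }
  parent <- integer(maxid)
  kid1 <- integer(maxid); kid2 <- integer(maxid)
  n_nodes <- sum(deg > 0L)
  order_out <- integer(n_nodes)
  stack <- integer(n_nodes); sp <- 1L; stack[1L] <- root
  parent[root] <- -1L
  k <- 0L
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    k <- k + 1L; order_out[k] <- v
    d <- deg[v]
    for (j in seq_len(d)) {
      w <- nb[j, v]
      if (w != parent[v]) {
        parent[w] <- v
        if (kid1[v] == 0L) kid1[v] <- w else kid2[v] <- w
        sp <- sp + 1L; stack[sp] <- w
      }
    }
  }
  list(post = order_out[k:1L], parent = parent, kid1 = kid1, kid2 = kid2)
}

ut_adjlist <- function(ut) {
  e1 <- ut$edges[, 1L]; e2 <- ut$edges[, 2L]
  maxid <- max(e1, e2)
  adj <- vector("list", maxid)
  for (i in seq_along(e1)) {
    adj[[e1[i]]] <- c(adj[[e1[i]]], e2[i])
    adj[[e2[i]]] <- c(adj[[e2[i]]], e1[i])
  }
  adj
}

canon_newick <- function(ut) {
  tips <- ut_tips(ut)
  r <- tips[1L]
  adj <- ut_adjlist(ut)
  ser <- function(v, p) {
    kids <- setdiff(adj[[v]], p)
    if (!length(kids)) return(ut$labels[v])
    parts <- sort(vapply(kids, ser, character(1), p = v))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0("(", ser(adj[[r]][1L], r), ",", ut$labels[r], ");")
}

ut_to_phylo <- function(ut) {
  phy <- ape::read.tree(text = canon_newick(ut))
  ape::unroot(phy)
}

# ---- character data preparation ------------------------------------------

# cd: taxa; u_masks (tips x k_u integer bitmasks); u_index (char indices);
# o_allowed (list per ordered char of tips x (smax+1) logical); o_index
prep_chardata <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  am <- active_matrix(matrix)
  n <- nrow(am$cells); k <- ncol(am$cells)
  all_states <- suppressWarnings(as.integer(am$symbols))
  if (anyNA(all_states)) stop("non-numeric state symbols are not supported")
  full_mask <- sum(bitwShiftL(1L, all_states))
  u_idx <- which(!am$ordered); o_idx <- which(am$ordered)
  u_masks <- matrix(0L, n, length(u_idx))
  for (jj in seq_along(u_idx)) {
    col <- am$cells[, u_idx[jj]]
    u_masks[, jj] <- vapply(col, function(cell) {
      st <- cell_states(cell)
      if (is.null(st)) full_mask else sum(bitwShiftL(1L, st))
    }, integer(1))
  }
  o_allowed <- vector("list", length(o_idx))
  for (jj in seq_along(o_idx)) {
    col <- am$cells[, o_idx[jj]]
    smax <- max(c(0L, unlist(lapply(col, cell_states))))
    allow <- matrix(TRUE, n, smax + 1L)
    for (i in seq_len(n)) {
      st <- cell_states(col[i])
      if (!is.null(st)) {
        allow[i, ] <- FALSE
        allow[i, st + 1L] <- TRUE
      }
    }
    o_allowed[[jj]] <- allow
  }
  list(taxa = am$taxa, n_char = k, u_index = u_idx, o_index = o_idx,
       u_masks = u_masks, o_allowed = o_allowed, cells = am$cells,
       ordered = am$ordered)
}

# minimum over t of (|s-t| + f[t]) for all s, linear costs
linear_min_conv <- function(f) {
  S <- length(f)
  if (S > 1L) {
    for (t in 2:S) f[t] <- min(f[t], f[t - 1L] + 1L)
    for (t in (S - 1L):1L) f[t] <- min(f[t], f[t + 1L] + 1L)
  }
  f
}

# per-character steps of an unrooted tree; tip row i of cd corresponds to
# tip id tip_map[i] in the ut (tip_map = match(cd$taxa, ut$labels))
score_ut <- function(ut, cd, per_char = FALSE, tips = NULL) {
  if (is.null(tips)) tips <- ut_tips(ut)
  rows <- match(ut$labels[tips], cd$taxa)
  root <- tips[1L]
  trav <- ut_children_order(ut, root)
  post <- trav$post
  maxid <- max(post)
  ku <- ncol(cd$u_masks)
  steps_u <- integer(ku)
  root_child <- trav$kid1[root]
  if (ku) {
    M <- matrix(0L, maxid, ku)
    M[tips, ] <- cd$u_masks[rows, , drop = FALSE]
    for (v in post) {
      if (v <= ut$N) next
      a <- trav$kid1[v]; b <- trav$kid2[v]
      I <- bitwAnd(M[a, ], M[b, ])
      z <- I == 0L
      steps_u <- steps_u + z
      M[v, ] <- ifelse(z, bitwOr(M[a, ], M[b, ]), I)
    }
    z <- bitwAnd(M[root, ], M[root_child, ]) == 0L
    steps_u <- steps_u + z
  }
  steps_o <- integer(length(cd$o_allowed))
  for (jj in seq_along(cd$o_allowed)) {
    allow <- cd$o_allowed[[jj]]
    S <- ncol(allow)
    C <- matrix(0L, maxid, S)
    C[tips, ] <- ifelse(allow[rows, , drop = FALSE], 0L, INF)
    for (v in post) {
      if (v <= ut$N) next
      C[v, ] <- pmin(linear_min_conv(C[trav$kid1[v], ]), INF) +
        pmin(linear_min_conv(C[trav$kid2[v], ]), INF)
    }
    steps_o[jj] <- min(C[root, ] + linear_min_conv(C[root_child, ]))
  }
  if (!per_char) return(sum(steps_u) + sum(steps_o))
  s <- integer(cd$n_char)
  s[cd$u_index] <- steps_u
  s[cd$o_index] <- steps_o
  s
}

# ---- public scoring -------------------------------------------------------

#' Parsimony length of a single character on a tree
#'
#' The minimum number of state changes the tree requires for one character.
#' Unordered characters cost 1 per change (Fitch); ordered characters cost
#' `|i - j|` for a change from state `i` to `j` (linear Sankoff). Missing
#' (`"?"`) and gap (`"-"`) leaves never force changes; polymorphic cells
#' (`"{01}"`) may resolve to any listed state at no cost. The result does
#' not depend on rooting.
#'
#' @param tree A `phylo` tree whose tips are the scored taxa.
#' @param column Named character vector of cell values (names = tip labels).
#' @param ordered Logical: score with linear costs on the ordered scale?
#' @return Integer number of steps.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' char_length(tr, c(A = "0", B = "0", C = "1", D = "1"))        # 1
#' char_length(ape::read.tree(text = "(A,B);"),
#'             c(A = "0", B = "2"), ordered = TRUE)              # 2
char_length <- function(tree, column, ordered = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 2L) {
    # a 2-leaf tree has a single edge; score directly
    st <- lapply(column[tree$tip.label], cell_states)
    if (anyNA(match(tree$tip.label, names(column)))) {
      stop("column does not cover all leaves")
    }
    if (any(vapply(st, is.null, logical(1)))) return(0L)
    if (ordered) {
      return(as.integer(min(abs(outer(st[[1L]], st[[2L]], "-")))))
    }
    return(as.integer(!length(intersect(st[[1L]], st[[2L]]))))
  }
  if (anyNA(match(tree$tip.label, names(column)))) {
    stop("column does not cover all leaves")
  }
  m <- character_matrix(matrix(column[tree$tip.label], ncol = 1L,
                               dimnames = list(tree$tip.label, "char1")),
                        ordered = ordered)
  cd <- prep_chardata(m)
  ut <- ut_from_phylo(tree, labels = cd$taxa)
  as.integer(score_ut(ut, cd))
}

char_min_steps <- function(cells, ordered) {
  # minimum conceivable steps, from determinate cells only
  det <- lapply(cells, cell_states)
  det <- unlist(det[lengths(det) == 1L])
  if (length(det) < 2L) return(0L)
  if (ordered) max(det) - min(det) else length(unique(det)) - 1L
}

char_star_steps <- function(cells, ordered) {
  # length on a star tree: best single ancestral state
  sets <- lapply(cells, cell_states)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  if (!length(sets)) return(0L)
  states <- 0:9
  cost <- vapply(states, function(a) {
    sum(vapply(sets, function(s) {
      if (ordered) min(abs(a - s)) else as.integer(!(a %in% s))
    }, numeric(1)))
  }, numeric(1))
  as.integer(min(cost))
}

char_informative <- function(cells) {
  det <- lapply(cells, cell_states)
  det <- unlist(det[lengths(det) == 1L])
  if (length(det) < 2L) return(FALSE)
  sum(table(det) >= 2L) >= 2L
}

#' Tree length report with consistency and retention indices
#'
#' Scores every character of the matrix on the tree (honoring the ordered
#' flags) and reports the total length `L`, the per-character steps `s`,
#' minima `m` (the fewest steps any tree could need) and star-tree maxima
#' `g`, and the summary indices CI = sum(m)/L and
#' RI = (sum(g) - L)/(sum(g) - sum(m)). Minima are computed from
#' determinate cells, so polymorphic cells never inflate them. With an
#' all-constant matrix (L = 0) or sum(g) = sum(m) the indices are undefined
#' and reported as `NA`.
#'
#' @param tree A `phylo` tree over exactly the active taxa of `matrix`.
#' @param matrix A [character_matrix()].
#' @param exclude_uninformative Drop parsimony-uninformative characters from
#'   the index sums (the total length `L` still counts every character)?
#' @return Object of class `length_report`.
#' @export
tree_length <- function(tree, matrix, exclude_uninformative = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "character_matrix"))
  cd <- prep_chardata(matrix)
  if (!setequal(tree$tip.label, cd$taxa)) {
    stop("tree leaves and active matrix taxa differ")
  }
  ut <- ut_from_phylo(tree, labels = cd$taxa)
  s <- score_ut(ut, cd, per_char = TRUE)
  k <- cd$n_char
  m <- integer(k); g <- integer(k); info <- logical(k)
  for (j in seq_len(k)) {
    col <- cd$cells[, j]
    m[j] <- char_min_steps(col, cd$ordered[j])
    g[j] <- char_star_steps(col, cd$ordered[j])
    info[j] <- char_informative(col)
  }
  keep <- if (exclude_uninformative) info else rep(TRUE, k)
  L <- sum(s)
  Lk <- sum(s[keep]); mk <- sum(m[keep]); gk <- sum(g[keep])
  ci <- if (Lk > 0) mk / Lk else NA_real_
  ri <- if (gk > mk) (gk - Lk) / (gk - mk) else NA_real_
  structure(list(L = L, steps = s, min_steps = m, star_steps = g,
                 informative = info, CI = ci, RI = ri,
                 exclude_uninformative = exclude_uninformative),
            class = "length_report")
}

#' @export
print.length_report <- function(x, ...) {
  cat("Tree length: ", x$L, " steps over ", length(x$steps), " characters\n",
      sep = "")
  cat("CI = ", ifelse(is.na(x$CI), "undefined", format(round(x$CI, 3))),
      ", RI = ", ifelse(is.na(x$RI), "undefined", format(round(x$RI, 3))),
      if (x$exclude_uninformative) " (uninformative characters excluded)",
      "\n", sep = "")
  invisible(x)
}

# ---- constraints ----------------------------------------------------------

ut_splits <- function(ut, within = NULL) {
  # non-trivial splits as canonical label-set keys, optionally restricted to
  # the label subset `within`
  tips <- ut_tips(ut)
  labs <- ut$labels
  if (is.null(within)) within <- labs[tips]
  root <- tips[1L]
  trav <- ut_children_order(ut, root)
  below <- vector("list", max(trav$post))
  keys <- character()
  for (v in trav$post) {
    if (v <= ut$N) {
      below[[v]] <- labs[v]
    } else {
      below[[v]] <- c(below[[trav$kid1[v]]], below[[trav$kid2[v]]])
      side <- intersect(below[[v]], within)
      other <- setdiff(within, side)
      if (length(side) >= 2L && length(other) >= 2L) {
        a <- paste(sort(side), collapse = "|")
        b <- paste(sort(other), collapse = "|")
        keys <- c(keys, if (a < b) a else b)
      }
    }
  }
  unique(keys)
}

phylo_splits <- function(phy, within = NULL) {
  # splits of a possibly non-binary tree, restricted to `within`
  phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  if (is.null(within)) within <- phy$tip.label
  post <- ape::reorder.phylo(phy, "postorder")$edge
  below <- vector("list", max(post))
  for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
  keys <- character()
  for (i in seq_len(nrow(post))) {
    p <- post[i, 1L]; ch <- post[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
    if (ch > ntip) {
      side <- intersect(below[[ch]], within)
      other <- setdiff(within, side)
      if (length(side) >= 2L && length(other) >= 2L) {
        a <- paste(sort(side), collapse = "|")
        b <- paste(sort(other), collapse = "|")
        keys <- c(keys, if (a < b) a else b)
      }
    }
  }
  unique(keys)
}

constraint_prep <- function(constraint) {
  stopifnot(inherits(constraint, "phylo"))
  list(taxa = constraint$tip.label, tree = constraint)
}

ut_satisfies <- function(ut, cons) {
  present <- ut$labels[ut_tips(ut)]
  common <- intersect(cons$taxa, present)
  if (length(common) < 4L) return(TRUE)
  need <- phylo_splits(cons$tree, within = common)
  if (!length(need)) return(TRUE)
  have <- ut_splits(ut, within = common)
  all(need %in% have)
}

#' Does a tree display a backbone constraint?
#'
#' Backbone semantics: the tree, restricted to the taxa of the constraint,
#' must display every bipartition of the (possibly non-binary) constraint
#' tree; taxa absent from the constraint ("floaters") may attach anywhere.
#'
#' @param tree A `phylo` tree.
#' @param constraint A `phylo` tree over a subset of the tree's taxa.
#' @return `TRUE` or `FALSE`.
#' @export
satisfies_constraint <- function(tree, constraint) {
  stopifnot(inherits(tree, "phylo"))
  ut <- ut_from_phylo(tree)
  ut_satisfies(ut, constraint_prep(constraint))
}

# ---- tree surgery ---------------------------------------------------------

ut_base3 <- function(tip_ids, N, labels) {
  inner <- max(N, tip_ids) + 1L
  ut_new(cbind(rep(inner, 3L), tip_ids), labels)
}

ut_add_tip <- function(ut, tip, edge_i) {
  e <- ut$edges[edge_i, ]
  w <- max(ut$N, ut$edges) + 1L
  edges <- rbind(ut$edges[-edge_i, , drop = FALSE],
                 c(e[1L], w), c(w, e[2L]), c(w, tip))
  ut_new(edges, ut$labels)
}

reach <- function(edges, start) {
  nodes <- start
  repeat {
    hit <- edges[, 1L] %in% nodes | edges[, 2L] %in% nodes
    nxt <- unique(c(nodes, as.vector(edges[hit, , drop = FALSE])))
    if (length(nxt) == length(nodes)) return(nodes)
    nodes <- nxt
  }
}

suppress_node <- function(edges, v) {
  # remove a degree-2 node, joining its two neighbors
  hit <- which(edges[, 1L] == v | edges[, 2L] == v)
  nb <- setdiff(as.vector(edges[hit, , drop = FALSE]), v)
  rbind(edges[-hit, , drop = FALSE], nb)
}

tbr_neighbors <- function(ut) {
  out <- list()
  N <- ut$N
  m <- nrow(ut$edges)
  for (e in seq_len(m)) {
    u <- ut$edges[e, 1L]; v <- ut$edges[e, 2L]
    rest <- ut$edges[-e, , drop = FALSE]
    compA <- reach(rest, u)
    inA <- rest[, 1L] %in% compA
    edgesA <- rest[inA, , drop = FALSE]
    edgesB <- rest[!inA, , drop = FALSE]
    freed <- integer()
    if (u > N) { edgesA <- suppress_node(edgesA, u); freed <- c(freed, u) }
    if (v > N) { edgesB <- suppress_node(edgesB, v); freed <- c(freed, v) }
    pointsA <- if (nrow(edgesA) == 0L) list(u) else
      lapply(seq_len(nrow(edgesA)), function(i) edgesA[i, ])
    pointsB <- if (nrow(edgesB) == 0L) list(v) else
      lapply(seq_len(nrow(edgesB)), function(i) edgesB[i, ])
    for (pa in pointsA) {
      for (pb in pointsB) {
        ea <- edgesA; eb <- edgesB; ids <- freed
        if (length(pa) == 2L) {
          wa <- ids[1L]; ids <- ids[-1L]
          ea <- rbind(ea[!(ea[, 1L] == pa[1L] & ea[, 2L] == pa[2L]), ,
                         drop = FALSE], c(pa[1L], wa), c(wa, pa[2L]))
          enda <- wa
        } else enda <- pa
        if (length(pb) == 2L) {
          wb <- ids[1L]
          eb <- rbind(eb[!(eb[, 1L] == pb[1L] & eb[, 2L] == pb[2L]), ,
                         drop = FALSE], c(pb[1L], wb), c(wb, pb[2L]))
          endb <- wb
        } else endb <- pb
        out[[length(out) + 1L]] <- ut_new(rbind(ea, eb, c(enda, endb)),
                                          ut$labels)
      }
    }
  }
  out
}

# ---- search ---------------------------------------------------------------

#' Exhaustive parsimony search
#'
#' Enumerates every unrooted binary topology over the active taxa
#' (branch-and-bound: partial trees longer than the best complete tree are
#' pruned, which cannot discard an optimum since adding a leaf never
#' shortens a tree) and returns all optimal trees.
#'
#' @param matrix A [character_matrix()] with 3 to 9 active taxa.
#' @return List with `length` (best total steps) and `trees` (list of
#'   `phylo`, one per optimal topology).
#' @export
exhaustive_search <- function(matrix) {
  cd <- prep_chardata(matrix)
  N <- length(cd$taxa)
  if (N < 3L) stop("need at least 3 active taxa")
  if (N > 9L) stop("exhaustive search is limited to 9 taxa (", N, " given)")
  best <- Inf
  best_trees <- list()
  rec <- function(ut, nxt) {
    s <- score_ut(ut, cd)
    if (s > best) return()
    if (nxt > N) {
      if (s < best) {
        best <<- s
        best_trees <<- list(ut)
      } else {
        best_trees[[length(best_trees) + 1L]] <<- ut
      }
      return()
    }
    for (e in seq_len(nrow(ut$edges))) rec(ut_add_tip(ut, nxt, e), nxt + 1L)
  }
  rec(ut_base3(1:3, N, cd$taxa), 4L)
  # re-filter: ties found before a later improvement are discarded above,
  # but equal-score trees found before `best` dropped need a final check
  keep <- vapply(best_trees, function(u) score_ut(u, cd) == best, logical(1))
  best_trees <- best_trees[keep]
  list(length = as.integer(best), trees = lapply(best_trees, ut_to_phylo))
}

#' Heuristic parsimony search
#'
#' Random-addition-sequence starting trees followed by tree bisection and
#' reconnection (TBR) hill climbing. Each replicate draws a random taxon
#' addition order, builds a starting tree greedily, then applies the best
#' improving TBR rearrangement until none exists; trees of equal length
#' reachable from the optimum are pooled (bounded plateau walk). Trees
#' violating the backbone constraint are never accepted at any stage.
#' The same seed reproduces the same tree set exactly.
#'
#' @param matrix A [character_matrix()] with at least 4 active taxa.
#' @param n_replicates Number of random addition sequences.
#' @param seed Integer seed for the addition orders.
#' @param constraint Optional backbone constraint (`phylo` over a subset of
#'   the active taxa).
#' @param plateau_cap Maximum number of equal-length trees explored per
#'   replicate when pooling optimal trees.
#' @return List with `length`, `trees` (unique optimal `phylo` trees) and
#'   `newicks` (their canonical Newick strings).
#' @export
heuristic_search <- function(matrix, n_replicates = 10L, seed = 1L,
                             constraint = NULL, plateau_cap = 100L) {
  cd <- prep_chardata(matrix)
  N <- length(cd$taxa)
  if (N < 4L) stop("need at least 4 active taxa")
  cons <- if (!is.null(constraint)) {
    cp <- constraint_prep(constraint)
    missing_taxa <- setdiff(cp$taxa, cd$taxa)
    if (length(missing_taxa)) {
      stop("constraint taxa not in matrix: ",
           paste(missing_taxa, collapse = ", "))
    }
    cp
  } else NULL
  ok <- function(ut) is.null(cons) || ut_satisfies(ut, cons)

  pool <- new.env(parent = emptyenv())
  pool_best <- Inf
  add_to_pool <- function(ut, s) {
    if (s < pool_best) {
      rm(list = ls(pool), envir = pool)
      pool_best <<- s
    }
    if (s == pool_best) assign(canon_newick(ut), ut, envir = pool)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (rep_i in seq_len(n_replicates)) {
    ord <- sample.int(N)
    ut <- ut_base3(ord[1:3], N, cd$taxa)
    feasible <- TRUE
    for (t in ord[-(1:3)]) {
      cand_best <- NULL; cand_score <- Inf
      for (e in seq_len(nrow(ut$edges))) {
        cand <- ut_add_tip(ut, t, e)
        if (!ok(cand)) next
        s <- score_ut(cand, cd)
        if (s < cand_score) { cand_score <- s; cand_best <- cand }
      }
      if (is.null(cand_best)) { feasible <- FALSE; break }
      ut <- cand_best
    }
    if (!feasible) {
      stop("backbone constraint admits no placement for some taxon")
    }
    all_tips <- seq_len(N)
    cur <- score_ut(ut, cd, tips = all_tips)
    repeat {
      nbs <- tbr_neighbors(ut)
      improved <- FALSE
      for (nb in nbs) {
        s <- score_ut(nb, cd, tips = all_tips)
        if (s < cur && ok(nb)) { ut <- nb; cur <- s; improved <- TRUE; break }
      }
      if (!improved) break
    }
    # plateau: collect equal-length trees reachable from the local optimum
    frontier <- list(ut)
    seen <- canon_newick(ut)
    add_to_pool(ut, cur)
    while (length(frontier) && length(seen) < plateau_cap) {
      nxt <- list()
      for (f in frontier) {
        for (nb in tbr_neighbors(f)) {
          if (score_ut(nb, cd, tips = all_tips) != cur) next
          key <- canon_newick(nb)
          if (key %in% seen) next
          if (!ok(nb)) next
          seen <- c(seen, key)
          add_to_pool(nb, cur)
          nxt[[length(nxt) + 1L]] <- nb
          if (length(seen) >= plateau_cap) break
        }
        if (length(seen) >= plateau_cap) break
      }
      frontier <- nxt
    }
  }
  keys <- sort(ls(pool))
  trees <- lapply(keys, function(k) ut_to_phylo(get(k, envir = pool)))
  list(length = as.integer(pool_best), trees = trees, newicks = keys)
}

# ---- consensus and pruning ------------------------------------------------

#' Strict consensus of a set of trees
#'
#' Retains exactly the bipartitions common to every input tree; the result
#' may be non-binary.
#'
#' @param trees List of `phylo` trees (or a `multiPhylo`) over identical
#'   leaf sets.
#' @return A `phylo` tree.
#' @export
strict_consensus <- function(trees) {
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L)
  labs <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!setequal(tr$tip.label, labs) ||
        length(tr$tip.label) != length(labs)) {
      stop("trees have different leaf sets")
    }
  }
  if (length(trees) == 1L) return(trees[[1L]])
  shared <- Reduce(intersect, lapply(trees, phylo_splits))
  t0 <- labs[1L]
  # express each shared split as the clade not containing the anchor tip
  clades <- lapply(shared, function(k) {
    side <- strsplit(k, "|", fixed = TRUE)[[1L]]
    if (t0 %in% side) setdiff(labs, side) else side
  })
  build <- function(tipset, clades) {
    inside <- clades[vapply(clades, function(cl) all(cl %in% tipset) &&
                              length(cl) < length(tipset), logical(1))]
    # maximal clades within tipset
    maximal <- inside[vapply(seq_along(inside), function(i) {
      !any(vapply(seq_along(inside), function(j) {
        i != j && all(inside[[i]] %in% inside[[j]])
      }, logical(1)))
    }, logical(1))]
    covered <- unlist(maximal)
    parts <- c(
      vapply(maximal, function(cl) build(cl, inside), character(1)),
      setdiff(tipset, covered))
    if (length(parts) == 1L) return(parts)
    paste0("(", paste(sort(parts), collapse = ","), ")")
  }
  txt <- paste0("(", build(setdiff(labs, t0), clades), ",", t0, ");")
  ape::unroot(ape::read.tree(text = txt))
}

#' Prune taxa from a tree
#'
#' Removes the given leaves and suppresses the resulting degree-2 nodes.
#'
#' @param tree A `phylo` tree.
#' @param labels Leaf labels to remove (a strict subset of the leaves; at
#'   least 3 leaves must remain).
#' @return The pruned `phylo` tree.
#' @export
prune_taxa <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(labels)) return(tree)
  bad <- setdiff(labels, tree$tip.label)
  if (length(bad)) stop("not leaves of the tree: ", paste(bad, collapse = ", "))
  if (length(tree$tip.label) - length(labels) < 3L) {
    stop("pruning would leave fewer than 3 leaves")
  }
  ape::drop.tip(tree, labels)
}
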