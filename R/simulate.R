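# Seeded generators: random trees, contact tables evolved along a tree, and
# discrete character matrices, so every stage of the pipeline can be tested
# without external data. The contact evolution model is deliberately
# minimal: per-branch Poisson event counts for presence toggles, spatial
# relation switches and single-step depth moves on the ordinal scale.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random binary tree
#'
#' A rooted binary tree with branch lengths drawn uniformly on
#' [0.1, 1.9] (mean 1), fully determined by the seed.
#'
#' @param n_taxa Number of tips (at least 2).
#' @param seed Integer seed.
#' @param labels Optional tip labels; default `t1..tn`.
#' @return A `phylo` tree.
#' @export
random_tree <- function(n_taxa, seed, labels = NULL) {
  if (n_taxa < 2L) stop("need at least 2 taxa")
  if (is.null(labels)) labels <- paste0("t", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = TRUE, tip.label = labels,
                     br = function(k) stats::runif(k, 0.1, 1.9))
    tr
  })
}

#' Contact evolution model
#'
#' Rates are expected event counts per contact per unit branch length.
#'
#' @param rate_spatial_switch Spatial relation switches (a random segment is
#'   resampled uniformly over the six codes).
#' @param rate_depth_step Single-step depth moves (+1 or -1, clipped to the
#'   0..3 scale) of a random segment.
#' @param rate_gain_loss Presence toggles of the whole contact.
#' @param n_pairs Number of bone pairs in the ancestral table.
#' @param p_multi_segment Probability an ancestral present contact has two
#'   segments rather than one.
#' @param seed Integer seed.
#' @return Object of class `contact_evolution_model`.
#' @export
contact_evolution_model <- function(rate_spatial_switch = 0.3,
                                    rate_depth_step = 0.3,
                                    rate_gain_loss = 0.1,
                                    n_pairs = 50L,
                                    p_multi_segment = 0.2,
                                    seed = 1L) {
  stopifnot(rate_spatial_switch >= 0, rate_depth_step >= 0,
            rate_gain_loss >= 0, n_pairs >= 1L,
            p_multi_segment >= 0, p_multi_segment <= 1)
  structure(list(rate_spatial_switch = rate_spatial_switch,
                 rate_depth_step = rate_depth_step,
                 rate_gain_loss = rate_gain_loss,
                 n_pairs = as.integer(n_pairs),
                 p_multi_segment = p_multi_segment,
                 seed = as.integer(seed)),
            class = "contact_evolution_model")
}

draw_contact_state <- function(p_multi) {
  status <- sample(c("present", "absent"), 1L)
  if (status == "absent") return(list(status = "absent", segments = NULL))
  k <- if (stats::runif(1) < p_multi) 2L else 1L
  list(status = "present",
       segments = data.frame(spatial = sample(spatial_relations(), k,
                                              replace = TRUE),
                             depth = sample(names(depth_levels()), k,
                                            replace = TRUE)))
}

evolve_contact <- function(state, bl, model) {
  n_gl <- stats::rpois(1L, model$rate_gain_loss * bl)
  for (i in seq_len(n_gl)) {
    if (state$status == "present") {
      state <- list(status = "absent", segments = NULL)
    } else {
      state <- draw_contact_state(model$p_multi_segment)
      state$status <- "present"
      if (is.null(state$segments)) {
        state$segments <- data.frame(
          spatial = sample(spatial_relations(), 1L),
          depth = sample(names(depth_levels()), 1L))
      }
    }
  }
  if (state$status == "present") {
    n_sw <- stats::rpois(1L, model$rate_spatial_switch * bl)
    for (i in seq_len(n_sw)) {
      j <- sample.int(nrow(state$segments), 1L)
      state$segments$spatial[j] <- sample(spatial_relations(), 1L)
    }
    n_dp <- stats::rpois(1L, model$rate_depth_step * bl)
    for (i in seq_len(n_dp)) {
      j <- sample.int(nrow(state$segments), 1L)
      lev <- depth_level(state$segments$depth[j])
      lev <- min(max(lev + sample(c(-1L, 1L), 1L), 0L), 3L)
      state$segments$depth[j] <- names(depth_levels())[lev + 1L]
    }
  }
  state
}

states_to_rows <- function(taxon, pairs, states) {
  rows <- list()
  for (i in seq_along(states)) {
    st <- states[[i]]
    if (st$status == "present") {
      k <- nrow(st$segments)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = taxon, bone_a = pairs$bone_a[i], bone_b = pairs$bone_b[i],
        status = "present", segment_index = seq_len(k),
        spatial = st$segments$spatial, depth = st$segments$depth)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = taxon, bone_a = pairs$bone_a[i], bone_b = pairs$bone_b[i],
        status = st$status, segment_index = NA_integer_,
        spatial = NA_character_, depth = NA_character_)
    }
  }
  do.call(rbind, rows)
}

#' Simulate contact tables along a tree
#'
#' Draws an ancestral contact table (per pair: presence with probability
#' one half; a present contact carries one or, with probability
#' `p_multi_segment`, two segments with uniform spatial relation and depth)
#' and evolves it along every branch with Poisson event counts: presence
#' toggles, uniform spatial switches and clipped single-step depth moves.
#' Identical inputs reproduce identical tables.
#'
#' @param tree A rooted `phylo` tree with branch lengths (e.g. from
#'   [random_tree()]).
#' @param model A [contact_evolution_model()].
#' @return List with `tips` (a [contact_table()] over the tip taxa) and
#'   `ancestor` (single-taxon [contact_table()] of the root state).
#' @export
simulate_tables <- function(tree, model = contact_evolution_model()) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "contact_evolution_model"))
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  vocab <- setdiff(bone_vocabulary(), c("nasal", "columella"))
  all_pairs <- t(utils::combn(sort(vocab), 2L))
  if (model$n_pairs > nrow(all_pairs)) {
    stop("n_pairs exceeds the ", nrow(all_pairs), " available bone pairs")
  }
  with_seed(model$seed, {
    pick <- sort(sample.int(nrow(all_pairs), model$n_pairs))
    pairs <- data.frame(bone_a = all_pairs[pick, 1L],
                        bone_b = all_pairs[pick, 2L])
    anc <- lapply(seq_len(model$n_pairs), function(i) {
      st <- draw_contact_state(model$p_multi_segment)
      if (st$status == "absent") st$segments <- NULL
      st
    })
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    states <- vector("list", max(tree$edge))
    states[[root]] <- anc
    pre <- ape::reorder.phylo(tree, "cladewise")
    tip_rows <- list()
    for (i in seq_len(nrow(pre$edge))) {
      p <- pre$edge[i, 1L]; ch <- pre$edge[i, 2L]
      bl <- pre$edge.length[i]
      st <- lapply(states[[p]], evolve_contact, bl = bl, model = model)
      states[[ch]] <- st
      if (ch <= ntip) {
        tip_rows[[length(tip_rows) + 1L]] <-
          states_to_rows(tree$tip.label[ch], pairs, st)
      }
    }
    tips <- contact_table(do.call(rbind, tip_rows))
    ancestor <- contact_table(states_to_rows("ancestor", pairs, anc))
    list(tips = tips, ancestor = ancestor)
  })
}

#' The four-taxon study contact table
#'
#' The bone-contact table for *Desmatochelys lowii* (KUVP 1200),
#' *Eretmochelys imbricata*, *Dermochelys coriacea* and *Chelydra
#' serpentina*, transcribed from published per-bone anatomical descriptions
#' of the four skulls. Contacts whose suture type cannot be determined in
#' the fossil carry depth `"?"`; contacts whose spatial relation itself is
#' indeterminable are `status = "unknown"`. The transcription conventions
#' are laid out in the methods vignette; the file ships under
#' `inst/extdata/` so it can be corrected independently of the code.
#'
#' @return A [contact_table()] with four taxa.
#' @export
study_contacts <- function() {
  path <- system.file("extdata", "study_contacts.tsv", package = "sutura",
                      mustWork = TRUE)
  read_contact_table(path)
}

#' Simulate a discrete character matrix along a tree
#'
#' Symmetric-rates (Mk-like) evolution: along a branch of length `t` the
#' state is kept with probability `exp(-rate * t)` and otherwise resampled
#' uniformly among the `n_states` states. Used to exercise the parsimony
#' engine on data with tree signal.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param n_chars Number of characters.
#' @param n_states Number of states (2 to 10).
#' @param rate Change rate per unit branch length.
#' @param seed Integer seed.
#' @return A [character_matrix()] over the tree's tips.
#' @export
simulate_character_matrix <- function(tree, n_chars = 20L, n_states = 3L,
                                      rate = 0.5, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), n_states >= 2L, n_states <= 10L)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    states <- matrix(NA_integer_, max(tree$edge), n_chars)
    states[root, ] <- sample.int(n_states, n_chars, replace = TRUE) - 1L
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (i in seq_len(nrow(pre$edge))) {
      p <- pre$edge[i, 1L]; ch <- pre$edge[i, 2L]
      keep <- stats::runif(n_chars) < exp(-rate * pre$edge.length[i])
      new <- sample.int(n_states, n_chars, replace = TRUE) - 1L
      states[ch, ] <- ifelse(keep, states[p, ], new)
    }
    cells <- matrix(as.character(states[seq_len(ntip), , drop = FALSE]),
                    nrow = ntip, dimnames = list(tree$tip.label, NULL))
    character_matrix(cells, taxa = tree$tip.label,
                     symbols = as.character(seq_len(n_states) - 1L))
  })
}
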