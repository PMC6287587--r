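# End-to-end pipeline wiring: contacts -> similarity matrix and report;
# base character matrix -> patched matrix -> constrained search -> strict
# consensus -> pruned consensus, with a manifest logging every decision
# flag and seed so a run is reproducible from its inputs alone.

#' Pipeline configuration
#'
#' A flat list of paths and settings consumed by [run_phenetic_pipeline()]
#' and [run_phylo_pipeline()]. Referenced input paths must exist when the
#' config is built; a seed is mandatory for every stochastic stage.
#'
#' @param contacts Path to a long-TSV contact table (phenetic pipeline).
#' @param matrix Path to a NEXUS/TNT character matrix (phylogenetic
#'   pipeline).
#' @param constraint Optional path to a Newick backbone constraint.
#' @param out_dir Output directory (created if needed).
#' @param policy A [similarity_policy()].
#' @param add_new_characters Insert the seven additional characters?
#' @param apply_recoding Apply the built-in ten-entry recoding patch?
#' @param set_ordered_builtin Flag the built-in morphocline list as ordered?
#' @param deactivate Character vector of taxa to deactivate (or path to a
#'   one-label-per-line file).
#' @param prune Taxa to prune from the strict consensus (wildcards).
#' @param n_replicates,seed Heuristic search settings.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(contacts = NULL, matrix = NULL, constraint = NULL,
                            out_dir = ".", policy = similarity_policy(),
                            add_new_characters = FALSE, apply_recoding = FALSE,
                            set_ordered_builtin = FALSE,
                            deactivate = character(), prune = character(),
                            n_replicates = 10L, seed = NULL) {
  for (p in c(contacts, matrix, constraint)) {
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  }
  if (length(deactivate) == 1L && file.exists(deactivate)) {
    deactivate <- readLines(deactivate, warn = FALSE)
    deactivate <- trimws(deactivate[nzchar(trimws(deactivate))])
  }
  structure(list(contacts = contacts, matrix = matrix,
                 constraint = constraint, out_dir = out_dir, policy = policy,
                 add_new_characters = add_new_characters,
                 apply_recoding = apply_recoding,
                 set_ordered_builtin = set_ordered_builtin,
                 deactivate = deactivate, prune = prune,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "pipeline_config")
}

write_manifest <- function(config, extra, path) {
  pol <- config$policy
  lines <- c(
    sprintf("contacts\t%s", config$contacts %||% ""),
    sprintf("matrix\t%s", config$matrix %||% ""),
    sprintf("constraint\t%s", config$constraint %||% ""),
    sprintf("depth_threshold\t%d", pol$depth_threshold),
    sprintf("unknown_depth\t%s", pol$unknown_depth),
    sprintf("both_absent\t%s", pol$both_absent),
    sprintf("multi_segment\t%s", pol$multi_segment),
    sprintf("excluded_bones\t%s", paste(pol$excluded_bones, collapse = ",")),
    sprintf("add_new_characters\t%s", config$add_new_characters),
    sprintf("apply_recoding\t%s", config$apply_recoding),
    sprintf("set_ordered_builtin\t%s", config$set_ordered_builtin),
    sprintf("n_deactivated\t%d", length(config$deactivate)),
    sprintf("pruned\t%s", paste(config$prune, collapse = ",")),
    sprintf("n_replicates\t%d", config$n_replicates),
    sprintf("seed\t%s", config$seed %||% ""),
    extra)
  writeLines(lines, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the phenetic pipeline
#'
#' Reads the contact table, computes the similarity matrix under the
#' configured policy, and writes the percentage matrix, the per-pair counts
#' audit, a per-taxon rank report and a manifest of all settings.
#'
#' @param config A [pipeline_config()] with `contacts` set.
#' @return Invisibly, the `similarity_matrix`.
#' @export
run_phenetic_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$contacts)) stop("config$contacts is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- stage("read_contacts", read_contact_table(config$contacts))
  issues <- validate_contact_table(tab)
  if (nrow(issues)) {
    stop("pipeline stage 'validate' failed: ", nrow(issues),
         " issue(s); first: ", issues$issue[1L])
  }
  sm <- stage("similarity", similarity_matrix(tab, config$policy))
  stage("write", {
    write_similarity_matrix(sm, file.path(config$out_dir, "similarity.tsv"))
    ranks <- do.call(rbind, lapply(sm$taxa, function(t) {
      r <- rank_report(sm, t)
      cbind(focal = t, r)
    }))
    utils::write.table(ranks, file.path(config$out_dir, "rank_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(config,
                   sprintf("n_taxa\t%d", length(sm$taxa)),
                   file.path(config$out_dir, "manifest.tsv"))
  })
  invisible(sm)
}

#' Run the phylogenetic pipeline
#'
#' Reads the base matrix, optionally inserts the seven additional
#' characters, applies the recoding patch, flags the built-in ordered
#' characters and deactivates taxa; then runs the constrained heuristic
#' search, takes the strict consensus, prunes the named wildcard taxa, and
#' writes the patched matrix, the optimal trees, both consensus trees and a
#' length/CI/RI report plus a manifest.
#'
#' @param config A [pipeline_config()] with `matrix` and `seed` set.
#' @return Invisibly, a list with the patched `matrix`, `search` result,
#'   `consensus`, `pruned` consensus and the `length_report` of the first
#'   optimal tree.
#' @export
run_phylo_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$matrix)) stop("config$matrix is required")
  if (is.null(config$seed)) stop("a seed is mandatory for the search stage")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- stage("read_matrix", read_matrix(config$matrix))
  index_map <- seq_len(ncol(m$cells))
  if (config$add_new_characters) {
    ins <- stage("insert_characters", insert_characters(m))
    m <- ins$matrix
    index_map <- ins$index_map
  }
  if (config$apply_recoding) m <- stage("recode", apply_recoding_patch(m))
  if (config$set_ordered_builtin) m <- stage("set_ordered", set_ordered(m))
  if (length(config$deactivate)) {
    m <- stage("deactivate", deactivate_taxa(m, config$deactivate))
  }
  constraint <- if (!is.null(config$constraint)) {
    stage("read_constraint", ape::read.tree(config$constraint))
  } else NULL
  res <- stage("search", heuristic_search(m, config$n_replicates,
                                          seed = config$seed,
                                          constraint = constraint))
  cons <- stage("consensus", strict_consensus(res$trees))
  pruned <- if (length(config$prune)) {
    stage("prune", prune_taxa(cons, config$prune))
  } else cons
  report <- stage("score", tree_length(res$trees[[1L]], m))
  stage("write", {
    write_matrix(m, file.path(config$out_dir, "patched.nex"), "nexus")
    ape::write.tree(do.call(c, res$trees),
                    file.path(config$out_dir, "mpts.nwk"))
    ape::write.tree(cons, file.path(config$out_dir, "consensus.nwk"))
    ape::write.tree(pruned, file.path(config$out_dir, "consensus_pruned.nwk"))
    writeLines(c(sprintf("best_length\t%d", res$length),
                 sprintf("n_optimal_trees\t%d", length(res$trees)),
                 sprintf("CI\t%s", format(report$CI)),
                 sprintf("RI\t%s", format(report$RI))),
               file.path(config$out_dir, "length_report.tsv"))
    write_manifest(config,
                   c(sprintf("n_characters\t%d", ncol(m$cells)),
                     sprintf("n_taxa\t%d", length(m$taxa)),
                     sprintf("n_active\t%d", sum(m$active))),
                   file.path(config$out_dir, "manifest.tsv"))
  })
  invisible(list(matrix = m, index_map = index_map, search = res,
                 consensus = cons, pruned = pruned, length_report = report))
}
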