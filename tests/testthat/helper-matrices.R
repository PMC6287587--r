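# A synthetic stand-in for the unavailable published base matrix: the
# documented dimensions (154 taxa x 256 characters), with the fossil's row
# carrying the pre-update codings the recoding patch expects. Positions
# 8,18,21,74,80,84,89,98,100,102 are the base-numbering slots that the seven
# final-position insertions shift onto final indices
# 8,18,21,78,84,90,96,105,107,109.
synthetic_base_matrix <- function(n_taxa = 154, n_char = 256, seed = 101) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  taxa <- c("Odontochelys_semitestacea", "Desmatochelys_lowii",
            "Eretmochelys_imbricata", "Dermochelys_coriacea",
            "Chelydra_serpentina",
            sprintf("taxon_%03d", seq_len(n_taxa - 5)))
  cells <- matrix(sample(c("0", "1", "?"), n_taxa * n_char, replace = TRUE,
                         prob = c(0.45, 0.35, 0.2)),
                  n_taxa, n_char, dimnames = list(taxa, NULL))
  base_pos <- c(8, 18, 21, 74, 80, 84, 89, 98, 100, 102)
  base_val <- c("0", "1", "1", "1", "1", "0", "0", "0", "1", "0")
  cells["Desmatochelys_lowii", base_pos] <- base_val
  character_matrix(cells, taxa = taxa)
}
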