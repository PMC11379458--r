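# Derived species genomes: shared/absent insertions plus flank divergence.

#' Derive per-species genomes from an implanted assembly
#'
#' For each species on the tree, starts from the focal assembly, replaces
#' elements absent in that species by the empty pre-integration site (the
#' element and one TSD copy removed, leaving a single target-site copy), and
#' then mutates the whole derived genome (background and flanks) at a
#' per-site divergence equal to \code{flank_divergence} times the patristic
#' distance from the focal species on the tree.
#'
#' @param assembly Implanted [Biostrings::DNAStringSet] (the focal genome).
#' @param truth Truth table from [implant()].
#' @param species_tree An [ape::phylo] object or path to a newick file.
#' @param flank_divergence Per-site divergence per unit branch length.
#' @param presence_map Logical matrix, rows = \code{truth$locus_id}, columns
#'   = species (tree tip labels); \code{TRUE} where the insertion is present.
#' @param seed Integer seed.
#' @param focal Name of the focal species (must be a tree tip); its derived
#'   genome is the input assembly unchanged.
#' @return List with \code{genomes} (named list of
#'   [Biostrings::DNAStringSet]), \code{truth} (with the presence map
#'   attached as attribute \code{presence}), and \code{tree}.
#' @export
speciate <- function(assembly, truth, species_tree, flank_divergence = 0.01,
                     presence_map, seed = 1, focal = NULL) {
  tree <- if (inherits(species_tree, "phylo")) species_tree
          else ape::read.tree(species_tree)
  species <- colnames(presence_map)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  if (!setequal(rownames(presence_map), truth$locus_id))
    stop("presence_map rows must match truth locus ids")
  focal <- focal %||% species[1]
  if (!focal %in% tree$tip.label) stop("focal species absent from tree")
  dmat <- ape::cophenetic.phylo(tree)

  genomes <- with_seed(seed, lapply(species, function(sp) {
    chroms <- as.character(assembly)
    absent <- truth[!presence_map[truth$locus_id, sp], , drop = FALSE]
    if (nrow(absent)) {
      for (ch in unique(absent$chrom)) {
        rows <- absent[absent$chrom == ch, , drop = FALSE]
        rows <- rows[order(rows$start, decreasing = TRUE), , drop = FALSE]
        seq <- chroms[[ch]]
        for (k in seq_len(nrow(rows))) {
          # remove element plus the downstream TSD copy -> single target site
          seq <- paste0(substr(seq, 1, rows$start[k]),
                        substr(seq, rows$end[k] + rows$tsd_len[k] + 1,
                               nchar(seq)))
        }
        chroms[[ch]] <- seq
      }
    }
    d <- if (sp == focal) 0 else flank_divergence * dmat[focal, sp]
    if (d > 0) chroms <- vapply(chroms, mutate_divergence, character(1),
                                divergence = d)
    Biostrings::DNAStringSet(chroms)
  }))
  names(genomes) <- species
  attr(truth, "presence") <- presence_map
  list(genomes = genomes, truth = truth, tree = tree)
}
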