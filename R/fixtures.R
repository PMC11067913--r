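# Miniature squamate backbone with the four Jurassic/early-Cretaceous fossil
# node constraints, for exercising the constraint machinery at desk scale.

#' Miniature squamate backbone tree with the four fossil node constraints
#'
#' A hand-built, dated (Myr), 12-tip binary tree whose labelled clades mirror
#' the squamate backbone (Dibamia, Gekkota, Scincomorpha, Laterata,
#' Anguimorpha, Iguania, Serpentes), together with the four fossil-based
#' nodal constraints, each requiring Eurasia in the ancestral range:
#' Toxicofera (from the stem snake *Eophis underwoodi*, Middle Jurassic of the
#' UK), Iguania+Anguimorpha (from *Introrsisaurus pollicidens*, Late Jurassic
#' of Portugal), Paleoanguimorpha (from *Dalinghosaurus longidigitus*, Early
#' Cretaceous of China) and Laterata (from *Meyasaurus diazromerali*, Early
#' Cretaceous of Spain).
#'
#' @return list with `tree` (a `phylo`), `constraints` (list of four
#'   constraints, each with `name`, `mrca_taxa`, `required_areas`), and
#'   `space` (the 9-area, max-range-4 state space of [squamate_scheme()]).
#' @export
paper_constraint_fixture <- function() {
  newick <- paste0(
    "(Dibamus_sp:193,",
    "(Gekko_sp:180,",
    "(Scincus_sp:170,",
    "((Lacerta_sp:100,Teius_sp:100):68,",
    "((Python_sp:90,Naja_sp:90):72,",
    "((Anolis_sp:120,Iguana_sp:120):35,",
    "(Anguis_sp:140,(Shinisaurus_sp:80,Varanus_sp:80):60):15",
    "):7):6):2):10):13);"
  )
  tree <- ape::read.tree(text = newick)
  validate_tree(tree)
  scheme <- squamate_scheme()
  space <- build_state_space(length(scheme$areas), scheme$max_range_size,
                             include_null = TRUE, area_names = scheme$areas)
  constraints <- list(
    list(name = "toxicofera",
         mrca_taxa = c("Naja_sp", "Anolis_sp"),
         required_areas = "Eurasia"),
    list(name = "iguania_anguimorpha",
         mrca_taxa = c("Anolis_sp", "Varanus_sp"),
         required_areas = "Eurasia"),
    list(name = "paleoanguimorpha",
         mrca_taxa = c("Shinisaurus_sp", "Varanus_sp"),
         required_areas = "Eurasia"),
    list(name = "laterata",
         mrca_taxa = c("Lacerta_sp", "Teius_sp"),
         required_areas = "Eurasia")
  )
  list(tree = tree, constraints = constraints, space = space)
}
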