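# Readers and writers: Newick trees (via ape), Lagrange/PHYLIP-style
# geography files, and TSV node-constraint tables. Readers validate; writers
# produce files the readers accept.

#' Read a rooted, dated, binary Newick tree
#'
#' @param path Newick file.
#' @return a validated `phylo` tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stop("malformed Newick in ", path)
  validate_tree(tree)
  tree
}

#' Write a tree as Newick
#' @param tree a `phylo` tree.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Read a Lagrange/PHYLIP-style geography file
#'
#' Line 1: `n_taxa n_areas` optionally followed by parenthesized area names,
#' whitespace- or tab-separated. Each following line: a taxon name and a
#' presence string of 0/1 characters, one per area, in header column order
#' (column k maps to bit k-1 of the range bitmask).
#'
#' @param path geography file.
#' @return list with `areas` (character, synthesized as `A1..Am` when the
#'   header has no names), `ranges` (named integer bitmask vector), `n_taxa`,
#'   `n_areas`.
#' @export
read_geography <- function(path) {
  if (!file.exists(path)) stop("geography file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty geography file")
  header <- trimws(lines[1])
  m <- regmatches(header, regexec("^(\\d+)[ \t]+(\\d+)[ \t]*(\\((.*)\\))?\\s*$", header))[[1]]
  if (!length(m)) stop("malformed geography header: ", header)
  n_taxa <- as.integer(m[2]); n_areas <- as.integer(m[3])
  areas <- if (nzchar(m[5])) strsplit(trimws(m[5]), "[ \t]+")[[1]] else
    paste0("A", seq_len(n_areas))
  if (length(areas) != n_areas) stop("header area names do not match n_areas")

  rows <- lines[-1]
  if (length(rows) != n_taxa) {
    stop("geography file declares ", n_taxa, " taxa but has ", length(rows), " rows")
  }
  ranges <- integer(0)
  for (ln in rows) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(parts) != 2L) stop("malformed geography row: ", ln)
    taxon <- parts[1]; pres <- parts[2]
    if (nchar(pres) != n_areas) {
      stop("presence string of '", taxon, "' has length ", nchar(pres),
           ", expected ", n_areas)
    }
    if (grepl("[^01]", pres)) stop("bad character in presence string of '", taxon, "'")
    digits <- as.integer(strsplit(pres, "")[[1]])
    if (sum(digits) == 0L) stop("null tip range for taxon '", taxon, "'")
    bits <- sum(bitwShiftL(1L, which(digits == 1L) - 1L))
    if (taxon %in% names(ranges)) stop("duplicate taxon '", taxon, "'")
    ranges[taxon] <- as.integer(bits)
  }
  list(areas = areas, ranges = ranges, n_taxa = n_taxa, n_areas = n_areas)
}

#' Write a geography file
#'
#' Tab-separated, header with parenthesized area names; accepted back by
#' [read_geography()] bit-exactly.
#'
#' @param path output file.
#' @param ranges named integer bitmask vector.
#' @param space a `state_space` (supplies area names and order).
#' @export
write_geography <- function(path, ranges, space) {
  n <- space$n_areas
  header <- paste0(length(ranges), "\t", n, "\t(", paste(space$areas, collapse = " "), ")")
  rows <- vapply(seq_along(ranges), function(i) {
    digits <- as.integer(bitwAnd(ranges[i], bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
    paste0(names(ranges)[i], "\t", paste(digits, collapse = ""))
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a node-constraint table
#'
#' TSV with a header and columns `name`, `mrca_taxa` (comma-separated, at
#' least two tip names) and `required_areas` (comma-separated area names).
#' Each constraint is resolved against the tree; the resolved clade size is
#' reported via [message()].
#'
#' @param path constraint TSV.
#' @param tree a `phylo` tree the constraints must resolve on.
#' @param areas character vector of valid area names.
#' @return list of constraints (`name`, `mrca_taxa`, `required_areas`,
#'   `node`, `clade_size`).
#' @export
read_constraints <- function(path, tree, areas) {
  if (!file.exists(path)) stop("constraint file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "mrca_taxa", "required_areas")
  if (!all(need %in% names(df))) {
    stop("constraint table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$name)) stop("duplicate constraint names")
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    taxa <- strsplit(df$mrca_taxa[i], ",")[[1]]
    taxa <- trimws(taxa)
    if (length(taxa) < 2L) {
      stop("constraint '", df$name[i], "' needs at least 2 mrca taxa")
    }
    bad <- setdiff(taxa, tree$tip.label)
    if (length(bad)) {
      stop("constraint '", df$name[i], "': unknown tip(s): ",
           paste(bad, collapse = ", "))
    }
    req <- trimws(strsplit(df$required_areas[i], ",")[[1]])
    bad_area <- setdiff(req, areas)
    if (length(bad_area)) {
      stop("constraint '", df$name[i], "': unknown area(s): ",
           paste(bad_area, collapse = ", "))
    }
    node <- ape::getMRCA(tree, taxa)
    clade_size <- length(ape::extract.clade(tree, node)$tip.label)
    message("constraint '", df$name[i], "' -> node ", node,
            " (clade of ", clade_size, " tips)")
    out[[i]] <- list(name = df$name[i], mrca_taxa = taxa,
                     required_areas = req, node = node,
                     clade_size = clade_size)
  }
  out
}

#' Write a node-constraint table
#' @param constraints list of constraints (`name`, `mrca_taxa`, `required_areas`).
#' @param path output TSV.
#' @export
write_constraints <- function(constraints, path) {
  df <- do.call(rbind, lapply(constraints, function(cs) {
    data.frame(name = cs$name,
               mrca_taxa = paste(cs$mrca_taxa, collapse = ","),
               required_areas = paste(cs$required_areas, collapse = ","))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
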