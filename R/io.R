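#' Read and write the pipeline's standard file formats
#'
#' Trees travel as Newick, tables as tab-delimited text with a header row,
#' configurations as YAML. These are thin wrappers kept so every stage of
#' the pipeline reads and writes the same shapes.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @name corevol-io
NULL

#' @rdname corevol-io
#' @export
write_tree_file <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname corevol-io
#' @export
read_tree_file <- function(path) {
  ape::read.tree(path)
}

#' @rdname corevol-io
#' @param x Data frame to write.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname corevol-io
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname corevol-io
#' @param config Named list to serialise.
#' @export
write_config_file <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname corevol-io
#' @export
read_config_file <- function(path) {
  yaml::read_yaml(path)
}

#' Write per-species occupancy surfaces as one long table
#'
#' @param occupancy Named list (per species) of surface data frames.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_occupancy_file <- function(occupancy, path) {
  rows <- lapply(names(occupancy), function(sp) {
    cbind(data.frame(species = sp, stringsAsFactors = FALSE),
          occupancy[[sp]])
  })
  write_tsv_file(do.call(rbind, rows), path)
}

#' @rdname write_occupancy_file
#' @export
read_occupancy_file <- function(path) {
  df <- read_tsv_file(path)
  split(df[setdiff(names(df), "species")], df$species)
}
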