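# Plain-text I/O for curves and coefficient tables: CSV with the grid values
# as header and the taxon/node id as first column. Used by the command-line
# workbench; trees travel as Newick via read_newick()/write_newick().

#' Write a functional dataset to CSV
#'
#' First column `id`, remaining columns one per grid point with the grid
#' values as header names.
#'
#' @param fd A `pgp_fdata`.
#' @param file Output path.
#' @export
write_curves_csv <- function(fd, file) {
  if (!inherits(fd, "pgp_fdata")) stopf("fd must be a pgp_fdata")
  df <- data.frame(id = fd$ids, fd$curves, check.names = FALSE)
  colnames(df) <- c("id", format(fd$grid, digits = 10, trim = TRUE))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a functional dataset from CSV
#'
#' @param file Path to a CSV written by [write_curves_csv()].
#' @return A `pgp_fdata`.
#' @export
read_curves_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  grid <- as.numeric(colnames(df)[-1])
  functional_dataset(grid, df$id, as.matrix(df[, -1, drop = FALSE]))
}
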