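# Plain-text serialisation of the result containers: matrices as TSV with
# residue labels as header row/column, long-format CSVs, and JSON sidecars
# carrying the parameters that produced each artifact.

write_labeled_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_labeled_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, labels)
  m
}

#' Write a pair energy matrix to disk
#'
#' Emits the matrix as TSV (labels as header row/column), a long-format CSV
#' of interacting pairs, and a JSON sidecar echoing the evaluation
#' parameters.
#'
#' @param matrix A [pair_energy_matrix()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_pair_energy_matrix <- function(matrix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    tsv = file.path(dir, "energy_matrix.tsv"),
    csv = file.path(dir, "energy_pairs.csv"),
    json = file.path(dir, "energy_params.json")
  )
  write_labeled_matrix_tsv(matrix, paths$tsv)
  long <- tidy(matrix)
  utils::write.csv(long, paths$csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_frames = attr(matrix, "n_frames"), params = unclass(attr(matrix, "params"))),
    paths$json, digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}

#' Read a pair energy matrix written by [write_pair_energy_matrix()]
#' @param dir Directory holding `energy_matrix.tsv` and `energy_params.json`.
#' @return A [pair_energy_matrix()].
#' @export
read_pair_energy_matrix <- function(dir) {
  m <- read_labeled_matrix_tsv(file.path(dir, "energy_matrix.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "energy_params.json"), simplifyVector = TRUE)
  p <- meta$params
  new_pair_energy_matrix(m, n_frames = meta$n_frames,
                         params = nb_params(p$cutoff, p$switch_on, p$coulomb_const,
                                            p$dielectric, p$elec_scheme, p$scale14_elec))
}

#' Write a residue network to disk
#'
#' Weighted edge list (TSV: `source_label`, `target_label`, `cost`; undirected
#' edges listed once), dense adjacency TSV, and a JSON sidecar with the
#' semantics tag and directedness.
#'
#' @param network A [resnet()].
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    edges = file.path(dir, "network_edges.tsv"),
    adjacency = file.path(dir, "network_adjacency.tsv"),
    json = file.path(dir, "network_meta.json")
  )
  utils::write.table(tidy(network), paths$edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  adj <- network$costs
  adj[!is.finite(adj)] <- NA
  write_labeled_matrix_tsv(adj, paths$adjacency)
  jsonlite::write_json(
    list(n_nodes = network$n_nodes, directed = network$directed,
         semantics = network$semantics),
    paths$json, digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}

#' Read a residue network written by [write_network()]
#' @param dir Directory holding the network files.
#' @return A [resnet()].
#' @export
read_network <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "network_meta.json"), simplifyVector = TRUE)
  adj <- read_labeled_matrix_tsv(file.path(dir, "network_adjacency.tsv"))
  adj[is.na(adj)] <- Inf
  resnet(adj, directed = meta$directed, semantics = meta$semantics)
}

#' Write a residue profile as CSV
#'
#' Columns: ordinal, residue label, value, normalised value (if present),
#' unreachable count; semantics and normalisation recorded in a JSON sidecar.
#'
#' @param profile A `residue_profile`.
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_residue_profile <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(csv = file.path(dir, "profile.csv"),
                json = file.path(dir, "profile_meta.json"))
  utils::write.csv(as.data.frame(profile), paths$csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(normalized = isTRUE(attr(profile, "normalized")),
         norm_method = attr(profile, "norm_method"),
         semantics = attr(profile, "semantics"),
         direction = attr(profile, "direction")),
    paths$json, digits = NA, auto_unbox = TRUE, null = "null"
  )
  invisible(paths)
}

#' Read a residue profile written by [write_residue_profile()]
#' @param dir Directory holding `profile.csv` and `profile_meta.json`.
#' @return A `residue_profile`.
#' @export
read_residue_profile <- function(dir) {
  df <- utils::read.csv(file.path(dir, "profile.csv"),
                        colClasses = c(label = "character"))
  meta <- jsonlite::read_json(file.path(dir, "profile_meta.json"), simplifyVector = TRUE)
  out <- as_tibble(df)
  attr(out, "normalized") <- isTRUE(meta$normalized)
  attr(out, "norm_method") <- meta$norm_method
  attr(out, "semantics") <- meta$semantics
  attr(out, "direction") <- meta$direction
  class(out) <- c("residue_profile", class(out))
  out
}

#' Write an aligned two-row FASTA for an alignment map
#' @param map An `alignment_map`.
#' @param path Output path.
#' @param ids Two sequence headers.
#' @return The path, invisibly.
#' @export
write_alignment_fasta <- function(map, path, ids = c("seq_a", "seq_b")) {
  writeLines(c(paste0(">", ids[1]), attr(map, "aligned_a"),
               paste0(">", ids[2]), attr(map, "aligned_b")), path)
  invisible(path)
}
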