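#' Write an expression dataset to disk
#'
#' Either a MatrixMarket directory (\code{matrix.mtx} plus \code{genes.tsv}
#' and \code{cells.tsv} sidecars carrying the full gene/cell metadata) or a
#' dense CSV (gene rows, cell columns) with the same sidecars.
#'
#' @param dataset an \code{\link{expression_dataset}}.
#' @param dir output directory (created if needed).
#' @param format "mtx" or "csv".
#' @return the directory path, invisibly.
#' @export
write_counts <- function(dataset, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "expression_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(dataset$counts, sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
  } else {
    df <- data.frame(gene_id = rownames(dataset$counts),
                     dataset$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(dir, "counts.csv"), row.names = FALSE)
  }
  utils::write.table(dataset$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read an expression dataset written by \code{\link{write_counts}}
#'
#' @param dir directory containing \code{matrix.mtx} or \code{counts.csv}
#'   plus \code{genes.tsv} and \code{cells.tsv}.
#' @return an \code{\link{expression_dataset}}.
#' @export
read_counts <- function(dir) {
  gpath <- file.path(dir, "genes.tsv"); cpath <- file.path(dir, "cells.tsv")
  if (!file.exists(gpath) || !file.exists(cpath))
    stop_input("missing sidecar files genes.tsv / cells.tsv in %s", dir)
  gene_meta <- utils::read.delim(gpath, stringsAsFactors = FALSE)
  cell_meta <- utils::read.delim(cpath, stringsAsFactors = FALSE)
  mtx <- file.path(dir, "matrix.mtx")
  if (file.exists(mtx)) {
    counts <- as.matrix(Matrix::readMM(mtx))
    if (nrow(counts) != nrow(gene_meta) || ncol(counts) != nrow(cell_meta))
      stop_input("matrix is %d x %d but sidecars list %d genes and %d cells",
                 nrow(counts), ncol(counts), nrow(gene_meta), nrow(cell_meta))
    dimnames(counts) <- list(gene_meta$gene_id, cell_meta$cell_id)
  } else {
    df <- utils::read.csv(file.path(dir, "counts.csv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df$gene_id
    if (nrow(counts) != nrow(gene_meta) || ncol(counts) != nrow(cell_meta))
      stop_input("matrix is %d x %d but sidecars list %d genes and %d cells",
                 nrow(counts), ncol(counts), nrow(gene_meta), nrow(cell_meta))
  }
  expression_dataset(counts, cell_meta, gene_meta)
}

#' Marker panel JSON round trip
#'
#' Panels serialize as \code{{"target": ..., "on": [...], "off": {"microglia":
#' [...]}}}.
#'
#' @param panel a \code{\link{marker_panel}}.
#' @param path JSON file path.
#' @return \code{write_marker_panel}: the path, invisibly;
#'   \code{read_marker_panel}: the panel.
#' @export
write_marker_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  jsonlite::write_json(list(target = panel$target_type,
                            on = panel$on_markers,
                            off = panel$off_markers),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_marker_panel
#' @export
read_marker_panel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  off <- as.list(x$off)
  off <- lapply(off, as.character)
  marker_panel(target_type = x$target, on_markers = as.character(x$on),
               off_markers = off)
}

#' Read and write GMT gene-set collections
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @param collection named list of character vectors.
#' @param descriptions optional named descriptions (defaults to the set name).
#' @return \code{read_gmt}: named list of gene id vectors; \code{write_gmt}:
#'   the path, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 3L)
      stop_input("malformed GMT line (fewer than 3 fields): %s", f[1])
    f[-(1:2)]
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(names(collection)) || any(names(collection) == ""))
    stop_input("collection must be a named list")
  lines <- vapply(names(collection), function(nm) {
    desc <- descriptions[[nm]] %||% nm
    paste(c(nm, desc, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Contamination score table TSV round trip
#'
#' Plain TSV with self-describing \code{#}-prefixed header lines (package
#' version and seed when provided).
#'
#' @param scores a \code{contamination_table}.
#' @param path TSV file path.
#' @param seed optional seed recorded in the header.
#' @return \code{write_scores}: the path, invisibly; \code{read_scores}: the
#'   table.
#' @export
write_scores <- function(scores, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# patchglia contamination scores v%s",
                     as.character(utils::packageVersion("patchglia"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.table(scores, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  out <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  class(out) <- c("contamination_table", "data.frame")
  out
}

#' Signature set JSON round trip
#'
#' @param signatures a \code{signature_set}.
#' @param path JSON file path.
#' @return \code{write_signatures}: the path, invisibly;
#'   \code{read_signatures}: the \code{signature_set}.
#' @export
write_signatures <- function(signatures, path) {
  stopifnot(inherits(signatures, "signature_set"))
  jsonlite::write_json(unclass(signatures), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- lapply(x, as.character)
  structure(x, class = "signature_set")
}

#' Ground truth JSON round trip
#'
#' @param truth a \code{ground_truth}.
#' @param path JSON file path.
#' @return \code{write_ground_truth}: the path, invisibly;
#'   \code{read_ground_truth}: the \code{ground_truth}.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(lapply(unclass(truth), function(v)
    if (is.numeric(v)) as.list(v) else v), path, auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) stats::setNames(as.numeric(unlist(v)), names(unlist(v)))
  structure(list(f_true = num(x$f_true),
                 donor_effects = num(x$donor_effects),
                 celltype_effects = num(x$celltype_effects),
                 activated_genes = as.character(x$activated_genes),
                 ephys_gamma = num(x$ephys_gamma)),
            class = "ground_truth")
}

#' Simulation config YAML round trip
#'
#' @param config a \code{\link{simulation_config}}.
#' @param path YAML file path.
#' @return \code{write_sim_config}: the path, invisibly;
#'   \code{read_sim_config}: the config.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$ephys_features <- lapply(seq_len(nrow(config$ephys_features)), function(i)
    as.list(config$ephys_features[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$ephys_features))
    x$ephys_features <- do.call(rbind, lapply(x$ephys_features, as.data.frame))
  do.call(simulation_config, x)
}
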