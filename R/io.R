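# TSV/JSON readers and writers. Every output file is self-describing: a
# '#'-prefixed header records the package version and the configuration that
# produced it, so reruns are diffable.

.header_lines <- function(kind, extra = character(0)) {
  c(paste0("# surfcrf ", as.character(utils::packageVersion("surfcrf")),
           " ", kind), paste0("# ", extra))
}

#' Write and read a surface graph as TSV
#'
#' The file carries a `#nodes` block (`index`, `chain`, `resnum`, `icode`,
#' `aa`, `rasa`) and an `#edges` block (`i`, `j`, `distance`), with a header
#' naming the convention and cutoff.
#'
#' @param graph A `surface_graph`.
#' @param path Output file path.
#' @return `path`, invisibly (`read_graph_tsv` returns a `surface_graph`).
#' @export
write_graph_tsv <- function(graph, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.header_lines("graph",
    sprintf("convention: %s cutoff: %s", graph$convention, graph$cutoff)), con)
  writeLines("#nodes", con)
  nd <- graph$nodes
  writeLines("index\tchain\tresnum\ticode\taa\trasa", con)
  writeLines(sprintf("%d\t%s\t%d\t%s\t%s\t%s", nd$index, nd$chain,
                     as.integer(nd$resno), .blank(nd$insert), nd$resid,
                     ifelse(is.na(nd$rasa), "NA", format(nd$rasa, digits = 8))),
             con)
  writeLines("#edges", con)
  writeLines("i\tj\tdistance", con)
  ed <- graph$edges
  if (nrow(ed)) {
    writeLines(sprintf("%d\t%d\t%s", as.integer(ed$i), as.integer(ed$j),
                       format(ed$distance, digits = 8)), con)
  }
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  conv <- sub(".*convention: (\\S+).*", "\\1", hdr[grepl("convention:", hdr)][1])
  cutoff <- as.numeric(sub(".*cutoff: (\\S+).*", "\\1", hdr[grepl("cutoff:", hdr)][1]))
  i_nodes <- which(lines == "#nodes")
  i_edges <- which(lines == "#edges")
  if (!length(i_nodes) || !length(i_edges)) {
    stop("malformed graph file ", path, ": missing #nodes or #edges block")
  }
  nd <- utils::read.delim(text = lines[(i_nodes + 1):(i_edges - 1)],
                          colClasses = c("integer", "character", "integer",
                                         "character", "character", "numeric"),
                          na.strings = "NA")
  nd$icode[is.na(nd$icode)] <- ""
  nodes <- tibble::tibble(index = nd$index, chain = nd$chain, resno = nd$resnum,
                          insert = nd$icode, resid = nd$aa, rasa = nd$rasa)
  if (i_edges + 1 <= length(lines)) {
    ed <- utils::read.delim(text = lines[(i_edges + 1):length(lines)])
    edges <- tibble::tibble(i = as.integer(ed$i), j = as.integer(ed$j),
                            distance = as.numeric(ed$distance))
  } else {
    edges <- tibble::tibble(i = integer(0), j = integer(0), distance = numeric(0))
  }
  new_surface_graph(nodes, edges, conv, cutoff)
}

#' Write and read interface labels as TSV
#'
#' Two columns: position `index` and label (`I` or `N`).
#'
#' @param labels Character label vector.
#' @param path File path.
#' @param note Optional extra header line content.
#' @return `path` invisibly; `read_labels_tsv` returns the label vector.
#' @export
write_labels_tsv <- function(labels, path, note = character(0)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.header_lines("labels", note), con)
  writeLines("index\tlabel", con)
  writeLines(sprintf("%d\t%s", seq_along(labels), labels), con)
  invisible(path)
}

#' @rdname write_labels_tsv
#' @export
read_labels_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = lines, colClasses = c("integer", "character"))
  if (!all(df$label %in% c("I", "N"))) stop("malformed label file ", path)
  df$label[order(df$index)]
}

#' Write and read per-residue score files
#'
#' Score files are the interchange format with external predictors:
#' tab-separated `chain`, `resnum`, `icode`, `score`. `read_scores_tsv`
#' joins a score file onto a graph's node table and returns the score vector
#' in position order, erroring on surface positions without a score.
#'
#' @param scores Numeric scores aligned with `graph` positions.
#' @param graph A `surface_graph`.
#' @param path File path.
#' @return `path` invisibly; `read_scores_tsv` returns a numeric vector.
#' @export
write_scores_tsv <- function(scores, graph, path, note = character(0)) {
  stopifnot(length(scores) == n_positions(graph))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.header_lines("scores", note), con)
  writeLines("chain\tresnum\ticode\tscore", con)
  nd <- graph$nodes
  writeLines(sprintf("%s\t%d\t%s\t%s", nd$chain, as.integer(nd$resno),
                     .blank(nd$insert), format(scores, digits = 10)), con)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path, graph) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = lines,
                          colClasses = c("character", "integer", "character",
                                         "numeric"), na.strings = "NA")
  df$icode[is.na(df$icode)] <- ""
  key_file <- paste(df$chain, df$resnum, df$icode)
  nd <- graph$nodes
  key_graph <- paste(nd$chain, nd$resno, .blank(nd$insert))
  hit <- match(key_graph, key_file)
  if (anyNA(hit)) {
    stop("score file ", path, " is missing ", sum(is.na(hit)),
         " surface position(s), e.g. ", key_graph[which(is.na(hit))[1]])
  }
  df$score[hit]
}

#' Serialize a pCRF model to JSON
#'
#' A single JSON document holding the characteristic names, bin boundaries,
#' weight vectors, `delta`, `eta3` and a format-version string.
#'
#' @param model A `pcrf_model`.
#' @param path File path.
#' @return `path` invisibly; `read_model` returns the `pcrf_model`.
#' @export
write_model <- function(model, path) {
  doc <- list(version = model$version,
              node_characteristic = model$node_characteristic,
              edge_characteristics = model$edge_characteristics,
              bins = lapply(model$bins, function(b)
                list(boundaries = b$boundaries, n_bins = b$n_bins)),
              alpha = model$alpha, beta = model$beta,
              delta = model$delta, eta3 = model$eta3)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$version, "surfcrf-model-1")) {
    stop("unrecognized model format version in ", path)
  }
  bins <- lapply(doc$bins, function(b)
    structure(list(boundaries = as.numeric(b$boundaries),
                   n_bins = as.integer(b$n_bins)), class = "bin_spec"))
  pcrf_model(bins = bins, alpha = doc$alpha,
             beta = as.list(doc$beta), delta = doc$delta, eta3 = doc$eta3,
             node_characteristic = doc$node_characteristic,
             edge_characteristics = doc$edge_characteristics)
}

#' Write decoded predictions as TSV
#'
#' Columns: `index`, `chain`, `resnum`, `label`, and (if supplied) the
#' posterior probability of the interface label.
#'
#' @param decode A `pcrf_decode`.
#' @param graph The decoded `surface_graph`.
#' @param path File path.
#' @param posterior Optional numeric vector of `P(I)` per position.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(decode, graph, path, posterior = NULL,
                                  note = character(0)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.header_lines("predictions",
    c(sprintf("score: %s exact: %s", format(decode$score), decode$exact),
      note)), con)
  nd <- graph$nodes
  if (is.null(posterior)) {
    writeLines("index\tchain\tresnum\tlabel", con)
    writeLines(sprintf("%d\t%s\t%d\t%s", nd$index, nd$chain,
                       as.integer(nd$resno), decode$labels), con)
  } else {
    writeLines("index\tchain\tresnum\tlabel\tposterior_I", con)
    writeLines(sprintf("%d\t%s\t%d\t%s\t%s", nd$index, nd$chain,
                       as.integer(nd$resno), decode$labels,
                       format(posterior, digits = 6)), con)
  }
  invisible(path)
}
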