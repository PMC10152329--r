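# Graph export for property-graph bulk importers (one nodes CSV per node
# type, one edges CSV per relation, manifest JSON alongside), plus
# portable N-Triples and GraphML serializations. Weights are written with
# 17 significant digits so the CSV round trip is exact.

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Export a knowledge graph
#'
#' `csv_bulk` writes `nodes_<Type>.csv` per node type (id, type and the
#' type's property columns) and `edges_<relation>.csv` per relation (src,
#' dst and, for weighted relations, weight), plus `manifest.json`.
#' `ntriples` writes `graph.nt`; unweighted edges are plain triples and
#' weighted edges are reified as `rdf:Statement` resources carrying a
#' `weight` property (the stated convention for edge properties in RDF).
#' `graphml` writes `graph.graphml` via igraph.
#'
#' @param kg an `ndkg_graph` (should pass [validate_schema()]).
#' @param dir output directory (created if needed).
#' @param format `"csv_bulk"`, `"ntriples"` or `"graphml"`.
#' @return invisibly, the files written.
#' @export
export_graph <- function(kg, dir, format = c("csv_bulk", "ntriples", "graphml")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_ndkg("cannot create output directory ", dir)
  files <- switch(format,
                  csv_bulk = .export_csv(kg, dir),
                  ntriples = .export_nt(kg, dir),
                  graphml = .export_graphml(kg, dir))
  invisible(files)
}

.export_csv <- function(kg, dir) {
  files <- character()
  for (tp in unique(kg$nodes$node_type)) {
    sub <- kg$nodes[kg$nodes$node_type == tp, , drop = FALSE]
    keep <- c("node_id", "node_type",
              names(sub)[colSums(!is.na(sub)) > 0])
    sub <- sub[unique(keep)]
    f <- file.path(dir, paste0("nodes_", tp, ".csv"))
    utils::write.csv(sub, f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  for (rl in unique(kg$edges$rel)) {
    sub <- kg$edges[kg$edges$rel == rl, , drop = FALSE]
    out <- data.frame(src = sub$src, dst = sub$dst, stringsAsFactors = FALSE)
    if (rl %in% .weighted_relations) out$weight <- .fmt_num(sub$weight)
    f <- file.path(dir, paste0("edges_", rl, ".csv"))
    utils::write.csv(out, f, row.names = FALSE, na = "", quote = TRUE)
    files <- c(files, f)
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(kg$manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  c(files, mf)
}

#' Import a csv_bulk export
#'
#' Reads the files written by `export_graph(..., format = "csv_bulk")`
#' back into an `ndkg_graph`; node and edge multisets and weights round
#' trip exactly.
#'
#' @param dir directory holding the export.
#' @return an `ndkg_graph`.
#' @export
import_graph_csv <- function(dir) {
  nfiles <- list.files(dir, pattern = "^nodes_.*\\.csv$", full.names = TRUE)
  efiles <- list.files(dir, pattern = "^edges_.*\\.csv$", full.names = TRUE)
  if (!length(nfiles)) stop_ndkg("no node CSVs under ", dir)
  nodes <- .empty_nodes()
  for (f in nfiles) {
    df <- utils::read.csv(f, stringsAsFactors = FALSE, colClasses = "character")
    row <- .empty_nodes()[seq_len(nrow(df)), , drop = FALSE]
    full <- nodes[0, ]
    for (cc in names(full)) {
      full[seq_len(nrow(df)), cc] <- if (cc %in% names(df)) {
        ifelse(nzchar(df[[cc]]), df[[cc]], NA_character_)
      } else NA_character_
    }
    nodes <- rbind(nodes, full)
  }
  edges <- .edge_rows(character())
  for (f in efiles) {
    rl <- sub("^edges_(.*)\\.csv$", "\\1", basename(f))
    df <- utils::read.csv(f, stringsAsFactors = FALSE, colClasses = "character")
    w <- if ("weight" %in% names(df)) as.numeric(df$weight) else NA_real_
    if (nrow(df)) edges <- rbind(edges, .edge_rows(df$src, rl, df$dst, w))
  }
  manifest <- list()
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, manifest = manifest),
            class = "ndkg_graph")
}

.nt_uri <- function(kind, id) {
  sprintf("<urn:ndkg:%s:%s>", kind, utils::URLencode(id, reserved = TRUE))
}

.nt_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  sprintf("\"%s\"", x)
}

.export_nt <- function(kg, dir) {
  f <- file.path(dir, "graph.nt")
  con <- file(f, "w", encoding = "UTF-8")
  on.exit(close(con))
  rdf <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  lines <- character()
  node_uri <- stats::setNames(.nt_uri("node", kg$nodes$node_id), kg$nodes$node_id)
  lines <- c(lines, sprintf("%s <%stype> %s .", node_uri,
                            rdf, .nt_uri("class", kg$nodes$node_type)))
  for (prop in c("canonical", "concept_id", "url", "source",
                 "resource_type", "subtype", "label")) {
    has <- !is.na(kg$nodes[[prop]])
    if (any(has)) {
      lines <- c(lines, sprintf("%s %s %s .",
                                node_uri[has], .nt_uri("prop", prop),
                                .nt_literal(kg$nodes[[prop]][has])))
    }
  }
  ed <- kg$edges
  weighted <- !is.na(ed$weight)
  if (any(!weighted)) {
    e <- ed[!weighted, ]
    lines <- c(lines, sprintf("%s %s %s .", node_uri[e$src],
                              .nt_uri("rel", e$rel), node_uri[e$dst]))
  }
  if (any(weighted)) {
    e <- ed[weighted, ]
    st <- .nt_uri("edge", sprintf("e%d", which(weighted)))
    lines <- c(lines,
               sprintf("%s <%stype> <%sStatement> .", st, rdf, rdf),
               sprintf("%s <%ssubject> %s .", st, rdf, node_uri[e$src]),
               sprintf("%s <%spredicate> %s .", st, rdf, .nt_uri("rel", e$rel)),
               sprintf("%s <%sobject> %s .", st, rdf, node_uri[e$dst]),
               sprintf("%s %s \"%s\"^^<http://www.w3.org/2001/XMLSchema#double> .",
                       st, .nt_uri("prop", "weight"), .fmt_num(e$weight)))
  }
  writeLines(lines, con)
  f
}

.export_graphml <- function(kg, dir) {
  f <- file.path(dir, "graph.graphml")
  verts <- kg$nodes
  names(verts)[1] <- "name"
  ed <- kg$edges[c("src", "dst", "rel", "weight")]
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = verts)
  igraph::write_graph(g, f, format = "graphml")
  f
}
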