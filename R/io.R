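# Plain-text readers and writers: TSV tables (counts, taxonomy,
# metadata, environment, agronomy, distances) and Gephi-compatible
# network exports (GraphML, GEXF, edge list).

#' Write / read a count table as TSV
#'
#' Taxa as rows, samples as columns; the first column holds the taxon
#' identifier.
#'
#' @param counts taxa x samples matrix.
#' @param path file path.
#' @return `read_count_table` returns the matrix; writers return the
#'   path invisibly.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(taxon = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a taxonomy table as TSV
#'
#' Two columns: taxon identifier and a semicolon-delimited six-rank
#' lineage (domain;phylum;class;order;family;genus). Missing trailing
#' ranks are allowed and read back as `NA`.
#'
#' @param taxonomy data frame with taxon rownames and rank columns.
#' @param path file path.
#' @return `read_taxonomy` returns the taxonomy data frame.
#' @export
write_taxonomy <- function(taxonomy, path) {
  ranks <- intersect(.RANKS, colnames(taxonomy))
  lineage <- apply(taxonomy[, ranks, drop = FALSE], 1, paste, collapse = ";")
  write.table(data.frame(taxon = rownames(taxonomy), lineage = lineage),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  parts <- strsplit(df$lineage, ";", fixed = TRUE)
  n_rank <- max(lengths(parts))
  ranks <- .RANKS[seq_len(n_rank)]
  out <- as.data.frame(do.call(rbind, lapply(parts, function(p)
    c(p, rep(NA_character_, n_rank - length(p))))),
    stringsAsFactors = FALSE)
  colnames(out) <- ranks
  rownames(out) <- df$taxon
  out
}

#' Write / read a generic sample table as TSV
#'
#' For metadata, environmental matrices and agronomic records; the first
#' column of the file holds the identifier used as rownames when
#' `rownames_col` is given.
#'
#' @param x data frame or matrix.
#' @param path file path.
#' @param rownames_col when writing, the column name under which to store
#'   rownames; when reading, the column to turn back into rownames
#'   (`NULL` keeps it as a column).
#' @return `read_table_tsv` returns a data frame.
#' @export
write_table_tsv <- function(x, path, rownames_col = NULL) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.null(rownames_col))
    df <- cbind(setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                         rownames_col), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path, rownames_col = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(rownames_col) && rownames_col %in% colnames(df)) {
    rownames(df) <- df[[rownames_col]]
    df[[rownames_col]] <- NULL
  }
  df
}

#' Read a genus-to-guild map
#'
#' TSV with columns `genus` and `guild`; see [default_guild_map()] for
#' the bundled nitrogen-cycle example.
#'
#' @param path file path.
#' @return data frame with `genus` and `guild` columns.
#' @export
read_guild_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genus", "guild") %in% colnames(df)))
    stop("guild map needs `genus` and `guild` columns")
  df
}

#' Export a co-occurrence network for Gephi
#'
#' `write_network_graphml` writes GraphML via igraph;
#' `write_network_gexf` writes GEXF 1.2 with node abundance and edge
#' rho/sign/q attributes; `write_edge_list` writes a plain CSV edge list
#' (source, target, rho, sign, q).
#'
#' @param net a `cooccurrence_network`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net, keep_isolated = TRUE), path,
                      format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_edge_list <- function(net, path) {
  write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' @rdname write_network_graphml
#' @export
write_network_gexf <- function(net, path) {
  stopifnot(inherits(net, "cooccurrence_network"))
  nodes <- net$nodes
  edges <- net$edges
  id <- .xml_escape(nodes$taxon)
  node_xml <- sprintf(
    paste0('      <node id="%s" label="%s">\n',
           '        <attvalues><attvalue for="0" value="%s"/></attvalues>\n',
           '      </node>'),
    id, id, ifelse(is.na(nodes$abundance), "", format(nodes$abundance)))
  edge_xml <- if (nrow(edges)) sprintf(
    paste0('      <edge id="%d" source="%s" target="%s" weight="%s">\n',
           '        <attvalues>\n',
           '          <attvalue for="1" value="%s"/>\n',
           '          <attvalue for="2" value="%s"/>\n',
           '          <attvalue for="3" value="%s"/>\n',
           '        </attvalues>\n',
           '      </edge>'),
    seq_len(nrow(edges)) - 1, .xml_escape(edges$from), .xml_escape(edges$to),
    format(abs(edges$rho)), format(edges$rho), edges$sign,
    format(edges$q)) else character(0)
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph defaultedgetype="undirected" mode="static">',
    '    <attributes class="node">',
    '      <attribute id="0" title="abundance" type="double"/>',
    '    </attributes>',
    '    <attributes class="edge">',
    '      <attribute id="1" title="rho" type="double"/>',
    '      <attribute id="2" title="sign" type="string"/>',
    '      <attribute id="3" title="q" type="double"/>',
    '    </attributes>',
    '    <nodes>', node_xml, '    </nodes>',
    '    <edges>', edge_xml, '    </edges>',
    '  </graph>',
    '</gexf>')
  writeLines(xml, path)
  invisible(path)
}

#' Write a module partition as TSV
#'
#' @param partition a `module_partition`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(taxon = names(partition$module_of),
                   module = partition$module_names[partition$module_of],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated data to a directory
#'
#' Writes the count table, taxonomy, metadata, environmental matrix,
#' agronomic table (all TSV) and the ground truth (JSON, without the
#' latent matrix) produced by the simulator.
#'
#' @param sim a `community_simulation`.
#' @param env samples x factors matrix from [simulate_environment()].
#' @param agronomy data frame from [simulate_agronomy()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, env, agronomy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = write_count_table(sim$counts, file.path(dir, "counts.tsv")),
    taxonomy = write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv")),
    metadata = write_table_tsv(sim$metadata, file.path(dir, "metadata.tsv")),
    environment = write_table_tsv(env, file.path(dir, "environment.tsv"),
                                  rownames_col = "sample"),
    agronomy = write_table_tsv(agronomy, file.path(dir, "agronomy.tsv")),
    guild_map = write_table_tsv(default_guild_map(),
                                file.path(dir, "guild_map.tsv")))
  truth <- sim$truth
  truth$latent <- NULL
  truth$differential <- as.list(truth$differential)
  jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  paths["ground_truth"] <- file.path(dir, "ground_truth.json")
  invisible(paths)
}
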